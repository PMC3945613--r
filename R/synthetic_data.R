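## Synthetic-data generators: one per input modality of the pipeline.
## Every generator takes an explicit integer seed inside its config and
## restores the caller's RNG state, so identical config => identical output
## and no global state leaks.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(as.integer(seed))
  expr
}

## ---- arena snapshots --------------------------------------------------

#' Configuration for simulated arena snapshots
#'
#' Describes a circular chamber of flies: the default geometry is a 90-mm
#' internal-diameter horizontal chamber holding 40 males, the standard
#' social-clustering assay. `cluster_strength = 0` gives complete spatial
#' randomness (uniform placement); positive values place flies around
#' `n_clusters` parent centers with Gaussian dispersion
#' `arena_radius / (1 + 2 * cluster_strength)` (a Matern-style cluster
#' process), so larger values give tighter aggregation. A hard-core minimum
#' inter-fly distance (default 2 mm, roughly a fly body length) is enforced
#' by thinning.
#'
#' @param n_flies number of flies (>= 2).
#' @param arena_radius chamber radius in mm.
#' @param hardcore minimum pairwise distance in mm (>= 0, < arena_radius).
#' @param cluster_strength aggregation level, >= 0; 0 = uniform.
#' @param n_clusters number of parent centers when clustering.
#' @param seed integer RNG seed.
#' @return an `arena_sim_config` list.
#' @export
arena_sim_config <- function(n_flies = 40, arena_radius = 45, hardcore = 2,
                             cluster_strength = 0, n_clusters = 4, seed = 1L) {
  stopifnot(n_flies >= 2, arena_radius > hardcore, hardcore >= 0,
            cluster_strength >= 0, n_clusters >= 1)
  structure(list(n_flies = as.integer(n_flies), arena_radius = arena_radius,
                 hardcore = hardcore, cluster_strength = cluster_strength,
                 n_clusters = as.integer(n_clusters), seed = as.integer(seed)),
            class = "arena_sim_config")
}

#' Simulate one arena snapshot
#'
#' Draws fly coordinates inside the disc under the process described in
#' [arena_sim_config()] and returns an [arena_snapshot()]. Placement is
#' sequential with rejection: a candidate closer than the hard core to any
#' accepted fly is redrawn, up to 1000 attempts per fly, after which the
#' packing is declared infeasible and an error reports the attempted
#' density.
#'
#' @param config an [arena_sim_config()].
#' @param chamber_id,capture_index labels carried into the snapshot.
#' @return an `arena_snapshot`.
#' @export
simulate_arena <- function(config, chamber_id = "sim", capture_index = 1L) {
  stopifnot(inherits(config, "arena_sim_config"))
  with_seed(config$seed, {
    n <- config$n_flies; R <- config$arena_radius
    hc <- config$hardcore; s <- config$cluster_strength
    clustered <- s > 0
    if (clustered) {
      # parent centers kept inside 0.7 R so offspring clouds sit in the arena
      pr <- 0.7 * R * sqrt(runif(config$n_clusters))
      pth <- runif(config$n_clusters, 0, 2 * pi)
      parents <- cbind(pr * cos(pth), pr * sin(pth))
      sigma <- R / (1 + 2 * s)
      assign_k <- sample.int(config$n_clusters, n, replace = TRUE)
    }
    pts <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        if (clustered) {
          p <- parents[assign_k[i], ] + rnorm(2, 0, sigma)
          if (sqrt(sum(p^2)) > R) next   # truncate offspring to the disc
        } else {
          r <- R * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
          p <- c(r * cos(th), r * sin(th))
        }
        if (i == 1L ||
            all(sqrt(rowSums(sweep(pts[seq_len(i - 1L), , drop = FALSE],
                                   2, p)^2)) >= hc)) {
          pts[i, ] <- p; placed <- TRUE; break
        }
      }
      if (!placed)
        stop(sprintf(paste0("hard-core packing failed at fly %d: %d flies with a ",
                            "%.3g mm exclusion radius exceed the feasible density ",
                            "of a %.3g mm arena"), i, n, hc, R))
    }
    colnames(pts) <- c("x", "y")
    arena_snapshot(pts, arena_radius = R, chamber_id = chamber_id,
                   capture_index = capture_index)
  })
}

## ---- locomotor activity -----------------------------------------------

#' Configuration for simulated beam-crossing activity
#'
#' The deterministic daily rate curve is `baseline + morning bump + evening
#' bump`, where each bump is a Gaussian in time-of-day centered at the
#' lights-on / lights-off transition with standard deviation `peak_width`
#' minutes. Counts per fly per bin are independent Poisson draws around the
#' curve. A knockdown genotype's morning bump (the lights-on peak and the
#' activity ramping up to it) is scaled by `knockdown_multiplier`; the
#' evening bump is untouched. Defaults mirror the standard assay: 5-min
#' bins over 7 days of a 12/12 light/dark cycle.
#'
#' @param n_flies_per_genotype flies per genotype.
#' @param n_days recording days.
#' @param bin_width bin width in minutes; must divide 1440.
#' @param baseline_rate expected counts per bin away from peaks.
#' @param morning_peak_height,evening_peak_height bump heights, counts/bin.
#' @param peak_width bump standard deviation, minutes.
#' @param knockdown_multiplier factor in `[0, 1]` applied to the morning
#'   bump of knockdown genotypes.
#' @param lights_on,lights_off transition clock hours in `[0, 24)`.
#' @param seed integer RNG seed.
#' @return an `activity_sim_config` list.
#' @export
activity_sim_config <- function(n_flies_per_genotype = 16, n_days = 7,
                                bin_width = 5, baseline_rate = 1,
                                morning_peak_height = 10,
                                evening_peak_height = 10,
                                peak_width = 60, knockdown_multiplier = 1,
                                lights_on = 8, lights_off = 20, seed = 1L) {
  stopifnot(n_flies_per_genotype >= 1, n_days >= 1,
            1440 %% bin_width == 0,
            baseline_rate >= 0, morning_peak_height >= 0,
            evening_peak_height >= 0, peak_width > 0,
            knockdown_multiplier >= 0, knockdown_multiplier <= 1,
            lights_on >= 0, lights_on < 24, lights_off >= 0, lights_off < 24,
            lights_on != lights_off)
  structure(list(n_flies_per_genotype = as.integer(n_flies_per_genotype),
                 n_days = as.integer(n_days), bin_width = bin_width,
                 baseline_rate = baseline_rate,
                 morning_peak_height = morning_peak_height,
                 evening_peak_height = evening_peak_height,
                 peak_width = peak_width,
                 knockdown_multiplier = knockdown_multiplier,
                 lights_on = lights_on, lights_off = lights_off,
                 seed = as.integer(seed)),
            class = "activity_sim_config")
}

#' Deterministic daily rate curve of the activity simulator
#'
#' Expected counts per bin at each time-of-day bin, for a genotype whose
#' morning bump is scaled by `multiplier`. Gaussian bumps wrap around
#' midnight.
#'
#' @param config an [activity_sim_config()].
#' @param multiplier morning-bump scale for this genotype.
#' @return numeric vector of length `1440 / bin_width`.
#' @export
activity_rate_curve <- function(config, multiplier = 1) {
  bpd <- 1440 %/% config$bin_width
  tod <- (seq_len(bpd) - 0.5) * config$bin_width   # bin-center minutes
  bump <- function(center_min, height) {
    d <- abs(tod - center_min)
    d <- pmin(d, 1440 - d)                          # circular distance
    height * exp(-d^2 / (2 * config$peak_width^2))
  }
  config$baseline_rate +
    multiplier * bump(config$lights_on * 60, config$morning_peak_height) +
    bump(config$lights_off * 60, config$evening_peak_height)
}

#' Simulate activity tables for a set of genotypes
#'
#' @param config an [activity_sim_config()].
#' @param genotypes named numeric vector: genotype label -> morning-bump
#'   multiplier. Use 1 for controls; a knockdown genotype typically uses
#'   `config$knockdown_multiplier`. Default is a single control genotype.
#' @return an [activity_table()] holding all genotypes on a shared bin grid
#'   starting at midnight of day 1.
#' @export
simulate_activity <- function(config,
                              genotypes = c(control = 1)) {
  stopifnot(inherits(config, "activity_sim_config"))
  if (is.null(names(genotypes)) || anyNA(names(genotypes)) ||
      any(names(genotypes) == ""))
    stop("'genotypes' must be a named numeric vector of morning-bump multipliers")
  stopifnot(all(genotypes >= 0), all(genotypes <= 1))
  with_seed(config$seed, {
    bpd <- 1440 %/% config$bin_width
    nb <- bpd * config$n_days
    nf <- config$n_flies_per_genotype
    counts <- NULL; geno <- character(0); ids <- character(0)
    for (g in names(genotypes)) {
      rate <- rep(activity_rate_curve(config, genotypes[[g]]), config$n_days)
      m <- matrix(rpois(nf * nb, rep(rate, each = nf)), nrow = nf)
      counts <- rbind(counts, m)
      geno <- c(geno, rep(g, nf))
      ids <- c(ids, paste0(g, "_", seq_len(nf)))
    }
    rownames(counts) <- ids
    activity_table(counts, genotype = geno, bin_width = config$bin_width,
                   start_minute = 0,
                   schedule = light_schedule(config$lights_on, config$lights_off))
  })
}

## ---- expression matrices ----------------------------------------------

#' Configuration for simulated RPKM expression profiles
#'
#' Module genes share one latent per-sample profile on the log10 scale; each
#' module gene adds independent Gaussian noise with the latent scale set so
#' that the expected pairwise Pearson correlation equals `module_rho`
#' (latent sd = `noise_sd * sqrt(rho / (1 - rho))`; with `module_rho = 1`
#' the profiles are identical up to baseline shifts). Non-module genes are
#' independent. RPKM values are `10^log10value`, so all values are positive.
#' Defaults emulate a 30-sample developmental series.
#'
#' @param n_genes total genes, including the module.
#' @param n_samples samples (columns), >= 3. 29 (tissue panel) or 30
#'   (developmental series) in the emulated datasets.
#' @param module_genes names of the co-regulated genes; other genes are
#'   auto-named `gene_1 ...`.
#' @param module_rho target pairwise correlation within the module, (0, 1].
#' @param noise_sd per-gene noise sd in log10-RPKM units.
#' @param seed integer RNG seed.
#' @return an `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes = 24, n_samples = 30,
                                  module_genes = c("na", "mid1", "unc79", "unc80"),
                                  module_rho = 0.9, noise_sd = 0.3, seed = 1L) {
  stopifnot(n_samples >= 3, module_rho > 0, module_rho <= 1, noise_sd >= 0,
            length(module_genes) >= 1, n_genes >= length(module_genes),
            !anyDuplicated(module_genes))
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 module_genes = module_genes, module_rho = module_rho,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate an RPKM expression matrix with a planted co-expression module
#'
#' @param config an [expression_sim_config()].
#' @param dataset_kind `"tissue"` or `"developmental"`; label only.
#' @return an [expression_matrix()].
#' @export
simulate_expression <- function(config, dataset_kind = "developmental") {
  stopifnot(inherits(config, "expression_sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes; ns <- config$n_samples
    nm <- length(config$module_genes)
    genes <- c(config$module_genes,
               if (ng > nm) paste0("gene_", seq_len(ng - nm)))
    rho <- config$module_rho; sdn <- config$noise_sd
    # per-gene log10 baseline, realistic 0..3 decade spread; module genes
    # share one baseline (the latent profile is shared in full, so with
    # rho = 1 and zero noise their RPKM profiles are identical)
    mu <- runif(ng, 0.5, 2.5)
    mu[seq_len(nm)] <- mu[1]
    indep_sd <- if (sdn > 0) sdn else 0.5   # scale of independent genes
    z <- rnorm(ns)                           # shared latent profile, sd 1
    lat_sd <- if (rho < 1) sdn * sqrt(rho / (1 - rho)) else 1
    logv <- matrix(NA_real_, ng, ns)
    for (i in seq_len(ng)) {
      logv[i, ] <- if (i <= nm) {
        mu[i] + lat_sd * z + if (rho < 1) rnorm(ns, 0, sdn) else 0
      } else {
        mu[i] + rnorm(ns, 0, indep_sd)
      }
    }
    vals <- 10^logv
    dimnames(vals) <- list(genes, sprintf("sample_%02d", seq_len(ns)))
    expression_matrix(vals, dataset_kind = dataset_kind)
  })
}

## ---- multiple sequence alignments -------------------------------------

#' Configuration for simulated protein alignments
#'
#' Emulates an alignment carrying a conserved cysteine-rich motif: `length`
#' columns, of which `motif_positions` hold the expected residue (cysteine)
#' with probability `motif_conservation` per sequence; every other column
#' has a random consensus residue carried with probability
#' `background_conservation` (otherwise a uniform residue). Gaps are
#' injected per cell at `gap_rate`, never in the first (reference) row; the
#' reference row always carries the consensus / motif residue, so motif
#' coordinates are exact in the reference.
#'
#' @param n_seqs sequences (rows).
#' @param length alignment columns.
#' @param motif_positions 1-based column indices of the motif.
#' @param motif_conservation fraction in `[0, 1]`.
#' @param background_conservation fraction in `[0, 1]`.
#' @param gap_rate per-cell gap probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return an `msa_sim_config` list.
#' @export
msa_sim_config <- function(n_seqs = 50, length = 200,
                           motif_positions = c(20, 45, 90, 130, 170),
                           motif_conservation = 1,
                           background_conservation = 0.3,
                           gap_rate = 0.05, seed = 1L) {
  stopifnot(n_seqs >= 2, length >= 1,
            all(motif_positions >= 1), all(motif_positions <= length),
            !anyDuplicated(motif_positions),
            motif_conservation >= 0, motif_conservation <= 1,
            background_conservation >= 0, background_conservation <= 1,
            gap_rate >= 0, gap_rate <= 1)
  structure(list(n_seqs = as.integer(n_seqs), length = as.integer(length),
                 motif_positions = as.integer(motif_positions),
                 motif_conservation = motif_conservation,
                 background_conservation = background_conservation,
                 gap_rate = gap_rate, seed = as.integer(seed)),
            class = "msa_sim_config")
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Simulate a gapped protein alignment with a planted motif
#'
#' @param config an [msa_sim_config()].
#' @param expected_residue motif residue, default cysteine.
#' @return an [msa()] whose first row (`ref`) is the ungapped reference.
#' @export
simulate_msa <- function(config, expected_residue = "C") {
  stopifnot(inherits(config, "msa_sim_config"))
  with_seed(config$seed, {
    n <- config$n_seqs; L <- config$length
    is_motif <- seq_len(L) %in% config$motif_positions
    consensus <- ifelse(is_motif, expected_residue, sample(AA20, L, replace = TRUE))
    p_keep <- ifelse(is_motif, config$motif_conservation,
                     config$background_conservation)
    m <- matrix("", n, L)
    m[1, ] <- consensus                     # reference row: exact consensus
    for (i in seq(2, length.out = n - 1)) {
      keep <- runif(L) < p_keep
      row <- ifelse(keep, consensus, sample(AA20, L, replace = TRUE))
      gap <- runif(L) < config$gap_rate
      row[gap] <- "-"
      m[i, ] <- row
    }
    seqs <- apply(m, 1, paste0, collapse = "")
    names(seqs) <- c("ref", sprintf("seq_%03d", seq(2, length.out = n - 1)))
    msa(seqs, reference_id = "ref")
  })
}
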