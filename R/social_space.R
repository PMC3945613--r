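## Social-space analysis: nearest-neighbor distances from chamber
## snapshots, 5-mm frequency histograms, the Social Space Index
## (SSI = %bin1 - %bin2), and genotype comparisons via repeated-measures
## ANOVA with Dunnett's many-to-one post-hoc.

#' One chamber snapshot of fly coordinates
#'
#' @param coordinates two-column numeric matrix (x, y) in mm, origin at the
#'   arena center; >= 2 flies, all within `arena_radius` of the center.
#' @param arena_radius arena radius in mm (45 for the standard 90-mm
#'   chamber).
#' @param chamber_id chamber label.
#' @param capture_index which of the periodic captures this is (1..5 in the
#'   standard assay).
#' @return an `arena_snapshot` list.
#' @export
arena_snapshot <- function(coordinates, arena_radius = 45,
                           chamber_id = "chamber1", capture_index = 1L) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 2L) stop("coordinates must be an n x 2 matrix")
  if (nrow(coordinates) < 2L) stop("need >= 2 flies in a snapshot")
  if (anyNA(coordinates)) stop("missing coordinate")
  r <- sqrt(rowSums(coordinates^2))
  if (any(r > arena_radius + 1e-9))
    stop(sprintf("fly %d lies outside the %g mm arena (|p| = %.3g mm)",
                 which(r > arena_radius + 1e-9)[1], arena_radius, max(r)))
  colnames(coordinates) <- c("x", "y")
  structure(list(chamber_id = chamber_id,
                 capture_index = as.integer(capture_index),
                 coordinates = coordinates, arena_radius = arena_radius),
            class = "arena_snapshot")
}

#' Read chamber snapshots from a coordinates CSV
#'
#' Expected columns: `chamber_id, capture_index, fly_index, x_mm, y_mm`.
#' An optional `pixels_per_mm` converts pixel coordinates to mm on the fly.
#'
#' @param path CSV file.
#' @param arena_radius arena radius in mm.
#' @param pixels_per_mm if the coordinates are in pixels, the conversion
#'   factor; `NULL` means the file is already in mm.
#' @return list of [arena_snapshot()]s, one per (chamber, capture).
#' @export
read_coords <- function(path, arena_radius = 45, pixels_per_mm = NULL) {
  df <- utils::read.csv(path)
  need <- c("chamber_id", "capture_index", "fly_index", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("coordinates file needs columns: ", paste(need, collapse = ", "))
  if (!is.null(pixels_per_mm)) {
    df$x_mm <- df$x_mm / pixels_per_mm
    df$y_mm <- df$y_mm / pixels_per_mm
  }
  key <- interaction(df$chamber_id, df$capture_index, drop = TRUE)
  lapply(split(df, key), function(sub) {
    arena_snapshot(cbind(sub$x_mm, sub$y_mm), arena_radius = arena_radius,
                   chamber_id = as.character(sub$chamber_id[1]),
                   capture_index = sub$capture_index[1])
  })
}

#' Write snapshots as a coordinates CSV
#' @param snapshots an [arena_snapshot()] or list of them.
#' @param path output path.
#' @export
write_coords <- function(snapshots, path) {
  if (inherits(snapshots, "arena_snapshot")) snapshots <- list(snapshots)
  df <- do.call(rbind, lapply(snapshots, function(s) {
    data.frame(chamber_id = s$chamber_id, capture_index = s$capture_index,
               fly_index = seq_len(nrow(s$coordinates)),
               x_mm = s$coordinates[, 1], y_mm = s$coordinates[, 2])
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Nearest-neighbor distance of every fly
#'
#' For each fly, the minimum Euclidean distance to any other fly in the
#' snapshot. Coincident flies (distance 0) are legal — particle centroids
#' from an image can coincide — and produce a warning.
#'
#' @param x an [arena_snapshot()] or an n x 2 coordinate matrix.
#' @return numeric vector of length n, in mm.
#' @export
nearest_neighbor_distances <- function(x) {
  coords <- if (inherits(x, "arena_snapshot")) x$coordinates else as.matrix(x)
  n <- nrow(coords)
  if (n < 2L) stop("need >= 2 flies for nearest-neighbor distances")
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  if (any(nnd == 0)) warning("coincident fly coordinates (distance 0)")
  unname(nnd)
}

#' Frequency histogram of nearest-neighbor distances
#'
#' Half-open 5-mm bins `[0, 5), [5, 10), ...` (a distance of exactly 5 mm
#' falls in the second bin); percentages of the population per bin.
#'
#' @param distances nonempty vector of nearest-neighbor distances, mm.
#' @param bin_width bin width in mm.
#' @param n_bins number of bins; default enough to cover `max(distances)`.
#' @return a `social_space_histogram` list: `percent` (per bin, summing to
#'   100), `breaks`, `bin_width`, `n` (flies).
#' @export
distance_histogram <- function(distances, bin_width = 5, n_bins = NULL) {
  if (length(distances) == 0L) stop("no distances")
  if (any(distances < 0)) stop("negative distance")
  if (is.null(n_bins)) n_bins <- max(2L, floor(max(distances) / bin_width) + 1L)
  breaks <- seq(0, by = bin_width, length.out = n_bins + 1L)
  idx <- pmin(floor(distances / bin_width) + 1L, n_bins)  # last bin catches overflow
  cnt <- tabulate(idx, nbins = n_bins)
  structure(list(percent = 100 * cnt / length(distances), breaks = breaks,
                 bin_width = bin_width, n = length(distances)),
            class = "social_space_histogram")
}

#' @export
print.social_space_histogram <- function(x, ...) {
  lab <- sprintf("[%g,%g)", head(x$breaks, -1), x$breaks[-1])
  cat("Nearest-neighbor distance histogram (n =", x$n, "flies)\n")
  print(setNames(round(x$percent, 2), lab))
  invisible(x)
}

#' Average the histograms of one chamber's captures
#'
#' Per-bin arithmetic mean of the capture percentages (the standard
#' treatment of the 5 periodic captures of a chamber). All histograms must
#' share the same binning.
#'
#' @param histograms list of [distance_histogram()] results.
#' @return a `social_space_histogram` of the averaged percentages.
#' @export
average_chamber <- function(histograms) {
  stopifnot(length(histograms) >= 1,
            all(vapply(histograms, inherits, logical(1),
                       "social_space_histogram")))
  bw <- vapply(histograms, `[[`, numeric(1), "bin_width")
  nb <- vapply(histograms, function(h) length(h$percent), integer(1))
  if (length(unique(bw)) != 1L)
    stop("mismatched bin widths across captures")
  # pad to the longest histogram so captures with shorter tails average
  nmax <- max(nb)
  pct <- vapply(histograms, function(h) c(h$percent, rep(0, nmax - length(h$percent))),
                numeric(nmax))
  structure(list(percent = rowMeans(matrix(pct, nrow = nmax)),
                 breaks = seq(0, by = bw[1], length.out = nmax + 1L),
                 bin_width = bw[1],
                 n = round(mean(vapply(histograms, `[[`, numeric(1), "n")))),
            class = "social_space_histogram")
}

#' Social Space Index
#'
#' `SSI = %flies in bin 1 (0-5 mm) - %flies in bin 2 (5-10 mm)`: positive
#' when flies aggregate, around zero-to-negative under spatial randomness.
#'
#' @param histogram a [distance_histogram()] with >= 2 bins.
#' @return the SSI value, in `[-100, 100]`.
#' @export
ssi <- function(histogram) {
  stopifnot(inherits(histogram, "social_space_histogram"),
            length(histogram$percent) >= 2L)
  histogram$percent[1] - histogram$percent[2]
}

#' Snapshot to SSI in one call
#'
#' Convenience pipeline: nearest-neighbor distances, 5-mm histogram, SSI.
#'
#' @param snapshot an [arena_snapshot()] or coordinate matrix.
#' @param bin_width histogram bin width, mm.
#' @return the SSI value.
#' @export
snapshot_ssi <- function(snapshot, bin_width = 5) {
  ssi(distance_histogram(nearest_neighbor_distances(snapshot),
                         bin_width = bin_width))
}

#' Compare genotype SSI values against a control
#'
#' Replicates (simultaneously run chamber sets) are treated as
#' repeated-measures blocks: a one-way repeated-measures ANOVA over
#' genotypes, then Dunnett's many-to-one comparisons of each genotype
#' against the control. Requires the same replicate count per genotype.
#'
#' @param ssi_values data frame with columns `genotype`, `replicate`,
#'   `ssi`, or a blocks x genotypes matrix with genotype column names.
#' @param control control genotype label.
#' @param alpha significance level.
#' @param n_mc,seed Monte-Carlo settings for [dunnett_test()].
#' @return list: `anova` (an `anova_outcome`), `dunnett` (a
#'   `dunnett_report`), `means` (per-genotype mean, s.e.m., n).
#' @export
compare_genotypes <- function(ssi_values, control, alpha = 0.05,
                              n_mc = 1e5, seed = 1L) {
  if (is.data.frame(ssi_values)) {
    need <- c("genotype", "replicate", "ssi")
    if (!all(need %in% names(ssi_values)))
      stop("need columns: ", paste(need, collapse = ", "))
    cnt <- table(ssi_values$genotype)
    if (length(unique(cnt)) != 1L)
      stop("unequal replicate counts across genotypes: ",
           "the repeated-measures design requires complete blocks")
    if (anyDuplicated(ssi_values[c("replicate", "genotype")]))
      stop("duplicate (replicate, genotype) entry")
    y <- tapply(ssi_values$ssi,
                list(ssi_values$replicate, ssi_values$genotype), mean)
    if (anyNA(y)) stop("replicate x genotype grid has missing cells")
  } else {
    y <- as.matrix(ssi_values)
  }
  if (!control %in% colnames(y)) stop("control genotype '", control, "' absent")
  means <- data.frame(genotype = colnames(y), mean = colMeans(y),
                      sem = apply(y, 2, sd) / sqrt(nrow(y)), n = nrow(y),
                      row.names = NULL)
  list(anova = rm_anova_oneway(y),
       dunnett = dunnett_test(y, control = control, alpha = alpha,
                              n_mc = n_mc, seed = seed),
       means = means)
}

#' Write a genotype comparison report as JSON
#' @param comparison output of [compare_genotypes()].
#' @param path output path.
#' @export
write_ssi_json <- function(comparison, path) {
  jsonlite::write_json(
    list(means = comparison$means,
         anova = as.data.frame(comparison$anova),
         dunnett = as.data.frame(comparison$dunnett)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
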