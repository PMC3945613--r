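## Repeated-measures ANOVA, Dunnett many-to-one comparisons, and the
## permutation-p estimator. Implemented from the sum-of-squares
## decompositions directly; balanced complete designs only.

#' One-way repeated-measures ANOVA
#'
#' Partitions the total sum of squares of a balanced blocks x conditions
#' response grid into condition, subject (block), and residual strata and
#' tests the condition effect against the residual (condition x block)
#' stratum: `F = MS_condition / MS_residual`.
#'
#' @param y numeric matrix, one row per subject/block, one column per
#'   condition. Column names label the conditions. No missing values.
#' @return an object of class `anova_outcome`: a data frame with one row per
#'   stratum (`effect`, `ss`, `df`, `ms`, `F`, `p`). Only the condition
#'   effect carries an F and p; its error stratum is the residual.
#' @details A fully constant response grid has zero mean squares in every
#'   stratum; the condition F is reported as 0 with p = 1 rather than 0/0.
#' @seealso [rm_anova_mixed()] for the between x within design,
#'   [dunnett_test()] for post-hoc many-to-one comparisons.
#' @export
#' @examples
#' y <- matrix(rnorm(24), nrow = 8,
#'             dimnames = list(NULL, c("ctrl", "kd1", "kd2")))
#' rm_anova_oneway(y)
rm_anova_oneway <- function(y) {
  y <- as.matrix(y)
  if (!is.numeric(y)) stop("response grid must be numeric")
  if (anyNA(y)) stop("missing cell in repeated-measures grid: design must be complete")
  n <- nrow(y); k <- ncol(y)
  if (n < 2L) stop("need >= 2 subjects")
  if (k < 2L) stop("need >= 2 conditions")

  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  ss_cond  <- n * sum((colMeans(y) - grand)^2)
  ss_subj  <- k * sum((rowMeans(y) - grand)^2)
  ss_res   <- ss_total - ss_cond - ss_subj
  ss_res   <- max(ss_res, 0)        # guard tiny negative rounding
  df_cond  <- k - 1L
  df_subj  <- n - 1L
  df_res   <- (n - 1L) * (k - 1L)

  ms_cond <- ss_cond / df_cond
  ms_res  <- ss_res / df_res
  if (ms_res == 0 && ms_cond == 0) {
    f <- 0; p <- 1
  } else if (ms_res == 0) {
    f <- Inf; p <- .Machine$double.xmin
  } else {
    f <- ms_cond / ms_res
    p <- pf(f, df_cond, df_res, lower.tail = FALSE)
  }

  out <- data.frame(
    effect = c("condition", "subject", "residual"),
    ss = c(ss_cond, ss_subj, ss_res),
    df = c(df_cond, df_subj, df_res),
    ms = c(ms_cond, ss_subj / df_subj, ms_res),
    F  = c(f, NA, NA),
    p  = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "error_strata") <- c(condition = "residual")
  attr(out, "n_subjects") <- n
  class(out) <- c("anova_outcome", "data.frame")
  out
}

#' Mixed two-way repeated-measures ANOVA (between x within)
#'
#' Split-plot decomposition for a design with one between-subject factor
#' (e.g. genotype) and one within-subject factor (e.g. time bin), each
#' subject measured at every within level. The between effect is tested
#' against subjects-within-groups; the within effect and the interaction are
#' tested against the within-subject residual.
#'
#' @param y numeric matrix, one row per subject, one column per within-factor
#'   level (all subjects share the same grid).
#' @param between factor (or coercible) of length `nrow(y)` giving each
#'   subject's between-factor level. Must be balanced: equal subjects per
#'   level.
#' @return an `anova_outcome` data frame with rows `between`, `subject`,
#'   `within`, `between:within`, `residual`.
#' @export
rm_anova_mixed <- function(y, between) {
  y <- as.matrix(y)
  if (anyNA(y)) stop("missing cell in repeated-measures grid: design must be complete")
  between <- factor(between)
  n <- nrow(y); tt <- ncol(y); g <- nlevels(between)
  if (length(between) != n) stop("'between' must label every row of 'y'")
  if (g < 2L) stop("need >= 2 between-factor levels")
  if (tt < 2L) stop("need >= 2 within-factor levels (not a repeated-measures design)")
  cnt <- table(between)
  if (any(cnt < 2L)) stop("need >= 2 subjects in every between-factor level")
  if (length(unique(cnt)) != 1L)
    stop("unbalanced design: unequal subjects per between-factor level")

  grand <- mean(y)
  ss_total <- sum((y - grand)^2)

  subj_mean <- rowMeans(y)
  grp_mean  <- tapply(subj_mean, between, mean)          # per-genotype mean
  ss_between <- tt * sum(cnt * (grp_mean - grand)^2)
  ss_subj    <- tt * sum((subj_mean - grp_mean[between])^2)

  t_mean <- colMeans(y)
  ss_within <- n * sum((t_mean - grand)^2)

  # cell means: between level x within level
  cell <- rowsum(y, between) / as.vector(cnt)
  inter <- sweep(sweep(cell, 1, grp_mean, "-"), 2, t_mean, "-") + grand
  ss_inter <- sum(as.vector(cnt) * inter^2)

  ss_res <- max(ss_total - ss_between - ss_subj - ss_within - ss_inter, 0)

  df <- c(between = g - 1L, subject = n - g,
          within = tt - 1L, inter = (g - 1L) * (tt - 1L),
          residual = (n - g) * (tt - 1L))
  ss <- c(ss_between, ss_subj, ss_within, ss_inter, ss_res)
  ms <- ss / df

  f_of <- function(ms_num, ms_err, df_num, df_err) {
    if (ms_err == 0 && ms_num == 0) return(c(0, 1))
    if (ms_err == 0) return(c(Inf, .Machine$double.xmin))
    f <- ms_num / ms_err
    c(f, pf(f, df_num, df_err, lower.tail = FALSE))
  }
  fb <- f_of(ms[1], ms[2], df[1], df[2])
  fw <- f_of(ms[3], ms[5], df[3], df[5])
  fi <- f_of(ms[4], ms[5], df[4], df[5])

  out <- data.frame(
    effect = c("between", "subject", "within", "between:within", "residual"),
    ss = ss, df = as.integer(df), ms = ms,
    F = c(fb[1], NA, fw[1], fi[1], NA),
    p = c(fb[2], NA, fw[2], fi[2], NA),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "error_strata") <- c(between = "subject", within = "residual",
                                 `between:within` = "residual")
  attr(out, "n_subjects") <- n
  class(out) <- c("anova_outcome", "data.frame")
  out
}

#' Dunnett's many-to-one comparisons for a repeated-measures design
#'
#' Two-sided comparisons of each treatment level against a shared control,
#' using the pooled within-block error term of the one-way repeated-measures
#' ANOVA. Familywise adjustment integrates the joint distribution of the k
#' correlated t statistics (common control, balanced design: pairwise
#' correlation 1/2) by Monte Carlo with a fixed seed, so results are
#' deterministic for a given `seed` and `n_mc`.
#'
#' @param y numeric matrix, blocks (replicates) x levels; column names are
#'   the level labels.
#' @param control name of the control column.
#' @param alpha familywise significance level for the decision column.
#' @param n_mc Monte-Carlo draws for the max-|t| null distribution.
#' @param seed integer seed for the Monte-Carlo integration.
#' @return a `dunnett_report` data frame: one row per non-control level with
#'   `diff` (level mean minus control mean), `se`, `t`, `df`, `p_raw`
#'   (unadjusted two-sided t), `p_adj` (Dunnett-adjusted, never below
#'   `p_raw`), and `significant` at `alpha`.
#' @details The adjusted p for comparison j is the Monte-Carlo estimate of
#'   `P(max_i |T_i| >= |t_j|)` where `(T_1, ..., T_k)` are equicorrelated t
#'   variates on the error df. With a single treatment level this reduces to
#'   the ordinary two-sided paired t-test.
#' @export
dunnett_test <- function(y, control, alpha = 0.05, n_mc = 1e5, seed = 1L) {
  y <- as.matrix(y)
  if (is.null(colnames(y))) stop("'y' must have column (level) names")
  if (!control %in% colnames(y)) stop("control level '", control, "' not found")
  if (anyNA(y)) stop("missing cell: Dunnett on a repeated-measures design requires complete blocks")
  n <- nrow(y)
  if (n < 2L) stop("need >= 2 blocks")
  k <- ncol(y) - 1L
  if (k < 1L) stop("need >= 1 treatment level besides the control")

  aov1 <- rm_anova_oneway(y)
  ms_err <- aov1$ms[aov1$effect == "residual"]
  df_err <- aov1$df[aov1$effect == "residual"]

  trt <- setdiff(colnames(y), control)
  diffs <- colMeans(y[, trt, drop = FALSE]) - mean(y[, control])
  se <- sqrt(2 * ms_err / n)
  tstat <- if (se > 0) diffs / se else ifelse(diffs == 0, 0, sign(diffs) * Inf)
  p_raw <- 2 * pt(abs(tstat), df_err, lower.tail = FALSE)

  # max-|t| null: T_j = (X_j - X_0)/sqrt(2) / s, shared chi-square scale
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  x0 <- rnorm(n_mc)
  mx <- rep(0, n_mc)
  for (j in seq_len(k)) {
    z <- abs(rnorm(n_mc) - x0) / sqrt(2)
    mx <- pmax(mx, z)
  }
  s <- sqrt(rchisq(n_mc, df_err) / df_err)
  mt <- mx / s
  p_adj <- vapply(abs(tstat), function(t0) mean(mt >= t0), numeric(1))
  p_adj <- pmin(1, pmax(p_adj, p_raw))

  out <- data.frame(
    level = trt, diff = as.numeric(diffs), se = se,
    t = as.numeric(tstat), df = df_err,
    p_raw = as.numeric(p_raw), p_adj = as.numeric(p_adj),
    significant = as.numeric(p_adj) < alpha,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "control") <- control
  attr(out, "alpha") <- alpha
  attr(out, "n_mc") <- n_mc
  class(out) <- c("dunnett_report", "data.frame")
  out
}

#' Permutation p-value with add-one correction
#'
#' `p = (1 + #draws at least as extreme) / (1 + n)`; ties count as extreme,
#' so p is conservative and never below `1/(n + 1)`.
#'
#' @param observed observed value of the test statistic.
#' @param null_draws numeric vector of statistic values under the null
#'   (>= 99 draws).
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`
#'   (doubles the smaller one-sided p, capped at 1).
#' @return the p-value.
#' @export
permutation_p <- function(observed, null_draws,
                          alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(null_draws) == 0L) stop("empty null distribution")
  if (length(null_draws) < 99L) stop("need >= 99 null draws")
  n <- length(null_draws)
  p_gr <- (1 + sum(null_draws >= observed)) / (1 + n)
  p_ls <- (1 + sum(null_draws <= observed)) / (1 + n)
  switch(alternative,
         greater = p_gr,
         less = p_ls,
         two.sided = min(1, 2 * min(p_gr, p_ls)))
}

#' @export
print.anova_outcome <- function(x, ...) {
  cat("Repeated-measures ANOVA (", attr(x, "n_subjects"), " subjects)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
print.dunnett_report <- function(x, ...) {
  cat("Dunnett many-to-one comparisons vs '", attr(x, "control"),
      "' (alpha = ", attr(x, "alpha"), ")\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
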