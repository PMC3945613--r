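test_that("one-way RM ANOVA matches a from-scratch SS decomposition and aov", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:8, 1); k <- sample(3:5, 1)
    y <- matrix(rnorm(n * k, sd = 2), n, k,
                dimnames = list(NULL, paste0("c", seq_len(k))))
    got <- rm_anova_oneway(y)
    oracle <- rm_oneway_oracle(y)
    expect_equal(got$ss, c(oracle$ss_cond, oracle$ss_subj, oracle$ss_res),
                 tolerance = 1e-10)
    expect_equal(got$F[1], oracle$f, tolerance = 1e-10)
    # independent cross-check against stats::aov error stratification
    df <- data.frame(y = as.vector(y),
                     cond = factor(rep(colnames(y), each = n)),
                     subj = factor(rep(seq_len(n), k)))
    fit <- summary(aov(y ~ cond + Error(subj), data = df))
    ref <- fit[["Error: Within"]][[1]]
    expect_equal(got$F[1], ref["cond", "F value"], tolerance = 1e-8)
    expect_equal(got$p[1], ref["cond", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("constant responses give F = 0, p = 1; degenerate designs error", {
  y <- matrix(5, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  out <- rm_anova_oneway(y)
  expect_equal(out$F[1], 0)
  expect_equal(out$p[1], 1)
  expect_error(rm_anova_oneway(y[1, , drop = FALSE]), "subjects")
  expect_error(rm_anova_oneway(cbind(y, NA)), "missing")
})

test_that("mixed RM ANOVA matches aov's split-plot strata", {
  set.seed(21)
  for (rep in 1:4) {
    g <- sample(2:3, 1); n_per <- sample(3:5, 1); tt <- sample(3:6, 1)
    n <- g * n_per
    geno <- rep(paste0("g", seq_len(g)), each = n_per)
    y <- matrix(rnorm(n * tt), n, tt) +
      rep(rnorm(n), tt)      # subject effects
    got <- rm_anova_mixed(y, geno)
    df <- data.frame(y = as.vector(y),
                     time = factor(rep(seq_len(tt), each = n)),
                     geno = factor(rep(geno, tt)),
                     subj = factor(rep(seq_len(n), tt)))
    fit <- summary(aov(y ~ geno * time + Error(subj), data = df))
    between <- fit[["Error: subj"]][[1]]
    within <- fit[["Error: Within"]][[1]]
    expect_equal(got$F[got$effect == "between"], between["geno", "F value"],
                 tolerance = 1e-8)
    expect_equal(got$F[got$effect == "within"], within["time", "F value"],
                 tolerance = 1e-8)
    expect_equal(got$F[got$effect == "between:within"],
                 within["geno:time", "F value"], tolerance = 1e-8)
    expect_equal(got$p[got$effect == "between"], between["geno", "Pr(>F)"],
                 tolerance = 1e-8)
  }
})

test_that("mixed ANOVA with two groups reduces to two-sample t statistics", {
  set.seed(31)
  n_per <- 6; tt <- 4
  geno <- rep(c("a", "b"), each = n_per)
  y <- matrix(rnorm(2 * n_per * tt), 2 * n_per, tt)
  got <- rm_anova_mixed(y, geno)
  # between effect == squared two-sample t on subject means
  tb <- t.test(rowMeans(y)[geno == "a"], rowMeans(y)[geno == "b"],
               var.equal = TRUE)
  expect_equal(got$F[got$effect == "between"], unname(tb$statistic^2),
               tolerance = 1e-8)
  # with 2 within levels the interaction == squared two-sample t on the
  # within-subject difference
  y2 <- y[, 1:2]
  got2 <- rm_anova_mixed(y2, geno)
  d <- y2[, 2] - y2[, 1]
  ti <- t.test(d[geno == "a"], d[geno == "b"], var.equal = TRUE)
  expect_equal(got2$F[got2$effect == "between:within"],
               unname(ti$statistic^2), tolerance = 1e-8)
})

test_that("SS decomposition is exact on random grids", {
  set.seed(41)
  for (rep in 1:10) {
    y <- matrix(rnorm(40, sd = 3), 8, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
    out <- rm_anova_oneway(y)
    expect_equal(sum(out$ss), sum((y - mean(y))^2), tolerance = 1e-8)
    geno <- rep(c("a", "b"), each = 4)
    outm <- rm_anova_mixed(y, geno)
    expect_equal(sum(outm$ss), sum((y - mean(y))^2), tolerance = 1e-8)
  }
})

test_that("Dunnett with one treatment reduces to the paired t-test", {
  set.seed(51)
  y <- matrix(rnorm(16, sd = 2), 8, 2, dimnames = list(NULL, c("ctrl", "trt")))
  rep1 <- dunnett_test(y, "ctrl", n_mc = 1e5, seed = 3)
  tt <- t.test(y[, "trt"], y[, "ctrl"], paired = TRUE)
  expect_equal(rep1$p_raw, tt$p.value, tolerance = 1e-10)
  expect_lt(abs(rep1$p_adj - tt$p.value), 0.005)
})

test_that("Dunnett adjusted p is never below the raw p and agrees with multcomp", {
  set.seed(61)
  y <- matrix(rnorm(32), 8, 4, dimnames = list(NULL, c("ctrl", "a", "b", "c")))
  y[, "b"] <- y[, "b"] + 1.5
  rep1 <- dunnett_test(y, "ctrl", n_mc = 2e5, seed = 5)
  expect_true(all(rep1$p_adj >= rep1$p_raw))
  expect_true(all(rep1$p_adj <= 1 & rep1$p_raw > 0))
  skip_if_not_installed("multcomp")
  df <- data.frame(y = as.vector(y),
                   cond = factor(rep(colnames(y), each = 8),
                                 levels = colnames(y)),
                   subj = factor(rep(1:8, 4)))
  fit <- multcomp::glht(aov(y ~ cond + subj, data = df),
                        linfct = multcomp::mcp(cond = "Dunnett"))
  ref <- summary(fit)$test$pvalues
  expect_equal(rep1$p_adj, as.numeric(ref), tolerance = 0.01)
})

test_that("Dunnett adjusted p matches an independent numerical integration (k = 2)", {
  # oracle: P(max_j |T_j| >= t0), T equicorrelated (rho = 1/2) on df_err
  # degrees of freedom, by double numerical integration over the shared
  # control variate and the chi-square scale
  p_oracle <- function(t0, df_err) {
    keep2 <- function(c0) {
      integrate(function(u) {
        dnorm(u) * (pnorm(u + sqrt(2) * c0) - pnorm(u - sqrt(2) * c0))^2
      }, -Inf, Inf)$value
    }
    1 - integrate(Vectorize(function(x) {
      dchisq(x, df_err) * keep2(t0 * sqrt(x / df_err))
    }), 0, df_err * 5)$value
  }
  set.seed(81)
  y <- matrix(rnorm(36), 12, 3, dimnames = list(NULL, c("ctrl", "a", "b")))
  y[, "a"] <- y[, "a"] + 1
  rep1 <- dunnett_test(y, "ctrl", n_mc = 3e5, seed = 9)
  for (i in 1:2)
    expect_equal(rep1$p_adj[i], p_oracle(abs(rep1$t[i]), rep1$df[i]),
                 tolerance = 0.005)
})

test_that("permutation p uses the add-one rule with conservative ties", {
  expect_equal(permutation_p(10, rep(1, 999)), 1 / 1000)
  expect_equal(permutation_p(5, c(rep(5, 50), rep(0, 49))),
               (1 + 50) / 100)                       # ties count as >=
  draws <- seq_len(999)
  expect_equal(permutation_p(500, draws), (1 + 500) / 1000)
  expect_equal(permutation_p(0, draws, alternative = "less"), 1 / 1000)
  expect_lte(permutation_p(500, draws, alternative = "two.sided"), 1)
  expect_error(permutation_p(1, numeric(0)), "empty")
  expect_error(permutation_p(1, 1:50), ">= 99")
})

test_that("add-one permutation p is uniform on its grid under the null", {
  set.seed(71)
  n <- 99
  ps <- replicate(2000, permutation_p(rnorm(1), rnorm(n)))
  # exact uniformity on {1/(n+1), ..., 1}
  expect_true(all(ps >= 1 / (n + 1) & ps <= 1))
  expect_lt(abs(mean(ps) - (1 + 1 / (n + 1)) / 2), 0.02)
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 0.015)
})
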