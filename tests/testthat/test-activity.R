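make_table <- function(counts, genotype = rep("g", nrow(counts)),
                       bin_width = 5) {
  activity_table(counts, genotype, bin_width)
}

test_that("long-format DAM files round-trip exactly", {
  cfg <- activity_sim_config(n_flies_per_genotype = 3, n_days = 2, seed = 33)
  tab <- simulate_activity(cfg, c(control = 1, kd = 0.2))
  path <- tempfile(fileext = ".tsv")
  write_dam(tab, path, format = "long")
  back <- read_dam(path, schedule = tab$schedule)
  expect_equal(unname(back$counts), unname(tab$counts))
  expect_equal(back$genotype, tab$genotype)
  expect_equal(back$bin_width, tab$bin_width)
})

test_that("monitor-format files parse with status and grid validation", {
  cfg <- activity_sim_config(n_flies_per_genotype = 2, n_days = 1, seed = 34)
  tab <- simulate_activity(cfg, c(a = 1, b = 1))
  path <- tempfile(fileext = ".txt")
  write_dam(tab, path, format = "monitor")
  gmap <- c(ch01 = "a", ch02 = "a", ch03 = "b", ch04 = "b")
  back <- read_dam(path, schedule = tab$schedule, genotype_map = gmap)
  expect_equal(nrow(back$counts), 4)
  expect_equal(unname(back$counts), unname(tab$counts))
  expect_equal(back$genotype, c("a", "a", "b", "b"))

  # dropping a row creates a detectable gap
  lines <- readLines(path)
  writeLines(lines[-10], path)
  expect_error(read_dam(path, genotype_map = gmap), "gap in the recording")

  # duplicated row -> non-monotone timestamps
  writeLines(c(lines[1:10], lines[10], lines[11:length(lines)]), path)
  expect_error(read_dam(path, genotype_map = gmap), "non-monotone")

  # invalid status code
  bad <- strsplit(lines[5], "\t")[[1]]; bad[4] <- "51"
  writeLines(c(lines[1:4], paste(bad, collapse = "\t"),
               lines[6:length(lines)]), path)
  expect_error(read_dam(path, genotype_map = gmap), "status code '51'")
})

test_that("negative counts are rejected at construction and parse time", {
  expect_error(make_table(matrix(c(1, -2, 3, 4), 2, 2)), "negative")
  path <- tempfile()
  writeLines(c("fly_id\tgenotype\tminute\tcount",
               "f1\tg\t0\t3", "f1\tg\t5\t-1"), path)
  expect_error(read_dam(path), "negative count")
})

test_that("the 24-h inactivity filter removes exactly the zero-day flies", {
  bpd <- 288; days <- 7
  set.seed(35)
  counts <- matrix(rpois(4 * bpd * days, 0.5), nrow = 4)
  counts[2, (2 * bpd + 1):(3 * bpd)] <- 0          # fly 2: silent on day 3
  counts[3, ] <- 0                                  # fly 3: always silent
  counts[4, ] <- 0                                  # fly 4: one count per day,
  for (d in seq_len(days)) counts[4, (d - 1) * bpd + 100] <- 1  # boundary case
  rownames(counts) <- paste0("f", 1:4)
  tab <- make_table(counts)
  res <- suppressMessages(filter_inactive(tab))
  expect_setequal(res$removed, c("f2", "f3"))
  expect_equal(rownames(res$table$counts), c("f1", "f4"))

  # rolling window catches a 24-h silent span crossing a day boundary
  counts2 <- matrix(1, 2, bpd * days)
  counts2[2, (bpd / 2):(bpd / 2 + bpd)] <- 0
  rownames(counts2) <- c("a", "b")
  aligned <- suppressMessages(filter_inactive(make_table(counts2)))
  expect_equal(aligned$removed, character(0))
  rolling <- suppressMessages(filter_inactive(make_table(counts2),
                                              rolling = TRUE))
  expect_equal(rolling$removed, "b")

  short <- make_table(matrix(1, 2, 10))
  expect_error(filter_inactive(short), "shorter than")
})

test_that("rebinning sums groups and conserves totals exactly", {
  x <- make_table(matrix(c(1, 0, 2, 0, 0, 1), 1, 6))
  y <- rebin(x, 30)
  expect_equal(as.vector(y$counts), 4)

  cfg <- activity_sim_config(n_flies_per_genotype = 5, seed = 36)
  tab <- simulate_activity(cfg)
  reb <- rebin(tab, 30)
  expect_equal(rowSums(reb$counts), rowSums(tab$counts))
  expect_identical(rebin(tab, 5), tab)
  expect_error(rebin(tab, 7), "not a multiple")
})

test_that("daily profiles average time-of-day bins over days", {
  const <- make_table(matrix(2, 3, 48 * 7), bin_width = 30)
  prof <- daily_profile(const)
  expect_equal(ncol(prof$per_fly), 48)
  expect_equal(unname(prof$summary$mean), rep(2, 48))
  expect_equal(unname(prof$summary$sem), rep(0, 48))

  one_day <- make_table(matrix(seq_len(48), 1, 48, byrow = TRUE),
                        bin_width = 30)
  p1 <- daily_profile(one_day)
  expect_equal(unname(p1$per_fly[1, ]), as.numeric(1:48))

  expect_error(daily_profile(make_table(matrix(1, 2, 50), bin_width = 30)),
               "whole number of days")
})

test_that("profile means track the configured rate curve at scale", {
  cfg <- activity_sim_config(n_flies_per_genotype = 100, seed = 37)
  prof <- daily_profile(rebin(simulate_activity(cfg), 30))
  rate30 <- colSums(matrix(activity_rate_curve(cfg), nrow = 6))
  expect_lt(mean(abs(prof$summary$mean - rate30) / rate30), 0.05)
})

test_that("per-bin comparison needs a real design and flags the knockdown", {
  cfg <- activity_sim_config(n_flies_per_genotype = 1, seed = 38)
  prof <- daily_profile(rebin(simulate_activity(cfg, c(a = 1, b = 1)), 30))
  expect_error(per_bin_comparison(prof), ">= 2 flies")

  cfg2 <- activity_sim_config(n_flies_per_genotype = 16,
                              knockdown_multiplier = 0.2, seed = 39)
  tab <- simulate_activity(cfg2, c(control = 1, kd = 0.2))
  prof2 <- daily_profile(rebin(tab, 30))
  cmp <- per_bin_comparison(prof2, control = "control")
  # morning bump bins (within one peak-width of lights-on) should light up
  centers <- (seq_len(48) - 0.5) * 30
  peak_bins <- which(abs(centers - 8 * 60) <= 60)
  flags <- cmp$per_bin$flag[cmp$per_bin$bin %in% peak_bins]
  expect_gte(mean(flags), 0.8)
  expect_lt(cmp$anova$p[cmp$anova$effect == "between:within"], 0.01)
})

test_that("per-bin type-I error stays near alpha under the null", {
  set.seed(40)
  flags <- unlist(lapply(1:400, function(i) {
    y <- matrix(rnorm(16 * 12), 16, 12) + rep(rnorm(16, sd = 0.7), 12)
    prof <- structure(list(
      per_fly = y, genotype = rep(c("a", "b"), each = 8), bin_width = 120,
      bin_start_minute = (0:11) * 120, schedule = light_schedule(),
      summary = NULL), class = "daily_profile")
    per_bin_comparison(prof)$per_bin$flag
  }))
  expect_gte(mean(flags), 0.04)
  expect_lte(mean(flags), 0.06)
})

test_that("transition indices: flat, concentrated, and ramped profiles", {
  flat <- daily_profile(make_table(matrix(1, 2, 48), bin_width = 30))
  ti <- transition_indices(flat)
  expect_equal(ti$light_dark_ratio, 1)
  expect_equal(ti$anticipation_on, 0.5)
  expect_equal(ti$anticipation_off, 0.5)

  # all activity in the 3 h before lights-off (20:00): bins 35..40 of 48
  conc <- matrix(0, 2, 48); conc[, 35:40] <- 5
  pc <- daily_profile(make_table(conc, bin_width = 30))
  expect_equal(transition_indices(pc)$anticipation_off, 1)

  # linear ramp over the 6 h before lights-off -> 0.75
  ramp <- matrix(0, 1, 48)
  ramp[1, 29:40] <- seq(0.25, 5.75, by = 0.5)   # bin-center ramp heights
  pr <- daily_profile(make_table(ramp, bin_width = 30))
  expect_equal(transition_indices(pr)$anticipation_off, 0.75)

  # zero denominator -> NA marker
  dark_only <- matrix(0, 1, 48); dark_only[1, 45:48] <- 1
  pd <- daily_profile(make_table(dark_only, bin_width = 30))
  expect_true(is.na(transition_indices(pd)$anticipation_on))
})
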