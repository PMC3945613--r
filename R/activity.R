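## Diurnal locomotor activity: DAM-style monitor file IO, the 24-h
## inactivity filter, rebinning, daily time-of-day profiles, mixed-ANOVA
## per-bin genotype comparisons, and light/dark + anticipation indices.

#' Light/dark schedule
#'
#' @param lights_on,lights_off transition clock hours in `[0, 24)`, e.g.
#'   8 and 20 for an LD 12:12 cycle with lights on at 08:00.
#' @return a `light_schedule` list.
#' @export
light_schedule <- function(lights_on = 8, lights_off = 20) {
  stopifnot(lights_on >= 0, lights_on < 24, lights_off >= 0, lights_off < 24,
            lights_on != lights_off)
  structure(list(lights_on = lights_on, lights_off = lights_off, cycle = 24),
            class = "light_schedule")
}

#' Per-fly beam-crossing counts on a uniform bin grid
#'
#' @param counts non-negative integer matrix, one row per fly, one column
#'   per time bin; rownames are fly ids.
#' @param genotype genotype label per fly.
#' @param bin_width bin width in minutes.
#' @param start_minute clock minute-of-day at which bin 1 starts (0 =
#'   midnight).
#' @param schedule a [light_schedule()].
#' @return an `activity_table` list.
#' @export
activity_table <- function(counts, genotype, bin_width, start_minute = 0,
                           schedule = light_schedule()) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative activity count")
  if (anyNA(counts)) stop("missing activity count")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("fly_", seq_len(nrow(counts)))
  stopifnot(length(genotype) == nrow(counts), inherits(schedule, "light_schedule"),
            bin_width > 0, 1440 %% bin_width == 0)
  structure(list(counts = counts, fly_ids = rownames(counts),
                 genotype = as.character(genotype), bin_width = bin_width,
                 start_minute = start_minute, schedule = schedule),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat("Activity table:", nrow(x$counts), "flies x", ncol(x$counts),
      sprintf("bins of %g min (%s)\n", x$bin_width,
              paste(unique(x$genotype), collapse = ", ")))
  invisible(x)
}

#' Read a locomotor activity monitor file
#'
#' Two layouts are accepted. `"monitor"` is the Trikinetics-style
#' tab-delimited export: reading index, date (`d b y`, e.g. `1 Jan 24`),
#' time (`HH:MM:SS`), a status code (1 = valid; any other code aborts the
#' read), then 32 channel count columns. Each row's timestamp marks the
#' start of its bin; rows must form a gapless uniform grid. `"long"` is a
#' tab-delimited table with header `fly_id  genotype  minute  count`,
#' `minute` being minutes since midnight of the first recording day.
#'
#' @param path input file.
#' @param schedule a [light_schedule()].
#' @param format `"auto"` (sniff the header), `"monitor"`, or `"long"`.
#' @param genotype_map for monitor files: named character vector mapping
#'   channel ids (`ch01`..`ch32`) to genotype labels; unmapped channels are
#'   dropped. `NULL` keeps all channels with genotype `"unknown"`.
#' @return an [activity_table()].
#' @export
read_dam <- function(path, schedule = light_schedule(),
                     format = c("auto", "monitor", "long"),
                     genotype_map = NULL) {
  format <- match.arg(format)
  first <- readLines(path, n = 1L)
  if (format == "auto")
    format <- if (grepl("^fly_id\t", first)) "long" else "monitor"
  if (format == "long") read_dam_long(path, schedule)
  else read_dam_monitor(path, schedule, genotype_map)
}

read_dam_monitor <- function(path, schedule, genotype_map) {
  raw <- read.delim(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(raw) != 36L)
    stop("monitor file must have 36 tab-separated columns ",
         "(index, date, time, status, 32 channels); found ", ncol(raw))
  status <- raw[[4]]
  if (any(status != "1"))
    stop("invalid monitor status code '", status[status != "1"][1],
         "' at row ", which(status != "1")[1])
  tt <- as.POSIXct(paste(raw[[2]], raw[[3]]), format = "%d %b %y %H:%M:%S",
                   tz = "UTC")
  if (anyNA(tt)) stop("unparseable date/time at row ", which(is.na(tt))[1])
  dm <- as.numeric(difftime(tt[-1], tt[-length(tt)], units = "mins"))
  if (any(dm <= 0)) stop("non-monotone timestamps at row ", which(dm <= 0)[1] + 1)
  if (length(dm)) {
    w <- dm[1]
    gap <- which(abs(dm - w) > 1e-9)
    if (length(gap))
      stop("gap in the recording grid between ", format(tt[gap[1]]),
           " and ", format(tt[gap[1] + 1]))
  } else w <- 5
  cnt <- vapply(raw[5:36], as.numeric, numeric(nrow(raw)))
  if (anyNA(cnt)) stop("non-numeric count cell")
  if (any(cnt < 0)) stop("negative count at row ",
                         which(rowSums(cnt < 0) > 0)[1])
  counts <- t(cnt)
  rownames(counts) <- sprintf("ch%02d", 1:32)
  geno <- rep("unknown", 32)
  if (!is.null(genotype_map)) {
    keep <- rownames(counts) %in% names(genotype_map)
    counts <- counts[keep, , drop = FALSE]
    geno <- unname(genotype_map[rownames(counts)])
  }
  lt <- as.POSIXlt(tt[1])
  activity_table(counts, genotype = geno, bin_width = w,
                 start_minute = lt$hour * 60 + lt$min, schedule = schedule)
}

read_dam_long <- function(path, schedule) {
  df <- read.delim(path, header = TRUE, sep = "\t")
  need <- c("fly_id", "genotype", "minute", "count")
  if (!all(need %in% names(df)))
    stop("long format needs columns: ", paste(need, collapse = ", "))
  if (any(df$count < 0)) stop("negative count for fly ",
                              df$fly_id[df$count < 0][1])
  ids <- unique(df$fly_id)
  minutes <- sort(unique(df$minute))
  w <- if (length(minutes) > 1) diff(minutes)[1] else 5
  if (length(minutes) > 1 && any(diff(minutes) != w))
    stop("gap in the recording grid near minute ",
         minutes[which(diff(minutes) != w)[1]])
  counts <- matrix(NA_real_, length(ids), length(minutes),
                   dimnames = list(ids, NULL))
  for (id in ids) {
    sub <- df[df$fly_id == id, ]
    if (is.unsorted(sub$minute, strictly = TRUE))
      stop("non-monotone timestamps for fly ", id)
    if (nrow(sub) != length(minutes))
      stop("fly ", id, " is missing bins from the shared grid")
    counts[id, ] <- sub$count
  }
  geno <- df$genotype[match(ids, df$fly_id)]
  activity_table(counts, genotype = geno, bin_width = w,
                 start_minute = minutes[1] %% 1440, schedule = schedule)
}

#' Write an activity table
#'
#' `"long"` writes the long tab-delimited layout [read_dam()] accepts;
#' `"monitor"` writes a Trikinetics-style 36-column file (at most 32 flies;
#' unused channels are zero-filled) starting on 1 Jan 24.
#'
#' @param x an [activity_table()].
#' @param path output path.
#' @param format `"long"` or `"monitor"`.
#' @export
write_dam <- function(x, path, format = c("long", "monitor")) {
  format <- match.arg(format)
  nb <- ncol(x$counts)
  minutes <- x$start_minute + (seq_len(nb) - 1) * x$bin_width
  if (format == "long") {
    df <- data.frame(
      fly_id = rep(x$fly_ids, times = nb),
      genotype = rep(x$genotype, times = nb),
      minute = rep(minutes, each = nrow(x$counts)),
      count = as.vector(x$counts))
    df <- df[order(match(df$fly_id, x$fly_ids), df$minute), ]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (nrow(x$counts) > 32L) stop("monitor layout holds at most 32 channels")
    t0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") + minutes * 60
    ch <- matrix(0L, nb, 32)
    ch[, seq_len(nrow(x$counts))] <- t(x$counts)
    df <- data.frame(seq_len(nb), format(t0, "%d %b %y"),
                     format(t0, "%H:%M:%S"), 1L, ch)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Discard flies with an inactive 24-h period
#'
#' A fly is removed iff at least one window-length span of the recording
#' has total count zero. By default windows are aligned to consecutive
#' days from the recording start; `rolling = TRUE` instead slides the
#' window over every bin offset (a stricter reading of "any 24-h period").
#'
#' @param x an [activity_table()].
#' @param window_hours window length, default 24.
#' @param rolling use a sliding window instead of aligned days.
#' @return list: `table` (the retained flies), `removed` (fly ids).
#' @export
filter_inactive <- function(x, window_hours = 24, rolling = FALSE) {
  stopifnot(inherits(x, "activity_table"))
  wb <- as.integer(round(window_hours * 60 / x$bin_width))
  nb <- ncol(x$counts)
  if (nb < wb) stop("recording shorter than the inactivity window")
  if (rolling) {
    cs <- cbind(0, t(apply(x$counts, 1, cumsum)))
    nwin <- nb - wb + 1L
    dead <- vapply(seq_len(nrow(x$counts)), function(i) {
      any(cs[i, (1:nwin) + wb] - cs[i, 1:nwin] == 0)
    }, logical(1))
  } else {
    nwin <- nb %/% wb
    dead <- vapply(seq_len(nrow(x$counts)), function(i) {
      any(vapply(seq_len(nwin), function(k)
        sum(x$counts[i, ((k - 1) * wb + 1):(k * wb)]) == 0, logical(1)))
    }, logical(1))
  }
  removed <- x$fly_ids[dead]
  if (length(removed))
    message("discarding ", length(removed), " inactive fly/flies: ",
            paste(removed, collapse = ", "))
  keep <- !dead
  if (!any(keep)) stop("all flies removed by the inactivity filter")
  list(table = activity_table(x$counts[keep, , drop = FALSE],
                              x$genotype[keep], x$bin_width,
                              x$start_minute, x$schedule),
       removed = removed)
}

#' Re-bin counts to a coarser grid
#'
#' Sums counts within consecutive groups of bins; per-fly totals are
#' conserved exactly.
#'
#' @param x an [activity_table()].
#' @param new_width new bin width in minutes; must be a multiple of the
#'   current width and divide the recording length.
#' @return an [activity_table()] at the new width.
#' @export
rebin <- function(x, new_width = 30) {
  stopifnot(inherits(x, "activity_table"))
  if (new_width %% x$bin_width != 0)
    stop("new width (", new_width, ") is not a multiple of the bin width (",
         x$bin_width, ")")
  k <- new_width %/% x$bin_width
  if (k == 1L) return(x)
  nb <- ncol(x$counts)
  if (nb %% k != 0) stop("recording length is not a whole number of new bins")
  grp <- rep(seq_len(nb %/% k), each = k)
  counts <- t(rowsum(t(x$counts), grp))
  rownames(counts) <- x$fly_ids
  activity_table(counts, x$genotype, new_width, x$start_minute, x$schedule)
}

#' Daily time-of-day activity profile
#'
#' Folds the recording to time-of-day: for each fly, each of the
#' `1440 / bin_width` daily bins is averaged over recording days; genotype
#' summaries are the mean and s.e.m. across flies. With the conventional
#' 30-min bins this yields the 48-bin daily profile.
#'
#' @param x an [activity_table()] spanning a whole number of days
#'   (typically after [rebin()] to 30 min).
#' @return a `daily_profile` list: `per_fly` (fly x daily-bin matrix of
#'   day-averaged counts), `genotype` (per fly), `bin_width`,
#'   `bin_start_minute` (clock minute each daily bin starts), `schedule`,
#'   and `summary` (data frame: genotype, bin, mean, sem, n).
#' @export
daily_profile <- function(x) {
  stopifnot(inherits(x, "activity_table"))
  bpd <- 1440 %/% x$bin_width
  nb <- ncol(x$counts)
  if (nb %% bpd != 0)
    stop("recording must span a whole number of days")
  n_days <- nb %/% bpd
  tod <- ((x$start_minute %/% x$bin_width) + seq_len(nb) - 1) %% bpd + 1
  per_fly <- t(rowsum(t(x$counts), tod)) / n_days   # fly x daily bin
  rownames(per_fly) <- x$fly_ids
  if (any(table(x$genotype) < 1)) stop("genotype without flies")
  summ <- do.call(rbind, lapply(sort(unique(x$genotype)), function(g) {
    m <- per_fly[x$genotype == g, , drop = FALSE]
    data.frame(genotype = g, bin = seq_len(bpd),
               mean = colMeans(m),
               sem = apply(m, 2, sd) / sqrt(nrow(m)),
               n = nrow(m))
  }))
  rownames(summ) <- NULL
  structure(list(per_fly = per_fly, genotype = x$genotype,
                 bin_width = x$bin_width,
                 bin_start_minute = (seq_len(bpd) - 1) * x$bin_width,
                 schedule = x$schedule, summary = summ),
            class = "daily_profile")
}

#' Per-bin genotype comparisons from a mixed repeated-measures ANOVA
#'
#' Fits the mixed two-way design (between factor genotype, within factor
#' time-of-day bin, subject = fly) with [rm_anova_mixed()] and flags, for
#' every daily bin, each non-control genotype whose mean differs from the
#' control. The per-bin contrasts use the pooled between + within error
#' term `(MS_subject + (T - 1) MS_residual) / T` appropriate for comparing
#' between-group means at a fixed within level, with Satterthwaite degrees
#' of freedom.
#'
#' @param profile a [daily_profile()] with >= 2 genotypes and >= 2 flies
#'   per genotype (balanced).
#' @param control control genotype; default the alphabetically first.
#' @param alpha per-bin significance level (no multiplicity correction by
#'   default, matching per-bin asterisks at P < 0.05).
#' @param bonferroni divide `alpha` by the number of bins.
#' @return list: `anova` (the omnibus `anova_outcome`), `per_bin` (data
#'   frame: genotype, bin, diff, t, df, p, flag), `alpha_used`.
#' @export
per_bin_comparison <- function(profile, control = NULL, alpha = 0.05,
                               bonferroni = FALSE) {
  stopifnot(inherits(profile, "daily_profile"))
  geno <- factor(profile$genotype)
  if (nlevels(geno) < 2L) stop("need >= 2 genotypes")
  if (any(table(geno) < 2L)) stop("need >= 2 flies per genotype")
  if (is.null(control)) control <- levels(geno)[1]
  if (!control %in% levels(geno)) stop("control genotype not present")
  y <- profile$per_fly
  aovm <- rm_anova_mixed(y, geno)
  ms <- setNames(aovm$ms, aovm$effect)
  df <- setNames(aovm$df, aovm$effect)
  tt <- ncol(y)
  n_per <- table(geno)[1]
  pooled <- (ms["subject"] + (tt - 1) * ms["residual"]) / tt
  df_sat <- pooled^2 / ((ms["subject"] / tt)^2 / df["subject"] +
                        ((tt - 1) * ms["residual"] / tt)^2 / df["residual"])
  se <- sqrt(2 * pooled / n_per)
  alpha_used <- if (bonferroni) alpha / tt else alpha
  trt <- setdiff(levels(geno), control)
  ctrl_mean <- colMeans(y[geno == control, , drop = FALSE])
  per_bin <- do.call(rbind, lapply(trt, function(g) {
    d <- colMeans(y[geno == g, , drop = FALSE]) - ctrl_mean
    tstat <- if (se > 0) d / se else ifelse(d == 0, 0, sign(d) * Inf)
    p <- 2 * pt(abs(tstat), df_sat, lower.tail = FALSE)
    data.frame(genotype = g, bin = seq_len(tt), diff = d, t = tstat,
               df = as.numeric(df_sat), p = p, flag = p < alpha_used)
  }))
  rownames(per_bin) <- NULL
  list(anova = aovm, per_bin = per_bin, alpha_used = alpha_used,
       control = control)
}

#' Light/dark and anticipation indices of a daily profile
#'
#' For each genotype mean profile: `light_dark_ratio` is total activity
#' during lights-on divided by total during lights-off;
#' `anticipation_on` / `anticipation_off` is activity in the
#' `short_window` hours preceding the transition divided by activity in
#' the `long_window` hours preceding it. A flat profile gives ratio 1 and
#' anticipation `short_window / long_window` (0.5 at the 3 h / 6 h
#' defaults); a zero denominator yields `NA`.
#'
#' @param profile a [daily_profile()].
#' @param schedule a [light_schedule()]; default the profile's.
#' @param short_window,long_window anticipation windows in hours.
#' @return data frame: genotype, light_dark_ratio, anticipation_on,
#'   anticipation_off.
#' @export
transition_indices <- function(profile, schedule = profile$schedule,
                               short_window = 3, long_window = 6) {
  stopifnot(inherits(profile, "daily_profile"),
            short_window > 0, long_window > short_window)
  w <- profile$bin_width
  bpd <- length(profile$bin_start_minute)
  start <- profile$bin_start_minute
  on_min <- schedule$lights_on * 60; off_min <- schedule$lights_off * 60
  # bin is "light" if its start lies in [on, off) (mod 24 h)
  in_light <- if (on_min < off_min) start >= on_min & start < off_min
              else start >= on_min | start < off_min
  window_bins <- function(trans_min, hours) {
    lo <- trans_min - hours * 60
    rel <- (start - lo) %% 1440
    rel < hours * 60
  }
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- do.call(rbind, lapply(sort(unique(profile$genotype)), function(g) {
    m <- profile$summary$mean[profile$summary$genotype == g]
    data.frame(
      genotype = g,
      light_dark_ratio = ratio(sum(m[in_light]), sum(m[!in_light])),
      anticipation_on = ratio(sum(m[window_bins(on_min, short_window)]),
                              sum(m[window_bins(on_min, long_window)])),
      anticipation_off = ratio(sum(m[window_bins(off_min, short_window)]),
                               sum(m[window_bins(off_min, long_window)])))
  }))
  rownames(out) <- NULL
  out
}

#' Write daily profiles as TSV
#' @param profile a [daily_profile()].
#' @param path output path.
#' @export
write_profile_table <- function(profile, path) {
  write.table(profile$summary, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a per-bin comparison report as JSON
#' @param comparison output of [per_bin_comparison()].
#' @param path output path.
#' @export
write_comparison_json <- function(comparison, path) {
  jsonlite::write_json(
    list(control = comparison$control, alpha = comparison$alpha_used,
         anova = as.data.frame(comparison$anova),
         per_bin = comparison$per_bin),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
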