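# Shared fixture builders; everything is generated in code.

# brute-force O(n^2) nearest-neighbor oracle, independent of dist()
nnd_brute <- function(coords) {
  n <- nrow(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((coords[i, 1] - coords[j, 1])^2 +
                (coords[i, 2] - coords[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# uniform points in a disc (independent of simulate_arena)
runif_disc <- function(n, radius) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

# write a small aligned FASTA and return its path
write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}

# write a small RPKM TSV and return its path
write_tmp_rpkm <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# from-scratch sum-of-squares oracle for the one-way RM design (loops only)
rm_oneway_oracle <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(y[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(y[i, ]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (y[i, j] - grand)^2
  ss_res <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_res / ((n - 1) * (k - 1)))
  lapply(list(ss_cond = ss_cond, ss_subj = ss_subj, ss_res = ss_res, f = f),
         unname)
}
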