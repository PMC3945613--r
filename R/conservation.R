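## Conservation profiling of protein alignments: aligned-FASTA IO,
## majority-gap column stripping, Shannon-entropy conservation scores,
## motif tracking through gapped reference coordinates, and a permutation
## test for regional conservation. Coordinates are 1-based and inclusive
## throughout.

MSA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                  "M","N","P","Q","R","S","T","V","W","Y","X","-")

#' Protein multiple sequence alignment
#'
#' @param seqs named character vector of equal-length aligned sequences over
#'   the 20 amino acids, `X`, and the gap `-`. Lowercase input is upcased.
#' @param reference_id the row used for motif coordinates; default first.
#' @return an `msa` list: `seq_ids`, `rows` (character matrix, one row per
#'   sequence, one column per alignment column), `reference_id`.
#' @export
msa <- function(seqs, reference_id = names(seqs)[1]) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequences with deviating length: ",
         paste(names(seqs)[lens != lens[1]], collapse = ", "))
  if (!reference_id %in% names(seqs))
    stop("reference sequence '", reference_id, "' not in alignment")
  rows <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(rows) <- names(seqs)
  bad <- matrix(!(rows %in% MSA_ALPHABET), nrow = nrow(rows))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("illegal character '%s' in sequence '%s' column %d",
                 rows[bad][1], rownames(rows)[idx[1]], idx[2]))
  }
  structure(list(seq_ids = names(seqs), rows = rows,
                 reference_id = reference_id),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Protein alignment:", nrow(x$rows), "sequences x", ncol(x$rows),
      "columns (reference:", x$reference_id, ")\n")
  invisible(x)
}

#' Read an aligned-FASTA protein alignment
#'
#' @param path aligned-FASTA file.
#' @param reference_id reference row id; default the first record.
#' @return an [msa()].
#' @export
read_alignment <- function(path, reference_id = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))   # drop description
  if (is.null(reference_id)) reference_id <- names(seqs)[1]
  msa(seqs, reference_id = reference_id)
}

#' Write an alignment as aligned FASTA
#' @param x an [msa()].
#' @param path output path.
#' @export
write_alignment <- function(x, path) {
  seqs <- apply(x$rows, 1, paste0, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Remove majority-gapped alignment columns
#'
#' Drops every column whose gap fraction is strictly greater than
#' `max_gap_fraction` (so a column that is exactly half gaps is retained at
#' the default 0.5). The mapping from retained to original column indices is
#' attached as `column_map`, strictly increasing and 1-based.
#'
#' @param x an [msa()].
#' @param max_gap_fraction threshold in `[0, 1)`.
#' @return the filtered [msa()] with attribute `column_map`.
#' @export
strip_gapped_columns <- function(x, max_gap_fraction = 0.5) {
  stopifnot(inherits(x, "msa"),
            max_gap_fraction >= 0, max_gap_fraction < 1)
  gap_frac <- colMeans(x$rows == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0L)
    stop("all columns exceed the gap threshold: nothing left to analyse")
  out <- msa(apply(x$rows[, keep, drop = FALSE], 1, paste0, collapse = ""),
             reference_id = x$reference_id)
  attr(out, "column_map") <- keep
  attr(out, "max_gap_fraction") <- max_gap_fraction
  out
}

entropy_score <- function(column) {
  res <- column[column != "-"]
  if (length(res) == 0L) return(NA_real_)     # all-gap: flagged, scored 0
  f <- table(res) / length(res)
  h <- -sum(f * log(f))
  min(max(1 - h / log(20), 0), 1)
}

#' Per-column conservation scores
#'
#' Score per column: `1 - H / ln(20)` where `H` is the Shannon entropy of
#' the residue frequencies. Gaps are treated as missing observations and
#' excluded from the frequencies (a column of identical residues scores 1;
#' a uniform column scores 0); columns left empty after gap removal are
#' flagged and scored 0. Scores are clipped to `[0, 1]` (a column dominated
#' by one residue among fewer than 20 observed could otherwise stray
#' outside due to the fixed ln(20) normalizer).
#'
#' @param x an [msa()], typically after [strip_gapped_columns()].
#' @return a `conservation_profile` data frame: `column` (index within this
#'   alignment), `original_column` (through `column_map` if present, else
#'   identical), `score`, `empty` (all-gap flag).
#' @export
conservation_scores <- function(x) {
  stopifnot(inherits(x, "msa"))
  if (nrow(x$rows) < 2L)
    stop("conservation is undefined for a single sequence")
  sc <- apply(x$rows, 2, entropy_score)
  cmap <- attr(x, "column_map")
  if (is.null(cmap)) cmap <- seq_along(sc)
  out <- data.frame(column = seq_along(sc), original_column = cmap,
                    score = ifelse(is.na(sc), 0, sc), empty = is.na(sc))
  attr(out, "max_gap_fraction") <- attr(x, "max_gap_fraction")
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Map ungapped reference positions to alignment columns
#'
#' @param x an [msa()].
#' @param positions 1-based positions in the ungapped reference sequence.
#' @return integer alignment column indices.
#' @keywords internal
reference_columns <- function(x, positions) {
  ref <- x$rows[x$reference_id, ]
  res_cols <- which(ref != "-")
  if (any(positions > length(res_cols)))
    stop("motif position beyond the ungapped reference length (",
         length(res_cols), " residues)")
  res_cols[positions]
}

#' Conservation of anchored motif positions
#'
#' Maps each ungapped reference position (e.g. the essential cysteines of
#' the Mid1 domain) through the reference row's gaps to its alignment
#' column, and reports the fraction of sequences carrying the expected
#' residue there. `X` and gaps never count as the expected residue.
#'
#' @param x an [msa()].
#' @param positions strictly increasing 1-based positions in the ungapped
#'   reference sequence.
#' @param expected_residue single residue, default `"C"`.
#' @return data frame: `position`, `column` (alignment column), `residue`
#'   (reference residue there), `fraction` of sequences with the expected
#'   residue.
#' @export
motif_conservation <- function(x, positions, expected_residue = "C") {
  stopifnot(inherits(x, "msa"), length(positions) >= 1,
            all(positions >= 1), !is.unsorted(positions, strictly = TRUE),
            expected_residue %in% setdiff(MSA_ALPHABET, c("X", "-")))
  cols <- reference_columns(x, positions)
  frac <- vapply(cols, function(j) mean(x$rows[, j] == expected_residue),
                 numeric(1))
  data.frame(position = as.integer(positions), column = as.integer(cols),
             residue = x$rows[x$reference_id, cols],
             fraction = frac, row.names = NULL)
}

#' Permutation test: is a region more conserved than the rest?
#'
#' Statistic: mean conservation score of the region columns minus the mean
#' of all other columns. The null is built by permuting which columns carry
#' the region label; p uses the add-one estimator of [permutation_p()],
#' one-sided for the region being the more conserved.
#'
#' @param profile a [conservation_scores()] result.
#' @param region_columns column indices (within the profile's `column`
#'   numbering) of the region; nonempty proper subset.
#' @param n_perm permutations, >= 99.
#' @param seed integer RNG seed.
#' @return list: `observed` (mean difference), `p`, `n_perm`.
#' @export
region_vs_rest_test <- function(profile, region_columns, n_perm = 999, seed = 1L) {
  stopifnot(inherits(profile, "conservation_profile"), n_perm >= 99)
  cols <- profile$column
  region_columns <- unique(as.integer(region_columns))
  if (length(region_columns) == 0L) stop("empty region")
  if (!all(region_columns %in% cols))
    stop("region columns outside the profile")
  if (length(region_columns) >= length(cols))
    stop("region must be a proper subset of the columns")
  s <- profile$score
  in_region <- cols %in% region_columns
  observed <- mean(s[in_region]) - mean(s[!in_region])
  m <- sum(in_region)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(s), m)
      mean(s[idx]) - mean(s[-idx])
    }, numeric(1))
  })
  list(observed = observed,
       p = permutation_p(observed, null, alternative = "greater"),
       n_perm = n_perm)
}

#' Write a conservation profile as TSV
#' @param profile a `conservation_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a motif conservation report as JSON
#' @param motif_report output of [motif_conservation()].
#' @param path output path.
#' @export
write_motif_json <- function(motif_report, path) {
  jsonlite::write_json(motif_report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
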