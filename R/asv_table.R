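#' ASV count table
#'
#' The central container of the amplicon pipeline: a set of equal-length ASV
#' (amplicon sequence variant) nucleotide sequences together with an integer
#' ASV-by-sample count matrix and per-sample metadata (site and replicate).
#'
#' @param sequences Named character vector, one nucleotide sequence per ASV;
#'   names are ASV ids and must match `rownames(counts)`.
#' @param counts Non-negative integer matrix, ASVs in rows, samples in
#'   columns, with dimnames.
#' @param samples Data frame with columns `sample`, `site`, `replicate`;
#'   `sample` must match `colnames(counts)`.  Defaults to metadata parsed
#'   from sample names of the form `"<site>_r<replicate>"`, or `NA` fields.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(sequences, counts, samples = NULL) {
  counts <- as.matrix(counts)
  # a 0 x 0 table is valid and dimnameless by construction in R
  if ((nrow(counts) > 0L || ncol(counts) > 0L) &&
      (is.null(rownames(counts)) || is.null(colnames(counts)))) {
    abort("`counts` must have ASV row names and sample column names")
  }
  if (!setequal(names(sequences), rownames(counts)) ||
      anyDuplicated(names(sequences)) > 0L) {
    abort("every ASV id must appear exactly once in both `sequences` and `counts` rows")
  }
  sequences <- sequences[rownames(counts)]
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (nrow(counts) > 0L && length(unique(nchar(sequences))) > 1L) {
    abort("ASV sequences must all have the same length after trimming")
  }
  samples <- samples %||% parse_sample_meta(colnames(counts))
  samples <- as_tibble(samples)
  if (!all(c("sample", "site", "replicate") %in% names(samples)) ||
      !setequal(samples$sample, colnames(counts))) {
    abort("`samples` needs columns sample/site/replicate matching the count columns")
  }
  samples <- samples[match(colnames(counts), samples$sample), ]
  structure(
    list(sequences = sequences, counts = counts, samples = samples),
    class = "asv_table"
  )
}

parse_sample_meta <- function(sample_names) {
  m <- regmatches(sample_names, regexec("^(.*)_r([0-9]+)$", sample_names))
  tibble(
    sample = sample_names,
    site = vapply(m, function(x) if (length(x) == 3L) x[2L] else NA_character_, ""),
    replicate = vapply(
      m, function(x) if (length(x) == 3L) as.integer(x[3L]) else NA_integer_, 1L
    )
  )
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf(
    "<asv_table> %d ASVs x %d samples (%s sites), %s reads total\n",
    nrow(x$counts), ncol(x$counts),
    length(unique(x$samples$site)), format(sum(x$counts), big.mark = ",")
  ))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Long (tidy) view of an ASV table
#'
#' @param x An [asv_table].
#' @param ... Unused.
#' @return A tibble with one row per ASV-sample pair: `asv_id`, `sample`,
#'   `site`, `replicate`, `count`.
#' @exportS3Method tibble::as_tibble
as_tibble.asv_table <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "asv_id") |>
    tidyr::pivot_longer(-"asv_id", names_to = "sample", values_to = "count")
  left_join(long, x$samples, by = "sample")
}

#' Write / read an ASV table as plain-text files
#'
#' Serializes to three files under `dir`: `asvs.fasta` (sequences),
#' `counts.tsv` (ASV-by-sample integer matrix with an `asv_id` header
#' column) and `samples.tsv` (sample metadata).
#'
#' @param x An [asv_table].
#' @param dir Output (input) directory.
#' @return `write_asv_table()` returns the directory invisibly;
#'   `read_asv_table()` returns an [asv_table].
#' @export
write_asv_table <- function(x, dir) {
  stopifnot(inherits(x, "asv_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(x$sequences, file.path(dir, "asvs.fasta"))
  counts <- data.frame(asv_id = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(counts, file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_asv_table
#' @export
read_asv_table <- function(dir) {
  seqs <- read_fasta(file.path(dir, "asvs.fasta"))
  counts <- utils::read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  samples <- as_tibble(utils::read.delim(file.path(dir, "samples.tsv")))
  mat <- as.matrix(counts[, -1, drop = FALSE])
  rownames(mat) <- counts[[1L]]
  asv_table(seqs, mat, samples)
}
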