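#' Read and write FASTA / FASTQ files
#'
#' Thin wrappers around Biostrings I/O.  Gzip-compressed inputs are accepted
#' transparently.  FASTQ qualities are kept as Phred+33 encoded strings in a
#' `qual` column.
#'
#' @param path File path (optionally `.gz`).
#' @param sequences Named character vector for `write_fasta()`.
#' @param reads Tibble with `id`, `seq` and (for FASTQ) `qual` columns.
#' @return `read_fasta()`: a named character vector of sequences.
#'   `read_fastq()`: a tibble with columns `id`, `seq`, `qual`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  check_records(ids, seqs)
  setNames(seqs, ids)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  check_records(names(sequences), sequences)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path,
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  check_records(ids, seqs)
  tibble(id = unname(ids), seq = unname(seqs),
         qual = unname(as.character(S4Vectors::mcols(set)$qualities)))
}

#' @rdname read_fasta
#' @export
write_fastq <- function(reads, path) {
  check_records(reads$id, reads$seq)
  stopifnot(all(nchar(reads$qual) == nchar(reads$seq)))
  qset <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual)
  )
  Biostrings::writeQualityScaledXStringSet(
    qset, path, compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

check_records <- function(ids, seqs) {
  if (any(!nzchar(ids)) || anyNA(ids)) abort("empty or missing record id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf("duplicate record id(s): %s", paste(head(dup, 3L), collapse = ", ")))
  }
  empty <- ids[!nzchar(seqs)]
  if (length(empty)) {
    abort(sprintf("empty sequence for record(s): %s", paste(head(empty, 3L), collapse = ", ")))
  }
  invisible(TRUE)
}

# Phred+33 string -> integer scores
phred_scores <- function(qual) lapply(qual, function(q) utf8ToInt(q) - 33L)

#' Quality/length read filter
#'
#' Keeps a read iff the fraction of its bases with Phred quality strictly
#' below `q_threshold` is at most `max_low_frac`, and its length is at least
#' `min_len`.  The defaults encode the standard amplicon cleaning rule used
#' for this pipeline: discard reads with Q < 30 at more than 3% of bases, or
#' shorter than 150 bp.
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` (Phred+33 strings),
#'   e.g. from [read_fastq()].
#' @param q_threshold Phred score defining a low-quality base (default 30).
#' @param max_low_frac Maximum tolerated fraction of low-quality bases
#'   (default 0.03).
#' @param min_len Minimum read length in nt (default 150).
#' @return The surviving rows of `reads`.
#' @export
filter_reads <- function(reads, q_threshold = 30, max_low_frac = 0.03,
                         min_len = 150) {
  if (!"qual" %in% names(reads) || anyNA(reads$qual)) {
    abort("reads must carry per-base qualities: the filter is quality-defined")
  }
  if (any(nchar(reads$qual) != nchar(reads$seq))) {
    abort("quality string length must equal sequence length")
  }
  low_frac <- vapply(
    phred_scores(reads$qual),
    function(q) mean(q < q_threshold),
    numeric(1)
  )
  keep <- low_frac <= max_low_frac & nchar(reads$seq) >= min_len
  reads[keep, , drop = FALSE]
}

#' Anchored primer trimming
#'
#' Matches one of the forward primers at the 5' end and the reverse
#' complement of the reverse primer at the 3' end, both anchored, allowing
#' IUPAC ambiguity codes in the primers and up to `max_mismatch` mismatches
#' per primer.  The defaults are the clade-specific pmoA primer set
#' (MPFpmo-F1/F2 and MPFpmo-R), whose 461-bp product leaves a 421-nt insert
#' after removing the two 20-nt primers.
#'
#' Primer absence is a valid outcome, not an error: unmatched reads get an
#' `NA` insert and are reported in the returned trim log columns.
#'
#' @param reads Tibble with `id` and `seq` columns.
#' @param forward Named character vector of candidate forward primers, tried
#'   in order.
#' @param reverse Reverse primer (as primer sequence; it is reverse
#'   complemented internally before matching the read's 3' end).
#' @param max_mismatch Maximum mismatches tolerated per primer (default 0).
#' @return `reads` with added columns `insert` (trimmed sequence or `NA`),
#'   `fwd_primer` (name of the matching forward primer or `NA`) and
#'   `trimmed` (logical).
#' @export
trim_primers <- function(reads,
                         forward = pmoa_primers()$forward,
                         reverse = pmoa_primers()$reverse,
                         max_mismatch = 0) {
  if (is.null(names(forward))) names(forward) <- paste0("F", seq_along(forward))
  rev_rc <- revcomp(reverse)
  out <- lapply(reads$seq, function(s) {
    n <- nchar(s)
    f_hit <- NA_character_
    f_len <- 0L
    for (f in names(forward)) {
      fp <- forward[[f]]
      if (n >= nchar(fp) &&
          iupac_mismatches(fp, substr(s, 1L, nchar(fp))) <= max_mismatch) {
        f_hit <- f
        f_len <- nchar(fp)
        break
      }
    }
    r_len <- nchar(rev_rc)
    r_ok <- n >= r_len &&
      iupac_mismatches(rev_rc, substr(s, n - r_len + 1L, n)) <= max_mismatch
    if (!is.na(f_hit) && r_ok && n > f_len + r_len) {
      list(insert = substr(s, f_len + 1L, n - r_len), fwd = f_hit)
    } else {
      list(insert = NA_character_, fwd = f_hit)
    }
  })
  reads$insert <- vapply(out, `[[`, "", "insert")
  reads$fwd_primer <- vapply(out, `[[`, "", "fwd")
  reads$trimmed <- !is.na(reads$insert)
  reads
}

#' The clade-targeted pmoA primer set
#'
#' The three primers designed for Methyloprofundus-clade pmoA amplification:
#' two forward primers (MPFpmo-F1, MPFpmo-F2) and one reverse (MPFpmo-R,
#' containing an IUPAC R).  They amplify a 461-bp product including primers,
#' i.e. a 421-nt insert.
#'
#' @return A list with elements `forward` (named character vector of two)
#'   and `reverse` (single string).
#' @export
pmoa_primers <- function() {
  list(
    forward = c(
      `MPFpmo-F1` = "ACTGTAGCGCCAATCGTATC",
      `MPFpmo-F2` = "ACTGTAGCGCCGATCGTTTC"
    ),
    reverse = "ACTGGAGCAACRTCTTTACC"
  )
}

# number of mismatching positions between an IUPAC pattern and a concrete
# subject of equal length; N in the subject only matches pattern N
iupac_mismatches <- function(pattern, subject) {
  pc <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  sc <- strsplit(toupper(subject), "", fixed = TRUE)[[1L]]
  stopifnot(length(pc) == length(sc))
  map <- Biostrings::IUPAC_CODE_MAP
  sum(!mapply(function(p, s) {
    s %in% strsplit(map[[p]], "")[[1L]]
  }, pc, sc))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Dereplicate trimmed reads into ASVs
#'
#' Collapses identical sequences into amplicon sequence variants with
#' per-sample counts.  This is exact dereplication: on error-free reads it
#' yields the same units as a denoiser; no error correction or chimera
#' removal is attempted.  ASV ids are assigned in order of descending total
#' count, ties broken by lexicographic sequence, so labels are reproducible.
#'
#' @param reads Tibble with columns `seq` and `sample`.
#' @param samples Optional sample metadata passed to [asv_table()].
#' @return An [asv_table].
#' @export
dereplicate <- function(reads, samples = NULL) {
  if (nrow(reads) == 0L) {
    return(asv_table(
      character(0),
      matrix(integer(0), 0, 0, dimnames = list(character(0), character(0))),
      tibble(sample = character(0), site = character(0), replicate = integer(0))
    ))
  }
  if (length(unique(nchar(reads$seq))) != 1L) {
    abort("reads must be trimmed to equal length before dereplication")
  }
  tab <- table(reads$seq, reads$sample)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  ord <- order(-rowSums(counts), rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  ids <- sprintf("ASV%04d", seq_len(nrow(counts)))
  seqs <- setNames(rownames(counts), ids)
  rownames(counts) <- ids
  asv_table(seqs, counts, samples)
}

#' Rarefy every sample to a fixed depth
#'
#' Subsamples each sample column without replacement to exactly `depth`
#' reads (the study design fixes 50,000 clade-assigned reads per sample so
#' diversity is comparable across samples).
#'
#' @param x An [asv_table].
#' @param depth Target reads per sample (default 50000).
#' @param seed Integer RNG seed.
#' @return An [asv_table] whose columns each sum to `depth`.
#' @export
subsample_counts <- function(x, depth = 50000, seed) {
  stopifnot(inherits(x, "asv_table"), depth >= 1)
  totals <- colSums(x$counts)
  short <- names(totals)[totals < depth]
  if (length(short)) {
    abort(sprintf(
      "sample(s) below the subsampling depth %d: %s",
      depth, paste(short, collapse = ", ")
    ))
  }
  counts <- local_seed(seed, {
    apply(x$counts, 2L, function(col) {
      drawn <- sample(rep.int(seq_along(col), col), depth, replace = FALSE)
      tabulate(drawn, nbins = length(col))
    })
  })
  counts <- matrix(as.integer(counts), nrow = nrow(x$counts),
                   dimnames = dimnames(x$counts))
  keep <- rowSums(counts) > 0L
  asv_table(x$sequences[keep], counts[keep, , drop = FALSE], x$samples)
}

#' Translate ASVs and collapse identical proteins
#'
#' Translates every ASV from the given frame with the standard genetic code
#' and groups ASVs whose translations are identical (the protein-level view
#' of the marker: synonymous ASVs collapse to one protein).  Internal stop
#' codons are flagged per ASV.  Protein ids follow descending member read
#' count, ties broken by lexicographic protein sequence.
#'
#' @param x An [asv_table].
#' @param frame Reading-frame offset 0, 1 or 2 (default 0; the forward
#'   primer preserves frame in pmoA).
#' @return A tibble with one row per ASV: `asv_id`, `protein_id`, `protein`,
#'   `internal_stop`.
#' @export
translate_collapse <- function(x, frame = 0) {
  stopifnot(inherits(x, "asv_table"))
  if (!frame %in% 0:2) abort("`frame` must be 0, 1 or 2")
  seqs <- substring(x$sequences, frame + 1L)
  seqs <- substr(seqs, 1L, (nchar(seqs) %/% 3L) * 3L)
  if (any(nchar(seqs) < 3L)) abort("sequences too short to translate in this frame")
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAStringSet(seqs),
    if.fuzzy.codon = "X"
  )))
  internal_stop <- grepl("\\*.", aa)
  per_asv <- tibble(
    asv_id = names(x$sequences), protein = unname(aa),
    internal_stop = internal_stop,
    total = rowSums(x$counts)[names(x$sequences)]
  )
  ord <- per_asv |>
    group_by(.data$protein) |>
    summarise(grand = sum(.data$total)) |>
    arrange(desc(.data$grand), .data$protein)
  ord$protein_id <- sprintf("P%04d", seq_len(nrow(ord)))
  per_asv |>
    left_join(ord[, c("protein", "protein_id")], by = "protein") |>
    select("asv_id", "protein_id", "protein", "internal_stop")
}
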