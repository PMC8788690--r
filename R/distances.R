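#' Evolutionary distances between equal-length marker sequences
#'
#' The amplicon model is alignment-free: all sequences must have identical
#' length (the clade marker region carries no indels), and any site where
#' either sequence has an `N` is dropped from both the mismatch count and the
#' number of compared sites (pairwise deletion).
#'
#' `p_distance()` is the proportion of differing compared sites.
#' `jc_correction()` applies the Jukes-Cantor multiple-hit correction
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3}p)}, which is undefined at
#' saturation (\eqn{p \ge 0.75}).  `jc_distance()` composes the two, and
#' `percent_identity()` returns \eqn{100(1 - p)}.
#'
#' @param x,y Nucleotide strings over `ACGTN`, same length.
#' @param p Observed proportion(s) of differing sites, in `[0, 0.75)`.
#' @return A length-one numeric (distance or percent identity).
#' @examples
#' p_distance("ACGT", "ACGA")
#' jc_correction(0.038952)   # ~0.04, the species-delineation threshold
#' @export
p_distance <- function(x, y) {
  m <- seq_matrix(c(x = x, y = y))
  mism_valid <- pair_mismatch(m[1L, ], m[2L, ])
  if (mism_valid[["valid"]] == 0L) {
    abort("no comparable sites: every position has an N in one of the sequences")
  }
  mism_valid[["mismatch"]] / mism_valid[["valid"]]
}

#' @rdname p_distance
#' @export
jc_correction <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) {
    abort("`p` must be a finite proportion in [0, 0.75)")
  }
  if (any(p >= 0.75)) {
    abort(
      "Jukes-Cantor distance is undefined at p >= 0.75 (saturation): the
       log argument 1 - 4p/3 is non-positive"
    )
  }
  -0.75 * log(1 - p * 4 / 3)
}

#' @rdname p_distance
#' @export
jc_distance <- function(x, y) jc_correction(p_distance(x, y))

#' @rdname p_distance
#' @export
percent_identity <- function(x, y) 100 * (1 - p_distance(x, y))

#' All pairwise distances for a set of sequences
#'
#' Computes the labeled symmetric matrix of p-distances or Jukes-Cantor
#' distances between every pair of equal-length sequences, with pairwise
#' deletion of `N` sites.
#'
#' @param sequences Named character vector of nucleotide sequences
#'   (`ACGTN`), all the same length.  Names become the matrix labels.
#' @param kind `"jc"` (default) or `"p"`.
#' @return A symmetric numeric matrix with zero diagonal and a `"kind"`
#'   attribute; dimnames are the sequence names.
#' @examples
#' pairwise_distances(c(a = "ACGTACGT", b = "ACGTACGA"), kind = "p")
#' @export
pairwise_distances <- function(sequences, kind = c("jc", "p")) {
  kind <- match.arg(kind)
  m <- seq_matrix(sequences)
  n <- nrow(m)
  valid <- !is.na(m)
  # mismatches via indicator products: matches = sum_b I_b I_b', compared
  # sites = V V'; avoids an O(n^2 L) interpreted loop
  num <- matrix(0, n, n)
  for (b in 1:4) {
    ib <- (!is.na(m)) & m == b
    mode(ib) <- "numeric"
    num <- num + tcrossprod(ib)
  }
  compared <- tcrossprod(valid * 1)
  if (n > 1 && any(compared[upper.tri(compared)] == 0)) {
    abort("some sequence pair shares no comparable (non-N) sites")
  }
  p <- (compared - num) / compared
  diag(p) <- 0
  d <- if (kind == "jc") {
    if (any(p[upper.tri(p)] >= 0.75)) {
      abort("Jukes-Cantor distance undefined: some pairs are saturated (p >= 0.75)")
    }
    jc_saturation_safe(p)
  } else {
    p
  }
  dimnames(d) <- list(names(sequences), names(sequences))
  attr(d, "kind") <- kind
  d
}

# jc on a matrix whose upper triangle was already checked; diagonal is 0
jc_saturation_safe <- function(p) -0.75 * log(1 - p * 4 / 3)

# Character sequences -> integer matrix (A=1, C=2, G=3, T=4, N=NA).
# Validates alphabet, equal lengths, and non-empty names when present.
seq_matrix <- function(sequences) {
  if (length(sequences) == 0L) abort("no sequences supplied")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    abort(sprintf(
      "sequences must all have the same length (alignment-free model); got lengths %s",
      paste(sort(unique(lens)), collapse = ", ")
    ))
  }
  chars <- matrix(
    unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
    nrow = length(sequences), byrow = TRUE
  )
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  out <- matrix(code[chars], nrow = nrow(chars))
  bad <- !(chars %in% c(names(code), "N"))
  if (any(bad)) {
    abort(sprintf(
      "sequences contain characters outside ACGTN: %s",
      paste(unique(chars[bad]), collapse = ", ")
    ))
  }
  rownames(out) <- names(sequences)
  out
}

# mismatch / compared-site count for two coded rows with NA = N
pair_mismatch <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  c(mismatch = sum(a[ok] != b[ok]), valid = sum(ok))
}
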