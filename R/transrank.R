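#' TPM normalization with optional upper-quartile scaling
#'
#' Converts aligned read counts to transcripts per million: per sample,
#' counts are optionally rescaled by an upper-quartile factor (the 75th
#' percentile of that sample's nonzero gene counts divided by the geometric
#' mean of those upper quartiles across samples), divided by gene length,
#' and normalized so every sample sums to 1e6.  Because TPM renormalizes
#' within each sample, the UQ factor leaves TPM itself unchanged; it is
#' retained in the exported `norm_count` column, where cross-sample
#' comparability matters.  With a single sample the UQ factor is identically
#' 1.
#'
#' @param counts Tibble with columns `gene_id`, `length_bp` and one integer
#'   count column per sample (e.g. from [simulate_expression_table()] or a
#'   TSV), or alternatively a gene-by-sample matrix plus `lengths`.
#' @param lengths Gene lengths in bp (only when `counts` is a matrix).
#' @param uq_adjust Apply upper-quartile scaling before the length/depth
#'   normalization (default `TRUE`).
#' @return A long tibble: `gene_id`, `length_bp`, `sample`, `count`,
#'   `norm_count`, `tpm`.  Within each sample, `tpm` sums to 1e6.
#' @examples
#' x <- tibble::tibble(gene_id = c("g1", "g2"), length_bp = c(100, 200),
#'                     s1 = c(10L, 10L))
#' tpm_normalize(x, uq_adjust = FALSE)   # TPM 666666.7 / 333333.3
#' @export
tpm_normalize <- function(counts, lengths = NULL, uq_adjust = TRUE) {
  if (is.matrix(counts)) {
    stopifnot(!is.null(lengths), length(lengths) == nrow(counts))
    counts <- bind_cols(
      tibble(gene_id = rownames(counts) %||% paste0("g", seq_len(nrow(counts))),
             length_bp = lengths),
      as_tibble(counts)
    )
  }
  stopifnot(all(c("gene_id", "length_bp") %in% names(counts)))
  if (any(counts$length_bp <= 0)) abort("gene lengths must be positive")
  sample_cols <- setdiff(names(counts), c("gene_id", "length_bp"))
  if (!length(sample_cols)) abort("no sample count columns found")
  mat <- as.matrix(counts[, sample_cols, drop = FALSE])
  if (any(mat < 0)) abort("counts must be non-negative")
  zero <- sample_cols[colSums(mat) == 0]
  if (length(zero)) {
    abort(sprintf("all-zero sample(s): %s", paste(zero, collapse = ", ")))
  }
  uq <- vapply(sample_cols, function(s) {
    x <- mat[, s]
    quantile(x[x > 0], 0.75, names = FALSE)
  }, numeric(1))
  factors <- if (uq_adjust) uq / exp(mean(log(uq))) else rep(1, length(uq))
  names(factors) <- sample_cols
  long <- counts |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols),
                        names_to = "sample", values_to = "count") |>
    mutate(norm_count = .data$count / unname(factors[.data$sample])) |>
    group_by(.data$sample) |>
    mutate(
      tpm = {
        rate <- .data$norm_count / .data$length_bp
        rate / sum(rate) * 1e6
      }
    ) |>
    ungroup()
  long
}

#' Inverse percentile rank transformation of TPM
#'
#' Within each sample, genes are ranked by descending TPM with average ranks
#' for ties.  Two derived scores are added: `top_percentile`
#' (\eqn{100 \cdot \mathrm{rank} / N}, in `(0, 100]`; small means highly
#' transcribed) and the inverse-percentile score `inv_score`
#' (\eqn{1 - \mathrm{rank} / N}), the rank-based quantity that stays
#' comparable across organisms and libraries because it is invariant to any
#' strictly monotone rescaling of TPM.
#'
#' @param tpm_table Long tibble from [tpm_normalize()] (needs `gene_id`,
#'   `sample`, `tpm`), or any tibble with those columns.
#' @return The input with added columns `top_percentile` and `inv_score`.
#' @export
rank_transform <- function(tpm_table) {
  stopifnot(all(c("gene_id", "sample", "tpm") %in% names(tpm_table)))
  tpm_table |>
    group_by(.data$sample) |>
    mutate(
      top_percentile = 100 * rank(-.data$tpm) / n(),
      inv_score = 1 - rank(-.data$tpm) / n()
    ) |>
    ungroup()
}

transcription_levels <- c("extremely high", "very high", "high",
                          "moderate", "low", "very low")

#' Six-level transcription category from the top percentile
#'
#' Maps a gene's top-percentile rank to one of six ordered transcription
#' levels: top 1% extremely high; 1–5% very high; 5–15% high; 15–30%
#' moderate; 30–50% low; bottom 50% very low.  (The very-high and high
#' bands each merge two finer ranking bands — 3%+5% and 10%+15% — to keep
#' the overview readable.)  Band boundaries are closed on the right.
#'
#' @param top_percentile Numeric vector in `(0, 100]`, e.g. from
#'   [rank_transform()].
#' @return An ordered factor with levels from `"extremely high"` down to
#'   `"very low"`.
#' @examples
#' categorize_transcription(c(0.5, 4, 60))
#' @export
categorize_transcription <- function(top_percentile) {
  if (any(is.na(top_percentile)) || any(top_percentile <= 0) ||
      any(top_percentile > 100)) {
    abort("`top_percentile` must lie in (0, 100]")
  }
  x <- cut(top_percentile, breaks = c(0, 1, 5, 15, 30, 50, 100),
           labels = transcription_levels, right = TRUE)
  # order levels so "extremely high" compares greatest, not first
  factor(x, levels = rev(transcription_levels), ordered = TRUE)
}

#' Dominant gene of a homolog group
#'
#' For enzymes encoded by homologs or multi-gene complexes, the
#' transcription level displayed for the group is that of its most highly
#' transcribed (catalytic-subunit) member in each sample; ties are broken by
#' lexicographically smallest gene id and reported.
#'
#' @param tpm_table Long tibble with `gene_id`, `sample`, `tpm` and a
#'   homolog-group column.
#' @param group_col Name of the homolog-group column (default
#'   `"homolog_group"`).
#' @return A tibble with one row per group and sample: group column,
#'   `sample`, `gene_id` (the dominant member), `tpm`, `tie` (logical).
#' @export
dominant_homolog <- function(tpm_table, group_col = "homolog_group") {
  stopifnot(group_col %in% names(tpm_table))
  if (nrow(tpm_table) == 0L) abort("empty homolog table")
  out <- tpm_table |>
    group_by(.data[[group_col]], .data$sample) |>
    arrange(desc(.data$tpm), .data$gene_id, .by_group = TRUE) |>
    summarise(
      # `tie` must be computed before `tpm` is overwritten by the scalar below
      tie = sum(.data$tpm == max(.data$tpm)) > 1L,
      gene_id = .data$gene_id[1L], tpm = .data$tpm[1L],
      .groups = "drop"
    ) |>
    select(dplyr::all_of(group_col), "sample", "gene_id", "tpm", "tie")
  if (any(out$tie)) {
    inform(sprintf(
      "%d homolog group/sample pairs had tied maximal TPM; lexicographically first gene kept",
      sum(out$tie)
    ))
  }
  out
}

#' Compare rank profiles of a gene set across samples
#'
#' Tests whether a fixed gene set (e.g. the 53 ribosomal protein genes used
#' as an activity proxy) is transcribed at systematically different rank
#' levels between samples.  Genes are blocks: a Friedman test
#' (chi-square, `n_samples - 1` df) on the inverse-percentile scores is
#' followed by one-sided Wilcoxon signed-rank tests on per-gene score
#' differences for every ordered sample pair, Bonferroni-adjusted over the
#' unordered pairs.  Exact signed-rank p-values are used whenever the
#' number of non-zero differences permits (no ties/zeros), the normal
#' approximation otherwise.
#'
#' @param scores Long tibble with `gene_id`, `sample`, `inv_score` (e.g.
#'   [rank_transform()] output filtered to the gene set).
#' @param alpha Family-wise significance level (default 0.05).
#' @return An object of class `rank_comparison`: list with `friedman`
#'   (one-row tibble) and `pairwise` (tibble with both one-sided directions
#'   per pair: `higher`, `lower`, `statistic`, `p_raw`, `p_adj`,
#'   `significant`).  With exactly two samples the Friedman row is `NA` and
#'   only the Wilcoxon pair is reported.
#' @export
compare_rank_profiles <- function(scores, alpha = 0.05) {
  stopifnot(all(c("gene_id", "sample", "inv_score") %in% names(scores)))
  wide <- scores |>
    select("gene_id", "sample", "inv_score") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "inv_score")
  if (any(!complete.cases(wide))) {
    abort("every gene in the set must be scored in every sample")
  }
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  n_samp <- ncol(m)
  if (n_samp < 2L) abort("need at least two samples")
  friedman <- if (n_samp >= 3L) {
    ft <- friedman.test(m)
    stat <- unname(ft$statistic)
    p <- ft$p.value
    if (is.nan(stat) && all(m == m[, 1L])) {
      # fully tied blocks carry no rank information: chi-square 0 by convention
      stat <- 0
      p <- 1
    }
    tibble(statistic = stat, df = unname(ft$parameter), p_value = p)
  } else {
    tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  }
  pairs <- utils::combn(colnames(m), 2L)
  n_pairs <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    a <- pairs[1L, i]
    b <- pairs[2L, i]
    purrr::map_dfr(list(c(a, b), c(b, a)), function(dir) {
      if (all(m[, dir[1L]] == m[, dir[2L]])) {
        # identical profiles: no non-zero differences for the signed-rank test
        return(tibble(higher = dir[1L], lower = dir[2L],
                      statistic = 0, p_raw = 1))
      }
      wt <- suppressWarnings(
        wilcox.test(m[, dir[1L]], m[, dir[2L]], paired = TRUE,
                    alternative = "greater")
      )
      tibble(higher = dir[1L], lower = dir[2L],
             statistic = unname(wt$statistic), p_raw = wt$p.value)
    })
  })
  pw <- mutate(pw,
               p_adj = pmin(1, .data$p_raw * n_pairs),
               significant = .data$p_adj < alpha)
  structure(
    list(friedman = friedman, pairwise = pw, alpha = alpha,
         n_pairs = n_pairs, n_genes = nrow(m)),
    class = "rank_comparison"
  )
}

#' @export
print.rank_comparison <- function(x, ...) {
  if (!is.na(x$friedman$statistic)) {
    cat(sprintf("Friedman chi-square = %.4f, df = %d, p = %.4g (%d genes)\n",
                x$friedman$statistic, x$friedman$df, x$friedman$p_value,
                x$n_genes))
  }
  cat(sprintf("One-sided Wilcoxon signed-rank pairs (Bonferroni over %d pairs):\n",
              x$n_pairs))
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_rank_profiles
#' @param x A `rank_comparison`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rank_comparison <- function(x, ...) x$pairwise

#' @rdname compare_rank_profiles
#' @exportS3Method generics::glance
glance.rank_comparison <- function(x, ...) x$friedman
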