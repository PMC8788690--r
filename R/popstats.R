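#' Alpha diversity of species-like-group populations
#'
#' Per-sample observed richness, bias-corrected Chao1, Shannon entropy
#' (nats) and Gini-Simpson index, computed on group-level counts:
#' \deqn{H = -\sum p_i \ln p_i, \quad D = 1 - \sum p_i^2, \quad
#'   \mathrm{Chao1} = S_{obs} + \frac{F_1 (F_1 - 1)}{2 (F_2 + 1)}}
#' where \eqn{F_1, F_2} are the numbers of groups observed exactly once and
#' twice.  Singleton/doubleton counts are retained for audit.  Chao1 needs
#' raw counts, so relative abundances are not accepted.
#'
#' @param counts Group-by-sample matrix of non-negative integer counts
#'   (e.g. from [group_counts()]), or a long tibble with columns
#'   `group_id`, `sample`, `count`.
#' @param chao1_variant `"bias-corrected"` (default) or `"classic"`
#'   (\eqn{S_{obs} + F_1^2 / (2 F_2)}; undefined with no doubletons, where
#'   the bias-corrected form is used instead).
#' @param shannon_base Base of the Shannon logarithm (default `exp(1)`,
#'   i.e. nats).
#' @return A tibble with one row per sample: `sample`, `s_obs`, `f1`, `f2`,
#'   `chao1`, `shannon`, `simpson`.
#' @examples
#' m <- cbind(a = c(5, 3, 1, 1, 2))
#' rownames(m) <- paste0("G", 1:5)
#' alpha_diversity(m)   # chao1 = 5.5
#' @export
alpha_diversity <- function(counts, chao1_variant = c("bias-corrected", "classic"),
                            shannon_base = exp(1)) {
  chao1_variant <- match.arg(chao1_variant)
  if (is.data.frame(counts)) {
    counts <- tidyr::pivot_wider(counts, names_from = "sample",
                                 values_from = "count", values_fill = 0L)
    m <- as.matrix(counts[, -1, drop = FALSE])
    rownames(m) <- counts[[1L]]
    counts <- m
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("alpha diversity needs non-negative integer group counts")
  }
  zero <- colnames(counts)[colSums(counts) == 0]
  if (length(zero)) {
    abort(sprintf("all-zero sample(s): %s", paste(zero, collapse = ", ")))
  }
  purrr::map_dfr(colnames(counts), function(s) {
    x <- counts[, s]
    x <- x[x > 0]
    p <- x / sum(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    chao1 <- if (chao1_variant == "classic" && f2 > 0) {
      length(x) + f1^2 / (2 * f2)
    } else {
      length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
    }
    tibble(
      sample = s, s_obs = length(x), f1 = f1, f2 = f2, chao1 = chao1,
      shannon = -sum(p * log(p, base = shannon_base)),
      simpson = 1 - sum(p^2)
    )
  })
}

#' Nonparametric cross-site comparison of a diversity index
#'
#' Kruskal-Wallis test (tie-corrected, chi-square approximation with
#' `n_sites - 1` degrees of freedom) across sites, followed by Dunn's
#' post hoc z tests on all site pairs with Bonferroni adjustment
#' (`p_adj = min(1, p_raw * n_pairs)`).  Significance level defaults
#' to 0.05.
#'
#' @param data Data frame with one diversity value per sample.
#' @param value,site Column names (strings) of the index value and the site
#'   factor (defaults `"value"`, `"site"`).
#' @param alpha Family-wise significance level (default 0.05).
#' @param p_method How the omnibus p-value is computed: `"asymptotic"`
#'   (chi-square, the default) or `"permutation"` (Monte Carlo permutation of
#'   site labels, recommended for very small replicate counts where the
#'   chi-square approximation is conservative;
#'   \eqn{p = (1 + \#\{H^* \ge H\}) / (n_{perm} + 1)}).
#' @param n_perm,perm_seed Number of label permutations and RNG seed used
#'   when `p_method = "permutation"`.
#' @return An object of class `alpha_comparison`: list with `kw` (one-row
#'   tibble: `statistic`, `df`, `p_value`) and `pairwise` (tibble per site
#'   pair: `site1`, `site2`, `z`, `p_raw`, `p_adj`, `significant`), plus
#'   `alpha` and `n_pairs`.  `tidy()` returns the pairwise table,
#'   `glance()` the omnibus row.
#' @export
compare_alpha <- function(data, value = "value", site = "site", alpha = 0.05,
                          p_method = c("asymptotic", "permutation"),
                          n_perm = 9999, perm_seed = 1) {
  p_method <- match.arg(p_method)
  v <- data[[value]]
  g <- factor(data[[site]])
  if (nlevels(g) < 2L) abort("need at least two sites")
  small <- names(table(g))[table(g) < 2L]
  if (length(small)) {
    abort(sprintf("site(s) with fewer than 2 values: %s", paste(small, collapse = ", ")))
  }
  kw <- kruskal.test(v, g)
  kw_stat <- unname(kw$statistic)
  kw_p <- kw$p.value
  if (is.nan(kw_stat) && length(unique(v)) == 1L) {
    # fully tied data carry no rank information: H = 0 by convention
    kw_stat <- 0
    kw_p <- 1
  } else if (p_method == "permutation") {
    kw_p <- kw_permutation_p(v, g, kw_stat, n_perm, perm_seed)
  }
  # Dunn's test: z from mean ranks with tie-corrected pooled variance
  n <- length(v)
  r <- rank(v)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  var_base <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  mean_rank <- tapply(r, g, mean)
  sizes <- table(g)
  pairs <- utils::combn(levels(g), 2L)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]
    b <- pairs[2L, i]
    se <- sqrt(var_base * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z <- if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
    tibble(site1 = a, site2 = b, z = z, p_raw = 2 * pnorm(-abs(z)))
  })
  m <- nrow(pw)
  pw <- mutate(pw,
               p_adj = pmin(1, .data$p_raw * m),
               significant = .data$p_adj < alpha)
  structure(
    list(
      kw = tibble(statistic = kw_stat, df = unname(kw$parameter),
                  p_value = kw_p),
      pairwise = pw, alpha = alpha, n_pairs = m,
      per_pair_threshold = alpha / m
    ),
    class = "alpha_comparison"
  )
}

# Monte Carlo permutation p-value for the Kruskal-Wallis H.  H depends on
# the data only through the ranks, and the tie pattern is invariant under
# label permutation, so permuting the rank vector across the fixed group
# layout samples the exact conditional null.
kw_permutation_p <- function(v, g, h_obs, n_perm, perm_seed) {
  r <- rank(v)
  n <- length(v)
  sizes <- as.integer(table(g))
  ties <- table(r)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  local_seed(perm_seed, {
    perm <- vapply(seq_len(n_perm), function(i) sample(r), numeric(n))
    sums <- rowsum(perm, g)                      # group rank sums per permutation
    h <- (12 / (n * (n + 1)) * colSums(sums^2 / sizes) - 3 * (n + 1)) / correction
    (1 + sum(h >= h_obs - 1e-12)) / (n_perm + 1)
  })
}

#' @export
print.alpha_comparison <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis H = %.4f, df = %d, p = %.4g\nDunn pairs (Bonferroni over %d pairs, alpha %.3g):\n",
    x$kw$statistic, x$kw$df, x$kw$p_value, x$n_pairs, x$alpha
  ))
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_alpha
#' @param x An `alpha_comparison` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.alpha_comparison <- function(x, ...) x$pairwise

#' @rdname compare_alpha
#' @exportS3Method generics::glance
glance.alpha_comparison <- function(x, ...) x$kw

#' Biofilm doubling time from protein accumulation
#'
#' Estimates exponential growth by least squares on \eqn{\ln(\text{protein})}
#' versus time; doubling time is \eqn{\ln 2 / b} for slope \eqn{b}.  A
#' non-positive slope means no measurable growth and yields an `NA` doubling
#' time with `growing = FALSE`.
#'
#' @param data Data frame of time-course protein measurements.
#' @param time,protein Column names (strings) for time (days) and protein
#'   amount (any mass unit, strictly positive).
#' @return A one-row tibble: `rate` (per day), `doubling_time` (days),
#'   `r_squared`, `n`, `growing`.
#' @examples
#' doubling_time(data.frame(t = c(0, 5.2, 10.4), p = c(1, 2, 4)),
#'               time = "t", protein = "p")
#' @export
doubling_time <- function(data, time = "time", protein = "protein") {
  t <- data[[time]]
  p <- data[[protein]]
  if (length(t) < 3L) abort("need at least three time points")
  if (any(p <= 0)) abort("protein amounts must be strictly positive")
  fit <- lm(log(p) ~ t)
  b <- unname(coef(fit)[2L])
  # exactly exponential input is legitimate; summary.lm warns on zero residuals
  r2 <- suppressWarnings(summary(fit))$r.squared
  growing <- b > 0
  tibble(
    rate = b,
    doubling_time = if (growing) log(2) / b else NA_real_,
    r_squared = r2, n = length(t), growing = growing
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (1 = identical partitions, ~0 = random agreement).  Used to score how
#' well recovered species-like groups match a simulation's ground truth.
#'
#' @param a,b Vectors of cluster labels over the same items (same length and
#'   order).
#' @return The adjusted Rand index, a number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(length(a))
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
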