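#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} over group
#' abundances, via `vegan::vegdist`.
#'
#' @param comp Either a group-by-sample abundance matrix, or a long tibble
#'   (`group_id`, `sample` or `site`, `abundance`) as returned by
#'   [composition_matrix()].
#' @return A labeled symmetric sample-by-sample matrix in `[0, 1]` with a
#'   `"kind"` attribute of `"bray-curtis"`.
#' @export
bray_curtis <- function(comp) {
  if (is.data.frame(comp)) {
    unit <- intersect(c("sample", "site"), names(comp))[1L]
    if (is.na(unit)) abort("long input needs a `sample` or `site` column")
    comp <- tidyr::pivot_wider(comp[, c("group_id", unit, "abundance")],
                               names_from = dplyr::all_of(unit),
                               values_from = "abundance", values_fill = 0)
    m <- as.matrix(comp[, -1, drop = FALSE])
    rownames(m) <- comp[[1L]]
    comp <- m
  }
  if (any(comp < 0)) abort("abundances must be non-negative")
  zero <- colnames(comp)[colSums(comp) == 0]
  if (length(zero)) {
    abort(sprintf("all-zero sample(s): %s", paste(zero, collapse = ", ")))
  }
  d <- as.matrix(vegan::vegdist(t(comp), method = "bray"))
  attr(d, "kind") <- "bray-curtis"
  d
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds samples in `k` dimensions by minimizing Kruskal's stress-1
#' \deqn{\sigma_1 = \sqrt{\sum_{i<j} (\hat d_{ij} - \theta_{ij})^2 /
#'   \sum_{i<j} \hat d_{ij}^2}}
#' where \eqn{\hat d} are configuration distances and \eqn{\theta} is the
#' isotonic (monotone non-decreasing, pool-adjacent-violators) regression of
#' \eqn{\hat d} on the rank order of the input dissimilarities (weak
#' treatment of ties).  Each start alternates the isotonic fit with a
#' Guttman-transform configuration update; an update that would increase
#' stress is rejected, so the stress trace within a start is non-increasing.
#' The first start is the classical metric-scaling (principal-coordinate)
#' configuration, the rest are random; the best of `n_starts` is returned.
#'
#' @param dm Symmetric dissimilarity matrix with at least `k + 2` points.
#' @param k Embedding dimension (default 2).
#' @param n_starts Number of initializations (default 20).
#' @param max_iter Iteration cap per start (default 500).
#' @param tol Stress-decrease convergence tolerance (default 1e-7).
#' @param seed Integer RNG seed for the random starts.
#' @return An object of class `nmds_fit`: list with `points` (tibble
#'   `sample`, `NMDS1`, ..., centered at the origin), `stress`, `converged`,
#'   `n_starts`, `k`, `seed`, and `trace` (stress per iteration of the best
#'   start).  `tidy()` returns the coordinates, `glance()` the fit summary.
#' @export
nmds_embed <- function(dm, k = 2, n_starts = 20, max_iter = 500,
                       tol = 1e-7, seed) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (k >= n - 1L) abort("`k` must be smaller than n - 1")
  if (any(!is.finite(dm))) abort("dissimilarities must be finite")
  if (max(abs(dm - t(dm))) > 1e-12) abort("dissimilarity matrix must be symmetric")
  labels <- rownames(dm) %||% paste0("s", seq_len(n))
  low <- lower.tri(dm)
  d <- dm[low]
  scale0 <- max(d)
  starts <- local_seed(seed, {
    c(
      list(cmdscale_start(dm, k)),
      lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
        matrix(runif(n * k, -0.5, 0.5) * scale0, n, k)
      })
    )
  })
  runs <- lapply(starts, function(X0) {
    nmds_one_start(X0, d, low, n, max_iter, tol)
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "stress"))]]
  X <- best$X
  X <- sweep(X, 2L, colMeans(X))
  pts <- as_tibble(setNames(as.data.frame(X), paste0("NMDS", seq_len(k))))
  pts <- bind_cols(tibble(sample = labels), pts)
  structure(
    list(points = pts, stress = best$stress, converged = best$converged,
         trace = best$trace, n_starts = n_starts, k = k, seed = seed),
    class = "nmds_fit"
  )
}

cmdscale_start <- function(dm, k) {
  X <- suppressWarnings(cmdscale(dm, k = k))
  if (ncol(X) < k) X <- cbind(X, matrix(0, nrow(X), k - ncol(X)))
  X
}

nmds_one_start <- function(X, d, low, n, max_iter, tol) {
  prev_stress <- Inf
  prev_X <- X
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    D <- as.matrix(dist(X))[low]
    theta <- isotonic_fit(d, D)
    s <- sqrt(sum((D - theta)^2) / sum(D^2))
    if (s > prev_stress + 1e-15) {
      # an update that worsened stress: keep the previous configuration
      X <- prev_X
      s <- prev_stress
      break
    }
    trace <- c(trace, s)
    if (prev_stress - s < tol) {
      converged <- TRUE
      break
    }
    prev_stress <- s
    prev_X <- X
    X <- guttman_update(X, d, theta, low, n)
  }
  list(X = X, stress = if (length(trace)) min(trace) else s,
       trace = trace, converged = converged)
}

# isotonic regression of configuration distances D on the rank order of the
# dissimilarities d; weak (primary) handling of ties: tied d are ordered by
# D so PAVA never forces equality inside a tie block
isotonic_fit <- function(d, D) {
  ord <- order(d, D)
  fit <- isoreg(D[ord])$yf
  theta <- numeric(length(d))
  theta[ord] <- fit
  theta
}

# one Guttman-transform step towards the fitted disparities theta
guttman_update <- function(X, d, theta, low, n) {
  Dm <- as.matrix(dist(X))
  Th <- matrix(0, n, n)
  Th[low] <- theta
  Th <- Th + t(Th)
  ratio <- ifelse(Dm > 0, Th / Dm, 0)
  B <- -ratio
  diag(B) <- rowSums(ratio)
  (B %*% X) / n
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf(
    "<nmds_fit> %d points in %d dims; stress-1 = %.4g (%s, best of %d starts)\n",
    nrow(x$points), x$k, x$stress,
    if (x$converged) "converged" else "not converged", x$n_starts
  ))
  invisible(x)
}

#' @rdname nmds_embed
#' @param x,object An `nmds_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nmds_fit <- function(x, ...) x$points

#' @rdname nmds_embed
#' @exportS3Method generics::glance
glance.nmds_fit <- function(x, ...) {
  tibble(stress = x$stress, converged = x$converged,
         n_starts = x$n_starts, k = x$k, n_iter = length(x$trace))
}

#' Per-site confidence ellipses for an NMDS configuration
#'
#' Computes 95% (by default) covariance-ellipse parameters over the
#' replicate points of each site — the numbers behind the ellipses usually
#' drawn on clade-population NMDS plots.
#'
#' @param fit An `nmds_fit` with `k = 2`.
#' @param meta Data frame with columns `sample` and `site`.
#' @param conf Confidence level (default 0.95).
#' @return A tibble per site: `site`, `x0`, `y0` (center), `r1`, `r2`
#'   (semi-axes), `angle` (radians of the major axis).
#' @export
nmds_ellipses <- function(fit, meta, conf = 0.95) {
  stopifnot(fit$k == 2L)
  pts <- left_join(fit$points, as_tibble(meta)[, c("sample", "site")],
                   by = "sample")
  q <- qchisq(conf, df = 2)
  pts |>
    group_by(.data$site) |>
    summarise(
      x0 = mean(.data$NMDS1), y0 = mean(.data$NMDS2),
      {
        v <- cov(cbind(.data$NMDS1, .data$NMDS2))
        e <- eigen(v, symmetric = TRUE)
        tibble(r1 = sqrt(pmax(e$values[1L], 0) * q),
               r2 = sqrt(pmax(e$values[2L], 0) * q),
               angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]))
      },
      .groups = "drop"
    )
}
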