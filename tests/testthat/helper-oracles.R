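# Independent oracles and small fixture builders used across the suite.

# Brute-force p-distance between two equal-length strings (character loop,
# independent of the package's matrix kernel).
oracle_p <- function(x, y) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  ok <- a != "N" & b != "N"
  sum(a[ok] != b[ok]) / sum(ok)
}

oracle_jc <- function(x, y) -0.75 * log(1 - 4 * oracle_p(x, y) / 3)

# Random unrooted binary tree with positive branch lengths and its additive
# (path-length) distance matrix; the NJ reconstruction oracle.
random_additive_case <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, br = function(n) runif(n, 0.05, 0.5))
  tr <- ape::unroot(tr)
  dm <- cophenetic(tr)
  dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
  list(tree = tr, dm = dm)
}

# Exact null distribution of the one-sided Wilcoxon signed-rank statistic
# W+ for n untied pairs, by dynamic-programming convolution over the 2^n
# equally likely sign assignments.  Returns P(W+ >= w).
signrank_tail_exact <- function(w, n) {
  max_w <- n * (n + 1) / 2
  f <- c(1, rep(0, max_w))          # f[k+1] = #assignments with W+ = k
  for (i in seq_len(n)) {
    g <- f
    g[(i + 1):(max_w + 1)] <- g[(i + 1):(max_w + 1)] + f[1:(max_w - i + 1)]
    f <- g
  }
  sum(f[(w + 1):(max_w + 1)]) / 2^n
}

# Hand computation of the tie-corrected Kruskal-Wallis statistic.
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Hand computation of the Friedman chi-square (no within-block ties).
oracle_friedman <- function(m) {
  ranks <- t(apply(m, 1, rank))
  k <- ncol(m)
  n <- nrow(m)
  12 / (n * k * (k + 1)) * sum(colSums(ranks)^2) - 3 * n * (k + 1)
}

# FASTQ-style read tibble with uniform quality q over a given sequence.
make_read <- function(id, seq, q = 40, sample = "s1") {
  tibble::tibble(
    id = id, seq = seq,
    qual = strrep(intToUtf8(q + 33), nchar(seq)),
    sample = sample
  )
}

# Default-design synthetic community, one call per seed.
recovery_run <- function(seed, criteria = c("tree-clade", "complete",
                                            "single", "average")) {
  com <- simulate_community(seed = seed)
  dm <- pairwise_distances(com$table$sequences, "jc")
  tr <- nj_tree(dm, "bionj")
  truth <- com$truth$species_id[match(rownames(dm), com$truth$asv_id)]
  parts <- lapply(criteria, function(cr) {
    g <- cut_into_groups(tr, dm, 0.04, cr)
    g$group_id[match(rownames(dm), g$asv_id)]
  })
  names(parts) <- criteria
  list(truth = truth, parts = parts,
       n_groups = vapply(parts, function(p) length(unique(p)), integer(1)),
       ari = vapply(parts, function(p) adjusted_rand_index(p, truth), numeric(1)))
}
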