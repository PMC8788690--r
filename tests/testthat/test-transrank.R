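test_that("TPM matches the closed form and always sums to 1e6", {
  x <- tibble::tibble(gene_id = c("g1", "g2"), length_bp = c(100, 200),
                      s1 = c(10L, 10L))
  tpm <- tpm_normalize(x, uq_adjust = FALSE)
  expect_equal(tpm$tpm, c(2e6 / 3, 1e6 / 3))
  expect_equal(sum(tpm$tpm), 1e6)

  # multi-sample: each column sums to 1e6 and UQ scaling cannot change TPM
  set.seed(3)
  y <- tibble::tibble(
    gene_id = paste0("g", 1:50), length_bp = sample(300:3000, 50),
    a = rpois(50, 40L), b = rpois(50, 400L), c = rpois(50, 4L)
  )
  y[y == 0] <- 1L
  t_raw <- tpm_normalize(y, uq_adjust = FALSE)
  t_uq <- tpm_normalize(y, uq_adjust = TRUE)
  sums <- tapply(t_uq$tpm, t_uq$sample, sum)
  expect_true(all(abs(sums - 1e6) < 1e-6))
  expect_equal(t_uq$tpm, t_raw$tpm)
  # but norm_count does change, and the UQ factors multiply to 1 geometrically
  expect_false(isTRUE(all.equal(t_uq$norm_count, t_raw$norm_count)))

  # single sample: UQ factor is 1, norm_count equals count
  one <- tpm_normalize(x, uq_adjust = TRUE)
  expect_equal(one$norm_count, one$count)

  # matrix interface agrees with the tibble interface
  m <- as.matrix(y[, c("a", "b", "c")])
  rownames(m) <- y$gene_id
  tm <- tpm_normalize(m, lengths = y$length_bp, uq_adjust = FALSE)
  expect_equal(dplyr::arrange(tm, gene_id, sample)$tpm,
               dplyr::arrange(t_raw, gene_id, sample)$tpm)

  expect_error(tpm_normalize(tibble::tibble(gene_id = "g", length_bp = 0,
                                            s = 1L)), "positive")
  expect_error(tpm_normalize(tibble::tibble(gene_id = "g", length_bp = 10,
                                            s = 0L)), "all-zero")
})

test_that("rank transform uses average ties and descending TPM", {
  tab <- tibble::tibble(
    gene_id = paste0("g", 1:4), sample = "s1",
    tpm = c(100, 50, 50, 10)
  )
  r <- rank_transform(tab)
  # ranks 1, 2.5, 2.5, 4 of N = 4
  expect_equal(r$top_percentile, c(25, 62.5, 62.5, 100))
  expect_equal(r$inv_score, 1 - c(1, 2.5, 2.5, 4) / 4)

  # all-tied sample: every gene at the average rank
  flat <- tibble::tibble(gene_id = paste0("g", 1:10), sample = "s",
                         tpm = rep(7, 10))
  rf <- rank_transform(flat)
  expect_true(all(rf$top_percentile == 55))
})

test_that("rank scores are invariant to strictly monotone TPM rescaling", {
  set.seed(14)
  tab <- tibble::tibble(gene_id = paste0("g", 1:100), sample = "s1",
                        tpm = rlnorm(100))
  r1 <- rank_transform(tab)
  tab2 <- dplyr::mutate(tab, tpm = log1p(tpm)^3 + 5)
  r2 <- rank_transform(tab2)
  expect_equal(r1$top_percentile, r2$top_percentile)
  expect_equal(r1$inv_score, r2$inv_score)
})

test_that("transcription categories cut at the six published band edges", {
  expect_equal(
    as.character(categorize_transcription(c(0.5, 4, 60))),
    c("extremely high", "very high", "very low")
  )
  # right-closed boundaries: 1, 5, 15, 30, 50, 100 fall in the upper band
  expect_equal(
    as.character(categorize_transcription(c(1, 5, 15, 30, 50, 100))),
    c("extremely high", "very high", "high", "moderate", "low", "very low")
  )
  lv <- categorize_transcription(c(2, 80))
  expect_s3_class(lv, "ordered")
  expect_true(lv[1] > lv[2])   # "very high" outranks "very low"
  expect_error(categorize_transcription(c(0, 50)), "\\(0, 100\\]")
  expect_error(categorize_transcription(101), "\\(0, 100\\]")
})

test_that("category counts on N = 1000 distinct genes match band widths", {
  set.seed(4)
  tab <- tibble::tibble(gene_id = paste0("g", 1:1000), sample = "s1",
                        tpm = sample(seq_len(1000)))
  r <- rank_transform(tab)
  counts <- table(categorize_transcription(r$top_percentile))
  expect_equal(
    as.integer(counts[c("extremely high", "very high", "high",
                        "moderate", "low", "very low")]),
    c(10L, 40L, 100L, 150L, 200L, 500L)
  )
})

test_that("dominant_homolog picks the argmax and reports ties", {
  tab <- tibble::tibble(
    gene_id = c("pmoA1", "pmoA2", "mdh1", "mdh2"),
    homolog_group = c("pmoA", "pmoA", "mdh", "mdh"),
    sample = "s1",
    tpm = c(300, 120, 50, 50)
  )
  expect_message(out <- dominant_homolog(tab), "tied")
  expect_equal(out$gene_id[out$homolog_group == "pmoA"], "pmoA1")
  expect_equal(out$tpm[out$homolog_group == "pmoA"], 300)
  # the tie resolves to the lexicographically first gene and is flagged
  expect_equal(out$gene_id[out$homolog_group == "mdh"], "mdh1")
  expect_true(out$tie[out$homolog_group == "mdh"])
  expect_false(out$tie[out$homolog_group == "pmoA"])
  expect_error(dominant_homolog(tab[0, ]), "empty")
})

test_that("the Friedman omnibus matches the hand formula", {
  set.seed(26)
  n_genes <- 15
  scores <- tidyr::expand_grid(gene_id = paste0("g", 1:n_genes),
                               sample = c("a", "b", "c"))
  scores$inv_score <- runif(nrow(scores))
  cmp <- compare_rank_profiles(scores)
  m <- matrix(scores$inv_score[order(scores$sample, scores$gene_id)],
              n_genes, 3,
              dimnames = list(paste0("g", 1:n_genes), c("a", "b", "c")))
  expect_equal(glance(cmp)$statistic, oracle_friedman(m))
  expect_equal(glance(cmp)$df, 2L)
  expect_equal(glance(cmp)$p_value,
               pchisq(oracle_friedman(m), 2, lower.tail = FALSE))
  # both one-sided directions reported per pair
  expect_equal(nrow(tidy(cmp)), 6L)
})

test_that("exact one-sided signed-rank p-values match the DP oracle", {
  set.seed(31)
  for (n in c(8, 12, 20)) {
    diffs <- round(rnorm(n), 6)
    base <- runif(n)
    scores <- dplyr::bind_rows(
      tibble::tibble(gene_id = paste0("g", 1:n), sample = "a",
                     inv_score = base + diffs),
      tibble::tibble(gene_id = paste0("g", 1:n), sample = "b",
                     inv_score = base)
    )
    cmp <- compare_rank_profiles(scores)
    row <- tidy(cmp)[tidy(cmp)$higher == "a", ]
    w <- sum(rank(abs(diffs))[diffs > 0])
    expect_equal(row$statistic, w)
    expect_equal(row$p_raw, signrank_tail_exact(w, n))
  }
})

test_that("identical samples give zero Friedman signal and p = 1 pairs", {
  scores <- tidyr::expand_grid(gene_id = paste0("g", 1:10),
                               sample = c("a", "b", "c"))
  scores$inv_score <- rep(seq(0.05, 0.95, length.out = 10), each = 3)
  cmp <- compare_rank_profiles(scores)
  expect_equal(glance(cmp)$statistic, 0)
  expect_false(any(tidy(cmp)$significant))
})

test_that("a uniformly shifted sample is detected one-sidedly", {
  set.seed(44)
  base <- runif(30, 0.2, 0.8)
  scores <- dplyr::bind_rows(
    tibble::tibble(gene_id = paste0("g", 1:30), sample = "high",
                   inv_score = pmin(base + 0.1, 1)),
    tibble::tibble(gene_id = paste0("g", 1:30), sample = "low",
                   inv_score = base)
  )
  cmp <- compare_rank_profiles(scores)
  up <- tidy(cmp)[tidy(cmp)$higher == "high", ]
  down <- tidy(cmp)[tidy(cmp)$higher == "low", ]
  expect_lt(up$p_raw, 0.001)
  expect_gt(down$p_raw, 0.5)
  expect_true(up$significant)

  # missing gene/sample combinations are an error, not silent drops
  expect_error(compare_rank_profiles(scores[-1, ]), "every sample")
  expect_error(
    compare_rank_profiles(dplyr::filter(scores, sample == "low")),
    "two samples"
  )
})
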