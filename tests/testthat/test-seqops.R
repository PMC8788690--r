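test_that("FASTA and FASTQ round-trip through files, gzip included", {
  seqs <- c(a = "ACGT", b = "GGCCA")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)

  fgz <- withr::local_tempfile(fileext = ".fasta.gz")
  write_fasta(seqs, fgz)
  expect_identical(read_fasta(fgz), seqs)

  reads <- make_read("r1", "ACGTACGT", q = 38)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$qual, reads$qual)

  expect_error(write_fasta(c(a = "ACGT", a = "ACGT"), f), "duplicate")
  expect_error(write_fasta(c(a = ""), f), "empty sequence")
})

test_that("the quality/length filter applies both printed rules", {
  keep_long <- make_read("ok", strrep("A", 200), q = 40)
  too_short <- make_read("short", strrep("A", 100), q = 40)
  # 10 of 200 bases (5%) at Q20 -> above the 3% low-quality allowance
  bad_q <- tibble::tibble(
    id = "lowq", seq = strrep("A", 200),
    qual = paste0(strrep(intToUtf8(20 + 33), 10), strrep(intToUtf8(40 + 33), 190)),
    sample = "s1"
  )
  # exactly 3% low-quality bases: boundary is kept (rule is "over 3%")
  edge <- tibble::tibble(
    id = "edge", seq = strrep("A", 200),
    qual = paste0(strrep(intToUtf8(20 + 33), 6), strrep(intToUtf8(40 + 33), 194)),
    sample = "s1"
  )
  all_reads <- dplyr::bind_rows(keep_long, too_short, bad_q, edge)
  kept <- filter_reads(all_reads)
  expect_setequal(kept$id, c("ok", "edge"))

  # Q29 counts as low (strict <30), Q30 does not
  q29 <- tibble::tibble(id = "q29", seq = strrep("A", 200),
                        qual = strrep(intToUtf8(29 + 33), 200), sample = "s1")
  q30 <- tibble::tibble(id = "q30", seq = strrep("A", 200),
                        qual = strrep(intToUtf8(30 + 33), 200), sample = "s1")
  expect_identical(filter_reads(dplyr::bind_rows(q29, q30))$id, "q30")

  expect_error(filter_reads(tibble::tibble(id = "x", seq = "ACGT")),
               "quality")
})

test_that("filtering is monotone in its thresholds", {
  set.seed(42)
  reads <- purrr::map_dfr(1:40, function(i) {
    len <- sample(100:250, 1)
    tibble::tibble(
      id = paste0("r", i), seq = strrep("A", len),
      qual = intToUtf8(sample(20:40, len, replace = TRUE) + 33),
      sample = "s1"
    )
  })
  base_ids <- filter_reads(reads)$id
  expect_true(all(filter_reads(reads, q_threshold = 32)$id %in% base_ids))
  expect_true(all(filter_reads(reads, max_low_frac = 0.01)$id %in% base_ids))
  expect_true(all(filter_reads(reads, min_len = 200)$id %in% base_ids))
})

test_that("primer trimming recovers the 421-nt insert from a 461-bp amplicon", {
  pr <- pmoa_primers()
  set.seed(1)
  insert <- paste(sample(c("A", "C", "G", "T"), 421, replace = TRUE),
                  collapse = "")
  # a sequenced read carries a concrete base (here G) at the primer's R site
  rev_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(sub("R", "G", pr$reverse)))
  )
  amplicon <- paste0(pr$forward[["MPFpmo-F1"]], insert, rev_rc)
  expect_equal(nchar(amplicon), 461L)

  out <- trim_primers(make_read("a", amplicon))
  expect_identical(out$insert, insert)
  expect_identical(out$fwd_primer, "MPFpmo-F1")

  # second forward primer also matches; a primer-free read does not
  out2 <- trim_primers(make_read("b", paste0(pr$forward[["MPFpmo-F2"]], insert, rev_rc)))
  expect_identical(out2$fwd_primer, "MPFpmo-F2")
  none <- trim_primers(make_read("c", insert))
  expect_true(is.na(none$insert))
  expect_false(none$trimmed)
})

test_that("the IUPAC R in the reverse primer matches both A and G", {
  pr <- pmoa_primers()
  insert <- strrep("ACGT", 20)
  for (base in c("A", "G")) {
    concrete_rev <- sub("R", base, pr$reverse)
    rev_rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(concrete_rev))
    )
    read <- make_read(base, paste0(pr$forward[["MPFpmo-F1"]], insert, rev_rc))
    expect_identical(trim_primers(read)$insert, insert)
  }
  # C at the R position is a mismatch at max_mismatch = 0 but not 1
  concrete_rev <- sub("R", "C", pr$reverse)
  rev_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(concrete_rev))
  )
  read <- make_read("x", paste0(pr$forward[["MPFpmo-F1"]], insert, rev_rc))
  expect_true(is.na(trim_primers(read)$insert))
  expect_identical(trim_primers(read, max_mismatch = 1)$insert, insert)
})

test_that("dereplication counts identical reads per sample with stable ids", {
  reads <- tibble::tibble(
    seq = c("ACGT", "ACGT", "ACGA"),
    sample = "s1"
  )
  tab <- dereplicate(reads)
  expect_equal(dim(tab), c(2L, 1L))
  expect_identical(unname(tab$sequences["ASV0001"]), "ACGT")
  expect_identical(unname(tab$counts[, "s1"]), c(2L, 1L))

  shared <- tibble::tibble(seq = "ACGT", sample = c("a", "b", "c"))
  tab3 <- dereplicate(shared)
  expect_equal(dim(tab3), c(1L, 3L))
  expect_true(all(tab3$counts == 1L))

  expect_equal(dim(dereplicate(tibble::tibble(seq = character(0),
                                              sample = character(0)))),
               c(0L, 0L))
  expect_error(dereplicate(tibble::tibble(seq = c("ACGT", "ACG"),
                                          sample = "s1")), "equal length")
})

test_that("dereplicate of expanded counts is the identity on the table", {
  com <- simulate_community(n_species = 4, variants_per_species = c(1, 4),
                            depth = 300, seed = 17)
  long <- tibble::as_tibble(com$table)
  expanded <- long[rep(seq_len(nrow(long)), long$count), ]
  expanded$seq <- com$table$sequences[expanded$asv_id]
  redone <- dereplicate(expanded[, c("seq", "sample")])
  # same sequences, same counts (ids may renumber among equal totals)
  m1 <- com$table$counts[order(com$table$sequences), , drop = FALSE]
  m2 <- redone$counts[order(redone$sequences), colnames(m1), drop = FALSE]
  expect_identical(unname(m1[rowSums(m1) > 0, , drop = FALSE]), unname(m2))
})

test_that("subsampling hits the depth exactly and preserves proportions on average", {
  com <- simulate_community(n_species = 5, variants_per_species = 1,
                            depth = 2000, seed = 23)
  sub <- subsample_counts(com$table, depth = 500, seed = 1)
  expect_true(all(colSums(sub$counts) == 500L))

  # depth equal to the column total leaves the column unchanged
  same <- subsample_counts(com$table, depth = 2000, seed = 1)
  keep <- rownames(com$table$counts) %in% rownames(same$counts)
  expect_identical(unname(same$counts), unname(com$table$counts[keep, ]))

  expect_error(subsample_counts(com$table, depth = 2001, seed = 1), "below")

  # hypergeometric mean: subsampled proportion is unbiased over 200 seeds
  asv <- rownames(com$table$counts)[1]
  p0 <- com$table$counts[asv, 1] / 2000
  props <- vapply(1:200, function(s) {
    sc <- subsample_counts(com$table, depth = 400, seed = s)$counts
    if (!asv %in% rownames(sc)) 0 else sc[asv, 1] / 400
  }, numeric(1))
  se <- sqrt(p0 * (1 - p0) / 400 / 200)   # ignores the small FPC, conservative
  expect_lt(abs(mean(props) - p0), 3 * se)
})

test_that("translation collapses synonymous ASVs and flags internal stops", {
  # GCT and GCA both encode alanine: one protein, two ASVs
  counts <- matrix(c(5L, 3L, 2L), 3, 1,
                   dimnames = list(c("A1", "A2", "A3"), "s1"))
  tab <- asv_table(
    c(A1 = "ATGGCT", A2 = "ATGGCA", A3 = "ATGTAA"),
    counts
  )
  tc <- translate_collapse(tab)
  expect_identical(tc$protein[tc$asv_id == "A1"], "MA")
  expect_identical(tc$protein_id[tc$asv_id == "A1"],
                   tc$protein_id[tc$asv_id == "A2"])
  expect_equal(dplyr::n_distinct(tc$protein_id), 2L)
  # terminal stop is not an internal stop
  expect_false(any(tc$internal_stop))

  stopy <- asv_table(c(B1 = "TAAGCTGGA"),
                     matrix(1L, 1, 1, dimnames = list("B1", "s1")))
  expect_true(translate_collapse(stopy)$internal_stop)

  # idempotence: collapsing the collapsed proteins changes nothing
  expect_equal(dplyr::n_distinct(tc$protein), dplyr::n_distinct(tc$protein_id))
  expect_error(translate_collapse(tab, frame = 3), "frame")
})
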