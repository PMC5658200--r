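toy_labels <- function(aln, n1) {
  ids <- rownames(aln)
  stats::setNames(c(rep("Type1", n1), rep("Type2", length(ids) - n1)), ids)
}

test_that("signature finder flags columns with differing type consensus", {
  aln <- as_alignment(c(t1a = "AAGT", t1b = "AAGT", t1c = "AAGT",
                        t2a = "AAAT", t2b = "AAAT", t2c = "AAAT"))
  sig <- find_signature(aln, toy_labels(aln, 3))
  expect_equal(sig$position, 3L)
  expect_equal(sig$base_type1, "G")
  expect_equal(sig$base_type2, "A")
  expect_equal(sig$saturation_type1, 1)
  expect_equal(sig$saturation_type2, 1)
  # identical groups give an empty signature
  aln2 <- as_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  expect_equal(nrow(find_signature(aln2, toy_labels(aln2, 2))), 0L)
  # sub-threshold saturation excludes the column (2/3 < 0.85)
  aln3 <- as_alignment(c(t1a = "AAGT", t1b = "AAAT", t1c = "AAGT",
                         t2a = "AATT", t2b = "AATT", t2c = "AATT"))
  expect_equal(nrow(find_signature(aln3, toy_labels(aln3, 3))), 0L)
  # ... but enters at a permissive threshold
  expect_equal(find_signature(aln3, toy_labels(aln3, 3),
                              saturation_threshold = 0.6)$position, 3L)
  expect_error(find_signature(aln, stats::setNames(rep("Type2", 6),
                                                   rownames(aln))),
               "no sequences labelled Type1")
})

test_that("signature finder equals brute-force column enumeration", {
  set.seed(13)
  for (i in 1:6) {
    aln <- random_alignment(sample(4:10, 1), 50, gap_prob = 0.05,
                            alphabet = c("A", "C"))
    labels <- toy_labels(aln, sample(2:(nrow(aln) - 2), 1))
    for (thr in c(0.6, 0.85, 1.0)) {
      got <- find_signature(aln, labels, thr)
      want <- brute_signature(aln, labels, thr)
      expect_equal(got$position, want$position)
      expect_equal(got$base_type1, want$base_type1)
      expect_equal(got$base_type2, want$base_type2)
    }
  }
})

test_that("classification fractions are consistent and sum to 100", {
  aln <- as_alignment(c(t1a = "AAGTC", t1b = "AAGTC",
                        t2a = "AATTG", t2b = "AATTG"))
  sig <- find_signature(aln, toy_labels(aln, 2))
  expect_equal(sig$position, c(3L, 5L))
  full1 <- classify_sequence("AAGTC", sig)
  expect_equal(c(full1$frac_type1, full1$frac_type2, full1$frac_other),
               c(100, 0, 0))
  # matches Type1 at one position, neither type at the other
  half <- classify_sequence("AAGTA", sig)
  expect_equal(c(half$frac_type1, half$frac_type2, half$frac_other),
               c(50, 0, 50))
  expect_error(classify_sequence("AA-T-", sig), "missing")
  expect_error(classify_sequence("AAGT", sig), "width")
  # largest-remainder rounding keeps the triple summing to 100
  set.seed(3)
  aln2 <- random_alignment(6, 40, alphabet = c("A", "G"))
  labels2 <- toy_labels(aln2, 3)
  sig2 <- find_signature(aln2, labels2, 0.6)
  if (nrow(sig2) >= 3) {
    for (id in rownames(aln2)) {
      sc <- classify_sequence(paste(aln2[id, ], collapse = ""), sig2)
      expect_equal(sc$frac_type1 + sc$frac_type2 + sc$frac_other, 100)
      expect_true(all(c(sc$frac_type1, sc$frac_type2, sc$frac_other) ==
                        round(c(sc$frac_type1, sc$frac_type2,
                                sc$frac_other))))
    }
  }
})

test_that("reversion detection flags opposite-type consensus bases", {
  aln <- as_alignment(c(t1a = "AAGTC", t1b = "AAGTC", t1c = "AAATC",
                        t2a = "AATTG", t2b = "AATTG", t2c = "AATTG"))
  sig <- find_signature(aln, toy_labels(aln, 3), saturation_threshold = 0.6)
  expect_equal(sig$position, c(3L, 5L))
  # t1c does not carry the Type2 base anywhere -> its deviation at pos 3
  # (A vs consensus G) is not a reversion
  rev0 <- detect_reversions(aln, toy_labels(aln, 3), sig)
  expect_equal(nrow(rev0), 0L)
  # plant a genuine reversion: a Type1 row carrying the Type2 base T at 3
  aln2 <- as_alignment(c(t1a = "AAGTC", t1b = "AAGTC", t1c = "AATTC",
                         t2a = "AATTG", t2b = "AATTG", t2c = "AATTG"))
  sig2 <- find_signature(aln2, toy_labels(aln2, 3),
                         saturation_threshold = 0.6)
  rev1 <- detect_reversions(aln2, toy_labels(aln2, 3), sig2)
  expect_equal(nrow(rev1), 1L)
  expect_equal(rev1$position, 3L)
  expect_equal(rev1$seq_id, "t1c")
  expect_equal(rev1$observed_base, "T")
})

test_that("type-specific primer windows require conservation and contrast", {
  # 30-column alignment: columns 1-24 conserved in both types except
  # 4 cross-type mismatches at 3, 8, 14, 20
  base <- strsplit("ACGTACGTACGTACGTACGTACGTACGTAC", "")[[1]]
  t1 <- base; t2 <- base
  t2[c(3, 8, 14, 20)] <- c("T", "C", "A", "G")  # differ from t1 there
  aln <- as_alignment(c(t1a = paste(t1, collapse = ""),
                        t1b = paste(t1, collapse = ""),
                        t2a = paste(t2, collapse = ""),
                        t2b = paste(t2, collapse = "")))
  pr <- design_type_primers(aln, toy_labels(aln, 2), length_range = c(20, 20))
  expect_true(all(pr$cross_mismatches >= 3))
  expect_true(nrow(pr) > 0)
  first_t1 <- pr[pr$type == "Type1", ][1, ]
  expect_equal(first_t1$start, 1L)
  expect_equal(first_t1$primer,
               revcomp(paste(t1[1:20], collapse = "")))
  # identical types yield nothing
  aln_same <- as_alignment(c(a = paste(base, collapse = ""),
                             b = paste(base, collapse = ""),
                             c = paste(base, collapse = ""),
                             d = paste(base, collapse = "")))
  expect_equal(nrow(design_type_primers(aln_same, toy_labels(aln_same, 2),
                                        length_range = c(20, 20))), 0L)
  # a window with only 1 cross mismatch fails the default threshold
  t2b <- base; t2b[3] <- "T"
  aln1 <- as_alignment(c(t1a = paste(base, collapse = ""),
                         t1b = paste(base, collapse = ""),
                         t2a = paste(t2b, collapse = ""),
                         t2b = paste(t2b, collapse = "")))
  expect_equal(nrow(design_type_primers(aln1, toy_labels(aln1, 2),
                                        length_range = c(20, 20))), 0L)
  expect_true(nrow(design_type_primers(aln1, toy_labels(aln1, 2),
                                       length_range = c(20, 20),
                                       min_cross_mismatches = 1)) > 0)
})

test_that("signature recovery on planted synthetic data", {
  # exact recovery at zero within-type noise
  ds0 <- generate_dataset(synthetic_config(n_species = 1,
                                           strains_per_species = 2,
                                           within_type_site_noise = 0,
                                           seed = 5))
  labels <- stats::setNames(ds0$metadata$operon_type, ds0$metadata$id)
  sig0 <- find_signature(ds0$aln_16s, labels)
  expect_identical(sig0$position, ds0$truth$signature_positions)
  # recall >= 0.95 at 5% within-type site noise; enough Type 1 copies
  # (one per strain) that the 85% saturation consensus tolerates the
  # expected number of mutated copies per column
  ds1 <- generate_dataset(synthetic_config(n_species = 1,
                                           strains_per_species = 21,
                                           within_type_site_noise = 0.05,
                                           seed = 6))
  labels1 <- stats::setNames(ds1$metadata$operon_type, ds1$metadata$id)
  sig1 <- find_signature(ds1$aln_16s, labels1)
  recall <- mean(ds1$truth$signature_positions %in% sig1$position)
  expect_gte(recall, 0.95)
})
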