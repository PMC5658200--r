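test_that("helix folding pairs canonical bases antiparallel", {
  # G:C, G:C, C:G, A:T, T:A (DNA alphabet; RNA input is normalized)
  expect_equal(fold_helix("GGCAU", "AUGCC"), rep(TRUE, 5))
  # non-canonical positions stay open
  expect_equal(fold_helix("GGCAT", "ATGCA"), c(FALSE, rep(TRUE, 4)))
  # G-T wobble is canonical unless disabled
  expect_true(fold_helix("G", "T")[1])
  expect_false(fold_helix("G", "T", wobble = FALSE)[1])
  expect_error(fold_helix("GGC", "GC"), "length")
})

test_that("the closure rule closes <= max_closable reference mismatches", {
  # reference-mismatch position whose target bases pair -> closed
  expect_true(fold_helix("GAAAA", "TTTTC",
                         reference_mismatch_positions = 1)[1])
  # three closable reference mismatches exceed the default allowance of 2
  m <- fold_helix("GGGAA", "TTCCC", reference_mismatch_positions = 1:3)
  expect_equal(m[1:3], rep(FALSE, 3))
  # the same positions close when the allowance admits them
  m3 <- fold_helix("GGGAA", "TTCCC", reference_mismatch_positions = 1:3,
                   max_closable = 3)
  expect_equal(m3[1:3], rep(TRUE, 3))
  # a reference mismatch that cannot pair is never closed
  expect_false(fold_helix("CAAAA", "TTTTA",
                          reference_mismatch_positions = 1)[1])
  # with no reference mismatches the rule reduces to canonical masking
  expect_equal(fold_helix("GGCAT", "ATGCC", max_closable = 0),
               fold_helix("GGCAT", "ATGCC"))
})

test_that("closed positions always hold canonical pairs (property)", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    s5 <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    s3 <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    ref <- sample(n, sample(0:3, 1))
    mask <- fold_helix(s5, s3, reference_mismatch_positions = ref)
    v5 <- strsplit(s5, "")[[1]]
    partner <- rev(strsplit(s3, "")[[1]])
    ok <- (v5 == "A" & partner == "T") | (v5 == "T" & partner == "A") |
      (v5 == "G" & partner %in% c("C", "T")) |
      (v5 == "C" & partner == "G") | (v5 == "T" & partner == "G")
    expect_true(all(!mask | ok))
  }
})

test_that("column-to-model mapping counts non-gap model residues", {
  aln <- as_alignment(c(model = "ACGT", other = "ACTT"))
  cm <- map_columns_to_model(aln, "model")
  expect_equal(cm$model_position, 1:4)
  aln2 <- as_alignment(c(model = "AC-GT", other = "ACTGT"))
  cm2 <- map_columns_to_model(aln2, "model", model_length = 4)
  expect_equal(cm2$model_position, c(1L, 2L, NA, 3L, 4L))
  expect_equal(cm2$insertion_after[3], 2L)
  expect_error(map_columns_to_model(aln2, "model", model_length = 5),
               "model length")
  expect_error(map_columns_to_model(aln2, "nope"), "not in alignment")
})

test_that("helix variability localizes substitutions and indels", {
  hmap <- helix_map(data.frame(molecule = "16S",
                               helix = c("H9", "H10"),
                               strand5_start = c(5, 25),
                               strand5_end = c(8, 28),
                               strand3_start = c(13, 33),
                               strand3_end = c(16, 36)))
  width <- 40
  base <- rep("A", width)
  # make H9 and H10 fold in the Type2 state: strand3 = complement
  base[13:16] <- "T"; base[33:36] <- "T"
  t2 <- base
  t1 <- base
  t1[6] <- "G"   # substitution inside H9 strand5 (breaks one pair)
  t1[20] <- "C"  # substitution in an unpaired region
  mk <- function(v) paste(v, collapse = "")
  aln <- as_alignment(c(t1a = mk(t1), t1b = mk(t1),
                        t2a = mk(t2), t2b = mk(t2)))
  labels <- stats::setNames(c("Type1", "Type1", "Type2", "Type2"),
                            rownames(aln))
  sig <- find_signature(aln, labels)
  expect_equal(sig$position, c(6L, 20L))
  sc <- helix_variability(aln, labels, sig, hmap)
  ph <- sc$per_helix
  expect_equal(ph$substitutions[ph$helix == "H9"], 1L)
  expect_equal(ph$substitutions[ph$helix == "H10"], 0L)
  expect_equal(sc$unpaired_substitutions, 1L)
  # G opposite T still pairs by wobble -> H9 mask unchanged
  expect_false(ph$structure_altering[ph$helix == "H9"])
  # breaking a pair non-canonically alters the mask
  t1b <- t1; t1b[6] <- "C"
  alnb <- as_alignment(c(t1a = mk(t1b), t1b = mk(t1b),
                         t2a = mk(t2), t2b = mk(t2)))
  sigb <- find_signature(alnb, labels)
  scb <- helix_variability(alnb, labels, sigb, hmap)
  expect_true(scb$per_helix$structure_altering[
    scb$per_helix$helix == "H9"])
  # identical consensuses -> all zero
  aln0 <- as_alignment(c(t1a = mk(t2), t1b = mk(t2),
                         t2a = mk(t2), t2b = mk(t2)))
  sig0 <- find_signature(aln0, labels)
  sc0 <- helix_variability(aln0, labels, sig0, hmap)
  expect_true(all(sc0$per_helix$substitutions == 0))
  expect_true(all(!sc0$per_helix$structure_altering))
})

test_that("an insertion inside a helix flags a structure change", {
  hmap <- helix_map(data.frame(molecule = "16S", helix = "H10",
                               strand5_start = 5, strand5_end = 8,
                               strand3_start = 13, strand3_end = 16))
  t2 <- rep("A", 24); t2[13:16] <- "T"
  # Type1 carries a 4-base insertion inside the H10 5' strand: model
  # (Type2) rows show gaps at the inserted columns
  ins_at <- 6
  t1 <- append(t2, c("C", "C", "C", "C"), after = ins_at)
  t2g <- append(t2, c("-", "-", "-", "-"), after = ins_at)
  mk <- function(v) paste(v, collapse = "")
  aln <- as_alignment(c(t1a = mk(t1), t1b = mk(t1),
                        t2a = mk(t2g), t2b = mk(t2g)))
  labels <- stats::setNames(c("Type1", "Type1", "Type2", "Type2"),
                            rownames(aln))
  sig <- find_signature(aln, labels)
  sc <- helix_variability(aln, labels, sig, hmap, model_row_id = "t2a")
  ph <- sc$per_helix
  expect_equal(ph$insertions[ph$helix == "H10"], 4L)
  # conservation of assignment: helix + unpaired = signature + indels
  total <- sum(ph$substitutions + ph$insertions + ph$deletions) +
    sc$unpaired_substitutions + sc$unpaired_indels
  expect_equal(total, nrow(sig) + 4L)
})

test_that("dot-bracket rendering mirrors the mask", {
  mask <- c(TRUE, TRUE, FALSE, TRUE)
  expect_equal(dot_bracket(mask, loop_length = 3), "((.(...).))")
})
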