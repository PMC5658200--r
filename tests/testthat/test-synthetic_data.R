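test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_species = 1, strains_per_species = 1, seed = 4)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$seqs, d2$seqs)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(synthetic_config(n_species = 1,
                                          strains_per_species = 1,
                                          seed = 5))
  expect_false(identical(d1$seqs$residues, d3$seqs$residues))
})

test_that("planted between-type divergence is exact at zero noise", {
  cfg <- synthetic_config(n_species = 1, strains_per_species = 1,
                          within_type_site_noise = 0, seed = 12)
  ds <- generate_dataset(cfg)
  m <- ds$metadata[ds$metadata$region == "16S", ]
  t1 <- ds$seqs$residues[ds$seqs$id == m$id[m$operon_type == "Type1"][1]]
  t2 <- ds$seqs$residues[ds$seqs$id == m$id[m$operon_type == "Type2"][1]]
  d <- p_distance(t1, t2)
  expect_equal(d$distance, 123 / 1500)
  # Type 2 copies are identical at zero noise
  t2b <- ds$seqs$residues[ds$seqs$id == m$id[m$operon_type == "Type2"][2]]
  expect_identical(t2, t2b)
})

test_that("between_type_divergence overrides the planted count", {
  cfg <- synthetic_config(n_species = 1, strains_per_species = 1,
                          between_type_divergence = 0.08,
                          within_type_site_noise = 0, seed = 2)
  expect_equal(cfg$signature_positions, 120L)
  ds <- generate_dataset(cfg)
  expect_length(ds$truth$signature_positions, 120)
})

test_that("signature positions live in the designated helices", {
  ds <- generate_dataset(synthetic_config(n_species = 1,
                                          strains_per_species = 1,
                                          seed = 3))
  hx <- ds$truth$signature_helix
  expect_true(all(hx %in% ds$config$signature_helices))
  expect_equal(sum(ds$truth$helix_counts), 123)
})

test_that("reversion planting is detected at the expected rate", {
  # modest rate over many strains so that single reversions do not erode
  # the 85% consensus at the affected columns
  r <- 0.02
  ds <- generate_dataset(synthetic_config(n_species = 1,
                                          strains_per_species = 21,
                                          within_type_site_noise = 0,
                                          reversion_rate = r, seed = 14))
  labels <- stats::setNames(ds$metadata$operon_type, ds$metadata$id)
  sig <- find_signature(ds$aln_16s, labels)
  revs <- detect_reversions(ds$aln_16s, labels, sig)
  n_seq <- nrow(ds$aln_16s)
  expected <- r * 123 * n_seq
  sd <- sqrt(expected * (1 - r))
  # planted events within 4 binomial standard deviations of expectation
  expect_lt(abs(ds$truth$reversion_events - expected), 4 * sd)
  # detection recovers the bulk of planted events (a position can drop
  # out of the signature when several copies revert at once)
  expect_gte(nrow(revs), 0.9 * ds$truth$reversion_events)
  expect_lte(nrow(revs), ds$truth$reversion_events)
})

test_that("clone libraries follow the sampling weights", {
  ds <- generate_dataset(synthetic_config(n_species = 1,
                                          strains_per_species = 1,
                                          seed = 7))
  ops <- ds$seqs[ds$seqs$region == "16S", ]
  expect_error(simulate_clone_library(ops, 0), "positive")
  expect_error(simulate_clone_library(ops, 5, rep(0, nrow(ops))),
               "not all zero")
  # uniform weights: frequencies approach 1/k
  lib <- simulate_clone_library(ops, 2000, seed = 9)
  src <- sub("_clone[0-9]+$", "", lib$id)
  freq <- table(src) / 2000
  expect_true(all(abs(freq - 1 / nrow(ops)) < 0.05))
  # zero weight on the divergent type reproduces the cloning bias
  w <- ifelse(ops$operon_type == "Type1", 0, 1)
  lib0 <- simulate_clone_library(ops, 50, w, seed = 9)
  expect_false(any(lib0$operon_type == "Type1"))
  # small libraries can miss operons; the source set still lists all
  lib8 <- simulate_clone_library(ops, 8, seed = 1)
  expect_lte(length(unique(sub("_clone[0-9]+$", "", lib8$id))), nrow(ops))
  expect_equal(nrow(ops), 5L)
  # determinism
  expect_identical(simulate_clone_library(ops, 20, seed = 3)$residues,
                   simulate_clone_library(ops, 20, seed = 3)$residues)
})

test_that("contradictory configurations are rejected", {
  expect_error(synthetic_config(signature_positions = 2000, len_16s = 1500),
               "exceed")
  expect_error(synthetic_config(n_type1 = 5, operons_per_strain = 5))
  expect_error(generate_dataset(synthetic_config(signature_positions = 200)),
               "capacity")
})
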