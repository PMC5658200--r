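idm <- function(strains, fill = 100) {
  n <- length(strains)
  matrix(fill, n, n, dimnames = list(strains, strains))
}

test_that("identity linkage merges only above-threshold pairs", {
  st <- c("A", "B")
  m1 <- idm(st); m1["A", "B"] <- m1["B", "A"] <- 99.5
  m2 <- idm(st); m2["A", "B"] <- m2["B", "A"] <- 99.2
  p <- delimit(list(Type1 = m1, Type2 = m2))
  expect_length(p$clusters, 1)
  # a low identity in EITHER operon type separates
  m2["A", "B"] <- m2["B", "A"] <- 98.0
  p2 <- delimit(list(Type1 = m1, Type2 = m2))
  expect_length(p2$clusters, 2)
  # the boundary value itself separates (<= threshold rule)
  m2["A", "B"] <- m2["B", "A"] <- 98.7
  expect_length(delimit(list(Type1 = m1, Type2 = m2))$clusters, 2)
})

test_that("single linkage builds components, distant strain splits off", {
  st <- c("A", "B", "C")
  m <- idm(st)
  m["A", "C"] <- m["C", "A"] <- 98.0
  m["B", "C"] <- m["C", "B"] <- 97.5
  p <- delimit(list(Type2 = m))
  expect_equal(partition_sets(p$clusters), list(c("A", "B"), "C"))
})

test_that("morphology splits even molecularly near-identical strains", {
  st <- c("sa", "sh")
  m <- idm(st); m["sa", "sh"] <- m["sh", "sa"] <- 99.9
  p <- delimit(list(Type2 = m),
               morphospecies = c(sa = "morphospecies_a",
                                 sh = "morphospecies_b"))
  expect_length(p$clusters, 2)
  expect_equal(p$provenance$criterion, 3L)
  expect_match(p$provenance$detail, "morphospecies")
})

test_that("criteria refine monotonically and degenerate thresholds behave", {
  set.seed(19)
  st <- paste0("s", 1:6)
  m <- idm(st)
  vals <- sample(c(97, 99, 99.9), 15, TRUE)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  base <- delimit(list(Type2 = m))
  morph <- stats::setNames(sample(c("m1", "m2"), 6, TRUE), st)
  refined <- delimit(list(Type2 = m), morphospecies = morph)
  # every refined cluster is inside one base cluster (no merging)
  for (cl in refined$clusters) {
    inside <- vapply(base$clusters, function(b) all(cl %in% b), logical(1))
    expect_equal(sum(inside), 1L)
  }
  expect_gte(length(refined$clusters), length(base$clusters))
  # threshold 100: every non-identical pair separated
  p100 <- delimit(list(Type2 = m), threshold = 100)
  expect_length(p100$clusters, 6)
  # threshold 0 and uniform labels: a single cluster
  p0 <- delimit(list(Type2 = m), threshold = 0,
                morphospecies = stats::setNames(rep("m", 6), st))
  expect_length(p0$clusters, 1)
})

test_that("delimitation equals the transitive-closure oracle (<= 8 strains)", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    st <- paste0("s", seq_len(n))
    mats <- lapply(1:2, function(k) {
      m <- idm(st)
      v <- sample(c(96, 98.7, 99, 99.9), n * (n - 1) / 2, TRUE)
      m[upper.tri(m)] <- v
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    })
    names(mats) <- c("Type1", "Type2")
    morph <- stats::setNames(sample(c("a", "b"), n, TRUE), st)
    got <- delimit(mats, morphospecies = morph)
    want <- brute_delimit(mats, 98.7, morphospecies = morph)
    expect_equal(partition_sets(got$clusters), partition_sets(want))
  }
})

test_that("missing pairwise identity and unlabelled strains error", {
  st <- c("A", "B")
  m <- idm(st); m["A", "B"] <- m["B", "A"] <- NA
  expect_error(delimit(list(Type2 = m)), "missing pairwise identity.*A vs B")
  m2 <- idm(st)
  expect_error(delimit(list(Type2 = m2), morphospecies = c(A = "x")),
               "without morphospecies")
})

test_that("clade labels come from the smallest labelled ancestor", {
  tree <- ape::read.tree(text = "((t1,t2)cladeA,(t3,(t4,t5)cladeB));")
  cl <- clades_from_tree(tree)
  expect_equal(unname(cl[c("t1", "t2")]), c("cladeA", "cladeA"))
  expect_equal(unname(cl[c("t4", "t5")]), c("cladeB", "cladeB"))
  expect_true(is.na(cl["t3"]))
  # clades act as criterion 2
  st <- c("t1", "t2")
  m <- idm(st)
  p <- delimit(list(Type2 = m), clades = c(t1 = "cladeA", t2 = "cladeB"))
  expect_length(p$clusters, 2)
  expect_equal(p$provenance$criterion, 2L)
})
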