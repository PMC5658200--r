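# Independent brute-force oracles. These deliberately avoid the package's
# code paths: the aligner oracle enumerates every global alignment, the
# distance oracle scans columns one by one, the signature oracle calls
# consensus per column from scratch, and the delimitation oracle takes
# connected components by transitive closure of the adjacency matrix.

brute_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(av)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

brute_p_distance <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sites <- 0L; mism <- 0L
  for (k in seq_along(av)) {
    if (av[k] %in% c("A", "C", "G", "T") && bv[k] %in% c("A", "C", "G", "T")) {
      sites <- sites + 1L
      if (av[k] != bv[k]) mism <- mism + 1L
    }
  }
  list(distance = if (sites > 0) mism / sites else NA_real_, sites = sites)
}

brute_signature <- function(aln, labels, thr = 0.85) {
  ids <- rownames(aln)
  col_consensus <- function(tp, p) {
    col <- aln[ids[labels[ids] == tp], p]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0) return(NULL)
    tab <- table(col)
    tab <- tab[order(-tab, names(tab))]
    if (length(tab) > 1 && tab[1] == tab[2]) return(NULL)
    if (tab[1] / sum(tab) < thr) return(NULL)
    names(tab)[1]
  }
  pos <- integer(0); b1 <- character(0); b2 <- character(0)
  for (p in seq_len(ncol(aln))) {
    c1 <- col_consensus("Type1", p)
    c2 <- col_consensus("Type2", p)
    if (!is.null(c1) && !is.null(c2) && c1 != c2) {
      pos <- c(pos, p); b1 <- c(b1, c1); b2 <- c(b2, c2)
    }
  }
  data.frame(position = pos, base_type1 = b1, base_type2 = b2,
             stringsAsFactors = FALSE)
}

brute_delimit <- function(identities, threshold = 98.7, clades = NULL,
                          morphospecies = NULL) {
  strains <- rownames(identities[[1]])
  n <- length(strains)
  adj <- matrix(TRUE, n, n)
  for (m in identities) adj <- adj & (m > threshold)
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) reach <- (reach %*% (adj * 1)) > 0
  key <- apply(reach, 1, function(r) paste(which(r), collapse = ","))
  if (!is.null(clades)) key <- paste(key, clades[strains])
  if (!is.null(morphospecies)) key <- paste(key, morphospecies[strains])
  unname(lapply(split(strains, key), sort))
}

# canonical form of a partition for set comparison
partition_sets <- function(clusters) {
  s <- lapply(clusters, sort)
  s[order(vapply(s, `[`, character(1), 1))]
}

random_alignment <- function(nrow, ncol, gap_prob = 0,
                             alphabet = c("A", "C", "G", "T")) {
  pool <- c(alphabet, if (gap_prob > 0) "-")
  prob <- c(rep((1 - gap_prob) / length(alphabet), length(alphabet)),
            if (gap_prob > 0) gap_prob)
  m <- matrix(sample(pool, nrow * ncol, replace = TRUE, prob = prob),
              nrow, ncol)
  rownames(m) <- paste0("s", seq_len(nrow))
  strs <- apply(m, 1, paste, collapse = "")
  as_alignment(strs)
}
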