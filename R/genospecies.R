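# Genospecies delimitation.
#
# Strains are partitioned by three criteria applied in sequence:
#   1. identity: two strains belong to the same candidate cluster only
#      when their 16S identity exceeds the threshold (default 98.7%) in
#      EVERY available operon type; identity at or below the threshold in
#      either operon separates them. Candidate clusters are the connected
#      components of the resulting graph (single linkage, the
#      minimal-assumption reading when no clustering procedure is
#      stated).
#   2. phylogeny: components whose members occupy different labelled tree
#      clades are split. Clade membership is a user input (labels on a
#      tree), not an inference.
#   3. morphology: components containing different morphospecies labels
#      are split even when molecular support for separation is weak.
# Later criteria only ever split clusters (monotone refinement).

#' Partition strains into genospecies
#'
#' @param identities named list, one element per operon type, each a
#'   symmetric matrix of percent 16S identity with strain ids as
#'   dimnames. All matrices must cover the same strains; an NA off the
#'   diagonal is a missing comparison and is an error.
#' @param threshold percent identity; pairs at or below it (in any
#'   operon type) are separated.
#' @param clades optional named character vector strain -> clade label.
#' @param morphospecies optional named character vector strain ->
#'   morphospecies label.
#' @return object of class \code{rrn_partition}: list with
#'   \code{clusters} (list of strain-id vectors), \code{provenance}
#'   (data frame recording every split and the criterion that caused it)
#'   and \code{threshold}.
#' @export
#' @examples
#' idm <- matrix(c(100, 99.5, 99.5, 100), 2, 2,
#'               dimnames = list(c("s1", "s2"), c("s1", "s2")))
#' delimit(list(Type2 = idm))
delimit <- function(identities, threshold = 98.7, clades = NULL,
                    morphospecies = NULL) {
  if (!length(identities)) stop("no identity matrices supplied")
  strains <- rownames(identities[[1]])
  for (nm in names(identities)) {
    m <- identities[[nm]]
    if (!identical(rownames(m), strains) || !identical(colnames(m), strains))
      stop("identity matrices must share one strain set (", nm, " differs)")
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("missing pairwise identity in ", nm, ": ",
           strains[bad[1, 1]], " vs ", strains[bad[1, 2]])
    }
  }
  n <- length(strains)
  link <- matrix(TRUE, n, n)
  for (m in identities) link <- link & (m > threshold)
  diag(link) <- TRUE

  # connected components (criterion 1), by breadth-first search
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(link[v, ] & is.na(comp)))
    }
  }
  comp <- as.character(comp)
  prov <- data.frame(criterion = integer(0), detail = character(0),
                     stringsAsFactors = FALSE)

  refine <- function(comp, labels, criterion, what) {
    if (is.null(labels)) return(comp)
    miss <- setdiff(strains, names(labels))
    if (length(miss)) stop("strain(s) without ", what, " label: ",
                           paste(miss, collapse = ", "))
    for (cl in unique(comp)) {
      members <- which(comp == cl)
      labs <- labels[strains[members]]
      if (length(unique(labs)) > 1) {
        prov <<- rbind(prov, data.frame(
          criterion = criterion,
          detail = paste0("cluster {",
                          paste(strains[members], collapse = ","),
                          "} split by ", what, ": ",
                          paste(unique(labs), collapse = " | ")),
          stringsAsFactors = FALSE))
        comp[members] <- paste0(comp[members], "/", labs)
      }
    }
    comp
  }
  comp <- refine(comp, clades, 2L, "tree clade")
  comp <- refine(comp, morphospecies, 3L, "morphospecies")

  clusters <- unname(split(strains, comp))
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1))]
  structure(list(clusters = clusters, provenance = prov,
                 threshold = threshold),
            class = "rrn_partition")
}

#' @export
print.rrn_partition <- function(x, ...) {
  cat("rrn_partition:", length(x$clusters), "genospecies at >",
      x$threshold, "% linkage\n")
  for (cl in x$clusters) cat(" -", paste(cl, collapse = ", "), "\n")
  invisible(x)
}

#' Clade labels from a labelled newick tree
#'
#' The clade of each tip is the label of its smallest labelled ancestor
#' node; tips under no labelled node get NA.
#'
#' @param tree an \code{ape::phylo} with (possibly sparse) node labels.
#' @return named character vector tip -> clade label.
#' @export
clades_from_tree <- function(tree) {
  if (is.null(tree$node.label)) {
    return(stats::setNames(rep(NA_character_, length(tree$tip.label)),
                           tree$tip.label))
  }
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  out <- vapply(seq_len(ntip), function(tip) {
    v <- parent[tip]
    while (v != 0) {
      lab <- tree$node.label[v - ntip]
      if (!is.na(lab) && nzchar(lab)) return(lab)
      v <- parent[v]
    }
    NA_character_
  }, character(1))
  stats::setNames(out, tree$tip.label)
}
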