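# p-distance and percent-identity summaries.
#
# Identity is reported as 100 * (1 - p), divergence as 100 * p, so
# identity + divergence = 100 exactly for every pair. Under the default
# pairwise-deletion policy columns holding a gap, N or any partial
# ambiguity code in either sequence are excluded from the compared sites,
# mirroring the usual distance-matrix default of phylogenetics software.
# Note p-distance under pairwise deletion need not obey the triangle
# inequality: each pair may be compared over a different site set.

#' Uncorrected pairwise distance between two aligned rows
#'
#' @param a,b aligned residue strings of equal length.
#' @param policy \code{"pairwise_deletion"} (default): columns with missing
#'   data in either sequence are dropped from the denominator.
#'   \code{"gaps_as_difference"}: a column where exactly one sequence has
#'   missing data counts as a compared, differing site (columns missing in
#'   both are still dropped).
#' @return list with \code{distance} (fraction in [0,1]) and \code{sites}
#'   (number of compared columns).
#' @export
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25 over 4 sites
#' p_distance("AC-T", "ACGT")  # 0 over 3 sites
p_distance <- function(a, b, policy = c("pairwise_deletion",
                                        "gaps_as_difference")) {
  policy <- match.arg(policy)
  a <- normalize_residues(a); b <- normalize_residues(b)
  if (nchar(a) != nchar(b)) stop("aligned rows must have equal length")
  av <- chars(a); bv <- chars(b)
  da <- is_determined(av); db <- is_determined(bv)
  if (policy == "pairwise_deletion") {
    use <- da & db
    mism <- sum(av[use] != bv[use])
  } else {
    use <- da | db
    mism <- sum((av[use] != bv[use]) | !(da[use] & db[use]))
  }
  sites <- sum(use)
  if (sites == 0) stop("no comparable sites")
  list(distance = mism / sites, sites = as.integer(sites))
}

#' All-pairs distance/identity matrix for an alignment
#'
#' @param aln an \code{rrn_alignment}.
#' @inheritParams p_distance
#' @return an \code{rrn_dist} object: list with \code{ids}, symmetric
#'   matrices \code{p} (p-distance) and \code{sites}. Percent identity is
#'   recovered with [identity_percent()].
#' @export
identity_matrix <- function(aln, policy = c("pairwise_deletion",
                                            "gaps_as_difference")) {
  policy <- match.arg(policy)
  if (nrow(aln) < 2) stop("need at least 2 sequences")
  ids <- rownames(aln)
  n <- length(ids)
  p <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(sites) <- ncol(aln)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- tryCatch(
        p_distance(aln_row(aln, ids[i]), aln_row(aln, ids[j]), policy),
        error = function(e) stop("pair ", ids[i], " vs ", ids[j], ": ",
                                 conditionMessage(e), call. = FALSE))
      p[i, j] <- p[j, i] <- d$distance
      sites[i, j] <- sites[j, i] <- d$sites
    }
  }
  structure(list(ids = ids, p = p, sites = sites, policy = policy),
            class = "rrn_dist")
}

#' Percent identity from an rrn_dist
#'
#' @param dm an \code{rrn_dist}.
#' @return symmetric matrix of \code{100 * (1 - p)}.
#' @export
identity_percent <- function(dm) 100 * (1 - dm$p)

#' Percent divergence from an rrn_dist
#'
#' @param dm an \code{rrn_dist}.
#' @return symmetric matrix of \code{100 * p}.
#' @export
divergence_percent <- function(dm) 100 * dm$p

#' @export
print.rrn_dist <- function(x, ...) {
  cat("rrn_dist:", length(x$ids), "sequences,", x$policy, "\n")
  invisible(x)
}

#' Min/max percent identity between two labelled groups
#'
#' Summarizes the identity range over all qualifying pairs, e.g. the
#' within-strain range between the divergent operon type and the majority
#' type, as printed in comparative operon studies.
#'
#' @param dm an \code{rrn_dist}.
#' @param groups named character vector mapping every id to a group label.
#' @param pair length-2 character: the two group labels to compare (equal
#'   labels select within-group pairs).
#' @param strains optional named character vector mapping id to strain,
#'   required when \code{within_strain_only}.
#' @param within_strain_only restrict to pairs sharing a strain.
#' @return list of class \code{rrn_range}: \code{group_a}, \code{group_b},
#'   \code{min_identity}, \code{max_identity}, \code{n_pairs}.
#' @export
range_summary <- function(dm, groups, pair, strains = NULL,
                          within_strain_only = FALSE) {
  ids <- dm$ids
  miss <- setdiff(ids, names(groups))
  if (length(miss)) stop("unlabelled id(s): ", paste(miss, collapse = ", "))
  if (within_strain_only && is.null(strains)) {
    stop("within_strain_only requires strain metadata")
  }
  idx_a <- which(groups[ids] == pair[1])
  idx_b <- which(groups[ids] == pair[2])
  pairs <- expand.grid(i = idx_a, j = idx_b)
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  if (pair[1] == pair[2]) pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
  if (within_strain_only) {
    keep <- strains[ids[pairs$i]] == strains[ids[pairs$j]]
    pairs <- pairs[!is.na(keep) & keep, , drop = FALSE]
  }
  # unordered dedup for cross-group pairs
  key <- paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  if (nrow(pairs) == 0) stop("no qualifying pairs for ", pair[1], " vs ",
                             pair[2])
  idt <- 100 * (1 - dm$p[cbind(pairs$i, pairs$j)])
  structure(list(group_a = pair[1], group_b = pair[2],
                 min_identity = min(idt), max_identity = max(idt),
                 n_pairs = nrow(pairs)),
            class = "rrn_range")
}

#' @export
print.rrn_range <- function(x, ...) {
  cat(sprintf("%s vs %s: identity %.1f-%.1f%% over %d pair(s)\n",
              x$group_a, x$group_b, x$min_identity, x$max_identity,
              x$n_pairs))
  invisible(x)
}

#' Write pairwise distances as TSV
#'
#' Columns: \code{id_a}, \code{id_b}, \code{sites}, \code{p_distance},
#' \code{identity_percent}.
#'
#' @param dm an \code{rrn_dist}.
#' @param path output path.
#' @export
write_distance_tsv <- function(dm, path) {
  n <- length(dm$ids)
  rows <- which(upper.tri(dm$p), arr.ind = TRUE)
  out <- data.frame(id_a = dm$ids[rows[, 1]], id_b = dm$ids[rows[, 2]],
                    sites = dm$sites[rows],
                    p_distance = dm$p[rows],
                    identity_percent = 100 * (1 - dm$p[rows]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
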