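# Operon typing from consistently variable alignment positions.
#
# A signature position is an alignment column at which each operon type
# has its own consensus base (agreement among non-missing residues at or
# above the saturation threshold, 85% by default) and the two consensus
# bases differ. The set of such columns is the diagnostic signature used
# to classify new sequences, count reversions (candidate gene-conversion
# events) and design type-specific primers.

# Per-type column consensus over an alignment. Returns for each column and
# type the consensus base (NA if none) and its saturation.
type_consensus <- function(aln, labels, types = c("Type1", "Type2")) {
  ids <- rownames(aln)
  miss <- setdiff(ids, names(labels))
  if (length(miss)) stop("unlabelled sequence(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(types, function(tp) {
    rows <- ids[labels[ids] == tp]
    if (length(rows) == 0) stop("no sequences labelled ", tp)
    sub <- aln[rows, , drop = FALSE]
    cb <- apply(sub, 2, consensus_base)
    list(base = vapply(cb, `[[`, character(1), "base"),
         saturation = vapply(cb, `[[`, numeric(1), "saturation"),
         n = length(rows))
  })
  names(out) <- types
  out
}

#' Find consistently variable positions between two operon types
#'
#' @param aln an \code{rrn_alignment}.
#' @param labels named character vector mapping sequence id to
#'   \code{"Type1"} or \code{"Type2"}.
#' @param saturation_threshold minimum within-type agreement (fraction of
#'   non-missing residues carrying the modal base) for a consensus call.
#' @return an \code{rrn_signature} data frame with columns
#'   \code{position}, \code{base_type1}, \code{base_type2},
#'   \code{saturation_type1}, \code{saturation_type2}, \code{helix}
#'   (NA until assigned), and the alignment width in attribute
#'   \code{"width"}.
#' @export
find_signature <- function(aln, labels, saturation_threshold = 0.85) {
  cons <- type_consensus(aln, labels)
  t1 <- cons$Type1; t2 <- cons$Type2
  ok <- !is.na(t1$base) & !is.na(t2$base) &
    t1$saturation >= saturation_threshold &
    t2$saturation >= saturation_threshold &
    t1$base != t2$base
  pos <- which(ok)
  out <- data.frame(position = pos,
                    base_type1 = t1$base[pos],
                    base_type2 = t2$base[pos],
                    saturation_type1 = t1$saturation[pos],
                    saturation_type2 = t2$saturation[pos],
                    helix = rep(NA_character_, length(pos)),
                    stringsAsFactors = FALSE)
  attr(out, "width") <- ncol(aln)
  attr(out, "saturation_threshold") <- saturation_threshold
  class(out) <- c("rrn_signature", "data.frame")
  out
}

#' Score a sequence against a type signature
#'
#' Over the signature positions at which the query carries an unambiguous
#' base, computes the share identical to each type's consensus; the
#' remainder is "other". Percentages are rounded so the triple sums to
#' 100 (largest-remainder by default).
#'
#' @param seq aligned residue string (same coordinate frame as the
#'   signature) or a single-row \code{rrn_seqs}.
#' @param sig an \code{rrn_signature}.
#' @param rounding \code{"largest_remainder"} (integer percents summing to
#'   100) or \code{"none"} (full precision).
#' @param seq_id identifier used in the report.
#' @return list: \code{seq_id}, \code{frac_type1}, \code{frac_type2},
#'   \code{frac_other}, \code{n_scored}.
#' @export
classify_sequence <- function(seq, sig, rounding = c("largest_remainder",
                                                     "none"),
                              seq_id = "query") {
  rounding <- match.arg(rounding)
  if (inherits(seq, "rrn_seqs")) { seq_id <- seq$id[1]; seq <- seq$residues[1] }
  seq <- normalize_residues(seq)
  width <- attr(sig, "width")
  if (!is.null(width) && nchar(seq) != width) {
    stop("sequence length ", nchar(seq),
         " does not match signature alignment width ", width)
  }
  bases <- chars(seq)[sig$position]
  use <- is_determined(bases)
  n <- sum(use)
  if (n == 0) stop("all signature positions missing in sequence ", seq_id)
  n1 <- sum(bases[use] == sig$base_type1[use])
  n2 <- sum(bases[use] == sig$base_type2[use])
  fr <- 100 * c(n1, n2, n - n1 - n2) / n
  if (rounding == "largest_remainder") fr <- round_largest_remainder(fr, 100L)
  list(seq_id = seq_id, frac_type1 = fr[1], frac_type2 = fr[2],
       frac_other = fr[3], n_scored = as.integer(n))
}

#' Type every sequence of an alignment against a signature
#'
#' @inheritParams classify_sequence
#' @param aln an \code{rrn_alignment}.
#' @return data frame with one row per sequence: the three percentages,
#'   \code{n_scored} and \code{assigned_type} (the type with the larger
#'   share; \code{"unknown"} on a tie).
#' @export
classify_alignment <- function(aln, sig,
                               rounding = c("largest_remainder", "none")) {
  rounding <- match.arg(rounding)
  rows <- lapply(rownames(aln), function(id) {
    sc <- classify_sequence(aln_row(aln, id), sig, rounding, seq_id = id)
    as.data.frame(sc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$assigned_type <- ifelse(out$frac_type1 > out$frac_type2, "Type1",
                              ifelse(out$frac_type2 > out$frac_type1,
                                     "Type2", "unknown"))
  out
}

#' Detect reversions at signature positions
#'
#' A reversion is an unambiguous residue in a sequence of one type that
#' equals the \emph{other} type's consensus base at a signature position,
#' the footprint expected from partial gene conversion between operon
#' copies.
#'
#' @inheritParams find_signature
#' @param sig an \code{rrn_signature} derived from the same alignment
#'   coordinates.
#' @return data frame with one row per hit: \code{position},
#'   \code{seq_id}, \code{operon_type}, \code{observed_base}. The number
#'   of distinct flagged positions is \code{length(unique(out$position))}.
#' @export
detect_reversions <- function(aln, labels, sig) {
  ids <- rownames(aln)
  miss <- setdiff(ids, names(labels))
  if (length(miss)) stop("unlabelled sequence(s): ",
                         paste(miss, collapse = ", "))
  hits <- list()
  for (id in ids) {
    tp <- labels[[id]]
    if (!tp %in% c("Type1", "Type2")) next
    other <- if (tp == "Type1") sig$base_type2 else sig$base_type1
    bases <- aln[id, sig$position]
    rev_at <- which(is_determined(bases) & bases == other)
    if (length(rev_at)) {
      hits[[id]] <- data.frame(position = sig$position[rev_at],
                               seq_id = id, operon_type = tp,
                               observed_base = bases[rev_at],
                               stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(position = integer(0), seq_id = character(0),
                      operon_type = character(0),
                      observed_base = character(0)))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$position, out$seq_id), ]
}

#' Propose type-specific primer windows
#'
#' Scans for alignment windows that are fully conserved (every sequence of
#' the target type identical, no gaps or ambiguity in any row) while
#' differing from the other type's consensus at a minimum number of
#' positions, the design logic behind type-discriminating reverse primers.
#'
#' @inheritParams find_signature
#' @param length_range candidate window lengths (min, max).
#' @param min_cross_mismatches minimum differences from the other type's
#'   consensus over the window.
#' @param reverse emit the reverse complement (reverse primer, 5'->3').
#' @return data frame sorted leftmost-first then shortest: \code{type},
#'   \code{start}, \code{end}, \code{length}, \code{primer},
#'   \code{cross_mismatches}, \code{three_prime_mismatch} (TRUE when the
#'   primer's 3' terminal base is a cross-type mismatch, the position most
#'   discriminating in PCR). Empty when no window qualifies.
#' @export
design_type_primers <- function(aln, labels, length_range = c(20, 30),
                                min_cross_mismatches = 3, reverse = TRUE) {
  cons <- type_consensus(aln, labels)
  ids <- rownames(aln)
  width <- ncol(aln)
  res <- list()
  for (tp in c("Type1", "Type2")) {
    other <- setdiff(c("Type1", "Type2"), tp)
    rows <- ids[labels[ids] == tp]
    sub <- aln[rows, , drop = FALSE]
    # column fully conserved and determined within the target type
    conserved <- apply(sub, 2, function(col) {
      all(is_determined(col)) && length(unique(col)) == 1
    })
    gapless <- apply(aln, 2, function(col) all(col != "-"))
    target <- cons[[tp]]$base
    cross <- cons[[other]]$base
    for (L in seq(length_range[1], length_range[2])) {
      if (L > width) break
      for (s in seq_len(width - L + 1)) {
        w <- s:(s + L - 1)
        if (!all(conserved[w] & gapless[w])) next
        mm <- !is.na(cross[w]) & target[w] != cross[w]
        if (sum(mm) < min_cross_mismatches) next
        primer <- paste(target[w], collapse = "")
        # reverse primer anneals to the plus strand: its 3' end sits on the
        # leftmost window position
        three_prime <- if (reverse) mm[1] else mm[L]
        if (reverse) primer <- revcomp(primer)
        res[[length(res) + 1]] <- data.frame(
          type = tp, start = s, end = s + L - 1, length = L, primer = primer,
          cross_mismatches = sum(mm), three_prime_mismatch = three_prime,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(type = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      primer = character(0), cross_mismatches = integer(0),
                      three_prime_mismatch = logical(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$type, out$start, out$length), ]
  rownames(out) <- NULL
  out
}

#' Write a signature table as TSV
#'
#' @param sig an \code{rrn_signature}.
#' @param path output path.
#' @export
write_signature_tsv <- function(sig, path) {
  utils::write.table(as.data.frame(sig), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
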