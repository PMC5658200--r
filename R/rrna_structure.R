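# Helix-level secondary-structure comparison.
#
# Reference helix coordinates (comparative-model numbering, e.g. H9, H10)
# are supplied as a HelixMap table in model coordinates. Helices are
# folded under canonical pairing (Watson-Crick plus, optionally, G-U
# wobble) with a closure rule: positions that are mismatched in the
# reference model may be drawn paired ("closed") when the target bases
# pair canonically, provided no more than `max_closable` such closures
# are needed in the helix.

#' Read a helix map TSV
#'
#' @param path TSV with columns \code{molecule}, \code{helix},
#'   \code{strand5_start}, \code{strand5_end}, \code{strand3_start},
#'   \code{strand3_end} (1-based closed intervals in model coordinates).
#' @return data frame of class \code{rrn_helixmap}.
#' @export
read_helix_map <- function(path) {
  hm <- utils::read.delim(path, stringsAsFactors = FALSE)
  helix_map(hm)
}

#' Construct / validate a helix map
#'
#' @param hm data frame with the columns listed in [read_helix_map()].
#' @return the validated map, classed \code{rrn_helixmap}.
#' @export
helix_map <- function(hm) {
  need <- c("molecule", "helix", "strand5_start", "strand5_end",
            "strand3_start", "strand3_end")
  miss <- setdiff(need, names(hm))
  if (length(miss)) stop("helix map lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(hm$helix)) stop("duplicate helix names")
  if (any(hm$strand5_end < hm$strand5_start) ||
      any(hm$strand3_end < hm$strand3_start)) {
    stop("malformed helix interval (end < start)")
  }
  if (any(hm$strand5_end >= hm$strand3_start)) {
    stop("strand5 must precede strand3 for every helix")
  }
  ivs <- rbind(cbind(hm$strand5_start, hm$strand5_end),
               cbind(hm$strand3_start, hm$strand3_end))
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  if (nrow(ivs) > 1 && any(ivs[-1, 1] <= ivs[-nrow(ivs), 2])) {
    stop("overlapping helix strand intervals")
  }
  class(hm) <- c("rrn_helixmap", "data.frame")
  hm
}

# Canonical pairing predicate (antiparallel): Watson-Crick, optionally G-U.
pairs_canonically <- function(x, y, wobble = TRUE) {
  wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  if (wobble) wc <- wc | (x == "G" & y == "T") | (x == "T" & y == "G")
  wc & is_determined(x) & is_determined(y)
}

#' Fold a helix under canonical pairing with the closure rule
#'
#' Position \code{i} of the 5' strand is tested against position
#' \code{L - i + 1} of the 3' strand (both strands given 5'->3').
#' Ordinary positions are paired iff the bases pair canonically.
#' Reference-mismatch positions (positions unpaired in the reference
#' model) are "closed" (marked paired) iff their bases pair canonically
#' and at most \code{max_closable} closures are needed in the helix;
#' when more would be needed, none are closed.
#'
#' @param strand5,strand3 residue strings, both 5'->3', equal length.
#' @param reference_mismatch_positions integer positions (on the 5'
#'   strand) mismatched in the reference model.
#' @param max_closable maximum closures per helix.
#' @param wobble count G-U as canonical.
#' @return logical pairing mask along the 5' strand.
#' @export
#' @examples
#' fold_helix("GGCAT", "ATGCC")  # all TRUE
fold_helix <- function(strand5, strand3,
                       reference_mismatch_positions = integer(0),
                       max_closable = 2, wobble = TRUE) {
  strand5 <- normalize_residues(strand5)
  strand3 <- normalize_residues(strand3)
  v5 <- chars(strand5); v3 <- chars(strand3)
  if (length(v5) != length(v3)) {
    stop("strand lengths differ (", length(v5), " vs ", length(v3),
         "); helix cannot be folded positionally")
  }
  partner <- rev(v3)
  canon <- pairs_canonically(v5, partner, wobble)
  mask <- canon
  ref <- intersect(reference_mismatch_positions, seq_along(v5))
  if (length(ref)) {
    closable <- canon[ref]
    if (sum(closable) > max_closable) {
      mask[ref] <- FALSE
    } else {
      mask[ref] <- closable
    }
  }
  mask
}

#' Dot-bracket string for a folded helix
#'
#' @param mask logical pairing mask from [fold_helix()].
#' @param loop_length number of unpaired loop positions between the
#'   strands (rendered as dots).
#' @return single dot-bracket string covering 5' strand, loop, 3' strand.
#' @export
dot_bracket <- function(mask, loop_length = 0) {
  paste0(paste(ifelse(mask, "(", "."), collapse = ""),
         strrep(".", loop_length),
         paste(rev(ifelse(mask, ")", ".")), collapse = ""))
}

#' Map alignment columns to model coordinates
#'
#' Model positions are counted along the non-gap residues of a designated
#' model row; columns opposite a model-row gap are insertions attributed
#' to the model position they follow.
#'
#' @param aln an \code{rrn_alignment}.
#' @param model_row_id row id of the model (reference) sequence.
#' @param model_length optional check on the ungapped model length.
#' @return data frame with one row per column: \code{column},
#'   \code{model_position} (NA for insertion columns),
#'   \code{insertion_after} (model position the insertion follows; 0 for
#'   insertions before the first model residue).
#' @export
map_columns_to_model <- function(aln, model_row_id, model_length = NULL) {
  if (!model_row_id %in% rownames(aln)) {
    stop("model row ", model_row_id, " not in alignment")
  }
  row <- aln[model_row_id, ]
  nongap <- row != "-"
  mp <- cumsum(nongap)
  if (!is.null(model_length) && max(mp) != model_length) {
    stop("ungapped model row length ", max(mp),
         " does not equal stated model length ", model_length)
  }
  data.frame(column = seq_along(row),
             model_position = ifelse(nongap, mp, NA_integer_),
             insertion_after = ifelse(nongap, NA_integer_, mp))
}

# Helix (or "unpaired") containing a model position.
helix_of_position <- function(pos, hmap) {
  hit5 <- pos >= hmap$strand5_start & pos <= hmap$strand5_end
  hit3 <- pos >= hmap$strand3_start & pos <= hmap$strand3_end
  hit <- which(hit5 | hit3)
  if (length(hit) == 0) "unpaired" else hmap$helix[hit[1]]
}

#' Quantify helix-localized heterogeneity between operon types
#'
#' Assigns every signature position (substitution) and every
#' consensus-level indel column to a helix or to the unpaired regions,
#' and flags helices whose pairing mask differs when the two type
#' consensus sequences are folded.
#'
#' @inheritParams find_signature
#' @param sig an \code{rrn_signature} from the same alignment.
#' @param hmap an \code{rrn_helixmap} in model coordinates.
#' @param model_row_id row whose ungapped coordinates define the model
#'   frame (defaults to the first Type2-labelled row).
#' @param max_closable,wobble passed to [fold_helix()].
#' @return list of class \code{rrn_structcmp}: \code{per_helix} data frame
#'   (\code{helix}, \code{substitutions}, \code{insertions},
#'   \code{deletions}, \code{structure_altering}, \code{detail}),
#'   \code{unpaired_substitutions}, \code{unpaired_indels}.
#' @export
helix_variability <- function(aln, labels, sig, hmap, model_row_id = NULL,
                              max_closable = 2, wobble = TRUE) {
  ids <- rownames(aln)
  if (is.null(model_row_id)) {
    model_row_id <- ids[labels[ids] == "Type2"][1]
  }
  colmap <- map_columns_to_model(aln, model_row_id)
  cons <- type_consensus(aln, labels)
  # gap-aware consensus rows (gap treated as a fifth state) for indels
  gapcons <- lapply(c("Type1", "Type2"), function(tp) {
    rows <- ids[labels[ids] == tp]
    apply(aln[rows, , drop = FALSE], 2, function(col) {
      tab <- sort(table(col), decreasing = TRUE)
      names(tab)[1]
    })
  })
  names(gapcons) <- c("Type1", "Type2")

  model_pos_of_column <- function(cl) {
    mp <- colmap$model_position[cl]
    if (is.na(mp)) colmap$insertion_after[cl] else mp
  }

  helices <- hmap$helix
  tally <- data.frame(helix = c(helices, "unpaired"),
                      substitutions = 0L, insertions = 0L, deletions = 0L,
                      structure_altering = FALSE, detail = "",
                      stringsAsFactors = FALSE)
  bump <- function(tally, hx, field) {
    i <- match(hx, tally$helix)
    tally[i, field] <- tally[i, field] + 1L
    tally
  }
  # substitutions: signature positions
  for (p in sig$position) {
    hx <- helix_of_position(model_pos_of_column(p), hmap)
    tally <- bump(tally, hx, "substitutions")
  }
  # consensus-level indels: gap in exactly one type's gap-aware consensus
  indel_cols <- which((gapcons$Type1 == "-") != (gapcons$Type2 == "-"))
  for (p in indel_cols) {
    hx <- helix_of_position(model_pos_of_column(p), hmap)
    # a gap in the Type1 consensus is a deletion in Type1 relative to the
    # Type2 (model) state; a gap in Type2 means Type1 carries an insertion
    field <- if (gapcons$Type1[p] == "-") "deletions" else "insertions"
    tally <- bump(tally, hx, field)
  }
  # structure-altering flags: fold each helix from both type consensuses
  cols_of_model <- function(pos_range) {
    which(colmap$model_position %in% pos_range)
  }
  for (k in seq_len(nrow(hmap))) {
    cl5 <- cols_of_model(hmap$strand5_start[k]:hmap$strand5_end[k])
    cl3 <- cols_of_model(hmap$strand3_start[k]:hmap$strand3_end[k])
    masks <- lapply(c("Type1", "Type2"), function(tp) {
      s5 <- gapcons[[tp]][cl5]; s3 <- gapcons[[tp]][cl3]
      s5 <- s5[s5 != "-"]; s3 <- s3[s3 != "-"]
      if (length(s5) == 0 || length(s3) == 0) return(NULL)
      if (length(s5) != length(s3)) return("lenmis")
      fold_helix(paste(s5, collapse = ""), paste(s3, collapse = ""),
                 max_closable = max_closable, wobble = wobble)
    })
    i <- match(hmap$helix[k], tally$helix)
    if (is.null(masks[[1]]) || is.null(masks[[2]])) next
    if (identical(masks[[1]], "lenmis") || identical(masks[[2]], "lenmis") ||
        length(masks[[1]]) != length(masks[[2]])) {
      tally$structure_altering[i] <- TRUE
      tally$detail[i] <- "strand length change between types"
    } else if (!identical(masks[[1]], masks[[2]])) {
      tally$structure_altering[i] <- TRUE
      tally$detail[i] <- paste0("pairing differs at strand position(s) ",
                                paste(which(masks[[1]] != masks[[2]]),
                                      collapse = ","))
    }
  }
  unp <- match("unpaired", tally$helix)
  structure(list(per_helix = tally[-unp, , drop = FALSE],
                 unpaired_substitutions = tally$substitutions[unp],
                 unpaired_indels = tally$insertions[unp] +
                   tally$deletions[unp]),
            class = "rrn_structcmp")
}

#' @export
print.rrn_structcmp <- function(x, ...) {
  ph <- x$per_helix
  active <- ph[ph$substitutions + ph$insertions + ph$deletions > 0 |
                 ph$structure_altering, ]
  cat("helix-level comparison:", nrow(active), "helix/helices affected;",
      x$unpaired_substitutions, "unpaired substitutions\n")
  invisible(x)
}
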