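# Internal helpers shared across modules: IUPAC semantics, residue
# normalization, reverse complement, rounding policies.

# IUPAC nucleotide classes (DNA alphabet; U is normalized to T on input).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

ALLOWED_RESIDUES <- c(names(IUPAC_SETS), "-")

#' @keywords internal
#' @noRd
normalize_residues <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]),
                 ALLOWED_RESIDUES)
  if (length(bad) > 0) {
    stop("invalid residue character(s): ", paste(bad, collapse = ", "))
  }
  x
}

# Split a residue string into a character vector of single bases.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# TRUE where a base carries pairwise-comparable information (unambiguous,
# non-gap). Gaps, N and partial ambiguity codes are missing data.
is_determined <- function(b) b %in% c("A", "C", "G", "T")

# Does an unambiguous query base satisfy an IUPAC consensus code?
# A query that is itself ambiguous (incl. N) or a gap matches nothing:
# missing data never counts as a match.
iupac_match <- function(query, code) {
  ok <- is_determined(query) & code %in% names(IUPAC_SETS)
  ok & mapply(function(q, cd) q %in% IUPAC_SETS[[cd]], query, code,
              USE.NAMES = FALSE)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D", N = "N", "-" = "-")

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented to their partner code and gaps
#' are preserved.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse-complemented strings.
#' @export
#' @examples
#' revcomp("TTGACA")
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(unname(COMPLEMENT[chars(s)])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Round a vector of non-negative percentages to integers that sum exactly
# to `total` (largest-remainder / Hamilton method). Ties on remainder are
# broken by position order for determinism.
round_largest_remainder <- function(x, total = 100L) {
  if (length(x) == 0) return(integer(0))
  stopifnot(all(x >= 0))
  fl <- floor(x)
  rem <- x - fl
  short <- as.integer(round(total - sum(fl)))
  out <- as.integer(fl)
  if (short > 0) {
    take <- order(-rem, seq_along(x))[seq_len(short)]
    out[take] <- out[take] + 1L
  }
  out
}

# Modal base of a character vector after dropping missing data.
# Returns list(base, saturation, n) where saturation = modal count / n.
# A tie for the mode yields base = NA (no consensus can be called).
consensus_base <- function(bases) {
  det <- bases[is_determined(bases)]
  n <- length(det)
  if (n == 0) return(list(base = NA_character_, saturation = NA_real_, n = 0L))
  tab <- table(factor(det, levels = c("A", "C", "G", "T")))
  top <- max(tab)
  winners <- names(tab)[tab == top]
  base <- if (length(winners) == 1L) winners else NA_character_
  list(base = base, saturation = top / n, n = as.integer(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
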