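#' Construct a table of sequence records
#'
#' Sequence records are kept in an ordinary data frame with one row per
#' sequence and columns \code{id}, \code{strain}, \code{region},
#' \code{operon_type} and \code{residues}. Residues are normalized to the
#' uppercase DNA alphabet (RNA input is accepted; U becomes T) and may
#' contain IUPAC ambiguity codes and \code{-} gaps.
#'
#' @param id character vector of unique sequence identifiers.
#' @param residues character vector of sequences.
#' @param strain optional strain identifiers.
#' @param region one of \code{"16S"}, \code{"ITS"}, \code{"23S"},
#'   \code{"5S"}, \code{"upstream"}, \code{"operon"}, \code{"other"}.
#' @param operon_type one of \code{"Type1"}, \code{"Type2"},
#'   \code{"unknown"}.
#' @return data frame of class \code{rrn_seqs}.
#' @export
seq_records <- function(id, residues, strain = NA_character_,
                        region = "other", operon_type = "unknown") {
  stopifnot(length(id) == length(residues))
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  residues <- normalize_residues(residues)
  if (any(nchar(residues) == 0)) stop("empty residue string")
  region <- match_region(region, length(id))
  operon_type <- match_type(operon_type, length(id))
  out <- data.frame(id = as.character(id),
                    strain = rep_len(as.character(strain), length(id)),
                    region = region, operon_type = operon_type,
                    residues = residues, stringsAsFactors = FALSE)
  class(out) <- c("rrn_seqs", "data.frame")
  out
}

REGIONS <- c("16S", "ITS", "23S", "5S", "upstream", "operon", "other")
OPERON_TYPES <- c("Type1", "Type2", "unknown")

match_region <- function(x, n) {
  x <- rep_len(as.character(x), n)
  bad <- setdiff(unique(x[!is.na(x)]), REGIONS)
  if (length(bad)) stop("unknown region: ", paste(bad, collapse = ", "))
  ifelse(is.na(x), "other", x)
}

match_type <- function(x, n) {
  x <- rep_len(as.character(x), n)
  bad <- setdiff(unique(x[!is.na(x)]), OPERON_TYPES)
  if (length(bad)) stop("unknown operon type: ", paste(bad, collapse = ", "))
  ifelse(is.na(x), "unknown", x)
}

#' Read sequences from a FASTA file
#'
#' Headers are parsed as \code{id [strain=S] [region=R] [type=T]}: the first
#' whitespace-separated token is the id, and any later \code{key=value}
#' tokens populate the record metadata.
#'
#' @param path path to a FASTA file.
#' @return an \code{rrn_seqs} data frame (see [seq_records()]).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  toks <- strsplit(trimws(headers), "\\s+")
  ids <- vapply(toks, `[[`, character(1), 1L)
  get_tok <- function(tk, key) {
    hit <- grep(paste0("^", key, "="), tk, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
  }
  strains <- vapply(toks, get_tok, character(1), "strain")
  regions <- vapply(toks, get_tok, character(1), "region")
  types <- vapply(toks, get_tok, character(1), "type")
  seq_records(id = ids, residues = as.character(set), strain = strains,
              region = regions, operon_type = types)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: metadata present in the records is emitted as
#' \code{key=value} header tokens so that a read/write cycle round-trips.
#'
#' @param seqs an \code{rrn_seqs} data frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  hdr <- seqs$id
  hdr <- paste0(hdr, ifelse(is.na(seqs$strain), "",
                            paste0(" strain=", seqs$strain)))
  hdr <- paste0(hdr, ifelse(seqs$region == "other", "",
                            paste0(" region=", seqs$region)))
  hdr <- paste0(hdr, ifelse(seqs$operon_type == "unknown", "",
                            paste0(" type=", seqs$operon_type)))
  lines <- as.vector(rbind(paste0(">", hdr), seqs$residues))
  writeLines(lines, path)
  invisible(path)
}

#' Build a column-indexed alignment from equal-length records
#'
#' @param seqs an \code{rrn_seqs} data frame (or named character vector of
#'   aligned strings) with at least two rows, all of equal length.
#' @return an \code{rrn_alignment}: a character matrix with one row per
#'   sequence and one column per alignment position (1-based), with the
#'   record metadata in attribute \code{"meta"}.
#' @export
as_alignment <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- seq_records(id = names(seqs) %||% paste0("seq", seq_along(seqs)),
                        residues = unname(seqs))
  }
  len <- nchar(seqs$residues)
  if (length(unique(len)) != 1) {
    ref <- as.integer(names(which.max(table(len))))
    bad <- seqs$id[len != ref]
    stop("unequal sequence lengths in alignment; offending id(s): ",
         paste(bad, collapse = ", "))
  }
  if (nrow(seqs) < 2) stop("an alignment needs at least 2 sequences")
  mat <- do.call(rbind, lapply(seqs$residues, chars))
  rownames(mat) <- seqs$id
  attr(mat, "meta") <- seqs[, c("id", "strain", "region", "operon_type")]
  class(mat) <- c("rrn_alignment", class(mat))
  mat
}

#' Read an aligned multi-FASTA
#'
#' @inheritParams read_fasta
#' @return an \code{rrn_alignment} (see [as_alignment()]).
#' @export
read_alignment <- function(path) as_alignment(read_fasta(path))

#' @export
print.rrn_alignment <- function(x, ...) {
  cat("rrn_alignment:", nrow(x), "sequences x", ncol(x), "columns\n")
  invisible(x)
}

# Row of an alignment as a residue string.
aln_row <- function(aln, id) paste(aln[id, ], collapse = "")

#' Optimal global pairwise alignment (Needleman-Wunsch)
#'
#' Linear gap penalty, deterministic traceback: on ties the diagonal
#' (substitution) move is preferred, then the vertical move (gap in
#' \code{b}), then the horizontal move (gap in \code{a}).
#'
#' @param a,b residue strings (or single-row \code{rrn_seqs}).
#' @param match,mismatch,gap alignment scores (gap is per gapped position).
#' @return list with \code{score}, \code{a_aligned}, \code{b_aligned} and
#'   \code{alignment} (a 2-row \code{rrn_alignment}).
#' @export
#' @examples
#' align_pair_global("ACGT", "AGT")$score
align_pair_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a_id <- "a"; b_id <- "b"
  if (inherits(a, "rrn_seqs")) { a_id <- a$id[1]; a <- a$residues[1] }
  if (inherits(b, "rrn_seqs")) { b_id <- b$id[1]; b <- b$residues[1] }
  a <- normalize_residues(a); b <- normalize_residues(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  av <- chars(a); bv <- chars(b)
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- gap * (0:m)
  S[, 1] <- gap * (0:n)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  # traceback with fixed move preference: diagonal, up, left
  i <- n; j <- m; ra <- character(0); rb <- character(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(av[i] == bv[j], match, mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1
    }
  }
  out_a <- paste(ra, collapse = ""); out_b <- paste(rb, collapse = "")
  aln <- as_alignment(stats::setNames(c(out_a, out_b), c(a_id, b_id)))
  list(score = S[n + 1, m + 1], a_aligned = out_a, b_aligned = out_b,
       alignment = aln)
}

#' Read a strain metadata table
#'
#' @param path TSV with columns \code{strain}, \code{morphospecies},
#'   \code{operon_type} (extra columns are kept).
#' @return data frame.
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
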