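# Sigma-70 promoter element scanning.
#
# Upstream regions (ending at the transcript start) are scanned for the
# -10 (Pribnow box, consensus TATAAT), -35 (consensus TTGACA) and the
# optional extended -52 element (consensus AWWWWWTTTTT). An operon
# promoter is called likely functional when the -35 and the -10 windows
# each match the consensus at 3-6 of their 6 positions; the -52 element
# is reported but never contributes to the functional call.

#' Promoter consensus and spacing model
#'
#' @param minus10,minus35,minus52 IUPAC consensus strings (lengths 6, 6
#'   and 11).
#' @param spacer_35_10 allowed gap (nt) between the -35 end and the -10
#'   start.
#' @param spacer_52_35 allowed gap between the -52 end and the -35 start.
#' @param spacer_10_tss allowed gap between the -10 end and the
#'   transcript start (the 3' end of the upstream sequence).
#' @param min_matches,max_matches bounds of the functionality rule
#'   applied to the -35 and -10 match counts.
#' @return list of class \code{rrn_prom_consensus}.
#' @export
promoter_consensus <- function(minus10 = "TATAAT", minus35 = "TTGACA",
                               minus52 = "AWWWWWTTTTT",
                               spacer_35_10 = c(16L, 19L),
                               spacer_52_35 = c(7L, 9L),
                               spacer_10_tss = c(3L, 6L),
                               min_matches = 3L, max_matches = 6L) {
  stopifnot(nchar(minus10) == 6, nchar(minus35) == 6, nchar(minus52) == 11)
  structure(list(minus10 = minus10, minus35 = minus35, minus52 = minus52,
                 spacer_35_10 = spacer_35_10, spacer_52_35 = spacer_52_35,
                 spacer_10_tss = spacer_10_tss,
                 min_matches = min_matches, max_matches = max_matches),
            class = "rrn_prom_consensus")
}

#' Count consensus matches in a window
#'
#' Positions match when the window's unambiguous base lies in the IUPAC
#' class of the consensus at that position; an ambiguous or missing query
#' base (incl. N) never matches.
#'
#' @param window residue string.
#' @param motif IUPAC consensus string of the same length.
#' @return integer match count.
#' @export
#' @examples
#' match_count("TTGACA", "TTGACA")  # 6
#' match_count("CACACA", "TTGACA")  # 3
match_count <- function(window, motif) {
  window <- normalize_residues(window)
  if (nchar(window) != nchar(motif)) {
    stop("window length ", nchar(window), " does not match motif length ",
         nchar(motif))
  }
  sum(iupac_match(chars(window), chars(motif)))
}

# Best window for a motif with starts restricted to `starts`:
# maximal match count, ties broken by the window closest to the 3' end.
best_window <- function(seq, motif, starts) {
  starts <- starts[starts >= 1 & starts + nchar(motif) - 1 <= nchar(seq)]
  if (length(starts) == 0) return(NULL)
  counts <- vapply(starts, function(s) {
    match_count(substr(seq, s, s + nchar(motif) - 1), motif)
  }, numeric(1))
  s <- starts[max(which(counts == max(counts)))]
  list(start = s, end = s + nchar(motif) - 1L,
       sequence = substr(seq, s, s + nchar(motif) - 1),
       matches = as.integer(max(counts)))
}

#' Scan an upstream region for promoter elements
#'
#' The -10 window is chosen first (maximal match count within the allowed
#' distance of the transcript start, i.e. the sequence 3' end), then the
#' -35 within the allowed spacer upstream of the -10, then the -52
#' upstream of the -35. Ties are broken toward the 3' end.
#'
#' @param upstream residue string or single-row \code{rrn_seqs}; must end
#'   at the transcript start and be at least 60 nt.
#' @param consensus an \code{rrn_prom_consensus}.
#' @return list of class \code{rrn_promoter}: \code{minus10},
#'   \code{minus35}, \code{minus52} (each \code{start}, \code{end},
#'   \code{sequence}, \code{matches}; \code{minus52} may be NULL when no
#'   window fits), \code{functional} and
#'   \code{transcript_start_context} (residues 3' of the -10 window).
#' @export
scan_promoter <- function(upstream, consensus = promoter_consensus()) {
  seq_id <- "upstream"
  if (inherits(upstream, "rrn_seqs")) {
    seq_id <- upstream$id[1]; upstream <- upstream$residues[1]
  }
  upstream <- normalize_residues(upstream)
  n <- nchar(upstream)
  span <- nchar(consensus$minus52) + consensus$spacer_52_35[1] +
    nchar(consensus$minus35) + consensus$spacer_35_10[1] +
    nchar(consensus$minus10) + consensus$spacer_10_tss[1]
  if (n < span) {
    stop("upstream sequence of ", seq_id, " (", n,
         " nt) shorter than the composite promoter span (", span, " nt)")
  }
  # -10: end must sit spacer_10_tss nt before the transcript start
  ends10 <- n - consensus$spacer_10_tss[2]:consensus$spacer_10_tss[1]
  m10 <- best_window(upstream, consensus$minus10, ends10 - 5L)
  # -35: its end precedes the -10 start by the allowed spacer
  ends35 <- m10$start - 1L - consensus$spacer_35_10[2]:consensus$spacer_35_10[1]
  m35 <- best_window(upstream, consensus$minus35, ends35 - 5L)
  if (is.null(m35)) stop("no room for a -35 window in ", seq_id)
  # -52: upstream of the -35
  ends52 <- m35$start - 1L - consensus$spacer_52_35[2]:consensus$spacer_52_35[1]
  m52 <- best_window(upstream, consensus$minus52, ends52 - 10L)
  functional <- m35$matches >= consensus$min_matches &&
    m35$matches <= consensus$max_matches &&
    m10$matches >= consensus$min_matches &&
    m10$matches <= consensus$max_matches
  structure(list(seq_id = seq_id, minus10 = m10, minus35 = m35,
                 minus52 = m52, functional = functional,
                 transcript_start_context = substr(upstream, m10$end + 1L,
                                                   n)),
            class = "rrn_promoter")
}

#' @export
print.rrn_promoter <- function(x, ...) {
  cat(sprintf("%s: -35 %s (%d/6), -10 %s (%d/6) -> %slikely functional\n",
              x$seq_id, x$minus35$sequence, x$minus35$matches,
              x$minus10$sequence, x$minus10$matches,
              if (x$functional) "" else "not "))
  invisible(x)
}

#' Tabulate promoter scans across upstream regions
#'
#' @param upstreams \code{rrn_seqs} of upstream regions.
#' @param consensus an \code{rrn_prom_consensus}.
#' @return data frame mirroring a promoter comparison table: one row per
#'   sequence with the three element windows, sequences, match counts and
#'   the functional call.
#' @export
promoter_table <- function(upstreams, consensus = promoter_consensus()) {
  rows <- lapply(seq_len(nrow(upstreams)), function(i) {
    p <- scan_promoter(upstreams[i, ], consensus)
    data.frame(id = p$seq_id,
               minus52 = if (is.null(p$minus52)) NA_character_ else
                 p$minus52$sequence,
               minus52_matches = if (is.null(p$minus52)) NA_integer_ else
                 p$minus52$matches,
               minus35 = p$minus35$sequence,
               minus35_start = p$minus35$start,
               minus35_matches = p$minus35$matches,
               minus10 = p$minus10$sequence,
               minus10_start = p$minus10$start,
               minus10_matches = p$minus10$matches,
               transcript_context = p$transcript_start_context,
               functional = p$functional,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
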