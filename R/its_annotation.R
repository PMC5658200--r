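# 16S-23S ITS domain annotation.
#
# The ITS between the 16S and 23S genes carries an ordered series of
# conserved domains: a leader, the D1-D1' helix, D2, a short spacer, D3,
# optionally tRNA-Ile / a V2 helix / tRNA-Ala, the Box-B helix, Box-A,
# D4, the V3 helix and the terminal D5. Domains are located by an ordered
# template search: motif domains by leftmost IUPAC match, helix domains
# by the first foldable stem-loop (leftmost start, then largest stem,
# then smallest loop) under canonical pairing.
#
# The shipped default template set (inst/extdata/its_templates.tsv) is a
# documented, editable starting point: only the D3 variants and the ITS
# start are fixed by comparative evidence for the study group; the other
# motifs are synthetic placeholders that users should replace with
# organism-specific templates.

ITS_DOMAIN_ORDER <- c("leader", "D1-D1'", "D2", "spacer_D2_D3", "D3",
                      "tRNA-Ile", "V2", "tRNA-Ala", "BoxB", "BoxA", "D4",
                      "V3", "D5")

#' Read an ITS domain template table
#'
#' @param path TSV with columns \code{domain}, \code{kind} (\code{motif},
#'   \code{terminal_motif} or \code{helix}), \code{pattern} (IUPAC string
#'   for motifs; \code{stem=a:b,loop=c:d[,max_start=s]} for helices) and
#'   \code{required} (\code{yes}/\code{no}).
#' @return data frame of class \code{rrn_its_templates}.
#' @export
read_its_templates <- function(path) {
  tp <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("domain", "kind", "pattern", "required")
  miss <- setdiff(need, names(tp))
  if (length(miss)) stop("template table lacks column(s): ",
                         paste(miss, collapse = ", "))
  class(tp) <- c("rrn_its_templates", "data.frame")
  tp
}

#' Default ITS domain templates shipped with the package
#'
#' @return template table (see [read_its_templates()]).
#' @export
default_its_templates <- function() {
  read_its_templates(system.file("extdata", "its_templates.tsv",
                                 package = "rrnhet", mustWork = TRUE))
}

# IUPAC pattern -> regular expression over ACGT.
iupac_regex <- function(pattern) {
  paste(vapply(chars(pattern), function(cd) {
    set <- IUPAC_SETS[[cd]]
    if (is.null(set)) stop("invalid IUPAC code in pattern: ", cd)
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Leftmost match of an IUPAC motif within seq[lo..hi]; NULL if none.
find_motif <- function(seq, pattern, lo, hi) {
  if (lo > hi) return(NULL)
  window <- substr(seq, lo, hi)
  m <- regexpr(iupac_regex(pattern), window)
  if (m == -1) return(NULL)
  start <- lo + as.integer(m) - 1L
  list(start = start, end = start + nchar(pattern) - 1L)
}

parse_helix_spec <- function(pattern) {
  kv <- strsplit(strsplit(pattern, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, character(1), 1))
  rng <- function(x) as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  list(stem = rng(vals$stem), loop = rng(vals$loop),
       max_start = if (!is.null(vals$max_start))
         as.integer(vals$max_start) else NA_integer_)
}

# First foldable stem-loop within seq[lo..hi]: leftmost start, then
# largest stem, then smallest loop; all stem pairs canonical (incl. G-U).
find_helix <- function(seq, spec, lo, hi, wobble = TRUE) {
  v <- chars(seq)
  kmin <- spec$stem[1]; kmax <- spec$stem[2]
  lmin <- spec$loop[1]; lmax <- spec$loop[2]
  smax <- if (!is.na(spec$max_start)) min(hi, lo + spec$max_start - 1L) else hi
  for (s in lo:smax) {
    for (k in kmax:kmin) {
      for (l in lmin:lmax) {
        e <- s + 2L * k + l - 1L
        if (e > hi) next
        i <- seq_len(k)
        if (all(pairs_canonically(v[s + i - 1L], v[e - i + 1L], wobble))) {
          return(list(start = s, end = e, stem = k, loop = l))
        }
      }
    }
  }
  NULL
}

its_row <- function(domain, start, end, present, seq) {
  data.frame(domain = domain,
             start = if (present) start else NA_integer_,
             end = if (present) end else NA_integer_,
             present = present,
             sequence = if (present) substr(seq, start, end) else "",
             stringsAsFactors = FALSE)
}

#' Annotate a 16S-23S ITS sequence
#'
#' @param seq ITS residue string or single-row \code{rrn_seqs} with
#'   \code{region == "ITS"}.
#' @param templates template table (default: shipped templates).
#' @param wobble count G-U as canonical when folding helix domains.
#' @return object of class \code{rrn_its}: data frame with columns
#'   \code{domain}, \code{start}, \code{end}, \code{present},
#'   \code{sequence} (rows ordered along the sequence; absent optional
#'   domains carry \code{present = FALSE}), with the 3-mer at the ITS
#'   start in attribute \code{"first3"} and the input id in
#'   \code{"seq_id"}.
#' @export
annotate_its <- function(seq, templates = default_its_templates(),
                         wobble = TRUE) {
  seq_id <- "its"
  if (inherits(seq, "rrn_seqs")) { seq_id <- seq$id[1]; seq <- seq$residues[1] }
  seq <- normalize_residues(seq)
  n <- nchar(seq)
  if (n < 50) stop("ITS sequence too short to annotate (", n, " nt)")
  tmpl <- function(d) {
    row <- templates[templates$domain == d, , drop = FALSE]
    if (nrow(row) == 0) stop("no template for domain ", d)
    row[1, ]
  }
  required <- function(d) identical(tmpl(d)$required, "yes")
  mandatory_motif <- function(d, lo, hi = n) {
    hit <- find_motif(seq, tmpl(d)$pattern, lo, hi)
    if (is.null(hit)) stop("mandatory domain ", d,
                           " not found in ", seq_id)
    hit
  }

  # D1-D1' helix must start near the ITS 5' end
  d1spec <- parse_helix_spec(tmpl("D1-D1'")$pattern)
  lim <- if (!is.na(d1spec$max_start)) d1spec$max_start else 40L
  d1 <- find_helix(seq, d1spec, 1L, n, wobble)
  if (is.null(d1) || d1$start > lim) {
    stop("no D1-D1' helix foldable within the first ", lim, " nt of ",
         seq_id)
  }
  d2 <- mandatory_motif("D2", d1$end + 1L)
  d3 <- mandatory_motif("D3", d2$end + 1L)
  boxa <- mandatory_motif("BoxA", d3$end + 1L)

  # optional tRNAs and V2 sit between D3 and Box-A
  trna_ile <- find_motif(seq, tmpl("tRNA-Ile")$pattern, d3$end + 1L,
                         boxa$start - 1L)
  ala_lo <- if (!is.null(trna_ile)) trna_ile$end + 1L else d3$end + 1L
  trna_ala <- find_motif(seq, tmpl("tRNA-Ala")$pattern, ala_lo,
                         boxa$start - 1L)
  v2 <- NULL
  if (!is.null(trna_ile) && !is.null(trna_ala)) {
    v2 <- find_helix(seq, parse_helix_spec(tmpl("V2")$pattern),
                     trna_ile$end + 1L, trna_ala$start - 1L, wobble)
  }
  boxb_lo <- if (!is.null(trna_ala)) trna_ala$end + 1L else
    if (!is.null(trna_ile)) trna_ile$end + 1L else d3$end + 1L
  boxb <- find_helix(seq, parse_helix_spec(tmpl("BoxB")$pattern), boxb_lo,
                     boxa$start - 1L, wobble)
  if (is.null(boxb)) stop("no Box-B helix foldable before Box-A in ", seq_id)

  d4 <- mandatory_motif("D4", boxa$end + 1L)
  v3 <- find_helix(seq, parse_helix_spec(tmpl("V3")$pattern), d4$end + 1L,
                   n, wobble)
  if (is.null(v3)) stop("no V3 helix foldable after D4 in ", seq_id)
  d5kind <- tmpl("D5")$kind
  d5hit <- find_motif(seq, tmpl("D5")$pattern, v3$end + 1L, n)
  if (is.null(d5hit)) stop("mandatory domain D5 not found in ", seq_id)
  d5 <- list(start = d5hit$start,
             end = if (identical(d5kind, "terminal_motif")) n else d5hit$end)

  rows <- rbind(
    its_row("leader", 1L, d1$start - 1L, d1$start > 1L, seq),
    its_row("D1-D1'", d1$start, d1$end, TRUE, seq),
    its_row("D2", d2$start, d2$end, TRUE, seq),
    its_row("spacer_D2_D3", d2$end + 1L, d3$start - 1L,
            d3$start > d2$end + 1L, seq),
    its_row("D3", d3$start, d3$end, TRUE, seq),
    its_row("tRNA-Ile", trna_ile$start %||% NA, trna_ile$end %||% NA,
            !is.null(trna_ile), seq),
    its_row("V2", v2$start %||% NA, v2$end %||% NA, !is.null(v2), seq),
    its_row("tRNA-Ala", trna_ala$start %||% NA, trna_ala$end %||% NA,
            !is.null(trna_ala), seq),
    its_row("BoxB", boxb$start, boxb$end, TRUE, seq),
    its_row("BoxA", boxa$start, boxa$end, TRUE, seq),
    its_row("D4", d4$start, d4$end, TRUE, seq),
    its_row("V3", v3$start, v3$end, TRUE, seq),
    its_row("D5", d5$start, d5$end, TRUE, seq))
  pres <- rows[rows$present, ]
  if (any(diff(pres$start) <= 0) || any(pres$start[-1] <= pres$end[-nrow(pres)])) {
    stop("overlapping domain intervals in ", seq_id)
  }
  for (d in ITS_DOMAIN_ORDER) {
    if (!d %in% rows$domain) stop("internal: domain ", d, " missing")
  }
  miss_req <- vapply(c("tRNA-Ile", "V2", "tRNA-Ala"), function(d) {
    required(d) && !rows$present[rows$domain == d]
  }, logical(1))
  if (any(miss_req)) {
    stop("required domain(s) absent: ",
         paste(c("tRNA-Ile", "V2", "tRNA-Ala")[miss_req], collapse = ", "))
  }
  attr(rows, "first3") <- substr(seq, 1, 3)
  attr(rows, "seq_id") <- seq_id
  attr(rows, "length") <- n
  class(rows) <- c("rrn_its", "data.frame")
  rows
}

domain_length <- function(ann, domain) {
  row <- ann[ann$domain == domain, ]
  if (!row$present[1]) return(NA_integer_)
  row$end[1] - row$start[1] + 1L
}

domain_sequence <- function(ann, domain) {
  row <- ann[ann$domain == domain, ]
  if (!row$present[1]) NA_character_ else row$sequence[1]
}

#' Comparative ITS feature table across operon types
#'
#' Summarizes, per label, the ITS features that distinguish divergent
#' operon architectures: the first three ITS bases, the length range of
#' the D2-D3 spacer, the D3 motif variants, the D4 and D5 length ranges
#' and the tRNA presence pattern.
#'
#' @param annotations list of \code{rrn_its} objects.
#' @param labels character vector (same length) of operon-type labels.
#' @return data frame with one row per label.
#' @export
its_feature_table <- function(annotations, labels) {
  stopifnot(length(annotations) == length(labels))
  out <- lapply(split(annotations, labels), function(anns) {
    sp <- vapply(anns, domain_length, integer(1), "spacer_D2_D3")
    d4 <- vapply(anns, domain_length, integer(1), "D4")
    d5 <- vapply(anns, domain_length, integer(1), "D5")
    f3 <- vapply(anns, function(a) attr(a, "first3"), character(1))
    d3 <- vapply(anns, domain_sequence, character(1), "D3")
    ile <- vapply(anns, function(a) a$present[a$domain == "tRNA-Ile"],
                  logical(1))
    ala <- vapply(anns, function(a) a$present[a$domain == "tRNA-Ala"],
                  logical(1))
    data.frame(n = length(anns),
               first3 = paste(sort(unique(f3)), collapse = "/"),
               spacer_d2_d3_min = min(sp, na.rm = TRUE),
               spacer_d2_d3_max = max(sp, na.rm = TRUE),
               d3_motifs = paste(sort(unique(d3)), collapse = "/"),
               d4_min = min(d4, na.rm = TRUE),
               d4_max = max(d4, na.rm = TRUE),
               d5_min = min(d5, na.rm = TRUE),
               d5_max = max(d5, na.rm = TRUE),
               trna_pattern = sprintf("Ile:%d/%d;Ala:%d/%d", sum(ile),
                                      length(ile), sum(ala), length(ala)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(label = rownames(res), stringsAsFactors = FALSE),
               res)
  rownames(res) <- NULL
  res
}

#' Write ITS annotations as a GFF-like TSV
#'
#' @param annotations list of \code{rrn_its} objects.
#' @param path output path.
#' @export
write_its_tsv <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    d <- as.data.frame(a)
    d$seqid <- attr(a, "seq_id")
    d[, c("seqid", "domain", "start", "end", "present", "sequence")]
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
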