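# Seeded synthetic multi-operon datasets.
#
# The generator emulates the study design every stage of the pipeline
# assumes: each strain carries `operons_per_strain` rRNA operons of which
# `n_type1` are a highly divergent type (Type 1) and the rest are
# near-identical copies (Type 2); between-type divergence is planted as
# an exact set of signature substitutions localized in designated
# helices; operon types differ in ITS architecture (Type 1: ITS starts
# AAC, D2-D3 spacer 10-11 nt, D3 = GGTAY, D5 6 nt; Type 2: ITS starts
# TTT, spacer 4-6 nt, D3 = GGTTC, D5 15-16 nt) and carry type-specific
# sigma-70 promoters; species are separated by additional planted
# mutations so that identity-based delimitation recovers them. Background
# sequence is i.i.d. uniform over ACGT outside the planted templates.
# All randomness flows from one seed; reruns are byte-identical.

#' Configuration for the synthetic dataset generator
#'
#' @param n_species number of genospecies.
#' @param strains_per_species strains per genospecies.
#' @param operons_per_strain rRNA operon copies per strain.
#' @param n_type1 how many of those copies are the divergent Type 1.
#' @param len_16s,len_23s gene lengths (nt).
#' @param signature_positions number of planted between-type
#'   substitutions in the 16S; ignored when
#'   \code{between_type_divergence} is given.
#' @param between_type_divergence optional fraction; when supplied the
#'   planted substitution count is \code{round(d * len_16s)}.
#' @param within_type_site_noise per-site, per-copy substitution
#'   probability within a type.
#' @param species_divergence fraction of 16S sites carrying
#'   species-private substitutions (planted off the signature so that
#'   between-species identity drops below the delimitation threshold
#'   without disturbing the signature).
#' @param reversion_rate per-signature-position, per-sequence probability
#'   of carrying the other type's consensus base (gene-conversion
#'   footprint).
#' @param helix_map optional \code{rrn_helixmap} for the 16S; defaults to
#'   a regular synthetic map of 12 helices.
#' @param signature_helices helix names hosting the planted signature.
#' @param clone_library list(\code{n_clones}, \code{type1_bias_weight}):
#'   sampling weights emulating PCR bias against the divergent type.
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @return validated config list of class \code{rrn_syncfg}.
#' @export
synthetic_config <- function(n_species = 3L, strains_per_species = 3L,
                             operons_per_strain = 5L, n_type1 = 1L,
                             len_16s = 1500L, len_23s = 600L,
                             signature_positions = 123L,
                             between_type_divergence = NULL,
                             within_type_site_noise = 0.002,
                             species_divergence = 0.02,
                             reversion_rate = 0,
                             helix_map = NULL, signature_helices = NULL,
                             clone_library = list(n_clones = 10L,
                                                  type1_bias_weight = 0.5),
                             seed = 1L) {
  if (!is.null(between_type_divergence)) {
    stopifnot(between_type_divergence >= 0, between_type_divergence <= 1)
    signature_positions <- as.integer(round(between_type_divergence *
                                              len_16s))
  }
  stopifnot(n_species >= 1, strains_per_species >= 1,
            operons_per_strain >= 2, n_type1 >= 1,
            n_type1 < operons_per_strain,
            within_type_site_noise >= 0, within_type_site_noise <= 1,
            species_divergence >= 0, species_divergence <= 1,
            reversion_rate >= 0, reversion_rate <= 1)
  if (signature_positions > len_16s) {
    stop("signature positions (", signature_positions,
         ") exceed 16S length (", len_16s, ")")
  }
  if (is.null(helix_map)) helix_map <- default_synthetic_helix_map(len_16s)
  if (is.null(signature_helices)) {
    signature_helices <- c("H6", "H9", "H10", "H27", "H28", "H33", "H42")
  }
  stopifnot(all(signature_helices %in% helix_map$helix))
  structure(list(n_species = as.integer(n_species),
                 strains_per_species = as.integer(strains_per_species),
                 operons_per_strain = as.integer(operons_per_strain),
                 n_type1 = as.integer(n_type1),
                 len_16s = as.integer(len_16s),
                 len_23s = as.integer(len_23s),
                 signature_positions = as.integer(signature_positions),
                 within_type_site_noise = within_type_site_noise,
                 species_divergence = species_divergence,
                 reversion_rate = reversion_rate,
                 helix_map = helix_map,
                 signature_helices = signature_helices,
                 clone_library = clone_library,
                 seed = as.integer(seed)),
            class = "rrn_syncfg")
}

#' Regular synthetic helix map for a 16S-length molecule
#'
#' Twelve 10-bp helices at regular offsets, named after helices commonly
#' discussed in comparative 16S models. A demonstration map for synthetic
#' data, not comparative-model coordinates.
#'
#' @param len_16s molecule length.
#' @return an \code{rrn_helixmap}.
#' @export
default_synthetic_helix_map <- function(len_16s = 1500L) {
  names <- c("H6", "H9", "H10", "H15", "H18", "H21", "H24", "H27", "H28",
             "H33", "H38", "H42")
  starts <- 40L + (seq_along(names) - 1L) * 120L
  stopifnot(max(starts) + 27L <= len_16s)
  helix_map(data.frame(molecule = "16S", helix = names,
                       strand5_start = starts, strand5_end = starts + 9L,
                       strand3_start = starts + 18L,
                       strand3_end = starts + 27L,
                       stringsAsFactors = FALSE))
}

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                              collapse = "")

mutate_base <- function(b) vapply(b, function(x)
  sample(setdiff(BASES, x), 1L), character(1), USE.NAMES = FALSE)

# Draw a concrete instance of an IUPAC pattern.
instantiate_pattern <- function(pattern) {
  paste(vapply(chars(pattern), function(cd) {
    set <- IUPAC_SETS[[cd]]
    if (length(set) == 1) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

# Random stem-loop instance: list(seq, stem, loop) with Watson-Crick arms.
instantiate_helix <- function(spec) {
  k <- if (spec$stem[1] == spec$stem[2]) spec$stem[1] else
    sample(spec$stem[1]:spec$stem[2], 1L)
  l <- if (spec$loop[1] == spec$loop[2]) spec$loop[1] else
    sample(spec$loop[1]:spec$loop[2], 1L)
  arm5 <- rand_seq(k)
  list(seq = paste0(arm5, rand_seq(l), revcomp(arm5)), stem = k, loop = l)
}

# Assemble one ITS with ground-truth boundaries; per-type architecture.
# with_trnas toggles the optional tRNA-Ile / V2 / tRNA-Ala block.
build_its <- function(type, with_trnas, templates) {
  tmpl <- function(d) templates[templates$domain == d, , drop = FALSE][1, ]
  parts <- character(0)
  truth <- data.frame(domain = character(0), start = integer(0),
                      end = integer(0), present = logical(0),
                      stringsAsFactors = FALSE)
  pos <- 0L
  push <- function(domain, s, present = TRUE) {
    if (present && nchar(s) > 0) {
      parts <<- c(parts, s)
      truth <<- rbind(truth, data.frame(
        domain = domain, start = pos + 1L, end = pos + nchar(s),
        present = TRUE, stringsAsFactors = FALSE))
      pos <<- pos + nchar(s)
    } else {
      truth <<- rbind(truth, data.frame(
        domain = domain, start = NA_integer_, end = NA_integer_,
        present = FALSE, stringsAsFactors = FALSE))
    }
  }
  first3 <- if (type == "Type1") "AAC" else "TTT"
  push("leader", paste0(first3, rand_seq(sample(4:8, 1L))))
  push("D1-D1'", instantiate_helix(parse_helix_spec(tmpl("D1-D1'")$pattern))$seq)
  push("D2", instantiate_pattern(tmpl("D2")$pattern))
  spacer_len <- if (type == "Type1") sample(10:11, 1L) else sample(4:6, 1L)
  push("spacer_D2_D3", rand_seq(spacer_len))
  d3 <- if (type == "Type1") {
    paste0("GGTA", sample(c("C", "T"), 1L))  # GGTAY
  } else "GGTTC"
  push("D3", d3)
  if (with_trnas) {
    push("pre_ile", rand_seq(sample(2:4, 1L)))
    push("tRNA-Ile", instantiate_pattern(tmpl("tRNA-Ile")$pattern))
    push("pre_v2", rand_seq(sample(1:3, 1L)))
    push("V2", instantiate_helix(parse_helix_spec(tmpl("V2")$pattern))$seq)
    push("pre_ala", rand_seq(sample(1:3, 1L)))
    push("tRNA-Ala", instantiate_pattern(tmpl("tRNA-Ala")$pattern))
  } else {
    push("tRNA-Ile", "", FALSE)
    push("V2", "", FALSE)
    push("tRNA-Ala", "", FALSE)
  }
  push("pre_boxb", rand_seq(sample(2:4, 1L)))
  push("BoxB", instantiate_helix(parse_helix_spec(tmpl("BoxB")$pattern))$seq)
  push("pre_boxa", rand_seq(sample(2:4, 1L)))
  push("BoxA", instantiate_pattern(tmpl("BoxA")$pattern))
  push("pre_d4", rand_seq(sample(2:4, 1L)))
  push("D4", instantiate_pattern(tmpl("D4")$pattern))
  push("pre_v3", rand_seq(sample(1:3, 1L)))
  push("V3", instantiate_helix(parse_helix_spec(tmpl("V3")$pattern))$seq)
  push("pre_d5", rand_seq(sample(1:3, 1L)))
  d5_anchor <- instantiate_pattern(tmpl("D5")$pattern)
  d5_tail <- if (type == "Type1") "" else rand_seq(sample(9:10, 1L))
  push("D5", paste0(d5_anchor, d5_tail))
  list(seq = paste(parts, collapse = ""),
       truth = truth[!grepl("^pre_", truth$domain), , drop = FALSE])
}

# Generate an ITS whose annotation under the same templates recovers the
# planted boundaries exactly; resamples flanks on accidental matches.
build_verified_its <- function(type, with_trnas, templates,
                               max_tries = 60L) {
  for (i in seq_len(max_tries)) {
    cand <- build_its(type, with_trnas, templates)
    ann <- tryCatch(annotate_its(cand$seq, templates), error = function(e)
      NULL)
    if (is.null(ann)) next
    got <- as.data.frame(ann)[, c("domain", "start", "end", "present")]
    want <- cand$truth
    want <- want[match(got$domain, want$domain), ]
    rownames(got) <- rownames(want) <- NULL
    if (isTRUE(all.equal(got, want))) return(cand)
  }
  stop("could not generate a round-trip-verifiable ITS in ", max_tries,
       " attempts")
}

# Planted promoter upstream region with verified element recovery.
build_verified_promoter <- function(type, consensus = promoter_consensus(),
                                    max_tries = 60L) {
  els <- if (type == "Type1") {
    list(m52 = "AAAAGTACGGT", m35 = "CACACA", m10 = "TACAAT")
  } else {
    list(m52 = "AATTTTTTTGA", m35 = "TTGACA", m10 = "TATATT")
  }
  for (i in seq_len(max_tries)) {
    sp52 <- sample(consensus$spacer_52_35[1]:consensus$spacer_52_35[2], 1L)
    sp3510 <- sample(consensus$spacer_35_10[1]:consensus$spacer_35_10[2], 1L)
    sptss <- sample(consensus$spacer_10_tss[1]:consensus$spacer_10_tss[2], 1L)
    pad <- 80L - (11L + sp52 + 6L + sp3510 + 6L + sptss)
    seq <- paste0(rand_seq(pad), els$m52, rand_seq(sp52), els$m35,
                  rand_seq(sp3510), els$m10, rand_seq(sptss))
    windows <- list(
      minus52 = c(pad + 1L, pad + 11L),
      minus35 = c(pad + 11L + sp52 + 1L, pad + 11L + sp52 + 6L),
      minus10 = c(pad + 17L + sp52 + sp3510 + 1L,
                  pad + 17L + sp52 + sp3510 + 6L))
    sc <- tryCatch(scan_promoter(seq, consensus), error = function(e) NULL)
    if (is.null(sc)) next
    ok <- sc$minus10$start == windows$minus10[1] &&
      sc$minus35$start == windows$minus35[1] &&
      !is.null(sc$minus52) && sc$minus52$start == windows$minus52[1]
    if (ok) return(list(seq = seq, windows = windows,
                        functional = sc$functional))
  }
  stop("could not generate a verifiable promoter region in ", max_tries,
       " attempts")
}

#' Generate a synthetic multi-strain rRNA operon dataset
#'
#' @param cfg an \code{rrn_syncfg} from [synthetic_config()].
#' @param templates ITS template table used both to build and (later) to
#'   annotate the ITS regions.
#' @return object of class \code{rrn_dataset}: list with \code{config},
#'   \code{seqs} (all regions, tagged), \code{aln_16s} and
#'   \code{aln_23s} (gapless alignments of the per-operon genes),
#'   \code{metadata} (per-sequence strain / region / type table),
#'   \code{helix_map} and \code{truth} (planted operon types, signature
#'   positions with helix assignment, genospecies, ITS boundaries,
#'   promoter windows, reversion count).
#' @export
generate_dataset <- function(cfg = synthetic_config(),
                             templates = default_its_templates()) {
  set.seed(cfg$seed)
  len <- cfg$len_16s
  hmap <- cfg$helix_map

  # helix positions available for the planted signature
  helix_pos <- unlist(lapply(which(hmap$helix %in% cfg$signature_helices),
                             function(k) c(hmap$strand5_start[k]:hmap$strand5_end[k],
                                           hmap$strand3_start[k]:hmap$strand3_end[k])))
  helix_pos <- helix_pos[helix_pos <= len]
  if (cfg$signature_positions > length(helix_pos)) {
    stop("signature positions (", cfg$signature_positions,
         ") exceed capacity of designated helices (", length(helix_pos),
         " sites)")
  }
  sig_pos <- sort(sample(helix_pos, cfg$signature_positions))
  sig_helix <- vapply(sig_pos, helix_of_position, character(1), hmap)

  anc2_16s <- chars(rand_seq(len))
  anc1_16s <- anc2_16s
  anc1_16s[sig_pos] <- mutate_base(anc2_16s[sig_pos])

  n_sig_23s <- as.integer(round(cfg$signature_positions / len * cfg$len_23s))
  sig_23s <- sort(sample(cfg$len_23s, n_sig_23s))
  anc2_23s <- chars(rand_seq(cfg$len_23s))
  anc1_23s <- anc2_23s
  anc1_23s[sig_23s] <- mutate_base(anc2_23s[sig_23s])

  # species-private substitutions, planted off the 16S signature
  free_pos <- setdiff(seq_len(len), sig_pos)
  m_sp <- as.integer(ceiling(cfg$species_divergence * len / 2))
  m_sp23 <- as.integer(ceiling(cfg$species_divergence * cfg$len_23s / 2))

  noise <- function(v, rate) {
    if (rate <= 0) return(v)
    hit <- which(stats::runif(length(v)) < rate)
    if (length(hit)) v[hit] <- mutate_base(v[hit])
    v
  }

  its_templates <- templates
  # ITS and promoter instances shared per operon slot / type
  op_types <- c(rep("Type1", cfg$n_type1),
                rep("Type2", cfg$operons_per_strain - cfg$n_type1))
  with_trnas <- rep(c(TRUE, FALSE),
                    length.out = cfg$operons_per_strain - cfg$n_type1)
  its_slots <- vector("list", cfg$operons_per_strain)
  for (k in seq_len(cfg$operons_per_strain)) {
    tr <- if (op_types[k] == "Type1") TRUE else
      with_trnas[k - cfg$n_type1]
    its_slots[[k]] <- build_verified_its(op_types[k], tr, its_templates)
  }
  prom <- list(Type1 = build_verified_promoter("Type1"),
               Type2 = build_verified_promoter("Type2"))

  ids <- character(0); strains <- character(0); regions <- character(0)
  types <- character(0); residues <- character(0)
  add_seq <- function(id, strain, region, type, res) {
    ids <<- c(ids, id); strains <<- c(strains, strain)
    regions <<- c(regions, region); types <<- c(types, type)
    residues <<- c(residues, res)
  }
  genospecies <- character(0)
  its_truth <- list()
  reversion_events <- 0L

  for (g in seq_len(cfg$n_species)) {
    sp_label <- paste0("species", g)
    sp_pos16 <- sample(free_pos, m_sp)
    sp_base16 <- mutate_base(anc2_16s[sp_pos16])
    sp_pos23 <- sample(cfg$len_23s, m_sp23)
    sp_base23 <- mutate_base(anc2_23s[sp_pos23])
    sp1_16s <- anc1_16s; sp2_16s <- anc2_16s
    sp1_16s[sp_pos16] <- sp_base16; sp2_16s[sp_pos16] <- sp_base16
    sp1_23s <- anc1_23s; sp2_23s <- anc2_23s
    sp1_23s[sp_pos23] <- sp_base23; sp2_23s[sp_pos23] <- sp_base23
    # avoid turning a species site into an accidental signature conflict:
    # species substitutions are applied identically to both types, so
    # between-type differences remain exactly the planted signature.
    for (h in seq_len(cfg$strains_per_species)) {
      strain <- paste0("sp", g, "_st", h)
      genospecies[strain] <- sp_label
      for (k in seq_len(cfg$operons_per_strain)) {
        tp <- op_types[k]
        base16 <- if (tp == "Type1") sp1_16s else sp2_16s
        base23 <- if (tp == "Type1") sp1_23s else sp2_23s
        v16 <- noise(base16, cfg$within_type_site_noise)
        v23 <- noise(base23, cfg$within_type_site_noise)
        if (cfg$reversion_rate > 0) {
          other16 <- if (tp == "Type1") anc2_16s else anc1_16s
          flip <- which(stats::runif(length(sig_pos)) < cfg$reversion_rate)
          if (length(flip)) {
            v16[sig_pos[flip]] <- other16[sig_pos[flip]]
            reversion_events <- reversion_events + length(flip)
          }
        }
        op_id <- paste0(strain, "_op", k)
        add_seq(paste0(op_id, "_16S"), strain, "16S", tp,
                paste(v16, collapse = ""))
        add_seq(paste0(op_id, "_23S"), strain, "23S", tp,
                paste(v23, collapse = ""))
        add_seq(paste0(op_id, "_ITS"), strain, "ITS", tp,
                its_slots[[k]]$seq)
        its_truth[[paste0(op_id, "_ITS")]] <- its_slots[[k]]$truth
        add_seq(paste0(op_id, "_upstream"), strain, "upstream", tp,
                prom[[tp]]$seq)
      }
    }
  }

  seqs <- seq_records(id = ids, residues = residues, strain = strains,
                      region = regions, operon_type = types)
  aln_16s <- as_alignment(seqs[seqs$region == "16S", ])
  aln_23s <- as_alignment(seqs[seqs$region == "23S", ])
  truth <- list(
    operon_type = stats::setNames(types, ids),
    signature_positions = sig_pos,
    signature_helix = stats::setNames(sig_helix, sig_pos),
    signature_positions_23s = sig_23s,
    genospecies = genospecies,
    its_boundaries = its_truth,
    promoter_windows = lapply(prom, `[[`, "windows"),
    helix_counts = table(sig_helix),
    reversion_events = reversion_events)
  structure(list(config = cfg, seqs = seqs, aln_16s = aln_16s,
                 aln_23s = aln_23s,
                 metadata = seqs[, c("id", "strain", "region",
                                     "operon_type")],
                 helix_map = hmap, truth = truth),
            class = "rrn_dataset")
}

#' @export
print.rrn_dataset <- function(x, ...) {
  cfg <- x$config
  cat("rrn_dataset:", cfg$n_species, "species x", cfg$strains_per_species,
      "strains x", cfg$operons_per_strain, "operons, seed", cfg$seed, "\n")
  invisible(x)
}

#' Simulate a clone library from one strain's operon set
#'
#' Clones are drawn with replacement under per-operon weights, emulating
#' PCR amplification bias (a zero weight reproduces a type missed by
#' cloning altogether).
#'
#' @param operons \code{rrn_seqs} of the operon sequences to sample.
#' @param n_clones number of clones (> 0).
#' @param weights non-negative sampling weights, one per operon row.
#' @param seed integer seed.
#' @return \code{rrn_seqs} of clone sequences, ids
#'   \code{<operon>_clone<i>}.
#' @export
simulate_clone_library <- function(operons, n_clones, weights = NULL,
                                   seed = 1L) {
  if (n_clones < 1) stop("n_clones must be positive")
  weights <- weights %||% rep(1, nrow(operons))
  stopifnot(length(weights) == nrow(operons))
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero")
  }
  set.seed(seed)
  draw <- sample(seq_len(nrow(operons)), n_clones, replace = TRUE,
                 prob = weights)
  src <- operons[draw, ]
  seq_records(id = paste0(src$id, "_clone", seq_len(n_clones)),
              residues = src$residues, strain = src$strain,
              region = src$region, operon_type = src$operon_type)
}

#' Write a synthetic dataset to a directory
#'
#' Emits \code{sequences.fasta}, \code{alignment_16s.fasta},
#' \code{alignment_23s.fasta}, \code{metadata.tsv},
#' \code{helix_map.tsv}, \code{truth.json} and \code{config.yaml}.
#'
#' @param ds an \code{rrn_dataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$seqs, file.path(dir, "sequences.fasta"))
  write_fasta(ds$seqs[ds$seqs$region == "16S", ],
              file.path(dir, "alignment_16s.fasta"))
  write_fasta(ds$seqs[ds$seqs$region == "23S", ],
              file.path(dir, "alignment_23s.fasta"))
  utils::write.table(ds$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(ds$helix_map),
                     file.path(dir, "helix_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  # named vectors must become lists to keep their names in JSON
  truth$helix_counts <- as.list(truth$helix_counts)
  truth$operon_type <- as.list(truth$operon_type)
  truth$signature_helix <- as.list(truth$signature_helix)
  truth$genospecies <- as.list(truth$genospecies)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- ds$config
  cfg$helix_map <- NULL
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
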