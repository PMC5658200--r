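# End-to-end orchestration: typing -> divergence ranges -> ITS feature
# table -> promoter table -> helix variability -> genospecies, plus a
# machine-readable summary. Each stage is the module function applied to
# the dataset; every number in the summary is traceable to a stage table.

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory path.
#' @return an \code{rrn_dataset} (without the original config object;
#'   config values come from \code{config.yaml}).
#' @export
read_dataset <- function(dir) {
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  hmap <- read_helix_map(file.path(dir, "helix_map.tsv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  if (!is.null(truth)) {
    truth$its_boundaries <- lapply(truth$its_boundaries, function(d) {
      d$start <- as.integer(d$start); d$end <- as.integer(d$end); d
    })
  }
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  structure(list(config = cfg, seqs = seqs,
                 aln_16s = as_alignment(seqs[seqs$region == "16S", ]),
                 aln_23s = if (sum(seqs$region == "23S") >= 2)
                   as_alignment(seqs[seqs$region == "23S", ]) else NULL,
                 metadata = seqs[, c("id", "strain", "region",
                                     "operon_type")],
                 helix_map = hmap, truth = truth),
            class = "rrn_dataset")
}

# Per-strain, per-type majority-rule consensus rows of an alignment.
strain_type_consensus <- function(aln, strains, labels, type) {
  ids <- rownames(aln)
  pick <- ids[labels[ids] == type]
  by_strain <- split(pick, strains[pick])
  rows <- vapply(by_strain, function(members) {
    sub <- aln[members, , drop = FALSE]
    apply(sub, 2, function(col) {
      cb <- consensus_base(col)
      if (is.na(cb$base)) col[1] else cb$base
    })
  }, character(ncol(aln)))
  t(rows)
}

#' Run the full operon-heterogeneity pipeline
#'
#' @param dataset an \code{rrn_dataset} (from [generate_dataset()] or
#'   [read_dataset()]).
#' @param out_dir optional directory for the report bundle
#'   (\code{summary.json} plus per-stage TSVs).
#' @param saturation_threshold consensus saturation for the signature.
#' @param identity_threshold percent identity for genospecies
#'   delimitation.
#' @param consensus promoter consensus/spacing model.
#' @param max_closable helix-closure allowance.
#' @param its_templates template table for ITS annotation.
#' @param use_morphology,use_tree toggle delimitation criteria 3 and 2;
#'   when off, the partition rests on the remaining criteria and the
#'   provenance records say so.
#' @param clades optional named vector strain -> clade label (criterion
#'   2); see [clades_from_tree()].
#' @return list of class \code{rrn_report}: stage tables plus a
#'   \code{summary} list of the headline numbers.
#' @export
run_pipeline <- function(dataset, out_dir = NULL,
                         saturation_threshold = 0.85,
                         identity_threshold = 98.7,
                         consensus = promoter_consensus(),
                         max_closable = 2,
                         its_templates = default_its_templates(),
                         use_morphology = TRUE, use_tree = FALSE,
                         clades = NULL) {
  seqs <- dataset$seqs
  meta <- dataset$metadata
  aln16 <- dataset$aln_16s
  labels <- stats::setNames(meta$operon_type, meta$id)
  strains <- stats::setNames(meta$strain, meta$id)
  truth <- dataset$truth

  # --- operon typing ---
  sig <- find_signature(aln16, labels, saturation_threshold)
  typing <- classify_alignment(aln16, sig)
  typing_accuracy <- 100 * mean(typing$assigned_type ==
                                  labels[typing$seq_id])
  reversions <- detect_reversions(aln16, labels, sig)

  # --- divergence ranges ---
  dm16 <- identity_matrix(aln16)
  within_range <- range_summary(dm16, labels[dm16$ids],
                                c("Type1", "Type2"),
                                strains = strains[dm16$ids],
                                within_strain_only = TRUE)
  type2_range <- if (sum(labels[dm16$ids] == "Type2") >= 2)
    range_summary(dm16, labels[dm16$ids], c("Type2", "Type2")) else NULL
  ranges_23s <- NULL
  if (!is.null(dataset$aln_23s)) {
    dm23 <- identity_matrix(dataset$aln_23s)
    ranges_23s <- range_summary(dm23, labels[dm23$ids],
                                c("Type1", "Type2"),
                                strains = strains[dm23$ids],
                                within_strain_only = TRUE)
  }

  # --- ITS features ---
  its_rows <- which(seqs$region == "ITS")
  its_anns <- lapply(its_rows, function(i) annotate_its(seqs[i, ],
                                                        its_templates))
  its_table <- its_feature_table(its_anns, seqs$operon_type[its_rows])
  its_recovery <- NA_real_
  if (!is.null(truth$its_boundaries)) {
    ok <- vapply(seq_along(its_rows), function(j) {
      want <- truth$its_boundaries[[seqs$id[its_rows[j]]]]
      if (is.null(want)) return(NA)
      got <- as.data.frame(its_anns[[j]])[, c("domain", "start", "end",
                                              "present")]
      want <- want[match(got$domain, want$domain),
                   c("domain", "start", "end", "present")]
      rownames(got) <- rownames(want) <- NULL
      isTRUE(all.equal(got, want))
    }, logical(1))
    its_recovery <- 100 * mean(ok, na.rm = TRUE)
  }

  # --- promoters ---
  ups <- seqs[seqs$region == "upstream", ]
  ups <- ups[!duplicated(ups$residues), ]
  prom_table <- if (nrow(ups)) promoter_table(ups, consensus) else NULL
  prom_recovery <- NA_real_
  if (!is.null(truth$promoter_windows) && nrow(ups)) {
    ok <- vapply(seq_len(nrow(ups)), function(i) {
      want <- truth$promoter_windows[[ups$operon_type[i]]]
      if (is.null(want)) return(NA)
      sc <- scan_promoter(ups[i, ], consensus)
      sc$minus10$start == want$minus10[1] &&
        sc$minus35$start == want$minus35[1] &&
        (!is.null(sc$minus52) && sc$minus52$start == want$minus52[1])
    }, logical(1))
    prom_recovery <- 100 * mean(ok, na.rm = TRUE)
  }

  # --- helix variability ---
  struct <- helix_variability(aln16, labels, sig, dataset$helix_map,
                              max_closable = max_closable)

  # --- genospecies ---
  strain_ids <- sort(unique(meta$strain[meta$region == "16S"]))
  identities <- list()
  for (tp in c("Type1", "Type2")) {
    if (!any(labels[rownames(aln16)] == tp)) next
    consm <- strain_type_consensus(aln16, strains, labels, tp)
    consm <- consm[strain_ids, , drop = FALSE]
    strs <- apply(consm, 1, paste, collapse = "")
    caln <- as_alignment(stats::setNames(strs, strain_ids))
    identities[[tp]] <- identity_percent(identity_matrix(caln))
  }
  morph <- NULL
  if (use_morphology && !is.null(truth$genospecies)) {
    morph <- unlist(truth$genospecies)
  }
  partition <- delimit(identities, threshold = identity_threshold,
                       clades = if (use_tree) clades else NULL,
                       morphospecies = morph)

  summary <- list(
    n_sequences = nrow(seqs),
    signature_positions = nrow(sig),
    typing_accuracy_pct = typing_accuracy,
    reversion_positions = length(unique(reversions$position)),
    within_strain_16s_identity_min = within_range$min_identity,
    within_strain_16s_identity_max = within_range$max_identity,
    within_strain_16s_divergence_min = 100 - within_range$max_identity,
    within_strain_16s_divergence_max = 100 - within_range$min_identity,
    type2_16s_identity_min = if (is.null(type2_range)) NA else
      type2_range$min_identity,
    within_strain_23s_identity_min = if (is.null(ranges_23s)) NA else
      ranges_23s$min_identity,
    within_strain_23s_identity_max = if (is.null(ranges_23s)) NA else
      ranges_23s$max_identity,
    its_boundary_recovery_pct = its_recovery,
    promoter_window_recovery_pct = prom_recovery,
    promoter_functional_fraction = if (is.null(prom_table)) NA else
      mean(prom_table$functional),
    helices_with_substitutions = sum(struct$per_helix$substitutions > 0),
    genospecies_count = length(partition$clusters),
    thresholds = list(saturation = saturation_threshold,
                      identity = identity_threshold,
                      promoter_matches = c(consensus$min_matches,
                                           consensus$max_matches),
                      max_closable = max_closable))

  report <- structure(list(summary = summary, signature = sig,
                           typing = typing, reversions = reversions,
                           distances_16s = dm16,
                           within_strain_range = within_range,
                           its_features = its_table,
                           promoters = prom_table,
                           structure = struct, partition = partition),
                      class = "rrn_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle
#'
#' @param report an \code{rrn_report}.
#' @param out_dir output directory.
#' @return invisibly, \code{out_dir}.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_signature_tsv(report$signature, file.path(out_dir, "signature.tsv"))
  utils::write.table(report$typing, file.path(out_dir, "typing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_distance_tsv(report$distances_16s,
                     file.path(out_dir, "distances_16s.tsv"))
  utils::write.table(report$its_features,
                     file.path(out_dir, "its_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$promoters)) {
    utils::write.table(report$promoters,
                       file.path(out_dir, "promoters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$structure$per_helix,
                     file.path(out_dir, "helix_variability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(clusters = report$partition$clusters,
                            provenance = report$partition$provenance,
                            threshold = report$partition$threshold),
                       file.path(out_dir, "genospecies.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.rrn_report <- function(x, ...) {
  s <- x$summary
  cat("rrn_report:\n")
  cat("  signature positions:", s$signature_positions, "\n")
  cat("  typing accuracy:", s$typing_accuracy_pct, "%\n")
  cat(sprintf("  within-strain 16S identity: %.1f-%.1f%%\n",
              s$within_strain_16s_identity_min,
              s$within_strain_16s_identity_max))
  cat("  genospecies:", s$genospecies_count, "\n")
  invisible(x)
}
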