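#' Run the full crAss-like phage analysis on a fixture directory
#'
#' Chains every stage on a community fixture (as written by
#' [simulate_community()], or assembled from real tables in the same
#' layout): viral-contig retention and dual-route crAss identification,
#' vOTU clustering, TerL-tree family classification, genetic-code and
#' genome-structure characterization, anti-CRISPR/CAZyme accounting,
#' CRISPR-spacer host linkage, coverage-gated RPKM quantification with
#' prevalence rules, and fat-vs-lean association. Writes the stage tables
#' under `outdir` and returns everything invisibly.
#'
#' @param fixture_dir Fixture directory.
#' @param outdir Output directory (created).
#' @param cfg [crass_thresholds()].
#' @param mode Route-combination mode for the final crAss call.
#' @return Invisibly, a list with each stage's results (see the stage
#'   functions).
#' @export
run_pipeline <- function(fixture_dir, outdir = file.path(fixture_dir,
                                                         "results"),
                         cfg = crass_thresholds(), mode = "union") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  # --- detection ---------------------------------------------------------
  phages <- genome_records(read_fasta(file.path(fixture_dir,
                                                "phages.fasta")))
  bacteria <- genome_records(read_fasta(file.path(fixture_dir,
                                                  "bacteria.fasta")))
  contigs <- rbind(phages, bacteria)
  scores <- utils::read.delim(file.path(fixture_dir, "scores.tsv"))
  calls <- detect_crass(contigs, scores, cfg = cfg, mode = mode)
  write_tsv(calls, file.path(outdir, "crass_calls.tsv"))
  crass <- contigs[contigs$id %in% calls$contig_id[calls$is_crass], ,
                   drop = FALSE]
  write_fasta(crass[, c("id", "seq")], file.path(outdir, "crass.fasta"))
  res$calls <- calls; res$crass <- crass

  # --- vOTU clustering ---------------------------------------------------
  clusters <- greedy_cluster(crass, cfg)
  write_tsv(clusters, file.path(outdir, "clusters.tsv"))
  membership <- cluster_membership(clusters)
  reps <- crass[match(clusters$rep_id, crass$id), , drop = FALSE]
  write_fasta(reps[, c("id", "seq")],
              file.path(outdir, "representatives.fasta"))
  res$clusters <- clusters; res$reps <- reps

  # --- per-representative genome features --------------------------------
  profiles <- crass_profiles()
  feats <- lapply(seq_len(nrow(reps)), function(i) {
    g <- reps[i, ]
    cc <- infer_genetic_code(g)
    ann <- annotate_markers(g, profiles, code = cc$code)
    trnas <- detect_suppressor_trna(g)
    tiled <- tile_genes(ann)
    list(genome_id = g$id, code = cc$code,
         coding_density = cc$coding_density, annotation = ann,
         trnas = trnas,
         blocks = c(ihf54_mcp = count_genes_between(tiled, "IHF_54",
                                                    "MCP"),
                    mcp_portal = count_genes_between(tiled, "MCP",
                                                     "portal"),
                    terl_primase = count_genes_between(tiled, "TerL",
                                                       "primase")))
  })
  names(feats) <- reps$id
  code_calls <- do.call(rbind, lapply(feats, function(f)
    data.frame(genome_id = f$genome_id, code = f$code,
               density_11 = f$coding_density[["11"]],
               density_4 = f$coding_density[["4"]],
               density_15 = f$coding_density[["15"]],
               n_suppressor_trna = nrow(f$trnas))))
  write_tsv(code_calls, file.path(outdir, "code_calls.tsv"))
  block_counts <- do.call(rbind, lapply(feats, function(f)
    data.frame(genome_id = f$genome_id, t(f$blocks))))
  write_tsv(block_counts, file.path(outdir, "block_counts.tsv"))
  annotation <- do.call(rbind, lapply(feats, `[[`, "annotation"))
  write_gff3(annotation, file.path(outdir, "annotation.gff3"))
  res$features <- feats; res$code_calls <- code_calls
  res$block_counts <- block_counts

  # unannotated fraction across all called genes
  res$unannotated_fraction <-
    if (nrow(annotation)) mean(annotation$label == "unknown") else NA_real_

  # --- TerL-tree family classification -----------------------------------
  refs <- read_fasta(file.path(fixture_dir, "reference_terl.faa"),
                     "protein")
  ref_tax <- utils::read.delim(file.path(fixture_dir,
                                         "reference_taxonomy.tsv"))
  refs$family <- ref_tax$family[match(refs$id, ref_tax$id)]
  terl <- do.call(rbind, lapply(feats, function(f) {
    ann <- f$annotation
    hit <- ann[ann$label == "TerL", , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    hit <- hit[order(-hit$score), ][1, ]
    g <- reps[match(f$genome_id, reps$id), ]
    data.frame(id = f$genome_id, seq = orf_protein(g, hit, f$code))
  }))
  cls <- classify_votus(terl, refs)
  asg <- cls$assignments
  missing <- setdiff(reps$id, asg$leaf_id)
  if (length(missing))
    asg <- rbind(asg, data.frame(leaf_id = missing,
                                 family = "unclassified",
                                 assigning_mrca = NA_integer_))
  names(asg)[names(asg) == "leaf_id"] <- "votu_id"
  write_tsv(asg, file.path(outdir, "taxonomy_assignments.tsv"))
  ape::write.tree(cls$tree, file.path(outdir, "terl_tree.nwk"))
  res$tree <- cls$tree; res$taxonomy <- asg

  votu_family <- stats::setNames(asg$family, asg$votu_id)
  genome_family <- data.frame(
    genome_id = membership$genome_id,
    family = unname(votu_family[membership$rep_id]))

  # --- gene-block statistics (pairwise family rank-sum tests) ------------
  bc <- merge(block_counts, data.frame(genome_id = names(votu_family),
                                       family = unname(votu_family)))
  bc <- bc[bc$family != "unclassified", , drop = FALSE]
  tests <- list()
  for (blk in c("ihf54_mcp", "mcp_portal", "terl_primase")) {
    fams <- sort(unique(bc$family))
    for (i in seq_along(fams)) for (j in seq_along(fams)) {
      if (i >= j) next
      x <- bc[[blk]][bc$family == fams[i]]
      y <- bc[[blk]][bc$family == fams[j]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) next
      wt <- wilcoxon_rank_sum(x, y)
      tests[[length(tests) + 1L]] <-
        data.frame(block = blk, family1 = fams[i], family2 = fams[j],
                   n1 = length(x), n2 = length(y), W = wt$W, p = wt$p)
    }
  }
  block_tests <- if (length(tests)) do.call(rbind, tests)
  else data.frame(block = character(), family1 = character(),
                  family2 = character(), n1 = integer(), n2 = integer(),
                  W = numeric(), p = numeric())
  write_tsv(block_tests, file.path(outdir, "block_tests.tsv"))
  res$block_tests <- block_tests

  # --- anti-CRISPR and CAZyme accounting ---------------------------------
  acr_path <- file.path(fixture_dir, "acr_predictions.tsv")
  if (file.exists(acr_path)) {
    acr <- utils::read.delim(acr_path)
    names(acr)[names(acr) == "protein_id"] <- "protein_id"
    acr_kept <- filter_acr(acr, cfg)
    write_tsv(acr_kept, file.path(outdir, "acr_retained.tsv"))
    res$acr_retained <- acr_kept
  }
  caz_path <- file.path(fixture_dir, "cazyme_hits.tsv")
  if (file.exists(caz_path)) {
    caz <- utils::read.delim(caz_path)
    caz_prev <- cazyme_cluster_prevalence(
      caz, genome_family[genome_family$family != "unclassified", ])
    write_tsv(caz_prev, file.path(outdir, "cazyme_prevalence.tsv"))
    res$cazyme_prevalence <- caz_prev
  }

  # --- CRISPR host linkage ------------------------------------------------
  arrays <- list()
  for (i in seq_len(nrow(bacteria)))
    arrays <- c(arrays, find_crispr_arrays(bacteria[i, ]))
  taxonomy <- utils::read.delim(file.path(fixture_dir, "taxonomy.tsv"))
  hosts <- assign_hosts(arrays, crass, membership, taxonomy, cfg)
  write_tsv(hosts$assignments, file.path(outdir, "host_assignments.tsv"))
  write_tsv(hosts$genus_summary, file.path(outdir,
                                           "host_genus_summary.tsv"))
  arr_tab <- do.call(rbind, lapply(arrays, function(a)
    data.frame(genome_id = a$genome_id, repeat_seq = a$repeat_seq,
               n_repeats = length(a$repeat_positions),
               start = a$repeat_positions[1],
               n_spacers = nrow(a$spacers))))
  if (!is.null(arr_tab))
    write_tsv(arr_tab, file.path(outdir, "crispr_arrays.tsv"))
  res$arrays <- arrays; res$hosts <- hosts

  # --- quantification, prevalence, association ---------------------------
  metadata <- utils::read.delim(file.path(fixture_dir, "metadata.tsv"))
  read_files <- file.path(fixture_dir, "reads",
                          paste0(metadata$sample, ".fasta"))
  alignments <- list(); totals <- numeric()
  for (k in seq_along(read_files)) {
    rd <- read_fasta(read_files[k])
    alignments[[metadata$sample[k]]] <- map_reads(rd, reps, cfg)
    totals[metadata$sample[k]] <- nrow(rd)
  }
  ab <- quantify(alignments, reps, totals, cfg)
  utils::write.table(data.frame(votu_id = rownames(ab$rpkm), ab$rpkm,
                                check.names = FALSE),
                     file.path(outdir, "rpkm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prev <- prevalence(ab$detected,
                     stats::setNames(metadata$population, metadata$sample),
                     votu_family)
  assoc <- associate_groups(ab$rpkm,
                            stats::setNames(metadata$group,
                                            metadata$sample), cfg)
  write_tsv(assoc, file.path(outdir, "associations.tsv"))
  res$abundance <- ab; res$prevalence <- prev; res$associations <- assoc
  res$metadata <- metadata

  # --- summary ------------------------------------------------------------
  summary <- data.frame(
    metric = c("n_contigs", "n_crass", "n_votus", "n_classified",
               "n_alt_code", "unannotated_fraction", "n_votus_with_host",
               "n_significant_assoc"),
    value = c(nrow(contigs), nrow(crass), nrow(clusters),
              sum(asg$family != "unclassified"),
              sum(code_calls$code != 11), res$unannotated_fraction,
              length(unique(hosts$assignments$votu_id)),
              sum(assoc$significant)))
  write_tsv(summary, file.path(outdir, "summary.tsv"))
  res$summary <- summary
  invisible(res)
}
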