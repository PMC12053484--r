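#!/usr/bin/env Rscript
# Stage 4 - genome features of the vOTU representatives.
#
# Per representative: genetic-code inference by coding-density comparison
# (codes 11 / 4 / 15), suppressor-tRNA detection, marker annotation against
# the five profiles, and gene counts in the three marker-bounded blocks
# (IHF_54-MCP and MCP-portal for assembly, TerL-primase for replication).
# Recovered codes and blocks are compared against the planted truth.
#
# Usage: Rscript analysis/04_features.R [fixture_dir] [outdir]

suppressPackageStartupMessages(library(crasskit))
args <- commandArgs(trailingOnly = TRUE)
fixture <- if (length(args) >= 1) args[1] else "results/fixture"
outdir <- if (length(args) >= 2) args[2] else "results/pipeline"

reps <- genome_records(read_fasta(file.path(outdir,
                                            "representatives.fasta")))
profiles <- crass_profiles()
rows_code <- list(); rows_block <- list(); ann_all <- list()
for (i in seq_len(nrow(reps))) {
  g <- reps[i, ]
  cc <- infer_genetic_code(g)
  ann <- annotate_markers(g, profiles, code = cc$code)
  trnas <- detect_suppressor_trna(g)
  rows_code[[i]] <- data.frame(
    genome_id = g$id, code = cc$code,
    density_11 = cc$coding_density[["11"]],
    density_4 = cc$coding_density[["4"]],
    density_15 = cc$coding_density[["15"]],
    n_suppressor_trna = nrow(trnas))
  tiled <- tile_genes(ann)
  rows_block[[i]] <- data.frame(
    genome_id = g$id,
    ihf54_mcp = count_genes_between(tiled, "IHF_54", "MCP"),
    mcp_portal = count_genes_between(tiled, "MCP", "portal"),
    terl_primase = count_genes_between(tiled, "TerL", "primase"))
  ann_all[[i]] <- ann
}
code_calls <- do.call(rbind, rows_code)
block_counts <- do.call(rbind, rows_block)
annotation <- do.call(rbind, ann_all)
write.table(code_calls, file.path(outdir, "code_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(block_counts, file.path(outdir, "block_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(annotation, file.path(outdir, "annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(fixture, "truth_phages.tsv"))
m <- merge(code_calls, truth, by = "genome_id")
cat(sprintf("genetic codes recovered: %d/%d\n", sum(m$code.x == m$code.y),
            nrow(m)))
cat(sprintf("suppressor tRNA presence agrees: %d/%d\n",
            sum((m$n_suppressor_trna > 0) == m$has_suppressor), nrow(m)))
tb <- read.delim(file.path(fixture, "truth_blocks.tsv"))
mb <- merge(block_counts, tb, by = "genome_id")
for (b in c("ihf54_mcp", "mcp_portal", "terl_primase"))
  cat(sprintf("block %-13s exact: %d/%d\n", b,
              sum(mb[[paste0(b, ".x")]] == mb[[paste0(b, ".y")]],
                  na.rm = TRUE), nrow(mb)))
cat(sprintf("unannotated gene fraction: %.1f%%\n",
            100 * mean(annotation$label == "unknown")))
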