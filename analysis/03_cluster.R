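#!/usr/bin/env Rscript
# Stage 3 - vOTU dereplication at 95% ANI / 85% aligned fraction.
#
# Greedy longest-first clustering of the crAss-like genome set; the longest
# member represents each vOTU. On the default fixture every phage genome is
# its own species-rank vOTU (backgrounds are unrelated), which the script
# reports alongside the pairwise ANI table.
#
# Usage: Rscript analysis/03_cluster.R [outdir]

suppressPackageStartupMessages(library(crasskit))
args <- commandArgs(trailingOnly = TRUE)
outdir <- if (length(args) >= 1) args[1] else "results/pipeline"

crass <- genome_records(read_fasta(file.path(outdir, "crass.fasta")))
clusters <- greedy_cluster(crass)
write.table(clusters, file.path(outdir, "clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
reps <- crass[match(clusters$rep_id, crass$id), ]
write_fasta(reps[, c("id", "seq")],
            file.path(outdir, "representatives.fasta"))

tab <- crasskit:::ani_table(crass)
write.table(tab, file.path(outdir, "ani.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d genomes -> %d vOTUs (%d singletons)\n", nrow(crass),
            nrow(clusters), sum(clusters$n_members == 1)))
if (nrow(tab)) {
  near <- tab[tab$ani >= 95 & tab$af >= 85, ]
  cat(sprintf("pairs above the clustering cutoffs: %d\n", nrow(near)))
}
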