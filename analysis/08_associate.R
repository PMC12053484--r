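#!/usr/bin/env Rscript
# Stage 8 - fat-vs-lean abundance association.
#
# Total-sum scaling, log2 transform with half-minimum pseudocount, per-vOTU
# linear model on the group factor, BH adjustment, and the signed
# significance score -log10(qval) * sign(coeff). The three planted
# |log2FC| = 2 effects (two fat-enriched, one lean-enriched) are the truth.
#
# Usage: Rscript analysis/08_associate.R [fixture_dir] [outdir]

suppressPackageStartupMessages(library(crasskit))
args <- commandArgs(trailingOnly = TRUE)
fixture <- if (length(args) >= 1) args[1] else "results/fixture"
outdir <- if (length(args) >= 2) args[2] else "results/pipeline"

rpkm_tab <- read.delim(file.path(outdir, "rpkm.tsv"), check.names = FALSE)
rpkm <- as.matrix(rpkm_tab[, -1])
rownames(rpkm) <- rpkm_tab$votu_id
metadata <- read.delim(file.path(fixture, "metadata.tsv"))

assoc <- associate_groups(rpkm, setNames(metadata$group, metadata$sample))
write.table(assoc, file.path(outdir, "associations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(fixture, "truth_effects.tsv"))
sig <- assoc[assoc$significant, ]
cat(sprintf("significant at q < 0.05: %d (%d enriched in fat, %d in lean)\n",
            nrow(sig), sum(sig$coeff > 0), sum(sig$coeff < 0)))
hit <- merge(sig, truth, by.x = "votu_id", by.y = "phage_id")
cat(sprintf("planted effects recovered: %d/%d (signs agree: %d)\n",
            nrow(hit), nrow(truth),
            sum(sign(hit$coeff) == sign(hit$log2fc))))
cat(sprintf("false associations: %d\n",
            nrow(sig) - nrow(hit)))
cat("signed scores of recovered effects:\n")
print(hit[, c("votu_id", "log2fc", "coeff", "qval", "signed_score")],
      row.names = FALSE)
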