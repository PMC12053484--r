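#!/usr/bin/env Rscript
# Stage 7 - read mapping, coverage-gated RPKM and prevalence.
#
# Maps each sample's reads to the vOTU representatives (90% identity, 95%
# of the read aligned), computes RPKM with the 75% covered-fraction gate,
# then the prevalence rules: per-vOTU sample prevalence, per-population
# detection, and per-sample family (cluster) presence. Recovery is measured
# as the Spearman correlation between RPKM and the planted relative
# abundances.
#
# Usage: Rscript analysis/07_quantify.R [fixture_dir] [outdir]

suppressPackageStartupMessages(library(crasskit))
args <- commandArgs(trailingOnly = TRUE)
fixture <- if (length(args) >= 1) args[1] else "results/fixture"
outdir <- if (length(args) >= 2) args[2] else "results/pipeline"

reps <- genome_records(read_fasta(file.path(outdir,
                                            "representatives.fasta")))
metadata <- read.delim(file.path(fixture, "metadata.tsv"))
alignments <- list(); totals <- numeric()
for (s in metadata$sample) {
  rd <- read_fasta(file.path(fixture, "reads", paste0(s, ".fasta")))
  alignments[[s]] <- map_reads(rd, reps)
  totals[s] <- nrow(rd)
}
ab <- quantify(alignments, reps, totals)
write.table(data.frame(votu_id = rownames(ab$rpkm), ab$rpkm,
                       check.names = FALSE),
            file.path(outdir, "rpkm.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(votu_id = rownames(ab$covered_fraction),
                       ab$covered_fraction, check.names = FALSE),
            file.path(outdir, "covered_fraction.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

asg <- read.delim(file.path(outdir, "taxonomy_assignments.tsv"))
fam <- setNames(asg$family, asg$votu_id)
prev <- prevalence(ab$detected,
                   setNames(metadata$population, metadata$sample), fam)
write.table(data.frame(votu_id = names(prev$sample_prevalence),
                       prevalence = prev$sample_prevalence),
            file.path(outdir, "prevalence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("mapped fraction per sample: %.1f%% (mean)\n",
            100 * mean(vapply(metadata$sample, function(s)
              nrow(alignments[[s]]) / totals[s], 0))))
truth <- read.delim(file.path(fixture, "truth_abundance.tsv"),
                    check.names = FALSE)
tr <- as.matrix(truth[, -1]); rownames(tr) <- truth$genome_id
common <- intersect(rownames(tr), rownames(ab$rpkm))
rho <- cor(as.vector(ab$rpkm[common, colnames(tr)]),
           as.vector(tr[common, ]), method = "spearman")
cat(sprintf("Spearman(planted abundance, RPKM): %.3f\n", rho))
cat(sprintf("detected vOTU-sample pairs: %d/%d\n", sum(ab$detected),
            length(ab$detected)))
cat(sprintf("max sample prevalence: %.1f%%\n",
            max(prev$sample_prevalence)))
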