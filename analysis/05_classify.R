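#!/usr/bin/env Rscript
# Stage 5 - TerL phylogeny and MRCA-based family assignment.
#
# Extracts the TerL protein of each representative from the stage-4
# annotation, aligns them with the labeled reference TerL set, builds a
# p-distance neighbor-joining tree, midpoint-roots it, and propagates
# reference families to the unlabeled leaves by the MRCA rule. Leaves
# outside every labeled clade stay unclassified and are dropped from
# family-level analyses. Pairwise family rank-sum tests on the gene blocks
# are run at the end.
#
# Usage: Rscript analysis/05_classify.R [fixture_dir] [outdir]

suppressPackageStartupMessages(library(crasskit))
args <- commandArgs(trailingOnly = TRUE)
fixture <- if (length(args) >= 1) args[1] else "results/fixture"
outdir <- if (length(args) >= 2) args[2] else "results/pipeline"

reps <- genome_records(read_fasta(file.path(outdir,
                                            "representatives.fasta")))
ann <- read.delim(file.path(outdir, "annotation.tsv"))
codes <- read.delim(file.path(outdir, "code_calls.tsv"))

terl <- do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
  g <- reps[i, ]
  hit <- ann[ann$genome_id == g$id & ann$label == "TerL", ]
  if (!nrow(hit)) return(NULL)
  hit <- hit[order(-hit$score), ][1, ]
  data.frame(id = g$id,
             seq = crasskit:::orf_protein(g, hit,
                                          codes$code[codes$genome_id ==
                                                       g$id]))
}))
refs <- read_fasta(file.path(fixture, "reference_terl.faa"), "protein")
ref_tax <- read.delim(file.path(fixture, "reference_taxonomy.tsv"))
refs$family <- ref_tax$family[match(refs$id, ref_tax$id)]

cls <- classify_votus(terl, refs)
asg <- cls$assignments
names(asg)[1] <- "votu_id"
write.table(asg, file.path(outdir, "taxonomy_assignments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ape::write.tree(cls$tree, file.path(outdir, "terl_tree.nwk"))

truth <- read.delim(file.path(fixture, "truth_phages.tsv"))
m <- merge(asg, truth, by.x = "votu_id", by.y = "genome_id")
cat(sprintf("family labels recovered: %d/%d\n",
            sum(m$family.x == m$family.y), nrow(m)))
cat(sprintf("unclassified: %d\n", sum(asg$family == "unclassified")))

# gene-block comparisons between families (two-sided rank-sum)
bc <- merge(read.delim(file.path(outdir, "block_counts.tsv")),
            asg[, c("votu_id", "family")],
            by.x = "genome_id", by.y = "votu_id")
bc <- bc[bc$family != "unclassified", ]
rows <- list()
for (blk in c("ihf54_mcp", "mcp_portal", "terl_primase")) {
  fams <- sort(unique(bc$family))
  for (i in seq_along(fams)) for (j in seq_along(fams)) {
    if (i >= j) next
    x <- stats::na.omit(bc[[blk]][bc$family == fams[i]])
    y <- stats::na.omit(bc[[blk]][bc$family == fams[j]])
    if (!length(x) || !length(y)) next
    wt <- wilcoxon_rank_sum(x, y)
    rows[[length(rows) + 1]] <- data.frame(
      block = blk, family1 = fams[i], family2 = fams[j],
      median1 = stats::median(x), median2 = stats::median(y),
      W = wt$W, p = wt$p)
  }
}
tests <- do.call(rbind, rows)
write.table(tests, file.path(outdir, "block_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("block contrasts with p < 0.05:\n")
print(tests[tests$p < 0.05, c("block", "family1", "family2", "median1",
                              "median2", "p")], row.names = FALSE)
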