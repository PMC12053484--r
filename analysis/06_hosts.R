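#!/usr/bin/env Rscript
# Stage 6 - CRISPR arrays and spacer-based host assignment.
#
# Detects CRISPR arrays in the bacterial genomes, matches every extracted
# spacer against the crAss-like genomes at one mismatch over the whole
# spacer, aggregates hits to (vOTU x bacterium), joins taxonomy and
# summarizes host-genus breadth. Planted links (and 2-mismatch decoys,
# which must stay unmatched) provide the truth.
#
# Usage: Rscript analysis/06_hosts.R [fixture_dir] [outdir]

suppressPackageStartupMessages(library(crasskit))
args <- commandArgs(trailingOnly = TRUE)
fixture <- if (length(args) >= 1) args[1] else "results/fixture"
outdir <- if (length(args) >= 2) args[2] else "results/pipeline"

bacteria <- genome_records(read_fasta(file.path(fixture, "bacteria.fasta")))
crass <- genome_records(read_fasta(file.path(outdir, "crass.fasta")))
clusters <- read.delim(file.path(outdir, "clusters.tsv"))
taxonomy <- read.delim(file.path(fixture, "taxonomy.tsv"))

arrays <- list()
for (i in seq_len(nrow(bacteria)))
  arrays <- c(arrays, find_crispr_arrays(bacteria[i, ]))
cat(sprintf("CRISPR arrays found: %d in %d bacteria\n", length(arrays),
            nrow(bacteria)))

membership <- crasskit:::cluster_membership(clusters)
hosts <- assign_hosts(arrays, crass, membership, taxonomy)
write.table(hosts$assignments, file.path(outdir, "host_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(hosts$genus_summary, file.path(outdir,
                                           "host_genus_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(fixture, "truth_hosts.tsv"))
real <- truth[!truth$decoy, ]
got <- paste(hosts$assignments$bacterial_genome_id,
             hosts$assignments$votu_id)
want <- unique(paste(real$genome_id, real$phage_id))
cat(sprintf("planted links recovered: %d/%d; false links: %d\n",
            sum(want %in% got), length(want), sum(!got %in% want)))
cat(sprintf("vOTUs with >=1 host: %d (planted: %d)\n",
            length(unique(hosts$assignments$votu_id)),
            length(unique(real$phage_id))))
cat(sprintf("multi-genus vOTUs: %d/%d\n",
            sum(hosts$votu_breadth$multi_genus),
            nrow(hosts$votu_breadth)))
cat("top host genera (vOTU counts):\n")
print(utils::head(hosts$genus_summary, 5), row.names = FALSE)
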