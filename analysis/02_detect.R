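#!/usr/bin/env Rscript
# Stage 2 - viral-contig retention and dual-route crAss-like identification.
#
# Runs the four-criterion retention rule on the predictor score table, then
# both identification routes (signature-protein alignment; six-frame profile
# search) on every retained contig, and compares the final union call with
# the planted truth (all phage contigs are true crAss-like genomes, all
# bacterial contigs are decoys).
#
# Usage: Rscript analysis/02_detect.R [fixture_dir] [outdir]

suppressPackageStartupMessages(library(crasskit))
args <- commandArgs(trailingOnly = TRUE)
fixture <- if (length(args) >= 1) args[1] else "results/fixture"
outdir <- if (length(args) >= 2) args[2] else "results/pipeline"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

phages <- genome_records(read_fasta(file.path(fixture, "phages.fasta")))
bacteria <- genome_records(read_fasta(file.path(fixture, "bacteria.fasta")))
contigs <- rbind(phages, bacteria)
scores <- read.delim(file.path(fixture, "scores.tsv"))

calls <- detect_crass(contigs, scores)
write.table(calls, file.path(outdir, "crass_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
crass <- contigs[contigs$id %in% calls$contig_id[calls$is_crass], ]
write_fasta(crass[, c("id", "seq")], file.path(outdir, "crass.fasta"))

is_phage <- calls$contig_id %in% phages$id
sens <- mean(calls$is_crass[is_phage])
spec_ <- mean(!calls$is_crass[!is_phage])
cat(sprintf("retained %d/%d contigs; crAss calls: %d\n",
            sum(calls$retained), nrow(calls), sum(calls$is_crass)))
cat(sprintf("sensitivity on planted phages: %.1f%%\n", 100 * sens))
cat(sprintf("specificity on bacterial decoys: %.1f%%\n", 100 * spec_))
cat(sprintf("route agreement: route1 only %d, route2 only %d, both %d\n",
            sum(calls$route1_hit != "none" & calls$route2_hits == ""),
            sum(calls$route1_hit == "none" & calls$route2_hits != ""),
            sum(calls$route1_hit != "none" & calls$route2_hits != "")))
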