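#!/usr/bin/env Rscript
# Regenerates the synthetic reference data shipped under inst/extdata/:
#   markers/marker_families.faa  family-level marker protein consensi
#   profiles/<marker>.faa        seed alignments for the marker profiles
#   profiles/thresholds.tsv      stored profile calibration thresholds
#   signatures/signatures.faa    discovery signature proteins
#   trna/trna_templates.fasta    suppressor-tRNA cassette template
# All sequences are synthetic (seeded random draws); none are copied from
# any database. Run from the repository root with the package installed.

library(crasskit)

set.seed(7121)

aa <- names(crasskit:::aa_background())
bg <- crasskit:::aa_background()

rand_prot <- function(n) paste(sample(aa, n, TRUE, prob = bg), collapse = "")

mutate_prot <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  idx <- which(stats::runif(length(ch)) < rate)
  ch[idx] <- vapply(idx, function(i)
    sample(setdiff(aa, ch[i]), 1, prob = bg[setdiff(aa, ch[i])]), "")
  paste(ch, collapse = "")
}

marker_len <- c(IHF_54 = 130, MCP = 450, portal = 550, TerL = 600,
                primase = 700)
families <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")
family_div <- 0.18   # per-family substitution rate from the base consensus

dir.create("inst/extdata/markers", recursive = TRUE, showWarnings = FALSE)
dir.create("inst/extdata/profiles", recursive = TRUE, showWarnings = FALSE)
dir.create("inst/extdata/signatures", recursive = TRUE, showWarnings = FALSE)
dir.create("inst/extdata/trna", recursive = TRUE, showWarnings = FALSE)

base_seq <- list()
fam_rows <- list()
for (m in names(marker_len)) {
  base_seq[[m]] <- rand_prot(marker_len[[m]])
  for (f in families) {
    fam_rows[[paste(m, f, sep = "|")]] <-
      data.frame(id = paste(m, f, sep = "|"),
                 seq = mutate_prot(base_seq[[m]], family_div))
  }
}
fam_tab <- do.call(rbind, fam_rows)
write_fasta(fam_tab, "inst/extdata/markers/marker_families.faa")

# Seed alignments: the six family consensi plus one lightly diverged copy
# each (ungapped, equal length -> trivially a valid alignment).
thr_rows <- list()
for (m in names(marker_len)) {
  fam_seqs <- fam_tab$seq[grepl(paste0("^", m, "\\|"), fam_tab$id)]
  extra <- vapply(fam_seqs, mutate_prot, "", rate = 0.05)
  seed_aln <- data.frame(
    id = c(paste0(m, "_fam", seq_along(fam_seqs)),
           paste0(m, "_var", seq_along(extra))),
    seq = c(fam_seqs, unname(extra)))
  write_fasta(seed_aln, file.path("inst/extdata/profiles",
                                  paste0(m, ".faa")))
  prof <- build_profile(m, seed_aln$seq)
  prof <- calibrate_profile(prof, n_shuffles = 10000, seed = 20241)
  thr_rows[[m]] <- data.frame(marker = m, threshold = prof$threshold,
                              n_shuffles = 10000, calib_seed = 20241)
  # sanity margin: every family consensus must score far above threshold
  sc <- vapply(fam_seqs, function(s)
    pssm_search(s, prof, use_threshold = FALSE)$score, 0)
  message(sprintf("%-8s threshold %7.2f  min family score %8.1f",
                  m, prof$threshold, min(sc)))
}
write.table(do.call(rbind, thr_rows), "inst/extdata/profiles/thresholds.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

# Signatures: the terminase signature is the TerL base consensus; the
# polymerase signature is an independent synthetic polymerase-sized protein.
write_fasta(data.frame(id = c("UGP_018", "UGP_092"),
                       seq = c(rand_prot(750), base_seq[["TerL"]])),
            "inst/extdata/signatures/signatures.faa")

# Suppressor tRNA cassette template (~85 nt) with the anticodon at a fixed
# 0-based offset; shipped with the TAG-suppressing anticodon CTA.
tr_off <- 34L
tmpl <- paste(sample(c("A", "C", "G", "T"), 85, TRUE), collapse = "")
substr(tmpl, tr_off + 1L, tr_off + 3L) <- "CTA"
writeLines(c(sprintf(">supp_trna_template anticodon_offset=%d", tr_off),
             tmpl),
           "inst/extdata/trna/trna_templates.fasta")

message("extdata written")
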