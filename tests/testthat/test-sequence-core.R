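test_that("FASTA round-trip is the identity and duplicate ids error", {
  withr::with_seed(11, {
    recs <- data.frame(id = sprintf("seq%02d", 1:8),
                       seq = vapply(sample(5:200, 8), rnd_dna, ""))
  })
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_identical(back, recs)

  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGTT"), f2)
  expect_error(read_fasta(f2), "duplicate")

  f3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(">a\nacgu", f3)
  expect_identical(read_fasta(f3)$seq, "ACGT")

  f4 <- withr::local_tempfile(fileext = ".fa")
  file.create(f4)
  expect_identical(nrow(read_fasta(f4)), 0L)
})

test_that("six-frame translation matches a codon-table oracle", {
  g <- one_genome("t", "ATGAAATAG")
  fr <- six_frame_translate(g[1, ])
  expect_identical(fr$seq[fr$frame == 1], "MK*")
  frc <- six_frame_translate(g[1, ], clean = TRUE)
  expect_identical(frc$seq[frc$frame == 1], "MKX")

  withr::with_seed(21, {
    for (rep in 1:20) {
      s <- rnd_dna(sample(30:120, 1))
      g <- one_genome("r", s)
      fr <- six_frame_translate(g[1, ])
      rc <- revcomp(s)
      for (f in 1:3) {
        expect_identical(fr$seq[fr$frame == f],
                         oracle_translate(substring(s, f)))
        expect_identical(fr$seq[fr$frame == -f],
                         oracle_translate(substring(rc, f)))
      }
      # frame -1 of the reverse complement equals frame +1 of the original
      fr_rc <- six_frame_translate(one_genome("rc", rc)[1, ])
      expect_identical(fr_rc$seq[fr_rc$frame == -1],
                       fr$seq[fr$frame == 1])
    }
  })
  expect_error(six_frame_translate(one_genome("b", "ACGTRY")[1, ]),
               "outside")
})

test_that("N-containing codons translate to X and never act as stops", {
  g <- genome_records(data.frame(id = "n", seq = "ATGTNAAAATAA"))
  orfs <- find_orfs(g[1, ], 11, 1)
  expect_identical(nrow(orfs), 1L)       # TNA did not terminate the ORF
  expect_identical(orfs$length_aa, 3L)
  expect_identical(translate_codons("TNA"), "X")
})

test_that("ORF calling finds planted maximal ORFs", {
  withr::with_seed(31, {
    sense <- paste(vapply(1:97, function(i)
      sample(setdiff(names(Biostrings::GENETIC_CODE)[
        Biostrings::GENETIC_CODE != "*"], "ATG"), 1), ""), collapse = "")
    core <- paste0("ATG", sense, "TAA")
    flank5 <- rnd_dna(51); flank3 <- rnd_dna(60)
  })
  # the in-frame TAA guard pins the ORF start to the planted ATG
  g <- one_genome("o", paste0(flank5, "TAA", core, flank3))
  orfs <- find_orfs(g[1, ], 11, 90)
  hit <- orfs[orfs$start == 54 & orfs$strand == "+", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$end - hit$start, nchar(core))
  expect_identical(hit$length_aa, 98L)
})

test_that("internal TAG splits a gene under code 11 but not code 15", {
  withr::with_seed(32, {
    mk <- function(n) paste(vapply(seq_len(n), function(i)
      sample(setdiff(names(Biostrings::GENETIC_CODE)[
        Biostrings::GENETIC_CODE != "*"], "ATG"), 1), ""), collapse = "")
    seq <- paste0(rnd_dna(30), "TAA", "ATG", mk(80), "TAG", mk(80), "TAA",
                  rnd_dna(30))
  })
  g <- one_genome("s", seq)
  o11 <- find_orfs(g[1, ], 11, 100)
  o15 <- find_orfs(g[1, ], 15, 100)
  expect_identical(nrow(o11[o11$strand == "+", ]), 0L)
  expect_identical(nrow(o15[o15$strand == "+", ]), 1L)
  expect_identical(o15$length_aa[o15$strand == "+"], 162L)
})

test_that("code-15 calls equal code-11 calls after in-frame TAG rewriting", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      g <- simulate_code_genome(15, n_genes = 6, seed = 500 + rep)
      o15 <- find_orfs(g[1, ], 15, 40)
      # rewrite TAG codons in every frame where they are in-frame, per frame
      for (fr in c(1L, 2L, 3L)) {
        s <- g$seq
        pos <- seq(fr, nchar(s) - 2, by = 3)
        cod <- substring(s, pos, pos + 2)
        tag <- pos[cod == "TAG"]
        for (p in tag) substr(s, p, p + 2) <- "CAG"
        g2 <- one_genome("rw", s)
        o11 <- find_orfs(g2[1, ], 11, 40)
        expect_equal(o11[o11$frame == fr, c("start", "end")],
                     o15[o15$frame == fr, c("start", "end")],
                     ignore_attr = TRUE)
      }
    }
  })
})

test_that("Smith-Waterman equals an independent DP oracle", {
  withr::with_seed(41, {
    for (rep in 1:40) {
      q <- rnd_prot(sample(5:60, 1)); t <- rnd_prot(sample(5:60, 1))
      a <- align_protein_local(q, t)
      expect_equal(a$score, oracle_sw_score(q, t))
    }
  })
})

test_that("Smith-Waterman agrees with Biostrings on random pairs", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      q <- rnd_prot(sample(20:80, 1)); t <- rnd_prot(sample(20:80, 1))
      ref <- Biostrings::pairwiseAlignment(
        q, t, type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
      expect_equal(align_protein_local(q, t)$score, ref)
    }
  })
})

test_that("self-alignment is perfect and beats the reversed sequence", {
  withr::with_seed(43, {
    s <- rnd_prot(400)
    a <- align_protein_local(s, s)
    expect_equal(a$identity, 100)
    expect_identical(a$aln_len, 400L)
    expect_lt(a$evalue, 1e-100)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_lt(align_protein_local(s, rev_s)$score, a$score)
  })
  expect_error(align_protein_local("MKV*", "MKV"), "invalid")
})

test_that("alignment results are deterministic", {
  withr::with_seed(44, { q <- rnd_prot(50); t <- rnd_prot(70) })
  expect_identical(align_protein_local(q, t), align_protein_local(q, t))
})

test_that("PSSM search equals a brute-force window oracle", {
  withr::with_seed(51, {
    for (rep in 1:25) {
      nc <- sample(15:40, 1)
      pr <- build_profile("t", replicate(4, rnd_prot(nc)))
      prot <- rnd_prot(sample(20:80, 1))
      got <- pssm_search(prot, pr, use_threshold = FALSE)
      expect_equal(got$score, oracle_pssm_score(prot, pr$pssm),
                   tolerance = 1e-9)
    }
  })
})

test_that("profile consensus hits; shuffled composition does not", {
  pr <- toy_profile()
  hit <- pssm_search(pr$consensus, pr)
  expect_false(is.null(hit))
  expect_identical(hit$t_start, 0L)
  expect_identical(hit$t_end, pr$n_col)
  withr::with_seed(52, {
    cons <- strsplit(pr$consensus, "")[[1]]
    fp <- 0
    for (i in 1:200) {
      shuf <- paste(sample(cons), collapse = "")
      if (!is.null(pssm_search(shuf, pr))) fp <- fp + 1
    }
    expect_lte(fp / 200, 0.01)
  })
})

test_that("stored profile thresholds are reproducible by recalibration", {
  pr <- crass_profiles(c("IHF_54"))[[1]]
  re <- calibrate_profile(pr, n_shuffles = 2000, seed = 20241)
  # same procedure at reduced sampling lands near the stored threshold
  expect_lt(abs(re$threshold - pr$threshold), 3)
  # planted family consensi clear the threshold by a wide margin
  cons <- crasskit:::marker_family_consensi()
  fams <- cons$seq[grepl("^IHF_54\\|", cons$id)]
  for (s in fams)
    expect_gt(pssm_search(s, pr, use_threshold = FALSE)$score,
              3 * pr$threshold)
})

test_that("GFF3 output is 1-based inclusive", {
  ann <- data.frame(genome_id = "g", start = 0L, end = 90L, strand = "+",
                    label = "TerL", score = 41.5)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, f)
  lines <- readLines(f)
  expect_identical(lines[1], "##gff-version 3")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_identical(fields[4], "1")
  expect_identical(fields[5], "90")
  expect_match(fields[9], "label=TerL")
})

test_that("every threshold resolves to one config field", {
  cfg <- crass_thresholds()
  expect_s3_class(cfg, "crass_thresholds")
  expect_identical(cfg$sig_minlen, 350)
  expect_identical(cfg$crass_min_genome, 70000)
  expect_error(crass_thresholds(ani_thresh = 150))
})
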