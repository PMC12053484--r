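planted_array <- function(n_repeats = 4, rep_len = 29, sp_len = 32,
                          seed = 301) {
  withr::with_seed(seed, {
    rep_seq <- rnd_dna(rep_len)
    spacers <- replicate(n_repeats - 1, rnd_dna(sp_len))
    # distinct boundary bases so array boundaries are unambiguous
    bases <- c("A", "C", "G", "T")
    for (i in seq_along(spacers)) {
      substr(spacers[i], 1, 1) <- bases[i %% 4 + 1]
      substr(spacers[i], sp_len, sp_len) <- bases[(i + 1) %% 4 + 1]
    }
    left <- rnd_dna(500); right <- rnd_dna(500)
  })
  body <- paste0(paste0(rep_seq, spacers, collapse = ""), rep_seq)
  list(genome = one_genome("b", paste0(left, body, right)),
       rep_seq = rep_seq, spacers = spacers,
       rep_starts = 500 + cumsum(c(0, rep(rep_len + sp_len,
                                          n_repeats - 1))))
}

test_that("planted arrays are recovered at exact coordinates", {
  pa <- planted_array()
  arr <- find_crispr_arrays(pa$genome[1, ])
  expect_identical(length(arr), 1L)
  a <- arr[[1]]
  expect_identical(a$repeat_seq, pa$rep_seq)
  expect_identical(a$repeat_positions, as.integer(pa$rep_starts))
  expect_identical(nrow(a$spacers), 3L)       # 4 repeats -> 3 spacers
  expect_identical(a$spacers$seq, pa$spacers)
})

test_that("tandem repeats without spacers are rejected", {
  withr::with_seed(302, unit <- rnd_dna(30))
  g <- one_genome("t", paste0(rnd_dna(300), strrep(unit, 6), rnd_dna(300)))
  expect_identical(length(find_crispr_arrays(g[1, ])), 0L)
})

test_that("random sequence yields no arrays", {
  withr::with_seed(303, {
    n_found <- 0
    for (i in 1:15) {
      g <- one_genome("r", rnd_dna(50000))
      n_found <- n_found + length(find_crispr_arrays(g[1, ]))
    }
  })
  expect_identical(n_found, 0)
})

test_that("spacer matching is exact Hamming with a one-mismatch cap", {
  withr::with_seed(311, {
    sp <- rnd_dna(32)
    ph <- one_genome("p", paste0(rnd_dna(1000), sp, rnd_dna(1000)))
  })
  h0 <- match_spacer(sp, ph[1, ])
  expect_identical(h0$position, 1000L)
  expect_identical(h0$strand, "+")
  expect_identical(h0$mismatches, 0L)

  sp1 <- substitute_dna(sp, 1)
  expect_identical(match_spacer(sp1, ph[1, ])$mismatches, 1L)
  sp2 <- substitute_dna(sp, 2)
  expect_identical(nrow(match_spacer(sp2, ph[1, ])), 0L)
  expect_error(match_spacer("ACGTNACGTACGTACGTACGT", ph[1, ]), "N")
  expect_error(match_spacer("ACGT", ph[1, ]))
})

test_that("matcher equals the brute-force scan and is strand-symmetric", {
  withr::with_seed(312, {
    for (i in 1:5) {
      ph <- one_genome("p", rnd_dna(3000))
      sp <- substring(ph$seq, 1200, 1231)
      sp <- substitute_dna(sp, sample(0:1, 1))
      got <- match_spacer(sp, ph[1, ])
      got <- got[order(got$position, got$strand), ]
      want <- oracle_hamming_hits(sp, ph$seq, 1)
      want <- want[order(want$position, want$strand), ]
      expect_equal(got, want, ignore_attr = TRUE)
      # reverse-complementing the genome flips strands bijectively
      rcph <- one_genome("rc", revcomp(ph$seq))
      got_rc <- match_spacer(sp, rcph[1, ])
      expect_identical(nrow(got_rc), nrow(got))
      expect_setequal(3000 - 32 - got_rc$position, got$position)
    }
  })
})

test_that("host assignment aggregates links and flags multi-genus vOTUs", {
  withr::with_seed(321, {
    p1 <- one_genome("phA", rnd_dna(5000))
    p2 <- one_genome("phB", rnd_dna(5000))
    phages <- rbind(p1, p2)
    sp_a <- substring(p1$seq, 100, 131)
    sp_b <- substring(p1$seq, 900, 933)
    sp_c <- substring(p2$seq, 2000, 2031)
  })
  spacers <- data.frame(genome_id = c("bac1", "bac2", "bac2"),
                        seq = c(sp_a, sp_b, sp_c))
  membership <- data.frame(genome_id = c("phA", "phB"),
                           rep_id = c("phA", "phB"))
  taxonomy <- data.frame(
    genome_id = c("bac1", "bac2"),
    lineage = c("d__B;p__X;c__X;o__X;f__X;g__Prevotella;s__P sp1",
                "d__B;p__X;c__X;o__X;f__X;g__Bacteroides;s__B sp2"))
  res <- assign_hosts(spacers, phages, membership, taxonomy)
  expect_identical(nrow(res$assignments), 3L)
  br <- res$votu_breadth
  expect_true(br$multi_genus[br$votu_id == "phA"])
  expect_false(br$multi_genus[br$votu_id == "phB"])
  expect_identical(res$genus_summary$n_votus[
    res$genus_summary$genus == "Bacteroides"], 2L)

  expect_warning(
    res2 <- assign_hosts(spacers, phages, membership, taxonomy[1, ]),
    "taxonomy")
  expect_true("unknown" %in% res2$assignments$genus)

  none <- assign_hosts(data.frame(genome_id = "b", seq = strrep("AC", 16)),
                       phages, membership, taxonomy)
  expect_identical(nrow(none$assignments), 0L)
})

test_that("simulated communities: planted links recovered, decoys not", {
  spec <- community_spec(n_phages = 6, n_bacteria = 8,
                         genome_len_range = c(70000, 80000), seed = 331)
  phage_sims <- lapply(1:6, function(i) simulate_phage(spec, i))
  phages <- do.call(rbind, lapply(phage_sims, `[[`, "genome"))
  bact <- simulate_bacteria(spec, phages)
  arrays <- list()
  for (i in seq_len(nrow(bact$genomes)))
    arrays <- c(arrays, find_crispr_arrays(bact$genomes[i, ]))
  membership <- data.frame(genome_id = phages$id, rep_id = phages$id)
  res <- assign_hosts(arrays, phages, membership, bact$taxonomy)
  truth <- bact$links
  real <- truth[!truth$decoy, ]
  got_pairs <- paste(res$assignments$bacterial_genome_id,
                     res$assignments$votu_id)
  expect_true(all(paste(real$genome_id, real$phage_id) %in% got_pairs))
  # no link that is not planted (decoys at 2 mismatches never match)
  expect_true(all(got_pairs %in% paste(real$genome_id, real$phage_id)))
})
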