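small_spec <- function(...) community_spec(
  n_phages = 4, n_bacteria = 6, n_samples = 4, reads_per_sample = 2000,
  genome_len_range = c(70000, 80000), seed = 501, ...)

test_that("the generator is byte-deterministic under a fixed seed", {
  spec <- small_spec()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_community(spec, d1)
  simulate_community(spec, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("phage truth is internally consistent", {
  spec <- small_spec()
  for (i in 1:4) {
    ps <- simulate_phage(spec, i)
    g <- ps$genome
    expect_gte(g$length, 70000)
    truth <- ps$genes
    # marker order is canonical along the genome
    marks <- truth[truth$label != "filler", ]
    expect_identical(marks$label[order(marks$start)],
                     c("IHF_54", "MCP", "portal", "TerL", "primase"))
    # every truth gene translates under the true code without stops
    for (j in seq_len(nrow(truth))) {
      nt <- substring(g$seq, truth$start[j] + 1, truth$end[j])
      if (truth$strand[j] == "-") nt <- revcomp(nt)
      aa <- translate_codons(nt, ps$code)
      expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
      expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    }
    # planted filler counts match the block-count operation on truth
    expect_identical(count_genes_between(truth, "IHF_54", "MCP"),
                     unname(ps$blocks["ihf54_mcp"]))
    expect_identical(count_genes_between(truth, "MCP", "portal"),
                     unname(ps$blocks["mcp_portal"]))
    expect_identical(count_genes_between(truth, "TerL", "primase"),
                     unname(ps$blocks["terl_primase"]))
  }
})

test_that("code mix of 11 only plants no suppressor tRNA", {
  spec <- community_spec(n_phages = 3, code_mix = c("11" = 1, "4" = 0,
                                                    "15" = 0),
                         genome_len_range = c(70000, 75000), seed = 502)
  for (i in 1:3) {
    ps <- simulate_phage(spec, i)
    expect_identical(ps$code, 11L)
    expect_null(ps$trna)
    expect_identical(nrow(detect_suppressor_trna(ps$genome[1, ])), 0L)
  }
})

test_that("alternative-code phages carry a matching cassette", {
  spec <- community_spec(n_phages = 8, code_mix = c("11" = 0.25,
                                                    "4" = 0.25,
                                                    "15" = 0.5),
                         family_mix = c(alpha = 0.25, beta = 0.25,
                                        delta = 0.25, zeta = 0.25),
                         genome_len_range = c(70000, 75000), seed = 503)
  plan <- crasskit:::phage_plan(spec)
  expect_true(all(plan$code[plan$family == "alpha"] == 11L))
  alt <- which(plan$code != 11L)
  expect_gte(length(alt), 2)
  ps <- simulate_phage(spec, alt[1])
  expect_identical(ps$trna$anticodon,
                   if (ps$code == 15) "CTA" else "TCA")
  hits <- detect_suppressor_trna(ps$genome[1, ])
  expect_identical(hits$position, ps$trna$position)
})

test_that("bacterial arrays have the planted repeat/spacer structure", {
  spec <- small_spec()
  phage_sims <- lapply(1:4, function(i) simulate_phage(spec, i))
  phages <- do.call(rbind, lapply(phage_sims, `[[`, "genome"))
  bact <- simulate_bacteria(spec, phages)
  expect_identical(nrow(bact$genomes), 6L)
  for (i in seq_len(nrow(bact$arrays))) {
    a <- bact$arrays[i, ]
    spacers <- strsplit(a$spacer_seqs, ",")[[1]]
    expect_identical(length(spacers), a$n_repeats - 1L)
    expect_true(all(nchar(spacers) >= 17 & nchar(spacers) <= 50))
    # repeats are planted verbatim at the recorded position
    g <- bact$genomes$seq[bact$genomes$id == a$genome_id]
    expect_identical(substring(g, a$start + 1,
                               a$start + nchar(a$repeat_seq)),
                     a$repeat_seq)
  }
  # planted links: <=1 mismatch against the phage; decoys exactly 2
  for (i in seq_len(nrow(bact$links))) {
    l <- bact$links[i, ]
    ph <- phages[phages$id == l$phage_id, ]
    hits <- match_spacer(l$spacer_seq, ph,
                         crass_thresholds(spacer_max_mismatch = 2))
    expect_equal(min(hits$mismatches), l$mismatches)
  }
})

test_that("error-free reads are perfect copies; abundance ratios hold", {
  spec <- community_spec(n_phages = 2, n_samples = 1,
                         reads_per_sample = 4000, subst_error = 0,
                         genome_len_range = c(70000, 70500),
                         family_mix = c(alpha = 1, beta = 0, delta = 0,
                                        zeta = 0),
                         code_mix = c("11" = 1, "4" = 0, "15" = 0),
                         effect_log2fc = numeric(0), seed = 504)
  phages <- do.call(rbind, lapply(1:2, function(i)
    simulate_phage(spec, i)$genome))
  rd <- simulate_reads(spec, phages)
  reads <- rd$reads[[1]]
  withr::with_seed(505, sel <- sample(nrow(reads), 50))
  for (i in sel) {
    m <- map_reads(reads[i, , drop = FALSE], phages)
    expect_equal(m$identity, 100)
    expect_identical(m$votu_rep_id, reads$source[i])
  }
  # read counts proportional to planted abundance x length (binomial CI)
  rel <- rd$abundance[, 1]
  w <- rel * phages$length; w <- w / sum(w)
  n1 <- sum(reads$source == phages$id[1])
  ci <- stats::binom.test(n1, nrow(reads), w[1])$conf.int
  expect_true(w[1] >= ci[1] && w[1] <= ci[2])
})

test_that("reference TerL sets span all six families", {
  refs <- simulate_references(small_spec())
  expect_setequal(unique(refs$family),
                  c("alpha", "beta", "gamma", "delta", "epsilon", "zeta"))
  expect_identical(nrow(refs), 18L)
})
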