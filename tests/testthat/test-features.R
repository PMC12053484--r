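test_that("planted genetic codes are recovered; standard code is the tie", {
  for (code in c(11, 4, 15)) {
    g <- simulate_code_genome(code, n_genes = 25, seed = 200 + code)
    cc <- infer_genetic_code(g[1, ])
    expect_identical(cc$code, as.integer(code))
    expect_true(all(cc$coding_density >= 0 & cc$coding_density <= 1))
  }
  # standard genome: alternative densities sit within the margin, 11 wins
  g11 <- simulate_code_genome(11, n_genes = 25, seed = 211)
  cc <- infer_genetic_code(g11[1, ])
  expect_identical(cc$code, 11L)
  expect_lt(max(cc$coding_density[c("4", "15")]) -
              cc$coding_density[["11"]], 0.05)
})

test_that("suppressor tRNA cassettes are found on both strands", {
  tmpl <- trna_templates()[1, ]
  cas15 <- tmpl$seq
  substr(cas15, tmpl$anticodon_offset + 1, tmpl$anticodon_offset + 3) <- "CTA"
  cas4 <- tmpl$seq
  substr(cas4, tmpl$anticodon_offset + 1, tmpl$anticodon_offset + 3) <- "TCA"
  withr::with_seed(221, {
    g15 <- one_genome("g15", paste0(rnd_dna(3000), cas15, rnd_dna(3000)))
    g4 <- one_genome("g4", paste0(rnd_dna(3000), revcomp(cas4),
                                  rnd_dna(3000)))
    g0 <- one_genome("g0", rnd_dna(8000))
  })
  hit15 <- detect_suppressor_trna(g15[1, ])
  expect_identical(nrow(hit15), 1L)
  expect_identical(hit15$anticodon, "CTA")
  expect_identical(hit15$suppresses, "TAG")
  expect_identical(hit15$position, 3000L)

  hit4 <- detect_suppressor_trna(g4[1, ])
  expect_identical(nrow(hit4), 1L)
  expect_identical(hit4$strand, "-")
  expect_identical(hit4$anticodon, "TCA")
  expect_identical(hit4$suppresses, "TGA")

  expect_identical(nrow(detect_suppressor_trna(g0[1, ])), 0L)
})

test_that("planted markers are recovered in order; decoys stay unknown", {
  spec <- community_spec(n_phages = 4, seed = 231)
  ps <- simulate_phage(spec, 1)
  ann <- annotate_markers(ps$genome[1, ], code = ps$code)
  truth <- ps$genes[ps$genes$label != "filler", ]
  for (i in seq_len(nrow(truth))) {
    ov <- ann[ann$start < truth$end[i] & ann$end > truth$start[i] &
                ann$strand == truth$strand[i], ]
    expect_true(truth$label[i] %in% ov$label)
  }
  got_marks <- ann[ann$label != "unknown", ]
  got_marks <- got_marks[order(got_marks$start), ]
  expect_identical(unique(got_marks$label),
                   c("IHF_54", "MCP", "portal", "TerL", "primase"))

  withr::with_seed(232, decoy <- one_genome("d", rnd_dna(20000)))
  ann_d <- annotate_markers(decoy[1, ], code = 11)
  expect_true(all(ann_d$label == "unknown"))
})

test_that("gene-block counts use planted truth, arcs and best copies", {
  genes <- data.frame(
    genome_id = "g", start = seq(0, 900, by = 100),
    end = seq(0, 900, by = 100) + 90, strand = "+",
    label = c("IHF_54", rep("filler", 3), "MCP", "portal", "TerL",
              rep("filler", 2), "primase"),
    length_aa = 29)
  expect_identical(count_genes_between(genes, "IHF_54", "MCP"), 3L)
  expect_identical(count_genes_between(genes, "MCP", "portal"), 0L)
  expect_identical(count_genes_between(genes, "TerL", "primase"), 2L)
  expect_true(is.na(count_genes_between(genes[genes$label != "primase", ],
                                        "TerL", "primase")))

  # circular: the shorter arc wins
  circ <- data.frame(genome_id = "c",
                     start = c(0, 200, 400, 600, 800),
                     end = c(90, 290, 490, 690, 890), strand = "+",
                     label = c("MCP", "filler", "filler", "filler",
                               "IHF_54"),
                     length_aa = 29)
  expect_identical(count_genes_between(circ, "IHF_54", "MCP",
                                       circular = TRUE,
                                       genome_length = 1000), 0L)
  expect_identical(count_genes_between(circ, "IHF_54", "MCP"), 3L)

  dup <- rbind(genes, data.frame(genome_id = "g", start = 950, end = 990,
                                 strand = "+", label = "MCP",
                                 length_aa = 12))
  dup$score <- c(rep(1, 10), 0.1)
  expect_warning(k <- count_genes_between(dup, "IHF_54", "MCP"), "copy")
  expect_identical(k, 3L)
})

test_that("block counts are invariant under reverse complementation", {
  spec <- community_spec(n_phages = 4, seed = 233)
  ps <- simulate_phage(spec, 2)
  genes <- ps$genes
  L <- ps$genome$length
  flipped <- genes
  flipped$start <- L - genes$end
  flipped$end <- L - genes$start
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  flipped <- flipped[order(flipped$start), ]
  for (pair in list(c("IHF_54", "MCP"), c("MCP", "portal"),
                    c("TerL", "primase")))
    expect_identical(count_genes_between(genes, pair[1], pair[2]),
                     count_genes_between(flipped, pair[1], pair[2]))
})

test_that("rank-sum p-values are exact for small n and sane for ties", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p, 2 / 6)
  expect_identical(r$W, 3)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p, 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)

  withr::with_seed(241, {
    for (i in 1:40) {
      n <- sample(2:4, 1); m <- sample(2:4, 1)
      x <- sample(1:5, n, TRUE); y <- sample(1:5, m, TRUE)
      expect_equal(wilcoxon_rank_sum(x, y)$p, oracle_wilcoxon_p(x, y))
    }
  })
})

test_that("normal approximation tracks the exact branch", {
  withr::with_seed(242, {
    diffs <- replicate(20, {
      x <- stats::rnorm(5); y <- stats::rnorm(5, 0.5)
      exact <- wilcoxon_rank_sum(x, y)$p
      approx <- stats::wilcox.test(x, y, exact = FALSE,
                                   correct = TRUE)$p.value
      abs(exact - approx)
    })
  })
  expect_lt(stats::median(diffs), 0.05)
})

test_that("anti-CRISPR filtering applies both predictors and the length cap", {
  grid <- expand.grid(pred_a = c(TRUE, FALSE), pred_b = c(TRUE, FALSE),
                      length_aa = c(150, 250))
  grid$protein_id <- sprintf("p%d", seq_len(nrow(grid)))
  kept <- filter_acr(grid)
  expect_identical(kept$protein_id,
                   grid$protein_id[grid$pred_a & grid$pred_b &
                                     grid$length_aa <= 200])
  # boundary: exactly 200 residues is retained ("> 200 ... removed")
  edge <- data.frame(protein_id = c("a", "b"), length_aa = c(200, 201),
                     pred_a = TRUE, pred_b = TRUE)
  expect_identical(filter_acr(edge)$protein_id, "a")
  # idempotent subset
  expect_identical(filter_acr(kept), kept)
})

test_that("CAZyme prevalence reproduces a hand-built truth table", {
  fams <- data.frame(genome_id = sprintf("g%d", 1:10),
                     family = rep(c("alpha", "beta"), each = 5))
  annots <- data.frame(genome_id = c("g1", "g2", "g6", "g6", "g7"),
                       cazyme_type = c("GH73", "GH73", "GH108", "GH108",
                                       "GH108"))
  tab <- cazyme_cluster_prevalence(annots, fams)
  get <- function(f, t) tab$prevalence[tab$family == f &
                                         tab$cazyme_type == t]
  expect_equal(get("alpha", "GH73"), 40)
  expect_equal(get("beta", "GH73"), 0)
  expect_equal(get("beta", "GH108"), 40)   # g6 counted once
  expect_equal(get("alpha", "GH108"), 0)
  expect_identical(nrow(tab), 4L)
})
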