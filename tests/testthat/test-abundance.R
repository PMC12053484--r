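test_that("read mapping applies the identity and aligned-percent gates", {
  withr::with_seed(401, {
    rep1 <- one_genome("rep1", rnd_dna(20000))
    clean <- substring(rep1$seq, 5001, 5150)
    noisy <- substitute_dna(clean, 17)            # ~11% substitutions
    edge <- paste0(substring(rep1$seq, 19926, 20000), rnd_dna(75))
  })
  reads <- data.frame(id = c("ok", "noisy", "edge"),
                      seq = c(clean, noisy, edge))
  m <- map_reads(reads, rep1)
  expect_identical(m$read_id, "ok")
  expect_equal(m$identity, 100)
  expect_identical(m$start, 5000L)
  expect_identical(m$end, 5150L)

  # reverse-complemented reads map to the same place
  m2 <- map_reads(data.frame(id = "rc", seq = revcomp(clean)), rep1)
  expect_identical(m2$start, 5000L)
  expect_identical(m2$strand, "-")
})

test_that("RPKM matches its closed form and the 75% gates are literal", {
  reps <- genome_records(data.frame(id = c("v1", "v2"),
                                    seq = c(strrep("ACGT", 25000),
                                            strrep("ACGT", 10000))))
  mk_aln <- function(n, rep_id, len, cover_to) {
    starts <- floor(seq(0, cover_to - 150, length.out = n))
    data.frame(read_id = sprintf("%s_%d", rep_id, 1:n),
               votu_rep_id = rep_id, identity = 100,
               aligned_percent = 100, start = starts, end = starts + 150)
  }
  # v1: 1,000 reads covering everything; closed form 1000*1e9/(1e5*1e6)=10
  aln <- rbind(mk_aln(1000, "v1", 1e5, 1e5),
               mk_aln(200, "v2", 4e4, 0.749 * 4e4))
  ab <- quantify(list(s1 = aln), reps, c(s1 = 1e6))
  expect_equal(ab$rpkm["v1", "s1"], 10)
  expect_true(ab$detected["v1", "s1"])
  # v2 covered below 75%: abundance forced to zero, not detected
  expect_lt(ab$covered_fraction["v2", "s1"], 75)
  expect_equal(ab$rpkm["v2", "s1"], 0)
  expect_false(ab$detected["v2", "s1"])

  # boundary: exactly 75% covered keeps its abundance but is NOT detected
  aln75 <- mk_aln(200, "v2", 4e4, 0.75 * 4e4)
  ab75 <- quantify(list(s1 = aln75), reps, c(s1 = 1e6))
  expect_equal(ab75$covered_fraction["v2", "s1"], 75)
  expect_gt(ab75$rpkm["v2", "s1"], 0)
  expect_false(ab75$detected["v2", "s1"])

  ab0 <- quantify(list(s1 = aln[0, ]), reps, c(s1 = 1e6))
  expect_true(all(ab0$rpkm == 0))
})

test_that("prevalence and cluster-presence rules are literal", {
  det <- matrix(FALSE, 2, 13,
                dimnames = list(c("v1", "v2"), sprintf("s%02d", 1:13)))
  det["v1", 1:4] <- TRUE
  det["v2", 5] <- TRUE
  pops <- stats::setNames(rep(c("P1", "P2"), c(6, 7)), colnames(det))
  pr <- prevalence(det, pops, votu_family = c(v1 = "alpha", v2 = "beta"))
  expect_equal(unname(pr$sample_prevalence["v1"]), 100 * 4 / 13)
  expect_true(pr$population_detected["v2", "P1"])   # one sample suffices
  expect_false(pr$population_detected["v2", "P2"])
  expect_true(pr$cluster_presence["alpha", "s01"])
  expect_false(pr$cluster_presence["alpha", "s05"])
  expect_true(pr$cluster_presence["beta", "s05"])
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(411, p <- stats::runif(30))
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
})

test_that("group association recovers planted effects with signed scores", {
  withr::with_seed(421, {
    n_votu <- 30; n_per <- 8
    samples <- sprintf("s%02d", 1:(2 * n_per))
    groups <- stats::setNames(rep(c("lean", "fat"), each = n_per), samples)
    base <- stats::rlnorm(n_votu, 2, 0.5)
    rpkm <- sapply(samples, function(s)
      base * stats::rlnorm(n_votu, 0, 0.2))
    rownames(rpkm) <- sprintf("v%02d", 1:n_votu)
    rpkm["v01", groups[samples] == "fat"] <-
      rpkm["v01", groups[samples] == "fat"] * 4      # log2FC = +2
    rpkm["v02", groups[samples] == "fat"] <-
      rpkm["v02", groups[samples] == "fat"] / 4      # log2FC = -2
  })
  res <- associate_groups(rpkm, groups)
  r1 <- res[res$votu_id == "v01", ]
  r2 <- res[res$votu_id == "v02", ]
  expect_true(r1$coeff > 0 && r1$qval < 0.05 && r1$significant)
  expect_true(r2$coeff < 0 && r2$qval < 0.05)
  expect_equal(r1$signed_score, -log10(r1$qval))
  expect_equal(r2$signed_score, log10(r2$qval))
  # formula check at q = 0.001 with a negative coefficient
  fake <- res[1, ]; fake$qval <- 0.001; fake$coeff <- -1
  expect_equal(-log10(fake$qval) * sign(fake$coeff), -3)
})

test_that("degenerate and absent vOTUs are handled", {
  withr::with_seed(422, {
    rpkm <- matrix(stats::rlnorm(40), 5, 8,
                   dimnames = list(sprintf("v%d", 1:5),
                                   sprintf("s%d", 1:8)))
    rpkm["v5", ] <- 0                     # absent everywhere -> excluded
  })
  groups <- stats::setNames(rep(c("lean", "fat"), each = 4),
                            colnames(rpkm))
  res <- associate_groups(rpkm, groups)
  expect_false("v5" %in% res$votu_id)
  expect_identical(nrow(res), 4L)
})

test_that("permuted labels give approximately uniform p-values", {
  withr::with_seed(423, {
    n_votu <- 40
    samples <- sprintf("s%02d", 1:16)
    base <- stats::rlnorm(n_votu, 2, 0.5)
    rpkm <- sapply(samples, function(s) base * stats::rlnorm(n_votu, 0, 0.3))
    rownames(rpkm) <- sprintf("v%02d", 1:n_votu)
    pvals <- unlist(lapply(1:10, function(i) {
      groups <- stats::setNames(sample(rep(c("lean", "fat"), each = 8)),
                                samples)
      associate_groups(rpkm, groups)$pval
    }))
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})
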