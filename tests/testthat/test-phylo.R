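test_that("progressive alignment handles the canonical small cases", {
  m <- progressive_msa(c(a = "ACDEFG", b = "ACDEFG"))
  expect_identical(unname(m), c("ACDEFG", "ACDEFG"))   # no gaps

  m2 <- progressive_msa(c(a = "ACDEFG", b = "ACEFG"))
  expect_identical(unname(m2), c("ACDEFG", "AC-EFG"))  # gap at the D column

  withr::with_seed(91, {
    seqs <- stats::setNames(vapply(sample(20:60, 5), rnd_prot, ""),
                            paste0("s", 1:5))
  })
  m3 <- progressive_msa(seqs)
  expect_identical(length(unique(nchar(m3))), 1L)
  expect_gte(nchar(m3[1]), max(nchar(seqs)))
  expect_identical(gsub("-", "", m3[names(seqs)]), seqs)
  expect_error(progressive_msa(c(a = "ACD")), "at least 2")
})

test_that("p-distances count mismatches over comparable columns", {
  msa <- c(a = "AAAAAAAAAA", b = "AAAAAAATTT", c = "AAAAAAAAAA")
  d <- distance_matrix(msa)
  expect_equal(d["a", "b"], 0.3)
  expect_equal(d["a", "c"], 0)
  expect_true(isSymmetric(d))
  expect_error(distance_matrix(c(a = "A---", b = "-TTT")), "comparable")
})

test_that("3-taxon neighbor joining matches the closed form", {
  d <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(bl[["A"]], (5 + 9 - 8) / 2)
  expect_equal(bl[["B"]], (5 + 8 - 9) / 2)
  expect_equal(bl[["C"]], (9 + 8 - 5) / 2)
})

test_that("neighbor joining exactly recovers additive distances", {
  # fixed 4-taxon additive matrix from tree ((A:1,B:2):1,(C:3,D:4):1)
  d <- matrix(c(0, 3, 6, 7,
                3, 0, 7, 8,
                6, 7, 0, 7,
                7, 8, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-12)
  # AB|CD split present
  splits <- ape::prop.part(ape::unroot(tr))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0.5, 0, 1, 2, 1, 0),
                                       3, 3)), "symmetric")

  withr::with_seed(92, {
    for (i in 1:15) {
      n <- sample(4:10, 1)
      at <- random_additive_tree(n)
      rec <- neighbor_joining(at$d)
      expect_equal(ape::cophenetic.phylo(rec)[rownames(at$d),
                                              colnames(at$d)],
                   at$d, tolerance = 1e-9)
    }
  })
})

test_that("midpoint rooting balances the two farthest leaves", {
  tr2 <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2,
                                      byrow = TRUE),
                        edge.length = c(3, 7), Nnode = 1L,
                        tip.label = c("x", "y")),
                   class = "phylo", order = "cladewise")
  rooted <- midpoint_root(tr2)
  depths <- ape::node.depth.edgelength(rooted)[1:2]
  expect_equal(depths, c(5, 5))

  withr::with_seed(93, {
    for (i in 1:10) {
      at <- random_additive_tree(sample(4:8, 1))
      rooted <- midpoint_root(at$tree)
      depths <- ape::node.depth.edgelength(rooted)[
        seq_along(rooted$tip.label)]
      # max root-leaf depth is half the tree diameter (the minimum possible)
      expect_equal(max(depths), max(at$d) / 2, tolerance = 1e-9)
      # rooting preserves the leaf path-distance matrix
      expect_equal(ape::cophenetic.phylo(rooted)[rownames(at$d),
                                                 colnames(at$d)],
                   at$d, tolerance = 1e-9)
    }
  })

  flat <- ape::rtree(4)
  flat$edge.length <- rep(0, nrow(flat$edge))
  expect_warning(midpoint_root(flat), "zero")
})

test_that("bootstrap support is high for well-separated clades", {
  withr::with_seed(95, {
    a <- rnd_prot(80)
    b <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
    mut <- function(s) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(80, 4)
      ch[idx] <- vapply(idx, function(i) rnd_prot(1), "")
      paste(ch, collapse = "")
    }
    msa <- c(a1 = mut(a), a2 = mut(a), b1 = mut(b), b2 = mut(b))
  })
  tr <- nj_bootstrap(msa, n_boot = 50, seed = 9)
  expect_identical(length(tr$node.label), tr$Nnode)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 1))
  # the a|b split is recovered in (nearly) every replicate
  expect_gte(max(tr$node.label), 0.9)
  # seeded: reproducible
  tr2 <- nj_bootstrap(msa, n_boot = 50, seed = 9)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("MRCA propagation assigns descendants and leaves outsiders", {
  tree <- midpoint_root(ape::read.tree(
    text = "((h1:1,(h2:1,p1:1):1):1,((h3:1,h4:1):1,out:9):1);"))
  ref <- data.frame(leaf_id = c("h1", "h2", "h3", "h4"),
                    family = c("alpha", "alpha", "beta", "beta"))
  asg <- propagate_taxonomy(tree, ref)
  get <- function(l) asg$family[asg$leaf_id == l]
  expect_identical(get("p1"), "alpha")
  expect_identical(get("h3"), "beta")
  expect_identical(get("out"), "unclassified")
  expect_error(propagate_taxonomy(tree, rbind(ref, data.frame(
    leaf_id = "nope", family = "gamma"))), "zero leaves")
})

test_that("nested labeled clades resolve to the smallest enclosing clade", {
  tree <- midpoint_root(ape::read.tree(
    text = "(((d1:1,(d2:1,p1:1):1):1,a1:4):1,(a2:1,a3:1):4);"))
  ref <- data.frame(leaf_id = c("a1", "a2", "a3", "d1", "d2"),
                    family = c("alpha", "alpha", "alpha", "delta",
                               "delta"))
  asg <- propagate_taxonomy(tree, ref)
  # p1 sits inside the delta MRCA, itself inside the broader alpha MRCA
  expect_identical(asg$family[asg$leaf_id == "p1"], "delta")
  # reference leaves keep their own labels
  for (l in ref$leaf_id)
    expect_identical(asg$family[asg$leaf_id == l],
                     ref$family[ref$leaf_id == l])
})

test_that("planted families are fully recovered from simulated TerL sets", {
  spec <- community_spec(n_phages = 6, seed = 101)
  refs <- simulate_references(spec)
  withr::with_seed(94, {
    cons <- crasskit:::marker_family_consensi()
    fams <- c("alpha", "beta", "delta", "zeta")
    pigs <- do.call(rbind, lapply(1:8, function(i) {
      f <- fams[(i - 1) %% 4 + 1]
      data.frame(id = sprintf("pig%02d", i),
                 seq = crasskit:::mutate_protein(
                   cons$seq[cons$id == paste0("TerL|", f)], 0.05),
                 family = f)
    }))
  })
  cls <- classify_votus(pigs[, c("id", "seq")], refs)
  got <- cls$assignments
  expect_identical(got$family[match(pigs$id, got$leaf_id)], pigs$family)
})
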