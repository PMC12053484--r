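# 3-mer composition distance between protein sequences (guide-tree metric).
kmer_distance <- function(seqs, k = 3L) {
  n <- length(seqs)
  km <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character())
    substring(s, seq_len(nchar(s) - k + 1L), seq_len(nchar(s) - k + 1L) + k - 1L)
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ti <- table(km[[i]]); tj <- table(km[[j]])
    shared <- sum(pmin(ti[names(tj)], tj), na.rm = TRUE)
    denom <- min(length(km[[i]]), length(km[[j]]))
    d[i, j] <- d[j, i] <- if (denom > 0) 1 - shared / denom else 1
  }
  d
}

# Alignment rows -> alphabet x columns frequency profile (gaps contribute 0).
profile_freqs <- function(rows, alphabet = aa_alphabet()) {
  mat <- do.call(rbind, strsplit(rows, ""))
  f <- matrix(0, length(alphabet), ncol(mat), dimnames = list(alphabet, NULL))
  for (j in seq_len(ncol(mat))) {
    tb <- table(factor(mat[, j], levels = alphabet))
    f[, j] <- as.numeric(tb) / nrow(mat)
  }
  f
}

#' Progressive multiple sequence alignment
#'
#' A compact progressive aligner for marker proteins: UPGMA guide tree on
#' 3-mer composition distances, then profile-profile global alignment
#' (expected BLOSUM62 column score, linear gap penalty) along the guide
#' tree. All output rows have equal length.
#'
#' @param proteins Data frame with `id`, `seq` (>= 2 rows), or a named
#'   character vector.
#' @param gap Linear gap penalty per column.
#' @return Named character vector of aligned rows (with `-` gaps), in input
#'   order.
#' @export
progressive_msa <- function(proteins, gap = 8) {
  if (is.character(proteins))
    proteins <- data.frame(id = names(proteins), seq = unname(proteins))
  n <- nrow(proteins)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  seqs <- toupper(proteins$seq)
  if (n == 2) {
    merged <- align_two_groups(stats::setNames(seqs[1], proteins$id[1]),
                               stats::setNames(seqs[2], proteins$id[2]), gap)
  } else {
    d <- kmer_distance(seqs)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    node_aln <- vector("list", n - 1L)
    get_rows <- function(ix) {
      if (ix < 0) stats::setNames(seqs[-ix], proteins$id[-ix])
      else node_aln[[ix]]
    }
    for (s in seq_len(n - 1L)) {
      g1 <- get_rows(hc$merge[s, 1]); g2 <- get_rows(hc$merge[s, 2])
      node_aln[[s]] <- align_two_groups(g1, g2, gap)
    }
    merged <- node_aln[[n - 1L]]
  }
  merged[proteins$id]
}

# Align two groups of already-aligned rows (profile-profile NW).
align_two_groups <- function(g1, g2, gap = 8) {
  if (is.null(names(g1))) names(g1) <- "seq1"
  if (is.null(names(g2))) names(g2) <- "seq2"
  f1 <- profile_freqs(g1); f2 <- profile_freqs(g2)
  S <- t(f1) %*% blosum62() %*% f2
  path <- cpp_nw_path(S, gap)
  expand <- function(rows, idx) {
    mat <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow(mat), length(idx))
    out[, idx > 0] <- mat[, idx[idx > 0], drop = FALSE]
    stats::setNames(apply(out, 1, paste, collapse = ""), names(rows))
  }
  c(expand(g1, path$i), expand(g2, path$j))
}

#' Pairwise p-distances from an alignment
#'
#' `d(i, j)` is the fraction of mismatching positions among columns where
#' neither row has a gap (pairwise deletion). A pair with no comparable
#' positions is an error.
#'
#' @param msa Named character vector of equal-length aligned rows.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(msa) {
  n <- length(msa)
  stopifnot(n >= 2, length(unique(nchar(msa))) == 1)
  mat <- do.call(rbind, strsplit(msa, ""))
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok))
      stop("no comparable positions between rows ", i, " and ", j,
           call. = FALSE)
    d[i, j] <- d[j, i] <- mean(mat[i, ok] != mat[j, ok])
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining (via [ape::nj()]). Negative branch
#' lengths are clamped to zero with the deficit transferred to the sibling
#' branch, so leaf-to-leaf path lengths through the parent are preserved.
#'
#' @param d Symmetric non-negative distance matrix, n >= 3.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  stopifnot(nrow(d) >= 3, all(d >= -1e-12))
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sib))
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr
}

#' Midpoint rooting
#'
#' Roots a tree at the midpoint of its longest leaf-to-leaf path, making the
#' two farthest leaves equidistant from the root. A tree whose branch
#' lengths are all zero is rooted at its first internal node with a warning.
#'
#' @param tree A `phylo` tree with >= 2 leaves.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  nt <- length(tree$tip.label)
  stopifnot(nt >= 2)
  if (all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; rooting at the first leaf")
    return(ape::root(tree, outgroup = tree$tip.label[1],
                     resolve.root = TRUE))
  }
  if (nt == 2) return(two_leaf_midpoint(tree))
  phangorn::midpoint(tree)
}

two_leaf_midpoint <- function(tree) {
  total <- sum(tree$edge.length)
  structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = c(total / 2, total / 2),
                 tip.label = tree$tip.label, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Seeded bootstrap over alignment columns: each replicate resamples
#' columns with replacement, rebuilds the p-distance NJ tree, and clade
#' support is the fraction of replicates containing each internal
#' bipartition of the reference tree.
#'
#' @param msa Named character vector of aligned rows.
#' @param tree The tree whose clades are scored (default: NJ on `msa`).
#' @param n_boot Number of replicates.
#' @param seed RNG seed.
#' @return The tree with `node.label` set to support fractions.
#' @export
nj_bootstrap <- function(msa, tree = NULL, n_boot = 100, seed = 1) {
  mat <- do.call(rbind, strsplit(msa, ""))
  rownames(mat) <- names(msa)
  if (is.null(tree)) tree <- neighbor_joining(distance_matrix(msa))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  reps <- lapply(seq_len(n_boot), function(i) {
    cols <- sample(ncol(mat), replace = TRUE)
    rows <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    neighbor_joining(distance_matrix(rows))
  })
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- counts / n_boot
  tree
}

#' Propagate reference taxonomy by the MRCA rule
#'
#' For each reference family, the most recent common ancestor of all
#' reference leaves carrying that family is found; every leaf descending
#' from that MRCA is assignable to the family. Leaves under several labeled
#' MRCAs take the label of the smallest (fewest-leaf) enclosing clade (ties:
#' lexicographically first family). Leaves under none are `"unclassified"`
#' (and are dropped from downstream family-level analyses).
#'
#' @param tree Rooted `phylo` tree.
#' @param ref Data frame with `leaf_id`, `family` for the reference leaves.
#' @return Data frame `leaf_id, family, assigning_mrca` for every leaf.
#' @export
propagate_taxonomy <- function(tree, ref) {
  tips <- tree$tip.label
  fams <- sort(unique(ref$family))
  clades <- lapply(fams, function(fam) {
    leaves <- intersect(ref$leaf_id[ref$family == fam], tips)
    if (!length(leaves))
      stop("reference family with zero leaves in tree: ", fam, call. = FALSE)
    if (length(leaves) == 1L) {
      node <- match(leaves, tips)
      desc <- leaves
    } else {
      node <- ape::getMRCA(tree, leaves)
      desc <- tips[phangorn::Descendants(tree, node, type = "tips")[[1]]]
    }
    list(family = fam, node = node, desc = desc, size = length(desc))
  })
  out <- lapply(tips, function(lf) {
    cover <- Filter(function(cl) lf %in% cl$desc, clades)
    if (!length(cover))
      return(data.frame(leaf_id = lf, family = "unclassified",
                        assigning_mrca = NA_integer_))
    sizes <- vapply(cover, `[[`, 0L, "size")
    best <- cover[[which.min(sizes)]]
    data.frame(leaf_id = lf, family = best$family,
               assigning_mrca = best$node)
  })
  do.call(rbind, out)
}

#' Classify vOTU representatives on a TerL tree
#'
#' End-to-end family assignment: aligns the TerL proteins of the vOTU
#' representatives together with labeled reference TerL proteins, builds a
#' p-distance neighbor-joining tree, midpoint-roots it, and propagates the
#' reference families by the MRCA rule.
#'
#' @param terl Protein data frame for the unlabeled representatives.
#' @param ref_terl Protein data frame for references, with a `family` column.
#' @return List with the rooted `tree` and the `assignments` table
#'   (reference leaves excluded).
#' @export
classify_votus <- function(terl, ref_terl) {
  stopifnot(nrow(terl) >= 1, nrow(ref_terl) >= 2)
  all <- rbind(terl[, c("id", "seq")], ref_terl[, c("id", "seq")])
  msa <- progressive_msa(all)
  tree <- midpoint_root(neighbor_joining(distance_matrix(msa)))
  asg <- propagate_taxonomy(tree, data.frame(leaf_id = ref_terl$id,
                                             family = ref_terl$family))
  list(tree = tree,
       assignments = asg[asg$leaf_id %in% terl$id, , drop = FALSE])
}
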