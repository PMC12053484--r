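#' Infer the genetic code of a genome
#'
#' Emulates alternative-code-aware gene calling: ORFs are called under codes
#' 11, 4 (TGA = Trp) and 15 (TAG = Gln); the coding density of each code is
#' the fraction of the genome covered by the union of its ORF spans. The
#' standard code is preferred unless an alternative exceeds its density by
#' the margin `delta` (a guard against spurious alternative-code calls).
#'
#' @param genome One genome row, >= 3 kb.
#' @param min_len_aa Minimum ORF length used for density.
#' @param delta Density margin an alternative code must exceed.
#' @return List with `genome_id`, `code` (11, 4 or 15) and the named
#'   `coding_density` vector.
#' @export
infer_genetic_code <- function(genome, min_len_aa = 60, delta = 0.05) {
  stopifnot(genome$length >= 3000)
  dens <- vapply(c("11", "4", "15"), function(code) {
    orfs <- find_orfs(genome, code = as.integer(code), min_len_aa = min_len_aa)
    if (!nrow(orfs)) return(0)
    ir <- IRanges::IRanges(start = orfs$start + 1L, end = orfs$end)
    sum(IRanges::width(IRanges::reduce(ir))) / genome$length
  }, 0)
  alt <- dens[c("4", "15")]
  best_alt <- names(alt)[which.max(alt)]
  code <- if (alt[[best_alt]] > dens[["11"]] + delta) as.integer(best_alt)
  else 11L
  list(genome_id = genome$id, code = code, coding_density = dens)
}

#' Detect suppressor tRNA cassettes
#'
#' Scans both strands for near-exact (>= 90% identity, substitution-only)
#' matches to the packaged tRNA cassette templates and reads the anticodon
#' at the template's fixed offset. Only stop-codon-suppressing anticodons
#' are reported: CTA (reads through TAG) and TCA (reads through TGA).
#'
#' @param genome One genome row.
#' @param templates Template table from [trna_templates()].
#' @return Data frame `genome_id, position, strand, anticodon, suppresses`
#'   (zero rows when none found).
#' @export
detect_suppressor_trna <- function(genome, templates = trna_templates()) {
  subject <- Biostrings::DNAString(genome$seq)
  out <- list()
  for (i in seq_len(nrow(templates))) {
    tmpl <- templates$seq[i]
    off <- templates$anticodon_offset[i]
    max_mm <- floor(0.10 * nchar(tmpl))
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tmpl else revcomp(tmpl)
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mm)
      for (s in BiocGenerics::start(m)) {
        hit <- substring(genome$seq, s, s + nchar(tmpl) - 1L)
        if (strand == "-") hit <- revcomp(hit)
        anticodon <- substring(hit, off + 1L, off + 3L)
        if (anticodon %in% c("CTA", "TCA"))
          out[[length(out) + 1L]] <-
            data.frame(genome_id = genome$id, position = s - 1L,
                       strand = strand, anticodon = anticodon,
                       suppresses = revcomp(anticodon))
      }
    }
  }
  if (!length(out))
    return(data.frame(genome_id = character(), position = integer(),
                      strand = character(), anticodon = character(),
                      suppresses = character()))
  unique(do.call(rbind, out))
}

#' Annotate genes with marker labels
#'
#' Calls genes under the genome's (inferred) genetic code and labels each
#' with the best-scoring marker profile at or above its calibrated
#' threshold, else `"unknown"`.
#'
#' @param genome One genome row.
#' @param profiles Named list of calibrated profiles (default all five
#'   packaged markers).
#' @param code Genetic code to call genes under (default: inferred).
#' @param min_len_aa Minimum gene length.
#' @return Gene-annotation data frame with `label` and `score` columns.
#' @export
annotate_markers <- function(genome, profiles = crass_profiles(),
                             code = NULL, min_len_aa = 60) {
  if (is.null(code)) code <- infer_genetic_code(genome)$code
  orfs <- find_orfs(genome, code = code, min_len_aa = min_len_aa)
  if (!nrow(orfs)) return(cbind(orfs, score = numeric()))
  orfs$label <- "unknown"
  orfs$score <- NA_real_
  for (i in seq_len(nrow(orfs))) {
    prot <- orf_protein(genome, orfs[i, ], code = code)
    best <- NULL
    for (pr in profiles) {
      h <- pssm_search(prot, pr)
      if (!is.null(h) && (is.null(best) || h$score > best$score)) {
        best <- h
      }
    }
    if (!is.null(best)) {
      orfs$label[i] <- best$target_id
      orfs$score[i] <- best$score
    }
  }
  orfs
}

#' Reduce overlapping ORF calls to a non-overlapping gene tiling
#'
#' ORF calling keeps maximal ORFs in all six frames, so calls overlap; for
#' gene counting a single consistent gene set is needed. This picks the
#' non-overlapping subset maximizing total coding bases minus a per-gene
#' start cost (weighted-interval dynamic programming) - a deterministic
#' stand-in for a coding-statistics gene caller. The start cost plays the
#' role of a gene-calling prior: it stops pairs of short spurious ORFs that
#' spill into the intergenic gaps from outscoring one real gene, while any
#' ORF longer than the cost still pays for itself.
#'
#' @param genes Gene-annotation data frame (`start`, `end`).
#' @param gene_penalty Per-gene cost in bases.
#' @return The selected subset, sorted by start.
#' @export
tile_genes <- function(genes, gene_penalty = 250) {
  n <- nrow(genes)
  if (n <= 1) return(genes)
  ord <- order(genes$end, genes$start)
  g <- genes[ord, , drop = FALSE]
  # p[i]: last interval (in end order) ending at or before g$start[i]
  p <- findInterval(g$start, g$end)
  w <- as.numeric(g$end - g$start) - gene_penalty
  best <- numeric(n + 1)
  take <- logical(n)
  for (i in seq_len(n)) {
    with_i <- w[i] + best[p[i] + 1]
    if (with_i > best[i]) {           # strict: ties prefer earlier genes
      best[i + 1] <- with_i
      take[i] <- TRUE
    } else {
      best[i + 1] <- best[i]
    }
  }
  keep <- logical(n)
  i <- n
  while (i >= 1) {
    if (take[i] && best[i + 1] == w[i] + best[p[i] + 1]) {
      keep[i] <- TRUE
      i <- p[i]
    } else i <- i - 1
  }
  out <- g[keep, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

#' Count genes between two marker genes
#'
#' Counts the genes lying strictly between markers `a` and `b` (by gene
#' midpoints, markers excluded). On circular genomes the shorter arc is
#' used. `NA` when either marker is absent; when a marker occurs more than
#' once the highest-scoring copy is used, with a warning.
#'
#' @param genes Gene-annotation data frame (with `label`, optionally
#'   `score`), sorted by start.
#' @param a,b Marker labels.
#' @param circular Is the genome circular?
#' @param genome_length Needed for circular genomes.
#' @return Integer count, or `NA` if a flanking marker is missing.
#' @export
count_genes_between <- function(genes, a, b, circular = FALSE,
                                genome_length = NULL) {
  pick <- function(lab) {
    hit <- genes[genes$label == lab, , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    if (nrow(hit) > 1) {
      warning("marker ", lab, " present ", nrow(hit),
              "x; using highest-scoring copy")
      sc <- if ("score" %in% names(hit)) hit$score else rep(0, nrow(hit))
      sc[is.na(sc)] <- -Inf
      hit <- hit[order(-sc, hit$start), , drop = FALSE]
    }
    hit[1, ]
  }
  ma <- pick(a); mb <- pick(b)
  if (is.null(ma) || is.null(mb)) return(NA_integer_)
  mid <- (genes$start + genes$end) / 2
  others <- genes$label != a & genes$label != b
  am <- (ma$start + ma$end) / 2
  bm <- (mb$start + mb$end) / 2
  if (!circular) {
    lo <- min(am, bm); hi <- max(am, bm)
    return(sum(others & mid > lo & mid < hi))
  }
  stopifnot(!is.null(genome_length))
  fwd <- (bm - am) %% genome_length      # arc a -> b going right
  rev <- (am - bm) %% genome_length
  if (fwd <= rev) {
    sum(others & ((mid - am) %% genome_length) > 0 &
          ((mid - am) %% genome_length) < fwd)
  } else {
    sum(others & ((mid - bm) %% genome_length) > 0 &
          ((mid - bm) %% genome_length) < rev)
  }
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test. For small samples (n + m <= 10) the p-value is
#' exact, by enumerating all labelings of the combined sample (ties are
#' handled by the enumeration itself); otherwise the normal approximation
#' with tie and continuity correction is used. Identical samples give p = 1.
#'
#' @param x,y Numeric samples.
#' @return List with the rank-sum statistic `W` (sum of ranks of `x`) and
#'   the two-sided `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  if (n + m <= 10) {
    combs <- utils::combn(n + m, n)
    Ws <- colSums(matrix(r[combs], nrow = n))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
  } else {
    if (all(pooled == pooled[1])) return(list(W = W, p = 1))
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  list(W = W, p = min(p, 1))
}

#' Filter anti-CRISPR candidates
#'
#' Retains candidates flagged by both predictors and no longer than
#' `acr_maxlen` residues (longer calls are treated as likely false
#' positives).
#'
#' @param cands Data frame with `protein_id, length_aa, pred_a, pred_b`.
#' @param cfg [crass_thresholds()].
#' @return The retained subset (same columns).
#' @export
filter_acr <- function(cands, cfg = crass_thresholds()) {
  keep <- cands$pred_a & cands$pred_b & cands$length_aa <= cfg$acr_maxlen
  cands[keep & !is.na(keep), , drop = FALSE]
}

#' CAZyme prevalence by phage family
#'
#' Percentage of genomes in each family carrying at least one gene of each
#' CAZyme type. Types absent from a family report 0.
#'
#' @param annots Data frame with `genome_id, cazyme_type`.
#' @param families Data frame with `genome_id, family`.
#' @return Data frame `family x cazyme_type` with a `prevalence` percentage
#'   column (all combinations present).
#' @export
cazyme_cluster_prevalence <- function(annots, families) {
  fams <- sort(unique(families$family))
  types <- sort(unique(annots$cazyme_type))
  grid <- expand.grid(family = fams, cazyme_type = types,
                      stringsAsFactors = FALSE)
  grid$prevalence <- vapply(seq_len(nrow(grid)), function(i) {
    in_fam <- families$genome_id[families$family == grid$family[i]]
    carriers <- unique(annots$genome_id[annots$cazyme_type ==
                                          grid$cazyme_type[i]])
    if (!length(in_fam)) return(0)
    100 * sum(in_fam %in% carriers) / length(in_fam)
  }, 0)
  grid
}
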