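#' Map reads to representative genomes
#'
#' Gapless seed-and-extend mapping of reads against the vOTU representative
#' genomes (both orientations). Each read keeps its single best placement
#' (most matching bases; ties to the first representative in canonical
#' order), and placements failing the identity (`read_min_identity`) or
#' aligned-percent (`read_min_aligned`) gates are dropped.
#'
#' @param reads Data frame with `id`, `seq` (reads >= 31 bases).
#' @param reps Representative genome data frame (canonical order = row
#'   order).
#' @param cfg [crass_thresholds()].
#' @param k Seed k-mer length.
#' @param seed_step Spacing of seeds along the read.
#' @return Data frame `read_id, votu_rep_id, identity, aligned_percent,
#'   start, end, strand` (0-based half-open on the representative).
#' @export
map_reads <- function(reads, reps, cfg = crass_thresholds(), k = 21L,
                      seed_step = 12L) {
  stopifnot(all(nchar(reads$seq) >= 31))
  m <- cpp_map_reads(reps$seq, reads$seq, k, seed_step,
                     cfg$read_min_identity, cfg$read_min_aligned)
  data.frame(read_id = reads$id[m$read],
             votu_rep_id = reps$id[m$ref],
             identity = 100 * m$n_match / m$aln_len,
             aligned_percent = 100 * m$aln_len / nchar(reads$seq[m$read]),
             start = m$start, end = m$end,
             strand = ifelse(m$strand > 0, "+", "-"))
}

#' Read alignments from a PAF file
#'
#' Import route for externally produced alignments: converts PAF records to
#' the read-alignment table [map_reads()] produces (one best record per read
#' is assumed).
#'
#' @param path PAF file.
#' @return Read-alignment data frame.
#' @export
read_paf_alignments <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(read_id = character(), votu_rep_id = character(),
                      identity = numeric(), aligned_percent = numeric(),
                      start = integer(), end = integer(),
                      strand = character()))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(read_id = f[, 1], votu_rep_id = f[, 6],
             identity = 100 * as.numeric(f[, 10]) / as.numeric(f[, 11]),
             aligned_percent = 100 *
               (as.numeric(f[, 4]) - as.numeric(f[, 3])) / as.numeric(f[, 2]),
             start = as.integer(f[, 8]), end = as.integer(f[, 9]),
             strand = f[, 5])
}

#' Coverage-gated RPKM quantification
#'
#' RPKM(v, s) = reads mapped to v in s x 1e9 / (genome length x total reads
#' in s). The covered fraction of each representative is the percentage of
#' its positions under at least one read. Abundance is forced to zero where
#' the covered fraction is below `min_covered_fraction`, and a vOTU counts
#' as detected only where the covered fraction strictly exceeds it (so a
#' genome covered at exactly 75% keeps a zero abundance and is not
#' detected).
#'
#' @param alignments Named list (per sample) of read-alignment tables.
#' @param reps Representative genome data frame.
#' @param total_reads Named vector of total reads per sample (> 0).
#' @param cfg [crass_thresholds()].
#' @return List of vOTU x sample matrices: `rpkm`, `covered_fraction`
#'   (percent), `detected` (logical), plus `counts`.
#' @export
quantify <- function(alignments, reps, total_reads, cfg = crass_thresholds()) {
  samples <- names(alignments)
  stopifnot(!is.null(samples), all(total_reads[samples] > 0))
  nv <- nrow(reps)
  mk <- function(x) matrix(x, nv, length(samples),
                           dimnames = list(reps$id, samples))
  counts <- mk(0); covered <- mk(0)
  for (s in samples) {
    aln <- alignments[[s]]
    if (is.null(aln) || nrow(aln) == 0) next
    tb <- table(factor(aln$votu_rep_id, levels = reps$id))
    counts[, s] <- as.numeric(tb)
    for (v in unique(aln$votu_rep_id)) {
      a <- aln[aln$votu_rep_id == v, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(start = a$start + 1L,
                                             end = a$end))
      covered[v, s] <- 100 * sum(IRanges::width(ir)) /
        reps$length[match(v, reps$id)]
    }
  }
  rpkm <- counts * 1e9 / outer(reps$length, as.numeric(total_reads[samples]))
  rpkm[covered < cfg$min_covered_fraction] <- 0
  detected <- covered > cfg$min_covered_fraction
  list(rpkm = rpkm, covered_fraction = covered, detected = detected,
       counts = counts)
}

#' Prevalence and population-level detection
#'
#' Sample prevalence of each vOTU (percent of samples where it is
#' detected), detection per population (a vOTU is detected in a population
#' if it is detected in at least one of its samples), and per-sample
#' cluster presence (a family is present in a sample if any of its member
#' vOTUs is detected there).
#'
#' @param detected vOTU x sample logical matrix (from [quantify()]).
#' @param sample_population Named vector mapping every sample to a
#'   population.
#' @param votu_family Optional named vector mapping vOTUs to families.
#' @return List: `sample_prevalence` (percent per vOTU),
#'   `population_detected` (vOTU x population logical), and (when families
#'   are given) `cluster_presence` (family x sample logical).
#' @export
prevalence <- function(detected, sample_population, votu_family = NULL) {
  samples <- colnames(detected)
  stopifnot(all(samples %in% names(sample_population)))
  prev <- 100 * rowMeans(detected)
  pops <- unique(sample_population[samples])
  pop_det <- vapply(pops, function(p) {
    cols <- samples[sample_population[samples] == p]
    apply(detected[, cols, drop = FALSE], 1, any)
  }, logical(nrow(detected)))
  out <- list(sample_prevalence = prev, population_detected = pop_det)
  if (!is.null(votu_family)) {
    fams <- sort(unique(votu_family))
    cp <- t(vapply(fams, function(f) {
      vs <- intersect(names(votu_family)[votu_family == f],
                      rownames(detected))
      if (!length(vs)) return(stats::setNames(rep(FALSE, ncol(detected)),
                                              samples))
      apply(detected[vs, , drop = FALSE], 2, any)
    }, logical(ncol(detected))))
    out$cluster_presence <- cp
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (wraps [stats::p.adjust()]).
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`, same order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Two-group abundance association
#'
#' A compact MaAsLin-style association: per-sample total-sum scaling, then
#' `y = log2(x + pseudo)` with `pseudo` set to half the smallest nonzero
#' scaled abundance, a per-vOTU linear model `y ~ group`, BH adjustment
#' across tested vOTUs, and the signed significance score
#' `-log10(qval) * sign(coeff)`. vOTUs absent everywhere are excluded;
#' a vOTU with constant transformed abundance gets p = 1.
#'
#' @param rpkm vOTU x sample abundance matrix.
#' @param groups Named factor/character vector: sample -> group. The second
#'   level (default `"fat"` against `"lean"`) is the level whose positive
#'   coefficient means enrichment.
#' @param cfg [crass_thresholds()].
#' @param levels Group level order, reference first.
#' @return Data frame `votu_id, coeff, pval, qval, signed_score,
#'   significant`.
#' @export
associate_groups <- function(rpkm, groups, cfg = crass_thresholds(),
                             levels = c("lean", "fat")) {
  samples <- colnames(rpkm)
  stopifnot(all(samples %in% names(groups)))
  g <- factor(groups[samples], levels = levels)
  stopifnot(all(table(g) >= 3))
  tss <- sweep(rpkm, 2, pmax(colSums(rpkm), .Machine$double.eps), "/")
  keep <- rowSums(tss) > 0
  tss <- tss[keep, , drop = FALSE]
  if (!nrow(tss))
    return(data.frame(votu_id = character(), coeff = numeric(),
                      pval = numeric(), qval = numeric(),
                      signed_score = numeric(), significant = logical()))
  pseudo <- min(tss[tss > 0]) / 2
  y <- log2(tss + pseudo)
  res <- do.call(rbind, lapply(rownames(y), function(v) {
    yy <- y[v, ]
    if (stats::sd(yy) == 0)
      return(data.frame(votu_id = v, coeff = 0, pval = 1))
    fit <- summary(stats::lm(yy ~ g))$coefficients
    data.frame(votu_id = v, coeff = fit[2, 1], pval = fit[2, 4])
  }))
  res$qval <- bh_adjust(res$pval)
  res$signed_score <- -log10(pmax(res$qval, .Machine$double.xmin)) *
    sign(res$coeff)
  res$significant <- res$qval < cfg$assoc_q
  res
}
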