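GENUS_LINEAGES <- c(
  Prevotella = "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Prevotella",
  Parabacteroides = "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Tannerellaceae;g__Parabacteroides",
  UBA4372 = "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__UBA4372",
  Bacteroides = "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides",
  Phocaeicola = "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Phocaeicola",
  Prevotellamassilia = "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Prevotellamassilia",
  Eubacterium = "d__Bacteria;p__Firmicutes_A;c__Clostridia;o__Lachnospirales;f__Lachnospiraceae;g__Eubacterium")

GENUS_MIX <- c(Prevotella = 0.35, Parabacteroides = 0.15, UBA4372 = 0.10,
               Bacteroides = 0.10, Phocaeicola = 0.10,
               Prevotellamassilia = 0.05, Eubacterium = 0.15)

#' Simulate bacterial genomes with CRISPR arrays
#'
#' Each bacterium carries 1-2 CRISPR arrays (identical 28-32 bp repeats
#' alternating with 30-35 bp spacers). A planned subset of spacers are exact
#' or one-mismatch copies of phage subsequences (either strand) - the
#' planted host links - and a few are two-mismatch decoys that must not be
#' recovered as links. Spacer boundary bases are kept non-unanimous across
#' copies (using the unlinked random spacers only) so array boundaries are
#' locally unambiguous. Taxonomy spans Bacteroidota genera plus a
#' Firmicutes_A genus, per a fixed mix.
#'
#' @param spec A [community_spec()].
#' @param phages Phage genome data frame (`id, seq, length`).
#' @param exclude Optional data frame (`genome_id, start, end`) of phage
#'   regions spacers must not be drawn from. The community driver passes
#'   the marker gene spans here, keeping the bacteria marker-free so they
#'   act as clean detection decoys.
#' @return List: `genomes`, `taxonomy` (`genome_id, lineage`), `arrays`
#'   (truth array table), `links` (truth spacer links incl. decoys).
#' @export
simulate_bacteria <- function(spec, phages, exclude = NULL) {
  stopifnot(nrow(phages) >= 1)
  set.seed(derive_seed(spec$seed, 2000))
  nb <- spec$n_bacteria
  ids <- sprintf("MAG_%03d", seq_len(nb))
  genus <- sample(names(GENUS_MIX), nb, TRUE, prob = GENUS_MIX)
  taxonomy <- data.frame(
    genome_id = ids,
    lineage = paste0(GENUS_LINEAGES[genus], ";s__", genus, " sp",
                     seq_len(nb)))

  # link plan: host_fraction of the phages get 1-3 linking bacteria each
  n_tgt <- ceiling(spec$host_fraction * nrow(phages))
  targeted <- sample(phages$id, n_tgt)
  link_plan <- do.call(rbind, lapply(targeted, function(p) {
    data.frame(phage_id = p, genome_id = sample(ids, sample(1:3, 1)))
  }))

  draw_spacer <- function(phage_id, n_mm) {
    ps <- phages$seq[match(phage_id, phages$id)]
    excl <- if (is.null(exclude)) NULL
    else exclude[exclude$genome_id == phage_id, , drop = FALSE]
    len <- sample(30:35, 1)
    repeat {
      start <- sample(nchar(ps) - len + 1L, 1)   # 1-based
      if (is.null(excl) || !nrow(excl) ||
          !any((start - 1L) < excl$end &
                 (start - 1L + len) > excl$start)) break
    }
    sp <- substring(ps, start, start + len - 1L)
    if (sample(c(TRUE, FALSE), 1)) sp <- revcomp(sp)
    if (n_mm > 0) sp <- mutate_dna(sp, n_mm)
    sp
  }

  genomes <- list(); arrays <- list(); links <- list()
  per_bact <- split(link_plan$phage_id, link_plan$genome_id)
  for (b in seq_len(nb)) {
    id <- ids[b]
    planted <- list()
    for (p in per_bact[[id]]) {
      mm <- sample(0:1, 1)
      planted[[length(planted) + 1L]] <-
        list(seq = draw_spacer(p, mm), phage = p, mm = mm, decoy = FALSE)
    }
    if (stats::runif(1) < 0.3) {
      p <- sample(phages$id, 1)
      planted[[length(planted) + 1L]] <-
        list(seq = draw_spacer(p, 2), phage = p, mm = 2, decoy = TRUE)
    }
    n_arrays <- 1L + (stats::runif(1) < 0.3)
    slot_counts <- vapply(seq_len(n_arrays), function(i)
      sample(seq(spec$spacers_per_array[1], spec$spacers_per_array[2]), 1),
      0L)
    while (sum(slot_counts - 1L) < length(planted))   # >=1 random spacer each
      slot_counts[1] <- slot_counts[1] + 1L
    assign_arr <- rep(seq_len(n_arrays), slot_counts - 1L)[
      seq_along(planted)]
    seq_bact <- rand_dna(spec$bacteria_len)
    pos_next <- sample(500:1500, 1)
    for (ai in seq_len(n_arrays)) {
      rep_seq <- rand_dna(sample(28:32, 1))
      n_sp <- slot_counts[ai]
      mine <- planted[assign_arr == ai]
      spacers <- vapply(seq_len(n_sp), function(i) {
        if (i <= length(mine)) mine[[i]]$seq else rand_dna(sample(30:35, 1))
      }, "")
      free <- setdiff(seq_len(n_sp), seq_along(mine))
      # keep boundary bases non-unanimous using the free (random) spacers
      for (side in c("first", "last")) {
        bnd <- if (side == "first") substring(spacers, 1, 1)
        else substring(spacers, nchar(spacers), nchar(spacers))
        if (length(unique(bnd)) == 1L && length(free)) {
          i <- free[1]
          alt <- sample(setdiff(c("A", "C", "G", "T"), bnd[1]), 1)
          if (side == "first") substr(spacers[i], 1, 1) <- alt
          else substr(spacers[i], nchar(spacers[i]),
                      nchar(spacers[i])) <- alt
        }
      }
      arr_seq <- paste0(paste0(rep_seq, spacers, collapse = ""), rep_seq)
      if (pos_next + nchar(arr_seq) > nchar(seq_bact) - 500) break
      substr(seq_bact, pos_next, pos_next + nchar(arr_seq) - 1L) <- arr_seq
      rstarts <- pos_next - 1L +
        cumsum(c(0L, rep(nchar(rep_seq) + nchar(spacers))))[
          seq_len(n_sp + 1L)]
      arrays[[length(arrays) + 1L]] <-
        data.frame(genome_id = id, array = ai, repeat_seq = rep_seq,
                   n_repeats = n_sp + 1L, start = rstarts[1],
                   spacer_seqs = paste(spacers, collapse = ","))
      for (k in seq_along(mine))
        links[[length(links) + 1L]] <-
          data.frame(genome_id = id, phage_id = mine[[k]]$phage,
                     spacer_seq = spacers[k], mismatches = mine[[k]]$mm,
                     decoy = mine[[k]]$decoy)
      pos_next <- pos_next + nchar(arr_seq) + sample(800:2000, 1)
    }
    genomes[[b]] <- data.frame(id = id, seq = seq_bact)
  }
  list(genomes = genome_records(do.call(rbind, genomes)),
       taxonomy = taxonomy,
       arrays = do.call(rbind, arrays),
       links = if (length(links)) do.call(rbind, links)
       else data.frame(genome_id = character(), phage_id = character(),
                       spacer_seq = character(), mismatches = integer(),
                       decoy = logical()))
}

# Apply per-base substitution errors to a vector of reads.
apply_read_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  k <- stats::rbinom(length(reads), nchar(reads), rate)
  for (i in which(k > 0)) {
    pos <- sample(nchar(reads[i]), k[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  reads
}

#' Simulate multi-sample read sets with planted abundances
#'
#' Baseline relative abundances are log-normal; each sample adds log-normal
#' jitter, and the planted fat-vs-lean effects multiply the abundance of the
#' effect vOTUs by `2^log2fc` in fat samples. Reads are drawn uniformly
#' along each genome in proportion to relative abundance x genome length,
#' from either strand, with substitution errors.
#'
#' @param spec A [community_spec()].
#' @param phages Phage genome data frame.
#' @return List: `reads` (named list of per-sample read data frames),
#'   `abundance` (phage x sample true relative abundances), `effects`
#'   (phage_id, log2fc), `metadata` (sample, group, population).
#' @export
simulate_reads <- function(spec, phages) {
  set.seed(derive_seed(spec$seed, 3000))
  n <- nrow(phages)
  samples <- names(spec$group_design)
  base <- stats::rlnorm(n, 0, spec$abund_sdlog)
  k <- min(length(spec$effect_log2fc), n)
  # effects go to mid-ranked phages: well covered by reads, yet holding a
  # small share of total mass, so the planted fold-changes do not distort
  # the total-sum-scaled abundances of the unaffected community
  ranks <- pmin(floor(n / 2) + seq_len(k) - 1L, n)
  eff_idx <- order(-base)[unique(ranks)][seq_len(k)]
  eff_idx <- eff_idx[!is.na(eff_idx)]
  k <- length(eff_idx)
  effects <- data.frame(phage_id = phages$id[eff_idx],
                        log2fc = spec$effect_log2fc[seq_len(k)])
  abund <- matrix(0, n, length(samples),
                  dimnames = list(phages$id, samples))
  reads <- list()
  for (s in samples) {
    a <- base * stats::rlnorm(n, 0, spec$sample_noise_sdlog)
    if (spec$group_design[[s]] == "fat")
      a[eff_idx] <- a[eff_idx] * 2 ^ effects$log2fc
    rel <- a / sum(a)
    abund[, s] <- rel
    w <- rel * phages$length
    counts <- as.integer(stats::rmultinom(1, spec$reads_per_sample,
                                          w / sum(w)))
    rs <- character(0); src <- character(0)
    for (g in seq_len(n)) {
      if (counts[g] == 0) next
      L <- phages$length[g]
      starts <- sample(L - spec$read_len + 1L, counts[g], replace = TRUE)
      rr <- substring(phages$seq[g], starts, starts + spec$read_len - 1L)
      flip <- stats::runif(counts[g]) < 0.5
      rr[flip] <- vapply(rr[flip], revcomp, "", USE.NAMES = FALSE)
      rs <- c(rs, rr); src <- c(src, rep(phages$id[g], counts[g]))
    }
    ord <- sample(length(rs))
    rs <- apply_read_errors(rs[ord], spec$subst_error)
    reads[[s]] <- data.frame(id = sprintf("%s_r%06d", s, seq_along(rs)),
                             seq = rs, source = src[ord])
  }
  metadata <- data.frame(sample = samples,
                         group = unname(spec$group_design[samples]),
                         population = rep(c("farmA", "farmB"),
                                          length.out = length(samples)))
  list(reads = reads, abundance = abund, effects = effects,
       metadata = metadata)
}

#' Simulate labeled reference TerL proteins
#'
#' Reference ("human-like") TerL sequences for all six families, drawn
#' around the family consensi; these carry the taxonomy labels that the
#' MRCA rule propagates to the unlabeled community genomes.
#'
#' @param spec A [community_spec()].
#' @return Protein data frame with a `family` column.
#' @export
simulate_references <- function(spec) {
  set.seed(derive_seed(spec$seed, 4000))
  consensi <- marker_family_consensi()
  fams <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")
  do.call(rbind, lapply(fams, function(f) {
    cons <- consensi$seq[consensi$id == paste("TerL", f, sep = "|")]
    do.call(rbind, lapply(seq_len(spec$n_ref_per_family), function(i)
      data.frame(id = sprintf("human_%s_%02d", f, i),
                 seq = mutate_protein(cons, spec$intra_family_div),
                 family = f)))
  }))
}

# Predictor-style score table: phages get virus-like scores; a third of the
# bacteria slip through as VIBRANT-positives (the routes must reject them),
# the rest fail every retention criterion.
simulate_scores <- function(spec, phages, bacteria) {
  set.seed(derive_seed(spec$seed, 5000))
  np <- nrow(phages); nb <- nrow(bacteria)
  data.frame(
    contig_id = c(phages$id, bacteria$id),
    vs2_score = round(c(stats::runif(np, 0.91, 0.99),
                        stats::runif(nb, 0.05, 0.55)), 4),
    dvf_score = round(c(stats::runif(np, 0.5, 1),
                        stats::runif(nb, 0.1, 0.6)), 4),
    dvf_p = round(c(stats::runif(np, 0, 0.2),
                    stats::runif(nb, 0.2, 0.9)), 4),
    vibrant_positive = c(stats::runif(np) < 0.5,
                         seq_len(nb) %% 3 == 0))
}

# Plant CAZyme labels and anti-CRISPR predictor calls on filler genes.
# Family-preferential CAZyme types mirror the reported pattern (GH73 in
# beta/zeta only, GH108 in alpha/delta only).
simulate_annotations <- function(spec, phage_sims) {
  set.seed(derive_seed(spec$seed, 6000))
  type_prob <- list(
    GH73 = c(beta = 0.35, zeta = 0.35),
    GH108 = c(alpha = 0.35, delta = 0.35),
    GH24 = c(alpha = 0.15, beta = 0.15, delta = 0.15, zeta = 0.15),
    GH23 = c(alpha = 0.10, beta = 0.10, delta = 0.10, zeta = 0.10),
    GT2 = c(alpha = 0.12, beta = 0.12, delta = 0.12, zeta = 0.12))
  caz <- list(); acr <- list(); acr_truth <- character()
  for (ps in phage_sims) {
    gid <- ps$genome$id
    genes <- ps$genes
    genes$protein_id <- sprintf("%s_g%03d", gid, seq_len(nrow(genes)))
    fillers <- which(genes$label == "filler")
    for (ty in names(type_prob)) {
      p <- type_prob[[ty]]
      if (!ps$family %in% names(p)) next
      if (stats::runif(1) < p[[ps$family]] && length(fillers)) {
        sel <- sample(fillers, min(sample(1:2, 1), length(fillers)))
        caz[[length(caz) + 1L]] <-
          data.frame(genome_id = gid, protein_id = genes$protein_id[sel],
                     cazyme_type = ty)
      }
    }
    short <- fillers[genes$length_aa[fillers] <= 180]
    long <- fillers[genes$length_aa[fillers] > spec$acr_long_min %||% 200]
    true_acr <- if (length(short)) sample(short, min(3, length(short)))
    else integer(0)
    rest <- setdiff(fillers, true_acr)
    one_pred <- if (length(rest)) sample(rest, min(3, length(rest)))
    else integer(0)
    long_fp <- setdiff(long, true_acr)[seq_len(min(1, length(
      setdiff(long, true_acr))))]
    rows <- rbind(
      if (length(true_acr)) data.frame(idx = true_acr, pred_a = TRUE,
                                       pred_b = TRUE),
      if (length(one_pred)) data.frame(idx = one_pred,
                                       pred_a = seq_along(one_pred) %% 2 ==
                                         0, pred_b = seq_along(one_pred) %%
                                         2 == 1),
      if (length(long_fp)) data.frame(idx = long_fp, pred_a = TRUE,
                                      pred_b = TRUE))
    if (!is.null(rows) && nrow(rows)) {
      acr[[length(acr) + 1L]] <-
        data.frame(protein_id = genes$protein_id[rows$idx],
                   genome_id = gid,
                   length_aa = genes$length_aa[rows$idx],
                   pred_a = rows$pred_a, pred_b = rows$pred_b)
      acr_truth <- c(acr_truth, genes$protein_id[true_acr])
    }
  }
  list(cazymes = if (length(caz)) do.call(rbind, caz)
       else data.frame(genome_id = character(), protein_id = character(),
                       cazyme_type = character()),
       acr_predictions = if (length(acr)) do.call(rbind, acr)
       else data.frame(protein_id = character(), genome_id = character(),
                       length_aa = integer(), pred_a = logical(),
                       pred_b = logical()),
       acr_truth = acr_truth)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a complete synthetic community fixture
#'
#' Runs every simulator stage under the spec's single seed and writes the
#' fixture directory: `phages.fasta`, `bacteria.fasta`, `taxonomy.tsv`,
#' `reference_terl.faa` + `reference_taxonomy.tsv`, `scores.tsv`,
#' `acr_predictions.tsv`, `cazyme_hits.tsv`, `reads/<sample>.fasta`,
#' `metadata.tsv`, `spec.yaml` and the `truth_*.tsv` tables. Byte-identical
#' for a fixed spec.
#'
#' @param spec A [community_spec()].
#' @param outdir Fixture directory (created).
#' @return Invisibly, a list with all in-memory pieces (phage sims,
#'   bacteria, reads, truth tables).
#' @export
simulate_community <- function(spec, outdir) {
  dir.create(file.path(outdir, "reads"), recursive = TRUE,
             showWarnings = FALSE)
  phage_sims <- lapply(seq_len(spec$n_phages), function(i)
    simulate_phage(spec, i))
  phages <- do.call(rbind, lapply(phage_sims, `[[`, "genome"))
  # spacers are never drawn from marker genes or tRNA cassettes, so the
  # bacteria stay marker-free decoys for the detection routes
  marker_spans <- do.call(rbind, c(
    lapply(phage_sims, function(ps) {
      m <- ps$genes[ps$genes$label != "filler", c("genome_id", "start",
                                                  "end")]
      if (!is.null(ps$trna))
        m <- rbind(m, data.frame(genome_id = ps$trna$genome_id,
                                 start = ps$trna$position,
                                 end = ps$trna$position + 100L))
      m
    })))
  bact <- simulate_bacteria(spec, phages, exclude = marker_spans)
  rd <- simulate_reads(spec, phages)
  refs <- simulate_references(spec)
  scores <- simulate_scores(spec, phages, bact$genomes)
  ann <- simulate_annotations(spec, phage_sims)

  write_fasta(phages[, c("id", "seq")], file.path(outdir, "phages.fasta"))
  write_fasta(bact$genomes[, c("id", "seq")],
              file.path(outdir, "bacteria.fasta"))
  write_tsv(bact$taxonomy, file.path(outdir, "taxonomy.tsv"))
  write_fasta(refs[, c("id", "seq")],
              file.path(outdir, "reference_terl.faa"))
  write_tsv(refs[, c("id", "family")],
            file.path(outdir, "reference_taxonomy.tsv"))
  write_tsv(scores, file.path(outdir, "scores.tsv"))
  write_tsv(ann$acr_predictions, file.path(outdir, "acr_predictions.tsv"))
  write_tsv(ann$cazymes, file.path(outdir, "cazyme_hits.tsv"))
  write_tsv(rd$metadata, file.path(outdir, "metadata.tsv"))
  for (s in names(rd$reads))
    write_fasta(rd$reads[[s]][, c("id", "seq")],
                file.path(outdir, "reads", paste0(s, ".fasta")))

  truth_phages <- do.call(rbind, lapply(phage_sims, function(ps)
    data.frame(genome_id = ps$genome$id, family = ps$family,
               code = ps$code, length = ps$genome$length,
               has_suppressor = !is.null(ps$trna))))
  truth_genes <- do.call(rbind, lapply(phage_sims, `[[`, "genes"))
  truth_blocks <- do.call(rbind, lapply(phage_sims, function(ps)
    data.frame(genome_id = ps$genome$id, t(ps$blocks))))
  truth_trnas <- do.call(rbind, lapply(phage_sims, `[[`, "trna"))
  truth_abund <- data.frame(genome_id = rownames(rd$abundance),
                            rd$abundance, check.names = FALSE)
  write_tsv(truth_phages, file.path(outdir, "truth_phages.tsv"))
  write_tsv(truth_genes, file.path(outdir, "truth_genes.tsv"))
  write_tsv(truth_blocks, file.path(outdir, "truth_blocks.tsv"))
  if (!is.null(truth_trnas))
    write_tsv(truth_trnas, file.path(outdir, "truth_trnas.tsv"))
  write_tsv(bact$links, file.path(outdir, "truth_hosts.tsv"))
  write_tsv(bact$arrays, file.path(outdir, "truth_arrays.tsv"))
  write_tsv(truth_abund, file.path(outdir, "truth_abundance.tsv"))
  write_tsv(rd$effects, file.path(outdir, "truth_effects.tsv"))
  write_tsv(data.frame(protein_id = ann$acr_truth),
            file.path(outdir, "truth_acr.tsv"))
  spec_out <- unclass(spec)
  spec_out$group_design <- as.list(spec_out$group_design)
  yaml::write_yaml(spec_out, file.path(outdir, "spec.yaml"))
  invisible(list(spec = spec, phage_sims = phage_sims, phages = phages,
                 bacteria = bact, reads = rd, references = refs,
                 scores = scores, annotations = ann,
                 truth = list(phages = truth_phages, genes = truth_genes,
                              blocks = truth_blocks, trnas = truth_trnas,
                              hosts = bact$links, abundance = rd$abundance,
                              effects = rd$effects,
                              acr = ann$acr_truth)))
}
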