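#' Specification of a synthetic phage-host community
#'
#' Collects every knob of the synthetic-community generator. The defaults
#' define the package's standard study conditions: 20 crAss-like phage
#' genomes of 70-110 kb (zeta-family genomes drawn ~1.5x longer), family and
#' genetic-code mixes patterned on the composition reported for pig gut
#' crAss-like phages (alpha never uses an alternative code), 30 bacterial
#' genomes carrying CRISPR arrays with half the phages receiving planted
#' spacer links, and 16 read samples in an 8 fat / 8 lean design with three
#' planted abundance effects of |log2 fold-change| 2.
#'
#' @param n_phages Number of phage genomes.
#' @param genome_len_range Genome length range, bases.
#' @param family_mix Named proportions over `alpha,beta,delta,zeta` (sum 1).
#' @param code_mix Named proportions over genetic codes `11,4,15` (sum 1).
#' @param n_bacteria Number of bacterial genomes.
#' @param bacteria_len Bacterial genome length, bases.
#' @param spacers_per_array Range of spacers per CRISPR array.
#' @param host_fraction Fraction of phages receiving at least one planted
#'   spacer link.
#' @param n_samples,reads_per_sample,read_len Read-set design.
#' @param subst_error Per-base substitution error rate of simulated reads.
#' @param group_design Named vector sample -> `fat`/`lean`; default splits
#'   samples half and half.
#' @param effect_log2fc Planted fat-vs-lean log2 fold-changes, applied to the
#'   highest-abundance phages (so effects act on consistently detected
#'   vOTUs).
#' @param abund_sdlog,sample_noise_sdlog Log-normal spread of baseline
#'   relative abundances and of per-sample jitter.
#' @param intra_family_div Amino-acid substitution rate of marker draws
#'   around their family consensus.
#' @param recoded_fraction Fraction of genes in alternative-code genomes
#'   carrying recoded stop codons (1-4 per recoded gene).
#' @param filler_len_range Filler gene length range, residues.
#' @param intergenic_range Intergenic spacer length range, bases.
#' @param n_ref_per_family Reference TerL sequences emitted per family
#'   (all six families, including gamma and epsilon which have no pig-like
#'   members).
#' @param seed Global integer seed; fixes every generated artifact.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_phages = 20,
                           genome_len_range = c(70000, 110000),
                           family_mix = c(alpha = 0.26, beta = 0.44,
                                          delta = 0.21, zeta = 0.09),
                           code_mix = c("11" = 0.70, "15" = 0.25,
                                        "4" = 0.05),
                           n_bacteria = 30,
                           bacteria_len = 30000,
                           spacers_per_array = c(3, 6),
                           host_fraction = 0.5,
                           n_samples = 16,
                           reads_per_sample = 50000,
                           read_len = 150,
                           subst_error = 0.005,
                           group_design = NULL,
                           effect_log2fc = c(2, 2, -2),
                           abund_sdlog = 0.75,
                           sample_noise_sdlog = 0.25,
                           intra_family_div = 0.05,
                           recoded_fraction = 0.2,
                           filler_len_range = c(100, 600),
                           intergenic_range = c(40, 120),
                           n_ref_per_family = 3,
                           seed = 42) {
  stopifnot(abs(sum(family_mix) - 1) < 1e-6, abs(sum(code_mix) - 1) < 1e-6,
            genome_len_range[1] >= 70000)
  if (is.null(group_design)) {
    group_design <- stats::setNames(
      rep(c("fat", "lean"), each = ceiling(n_samples / 2))[
        seq_len(n_samples)],
      sprintf("s%02d", seq_len(n_samples)))
  }
  structure(mget(names(formals(community_spec))), class = "community_spec")
}

# Largest-remainder integer allocation of n items to named proportions.
allocate_counts <- function(n, mix) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base), seq_along(raw))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

# Deterministic family and genetic-code assignment for each phage index.
# Alpha-family phages always use the standard code; alternative-code mass is
# reassigned to the remaining families.
phage_plan <- function(spec) {
  fams <- rep(names(spec$family_mix), allocate_counts(spec$n_phages,
                                                      spec$family_mix))
  codes <- rep(names(spec$code_mix), allocate_counts(spec$n_phages,
                                                     spec$code_mix))
  # alternative codes go to non-alpha genomes, spread evenly across them
  plan <- data.frame(index = seq_len(spec$n_phages), family = fams,
                     code = 11L)
  alt <- as.integer(codes[codes != "11"])
  non_alpha <- which(fams != "alpha")
  if (length(alt) && length(non_alpha)) {
    alt <- alt[seq_len(min(length(alt), length(non_alpha)))]
    slots <- non_alpha[unique(round(seq(1, length(non_alpha),
                                        length.out = length(alt))))]
    plan$code[slots] <- alt[seq_along(slots)]
  }
  plan$id <- sprintf("pig_phage_%03d", plan$index)
  plan
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Intergenic spacer with stop guards at both ends: the terminal TAA is in
# frame with the following gene and the leading TTA reads as TAA on the
# minus strand of the preceding gene, so called ORF coordinates equal the
# planted ones exactly.
intergenic_dna <- function(n) {
  n <- max(n, 8L)
  paste0("TTA", rand_dna(n - 6L), "TAA")
}

mutate_dna <- function(seq, n_subst) {
  ch <- str_chars(seq)
  idx <- sample(length(ch), n_subst)
  ch[idx] <- vapply(ch[idx], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  paste(ch, collapse = "")
}

mutate_protein <- function(seq, rate) {
  bg <- aa_background()
  ch <- str_chars(seq)
  idx <- which(stats::runif(length(ch)) < rate)
  for (i in idx) {
    alt <- setdiff(names(bg), ch[i])
    ch[i] <- sample(alt, 1, prob = bg[alt])
  }
  paste(ch, collapse = "")
}

random_protein <- function(len) {
  bg <- aa_background()
  paste(sample(names(bg), len, TRUE, prob = bg), collapse = "")
}

# Codon sets of the standard code, used for reverse translation. Synonymous
# codons are weighted toward TA/TG dinucleotides, which seeds stop codons in
# the shifted reading frames - as in AT-rich phage genomes - so spurious
# stop-free runs in alternative frames stay short and the called gene tiling
# is unambiguous.
codon_sets <- function() {
  tab <- Biostrings::GENETIC_CODE
  sets <- split(names(tab), tab)
  lapply(sets, function(s) {
    w <- 1 + 3 * vapply(s, function(cd) lengths(regmatches(
      cd, gregexpr("TA", cd))), 0L) +
      vapply(s, function(cd) lengths(regmatches(
        cd, gregexpr("TG", cd))), 0L)
    list(codons = s, w = unname(w))
  })
}

# Reverse-translate a protein under a genome's genetic code. In a recoded
# gene the reassigned stop codon is the dominant codon for its amino acid
# (as in genomes that have captured a stop codon): each glutamine (code 15,
# TAG) or tryptophan (code 4, TGA) site uses the stop codon with probability
# recode_site_prob. recode_n instead plants an exact number of recoded
# sites. Returns the coding sequence including a terminal stop codon valid
# under all candidate codes.
reverse_translate <- function(aa, code = 11, recode_n = 0,
                              recode_site_prob = NULL) {
  sets <- codon_sets()
  ch <- str_chars(aa)
  codons <- vapply(ch, function(a) {
    s <- sets[[a]]
    if (length(s$codons) == 1) s$codons
    else sample(s$codons, 1, prob = s$w)
  }, "", USE.NAMES = FALSE)
  if (recode_n > 0 || !is.null(recode_site_prob)) {
    target_aa <- if (code == 15) "Q" else if (code == 4) "W" else NA
    if (!is.na(target_aa)) {
      pos <- which(ch == target_aa)
      if (length(pos)) {
        pos <- if (!is.null(recode_site_prob))
          pos[stats::runif(length(pos)) < recode_site_prob]
        else sample(pos, min(recode_n, length(pos)))
        codons[pos] <- if (code == 15) "TAG" else "TGA"
      }
    }
  }
  # terminal stop is always TAA, the stop codon shared by all three codes:
  # code inference then rests on the recoded internal stops, not on
  # terminal read-through differences
  paste0(paste(codons, collapse = ""), "TAA")
}

# Genes start with methionine (an ATG start codon); the first residue is
# forced to M, preserving length.
force_met_start <- function(aa) {
  if (substr(aa, 1, 1) != "M") substr(aa, 1, 1) <- "M"
  aa
}

# Per-family gene-block size ranges (genes between marker pairs), patterned
# on the reported contrast: alpha/delta carry more genes between IHF_54 and
# MCP and fewer between MCP and portal than beta/zeta; zeta has the largest
# replication block between TerL and primase.
block_ranges <- function(family) {
  switch(family,
         alpha = ,
         delta = list(ihf54_mcp = c(18, 26), mcp_portal = c(2, 4),
                      terl_primase = c(9, 14)),
         beta = ,
         zeta = list(ihf54_mcp = c(7, 12),
                     mcp_portal = c(8, 12),
                     terl_primase = if (family == "zeta") c(26, 34)
                     else c(9, 14)))
}

#' Simulate one crAss-like phage genome
#'
#' Builds a genome with the five marker genes in canonical order
#' (IHF_54 ... MCP ... portal ... TerL ... primase), family-specific numbers
#' of filler genes between them, intergenic spacers, and - for genomes
#' assigned an alternative genetic code - recoded stop codons in a fraction
#' of genes plus a suppressor-tRNA cassette (anticodon CTA for code 15, TCA
#' for code 4). All truth is returned alongside the sequence.
#'
#' @param spec A [community_spec()].
#' @param index Phage index in `1..n_phages`.
#' @return List: `genome` (one-row genome data frame), `family`, `code`,
#'   `genes` (truth annotations with `label`, `recoded`), `blocks` (planted
#'   between-marker gene counts), `trna` (cassette truth or NULL).
#' @export
simulate_phage <- function(spec, index) {
  plan <- phage_plan(spec)[index, ]
  set.seed(derive_seed(spec$seed, 1000 + index))
  family <- plan$family; code <- plan$code
  len_range <- spec$genome_len_range
  if (family == "zeta") len_range <- round(len_range * 1.5)
  target_len <- sample(seq(len_range[1], len_range[2]), 1)

  consensi <- marker_family_consensi()
  marker_names <- c("IHF_54", "MCP", "portal", "TerL", "primase")
  markers <- lapply(marker_names, function(m) {
    cons <- consensi$seq[consensi$id == paste(m, family, sep = "|")]
    mutate_protein(cons, spec$intra_family_div)
  })
  names(markers) <- marker_names
  # TerL descends from one of the labeled reference lineages of its family
  # (as pig vOTUs relate to known human references), which guarantees the
  # genome nests inside the family's reference MRCA on the TerL tree
  refs <- local({
    saved <- .Random.seed_save()
    on.exit(.Random.seed_restore(saved))
    simulate_references(spec)
  })
  fam_refs <- refs[refs$family == family, , drop = FALSE]
  markers$TerL <- mutate_protein(fam_refs$seq[sample(nrow(fam_refs), 1)],
                                 spec$intra_family_div * 0.6)

  br <- block_ranges(family)
  blocks <- c(ihf54_mcp = sample(seq(br$ihf54_mcp[1], br$ihf54_mcp[2]), 1),
              mcp_portal = sample(seq(br$mcp_portal[1], br$mcp_portal[2]), 1),
              terl_primase = sample(seq(br$terl_primase[1],
                                        br$terl_primase[2]), 1))
  n_portal_terl <- sample(3:6, 1)

  new_filler <- function() random_protein(sample(
    seq(spec$filler_len_range[1], spec$filler_len_range[2]), 1))

  # gene plan: label + protein, markers interleaved with filler blocks
  labels <- c(rep("filler", 0), "IHF_54", rep("filler", blocks["ihf54_mcp"]),
              "MCP", rep("filler", blocks["mcp_portal"]), "portal",
              rep("filler", n_portal_terl), "TerL",
              rep("filler", blocks["terl_primase"]), "primase")
  prots <- lapply(labels, function(l)
    if (l == "filler") new_filler() else markers[[l]])

  gene_nt <- function(aa) {
    aa <- force_met_start(aa)
    # tryptophan is ~3x rarer than glutamine, so the code-4 per-gene
    # fraction is scaled up to plant a comparable recoded-codon density
    frac <- min(1, spec$recoded_fraction * (if (code == 4) 3 else 1))
    recoded <- code != 11 && stats::runif(1) < frac
    nt <- reverse_translate(aa, code,
                            recode_site_prob = if (recoded) 0.8)
    list(nt = nt, recoded = recoded)
  }
  genes <- lapply(prots, gene_nt)

  gap_len <- function() sample(seq(spec$intergenic_range[1],
                                   spec$intergenic_range[2]), 1)
  core_len <- sum(vapply(genes, function(g) nchar(g$nt), 0)) +
    (length(genes) + 1) * mean(spec$intergenic_range)
  if (core_len > target_len)
    stop("markers and planted gene blocks do not fit in requested length",
         call. = FALSE)

  # extra filler genes in the terminal segments keep block counts intact
  extra <- list()
  budget <- target_len - core_len - 2000
  while (budget > 3 * spec$filler_len_range[2]) {
    aa <- new_filler()
    g <- gene_nt(aa)
    extra[[length(extra) + 1L]] <- list(aa = aa, g = g)
    budget <- budget - nchar(g$nt) - mean(spec$intergenic_range)
  }
  n_pre <- length(extra) %/% 2
  pre <- extra[seq_len(n_pre)]
  post <- extra[setdiff(seq_along(extra), seq_len(n_pre))]

  all_labels <- c(rep("filler", length(pre)), labels,
                  rep("filler", length(post)))
  all_prots <- c(lapply(pre, `[[`, "aa"), prots, lapply(post, `[[`, "aa"))
  all_genes <- c(lapply(pre, `[[`, "g"), genes, lapply(post, `[[`, "g"))

  # suppressor cassette for alternative-code genomes
  trna <- NULL
  cassette <- NULL
  if (code != 11) {
    tmpl <- trna_templates()[1, ]
    anticodon <- if (code == 15) "CTA" else "TCA"
    cas <- tmpl$seq
    substr(cas, tmpl$anticodon_offset + 1L, tmpl$anticodon_offset + 3L) <-
      anticodon
    cassette <- list(seq = cas, slot = min(3L, length(all_genes)),
                     anticodon = anticodon)
  }

  pieces <- character(); ann <- list(); pos <- 0L
  add_piece <- function(s) { pieces[[length(pieces) + 1L]] <<- s
    pos <<- pos + nchar(s) }
  add_piece(intergenic_dna(gap_len()))
  for (i in seq_along(all_genes)) {
    g <- all_genes[[i]]
    strand <- if (all_labels[i] == "filler") sample(c("+", "-"), 1) else "+"
    nt <- if (strand == "+") g$nt else revcomp(g$nt)
    start <- pos
    add_piece(nt)
    ann[[i]] <- data.frame(genome_id = plan$id, start = start, end = pos,
                           strand = strand, label = all_labels[i],
                           length_aa = (nchar(g$nt) %/% 3L) - 1L,
                           recoded = g$recoded)
    add_piece(intergenic_dna(gap_len()))
    if (!is.null(cassette) && i == cassette$slot) {
      trna <- data.frame(genome_id = plan$id, position = pos,
                         anticodon = cassette$anticodon,
                         suppresses = revcomp(cassette$anticodon))
      add_piece(cassette$seq)
      add_piece(intergenic_dna(gap_len()))
    }
  }
  if (pos < target_len) add_piece(rand_dna(target_len - pos))
  seq <- paste(pieces, collapse = "")
  genome <- genome_records(data.frame(id = plan$id, seq = seq),
                           source_sample = "synthetic")
  list(genome = genome, family = family, code = code,
       genes = do.call(rbind, ann), blocks = blocks, trna = trna)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a gene-dense genome with a planted genetic code
#'
#' A reduced genome (no markers) for genetic-code recovery experiments:
#' back-to-back random genes with short intergenic spacers, a fraction of
#' them carrying recoded stops when an alternative code is planted. The
#' decisive signal - the coding-density differential between candidate
#' codes - is the same as in full-size genomes.
#'
#' @param code Planted genetic code (11, 4 or 15).
#' @param n_genes Number of genes.
#' @param gene_len_range Gene length range, residues.
#' @param recoded_fraction Fraction of genes with recoded stops under an
#'   alternative code.
#' @param intergenic_range Intergenic spacer range, bases.
#' @param seed RNG seed.
#' @param id Genome id.
#' @return One-row genome data frame.
#' @export
simulate_code_genome <- function(code, n_genes = 30,
                                 gene_len_range = c(150, 500),
                                 recoded_fraction = 0.2,
                                 intergenic_range = c(40, 120), seed = 1,
                                 id = sprintf("code%s_genome", code)) {
  set.seed(seed)
  pieces <- character()
  add <- function(s) pieces[[length(pieces) + 1L]] <<- s
  add(intergenic_dna(sample(seq(intergenic_range[1],
                                intergenic_range[2]), 1)))
  for (i in seq_len(n_genes)) {
    aa <- force_met_start(random_protein(
      sample(seq(gene_len_range[1], gene_len_range[2]), 1)))
    frac <- min(1, recoded_fraction * (if (code == 4) 3 else 1))
    recoded <- code != 11 && stats::runif(1) < frac
    nt <- reverse_translate(aa, code,
                            recode_site_prob = if (recoded) 0.8)
    if (stats::runif(1) < 0.3) nt <- revcomp(nt)
    add(nt)
    add(intergenic_dna(sample(seq(intergenic_range[1],
                                  intergenic_range[2]), 1)))
  }
  genome_records(data.frame(id = id, seq = paste(pieces, collapse = "")))
}
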