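# Shared fixtures and independent brute-force oracles. Oracles are written
# plainly (no shared code with the implementation paths they check).

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

rnd_prot <- function(n) paste(sample(strsplit(
  "ARNDCQEGHILKMFPSTWYV", "")[[1]], n, TRUE), collapse = "")

substitute_dna <- function(seq, n_subst) {
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), n_subst)
  ch[idx] <- vapply(ch[idx], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  paste(ch, collapse = "")
}

one_genome <- function(id, seq) crasskit::genome_records(
  data.frame(id = id, seq = seq))

# --- affine-gap local alignment score, straightforward three-matrix DP ----
oracle_sw_score <- function(q, t, gap_open = 11, gap_ext = 1) {
  B <- crasskit:::blosum62()
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + B[qc[i - 1], tc[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# --- brute-force best gapless profile window ------------------------------
oracle_pssm_score <- function(prot, pssm) {
  pc <- strsplit(prot, "")[[1]]
  n <- length(pc); m <- nrow(pssm)
  best <- 0
  for (i in seq_len(n)) {        # window start in protein
    for (j in seq_len(m)) {      # window start in profile
      s <- 0
      for (k in 0:(min(n - i, m - j))) {
        s <- s + pssm[j + k, pc[i + k]]
        best <- max(best, s)
      }
    }
  }
  best
}

# --- brute-force Hamming scan over every offset ---------------------------
oracle_hamming_hits <- function(spacer, genome, max_mm) {
  hits <- NULL
  for (pat in c(spacer, crasskit::revcomp(spacer))) {
    pc <- strsplit(pat, "")[[1]]
    gc <- strsplit(genome, "")[[1]]
    strand <- if (pat == spacer) "+" else "-"
    if (length(gc) < length(pc)) next
    for (s in seq_len(length(gc) - length(pc) + 1L)) {
      mm <- sum(gc[s:(s + length(pc) - 1L)] != pc)
      if (mm <= max_mm)
        hits <- rbind(hits, data.frame(position = s - 1L, strand = strand,
                                       mismatches = mm))
    }
    if (pat == crasskit::revcomp(spacer) && spacer ==
        crasskit::revcomp(spacer)) break   # palindrome: avoid double count
  }
  hits
}

# --- exact two-sided rank-sum p by full enumeration -----------------------
oracle_wilcoxon_p <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_len(n)])
  mu <- n * (length(x) + length(y) + 1) / 2
  combs <- utils::combn(length(r), n)
  Ws <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# --- simple codon-table translation oracle --------------------------------
oracle_translate <- function(seq, code = 11) {
  tab <- Biostrings::GENETIC_CODE
  if (code == 4) tab[["TGA"]] <- "W"
  if (code == 15) tab[["TAG"]] <- "Q"
  out <- character()
  for (p in seq(1, nchar(seq) - 2, by = 3)) {
    cod <- substr(seq, p, p + 2)
    out <- c(out, if (grepl("N", cod)) "X" else tab[[cod]])
  }
  paste(out, collapse = "")
}

# Random additive tree and its exact leaf distance matrix (for NJ checks).
random_additive_tree <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Tiny calibrated profile for PSSM tests.
toy_profile <- function(ncol = 30, n_seqs = 6, div = 0.1, seed = 99) {
  withr::with_seed(seed, {
    base <- rnd_prot(ncol)
    seqs <- vapply(seq_len(n_seqs), function(i) {
      ch <- strsplit(base, "")[[1]]
      idx <- which(stats::runif(ncol) < div)
      ch[idx] <- vapply(idx, function(k) sample(strsplit(
        "ARNDCQEGHILKMFPSTWYV", "")[[1]], 1), "")
      paste(ch, collapse = "")
    }, "")
    pr <- crasskit::build_profile("toy", seqs)
    crasskit::calibrate_profile(pr, n_shuffles = 300, seed = seed)
  })
}
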