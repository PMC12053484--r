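# Robinson & Robinson background amino-acid frequencies, the standard
# composition used for log-odds profile columns.
aa_background <- function() {
  c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
    Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
    L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
    S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
}

#' Build a position-specific score matrix from a seed alignment
#'
#' Columns with more than 50% gaps are dropped; remaining columns get
#' log2-odds scores against the Robinson-Robinson background with a
#' single-count pseudocount. X (and any non-standard letter) scores 0
#' everywhere.
#'
#' @param name Marker name.
#' @param seqs Character vector of aligned sequences (equal length, `-` for
#'   gaps).
#' @param threshold Calibrated hit threshold (bits); see
#'   [calibrate_profile()]. `NA` builds an uncalibrated profile.
#' @return An object of class `crass_profile`.
#' @export
build_profile <- function(name, seqs, threshold = NA_real_) {
  stopifnot(length(seqs) >= 1, length(unique(nchar(seqs))) == 1)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  keep <- colMeans(mat == "-") <= 0.5
  mat <- mat[, keep, drop = FALSE]
  bg <- aa_background()
  alphabet <- aa_alphabet()
  pssm <- matrix(0, nrow = ncol(mat), ncol = length(alphabet),
                 dimnames = list(NULL, alphabet))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% names(bg)]
    n <- length(col)
    cnt <- table(factor(col, levels = names(bg)))
    p <- (as.numeric(cnt) + bg) / (n + 1)
    pssm[j, names(bg)] <- log2(p / bg)
  }
  consensus <- apply(mat, 2, function(col) {
    col <- col[col %in% names(bg)]
    if (!length(col)) "X" else names(which.max(table(col)))
  })
  structure(list(name = name, pssm = pssm, n_col = ncol(mat),
                 consensus = paste(consensus, collapse = ""),
                 threshold = threshold),
            class = "crass_profile")
}

#' Calibrate a profile hit threshold by composition shuffling
#'
#' Best gapless match scores are collected on seeded random proteins drawn
#' from the profile's own residue composition; the hit threshold is the
#' 99.9th percentile of the null best-score distribution, extrapolated by a
#' Gumbel tail fit from the calibration protein length to the residue search
#' space of a whole-genome six-frame scan (`search_space`), so that a
#' marker-free genome clears the threshold nowhere. Computed once per
#' profile and stored with it.
#'
#' @param profile A `crass_profile`.
#' @param n_shuffles Number of random proteins.
#' @param len Length of each random protein (default twice the profile width).
#' @param seed RNG seed.
#' @param quantile_p Percentile defining the threshold.
#' @param search_space Residue search space the threshold is scaled to
#'   (`NULL` for the raw percentile at calibration length).
#' @return The profile with its `threshold` set.
#' @export
calibrate_profile <- function(profile, n_shuffles = 10000,
                              len = 2L * profile$n_col, seed = 20241,
                              quantile_p = 0.999, search_space = 2e5) {
  bg <- aa_background()
  comp <- colMeans(2 ^ profile$pssm[, names(bg), drop = FALSE] *
                     rep(bg, each = profile$n_col))
  comp <- comp / sum(comp)
  alphabet <- aa_alphabet()
  idx <- match(names(bg), alphabet) - 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  prots <- replicate(n_shuffles,
                     sample(idx, len, replace = TRUE, prob = comp),
                     simplify = FALSE)
  scores <- cpp_pssm_scores(prots, profile$pssm)
  if (is.null(search_space)) {
    profile$threshold <- unname(stats::quantile(scores, quantile_p))
  } else {
    # Gumbel moment fit of the best-score null; shifting the location by
    # log(search_space / len) gives the null for the larger search space.
    beta <- stats::sd(scores) * sqrt(6) / pi
    mu <- mean(scores) - 0.57721566 * beta
    profile$threshold <- mu + beta * (log(search_space / len) -
                                        log(-log(quantile_p)))
  }
  profile
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Search a protein with a profile
#'
#' Best gapless local match of the profile's log-odds matrix in the protein
#' (local in both the protein and the profile). A hit is reported only when
#' the score reaches the profile's calibrated threshold.
#'
#' @param protein Protein record (one-row data frame) or string.
#' @param profile A calibrated `crass_profile`.
#' @param use_threshold Report `NULL` below threshold (default); `FALSE`
#'   always returns the best match.
#' @return One-row alignment data frame, or `NULL` when there is no hit.
#' @export
pssm_search <- function(protein, profile, use_threshold = TRUE) {
  pid <- if (is.character(protein)) "protein" else protein$id
  ps <- if (is.character(protein)) protein else protein$seq
  pi <- aa_to_int(ps)
  r <- cpp_pssm_best(pi, profile$pssm)
  if (use_threshold) {
    if (is.na(profile$threshold))
      stop("profile ", profile$name, " is not calibrated", call. = FALSE)
    if (r$score < profile$threshold) return(NULL)
  }
  data.frame(query_id = pid, target_id = profile$name, score = r$score,
             evalue = NA_real_, identity = NA_real_,
             aln_len = r$prot_end - r$prot_start,
             q_start = r$prot_start, q_end = r$prot_end,
             t_start = r$prof_start, t_end = r$prof_end, strand = "+")
}

extdata_path <- function(...) {
  p <- system.file("extdata", ..., package = "crasskit")
  if (!nzchar(p)) stop("missing package data: ", file.path(...), call. = FALSE)
  p
}

profile_cache <- new.env(parent = emptyenv())

#' Load the packaged marker profiles
#'
#' Seed alignments and stored calibration thresholds for the five
#' crAss-like marker proteins (IHF_54, MCP, portal, TerL, primase). The seed
#' sequences are synthetic package data generated alongside the community
#' simulator, not copies of any database profile.
#'
#' @param markers Which markers to load.
#' @return Named list of calibrated `crass_profile` objects.
#' @export
crass_profiles <- function(markers = c("IHF_54", "MCP", "portal", "TerL",
                                       "primase")) {
  key <- paste(markers, collapse = ",")
  if (!is.null(profile_cache[[key]])) return(profile_cache[[key]])
  thr <- utils::read.delim(extdata_path("profiles", "thresholds.tsv"))
  out <- lapply(markers, function(m) {
    fa <- read_fasta(extdata_path("profiles", paste0(m, ".faa")), "protein")
    stopifnot(nchar(fa$seq[1]) >= 50)
    build_profile(m, fa$seq, threshold = thr$threshold[match(m, thr$marker)])
  })
  names(out) <- markers
  profile_cache[[key]] <- out
  out
}

#' Load the packaged crAss signature proteins
#'
#' The two discovery signatures: a terminase (UGP_092-like) and a polymerase
#' (UGP_018-like). Synthetic package data.
#'
#' @return Protein data frame with ids `UGP_018` and `UGP_092`.
#' @export
crass_signatures <- function() {
  read_fasta(extdata_path("signatures", "signatures.faa"), "protein")
}

#' Load the packaged suppressor-tRNA templates
#'
#' Synthetic tRNA cassette backbones with the anticodon position recorded in
#' the FASTA header (`anticodon_offset=<0-based>`).
#'
#' @return Data frame with `id, seq, anticodon_offset`.
#' @export
trna_templates <- function() {
  path <- extdata_path("trna", "trna_templates.fasta")
  fa <- read_fasta(path, "dna")
  hdr <- grep("^>", readLines(path), value = TRUE)
  off <- as.integer(sub(".*anticodon_offset=([0-9]+).*", "\\1", hdr))
  fa$anticodon_offset <- off
  fa
}

# Family-level marker consensus coding sequences used by the community
# simulator (synthetic package data; ids are "<marker>|<family>").
marker_family_consensi <- function() {
  read_fasta(extdata_path("markers", "marker_families.faa"), "protein")
}
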