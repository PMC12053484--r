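#' Viral-contig retention rule
#'
#' A contig is retained when it meets any one of four criteria on the
#' virus-predictor score table: (1) VirSorter2-style score >= 0.9;
#' (2) DeepVirFinder-style score >= 0.9 and p < 0.01; (3) VirSorter2 score
#' > 0.7, DeepVirFinder score > 0.7 and p < 0.05; (4) a positive VIBRANT-style
#' prediction. Missing values fail every criterion that needs them.
#'
#' @param rec Data frame with columns `vs2_score`, `dvf_score`, `dvf_p`,
#'   `vibrant_positive` (NA allowed).
#' @param cfg [crass_thresholds()].
#' @return Logical vector, one value per row.
#' @export
retain_viral_contig <- function(rec, cfg = crass_thresholds()) {
  vs2 <- rec$vs2_score; dvf <- rec$dvf_score; p <- rec$dvf_p
  vib <- rec$vibrant_positive
  c1 <- !is.na(vs2) & vs2 >= cfg$vs2_hi
  c2 <- !is.na(dvf) & !is.na(p) & dvf >= cfg$dvf_hi & p < cfg$dvf_p_hi
  c3 <- !is.na(vs2) & !is.na(dvf) & !is.na(p) &
    vs2 > cfg$vs2_lo & dvf > cfg$dvf_lo & p < cfg$dvf_p_lo
  c4 <- !is.na(vib) & vib
  c1 | c2 | c3 | c4
}

#' Signature-protein route of crAss-like identification
#'
#' Calls genes under the standard code, aligns the two discovery signature
#' proteins (polymerase UGP_018-like, terminase UGP_092-like) to every
#' predicted protein, and keeps hits with E-value below `sig_evalue` and
#' alignment length of at least `sig_minlen` residues. The route passes when
#' there is at least one hit and the genome is longer than
#' `crass_min_genome`.
#'
#' @param genome One genome row.
#' @param signatures Protein data frame (default the packaged signatures).
#' @param cfg [crass_thresholds()].
#' @param min_len_aa Minimum called-gene length.
#' @return List with `pass`, `hit` (`"polymerase"`, `"terminase"` or
#'   `"none"`), and the hit table.
#' @export
signature_route <- function(genome, signatures = crass_signatures(),
                            cfg = crass_thresholds(), min_len_aa = 60) {
  if (nrow(signatures) == 0) stop("empty signature set", call. = FALSE)
  orfs <- find_orfs(genome, code = 11, min_len_aa = min_len_aa)
  hits <- list()
  for (i in seq_len(nrow(orfs))) {
    prot <- orf_protein(genome, orfs[i, ], code = 11)
    if (!nzchar(prot)) next
    for (j in seq_len(nrow(signatures))) {
      a <- align_protein_local(signatures[j, ], data.frame(
        id = sprintf("%s_orf%d", genome$id, i), seq = prot))
      if (a$evalue < cfg$sig_evalue && a$aln_len >= cfg$sig_minlen)
        hits[[length(hits) + 1L]] <- a
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else NULL
  pass <- !is.null(hits) && genome$length > cfg$crass_min_genome
  hit <- "none"
  if (!is.null(hits)) {
    best <- hits[order(hits$evalue), ][1, ]
    hit <- if (best$query_id == "UGP_018") "polymerase" else "terminase"
  }
  list(pass = pass, hit = hit, hits = hits)
}

#' Structural-profile route of crAss-like identification
#'
#' Six-frame translates the genome (stops rewritten to X, so genomes using
#' alternative genetic codes still yield long fragments), splits each frame
#' on X runs into peptides of at least `min_peptide` residues, and searches
#' every peptide against the three conserved structural-protein profiles
#' (TerL, portal, MCP). The route passes when any profile is hit in any
#' frame.
#'
#' @param genome One genome row.
#' @param profiles Named list of calibrated profiles (default the packaged
#'   TerL/portal/MCP set).
#' @param cfg [crass_thresholds()].
#' @param min_peptide Minimum peptide length searched.
#' @return List with `pass` and a hit table (`profile`, `frame`, `score`).
#' @export
structural_route <- function(genome,
                             profiles = crass_profiles(c("TerL", "portal",
                                                         "MCP")),
                             cfg = crass_thresholds(), min_peptide = 50) {
  stopifnot(length(profiles) >= 1)
  frames <- six_frame_translate(genome, clean = TRUE)
  hits <- list()
  for (f in seq_len(nrow(frames))) {
    peps <- strsplit(frames$seq[f], "X+")[[1]]
    peps <- peps[nchar(peps) >= min_peptide]
    for (pep in peps) {
      for (pr in profiles) {
        h <- pssm_search(pep, pr)
        if (!is.null(h))
          hits[[length(hits) + 1L]] <-
            data.frame(profile = pr$name, frame = frames$frame[f],
                       score = h$score)
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits)
  else data.frame(profile = character(), frame = integer(),
                  score = numeric())
  list(pass = nrow(hits) > 0, hits = hits)
}

#' Combine the two identification routes
#'
#' The final crAss-like call combines the signature route and the structural
#' route; by default the union (either route suffices), with an intersection
#' mode available for sensitivity analysis.
#'
#' @param contig_id Contig/genome id.
#' @param route1,route2 Results of [signature_route()] / [structural_route()].
#' @param mode `"union"` or `"intersection"`.
#' @return One-row data frame: `contig_id, route1_hit, route2_hits,
#'   is_crass`.
#' @export
call_crass <- function(contig_id, route1, route2, mode = c("union",
                                                           "intersection")) {
  mode <- match.arg(mode)
  is_crass <- if (mode == "union") route1$pass || route2$pass
  else route1$pass && route2$pass
  data.frame(contig_id = contig_id, route1_hit = route1$hit,
             route2_hits = paste(unique(route2$hits$profile), collapse = ","),
             is_crass = is_crass)
}

#' Run crAss-like detection on a genome collection
#'
#' Applies the retention rule (when a score table is supplied) and both
#' identification routes to each genome.
#'
#' @param genomes Genome data frame.
#' @param scores Optional predictor score table with a `contig_id` column.
#' @param signatures,profiles,cfg,mode Passed through to the route functions.
#' @return Data frame with one row per genome: retention flag, route
#'   evidence and the final call. Genomes failing retention are not routed.
#' @export
detect_crass <- function(genomes, scores = NULL,
                         signatures = crass_signatures(),
                         profiles = crass_profiles(c("TerL", "portal", "MCP")),
                         cfg = crass_thresholds(), mode = "union") {
  retained <- rep(TRUE, nrow(genomes))
  if (!is.null(scores)) {
    m <- scores[match(genomes$id, scores$contig_id), , drop = FALSE]
    retained <- retain_viral_contig(m, cfg)
    retained[is.na(retained)] <- FALSE
  }
  out <- lapply(seq_len(nrow(genomes)), function(i) {
    if (!retained[i])
      return(data.frame(contig_id = genomes$id[i], retained = FALSE,
                        route1_hit = "none", route2_hits = "",
                        is_crass = FALSE))
    r1 <- signature_route(genomes[i, ], signatures, cfg)
    r2 <- structural_route(genomes[i, ], profiles, cfg)
    cbind(data.frame(contig_id = genomes$id[i], retained = TRUE)[, ],
          call_crass(genomes$id[i], r1, r2, mode)[, -1, drop = FALSE])
  })
  do.call(rbind, out)
}
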