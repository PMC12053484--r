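#' Analysis thresholds
#'
#' Single source of truth for every numeric gate the pipeline applies:
#' viral-contig retention scores, crAss-like signature-hit gates, vOTU
#' clustering cutoffs, anti-CRISPR length filter, spacer mismatch cap,
#' read-mapping and coverage gates, and the association q-value threshold.
#'
#' @param vs2_hi,vs2_lo VirSorter2-style score cutoffs (criterion 1 uses
#'   `>= vs2_hi`; criterion 3 uses `> vs2_lo`).
#' @param dvf_hi,dvf_lo DeepVirFinder-style score cutoffs.
#' @param dvf_p_hi,dvf_p_lo DeepVirFinder p-value cutoffs (strict `<`).
#' @param sig_evalue E-value gate for signature-protein hits.
#' @param sig_minlen Minimum alignment length (residues) for signature hits.
#' @param crass_min_genome Minimum genome length (bases) for a crAss-like call.
#' @param ani_thresh,af_thresh vOTU clustering: percent average nucleotide
#'   identity and percent aligned fraction of the shorter genome.
#' @param acr_maxlen Maximum anti-CRISPR candidate length, residues.
#' @param spacer_max_mismatch Maximum mismatches for a spacer-to-genome hit.
#' @param read_min_identity,read_min_aligned Percent identity and percent of
#'   the read aligned required to keep a read mapping.
#' @param min_covered_fraction Percent of a representative genome that must be
#'   covered before its abundance counts (below it RPKM is zeroed; detection
#'   requires strictly more than it).
#' @param assoc_q q-value threshold for calling a group association.
#' @return A named list of class `crass_thresholds`.
#' @export
crass_thresholds <- function(vs2_hi = 0.9, vs2_lo = 0.7,
                             dvf_hi = 0.9, dvf_lo = 0.7,
                             dvf_p_hi = 0.01, dvf_p_lo = 0.05,
                             sig_evalue = 1e-5, sig_minlen = 350,
                             crass_min_genome = 70000,
                             ani_thresh = 95.0, af_thresh = 85.0,
                             acr_maxlen = 200,
                             spacer_max_mismatch = 1,
                             read_min_identity = 90.0,
                             read_min_aligned = 95.0,
                             min_covered_fraction = 75.0,
                             assoc_q = 0.05) {
  cfg <- list(vs2_hi = vs2_hi, vs2_lo = vs2_lo, dvf_hi = dvf_hi,
              dvf_lo = dvf_lo, dvf_p_hi = dvf_p_hi, dvf_p_lo = dvf_p_lo,
              sig_evalue = sig_evalue, sig_minlen = sig_minlen,
              crass_min_genome = crass_min_genome,
              ani_thresh = ani_thresh, af_thresh = af_thresh,
              acr_maxlen = acr_maxlen,
              spacer_max_mismatch = spacer_max_mismatch,
              read_min_identity = read_min_identity,
              read_min_aligned = read_min_aligned,
              min_covered_fraction = min_covered_fraction,
              assoc_q = assoc_q)
  pct <- c("ani_thresh", "af_thresh", "read_min_identity",
           "read_min_aligned", "min_covered_fraction")
  stopifnot(all(unlist(cfg[pct]) >= 0), all(unlist(cfg[pct]) <= 100),
            all(unlist(cfg[c("vs2_hi", "vs2_lo", "dvf_hi", "dvf_lo",
                             "dvf_p_hi", "dvf_p_lo", "assoc_q")]) >= 0),
            all(unlist(cfg[c("vs2_hi", "vs2_lo", "dvf_hi", "dvf_lo",
                             "dvf_p_hi", "dvf_p_lo", "assoc_q")]) <= 1))
  structure(cfg, class = "crass_thresholds")
}
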