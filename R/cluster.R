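# ANI and aligned fraction from a set of alignment blocks between two
# genomes. Overlapping blocks are merged per genome before span computation;
# identity is averaged weighted by aligned columns.
ani_from_blocks <- function(blocks, len_q, len_t, af_mode = c("shorter",
                                                              "query")) {
  af_mode <- match.arg(af_mode)
  if (is.null(blocks) || nrow(blocks) == 0) return(c(ani = 0, af = 0))
  ani <- sum(blocks$identity * blocks$aln_len) / sum(blocks$aln_len)
  use_query <- af_mode == "query" || (af_mode == "shorter" && len_q <= len_t)
  if (use_query) {
    ir <- IRanges::IRanges(start = blocks$q_start + 1L, end = blocks$q_end)
    span <- sum(IRanges::width(IRanges::reduce(ir)))
    af <- 100 * span / len_q
  } else {
    ir <- IRanges::IRanges(start = blocks$t_start + 1L, end = blocks$t_end)
    span <- sum(IRanges::width(IRanges::reduce(ir)))
    af <- 100 * span / len_t
  }
  c(ani = ani, af = af)
}

#' Average nucleotide identity between two genomes
#'
#' ANI is the column-weighted mean identity over merged alignment blocks; the
#' aligned fraction (AF) is the merged aligned span as a percentage of the
#' shorter genome (MIUViG-style dereplication intent; `af_mode = "query"`
#' computes it over the first genome instead). `(0, 0)` when nothing aligns.
#'
#' @param a,b Genome rows.
#' @param af_mode `"shorter"` (default) or `"query"`.
#' @return Named numeric vector `c(ani, af)`, both percentages.
#' @export
pairwise_ani <- function(a, b, af_mode = "shorter") {
  blocks <- align_nt_banded(a, b)
  ani_from_blocks(blocks, a$length, b$length, af_mode)
}

# All-vs-all (ani, af) table for a genome set from a single minimap2 run.
# One row per unordered pair with any alignment; for pairs aligned in both
# directions the direction with more aligned columns wins (ties:
# lexicographic by query id).
ani_table <- function(genomes, af_mode = "shorter") {
  blocks <- allvall_blocks(genomes)
  empty <- data.frame(id1 = character(), id2 = character(),
                      ani = numeric(), af = numeric())
  if (nrow(blocks) == 0) return(empty)
  lens <- stats::setNames(genomes$length, genomes$id)
  key <- paste(blocks$query_id, blocks$target_id, sep = "\r")
  per_dir <- lapply(split(blocks, key), function(b) {
    qid <- b$query_id[1]; tid <- b$target_id[1]
    st <- ani_from_blocks(b, lens[[qid]], lens[[tid]], af_mode)
    data.frame(id1 = qid, id2 = tid, ani = st[["ani"]], af = st[["af"]],
               cols = sum(b$aln_len))
  })
  tab <- do.call(rbind, per_dir)
  ukey <- ifelse(tab$id1 < tab$id2, paste(tab$id1, tab$id2, sep = "\r"),
                 paste(tab$id2, tab$id1, sep = "\r"))
  picked <- lapply(split(tab, ukey), function(t) {
    t <- t[order(-t$cols, t$id1), , drop = FALSE]
    t[1, c("id1", "id2", "ani", "af")]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Greedy vOTU clustering
#'
#' Dereplicates genomes into vOTUs at 95% ANI over 85% aligned fraction.
#' Genomes are scanned longest-first (ties by id); each genome joins the
#' first existing centroid it matches at `ani >= ani_thresh` and
#' `af >= af_thresh`, else founds a new vOTU. The centroid (the longest
#' member) is the representative.
#'
#' @param genomes Genome data frame with unique ids.
#' @param cfg [crass_thresholds()].
#' @param af_mode Aligned-fraction convention, see [pairwise_ani()].
#' @return Data frame with one row per vOTU: `rep_id`, comma-joined
#'   `member_ids`, `n_members`.
#' @export
greedy_cluster <- function(genomes, cfg = crass_thresholds(),
                           af_mode = "shorter") {
  stopifnot(!anyDuplicated(genomes$id))
  ord <- order(-genomes$length, genomes$id)
  genomes <- genomes[ord, , drop = FALSE]
  tab <- ani_table(genomes, af_mode)
  pkey <- paste(tab$id1, tab$id2, sep = "\r")
  lookup <- function(x, y) {
    i <- match(paste(x, y, sep = "\r"), pkey)
    if (is.na(i)) i <- match(paste(y, x, sep = "\r"), pkey)
    if (is.na(i)) c(ani = 0, af = 0) else c(ani = tab$ani[i], af = tab$af[i])
  }
  centroids <- character()
  members <- list()
  for (i in seq_len(nrow(genomes))) {
    id <- genomes$id[i]
    placed <- FALSE
    for (c_id in centroids) {
      st <- lookup(id, c_id)
      if (st[["ani"]] >= cfg$ani_thresh && st[["af"]] >= cfg$af_thresh) {
        members[[c_id]] <- c(members[[c_id]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, id)
      members[[id]] <- id
    }
  }
  data.frame(rep_id = centroids,
             member_ids = vapply(members[centroids], paste, "",
                                 collapse = ","),
             n_members = vapply(members[centroids], length, 0L))
}

# Expand a cluster table into a long genome -> vOTU membership table.
cluster_membership <- function(clusters) {
  do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
    data.frame(genome_id = strsplit(clusters$member_ids[i], ",")[[1]],
               rep_id = clusters$rep_id[i])
  }))
}
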