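#' Find CRISPR arrays in a bacterial genome
#'
#' CRT/MinCED-style detection: exact k-mer seeds recurring at least
#' `min_repeats` times with consecutive spacings compatible with the repeat
#' and spacer length bounds propose candidate arrays; repeat boundaries are
#' extended around the seed while all copies stay within one interior
#' mismatch of the first copy, then trimmed back so terminal repeat columns
#' are unanimous. Overlapping candidates resolve to the higher repeat count.
#'
#' @param genome One genome row, >= 200 bases.
#' @param repeat_len Allowed repeat length range (bases).
#' @param spacer_len Allowed spacer length range (bases).
#' @param min_repeats Minimum number of repeat copies.
#' @param seed_k Seed k-mer size.
#' @return List of arrays; each is a list with `genome_id`, `repeat_seq`,
#'   `repeat_positions` (0-based starts) and a `spacers` data frame
#'   (`seq, start, end`, 0-based half-open).
#' @export
find_crispr_arrays <- function(genome, repeat_len = c(23L, 47L),
                               spacer_len = c(17L, 50L), min_repeats = 3L,
                               seed_k = 16L) {
  s <- check_dna(genome$seq)
  L <- nchar(s)
  stopifnot(L >= 200)
  min_period <- repeat_len[1] + spacer_len[1]
  max_period <- repeat_len[2] + spacer_len[2]
  starts <- seq_len(L - seed_k + 1L)
  kmers <- substring(s, starts, starts + seed_k - 1L)
  occ <- split(starts, kmers)
  occ <- occ[lengths(occ) >= min_repeats]
  if (!length(occ)) return(list())
  # candidate seeds in genome order
  occ <- occ[order(vapply(occ, `[[`, 0L, 1L))]
  covered <- integer(0)
  arrays <- list()
  for (pos_all in occ) {
    if (pos_all[1] %in% covered) next
    runs <- split(pos_all, cumsum(c(TRUE, diff(pos_all) < min_period |
                                      diff(pos_all) > max_period)))
    for (pos in runs) {
      if (length(pos) < min_repeats || pos[1] %in% covered) next
      ext <- extend_repeat(s, pos, seed_k, repeat_len, spacer_len)
      if (is.null(ext)) next
      rstart <- pos - ext$left
      rlen <- seed_k + ext$left + ext$right
      if (rlen < repeat_len[1] || rlen > repeat_len[2]) next
      gaps <- diff(rstart) - rlen
      if (any(gaps < spacer_len[1] | gaps > spacer_len[2])) next
      sp_start <- rstart[-length(rstart)] + rlen
      sp_end <- rstart[-1]
      arrays[[length(arrays) + 1L]] <- list(
        genome_id = genome$id,
        repeat_seq = substring(s, rstart[1], rstart[1] + rlen - 1L),
        repeat_positions = rstart - 1L,
        spacers = data.frame(seq = substring(s, sp_start, sp_end - 1L),
                             start = sp_start - 1L, end = sp_end - 1L))
      covered <- c(covered, seq(rstart[1], rstart[length(rstart)] + rlen))
    }
  }
  if (!length(arrays)) return(list())
  # overlap resolution: more repeats win, then leftmost
  span <- t(vapply(arrays, function(a)
    c(min(a$repeat_positions), max(a$repeat_positions) +
        nchar(a$repeat_seq)), numeric(2)))
  nrep <- vapply(arrays, function(a) length(a$repeat_positions), 0L)
  ord <- order(-nrep, span[, 1])
  keep <- logical(length(arrays))
  taken <- NULL
  for (i in ord) {
    iv <- span[i, ]
    if (is.null(taken) || all(iv[1] >= taken[, 2] | iv[2] <= taken[, 1])) {
      keep[i] <- TRUE
      taken <- rbind(taken, iv)
    }
  }
  arrays <- arrays[keep]
  arrays[order(vapply(arrays, function(a) a$repeat_positions[1], 0L))]
}

# Extend repeat copies left/right around seed occurrences, with a one-
# mismatch-per-copy interior tolerance and unanimity-trimmed boundaries.
extend_repeat <- function(s, pos, k, repeat_len, spacer_len) {
  n <- length(pos)
  min_gap_budget <- min(diff(pos)) - spacer_len[1]  # max repeat length here
  max_rlen <- min(repeat_len[2], min_gap_budget)
  if (max_rlen < repeat_len[1]) return(NULL)
  col_at <- function(offsets) substring(s, offsets, offsets)
  grow <- function(side) {
    mm <- integer(n)
    ext <- 0L
    ok_cols <- logical(0)   # unanimity per extension column
    repeat {
      if (k + ext + 1L > max_rlen) break
      off <- if (side == "left") pos - ext - 1L else pos + k + ext
      if (any(off < 1L) || any(off > nchar(s))) break
      ch <- col_at(off)
      newmm <- mm + (ch != ch[1])
      if (any(newmm > 1L)) break
      mm <- newmm
      ext <- ext + 1L
      ok_cols <- c(ok_cols, all(ch == ch[1]))
    }
    # trim back to the last unanimous boundary column
    while (ext > 0L && !ok_cols[ext]) ext <- ext - 1L
    ext
  }
  left <- grow("left")
  # recompute budget including left growth
  saved_k <- k + left
  mm_used <- {
    offm <- outer(pos - left, 0:(saved_k - 1L), `+`)
    ref <- substring(s, offm[1, ], offm[1, ] + 0L)
    counts <- integer(n)
    for (i in seq_len(n)) {
      ch <- substring(s, offm[i, ], offm[i, ])
      counts[i] <- sum(ch != ref)
    }
    counts
  }
  grow_right <- function() {
    mm <- mm_used
    ext <- 0L
    ok_cols <- logical(0)
    repeat {
      if (saved_k + ext + 1L > max_rlen) break
      off <- pos + k + ext
      if (any(off > nchar(s))) break
      ch <- substring(s, off, off)
      newmm <- mm + (ch != ch[1])
      if (any(newmm > 1L)) break
      mm <- newmm
      ext <- ext + 1L
      ok_cols <- c(ok_cols, all(ch == ch[1]))
    }
    while (ext > 0L && !ok_cols[ext]) ext <- ext - 1L
    ext
  }
  list(left = left, right = grow_right())
}

#' Match a CRISPR spacer against a phage genome
#'
#' Reports every position on either strand where the spacer matches the
#' genome over its whole length with at most `spacer_max_mismatch`
#' substitutions (no indels; the one-mismatch criterion is a Hamming
#' condition).
#'
#' @param spacer Spacer sequence (17-50 bases, no N).
#' @param phage One genome row.
#' @param cfg [crass_thresholds()].
#' @return Data frame `position` (0-based, on the forward genome), `strand`,
#'   `mismatches`.
#' @export
match_spacer <- function(spacer, phage, cfg = crass_thresholds()) {
  spacer <- toupper(spacer)
  if (grepl("N", spacer, fixed = TRUE))
    stop("spacer contains N", call. = FALSE)
  stopifnot(nchar(spacer) >= 17, nchar(spacer) <= 50)
  genome_int <- dna_to_int(phage$seq)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else revcomp(spacer)
    m <- cpp_hamming_scan(genome_int, dna_to_int(pat),
                          cfg$spacer_max_mismatch)
    if (nrow(m))
      out[[strand]] <- data.frame(position = m[, 1], strand = strand,
                                  mismatches = m[, 2])
  }
  if (!length(out))
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Parse "d__...;p__...;...;s__..." lineage strings into a 7-column rank
# data frame; rank prefixes are stripped.
parse_lineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  ranks <- c("domain", "phylum", "class", "order", "family", "genus",
             "species")
  do.call(rbind, lapply(parts, function(p) {
    p <- sub("^[a-z]__", "", trimws(p))
    p <- c(p, rep("unknown", 7))[1:7]
    p[!nzchar(p)] <- "unknown"
    as.data.frame(as.list(stats::setNames(p, ranks)))
  }))
}

#' Assign bacterial hosts to vOTUs via CRISPR spacers
#'
#' Aggregates spacer-to-phage hits to the (vOTU x bacterial genome) level,
#' joins bacterial taxonomy, and summarizes host-genus breadth per vOTU
#' (single-genus vs multi-genus).
#'
#' @param arrays List of CRISPR arrays (from [find_crispr_arrays()], run on
#'   each bacterium) or a data frame with `genome_id, seq` spacer rows.
#' @param phages Phage genome data frame.
#' @param membership Data frame `genome_id, rep_id` mapping phage genomes to
#'   vOTUs (e.g. [cluster_membership()]).
#' @param taxonomy Data frame `genome_id, lineage` for the bacteria
#'   (semicolon-separated 7 ranks). Bacteria without taxonomy keep their
#'   assignments with an `"unknown"` lineage, with a warning.
#' @param cfg [crass_thresholds()].
#' @return List: `assignments` (one row per vOTU x bacterium),
#'   `genus_summary` (vOTU counts per genus), `votu_breadth` (per-vOTU
#'   number of host genera and a `multi_genus` flag).
#' @export
assign_hosts <- function(arrays, phages, membership, taxonomy,
                         cfg = crass_thresholds()) {
  spacers <- if (is.data.frame(arrays)) arrays
  else do.call(rbind, lapply(arrays, function(a)
    data.frame(genome_id = a$genome_id, seq = a$spacers$seq)))
  if (is.null(spacers) || nrow(spacers) == 0)
    spacers <- data.frame(genome_id = character(), seq = character())
  hits <- list()
  for (i in seq_len(nrow(spacers))) {
    for (j in seq_len(nrow(phages))) {
      h <- match_spacer(spacers$seq[i], phages[j, ], cfg)
      if (nrow(h))
        hits[[length(hits) + 1L]] <-
          data.frame(bacterial_genome_id = spacers$genome_id[i],
                     phage_id = phages$id[j],
                     mismatches = min(h$mismatches))
    }
  }
  empty_asg <- data.frame(votu_id = character(),
                          bacterial_genome_id = character(),
                          n_matching_spacers = integer(),
                          mismatches_per_hit = character(),
                          genus = character(), lineage = character())
  if (!length(hits))
    return(list(assignments = empty_asg,
                genus_summary = data.frame(genus = character(),
                                           n_votus = integer()),
                votu_breadth = data.frame(votu_id = character(),
                                          n_genera = integer(),
                                          multi_genus = logical())))
  hits <- do.call(rbind, hits)
  hits$votu_id <- membership$rep_id[match(hits$phage_id,
                                          membership$genome_id)]
  hits <- hits[!is.na(hits$votu_id), , drop = FALSE]
  key <- paste(hits$votu_id, hits$bacterial_genome_id, sep = "\r")
  asg <- do.call(rbind, lapply(split(hits, key), function(h) {
    data.frame(votu_id = h$votu_id[1],
               bacterial_genome_id = h$bacterial_genome_id[1],
               n_matching_spacers = nrow(h),
               mismatches_per_hit = paste(sort(h$mismatches),
                                          collapse = ","))
  }))
  lin <- taxonomy$lineage[match(asg$bacterial_genome_id,
                                taxonomy$genome_id)]
  if (anyNA(lin)) {
    warning("bacterial genome(s) missing taxonomy; using 'unknown' lineage")
    lin[is.na(lin)] <- paste(rep("unknown", 7), collapse = ";")
  }
  ranks <- parse_lineage(lin)
  asg$genus <- ranks$genus
  asg$lineage <- lin
  rownames(asg) <- NULL
  breadth <- do.call(rbind, lapply(split(asg, asg$votu_id), function(a)
    data.frame(votu_id = a$votu_id[1],
               n_genera = length(unique(a$genus)),
               multi_genus = length(unique(a$genus)) >= 2)))
  gs <- do.call(rbind, lapply(split(asg, asg$genus), function(a)
    data.frame(genus = a$genus[1],
               n_votus = length(unique(a$votu_id)))))
  rownames(breadth) <- rownames(gs) <- NULL
  list(assignments = asg, genus_summary = gs[order(-gs$n_votus, gs$genus), ],
       votu_breadth = breadth)
}
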