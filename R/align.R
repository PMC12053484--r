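KA_LAMBDA <- 0.267
KA_K <- 0.041

# Karlin-Altschul E-value for a local protein alignment score, with
# search space |query| x |target|. The decision gate (1e-5) dominates in
# practice; the constants are the standard BLOSUM62 ones.
protein_evalue <- function(score, qlen, tlen) {
  KA_K * as.numeric(qlen) * as.numeric(tlen) * exp(-KA_LAMBDA * score)
}

#' Local protein alignment (Smith-Waterman)
#'
#' Affine-gap Smith-Waterman under BLOSUM62 (gap open 11, extension 1; a gap
#' of length L costs `11 + L`). Deterministic: the first maximal cell in scan
#' order wins and traceback prefers diagonal moves. Sequences may contain the
#' 20 amino acids plus X.
#'
#' @param query,target Protein records (one-row data frames with `id`, `seq`)
#'   or plain strings.
#' @param gap_open,gap_ext Gap penalties.
#' @return One-row alignment data frame: `query_id, target_id, score, evalue,
#'   identity, aln_len, q_start, q_end, t_start, t_end, strand` with 0-based
#'   half-open coordinates.
#' @export
align_protein_local <- function(query, target, gap_open = 11, gap_ext = 1) {
  qid <- if (is.character(query)) "query" else query$id
  tid <- if (is.character(target)) "target" else target$id
  qs <- if (is.character(query)) query else query$seq
  ts <- if (is.character(target)) target else target$seq
  stopifnot(nzchar(qs), nzchar(ts))
  qi <- aa_to_int(qs); ti <- aa_to_int(ts)
  r <- cpp_sw_align(qi, ti, blosum62(), gap_open, gap_ext)
  data.frame(query_id = qid, target_id = tid, score = r$score,
             evalue = protein_evalue(r$score, nchar(qs), nchar(ts)),
             identity = if (r$n_cols > 0) 100 * r$n_match / r$n_cols else 0,
             aln_len = r$n_cols,
             q_start = r$q_start, q_end = r$q_end,
             t_start = r$t_start, t_end = r$t_end, strand = "+")
}

minimap2_path <- function() {
  p <- Sys.which("minimap2")
  if (!nzchar(p)) stop("minimap2 not found on PATH", call. = FALSE)
  p
}

# Run minimap2 (-c --eqx) and return the raw PAF lines.
run_minimap2 <- function(target_fa, query_fa, preset = "asm20") {
  out <- tempfile(fileext = ".paf")
  on.exit(unlink(out))
  status <- system2(minimap2_path(),
                    c("-c", "--eqx", "-x", preset, "-t", "1",
                      shQuote(target_fa), shQuote(query_fa)),
                    stdout = out, stderr = FALSE)
  if (status != 0) stop("minimap2 failed (status ", status, ")", call. = FALSE)
  readLines(out)
}

# Parse PAF lines (requiring the cg:Z: tag) and split each alignment at
# indels >= split_indel bases, yielding per-block match counts and spans on
# both sequences. Small indels stay inside a block and count as aligned
# (non-identical) columns.
paf_to_blocks <- function(lines, split_indel = 50L) {
  empty <- data.frame(query_id = character(), target_id = character(),
                      score = numeric(), evalue = numeric(),
                      identity = numeric(), aln_len = integer(),
                      q_start = integer(), q_end = integer(),
                      t_start = integer(), t_end = integer(),
                      strand = character())
  if (!length(lines)) return(empty)
  rows <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", f, value = TRUE)[1])
    if (is.na(cg)) next
    qid <- f[1]; tid <- f[6]; strand <- f[5]
    qs <- as.integer(f[3]); qe <- as.integer(f[4])
    ts <- as.integer(f[8])
    m <- regmatches(cg, gregexpr("[0-9]+[=XID]", cg))[[1]]
    lens <- as.integer(sub("[=XID]$", "", m))
    ops <- sub("^[0-9]+", "", m)
    tpos <- ts
    qpos <- if (strand == "+") qs else qe   # '-' walks the query backwards
    step <- if (strand == "+") 1L else -1L
    blk_q0 <- qpos; blk_t0 <- tpos; nmatch <- 0L; ncols <- 0L
    flush <- function() {
      if (ncols > 0L) {
        q0 <- min(blk_q0, qpos); q1 <- max(blk_q0, qpos)
        rows[[length(rows) + 1L]] <<-
          data.frame(query_id = qid, target_id = tid, score = nmatch,
                     evalue = NA_real_, identity = 100 * nmatch / ncols,
                     aln_len = ncols, q_start = q0, q_end = q1,
                     t_start = blk_t0, t_end = tpos, strand = strand)
      }
    }
    for (k in seq_along(ops)) {
      op <- ops[k]; len <- lens[k]
      if (op %in% c("=", "X")) {
        if (op == "=") nmatch <- nmatch + len
        ncols <- ncols + len
        qpos <- qpos + step * len; tpos <- tpos + len
      } else if (len >= split_indel) {
        flush()
        if (op == "I") qpos <- qpos + step * len else tpos <- tpos + len
        blk_q0 <- qpos; blk_t0 <- tpos; nmatch <- 0L; ncols <- 0L
      } else {
        ncols <- ncols + len
        if (op == "I") qpos <- qpos + step * len else tpos <- tpos + len
      }
    }
    flush()
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Banded nucleotide alignment between two genomes
#'
#' K-mer anchored, chained local alignment (minimap2, `-c --eqx`), with each
#' chain split at indels of `split_indel` bases or more so that blocks report
#' contiguous aligned spans and per-block identity on both sequences. This is
#' the substrate for ANI/aligned-fraction computation.
#'
#' @param a,b Genome rows; `a` is the query.
#' @param preset minimap2 preset.
#' @param split_indel Indel size at which a chain is split into blocks.
#' @return Alignment-block data frame (possibly empty), same columns as
#'   [align_protein_local()].
#' @export
align_nt_banded <- function(a, b, preset = "asm20", split_indel = 50L) {
  qfa <- tempfile(fileext = ".fa"); tfa <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qfa, tfa)))
  write_fasta(a[, c("id", "seq")], qfa)
  write_fasta(b[, c("id", "seq")], tfa)
  paf_to_blocks(run_minimap2(tfa, qfa, preset), split_indel)
}

# All-vs-all alignment blocks for a genome set (one minimap2 run of the set
# against itself; self-hits removed).
allvall_blocks <- function(genomes, preset = "asm20", split_indel = 50L) {
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  write_fasta(genomes[, c("id", "seq")], fa)
  b <- paf_to_blocks(run_minimap2(fa, fa, preset), split_indel)
  b[b$query_id != b$target_id, , drop = FALSE]
}

#' Write alignment blocks as PAF
#'
#' Minimal PAF writer (12 mandatory columns) for alignment-block tables.
#'
#' @param blocks Alignment-block data frame.
#' @param lengths Named vector of sequence lengths.
#' @param path Output file.
#' @export
write_paf <- function(blocks, lengths, path) {
  lines <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    paste(b$query_id, lengths[[b$query_id]], b$q_start, b$q_end, b$strand,
          b$target_id, lengths[[b$target_id]], b$t_start, b$t_end,
          round(b$identity * b$aln_len / 100), b$aln_len, 255, sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
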