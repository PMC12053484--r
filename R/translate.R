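#' Genetic code table
#'
#' Codon-to-amino-acid maps for the three translation tables the analysis
#' considers: 11 (standard bacterial/phage), 4 (TGA read as tryptophan) and
#' 15 (TAG read as glutamine). Stops translate to `*`.
#'
#' @param code One of 11, 4, 15.
#' @return Named character vector over the 64 codons.
#' @export
genetic_code_table <- function(code = 11) {
  code <- as.integer(code)
  tab <- Biostrings::GENETIC_CODE
  if (code == 4L) tab[["TGA"]] <- "W"
  else if (code == 15L) tab[["TAG"]] <- "Q"
  else if (code != 11L) stop("unsupported genetic code: ", code, call. = FALSE)
  tab
}

# Stop codon set per translation table.
stop_codons <- function(code = 11) {
  switch(as.character(code),
         "11" = c("TAA", "TAG", "TGA"),
         "4"  = c("TAA", "TAG"),
         "15" = c("TAA", "TGA"),
         stop("unsupported genetic code: ", code, call. = FALSE))
}

# Translate an in-frame nucleotide string; codons containing N become X
# (and never count as stops). Trailing partial codons are dropped.
translate_codons <- function(seq, code = 11) {
  tab <- genetic_code_table(code)
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  pos <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(seq, pos, pos + 2L)
  aa <- tab[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation of a genome
#'
#' Translates frames +1..+3 of the sequence and +1..+3 of its reverse
#' complement (reported as -1..-3) under the standard code. With
#' `clean = TRUE` stop symbols are rewritten to `X`, mirroring how six-frame
#' translations are prepared for profile searches of genomes that may use
#' alternative genetic codes.
#'
#' @param genome One genome row (see [genome_records()]).
#' @param clean Replace `*` by `X`.
#' @return Data frame of six protein records with a `frame` column in
#'   `+1,+2,+3,-1,-2,-3`.
#' @export
six_frame_translate <- function(genome, clean = FALSE) {
  seq <- check_dna(genome$seq)
  if (nchar(seq) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  rc <- revcomp(seq)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  out <- lapply(frames, function(f) {
    s <- if (f > 0) substring(seq, f) else substring(rc, -f)
    aa <- translate_codons(s, 11)
    if (clean) aa <- gsub("*", "X", aa, fixed = TRUE)
    data.frame(id = sprintf("%s_frame%+d", genome$id, f), seq = aa,
               source_genome = genome$id, frame = f, genetic_code = 11L)
  })
  do.call(rbind, out)
}

#' Call open reading frames
#'
#' Finds all maximal ATG-to-stop reading frames on both strands under the
#' requested genetic code. Within a frame, each stop closes at most one ORF,
#' started at the first ATG after the previous stop (the maximal ORF);
#' overlaps across frames and strands are allowed. Reported spans include the
#' stop codon; `length_aa` excludes it. Codons containing N never act as
#' stops or starts.
#'
#' @param genome One genome row.
#' @param code Genetic code: 11, 4 or 15.
#' @param min_len_aa Minimum ORF length in residues (excluding the stop).
#' @return Gene-annotation data frame (`genome_id, start, end, strand, label,
#'   length_aa, frame`) with 0-based half-open coordinates, sorted by start.
#' @export
find_orfs <- function(genome, code = 11, min_len_aa = 60) {
  stopifnot(min_len_aa >= 1)
  seq <- check_dna(genome$seq)
  L <- nchar(seq)
  rc <- revcomp(seq)
  stops <- stop_codons(code)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (off in 0:2) {
      n <- (nchar(s) - off) %/% 3L
      if (n < 2L) next
      pos <- seq.int(off + 1L, by = 3L, length.out = n)
      codons <- substring(s, pos, pos + 2L)
      is_stop <- codons %in% stops & !grepl("N", codons, fixed = TRUE)
      is_atg <- codons == "ATG"
      stop_idx <- which(is_stop)
      if (!length(stop_idx)) next
      prev <- c(0L, stop_idx[-length(stop_idx)])
      atg_idx <- which(is_atg)
      for (k in seq_along(stop_idx)) {
        cand <- atg_idx[atg_idx > prev[k] & atg_idx < stop_idx[k]]
        if (!length(cand)) next
        a <- cand[1L]
        len_aa <- stop_idx[k] - a
        if (len_aa < min_len_aa) next
        # 0-based half-open on the working strand, stop codon included
        s0 <- pos[a] - 1L
        e0 <- pos[stop_idx[k]] + 2L
        if (strand == "-") { tmp <- L - e0; e0 <- L - s0; s0 <- tmp }
        res[[length(res) + 1L]] <-
          data.frame(genome_id = genome$id, start = s0, end = e0,
                     strand = strand, label = "unknown", length_aa = len_aa,
                     frame = if (strand == "+") off + 1L else -(off + 1L))
      }
    }
  }
  if (!length(res))
    return(data.frame(genome_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      label = character(), length_aa = integer(),
                      frame = integer()))
  out <- do.call(rbind, res)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# Extract and translate the protein of one called ORF under a given code.
orf_protein <- function(genome, orf, code = 11) {
  s <- substring(genome$seq, orf$start + 1L, orf$end)
  if (orf$strand == "-") s <- revcomp(s)
  aa <- translate_codons(s, code)
  sub("\\*$", "", aa)
}
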