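#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that returns a plain
#' data frame. Sequences are upper-cased; in nucleotide mode `U` is rewritten
#' to `T`. Record ids are the first whitespace-delimited token of the header
#' and must be unique.
#'
#' @param path FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @return A data frame with columns `id` and `seq`, in file order; zero rows
#'   for an empty file.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (file.size(path) == 0)
    return(data.frame(id = character(), seq = character()))
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(set))
  if (type == "dna") seqs <- chartr("U", "T", seqs)
  data.frame(id = ids, seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x A data frame with `id` and `seq` columns, or a named character
#'   vector.
#' @param path Output file.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- data.frame(id = names(x), seq = unname(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$seq[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build genome records from id/sequence pairs
#'
#' The genome container used throughout: one row per contig/genome with the
#' sequence held as a character column.
#'
#' @param x Data frame with `id`, `seq` (e.g. from [read_fasta()]).
#' @param circular Logical, recycled.
#' @param source_sample Provenance label, recycled.
#' @return Data frame with columns `id, seq, length, circular, source_sample`.
#' @export
genome_records <- function(x, circular = FALSE, source_sample = "") {
  stopifnot(!anyDuplicated(x$id), all(nzchar(x$seq)))
  seqs <- vapply(x$seq, check_dna, "", USE.NAMES = FALSE)
  data.frame(id = x$id, seq = seqs, length = nchar(seqs),
             circular = rep_len(circular, nrow(x)),
             source_sample = rep_len(source_sample, nrow(x)))
}

#' Write gene annotations as GFF3
#'
#' Converts the internal 0-based half-open gene table to 1-based inclusive
#' GFF3 records (type `CDS`, label and score in the attributes).
#'
#' @param annots Gene-annotation data frame (`genome_id, start, end,
#'   strand, label`, optional `score`).
#' @param path Output file.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annots, path, source = "crasskit") {
  score <- if ("score" %in% names(annots)) {
    ifelse(is.na(annots$score), ".", formatC(annots$score, format = "f",
                                             digits = 2))
  } else rep(".", nrow(annots))
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(annots)), function(i)
               paste(annots$genome_id[i], source, "CDS",
                     annots$start[i] + 1L, annots$end[i], score[i],
                     annots$strand[i], "0",
                     paste0("ID=", annots$genome_id[i], "_g", i,
                            ";label=", annots$label[i]),
                     sep = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

# Fetch one genome row by id (helper used by drivers).
genome_by_id <- function(genomes, id) {
  i <- match(id, genomes$id)
  if (is.na(i)) stop("unknown genome id: ", id, call. = FALSE)
  genomes[i, , drop = FALSE]
}
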