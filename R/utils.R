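#' @useDynLib crasskit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Split a string into single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a nucleotide string
#'
#' @param x A character scalar over `A,C,G,T,N` (lower case accepted).
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  paste(rev(str_chars(comp)), collapse = "")
}

# Validate a nucleotide sequence (A,C,G,T,N only), returning it upper-cased.
check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  if (grepl("[^ACGTN]", x))
    stop(what, " contains characters outside A,C,G,T,N", call. = FALSE)
  x
}

# 0-based integer coding of DNA (A=0,C=1,G=2,T=3, N and others -1),
# the representation the C++ kernels use.
dna_to_int <- function(x) {
  code <- rep.int(-1L, 127L)
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  unname(code[utf8ToInt(toupper(x))])
}

# Amino-acid alphabet shared by the alignment kernels: the BLOSUM62 row order.
aa_alphabet <- function() {
  rownames(blosum62())
}

blosum62_cache <- new.env(parent = emptyenv())

# The BLOSUM62 substitution matrix (from Biostrings), cached.
blosum62 <- function() {
  if (is.null(blosum62_cache$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$mat <- e$BLOSUM62
  }
  blosum62_cache$mat
}

# 0-based integer coding of a protein against an alphabet; errors on
# characters outside the allowed set.
aa_to_int <- function(x, allowed = c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X"),
                      alphabet = aa_alphabet()) {
  chars <- str_chars(toupper(x))
  bad <- setdiff(unique(chars), allowed)
  if (length(bad))
    stop("protein sequence contains invalid characters: ",
         paste(bad, collapse = ","), call. = FALSE)
  match(chars, alphabet) - 1L
}

# Deterministic stage seeds derived from one global integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}
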