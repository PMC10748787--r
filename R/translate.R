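# Six-frame translation of DNA queries (standard genetic code).

DNA_CHARS <- c("A", "C", "G", "T", "N")

# cached copy of the standard code (the exported Biostrings binding is
# surprisingly expensive to dereference in a tight loop)
.pg_cache <- new.env(parent = emptyenv())
genetic_code <- function() {
  if (is.null(.pg_cache$gc)) .pg_cache$gc <- Biostrings::GENETIC_CODE
  .pg_cache$gc
}

#' Translate one in-frame DNA string to amino acids
#'
#' Standard genetic code; trailing partial codons are dropped; codons
#' containing `N` translate to `X`; stop codons to `*`.
#' @param dna DNA string over A/C/G/T/N.
#' @return amino-acid string.
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  L <- nchar(dna) %/% 3L * 3L
  if (L == 0L) return("")
  codons <- substring(dna, seq(1L, L, by = 3L), seq(3L, L, by = 3L))
  gc <- genetic_code()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Translate a DNA sequence in all six reading frames
#'
#' Three forward frames and three frames of the reverse complement.
#' @param dna DNA string over A/C/G/T/N (case-insensitive).
#' @return named character vector of six amino-acid strings, names
#'   `+1 +2 +3 -1 -2 -3`.
#' @export
translate_six_frames <- function(dna) {
  dna <- toupper(dna)
  bad <- setdiff(unique(strsplit(dna, "")[[1L]]), DNA_CHARS)
  if (length(bad)) {
    stop("non-nucleotide character in DNA query: ", paste(bad, collapse = " "))
  }
  rc <- revcomp(dna)
  out <- c(
    "+1" = translate_dna(dna),
    "+2" = translate_dna(substring(dna, 2L)),
    "+3" = translate_dna(substring(dna, 3L)),
    "-1" = translate_dna(rc),
    "-2" = translate_dna(substring(rc, 2L)),
    "-3" = translate_dna(substring(rc, 3L))
  )
  out
}
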