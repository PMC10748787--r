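# MSA container: a rectangular character matrix over the amino-acid alphabet
# plus the gap character '-'. One MSA is the unit of panproteome membership.

#' Amino-acid alphabet accepted in MSAs and queries
#'
#' The 20 standard amino acids plus `X` (unknown) and `*` (stop). Real
#' proteomes contain `X` and `*` (e.g. from fuzzy or stop codons), so they
#' are treated as ordinary symbols throughout graph building and indexing.
#' @keywords internal
AA_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

GAP_CHAR <- "-"

#' Construct an MSA object from aligned rows
#'
#' @param rows character vector of aligned sequences (equal lengths; residues
#'   and `-` gaps).
#' @param row_names unique names, one per row. Defaults to `names(rows)` or
#'   `seq1, seq2, ...`.
#' @param msa_id identifier of the MSA (for FASTA input, the file stem).
#' @return an object of class `msa` with fields `msa_id`, `row_names` and
#'   `matrix` (n rows x m columns of single characters).
#' @export
msa <- function(rows, row_names = NULL, msa_id = "msa") {
  if (length(rows) < 1L) stop("an MSA needs at least one row")
  if (is.null(row_names)) {
    row_names <- names(rows)
    if (is.null(row_names)) row_names <- paste0("seq", seq_along(rows))
  }
  if (length(row_names) != length(rows)) {
    stop("row_names must match the number of rows")
  }
  if (anyDuplicated(row_names)) {
    stop("duplicate row names in MSA '", msa_id, "': ",
         paste(unique(row_names[duplicated(row_names)]), collapse = ", "))
  }
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- row_names[widths != widths[1L]][1L]
    stop("MSA '", msa_id, "' is not rectangular: record '", bad,
         "' has length ", nchar(rows[row_names == bad][1L]),
         " but the first record has length ", widths[1L])
  }
  if (widths[1L] < 1L) stop("MSA '", msa_id, "' has zero columns")
  chars <- strsplit(rows, "", fixed = TRUE)
  allowed <- c(AA_CHARS, GAP_CHAR)
  for (i in seq_along(chars)) {
    bad <- setdiff(unique(chars[[i]]), allowed)
    if (length(bad)) {
      stop("record '", row_names[i], "' in MSA '", msa_id,
           "' contains characters outside the amino-acid alphabet: ",
           paste(bad, collapse = " "))
    }
  }
  mat <- do.call(rbind, chars)
  rownames(mat) <- row_names
  structure(list(msa_id = msa_id, row_names = row_names, matrix = mat),
            class = "msa")
}

#' Read one MSA from an aligned FASTA file
#'
#' Records may wrap lines; characters are upper-cased. The MSA identifier is
#' the file name without its extension.
#'
#' @param path path to an aligned FASTA file.
#' @return an [msa] object.
#' @export
read_msa_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  rows <- as.character(set)
  # FASTA headers: keep the first whitespace-delimited token as the name
  nms <- sub("\\s.*$", "", names(set))
  msa(rows, row_names = nms, msa_id = file_stem(path))
}

file_stem <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Degapped rows of an MSA
#' @param x an [msa] object.
#' @return named character vector of rows with gap characters removed.
#' @export
degap_rows <- function(x) {
  stopifnot(inherits(x, "msa"))
  rows <- apply(x$matrix, 1L, function(r) paste(r[r != GAP_CHAR], collapse = ""))
  names(rows) <- x$row_names
  rows
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA '", x$msa_id, "': ", nrow(x$matrix), " rows x ",
      ncol(x$matrix), " columns\n", sep = "")
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$matrix)

#' A small worked-example MSA of three protein sequences
#'
#' Three aligned rows (`-MEPTPEQ`, `---T--MA`, `MSETQSTQ`) exercising gap
#' bridging during graph construction and a compactable linear stretch.
#' @return an [msa] object with 3 rows and 8 columns.
#' @export
example_msa <- function() {
  msa(c(r1 = "-MEPTPEQ", r2 = "---T--MA", r3 = "MSETQSTQ"), msa_id = "example")
}

#' Write an MSA to aligned FASTA
#' @param x an [msa] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  rows <- apply(x$matrix, 1L, paste, collapse = "")
  writeLines(paste0(">", x$row_names, "\n", rows), path)
  invisible(path)
}
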