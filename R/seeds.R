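# Seed extraction (k-mers and (w,k)-minimizers) and the seed -> MSA index.

#' Seed extraction parameters
#'
#' @param k seed length (>= 1).
#' @param w window size in k-mers (>= 1); ignored in k-mer mode, and `w = 1`
#'   in minimizer mode is equivalent to the plain k-mer index.
#' @param mode `"kmer"` or `"minimizer"`.
#' @return an object of class `seed_params`.
#' @export
seed_params <- function(k = 5L, w = 1L, mode = c("kmer", "minimizer")) {
  mode <- match.arg(mode)
  k <- as.integer(k); w <- as.integer(w)
  if (k < 1L) stop("k must be >= 1")
  if (w < 1L) stop("w must be >= 1")
  structure(list(k = k, w = w, mode = mode), class = "seed_params")
}

#' Extract all consecutive k-mers of a sequence
#'
#' A sequence of length m yields max(0, m - k + 1) k-mers, in order.
#' @param seq gap-free sequence string.
#' @param k seed length.
#' @return character vector of k-mers (possibly empty).
#' @export
extract_kmers <- function(seq, k) {
  m <- nchar(seq)
  if (m < k) return(character(0))
  substring(seq, 1:(m - k + 1L), k:m)
}

#' Extract (w,k)-minimizers of a sequence
#'
#' For every window of `w` consecutive k-mers, the lexicographically smallest
#' (plain byte order on upper-case letters) is selected; a k-mer occurrence
#' selected by several consecutive windows is emitted once. Computed with a
#' monotone-deque sliding-window minimum in linear time. Sequences shorter
#' than k + w - 1 but at least k long yield the single smallest k-mer of the
#' whole sequence; shorter still, nothing.
#'
#' @param seq gap-free sequence string.
#' @param params a [seed_params] object (minimizer mode; `w = 1` reduces to
#'   [extract_kmers()]).
#' @return character vector of minimizers in window order.
#' @export
extract_minimizers <- function(seq, params) {
  k <- params$k; w <- params$w
  kmers <- extract_kmers(seq, k)
  nk <- length(kmers)
  if (nk == 0L) return(character(0))
  if (w == 1L) return(kmers)
  if (nk < w) return(kmers[match(min(kmers), kmers)])
  # monotone deque of k-mer indices; front always the leftmost window minimum
  dq <- integer(nk); head <- 1L; tail <- 0L
  out_pos <- integer(nk - w + 1L)
  for (i in seq_len(nk)) {
    while (tail >= head && kmers[dq[tail]] > kmers[i]) tail <- tail - 1L
    tail <- tail + 1L
    dq[tail] <- i
    if (dq[head] <= i - w) head <- head + 1L
    if (i >= w) out_pos[i - w + 1L] <- dq[head]
  }
  # deduplicate consecutive windows that select the same k-mer occurrence
  keep <- c(TRUE, out_pos[-1L] != out_pos[-length(out_pos)])
  kmers[out_pos[keep]]
}

extract_seeds <- function(seq, params) {
  if (params$mode == "kmer") extract_kmers(seq, params$k)
  else extract_minimizers(seq, params)
}

#' Per-MSA normalized seed counts
#'
#' Counts seed occurrences across all rows of the MSA (gaps removed,
#' duplicates within a row counted) and divides by the number of rows. The
#' normalized count is the sort key for the index value lists.
#'
#' @param x an [msa] object.
#' @param params a [seed_params] object.
#' @return named numeric vector: seed -> occurrences / n_rows.
#' @export
seed_normalized_counts <- function(x, params) {
  rows <- degap_rows(x)
  seeds <- unlist(lapply(rows, extract_seeds, params = params), use.names = FALSE)
  if (!length(seeds)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(seeds)
  stats::setNames(as.numeric(tab) / length(rows), names(tab))
}

#' Build the seed index over a collection of MSAs
#'
#' Every seed maps to the list of MSA identifiers containing it, ordered by
#' descending normalized count (ties broken by ascending MSA id) and, when
#' `seed_limit > 0`, truncated to the top `seed_limit` entries.
#'
#' @param msas list of [msa] objects.
#' @param params a [seed_params] object.
#' @param seed_limit maximum MSAs kept per seed; 0 keeps all.
#' @return an object of class `seed_index` with fields `params`, `seed_limit`
#'   and `entries` (named list seed -> character vector of MSA ids).
#' @export
build_index <- function(msas, params = seed_params(), seed_limit = 0L) {
  if (!length(msas)) stop("build_index needs at least one MSA")
  seed_limit <- as.integer(seed_limit)
  if (seed_limit < 0L) stop("seed_limit must be >= 0")
  seed_v <- character(0); msa_v <- character(0); cnt_v <- numeric(0)
  for (x in msas) {
    nc <- seed_normalized_counts(x, params)
    if (length(nc)) {
      seed_v <- c(seed_v, names(nc))
      msa_v <- c(msa_v, rep(x$msa_id, length(nc)))
      cnt_v <- c(cnt_v, unname(nc))
    }
  }
  if (!length(seed_v)) {
    warning("no seeds extracted (k larger than every degapped row?); index is empty")
    entries <- stats::setNames(list(), character(0))
  } else {
    o <- order(seed_v, -cnt_v, msa_v, method = "radix")
    entries <- split(msa_v[o], seed_v[o])
    if (seed_limit > 0L) {
      entries <- lapply(entries, function(v) v[seq_len(min(seed_limit, length(v)))])
    }
  }
  structure(list(params = params, seed_limit = seed_limit, entries = entries),
            class = "seed_index")
}

INDEX_FORMAT <- "protgraph-seed-index"
INDEX_VERSION <- 1L

#' Save a seed index to disk
#'
#' A versioned serialized container holding the seed parameters, the seed
#' limit and the entries; [load_index()] restores it bit-for-bit.
#' @param idx a `seed_index`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_index <- function(idx, path) {
  stopifnot(inherits(idx, "seed_index"))
  saveRDS(list(format = INDEX_FORMAT, version = INDEX_VERSION,
               params = idx$params, seed_limit = idx$seed_limit,
               entries = idx$entries),
          path)
  invisible(path)
}

#' Load a seed index saved by [save_index()]
#' @param path path to the index file.
#' @return a `seed_index`.
#' @export
load_index <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, INDEX_FORMAT)) {
    stop(path, " is not a seed index file")
  }
  if (!identical(obj$version, INDEX_VERSION)) {
    stop("index version ", obj$version, " in ", path,
         " is not supported (expected ", INDEX_VERSION, ")")
  }
  structure(list(params = obj$params, seed_limit = obj$seed_limit,
                 entries = obj$entries),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index: ", length(x$entries), " seeds (mode=", x$params$mode,
      ", k=", x$params$k, ", w=", x$params$w,
      ", seed_limit=", x$seed_limit, ")\n", sep = "")
  invisible(x)
}
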