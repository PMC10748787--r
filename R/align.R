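# Graph-aware local alignment: a partial-order extension of Smith-Waterman.
#
# The DAG is topologically sorted and the node labels concatenated into one
# target string; DP columns are target positions and rows are query symbols
# (amino acids, or nucleotides in frameshift-aware DNA mode). Inside a node a
# column's only predecessor is the previous column; at the first column of a
# node the predecessors are the last columns of all parent nodes, and the
# cell score is the max over those predecessor columns. Everything is a local
# alignment: every cell is floored at 0 and traceback stops at a 0 cell.

SUB_MATRICES <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
                  "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")

#' Load a named substitution matrix
#' @param name one of the BLOSUM/PAM matrices shipped with Biostrings.
#' @return integer matrix with amino-acid row/column names.
#' @export
load_sub_matrix <- function(name = "BLOSUM62") {
  name <- match.arg(name, SUB_MATRICES)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Alignment configuration
#'
#' @param sub_matrix substitution matrix name (default BLOSUM62) or a scored
#'   matrix with residue dimnames.
#' @param gap_penalty linear gap penalty per gap column (negative).
#' @param frameshift_penalty penalty for a single-nucleotide frameshift jump
#'   in DNA mode (negative).
#' @param min_identity minimum alignment identity in \[0,1\] for an alignment
#'   to be reported (0 reports all).
#' @param align_limit maximum candidate graphs aligned per query (0 = all
#'   index matches).
#' @param min_len_frac minimum fraction of the query that must be covered by
#'   the alignment.
#' @param unknown_penalty substitution score used when a residue pair is
#'   absent from the matrix (e.g. unusual symbols).
#' @return an object of class `align_config`.
#' @export
align_config <- function(sub_matrix = "BLOSUM62",
                         gap_penalty = -3L,
                         frameshift_penalty = -4L,
                         min_identity = 0,
                         align_limit = 5L,
                         min_len_frac = 0,
                         unknown_penalty = -4L) {
  if (is.character(sub_matrix)) {
    sub_name <- sub_matrix
    sub_matrix <- load_sub_matrix(sub_matrix)
  } else {
    sub_name <- "custom"
  }
  if (gap_penalty > 0 || frameshift_penalty > 0) {
    stop("gap and frameshift penalties must be <= 0")
  }
  if (min_identity < 0 || min_identity > 1) stop("min_identity must be in [0,1]")
  if (min_len_frac < 0 || min_len_frac > 1) stop("min_len_frac must be in [0,1]")
  structure(list(sub_name = sub_name, sub_matrix = sub_matrix,
                 gap_penalty = as.numeric(gap_penalty),
                 frameshift_penalty = as.numeric(frameshift_penalty),
                 min_identity = min_identity,
                 align_limit = as.integer(align_limit),
                 min_len_frac = min_len_frac,
                 unknown_penalty = as.numeric(unknown_penalty)),
            class = "align_config")
}

row_max <- function(M) {
  if (ncol(M) == 1L) M[, 1L]
  else do.call(pmax, lapply(seq_len(ncol(M)), function(c) M[, c]))
}

# Substitution scores for every (a, b) pair of two character vectors, with
# the fallback penalty for symbols absent from the matrix.
sub_score_matrix <- function(a, b, cfg) {
  sm <- cfg$sub_matrix
  ra <- match(a, rownames(sm)); cb <- match(b, colnames(sm))
  S <- matrix(cfg$unknown_penalty, nrow = length(a), ncol = length(b))
  ok_a <- which(!is.na(ra)); ok_b <- which(!is.na(cb))
  if (length(ok_a) && length(ok_b)) {
    S[ok_a, ok_b] <- sm[ra[ok_a], cb[ok_b], drop = FALSE]
  }
  S
}

#' Topological DP layout of a protein graph
#'
#' Concatenates the node labels in topological order into the target string
#' and records, for every target column, its predecessor columns: the
#' previous column inside a node, or the last columns of all parent nodes at
#' a node's first column (none for source nodes).
#'
#' @param g a `protein_graph`.
#' @return an object of class `dp_layout` with fields `order` (node ids),
#'   `target`, `preds` (list of integer predecessor columns per target
#'   column), `col_node` (node id of each column), `node_start`/`node_end`
#'   (1-based target column range per node id).
#' @export
graph_layout <- function(g) {
  ord <- topological_sort(g)
  lens <- nchar(g$labels)
  nn <- length(ord)
  node_start <- integer(n_nodes(g)); node_end <- integer(n_nodes(g))
  pos <- 1L
  for (v in ord) {
    node_start[v] <- pos
    node_end[v] <- pos + lens[[v]] - 1L
    pos <- pos + lens[[v]]
  }
  n <- pos - 1L
  target <- paste(g$labels[ord], collapse = "")
  col_node <- integer(n)
  for (v in ord) col_node[node_start[v]:node_end[v]] <- v
  parents <- adjacency(g, reverse = TRUE)
  preds <- vector("list", n)
  for (v in ord) {
    s <- node_start[v]
    preds[[s]] <- sort(node_end[parents[[v]]])
    if (node_end[v] > s) {
      for (j in (s + 1L):node_end[v]) preds[[j]] <- j - 1L
    }
  }
  structure(list(order = ord, target = target, preds = preds,
                 col_node = col_node, node_start = node_start,
                 node_end = node_end),
            class = "dp_layout")
}

new_graph_alignment <- function(query_name, graph_id, score, node_path,
                                query_interval, query_len, path_interval,
                                path_len, cigar, matches, block_len, identity,
                                strand = "+", frame = "none",
                                frameshift_count = 0L) {
  structure(list(query_name = query_name, graph_id = graph_id, score = score,
                 node_path = node_path, query_interval = query_interval,
                 query_len = query_len, path_interval = path_interval,
                 path_len = path_len, cigar = cigar, matches = matches,
                 block_len = block_len, identity = identity, strand = strand,
                 frame = frame, frameshift_count = frameshift_count),
            class = "graph_alignment")
}

#' @export
print.graph_alignment <- function(x, ...) {
  cat("alignment of '", x$query_name, "' to graph '", x$graph_id,
      "': score ", x$score, ", identity ", round(x$identity, 3),
      ", nodes ", paste(x$node_path, collapse = ">"),
      if (x$frameshift_count > 0) paste0(", ", x$frameshift_count, " frameshift(s)"),
      "\n", sep = "")
  invisible(x)
}

# Shared post-processing of a traceback: ops is a character vector of
# per-column operations ('=', 'X', 'I', 'D'), cols the consumed target
# columns (ascending). Builds node path, path interval and CIGAR.
finish_alignment <- function(ops, cols, lay, g) {
  r <- rle(ops)
  cigar <- paste0(r$lengths, r$values, collapse = "")
  npath <- unique(lay$col_node[cols])
  plen <- sum(nchar(g$labels[npath]))
  first <- cols[1L]; last <- cols[length(cols)]
  pstart <- first - lay$node_start[npath[1L]]
  pend <- plen - (lay$node_end[npath[length(npath)]] - last)
  list(cigar = cigar, node_path = npath, path_len = plen,
       path_interval = c(pstart, pend),
       matches = sum(ops == "="), block_len = length(ops),
       identity = sum(ops == "=") / length(ops))
}

#' Locally align an amino-acid query to a protein graph
#'
#' Partial-order Smith-Waterman: the score of a cell is the maximum over all
#' predecessor target columns of the usual three moves (substitution,
#' query gap, target gap, all linear) floored at 0. Traceback starts at the
#' best cell (largest score; ties resolved toward the largest query position,
#' then the largest target column) and follows the recorded provenance, with
#' move precedence substitution > target gap > query gap and the smallest
#' predecessor column winning ties.
#'
#' @param query amino-acid query string.
#' @param g a `protein_graph` (a DAG).
#' @param cfg an [align_config].
#' @param query_name name recorded in the result.
#' @return a `graph_alignment`, or `NULL` when no alignment scores above 0 or
#'   the identity / query-coverage thresholds are not met.
#' @export
align_protein <- function(query, g, cfg = align_config(), query_name = "query") {
  query <- toupper(query)
  lay <- graph_layout(g)
  qch <- strsplit(query, "")[[1L]]
  tch <- strsplit(lay$target, "")[[1L]]
  m <- length(qch); n <- length(tch)
  if (m == 0L || n == 0L) return(NULL)
  SUB <- sub_score_matrix(qch, tch, cfg)
  gap <- cfg$gap_penalty
  H <- matrix(0, m + 1L, n + 1L)
  best <- 0; bi <- 0L; bj <- 0L
  gseq <- gap * seq_len(m)
  for (j in seq_len(n)) {
    P <- lay$preds[[j]]
    if (!length(P)) P <- 0L
    # max over predecessor columns, shared by substitution and target-gap
    RM <- if (length(P) == 1L) H[, P + 1L] else row_max(H[, P + 1L, drop = FALSE])
    diag_v <- RM[seq_len(m)] + SUB[, j]
    tgap_v <- RM[-1L] + gap
    m0 <- pmax(diag_v, tgap_v, 0)
    # query-gap chain within the column: H[i] = max(m0[i], H[i-1] + gap)
    col <- gseq + cummax(m0 - gseq)
    H[-1L, j + 1L] <- col
    cb <- max(col)
    if (cb > 0 && cb >= best) {
      ic <- m + 1L - which.max(rev(col))       # largest i among column ties
      if (cb > best || ic > bi || (ic == bi && j > bj)) {
        best <- cb; bi <- ic; bj <- j
      }
    }
  }
  if (best <= 0) return(NULL)
  # traceback: recompute the winning move at each visited cell, with the
  # precedence substitution > target gap > query gap and the smallest
  # predecessor column first
  ops <- character(0); cols <- integer(0)
  i <- bi; j <- bj
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0) {
    v <- H[i + 1L, j + 1L]
    P <- lay$preds[[j]]
    if (!length(P)) P <- 0L
    k <- 0L; bp <- 0L
    for (p in P) {
      if (H[i, p + 1L] + SUB[i, j] == v) { k <- 1L; bp <- p; break }
    }
    if (k == 0L) for (p in P) {
      if (H[i + 1L, p + 1L] + gap == v) { k <- 2L; bp <- p; break }
    }
    if (k == 0L && H[i, j + 1L] + gap == v) k <- 3L
    if (k == 1L) {
      ops <- c(if (qch[i] == tch[j]) "=" else "X", ops)
      cols <- c(j, cols)
      i <- i - 1L; j <- bp
    } else if (k == 2L) {
      ops <- c("D", ops); cols <- c(j, cols)
      j <- bp
    } else if (k == 3L) {
      ops <- c("I", ops)
      i <- i - 1L
    } else stop("internal error: traceback lost provenance")
  }
  fin <- finish_alignment(ops, cols, lay, g)
  aln <- new_graph_alignment(query_name, g$graph_id, best, fin$node_path,
                             query_interval = c(i, bi), query_len = m,
                             path_interval = fin$path_interval,
                             path_len = fin$path_len, cigar = fin$cigar,
                             matches = fin$matches, block_len = fin$block_len,
                             identity = fin$identity)
  if (aln$identity < cfg$min_identity) return(NULL)
  if ((bi - i) / m < cfg$min_len_frac) return(NULL)
  aln
}

#' Frameshift-aware local alignment of a DNA query to a protein graph
#'
#' DP rows are nucleotide positions, columns are target (amino-acid)
#' positions. Each nucleotide is treated as a potential third codon position:
#' the substitution move consumes the codon ending at the row and one target
#' column; a codon may also be consumed against a target gap, or a target
#' column against a query gap (both at the linear gap penalty). Two
#' frameshift jumps consume 4 or 2 nucleotides against one target column at
#' the frameshift penalty, modelling a single-nucleotide insertion or
#' deletion in the DNA. At node boundaries "previous column" again means the
#' max over all predecessor columns. Both strands are attempted and the
#' higher-scoring one returned (ties prefer the forward strand). Query
#' coordinates in the result are on the original (forward) sequence.
#'
#' @param dna DNA query string over A/C/G/T/N.
#' @param g a `protein_graph`.
#' @param cfg an [align_config].
#' @param query_name name recorded in the result.
#' @param strands strands to attempt (`"+"`, `"-"`).
#' @return a `graph_alignment` with `frameshift_count` set, or `NULL`.
#' @export
align_dna_frameshift <- function(dna, g, cfg = align_config(),
                                 query_name = "query",
                                 strands = c("+", "-")) {
  dna <- toupper(dna)
  bad <- setdiff(unique(strsplit(dna, "")[[1L]]), DNA_CHARS)
  if (length(bad)) {
    stop("non-nucleotide character in DNA query: ", paste(bad, collapse = " "))
  }
  lay <- graph_layout(g)
  best <- NULL
  for (s in strands) {
    seq <- if (s == "+") dna else revcomp(dna)
    a <- dna_dp_one_strand(seq, lay, g, cfg, query_name, s)
    if (!is.null(a) && (is.null(best) || a$score > best$score)) best <- a
  }
  if (is.null(best)) return(NULL)
  if (best$identity < cfg$min_identity) return(NULL)
  if ((best$query_interval[2L] - best$query_interval[1L]) / nchar(dna) <
      cfg$min_len_frac) return(NULL)
  best
}

dna_dp_one_strand <- function(seq, lay, g, cfg, query_name, strand) {
  tch <- strsplit(lay$target, "")[[1L]]
  n <- length(tch)
  L <- nchar(seq)
  if (L < 2L || n == 0L) return(NULL)
  # amino acid encoded by the codon ending at each position i >= 3
  aa_at <- rep(NA_character_, L)
  if (L >= 3L) {
    codons <- substring(seq, 1L:(L - 2L), 3L:L)
    gc <- genetic_code()
    aa <- unname(gc[codons])
    aa[is.na(aa)] <- "X"
    aa_at[3L:L] <- aa
  }
  SUB <- matrix(cfg$unknown_penalty, nrow = L, ncol = n)
  if (L >= 3L) SUB[3L:L, ] <- sub_score_matrix(aa_at[3L:L], tch, cfg)
  gap <- cfg$gap_penalty; fs <- cfg$frameshift_penalty
  H <- matrix(0, L + 1L, n + 1L)
  best <- 0; bi <- 0L; bj <- 0L
  rows_i <- seq_len(L)
  neg <- -Inf
  for (j in seq_len(n)) {
    P <- lay$preds[[j]]
    if (!length(P)) P <- 0L
    # the max over predecessor columns, shared by all predecessor-column
    # moves and shifted per move: codon substitution (i-3, pl), target gap
    # (i, pl), insertion frameshift (i-4, pl), deletion frameshift (i-2, pl)
    RM <- if (length(P) == 1L) H[, P + 1L] else row_max(H[, P + 1L, drop = FALSE])
    diag_v <- c(neg, neg, RM[seq_len(L - 2L)]) + SUB[, j]
    tgap_v <- RM[-1L] + gap
    insfs_v <- if (L >= 4L) c(neg, neg, neg, RM[seq_len(L - 3L)] + fs) else rep(neg, L)
    delfs_v <- c(neg, RM[seq_len(L - 1L)] + fs)
    m0 <- pmax(diag_v, tgap_v, insfs_v, delfs_v, 0)
    # codon-vs-target-gap chain within the column, in steps of three rows:
    # H[i] = max(m0[i], H[i-3] + gap)
    col <- m0
    for (r in 1:3) {
      idx <- seq.int(r, L, by = 3L)
      if (length(idx) > 1L) {
        t <- seq_along(idx)
        col[idx] <- gap * t + cummax(m0[idx] - gap * t)
      }
    }
    H[-1L, j + 1L] <- col
    cb <- max(col)
    if (cb > 0 && cb >= best) {
      ic <- L + 1L - which.max(rev(col))
      if (cb > best || ic > bi || (ic == bi && j > bj)) {
        best <- cb; bi <- ic; bj <- j
      }
    }
  }
  if (best <= 0) return(NULL)
  # traceback with recomputed provenance; precedence: substitution >
  # target gap > codon gap > insertion jump > deletion jump
  ops <- character(0); cols <- integer(0); nfs <- 0L
  i <- bi; j <- bj
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0) {
    v <- H[i + 1L, j + 1L]
    P <- lay$preds[[j]]
    if (!length(P)) P <- 0L
    k <- 0L; bp <- 0L
    if (i >= 3L) for (p in P) {
      if (H[i - 2L, p + 1L] + SUB[i, j] == v) { k <- 1L; bp <- p; break }
    }
    if (k == 0L) for (p in P) {
      if (H[i + 1L, p + 1L] + gap == v) { k <- 2L; bp <- p; break }
    }
    if (k == 0L && i >= 3L && H[i - 2L, j + 1L] + gap == v) k <- 3L
    if (k == 0L && i >= 4L) for (p in P) {
      if (H[i - 3L, p + 1L] + fs == v) { k <- 4L; bp <- p; break }
    }
    if (k == 0L && i >= 2L) for (p in P) {
      if (H[i - 1L, p + 1L] + fs == v) { k <- 5L; bp <- p; break }
    }
    if (k == 1L) {
      ops <- c(if (identical(aa_at[i], tch[j])) "=" else "X", ops)
      cols <- c(j, cols); i <- i - 3L; j <- bp
    } else if (k == 2L) {
      ops <- c("D", ops); cols <- c(j, cols); j <- bp
    } else if (k == 3L) {
      ops <- c("I", ops); i <- i - 3L
    } else if (k == 4L) {
      ops <- c("X", ops); cols <- c(j, cols); nfs <- nfs + 1L
      i <- i - 4L; j <- bp
    } else if (k == 5L) {
      ops <- c("X", ops); cols <- c(j, cols); nfs <- nfs + 1L
      i <- i - 2L; j <- bp
    } else stop("internal error: traceback lost provenance")
  }
  fin <- finish_alignment(ops, cols, lay, g)
  qs <- i; qe <- bi                       # 0-based half-open on this strand
  if (strand == "-") { tmp <- qs; qs <- L - qe; qe <- L - tmp }
  frame_num <- (i %% 3L) + 1L
  frame <- paste0(if (strand == "+") "+" else "-", frame_num)
  new_graph_alignment(query_name, g$graph_id, best, fin$node_path,
                      query_interval = c(qs, qe), query_len = L,
                      path_interval = fin$path_interval,
                      path_len = fin$path_len, cigar = fin$cigar,
                      matches = fin$matches, block_len = fin$block_len,
                      identity = fin$identity, strand = strand,
                      frame = frame, frameshift_count = nfs)
}

#' Rank candidate graphs for a query via the seed index
#'
#' Extracts seeds (with the index's own parameters) from each supplied
#' sequence — the amino-acid query, or all six translated frames of a DNA
#' query — looks every seed occurrence up in the index, and ranks graphs by
#' the total number of seed hits (ties broken by ascending graph id).
#'
#' @param seqs character vector of amino-acid sequences to draw seeds from.
#' @param idx a `seed_index`.
#' @param align_limit maximum number of candidates returned; 0 returns all.
#' @return character vector of MSA/graph ids, best first (possibly empty).
#' @export
select_candidates <- function(seqs, idx, align_limit = 0L) {
  seeds <- unlist(lapply(seqs, extract_seeds, params = idx$params),
                  use.names = FALSE)
  if (!length(seeds)) return(character(0))
  hit_lists <- idx$entries[seeds]
  hits <- unlist(hit_lists[!vapply(hit_lists, is.null, TRUE)], use.names = FALSE)
  if (!length(hits)) return(character(0))
  tab <- table(hits)
  ids <- names(tab)[order(-as.integer(tab), names(tab), method = "radix")]
  if (align_limit > 0L) ids <- ids[seq_len(min(align_limit, length(ids)))]
  ids
}

#' Alignment identity
#'
#' Identical residue columns divided by the total number of alignment
#' columns, gap columns included (the stricter convention).
#' @param aln a `graph_alignment`.
#' @return fraction in \[0,1\].
#' @export
compute_identity <- function(aln) {
  stopifnot(inherits(aln, "graph_alignment"))
  r <- parse_cigar(aln$cigar)
  sum(r$lengths[r$values == "="]) / sum(r$lengths)
}

parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[=XIDM]", cigar))[[1L]]
  list(lengths = lens, values = ops)
}
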