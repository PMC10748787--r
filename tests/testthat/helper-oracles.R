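# Independent oracles and fixture helpers for the test suite. Everything here
# is deliberately naive (textbook recurrences, brute-force enumeration) and
# shares no code with the package's own DP or minimizer implementations.

AA20_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n, alphabet = AA20_T) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Textbook Smith-Waterman, linear gaps, score only.
sw_score <- function(query, target, cfg) {
  q <- strsplit(query, "")[[1]]; t <- strsplit(target, "")[[1]]
  m <- length(q); n <- length(t)
  sm <- cfg$sub_matrix
  sub <- function(a, b) {
    if (a %in% rownames(sm) && b %in% colnames(sm)) sm[a, b]
    else cfg$unknown_penalty
  }
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      v <- max(H[i, j] + sub(q[i], t[j]),
               H[i, j + 1] + cfg$gap_penalty,
               H[i + 1, j] + cfg$gap_penalty,
               0)
      H[i + 1, j + 1] <- v
      if (v > best) best <- v
    }
  }
  best
}

# Literal frameshift-aware DP, sequence vs sequence (rows = DNA, cols =
# protein), with traceback; returns the best score and the number of
# frameshift jumps on the traceback (ties broken as in the package:
# substitution > target gap > query gap > insertion jump > deletion jump,
# best cell at the largest row then column).
fs_dp_literal <- function(dna, prot, cfg) {
  d <- strsplit(dna, "")[[1]]; p <- strsplit(prot, "")[[1]]
  L <- length(d); n <- length(p)
  sm <- cfg$sub_matrix
  gc <- Biostrings::GENETIC_CODE
  trans <- function(codon) {
    aa <- gc[[codon]]
    if (is.null(aa)) "X" else aa
  }
  sub <- function(a, b) {
    if (a %in% rownames(sm) && b %in% colnames(sm)) sm[a, b]
    else cfg$unknown_penalty
  }
  H <- matrix(0, L + 1, n + 1)
  mv <- matrix(0L, L + 1, n + 1)
  best <- 0; bi <- 0L; bj <- 0L
  for (j in seq_len(n)) {
    for (i in seq_len(L)) {
      cand <- c(
        if (i >= 3) H[i - 2, j] +
          sub(trans(paste(d[(i - 2):i], collapse = "")), p[j]) else -Inf,
        H[i + 1, j] + cfg$gap_penalty,
        if (i >= 3) H[i - 2, j + 1] + cfg$gap_penalty else -Inf,
        if (i >= 4) H[i - 3, j] + cfg$frameshift_penalty else -Inf,
        if (i >= 2) H[i - 1, j] + cfg$frameshift_penalty else -Inf,
        0)
      k <- which.max(cand)
      v <- cand[k]
      H[i + 1, j + 1] <- v
      mv[i + 1, j + 1] <- if (k == 6 || v <= 0) 0L else k
      if (v > 0 && (v > best || (v == best && (i > bi || (i == bi && j > bj))))) {
        best <- v; bi <- i; bj <- j
      }
    }
  }
  nfs <- 0L
  i <- bi; j <- bj
  while (i > 0 && j > 0 && mv[i + 1, j + 1] != 0L) {
    k <- mv[i + 1, j + 1]
    if (k == 1) { i <- i - 3; j <- j - 1 }
    else if (k == 2) { j <- j - 1 }
    else if (k == 3) { i <- i - 3 }
    else if (k == 4) { nfs <- nfs + 1L; i <- i - 4; j <- j - 1 }
    else { nfs <- nfs + 1L; i <- i - 2; j <- j - 1 }
  }
  list(score = best, n_frameshifts = nfs)
}

# Random small DAG with labelled nodes: node 1 is a source, every later node
# gets one or two parents among the earlier nodes.
random_dag <- function(max_nodes = 8, max_label = 3, alphabet = AA20_T) {
  nn <- sample(2:max_nodes, 1)
  labels <- vapply(seq_len(nn), function(i)
    random_aa(sample.int(max_label, 1), alphabet), "")
  names(labels) <- as.character(seq_len(nn))
  from <- integer(0); to <- integer(0)
  for (j in 2:nn) {
    parents <- sample(seq_len(j - 1), min(j - 1, sample(1:2, 1)))
    from <- c(from, parents); to <- c(to, rep(j, length(parents)))
  }
  edges <- unique(cbind(from = from, to = to))
  protgraph:::new_protein_graph("dag", labels, edges, list(), NULL)
}

# All source-to-sink path spellings of a DAG (brute-force DFS).
all_path_spellings <- function(g) {
  nn <- length(g$labels)
  e <- g$edges
  children <- lapply(seq_len(nn), function(v) e[e[, "from"] == v, "to"])
  indeg <- tabulate(e[, "to"], nbins = nn)
  sources <- which(indeg == 0)
  out <- character(0)
  walk <- function(v, acc) {
    acc <- paste0(acc, g$labels[[v]])
    ch <- children[[v]]
    if (!length(ch)) out[[length(out) + 1]] <<- acc
    else for (w in ch) walk(w, acc)
  }
  for (s in sources) walk(s, "")
  out
}

# Naive per-window minimizer oracle mirroring the stated convention: the
# leftmost smallest k-mer per window, each selected occurrence emitted once.
naive_minimizers <- function(seq, k, w) {
  m <- nchar(seq)
  if (m < k) return(character(0))
  kmers <- substring(seq, 1:(m - k + 1), k:m)
  if (w == 1) return(kmers)
  if (length(kmers) < w) return(kmers[match(min(kmers), kmers)])
  pos <- integer(0)
  for (s in 1:(length(kmers) - w + 1)) {
    win <- kmers[s:(s + w - 1)]
    pos <- c(pos, s + match(min(win), win) - 1)
  }
  keep <- c(TRUE, pos[-1] != pos[-length(pos)])
  kmers[pos[keep]]
}

# Three MSAs of 10, 7 and 3 rows in which the seed "MEP" occurs exactly 2, 4
# and 3 times; background rows avoid M, E and P entirely so the counts are
# exact by construction.
worked_index_msas <- function() {
  bg <- function(n, len, letters_) {
    vapply(seq_len(n), function(i)
      paste(sample(letters_, len, replace = TRUE), collapse = ""), "")
  }
  letters_ <- c("G", "H", "I", "K", "L", "N", "Q", "R")
  plant <- function(rows, which_rows) {
    for (i in which_rows) {
      rows[i] <- paste0(substr(rows[i], 1, 3), "MEP",
                        substr(rows[i], 7, nchar(rows[i])))
    }
    rows
  }
  withr::with_seed(42, {
    m1 <- msa(plant(bg(10, 12, letters_), 1:2), msa_id = "m1")
    m2 <- msa(plant(bg(7, 12, letters_), 1:4), msa_id = "m2")
    m3 <- msa(plant(bg(3, 12, letters_), 1:3), msa_id = "m3")
  })
  list(m1 = m1, m2 = m2, m3 = m3)
}
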