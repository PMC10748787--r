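# MSA -> DAG construction and path-preserving compaction.
#
# A protein graph is a DAG of sequence-labelled nodes with one named path per
# MSA row; spelling a path (concatenating its node labels) reproduces the
# degapped row. Node ids are positive integers assigned in construction order
# (column-major), which makes the id order a valid topological order for
# freshly built graphs; after compaction ids are renumbered consecutively.

new_protein_graph <- function(graph_id, labels, edges, paths, column_of) {
  structure(list(graph_id = graph_id,
                 labels = labels,     # named character: id -> label
                 edges = edges,       # integer matrix, columns from/to, deduped
                 paths = paths,       # named list: row_name -> integer vector
                 column_of = column_of), # 0-based source column of first char, or NULL
            class = "protein_graph")
}

empty_edges <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("from", "to")))
}

#' Build an uncompacted DAG from an MSA
#'
#' Scans the alignment column by column. Each (column, distinct non-gap
#' character) pair becomes one node; an edge joins the nodes of two characters
#' that are consecutive in some row once gaps are skipped (so a residue
#' followed by gaps connects forward to the row's next residue, bridging the
#' gap). One path per row records the node visits in column order. All-gap
#' columns produce no nodes; an all-gap row is an error because its path would
#' be empty.
#'
#' @param x an [msa] object.
#' @return a `protein_graph` with single-character node labels.
#' @export
build_graph_from_msa <- function(x) {
  stopifnot(inherits(x, "msa"))
  mat <- x$matrix
  n <- nrow(mat); m <- ncol(mat)
  labels <- character(0)
  column_of <- integer(0)
  from <- integer(0); to <- integer(0)
  last <- rep(NA_integer_, n)
  paths <- vector("list", n)
  for (i in seq_len(n)) paths[[i]] <- integer(0)
  nid <- 0L
  for (j in seq_len(m)) {
    seen <- list() # char -> node id for this column
    for (i in seq_len(n)) {
      ch <- mat[i, j]
      if (ch == GAP_CHAR) next
      id <- seen[[ch]]
      if (is.null(id)) {
        nid <- nid + 1L
        id <- nid
        labels[id] <- ch
        column_of[id] <- j - 1L  # 0-based provenance column
        seen[[ch]] <- id
      }
      if (!is.na(last[i])) {
        from <- c(from, last[i]); to <- c(to, id)
      }
      last[i] <- id
      paths[[i]] <- c(paths[[i]], id)
    }
  }
  if (any(is.na(last))) {
    bad <- x$row_names[is.na(last)][1L]
    stop("row '", bad, "' in MSA '", x$msa_id,
         "' consists entirely of gaps; its path would be empty")
  }
  edges <- unique(cbind(from = from, to = to))
  names(labels) <- as.character(seq_len(nid))
  names(column_of) <- names(labels)
  names(paths) <- x$row_names
  new_protein_graph(x$msa_id, labels, edges, paths, column_of)
}

n_nodes <- function(g) length(g$labels)

node_ids <- function(g) seq_len(length(g$labels))

adjacency <- function(g, reverse = FALSE) {
  adj <- vector("list", n_nodes(g))
  for (i in seq_along(adj)) adj[[i]] <- integer(0)
  e <- g$edges
  if (nrow(e)) {
    a <- if (reverse) e[, "to"] else e[, "from"]
    b <- if (reverse) e[, "from"] else e[, "to"]
    sp <- split(b, a)
    for (k in names(sp)) adj[[as.integer(k)]] <- sort(unique(sp[[k]]))
  }
  adj
}

#' Topologically sort a protein graph
#'
#' Kahn's algorithm with the smallest node id chosen first among available
#' nodes, giving a deterministic order. Errors if the edge relation has a
#' cycle.
#' @param g a `protein_graph`.
#' @return integer vector of node ids in topological order.
#' @export
topological_sort <- function(g) {
  nn <- n_nodes(g)
  indeg <- integer(nn)
  e <- g$edges
  if (nrow(e)) {
    t <- tabulate(e[, "to"], nbins = nn)
    indeg <- t
  }
  adj <- adjacency(g)
  avail <- sort(which(indeg == 0L))
  out <- integer(0)
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(out) != nn) stop("graph '", g$graph_id, "' contains a cycle")
  out
}

#' Spell a path: concatenate node labels in path order
#' @param g a `protein_graph`.
#' @param path_name name of the path (an MSA row name).
#' @return the spelled sequence (equals the degapped MSA row).
#' @export
spell_path <- function(g, path_name) {
  p <- g$paths[[path_name]]
  if (is.null(p)) stop("no path named '", path_name, "' in graph ", g$graph_id)
  paste(g$labels[p], collapse = "")
}

# Sorted vector of path indices traversing each node.
node_path_sets <- function(g) {
  sets <- vector("list", n_nodes(g))
  for (i in seq_along(sets)) sets[[i]] <- integer(0)
  for (pi in seq_along(g$paths)) {
    for (v in unique(g$paths[[pi]])) sets[[v]] <- c(sets[[v]], pi)
  }
  lapply(sets, sort)
}

#' Compact linear stretches of a protein graph
#'
#' Merges runs of adjacent nodes where the upstream node has out-degree one,
#' the downstream node has in-degree one, and the identical set of paths
#' traverses both nodes. The path-set condition preserves the path records:
#' without it, a merged node could swallow the start or end of some sequence,
#' which would then no longer be expressible as a node path. Labels are
#' concatenated, node ids renumbered consecutively, and paths rewritten; the
#' operation is idempotent and spelling any path is unchanged.
#'
#' @param g a `protein_graph` (freshly built or already compacted).
#' @return the compacted `protein_graph`.
#' @export
compact_graph <- function(g) {
  nn <- n_nodes(g)
  if (nn == 0L) return(g)
  e <- g$edges
  outdeg <- tabulate(e[, "from"], nbins = nn)
  indeg <- tabulate(e[, "to"], nbins = nn)
  psets <- node_path_sets(g)
  nxt <- rep(NA_integer_, nn)   # nxt[u] = v when the pair (u,v) is mergeable
  prv <- rep(NA_integer_, nn)
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      u <- e[r, "from"]; v <- e[r, "to"]
      if (outdeg[u] == 1L && indeg[v] == 1L && identical(psets[[u]], psets[[v]])) {
        nxt[u] <- v; prv[v] <- u
      }
    }
  }
  topo <- topological_sort(g)
  # chains: heads are nodes with no mergeable predecessor, walked via nxt
  group <- integer(nn)
  new_labels <- character(0)
  new_cols <- integer(0)
  gid <- 0L
  for (v in topo) {
    if (!is.na(prv[v])) next
    gid <- gid + 1L
    lab <- g$labels[[v]]
    u <- v
    group[u] <- gid
    while (!is.na(nxt[u])) {
      u <- nxt[u]
      group[u] <- gid
      lab <- paste0(lab, g$labels[[u]])
    }
    new_labels[gid] <- lab
    new_cols[gid] <- if (is.null(g$column_of)) NA_integer_ else g$column_of[[v]]
  }
  names(new_labels) <- as.character(seq_len(gid))
  new_edges <- empty_edges()
  if (nrow(e)) {
    gf <- group[e[, "from"]]; gt <- group[e[, "to"]]
    keep <- gf != gt
    new_edges <- unique(cbind(from = gf[keep], to = gt[keep]))
  }
  new_paths <- lapply(g$paths, function(p) {
    gp <- group[p]
    gp[c(TRUE, gp[-1L] != gp[-length(gp)])]
  })
  cols <- if (is.null(g$column_of)) NULL else stats::setNames(new_cols, names(new_labels))
  new_protein_graph(g$graph_id, new_labels, new_edges, new_paths, cols)
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("protein_graph '", x$graph_id, "': ", n_nodes(x), " nodes, ",
      nrow(x$edges), " edges, ", length(x$paths), " paths\n", sep = "")
  invisible(x)
}
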