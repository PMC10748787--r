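# GFA1 reading/writing. Dialect: S-lines carry the node id (decimal string)
# and label; L-lines always use '+' orientations and a 0M overlap (nodes do
# not overlap by construction); P-lines carry one degapped MSA row each, as
# comma-separated "id+" steps with '*' overlaps.

#' Write a protein graph as GFA1
#'
#' @param g a `protein_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(g, path) {
  stopifnot(inherits(g, "protein_graph"))
  lines <- c("H\tVN:Z:1.0")
  ids <- node_ids(g)
  lines <- c(lines, sprintf("S\t%d\t%s", ids, unname(g$labels[ids])))
  e <- g$edges
  if (nrow(e)) {
    o <- order(e[, "from"], e[, "to"])
    lines <- c(lines, sprintf("L\t%d\t+\t%d\t+\t0M", e[o, "from"], e[o, "to"]))
  }
  for (nm in names(g$paths)) {
    steps <- paste0(g$paths[[nm]], "+", collapse = ",")
    lines <- c(lines, sprintf("P\t%s\t%s\t*", nm, steps))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein graph from GFA1
#'
#' Segment names must be decimal integers (the dialect written by
#' [write_gfa()]). Graphs with cycles are rejected because the aligner
#' requires a DAG. A file without P-lines parses with a warning and empty
#' paths. Column provenance is not encoded in GFA, so `column_of` is `NULL`
#' on the returned graph.
#'
#' @param path path to a GFA1 file.
#' @param graph_id identifier for the graph; defaults to the file stem.
#' @return a `protein_graph`.
#' @export
read_gfa <- function(path, graph_id = file_stem(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(fields, `[[`, "", 1L)
  labels <- character(0)
  for (f in fields[types == "S"]) {
    id <- suppressWarnings(as.integer(f[[2L]]))
    if (is.na(id)) stop("non-integer segment name '", f[[2L]], "' in ", path)
    labels[as.character(id)] <- toupper(f[[3L]])
  }
  if (!length(labels)) stop("no S-lines in ", path)
  ids <- as.integer(names(labels))
  if (!setequal(ids, seq_len(max(ids))) || min(ids) != 1L) {
    stop("segment ids in ", path, " are not consecutive integers starting at 1")
  }
  labels <- labels[as.character(seq_len(max(ids)))]
  from <- integer(0); to <- integer(0)
  for (f in fields[types == "L"]) {
    from <- c(from, as.integer(f[[2L]]))
    to <- c(to, as.integer(f[[4L]]))
  }
  edges <- unique(cbind(from = from, to = to))
  paths <- list()
  for (f in fields[types == "P"]) {
    steps <- strsplit(f[[3L]], ",", fixed = TRUE)[[1L]]
    paths[[f[[2L]]]] <- as.integer(sub("[+-]$", "", steps))
  }
  if (!length(paths)) {
    warning("no P-lines in ", path, "; graph has no paths")
  }
  g <- new_protein_graph(graph_id, labels, edges, paths, NULL)
  topological_sort(g)  # errors on cycles
  g
}

#' Structural equality of two protein graphs
#'
#' Compares node labels, edges and paths (and ignores column provenance,
#' which GFA does not carry). Used for write/read round-trip checks.
#' @param g1,g2 `protein_graph` objects.
#' @return logical.
#' @export
graphs_identical <- function(g1, g2) {
  ord <- function(e) e[order(e[, "from"], e[, "to"]), , drop = FALSE]
  identical(unname(g1$labels), unname(g2$labels)) &&
    identical(unname(ord(g1$edges)), unname(ord(g2$edges))) &&
    identical(lapply(g1$paths, as.integer), lapply(g2$paths, as.integer))
}
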