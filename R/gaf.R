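# GAF (graph alignment format) output. One tab-separated record per reported
# alignment: the 12 standard columns plus typed tags for score, identity,
# graph id, frame, frameshift count and CIGAR.

#' Format one alignment as a GAF record
#'
#' Columns: query name, query length, query start, query end (0-based
#' half-open), strand, path (`>id>id...`; orientations are always `>` in a
#' DAG), path length, path start, path end, residue matches, alignment block
#' length, mapping quality (255 = unavailable). Tags: `AS:i` score, `id:f`
#' identity, `gi:Z` graph id, `fr:Z` frame, `fs:i` frameshift count, `bt:A`
#' best-alignment flag, `cg:Z` CIGAR.
#'
#' @param aln a `graph_alignment`.
#' @param best flag marking the query's overall best alignment.
#' @return a single GAF line (no newline).
#' @export
gaf_record <- function(aln, best = FALSE) {
  stopifnot(inherits(aln, "graph_alignment"))
  paste(aln$query_name, aln$query_len,
        aln$query_interval[1L], aln$query_interval[2L],
        aln$strand,
        paste0(">", aln$node_path, collapse = ""),
        aln$path_len, aln$path_interval[1L], aln$path_interval[2L],
        aln$matches, aln$block_len, 255L,
        paste0("AS:i:", aln$score),
        paste0("id:f:", sprintf("%.6g", aln$identity)),
        paste0("gi:Z:", aln$graph_id),
        paste0("fr:Z:", aln$frame),
        paste0("fs:i:", aln$frameshift_count),
        paste0("bt:A:", if (best) "1" else "0"),
        paste0("cg:Z:", aln$cigar),
        sep = "\t")
}

#' Write alignments to a GAF file
#'
#' Records are sorted by query name and then graph id so that output is
#' byte-identical across runs; each query's highest-scoring alignment is
#' flagged `bt:A:1`.
#'
#' @param alns list of `graph_alignment` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(alns, path) {
  if (!length(alns)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qn <- vapply(alns, `[[`, "", "query_name")
  gi <- vapply(alns, `[[`, "", "graph_id")
  sc <- vapply(alns, function(a) as.numeric(a$score), 0)
  best <- logical(length(alns))
  for (q in unique(qn)) {
    sel <- which(qn == q)
    best[sel[which.max(sc[sel])]] <- TRUE
  }
  o <- order(qn, gi, method = "radix")
  writeLines(vapply(seq_along(alns),
                    function(i) gaf_record(alns[[i]], best = best[i]),
                    "")[o],
             path)
  invisible(path)
}
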