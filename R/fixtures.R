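# Deterministic synthetic panproteomes and queries. Families are simulated
# directly in alignment coordinates (mutations, deletions and insertion
# columns applied to a common ancestor), so no external alignment tool is
# ever needed and an identical spec reproduces identical fixtures.

#' Specification of a synthetic panproteome fixture
#'
#' @param seed RNG seed; identical specs produce identical fixtures.
#' @param n_families number of protein families (MSAs).
#' @param rows_per_family sequences per family.
#' @param length ungapped ancestor length (residues).
#' @param sub_rate per-residue substitution probability per row.
#' @param gap_open per-row probability of one deletion and of one insertion
#'   event (event lengths geometric with mean 2, capped at 5).
#' @param queries_per_family queries sampled per family.
#' @param dna_indels single-nucleotide indels planted per DNA query.
#' @param indel_spacing minimum nucleotide distance between planted indels;
#'   defaults to 3k+1 positions for seed length k so that seeding survives.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_families = 5L, rows_per_family = 4L,
                         length = 60L, sub_rate = 0.05, gap_open = 0.1,
                         queries_per_family = 2L, dna_indels = 0L,
                         indel_spacing = 16L) {
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 rows_per_family = as.integer(rows_per_family),
                 length = as.integer(length), sub_rate = sub_rate,
                 gap_open = gap_open,
                 queries_per_family = as.integer(queries_per_family),
                 dna_indels = as.integer(dna_indels),
                 indel_spacing = as.integer(indel_spacing)),
            class = "fixture_spec")
}

with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Simulate one protein family as an MSA
#'
#' An ancestor sequence is drawn from `alphabet` and each row is a mutated
#' copy: substitutions per column at `sub_rate`, at most one deletion and one
#' insertion event per row at probability `gap_open` each. Insertions become
#' extra alignment columns that are gaps in every other row, so the result is
#' a valid alignment by construction. Rows that would lose every residue are
#' never produced (event lengths are capped well below the ancestor length).
#'
#' @param spec a [fixture_spec]; the family is drawn with `spec$seed`
#'   combined with `family_id`.
#' @param family_id identifier (and MSA id) such as `"fam1"`.
#' @param alphabet residue alphabet to draw from; restricting different
#'   families to disjoint alphabets guarantees they share no k-mers.
#' @return an [msa] object.
#' @export
make_family <- function(spec, family_id = "fam1", alphabet = AA20) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_rng_seed(spec$seed + 1000L * sum(utf8ToInt(family_id)) %% 100000L, {
    L <- spec$length
    n <- spec$rows_per_family
    anc <- sample(alphabet, L, replace = TRUE)
    rows <- matrix(rep(anc, each = n), nrow = n)
    for (i in seq_len(n)) {
      subst <- which(stats::runif(L) < spec$sub_rate)
      for (j in subst) {
        alt <- setdiff(alphabet, rows[i, j])
        if (length(alt)) rows[i, j] <- sample(alt, 1L)
      }
      if (stats::runif(1L) < spec$gap_open && L > 10L) {
        len <- min(5L, 1L + stats::rgeom(1L, 0.5))
        at <- sample.int(L - len, 1L)
        rows[i, at:(at + len - 1L)] <- GAP_CHAR
      }
    }
    # insertion events: extra columns, gap in every other row
    ins <- list()
    for (i in seq_len(n)) {
      if (stats::runif(1L) < spec$gap_open) {
        len <- min(5L, 1L + stats::rgeom(1L, 0.5))
        ins[[length(ins) + 1L]] <-
          list(row = i, at = sample.int(L, 1L),
               chars = sample(alphabet, len, replace = TRUE))
      }
    }
    if (length(ins)) {
      ord <- order(vapply(ins, `[[`, 0L, "at"), decreasing = TRUE)
      for (ev in ins[ord]) {
        block <- matrix(GAP_CHAR, nrow = n, ncol = length(ev$chars))
        block[ev$row, ] <- ev$chars
        rows <- cbind(rows[, seq_len(ev$at), drop = FALSE], block,
                      rows[, -seq_len(ev$at), drop = FALSE])
      }
    }
    msa(apply(rows, 1L, paste, collapse = ""),
        row_names = paste0(family_id, "_r", seq_len(n)),
        msa_id = family_id)
  })
}

#' Simulate a panproteome of disjoint families
#'
#' Families draw from pairwise disjoint residue alphabets
#' (`floor(20 / n_families)` letters each, at least 3), so no two families
#' share any k-mer and every query's true source is unambiguous ground
#' truth.
#'
#' @param spec a [fixture_spec] (`n_families <= 6` for disjoint alphabets).
#' @return named list of [msa] objects.
#' @export
make_panproteome <- function(spec) {
  nf <- spec$n_families
  size <- max(3L, 20L %/% nf)
  if (nf * size > 20L) stop("too many families for disjoint alphabets")
  lapply(stats::setNames(seq_len(nf), paste0("fam", seq_len(nf))), function(f) {
    ab <- AA20[((f - 1L) * size + 1L):(f * size)]
    make_family(spec, paste0("fam", f), alphabet = ab)
  })
}

# One codon per amino acid (a fixed, frequent-codon choice) so DNA fixtures
# are deterministic; every codon translates back to its amino acid under the
# standard code.
BACK_CODON <- c(A = "GCG", R = "CGT", N = "AAC", D = "GAT", C = "TGC",
                Q = "CAG", E = "GAA", G = "GGC", H = "CAT", I = "ATT",
                L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
                S = "AGC", T = "ACC", W = "TGG", Y = "TAT", V = "GTG",
                "*" = "TAA", X = "NNN")

#' Back-translate an amino-acid sequence with a fixed codon table
#' @param aa amino-acid string.
#' @return DNA string three times as long.
#' @export
back_translate <- function(aa) {
  chars <- strsplit(toupper(aa), "")[[1L]]
  codons <- BACK_CODON[chars]
  if (anyNA(codons)) {
    stop("cannot back-translate symbol(s): ",
         paste(unique(chars[is.na(codons)]), collapse = " "))
  }
  paste(codons, collapse = "")
}

#' Plant single-nucleotide indels into a DNA sequence
#'
#' Indel positions are spaced at least `spacing` nucleotides apart and kept
#' away from the sequence ends; each indel is an insertion (random base) or a
#' deletion with equal probability.
#'
#' @param dna DNA string.
#' @param n number of indels.
#' @param spacing minimum distance between indel positions.
#' @return list with `dna` (mutated sequence) and `events` (data.frame of
#'   position and type).
#' @export
plant_indels <- function(dna, n, spacing = 16L) {
  chars <- strsplit(dna, "")[[1L]]
  L <- length(chars)
  if (n == 0L) {
    return(list(dna = dna, events = data.frame(pos = integer(0),
                                               type = character(0))))
  }
  lo <- max(6L, spacing); hi <- L - max(6L, spacing)
  if (hi - lo < (n - 1L) * spacing) stop("sequence too short to plant ", n,
                                         " indels ", spacing, " nt apart")
  repeat {
    pos <- sort(sample(lo:hi, n))
    if (n == 1L || all(diff(pos) > spacing)) break
  }
  type <- sample(c("ins", "del"), n, replace = TRUE)
  for (i in rev(seq_len(n))) {
    if (type[i] == "ins") {
      chars <- append(chars, sample(c("A", "C", "G", "T"), 1L), after = pos[i])
    } else {
      chars <- chars[-pos[i]]
    }
  }
  list(dna = paste(chars, collapse = ""),
       events = data.frame(pos = pos, type = type))
}

#' Sample labelled queries from a panproteome
#'
#' Picks rows from each family as amino-acid queries (the degapped row) and
#' produces matching DNA queries by fixed-codon back-translation with
#' `spec$dna_indels` planted single-nucleotide indels. Each query records its
#' source family, giving ground truth for wrong-alignment counting.
#'
#' @param msas named list of [msa] objects.
#' @param spec a [fixture_spec].
#' @return list with `aa` (named character), `dna` (named character) and
#'   `truth` (data.frame: query, source, n_indels).
#' @export
make_queries <- function(msas, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_rng_seed(spec$seed + 777L, {
    aa <- character(0); dna <- character(0)
    truth <- data.frame(query = character(0), source = character(0),
                        n_indels = integer(0))
    for (x in msas) {
      rows <- degap_rows(x)
      take <- sample(names(rows), min(spec$queries_per_family, length(rows)))
      for (nm in take) {
        qname <- paste0("q_", nm)
        aa[qname] <- unname(rows[nm])
        pl <- plant_indels(back_translate(rows[nm]), spec$dna_indels,
                           spec$indel_spacing)
        dna[qname] <- pl$dna
        truth <- rbind(truth, data.frame(query = qname, source = x$msa_id,
                                         n_indels = nrow(pl$events)))
      }
    }
    list(aa = aa, dna = dna, truth = truth)
  })
}

write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Materialize a fixture set on disk
#'
#' Writes one aligned FASTA per family under `out_dir/msas/`, amino-acid and
#' DNA query FASTAs, and a ground-truth TSV. Driven by a YAML spec file from
#' the command line, or directly by a [fixture_spec].
#'
#' @param spec a [fixture_spec], or the path of a YAML file whose keys are
#'   [fixture_spec()] arguments.
#' @param out_dir output directory.
#' @return invisibly, the list of paths written.
#' @export
run_fixtures <- function(spec, out_dir) {
  if (is.character(spec)) {
    spec <- do.call(fixture_spec, yaml::read_yaml(spec))
  }
  stopifnot(inherits(spec, "fixture_spec"))
  msa_dir <- file.path(out_dir, "msas")
  dir.create(msa_dir, showWarnings = FALSE, recursive = TRUE)
  msas <- make_panproteome(spec)
  msa_paths <- vapply(names(msas), function(nm) {
    write_msa_fasta(msas[[nm]], file.path(msa_dir, paste0(nm, ".fa")))
  }, "")
  q <- make_queries(msas, spec)
  aa_path <- write_fasta(q$aa, file.path(out_dir, "queries_aa.fa"))
  dna_path <- write_fasta(q$dna, file.path(out_dir, "queries_dna.fa"))
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(q$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(msas = msa_paths, queries_aa = aa_path,
                 queries_dna = dna_path, truth = truth_path))
}
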