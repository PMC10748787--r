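cfg <- align_config()

test_that("the DP layout wires predecessor columns along graph edges", {
  g1 <- compact_graph(build_graph_from_msa(msa("MT")))
  lay <- graph_layout(g1)
  expect_equal(lay$target, "MT")
  expect_equal(lay$preds[[1]], integer(0))
  expect_equal(lay$preds[[2]], 1L)

  # two parallel nodes joining into one: the join's first column has two
  # predecessor columns
  gd <- compact_graph(build_graph_from_msa(msa(c("MAE-Q", "MA-TQ"))))
  layd <- graph_layout(gd)
  join <- which(strsplit(layd$target, "")[[1]] == "Q")
  expect_length(layd$preds[[join]], 2L)
})

test_that("a full path spelling aligns back with identity 1 and the self score", {
  gc <- compact_graph(build_graph_from_msa(example_msa()))
  b62 <- load_sub_matrix("BLOSUM62")
  for (nm in c("r1", "r2", "r3")) {
    q <- spell_path(gc, nm)
    a <- align_protein(q, gc, cfg)
    expect_equal(a$identity, 1)
    expect_equal(a$node_path, gc$paths[[nm]])
    qc <- strsplit(q, "")[[1]]
    expect_equal(a$score, sum(b62[cbind(qc, qc)]))
    expect_equal(a$query_interval, c(0L, nchar(q)))
    expect_equal(a$frameshift_count, 0L)
  }
})

test_that("on a single-node graph the DP reduces to classical Smith-Waterman", {
  withr::local_seed(19)
  for (trial in 1:40) {
    target <- random_aa(sample(5:20, 1))
    query <- random_aa(sample(3:15, 1))
    g <- compact_graph(build_graph_from_msa(msa(target, msa_id = "single")))
    a <- align_protein(query, g, cfg)
    want <- sw_score(query, target, cfg)
    expect_equal(if (is.null(a)) 0 else a$score, want)
  }
})

test_that("graph DP score equals the best classical score over all spelled paths", {
  withr::local_seed(23)
  for (trial in 1:150) {
    g <- random_dag(max_nodes = 8)
    query <- random_aa(sample(4:12, 1))
    a <- align_protein(query, g, cfg)
    got <- if (is.null(a)) 0 else a$score
    want <- max(0, vapply(all_path_spellings(g), sw_score, 0,
                          query = query, cfg = cfg))
    expect_equal(got, want)
  }
})

test_that("extending the target graph never decreases the local score", {
  withr::local_seed(29)
  for (trial in 1:20) {
    base <- random_aa(10)
    query <- random_aa(8)
    g1 <- compact_graph(build_graph_from_msa(msa(base)))
    g2 <- compact_graph(build_graph_from_msa(msa(paste0(base, random_aa(4)))))
    s1 <- align_protein(query, g1, cfg)
    s2 <- align_protein(query, g2, cfg)
    expect_gte(if (is.null(s2)) 0 else s2$score,
               if (is.null(s1)) 0 else s1$score)
  }
})

test_that("six-frame translation follows the standard code", {
  expect_equal(unname(translate_six_frames("ATGGAA")["+1"]), "ME")
  expect_equal(translate_dna("ATGGA"), "M")   # partial codon dropped
  expect_equal(translate_dna("ATGTAAANN"), "M*X")
  expect_error(translate_six_frames("ATGU"), "non-nucleotide")
  # frames of the reverse complement are the minus frames
  withr::local_seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  f1 <- translate_six_frames(s); f2 <- translate_six_frames(rc)
  expect_equal(unname(f1[c("-1", "-2", "-3")]), unname(f2[c("+1", "+2", "+3")]))
})

test_that("an exact back-translated path aligns like its protein and shifts count", {
  gc <- compact_graph(build_graph_from_msa(example_msa()))
  q <- spell_path(gc, "r3")
  dna <- back_translate(q)
  ap <- align_protein(q, gc, cfg)
  ad <- align_dna_frameshift(dna, gc, cfg)
  expect_equal(ad$identity, 1)
  expect_equal(ad$node_path, ap$node_path)
  expect_equal(ad$score, ap$score)
  expect_equal(ad$frameshift_count, 0L)
  expect_equal(ad$strand, "+")
})

test_that("single-node frameshift DP equals the literal sequence recurrence", {
  withr::local_seed(37)
  for (trial in 1:25) {
    prot <- random_aa(sample(6:14, 1))
    g <- compact_graph(build_graph_from_msa(msa(prot, msa_id = "single")))
    dna0 <- back_translate(random_aa(sample(8:12, 1)))
    for (q in 0:2) {
      dna <- if (q == 0) dna0 else plant_indels(dna0, q, spacing = 7)$dna
      a <- align_dna_frameshift(dna, g, cfg, strands = "+")
      want <- fs_dp_literal(dna, prot, cfg)
      expect_equal(if (is.null(a)) 0 else a$score, want$score)
      if (!is.null(a)) {
        expect_equal(a$frameshift_count, want$n_frameshifts)
      }
    }
  }
})

test_that("one planted indel produces exactly one penalized jump", {
  gc <- compact_graph(build_graph_from_msa(example_msa()))
  dna <- back_translate(spell_path(gc, "r3"))
  clean <- align_dna_frameshift(dna, gc, cfg)
  withr::local_seed(41)
  ins <- plant_indels(dna, 1, spacing = 6)
  a <- align_dna_frameshift(ins$dna, gc, cfg)
  expect_equal(a$frameshift_count, 1L)
  # literal recurrence: the jump replaces that codon's substitution score
  lit <- fs_dp_literal(ins$dna, spell_path(gc, "r3"), cfg)
  expect_equal(a$score, lit$score)
  expect_lt(a$score, clean$score)
})

test_that("candidate graphs are ranked by pooled seed hits and truncated", {
  idx <- structure(list(params = seed_params(k = 3, mode = "kmer"),
                        seed_limit = 0L,
                        entries = list(MEP = "m1", EPT = "m1", PTP = "m1",
                                       TPA = "m1", PAC = "m3")),
                   class = "seed_index")
  q <- "MEPTPAC"   # 5 seeds: 4 hit m1, 1 hits m3
  expect_equal(select_candidates(q, idx, align_limit = 1), "m1")
  expect_equal(select_candidates(q, idx, align_limit = 0), c("m1", "m3"))
  expect_equal(select_candidates("WWWWWW", idx), character(0))
})

test_that("identity counts identical columns over all alignment columns", {
  mk <- function(cigar) {
    structure(list(cigar = cigar), class = "graph_alignment")
  }
  expect_equal(compute_identity(mk("10=")), 1)
  expect_equal(compute_identity(mk("5=5X")), 0.5)
  expect_equal(compute_identity(mk("4=1X4=1D")), 0.8)
})

test_that("identity and coverage thresholds filter alignments", {
  g <- compact_graph(build_graph_from_msa(msa("MSETQSTQ")))
  q <- "MSEWQSTQ"   # internal mismatch: the local optimum spans all 8 columns
  expect_null(align_protein(q, g, align_config(min_identity = 0.95)))
  expect_s3_class(align_protein(q, g, align_config(min_identity = 0.8)),
                  "graph_alignment")
  ragged <- "QSTWWWWWW"   # only a third of the query can align
  expect_null(align_protein(ragged, g, align_config(min_len_frac = 0.9)))
  expect_s3_class(align_protein(ragged, g, align_config(min_len_frac = 0.2)),
                  "graph_alignment")
})
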