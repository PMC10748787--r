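test_that("graph construction follows the column rule on worked examples", {
  g <- build_graph_from_msa(example_msa())
  # one node per (column, distinct non-gap character)
  expect_equal(length(g$labels), 15L)
  # the gap in row 2 is bridged: its T (0-based column 3) connects straight
  # to its M (column 6)
  has_edge <- any(apply(g$edges, 1, function(e) {
    g$labels[e[1]] == "T" && g$column_of[e[1]] == 3L &&
      g$labels[e[2]] == "M" && g$column_of[e[2]] == 6L
  }))
  expect_true(has_edge)

  g1 <- build_graph_from_msa(msa("MT"))
  expect_equal(length(g1$labels), 2L)
  expect_equal(nrow(g1$edges), 1L)
  expect_equal(length(g1$paths[[1]]), 2L)

  # shared M, distinct A/G: 3 nodes, 2 edges, 2 paths
  g2 <- build_graph_from_msa(msa(c("MA", "MG")))
  expect_equal(length(g2$labels), 3L)
  expect_equal(nrow(g2$edges), 2L)
  expect_equal(length(g2$paths), 2L)

  expect_error(build_graph_from_msa(msa(c("MA", "--"))), "entirely of gaps")
})

test_that("compaction merges exactly the stretches the paths allow", {
  gc <- compact_graph(build_graph_from_msa(example_msa()))
  expect_true("PTPE" %in% gc$labels)
  expect_equal(unname(vapply(names(gc$paths), function(nm) spell_path(gc, nm), "")),
               c("MEPTPEQ", "TMA", "MSETQSTQ"))

  # path constraint: the four-node linear stretch M-T-Q-T cannot merge fully
  gc2 <- compact_graph(build_graph_from_msa(msa(c("MTQT", "--QT", "MT--"))))
  expect_setequal(unname(gc2$labels), c("MT", "QT"))
  expect_equal(spell_path(gc2, "seq2"), "QT")
  expect_equal(spell_path(gc2, "seq3"), "MT")

  gc3 <- compact_graph(build_graph_from_msa(msa("MEPT")))
  expect_equal(unname(gc3$labels), "MEPT")
})

test_that("round-trip, DAG and idempotence hold on random fixtures", {
  withr::local_seed(7)
  for (trial in 1:25) {
    spec <- fixture_spec(seed = trial, n_families = 1L,
                         rows_per_family = 5L, length = 50L,
                         sub_rate = 0.1, gap_open = 0.3)
    x <- make_family(spec, "fam")
    g <- build_graph_from_msa(x)
    gc <- compact_graph(g)
    expect_silent(topological_sort(g))
    expect_silent(topological_sort(gc))
    rows <- degap_rows(x)
    for (nm in names(rows)) {
      expect_equal(spell_path(g, nm), unname(rows[nm]))
      expect_equal(spell_path(gc, nm), unname(rows[nm]))
    }
    # counts never increase under compaction, and compaction is idempotent
    expect_lte(length(gc$labels), length(g$labels))
    expect_lte(nrow(gc$edges), nrow(g$edges))
    for (nm in names(rows)) {
      expect_lte(length(gc$paths[[nm]]), length(g$paths[[nm]]))
    }
    gcc <- compact_graph(gc)
    expect_true(graphs_identical(gc, gcc))
    # every edge lies on at least one path
    on_path <- unique(do.call(rbind, lapply(gc$paths, function(p) {
      if (length(p) < 2) return(NULL)
      cbind(p[-length(p)], p[-1])
    })))
    expect_equal(nrow(gc$edges), nrow(on_path))
  }
})

test_that("GFA write/read is the identity on the stated dialect", {
  gc <- compact_graph(build_graph_from_msa(msa("MT", msa_id = "one")))
  tf <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(gc, tf)
  lines <- readLines(tf)
  expect_equal(sum(startsWith(lines, "S")), 1L)
  expect_equal(sum(startsWith(lines, "L")), 0L)
  expect_equal(sum(startsWith(lines, "P")), 1L)

  ge <- compact_graph(build_graph_from_msa(example_msa()))
  write_gfa(ge, tf)
  back <- read_gfa(tf)
  expect_true(graphs_identical(ge, back))
  expect_equal(unname(vapply(names(back$paths),
                             function(nm) spell_path(back, nm), "")),
               c("MEPTPEQ", "TMA", "MSETQSTQ"))

  withr::local_seed(11)
  spec <- fixture_spec(seed = 3L, n_families = 1L, rows_per_family = 5L,
                       length = 50L, sub_rate = 0.15, gap_open = 0.3)
  g <- compact_graph(build_graph_from_msa(make_family(spec, "rand")))
  write_gfa(g, tf)
  expect_true(graphs_identical(g, read_gfa(tf)))
})

test_that("GFA reader rejects cycles and warns on missing paths", {
  tf <- withr::local_tempfile(fileext = ".gfa")
  writeLines(c("H\tVN:Z:1.0", "S\t1\tMA", "S\t2\tTC",
               "L\t1\t+\t2\t+\t0M", "L\t2\t+\t1\t+\t0M",
               "P\tp1\t1+,2+\t*"), tf)
  expect_error(read_gfa(tf), "cycle")
  writeLines(c("H\tVN:Z:1.0", "S\t1\tMA", "S\t2\tTC",
               "L\t1\t+\t2\t+\t0M"), tf)
  expect_warning(g <- read_gfa(tf), "P-lines")
  expect_equal(length(g$paths), 0L)
})
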