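test_that("dot-bracket parsing assigns arms and round-trips", {
  # canonical three-hairpin cloverleaf
  db <- "(((((((..(((.....))).(((((.......))))).....((((.....)))))))))))."
  seq <- strrep("A", nchar(db))
  st <- parse_structure_string(seq, db)
  expect_equal(nrow(st$aa_stem), 7)
  expect_equal(nrow(st$dhu_stem), 3)
  expect_equal(nrow(st$ac_stem), 5)
  expect_equal(nrow(st$tpsic_stem), 4)
  expect_false(st$degenerate_dhu)
  expect_equal(format_dotbracket(st), db)

  # two hairpins: D-arm replaced by a loop
  db2 <- "(((((((..........(((((.......)))))....((((.....)))))))))))."
  st2 <- parse_structure_string(strrep("A", nchar(db2)), db2)
  expect_true(st2$degenerate_dhu)
  expect_equal(nrow(st2$dhu_stem), 0)
  expect_equal(format_dotbracket(st2), db2)

  expect_error(parse_structure_string("AAAA", "((.."), "unbalanced")
  expect_error(parse_structure_string("AAAA", "))(("), "unbalanced")
})

test_that("folding recovers planted structures and mismatches exactly", {
  sim <- shared_sim()
  g <- sim$genome
  ft <- feature_table(g)
  for (tr in names(sim$truth$trna_structures)) {
    s <- extract_gene_sequence(g, tr)
    st <- fold_cloverleaf(s, ft$anticodon[match(tr, ft$gene)])
    expect_identical(format_dotbracket(st),
                     format_dotbracket(sim$truth$trna_structures[[tr]]),
                     label = paste("structure of", tr))
    expect_equal(nrow(count_mismatches(st, s)),
                 unname(sim$truth$trna_mismatch_counts[[tr]]),
                 label = paste("mismatch count of", tr))
    expect_equal(st$degenerate_dhu, tr %in% c("trnV", "trnS1"))
  }
})

test_that("folding is deterministic and validates its inputs", {
  sim <- shared_sim()
  s <- extract_gene_sequence(sim$genome, "trnA")
  a <- fold_cloverleaf(s, "TGC")
  b <- fold_cloverleaf(s, "TGC")
  expect_identical(format_dotbracket(a), format_dotbracket(b))
  expect_error(fold_cloverleaf(strrep("A", 60), "GGG"), "not found")
  expect_error(fold_cloverleaf(strrep("A", 30), "AAA"))
})

test_that("mismatch census counts non-canonical pairs, accepting G-U wobble", {
  db <- "((.((...)).((...)).))"
  # all-GC stems: nothing to report
  s0 <- "GGAGGAAACCAGGAAACCACC"
  st <- parse_structure_string(s0, db)
  expect_equal(nrow(count_mismatches(st, s0)), 0)
  # one U-U pair in the acceptor stem
  s1 <- "GTAGGAAACCAGGAAACCATC"
  mm <- count_mismatches(st, s1)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$pair, "U-U")
  expect_equal(mm$arm, "AA")
  # G-U wobble is canonical
  s2 <- "GGAGGAAACCAGGAAACTACC"
  expect_equal(nrow(count_mismatches(st, s2)), 0)
})

test_that("per-genome mismatch report mirrors the planted table", {
  sim <- shared_sim()
  rep <- trna_mismatch_report(sim$genome)
  expect_equal(rep$pair[rep$trna == "trnA"], "U-U")
  expect_equal(rep$arm[rep$trna == "trnA"], "AA")
  expect_equal(rep$pair[rep$trna == "trnE"], "A-C")
  expect_equal(rep$arm[rep$trna == "trnE"], "TPsiC")
  expect_equal(rep$arm[rep$trna == "trnW"], "AC")
  expect_setequal(rep$trna, c("trnA", "trnE", "trnW"))
})

test_that("spacer census equals generator truth and conserves length", {
  sim <- shared_sim()
  sc <- spacer_overlap_scan(sim$genome)
  expect_equal(as.data.frame(glance(sc)),
               as.data.frame(sim$truth$spacer_summary))
  recs <- tidy(sc)
  truth_recs <- sim$truth$spacer_records
  expect_equal(recs$upstream, truth_recs$upstream)
  expect_equal(recs$signed_length, truth_recs$signed_length)
  # exact conservation on the circular genome
  ft <- feature_table(sim$genome)
  expect_equal(sum(ft$length) + sum(recs$signed_length),
               nchar(sim$genome$sequence))
  expect_equal(sum(recs$signed_length[recs$signed_length > 0]),
               glance(sc)$total_intergenic_bp)
})

test_that("abutting genes yield a zero-length record", {
  sim <- shared_sim()
  recs <- tidy(spacer_overlap_scan(sim$genome))
  abut <- recs[recs$kind == "abut", ]
  expect_true(nrow(abut) > 0)
  expect_true(all(abut$signed_length == 0))
  expect_true(all(abut$sequence == ""))
})

test_that("junction motifs are found in the planted orientation", {
  sim <- shared_sim()
  sc <- spacer_overlap_scan(sim$genome)
  # atp8/atp6 overlap carries ATGATAA on the J strand
  hits <- find_motif(sc, "ATGATAA", where = "overlaps")
  expect_true(any(hits$upstream == "atp8" & hits$downstream == "atp6" &
                    hits$orientation == "forward"))
  ov <- tidy(sc)
  expect_equal(ov$signed_length[ov$upstream == "atp8"], -7L)
  expect_equal(toupper(ov$sequence[ov$upstream == "atp8"]), "ATGATAA")
  # nad4/nad4l gap carries ATTATAA in the N-strand reading
  hits2 <- find_motif(sc, "ATTATAA", where = "gaps")
  expect_true(any(hits2$upstream == "nad4" & hits2$downstream == "nad4l" &
                    hits2$orientation == "reverse"))
  # absent motif
  expect_equal(nrow(find_motif(sc, "GGGGGGGGGG")), 0)
  # motif equal to the whole gap
  gap <- tidy(sc)
  gap <- gap[gap$upstream == "nad4", ]
  hits3 <- find_motif(sc, revcomp(gap$sequence), where = "gaps")
  expect_true(any(hits3$upstream == "nad4" & hits3$offset == 1))
})
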