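test_that("codon counting reads frame 0, drops partials, tallies stops", {
  cc <- count_codons(list("ATTTTATAA"))
  expect_equal(unname(cc$counts["ATT"]), 1L)
  expect_equal(unname(cc$counts["TTA"]), 1L)
  expect_equal(unname(cc$stop_tally["TAA"]), 1L)
  expect_equal(cc$n_codons_total, 2L)

  cc2 <- count_codons(list("ATGA"))
  expect_equal(unname(cc2$counts["ATG"]), 1L)
  expect_equal(cc2$n_dropped_nt, 1L)
  expect_error(count_codons(list("ATGA"), drop_trailing_partial = FALSE),
               "multiple of 3")

  cc3 <- count_codons(list("ATGNNNAAA"))
  expect_equal(cc3$n_ambiguous, 1L)
  expect_equal(cc3$n_codons_total, 2L)
})

test_that("codon counts on a synthetic genome match an independent recount", {
  sim <- shared_sim()
  pcgs <- intersect(names(sim$truth$gene_seq), mitocomp:::MITO_PCGS)
  seqs <- unlist(sim$truth$gene_seq[pcgs])
  cc <- count_codons(seqs)
  # independent recount from the truth sequences
  expected <- table(factor(unlist(lapply(seqs, function(s) {
    n <- nchar(s) %/% 3
    cods <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
    if (cods[length(cods)] %in% c("TAA", "TAG")) cods <- cods[-length(cods)]
    cods
  })), levels = names(cc$counts)))
  expect_equal(unname(cc$counts), as.integer(expected))
  expect_equal(cc$n_codons_total,
               sum(cc$counts[mitocomp:::sense_codons()]))
})

test_that("RSCU obeys the family-sum law and flags missing codons", {
  counts <- stats::setNames(integer(64), names(mito_genetic_code()))
  counts["TTT"] <- 3L
  counts["TTC"] <- 1L
  tbl <- rscu(counts)
  expect_equal(tbl$rscu[tbl$codon == "TTT"], 1.5)
  expect_equal(tbl$rscu[tbl$codon == "TTC"], 0.5)

  # single codon of a 4-fold box takes the whole family weight
  counts2 <- stats::setNames(integer(64), names(mito_genetic_code()))
  counts2["GGA"] <- 10L
  tbl2 <- rscu(counts2)
  expect_equal(tbl2$rscu[tbl2$codon == "GGA"], 4)
  expect_equal(tbl2$rscu[tbl2$codon == "GGC"], 0)
  expect_true(tbl2$missing[tbl2$codon == "GGC"])

  # family-sum law on random count tables
  set.seed(7)
  for (rep in 1:5) {
    counts3 <- stats::setNames(
      as.integer(rpois(64, 20)), names(mito_genetic_code()))
    tbl3 <- rscu(counts3)
    sums <- tapply(tbl3$rscu, tbl3$amino_acid, sum)
    sizes <- tapply(tbl3$family_size, tbl3$amino_acid, unique)
    used <- tapply(tbl3$count, tbl3$amino_acid, sum) > 0
    expect_equal(as.numeric(sums[used]), as.numeric(sizes[used]))
    # weighted mean RSCU over sense codons of used families is exactly 1
    w <- tbl3$count > -1 & used[tbl3$amino_acid]
    expect_equal(mean(tbl3$rscu[w]), 1, tolerance = 1e-12)
  }

  # zero-usage family is undefined, not zero
  counts4 <- stats::setNames(integer(64), names(mito_genetic_code()))
  tbl4 <- rscu(counts4)
  expect_true(all(is.na(tbl4$rscu)))
  expect_s3_class(plot_rscu(rscu(count_codons(
    list("ATTTTAGGATTTATATTA")))), "ggplot")
})

test_that("uniform usage within every family gives RSCU 1 everywhere", {
  counts <- stats::setNames(rep(2L, 64), names(mito_genetic_code()))
  tbl <- rscu(counts)
  expect_true(all(abs(tbl$rscu - 1) < 1e-12))
})

test_that("start/stop classification handles complete, incomplete and abnormal cases", {
  sim <- shared_sim()
  rep <- classify_terminal_codons(sim$genome)
  expect_equal(nrow(rep), 13)
  expect_true(all(rep$start_class == "ATN"))
  expect_equal(rep$stop_class[rep$gene == "nad5"], "incomplete")
  expect_equal(rep$stop_codon[rep$gene == "nad5"], "T")
  expect_true(all(rep$stop_class[rep$gene != "nad5"] == "complete"))
  expect_true(all(rep$stop_codon[rep$gene != "nad5"] == "TAA"))
})

test_that("abnormal GTG start is classified as abnormal", {
  sim <- shared_sim()
  g <- sim$genome
  ft <- feature_table(g)
  row <- which(ft$gene == "atp8")
  s <- g$sequence
  # atp8 is J-strand in the ancestral arrangement: patch its first codon
  substr(s, ft$start[row] + 1, ft$start[row] + 3) <- "GTG"
  g2 <- new_mitogenome(g$accession, g$organism, s, g$topology, g$features)
  rep <- classify_terminal_codons(g2)
  expect_equal(rep$start_class[rep$gene == "atp8"], "abnormal")
  expect_equal(rep$start_codon[rep$gene == "atp8"], "GTG")
})

test_that("amino-acid usage ranks the A/T-rich codons first", {
  counts <- stats::setNames(integer(64), names(mito_genetic_code()))
  counts[c("TTA", "ATT", "TTT", "ATA")] <- c(40L, 35L, 30L, 25L)
  counts[c("GGA", "CCA")] <- c(5L, 4L)
  usage <- amino_acid_usage(counts)
  expect_equal(usage$amino_acid[1:4], c("L", "I", "F", "M"))
  expect_equal(sum(usage$frequency), 1)
  empty <- amino_acid_usage(stats::setNames(integer(64),
                                            names(mito_genetic_code())))
  expect_equal(nrow(empty), 0)
})
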