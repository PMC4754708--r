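test_that("codon-position splitting and re-interleaving are inverse", {
  aln <- c(t1 = "ATGCCCAAA", t2 = "ATACCTAAG")
  parts <- split_codon_positions(aln)
  expect_equal(parts$pos1, c(t1 = "ACA", t2 = "ACA"))
  expect_equal(parts$pos2, c(t1 = "TCA", t2 = "TCA"))
  expect_equal(parts$pos3, c(t1 = "GCA", t2 = "ATG"))
  rebuilt <- vapply(names(aln), function(tx) {
    ch <- character(9)
    ch[seq(1, 9, 3)] <- strsplit(parts$pos1[[tx]], "")[[1]]
    ch[seq(2, 9, 3)] <- strsplit(parts$pos2[[tx]], "")[[1]]
    ch[seq(3, 9, 3)] <- strsplit(parts$pos3[[tx]], "")[[1]]
    paste(ch, collapse = "")
  }, character(1))
  expect_equal(rebuilt, aln)
  # gap-only codon distributes its gaps positionally
  g <- split_codon_positions(c(t1 = "---AAA"))
  expect_equal(g$pos2[["t1"]], "-A")
  expect_error(split_codon_positions(c(t1 = "ATGC")), "multiple of 3")
})

test_that("translation follows the invertebrate mitochondrial code", {
  expect_equal(translate_alignment(c(t1 = "ATAGGG"))[["t1"]], "MG")
  expect_equal(translate_alignment(c(t1 = "------"))[["t1"]], "--")
  expect_equal(translate_alignment(c(t1 = "TGAAGA"))[["t1"]], "WS")
  out <- translate_alignment(c(t1 = "TAAATG"))
  expect_equal(out[["t1"]], "-M")
  expect_equal(attr(out, "internal_stops")$codon_index, 1L)
  # planted CDS translates to the expected peptide
  p <- simulate_codon_pair(50, omega = 0.5, t = 0, seed = 2)
  code <- Biostrings::getGeneticCode("5")
  cods <- substring(p$cds1, seq(1, 150, 3), seq(3, 150, 3))
  expect_equal(translate_alignment(stats::setNames(p$cds1, "x"))[["x"]],
               paste(code[cods], collapse = ""))
})

test_that("matrix variants satisfy their structural identities", {
  ga <- toy_gene_alignments()
  p123 <- build_matrix(ga, "P123")
  aa <- build_matrix(ga, "AA")
  p123r <- build_matrix(ga, "P123R")
  p12t <- build_matrix(ga, "P12T")
  # nucleotide sites are exactly three times the amino-acid sites
  expect_equal(p123$n_sites, 3 * aa$n_sites)
  # P123R adds the RNA genes
  expect_equal(p123r$n_sites,
               p123$n_sites + nchar(ga$rrnS[[1]]) + nchar(ga$trnF[[1]]))
  # default exclusions remove every PCG third position and the rRNAs
  expect_equal(p12t$n_sites,
               p123r$n_sites - p123$n_sites / 3 - nchar(ga$rrnS[[1]]))
  # charsets tile the matrix without overlap, for every variant
  for (m in list(p123, p123r, p12t, aa)) {
    cols <- sort(mitocomp:::charset_columns(m$charsets))
    expect_equal(cols, seq_len(m$n_sites))
    expect_equal(unique(nchar(m$seqs)), m$n_sites)
  }
})

test_that("taxa missing a gene are gap-filled, not dropped", {
  ga <- toy_gene_alignments()
  ga$nad2 <- ga$nad2[c("tax_a", "tax_b")]
  m <- build_matrix(ga, "P123")
  expect_setequal(names(m$seqs), c("tax_a", "tax_b", "tax_c", "tax_d"))
  cs <- m$charsets
  nad2_cols <- cs[cs$partition == "nad2_p1", ]
  block <- substr(m$seqs[["tax_c"]], nad2_cols$start - 0, nad2_cols$end)
  expect_true(grepl("^-+$", gsub("[^-]", "x", block)) || all(
    strsplit(substr(m$seqs[["tax_c"]], nad2_cols$start, nad2_cols$end),
             "")[[1]] == "-"))
})

test_that("exclusion of tRNAs and unknown partitions behave as configured", {
  ga <- toy_gene_alignments()
  names(ga)[names(ga) == "trnF"] <- "trnI"
  m <- build_matrix(ga, "P123R")  # trnI excluded by default
  expect_false("trnI" %in% m$charsets$partition)
  ga2 <- toy_gene_alignments()
  expect_error(build_matrix(ga2, "P12T", exclusions = "nope_p9"),
               "unknown partition")
})

test_that("NEXUS export round-trips and carries the charset block", {
  ga <- toy_gene_alignments()
  m <- build_matrix(ga, "P123")
  f <- withr::local_tempfile(fileext = ".nex")
  export_matrix(m, f, format = "NEXUS")
  txt <- readLines(f)
  expect_equal(sum(grepl("^  charset ", txt)), nrow(m$charsets))
  cs1 <- m$charsets[1, ]
  expect_true(any(grepl(sprintf("charset %s = %d-%d\\\\3;", cs1$partition,
                                cs1$start, cs1$end), txt)))
  back <- ape::read.nexus.data(f)
  expect_setequal(names(back), names(m$seqs))
  expect_equal(toupper(paste(back[["tax_a"]], collapse = "")),
               m$seqs[["tax_a"]])
  # byte-stable output
  f2 <- withr::local_tempfile(fileext = ".nex")
  export_matrix(m, f2, format = "NEXUS")
  expect_identical(readLines(f), readLines(f2))
})

test_that("PHYLIP/FASTA exports and the RAxML partition file are well-formed", {
  ga <- toy_gene_alignments()
  m <- build_matrix(ga, "P123")
  f <- withr::local_tempfile(fileext = ".phy")
  pf <- withr::local_tempfile(fileext = ".part")
  export_matrix(m, f, format = "PHYLIP", partition_path = pf)
  head <- strsplit(readLines(f)[1], " ")[[1]]
  expect_equal(as.integer(head), c(length(m$seqs), m$n_sites))
  part <- readLines(pf)
  expect_equal(length(part), nrow(m$charsets))
  # codon partition uses the stride-3 range syntax
  cs1 <- m$charsets[1, ]
  expect_true(any(grepl(sprintf("^DNA, %s = %d-%d\\\\3$", cs1$partition,
                                cs1$start, cs1$end), part)))
  fa <- withr::local_tempfile(fileext = ".fasta")
  map <- export_matrix(m, fa, format = "FASTA")
  expect_equal(map$original, map$sanitized)  # nothing to sanitize here
  expect_equal(sum(startsWith(readLines(fa), ">")), length(m$seqs))
  # awkward taxon names get sanitized with a mapping
  m2 <- m
  names(m2$seqs)[1] <- "Taxon one (type)"
  map2 <- export_matrix(m2, fa, format = "FASTA")
  expect_false(map2$sanitized[1] == map2$original[1])
})

test_that("saturation screen distinguishes low and high divergence", {
  seeds <- 1:6
  lo <- vapply(seeds, function(s) {
    saturation_scan(simulate_k80_alignment(8, 1200, 0.05, seed = s))$slope
  }, numeric(1))
  hi <- lapply(seeds, function(s) {
    saturation_scan(simulate_k80_alignment(8, 1200, 2.0, seed = s))
  })
  expect_true(all(lo >= 0.9 & lo <= 1.0))
  for (i in seq_along(seeds)) {
    expect_true(hi[[i]]$saturated)
    expect_true(is.na(hi[[i]]$slope) || hi[[i]]$slope < lo[i])
  }
})

test_that("pairwise distances agree with the reference implementation", {
  a <- simulate_k80_alignment(6, 800, 0.3, seed = 12)
  r <- saturation_scan(a)
  bin <- ape::as.DNAbin(t(sapply(a, function(s) strsplit(tolower(s),
                                                         "")[[1]])))
  k80 <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  raw <- as.matrix(ape::dist.dna(bin, model = "raw",
                                 pairwise.deletion = TRUE))
  for (i in seq_len(nrow(r$pairs))) {
    expect_equal(r$pairs$corrected_distance[i],
                 k80[r$pairs$taxon_a[i], r$pairs$taxon_b[i]],
                 tolerance = 1e-12)
    expect_equal(r$pairs$p_distance[i],
                 raw[r$pairs$taxon_a[i], r$pairs$taxon_b[i]],
                 tolerance = 1e-12)
  }
  # corrected distance never falls below the observed distance
  expect_true(all(r$pairs$corrected_distance >=
                    r$pairs$p_distance - 1e-12, na.rm = TRUE))
})

test_that("identical sequences give zero distances and no flag", {
  a <- stats::setNames(rep(strrep("ACGT", 50), 4), paste0("t", 1:4))
  r <- saturation_scan(a)
  expect_true(all(r$pairs$p_distance == 0))
  expect_true(is.na(r$slope))
  expect_false(r$saturated)
  expect_s3_class(plot_saturation(r), "ggplot")
})
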