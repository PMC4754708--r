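test_that("gene-name canonicalization maps common synonyms", {
  expect_equal(canonicalize_gene_name("COI"), "cox1")
  expect_equal(canonicalize_gene_name("COIII"), "cox3")
  expect_equal(canonicalize_gene_name("ND4L"), "nad4l")
  expect_equal(canonicalize_gene_name("cytochrome b"), "cob")
  expect_equal(canonicalize_gene_name("16S ribosomal RNA"), "rrnL")
  expect_equal(canonicalize_gene_name("12S"), "rrnS")
  expect_equal(canonicalize_gene_name("tRNA-Trp"), "trnW")
  expect_equal(canonicalize_gene_name("tRNA-Leu", anticodon = "UAG"), "trnL1")
  expect_equal(canonicalize_gene_name("tRNA-Leu", anticodon = "taa"), "trnL2")
  expect_equal(canonicalize_gene_name("tRNA-Ser", anticodon = "GCT"), "trnS1")
  expect_equal(canonicalize_gene_name("tRNA-Ser", anticodon = "UGA"), "trnS2")
  expect_equal(canonicalize_gene_name("tRNA-Leu"), "trnL")  # ambiguous
  expect_true(is.na(canonicalize_gene_name("hypothetical protein")))
})

test_that("GenBank write -> read round-trips a synthetic genome exactly", {
  sim <- shared_sim()
  g <- sim$genome
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, f)
  g2 <- expect_no_warning(read_genbank(f))
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$accession, g$accession)
  expect_identical(g2$features$gene, g$features$gene)
  expect_identical(g2$features$strand, g$features$strand)
  expect_identical(g2$features$start, g$features$start)
  expect_identical(g2$features$end, g$features$end)
  expect_true(g2$sequenced_complete)
  expect_equal(nrow(feature_table(g2)), 38)
})

test_that("extraction returns sense-strand sequence and handles strands", {
  ft <- tibble::tibble(
    gene = c("cox1", "trnC"), label = c("cox1", "trnC"),
    class = c("PCG", "tRNA"), strand = c("J", "N"),
    start = c(10L, 30L), end = c(16L, 36L), length = c(6L, 6L),
    anticodon = c(NA, "GCA"), note = "",
    intervals = list(cbind(10L, 16L), cbind(30L, 36L)))
  seq <- paste(rep("C", 50), collapse = "")
  substr(seq, 11, 16) <- "ATGTTT"
  substr(seq, 31, 36) <- "AAACAT"
  g <- new_mitogenome("SYNTEST1", "Synthetica exempli", seq, "circular", ft)
  expect_equal(extract_gene_sequence(g, "cox1"), "ATGTTT")
  expect_equal(extract_gene_sequence(g, "trnC"), revcomp("AAACAT"))
  expect_equal(revcomp(revcomp("AAACAT")), "AAACAT")
  expect_true(is.na(extract_gene_sequence(g, "nad2")))
})

test_that("origin-spanning features concatenate tail and head slices", {
  ft <- tibble::tibble(
    gene = c("cox1", "trnA"), label = c("cox1", "trnA"),
    class = c("PCG", "tRNA"), strand = c("J", "J"),
    start = c(34L, 10L), end = c(6L, 16L), length = c(12L, 6L),
    anticodon = c(NA, NA), note = "",
    intervals = list(rbind(cbind(34L, 40L), cbind(0L, 6L)),
                     cbind(10L, 16L)))
  seq <- paste(c(rep("G", 34), rep("A", 6)), collapse = "")
  g <- new_mitogenome("SYNTEST2", "Synthetica exempli", seq, "circular", ft)
  expect_equal(extract_gene_sequence(g, "cox1"),
               paste0(strrep("A", 6), strrep("G", 6)))
  # PCG length equals sum of interval lengths
  expect_equal(nchar(extract_gene_sequence(g, "cox1")), 12)
})

test_that("complement CDS labelled COI resolves to cox1 on the N strand", {
  gb <- c(
    "LOCUS       TESTREC1                 120 bp    DNA     circular INV 01-JAN-2026",
    "ACCESSION   TESTREC1",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "                     /organism=\"Synthetica exempli\"",
    "     CDS             complement(10..45)",
    "                     /gene=\"COI\"",
    "     tRNA            50..110",
    "                     /product=\"tRNA-Trp\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//")
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, f)
  g <- read_genbank(f)
  ft <- feature_table(g)
  expect_equal(ft$gene[1], "cox1")
  expect_equal(ft$strand[1], "N")
  expect_equal(ft$start[1], 9L)  # 0-based half-open conversion
  expect_equal(ft$end[1], 45L)
  expect_equal(ft$gene[2], "trnW")
})

test_that("ambiguous serine tRNA is assigned positionally and flagged", {
  sim <- shared_sim()
  g <- sim$genome
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, f)
  lines <- readLines(f)
  # strip trnS1's anticodon qualifier and relabel ambiguously
  i <- grep("/gene=\"trnS1\"", lines)
  lines[i] <- sub("trnS1", "trnS", lines[i])
  lines <- lines[-(i + 2L)]  # drop its anticodon line
  writeLines(lines, f)
  g2 <- read_genbank(f)
  ft <- feature_table(g2)
  row <- which(ft$label == "trnS")
  expect_equal(ft$gene[row], "trnS1")  # sits between trnN and trnE
  expect_match(ft$note[row], "inferred")
})

test_that("records with no recognizable genes are rejected", {
  gb <- c("LOCUS       BAD                   40 bp    DNA     linear INV 01-JAN-2026",
          "ACCESSION   BAD",
          "FEATURES             Location/Qualifiers",
          "     misc_feature    1..10",
          "                     /note=\"mystery\"",
          "ORIGIN",
          "        1 acgtacgtac acgtacgtac acgtacgtac acgtacgtac",
          "//")
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, f)
  expect_error(suppressWarnings(read_genbank(f)), "no recognized")
})

test_that("feature TSV and per-gene FASTA exports are consistent", {
  sim <- shared_sim()
  g <- sim$genome
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(g, tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), nrow(feature_table(g)))
  expect_equal(tab$length, tab$end - tab$start)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_gene_fasta(g, fa, genes = c("cox1", "trnW"))
  lines <- readLines(fa)
  expect_equal(sum(startsWith(lines, ">")), 2)
  expect_equal(lines[2], extract_gene_sequence(g, "cox1"))
})
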