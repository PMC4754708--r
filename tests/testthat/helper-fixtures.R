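# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# A default synthetic genome with planted mismatches, degenerate D-arms
# and an incomplete stop, reused across test files.
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_mitogenome(simulation_spec(
      seed = 101,
      trna_mismatches = list(
        trnA = list(list(arm = "AA", index = 3, pair = c("U", "U"))),
        trnE = list(list(arm = "TPsiC", index = 2, pair = c("A", "C"))),
        trnW = list(list(arm = "AC", index = 2, pair = c("U", "U")))),
      degenerate_dhu = c("trnV", "trnS1"),
      incomplete_stop = "nad5"))
  }
  .fixture_env$sim
}

# Small per-gene "alignments" for matrix building: identical-length
# sequences with a few planted substitutions, no real alignment needed.
toy_gene_alignments <- function(seed = 5) {
  set.seed(seed)
  taxa <- c("tax_a", "tax_b", "tax_c", "tax_d")
  mutate_seq <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(ch), k)
    ch[idx] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  make_gene <- function(len, stops_ok = FALSE) {
    base <- simulate_codon_pair(len %/% 3, omega = 0.5, t = 0,
                                seed = sample.int(1e6, 1))$cds1
    seqs <- vapply(seq_along(taxa), function(i) mutate_seq(base, 6),
                   character(1))
    names(seqs) <- taxa
    seqs
  }
  list(cox1 = make_gene(90), nad2 = make_gene(60), atp8 = make_gene(48),
       rrnS = {
         s <- paste(sample(c("A", "C", "G", "T"), 70, replace = TRUE),
                    collapse = "")
         out <- vapply(seq_along(taxa), function(i) mutate_seq(s, 5),
                       character(1))
         names(out) <- taxa
         out
       },
       trnF = {
         s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                    collapse = "")
         out <- vapply(seq_along(taxa), function(i) mutate_seq(s, 3),
                       character(1))
         names(out) <- taxa
         out
       })
}
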