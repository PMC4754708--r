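test_that("the ancestral arrangement constant is well-formed", {
  anc <- ancestral_insect_order()
  expect_equal(nrow(anc), 38)
  expect_setequal(anc$gene, canonical_gene_names())
  expect_equal(anc$sign[anc$gene == "trnW"], 1L)
  expect_equal(anc$sign[anc$gene == "trnC"], -1L)
  expect_equal(anc$sign[anc$gene == "trnY"], -1L)
  # rotation-invariant identity
  rot <- mitocomp:::new_gene_order(c(anc$gene[10:38], anc$gene[1:9]),
                                   c(anc$sign[10:38], anc$sign[1:9]))
  expect_equal(breakpoint_distance(anc, rot), 0)
  expect_equal(compare_to_ancestor(rot, anc)$n_events, 0)
})

test_that("gene order extraction recovers the generator's order", {
  sim <- shared_sim()
  go <- extract_gene_order(sim$genome)
  truth <- sim$truth$order
  expect_equal(go$gene, truth$gene)
  expect_equal(go$sign, truth$sign)
})

test_that("missing genes are reported absent, never rearranged", {
  sim <- simulate_mitogenome(simulation_spec(
    seed = 33, omit = c("trnI", "trnQ", "trnM")))
  go <- extract_gene_order(sim$genome)
  expect_setequal(attr(go, "missing"), c("trnI", "trnQ", "trnM"))
  expect_false(any(c("trnI", "trnQ", "trnM") %in% go$gene))
  rep <- compare_to_ancestor(go)
  expect_equal(rep$n_events, 0)
  expect_false(any(c("trnI", "trnQ", "trnM") %in% rep$status$gene))
})

test_that("rearrangement events permute orders as defined", {
  anc <- ancestral_insect_order()
  expect_equal(apply_rearrangement(anc, list()), anc)
  # two successive swaps restore the original
  ev <- list(list(type = "translocation", gene = "trnW", after = "trnC"))
  back <- list(list(type = "translocation", gene = "trnW", after = "nad2"))
  o <- apply_rearrangement(apply_rearrangement(anc, ev), back)
  expect_equal(o$gene, anc$gene)
  expect_equal(o$sign, anc$sign)
  # in-place inversion is an involution
  inv <- list(list(type = "inversion", gene = "cox1"))
  o2 <- apply_rearrangement(apply_rearrangement(anc, inv), inv)
  expect_equal(o2$sign, anc$sign)
  expect_error(
    apply_rearrangement(anc, list(list(type = "translocation",
                                       gene = "trnW", after = "trnW"))),
    "destination")
  expect_error(
    apply_rearrangement(anc, list(list(type = "translocation",
                                       gene = "trnX2", after = "nad2"))),
    "unknown gene")
})

test_that("the sawfly-style trnC/trnY relocation is classified exactly", {
  anc <- ancestral_insect_order()
  ev <- list(list(type = "translocation", gene = "trnC", after = "AT_rich"),
             list(type = "remote_inversion", gene = "trnY",
                  after = "AT_rich"))
  o <- apply_rearrangement(anc, ev)
  # order now runs trnY(J), trnC(N), trnI, nad2 around the circle
  n <- nrow(o)
  i <- match("trnY", o$gene)
  circ <- function(k) ((i + k - 1L) %% n) + 1L
  expect_equal(o$gene[c(circ(0), circ(1), circ(2))],
               c("trnY", "trnC", "trnI"))
  expect_equal(o$sign[circ(0)], 1L)   # strand switched by the remote inversion
  expect_equal(o$sign[circ(1)], -1L)  # translocation keeps the strand
  rep <- compare_to_ancestor(o)
  st <- rep$status
  expect_equal(st$status[st$gene == "trnC"], "translocated")
  expect_equal(st$status[st$gene == "trnY"], "remote_inverted")
  expect_true(all(st$status[!st$gene %in% c("trnC", "trnY")] == "in_place"))
  expect_equal(rep$n_events, 2)
  expect_gte(rep$breakpoint_count, 2)
})

test_that("single events and disjoint event pairs round-trip exactly", {
  anc <- ancestral_insect_order()
  genes <- setdiff(anc$gene, "AT_rich")
  n <- nrow(anc)
  far_destinations <- function(g) {
    i <- match(g, anc$gene)
    near <- anc$gene[((i - 3):(i + 2)) %% n + 1]
    setdiff(genes, c(near, g))
  }
  set.seed(99)
  types <- c("translocation", "remote_inversion", "inversion")
  status_of <- c(translocation = "translocated",
                 remote_inversion = "remote_inverted",
                 inversion = "inverted_in_place")
  # single events
  for (k in 1:30) {
    type <- sample(types, 1)
    g <- sample(genes, 1)
    ev <- list(list(type = type, gene = g,
                    after = if (type == "inversion") NULL
                            else sample(far_destinations(g), 1)))
    rep <- compare_to_ancestor(apply_rearrangement(anc, ev))
    expect_equal(rep$status$status[rep$status$gene == g],
                 unname(status_of[type]))
    expect_true(all(rep$status$status[rep$status$gene != g] == "in_place"))
    expect_equal(rep$n_events, 1)
  }
  # disjoint event pairs: distinct genes, distant destinations
  for (k in 1:20) {
    gs <- sample(genes, 2)
    evs <- lapply(gs, function(g) {
      type <- sample(types, 1)
      dest <- setdiff(far_destinations(g), gs)
      list(type = type, gene = g,
           after = if (type == "inversion") NULL else sample(dest, 1))
    })
    wanted <- stats::setNames(
      vapply(evs, function(e) unname(status_of[e$type]), character(1)), gs)
    rep <- compare_to_ancestor(apply_rearrangement(anc, evs))
    got <- stats::setNames(rep$status$status, rep$status$gene)
    expect_equal(got[gs], wanted)
    expect_true(all(got[setdiff(genes, gs)] == "in_place"))
  }
})

test_that("breakpoint distance agrees with the adjacency oracle", {
  set.seed(123)
  for (k in 1:100) {
    a <- random_gene_order(10)
    b <- mitocomp:::new_gene_order(sample(a$gene),
                                   sample(c(-1L, 1L), 10, replace = TRUE))
    expect_equal(breakpoint_distance(a, b), oracle_breakpoints(a, b))
  }
})

test_that("breakpoint distance satisfies identity, symmetry and the reversal convention", {
  set.seed(5)
  for (k in 1:20) {
    a <- random_gene_order(8)
    b <- mitocomp:::new_gene_order(sample(a$gene),
                                   sample(c(-1L, 1L), 8, replace = TRUE))
    expect_equal(breakpoint_distance(a, a), 0)
    expect_equal(breakpoint_distance(a, b), breakpoint_distance(b, a))
    mirror <- mitocomp:::new_gene_order(rev(a$gene), -rev(a$sign))
    expect_equal(breakpoint_distance(a, mirror), 0)
  }
  expect_error(breakpoint_distance(random_gene_order(5), random_gene_order(4)),
               "gene sets differ")
})

test_that("report accessors expose per-gene status and summary", {
  rep <- compare_to_ancestor(ancestral_insect_order())
  expect_equal(nrow(tidy(rep)), 38)
  gl <- glance(rep)
  expect_equal(gl$n_events, 0)
  expect_equal(gl$breakpoint_count, 0)
  expect_equal(gl$n_in_place, 38)
})
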