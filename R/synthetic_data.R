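# Synthetic annotated mitogenomes with full ground truth.
#
# The generator emulates the structure of a sawfly-like insect
# mitochondrial genome: 37 genes plus an A+T-rich region in a controllable
# circular order, strongly A+T-biased composition (defaults mirror
# published Symphyta protein-coding values, A+T about 79%), PCGs with ATN
# starts and TAA stops (optionally truncated to an incomplete T at a
# junction abutting the next gene), tRNAs built from planted cloverleaf
# structures with a controllable mismatch list, the characteristic 7-bp
# "ATGATAA" overlap between atp8 and atp6, and a junction plan of gaps,
# overlaps and abutments with known totals. A fixed integer seed drives
# one pseudo-random stream; per-gene sub-streams are derived by fixed
# offsets so truths do not depend on generation order.

DEFAULT_PCG_LENGTHS <- c(
  cox1 = 1539L, cox2 = 684L, cox3 = 789L, cob = 1140L, nad1 = 936L,
  nad2 = 1023L, nad3 = 354L, nad4 = 1341L, nad4l = 291L, nad5 = 1716L,
  nad6 = 525L, atp6 = 678L, atp8 = 162L)

DEFAULT_REGION_LENGTHS <- c(rrnL = 1350L, rrnS = 800L, AT_rich = 400L)

# Per-region base-composition targets (percent A, C, G, T).
DEFAULT_COMPOSITION <- list(
  PCG = c(A = 35.2, C = 10.4, G = 10.3, T = 44.1),
  rRNA = c(A = 44, C = 7, G = 9, T = 40),
  AT_rich = c(A = 43, C = 8, G = 7, T = 42),
  spacer = c(A = 43, C = 8, G = 7, T = 42))

#' Default junction plan for synthetic genomes
#'
#' Gaps, overlaps and abutments planted at ancestral-arrangement
#' junctions: the 7-bp atp8/atp6 overlap carrying the "ATGATAA" motif, a
#' 2-bp rrnL/trnV overlap, a 7-bp nad4/nad4l gap carrying "ATTATAA" in the
#' N-strand reading, a long cox3/trnG spacer, and a few short gaps.
#' Junctions not listed abut directly.
#'
#' @return Tibble: upstream, downstream, signed_length, motif.
#' @export
default_spacer_plan <- function() {
  tibble::tibble(
    upstream = c("atp8", "rrnL", "nad4", "cox3", "trnE", "nad3", "cob",
                 "rrnS"),
    downstream = c("atp6", "trnV", "nad4l", "trnG", "trnF", "trnA", "trnS2",
                   "AT_rich"),
    signed_length = c(-7L, -2L, 7L, 27L, 2L, 5L, 17L, 12L),
    motif = c("ATGATAA", NA, "TTATAAT", NA, NA, NA, NA, NA))
}

#' Specification for a synthetic mitogenome
#'
#' @param seed Integer seed driving all randomness.
#' @param events Rearrangement events applied to the ancestral order (see
#'   [apply_rearrangement()]); recorded in the truth.
#' @param omit Canonical gene names left unsequenced (absent, never
#'   imputed), e.g. `c("trnI", "trnQ", "trnM")`.
#' @param pcg_lengths Named lengths (nt, multiples of 3) of the 13 PCGs.
#' @param region_lengths Named lengths of rrnL, rrnS, AT_rich.
#' @param composition Per-region base-composition targets (percent
#'   A/C/G/T summing to 100) for `PCG`, `rRNA`, `AT_rich`, `spacer`.
#' @param spacer_plan Junction plan tibble (see [default_spacer_plan()]).
#' @param incomplete_stop Genes whose terminal TAA is truncated to a bare
#'   T abutting the downstream feature.
#' @param trna_mismatches Named list: per tRNA, a list of planted
#'   mismatches, each `list(arm =, index =, pair = c(b1, b2))` with `arm`
#'   in AA/DHU/AC/TPsiC, `index` the pair position from the stem's outer
#'   end, and `pair` the two bases (RNA alphabet).
#' @param degenerate_dhu tRNAs whose D-arm is replaced by a plain loop.
#' @param accession,organism Identifiers written into the record (clearly
#'   synthetic by default).
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            events = list(),
                            omit = character(0),
                            pcg_lengths = DEFAULT_PCG_LENGTHS,
                            region_lengths = DEFAULT_REGION_LENGTHS,
                            composition = DEFAULT_COMPOSITION,
                            spacer_plan = default_spacer_plan(),
                            incomplete_stop = character(0),
                            trna_mismatches = list(),
                            degenerate_dhu = character(0),
                            accession = "SYN000001",
                            organism = "Synthetica exempli") {
  for (r in names(composition)) {
    if (abs(sum(composition[[r]]) - 100) > 1e-9) {
      stop("composition percentages for ", r, " do not sum to 100",
           call. = FALSE)
    }
  }
  stopifnot(all(pcg_lengths > 0), all(region_lengths > 0))
  bad <- names(pcg_lengths)[pcg_lengths %% 3L != 0L]
  bad <- setdiff(bad, incomplete_stop)
  if (length(bad)) {
    stop("PCG lengths must be multiples of 3 (", paste(bad, collapse = ", "),
         ")", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), events = events, omit = omit,
                 pcg_lengths = pcg_lengths, region_lengths = region_lengths,
                 composition = composition, spacer_plan = spacer_plan,
                 incomplete_stop = incomplete_stop,
                 trna_mismatches = trna_mismatches,
                 degenerate_dhu = degenerate_dhu,
                 accession = accession, organism = organism),
            class = "simulation_spec")
}

# Fixed per-gene sub-seed: independent of generation order.
sub_seed <- function(seed, key) {
  offset <- match(key, c(canonical_gene_names(), "spacer", "layout"))
  (as.integer(seed) %% 1000003L) * 1013L + offset * 7919L
}

# Exact-composition random sequence: multiset of bases matching the target
# percentages (largest-remainder rounding), shuffled.
composition_multiset <- function(n, target) {
  p <- target[c("A", "C", "G", "T")] / 100
  base_counts <- floor(n * p)
  rem <- n - sum(base_counts)
  if (rem > 0) {
    frac <- n * p - base_counts
    add <- order(-frac)[seq_len(rem)]
    base_counts[add] <- base_counts[add] + 1
  }
  sample(rep(c("A", "C", "G", "T"), times = base_counts))
}

# Remove in-frame stop codons from a character vector of bases by swapping
# the stop's middle base with a compatible position (composition-preserving).
remove_frame_stops <- function(ch, protect = integer(0)) {
  n_cod <- length(ch) %/% 3L
  for (pass in 1:25) {
    dirty <- FALSE
    for (k in seq_len(n_cod)) {
      i <- 3L * k - 2L
      if (any(i:(i + 2L) %in% protect)) next
      cod <- paste(ch[i:(i + 2L)], collapse = "")
      if (cod %in% c("TAA", "TAG")) {
        cand <- setdiff(which(ch != ch[i + 1L]), protect)
        if (!length(cand)) break
        j <- cand[sample.int(length(cand), 1L)]
        tmp <- ch[i + 1L]; ch[i + 1L] <- ch[j]; ch[j] <- tmp
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  ch
}

generate_pcg <- function(gene, len, target, incomplete, seed) {
  set.seed(sub_seed(seed, gene))
  full_len <- if (incomplete) len + 2L else len
  stopifnot(full_len %% 3L == 0L, full_len >= 12L)
  ch <- composition_multiset(full_len, target)
  start <- c("ATT", "ATA", "ATG")[sample.int(3L, 1L)]
  ch[1:3] <- seq_chars(start)
  if (gene == "atp6") {
    # head carries the atp8/atp6 "ATGATAA" overlap motif in frame:
    # ATG | ATA | A.. (Met, Met, then an A-initial codon, never a stop)
    ch[1:7] <- seq_chars("ATGATAA")
  }
  if (gene == "atp8") {
    # tail carries the atp8/atp6 "ATGATAA" overlap motif in frame:
    # ... ATA | TGA | TAA (Met, Trp, stop)
    ch[(full_len - 8L):full_len] <- seq_chars("ATATGATAA")
    protect <- c(1:3, (full_len - 8L):full_len)
  } else {
    ch[(full_len - 2L):full_len] <- c("T", "A", "A")
    protect <- c(1:7, (full_len - 2L):full_len)
  }
  ch <- remove_frame_stops(ch, protect = protect)
  s <- paste(ch, collapse = "")
  if (incomplete) s <- substr(s, 1L, len)
  s
}

generate_plain_region <- function(gene, len, target, seed) {
  set.seed(sub_seed(seed, gene))
  paste(composition_multiset(len, target), collapse = "")
}

# ---------------------------------------------------------------------------
# tRNA construction from a planted cloverleaf plan

# Stem 5' arms use fixed, shift-unique G/C patterns and every loop/spacer
# base is A: since A pairs only with T/U (absent outside anticodons and
# planted acceptor-stem mismatches), the planted arrangement is the unique
# score optimum of the structure search and fold round-trips are exact.
STEM_PATTERNS <- list(aa = "GGCGGCC", d3 = "GGC", d4 = "GGGC",
                      ac = "GGGCC", t = "GGGC")

loop_bases <- function(n) rep("A", n)

build_trna <- function(gene, seed, mismatches = list(),
                       degenerate = FALSE) {
  set.seed(sub_seed(seed, gene))
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  aa_n <- 7L
  d_n <- if (degenerate) 0L else sample(3:4, 1L)
  d_loop <- if (degenerate) sample(7:9, 1L) else sample(5:7, 1L)
  ac_n <- 5L
  var_n <- sample(4:6, 1L)
  t_n <- 4L
  t_loop <- sample(5:6, 1L)

  aa5 <- seq_chars(STEM_PATTERNS$aa)
  aa3 <- rev(unname(comp[aa5]))
  d5 <- if (d_n) seq_chars(STEM_PATTERNS[[paste0("d", d_n)]])
        else character(0)
  d3 <- rev(unname(comp[d5]))
  ac5 <- seq_chars(STEM_PATTERNS$ac)
  ac3 <- rev(unname(comp[ac5]))
  t5 <- seq_chars(STEM_PATTERNS$t)
  t3 <- rev(unname(comp[t5]))

  anticodon <- chartr("U", "T", MITO_ANTICODONS[[gene]])
  ac_loop <- c(loop_bases(2L), seq_chars(anticodon), loop_bases(2L))
  s1 <- loop_bases(2L)          # spacer after acceptor 5' arm
  s2 <- loop_bases(1L)          # spacer before anticodon stem
  dl <- loop_bases(d_loop)
  vl <- loop_bases(var_n)
  tl <- loop_bases(t_loop)
  disc <- loop_bases(1L)

  # plant mismatches: set both bases of the chosen stem pair
  arm_sets <- list(AA = list(n = aa_n), DHU = list(n = d_n),
                   AC = list(n = ac_n), TPsiC = list(n = t_n))
  for (mm in mismatches) {
    arm <- match.arg(mm$arm, names(arm_sets))
    k <- mm$index
    nmax <- arm_sets[[arm]]$n
    stopifnot(k >= 1L, k <= max(1L, nmax - 2L))  # interior of the stem
    if (arm == "AC") stopifnot(k >= 2L)  # keep the loop-proximal end clean
    b <- chartr("U", "T", mm$pair)
    if (arm == "AA") { aa5[k] <- b[1]; aa3[aa_n - k + 1L] <- b[2] }
    if (arm == "DHU") { d5[k] <- b[1]; d3[d_n - k + 1L] <- b[2] }
    if (arm == "AC") { ac5[k] <- b[1]; ac3[ac_n - k + 1L] <- b[2] }
    if (arm == "TPsiC") { t5[k] <- b[1]; t3[t_n - k + 1L] <- b[2] }
  }

  ch <- c(aa5, s1, d5, dl, d3, s2, ac5, ac_loop, ac3, vl, t5, tl, t3,
          aa3, disc)
  L <- length(ch)
  # planted structure with absolute positions
  pos <- cumsum(c(0L, lengths(list(aa5, s1, d5, dl, d3, s2, ac5, ac_loop,
                                   ac3, vl, t5, tl, t3, aa3))))
  at <- function(i) pos[i] + 1L
  rng <- function(i, n) if (n) at(i):(at(i) + n - 1L) else integer(0)
  stem <- function(i5, n5, i3) {
    if (!n5) return(stem_matrix(integer(0), integer(0)))
    stem_matrix(rng(i5, n5), rev(rng(i3, n5)))
  }
  structure_truth <- new_cloverleaf(
    aa_stem = stem(1L, aa_n, 14L),
    dhu_stem = stem(3L, d_n, 5L),
    ac_stem = stem(7L, ac_n, 9L),
    tpsic_stem = stem(11L, t_n, 13L),
    dhu_loop = rng(4L, d_loop),
    ac_loop = rng(8L, 7L),
    tpsic_loop = rng(12L, t_loop),
    variable_loop = rng(10L, var_n),
    anticodon_positions = rng(8L, 7L)[3:5],
    length = L, degenerate_dhu = degenerate)
  list(seq = paste(ch, collapse = ""), structure = structure_truth,
       anticodon = anticodon,
       n_mismatches = length(mismatches))
}

# ---------------------------------------------------------------------------

#' Simulate an annotated mitogenome with known truth
#'
#' Deterministic for a fixed seed. The realized base composition of each
#' composition-targeted region (PCGs, rRNAs, A+T-rich, spacers) matches
#' its target up to rounding by construction; tRNA regions are
#' structure-driven and not composition-targeted. The emitted record
#' parses back through [read_genbank()] without warnings.
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `genome` (a `mitogenome`) and `truth`
#'   (class `mito_truth`): `order` (the true `gene_order`), `events`,
#'   `gene_seq` (named list of oriented gene sequences), `trna_structures`,
#'   `trna_mismatch_counts`, `spacer_records`, `spacer_summary`,
#'   `start_codons`, `incomplete_stop`.
#' @export
simulate_mitogenome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  base_order <- ancestral_insect_order()
  order <- apply_rearrangement(base_order, spec$events)
  if (length(spec$omit)) {
    keep <- !(order$gene %in% spec$omit)
    order <- new_gene_order(order$gene[keep], order$sign[keep],
                            missing = spec$omit)
  }
  # rotate so AT_rich closes the circle (no origin-spanning features)
  if ("AT_rich" %in% order$gene) {
    i <- match("AT_rich", order$gene)
    n <- nrow(order)
    idx <- ((i + seq_len(n) - 1L) %% n) + 1L
    order <- new_gene_order(order$gene[idx], order$sign[idx],
                            missing = attr(order, "missing"))
  }

  # per-gene oriented sequences and tRNA truths
  gene_seq <- list(); trna_structures <- list(); trna_mm <- integer(0)
  anticodons <- character(0)
  for (g in order$gene) {
    cls <- gene_class(g)
    if (cls == "PCG") {
      incomplete <- g %in% spec$incomplete_stop
      glen <- unname(spec$pcg_lengths[[g]])
      if (incomplete && glen %% 3L == 0L) glen <- glen - 2L
      gene_seq[[g]] <- generate_pcg(
        g, glen, spec$composition$PCG,
        incomplete = incomplete, seed = spec$seed)
    } else if (cls == "rRNA") {
      gene_seq[[g]] <- generate_plain_region(
        g, unname(spec$region_lengths[[g]]), spec$composition$rRNA,
        spec$seed)
    } else if (cls == "control") {
      gene_seq[[g]] <- generate_plain_region(
        g, unname(spec$region_lengths[["AT_rich"]]),
        spec$composition$AT_rich, spec$seed)
    } else {
      tr <- build_trna(g, spec$seed,
                       mismatches = spec$trna_mismatches[[g]] %||% list(),
                       degenerate = g %in% spec$degenerate_dhu)
      gene_seq[[g]] <- tr$seq
      trna_structures[[g]] <- tr$structure
      trna_mm[g] <- tr$n_mismatches
      anticodons[g] <- tr$anticodon
    }
  }

  # junction plan lookup
  plan <- spec$spacer_plan
  jkey <- paste(plan$upstream, plan$downstream)
  junction <- function(u, v) {
    k <- match(paste(u, v), jkey)
    if (is.na(k)) list(sl = 0L, motif = NA_character_)
    else list(sl = plan$signed_length[k], motif = plan$motif[k])
  }

  set.seed(sub_seed(spec$seed, "layout"))
  genome_chunks <- character(0)
  pos <- 0L
  feats <- empty_features()
  n <- nrow(order)
  spacer_records <- list()
  genomic_seq_of <- function(g) {
    if (order$sign[match(g, order$gene)] > 0) gene_seq[[g]]
    else revcomp(gene_seq[[g]])
  }
  genome_str <- ""
  for (i in seq_len(n)) {
    g <- order$gene[i]
    gs <- genomic_seq_of(g)
    if (i > 1L) {
      u <- order$gene[i - 1L]
      j <- junction(u, g)
      if (j$sl > 0L) {
        sp <- composition_multiset(j$sl, spec$composition$spacer)
        if (!is.na(j$motif) && nchar(j$motif) <= j$sl) {
          off <- sample.int(j$sl - nchar(j$motif) + 1L, 1L)
          sp[off:(off + nchar(j$motif) - 1L)] <- seq_chars(j$motif)
        }
        genome_str <- paste0(genome_str, paste(sp, collapse = ""))
        pos <- pos + j$sl
      } else if (j$sl < 0L) {
        k <- -j$sl
        if (k >= nchar(gs) || k >= nchar(genome_str)) {
          stop("infeasible spacer plan: overlap exceeds gene length",
               call. = FALSE)
        }
        # the upstream feature keeps its coordinates; its tail letters are
        # replaced by the head of the incoming gene
        genome_str <- substr(genome_str, 1L, nchar(genome_str) - k)
        pos <- pos - k
        # patch the stored upstream sequence so truths stay exact
        head_k <- substr(gs, 1L, k)
        us <- gene_seq[[u]]
        if (order$sign[match(u, order$gene)] > 0) {
          gene_seq[[u]] <- paste0(substr(us, 1L, nchar(us) - k), head_k)
        } else {
          gene_seq[[u]] <- paste0(revcomp(head_k), substr(us, k + 1L,
                                                          nchar(us)))
        }
      }
      spacer_records[[length(spacer_records) + 1L]] <- tibble::tibble(
        upstream = u, downstream = g, signed_length = j$sl)
    }
    start <- pos
    genome_str <- paste0(genome_str, gs)
    pos <- pos + nchar(gs)
    cls <- gene_class(g)
    feats <- dplyr::bind_rows(feats, tibble::tibble(
      gene = g, label = g, class = cls,
      strand = if (order$sign[i] > 0) "J" else "N",
      start = start, end = pos, length = nchar(gs),
      anticodon = if (cls == "tRNA") anticodons[[g]] else NA_character_,
      note = "", intervals = list(stem_matrix(start, pos))))
  }
  # closing junction back to the first gene
  jc <- junction(order$gene[n], order$gene[1L])
  if (jc$sl < 0L) stop("infeasible spacer plan: overlap across the origin",
                       call. = FALSE)
  if (jc$sl > 0L) {
    genome_str <- paste0(genome_str,
                         paste(composition_multiset(jc$sl,
                                                    spec$composition$spacer),
                               collapse = ""))
    pos <- pos + jc$sl
  }
  spacer_records[[length(spacer_records) + 1L]] <- tibble::tibble(
    upstream = order$gene[n], downstream = order$gene[1L],
    signed_length = jc$sl)

  feats$intervals <- lapply(seq_len(nrow(feats)), function(i) {
    stem_matrix(feats$start[i], feats$end[i])
  })
  genome <- new_mitogenome(spec$accession, spec$organism, genome_str,
                           "circular", feats)

  recs <- dplyr::bind_rows(spacer_records)
  gaps <- recs$signed_length[recs$signed_length > 0L]
  ovs <- -recs$signed_length[recs$signed_length < 0L]
  longest_idx <- if (length(gaps)) which.max(
    replace(recs$signed_length, recs$signed_length <= 0L, -1L)) else NA
  truth <- structure(list(
    order = order, events = spec$events, gene_seq = gene_seq,
    trna_structures = trna_structures, trna_mismatch_counts = trna_mm,
    spacer_records = recs,
    spacer_summary = tibble::tibble(
      total_intergenic_bp = sum(gaps),
      n_gap_locations = length(gaps),
      longest_gap = if (length(gaps)) max(gaps) else 0L,
      longest_gap_junction = if (length(gaps)) {
        paste(recs$upstream[longest_idx], recs$downstream[longest_idx],
              sep = "/")
      } else NA_character_,
      n_overlaps = length(ovs),
      overlap_min = if (length(ovs)) min(ovs) else NA_integer_,
      overlap_max = if (length(ovs)) max(ovs) else NA_integer_,
      n_abutting = sum(recs$signed_length == 0L)),
    incomplete_stop = spec$incomplete_stop), class = "mito_truth")
  list(genome = genome, truth = truth)
}

# ---------------------------------------------------------------------------

#' Simulate a diverged pair of coding sequences
#'
#' Evolves a daughter CDS from a random ancestor by per-codon Poisson
#' mutation proposals (expected `t` proposals per codon) with a
#' `kappa`-fold transition bias; nonsynonymous proposals are accepted with
#' probability `min(1, omega)` (for `omega > 1` synonymous proposals are
#' thinned by `1/omega` instead); proposals creating a stop codon under
#' the invertebrate mitochondrial code are rejected. Realized accepted
#' synonymous/nonsynonymous event counts are returned as truth.
#'
#' @param n_codons Number of codons.
#' @param omega dN/dS ratio (>= 0).
#' @param t Expected proposed substitutions per codon.
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed.
#' @return List: `cds1`, `cds2`, `true_Sd`, `true_Nd`.
#' @export
simulate_codon_pair <- function(n_codons, omega, t, kappa = 2, seed = 1L) {
  stopifnot(n_codons > 0, omega >= 0, t >= 0, kappa > 0)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  code <- mito_genetic_code()
  sense <- sense_codons()
  # A+T-biased ancestral codon usage, roughly mitochondrial
  base_p <- c(A = 0.35, C = 0.10, G = 0.10, T = 0.45)
  w <- vapply(sense, function(cod) {
    prod(base_p[seq_chars(cod)])
  }, numeric(1))
  anc <- sample(sense, n_codons, replace = TRUE, prob = w)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  bases <- c("A", "C", "G", "T")
  der <- anc
  sd <- 0L; nd <- 0L
  n_events <- stats::rpois(n_codons, t)
  p_accept_nonsyn <- min(1, omega)
  p_accept_syn <- if (omega > 1) 1 / omega else 1
  for (i in which(n_events > 0L)) {
    for (e in seq_len(n_events[i])) {
      cod <- seq_chars(der[i])
      p <- sample.int(3L, 1L)
      cur <- cod[p]
      others <- setdiff(bases, cur)
      wts <- ifelse(others == transitions[[cur]], kappa, 1)
      nb <- sample(others, 1L, prob = wts)
      cod[p] <- nb
      new_cod <- paste(cod, collapse = "")
      if (code[[new_cod]] == "*") next
      syn <- code[[new_cod]] == code[[der[i]]]
      pacc <- if (syn) p_accept_syn else p_accept_nonsyn
      if (stats::runif(1) <= pacc) {
        if (syn) sd <- sd + 1L else nd <- nd + 1L
        der[i] <- new_cod
      }
    }
  }
  list(cds1 = paste(anc, collapse = ""), cds2 = paste(der, collapse = ""),
       true_Sd = sd, true_Nd = nd)
}

#' Simulate a star-tree alignment under the K80 model
#'
#' Each taxon evolves independently from a common ancestor under Kimura's
#' two-parameter model with transition/transversion rate ratio `kappa`.
#' `t` is the expected pairwise divergence (substitutions per site
#' separating two taxa); per-taxon branch lengths are drawn uniformly
#' from `[0.5, 1.5] x t/2` so pairwise distances vary around `t`. Used to
#' exercise the saturation screen at controlled divergence.
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param n_sites Alignment length.
#' @param t Expected pairwise divergence (substitutions per site).
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences.
#' @export
simulate_k80_alignment <- function(n_taxa, n_sites, t, kappa = 2,
                                   seed = 1L) {
  stopifnot(n_taxa >= 3L, n_sites >= 1L, t >= 0, kappa > 0)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  transitions <- c(A = "G", C = "T", G = "A", T = "C")
  alpha <- kappa / (kappa + 2)
  beta <- 1 / (kappa + 2)
  anc <- sample(bases, n_sites, replace = TRUE)
  evolve <- function(b) {
    e1 <- exp(-4 * beta * b)
    e2 <- exp(-2 * (alpha + beta) * b)
    p_ts <- 1 / 4 + 1 / 4 * e1 - 1 / 2 * e2
    p_tv <- 1 / 4 - 1 / 4 * e1          # each of the two transversions
    u <- stats::runif(n_sites)
    out <- anc
    ts_idx <- u < p_ts
    out[ts_idx] <- transitions[anc[ts_idx]]
    tv1 <- !ts_idx & u < p_ts + p_tv
    tv2 <- !ts_idx & !tv1 & u < p_ts + 2 * p_tv
    # the two transversion targets of each base, deterministic order
    tv_map1 <- c(A = "C", C = "A", G = "C", T = "A")
    tv_map2 <- c(A = "T", C = "G", G = "T", T = "G")
    out[tv1] <- tv_map1[anc[tv1]]
    out[tv2] <- tv_map2[anc[tv2]]
    paste(out, collapse = "")
  }
  bl <- stats::runif(n_taxa, 0.5 * t, 1.5 * t) / 2
  stats::setNames(vapply(bl, evolve, character(1)),
                  sprintf("taxon%02d", seq_len(n_taxa)))
}
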