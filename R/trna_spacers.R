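# tRNA cloverleaf structures with mismatched-pair census, and intergenic
# spacer / overlap census with junction motif search.
#
# Pairing rule: Watson-Crick pairs plus the G-U wobble count as canonical
# (mismatch tables in the mitogenome literature list only pairs like U-U,
# A-C, A-A); T in DNA input is treated as U. Structure positions are
# 1-based indices on the tRNA sequence.

PAIR_SCORE_CANONICAL <- 2
PAIR_SCORE_WOBBLE <- 1
PAIR_SCORE_MISMATCH <- -1

CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG")
WOBBLE_PAIRS <- c("GU", "UG")

pair_kind <- function(b1, b2) {
  p <- paste0(b1, b2)
  ifelse(p %in% CANONICAL_PAIRS, "canonical",
         ifelse(p %in% WOBBLE_PAIRS, "wobble", "mismatch"))
}

pair_score <- function(b1, b2) {
  k <- pair_kind(b1, b2)
  ifelse(k == "canonical", PAIR_SCORE_CANONICAL,
         ifelse(k == "wobble", PAIR_SCORE_WOBBLE, PAIR_SCORE_MISMATCH))
}

new_cloverleaf <- function(aa_stem, dhu_stem, ac_stem, tpsic_stem,
                           dhu_loop, ac_loop, tpsic_loop, variable_loop,
                           anticodon_positions, length,
                           degenerate_dhu = FALSE) {
  structure(list(aa_stem = aa_stem, dhu_stem = dhu_stem, ac_stem = ac_stem,
                 tpsic_stem = tpsic_stem, dhu_loop = dhu_loop,
                 ac_loop = ac_loop, tpsic_loop = tpsic_loop,
                 variable_loop = variable_loop,
                 anticodon_positions = anticodon_positions,
                 length = length, degenerate_dhu = degenerate_dhu),
            class = "cloverleaf")
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat(sprintf(
    "<cloverleaf> %d nt | AA %d bp, DHU %d bp%s, AC %d bp, T-arm %d bp\n",
    x$length, nrow(x$aa_stem), nrow(x$dhu_stem),
    if (x$degenerate_dhu) " (D-arm replaced by loop)" else "",
    nrow(x$ac_stem), nrow(x$tpsic_stem)))
  invisible(x)
}

all_pairs <- function(structure) {
  rbind(structure$aa_stem, structure$dhu_stem, structure$ac_stem,
        structure$tpsic_stem)
}

#' Dot-bracket string of a cloverleaf structure
#'
#' @param structure A `cloverleaf`.
#' @return Dot-bracket string of the structure's length.
#' @export
format_dotbracket <- function(structure) {
  ch <- rep(".", structure$length)
  p <- all_pairs(structure)
  ch[p[, 1]] <- "("
  ch[p[, 2]] <- ")"
  paste(ch, collapse = "")
}

stem_matrix <- function(i, j) {
  m <- cbind(as.integer(i), as.integer(j))
  colnames(m) <- c("pos5", "pos3")
  m
}

#' Parse a dot-bracket secondary structure into a cloverleaf
#'
#' Pairs are read from balanced `(`/`)` brackets; hairpin helices are
#' assigned by position: with three hairpins they are DHU, anticodon and
#' TPsiC arms in 5'->3' order and the enclosing helix is the
#' amino-acid acceptor stem; with two hairpins the D-arm is taken as
#' replaced by a loop (`degenerate_dhu` flag), the common reduction in
#' metazoan mitochondrial tRNAs.
#'
#' @param seq tRNA sequence (DNA or RNA), same length as `structure`.
#' @param structure Dot-bracket string.
#' @return A `cloverleaf`.
#' @export
parse_structure_string <- function(seq, structure) {
  L <- nchar(structure)
  stopifnot(nchar(seq) == L)
  ch <- seq_chars(structure)
  stack <- integer(0)
  pairs <- list()
  for (i in seq_len(L)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets", call. = FALSE)
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    } else if (ch[i] != ".") {
      stop("unexpected character '", ch[i], "' in structure", call. = FALSE)
    }
  }
  if (length(stack)) stop("unbalanced brackets", call. = FALSE)
  p <- do.call(rbind, pairs)
  p <- p[order(p[, 1]), , drop = FALSE]
  # hairpin helices: pairs with no other pair nested strictly inside
  innermost <- vapply(seq_len(nrow(p)), function(k) {
    !any(p[, 1] > p[k, 1] & p[, 2] < p[k, 2])
  }, logical(1))
  # assign each pair to the hairpin whose innermost pair it stacks on, by
  # interval containment; remaining pairs form the closing (AA) stem
  hp <- which(innermost)
  hp <- hp[order(p[hp, 1])]
  helix_of <- rep(0L, nrow(p))
  for (h in seq_along(hp)) {
    k <- hp[h]
    inside <- p[, 1] <= p[k, 1] & p[, 2] >= p[k, 2]
    # a pair enclosing more than one hairpin belongs to the AA stem
    n_enclosed <- vapply(seq_len(nrow(p)), function(q) {
      sum(p[hp, 1] >= p[q, 1] & p[hp, 2] <= p[q, 2])
    }, integer(1))
    helix_of[inside & n_enclosed == 1L] <- h
  }
  n_hairpins <- length(hp)
  if (n_hairpins < 2L || n_hairpins > 3L) {
    stop("expected 2 or 3 hairpins, found ", n_hairpins, call. = FALSE)
  }
  take <- function(h) {
    q <- p[helix_of == h, , drop = FALSE]
    stem_matrix(q[, 1], q[, 2])
  }
  aa <- p[helix_of == 0L, , drop = FALSE]
  aa_stem <- stem_matrix(aa[, 1], aa[, 2])
  if (n_hairpins == 3L) {
    dhu <- take(1L); ac <- take(2L); tps <- take(3L)
    degenerate <- FALSE
  } else {
    dhu <- stem_matrix(integer(0), integer(0))
    ac <- take(1L); tps <- take(2L)
    degenerate <- TRUE
  }
  loop_of <- function(stem) {
    if (!nrow(stem)) return(integer(0))
    inner <- stem[which.max(stem[, 1]), ]
    (inner[1] + 1L):(inner[2] - 1L)
  }
  ac_loop <- loop_of(ac)
  vl_start <- max(ac[, 2]) + 1L
  vl_end <- if (nrow(tps)) min(tps[, 1]) - 1L else vl_start - 1L
  mid <- ac_loop[ceiling(length(ac_loop) / 2)]
  new_cloverleaf(aa_stem, dhu, ac, tps,
                 dhu_loop = loop_of(dhu), ac_loop = ac_loop,
                 tpsic_loop = loop_of(tps),
                 variable_loop = if (vl_end >= vl_start) vl_start:vl_end
                                 else integer(0),
                 anticodon_positions = (mid - 1L):(mid + 1L),
                 length = L, degenerate_dhu = degenerate)
}

#' Fold a tRNA sequence into a cloverleaf
#'
#' Deterministic heuristic folder: the anticodon is anchored at the centre
#' of a 7-nt loop; the anticodon stem (4-6 pairs), acceptor stem (6-8
#' pairs, one unpaired 3' discriminator nucleotide), D-arm (0-4 pairs; 0 =
#' D-arm replaced by a loop) and TPsiC arm (3-5 pairs) are then chosen to
#' maximize a pairing score (canonical pair +2, G-U wobble +1, mismatch
#' -1) subject to the arm-size ranges and non-crossing; ties are broken
#' 5'-most, then longest. A D-arm is only accepted at a positive net score
#' (two canonical pairs' worth), otherwise the region is reported as a
#' loop with the `degenerate_dhu` flag.
#'
#' @param seq tRNA sequence, 55-90 nt (DNA or RNA).
#' @param anticodon Anticodon triplet (must occur in `seq`).
#' @return A `cloverleaf`, or an error of class `fold_failure` when no
#'   arrangement satisfies the constraints.
#' @export
fold_cloverleaf <- function(seq, anticodon) {
  L <- nchar(seq)
  stopifnot(L >= 55L, L <= 90L)
  rna <- seq_chars(toupper(dna_to_rna(seq)))
  ac <- toupper(dna_to_rna(anticodon))
  stopifnot(nchar(ac) == 3L)
  hits <- which(vapply(seq_len(L - 2L), function(i) {
    paste(rna[i:(i + 2L)], collapse = "") == ac
  }, logical(1)))
  if (!length(hits)) {
    stop("anticodon ", anticodon, " not found in sequence", call. = FALSE)
  }
  score_pairs <- function(i, j) pair_score(rna[i], rna[j])

  best <- NULL
  for (a in hits) {
    loop <- (a - 2L):(a + 4L)                      # 7-nt anticodon loop
    if (loop[1] < 8L || loop[7] > L - 8L) next     # room for stems
    # anticodon stem: scores of pairs walking outwards from the loop
    sc_max <- min(6L, loop[1] - 1L, L - loop[7])
    if (sc_max < 4L) next
    ac_sc <- cumsum(vapply(seq_len(sc_max), function(k) {
      score_pairs(loop[1] - k, loop[7] + k)
    }, numeric(1)))
    sizes <- 4:sc_max
    sc <- sizes[order(-ac_sc[sizes], -sizes)][1]
    ac_stem <- stem_matrix(loop[1] - seq_len(sc), loop[7] + seq_len(sc))
    ac_stem <- ac_stem[order(ac_stem[, 1]), , drop = FALSE]
    ac_score <- ac_sc[sc]

    # acceptor stem: pair (k, L-k), discriminator unpaired at position L
    aa_max <- 8L
    aa_sc <- cumsum(vapply(seq_len(aa_max), function(k) {
      score_pairs(k, L - k)
    }, numeric(1)))
    asz <- (6:8)[order(-aa_sc[6:8], -(6:8))][1]
    aa_stem <- stem_matrix(seq_len(asz), L - seq_len(asz))
    aa_score <- aa_sc[asz]

    # D-arm search in the 5' region between acceptor and anticodon stems
    d_lo <- asz + 1L
    d_hi <- min(ac_stem[, 1]) - 1L
    dhu <- search_hairpin(rna, d_lo, d_hi, stem_range = 1:4,
                          loop_range = 3:10)
    if (is.null(dhu) || dhu$score < 2) {
      dhu_stem <- stem_matrix(integer(0), integer(0))
      dhu_loop <- if (d_hi >= d_lo) d_lo:d_hi else integer(0)
      degenerate <- TRUE
      d_score <- 0
    } else {
      dhu_stem <- dhu$stem; dhu_loop <- dhu$loop
      degenerate <- FALSE
      d_score <- dhu$score
    }

    # TPsiC arm in the 3' region between anticodon and acceptor stems
    t_lo <- max(ac_stem[, 2]) + 1L
    t_hi <- L - asz - 1L
    tps <- search_hairpin(rna, t_lo, t_hi, stem_range = 3:5,
                          loop_range = 3:9, anchor = "3prime")
    if (is.null(tps)) next
    vl_end <- min(tps$stem[, 1]) - 1L
    variable_loop <- if (vl_end >= t_lo) t_lo:vl_end else integer(0)
    if (length(variable_loop) > 12L) next

    total <- ac_score + aa_score + d_score + tps$score
    cand <- list(structure = new_cloverleaf(
      aa_stem, dhu_stem, ac_stem, tps$stem, dhu_loop,
      ac_loop = loop, tpsic_loop = tps$loop,
      variable_loop = variable_loop,
      anticodon_positions = a:(a + 2L), length = L,
      degenerate_dhu = degenerate), score = total, at = a)
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  if (is.null(best)) {
    stop(structure(class = c("fold_failure", "error", "condition"),
                   list(message = "no cloverleaf satisfying constraints",
                        call = sys.call())))
  }
  best$structure
}

# Best-scoring hairpin (stem + loop) inside [lo, hi]; candidates ordered by
# score desc, then 5'-most, then longest stem. anchor = "3prime" pins the
# hairpin's 3' end to `hi` (the TPsiC arm abuts the acceptor stem).
search_hairpin <- function(rna, lo, hi, stem_range, loop_range,
                           anchor = c("free", "3prime")) {
  anchor <- match.arg(anchor)
  if (hi - lo + 1L < 2L * min(stem_range) + min(loop_range)) return(NULL)
  best <- NULL
  for (d in stem_range) {
    for (l in loop_range) {
      width <- 2L * d + l
      starts <- if (anchor == "3prime") hi - width + 1L else lo:(hi - width + 1L)
      starts <- starts[starts >= lo]
      for (p in starts) {
        i <- p + seq_len(d) - 1L
        j <- p + width - seq_len(d)
        sc <- sum(pair_score(rna[i], rna[j]))
        better <- is.null(best) || sc > best$score ||
          (sc == best$score && p < best$p) ||
          (sc == best$score && p == best$p && d > nrow(best$stem))
        if (better) {
          stem <- stem_matrix(i, j)
          best <- list(stem = stem, loop = (p + d):(p + d + l - 1L),
                       score = sc, p = p)
        }
      }
    }
  }
  best
}

#' Mismatched base pairs of a folded tRNA
#'
#' Every stem pair whose bases (read as RNA) fall outside the canonical
#' set {A-U, U-A, G-C, C-G, G-U, U-G} yields one record. Loop positions
#' are unpaired by definition and never counted.
#'
#' @param structure A `cloverleaf`.
#' @param seq The tRNA sequence the structure indexes into.
#' @return Tibble: arm (`AA`/`DHU`/`AC`/`TPsiC`), pos5, pos3, pair
#'   (e.g. `"U-U"`).
#' @export
count_mismatches <- function(structure, seq) {
  rna <- seq_chars(toupper(dna_to_rna(seq)))
  stopifnot(length(rna) >= structure$length)
  arms <- list(AA = structure$aa_stem, DHU = structure$dhu_stem,
               AC = structure$ac_stem, TPsiC = structure$tpsic_stem)
  purrr::map_dfr(names(arms), function(arm) {
    st <- arms[[arm]]
    if (!nrow(st)) return(tibble::tibble())
    k <- pair_kind(rna[st[, 1]], rna[st[, 2]])
    bad <- k == "mismatch"
    tibble::tibble(arm = arm, pos5 = st[bad, 1], pos3 = st[bad, 2],
                   pair = paste(rna[st[bad, 1]], rna[st[bad, 2]], sep = "-"))
  })
}

#' Table-style tRNA mismatch report for a genome
#'
#' Folds every annotated tRNA (anticodon from the annotation, falling back
#' to the standard insect mitochondrial anticodon) and tabulates
#' non-canonical stem pairs per gene and arm.
#'
#' @param genome A `mitogenome`.
#' @return Tibble: accession, trna, pair, arm, n.
#' @export
trna_mismatch_report <- function(genome) {
  ft <- feature_table(genome)
  trnas <- ft$gene[!is.na(ft$gene) & ft$class %in% "tRNA"]
  purrr::map_dfr(trnas, function(g) {
    s <- extract_gene_sequence(genome, g)
    ac <- ft$anticodon[match(g, ft$gene)]
    if (is.na(ac)) ac <- chartr("U", "T", MITO_ANTICODONS[[g]])
    st <- tryCatch(fold_cloverleaf(s, ac), error = function(e) NULL)
    if (is.null(st)) {
      return(tibble::tibble(accession = genome$accession, trna = g,
                            pair = NA_character_, arm = NA_character_,
                            n = NA_integer_))
    }
    mm <- count_mismatches(st, s)
    if (!nrow(mm)) return(tibble::tibble())
    dplyr::count(mm, pair = .data$pair, arm = .data$arm) |>
      dplyr::transmute(accession = genome$accession, trna = g,
                       pair = .data$pair, arm = .data$arm, n = .data$n)
  })
}

# ---------------------------------------------------------------------------
# Intergenic spacers and overlaps

substr_circular <- function(seq, start0, end0) {
  L <- nchar(seq)
  if (end0 <= L) return(substr(seq, start0 + 1L, end0))
  paste0(substr(seq, start0 + 1L, L), substr(seq, 1L, end0 - L))
}

#' Intergenic spacer and overlap census
#'
#' Walks consecutive annotated features in genomic order (wrapping across
#' the origin for circular molecules). For each junction the signed length
#' is `next.start - current.end`: positive = intergenic gap, negative =
#' overlap, zero = directly adjacent. Features fully nested inside another
#' are excluded from the walk (with a message). The A+T-rich region
#' participates as a feature — its flanks are junctions — but is itself an
#' annotated region, not a spacer.
#'
#' @param genome A `mitogenome`.
#' @return Object of class `spacer_scan`: `records` tibble (upstream,
#'   downstream, signed_length, kind, sequence — the gap sequence for
#'   gaps, the shared sequence for overlaps) and `summary` one-row tibble
#'   (total_intergenic_bp, n_gap_locations, longest_gap,
#'   longest_gap_junction, n_overlaps, overlap_min, overlap_max,
#'   n_abutting).
#' @export
spacer_overlap_scan <- function(genome) {
  ft <- feature_table(genome)
  ft <- ft[!is.na(ft$gene), ]
  stopifnot(nrow(ft) >= 2L)
  ft <- ft[order(ft$start, -ft$length), ]
  # exclude nested features
  nested <- vapply(seq_len(nrow(ft)), function(i) {
    any(ft$start <= ft$start[i] & ft$end >= ft$end[i] &
          seq_len(nrow(ft)) != i &
          !(ft$start == ft$start[i] & ft$end == ft$end[i] &
              seq_len(nrow(ft)) > i))
  }, logical(1))
  if (any(nested)) {
    message("excluded nested feature(s): ",
            paste(ft$gene[nested], collapse = ", "))
    ft <- ft[!nested, ]
  }
  n <- nrow(ft)
  L <- nchar(genome$sequence)
  idx_next <- c(2:n, 1L)
  last_junction <- genome$topology == "circular"
  rows <- purrr::map_dfr(seq_len(n - 1L + last_junction), function(i) {
    j <- idx_next[i]
    nxt_start <- if (j == 1L) ft$start[j] + L else ft$start[j]
    sl <- nxt_start - ft$end[i]
    seqv <- if (sl > 0) {
      substr_circular(genome$sequence, ft$end[i], nxt_start)
    } else if (sl < 0) {
      substr_circular(genome$sequence, nxt_start - (j == 1L) * L,
                      ft$end[i] - (j == 1L) * 0L)
    } else ""
    tibble::tibble(upstream = ft$gene[i], downstream = ft$gene[j],
                   signed_length = as.integer(sl),
                   kind = if (sl > 0) "gap" else if (sl < 0) "overlap"
                          else "abut",
                   sequence = seqv)
  })
  gaps <- rows[rows$kind == "gap", ]
  ovs <- rows[rows$kind == "overlap", ]
  summary <- tibble::tibble(
    total_intergenic_bp = sum(gaps$signed_length),
    n_gap_locations = nrow(gaps),
    longest_gap = if (nrow(gaps)) max(gaps$signed_length) else 0L,
    longest_gap_junction = if (nrow(gaps)) {
      k <- which.max(gaps$signed_length)
      paste(gaps$upstream[k], gaps$downstream[k], sep = "/")
    } else NA_character_,
    n_overlaps = nrow(ovs),
    overlap_min = if (nrow(ovs)) min(-ovs$signed_length) else NA_integer_,
    overlap_max = if (nrow(ovs)) max(-ovs$signed_length) else NA_integer_,
    n_abutting = sum(rows$kind == "abut"))
  structure(list(records = rows, summary = summary), class = "spacer_scan")
}

#' @export
print.spacer_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<spacer_scan> %d bp intergenic in %d location(s); %d overlap(s); %d abutting\n",
    s$total_intergenic_bp, s$n_gap_locations, s$n_overlaps, s$n_abutting))
  invisible(x)
}

#' @rdname tidy_mitocomp
#' @export
tidy.spacer_scan <- function(x, ...) x$records

#' @rdname tidy_mitocomp
#' @export
glance.spacer_scan <- function(x, ...) x$summary

#' Search junction sequences for a motif
#'
#' Exact-match search of a motif on the junction-local sequence of spacer
#' and/or overlap records, in both orientations (the orientation of the
#' match is reported).
#'
#' @param records Records tibble from [spacer_overlap_scan()] (or the
#'   `spacer_scan` object itself).
#' @param motif DNA motif.
#' @param where `"gaps"`, `"overlaps"` or `"both"`.
#' @return Tibble of hits: upstream, downstream, kind, orientation
#'   (`"forward"`/`"reverse"`), offset (1-based within the junction
#'   sequence as stored).
#' @export
find_motif <- function(records, motif, where = c("both", "gaps", "overlaps")) {
  if (inherits(records, "spacer_scan")) records <- records$records
  where <- match.arg(where)
  stopifnot(nzchar(motif))
  motif <- toupper(motif)
  keep <- switch(where, both = records$kind %in% c("gap", "overlap"),
                 gaps = records$kind == "gap",
                 overlaps = records$kind == "overlap")
  recs <- records[keep & nzchar(records$sequence), ]
  empty <- tibble::tibble(upstream = character(), downstream = character(),
                          kind = character(), orientation = character(),
                          offset = integer())
  if (!nrow(recs)) return(empty)
  dplyr::bind_rows(empty, purrr::map_dfr(seq_len(nrow(recs)), function(i) {
    s <- toupper(recs$sequence[i])
    hits <- tibble::tibble()
    f <- gregexpr(motif, s, fixed = TRUE)[[1]]
    if (f[1] != -1L) {
      hits <- dplyr::bind_rows(hits, tibble::tibble(
        upstream = recs$upstream[i], downstream = recs$downstream[i],
        kind = recs$kind[i], orientation = "forward", offset = as.integer(f)))
    }
    r <- gregexpr(motif, revcomp(s), fixed = TRUE)[[1]]
    if (r[1] != -1L) {
      hits <- dplyr::bind_rows(hits, tibble::tibble(
        upstream = recs$upstream[i], downstream = recs$downstream[i],
        kind = recs$kind[i], orientation = "reverse", offset = as.integer(r)))
    }
    hits
  }))
}
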