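# Circular signed gene orders and rearrangement analysis against the
# ancestral insect mitochondrial arrangement.
#
# An order is a tibble of (gene, sign) rows read clockwise around the
# circle; sign +1 = J-strand, -1 = N-strand. A signed circular adjacency
# (x -> y) is considered shared with its mirror (-y -> -x), the standard
# signed-permutation convention (so a full reversal of the circle has
# breakpoint distance 0).

new_gene_order <- function(gene, sign, missing = character(0)) {
  stopifnot(length(gene) == length(sign), !anyDuplicated(gene),
            length(gene) >= 1L, all(sign %in% c(-1L, 1L)))
  structure(tibble::tibble(gene = gene, sign = as.integer(sign)),
            missing = missing, class = c("gene_order", "tbl_df", "tbl",
                                         "data.frame"))
}

#' Format a gene order as a one-line arrangement string
#'
#' N-strand genes carry a `-` prefix, the convention of linear mitogenome
#' maps.
#'
#' @param order A `gene_order`.
#' @return Single string.
#' @export
format_gene_order <- function(order) {
  paste(ifelse(order$sign < 0, paste0("-", order$gene), order$gene),
        collapse = " ")
}

#' The ancestral insect mitochondrial gene arrangement
#'
#' The putative ancestral arrangement of the 37 genes plus the A+T-rich
#' region, as conserved in *Drosophila yakuba* and most insects: the
#' `trnI-trnQ-trnM` cluster before `nad2`, the `trnW-trnC-trnY` cluster
#' before `cox1`, and so on around the circle.
#'
#' @return A `gene_order` of 38 elements.
#' @export
ancestral_insect_order <- function() {
  genes <- c("trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY",
             "cox1", "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6",
             "cox3", "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1",
             "trnE", "trnF", "nad5", "trnH", "nad4", "nad4l", "trnT",
             "trnP", "nad6", "cob", "trnS2", "nad1", "trnL1", "rrnL",
             "trnV", "rrnS", "AT_rich")
  minus <- c("trnQ", "trnC", "trnY", "trnF", "nad5", "trnH", "nad4",
             "nad4l", "trnP", "nad1", "trnL1", "rrnL", "trnV", "rrnS")
  new_gene_order(genes, ifelse(genes %in% minus, -1L, 1L))
}

#' Extract the circular signed gene order of a genome
#'
#' Features are sorted by start coordinate on the deposited strand; ties
#' (identical starts) are broken by placing the longer feature first, with
#' a message. Canonical genes absent from the sequenced region are listed
#' in the `missing` attribute, never imputed.
#'
#' @param genome A `mitogenome`.
#' @return A `gene_order`.
#' @export
extract_gene_order <- function(genome) {
  ft <- feature_table(genome)
  ft <- ft[!is.na(ft$gene), ]
  stopifnot(nrow(ft) >= 1L)
  o <- order(ft$start, -ft$length)
  if (anyDuplicated(ft$start)) {
    message("tied feature starts broken by length (longer first)")
  }
  ft <- ft[o, ]
  missing <- setdiff(canonical_gene_names(), c(ft$gene, "AT_rich"))
  new_gene_order(ft$gene, ifelse(ft$strand == "J", 1L, -1L),
                 missing = missing)
}

#' Apply rearrangement events to a gene order
#'
#' Event semantics: `translocation` moves a gene (sign kept) to the
#' position immediately after `after` (circularly); `remote_inversion`
#' moves it there and flips its sign; `inversion` flips the sign in place
#' (no destination). Events are applied in sequence.
#'
#' @param order A `gene_order`.
#' @param events List of events, each a list with `type` (one of
#'   `"translocation"`, `"inversion"`, `"remote_inversion"`), `gene`, and
#'   (for the moving types) `after`, the gene it lands behind.
#' @return The permuted `gene_order`.
#' @export
apply_rearrangement <- function(order, events) {
  genes <- order$gene; signs <- order$sign
  for (ev in events) {
    type <- match.arg(ev$type, c("translocation", "inversion",
                                 "remote_inversion"))
    i <- match(ev$gene, genes)
    if (is.na(i)) stop("event names unknown gene: ", ev$gene, call. = FALSE)
    if (type == "inversion") {
      signs[i] <- -signs[i]
      next
    }
    if (is.null(ev$after) || identical(ev$after, ev$gene)) {
      stop("destination inside the moved gene: ", ev$gene, call. = FALSE)
    }
    j <- match(ev$after, genes)
    if (is.na(j)) stop("event names unknown gene: ", ev$after, call. = FALSE)
    g <- genes[i]; s <- signs[i]
    if (type == "remote_inversion") s <- -s
    genes <- genes[-i]; signs <- signs[-i]
    j <- match(ev$after, genes)
    genes <- append(genes, g, after = j)
    signs <- append(signs, s, after = j)
  }
  new_gene_order(genes, signs, missing = attr(order, "missing"))
}

# Canonical tokens for the signed circular adjacencies of an order,
# identifying (x,sx)->(y,sy) with (y,-sy)->(x,-sx). AT_rich is excluded
# (its boundaries are unreliable in partial genomes).
adjacency_set <- function(order, drop = "AT_rich") {
  keep <- !(order$gene %in% drop)
  g <- order$gene[keep]; s <- order$sign[keep]
  n <- length(g)
  if (n < 2L) return(character(0))
  nxt <- c(2:n, 1L)
  tok <- function(x, sx, y, sy) {
    a <- paste0(ifelse(sx > 0, "+", "-"), x, "|", ifelse(sy > 0, "+", "-"), y)
    b <- paste0(ifelse(-sy > 0, "+", "-"), y, "|",
                ifelse(-sx > 0, "+", "-"), x)
    pmin(a, b)
  }
  unique(tok(g, s, g[nxt], s[nxt]))
}

#' Breakpoint distance between two circular signed gene orders
#'
#' The number of signed circular adjacencies of `a` absent from `b`, under
#' the mirror convention (an adjacency and its reverse-complement count as
#' shared). The A+T-rich region is excluded from the adjacency walk.
#'
#' @param a,b `gene_order` objects over the same gene set.
#' @return Non-negative integer.
#' @export
breakpoint_distance <- function(a, b) {
  ga <- setdiff(a$gene, "AT_rich"); gb <- setdiff(b$gene, "AT_rich")
  if (!setequal(ga, gb)) {
    stop("gene sets differ: ",
         paste(c(setdiff(ga, gb), setdiff(gb, ga)), collapse = ", "),
         call. = FALSE)
  }
  length(setdiff(adjacency_set(a), adjacency_set(b)))
}

# Project an order onto a gene subset, preserving circular order.
project_order <- function(order, genes) {
  keep <- order$gene %in% genes
  new_gene_order(order$gene[keep], order$sign[keep],
                 missing = attr(order, "missing"))
}

# Longest common subsequence of signed token vectors; returns logical mask
# over `x` marking kept elements (deterministic backtrack).
lcs_mask <- function(x, y) {
  n <- length(x); m <- length(y)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1L, j + 1L] <- if (x[i] == y[j]) L[i, j] + 1L
        else max(L[i, j + 1L], L[i + 1L, j])
    }
  }
  keep <- logical(n)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (x[i] == y[j] && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      keep[i] <- TRUE; i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  keep
}

#' Compare a gene order to the ancestral arrangement
#'
#' The ancestor is first projected onto the observed gene set (missing
#' genes deleted, never reported as rearranged). A maximum-length common
#' circular signed subsequence anchors the genes that are in place; the
#' remainder are classified per gene: moved with a sign flip =
#' `remote_inverted`, moved with sign kept = `translocated`, sign flipped
#' between unchanged neighbours = `inverted_in_place`. The classification
#' is a heuristic minimum-event narrative ("at least N events"), not a
#' globally optimal rearrangement scenario. Breakpoints are the observed
#' signed circular adjacencies absent from the projected ancestor
#' (A+T-rich region excluded).
#'
#' @param observed A `gene_order`.
#' @param ancestor A `gene_order` containing at least the observed genes
#'   (default: [ancestral_insect_order()]).
#' @return Object of class `rearrangement_report`: `status` tibble (gene,
#'   sign, status), `breakpoint_count`, `conserved_blocks` (list of gene
#'   runs), `n_events`, `narrative` (character).
#' @export
compare_to_ancestor <- function(observed, ancestor = ancestral_insect_order()) {
  unknown <- setdiff(observed$gene, ancestor$gene)
  if (length(unknown)) {
    stop("observed contains genes unknown to ancestor: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  anc <- project_order(ancestor, observed$gene)
  tokens <- function(o) paste0(ifelse(o$sign > 0, "+", "-"), o$gene)
  ta <- tokens(anc)
  n <- nrow(observed)
  best_keep <- NULL; best_len <- -1L
  for (r in seq_len(n)) {
    idx <- c(r:n, seq_len(r - 1L))
    to <- tokens(observed)[idx]
    keep <- lcs_mask(to, ta)
    if (sum(keep) > best_len) {
      best_len <- sum(keep)
      best_keep <- logical(n); best_keep[idx] <- keep
    }
  }
  status <- rep("in_place", n)
  anc_neighbours <- function(g) {
    i <- match(g, anc$gene); m <- nrow(anc)
    c(anc$gene[if (i == 1L) m else i - 1L],
      anc$gene[if (i == m) 1L else i + 1L])
  }
  obs_neighbours <- function(g) {
    i <- match(g, observed$gene)
    c(observed$gene[if (i == 1L) n else i - 1L],
      observed$gene[if (i == n) 1L else i + 1L])
  }
  for (i in which(!best_keep)) {
    g <- observed$gene[i]
    flipped <- observed$sign[i] != anc$sign[match(g, anc$gene)]
    same_spot <- n > 2L && setequal(obs_neighbours(g), anc_neighbours(g))
    status[i] <- if (flipped && same_spot) "inverted_in_place"
      else if (flipped) "remote_inverted"
      else "translocated"
  }
  # conserved blocks: runs of in-place genes consecutive in both circles
  blocks <- list()
  if (any(best_keep)) {
    kept_idx <- which(best_keep)
    anc_pos <- match(observed$gene[kept_idx], anc$gene)
    run <- list(kept_idx[1])
    if (length(kept_idx) > 1L) {
      for (k in 2:length(kept_idx)) {
        contiguous_obs <- kept_idx[k] == kept_idx[k - 1L] + 1L
        contiguous_anc <- (anc_pos[k] - anc_pos[k - 1L]) %% nrow(anc) == 1L
        if (contiguous_obs && contiguous_anc) {
          run[[length(run) + 1L]] <- kept_idx[k]
        } else {
          blocks[[length(blocks) + 1L]] <- observed$gene[unlist(run)]
          run <- list(kept_idx[k])
        }
      }
    }
    blocks[[length(blocks) + 1L]] <- observed$gene[unlist(run)]
  }
  moved <- which(status != "in_place")
  narrative <- vapply(moved, function(i) {
    g <- observed$gene[i]
    prev <- observed$gene[if (i == 1L) n else i - 1L]
    switch(status[i],
           translocated = sprintf("translocation of %s to downstream of %s",
                                  g, prev),
           remote_inverted = sprintf(
             "remote inversion of %s to downstream of %s", g, prev),
           inverted_in_place = sprintf("in-place inversion of %s", g))
  }, character(1))
  structure(
    list(status = tibble::tibble(gene = observed$gene,
                                 sign = observed$sign, status = status),
         breakpoint_count = breakpoint_distance(observed, anc),
         conserved_blocks = blocks,
         n_events = length(moved),
         narrative = narrative),
    class = "rearrangement_report")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf("<rearrangement_report> at least %d event(s), %d breakpoint(s)\n",
              x$n_events, x$breakpoint_count))
  for (s in x$narrative) cat(" -", s, "\n")
  invisible(x)
}

#' @rdname tidy_mitocomp
#' @export
tidy.rearrangement_report <- function(x, ...) x$status

#' @rdname tidy_mitocomp
#' @export
glance.rearrangement_report <- function(x, ...) {
  tibble::tibble(n_events = x$n_events,
                 breakpoint_count = x$breakpoint_count,
                 n_conserved_blocks = length(x$conserved_blocks),
                 n_in_place = sum(x$status$status == "in_place"))
}
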