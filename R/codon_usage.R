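# Codon counting, RSCU, start/stop codon classification, and amino acid
# usage under the invertebrate mitochondrial code (translation table 5).

#' Count codons across coding sequences
#'
#' Codons are read in frame 0 from the start of each CDS. A trailing 1-2 nt
#' remainder (an incomplete stop codon completed by polyadenylation) is
#' dropped. Terminal complete stop codons go to a separate stop tally and
#' are excluded from the sense counts; codons containing ambiguity codes
#' are skipped and counted as ambiguous.
#'
#' @param cds_list Character vector/list of coding-orientation CDS strings.
#' @param drop_trailing_partial Drop a trailing partial codon (default
#'   `TRUE`; with `FALSE` a non-multiple-of-3 CDS is an error).
#' @return List of class `codon_counts`: `counts` (named integer vector,
#'   all 64 codons), `stop_tally` (named integer), `n_codons_total` (sense
#'   codons counted), `n_ambiguous`, `n_dropped_nt`.
#' @export
count_codons <- function(cds_list, drop_trailing_partial = TRUE) {
  cds_list <- as.character(unlist(cds_list, use.names = FALSE))
  stopifnot(all(nchar(cds_list) >= 3L))
  code <- mito_genetic_code()
  all_codons <- names(code)
  counts <- stats::setNames(integer(64), all_codons)
  stop_tally <- stats::setNames(integer(length(stop_codons())), stop_codons())
  n_amb <- 0L; n_drop <- 0L
  for (s in cds_list) {
    s <- toupper(s)
    rem <- nchar(s) %% 3L
    if (rem > 0L) {
      if (!drop_trailing_partial) {
        stop("CDS length not a multiple of 3", call. = FALSE)
      }
      n_drop <- n_drop + rem
      s <- substr(s, 1L, nchar(s) - rem)
    }
    cods <- codon_split(s)
    if (!length(cods)) next
    last <- cods[length(cods)]
    if (last %in% stop_codons()) {
      stop_tally[last] <- stop_tally[last] + 1L
      cods <- cods[-length(cods)]
    }
    ok <- cods %in% all_codons
    n_amb <- n_amb + sum(!ok)
    tab <- table(cods[ok])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  # internal stops (if any) are kept in `counts` under their codon but do
  # not enter the sense total
  sense <- sense_codons()
  structure(list(counts = counts, stop_tally = stop_tally,
                 n_codons_total = sum(counts[sense]),
                 n_ambiguous = n_amb, n_dropped_nt = n_drop,
                 code_table = 5L),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("<codon_counts> %d sense codons, %d terminal stops, %d ambiguous\n",
              x$n_codons_total, sum(x$stop_tally), x$n_ambiguous))
  invisible(x)
}

# Synonymous families of the invertebrate mitochondrial code: sense codons
# grouped by encoded amino acid.
codon_families <- function() {
  code <- mito_genetic_code()
  sense <- sense_codons()
  split(sense, code[sense])
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = k * n_c / sum(n_j, j in family)` for a synonymous family of
#' size `k`. Families with zero total usage get `NA` (undefined) rather
#' than zero. Stop codons are excluded throughout.
#'
#' @param counts A `codon_counts` object (or named integer vector over
#'   codons).
#' @return Tibble: codon, amino_acid, count, family_size, rscu, missing
#'   (logical: sense codon with zero count).
#' @export
rscu <- function(counts) {
  cnt <- if (inherits(counts, "codon_counts")) counts$counts else counts
  code <- mito_genetic_code()
  fams <- codon_families()
  purrr::map_dfr(names(fams), function(aa) {
    cods <- fams[[aa]]
    n <- as.numeric(cnt[cods])
    tot <- sum(n)
    val <- if (tot > 0) length(cods) * n / tot else rep(NA_real_, length(cods))
    tibble::tibble(codon = cods, amino_acid = aa, count = as.integer(n),
                   family_size = length(cods), rscu = val,
                   missing = n == 0)
  }) |>
    dplyr::arrange(.data$amino_acid, .data$codon)
}

#' Start and stop codon classification for all protein-coding genes
#'
#' The start is the first triplet of the CDS, classed `ATN` (canonical
#' invertebrate mitochondrial initiators), `abnormal` (GTG/TTG/AAA, seen in
#' sawfly mitogenomes), or `other`. The stop is a complete TAA/TAG when the
#' CDS length is a multiple of 3 and ends with a stop; a trailing T or TA
#' is called an incomplete stop only when the CDS length remainder matches
#' and the next annotated feature abuts (0 nt) or overlaps the CDS end —
#' the adjacency expected when polyadenylation completes the stop.
#' Anything else is flagged `nonstandard`.
#'
#' @param genome A `mitogenome`.
#' @return Tibble: gene, start_codon, start_class, stop_codon, stop_class
#'   (`"complete"`, `"incomplete"`, `"nonstandard"`).
#' @export
classify_terminal_codons <- function(genome) {
  ft <- feature_table(genome)
  pcgs <- ft[!is.na(ft$gene) & ft$class %in% "PCG", ]
  if (!nrow(pcgs)) stop("no annotated PCGs", call. = FALSE)
  glen <- nchar(genome$sequence)
  ord <- ft[order(ft$start), ]
  purrr::map_dfr(seq_len(nrow(pcgs)), function(i) {
    g <- pcgs$gene[i]
    s <- extract_gene_sequence(genome, g)
    start_codon <- substr(s, 1L, 3L)
    start_class <- if (grepl("^AT[ACGT]$", start_codon)) "ATN"
      else if (start_codon %in% c("GTG", "TTG", "AAA")) "abnormal"
      else "other"
    rem <- nchar(s) %% 3L
    if (rem == 0L) {
      last3 <- substr(s, nchar(s) - 2L, nchar(s))
      if (last3 %in% c("TAA", "TAG")) {
        return(tibble::tibble(gene = g, start_codon = start_codon,
                              start_class = start_class, stop_codon = last3,
                              stop_class = "complete"))
      }
      return(tibble::tibble(gene = g, start_codon = start_codon,
                            start_class = start_class, stop_codon = last3,
                            stop_class = "nonstandard"))
    }
    partial <- substr(s, nchar(s) - rem + 1L, nchar(s))
    ok_partial <- (rem == 1L && partial == "T") ||
      (rem == 2L && partial == "TA")
    # does the next feature (genomic order, same walk as the spacer census)
    # abut or overlap this CDS end?
    row <- which(ord$gene == g)[1]
    this_end <- ord$end[row]
    nxt <- if (row < nrow(ord)) ord$start[row + 1L]
      else if (genome$topology == "circular") ord$start[1L] + glen
      else NA_integer_
    adjacent <- !is.na(nxt) && (nxt - this_end) <= 0L
    tibble::tibble(gene = g, start_codon = start_codon,
                   start_class = start_class, stop_codon = partial,
                   stop_class = if (ok_partial && adjacent) "incomplete"
                                else "nonstandard")
  }) |> dplyr::arrange(.data$gene)
}

#' Amino acid usage from codon counts
#'
#' Translates sense-codon counts under translation table 5 and ranks amino
#' acids by usage.
#'
#' @param counts A `codon_counts` object.
#' @return Tibble ranked by count: amino_acid, count, frequency.
#' @export
amino_acid_usage <- function(counts) {
  cnt <- if (inherits(counts, "codon_counts")) counts$counts else counts
  code <- mito_genetic_code()
  sense <- sense_codons()
  n <- tapply(as.numeric(cnt[sense]), code[sense], sum)
  out <- tibble::tibble(amino_acid = names(n), count = as.integer(n))
  out <- out[out$count >= 0, ]
  tot <- sum(out$count)
  out$frequency <- if (tot > 0) out$count / tot else rep(NA_real_, nrow(out))
  if (tot == 0) out <- out[0, ]
  dplyr::arrange(out, dplyr::desc(.data$count))
}

#' RSCU bar plot
#'
#' @param rscu_tbl Output of [rscu()].
#' @return A ggplot object.
#' @export
plot_rscu <- function(rscu_tbl) {
  tbl <- rscu_tbl[!is.na(rscu_tbl$rscu), ]
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$amino_acid, y = .data$rscu,
                                    fill = .data$codon)) +
    ggplot2::geom_col(position = "stack", colour = "grey30",
                      linewidth = 0.1, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::theme_minimal()
}
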