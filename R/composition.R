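# Base composition, A+T content, and AT/GC strand skews.
#
# AT-skew = (A% - T%) / (A% + T%); GC-skew = (G% - C%) / (G% + C%).
# Negative AT-skew together with T-rich protein-coding sequence is the
# typical strand asymmetry of insect mitochondrial majority-strand genes.

#' Base composition of a DNA sequence
#'
#' Counts unambiguous bases; IUPAC ambiguity codes are tallied separately
#' and excluded from the percentage denominators and from both skews.
#'
#' @param seq DNA string.
#' @param region_label Optional label carried into the output.
#' @return One-row tibble: region, length, counts `n_a/n_c/n_g/n_t`,
#'   `n_ambiguous`, percentages `pct_a/pct_c/pct_g/pct_t`, `at_content`,
#'   `at_skew`, `gc_skew` (skews `NA` when their denominator is zero).
#' @export
base_composition <- function(seq, region_label = NA_character_) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (is.na(seq) || !nzchar(seq)) stop("empty sequence", call. = FALSE)
  ch <- seq_chars(toupper(seq))
  n_a <- sum(ch == "A"); n_c <- sum(ch == "C")
  n_g <- sum(ch == "G"); n_t <- sum(ch == "T")
  tot <- n_a + n_c + n_g + n_t
  n_amb <- length(ch) - tot
  pct <- if (tot > 0) c(n_a, n_c, n_g, n_t) / tot * 100 else rep(NA_real_, 4)
  tibble::tibble(
    region = region_label, length = length(ch),
    n_a = n_a, n_c = n_c, n_g = n_g, n_t = n_t, n_ambiguous = n_amb,
    pct_a = pct[1], pct_c = pct[2], pct_g = pct[3], pct_t = pct[4],
    at_content = pct[1] + pct[4],
    at_skew = skew(pct[1], pct[4]),
    gc_skew = skew(pct[3], pct[2]))
}

#' Strand skew
#'
#' `skew(x, y) = (x - y) / (x + y)`. For AT-skew pass `x = A%`, `y = T%`;
#' for GC-skew `x = G%`, `y = C%`. Counts work equally well since the
#' normalization cancels.
#'
#' @param x_pct,y_pct Percentages (or counts), vectorized.
#' @return Skew values in `[-1, 1]`; `NA` where `x + y == 0` (undefined,
#'   never silently zero).
#' @export
skew <- function(x_pct, y_pct) {
  s <- x_pct + y_pct
  out <- (x_pct - y_pct) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' Composition of an annotated genome region
#'
#' `"whole"` is the full deposited sequence; `"PCGs"` and `"tRNAs"`
#' concatenate each gene's coding-orientation (sense-strand) sequence;
#' `"rrnL"`/`"rrnS"` are the single rRNA genes; `"codon_pos1/2/3"` take
#' every third base of the concatenated PCG sense sequence, reading each
#' CDS in frame 0.
#'
#' @param genome A `mitogenome`.
#' @param region One of `"whole"`, `"PCGs"`, `"rrnL"`, `"rrnS"`,
#'   `"tRNAs"`, `"codon_pos1"`, `"codon_pos2"`, `"codon_pos3"`.
#' @param j_strand_only If `TRUE`, compute PCG-derived regions on the
#'   J-strand reading of every gene instead of the sense strand.
#' @return One-row tibble as [base_composition()], or an `absent-region`
#'   condition if the region has no annotated features.
#' @export
region_composition <- function(genome, region = c("whole", "PCGs", "rrnL",
                                                  "rrnS", "tRNAs",
                                                  "codon_pos1", "codon_pos2",
                                                  "codon_pos3"),
                               j_strand_only = FALSE) {
  region <- match.arg(region)
  if (region == "whole") {
    return(base_composition(genome$sequence, "whole"))
  }
  ft <- feature_table(genome)
  get_seqs <- function(genes) {
    genes <- intersect(genes, ft$gene)
    if (!length(genes)) return(character(0))
    vapply(genes, function(g) {
      s <- extract_gene_sequence(genome, g)
      if (j_strand_only && ft$strand[match(g, ft$gene)] == "N") s <- revcomp(s)
      s
    }, character(1))
  }
  seqs <- switch(region,
    PCGs = , codon_pos1 = , codon_pos2 = , codon_pos3 = get_seqs(MITO_PCGS),
    tRNAs = get_seqs(MITO_TRNAS),
    rrnL = get_seqs("rrnL"),
    rrnS = get_seqs("rrnS"))
  if (!length(seqs)) {
    stop(structure(class = c("absent_region", "error", "condition"),
                   list(message = paste0("region '", region,
                                         "' absent from annotation"),
                        call = sys.call())))
  }
  if (grepl("^codon_pos", region)) {
    pos <- as.integer(substr(region, 10L, 10L))
    seqs <- vapply(seqs, function(s) {
      ch <- seq_chars(s)
      n <- (length(ch) %/% 3L) * 3L
      paste(ch[seq(pos, n, by = 3L)], collapse = "")
    }, character(1))
  }
  base_composition(paste(seqs, collapse = ""), region)
}

#' Per-species composition/skew table for the PCG region
#'
#' One row per genome with A+T content, AT-skew and GC-skew of the
#' concatenated protein-coding genes, the quantities conventionally shown
#' as a three-dimensional scatter in comparative mitogenomics. Genomes
#' without annotated PCGs are flagged and returned with `NA` values rather
#' than dropped.
#'
#' @param genomes List of `mitogenome` objects.
#' @return Tibble: accession, organism, at_content, at_skew, gc_skew,
#'   flagged.
#' @export
scatter3d_table <- function(genomes) {
  stopifnot(length(genomes) >= 1L)
  purrr::map_dfr(genomes, function(g) {
    row <- tryCatch(region_composition(g, "PCGs"),
                    error = function(e) NULL)
    if (is.null(row)) {
      tibble::tibble(accession = g$accession, organism = g$organism,
                     at_content = NA_real_, at_skew = NA_real_,
                     gc_skew = NA_real_, flagged = TRUE)
    } else {
      tibble::tibble(accession = g$accession, organism = g$organism,
                     at_content = row$at_content, at_skew = row$at_skew,
                     gc_skew = row$gc_skew, flagged = FALSE)
    }
  })
}

#' Composition report table across regions
#'
#' Per-genome, per-region composition in the layout of published
#' mitogenome description tables (length and A+T% for whole/PCGs/rRNAs,
#' percentages rounded half-up to 2 decimals, skews to 3).
#'
#' @param genomes List of `mitogenome` objects.
#' @param regions Regions to include (see [region_composition()]).
#' @return Tibble with one row per genome x region.
#' @export
composition_report <- function(genomes,
                               regions = c("whole", "PCGs", "rrnL", "rrnS")) {
  purrr::map_dfr(genomes, function(g) {
    purrr::map_dfr(regions, function(r) {
      row <- tryCatch(region_composition(g, r), error = function(e) NULL)
      if (is.null(row)) return(tibble::tibble())
      tibble::tibble(accession = g$accession, organism = g$organism,
                     region = r, length = row$length,
                     at_pct = round_half_up(row$at_content, 2),
                     at_skew = round_half_up(row$at_skew, 3),
                     gc_skew = round_half_up(row$gc_skew, 3))
    })
  })
}

#' Scatter plot of PCG composition summary
#'
#' A+T content against AT-skew, with GC-skew mapped to color — a 2-D
#' rendering of the conventional 3-D composition scatter.
#'
#' @param tbl Output of [scatter3d_table()].
#' @return A ggplot object.
#' @export
plot_composition_scatter <- function(tbl) {
  tbl <- tbl[!tbl$flagged, ]
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$at_content, y = .data$at_skew,
                                    colour = .data$gc_skew)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$accession),
                       vjust = -1, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "A+T content of PCGs (%)", y = "AT-skew (PCGs)",
                  colour = "GC-skew") +
    ggplot2::theme_minimal()
}
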