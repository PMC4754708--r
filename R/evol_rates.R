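# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction under the
# invertebrate mitochondrial code.
#
# Site counting: each codon contributes S = sum over its three positions of
# (number of synonymous single-nucleotide changes)/3; changes to stop
# codons count as nonsynonymous, so N = 3 - S and S + N = 3 per codon.
# Difference counting: codons differing at d positions are resolved by
# equal-weight averaging over the d! substitution pathways, excluding
# pathways that pass through a stop codon; if every pathway is excluded the
# differences are split in proportion to the pair's site counts.

ng86_tables <- function() {
  tb <- .mitocomp_cache$ng86_tables
  if (!is.null(tb)) return(tb)
  code <- mito_genetic_code()
  codons <- names(code)
  bases <- c("A", "C", "G", "T")
  syn_sites <- stats::setNames(numeric(64), codons)
  for (cod in codons) {
    if (code[[cod]] == "*") { syn_sites[cod] <- NA_real_; next }
    s <- 0
    ch <- seq_chars(cod)
    for (p in 1:3) {
      for (b in setdiff(bases, ch[p])) {
        mut <- ch; mut[p] <- b
        mutc <- paste(mut, collapse = "")
        if (code[[mutc]] == code[[cod]]) s <- s + 1 / 3
      }
    }
    syn_sites[cod] <- s
  }
  tb <- list(syn_sites = syn_sites, pair = new.env(parent = emptyenv()))
  .mitocomp_cache$ng86_tables <- tb
  tb
}

# Pathway-averaged (Sd, Nd) for one codon pair; memoized.
ng86_pair_counts <- function(c1, c2) {
  tb <- ng86_tables()
  key <- paste0(c1, c2)
  hit <- tb$pair[[key]]
  if (!is.null(hit)) return(hit)
  code <- mito_genetic_code()
  diffs <- which(seq_chars(c1) != seq_chars(c2))
  d <- length(diffs)
  res <- if (d == 0L) {
    c(sd = 0, nd = 0)
  } else {
    perms <- all_permutations(diffs)
    path_sd <- numeric(0); path_nd <- numeric(0)
    for (ord in perms) {
      cur <- seq_chars(c1); tgt <- seq_chars(c2)
      sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; nxt[p] <- tgt[p]
        a <- code[[paste(cur, collapse = "")]]
        b <- code[[paste(nxt, collapse = "")]]
        if (b == "*") { ok <- FALSE; break }
        if (a == b) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { path_sd <- c(path_sd, sd); path_nd <- c(path_nd, nd) }
    }
    if (length(path_sd)) {
      c(sd = mean(path_sd), nd = mean(path_nd))
    } else {
      # all pathways pass through stops: split by the pair's site counts
      sbar <- mean(tb$syn_sites[c(c1, c2)])
      c(sd = d * sbar / 3, nd = d * (1 - sbar / 3))
    }
  }
  tb$pair[[key]] <- res
  res
}

all_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

jc_correct <- function(p) {
  arg <- 1 - 4 / 3 * p
  ifelse(is.na(p), NA_real_, ifelse(arg <= 0, NA_real_, -3 / 4 * log(arg)))
}

#' Nei-Gojobori Ka/Ks for a pair of coding sequences
#'
#' Sequences must be equal length, in frame 0 (the caller aligns/trims).
#' Codon pairs are excluded when either codon contains a gap or ambiguity
#' code or is a stop codon. The Jukes-Cantor correction maps pS/pN to
#' Ks/Ka; the ratio is `NA` (undefined flag) when Ks is 0 or a log
#' argument is non-positive (saturation).
#'
#' @param cds_a,cds_b Coding-orientation DNA strings of equal length,
#'   multiples of 3.
#' @return Object of class `ng86`: list with `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `Ks`, `Ka`, `ratio`, `n_codons_compared`, `saturated`.
#' @export
ng86 <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("sequences differ in length", call. = FALSE)
  }
  if (nchar(cds_a) %% 3L != 0L) {
    stop("sequence length not a multiple of 3", call. = FALSE)
  }
  tb <- ng86_tables()
  code <- mito_genetic_code()
  ca <- codon_split(cds_a); cb <- codon_split(cds_b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  clean <- clean & ca %in% sense_codons() & cb %in% sense_codons()
  ca <- ca[clean]; cb <- cb[clean]
  n <- length(ca)
  if (n == 0L) {
    return(structure(list(S = 0, N = 0, Sd = 0, Nd = 0, pS = NA_real_,
                          pN = NA_real_, Ks = NA_real_, Ka = NA_real_,
                          ratio = NA_real_, n_codons_compared = 0L,
                          saturated = FALSE), class = "ng86"))
  }
  S <- (sum(tb$syn_sites[ca]) + sum(tb$syn_sites[cb])) / 2
  N <- 3 * n - S
  sd_nd <- vapply(seq_len(n), function(i) {
    if (ca[i] == cb[i]) c(sd = 0, nd = 0) else ng86_pair_counts(ca[i], cb[i])
  }, numeric(2))
  Sd <- sum(sd_nd[1, ]); Nd <- sum(sd_nd[2, ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_correct(pS); Ka <- jc_correct(pN)
  saturated <- (!is.na(pS) && pS >= 3 / 4) || (!is.na(pN) && pN >= 3 / 4)
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio, n_codons_compared = n,
                 saturated = saturated),
            class = "ng86")
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf(
    "<ng86> %d codons | S=%.2f N=%.2f | Sd=%.2f Nd=%.2f | Ks=%s Ka=%s Ka/Ks=%s%s\n",
    x$n_codons_compared, x$S, x$N, x$Sd, x$Nd,
    formatC(x$Ks, digits = 4), formatC(x$Ka, digits = 4),
    if (is.na(x$ratio)) "undefined" else formatC(x$ratio, digits = 4),
    if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' @rdname tidy_mitocomp
#' @export
tidy.ng86 <- function(x, ...) {
  tibble::tibble(S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd, pS = x$pS,
                 pN = x$pN, Ks = x$Ks, Ka = x$Ka, ratio = x$ratio,
                 n_codons_compared = x$n_codons_compared,
                 saturated = x$saturated)
}

#' Ka/Ks of genomes against a reference taxon
#'
#' Per-gene and concatenated NG86 rates of each genome's protein-coding
#' genes against the orthologue in a designated reference genome (the
#' conventional outgroup comparison). Inputs are expected to be directly
#' comparable (same length); unequal pairs are truncated to the shared
#' codon span, which is only appropriate for closely length-conserved
#' mitochondrial PCGs or pre-aligned input.
#'
#' @param genomes List of `mitogenome` objects.
#' @param reference A `mitogenome` providing the reference sequence.
#' @param genes Canonical PCG names to compare (default: all 13).
#' @return Tibble with one row per (accession, gene) plus a
#'   `"concatenated"` row per accession; `absent` flags genes missing from
#'   a genome. Undefined ratios are `NA`, never 0.
#' @export
rates_vs_reference <- function(genomes, reference, genes = MITO_PCGS) {
  purrr::map_dfr(genomes, function(g) {
    acc_a <- character(0); acc_b <- character(0)
    rows <- purrr::map_dfr(genes, function(gene) {
      sa <- extract_gene_sequence(g, gene)
      sb <- extract_gene_sequence(reference, gene)
      if (is.na(sa) || is.na(sb)) {
        return(tibble::tibble(accession = g$accession, gene = gene,
                              absent = TRUE, Ka = NA_real_, Ks = NA_real_,
                              ratio = NA_real_, saturated = NA))
      }
      L <- (min(nchar(sa), nchar(sb)) %/% 3L) * 3L
      sa <- substr(sa, 1L, L); sb <- substr(sb, 1L, L)
      acc_a <<- c(acc_a, sa); acc_b <<- c(acc_b, sb)
      r <- ng86(sa, sb)
      tibble::tibble(accession = g$accession, gene = gene, absent = FALSE,
                     Ka = r$Ka, Ks = r$Ks, ratio = r$ratio,
                     saturated = r$saturated)
    })
    if (length(acc_a)) {
      r <- ng86(paste(acc_a, collapse = ""), paste(acc_b, collapse = ""))
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        accession = g$accession, gene = "concatenated", absent = FALSE,
        Ka = r$Ka, Ks = r$Ks, ratio = r$ratio, saturated = r$saturated))
    }
    rows
  })
}

#' Grouped bar plot of Ka, Ks and Ka/Ks per species
#'
#' @param rates_tbl Output of [rates_vs_reference()] (typically the
#'   concatenated rows).
#' @return A ggplot object.
#' @export
plot_rates <- function(rates_tbl) {
  long <- tidyr::pivot_longer(
    rates_tbl[!rates_tbl$absent, c("accession", "gene", "Ka", "Ks", "ratio")],
    cols = c("Ka", "Ks", "ratio"), names_to = "quantity")
  long$quantity <- factor(long$quantity, levels = c("Ka", "Ks", "ratio"),
                          labels = c("Ka", "Ks", "Ka/Ks"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$accession, y = .data$value,
                                     fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
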