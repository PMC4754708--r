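# Partitioned supermatrix construction and substitution-saturation
# screening.
#
# Matrix variants follow mitogenome practice: P123 = all three codon
# positions of the PCGs; P123R = P123 plus rRNA and tRNA genes; P12T =
# P123R minus saturated partitions (by default every PCG third position
# and both rRNAs); AA = translated PCGs. Nucleotide matrices keep genes as
# contiguous blocks with codon-position charsets defined by a stride of 3
# ("start-end\3"), the layout PartitionFinder/RAxML partition files use.

ALIGN_GAP <- "-"

#' Read an aligned FASTA file
#'
#' @param path FASTA path (nucleotide or amino acid).
#' @return Named character vector of equal-length aligned sequences,
#'   uppercase.
#' @export
read_alignment_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "AA")
  out <- toupper(vapply(recs, as.character, character(1)))
  names(out) <- names(recs)
  if (length(unique(nchar(out))) > 1L) {
    stop("sequences in ", path, " are not aligned (unequal lengths)",
         call. = FALSE)
  }
  out
}

check_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L,
            !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (length(unique(nchar(seqs))) > 1L) {
    stop("alignment rows have unequal length", call. = FALSE)
  }
  invisible(seqs)
}

#' Split an in-frame alignment into the three codon positions
#'
#' Columns 1,4,7,... go to position 1, and so on. Re-interleaving the
#' three outputs reproduces the input.
#'
#' @param seqs Named character vector (aligned, length a multiple of 3,
#'   frame 0).
#' @return List of three named character vectors (`pos1`, `pos2`, `pos3`).
#' @export
split_codon_positions <- function(seqs) {
  check_alignment(seqs)
  L <- nchar(seqs[[1]])
  if (L %% 3L != 0L) stop("alignment length not a multiple of 3",
                          call. = FALSE)
  pick <- function(k) {
    idx <- seq(k, L, by = 3L)
    vapply(seqs, function(s) {
      paste(seq_chars(s)[idx], collapse = "")
    }, character(1))
  }
  list(pos1 = pick(1L), pos2 = pick(2L), pos3 = pick(3L))
}

#' Translate an in-frame nucleotide alignment
#'
#' Translation table 5; codons containing a gap (or ambiguity) become the
#' gap residue. Internal stops are reported in the `internal_stops`
#' attribute rather than silently translated.
#'
#' @param seqs Named character vector (aligned, length a multiple of 3).
#' @return Named character vector of aligned amino-acid sequences, with
#'   attribute `internal_stops` (tibble taxon/codon_index) when present.
#' @export
translate_alignment <- function(seqs) {
  check_alignment(seqs)
  L <- nchar(seqs[[1]])
  if (L %% 3L != 0L) stop("alignment length not a multiple of 3",
                          call. = FALSE)
  code <- mito_genetic_code()
  stops <- list()
  out <- vapply(names(seqs), function(tx) {
    cods <- codon_split(toupper(seqs[[tx]]))
    aa <- vapply(seq_along(cods), function(i) {
      cod <- cods[i]
      if (!grepl("^[ACGT]{3}$", cod)) return(ALIGN_GAP)
      r <- code[[cod]]
      if (r == "*") {
        if (i < length(cods)) {
          stops[[length(stops) + 1L]] <<- tibble::tibble(taxon = tx,
                                                         codon_index = i)
        }
        return(ALIGN_GAP)
      }
      r
    }, character(1))
    paste(aa, collapse = "")
  }, character(1))
  if (length(stops)) attr(out, "internal_stops") <- dplyr::bind_rows(stops)
  out
}

# Fill missing taxa with gap-only rows and order rows consistently.
gap_fill <- function(seqs, taxa) {
  L <- nchar(seqs[[1]])
  out <- stats::setNames(rep(strrep(ALIGN_GAP, L), length(taxa)), taxa)
  out[names(seqs)] <- unname(seqs)
  out
}

#' Build a partitioned supermatrix
#'
#' Concatenates per-gene alignments into one of four matrix variants,
#' gap-filling taxa that lack a gene, and emits a charset table. PCG
#' blocks get codon-position charsets (`<gene>_p1/2/3`, stride 3); RNA
#' genes get per-gene charsets. `trnI` and `trnQ` are excluded from the
#' RNA complement by default (they are missing from too many partial
#' mitogenomes to align usefully).
#'
#' @param gene_alignments Named list: canonical gene name -> named
#'   character vector of aligned sequences (in-frame nucleotides for
#'   PCGs).
#' @param variant `"P123"`, `"P123R"`, `"P12T"` or `"AA"`.
#' @param exclusions Charset names dropped for `P12T` (default: every PCG
#'   third position and both rRNAs, the partitions that show saturation).
#' @param exclude_trnas tRNAs never included in RNA blocks.
#' @return Object of class `supermatrix`: `variant`, `seqs` (named
#'   character vector), `charsets` tibble (partition, start, end, stride;
#'   1-based inclusive columns), `n_sites`, `taxa`.
#' @export
build_matrix <- function(gene_alignments,
                         variant = c("P123", "P123R", "P12T", "AA"),
                         exclusions = NULL,
                         exclude_trnas = c("trnI", "trnQ")) {
  variant <- match.arg(variant)
  stopifnot(length(gene_alignments) >= 1L, !is.null(names(gene_alignments)))
  purrr::walk(gene_alignments, check_alignment)
  cls <- gene_class(names(gene_alignments))
  pcg <- names(gene_alignments)[cls %in% "PCG"]
  rna <- setdiff(names(gene_alignments)[cls %in% c("rRNA", "tRNA")],
                 exclude_trnas)
  pcg <- pcg[order(match(pcg, MITO_PCGS))]
  rna <- rna[order(match(rna, c(MITO_RRNAS, MITO_TRNAS)))]
  taxa <- sort(unique(unlist(lapply(gene_alignments, names))))

  if (variant == "AA") {
    if (!length(pcg)) stop("no PCG alignments supplied", call. = FALSE)
    blocks <- lapply(pcg, function(g) {
      gap_fill(translate_alignment(gene_alignments[[g]]), taxa)
    })
    names(blocks) <- pcg
    return(assemble_blocks(blocks, stride3 = character(0), variant, taxa))
  }

  genes <- switch(variant, P123 = pcg, P123R = , P12T = c(pcg, rna))
  if (!length(genes)) stop("no alignments selected", call. = FALSE)
  blocks <- lapply(genes, function(g) gap_fill(gene_alignments[[g]], taxa))
  names(blocks) <- genes
  sm <- assemble_blocks(blocks, stride3 = pcg, variant, taxa)
  if (variant != "P12T") return(sm)

  if (is.null(exclusions)) {
    exclusions <- c(paste0(pcg, "_p3"), intersect(c("rrnS", "rrnL"), genes))
  }
  drop_partitions(sm, exclusions)
}

assemble_blocks <- function(blocks, stride3, variant, taxa) {
  pos <- 0L
  charsets <- list()
  for (g in names(blocks)) {
    w <- nchar(blocks[[g]][[1]])
    if (g %in% stride3) {
      if (w %% 3L != 0L) stop("in-frame PCG block ", g,
                              " has length not a multiple of 3",
                              call. = FALSE)
      for (k in 1:3) {
        charsets[[length(charsets) + 1L]] <- tibble::tibble(
          partition = sprintf("%s_p%d", g, k), start = pos + k,
          end = pos + w, stride = 3L)
      }
    } else {
      charsets[[length(charsets) + 1L]] <- tibble::tibble(
        partition = g, start = pos + 1L, end = pos + w, stride = 1L)
    }
    pos <- pos + w
  }
  seqs <- vapply(taxa, function(tx) {
    paste(vapply(blocks, function(b) b[[tx]], character(1)), collapse = "")
  }, character(1))
  structure(list(variant = variant, seqs = seqs,
                 charsets = dplyr::bind_rows(charsets), n_sites = pos,
                 taxa = taxa),
            class = "supermatrix")
}

charset_columns <- function(cs) {
  unlist(lapply(seq_len(nrow(cs)), function(i) {
    seq(cs$start[i], cs$end[i], by = cs$stride[i])
  }))
}

# Remove named partitions, reordering the remaining columns into
# contiguous, stride-1 charset blocks.
drop_partitions <- function(sm, exclusions) {
  unknown <- setdiff(exclusions, sm$charsets$partition)
  if (length(unknown)) {
    stop("unknown partition(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- sm$charsets[!(sm$charsets$partition %in% exclusions), ]
  if (!nrow(keep)) stop("no partitions left after exclusions", call. = FALSE)
  cols <- list(); charsets <- list(); pos <- 0L
  for (i in seq_len(nrow(keep))) {
    idx <- seq(keep$start[i], keep$end[i], by = keep$stride[i])
    cols[[i]] <- idx
    charsets[[i]] <- tibble::tibble(partition = keep$partition[i],
                                    start = pos + 1L,
                                    end = pos + length(idx), stride = 1L)
    pos <- pos + length(idx)
  }
  idx <- unlist(cols)
  seqs <- vapply(sm$seqs, function(s) {
    paste(seq_chars(s)[idx], collapse = "")
  }, character(1))
  structure(list(variant = "P12T", seqs = seqs,
                 charsets = dplyr::bind_rows(charsets), n_sites = pos,
                 taxa = sm$taxa),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix %s> %d taxa x %d sites, %d partition(s)\n",
              x$variant, length(x$seqs), x$n_sites, nrow(x$charsets)))
  invisible(x)
}

sanitize_taxa <- function(taxa) {
  clean <- gsub("[^A-Za-z0-9_.]", "_", taxa)
  clean <- make.unique(clean, sep = "_")
  tibble::tibble(original = taxa, sanitized = clean)
}

raxml_partition_lines <- function(charsets, datatype = "DNA") {
  vapply(seq_len(nrow(charsets)), function(i) {
    rng <- if (charsets$stride[i] > 1L) {
      sprintf("%d-%d\\%d", charsets$start[i], charsets$end[i],
              charsets$stride[i])
    } else {
      sprintf("%d-%d", charsets$start[i], charsets$end[i])
    }
    sprintf("%s, %s = %s", datatype, charsets$partition[i], rng)
  }, character(1))
}

#' Export a supermatrix with partition definitions
#'
#' Writes the alignment in NEXUS (with a `sets` block of charsets),
#' relaxed PHYLIP, or FASTA, and optionally a RAxML-style partition file
#' (`DNA, name = start-end` with `\3` strides for codon-position
#' charsets). Taxon names with characters outside `[A-Za-z0-9_.]` are
#' sanitized; the mapping is returned. Output is byte-stable for a fixed
#' input.
#'
#' @param matrix A `supermatrix`.
#' @param path Alignment output path.
#' @param format `"NEXUS"`, `"PHYLIP"` or `"FASTA"`.
#' @param partition_path Optional path for a RAxML partition file.
#' @return Invisibly, the taxon-name mapping tibble.
#' @export
export_matrix <- function(matrix, path,
                          format = c("NEXUS", "PHYLIP", "FASTA"),
                          partition_path = NULL) {
  format <- match.arg(format)
  map <- sanitize_taxa(names(matrix$seqs))
  seqs <- stats::setNames(unname(matrix$seqs), map$sanitized)
  datatype <- if (matrix$variant == "AA") "protein" else "DNA"
  if (format == "NEXUS") {
    x <- lapply(seqs, function(s) seq_chars(tolower(s)))
    ape::write.nexus.data(x, file = path, format = datatype,
                          interleaved = FALSE)
    sets <- c("begin sets;",
              vapply(seq_len(nrow(matrix$charsets)), function(i) {
                cs <- matrix$charsets[i, ]
                rng <- if (cs$stride > 1L) {
                  sprintf("%d-%d\\%d", cs$start, cs$end, cs$stride)
                } else sprintf("%d-%d", cs$start, cs$end)
                sprintf("  charset %s = %s;", cs$partition, rng)
              }, character(1)),
              "end;")
    cat(paste0(sets, "\n"), file = path, append = TRUE, sep = "")
  } else if (format == "PHYLIP") {
    lines <- c(sprintf("%d %d", length(seqs), matrix$n_sites),
               sprintf("%s  %s", names(seqs), unname(seqs)))
    writeLines(lines, path)
  } else {
    writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))),
               path)
  }
  if (!is.null(partition_path)) {
    writeLines(raxml_partition_lines(
      matrix$charsets, datatype = if (datatype == "protein") "MTART"
                                  else "DNA"), partition_path)
  }
  invisible(map)
}

# ---------------------------------------------------------------------------
# Saturation screening

#' Substitution-saturation screen of an alignment partition
#'
#' For every taxon pair, computes the p-distance (pairwise deletion of
#' gaps/ambiguity), transition and transversion proportions, and the
#' K80-corrected distance; then regresses p-distance on corrected
#' distance. Saturated sequence shows observed distances plateauing while
#' corrected distances grow: the partition is flagged when the slope
#' falls below `slope_threshold` (default 0.6) or the corrected distance
#' is undefined for more than 10% of pairs.
#'
#' @param seqs Named character vector of aligned nucleotide sequences
#'   (>= 3 taxa).
#' @param name Partition label carried into the result.
#' @param slope_threshold Slope below which the partition is flagged.
#' @return Object of class `saturation_result`: `pairs` tibble (taxon_a,
#'   taxon_b, n_sites, p_distance, s_proportion, v_proportion,
#'   corrected_distance), `slope`, `r_squared`, `prop_undefined`,
#'   `saturated`, `partition`.
#' @export
saturation_scan <- function(seqs, name = "partition",
                            slope_threshold = 0.6) {
  check_alignment(seqs)
  stopifnot(length(seqs) >= 3L)
  taxa <- names(seqs)
  mat <- do.call(rbind, lapply(seqs, seq_chars))
  is_base <- mat %in% c("A", "C", "G", "T")
  dim(is_base) <- dim(mat)
  purine <- mat %in% c("A", "G")
  dim(purine) <- dim(mat)
  pairs <- list()
  for (i in seq_len(length(taxa) - 1L)) {
    for (j in (i + 1L):length(taxa)) {
      ok <- is_base[i, ] & is_base[j, ]
      n <- sum(ok)
      if (n == 0L) {
        message("all-gap pair skipped: ", taxa[i], " / ", taxa[j])
        next
      }
      diff <- ok & (mat[i, ] != mat[j, ])
      ts <- diff & (purine[i, ] == purine[j, ])
      P <- sum(ts) / n
      Q <- (sum(diff) - sum(ts)) / n
      p <- P + Q
      a1 <- 1 - 2 * P - Q
      a2 <- 1 - 2 * Q
      d <- if (a1 > 0 && a2 > 0) -0.5 * log(a1 * sqrt(a2)) else NA_real_
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        taxon_a = taxa[i], taxon_b = taxa[j], n_sites = n,
        p_distance = p, s_proportion = P, v_proportion = Q,
        corrected_distance = d)
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  prop_undef <- mean(is.na(pairs$corrected_distance))
  ok <- !is.na(pairs$corrected_distance)
  slope <- NA_real_; r2 <- NA_real_
  if (sum(ok) >= 2L && stats::var(pairs$corrected_distance[ok]) > 0) {
    fit <- stats::lm(p_distance ~ corrected_distance, data = pairs[ok, ])
    slope <- unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  saturated <- (!is.na(slope) && slope < slope_threshold) ||
    prop_undef > 0.10
  structure(list(pairs = pairs, slope = slope, r_squared = r2,
                 prop_undefined = prop_undef, saturated = saturated,
                 partition = name, slope_threshold = slope_threshold),
            class = "saturation_result")
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf(
    "<saturation_result %s> slope %s, R^2 %s, %.0f%% undefined%s\n",
    x$partition, formatC(x$slope, digits = 3),
    formatC(x$r_squared, digits = 3), 100 * x$prop_undefined,
    if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' @rdname tidy_mitocomp
#' @export
tidy.saturation_result <- function(x, ...) x$pairs

#' @rdname tidy_mitocomp
#' @export
glance.saturation_result <- function(x, ...) {
  tibble::tibble(partition = x$partition, slope = x$slope,
                 r_squared = x$r_squared,
                 prop_undefined = x$prop_undefined,
                 saturated = x$saturated)
}

#' Saturation scatter plot
#'
#' Observed p-distance against K80-corrected distance, with the 1:1 line;
#' saturated partitions bend away below the diagonal.
#'
#' @param x A `saturation_result`, or a list of them.
#' @return A ggplot object.
#' @export
plot_saturation <- function(x) {
  if (inherits(x, "saturation_result")) x <- list(x)
  tbl <- purrr::map_dfr(x, function(r) {
    dplyr::mutate(r$pairs, partition = r$partition)
  })
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$corrected_distance,
                                    y = .data$p_distance,
                                    colour = .data$partition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "K80-corrected distance", y = "p-distance",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
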