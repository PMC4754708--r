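# Reading, writing, and normalizing annotated mitochondrial genomes.
#
# Internal coordinates are 0-based half-open; GenBank I/O converts from/to
# the 1-based inclusive convention at the boundary. A feature may span
# several genomic intervals (join locations, origin-spanning features on a
# circular molecule); intervals are stored in transcription order on the
# J-strand and the whole concatenation is reverse-complemented for
# N-strand genes.

#' Construct a mitogenome object
#'
#' Low-level constructor used by [read_genbank()] and
#' [simulate_mitogenome()]. Most users will not call this directly.
#'
#' @param accession Accession string.
#' @param organism Organism name.
#' @param sequence IUPAC DNA string (single string).
#' @param topology `"circular"` or `"linear"` (a linear sequenced region of
#'   a circular molecule).
#' @param features Tibble with columns `gene` (canonical name or `NA`),
#'   `label` (raw annotation label), `class` (`PCG`/`tRNA`/`rRNA`/`control`
#'   or `NA`), `strand` (`"J"` or `"N"`), `start`, `end` (0-based half-open
#'   span of the first/last interval), `length` (total nt), `anticodon`
#'   (triplet or `NA`), `note`, and list-column `intervals` (integer
#'   matrices with columns start, end).
#' @return Object of class `mitogenome`.
#' @export
new_mitogenome <- function(accession, organism, sequence, topology, features) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTRYSWKMBDHVN]*$", sequence)) {
    stop("sequence contains non-IUPAC letters", call. = FALSE)
  }
  topology <- match.arg(topology, c("circular", "linear"))
  len <- nchar(sequence)
  for (iv in features$intervals) {
    if (any(iv[, 1] < 0 | iv[, 2] > len | iv[, 1] >= iv[, 2])) {
      stop("feature interval outside [0, genome length)", call. = FALSE)
    }
  }
  dup_ok <- grepl("duplicate", features$note %||% "")
  named <- features$gene[!is.na(features$gene) & !dup_ok]
  if (anyDuplicated(named)) {
    stop("duplicated canonical gene names not flagged as duplicates: ",
         paste(unique(named[duplicated(named)]), collapse = ", "),
         call. = FALSE)
  }
  present <- features$gene[!is.na(features$gene)]
  complete <- all(setdiff(canonical_gene_names(), "AT_rich") %in% present)
  structure(
    list(accession = accession, organism = organism, sequence = sequence,
         topology = topology, features = features,
         sequenced_complete = complete),
    class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s (%s), %s, %d bp, %d features%s\n",
              x$accession, x$organism, x$topology, nchar(x$sequence),
              nrow(x$features),
              if (x$sequenced_complete) ", complete gene set" else ""))
  invisible(x)
}

#' Feature table of a mitogenome
#'
#' @param genome A `mitogenome`.
#' @param drop_duplicates Drop features flagged as duplicate annotations.
#' @return Tibble of features.
#' @export
feature_table <- function(genome, drop_duplicates = TRUE) {
  ft <- genome$features
  if (drop_duplicates) ft <- ft[!grepl("duplicate", ft$note %||% ""), ]
  ft
}

empty_features <- function() {
  tibble::tibble(gene = character(), label = character(), class = character(),
                 strand = character(), start = integer(), end = integer(),
                 length = integer(), anticodon = character(),
                 note = character(), intervals = list())
}

# ---------------------------------------------------------------------------
# Gene-name canonicalization

PCG_SYNONYMS <- c(
  "cox1" = "cox1", "coi" = "cox1", "co1" = "cox1", "coxi" = "cox1",
  "cytochromecoxidasesubuniti" = "cox1", "cytochromecoxidasesubunit1" = "cox1",
  "cox2" = "cox2", "coii" = "cox2", "co2" = "cox2", "coxii" = "cox2",
  "cytochromecoxidasesubunitii" = "cox2", "cytochromecoxidasesubunit2" = "cox2",
  "cox3" = "cox3", "coiii" = "cox3", "co3" = "cox3", "coxiii" = "cox3",
  "cytochromecoxidasesubunitiii" = "cox3", "cytochromecoxidasesubunit3" = "cox3",
  "cob" = "cob", "cytb" = "cob", "cytochromeb" = "cob", "cb" = "cob",
  "nad1" = "nad1", "nd1" = "nad1", "nadhdehydrogenasesubunit1" = "nad1",
  "nad2" = "nad2", "nd2" = "nad2", "nadhdehydrogenasesubunit2" = "nad2",
  "nad3" = "nad3", "nd3" = "nad3", "nadhdehydrogenasesubunit3" = "nad3",
  "nad4" = "nad4", "nd4" = "nad4", "nadhdehydrogenasesubunit4" = "nad4",
  "nad4l" = "nad4l", "nd4l" = "nad4l", "nadhdehydrogenasesubunit4l" = "nad4l",
  "nad5" = "nad5", "nd5" = "nad5", "nadhdehydrogenasesubunit5" = "nad5",
  "nad6" = "nad6", "nd6" = "nad6", "nadhdehydrogenasesubunit6" = "nad6",
  "atp6" = "atp6", "atpase6" = "atp6", "atpsynthasef0subunit6" = "atp6",
  "atpsynthasesubunit6" = "atp6",
  "atp8" = "atp8", "atpase8" = "atp8", "atpsynthasef0subunit8" = "atp8",
  "atpsynthasesubunit8" = "atp8",
  "rrnl" = "rrnL", "16s" = "rrnL", "16srrna" = "rrnL", "lrrna" = "rrnL",
  "16sribosomalrna" = "rrnL", "largesubunitribosomalrna" = "rrnL",
  "rrns" = "rrnS", "12s" = "rrnS", "12srrna" = "rrnS", "srrna" = "rrnS",
  "12sribosomalrna" = "rrnS", "smallsubunitribosomalrna" = "rrnS",
  "dloop" = "AT_rich", "atrich" = "AT_rich", "atrichregion" = "AT_rich",
  "controlregion" = "AT_rich", "atrich_region" = "AT_rich")

AA3_TO_TRNA <- c(
  ala = "trnA", cys = "trnC", asp = "trnD", glu = "trnE", phe = "trnF",
  gly = "trnG", his = "trnH", ile = "trnI", lys = "trnK", leu = "trnL",
  met = "trnM", asn = "trnN", pro = "trnP", gln = "trnQ", arg = "trnR",
  ser = "trnS", thr = "trnT", val = "trnV", trp = "trnW", tyr = "trnY")

#' Canonicalize a gene label
#'
#' Maps common annotation synonyms (COI, 16S, ND4L, tRNA-Leu, ...) onto the
#' package's canonical names. Duplicated leucine/serine tRNAs are resolved
#' by their anticodon (UAG -> `trnL1` for CUN codons, UAA -> `trnL2`;
#' UCU/GCU -> `trnS1` for AGN, UGA -> `trnS2`); without an anticodon the
#' ambiguous placeholders `"trnL"` / `"trnS"` are returned for the caller
#' to disambiguate positionally.
#'
#' @param raw_label Annotation label (gene or product qualifier).
#' @param anticodon Optional anticodon triplet (RNA or DNA alphabet).
#' @return Canonical name, `"trnL"`/`"trnS"` if ambiguous, or `NA` if the
#'   label cannot be mapped.
#' @export
canonicalize_gene_name <- function(raw_label, anticodon = NULL) {
  stopifnot(is.character(raw_label), nzchar(raw_label))
  key <- tolower(gsub("[^a-z0-9]", "", tolower(raw_label)))
  if (key %in% names(PCG_SYNONYMS)) return(unname(PCG_SYNONYMS[[key]]))
  if (raw_label %in% canonical_gene_names()) return(raw_label)

  # tRNA labels: trnL1, trnW, tRNA-Leu, trnS2, trn l (uag), ...
  m <- regmatches(key, regexec("^trna?([a-z]{1,3})([12]?)$", key))[[1]]
  if (length(m) == 3L) {
    aa <- m[2]; idx <- m[3]
    base <- if (nchar(aa) == 3L && aa %in% names(AA3_TO_TRNA)) {
      AA3_TO_TRNA[[aa]]
    } else if (nchar(aa) == 1L &&
               paste0("trn", toupper(aa)) %in%
                 c(MITO_TRNAS, "trnL", "trnS")) {
      paste0("trn", toupper(aa))
    } else NA_character_
    if (!is.na(base)) {
      if (nzchar(idx)) {
        cand <- paste0(base, idx)
        if (cand %in% MITO_TRNAS) return(cand)
      }
      if (base %in% c("trnL", "trnS")) {
        ac <- if (!is.null(anticodon) && !is.na(anticodon) && nzchar(anticodon))
          toupper(dna_to_rna(anticodon)) else ""
        if (base == "trnL") {
          if (ac == "UAG") return("trnL1")
          if (ac == "UAA") return("trnL2")
          return("trnL")
        } else {
          if (ac %in% c("UCU", "GCU")) return("trnS1")
          if (ac == "UGA") return("trnS2")
          return("trnS")
        }
      }
      return(base)
    }
  }
  NA_character_
}

# ---------------------------------------------------------------------------
# GenBank flat-file reading

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses the first record of a GenBank flat file (LOCUS, ACCESSION,
#' ORGANISM, FEATURES with CDS/tRNA/rRNA/D-loop/misc_feature entries,
#' ORIGIN), canonicalizes gene names, and converts coordinates to the
#' internal 0-based half-open convention. Unrecognizable features are
#' retained with `class = NA` and a warning. Duplicate annotations of one
#' gene keep the longest; the rest are flagged `"duplicate"`. Ambiguous
#' Leu/Ser tRNAs lacking an anticodon are assigned `L1/L2` or `S1/S2` by
#' positional match to the ancestral insect gene order and flagged
#' `"inferred"`.
#'
#' @param path Path to a GenBank flat file.
#' @return A `mitogenome`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop("not a GenBank flat file (missing LOCUS line): ", path, call. = FALSE)
  }
  topology <- if (grepl("circular", lines[1], ignore.case = TRUE))
    "circular" else "linear"
  accession <- NA_character_
  organism <- NA_character_
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) accession <- strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  org_line <- grep("^ {2}ORGANISM", lines, value = TRUE)
  if (length(org_line)) organism <- trimws(sub("^ {2}ORGANISM", "", org_line[1]))

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (!length(feat_start) || !length(origin_start)) {
    stop("malformed GenBank record (missing FEATURES or ORIGIN): ", path,
         call. = FALSE)
  }
  end_rec <- grep("^//", lines)
  end_rec <- if (length(end_rec)) end_rec[1] else length(lines) + 1L

  # sequence
  seq_lines <- lines[(origin_start[1] + 1L):(end_rec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  # raw features: key + location (possibly continued) + qualifiers
  flines <- lines[(feat_start[1] + 1L):(origin_start[1] - 1L)]
  raw <- list(); cur <- NULL; cur_qual <- NULL
  for (i in seq_along(flines)) {
    ln <- flines[i]
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) raw[[length(raw) + 1L]] <- cur
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      loc <- trimws(sub("^ {5}\\S+\\s*", "", ln))
      cur <- list(key = key, loc = loc, quals = list(), line = i)
      cur_qual <- NULL
    } else if (grepl("^\\s+/", ln)) {
      q <- sub("^\\s+/", "", ln)
      eq <- regexpr("=", q, fixed = TRUE)
      if (eq > 0) {
        nm <- substr(q, 1L, eq - 1L)
        val <- gsub("^\"|\"$", "", substr(q, eq + 1L, nchar(q)))
      } else {
        nm <- q; val <- TRUE
      }
      cur$quals[[nm]] <- val
      cur_qual <- nm
    } else if (!is.null(cur)) {
      ext <- trimws(ln)
      if (is.null(cur_qual)) {
        cur$loc <- paste0(cur$loc, ext)  # continued location
      } else {
        cur$quals[[cur_qual]] <-
          gsub("^\"|\"$", "", paste(cur$quals[[cur_qual]], ext))
      }
    }
  }
  if (!is.null(cur)) raw[[length(raw) + 1L]] <- cur

  keep_keys <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")
  rows <- list()
  for (f in raw) {
    if (f$key == "source") {
      if (is.na(organism) && !is.null(f$quals$organism))
        organism <- f$quals$organism
      next
    }
    if (!f$key %in% keep_keys) next
    loc <- tryCatch(parse_gb_location(f$loc), error = function(e) {
      stop(sprintf("malformed location '%s' at feature line %d: %s",
                   f$loc, f$line, conditionMessage(e)), call. = FALSE)
    })
    label <- f$quals$gene %||% f$quals$product %||% f$quals$note %||% f$key
    anticodon <- parse_anticodon_qualifier(f$quals$anticodon)
    gene <- switch(f$key,
      "D-loop" = "AT_rich",
      canonicalize_gene_name(label, anticodon))
    if (f$key == "misc_feature" &&
        (is.na(gene) || is.null(gene)) &&
        grepl("a\\+?t[- ]rich|control region", tolower(label))) {
      gene <- "AT_rich"
    }
    cls <- if (!is.na(gene) && gene %in% c("trnL", "trnS")) "tRNA"
           else gene_class(gene)
    iv <- loc$intervals
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = if (is.na(gene)) NA_character_ else gene,
      label = as.character(label), class = cls,
      strand = if (loc$complement) "N" else "J",
      start = iv[1L, 1L], end = iv[nrow(iv), 2L],
      length = sum(iv[, 2L] - iv[, 1L]),
      anticodon = anticodon %||% NA_character_,
      note = "", intervals = list(iv))
  }
  if (!length(rows)) stop("no features found in ", path, call. = FALSE)
  ft <- dplyr::bind_rows(rows)

  # positional disambiguation of ambiguous Leu/Ser tRNAs
  ft <- resolve_ambiguous_trnas(ft)

  if (any(is.na(ft$gene))) {
    warning(sprintf("%d unrecognized feature(s) retained (labels: %s)",
                    sum(is.na(ft$gene)),
                    paste(utils::head(ft$label[is.na(ft$gene)], 3),
                          collapse = ", ")), call. = FALSE)
  }
  if (!any(!is.na(ft$gene))) {
    stop("no recognized mitochondrial genes in ", path, call. = FALSE)
  }

  # duplicates: per canonical name keep the longest, flag the rest
  for (g in unique(stats::na.omit(ft$gene))) {
    idx <- which(ft$gene == g)
    if (length(idx) > 1L) {
      keep <- idx[which.max(ft$length[idx])]
      losers <- setdiff(idx, keep)
      ft$note[losers] <- paste0(ft$note[losers], "duplicate")
    }
  }

  new_mitogenome(accession, organism, sequence, topology, ft)
}

# Parse a GenBank location string into intervals (0-based half-open) and a
# complement flag. Supports n..m, single positions, join(), order(),
# complement() (outermost), and <, > partial markers.
parse_gb_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  complement <- FALSE
  if (grepl("^complement\\(", loc)) {
    complement <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  iv <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      se <- rep(as.integer(p), 2L)
    }
    if (any(is.na(se)) || se[2] < se[1]) stop("bad span '", p, "'")
    c(se[1] - 1L, se[2])
  }, integer(2)))
  dimnames(iv) <- NULL
  list(intervals = iv, complement = complement)
}

parse_anticodon_qualifier <- function(q) {
  if (is.null(q) || isTRUE(q)) return(NULL)
  m <- regmatches(q, regexec("seq:([A-Za-z]{3})", q))[[1]]
  if (length(m) == 2L) return(toupper(m[2]))
  q <- gsub("[^A-Za-z]", "", q)
  if (nchar(q) == 3L) toupper(q) else NULL
}

# Assign trnL -> trnL1/trnL2 and trnS -> trnS1/trnS2 by positional match to
# the ancestral arrangement (neighbouring genes), flagged "inferred".
resolve_ambiguous_trnas <- function(ft) {
  amb <- which(ft$gene %in% c("trnL", "trnS"))
  if (!length(amb)) return(ft)
  ord <- order(vapply(ft$intervals, function(iv) iv[1, 1], numeric(1)))
  pos <- match(seq_len(nrow(ft)), ord)  # rank of each row in genomic order
  n <- nrow(ft)
  neighbours <- function(i) {
    r <- pos[i]
    idx <- ord[c((r - 2):(r - 1), (r + 1):(r + 2))]
    idx <- idx[!is.na(idx) & idx >= 1 & idx <= n]
    ft$gene[idx]
  }
  for (i in amb) {
    nb <- neighbours(i)
    assigned <- if (ft$gene[i] == "trnL") {
      if (any(nb %in% c("cox1", "cox2"))) "trnL2"
      else if (any(nb %in% c("nad1", "rrnL"))) "trnL1"
      else if (!"trnL1" %in% ft$gene) "trnL1" else "trnL2"
    } else {
      if (any(nb %in% c("trnN", "trnE"))) "trnS1"
      else if (any(nb %in% c("cob", "nad1"))) "trnS2"
      else if (!"trnS1" %in% ft$gene) "trnS1" else "trnS2"
    }
    ft$gene[i] <- assigned
    ft$note[i] <- paste0(ft$note[i], "inferred")
  }
  ft
}

# ---------------------------------------------------------------------------
# Writing

#' Write a mitogenome as a GenBank flat file
#'
#' Inverse of [read_genbank()]: emits LOCUS/ACCESSION/ORGANISM, a feature
#' table (CDS, tRNA, rRNA, D-loop entries with gene/product/anticodon
#' qualifiers), and the ORIGIN sequence block. Reading the emitted file
#' back reproduces sequence, feature names, strands and coordinates
#' exactly.
#'
#' @param genome A `mitogenome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  len <- nchar(genome$sequence)
  topo <- if (genome$topology == "circular") "circular" else "linear  "
  out <- c(
    sprintf("LOCUS       %-16s %6d bp    DNA     %s INV 01-JAN-2026",
            genome$accession, len, topo),
    sprintf("DEFINITION  %s mitochondrion.", genome$organism),
    sprintf("ACCESSION   %s", genome$accession),
    "SOURCE      mitochondrion",
    sprintf("  ORGANISM  %s", genome$organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len),
    sprintf("                     /organism=\"%s\"", genome$organism))

  qual <- function(name, value) {
    sprintf("                     /%s=\"%s\"", name, value)
  }
  ft <- genome$features
  for (i in seq_len(nrow(ft))) {
    iv <- ft$intervals[[i]]
    spans <- sprintf("%d..%d", iv[, 1] + 1L, iv[, 2])
    loc <- if (length(spans) > 1L)
      sprintf("join(%s)", paste(spans, collapse = ",")) else spans
    if (ft$strand[i] == "N") loc <- sprintf("complement(%s)", loc)
    key <- switch(ft$class[i] %||% "misc_feature",
                  PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control = "D-loop", "misc_feature")
    if (is.na(ft$class[i])) key <- "misc_feature"
    out <- c(out, sprintf("     %-15s %s", key, loc))
    g <- ft$gene[i]
    lbl <- if (!is.na(g) && g != "AT_rich") g else ft$label[i]
    if (!is.na(g) && g != "AT_rich") out <- c(out, qual("gene", g))
    prod <- if (is.na(g)) ft$label[i]
      else if (g %in% MITO_TRNAS) sprintf("tRNA-%s", TRNA_AA[[g]])
      else if (g == "AT_rich") "A+T-rich region"
      else g
    if (key != "D-loop") out <- c(out, qual("product", prod))
    if (key == "D-loop") out <- c(out, qual("note", "A+T-rich region"))
    if (!is.na(ft$anticodon[i]) && nzchar(ft$anticodon[i])) {
      out <- c(out, qual("anticodon", sprintf("(seq:%s)",
                                              tolower(ft$anticodon[i]))))
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$sequence)
  starts <- seq(1L, len, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, len))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Write the feature table as TSV
#'
#' Columns: accession, gene, class, strand, start, end, length (0-based
#' half-open coordinates).
#'
#' @param genome A `mitogenome`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(genome, path) {
  ft <- feature_table(genome)
  out <- tibble::tibble(accession = genome$accession, gene = ft$gene,
                        class = ft$class, strand = ft$strand,
                        start = ft$start, end = ft$end, length = ft$length)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-gene FASTA
#'
#' Writes the coding-orientation sequence of each selected gene, one FASTA
#' record per gene, headers `accession|gene`.
#'
#' @param genome A `mitogenome`.
#' @param path Output FASTA path.
#' @param genes Canonical names to write (default: all named features).
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genome, path, genes = NULL) {
  ft <- feature_table(genome)
  genes <- genes %||% stats::na.omit(ft$gene)
  con <- file(path, "w"); on.exit(close(con))
  for (g in genes) {
    s <- extract_gene_sequence(genome, g)
    if (is.na(s)) next
    writeLines(c(sprintf(">%s|%s", genome$accession, g), s), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Extraction

#' Extract the coding-orientation sequence of a gene
#'
#' Concatenates the feature's genomic intervals (handling origin-spanning
#' features of circular molecules, stored as multiple intervals) and
#' reverse-complements the result for N-strand genes, returning the
#' sense-strand sequence 5'->3'.
#'
#' @param genome A `mitogenome`.
#' @param name Canonical gene name.
#' @return DNA string, or `NA` if the gene is absent (missing genes are a
#'   signal, not an error, at pipeline level).
#' @export
extract_gene_sequence <- function(genome, name) {
  ft <- feature_table(genome)
  i <- which(ft$gene == name)
  if (!length(i)) return(NA_character_)
  i <- i[1L]
  iv <- ft$intervals[[i]]
  s <- paste(substring(genome$sequence, iv[, 1] + 1L, iv[, 2]), collapse = "")
  if (ft$strand[i] == "N") s <- revcomp(s)
  s
}
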