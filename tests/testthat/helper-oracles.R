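# Independent brute-force oracles, deliberately coded differently from the
# package implementation.

oracle_code <- function() Biostrings::getGeneticCode("5")

# Synonymous site count of one codon: fraction of the nine single-base
# changes that preserve the amino acid (changes to stops count as
# nonsynonymous).
oracle_syn_sites <- function(codon) {
  code <- oracle_code()
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == ch[pos]) next
      mut <- ch
      mut[pos] <- b
      if (code[[paste(mut, collapse = "")]] == code[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# All orderings of a vector, via recursive insertion (distinct from the
# selection-recursion used in the package).
oracle_orderings <- function(v) {
  if (length(v) <= 1L) return(list(v))
  shorter <- oracle_orderings(v[-1L])
  out <- list()
  for (s in shorter) {
    for (k in 0:length(s)) {
      out[[length(out) + 1L]] <- append(s, v[1L], after = k)
    }
  }
  out
}

# Pathway-averaged synonymous/nonsynonymous differences for a codon pair.
oracle_pair_diffs <- function(c1, c2) {
  code <- oracle_code()
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(0, 0))
  acc <- matrix(numeric(0), ncol = 2)
  for (ord in oracle_orderings(pos)) {
    cur <- a
    sd <- 0
    nd <- 0
    valid <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      if (code[[paste(nxt, collapse = "")]] == "*") {
        valid <- FALSE
        break
      }
      if (code[[paste(cur, collapse = "")]] ==
          code[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (valid) acc <- rbind(acc, c(sd, nd))
  }
  if (nrow(acc)) {
    colMeans(acc)
  } else {
    sbar <- (oracle_syn_sites(c1) + oracle_syn_sites(c2)) / 2
    c(length(pos) * sbar / 3, length(pos) * (1 - sbar / 3))
  }
}

# Full NG86 recount for two aligned in-frame sequences.
oracle_ng86 <- function(s1, s2) {
  code <- oracle_code()
  stops <- names(code)[code == "*"]
  n <- nchar(s1) %/% 3
  ca <- substring(s1, 3 * seq_len(n) - 2, 3 * seq_len(n))
  cb <- substring(s2, 3 * seq_len(n) - 2, 3 * seq_len(n))
  keep <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    !(ca %in% stops) & !(cb %in% stops)
  ca <- ca[keep]
  cb <- cb[keep]
  S <- mean(c(sum(vapply(ca, oracle_syn_sites, numeric(1))),
              sum(vapply(cb, oracle_syn_sites, numeric(1)))))
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) oracle_pair_diffs(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d[1, ])
  Nd <- sum(d[2, ])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (1 - 4 / 3 * p <= 0) NA_real_ else
    -3 / 4 * log(1 - 4 / 3 * p)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       Ks = jc(pS), Ka = jc(pN),
       ratio = if (!is.na(jc(pS)) && jc(pS) > 0) jc(pN) / jc(pS)
               else NA_real_)
}

# Brute-force breakpoint count via explicit adjacency enumeration.
oracle_breakpoints <- function(a, b) {
  adjacencies <- function(o) {
    n <- nrow(o)
    out <- character(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      fwd <- sprintf("%+d%s/%+d%s", o$sign[i], o$gene[i], o$sign[j],
                     o$gene[j])
      mir <- sprintf("%+d%s/%+d%s", -o$sign[j], o$gene[j], -o$sign[i],
                     o$gene[i])
      out <- c(out, if (fwd < mir) fwd else mir)
    }
    unique(out)
  }
  sum(!(adjacencies(a) %in% adjacencies(b)))
}

random_gene_order <- function(n) {
  mitocomp:::new_gene_order(sample(paste0("g", seq_len(n))),
                            sample(c(-1L, 1L), n, replace = TRUE))
}
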