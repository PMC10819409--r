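# Independent brute-force oracles. These deliberately avoid the package's
# vectorised search internals: plain character vectors, per-position loops,
# and their own IUPAC/complement tables.

.orc_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

orc_revcomp <- function(s) {
  from <- "ACGTRYSWKMBDHVN"
  to <- "TGCAYRSWMKVHDBN"
  paste(rev(strsplit(chartr(from, to, toupper(s)), "")[[1]]), collapse = "")
}

.orc_mm <- function(gch, pch) sum(gch != pch | gch == "N")

# minimal mismatches of pattern vs a genomic span under one bulge setting
.orc_span_mm <- function(span, pat, btype, b) {
  L <- length(pat)
  if (btype == "none") return(.orc_mm(span, pat))
  best <- Inf
  if (btype == "dna") {
    for (j in seq_len(L - 1L)) {
      mm <- .orc_mm(span[seq_len(j)], pat[seq_len(j)]) +
        .orc_mm(span[(j + b + 1L):(L + b)], pat[(j + 1L):L])
      if (mm < best) best <- mm
    }
  } else {
    for (j in seq_len(L - b - 1L)) {
      mm <- .orc_mm(span[seq_len(j)], pat[seq_len(j)]) +
        .orc_mm(span[(j + 1L):(L - b)], pat[(j + b + 1L):L])
      if (mm < best) best <- mm
    }
  }
  best
}

.orc_pam_ok <- function(chars, at, pam) {
  G <- length(chars)
  plen <- length(pam)
  if (at < 1L || at + plen - 1L > G) return(FALSE)
  for (i in seq_len(plen)) {
    b <- chars[[at + i - 1L]]
    if (b == "N" || !(b %in% .orc_iupac[[pam[[i]]]])) return(FALSE)
  }
  TRUE
}

# exhaustive enumeration of every window and every single-bulge alignment
orc_find_sites <- function(genome, guide, max_mm, max_bulge) {
  L <- nchar(guide$protospacer)
  rows <- list()
  for (cname in names(genome)) {
    chars <- strsplit(genome[[cname]], "")[[1]]
    G <- length(chars)
    for (strand in c("+", "-")) {
      pat <- strsplit(if (strand == "+") guide$protospacer
                      else orc_revcomp(guide$protospacer), "")[[1]]
      pam <- strsplit(if (strand == "+") guide$pam_pattern
                      else orc_revcomp(guide$pam_pattern), "")[[1]]
      pam_after <- if (strand == "+") guide$pam_side == "three_prime"
                   else guide$pam_side != "three_prime"
      configs <- list(list("none", 0L))
      if (max_bulge > 0L) for (b in seq_len(max_bulge))
        configs <- c(configs, list(list("dna", b), list("rna", b)))
      for (cf in configs) {
        btype <- cf[[1]]; b <- cf[[2]]
        slen <- L + if (btype == "dna") b else if (btype == "rna") -b else 0L
        if (slen > G) next
        for (p in seq_len(G - slen + 1L)) {
          span <- chars[p:(p + slen - 1L)]
          if (any(span == "N")) next
          mm <- .orc_span_mm(span, pat, btype, b)
          if (mm > max_mm) next
          pat_at <- if (pam_after) p + slen else p - length(pam)
          if (!.orc_pam_ok(chars, pat_at, pam)) next
          rows[[length(rows) + 1L]] <- data.frame(
            contig = cname, start = p, end = p + slen - 1L, strand = strand,
            mismatches = mm,
            dna_bulge = if (btype == "dna") b else 0L,
            rna_bulge = if (btype == "rna") b else 0L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), dna_bulge = integer(),
                      rna_bulge = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start, out$strand, out$end), , drop = FALSE]
}

# engine output reduced to the oracle's comparable columns
site_key_frame <- function(sites) {
  out <- sites[, c("contig", "start", "end", "strand", "mismatches",
                   "dna_bulge", "rna_bulge")]
  out <- out[order(out$contig, out$start, out$strand, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force ungapped window scan for the string-search screen
orc_window_scan <- function(genome, contig, vstart, vend, proto, window,
                            max_mm) {
  chars <- strsplit(genome[[contig]], "")[[1]]
  G <- length(chars)
  ws <- max(1L, vstart - window); we <- min(G, vend + window)
  L <- nchar(proto)
  rows <- list()
  for (orient in c("plus", "minus")) {
    pat <- strsplit(if (orient == "plus") proto else orc_revcomp(proto),
                    "")[[1]]
    for (p in ws:(we - L + 1L)) {
      mm <- .orc_mm(chars[p:(p + L - 1L)], pat)
      if (mm <= max_mm)
        rows[[length(rows) + 1L]] <- data.frame(
          match_start = p, match_end = p + L - 1L, orientation = orient,
          mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(match_start = integer(), match_end = integer(),
                      orientation = character(), mismatches = integer()))
  out <- do.call(rbind, rows)
  out[order(out$match_start, out$orientation), , drop = FALSE]
}

# numerical-integration oracle for the upper tail of the t distribution
orc_t_tail <- function(t, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, lower = t, upper = Inf, rel.tol = 1e-10)$value
}
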