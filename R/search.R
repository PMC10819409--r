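## Core off-target search engine: bounded-mismatch, bounded-single-bulge,
## PAM-anchored scan of both genome strands.
##
## Alignment model (the model shared by alignment-based off-target
## predictors such as Cas-OFFinder):
##   * substitutions only on aligned guide/genome positions;
##   * at most ONE contiguous bulge per alignment, either a DNA bulge
##     (extra unpaired genomic bases; genomic span = L + b) or an RNA bulge
##     (unpaired guide bases, genomic positions skipped; genomic span = L - b);
##   * bulges are strictly interior to the alignment — a terminal bulge is
##     just a shorter or shifted ungapped match;
##   * the PAM must match its IUPAC pattern exactly (no mismatch budget),
##     immediately adjacent to the protospacer span on the PAM side, read
##     in strand orientation;
##   * a genomic N never matches anything (guide base, or any IUPAC code,
##     including N itself), so assembly gaps and masked regions never yield
##     predicted sites.
## For a fixed genomic span the bulge type and size are forced by the span
## length, so per (contig, start, end, strand) the engine reports the
## placement minimising mismatches (ties: leftmost bulge).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Match a genomic base against an IUPAC code
#'
#' Vectorised positionwise IUPAC matching as used for PAM recognition.
#' A genomic `N` matches no code — including the degenerate code `N` —
#' so masked or gap regions of an assembly can never satisfy a PAM.
#'
#' @param base Character vector of single genomic bases (`A,C,G,T,N`).
#' @param code Character vector of single IUPAC codes.
#' @return Logical vector.
#' @examples
#' iupac_match("G", "N")   # TRUE
#' iupac_match("T", "V")   # FALSE
#' iupac_match("N", "N")   # FALSE: genomic N matches nothing
#' @export
iupac_match <- function(base, code) {
  stopifnot(all(nchar(base) == 1L), all(nchar(code) == 1L))
  base <- toupper(base); code <- toupper(code)
  if (!all(base %in% c("A", "C", "G", "T", "N")))
    stop("invalid base: ", paste(setdiff(base, c("A","C","G","T","N")), collapse = ","))
  if (!all(code %in% names(IUPAC_SETS)))
    stop("invalid IUPAC code: ", paste(setdiff(code, names(IUPAC_SETS)), collapse = ","))
  mapply(function(b, k) b != "N" && b %in% IUPAC_SETS[[k]], base, code,
         USE.NAMES = FALSE)
}

#' Reverse-complement a DNA or IUPAC string
#'
#' @param seq Character vector of sequences over the IUPAC alphabet
#'   (complement is defined for every IUPAC code, so PAM patterns such as
#'   `"NGG"` reverse-complement to `"CCN"`).
#' @return Character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    if (!all(ch %in% names(IUPAC_COMPLEMENT)))
      stop("invalid character in sequence: ",
           paste(setdiff(ch, names(IUPAC_COMPLEMENT)), collapse = ","))
    paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Define a guide query
#'
#' Bundles one Cas system's protospacer and PAM requirement. For Cas9-style
#' guides the PAM (e.g. `NGG`) lies 3' of the protospacer; for Cas12a-style
#' guides (e.g. `TTTV`) it lies 5'.
#'
#' @param guide_id Label for the guide.
#' @param protospacer Protospacer sequence, 18-24 nt over `A,C,G,T`.
#' @param pam_pattern IUPAC PAM pattern, e.g. `"NGG"` or `"TTTV"`.
#' @param pam_side `"three_prime"` or `"five_prime"`.
#' @param cas_label Free-text Cas protein label.
#' @return Object of class `guide_query`.
#' @export
guide_query <- function(guide_id, protospacer, pam_pattern,
                        pam_side = c("three_prime", "five_prime"),
                        cas_label = "Cas9") {
  pam_side <- match.arg(pam_side)
  protospacer <- toupper(protospacer)
  pam_pattern <- toupper(pam_pattern)
  if (!grepl("^[ACGT]+$", protospacer))
    stop("protospacer must be over {A,C,G,T}: ", protospacer)
  if (nchar(protospacer) < 18L || nchar(protospacer) > 24L)
    stop("protospacer length must be 18-24 nt, got ", nchar(protospacer))
  ch <- strsplit(pam_pattern, "")[[1]]
  if (length(ch) == 0L || !all(ch %in% names(IUPAC_SETS)))
    stop("invalid IUPAC code in PAM pattern: ", pam_pattern)
  structure(list(guide_id = as.character(guide_id), protospacer = protospacer,
                 pam_pattern = pam_pattern, pam_side = pam_side,
                 cas_label = cas_label),
            class = "guide_query")
}

#' Define a search sensitivity profile
#'
#' A profile is the (maximum mismatches, maximum bulge size) pair under
#' which one alignment-based predictor searches. `max_bulge = 0` disallows
#' bulges entirely; otherwise a single DNA or RNA bulge up to `max_bulge`
#' bases is allowed (the bulge-size bound applies to both bulge types).
#'
#' @param name Profile label.
#' @param max_mismatches Maximum substitutions on aligned positions (<= 8).
#' @param max_bulge Maximum bulge length (<= 3); 0 disallows bulges.
#' @return Object of class `search_profile`.
#' @export
search_profile <- function(name, max_mismatches, max_bulge = 0L) {
  max_mismatches <- as.integer(max_mismatches)
  max_bulge <- as.integer(max_bulge)
  stopifnot(max_mismatches >= 0L, max_mismatches <= 8L,
            max_bulge >= 0L, max_bulge <= 3L)
  structure(list(name = as.character(name), max_mismatches = max_mismatches,
                 max_bulge = max_bulge),
            class = "search_profile")
}

#' The four default tool-like search profiles
#'
#' The ensemble default: four alignment-based predictor configurations,
#' two bulge-blind (3 or 5 mismatches, no bulge) and two bulge-aware
#' (5 mismatches, bulge up to 2).
#'
#' @return List of [search_profile()] objects.
#' @export
default_search_profiles <- function() {
  list(search_profile("chopchop", 3L, 0L),
       search_profile("cas_offinder", 5L, 2L),
       search_profile("crispritz", 5L, 2L),
       search_profile("crispr_offinder", 5L, 0L))
}

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)

.encode <- function(seq) {
  unname(.BASE_CODE[strsplit(seq, "")[[1]]])
}

## mismatch count vectors for one scanning pattern over one contig strand.
## Returns, for every candidate span, (start, end, mm, dna_bulge, rna_bulge).
.scan_pattern <- function(gcode, pattern_code, max_mm, max_bulge) {
  G <- length(gcode)
  L <- length(pattern_code)
  if (G < L - max_bulge || G < 1L) return(NULL)
  bmax <- max_bulge
  ## padded genome so shifted lookups stay in range; sentinel -1 mismatches all
  pad <- bmax + L + 1L
  gp <- c(rep(-1L, pad), gcode, rep(-1L, pad))
  at <- function(idx) gp[idx + pad]
  P <- G  # candidate span starts 1..G (out-of-range spans filtered later)
  p_idx <- seq_len(P)
  ## suffix mismatch sums T[[shift]][[j]](p) = sum_{i=j..L} [g[p+i-1+shift] != q[i]]
  shifts <- unique(c(0L, if (bmax > 0L) c(seq_len(bmax), -seq_len(bmax))))
  Tsuf <- list()
  for (s in shifts) {
    suf <- vector("list", L + 1L)
    suf[[L + 1L]] <- rep(0L, P)
    for (j in L:1) {
      gi <- at(p_idx + j - 1L + s)
      mism <- as.integer(gi != pattern_code[[j]])  # N (0) or sentinel never equal
      suf[[j]] <- suf[[j + 1L]] + mism
    }
    Tsuf[[as.character(s)]] <- suf
  }
  T0 <- Tsuf[["0"]]
  nN <- cumsum(c(0L, as.integer(gcode == 0L)))  # N count prefix
  n_in <- function(st, en) nN[pmin(en, G) + 1L] - nN[pmax(st, 1L)]
  res <- list()
  add <- function(st, sp_len, mm, db, rb) {
    en <- st + sp_len - 1L
    ok <- st >= 1L & en <= G & mm <= max_mm
    if (!any(ok)) return()
    st <- st[ok]; en <- en[ok]; mm <- mm[ok]
    ok2 <- n_in(st, en) == 0L
    if (!any(ok2)) return()
    res[[length(res) + 1L]] <<- data.frame(start = st[ok2], end = en[ok2],
                                           mismatches = mm[ok2],
                                           dna_bulge = db, rna_bulge = rb)
  }
  ## ungapped
  add(p_idx, L, T0[[1L]], 0L, 0L)
  if (bmax > 0L) {
    for (b in seq_len(bmax)) {
      ## DNA bulge: b extra genomic bases after guide position j (j in 1..L-1)
      Tb <- Tsuf[[as.character(b)]]
      mm <- NULL
      for (j in seq_len(L - 1L)) {
        v <- (T0[[1L]] - T0[[j + 1L]]) + Tb[[j + 1L]]
        mm <- if (is.null(mm)) v else pmin(mm, v)
      }
      add(p_idx, L + b, mm, b, 0L)
      ## RNA bulge: guide positions j+1..j+b unpaired (j in 1..L-b-1)
      if (L - b >= 2L) {
        Tnb <- Tsuf[[as.character(-b)]]
        mm <- NULL
        for (j in seq_len(L - b - 1L)) {
          v <- (T0[[1L]] - T0[[j + 1L]]) + Tnb[[j + b + 1L]]
          mm <- if (is.null(mm)) v else pmin(mm, v)
        }
        add(p_idx, L - b, mm, 0L, b)
      }
    }
  }
  if (length(res) == 0L) NULL else do.call(rbind, res)
}

## exact IUPAC PAM check at fixed positions of a contig (char vector form)
.pam_ok_at <- function(contig_chars, pstart, pam_chars) {
  G <- length(contig_chars)
  plen <- length(pam_chars)
  vapply(pstart, function(s) {
    if (s < 1L || s + plen - 1L > G) return(FALSE)
    obs <- contig_chars[s:(s + plen - 1L)]
    all(vapply(seq_len(plen), function(i) {
      b <- obs[[i]]
      b != "N" && b %in% IUPAC_SETS[[pam_chars[[i]]]]
    }, logical(1)))
  }, logical(1))
}

#' Find all genomic sites matching a guide under a search profile
#'
#' Scans every contig on both strands for alignments of the protospacer with
#' at most `profile$max_mismatches` substitutions and (when
#' `profile$max_bulge > 0`) optionally one interior DNA or RNA bulge of up to
#' `max_bulge` bases, requiring an exact IUPAC match of the PAM pattern
#' immediately adjacent to the protospacer span on the guide's PAM side.
#' Genomic `N` bases match nothing, so sites never overlap assembly gaps.
#'
#' @param genome Named character vector of contig sequences
#'   (see [read_fasta()]).
#' @param guide A [guide_query()].
#' @param profile A [search_profile()].
#' @return data.frame of sites sorted by (contig, start, strand) with columns
#'   `contig`, `start`, `end` (protospacer span, 1-based inclusive),
#'   `strand`, `mismatches`, `dna_bulge`, `rna_bulge`, `pam_start`,
#'   `pam_end`, `pam_seq` (in guide orientation, so it always satisfies the
#'   PAM pattern positionwise), `aligned_genomic_seq` (plus-strand text of
#'   the span), `guide_id`. At most one row per (contig, start, end, strand),
#'   carrying the minimal-mismatch alignment for that span.
#' @examples
#' genome <- c(c1 = paste0(strrep("A", 50), "ACCCCCAGACCTGGAACGGC", "AGG",
#'                         strrep("A", 50)))
#' g <- guide_query("kcnq2", "ACCCCCAGACCTGGAACGGC", "NGG")
#' find_sites(genome, g, search_profile("strict", 3, 0))
#' @export
find_sites <- function(genome, guide, profile) {
  stopifnot(inherits(guide, "guide_query"), inherits(profile, "search_profile"))
  if (!is.character(genome) || length(genome) == 0L || is.null(names(genome)))
    stop("genome must be a non-empty named character vector")
  out <- list()
  plen <- nchar(guide$pam_pattern)
  for (cname in names(genome)) {
    cseq <- genome[[cname]]
    cchars <- strsplit(cseq, "")[[1]]
    gcode <- unname(.BASE_CODE[cchars])
    for (strand in c("+", "-")) {
      if (strand == "+") {
        pattern <- guide$protospacer
        pam <- guide$pam_pattern
        pam_after <- guide$pam_side == "three_prime"
      } else {
        pattern <- reverse_complement(guide$protospacer)
        pam <- reverse_complement(guide$pam_pattern)
        ## 3' in guide orientation lies genomically LEFT of a minus-strand span
        pam_after <- guide$pam_side != "three_prime"
      }
      cand <- .scan_pattern(gcode, .encode(pattern), profile$max_mismatches,
                            profile$max_bulge)
      if (is.null(cand) || nrow(cand) == 0L) next
      if (pam_after) {
        pstart <- cand$end + 1L
      } else {
        pstart <- cand$start - plen
      }
      pam_chars <- strsplit(pam, "")[[1]]
      ok <- .pam_ok_at(cchars, pstart, pam_chars)
      if (!any(ok)) next
      cand <- cand[ok, , drop = FALSE]
      pstart <- pstart[ok]
      cand$contig <- cname
      cand$strand <- strand
      cand$pam_start <- pstart
      cand$pam_end <- pstart + plen - 1L
      pam_txt <- substring(cseq, pstart, pstart + plen - 1L)
      ## report the PAM in guide orientation so it matches pam_pattern
      cand$pam_seq <- if (strand == "-") reverse_complement(pam_txt) else pam_txt
      cand$aligned_genomic_seq <- substring(cseq, cand$start, cand$end)
      out[[length(out) + 1L]] <- cand
    }
  }
  cols <- c("contig", "start", "end", "strand", "mismatches", "dna_bulge",
            "rna_bulge", "pam_start", "pam_end", "pam_seq",
            "aligned_genomic_seq")
  if (length(out) == 0L) {
    res <- data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      dna_bulge = integer(), rna_bulge = integer(),
                      pam_start = integer(), pam_end = integer(),
                      pam_seq = character(), aligned_genomic_seq = character(),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)[, cols]
    res <- res[order(res$contig, res$start, res$strand, res$end), , drop = FALSE]
    rownames(res) <- NULL
  }
  res$guide_id <- rep(guide$guide_id, nrow(res))
  res
}
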