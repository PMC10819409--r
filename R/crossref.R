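#' Cross-referencing configuration
#'
#' @param window Flank in bp added to both sides of each variant when
#'   intersecting with predicted sites or string-search scanning
#'   (default 200).
#' @param on_target_radius Distance in bp from the intended target interval
#'   within which a variant is labelled `on_target` (default 2000; loci up
#'   to 2 kb around the target deserve scrutiny after editing).
#' @param string_search_max_mismatches Substitution budget for the ungapped
#'   guide string search (default 4).
#' @return Object of class `crossref_config`.
#' @export
crossref_config <- function(window = 200L, on_target_radius = 2000L,
                            string_search_max_mismatches = 4L) {
  stopifnot(window >= 0, on_target_radius >= 0,
            string_search_max_mismatches >= 0)
  structure(list(window = as.integer(window),
                 on_target_radius = as.integer(on_target_radius),
                 string_search_max_mismatches =
                   as.integer(string_search_max_mismatches)),
            class = "crossref_config")
}

#' Cross-reference screened variants with predicted off-target sites
#'
#' Reports every (variant, site) pair on the same contig where the window
#' `[variant$start - window, variant$end + window]` intersects the site's
#' protospacer-or-PAM span. Distance is measured between the closed variant
#' REF span and the closed site span (protospacer plus PAM); overlapping
#' spans have distance 0. Pairs are labelled `on_target` when the variant
#' lies within `on_target_radius` of the intended target interval, else
#' `off_target_candidate`.
#'
#' @param variants data.frame of screened variant records.
#' @param sites data.frame of predicted sites (see [predict_offtargets()]).
#' @param target_interval List or one-row data.frame with `contig`, `start`,
#'   `end` of the intended target site; may be `NULL`, in which case every
#'   hit is an `off_target_candidate`.
#' @param config A [crossref_config()].
#' @return data.frame with one row per qualifying pair: variant coordinates
#'   and alleles, site coordinates/strand/provenance, `distance`, `label`,
#'   sorted by variant position then site position. Variants on contigs
#'   absent from the site list trigger a warning and are reported in the
#'   `unlinked` attribute.
#' @export
crossref_sites <- function(variants, sites, target_interval = NULL,
                           config = crossref_config()) {
  stopifnot(is.data.frame(variants), is.data.frame(sites),
            inherits(config, "crossref_config"))
  empty <- data.frame(contig = character(), variant_start = integer(),
                      variant_end = integer(), ref = character(),
                      alt = character(), site_start = integer(),
                      site_end = integer(), site_strand = character(),
                      sources = character(), distance = integer(),
                      label = character(), stringsAsFactors = FALSE)
  if (nrow(variants) == 0L) return(empty)
  missing_contig <- setdiff(unique(variants$contig),
                            unique(c(sites$contig, character(0))))
  if (length(missing_contig) && nrow(sites)) {
    warning("variant contig(s) absent from predicted sites: ",
            paste(missing_contig, collapse = ", "),
            "; those variants are reported unlinked")
  }
  if (nrow(sites) == 0L) {
    attr(empty, "unlinked") <- variants
    return(empty)
  }
  ## full site span includes the PAM
  s_start <- pmin(sites$start, sites$pam_start)
  s_end <- pmax(sites$end, sites$pam_end)
  vr <- GenomicRanges::GRanges(variants$contig,
                               IRanges::IRanges(variants$start, variants$end))
  sr <- GenomicRanges::GRanges(sites$contig,
                               IRanges::IRanges(s_start, s_end))
  ov <- GenomicRanges::findOverlaps(vr, sr, maxgap = config$window)
  vi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  if (length(vi) == 0L) {
    attr(empty, "unlinked") <- variants
    return(empty)
  }
  dist <- interval_distance(variants$start[vi], variants$end[vi],
                            s_start[si], s_end[si])
  keep <- dist <= config$window
  vi <- vi[keep]; si <- si[keep]; dist <- dist[keep]
  lab <- rep("off_target_candidate", length(vi))
  if (!is.null(target_interval)) {
    ti <- as.list(target_interval)
    same <- variants$contig[vi] == ti$contig
    d_t <- interval_distance(variants$start[vi], variants$end[vi],
                             ti$start, ti$end)
    lab[same & d_t <= config$on_target_radius] <- "on_target"
  }
  out <- data.frame(contig = variants$contig[vi],
                    variant_start = variants$start[vi],
                    variant_end = variants$end[vi],
                    ref = variants$ref[vi], alt = variants$alt[vi],
                    site_start = sites$start[si], site_end = sites$end[si],
                    site_strand = sites$strand[si],
                    sources = if ("sources" %in% names(sites))
                        sites$sources[si] else NA_character_,
                    distance = as.integer(dist), label = lab,
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$variant_start, out$site_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  linked <- unique(vi)
  attr(out, "unlinked") <- variants[setdiff(seq_len(nrow(variants)), linked), ,
                                    drop = FALSE]
  out
}

## ungapped mismatch counts of `pattern` at every offset of `text` (chars)
.ungapped_mm <- function(text_chars, pattern_chars) {
  L <- length(pattern_chars)
  P <- length(text_chars) - L + 1L
  if (P < 1L) return(integer(0))
  mm <- rep(0L, P)
  idx <- seq_len(P)
  for (i in seq_len(L)) {
    b <- text_chars[idx + i - 1L]
    mm <- mm + as.integer(b != pattern_chars[[i]] | b == "N")
  }
  mm
}

#' Guide string-search screen around variants
#'
#' For each variant, extracts the genomic flank
#' `[start - window, end + window]` and scans it, ungapped and with no PAM
#' requirement, for the protospacer in both orientations (gRNA+ and gRNA-)
#' allowing up to `string_search_max_mismatches` substitutions. Dropping the
#' PAM makes this a superset detector for ungapped low-mismatch loci; it is
#' what recovers guide-adjacent edits at loci where the PAM-anchored
#' prediction fails (for example guides designed against variant-bearing
#' haplotypes).
#'
#' @param genome Named character vector of contigs.
#' @param guide A [guide_query()].
#' @param variants data.frame of screened variant records.
#' @param config A [crossref_config()].
#' @return data.frame with one row per qualifying placement: variant
#'   coordinates, `match_start`, `match_end`, `orientation`
#'   (`plus`/`minus`), `mismatches`.
#' @export
string_search_screen <- function(genome, guide, variants,
                                 config = crossref_config()) {
  stopifnot(inherits(guide, "guide_query"), is.data.frame(variants))
  pat_plus <- strsplit(guide$protospacer, "")[[1]]
  pat_minus <- strsplit(reverse_complement(guide$protospacer), "")[[1]]
  L <- length(pat_plus)
  out <- list()
  for (r in seq_len(nrow(variants))) {
    v <- variants[r, ]
    if (!v$contig %in% names(genome))
      stop("variant contig '", v$contig, "' not in genome")
    G <- nchar(genome[[v$contig]])
    if (v$start < 1L || v$end > G)
      stop("variant at ", v$contig, ":", v$start, " beyond contig bounds")
    ws <- max(1L, v$start - config$window)
    we <- min(G, v$end + config$window)
    flank <- strsplit(substring(genome[[v$contig]], ws, we), "")[[1]]
    for (orient in c("plus", "minus")) {
      pat <- if (orient == "plus") pat_plus else pat_minus
      mm <- .ungapped_mm(flank, pat)
      hit <- which(mm <= config$string_search_max_mismatches)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          contig = v$contig, variant_start = v$start, variant_end = v$end,
          match_start = ws + hit - 1L, match_end = ws + hit + L - 2L,
          orientation = orient, mismatches = mm[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(), variant_start = integer(),
                      variant_end = integer(), match_start = integer(),
                      match_end = integer(), orientation = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$variant_start, res$match_start,
                   res$orientation), , drop = FALSE]
  rownames(res) <- NULL
  res
}
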