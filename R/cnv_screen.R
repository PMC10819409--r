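#' CNV screening configuration
#'
#' @param min_size Size floor in bp; calls are retained only when STRICTLY
#'   larger (default 1000, i.e. "> 1 kb").
#' @param min_reciprocal_overlap Reciprocal-overlap fraction two same-type
#'   calls must share to be considered the same event (default 0.5, the
#'   field's 50% convention).
#' @param large_rare_min,large_rare_max Size band (bp) for the "large rare"
#'   category (defaults 3 Mb and 10 Mb).
#' @return Object of class `cnv_config`.
#' @export
cnv_config <- function(min_size = 1000L, min_reciprocal_overlap = 0.5,
                       large_rare_min = 3e6, large_rare_max = 1e7) {
  stopifnot(min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1,
            large_rare_min < large_rare_max)
  structure(list(min_size = min_size,
                 min_reciprocal_overlap = min_reciprocal_overlap,
                 large_rare_min = large_rare_min,
                 large_rare_max = large_rare_max),
            class = "cnv_config")
}

## reciprocal overlap between all (a, b) pairs; returns data.frame of pairs
.reciprocal_pairs <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(), j = integer(), ro = numeric()))
  ga <- GenomicRanges::GRanges(a$contig, IRanges::IRanges(a$start, a$end))
  gb <- GenomicRanges::GRanges(b$contig, IRanges::IRanges(b$start, b$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  i <- S4Vectors::queryHits(ov); j <- S4Vectors::subjectHits(ov)
  if (length(i) == 0L)
    return(data.frame(i = integer(), j = integer(), ro = numeric()))
  inter <- pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j]) + 1
  la <- a$end[i] - a$start[i] + 1
  lb <- b$end[j] - b$start[j] + 1
  data.frame(i = i, j = j, ro = pmin(inter / la, inter / lb))
}

#' Retain CNV calls supported by both callers and above the size floor
#'
#' A call from set A is retained iff its length exceeds `min_size` and some
#' call of the same CNV type in set B reciprocally overlaps it by at least
#' `min_reciprocal_overlap` (set `require_concordance = FALSE` to keep
#' size-filtered single-caller calls, e.g. when only one caller ran).
#' Retained calls carry both callers' labels in `sources`.
#'
#' @param calls_a,calls_b data.frames with columns `contig`, `start`, `end`,
#'   `cnv_type` (`deletion`/`duplication`) and `source` (caller label).
#' @param config A [cnv_config()].
#' @param require_concordance Require support from the second call set.
#' @return data.frame of retained calls from `calls_a` with a `sources`
#'   column.
#' @export
concordant_cnvs <- function(calls_a, calls_b, config = cnv_config(),
                            require_concordance = TRUE) {
  stopifnot(is.data.frame(calls_a), is.data.frame(calls_b),
            inherits(config, "cnv_config"))
  len <- calls_a$end - calls_a$start + 1
  big <- len > config$min_size
  supported <- rep(!require_concordance, nrow(calls_a))
  matched_src <- rep(NA_character_, nrow(calls_a))
  for (ty in unique(calls_a$cnv_type)) {
    ai <- which(calls_a$cnv_type == ty)
    bi <- which(calls_b$cnv_type == ty)
    pr <- .reciprocal_pairs(calls_a[ai, , drop = FALSE],
                            calls_b[bi, , drop = FALSE])
    ok <- pr[pr$ro >= config$min_reciprocal_overlap, , drop = FALSE]
    supported[ai[unique(ok$i)]] <- TRUE
    matched_src[ai[ok$i]] <- calls_b$source[bi[ok$j]]
  }
  keep <- big & supported
  out <- calls_a[keep, , drop = FALSE]
  out$sources <- ifelse(is.na(matched_src[keep]), out$source,
                        paste(out$source, matched_src[keep], sep = ","))
  rownames(out) <- NULL
  out
}

#' Classify retained CNVs as unintended/de novo categories
#'
#' Applies the fixed precedence: a call matching a parental call of the same
#' type (reciprocal overlap at or above the configured fraction) is
#' `not_de_novo`; otherwise a call whose length falls inside the large-rare
#' band is `large_rare`; otherwise a call intersecting any coding exon is
#' `exonic`; everything else is `other_de_novo`.
#'
#' @param cnvs data.frame of retained calls (`contig`, `start`, `end`,
#'   `cnv_type`).
#' @param parent_calls data.frame of the parental line's calls, same schema.
#' @param coding_exons data.frame of exon intervals (`contig`, `start`,
#'   `end`).
#' @param config A [cnv_config()].
#' @return Character vector of categories, one per row of `cnvs`.
#' @export
classify_unintended <- function(cnvs, parent_calls, coding_exons,
                                config = cnv_config()) {
  stopifnot(is.data.frame(cnvs))
  n <- nrow(cnvs)
  if (n == 0L) return(character(0))
  in_parent <- rep(FALSE, n)
  for (ty in unique(cnvs$cnv_type)) {
    ci <- which(cnvs$cnv_type == ty)
    pi <- which(parent_calls$cnv_type == ty)
    pr <- .reciprocal_pairs(cnvs[ci, , drop = FALSE],
                            parent_calls[pi, , drop = FALSE])
    in_parent[ci[unique(pr$i[pr$ro >= config$min_reciprocal_overlap])]] <- TRUE
  }
  len <- cnvs$end - cnvs$start + 1
  large <- len >= config$large_rare_min & len <= config$large_rare_max
  exonic <- rep(FALSE, n)
  if (nrow(coding_exons)) {
    gc <- GenomicRanges::GRanges(cnvs$contig,
                                 IRanges::IRanges(cnvs$start, cnvs$end))
    ge <- GenomicRanges::GRanges(coding_exons$contig,
                                 IRanges::IRanges(coding_exons$start,
                                                  coding_exons$end))
    exonic <- GenomicRanges::countOverlaps(gc, ge) > 0L
  }
  ifelse(in_parent, "not_de_novo",
         ifelse(large, "large_rare",
                ifelse(exonic, "exonic", "other_de_novo")))
}

#' Read a BED-like CNV call table
#'
#' Tab-separated with a header row: `contig`, `start`, `end`, `cnv_type`,
#' `source`; coordinates 1-based inclusive. `#`-prefixed comment lines are
#' skipped.
#'
#' @param path File path.
#' @return data.frame of CNV calls.
#' @export
read_cnv_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "cnv_type", "source")
  if (!all(need %in% names(x)))
    stop("CNV table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  x
}
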