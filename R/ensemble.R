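#' Configure the prediction ensemble
#'
#' @param profiles List of [search_profile()] objects with unique names;
#'   defaults to the four tool-like profiles of
#'   [default_search_profiles()].
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(profiles = default_search_profiles()) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "search_profile")))
  nms <- vapply(profiles, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("profile names must be unique")
  structure(list(profiles = profiles), class = "ensemble_config")
}

#' Predict off-target sites with the profile ensemble
#'
#' Runs [find_sites()] once per configured profile and aggregates the
#' per-profile hit lists into one comprehensive, deduplicated site list.
#' Sites found by several profiles at the same (contig, start, end, strand)
#' are merged into a single row whose `sources` column lists every admitting
#' profile (comma-separated, in configuration order). Bulged and ungapped
#' alignments occupy different genomic spans and therefore remain distinct
#' rows.
#'
#' @param genome Named character vector of contig sequences.
#' @param guide A [guide_query()].
#' @param config An [ensemble_config()].
#' @return data.frame as from [find_sites()] plus a `sources` column,
#'   sorted by (contig, start, strand).
#' @export
predict_offtargets <- function(genome, guide, config = ensemble_config()) {
  stopifnot(inherits(config, "ensemble_config"))
  per <- lapply(config$profiles, function(p) {
    s <- find_sites(genome, guide, p)
    if (nrow(s)) s$.profile <- p$name
    s
  })
  allr <- do.call(rbind, per[vapply(per, nrow, integer(1)) > 0L])
  if (is.null(allr) || nrow(allr) == 0L) {
    out <- find_sites(genome, guide, config$profiles[[1L]])  # empty frame
    out$sources <- character(0)
    return(out)
  }
  key <- paste(allr$contig, allr$start, allr$end, allr$strand, sep = "\r")
  prof_order <- vapply(config$profiles, `[[`, character(1), "name")
  keep <- !duplicated(key)
  out <- allr[keep, setdiff(names(allr), ".profile"), drop = FALSE]
  src <- split(allr$.profile, key)
  out$sources <- vapply(key[keep], function(k) {
    paste(prof_order[prof_order %in% src[[k]]], collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  out <- out[order(out$contig, out$start, out$strand, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
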