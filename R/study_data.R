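## Accessors for the packaged study tables: the engineered-clone cohort,
## its guides, and the validated variant lists. All coordinates are hg19,
## 1-based inclusive.

.study_table <- function(file) {
  path <- system.file("extdata", file, package = "crisproff", mustWork = TRUE)
  lines <- readLines(path)
  ## cell-line labels legitimately contain "#", so strip only the leading
  ## comment lines rather than using read.table's comment parsing
  lines <- lines[!startsWith(lines, "#")]
  utils::read.table(text = lines, sep = "\t", header = TRUE,
                    comment.char = "", quote = "", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
}

#' Packaged clone cohort table
#'
#' The 16 CRISPR/Cas-engineered iPSC clones: intended target interval,
#' Cas protein, delivery method, CC/CNC status and per-clone WGS summary
#' (fold coverage, unique SNV/indel/SV counts).
#'
#' @return data.frame with one row per clone.
#' @export
study_clone_table <- function() .study_table("study_clones.tsv")

#' Packaged guide table
#'
#' Guides used across the targeted loci: protospacer, observed PAM,
#' degenerate PAM pattern, PAM side and Cas protein.
#'
#' @return data.frame with one row per guide.
#' @export
study_guide_table <- function() .study_table("study_guides.tsv")

#' Variants detected by the prediction and string-search stages
#'
#' The on-/near-target variants recovered by cross-referencing screened
#' variant calls with predicted sites (and the parallel guide string
#' search), one row per variant.
#'
#' @return data.frame.
#' @export
prediction_variant_table <- function() .study_table("prediction_variants.tsv")

#' Variants identified by unbiased WGS analysis
#'
#' Missense/deletion variants found genome-wide irrespective of off-target
#' prediction, one row per variant.
#'
#' @return data.frame.
#' @export
wgs_variant_table <- function() .study_table("wgs_variants.tsv")

#' Unintended on-target modification lesions
#'
#' One row per validated unintended on-target lesion; rows sharing
#' (`clone_id`, `event_id`) are physically linked (e.g. an insertion plus
#' an adjacent mono-allelic deletion) and count as a single event.
#'
#' @return data.frame.
#' @export
ontarget_event_table <- function() .study_table("ontarget_events.tsv")

#' Per-clone unintended-event counts
#'
#' Tallies one event per genome-wide WGS variant row plus one per
#' unintended on-target event, over every clone in the cohort (clones with
#' no events count 0). This is the event series underlying the grouped
#' rate comparisons.
#'
#' @param clones Clone table (default [study_clone_table()]).
#' @param wgs_variants Genome-wide variant table
#'   (default [wgs_variant_table()]).
#' @param ontarget_events On-target event table
#'   (default [ontarget_event_table()]).
#' @return `clones` with an added `n_unintended_events` column.
#' @export
unintended_event_counts <- function(clones = study_clone_table(),
                                    wgs_variants = wgs_variant_table(),
                                    ontarget_events = ontarget_event_table()) {
  on_ev <- unique(ontarget_events[, c("clone_id", "event_id")])
  ev <- c(wgs_variants$clone_id, on_ev$clone_id)
  unknown <- setdiff(unique(ev), clones$clone_id)
  if (length(unknown))
    stop("event clone id(s) not in clone table: ",
         paste(unknown, collapse = ", "))
  tab <- table(factor(ev, levels = clones$clone_id))
  clones$n_unintended_events <- as.integer(tab[clones$clone_id])
  clones
}
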