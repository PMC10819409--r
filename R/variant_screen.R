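#' Classify a variant by its REF/ALT alleles
#'
#' Equal-length alleles are substitutions (`SNV` for single bases, `MNV`
#' for multi-base blocks such as a 3-bp `AGT>CTG` replacement); length
#' differences are `insertion` (ALT longer) or `deletion` (REF longer).
#'
#' @param ref,alt Character vectors of alleles over `A,C,G,T`.
#' @return Character vector: `"SNV"`, `"MNV"`, `"insertion"` or `"deletion"`.
#' @export
classify_variant <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (length(ref) == 0L) return(character(0))
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("empty allele")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == la, ifelse(lr == 1L, "SNV", "MNV"),
         ifelse(la > lr, "insertion", "deletion"))
}

#' Is an indel at structural-variant scale?
#'
#' Indels whose REF/ALT length difference is at least `sv_min` bases
#' (default 50, the conventional SV size floor) are reported as structural
#' variants in cohort summaries.
#'
#' @param ref,alt Allele character vectors.
#' @param sv_min SV size floor in bp.
#' @return Logical vector.
#' @export
is_sv_scale <- function(ref, alt, sv_min = 50L) {
  abs(nchar(ref) - nchar(alt)) >= sv_min
}

#' Screening thresholds for unique variants
#'
#' @param min_depth Minimum clone read depth; calls strictly below are
#'   excluded (default 10, so DP = 10 is retained).
#' @param min_allele_fraction Minimum clone allele fraction; calls strictly
#'   below are excluded (default 0.2, so AF = 0.2 is retained).
#' @return Object of class `screen_thresholds`.
#' @export
screen_thresholds <- function(min_depth = 10L, min_allele_fraction = 0.2) {
  stopifnot(min_depth >= 0, min_allele_fraction >= 0, min_allele_fraction <= 1)
  structure(list(min_depth = min_depth,
                 min_allele_fraction = min_allele_fraction),
            class = "screen_thresholds")
}

#' Screen clone-vs-parent variant calls down to the unique-variant set
#'
#' A call is retained only when every rule holds: caller FILTER is `PASS`;
#' both genotypes are known; the clone is heterozygous alternative and the
#' parent homozygous reference; clone depth is known and at least
#' `min_depth`; clone allele fraction is known and at least
#' `min_allele_fraction`. Excluded calls are tallied under the FIRST failing
#' rule, checked in the fixed order filter, zygosity_unknown,
#' genotype_pattern, depth, allele_fraction.
#'
#' @param records data.frame of variant records (see [read_variant_file()]).
#' @param thresholds A [screen_thresholds()].
#' @return List with `retained` (data.frame subset of `records`),
#'   `excluded` (the complement, with an `exclusion_rule` column) and
#'   `tally` (named integer vector over the five rules).
#' @export
screen_unique_variants <- function(records, thresholds = screen_thresholds()) {
  stopifnot(is.data.frame(records), inherits(thresholds, "screen_thresholds"))
  rules <- c("filter", "zygosity_unknown", "genotype_pattern", "depth",
             "allele_fraction")
  n <- nrow(records)
  rule <- rep(NA_character_, n)
  if (n) {
    fail_filter <- records$filter_status != "PASS"
    fail_zyg <- records$clone_genotype == "unknown" |
                records$parent_genotype == "unknown"
    fail_geno <- records$clone_genotype != "het" |
                 records$parent_genotype != "hom_ref"
    fail_dp <- is.na(records$clone_depth) |
               records$clone_depth < thresholds$min_depth
    fail_af <- is.na(records$clone_allele_fraction) |
               records$clone_allele_fraction < thresholds$min_allele_fraction
    rule[fail_af] <- "allele_fraction"
    rule[fail_dp] <- "depth"
    rule[fail_geno] <- "genotype_pattern"
    rule[fail_zyg] <- "zygosity_unknown"
    rule[fail_filter] <- "filter"
  }
  keep <- is.na(rule)
  excluded <- records[!keep, , drop = FALSE]
  excluded$exclusion_rule <- rule[!keep]
  tally <- vapply(rules, function(r) sum(rule == r, na.rm = TRUE), integer(1))
  list(retained = records[keep, , drop = FALSE],
       excluded = excluded,
       tally = tally)
}
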