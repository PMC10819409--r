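#' Read a reference genome from FASTA
#'
#' Loads a (possibly line-wrapped, possibly soft-masked) multi-record FASTA
#' file and returns it as a named character vector of uppercase sequences,
#' one element per contig. Lowercase (soft-masked) bases are uppercased and
#' remain searchable; `N` bases are retained but never match any guide base
#' during site search.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are contig labels, values are
#'   uppercase sequences over `A`, `C`, `G`, `T`, `N`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgT", "NN"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate contig name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(!nzchar(nm)))
    stop("empty contig name in ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L)
      stop("contig '", nm[i], "': character '",
           substr(seqs[[i]], bad, bad), "' outside {A,C,G,T,N} at position ",
           as.integer(bad))
    if (nchar(seqs[[i]]) < 1L)
      stop("contig '", nm[i], "' has empty sequence")
  }
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  set <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

## map VCF-style GT strings to an allele-specific genotype for ALT index k
.genotype_for_allele <- function(gt, k) {
  out <- character(length(gt))
  for (i in seq_along(gt)) {
    g <- gt[[i]]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) { out[[i]] <- "unknown"; next }
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) { out[[i]] <- "unknown"; next }
    n_alt <- sum(al == as.character(k))
    out[[i]] <- c("hom_ref", "het", "hom_alt")[[n_alt + 1L]]
  }
  out
}

#' Read paired clone/parent variant calls from a two-sample VCF
#'
#' Parses a Mutect2-style VCF carrying the edited clone and its parental line
#' as two sample columns, decomposes multi-allelic records into one row per
#' ALT allele, and extracts the fields used by the unique-variant screen:
#' genotypes, clone read depth and clone allele fraction. The allele fraction
#' is taken from the clone's `AF` FORMAT field when present, falling back to
#' `AD_alt / (AD_ref + AD_alt)` when only `AD` is available, and is recorded
#' as `NA` (unknown) otherwise; unknown values are screened out downstream.
#'
#' @param path Path to a VCF (v4.2) file.
#' @param clone_sample,parent_sample Sample column names in the VCF header.
#' @return A data.frame of variant records with columns `contig`, `start`,
#'   `end` (1-based inclusive REF span), `ref`, `alt`, `clone_genotype`,
#'   `parent_genotype` (each one of `hom_ref`, `het`, `hom_alt`, `unknown`),
#'   `filter_status`, `clone_depth`, `clone_allele_fraction`, `variant_class`.
#' @seealso [screen_unique_variants()], [classify_variant()]
#' @export
read_variant_file <- function(path, clone_sample, parent_sample) {
  stopifnot(file.exists(path))
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  samp <- colnames(vcf)
  for (s in c(clone_sample, parent_sample))
    if (!s %in% samp)
      stop("sample '", s, "' absent from VCF header of ", path,
           " (samples: ", paste(samp, collapse = ", "), ")")
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  if (sum(n_alt) == 0L) return(empty_variant_frame())
  allele_index <- sequence(n_alt)
  ve <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(ve)
  gt <- VariantAnnotation::geno(ve)$GT
  clone_gt_raw <- gt[, clone_sample]
  parent_gt_raw <- gt[, parent_sample]
  clone_gt <- parent_gt <- character(length(ve))
  for (i in seq_along(clone_gt)) {
    clone_gt[[i]] <- .genotype_for_allele(clone_gt_raw[[i]], allele_index[[i]])
    parent_gt[[i]] <- .genotype_for_allele(parent_gt_raw[[i]], allele_index[[i]])
  }
  gfields <- VariantAnnotation::geno(ve)
  dp <- if ("DP" %in% names(gfields)) suppressWarnings(as.numeric(gfields$DP[, clone_sample]))
        else rep(NA_real_, length(ve))
  af <- if ("AF" %in% names(gfields)) suppressWarnings(as.numeric(gfields$AF[, clone_sample]))
        else rep(NA_real_, length(ve))
  if ("AD" %in% names(gfields)) {
    ad <- gfields$AD
    ## AD is (variant x sample x allele); after expand() allele 1 = REF, 2 = ALT
    if (length(dim(ad)) == 3L && dim(ad)[3] >= 2L) {
      ad_ref <- suppressWarnings(as.numeric(ad[, clone_sample, 1L]))
      ad_alt <- suppressWarnings(as.numeric(ad[, clone_sample, 2L]))
      fallback <- is.na(af) & !is.na(ad_ref) & !is.na(ad_alt) & (ad_ref + ad_alt) > 0
      af[fallback] <- ad_alt[fallback] / (ad_ref[fallback] + ad_alt[fallback])
    }
  }
  ref <- as.character(VariantAnnotation::ref(ve))
  alt <- as.character(VariantAnnotation::alt(ve))
  keep <- nzchar(alt) & alt != "*" & ref != alt
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    start = GenomicRanges::start(rr),
    end = GenomicRanges::start(rr) + nchar(ref) - 1L,
    ref = ref,
    alt = alt,
    clone_genotype = clone_gt,
    parent_genotype = parent_gt,
    filter_status = as.character(VariantAnnotation::filt(ve)),
    clone_depth = dp,
    clone_allele_fraction = af,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  out$variant_class <- classify_variant(out$ref, out$alt)
  rownames(out) <- NULL
  out
}

empty_variant_frame <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             ref = character(), alt = character(),
             clone_genotype = character(), parent_genotype = character(),
             filter_status = character(), clone_depth = numeric(),
             clone_allele_fraction = numeric(), variant_class = character(),
             stringsAsFactors = FALSE)
}

#' Write intervals (plus attribute columns) as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, converted at this boundary. Rows are written sorted by
#' (contig, start). Columns beyond `contig`, `start`, `end`, `strand` are
#' emitted as extra tab-separated columns after the canonical BED6 fields
#' (name and score default to `.` and `0` when absent).
#'
#' @param x data.frame with columns `contig`, `start`, `end` and optionally
#'   `strand`, `name`, `score`, plus any attribute columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(is.data.frame(x))
  extra <- setdiff(names(x), c("contig", "start", "end", "strand", "name", "score"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# BED6+ ", paste(c("chrom chromStart chromEnd name score strand",
                                        extra), collapse = " ")), con)
  if (nrow(x) == 0L) return(invisible(path))
  stopifnot(all(x$start >= 1L), all(x$end >= x$start))
  ord <- order(x$contig, x$start, x$end)
  x <- x[ord, , drop = FALSE]
  bed <- data.frame(chrom = x$contig,
                    chromStart = x$start - 1L,
                    chromEnd = x$end,
                    name = if ("name" %in% names(x)) x$name else ".",
                    score = if ("score" %in% names(x)) x$score else 0L,
                    strand = if ("strand" %in% names(x)) x$strand else ".",
                    stringsAsFactors = FALSE)
  for (col in extra) bed[[col]] <- x[[col]]
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED (BED6+) file back to 1-based inclusive intervals
#'
#' Inverse of [write_bed()]: `#`-prefixed lines are skipped and coordinates
#' converted back to the package's 1-based inclusive convention.
#'
#' @param path BED file path.
#' @param extra_names Optional names for columns beyond BED6.
#' @return data.frame with `contig`, `start`, `end`, `name`, `score`,
#'   `strand` and any extra columns.
#' @export
read_bed <- function(path, extra_names = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  x <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  ncols <- ncol(x)
  base <- c("contig", "start", "end", "name", "score", "strand")
  nm <- base[seq_len(min(ncols, 6L))]
  if (ncols > 6L) {
    ex <- if (!is.null(extra_names) && length(extra_names) == ncols - 6L) extra_names
          else paste0("V", seq_len(ncols - 6L))
    nm <- c(nm, ex)
  }
  names(x) <- nm
  x$start <- x$start + 1L
  x
}

## distance between two closed 1-based spans; 0 when they overlap
interval_distance <- function(start1, end1, start2, end2) {
  d <- pmax(start2 - end1, start1 - end2)
  pmax(d, 0L)
}
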