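## Pipeline orchestration: predict -> screen-variants -> crossref +
## string-search -> screen-cnv -> summarize, with stages communicating via
## documented TSV/BED/VCF files so each can also be run standalone.

.write_report <- function(df, path, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# crisproff ", stage), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guide table
#'
#' TSV with header columns `guide_id`, `protospacer`, `pam` (IUPAC pattern),
#' `pam_side`, and optionally `cas_label`.
#'
#' @param path File path.
#' @return List of [guide_query()] objects.
#' @export
read_guide_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("guide_id", "protospacer", "pam", "pam_side")
  if (!all(need %in% names(x)))
    stop("guide table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  if (nrow(x) == 0L) stop("guide table ", path, " is empty")
  lapply(seq_len(nrow(x)), function(i)
    guide_query(x$guide_id[i], x$protospacer[i], x$pam[i], x$pam_side[i],
                if ("cas_label" %in% names(x)) x$cas_label[i] else "Cas9"))
}

#' Assemble and validate a pipeline run configuration
#'
#' @param genome Path to the reference FASTA.
#' @param guides Path to the guide table (see [read_guide_table()]).
#' @param vcf Path to the two-sample clone/parent VCF.
#' @param clone_sample,parent_sample Sample names in the VCF.
#' @param target_bed Path to a BED of intended target intervals whose name
#'   column matches guide ids.
#' @param cnv_a,cnv_b,cnv_parent Optional CNV call tables
#'   (see [read_cnv_table()]).
#' @param exons Optional coding-exon BED.
#' @param out Output directory (created if needed).
#' @param ensemble An [ensemble_config()].
#' @param thresholds A [screen_thresholds()].
#' @param crossref A [crossref_config()].
#' @param cnv A [cnv_config()].
#' @param seed Integer seed recorded in the manifest.
#' @return Object of class `run_config`.
#' @export
run_config <- function(genome, guides, vcf, clone_sample, parent_sample,
                       target_bed, cnv_a = NULL, cnv_b = NULL,
                       cnv_parent = NULL, exons = NULL, out = "crisproff_out",
                       ensemble = ensemble_config(),
                       thresholds = screen_thresholds(),
                       crossref = crossref_config(),
                       cnv = cnv_config(), seed = 1L) {
  paths <- list(genome = genome, guides = guides, vcf = vcf,
                target_bed = target_bed, cnv_a = cnv_a, cnv_b = cnv_b,
                cnv_parent = cnv_parent, exons = exons)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop("input '", nm, "' does not exist: ", p)
  }
  ## fail fast on an unusable guide table before any stage runs
  invisible(read_guide_table(guides))
  structure(c(paths,
              list(clone_sample = clone_sample,
                   parent_sample = parent_sample, out = out,
                   ensemble = ensemble, thresholds = thresholds,
                   crossref = crossref, cnv = cnv, seed = as.integer(seed))),
            class = "run_config")
}

#' Run the full detection pipeline
#'
#' Executes predict, screen-variants, crossref plus string-search,
#' screen-cnv (when CNV inputs are configured) and summarize, writing one
#' TSV/BED per stage plus a JSON run manifest (package version, config
#' echo, input checksums). Outputs are a pure function of inputs and
#' configuration; the only timestamp lives in the manifest.
#'
#' @param config A [run_config()].
#' @return Invisible list of output paths and the stage tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out, "manifest.json")
  stage <- "setup"
  result <- tryCatch({
    genome <- read_fasta(config$genome)
    guides <- read_guide_table(config$guides)
    targets <- read_bed(config$target_bed)

    stage <- "predict"
    sites <- do.call(rbind, lapply(guides, function(g)
      predict_offtargets(genome, g, config$ensemble)))
    .write_report(sites, file.path(config$out, "predicted_sites.tsv"),
                  "predict")
    write_bed(data.frame(contig = sites$contig, start = sites$start,
                         end = sites$end,
                         name = paste0(sites$guide_id, "|", sites$sources),
                         score = sites$mismatches, strand = sites$strand,
                         mismatches = sites$mismatches,
                         dna_bulge = sites$dna_bulge,
                         rna_bulge = sites$rna_bulge,
                         pam_seq = sites$pam_seq),
              file.path(config$out, "predicted_sites.bed"))

    stage <- "screen-variants"
    records <- read_variant_file(config$vcf, config$clone_sample,
                                 config$parent_sample)
    screened <- screen_unique_variants(records, config$thresholds)
    .write_report(screened$retained,
                  file.path(config$out, "retained_variants.tsv"),
                  "screen-variants")
    .write_report(data.frame(rule = names(screened$tally),
                             n_excluded = as.integer(screened$tally)),
                  file.path(config$out, "exclusion_summary.tsv"),
                  "screen-variants")

    stage <- "crossref"
    hits <- list(); shits <- list()
    for (g in guides) {
      trow <- targets[targets$name == g$guide_id, , drop = FALSE]
      ti <- if (nrow(trow)) list(contig = trow$contig[1],
                                 start = trow$start[1], end = trow$end[1])
            else NULL
      gs <- sites[sites$guide_id == g$guide_id, , drop = FALSE]
      h <- suppressWarnings(
        crossref_sites(screened$retained, gs, ti, config$crossref))
      if (nrow(h)) { h$guide_id <- g$guide_id; hits[[g$guide_id]] <- h }
      s <- string_search_screen(genome, g, screened$retained,
                                config$crossref)
      if (nrow(s)) { s$guide_id <- g$guide_id; shits[[g$guide_id]] <- s }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else
      data.frame(contig = character(), variant_start = integer(),
                 label = character())
    shits <- if (length(shits)) do.call(rbind, shits) else
      data.frame(contig = character(), variant_start = integer(),
                 mismatches = integer())
    rownames(hits) <- rownames(shits) <- NULL
    .write_report(hits, file.path(config$out, "crossref_hits.tsv"),
                  "crossref")
    .write_report(shits, file.path(config$out, "string_search_hits.tsv"),
                  "string-search")

    stage <- "screen-cnv"
    cnv_out <- NULL
    if (!is.null(config$cnv_a) && !is.null(config$cnv_b)) {
      ca <- read_cnv_table(config$cnv_a)
      cb <- read_cnv_table(config$cnv_b)
      cp <- if (!is.null(config$cnv_parent)) read_cnv_table(config$cnv_parent)
            else ca[0, , drop = FALSE]
      ex <- if (!is.null(config$exons)) read_bed(config$exons)
            else data.frame(contig = character(), start = integer(),
                            end = integer())
      cnv_out <- concordant_cnvs(ca, cb, config$cnv)
      cnv_out$category <- classify_unintended(cnv_out, cp, ex, config$cnv)
      .write_report(cnv_out, file.path(config$out, "cnv_screen.tsv"),
                    "screen-cnv")
    }

    stage <- "summarize"
    summary <- data.frame(
      stage = c("predicted_sites", "variants_in", "variants_retained",
                "crossref_hits", "on_target_hits", "string_search_hits",
                "cnv_retained"),
      n = c(nrow(sites), nrow(records), nrow(screened$retained),
            nrow(hits), sum(hits$label == "on_target"), nrow(shits),
            if (is.null(cnv_out)) NA_integer_ else nrow(cnv_out)))
    .write_report(summary, file.path(config$out, "run_summary.tsv"),
                  "summarize")
    list(sites = sites, screened = screened, hits = hits,
         string_hits = shits, cnv = cnv_out, summary = summary)
  }, error = function(e) e)
  failed <- inherits(result, "error")
  inputs <- Filter(Negate(is.null),
                   config[c("genome", "guides", "vcf", "target_bed", "cnv_a",
                            "cnv_b", "cnv_parent", "exons")])
  manifest <- list(
    package = "crisproff",
    version = as.character(utils::packageVersion("crisproff")),
    status = if (failed) paste0("FAILED at stage ", stage) else "OK",
    seed = config$seed,
    config = list(
      clone_sample = config$clone_sample,
      parent_sample = config$parent_sample,
      profiles = lapply(config$ensemble$profiles, unclass),
      thresholds = unclass(config$thresholds),
      crossref = unclass(config$crossref),
      cnv = unclass(config$cnv)),
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  if (failed)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(result))
  invisible(c(result, list(out = config$out, manifest = manifest_path)))
}
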