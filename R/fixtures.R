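## Deterministic synthetic-data generator. Every generator is a pure
## function of (seed, parameters): genomes with planted guide matches,
## paired clone/parent variant calls, and dual-caller CNV call sets, each
## with a machine-readable truth table, so the whole pipeline can be tested
## without any external data.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a random genome
#'
#' IID bases at a specified GC fraction (default 0.41, a human-like base
#' composition). Reproducible for a fixed seed.
#'
#' @param seed Integer seed.
#' @param contig_lengths Named or unnamed integer vector of contig lengths
#'   (each >= 1000); unnamed contigs are called `c1`, `c2`, ...
#' @param gc_fraction Expected GC fraction in (0, 1).
#' @return Named character vector of contig sequences.
#' @export
simulate_genome <- function(seed, contig_lengths = c(c1 = 20000L),
                            gc_fraction = 0.41) {
  stopifnot(all(contig_lengths >= 1000L), gc_fraction > 0, gc_fraction < 1)
  nm <- names(contig_lengths)
  if (is.null(nm)) nm <- paste0("c", seq_along(contig_lengths))
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  .with_seed(seed, {
    seqs <- vapply(contig_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    names(seqs) <- nm
    seqs
  })
}

#' Describe one planted guide match
#'
#' @param contig Contig name.
#' @param position 1-based genomic start of the protospacer span.
#' @param strand `"+"` or `"-"`.
#' @param n_mismatches Substitutions to plant (<= 8).
#' @param bulge_type `"none"`, `"dna"` or `"rna"`.
#' @param bulge_length Bulge length (<= 3; 0 iff `bulge_type == "none"`).
#' @param pam_valid Plant a valid PAM (`FALSE` plants a PAM violating the
#'   pattern, so no profile may report the site).
#' @return One-row data.frame.
#' @export
plant_spec <- function(contig, position, strand = "+", n_mismatches = 0L,
                       bulge_type = c("none", "dna", "rna"),
                       bulge_length = 0L, pam_valid = TRUE) {
  bulge_type <- match.arg(bulge_type)
  stopifnot(n_mismatches >= 0L, n_mismatches <= 8L,
            bulge_length >= 0L, bulge_length <= 3L,
            (bulge_type == "none") == (bulge_length == 0L))
  data.frame(contig = contig, position = as.integer(position),
             strand = strand, n_mismatches = as.integer(n_mismatches),
             bulge_type = bulge_type, bulge_length = as.integer(bulge_length),
             pam_valid = pam_valid, stringsAsFactors = FALSE)
}

## minimal mismatch count of `core` (guide-orientation genomic text) vs
## guide over all interior bulge placements; plain character-level check,
## used to record the realized truth of a plant
.span_min_mm <- function(core, guide_seq, bulge_type, b) {
  g <- strsplit(guide_seq, "")[[1]]
  s <- strsplit(core, "")[[1]]
  L <- length(g)
  cmp <- function(gi, si) sum(g[gi] != s[si] | s[si] == "N")
  if (bulge_type == "none") return(cmp(seq_len(L), seq_len(L)))
  best <- Inf
  if (bulge_type == "dna") {
    for (j in seq_len(L - 1L)) {
      mm <- cmp(seq_len(j), seq_len(j)) +
        cmp((j + 1L):L, (j + b + 1L):(L + b))
      best <- min(best, mm)
    }
  } else {
    for (j in seq_len(L - b - 1L)) {
      mm <- cmp(seq_len(j), seq_len(j)) +
        cmp((j + b + 1L):L, (j + 1L):(L - b))
      best <- min(best, mm)
    }
  }
  best
}

.realize_pam <- function(pam_pattern, valid) {
  codes <- strsplit(pam_pattern, "")[[1]]
  pam <- vapply(codes, function(k) {
    set <- IUPAC_SETS[[k]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1), USE.NAMES = FALSE)
  if (!valid) {
    constrained <- which(vapply(codes, function(k)
      length(IUPAC_SETS[[k]]) < 4L, logical(1)))
    if (length(constrained) == 0L)
      stop("cannot plant an invalid PAM for fully degenerate pattern ",
           pam_pattern)
    i <- constrained[[1L]]
    pam[[i]] <- sample(setdiff(c("A", "C", "G", "T"),
                               IUPAC_SETS[[codes[[i]]]]), 1L)
  }
  paste(pam, collapse = "")
}

#' Plant guide matches into a genome
#'
#' Overwrites each requested locus with a sequence realizing the requested
#' mismatch count, bulge state and PAM validity relative to the guide. The
#' realized minimal mismatch count for the planted span (which can be lower
#' than requested when substituted or inserted bases create an alternative
#' placement) is recorded in the truth table.
#'
#' @param genome Named character vector of contigs.
#' @param guide A [guide_query()].
#' @param specs data.frame of [plant_spec()] rows (non-overlapping,
#'   within bounds).
#' @param seed Integer seed for the random choices (substituted/inserted
#'   bases, bulge placement, PAM realization).
#' @return List with `genome` (modified) and `truth` (data.frame with the
#'   planted span coordinates, strand, realized `mismatches`, `dna_bulge`,
#'   `rna_bulge`, `pam_valid`).
#' @export
plant_sites <- function(genome, guide, specs, seed = 1L) {
  stopifnot(inherits(guide, "guide_query"), is.data.frame(specs))
  L <- nchar(guide$protospacer)
  plen <- nchar(guide$pam_pattern)
  .with_seed(seed, {
    occupied <- list()
    truth <- list()
    for (r in seq_len(nrow(specs))) {
      sp <- specs[r, ]
      if (!sp$contig %in% names(genome))
        stop("plant contig '", sp$contig, "' not in genome")
      b <- sp$bulge_length
      core_len <- L + ifelse(sp$bulge_type == "dna", b,
                             ifelse(sp$bulge_type == "rna", -b, 0L))
      gchars <- strsplit(guide$protospacer, "")[[1]]
      ## apply bulge
      if (sp$bulge_type == "dna") {
        j <- sample(seq_len(L - 1L), 1L)
        ins <- sample(c("A", "C", "G", "T"), b, replace = TRUE)
        core <- append(gchars, ins, after = j)
        aligned <- setdiff(seq_len(core_len), (j + 1L):(j + b))
      } else if (sp$bulge_type == "rna") {
        j <- sample(seq_len(L - b - 1L), 1L)
        core <- gchars[-((j + 1L):(j + b))]
        aligned <- seq_len(core_len)
      } else {
        core <- gchars
        aligned <- seq_len(core_len)
      }
      ## apply substitutions on aligned positions
      if (sp$n_mismatches > 0L) {
        pos <- sample(aligned, sp$n_mismatches)
        for (p in pos)
          core[[p]] <- sample(setdiff(c("A", "C", "G", "T"), core[[p]]), 1L)
      }
      core_txt <- paste(core, collapse = "")
      pam_txt <- .realize_pam(guide$pam_pattern, sp$pam_valid)
      full <- if (guide$pam_side == "three_prime")
        paste0(core_txt, pam_txt) else paste0(pam_txt, core_txt)
      pam_left_of_span <-
        (sp$strand == "+" && guide$pam_side == "five_prime") ||
        (sp$strand == "-" && guide$pam_side == "three_prime")
      span_start <- sp$position
      span_end <- span_start + core_len - 1L
      full_start <- if (pam_left_of_span) span_start - plen else span_start
      full_end <- full_start + nchar(full) - 1L
      if (full_start < 1L || full_end > nchar(genome[[sp$contig]]))
        stop("plant at ", sp$contig, ":", sp$position, " out of bounds")
      for (oc in occupied)
        if (oc$contig == sp$contig && full_start <= oc$end &&
            full_end >= oc$start)
          stop("plants overlap at ", sp$contig, ":", sp$position)
      occupied[[length(occupied) + 1L]] <-
        list(contig = sp$contig, start = full_start, end = full_end)
      genomic <- if (sp$strand == "-") reverse_complement(full) else full
      ## orientation: on "-", the guide-orientation text maps right-to-left
      substr(genome[[sp$contig]], full_start, full_end) <- genomic
      truth[[length(truth) + 1L]] <- data.frame(
        guide_id = guide$guide_id, contig = sp$contig,
        start = span_start, end = span_end, strand = sp$strand,
        mismatches = .span_min_mm(core_txt, guide$protospacer,
                                  sp$bulge_type, b),
        dna_bulge = ifelse(sp$bulge_type == "dna", b, 0L),
        rna_bulge = ifelse(sp$bulge_type == "rna", b, 0L),
        pam_valid = sp$pam_valid, stringsAsFactors = FALSE)
    }
    list(genome = genome, truth = do.call(rbind, truth))
  })
}

.vcf_header <- function(genome, clone_sample, parent_sample) {
  c("##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=weak_evidence,Description=\"Failed caller filter\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    paste0("##contig=<ID=", names(genome), ",length=", nchar(genome), ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", clone_sample, parent_sample, sep = "\t"))
}

#' Simulate a paired clone/parent variant call file
#'
#' Emits a two-sample VCF of somatic-style calls around predicted sites in
#' four truth classes: `linked_pass` (within the cross-reference window of
#' a site, passes every screen rule), `linked_fail_<rule>` (fails exactly
#' the named screen rule), `unlinked_pass` (passes the screen, far from all
#' sites) and `on_target` (inside the designated target interval).
#'
#' @param seed Integer seed.
#' @param genome Named character vector of contigs.
#' @param sites Predicted site table (see [predict_offtargets()]); linked
#'   variants are placed near these spans.
#' @param target_interval List with `contig`, `start`, `end`.
#' @param path Output VCF path.
#' @param clone_sample,parent_sample Sample names for the two columns.
#' @param window Linking window in bp (matches the cross-reference default).
#' @return List with `vcf` (the path) and `truth` (data.frame with
#'   `contig`, `start`, `class`, `expected_retained`, `expected_rule`,
#'   `expected_linked`, `expected_label`).
#' @export
simulate_variant_files <- function(seed, genome, sites, target_interval,
                                   path, clone_sample = "clone",
                                   parent_sample = "parent",
                                   window = 200L, on_target_radius = 2000L) {
  stopifnot(is.data.frame(sites), nrow(sites) >= 1L)
  fail_rules <- c("filter", "zygosity_unknown", "genotype_pattern", "depth",
                  "allele_fraction")
  .with_seed(seed, {
    ## choose distinct off-target site anchors, away from the target
    ti <- as.list(target_interval)
    s_off <- sites[!(sites$contig == ti$contig &
                       interval_distance(sites$start, sites$end,
                                         ti$start, ti$end) <= 2L * window), ,
                   drop = FALSE]
    need <- 3L + length(fail_rules)
    ## bulged/ungapped alignments of one locus occupy overlapping spans;
    ## thin to one representative per cluster so anchors are well separated
    s_off <- s_off[order(s_off$contig, s_off$start), , drop = FALSE]
    keep <- logical(nrow(s_off))
    last_contig <- ""; last_end <- -Inf
    for (i in seq_len(nrow(s_off))) {
      if (s_off$contig[i] != last_contig ||
          s_off$start[i] > last_end + 2L * window) {
        keep[i] <- TRUE
        last_contig <- s_off$contig[i]; last_end <- s_off$end[i]
      }
    }
    s_off <- s_off[keep, , drop = FALSE]
    if (nrow(s_off) < need)
      stop("need at least ", need, " well-separated off-target sites to ",
           "anchor variants, have ", nrow(s_off))
    anchors <- s_off[sample(nrow(s_off), need), , drop = FALSE]
    recs <- list()
    truth <- list()
    emit <- function(contig, pos, class, gt_c, gt_p, dp, af, filt,
                     retained, rule, linked, label) {
      ref <- substring(genome[[contig]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      af_txt <- ifelse(is.na(af), ".", format(af, digits = 3))
      recs[[length(recs) + 1L]] <<- paste(
        contig, pos, ".", ref, alt, "50", filt, ".", "GT:DP:AF",
        paste(gt_c, dp, af_txt, sep = ":"),
        paste(gt_p, "30", "0", sep = ":"), sep = "\t")
      truth[[length(truth) + 1L]] <<- data.frame(
        contig = contig, start = as.integer(pos), class = class,
        expected_retained = retained, expected_rule = rule,
        expected_linked = linked, expected_label = label,
        stringsAsFactors = FALSE)
    }
    near <- function(site) {
      ## a position within `window` of the site span (and inside the contig)
      off <- sample(10L:(window - 10L), 1L)
      max(1L, site$start - off)
    }
    expected_label <- function(contig, pos) {
      if (contig == ti$contig &&
          interval_distance(pos, pos, ti$start, ti$end) <= on_target_radius)
        "on_target" else "off_target_candidate"
    }
    k <- 0L
    for (i in 1:3) {
      k <- k + 1L; a <- anchors[k, ]
      pos <- near(a)
      emit(a$contig, pos, "linked_pass", "0/1", "0/0", 30L, 0.4, "PASS",
           TRUE, NA_character_, TRUE, expected_label(a$contig, pos))
    }
    for (rule in fail_rules) {
      k <- k + 1L; a <- anchors[k, ]
      pos <- near(a)
      switch(rule,
        filter = emit(a$contig, pos, "linked_fail_filter", "0/1", "0/0",
                      30L, 0.4, "weak_evidence", FALSE, rule, TRUE, NA),
        zygosity_unknown = emit(a$contig, pos, "linked_fail_zygosity_unknown",
                                "./.", "0/0", 30L, 0.4, "PASS", FALSE, rule,
                                TRUE, NA),
        genotype_pattern = emit(a$contig, pos, "linked_fail_genotype_pattern",
                                "1/1", "0/0", 30L, 0.4, "PASS", FALSE, rule,
                                TRUE, NA),
        depth = emit(a$contig, pos, "linked_fail_depth", "0/1", "0/0",
                     sample(1L:9L, 1L), 0.4, "PASS", FALSE, rule, TRUE, NA),
        allele_fraction = emit(a$contig, pos, "linked_fail_allele_fraction",
                               "0/1", "0/0", 30L,
                               round(stats::runif(1, 0.02, 0.19), 2), "PASS",
                               FALSE, rule, TRUE, NA))
    }
    ## unlinked passes: positions > 2*window from every site span
    placed <- vapply(truth, function(t) paste0(t$contig, ":", t$start),
                     character(1))
    n_unlinked <- 0L
    while (n_unlinked < 3L) {
      ctg <- sample(names(genome), 1L)
      pos <- sample(seq(window + 1L, nchar(genome[[ctg]]) - window), 1L)
      ss <- sites[sites$contig == ctg, , drop = FALSE]
      d <- if (nrow(ss)) min(interval_distance(pos, pos, ss$start, ss$end))
           else Inf
      d_t <- if (ctg == ti$contig)
        interval_distance(pos, pos, ti$start, ti$end) else Inf
      if (d > 2L * window && d_t > 3000L &&
          !paste0(ctg, ":", pos) %in% placed) {
        emit(ctg, pos, "unlinked_pass", "0/1", "0/0", 40L, 0.5, "PASS",
             TRUE, NA_character_, FALSE, NA)
        placed <- c(placed, paste0(ctg, ":", pos))
        n_unlinked <- n_unlinked + 1L
      }
    }
    ## on-target variant inside the intended interval
    emit(ti$contig, sample(ti$start:ti$end, 1L), "on_target", "0/1", "0/0",
         35L, 0.45, "PASS", TRUE, NA_character_, TRUE, "on_target")
    truth <- do.call(rbind, truth)
    ord <- order(truth$contig, truth$start)
    writeLines(c(.vcf_header(genome, clone_sample, parent_sample),
                 unlist(recs)[ord]), path)
    list(vcf = path, truth = truth[ord, , drop = FALSE])
  })
}

#' Simulate dual-caller CNV call sets with truth
#'
#' Generates CNV calls for two callers, a parental call set and a coding
#' exon annotation on a nominal chromosome, covering every screening
#' outcome: concordant de novo calls classified `other_de_novo`,
#' `large_rare` (3-10 Mb) and `exonic`; a parental-shared call
#' (`not_de_novo`); a sub-1-kb call removed by the size rule; and
#' discordant calls (low reciprocal overlap, or type mismatch) removed by
#' the concordance rule.
#'
#' @param seed Integer seed.
#' @param contig Nominal chromosome name.
#' @return List with `calls_a`, `calls_b`, `parent_calls`, `coding_exons`
#'   and `truth` (one row per caller-A call: `expected_retained`,
#'   `expected_category`).
#' @export
simulate_cnv_calls <- function(seed, contig = "chr_sim") {
  .with_seed(seed, {
    jit <- function() sample.int(2000L, 1L)
    mk <- function(start, len, type) {
      data.frame(contig = contig, start = start, end = start + len - 1L,
                 cnv_type = type, stringsAsFactors = FALSE)
    }
    a <- list(); b <- list(); truth <- list()
    addcase <- function(start, len, type, in_b, b_frac, b_type, retained,
                        category) {
      ca <- mk(start, len, type)
      a[[length(a) + 1L]] <<- ca
      if (in_b) {
        blen <- max(1L, round(len * b_frac))
        b[[length(b) + 1L]] <<- mk(start, blen, b_type)
      }
      truth[[length(truth) + 1L]] <<- data.frame(
        start = start, expected_retained = retained,
        expected_category = if (retained) category else NA_character_,
        stringsAsFactors = FALSE)
    }
    base <- 1e6
    addcase(base + jit(), 5000L, "deletion", TRUE, 1, "deletion",
            TRUE, "other_de_novo")
    addcase(base + 2e6 + jit(), 5e6, "deletion", TRUE, 0.95, "deletion",
            TRUE, "large_rare")
    exon_anchor <- base + 9e6 + jit()
    addcase(exon_anchor, 2000L, "duplication", TRUE, 1, "duplication",
            TRUE, "exonic")
    parent_anchor <- base + 11e6 + jit()
    addcase(parent_anchor, 10000L, "deletion", TRUE, 0.9, "deletion",
            TRUE, "not_de_novo")
    addcase(base + 13e6 + jit(), 800L, "deletion", TRUE, 1, "deletion",
            FALSE, NA)
    addcase(base + 15e6 + jit(), 5000L, "deletion", TRUE, 0.3, "deletion",
            FALSE, NA)
    addcase(base + 17e6 + jit(), 5000L, "deletion", TRUE, 1, "duplication",
            FALSE, NA)
    calls_a <- do.call(rbind, a); calls_a$source <- "caller_a"
    calls_b <- do.call(rbind, b); calls_b$source <- "caller_b"
    parent <- mk(parent_anchor, 10000L, "deletion")
    parent$source <- "caller_a"
    exons <- data.frame(contig = contig,
                        start = c(exon_anchor + 500L, base + 20e6),
                        end = c(exon_anchor + 650L, base + 20e6 + 150L),
                        stringsAsFactors = FALSE)
    list(calls_a = calls_a, calls_b = calls_b, parent_calls = parent,
         coding_exons = exons, truth = do.call(rbind, truth))
  })
}

#' Simulate a complete pipeline scenario on disk
#'
#' Builds a seeded end-to-end fixture: a random genome with an on-target
#' match and several planted off-target matches for one guide, a paired
#' clone/parent VCF with truth-labelled variants, dual-caller CNV tables,
#' a coding-exon BED and a target BED, all written under `dir` together
#' with JSON-lines truth files.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param guide A [guide_query()]; default is a packaged study guide.
#' @param contig_lengths Genome shape.
#' @return List of file paths plus the in-memory `truth` tables.
#' @export
simulate_scenario <- function(seed, dir,
                              guide = guide_query("gnaq_c548",
                                                  "CTAAGCACATCTTGTTGCGT",
                                                  "NGG", "three_prime",
                                                  "Cas9"),
                              contig_lengths = c(c1 = 20000L, c2 = 12000L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(seed, contig_lengths)
  L <- nchar(guide$protospacer)
  ## plants spaced >= 2 * (guide length + window) to prevent cross-talk
  gap <- 2L * (L + 200L)
  pos <- function(i) 500L + (i - 1L) * gap
  specs <- rbind(
    plant_spec("c1", pos(1), "+", 0L),                    # on-target
    plant_spec("c1", pos(2), "+", 2L),
    plant_spec("c1", pos(3), "-", 4L),
    plant_spec("c1", pos(4), "+", 1L, "dna", 1L),
    plant_spec("c1", pos(5), "-", 2L, "rna", 1L),
    plant_spec("c1", pos(6), "+", 0L, pam_valid = FALSE),
    plant_spec("c2", pos(1), "+", 3L),
    plant_spec("c2", pos(2), "-", 1L),
    plant_spec("c2", pos(3), "+", 2L, "dna", 2L),
    plant_spec("c2", pos(4), "-", 3L))
  planted <- plant_sites(genome, guide, specs, seed = seed + 1L)
  genome <- planted$genome
  target <- list(contig = "c1", start = pos(1),
                 end = pos(1) + L - 1L)
  sites <- predict_offtargets(genome, guide, ensemble_config())
  vcf <- simulate_variant_files(seed + 2L, genome, sites, target,
                                file.path(dir, "variants.vcf"))
  cnv <- simulate_cnv_calls(seed + 3L)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    guides = file.path(dir, "guides.tsv"),
    vcf = vcf$vcf,
    target_bed = file.path(dir, "target.bed"),
    cnv_a = file.path(dir, "cnv_a.tsv"),
    cnv_b = file.path(dir, "cnv_b.tsv"),
    cnv_parent = file.path(dir, "cnv_parent.tsv"),
    exons = file.path(dir, "exons.bed"),
    truth_sites = file.path(dir, "truth_sites.jsonl"),
    truth_variants = file.path(dir, "truth_variants.jsonl"),
    truth_cnv = file.path(dir, "truth_cnv.jsonl"))
  write_fasta(genome, paths$genome)
  utils::write.table(
    data.frame(guide_id = guide$guide_id, protospacer = guide$protospacer,
               pam = guide$pam_pattern, pam_side = guide$pam_side,
               cas_label = guide$cas_label),
    paths$guides, sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(data.frame(contig = target$contig, start = target$start,
                       end = target$end, name = guide$guide_id,
                       strand = "+"), paths$target_bed)
  for (nm in c("cnv_a", "cnv_b", "cnv_parent")) {
    tab <- switch(nm, cnv_a = cnv$calls_a, cnv_b = cnv$calls_b,
                  cnv_parent = cnv$parent_calls)
    utils::write.table(tab, paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_bed(cnv$coding_exons, paths$exons)
  .write_jsonl <- function(df, path) {
    writeLines(vapply(seq_len(nrow(df)), function(i)
      as.character(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                    na = "null")),
      character(1)), path)
  }
  .write_jsonl(planted$truth, paths$truth_sites)
  .write_jsonl(vcf$truth, paths$truth_variants)
  .write_jsonl(cnv$truth, paths$truth_cnv)
  c(paths, list(truth = list(sites = planted$truth, variants = vcf$truth,
                             cnv = cnv$truth),
                target = target, guide = guide))
}
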