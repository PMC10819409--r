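fake_site <- function(contig, start, end, strand = "+", pam_len = 3L) {
  ## site span with a 3' PAM immediately to the right
  data.frame(contig = contig, start = start, end = end, strand = strand,
             mismatches = 0L, dna_bulge = 0L, rna_bulge = 0L,
             pam_start = end + 1L, pam_end = end + pam_len,
             pam_seq = "AGG", sources = "cas_offinder",
             stringsAsFactors = FALSE)
}

fake_variant <- function(contig, start, end = start, ref = "A", alt = "T") {
  data.frame(contig = contig, start = start, end = end, ref = ref, alt = alt,
             clone_genotype = "het", parent_genotype = "hom_ref",
             filter_status = "PASS", clone_depth = 30,
             clone_allele_fraction = 0.4, variant_class = "SNV",
             stringsAsFactors = FALSE)
}

test_that("crossref links variants to sites within the 200-bp window", {
  sites <- rbind(fake_site("c1", 10150L, 10172L),
                 fake_site("c1", 10500L, 10522L))
  hits <- crossref_sites(fake_variant("c1", 10000L), sites, NULL)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$site_start, 10150L)
  expect_equal(hits$distance, 150L)
  expect_identical(hits$label, "off_target_candidate")
  ## distance counts from the PAM-inclusive span end when nearer
  left <- crossref_sites(fake_variant("c1", 10150L),
                         fake_site("c1", 10000L, 10020L), NULL)
  expect_equal(left$distance, 10150L - 10023L)
})

test_that("overlap gives distance zero and window zero keeps only overlaps", {
  site <- fake_site("c1", 995L, 1017L)
  ov <- crossref_sites(fake_variant("c1", 1000L), site, NULL)
  expect_equal(ov$distance, 0L)
  cfg0 <- crossref_config(window = 0L)
  expect_equal(nrow(crossref_sites(fake_variant("c1", 1000L), site, NULL,
                                   cfg0)), 1L)
  expect_equal(nrow(crossref_sites(fake_variant("c1", 1021L), site, NULL,
                                   cfg0)), 0L)
})

test_that("on-target labelling uses the target interval and radius", {
  target <- list(contig = "c1", start = 5000L, end = 5019L)
  sites <- rbind(fake_site("c1", 5000L, 5019L),
                 fake_site("c1", 7000L, 7019L),
                 fake_site("c1", 9000L, 9019L))
  vars <- rbind(fake_variant("c1", 5050L),   # 31 bp from target
                fake_variant("c1", 6950L),   # 1931 bp: still on-target radius
                fake_variant("c1", 9100L))   # far from target, near site 2
  hits <- crossref_sites(vars, sites, target)
  lab <- hits$label[order(hits$variant_start)]
  expect_identical(lab, c("on_target", "on_target", "off_target_candidate"))
})

test_that("variants on contigs without sites are warned and reported unlinked", {
  sites <- fake_site("c1", 1000L, 1022L)
  vars <- rbind(fake_variant("c1", 1100L), fake_variant("cX", 500L))
  expect_warning(hits <- crossref_sites(vars, sites, NULL), "cX")
  expect_equal(nrow(hits), 1L)
  expect_equal(attr(hits, "unlinked")$contig, "cX")
})

test_that("string search finds planted protospacers in both orientations", {
  proto <- "CTAAGCACATCTTGTTGCGT"
  g <- guide_query("g", proto, "NGG")
  ## plant: exact copy 100 bp downstream with 2 substitutions, no PAM
  mutated <- proto
  substr(mutated, 1, 1) <- "A"   # C>A
  substr(mutated, 5, 5) <- "A"   # G>A
  stopifnot(sum(strsplit(mutated, "")[[1]] != strsplit(proto, "")[[1]]) == 2L)
  genome <- c(c1 = paste0(strrep("G", 999),  "C",  # variant locus at 1000
                          strrep("C", 99), mutated,
                          strrep("G", 500)))
  v <- fake_variant("c1", 1000L)
  hits <- string_search_screen(genome, g, v)
  fwd <- hits[hits$orientation == "plus" & hits$match_start == 1100L, ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$mismatches, 2L)
  ## reverse-complement plant with 0 substitutions
  genome2 <- c(c1 = paste0(strrep("G", 999), "C", strrep("C", 79),
                           reverse_complement(proto), strrep("G", 500)))
  hits2 <- string_search_screen(genome2, g, v)
  rev <- hits2[hits2$orientation == "minus" & hits2$mismatches == 0L, ]
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$match_start, 1080L)
  ## a 5-substitution plant exceeds the 4-mismatch budget
  worse <- mutated
  substr(worse, 12, 12) <- "A"; substr(worse, 15, 15) <- "C"  # T>A, T>C
  substr(worse, 18, 18) <- "A"                                # C>A
  stopifnot(sum(strsplit(worse, "")[[1]] != strsplit(proto, "")[[1]]) == 5L)
  genome3 <- c(c1 = paste0(strrep("G", 999), "C", strrep("C", 99), worse,
                           strrep("G", 500)))
  expect_equal(nrow(string_search_screen(genome3, g, v)), 0L)
})

test_that("string search equals the brute-force window scan", {
  genome <- simulate_genome(3L, c(c1 = 4000L))
  g <- guide_query("g", "ATCAGGAAAGCAGTGTTGGC", "NGG")
  v <- rbind(fake_variant("c1", 1200L), fake_variant("c1", 3000L))
  cfg <- crossref_config()
  hits <- string_search_screen(genome, g, v, cfg)
  for (i in seq_len(nrow(v))) {
    orc <- orc_window_scan(genome, "c1", v$start[i], v$end[i],
                           g$protospacer, cfg$window,
                           cfg$string_search_max_mismatches)
    got <- hits[hits$variant_start == v$start[i],
                c("match_start", "match_end", "orientation", "mismatches")]
    rownames(got) <- rownames(orc) <- NULL
    expect_identical(got, orc)
  }
})

test_that("string search recovers PAM-less guide loci that prediction misses", {
  ## a guide designed against a variant-bearing haplotype: the genomic
  ## reference carries the protospacer but no PAM, so PAM-anchored
  ## prediction is blind to it while the string search is not
  proto <- "GTCCTGTGCAGAAGAGTCCA"
  g <- guide_query("g", proto, "NGG")
  genome <- c(c1 = paste0(strrep("T", 999), "C", strrep("T", 49), proto,
                          "ATT", strrep("T", 300)))
  pred <- predict_offtargets(genome, g, ensemble_config())
  expect_equal(nrow(pred), 0L)
  v <- fake_variant("c1", 1000L)
  ss <- string_search_screen(genome, g, v)
  expect_gte(nrow(ss), 1L)
  expect_true(any(ss$match_start == 1050L & ss$mismatches == 0L))
})

test_that("string search is a superset detector for ungapped low-mm sites", {
  genome <- simulate_genome(19L, c(c1 = 5000L))
  g <- guide_query("g", "ACCCCCAGACCTGGAACGGC", "NGG")
  planted <- plant_sites(genome, g, plant_spec("c1", 2000L, "+", 3L),
                         seed = 4L)
  sites <- predict_offtargets(planted$genome, g, ensemble_config())
  near <- sites[sites$mismatches <= 4L & sites$dna_bulge == 0L &
                  sites$rna_bulge == 0L, ]
  expect_gte(nrow(near), 1L)
  for (i in seq_len(nrow(near))) {
    v <- fake_variant(near$contig[i], pmax(1L, near$start[i] - 100L))
    ss <- string_search_screen(planted$genome, g, v)
    expect_true(any(ss$match_start == near$start[i] &
                      ss$mismatches == near$mismatches[i]))
  }
})

test_that("shrinking the window never adds string-search hits", {
  genome <- simulate_genome(23L, c(c1 = 3000L))
  g <- guide_query("g", "CAAGGGAAGAGCTTATTCTT", "NGG")
  v <- fake_variant("c1", 1500L)
  wide <- string_search_screen(genome, g, v, crossref_config(window = 400L))
  narrow <- string_search_screen(genome, g, v, crossref_config(window = 150L))
  key <- function(h) paste(h$match_start, h$orientation)
  expect_true(all(key(narrow) %in% key(wide)))
})
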