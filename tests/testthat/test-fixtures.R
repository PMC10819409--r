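test_that("genome simulation is a pure function of seed and parameters", {
  g1 <- simulate_genome(1L, c(c1 = 10000L), 0.41)
  g2 <- simulate_genome(1L, c(c1 = 10000L), 0.41)
  g3 <- simulate_genome(2L, c(c1 = 10000L), 0.41)
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))
  expect_equal(nchar(g1[["c1"]]), 10000L)
})

test_that("simulated base composition tracks the requested GC fraction", {
  g <- simulate_genome(17L, c(c1 = 100000L), 0.5)
  ch <- strsplit(g[["c1"]], "")[[1]]
  gc <- mean(ch %in% c("G", "C"))
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
  g41 <- simulate_genome(18L, c(c1 = 50000L), 0.41)
  gc41 <- mean(strsplit(g41[["c1"]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc41 - 0.41), 0.02)
})

test_that("planted sites across all mismatch/bulge classes are recovered exactly", {
  g <- guide_query("g", "CTAAGCACATCTTGTTGCGT", "NGG")
  set.seed(1234)
  classes <- expand.grid(mm = 0:5, cfg = c("none", "dna1", "dna2",
                                           "rna1", "rna2"),
                         stringsAsFactors = FALSE)
  picks <- classes[sample(nrow(classes), 20L), ]
  specs <- do.call(rbind, lapply(seq_len(nrow(picks)), function(i) {
    btype <- sub("[0-9]", "", picks$cfg[i])
    blen <- if (btype == "none") 0L else as.integer(sub("[a-z]+", "",
                                                        picks$cfg[i]))
    plant_spec("c1", 400L + (i - 1L) * 900L,
               strand = sample(c("+", "-"), 1L),
               n_mismatches = picks$mm[i], bulge_type = btype,
               bulge_length = blen)
  }))
  genome <- simulate_genome(55L, c(c1 = 20000L))
  planted <- plant_sites(genome, g, specs, seed = 77L)
  sites <- find_sites(planted$genome, g, search_profile("wide", 5, 2))
  tr <- planted$truth
  for (i in seq_len(nrow(tr))) {
    hit <- sites[sites$start == tr$start[i] & sites$end == tr$end[i] &
                   sites$strand == tr$strand[i], ]
    expect_equal(nrow(hit), 1L, info = paste("plant", i))
    expect_equal(hit$mismatches, tr$mismatches[i], info = paste("plant", i))
    expect_equal(hit$dna_bulge, tr$dna_bulge[i])
    expect_equal(hit$rna_bulge, tr$rna_bulge[i])
  }
})

test_that("plants without a valid PAM are invisible to every profile", {
  g <- guide_query("g", "ACCCCCAGACCTGGAACGGC", "NGG")
  genome <- simulate_genome(66L, c(c1 = 3000L))
  planted <- plant_sites(genome, g,
                         plant_spec("c1", 1000L, "+", 0L, pam_valid = FALSE),
                         seed = 5L)
  for (p in default_search_profiles()) {
    s <- find_sites(planted$genome, g, p)
    expect_equal(nrow(s[s$start == 1000L & s$strand == "+" &
                          s$end == 1019L, ]), 0L)
  }
})

test_that("overlapping or out-of-bounds plants are rejected", {
  g <- guide_query("g", "ACCCCCAGACCTGGAACGGC", "NGG")
  genome <- simulate_genome(9L, c(c1 = 2000L))
  expect_error(plant_sites(genome, g,
                           rbind(plant_spec("c1", 500L),
                                 plant_spec("c1", 510L))), "overlap")
  expect_error(plant_sites(genome, g, plant_spec("c1", 1995L)), "bounds")
})

test_that("simulated variant files round-trip and screen exactly as labelled", {
  scen <- simulate_scenario(31L, tempfile("scen"))
  v <- read_variant_file(scen$vcf, "clone", "parent")
  tr <- scen$truth$variants
  expect_equal(nrow(v), nrow(tr))
  sc <- screen_unique_variants(v)
  key <- function(df, s) paste(df$contig, s)
  retained_keys <- paste(sc$retained$contig, sc$retained$start)
  expect_setequal(retained_keys,
                  paste(tr$contig, tr$start)[tr$expected_retained])
  ## each failing record is excluded under exactly its planted rule
  ex <- sc$excluded
  for (i in which(!tr$expected_retained)) {
    row <- ex[ex$contig == tr$contig[i] & ex$start == tr$start[i], ]
    expect_equal(nrow(row), 1L)
    expect_identical(row$exclusion_rule, tr$expected_rule[i])
  }
})

test_that("scenario fixture files round-trip through the package readers", {
  scen <- simulate_scenario(8L, tempfile("scen"))
  g <- read_fasta(scen$genome)
  expect_identical(g, read_fasta(scen$genome))
  tb <- read_bed(scen$target_bed)
  expect_equal(tb$start, scen$target$start)
  expect_equal(tb$end, scen$target$end)
  cn <- read_cnv_table(scen$cnv_a)
  expect_true(all(c("contig", "start", "end", "cnv_type", "source") %in%
                    names(cn)))
  gl <- read_guide_table(scen$guides)
  expect_identical(gl[[1]]$protospacer, scen$guide$protospacer)
  truth_lines <- readLines(scen$truth_sites)
  expect_equal(length(truth_lines), nrow(scen$truth$sites))
  expect_silent(lapply(truth_lines, jsonlite::fromJSON))
})
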