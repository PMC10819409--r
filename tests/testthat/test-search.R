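kcnq2_guide <- guide_query("kcnq2_c875_877", "ACCCCCAGACCTGGAACGGC", "NGG",
                           "three_prime", "Cas9")

test_that("iupac_match implements IUPAC sets with genomic N matching nothing", {
  expect_true(iupac_match("G", "N"))
  expect_true(iupac_match("A", "V"))
  expect_false(iupac_match("T", "V"))
  expect_true(iupac_match("G", "V"))   # TTTG satisfies TTTV
  expect_false(iupac_match("N", "N"))
  expect_false(iupac_match("N", "A"))
  expect_error(iupac_match("A", "X"), "invalid IUPAC")
})

test_that("reverse_complement handles DNA and IUPAC codes and is an involution", {
  expect_identical(reverse_complement("AAGG"), "CCTT")
  expect_identical(reverse_complement("NGG"), "CCN")
  expect_identical(reverse_complement("TTTV"), "BAAA")
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N", "R", "V"), 15,
                      replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
  expect_error(reverse_complement("ACGU"), "invalid character")
})

test_that("guide_query validates alphabet, length and PAM codes", {
  expect_error(guide_query("g", "ACGTACGTACGTACGTACGU", "NGG"), "A,C,G,T")
  expect_error(guide_query("g", "ACGT", "NGG"), "18-24")
  expect_error(guide_query("g", strrep("A", 20), "NXG"), "IUPAC")
})

test_that("a planted guide with its PAM is recovered exactly once", {
  genome <- c(c1 = paste0(strrep("T", 100), "ACCCCCAGACCTGGAACGGC", "AGG",
                          strrep("T", 100)))
  s <- find_sites(genome, kcnq2_guide, search_profile("strict", 3, 0))
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 101L)
  expect_equal(s$end, 120L)
  expect_identical(s$strand, "+")
  expect_equal(s$mismatches, 0L)
  expect_identical(s$pam_seq, "AGG")
  expect_equal(s$pam_start, 121L)
})

test_that("mismatch budget is a strict threshold", {
  proto <- "ACCCCCAGACCTGGAACGGC"
  mutated <- paste0(substr(proto, 1, 9), "T", substr(proto, 11, 20))
  stopifnot(mutated != proto)
  genome <- c(c1 = paste0(strrep("T", 100), mutated, "AGG", strrep("T", 100)))
  hit <- find_sites(genome, kcnq2_guide, search_profile("p", 3, 0))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mismatches, 1L)
  none <- find_sites(genome, kcnq2_guide, search_profile("p0", 0, 0))
  expect_equal(nrow(none), 0L)
})

test_that("a site missing its PAM is never reported", {
  genome <- c(c1 = paste0(strrep("T", 100), "ACCCCCAGACCTGGAACGGC", "ATT",
                          strrep("T", 100)))
  for (p in default_search_profiles())
    expect_equal(nrow(find_sites(genome, kcnq2_guide, p)), 0L)
})

test_that("five-prime PAM guides anchor the PAM on the correct side", {
  g12a <- guide_query("ash1l_c773", "ATCAGGAAAGCAGTGTTGGC", "TTTV",
                      "five_prime", "Cas12a")
  plus <- c(c1 = paste0(strrep("C", 80), "TTTG", "ATCAGGAAAGCAGTGTTGGC",
                        strrep("C", 80)))
  s <- find_sites(plus, g12a, search_profile("p", 3, 0))
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 85L)
  expect_identical(s$pam_seq, "TTTG")
  expect_equal(s$pam_end, s$start - 1L)  # PAM abuts the 5' end
  minus <- c(c1 = paste0(strrep("C", 80),
                         reverse_complement("TTTGATCAGGAAAGCAGTGTTGGC"),
                         strrep("C", 80)))
  sm <- find_sites(minus, g12a, search_profile("p", 3, 0))
  expect_equal(nrow(sm), 1L)
  expect_identical(sm$strand, "-")
  expect_identical(sm$pam_seq, "TTTG")
  expect_equal(sm$pam_start, sm$end + 1L)  # genomically right of the span
})

test_that("N bases in protospacer or PAM suppress sites", {
  base <- paste0(strrep("T", 100), "ACCCCCAGACCTGGAACGGC", "AGG",
                 strrep("T", 100))
  in_proto <- base
  substr(in_proto, 110, 110) <- "N"
  expect_equal(nrow(find_sites(c(c1 = in_proto), kcnq2_guide,
                               search_profile("p", 3, 0))), 0L)
  in_pam <- base
  substr(in_pam, 121, 121) <- "N"  # the N position of NGG
  expect_equal(nrow(find_sites(c(c1 = in_pam), kcnq2_guide,
                               search_profile("p", 3, 0))), 0L)
})

test_that("bulged sites appear only under bulge-aware profiles", {
  g <- guide_query("g", "ACGTTGCAACGGATTCGCAT", "NGG")
  planted <- plant_sites(
    simulate_genome(21L, c(c1 = 3000L)), g,
    rbind(plant_spec("c1", 500L, "+", 0L, "dna", 1L),
          plant_spec("c1", 1500L, "-", 1L, "rna", 2L)),
    seed = 3L)
  aware <- find_sites(planted$genome, g, search_profile("aware", 5, 2))
  blind <- find_sites(planted$genome, g, search_profile("blind", 5, 0))
  tr <- planted$truth
  for (r in seq_len(nrow(tr))) {
    hit <- aware[aware$start == tr$start[r] & aware$strand == tr$strand[r] &
                   aware$end == tr$end[r], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$mismatches, tr$mismatches[r])
    expect_equal(hit$dna_bulge, tr$dna_bulge[r])
    expect_equal(hit$rna_bulge, tr$rna_bulge[r])
    expect_equal(nrow(blind[blind$start == tr$start[r] &
                              blind$end == tr$end[r] &
                              blind$strand == tr$strand[r], ]), 0L)
  }
})

test_that("engine matches the exhaustive oracle on random genomes", {
  set.seed(42)
  for (rep in 1:3) {
    genome <- simulate_genome(100L + rep, c(g1 = 1000L))
    proto <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                   collapse = "")
    g <- guide_query(paste0("rg", rep), proto, "NGG")
    for (prof in list(c(5L, 2L), c(3L, 0L))) {
      eng <- find_sites(genome, g, search_profile("p", prof[1], prof[2]))
      orc <- orc_find_sites(genome, g, prof[1], prof[2])
      rownames(orc) <- NULL
      expect_identical(site_key_frame(eng), orc)
    }
  }
})

test_that("site sets are monotone in mismatch and bulge budgets", {
  genome <- simulate_genome(77L, c(g1 = 2000L))
  g <- guide_query("g", "TTGACCACCATTGGCTACGG", "NGG")
  key <- function(s) paste(s$contig, s$start, s$end, s$strand)
  prev <- character(0)
  for (m in 0:5) {
    cur <- key(find_sites(genome, g, search_profile("p", m, 0)))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  m5b0 <- key(find_sites(genome, g, search_profile("p", 5, 0)))
  m5b2 <- key(find_sites(genome, g, search_profile("p", 5, 2)))
  expect_true(all(m5b0 %in% m5b2))
})

test_that("search is strand-symmetric under genome reverse-complementation", {
  g <- guide_query("g", "CTAAGCACATCTTGTTGCGT", "NGG")
  genome <- plant_sites(simulate_genome(7L, c(g1 = 1500L)), g,
                        rbind(plant_spec("g1", 300L, "+", 2L),
                              plant_spec("g1", 900L, "-", 1L, "dna", 1L)),
                        seed = 6L)$genome
  flipped <- c(g1 = reverse_complement(genome[["g1"]]))
  L <- nchar(genome[["g1"]])
  fwd <- find_sites(genome, g, search_profile("p", 5, 2))
  rev <- find_sites(flipped, g, search_profile("p", 5, 2))
  mirror <- data.frame(contig = rev$contig,
                       start = L - rev$end + 1L, end = L - rev$start + 1L,
                       strand = as.character(ifelse(rev$strand == "+",
                                                    "-", "+")),
                       mismatches = rev$mismatches,
                       dna_bulge = rev$dna_bulge, rna_bulge = rev$rna_bulge)
  mirror <- mirror[order(mirror$contig, mirror$start, mirror$strand,
                         mirror$end), ]
  rownames(mirror) <- NULL
  expect_identical(site_key_frame(fwd), mirror)
})
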