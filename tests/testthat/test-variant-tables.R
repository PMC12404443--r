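test_that("HGVS p. consequences parse to one-letter missense changes", {
  out <- parse_protein_consequence(c("p.Met309Val", "p.Ala256Thr"))
  expect_equal(out$ref_aa, c("M", "A"))
  expect_equal(out$position, c(309L, 256L))
  expect_equal(out$alt_aa, c("V", "T"))
})

test_that("non-missense and malformed consequences fail with distinct causes", {
  expect_error(parse_protein_consequence("p.Met309Ter"),
               class = "ardscan_nonsense_not_missense")
  expect_error(parse_protein_consequence("p.Met309fsTer12"),
               class = "ardscan_nonsense_not_missense")
  expect_error(parse_protein_consequence("p.Met309Met"),
               class = "ardscan_synonymous_not_missense")
  expect_error(parse_protein_consequence("p.Xyz309Val"),
               class = "ardscan_unknown_code")
  expect_error(parse_protein_consequence("c.925A>G"),
               class = "ardscan_malformed_hgvs")
})

test_that("one-letter -> three-letter -> parse round trip is identity on all amino acids", {
  aas <- amino_acid_properties()$aa
  for (ref in aas) {
    alts <- setdiff(aas, ref)
    hgvs <- format_protein_consequence(rep(ref, length(alts)), 42L, alts)
    back <- parse_protein_consequence(hgvs)
    expect_equal(back$ref_aa, rep(ref, length(alts)))
    expect_equal(back$alt_aa, alts)
    expect_equal(back$position, rep(42L, length(alts)))
  }
})

test_that("numbering maps apply a signed offset and invert exactly", {
  human_to_rat <- numbering_map(-1, "human TRPV1", "rat TRPV1")
  expect_equal(map_numbering(309, human_to_rat), 308L)
  expect_equal(map_numbering(256, numbering_map(0)), 256L)
  expect_error(map_numbering(1, human_to_rat), class = "ardscan_out_of_range")
  # apply then invert is identity
  pos <- c(111L, 308L, 361L)
  expect_equal(map_numbering(map_numbering(pos, human_to_rat), numbering_map(1)), pos)
})

test_that("build_spectra sums duplicate changes and keys by reference numbering", {
  v <- tibble::tibble(
    ref_aa = "M", position = 309L,
    alt_aa = c("V", "V", "T"), allele_count = c(100L, 21L, 8L)
  )
  # oracle: brute-force aggregation of the raw rows
  expected_v <- sum(v$allele_count[v$alt_aa == "V"])
  sp <- build_spectra(v, numbering_map(-1))
  expect_equal(sp$position, c(308L, 308L))
  expect_equal(sp$allele_count[sp$alt_aa == "V"], expected_v)
  expect_equal(sp$allele_count[sp$alt_aa == "T"], 8L)

  empty <- build_spectra(v[0, ])
  expect_equal(nrow(empty), 0L)

  two <- build_spectra(
    tibble::tibble(ref_aa = c("M", "T"), position = c(309L, 310L),
                   alt_aa = "V", allele_count = c(121L, 5L)),
    numbering_map(-1)
  )
  expect_setequal(two$position, c(308L, 309L))
})

test_that("aggregation conserves allele totals and ignores row order", {
  withr::with_seed(7, {
    n <- 60
    pos <- sample(100:150, n, replace = TRUE)
    refs <- setNames(sample(amino_acid_properties()$aa, 51, replace = TRUE), 100:150)
    v <- tibble::tibble(
      ref_aa = unname(refs[as.character(pos)]),
      position = pos,
      alt_aa = purrr::map_chr(unname(refs[as.character(pos)]),
                              ~ sample(setdiff(amino_acid_properties()$aa, .x), 1)),
      allele_count = sample(1:50, n, replace = TRUE)
    )
  })
  sp <- build_spectra(v)
  expect_equal(sum(sp$allele_count), sum(v$allele_count))
  shuffled <- build_spectra(v[sample(nrow(v)), ])
  expect_equal(sp, shuffled)
})

test_that("conflicting reference amino acids at one mapped position are rejected", {
  v <- tibble::tibble(ref_aa = c("M", "T"), position = c(309L, 309L),
                      alt_aa = c("V", "A"), allele_count = 1L)
  expect_error(build_spectra(v), class = "ardscan_reference_mismatch")
})

test_that("variant types count distinct alternate amino acids, not alleles", {
  tc <- variant_type_count(m308_spectrum())
  expect_equal(tc$n_types, 4L)
  expect_equal(tc$total_alleles, 133L)
  expect_equal(variant_type_count(m308_spectrum()[1, ])$n_types, 1L)
  expect_equal(nrow(variant_type_count(m308_spectrum()[0, ])), 0L)
  # bound: at most 19 alternate amino acids
  all20 <- tibble::tibble(position = 1L, ref_aa = "A",
                          alt_aa = setdiff(amino_acid_properties()$aa, "A"),
                          allele_count = 1L)
  expect_equal(variant_type_count(all20)$n_types, 19L)
})

test_that("spectrum normalization maps the most common allele to exactly 1", {
  ns <- normalized_spectrum(m308_spectrum())
  expect_identical(ns$fraction[ns$alt_aa == "V"], 1.0)
  expect_equal(ns$fraction[ns$alt_aa == "T"], 8 / 121)
  expect_true(all(ns$fraction > 0 & ns$fraction <= 1))
  tie <- normalized_spectrum(tibble::tibble(position = 1L, ref_aa = "M",
                                            alt_aa = c("A", "C"),
                                            allele_count = c(5L, 5L)))
  expect_equal(tie$fraction, c(1, 1))
  expect_error(normalized_spectrum(m308_spectrum()[0, ]),
               class = "ardscan_empty_spectrum")
})

test_that("residue-class aggregation finds class positions and pools their spectra", {
  sp <- tibble::tibble(position = c(1L, 3L), ref_aa = "M",
                       alt_aa = c("V", "V"), allele_count = c(10L, 5L))
  out <- residue_class_spectrum(sp, "MAMA", start = 1L, residue_class = "M",
                                range = c(1, 4))
  expect_equal(out$positions, c(1L, 3L))
  expect_equal(out$spectrum$allele_count[out$spectrum$alt_aa == "V"], 15L)
  expect_identical(out$spectrum$fraction[[1]], 1.0)

  absent <- residue_class_spectrum(sp, "MAMA", 1L, "W", c(1, 4))
  expect_equal(absent$positions, integer(0))
  expect_equal(nrow(absent$spectrum), 0L)

  expect_error(residue_class_spectrum(sp, "MAMA", 1L, "M", c(1, 9)),
               class = "ardscan_out_of_range")
})

test_that("variant CSV reading skips bad rows, defaults counts, and aggregates", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "protein_consequence,allele_count",
    "p.Met309Val,100",
    "p.Met309Val,21",
    "p.Met309Thr,8",
    "p.Met309Ter,3",
    "p.Ala256Thr,",
    "garbage,1"
  ), csv)
  expect_warning(expect_warning(
    v <- read_variant_csv(csv, source_release = "synthetic test export"),
    "default to 1"), "skipped")
  expect_equal(nrow(v), 4L)
  expect_equal(v$allele_count[v$position == 256], 1L)
  skipped <- attr(v, "skipped")
  expect_equal(sum(unlist(skipped)), 2)
  sp <- build_spectra(v, numbering_map(-1))
  expect_equal(sp$allele_count[sp$position == 308 & sp$alt_aa == "V"], 121L)
})
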