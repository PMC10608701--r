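specA <- cbind(mz = c(85.03, 101.02), intensity = c(100, 50))
specB <- cbind(mz = c(85.03, 101.02), intensity = c(50, 100))

test_that("MS2 cosine has the expected fixed points and frozen values", {
  expect_equal(ms2_cosine(specA, specA), 1)
  # identical up to global scaling is still 1
  scaled <- specA; scaled[, 2] <- specA[, 2] * 7
  expect_equal(ms2_cosine(specA, scaled), 1)
  # no fragments within tolerance
  far <- cbind(mz = c(300.1, 401.2), intensity = c(10, 20))
  expect_equal(ms2_cosine(specA, far), 0)
  # swapped intensities: cos((10, sqrt(50)) , (sqrt(50), 10)) = 2*sqrt(2)/3
  expect_equal(ms2_cosine(specA, specB), 2 * sqrt(2) / 3, tolerance = 1e-9)
  expect_equal(ms2_cosine(specA, specB, scaling = "none"), 0.8,
               tolerance = 1e-9)
})

test_that("MS2 cosine is symmetric, bounded and rejects empty spectra", {
  set.seed(11)
  for (i in 1:20) {
    a <- cbind(mz = sort(runif(5, 50, 300)), intensity = runif(5, 1, 100))
    b <- cbind(mz = sort(runif(4, 50, 300)) + sample(c(0, 0.005), 4, TRUE),
               intensity = runif(4, 1, 100))
    s1 <- ms2_cosine(a, b); s2 <- ms2_cosine(b, a)
    expect_equal(s1, s2, tolerance = 1e-12)
    expect_gte(s1, 0); expect_lte(s1, 1)
  }
  expect_error(ms2_cosine(specA, specA[0, , drop = FALSE]), "non-empty")
  bad <- cbind(mz = 100, intensity = 0)
  expect_error(ms2_cosine(specA, bad), "> 0")
})

test_that("library matching assigns all four confidence tiers correctly", {
  lib <- fixture_library()
  glu_mass <- monoisotopic_mass("C5H9NO4")
  cand <- decompose(glu_mass, 5, 1)

  # RT within tolerance of the authenticated standard
  q <- quartet_row(glu_mass - isotope_deltas()$proton, rt = 7.3, c = 5, n = 1)
  hit <- match_library(q[1, ], cand, lib)
  expect_equal(hit$tier, "standard_confirmed")
  expect_equal(hit$name, "Glutamate")

  # RT far off, but MS2 matches the library spectrum
  q2 <- quartet_row(glu_mass - isotope_deltas()$proton, rt = 15, c = 5, n = 1)
  query_ms2 <- lib$ms2[[1]]
  hit2 <- match_library(q2[1, ], cand, lib, query_ms2 = query_ms2)
  expect_equal(hit2$tier, "ms2_matched")
  expect_gte(hit2$matches$score[1], 0.7)

  # mass match without RT or MS2 evidence
  glc_mass <- monoisotopic_mass("C6H12O6")
  q3 <- quartet_row(glc_mass - isotope_deltas()$proton, rt = 3, c = 6, n = 0)
  hit3 <- match_library(q3[1, ], decompose(glc_mass, 6, 0), lib)
  expect_equal(hit3$tier, "putative_formula")
  expect_equal(hit3$name, "Glucose")

  # nothing in the library at this mass: formula-only putative
  q4 <- quartet_row(299.9, rt = 3, c = 8, n = 2)
  M4 <- neutral_mass(299.9, "negative")
  hit4 <- match_library(q4[1, ], decompose(M4, 8, 2, tol_ppm = 30), lib)
  expect_true(hit4$tier %in% c("putative_formula", "unannotated"))

  # no formula candidates at all
  hit5 <- match_library(q4[1, ], decompose(M4, 8, 2, tol_ppm = 1e-6), lib)
  expect_equal(hit5$tier, "unannotated")
})

test_that("labeling-inferred atom counts veto library matches", {
  lib <- fixture_library()
  glc_mass <- monoisotopic_mass("C6H12O6")
  # right mass, wrong (c, n): glucose is C6N0 but the quartet says (5, 1)
  q <- quartet_row(glc_mass - isotope_deltas()$proton, rt = 3, c = 5, n = 1)
  hit <- match_library(q[1, ], NULL, lib)
  expect_false(isTRUE(hit$name == "Glucose"))
  expect_equal(nrow(hit$matches), 0)
})

test_that("adding evidence never lowers the annotation tier", {
  lib <- fixture_library()
  glu_mass <- monoisotopic_mass("C5H9NO4")
  cand <- decompose(glu_mass, 5, 1)
  rank_of <- function(tier) match(tier, rev(c("standard_confirmed",
                                              "ms2_matched",
                                              "putative_formula",
                                              "unannotated")))
  set.seed(13)
  for (i in 1:15) {
    rt <- runif(1, 1, 20)
    q <- quartet_row(glu_mass - isotope_deltas()$proton, rt = rt, c = 5, n = 1)
    base <- match_library(q[1, ], cand, lib)
    with_ms2 <- match_library(q[1, ], cand, lib, query_ms2 = lib$ms2[[1]])
    expect_gte(rank_of(with_ms2$tier), rank_of(base$tier))
    # an RT-matching library is strictly more evidence than an RT-free one
    lib_no_rt <- lib; lib_no_rt$rt <- NA_real_
    less <- match_library(q[1, ], cand, lib_no_rt, query_ms2 = lib$ms2[[1]])
    expect_gte(rank_of(with_ms2$tier), rank_of(less$tier))
  }
})

test_that("annotate_quartets produces one tiered row per quartet", {
  lib <- fixture_library()
  ch <- make_channel(glutamate_compound())
  cred <- credential(match_quartets(ch$U, ch$C13, ch$N15, ch$C13N15))
  ann <- annotate_quartets(cred, lib)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$tier, "standard_confirmed")
  expect_equal(ann$name, "Glutamate")
  expect_equal(ann$formula, "C5H9NO4")
  expect_identical(attr(ann, "source"), "ESI")
})
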