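test_that("expected mass shifts equal sums of isotopic mass differences", {
  expect_equal(expected_shift(0, 0), 0)
  # 5 * (13.0033548378 - 12)
  expect_equal(expected_shift(5, 0), 5.0167742, tolerance = 1e-7)
  # 5 * 1.0033548378 + (15.0001088982 - 14.0030740048)
  expect_equal(expected_shift(5, 1), 6.0138091, tolerance = 1e-7)
  expect_error(expected_shift(-1, 0), "non-negative")
})

test_that("neutral mass conversion handles both polarities with the electron term", {
  glu <- 147.05315777
  expect_equal(neutral_mass(glu - 1.00727646677, "negative"), glu,
               tolerance = 1e-9)
  urea <- 60.03236276
  expect_equal(neutral_mass(urea + 1.00727646677, "positive"), urea,
               tolerance = 1e-8)
  # [M-H]- and [M+H]+ of the same compound agree on the neutral mass
  M <- 180.06339
  expect_equal(neutral_mass(M - 1.00727646677, "negative"),
               neutral_mass(M + 1.00727646677, "positive"), tolerance = 1e-9)
})

test_that("a noiseless planted quartet is matched with exact atom counts", {
  ch <- make_channel(glutamate_compound())
  qt <- match_quartets(ch$U, ch$C13, ch$N15, ch$C13N15)
  expect_equal(nrow(qt), 1)
  expect_equal(qt$c, 5)
  expect_equal(qt$n, 1)
  expect_equal(qt$support, "full")
  expect_equal(qt$ppm_residual, 0, tolerance = 1e-9)
  expect_false(qt$ambiguous)
  expect_equal(nrow(credential(qt)), 1)
})

test_that("empty labeled sets yield no quartets", {
  ch <- make_channel(glutamate_compound())
  empty <- peak_set(numeric(0), numeric(0), numeric(0),
                    condition = "C13", polarity = "negative", source = "ESI")
  qt <- match_quartets(ch$U, empty, empty, empty)
  expect_equal(nrow(qt), 0)
})

test_that("mixed polarity or source inputs are rejected", {
  ch <- make_channel(glutamate_compound())
  pos <- peak_set(100, 1, 1e5, condition = "C13", polarity = "positive",
                  source = "ESI")
  expect_error(match_quartets(ch$U, pos, ch$N15, ch$C13N15), "polarity")
  apci <- peak_set(100, 1, 1e5, condition = "C13", polarity = "negative",
                   source = "APCI")
  expect_error(match_quartets(ch$U, apci, ch$N15, ch$C13N15), "source")
})

test_that("missing dual partner demotes support to triad and blocks credentialing", {
  comp <- glutamate_compound()
  comp$dropdual <- TRUE
  ch <- make_channel(comp)
  qt <- match_quartets(ch$U, ch$C13, ch$N15, ch$C13N15)
  expect_equal(qt$support, "triad")
  expect_equal(qt$c, 5)
  expect_equal(qt$n, 1)
  expect_equal(nrow(credential(qt)), 0)
})

test_that("co-elution and intensity-ratio gates are enforced", {
  comp <- glutamate_compound()
  ch <- make_channel(comp)
  # move the 13C partner out of the co-elution window
  far <- as.data.frame(ch$C13); far$rt <- far$rt + 1
  c13_far <- peak_set(far$mz, far$rt, far$intensity, condition = "C13",
                      polarity = "negative", source = "ESI")
  qt <- match_quartets(ch$U, c13_far, ch$N15, ch$C13N15,
                       match_config(rt_tol = 0.5))
  expect_false(any(qt$support == "full"))
  # partner intensity outside the allowed labeled/unlabeled ratio
  dim13 <- as.data.frame(ch$C13); dim13$intensity <- dim13$intensity / 100
  c13_dim <- peak_set(dim13$mz, dim13$rt, dim13$intensity, condition = "C13",
                      polarity = "negative", source = "ESI")
  qt2 <- match_quartets(ch$U, c13_dim, ch$N15, ch$C13N15)
  expect_false(any(qt2$support == "full"))
})

test_that("conflicting claims resolve greedily by unlabeled intensity", {
  # two unlabeled peaks close enough to claim the same 13C partner; the
  # more intense one wins and the other is demoted
  d <- isotope_deltas()
  base <- 150.0
  u <- peak_set(c(base, base + 1e-4), c(5, 5), c(2e6, 1e6))
  c13 <- peak_set(base + 3 * d$d13C, 5, 2e6, condition = "C13")
  n15 <- peak_set(c(base + d$d15N, base + 1e-4 + d$d15N), c(5, 5), c(2e6, 1e6),
                  condition = "N15")
  dual <- peak_set(base + 3 * d$d13C + d$d15N, 5, 2e6, condition = "C13N15")
  qt <- match_quartets(u, c13, n15, dual)
  expect_equal(nrow(qt), 2)
  winner <- qt[which.max(qt$intensity), ]
  loser <- qt[which.min(qt$intensity), ]
  expect_equal(winner$support, "full")
  expect_equal(winner$c, 3)
  expect_false(loser$support == "full")
  cred <- credential(qt)
  expect_equal(nrow(cred), 1)
  expect_equal(cred$intensity, 2e6)
})

test_that("matching equals the brute-force oracle on random small instances", {
  for (seed in 1:40) {
    inst <- random_instance(seed)
    got <- match_quartets(inst$U, inst$C13, inst$N15, inst$C13N15)
    want <- oracle_match_quartets(inst$U, inst$C13, inst$N15, inst$C13N15,
                                  match_config())
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    for (col in c("u_mz", "c", "n", "support", "ppm_residual", "mz_13c",
                  "mz_15n", "mz_dual", "ambiguous"))
      expect_equal(got[[col]], want[[col]], tolerance = 1e-9,
                   info = paste("seed", seed, "col", col))
  }
})

test_that("credentialed partner m/z values satisfy the ppm tolerance", {
  cfg <- match_config()
  d <- isotope_deltas()
  for (seed in 41:55) {
    inst <- random_instance(seed)
    cred <- credential(match_quartets(inst$U, inst$C13, inst$N15, inst$C13N15,
                                      cfg))
    if (!nrow(cred)) next
    for (i in seq_len(nrow(cred))) {
      pred <- cred$u_mz[i] + c(cred$c[i] * d$d13C, cred$n[i] * d$d15N,
                               cred$c[i] * d$d13C + cred$n[i] * d$d15N)
      obs <- c(cred$mz_13c[i], cred$mz_15n[i], cred$mz_dual[i])
      expect_true(all(abs(obs - pred) / pred * 1e6 <= cfg$mz_tol_ppm + 1e-9))
    }
  }
})

test_that("shrinking tolerances never enlarges the credentialed set", {
  for (seed in 56:70) {
    inst <- random_instance(seed)
    wide <- credential(match_quartets(inst$U, inst$C13, inst$N15, inst$C13N15,
                                      match_config(mz_tol_ppm = 8, rt_tol = 0.6)))
    narrow <- credential(match_quartets(inst$U, inst$C13, inst$N15,
                                        inst$C13N15,
                                        match_config(mz_tol_ppm = 3, rt_tol = 0.2)))
    expect_lte(nrow(narrow), nrow(wide))
  }
})

test_that("matching output is deterministic for identical inputs", {
  inst <- random_instance(99)
  a <- match_quartets(inst$U, inst$C13, inst$N15, inst$C13N15)
  b <- match_quartets(inst$U, inst$C13, inst$N15, inst$C13N15)
  expect_identical(a, b)
})
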