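write_csv_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("peak tables read sorted by m/z with validated rows", {
  f <- write_csv_fixture(c("mz,rt,intensity,snr",
                           "146.0459,7.2,1e6,20",
                           "147.0532,7.2,2e5,15",
                           "90.0550,3.1,5e5,8"))
  ps <- read_peak_table(f, "U", "negative", "ESI")
  expect_s3_class(ps, "peak_set")
  expect_equal(nrow(ps), 3)
  expect_equal(ps$mz, sort(c(146.0459, 147.0532, 90.0550)))
  expect_identical(attr(ps, "condition"), "U")
})

test_that("empty and malformed peak tables are reported, not dropped", {
  f <- write_csv_fixture("mz,rt,intensity,snr")
  expect_warning(ps <- read_peak_table(f), "empty")
  expect_equal(nrow(ps), 0)

  f2 <- write_csv_fixture(c("mz,rt,intensity", "100.1,1.0,5e5",
                            "NA,2.0,1e5", "102.2,3.0,2e5"))
  expect_error(read_peak_table(f2), "row\\(s\\): 2")

  f3 <- write_csv_fixture(c("mz,rt", "100.1,1.0"))
  expect_error(read_peak_table(f3), "intensity")

  expect_error(read_peak_table("no/such/file.csv"), "not found")
})

test_that("snr column is optional and defaults to +Inf", {
  f <- write_csv_fixture(c("mz,rt,intensity", "100.1,1.0,5e5"))
  ps <- read_peak_table(f)
  expect_equal(ps$snr, Inf)
  expect_equal(nrow(filter_peaks(ps, min_snr = 5)), 1)
})

test_that("peak tables round-trip through disk at printed precision", {
  ps <- peak_set(mz = c(146.045875, 90.054984), rt = c(7.234, 3.101),
                 intensity = c(123456.7, 98765.4), snr = c(21.5, 8.25))
  f <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(ps, f)
  back <- read_peak_table(f)
  expect_equal(back$mz, ps$mz)
  expect_equal(back$rt, ps$rt)
  expect_equal(back$intensity, ps$intensity)
  expect_equal(back$snr, ps$snr)
})

test_that("S/N filter is strict and the scan range is enforced", {
  ps <- peak_set(mz = c(65.0, 100.0, 200.0, 300.0), rt = rep(1, 4),
                 intensity = rep(1e5, 4), snr = c(10, 3, 5, 7))
  out <- filter_peaks(ps, min_snr = 5, mz_range = c(70, 1000))
  # snr == 5 fails the strict inequality; mz 65 is outside the scan range
  expect_equal(out$mz, 300.0)
  expect_equal(nrow(filter_peaks(ps, min_snr = 0)), 3)  # only range applies
  expect_error(filter_peaks(ps, mz_range = c(1000, 70)), "increasing")
  expect_error(filter_peaks(ps, min_snr = -1))
})

test_that("peak filtering is idempotent and a subset of its input", {
  set.seed(5)
  ps <- peak_set(mz = runif(50, 60, 1100), rt = runif(50, 0, 20),
                 intensity = rlnorm(50, 12, 1), snr = rexp(50, 1 / 8))
  once <- filter_peaks(ps)
  twice <- filter_peaks(once)
  expect_identical(as.data.frame(once), as.data.frame(twice))
  expect_true(all(once$mz %in% ps$mz))
  expect_true(all(once$snr > 5 & once$mz >= 70 & once$mz <= 1000))
})

test_that("reference libraries parse formulas and recompute masses", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tformula\trt",
               "Glutamate\tC5H9NO4\t7.2",
               "Urea\tCH4N2O\tNA"), f)
  lib <- read_library(f)
  expect_equal(lib$neutral_mass[lib$name == "Glutamate"], 147.05316,
               tolerance = 1e-7)
  expect_equal(lib$counts[[which(lib$name == "Urea")]],
               c(C = 1L, H = 4L, N = 2L, O = 1L, P = 0L, S = 0L))
  expect_true(is.na(lib$rt[2]))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tformula", "Bad\tC5H9NOX4"), f2)
  expect_error(read_library(f2), "X")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tformula\tneutral_mass", "Glutamate\tC5H9NO4\t147.06"), f3)
  expect_warning(read_library(f3), "disagrees")
})

test_that("library masses agree with the generator for sampled formulas", {
  lib <- sample_library(100, seed = 23)
  recomputed <- vapply(lib$counts, monoisotopic_mass, numeric(1))
  expect_equal(recomputed, lib$neutral_mass, tolerance = 1e-6)
})

test_that("MSP spectra round-trip and attach to library entries by name", {
  lib <- fixture_library()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  msp <- withr::local_tempfile(fileext = ".msp")
  write_library(lib, tsv, msp)
  back <- read_library(tsv, msp)
  expect_equal(back$name, lib$name)
  expect_equal(back$ms2[[1]][, "mz"], lib$ms2[[1]][, "mz"], tolerance = 1e-5)
  expect_null(back$ms2[[3]])
  sp <- read_msp(msp)
  expect_named(sp, c("Glutamate", "Urea"))
  expect_equal(nrow(sp$Urea), 2)
})
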