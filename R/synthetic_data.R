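#' Simulation configuration
#'
#' Conditions of the synthetic four-condition labeling study. Defaults
#' emulate a fully labeled reference culture measured on a high-resolution
#' instrument: ~2 ppm mass noise, 0.05 min RT jitter, 10% chance that any
#' given labeled partner is missing, and one unlabeled-only background
#' (decoy) peak per compound — the media-contaminant artifact class that
#' credentialing is designed to remove.
#'
#' @param n_compounds Number of library compounds to simulate. Default 1000.
#' @param ppm_noise_sd SD of multiplicative m/z noise, in ppm. Default 2.
#' @param rt_jitter_sd SD of per-peak RT jitter, in minutes. Default 0.05.
#' @param dropout Probability that each labeled partner peak (13C, 15N,
#'   dual) is missing, independently. The unlabeled anchor is always
#'   planted. Default 0.1.
#' @param decoy_density Unlabeled-only background peaks per compound per
#'   channel. Default 1.
#' @param esi_only,apci_only Fractions of compounds detectable only by ESI
#'   / only by APCI (the remainder are seen by both sources). Defaults 0.4
#'   and 0.25, mirroring the complementary-coverage design of a
#'   two-ion-source acquisition.
#' @param prob_negative Probability a compound ionizes in negative mode
#'   (otherwise positive). Default 0.6 — HILIC at basic pH favors
#'   deprotonation.
#' @param seed Integer seed fixing all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_compounds = 1000L, ppm_noise_sd = 2,
                       rt_jitter_sd = 0.05, dropout = 0.1,
                       decoy_density = 1, esi_only = 0.4, apci_only = 0.25,
                       prob_negative = 0.6, seed = 1L) {
  stopifnot(n_compounds >= 1, ppm_noise_sd >= 0, rt_jitter_sd >= 0,
            dropout >= 0, dropout <= 1, decoy_density >= 0,
            esi_only >= 0, apci_only >= 0, esi_only + apci_only <= 1,
            prob_negative >= 0, prob_negative <= 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 ppm_noise_sd = ppm_noise_sd, rt_jitter_sd = rt_jitter_sd,
                 dropout = dropout, decoy_density = decoy_density,
                 esi_only = esi_only, apci_only = apci_only,
                 prob_negative = prob_negative, seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a synthetic reference library
#'
#' Draws chemically plausible CHNOPS formulas: integer RDBE is chosen first
#' and the hydrogen count solved from it, so every sampled formula passes
#' the even-electron RDBE filter by construction; masses fall in 75-990 Da
#' (keeping both ion forms inside a 70-1000 scan range), H/C in [0.2, 3.1],
#' RDBE in [0, 25]. Each entry gets a random RT in [1, 20] min and a
#' synthetic MS2 spectrum.
#'
#' @param n Number of entries (>= 1).
#' @param seed Integer seed.
#' @return A `ref_library` (see [read_library()]).
#' @export
sample_library <- function(n, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  entries <- vector("list", n)
  i <- 0L
  while (i < n) {
    C <- sample(2:35, 1)
    N <- stats::rbinom(1, 6, 0.25)
    O <- stats::rbinom(1, 12, 0.35)
    P <- stats::rbinom(1, 3, 0.08)
    S <- stats::rbinom(1, 3, 0.06)
    hmax <- floor(min(3.1 * C, 2 * (C + 1) + N + P))
    hmin <- ceiling(0.2 * C)
    # integer RDBE first, H solved from it: guarantees even-electron counts
    rd_hi <- min(25, floor(C + 1 + (N + P) / 2 - hmin / 2))
    if (rd_hi < 0) next
    rd_lo <- max(0, ceiling(C + 1 + (N + P) / 2 - hmax / 2))
    if (rd_lo > rd_hi) next
    rd <- sample(rd_lo:rd_hi, 1)
    H <- as.integer(2 * (C + 1) + N + P - 2 * rd)
    if (H < hmin || H > hmax || H > 80) next
    counts <- c(C = C, H = H, N = N, O = O, P = P, S = S)
    mass <- monoisotopic_mass(counts)
    if (mass < 75 || mass > 990) next
    i <- i + 1L
    nfrag <- sample(3:8, 1)
    frag_mz <- sort(stats::runif(nfrag, 50, max(51, mass - 1)))
    frag_in <- stats::runif(nfrag, 5, 100)
    frag_in <- frag_in / max(frag_in) * 100
    ms2 <- cbind(mz = frag_mz, intensity = frag_in)
    entries[[i]] <- list(name = sprintf("SYN-%04d", i),
                         counts = counts, mass = mass,
                         rt = stats::runif(1, 1, 20), ms2 = ms2)
  }
  lib <- data.frame(
    name = vapply(entries, `[[`, character(1), "name"),
    formula = vapply(entries, function(e) formula_string(e$counts), character(1)),
    neutral_mass = vapply(entries, `[[`, numeric(1), "mass"),
    rt = vapply(entries, `[[`, numeric(1), "rt"),
    stringsAsFactors = FALSE)
  lib$counts <- lapply(entries, `[[`, "counts")
  lib$ms2 <- lapply(entries, `[[`, "ms2")
  structure(lib, class = c("ref_library", "data.frame"))
}

#' Simulate four-condition labeled peak sets with ground truth
#'
#' For every library compound and every ion-source/polarity channel in
#' which it is detectable, plants the unlabeled ion plus its 13C, 15N and
#' dual-labeled partners at the exact labeling mass shifts, then applies
#' multiplicative ppm noise, RT jitter, per-partner dropout, log-normal
#' intensities and unlabeled-only decoy peaks. Full isotopic enrichment is
#' assumed (no partial isotopologue envelopes), matching a culture labeled
#' for many generations.
#'
#' @param library A `ref_library`, e.g. from [sample_library()]. Only the
#'   first `cfg$n_compounds` entries are used.
#' @param cfg A [sim_config()].
#' @param deltas Isotope constants, see [isotope_deltas()].
#' @return A `sim_result` list: `channels` — named list (e.g. `"ESI-"`)
#'   each holding the four [peak_set()]s `U`, `C13`, `N15`, `C13N15`;
#'   `truth` — per-compound data frame (name, formula, c, n, rt, mass,
#'   polarity, sources); `planted` — one row per planted peak (name,
#'   channel, condition, mz, rt, intensity, is_decoy); `cfg`.
#' @export
simulate_quartets <- function(library, cfg = sim_config(),
                              deltas = isotope_deltas()) {
  if (!nrow(library)) stop("library is empty", call. = FALSE)
  set.seed(cfg$seed)
  lib <- library[seq_len(min(cfg$n_compounds, nrow(library))), , drop = FALSE]
  nc <- nrow(lib)

  u <- stats::runif(nc)
  sources <- ifelse(u < cfg$esi_only, "ESI",
                    ifelse(u < cfg$esi_only + cfg$apci_only, "APCI", "both"))
  polarity <- ifelse(stats::runif(nc) < cfg$prob_negative, "negative", "positive")
  cvec <- vapply(lib$counts, function(x) x[["C"]], numeric(1))
  nvec <- vapply(lib$counts, function(x) x[["N"]], numeric(1))

  truth <- data.frame(name = lib$name, formula = lib$formula,
                      c = as.integer(cvec), n = as.integer(nvec),
                      rt = lib$rt, neutral_mass = lib$neutral_mass,
                      polarity = polarity, sources = sources,
                      stringsAsFactors = FALSE)

  planted <- list()
  plant <- function(name, channel, condition, mz_true, rt_true, inten, decoy = FALSE) {
    mz <- mz_true * (1 + stats::rnorm(1, 0, cfg$ppm_noise_sd) * 1e-6)
    rt <- rt_true + stats::rnorm(1, 0, cfg$rt_jitter_sd)
    planted[[length(planted) + 1L]] <<-
      data.frame(name = name, channel = channel, condition = condition,
                 mz = mz, rt = rt, intensity = inten, is_decoy = decoy,
                 stringsAsFactors = FALSE)
  }

  for (i in seq_len(nc)) {
    srcs <- if (sources[i] == "both") c("ESI", "APCI") else sources[i]
    M <- lib$neutral_mass[i]
    umz <- if (polarity[i] == "negative") M - deltas$proton else M + deltas$proton
    shifts <- c(U = 0,
                C13 = cvec[i] * deltas$d13C,
                N15 = nvec[i] * deltas$d15N,
                C13N15 = cvec[i] * deltas$d13C + nvec[i] * deltas$d15N)
    for (src in srcs) {
      ch <- .channel(src, polarity[i])
      base <- stats::rlnorm(1, log(1e6), 1)
      for (cond in CONDITIONS) {
        if (cond != "U" && stats::runif(1) < cfg$dropout) next
        inten <- base * stats::rlnorm(1, 0, 0.3)
        plant(lib$name[i], ch, cond, umz + shifts[[cond]], lib$rt[i], inten)
      }
    }
  }

  # unlabeled-only decoys: background/media peaks with no labeled partners
  for (ch in unique(vapply(planted, `[[`, character(1), "channel"))) {
    nch <- sum(vapply(planted, function(p)
      p$channel == ch & p$condition == "U" & !p$is_decoy, logical(1)))
    ndec <- round(cfg$decoy_density * nch)
    if (ndec < 1) next
    for (k in seq_len(ndec))
      plant(sprintf("DECOY-%s-%04d", ch, k), ch, "U",
            stats::runif(1, 72, 998), stats::runif(1, 1, 20),
            stats::rlnorm(1, log(1e6), 1), decoy = TRUE)
  }

  planted <- do.call(rbind, planted)
  rownames(planted) <- NULL

  channels <- list()
  for (ch in sort(unique(planted$channel))) {
    src <- sub("[+-]$", "", ch)
    pol <- if (endsWith(ch, "+")) "positive" else "negative"
    channels[[ch]] <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cond) {
      sub <- planted[planted$channel == ch & planted$condition == cond, ,
                     drop = FALSE]
      peak_set(sub$mz, sub$rt, sub$intensity, Inf, cond, pol, src)
    })
  }

  structure(list(channels = channels, truth = truth, planted = planted,
                 cfg = cfg), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d compounds, %d channels (%s), %d planted peaks (%d decoys)\n",
              nrow(x$truth), length(x$channels),
              paste(names(x$channels), collapse = ", "),
              nrow(x$planted), sum(x$planted$is_decoy)))
  invisible(x)
}

#' Score quartet matching against simulation ground truth
#'
#' Links each matched quartet back to the planted peak it anchors on (exact
#' unlabeled m/z identity) and scores, per channel: how many planted
#' compounds were recovered with the correct `(c, n)` at any support level,
#' how many were credentialed (full support, unambiguous), and how many
#' decoys were (a) matched at all and (b) credentialed.
#'
#' @param sim A `sim_result` from [simulate_quartets()].
#' @param quartet_tables Named list of `quartet_tbl`s keyed by channel
#'   (from [match_quartets()] run on `sim$channels`).
#' @return A `recovery_summary` list: `per_channel` data frame and overall
#'   `recovery` (correct-(c,n) fraction of planted compounds),
#'   `credential_rate`, `decoys_credentialed`.
#' @export
evaluate_recovery <- function(sim, quartet_tables) {
  per <- lapply(names(quartet_tables), function(ch) {
    qt <- quartet_tables[[ch]]
    pu <- sim$planted[sim$planted$channel == ch &
                      sim$planted$condition == "U", , drop = FALSE]
    real <- pu[!pu$is_decoy, , drop = FALSE]
    idx <- match(round(real$mz, 9), round(qt$u_mz, 9))
    tc <- sim$truth$c[match(real$name, sim$truth$name)]
    tn <- sim$truth$n[match(real$name, sim$truth$name)]
    hit <- !is.na(idx)
    correct <- hit & qt$c[idx] == tc & qt$n[idx] == tn & !qt$ambiguous[idx]
    cred <- credential(qt)
    cidx <- match(round(real$mz, 9), round(cred$u_mz, 9))
    dec <- pu[pu$is_decoy, , drop = FALSE]
    data.frame(channel = ch, planted = nrow(real),
               matched = sum(hit), correct_cn = sum(correct, na.rm = TRUE),
               credentialed = sum(!is.na(cidx)),
               decoys = nrow(dec),
               decoys_matched = sum(round(dec$mz, 9) %in% round(qt$u_mz, 9)),
               decoys_credentialed = sum(round(dec$mz, 9) %in% round(cred$u_mz, 9)),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(per_channel = per,
                 recovery = sum(per$correct_cn) / sum(per$planted),
                 credential_rate = sum(per$credentialed) / sum(per$planted),
                 decoys_credentialed = sum(per$decoys_credentialed)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("<recovery_summary> correct-(c,n) recovery %.1f%%, credentialed %.1f%%, decoys credentialed %d\n",
              100 * x$recovery, 100 * x$credential_rate,
              x$decoys_credentialed))
  print(x$per_channel)
  invisible(x)
}

#' Write a simulation to disk as plain-text pipeline inputs
#'
#' Produces the on-disk layout consumed by [run_pipeline()]: one peak-table
#' CSV per channel and condition (`peaks_<SRC>_<neg|pos>_<COND>.csv`), the
#' reference library TSV + MSP, and the ground truth TSV.
#'
#' @param sim A `sim_result`.
#' @param library The `ref_library` the simulation was built from.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(sim$channels)) {
    src <- sub("[+-]$", "", ch)
    pol <- if (endsWith(ch, "+")) "pos" else "neg"
    for (cond in CONDITIONS)
      write_peak_table(sim$channels[[ch]][[cond]],
                       file.path(dir, sprintf("peaks_%s_%s_%s.csv", src, pol, cond)))
  }
  write_library(library, file.path(dir, "library.tsv"),
                file.path(dir, "library.msp"))
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
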