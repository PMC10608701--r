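# Fixture builders shared across test files.

DELTA <- isotope_deltas()

# Plant one or more exact quartets (no noise) plus optional extra unlabeled
# peaks, returning the four condition peak sets for one channel.
make_channel <- function(compounds, extra_u = NULL, polarity = "negative",
                         source = "ESI") {
  sgn <- if (polarity == "negative") -1 else 1
  mk <- function(rows, cond) {
    if (!nrow(rows)) return(peak_set(numeric(0), numeric(0), numeric(0),
                                     condition = cond, polarity = polarity,
                                     source = source))
    peak_set(rows$mz, rows$rt, rows$intensity, condition = cond,
             polarity = polarity, source = source)
  }
  u <- c13 <- n15 <- dd <- data.frame(mz = numeric(0), rt = numeric(0),
                                      intensity = numeric(0))
  for (i in seq_len(nrow(compounds))) {
    cp <- compounds[i, ]
    umz <- cp$mass + sgn * DELTA$proton
    inten <- if ("intensity" %in% names(cp)) cp$intensity else 1e6
    u <- rbind(u, data.frame(mz = umz, rt = cp$rt, intensity = inten))
    if (!isTRUE(cp$drop13))
      c13 <- rbind(c13, data.frame(mz = umz + cp$c * DELTA$d13C, rt = cp$rt,
                                   intensity = inten))
    if (!isTRUE(cp$drop15))
      n15 <- rbind(n15, data.frame(mz = umz + cp$n * DELTA$d15N, rt = cp$rt,
                                   intensity = inten))
    if (!isTRUE(cp$dropdual))
      dd <- rbind(dd, data.frame(mz = umz + cp$c * DELTA$d13C + cp$n * DELTA$d15N,
                                 rt = cp$rt, intensity = inten))
  }
  if (!is.null(extra_u)) u <- rbind(u, extra_u)
  list(U = mk(u, "U"), C13 = mk(c13, "C13"), N15 = mk(n15, "N15"),
       C13N15 = mk(dd, "C13N15"))
}

glutamate_compound <- function(rt = 7.2, intensity = 1e6)
  data.frame(mass = monoisotopic_mass("C5H9NO4"), rt = rt,
             intensity = intensity, c = 5, n = 1)

# Random small matching instance (<= 20 peaks per condition) with a mix of
# planted partial quartets, noise and clutter peaks.
random_instance <- function(seed) {
  set.seed(seed)
  ncomp <- sample(1:5, 1)
  comp <- data.frame(mass = runif(ncomp, 80, 400),
                     rt = runif(ncomp, 1, 19),
                     intensity = rlnorm(ncomp, log(1e6), 0.7),
                     c = sample(0:6, ncomp, replace = TRUE),
                     n = sample(0:3, ncomp, replace = TRUE))
  ch <- make_channel(comp)
  jitter_set <- function(ps, drop_p) {
    df <- as.data.frame(ps)
    keep <- runif(nrow(df)) > drop_p
    df <- df[keep, , drop = FALSE]
    if (nrow(df)) {
      df$mz <- df$mz * (1 + rnorm(nrow(df), 0, 2e-6))
      df$rt <- df$rt + rnorm(nrow(df), 0, 0.03)
    }
    nclutter <- sample(0:4, 1)
    if (nclutter)
      df <- rbind(df, data.frame(mz = runif(nclutter, 75, 450),
                                 rt = runif(nclutter, 1, 19),
                                 intensity = rlnorm(nclutter, log(1e6), 0.7),
                                 snr = Inf))
    peak_set(df$mz, df$rt, df$intensity,
             condition = attr(ps, "condition"), polarity = attr(ps, "polarity"),
             source = attr(ps, "source"))
  }
  list(U = jitter_set(ch$U, 0), C13 = jitter_set(ch$C13, 0.2),
       N15 = jitter_set(ch$N15, 0.2), C13N15 = jitter_set(ch$C13N15, 0.2))
}

# Small library fixture: glutamate (with RT + MS2), urea (MS2 only),
# glucose (neither), alanine (RT only).
fixture_library <- function() {
  mk_counts <- list(Glutamate = parse_formula("C5H9NO4"),
                    Urea = parse_formula("CH4N2O"),
                    Glucose = parse_formula("C6H12O6"),
                    Alanine = parse_formula("C3H7NO2"))
  lib <- data.frame(
    name = names(mk_counts),
    formula = vapply(mk_counts, formula_string, character(1)),
    neutral_mass = vapply(mk_counts, monoisotopic_mass, numeric(1)),
    rt = c(7.2, NA, NA, 9.5),
    stringsAsFactors = FALSE)
  lib$counts <- unname(mk_counts)
  lib$ms2 <- list(
    cbind(mz = c(84.0444, 102.0549, 128.0353), intensity = c(100, 40, 25)),
    cbind(mz = c(44.0495, 61.0396), intensity = c(100, 60)),
    NULL, NULL)
  structure(lib, class = c("ref_library", "data.frame"))
}

quartet_row <- function(u_mz, rt, c, n, support = "full", intensity = 1e6) {
  structure(data.frame(u_mz = u_mz, rt = rt, intensity = intensity,
                       c = c, n = n, support = support, ppm_residual = 0,
                       mz_13c = NA_real_, mz_15n = NA_real_, mz_dual = NA_real_,
                       ambiguous = FALSE, stringsAsFactors = FALSE),
            polarity = "negative", source = "ESI",
            class = c("quartet_tbl", "data.frame"))
}

# Minimal annotation_tbl for merge tests.
ann_tbl <- function(names, formulas, masses, rts, tiers, intensities = 1e6,
                    source = "ESI", polarity = "negative") {
  n <- length(names)
  structure(data.frame(u_mz = masses - DELTA$proton, rt = rts,
                       c = 1L, n = 0L, neutral_mass = masses,
                       formula = formulas, name = names, tier = tiers,
                       score = NA_real_, n_candidates = 1L,
                       intensity = rep_len(intensities, n),
                       stringsAsFactors = FALSE),
            polarity = polarity, source = source,
            class = c("annotation_tbl", "data.frame"))
}
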