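TIERS <- c("standard_confirmed", "ms2_matched", "putative_formula", "unannotated")

.tier_rank <- function(tier) match(tier, rev(TIERS))  # higher = better

#' Cosine similarity between two MS2 spectra
#'
#' Fragments are paired one-to-one within `frag_tol_mz`, closest m/z pairs
#' first, then the cosine is computed over the paired (and unpaired)
#' intensities. Intensities are square-root scaled by default, the usual
#' compromise that stops base peaks from dominating the score.
#'
#' @param spec_a,spec_b Two-column matrices (`mz`, `intensity`) with
#'   positive intensities; at least one fragment each.
#' @param frag_tol_mz Fragment m/z pairing tolerance (Th). Default 0.01.
#' @param scaling `"sqrt"` (default) or `"none"`.
#' @return Similarity in `[0, 1]`; symmetric in its arguments; 1 iff the
#'   spectra are identical up to global intensity scaling within tolerance.
#' @export
ms2_cosine <- function(spec_a, spec_b, frag_tol_mz = 0.01,
                       scaling = c("sqrt", "none")) {
  scaling <- match.arg(scaling)
  for (sp in list(spec_a, spec_b)) {
    if (is.null(sp) || !is.matrix(sp) || nrow(sp) == 0)
      stop("spectra must be non-empty two-column matrices", call. = FALSE)
    if (any(sp[, 2] <= 0)) stop("fragment intensities must be > 0", call. = FALSE)
  }
  f <- if (scaling == "sqrt") sqrt else identity
  ia <- f(spec_a[, 2]); ib <- f(spec_b[, 2])
  # greedy 1-to-1 pairing, closest m/z difference first
  d <- abs(outer(spec_a[, 1], spec_b[, 1], "-"))
  pairs <- which(d <= frag_tol_mz, arr.ind = TRUE)
  num <- 0
  if (nrow(pairs)) {
    pairs <- pairs[order(d[pairs]), , drop = FALSE]
    useda <- logical(nrow(spec_a)); usedb <- logical(nrow(spec_b))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (useda[i] || usedb[j]) next
      useda[i] <- usedb[j] <- TRUE
      num <- num + ia[i] * ib[j]
    }
  }
  num / (sqrt(sum(ia^2)) * sqrt(sum(ib^2)))
}

#' Annotation configuration
#'
#' @param mass_tol_ppm Library exact-mass tolerance (ppm). Default 5.
#' @param rt_tol RT tolerance for standard confirmation (min); default 0.5,
#'   the same chromatographic window as co-elution (one LC method, one RT
#'   scale).
#' @param ms2_threshold Minimum cosine for an MS2 match. Default 0.7.
#' @param frag_tol_mz Fragment pairing tolerance (Th). Default 0.01.
#' @return An `annotation_config` list.
#' @export
annotation_config <- function(mass_tol_ppm = 5, rt_tol = 0.5,
                              ms2_threshold = 0.7, frag_tol_mz = 0.01) {
  structure(list(mass_tol_ppm = mass_tol_ppm, rt_tol = rt_tol,
                 ms2_threshold = ms2_threshold, frag_tol_mz = frag_tol_mz),
            class = "annotation_config")
}

#' Match one credentialed quartet against a reference library
#'
#' Library entries are eligible only if their formula's C and N counts equal
#' the quartet's labeling-inferred `(c, n)` and their neutral mass is within
#' `mass_tol_ppm` — the labeling constraint is never overridden by library
#' evidence. Eligible entries are tiered: RT within `rt_tol` of a library RT
#' gives `standard_confirmed`; an MS2 cosine at or above `ms2_threshold`
#' gives `ms2_matched`; mass + formula agreement alone gives
#' `putative_formula`. With no library hit but at least one formula
#' candidate the quartet is `putative_formula` (formula only); with no
#' candidates it is `unannotated`.
#'
#' @param quartet One-row slice of a `quartet_tbl` (list or data frame row
#'   with `u_mz`, `rt`, `c`, `n`).
#' @param candidates [decompose()] output for the quartet's neutral mass.
#' @param library A `ref_library`.
#' @param cfg An [annotation_config()].
#' @param polarity Quartet polarity (for the neutral-mass conversion).
#' @param query_ms2 Optional observed MS2 spectrum for the quartet.
#' @return A list: `tier`, `matches` (data frame name/tier/score), `name`,
#'   `best_formula`.
#' @export
match_library <- function(quartet, candidates, library,
                          cfg = annotation_config(), polarity = "negative",
                          query_ms2 = NULL) {
  M <- neutral_mass(quartet$u_mz, polarity)
  cn <- vapply(library$counts, function(x) x[["C"]], numeric(1))
  nn <- vapply(library$counts, function(x) x[["N"]], numeric(1))
  ppm <- abs(library$neutral_mass - M) / M * 1e6
  elig <- which(cn == quartet$c & nn == quartet$n & ppm <= cfg$mass_tol_ppm)

  matches <- data.frame(name = character(0), tier = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  for (j in elig) {
    tier <- "putative_formula"; score <- NA_real_
    if (!is.null(query_ms2) && !is.null(library$ms2[[j]])) {
      cs <- ms2_cosine(query_ms2, library$ms2[[j]], cfg$frag_tol_mz)
      if (cs >= cfg$ms2_threshold) { tier <- "ms2_matched"; score <- cs }
    }
    if (!is.na(library$rt[j]) && abs(library$rt[j] - quartet$rt) <= cfg$rt_tol)
      tier <- "standard_confirmed"
    matches <- rbind(matches, data.frame(name = library$name[j], tier = tier,
                                         score = score, stringsAsFactors = FALSE))
  }
  if (nrow(matches)) {
    matches <- matches[order(-.tier_rank(matches$tier), matches$name), ,
                       drop = FALSE]
    rownames(matches) <- NULL
    tier <- matches$tier[1]
    name <- matches$name[1]
  } else if (!is.null(candidates) && nrow(candidates) > 0) {
    tier <- "putative_formula"; name <- NA_character_
  } else {
    tier <- "unannotated"; name <- NA_character_
  }
  best_formula <- if (!is.null(candidates) && nrow(candidates) > 0)
    candidates$formula[1] else NA_character_
  list(tier = tier, name = name, best_formula = best_formula,
       matches = matches)
}

#' Annotate all credentialed quartets of one source/polarity channel
#'
#' Runs [decompose()] and [match_library()] for every quartet and returns
#' the channel's annotation table.
#'
#' @param quartets A credentialed `quartet_tbl` (see [credential()]).
#' @param library A `ref_library`.
#' @param cfg An [annotation_config()].
#' @param bounds An [element_bounds()] passed to [decompose()].
#' @param formula_tol_ppm Tolerance for formula enumeration (ppm).
#' @param ms2_lookup Optional function `(u_mz, rt) -> spectrum or NULL`
#'   supplying observed MS2 spectra.
#' @return An `annotation_tbl` data frame with columns `u_mz`, `rt`, `c`,
#'   `n`, `neutral_mass`, `formula`, `name`, `tier`, `score`,
#'   `n_candidates`, `intensity`, plus `source`/`polarity` attributes.
#' @export
annotate_quartets <- function(quartets, library, cfg = annotation_config(),
                              bounds = element_bounds(), formula_tol_ppm = 5,
                              ms2_lookup = NULL) {
  stopifnot(inherits(quartets, "quartet_tbl"))
  pol <- attr(quartets, "polarity")
  rows <- lapply(seq_len(nrow(quartets)), function(i) {
    q <- quartets[i, ]
    M <- neutral_mass(q$u_mz, pol)
    cand <- decompose(M, q$c, q$n, formula_tol_ppm, bounds)
    ms2 <- if (is.null(ms2_lookup)) NULL else ms2_lookup(q$u_mz, q$rt)
    hit <- match_library(q, cand, library, cfg, pol, ms2)
    data.frame(u_mz = q$u_mz, rt = q$rt, c = q$c, n = q$n, neutral_mass = M,
               formula = hit$best_formula, name = hit$name, tier = hit$tier,
               score = if (nrow(hit$matches)) hit$matches$score[1] else NA_real_,
               n_candidates = nrow(cand), intensity = q$intensity,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(u_mz = numeric(0), rt = numeric(0), c = integer(0),
               n = integer(0), neutral_mass = numeric(0),
               formula = character(0), name = character(0),
               tier = character(0), score = numeric(0),
               n_candidates = integer(0), intensity = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, polarity = pol, source = attr(quartets, "source"),
            class = c("annotation_tbl", "data.frame"))
}

#' @export
print.annotation_tbl <- function(x, ...) {
  tab <- table(factor(x$tier, levels = TIERS))
  cat(sprintf("<annotation_tbl> %d quartets (%s %s): %s\n",
              nrow(x), attr(x, "source"), attr(x, "polarity"),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
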