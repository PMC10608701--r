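#' Matching configuration for quartet search
#'
#' Tolerances and search bounds for matching co-eluting labeled partners.
#' Defaults target 120,000-resolution Orbitrap data; all are config-exposed
#' because the screening criteria ("intensity and mass shift") admit
#' instrument-dependent windows.
#'
#' @param mz_tol_ppm Partner m/z tolerance in ppm (> 0). Default 5.
#' @param rt_tol Co-elution window in minutes (> 0). Default 0.5.
#' @param intensity_ratio_bounds Allowed labeled/unlabeled intensity ratio
#'   interval `c(lo, hi)` with `0 < lo < 1 < hi`. Default `c(0.2, 5)`.
#' @param c_max,n_max Upper search bounds on carbon / nitrogen counts
#'   (further capped by `floor(M/12)`, `floor(M/14)`). Defaults 40 and 10.
#' @return A `match_config` list.
#' @export
match_config <- function(mz_tol_ppm = 5, rt_tol = 0.5,
                         intensity_ratio_bounds = c(0.2, 5),
                         c_max = 40L, n_max = 10L) {
  if (mz_tol_ppm <= 0) stop("mz_tol_ppm must be > 0", call. = FALSE)
  if (rt_tol <= 0) stop("rt_tol must be > 0", call. = FALSE)
  b <- intensity_ratio_bounds
  if (length(b) != 2 || !(b[1] > 0 && b[1] < 1 && b[2] > 1))
    stop("intensity_ratio_bounds must satisfy 0 < lo < 1 < hi", call. = FALSE)
  structure(list(mz_tol_ppm = mz_tol_ppm, rt_tol = rt_tol,
                 intensity_ratio_bounds = b,
                 c_max = as.integer(c_max), n_max = as.integer(n_max)),
            class = "match_config")
}

#' Expected mass shift for a given carbon and nitrogen count
#'
#' The mass shift of a fully 13C/15N-labeled ion relative to its unlabeled
#' form: `c * (m13C - m12C) + n * (m15N - m14N)`.
#'
#' @param c,n Carbon and nitrogen atom counts (non-negative; vectorized).
#' @param deltas Isotope constants, see [isotope_deltas()].
#' @return Mass shift in Da.
#' @examples
#' expected_shift(5, 1)  # glutamate: 6.0138091 Da
#' @export
expected_shift <- function(c, n, deltas = isotope_deltas()) {
  if (any(c < 0) || any(n < 0))
    stop("atom counts must be non-negative", call. = FALSE)
  c * deltas$d13C + n * deltas$d15N
}

#' Neutral monoisotopic mass of an observed ion
#'
#' Assumes [M-H]- in negative mode and [M+H]+ in positive mode, with the
#' electron mass accounted for: at 5 ppm and m/z 70 the 0.55 mDa electron
#' term is itself ~8 ppm, so it cannot be neglected.
#'
#' @param mz Observed ion m/z (vectorized).
#' @param polarity `"positive"` or `"negative"`.
#' @param deltas Isotope constants, see [isotope_deltas()].
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(mz, polarity, deltas = isotope_deltas()) {
  polarity <- match.arg(polarity, POLARITIES)
  shift <- deltas$proton  # m(H) - m(e)
  if (polarity == "negative") mz + shift else mz - shift
}

# Find, for each predicted m/z, the best acceptable partner peak in a sorted
# labeled set: within ppm tolerance, co-eluting, intensity ratio in bounds,
# not yet claimed. Returns index (NA if none) and signed ppm error.
.find_partner <- function(pred, set, claimed, u_rt, u_int, cfg) {
  n <- length(pred)
  idx <- rep(NA_integer_, n); ppm <- rep(NA_real_, n)
  if (!nrow(set)) return(list(idx = idx, ppm = ppm))
  w  <- pred * cfg$mz_tol_ppm * 1e-6
  lo <- findInterval(pred - w, set$mz) + 1L
  hi <- findInterval(pred + w, set$mz)
  rb <- cfg$intensity_ratio_bounds
  for (k in which(hi >= lo)) {
    j <- lo[k]:hi[k]
    ok <- !claimed[j] &
      abs(set$rt[j] - u_rt) <= cfg$rt_tol &
      set$intensity[j] / u_int >= rb[1] &
      set$intensity[j] / u_int <= rb[2]
    j <- j[ok]
    if (!length(j)) next
    e <- (set$mz[j] - pred[k]) / pred[k] * 1e6
    best <- which.min(abs(e))
    idx[k] <- j[best]; ppm[k] <- e[best]
  }
  list(idx = idx, ppm = ppm)
}

.support_rank <- c(full = 3L, triad = 2L, pair = 1L)

#' Match labeled quartets across the four culture conditions
#'
#' For every unlabeled feature, searches the 13C, 15N and dual-labeled peak
#' sets for co-eluting partners at the mass shifts predicted by candidate
#' carbon counts `c` in `[0, min(c_max, floor(M/12))]` and nitrogen counts
#' `n` in `[0, min(n_max, floor(M/14))]`, and infers `(c, n)` from the best-
#' supported combination. Support levels: `full` (partners in all three
#' labeled conditions), `triad` (two), `pair` (dual partner only; `(c, n)`
#' then frequently ambiguous). Unlabeled features are processed in
#' descending intensity and each labeled peak is claimed by at most one
#' quartet, which makes conflict resolution deterministic. A feature whose
#' two best candidates tie on support and ppm residual is flagged
#' `ambiguous` and is excluded by [credential()].
#'
#' @param u,c13,n15,dual The four [peak_set()]s (conditions U, C13, N15,
#'   C13N15), sharing polarity and ion source.
#' @param cfg A [match_config()].
#' @param deltas Isotope constants, see [isotope_deltas()].
#' @return A `quartet_tbl` data frame: one row per matched unlabeled
#'   feature with columns `u_mz`, `rt`, `intensity`, `c`, `n`, `support`,
#'   `ppm_residual`, `mz_13c`, `mz_15n`, `mz_dual`, `ambiguous`.
#' @export
match_quartets <- function(u, c13, n15, dual, cfg = match_config(),
                           deltas = isotope_deltas()) {
  sets <- list(u, c13, n15, dual)
  stopifnot(all(vapply(sets, inherits, logical(1), "peak_set")))
  pol <- unique(vapply(sets, attr, character(1), "polarity"))
  src <- unique(vapply(sets, attr, character(1), "source"))
  if (length(pol) != 1L || length(src) != 1L)
    stop("all four peak sets must share polarity and ion source", call. = FALSE)

  claimed13 <- logical(nrow(c13)); claimed15 <- logical(nrow(n15))
  claimedD  <- logical(nrow(dual))
  ord <- order(-u$intensity, u$mz)
  rows <- vector("list", length(ord))

  for (pos in seq_along(ord)) {
    i <- ord[pos]
    umz <- u$mz[i]; urt <- u$rt[i]; uint <- u$intensity[i]
    M <- neutral_mass(umz, pol, deltas)
    cs <- 0:min(cfg$c_max, floor(M / 12))
    ns <- 0:min(cfg$n_max, floor(M / 14))

    h13 <- .find_partner(umz + cs * deltas$d13C, c13, claimed13, urt, uint, cfg)
    h15 <- .find_partner(umz + ns * deltas$d15N, n15, claimed15, urt, uint, cfg)
    cstar <- cs[!is.na(h13$idx)]; nstar <- ns[!is.na(h15$idx)]

    # candidate (c, n) pairs: any combination with at least one supporting
    # labeled partner; single-partner candidates carry pair support and an
    # undetermined second count, so they tie and get flagged ambiguous
    grid <- expand.grid(c = cs, n = ns)
    hasC <- grid$c %in% cstar; hasN <- grid$n %in% nstar
    hd <- .find_partner(umz + grid$c * deltas$d13C + grid$n * deltas$d15N,
                        dual, claimedD, urt, uint, cfg)
    hasD <- !is.na(hd$idx)
    keep <- hasC | hasN | hasD
    if (!any(keep)) next
    grid <- grid[keep, , drop = FALSE]
    hasC <- hasC[keep]; hasN <- hasN[keep]; hasD <- hasD[keep]
    dIdx <- hd$idx[keep]; dPpm <- hd$ppm[keep]

    i13 <- ifelse(hasC, h13$idx[match(grid$c, cs)], NA_integer_)
    p13 <- ifelse(hasC, h13$ppm[match(grid$c, cs)], NA_real_)
    i15 <- ifelse(hasN, h15$idx[match(grid$n, ns)], NA_integer_)
    p15 <- ifelse(hasN, h15$ppm[match(grid$n, ns)], NA_real_)

    npart <- hasC + hasN + hasD
    support <- c("pair", "triad", "full")[npart]
    res <- pmax(abs(p13), abs(p15), abs(dPpm), na.rm = TRUE)
    o <- order(-.support_rank[support], res, grid$c, grid$n)
    b <- o[1]
    ambiguous <- length(o) > 1 &&
      .support_rank[support[o[2]]] == .support_rank[support[b]] &&
      abs(res[o[2]] - res[b]) < 1e-6

    if (!is.na(i13[b])) claimed13[i13[b]] <- TRUE
    if (!is.na(i15[b])) claimed15[i15[b]] <- TRUE
    if (!is.na(dIdx[b])) claimedD[dIdx[b]] <- TRUE

    rows[[pos]] <- data.frame(
      u_mz = umz, rt = urt, intensity = uint,
      c = grid$c[b], n = grid$n[b], support = support[b],
      ppm_residual = res[b],
      mz_13c = if (is.na(i13[b])) NA_real_ else c13$mz[i13[b]],
      mz_15n = if (is.na(i15[b])) NA_real_ else n15$mz[i15[b]],
      mz_dual = if (is.na(dIdx[b])) NA_real_ else dual$mz[dIdx[b]],
      ambiguous = ambiguous, stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(u_mz = numeric(0), rt = numeric(0), intensity = numeric(0),
                      c = integer(0), n = integer(0), support = character(0),
                      ppm_residual = numeric(0), mz_13c = numeric(0),
                      mz_15n = numeric(0), mz_dual = numeric(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
  out <- out[order(out$u_mz, out$rt), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, polarity = pol, source = src,
            class = c("quartet_tbl", "data.frame"))
}

#' Credential quartets
#'
#' Keeps only quartets observed in all four conditions (`support == "full"`)
#' with an unambiguous `(c, n)` assignment. Peaks present only in unlabeled
#' medium (media components, background) cannot reach full support, which is
#' exactly the contaminant-exclusion rationale of isotope credentialing.
#'
#' @param quartets A `quartet_tbl` from [match_quartets()].
#' @return The credentialed subset, same class.
#' @export
credential <- function(quartets) {
  stopifnot(inherits(quartets, "quartet_tbl"))
  out <- quartets[quartets$support == "full" & !quartets$ambiguous, ,
                  drop = FALSE]
  rownames(out) <- NULL
  structure(out, polarity = attr(quartets, "polarity"),
            source = attr(quartets, "source"),
            class = c("quartet_tbl", "data.frame"))
}

#' @export
print.quartet_tbl <- function(x, ...) {
  cat(sprintf("<quartet_tbl> %d quartets (%s %s): %d full, %d triad, %d pair, %d ambiguous\n",
              nrow(x), attr(x, "source"), attr(x, "polarity"),
              sum(x$support == "full"), sum(x$support == "triad"),
              sum(x$support == "pair"), sum(x$ambiguous)))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
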