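#' Element bounds and plausibility filters for formula enumeration
#'
#' Per-element count ranges plus RDBE and H/C-ratio windows used to reject
#' chemically implausible compositions. Defaults follow the common
#' small-molecule heuristics used for water-soluble primary metabolites;
#' every bound is config-exposed.
#'
#' @param C,H,N,O,P,S Length-2 integer ranges `c(min, max)`.
#' @param rdbe_range Allowed ring-plus-double-bond-equivalents interval;
#'   lower bound must be >= 0.
#' @param hc_ratio_range Allowed H/C ratio interval (applied when C > 0).
#'   The default upper limit of 4 keeps heavily hydrogenated one-carbon
#'   metabolites such as urea (H/C = 4) admissible; the common-range
#'   heuristic of 3.1 would reject them.
#' @return An `element_bounds` list.
#' @export
element_bounds <- function(C = c(0L, 40L), H = c(0L, 80L), N = c(0L, 20L),
                           O = c(0L, 20L), P = c(0L, 4L), S = c(0L, 4L),
                           rdbe_range = c(0, 25), hc_ratio_range = c(0.1, 4)) {
  b <- list(C = C, H = H, N = N, O = O, P = P, S = S)
  for (el in names(b)) {
    if (length(b[[el]]) != 2 || b[[el]][1] > b[[el]][2] || b[[el]][1] < 0)
      stop("bounds for ", el, " must be a non-negative c(min, max)", call. = FALSE)
  }
  if (rdbe_range[1] < 0) stop("rdbe_range lower bound must be >= 0", call. = FALSE)
  structure(c(b, list(rdbe_range = rdbe_range, hc_ratio_range = hc_ratio_range)),
            class = "element_bounds")
}

# Vectorized core: given fixed per-row (c, n, o, p, s), solve H from the
# mass residual, then apply all plausibility filters. Returns a candidate
# data frame sorted by |ppm| then heteroatom count.
.decompose_grid <- function(neutral_mass, grid, tol_ppm, bounds) {
  residual <- neutral_mass -
    (grid$c * MONO_MASS[["C"]] + grid$n * MONO_MASS[["N"]] +
     grid$o * MONO_MASS[["O"]] + grid$p * MONO_MASS[["P"]] +
     grid$s * MONO_MASS[["S"]])
  h <- round(residual / MONO_MASS[["H"]])
  mass <- neutral_mass - residual + h * MONO_MASS[["H"]]
  ppm <- (mass - neutral_mass) / neutral_mass * 1e6
  rd  <- grid$c + 1 + (grid$n + grid$p) / 2 - h / 2
  ok <- h >= bounds$H[1] & h <= bounds$H[2] &
    abs(ppm) <= tol_ppm &
    rd >= bounds$rdbe_range[1] & rd <= bounds$rdbe_range[2] &
    abs(rd - round(rd)) < 1e-9 &
    (grid$c == 0 | (h / pmax(grid$c, 1) >= bounds$hc_ratio_range[1] &
                    h / pmax(grid$c, 1) <= bounds$hc_ratio_range[2]))
  out <- data.frame(C = grid$c[ok], H = as.integer(h[ok]), N = grid$n[ok],
                    O = grid$o[ok], P = grid$p[ok], S = grid$s[ok],
                    neutral_mass = mass[ok], ppm_error = ppm[ok],
                    rdbe = rd[ok])
  hetero <- out$N + out$O + out$P + out$S
  out <- out[order(abs(out$ppm_error), hetero, out$O, out$P, out$S), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate molecular formulas for a neutral mass with fixed C and N
#'
#' The core formula-prediction step: with the carbon and nitrogen counts
#' pinned by the isotope-labeling mass shifts, enumerates O, P and S counts
#' over their bounds and solves the hydrogen count from the mass residual
#' (H is determined, not searched, because all other element masses are
#' fixed). Candidates must fall within `tol_ppm`, have integer RDBE inside
#' `rdbe_range` (neutral even-electron molecules) and plausible H/C ratio.
#'
#' @param neutral_mass Query neutral monoisotopic mass (Da, > 0).
#' @param c,n Carbon and nitrogen counts fixed by the labeling experiment.
#' @param tol_ppm Mass tolerance in ppm (> 0). Default 5.
#' @param bounds An [element_bounds()].
#' @return A `formula_candidates` data frame sorted by `|ppm_error|` (ties:
#'   fewer heteroatoms) with columns `C,H,N,O,P,S`, `formula`,
#'   `neutral_mass`, `ppm_error`, `rdbe`, `rank`.
#' @examples
#' decompose(147.05316, c = 5, n = 1)  # glutamate at rank 1
#' @export
decompose <- function(neutral_mass, c, n, tol_ppm = 5,
                      bounds = element_bounds()) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  if (neutral_mass <= 0) stop("neutral_mass must be > 0", call. = FALSE)
  if (c < 0 || n < 0) stop("atom counts must be non-negative", call. = FALSE)
  grid <- expand.grid(o = bounds$O[1]:bounds$O[2],
                      p = bounds$P[1]:bounds$P[2],
                      s = bounds$S[1]:bounds$S[2])
  grid$c <- c; grid$n <- n
  out <- .decompose_grid(neutral_mass, grid, tol_ppm, bounds)
  out$formula <- vapply(seq_len(nrow(out)), function(i)
    formula_string(c(C = out$C[i], H = out$H[i], N = out$N[i],
                     O = out$O[i], P = out$P[i], S = out$S[i])), character(1))
  out$rank <- seq_len(nrow(out))
  structure(out[c("formula", "C", "H", "N", "O", "P", "S",
                  "neutral_mass", "ppm_error", "rdbe", "rank")],
            class = c("formula_candidates", "data.frame"))
}

#' Candidate-set sizes with and without the labeling constraint
#'
#' Quantifies how much the labeling-derived `(c, n)` constraint shrinks the
#' formula search space: returns the number of candidates with `(c, n)`
#' fixed versus with C and N free over their bounds (capped at
#' `floor(M/12)` and `floor(M/14)`). The constrained set is a subset of the
#' unconstrained one by construction.
#'
#' @inheritParams decompose
#' @return Named list `n_constrained`, `n_unconstrained`.
#' @export
constrained_gain <- function(neutral_mass, c, n, tol_ppm = 5,
                             bounds = element_bounds()) {
  cons <- decompose(neutral_mass, c, n, tol_ppm, bounds)
  cmaxi <- min(bounds$C[2], floor(neutral_mass / 12))
  nmaxi <- min(bounds$N[2], floor(neutral_mass / 14))
  if (cmaxi < bounds$C[1] || nmaxi < bounds$N[1])
    return(list(n_constrained = nrow(cons), n_unconstrained = nrow(cons)))
  grid <- expand.grid(c = bounds$C[1]:cmaxi, n = bounds$N[1]:nmaxi,
                      o = bounds$O[1]:bounds$O[2],
                      p = bounds$P[1]:bounds$P[2],
                      s = bounds$S[1]:bounds$S[2])
  un <- .decompose_grid(neutral_mass, grid, tol_ppm, bounds)
  list(n_constrained = nrow(cons), n_unconstrained = nrow(un))
}

#' @export
print.formula_candidates <- function(x, ...) {
  cat(sprintf("<formula_candidates> %d candidate(s)\n", nrow(x)))
  print(utils::head(as.data.frame(x)[c("rank", "formula", "neutral_mass",
                                       "ppm_error", "rdbe")], 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
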