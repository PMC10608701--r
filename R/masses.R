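# IUPAC monoisotopic atomic masses (Da); 12C = 12 exactly by definition.
MONO_MASS <- c(
  C = 12,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.99491461956,
  P = 30.97376163,
  S = 31.97207100
)

ELEMENTS <- names(MONO_MASS)

#' Physical constants for isotope mass shifts
#'
#' Mass differences used throughout quartet matching: the 13C-12C and 15N-14N
#' neutron-capture mass increments, plus the proton and electron masses used
#' to convert ion m/z to neutral mass.
#'
#' @return Named list with elements `d13C`, `d15N`, `proton`, `electron`
#'   (all Da).
#' @examples
#' isotope_deltas()$d13C   # 1.0033548
#' @export
isotope_deltas <- function() {
  list(
    d13C     = 1.0033548378,   # 13.0033548378 - 12
    d15N     = 0.9970348934,   # 15.0001088982 - 14.0030740048
    proton   = 1.00727646677,
    electron = 0.00054857991
  )
}

#' Parse a molecular formula string
#'
#' Accepts Hill-notation formulas over the CHNOPS alphabet (no charges, no
#' isotope markers). Element symbols may appear in any order; counts default
#' to 1.
#'
#' @param formula Formula string, e.g. `"C5H9NO4"`.
#' @return Named integer vector over `c("C","H","N","O","P","S")`.
#' @examples
#' parse_formula("CH4N2O")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("'formula' must be a single string", call. = FALSE)
  s <- gsub("[[:space:]]", "", formula)
  counts <- stats::setNames(integer(length(ELEMENTS)), ELEMENTS)
  if (!nzchar(s)) return(counts)
  # tokenize element + optional count; anything left over is invalid
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("invalid formula '", formula, "': unparseable characters", call. = FALSE)
  for (tok in toks) {
    el  <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    num <- sub("^[A-Z][a-z]?", "", tok)
    if (!el %in% ELEMENTS)
      stop("invalid formula '", formula, "': unknown element token '", el, "'",
           call. = FALSE)
    counts[el] <- counts[el] + if (nzchar(num)) as.integer(num) else 1L
  }
  counts
}

#' Monoisotopic mass of an element-count vector
#'
#' @param counts Named numeric vector of element counts; names must be a
#'   subset of `c("C","H","N","O","P","S")`. A formula string is also accepted.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(c(C = 5, H = 9, N = 1, O = 4))  # glutamate, 147.05316
#' @export
monoisotopic_mass <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (is.null(names(counts)) || !all(names(counts) %in% ELEMENTS))
    stop("unknown element key in 'counts'; alphabet is CHNOPS", call. = FALSE)
  if (any(counts < 0)) stop("element counts must be non-negative", call. = FALSE)
  sum(counts * MONO_MASS[names(counts)])
}

#' Ring-plus-double-bond equivalents
#'
#' RDBE = C + 1 + (N + P)/2 - H/2; O and S contribute zero. Integer-valued
#' for neutral even-electron molecules.
#'
#' @inheritParams monoisotopic_mass
#' @return RDBE (may be half-integer for radical/odd-electron compositions).
#' @examples
#' rdbe("C6H6")  # benzene: 4
#' @export
rdbe <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  g <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  g("C") + 1 + (g("N") + g("P")) / 2 - g("H") / 2
}

#' Format element counts as a Hill-notation formula string
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; unit
#' counts print without the digit.
#'
#' @inheritParams monoisotopic_mass
#' @return Formula string.
#' @examples
#' formula_string(c(C = 1, H = 4, N = 2, O = 1))  # "CH4N2O"
#' @export
formula_string <- function(counts) {
  full <- stats::setNames(numeric(length(ELEMENTS)), ELEMENTS)
  full[names(counts)] <- counts
  ord <- c("C", "H", sort(setdiff(ELEMENTS, c("C", "H"))))
  parts <- vapply(ord, function(el) {
    k <- full[[el]]
    if (k == 0) "" else if (k == 1) el else paste0(el, format(k, scientific = FALSE))
  }, character(1))
  paste0(parts, collapse = "")
}
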