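CONDITIONS <- c("U", "C13", "N15", "C13N15")
POLARITIES <- c("positive", "negative")
SOURCES    <- c("ESI", "APCI")

new_peak_set <- function(peaks, condition, polarity, source) {
  condition <- match.arg(condition, CONDITIONS)
  polarity  <- match.arg(polarity, POLARITIES)
  source    <- match.arg(source, SOURCES)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks,
            condition = condition, polarity = polarity, source = source,
            class = c("peak_set", "data.frame"))
}

#' Construct a peak set from vectors
#'
#' A `peak_set` is a data frame of centroided LC-MS features (columns `mz`,
#' `rt`, `intensity`, `snr`), kept sorted ascending by m/z, tagged with the
#' labeling condition, polarity and ion source it came from.
#'
#' @param mz Ion m/z values (Th).
#' @param rt Retention times (min).
#' @param intensity Peak areas/heights (> 0).
#' @param snr Signal-to-noise ratios (>= 0); defaults to `Inf` (pre-filtered).
#' @param condition One of `"U"`, `"C13"`, `"N15"`, `"C13N15"`.
#' @param polarity `"positive"` or `"negative"`.
#' @param source `"ESI"` or `"APCI"`.
#' @return A `peak_set`.
#' @export
peak_set <- function(mz, rt, intensity, snr = Inf,
                     condition = "U", polarity = "negative", source = "ESI") {
  n <- length(mz)
  if (length(rt) != n || length(intensity) != n)
    stop("mz, rt and intensity must have equal length", call. = FALSE)
  snr <- rep_len(snr, n)
  if (n && any(intensity <= 0)) stop("intensity must be > 0", call. = FALSE)
  if (n && any(snr < 0)) stop("snr must be >= 0", call. = FALSE)
  new_peak_set(data.frame(mz = as.numeric(mz), rt = as.numeric(rt),
                          intensity = as.numeric(intensity), snr = as.numeric(snr)),
               condition, polarity, source)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks | condition=%s polarity=%s source=%s\n",
              nrow(x), attr(x, "condition"), attr(x, "polarity"), attr(x, "source")))
  if (nrow(x)) {
    cat(sprintf("  m/z %.4f-%.4f, RT %.2f-%.2f min\n",
                min(x$mz), max(x$mz), min(x$rt), max(x$rt)))
    print(utils::head(as.data.frame(x), 6))
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' Read a peak table from CSV/TSV
#'
#' Reads a picked-peak table (columns `mz`, `rt`, `intensity`; `snr`
#' optional, defaulting to `Inf`). Malformed rows are reported with their
#' row numbers and reading fails rather than silently dropping data.
#'
#' @param path File path; delimiter inferred from extension (`.tsv`/`.txt`
#'   tab, otherwise comma) or given via `sep`.
#' @param condition,polarity,source Labels stamped onto the returned set.
#' @param sep Field separator override.
#' @return A [peak_set()].
#' @export
read_peak_table <- function(path, condition = "U", polarity = "negative",
                            source = "ESI", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("mz", "rt", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"snr" %in% names(df)) df$snr <- "Inf"
  if (nrow(df) == 0L) {
    warning("empty peak table: ", path, call. = FALSE)
    return(peak_set(numeric(0), numeric(0), numeric(0), numeric(0),
                    condition, polarity, source))
  }
  num <- lapply(df[c("mz", "rt", "intensity", "snr")],
                function(col) suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(num[c("mz", "rt", "intensity")], is.na)))
  if (length(bad))
    stop("non-numeric values in ", path, " at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  num$snr[is.na(num$snr)] <- Inf
  peak_set(num$mz, num$rt, num$intensity, num$snr, condition, polarity, source)
}

#' Write a peak table
#'
#' @param ps A [peak_set()].
#' @param path Output path; delimiter chosen as in [read_peak_table()].
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(ps, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(as.data.frame(ps)[c("mz", "rt", "intensity", "snr")],
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter peaks by signal-to-noise and scan range
#'
#' Keeps peaks with `snr > min_snr` (strict, matching the S/N > 5 picking
#' rule of 120k-resolution Orbitrap acquisition) and m/z inside the scan
#' range (default 70-1000 Th, inclusive).
#'
#' @param ps A [peak_set()].
#' @param min_snr Minimum S/N, strict inequality. Default 5.
#' @param mz_range Length-2 numeric scan range. Default `c(70, 1000)`.
#' @return Filtered `peak_set`.
#' @export
filter_peaks <- function(ps, min_snr = 5, mz_range = c(70, 1000)) {
  stopifnot(inherits(ps, "peak_set"))
  if (min_snr < 0) stop("min_snr must be >= 0", call. = FALSE)
  if (length(mz_range) != 2L || mz_range[1] >= mz_range[2])
    stop("mz_range must be an increasing length-2 interval", call. = FALSE)
  keep <- ps$snr > min_snr & ps$mz >= mz_range[1] & ps$mz <= mz_range[2]
  new_peak_set(as.data.frame(ps)[keep, , drop = FALSE],
               attr(ps, "condition"), attr(ps, "polarity"), attr(ps, "source"))
}

#' Read a reference metabolite library
#'
#' The library is a TSV with columns `name` and `formula` (Hill notation,
#' CHNOPS), optional `rt` (min) and optional `neutral_mass` (Da). Neutral
#' monoisotopic masses are always recomputed from the formula; a provided
#' mass deviating by more than 1e-3 Da raises a warning. MS2 spectra are
#' attached from a companion MSP file by matching on entry name.
#'
#' @param path Library TSV path.
#' @param msp_path Optional MSP spectral file (see [read_msp()]).
#' @return A `ref_library`: data frame with columns `name`, `formula`,
#'   `neutral_mass`, `rt`, and list-columns `counts` (element-count vectors)
#'   and `ms2` (two-column fragment matrices or `NULL`).
#' @export
read_library <- function(path, msp_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("name", "formula")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("library is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  counts <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(parse_formula(df$formula[i]),
             error = function(e) stop("library entry ", i, " ('", df$name[i],
                                      "'): ", conditionMessage(e), call. = FALSE))
  })
  mass <- vapply(counts, monoisotopic_mass, numeric(1))
  if ("neutral_mass" %in% names(df)) {
    given <- suppressWarnings(as.numeric(df$neutral_mass))
    off <- which(!is.na(given) & abs(given - mass) > 1e-3)
    if (length(off))
      warning("library mass disagrees with formula by > 1e-3 Da for entries: ",
              paste(df$name[off], collapse = ", "), call. = FALSE)
  }
  rt <- if ("rt" %in% names(df)) suppressWarnings(as.numeric(df$rt)) else
    rep(NA_real_, nrow(df))
  ms2 <- rep(list(NULL), nrow(df))
  if (!is.null(msp_path)) {
    spectra <- read_msp(msp_path)
    idx <- match(tolower(df$name), tolower(names(spectra)))
    ms2[!is.na(idx)] <- spectra[idx[!is.na(idx)]]
  }
  lib <- data.frame(name = df$name, formula = vapply(counts, formula_string, character(1)),
                    neutral_mass = mass, rt = rt, stringsAsFactors = FALSE)
  lib$counts <- counts
  lib$ms2 <- ms2
  structure(lib, class = c("ref_library", "data.frame"))
}

#' @export
print.ref_library <- function(x, ...) {
  cat(sprintf("<ref_library> %d entries (%d with RT, %d with MS2)\n",
              nrow(x), sum(!is.na(x$rt)),
              sum(!vapply(x$ms2, is.null, logical(1)))))
  print(utils::head(as.data.frame(x)[c("name", "formula", "neutral_mass", "rt")], 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Write a reference library TSV
#'
#' @param lib A `ref_library` (see [read_library()]).
#' @param path Output TSV path.
#' @param msp_path Optional path; when given, MS2 spectra are written there
#'   in MSP format.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path, msp_path = NULL) {
  utils::write.table(as.data.frame(lib)[c("name", "formula", "neutral_mass", "rt")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(msp_path)) {
    con <- file(msp_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(lib))) {
      sp <- lib$ms2[[i]]
      if (is.null(sp)) next
      writeLines(c(paste0("Name: ", lib$name[i]),
                   sprintf("PrecursorMZ: %.5f", lib$neutral_mass[i]),
                   paste0("Num Peaks: ", nrow(sp)),
                   sprintf("%.5f %.2f", sp[, 1], sp[, 2]),
                   ""), con)
    }
  }
  invisible(path)
}

#' Read an MSP-format spectral file
#'
#' Minimal MSP reader: blocks of `Name:` / optional `PrecursorMZ:` /
#' `Num Peaks:` followed by whitespace-separated `mz intensity` pairs.
#'
#' @param path MSP file path.
#' @return Named list of two-column matrices (`mz`, `intensity`).
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  name <- NULL; frags <- NULL
  flush <- function() {
    if (!is.null(name) && length(frags)) {
      m <- do.call(rbind, frags)
      colnames(m) <- c("mz", "intensity")
      spectra[[name]] <<- m
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (grepl("^Name:", ln, ignore.case = TRUE)) {
      flush()
      name <- trimws(sub("^Name:", "", ln, ignore.case = TRUE))
      frags <- list()
    } else if (grepl("^[0-9]", ln)) {
      parts <- as.numeric(strsplit(ln, "[[:space:]]+")[[1]])
      if (length(parts) >= 2 && !anyNA(parts[1:2]))
        frags[[length(frags) + 1L]] <- parts[1:2]
    }
  }
  flush()
  spectra
}

#' Read centroided peaks from an mzML file (optional adapter)
#'
#' Aggregates centroided scans of one polarity into a picked-peak table by
#' taking each scan's centroids as features (retention time from the scan
#' header). Requires the `mzR` package. The primary input path of this
#' package is picked-peak CSV/TSV; this adapter exists for users starting
#' from raw centroided data and applies the same downstream filters.
#'
#' @inheritParams read_peak_table
#' @return A [peak_set()].
#' @export
read_mzml_peaks <- function(path, condition = "U", polarity = "negative",
                            source = "ESI") {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML ingestion requires the 'mzR' package", call. = FALSE)
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hd <- mzR::header(h)
  ms1 <- which(hd$msLevel == 1)
  pk <- mzR::peaks(h, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  mz <- unlist(lapply(pk, function(m) m[, 1]))
  it <- unlist(lapply(pk, function(m) m[, 2]))
  rt <- rep(hd$retentionTime[ms1] / 60, vapply(pk, nrow, integer(1)))
  keep <- it > 0
  peak_set(mz[keep], rt[keep], it[keep], Inf, condition, polarity, source)
}
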