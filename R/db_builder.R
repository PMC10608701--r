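CHANNELS <- c("ESI+", "ESI-", "APCI+", "APCI-")

.channel <- function(source, polarity)
  paste0(source, if (polarity == "positive") "+" else "-")

#' Merge per-channel annotation tables into one metabolite database
#'
#' Entries from different ion sources / polarities that describe the same
#' metabolite — identical identity key and retention time within `rt_tol` —
#' collapse into one database entry whose `detected_in` is the union of
#' channels and whose tier is the best observed. The identity key is the
#' best-tier metabolite name when annotated, otherwise the Hill formula
#' string; conflicting identities at the same mass/RT stay separate.
#' Per-channel intensities are retained (not averaged) so source-coverage
#' heat maps can be reconstructed.
#'
#' @param ann_tables List of `annotation_tbl` objects (one per
#'   source/polarity channel).
#' @param rt_tol RT clustering tolerance in minutes. Default 0.5.
#' @return A `metab_db` data frame: `identity`, `formula`, `neutral_mass`,
#'   `rt`, `tier`, `detected_in` (comma-joined channels), `n_channels`, and
#'   one `intensity_<channel>` column per observed channel.
#' @export
merge_annotations <- function(ann_tables, rt_tol = 0.5) {
  if (!length(ann_tables)) stop("need at least one annotation table", call. = FALSE)
  stopifnot(all(vapply(ann_tables, inherits, logical(1), "annotation_tbl")))
  rows <- do.call(rbind, lapply(ann_tables, function(tb) {
    df <- as.data.frame(tb)
    df$channel <- .channel(attr(tb, "source"), attr(tb, "polarity"))
    df
  }))
  rows <- rows[rows$tier != "unannotated", , drop = FALSE]
  if (!nrow(rows)) return(.empty_db())
  rows$identity <- ifelse(is.na(rows$name), rows$formula, rows$name)
  rows <- rows[!is.na(rows$identity), , drop = FALSE]
  # canonical order first so clustering is independent of input permutation
  rows <- rows[order(rows$identity, rows$rt, rows$channel, rows$u_mz), ,
               drop = FALSE]

  entries <- list()
  for (id in unique(rows$identity)) {
    sub <- rows[rows$identity == id, , drop = FALSE]
    # single-linkage RT clustering within an identity
    cl <- cumsum(c(TRUE, diff(sub$rt) > rt_tol))
    for (g in unique(cl)) {
      grp <- sub[cl == g, , drop = FALSE]
      tiers <- .tier_rank(grp$tier)
      best <- which.max(tiers)
      inten <- tapply(grp$intensity, grp$channel, max)
      e <- data.frame(identity = id, formula = grp$formula[best],
                      neutral_mass = stats::median(grp$neutral_mass),
                      rt = stats::median(grp$rt), tier = grp$tier[best],
                      detected_in = paste(sort(unique(grp$channel)),
                                          collapse = ","),
                      n_channels = length(unique(grp$channel)),
                      stringsAsFactors = FALSE)
      for (ch in names(inten)) e[[paste0("intensity_", ch)]] <- inten[[ch]]
      entries[[length(entries) + 1L]] <- e
    }
  }
  cols <- unique(unlist(lapply(entries, names)))
  entries <- lapply(entries, function(e) { e[setdiff(cols, names(e))] <- NA; e[cols] })
  db <- do.call(rbind, entries)
  db <- db[order(db$identity, db$rt), , drop = FALSE]
  rownames(db) <- NULL
  structure(db, class = c("metab_db", "data.frame"))
}

.empty_db <- function() {
  structure(data.frame(identity = character(0), formula = character(0),
                       neutral_mass = numeric(0), rt = numeric(0),
                       tier = character(0), detected_in = character(0),
                       n_channels = integer(0), stringsAsFactors = FALSE),
            class = c("metab_db", "data.frame"))
}

#' Count database entries per ion source and polarity
#'
#' An entry detected in several channels contributes to each of their
#' counts but only once to the distinct total.
#'
#' @param db A `metab_db` from [merge_annotations()].
#' @return A `source_counts` list: `by_channel` (named counts over ESI+/
#'   ESI-/APCI+/APCI-) and `total` distinct entries.
#' @export
count_by_source <- function(db) {
  stopifnot(inherits(db, "metab_db"))
  chans <- strsplit(db$detected_in, ",", fixed = TRUE)
  counts <- vapply(CHANNELS, function(ch)
    sum(vapply(chans, function(x) ch %in% x, logical(1))), integer(1))
  structure(list(by_channel = counts, total = nrow(db)),
            class = "source_counts")
}

#' @export
print.source_counts <- function(x, ...) {
  cat("<source_counts>\n")
  for (ch in names(x$by_channel))
    cat(sprintf("  %-5s %d\n", ch, x$by_channel[[ch]]))
  cat(sprintf("  total distinct entries: %d\n", x$total))
  invisible(x)
}

#' @export
print.metab_db <- function(x, ...) {
  cat(sprintf("<metab_db> %d entries; tiers: %s\n", nrow(x),
              paste(names(table(x$tier)), table(x$tier), sep = "=",
                    collapse = ", ")))
  print(utils::head(as.data.frame(x)[c("identity", "formula", "neutral_mass",
                                       "rt", "tier", "detected_in")], 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
summary.metab_db <- function(object, ...) {
  cs <- count_by_source(object)
  cat(sprintf("Metabolite database: %d distinct entries\n", cs$total))
  print(cs)
  invisible(cs)
}
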