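# Readers and writers: JSON and long-form CSV for elicitation studies,
# CSV for score tables (including S1-style exports with per-panel expert
# rows plus assessor rows labelled pwg / pwi / ew).  Numbers are written
# with 17 significant digits so round-trips are bit-identical.

fmt17 <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

num17 <- function(x, what) {
  x[x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad))
    stop(sprintf("malformed numeric in %s at row(s) %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")))
  out
}

#' Write a study to JSON or CSV
#'
#' JSON keeps the full structure (panel metadata, item metadata, expert
#' label registry); the long-form CSV has one row per assessment joined
#' with the item metadata.  Either round-trips all numeric fields
#' bit-identically.
#'
#' @param study A `sej_study`.
#' @param path Output path; format chosen by extension (`.json` or
#'   `.csv`).
#' @param anonymize Replace display labels by `expert-<n>` on write.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path, anonymize = FALSE) {
  labels <- study$experts
  if (anonymize)
    labels <- stats::setNames(sprintf("expert-%03d", seq_along(labels)),
                              names(labels))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- list(
      panels = lapply(unname(study$panels), function(p) list(
        id = p$id, hazard = p$hazard, region = p$region,
        items = lapply(seq_len(nrow(p$items)), function(j) {
          r <- p$items[j, ]
          list(id = r$item, kind = r$kind, scale = r$scale, units = r$units,
               bounds = c(r$lower, r$upper), realization = r$realization)
        }),
        experts = p$experts,
        assessments = lapply(seq_len(nrow(p$assessments)), function(j) {
          a <- p$assessments[j, ]
          list(expert = a$expert, item = a$item,
               q05 = a$q05, q50 = a$q50, q95 = a$q95)
        }))),
      experts = as.list(labels))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
  } else {
    rows <- do.call(rbind, lapply(unname(study$panels), function(p) {
      a <- p$assessments
      it <- p$items[match(a$item, p$items$item), ]
      data.frame(panel = p$id, hazard = p$hazard, region = p$region,
                 expert = a$expert, item = a$item, kind = it$kind,
                 scale = it$scale, units = it$units,
                 lower = fmt17(it$lower), upper = fmt17(it$upper),
                 realization = fmt17(it$realization),
                 q05 = fmt17(a$q05), q50 = fmt17(a$q50), q95 = fmt17(a$q95),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read a study from JSON or CSV
#'
#' The loaded study is validated; any violation (non-monotone triple,
#' incomplete panel, missing realization, ...) aborts the load with the
#' offending panel/expert/item named.
#'
#' @param path Path to a file written by [write_study()] (or conforming to
#'   the same schema).
#' @return A `sej_study`.
#' @export
read_study <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    panels <- lapply(doc$panels, function(p) {
      items <- do.call(rbind, lapply(p$items, function(r) {
        b <- r$bounds
        data.frame(item = r$id, kind = r$kind, scale = r$scale,
                   units = r$units,
                   lower = if (is.null(b[[1]])) NA_real_ else as.numeric(b[[1]]),
                   upper = if (is.null(b[[2]])) NA_real_ else as.numeric(b[[2]]),
                   realization = if (is.null(r$realization)) NA_real_
                                 else as.numeric(r$realization),
                   stringsAsFactors = FALSE)
      }))
      assess <- do.call(rbind, lapply(p$assessments, function(a)
        data.frame(expert = a$expert, item = a$item,
                   q05 = as.numeric(a$q05), q50 = as.numeric(a$q50),
                   q95 = as.numeric(a$q95), stringsAsFactors = FALSE)))
      panel(p$id, unlist(p$experts), items, assess,
            hazard = p$hazard, region = p$region)
    })
    st <- study(panels, unlist(doc$experts))
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("panel", "expert", "item", "kind", "q05", "q50", "q95")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("study CSV missing column(s): ", paste(miss, collapse = ", "))
    for (col in c("lower", "upper", "realization", "q05", "q50", "q95"))
      raw[[col]] <- num17(raw[[col]], col)
    panels <- lapply(split(raw, factor(raw$panel, unique(raw$panel))),
                     function(d) {
      items <- d[!duplicated(d$item),
                 c("item", "kind", "scale", "units", "lower", "upper",
                   "realization")]
      panel(d$panel[1], unique(d$expert), items,
            d[, c("expert", "item", "q05", "q50", "q95")],
            hazard = d$hazard[1], region = d$region[1])
    })
    st <- study(unname(panels))
  }
  bad <- validate_study(st)
  if (length(bad))
    stop("invalid study in ", path, ":\n  ", paste(bad, collapse = "\n  "))
  st
}

#' Write a score table to CSV
#'
#' @param table Score table data frame (`panel`, `assessor`, `kind`,
#'   `statistical_accuracy`, `informativeness`, `combined`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  out <- data.frame(panel = table$panel, assessor = table$assessor,
                    kind = table$kind,
                    statistical_accuracy = fmt17(table$statistical_accuracy),
                    informativeness = fmt17(table$informativeness),
                    combined = fmt17(table$combined),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a score table (S1-style CSV)
#'
#' Expects per-panel rows for experts plus pooled assessors labelled
#' `pwg`, `pwi` and `ew`.  When no `kind` column is present it is derived
#' from the assessor label (a label of `pwg`/`pwi`/`ew`, case-insensitive,
#' is a DM row; anything else an expert).  Column names can be remapped via
#' `col_map` for exports whose headers differ.
#'
#' @param path CSV path.
#' @param col_map Optional named character vector mapping the canonical
#'   names (`panel`, `assessor`, `kind`, `statistical_accuracy`,
#'   `informativeness`, `combined`) to the file's column names.
#' @param quiet Suppress the loaded-counts message.
#' @return A score table data frame of class `sej_score_table`.
#' @export
read_score_table <- function(path, col_map = NULL, quiet = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!is.null(col_map))
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(raw))
        stop("col_map refers to absent column: ", col_map[[canon]])
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  need <- c("panel", "assessor", "statistical_accuracy", "informativeness")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("score table missing column(s): ", paste(miss, collapse = ", "))
  dm_labels <- c("pwg", "pwi", "ew")
  if (!"kind" %in% names(raw)) {
    low <- tolower(trimws(raw$assessor))
    raw$kind <- ifelse(low %in% dm_labels, low, "expert")
    raw$assessor <- ifelse(low %in% dm_labels, low, raw$assessor)
  }
  bad <- which(!raw$kind %in% c("expert", dm_labels))
  if (length(bad))
    stop(sprintf("unknown assessor kind '%s' at row %d", raw$kind[bad[1]],
                 bad[1]))
  out <- data.frame(
    panel = raw$panel, assessor = raw$assessor, kind = raw$kind,
    statistical_accuracy = num17(raw$statistical_accuracy,
                                 "statistical_accuracy"),
    informativeness = num17(raw$informativeness, "informativeness"),
    combined = if ("combined" %in% names(raw)) num17(raw$combined, "combined")
               else NA_real_,
    stringsAsFactors = FALSE)
  out$combined[is.na(out$combined)] <-
    (out$statistical_accuracy * out$informativeness)[is.na(out$combined)]
  key <- paste(out$panel, out$assessor)
  if (anyDuplicated(key))
    stop("duplicate (panel, assessor) rows: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  for (lab in dm_labels) {
    missing_dm <- setdiff(unique(out$panel), out$panel[out$kind == lab])
    if (length(missing_dm))
      warning(sprintf("no '%s' row for panel(s): %s", lab,
                      paste(utils::head(missing_dm, 5), collapse = ", ")))
  }
  if (!quiet)
    message(sprintf("read score table: %d panels, %d distinct experts, %d rows",
                    length(unique(out$panel)),
                    length(unique(out$assessor[out$kind == "expert"])),
                    nrow(out)))
  class(out) <- c("sej_score_table", "data.frame")
  out
}
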