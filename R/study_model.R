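# Domain types for quantile-elicitation studies.
#
# A study is a set of panels; a panel is a group of experts who each supply a
# 5/50/95% quantile triple for every item on the panel.  Calibration items
# carry a known realization and drive the performance scores; target items
# are the quantities of interest and contribute only to informativeness.

#' Construct a quantile triple
#'
#' Three marker quantiles (5, 50 and 95 percent) describing one assessor's
#' uncertainty about one item, in the item's own units.
#'
#' @param q05,q50,q95 Numeric scalars, strictly increasing.
#' @return A named numeric vector of class `sej_triple`.
#' @export
quantile_triple <- function(q05, q50, q95) {
  x <- c(q05 = as.numeric(q05), q50 = as.numeric(q50), q95 = as.numeric(q95))
  if (anyNA(x)) stop("quantile triple contains NA")
  if (!(x[1] < x[2] && x[2] < x[3]))
    stop(sprintf("quantile triple not strictly increasing: (%g, %g, %g)",
                 x[1], x[2], x[3]))
  class(x) <- "sej_triple"
  x
}

#' Construct an elicitation panel
#'
#' @param id Panel identifier.
#' @param experts Character vector of expert ids sitting on the panel.
#' @param items Data frame with columns `item`, `kind` ("calibration" or
#'   "target"), `scale` ("uniform" or "log"), `units`, `lower`, `upper`
#'   (natural bounds, may be `NA`) and `realization` (`NA` for target items).
#' @param assessments Data frame with columns `expert`, `item`, `q05`, `q50`,
#'   `q95`; one row per (expert, item) pair, complete over the panel.
#' @param hazard,region Free-text descriptors of the panel's subject.
#' @return An object of class `sej_panel`.
#' @export
panel <- function(id, experts, items, assessments,
                  hazard = "", region = "") {
  stopifnot(is.character(experts), is.data.frame(items),
            is.data.frame(assessments))
  need_i <- c("item", "kind", "scale", "units", "lower", "upper", "realization")
  miss <- setdiff(need_i, names(items))
  if (length(miss)) stop("items missing columns: ", paste(miss, collapse = ", "))
  need_a <- c("expert", "item", "q05", "q50", "q95")
  miss <- setdiff(need_a, names(assessments))
  if (length(miss)) stop("assessments missing columns: ", paste(miss, collapse = ", "))
  items <- items[, need_i]
  assessments <- assessments[, need_a]
  rownames(items) <- NULL
  rownames(assessments) <- NULL
  structure(
    list(id = as.character(id), hazard = hazard, region = region,
         experts = experts, items = items, assessments = assessments),
    class = "sej_panel")
}

#' Construct a study
#'
#' @param panels List of [panel()] objects.
#' @param experts Named character vector mapping expert id to display label;
#'   defaults to the identity map over all ids appearing in the panels.
#' @return An object of class `sej_study`.
#' @export
study <- function(panels, experts = NULL) {
  stopifnot(is.list(panels))
  ids <- vapply(panels, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate panel ids")
  names(panels) <- ids
  if (is.null(experts)) {
    all_e <- unique(unlist(lapply(panels, function(p) p$experts)))
    experts <- stats::setNames(all_e, all_e)
  }
  structure(list(panels = panels, experts = experts), class = "sej_study")
}

#' @export
print.sej_study <- function(x, ...) {
  np <- length(x$panels)
  ne <- length(x$experts)
  ni <- sum(vapply(x$panels, function(p) nrow(p$items), integer(1)))
  cat(sprintf("sej_study: %d panel(s), %d expert(s), %d item(s)\n", np, ne, ni))
  invisible(x)
}

#' Validate a study against the domain invariants
#'
#' Checks, per panel: at least one expert and one calibration item; every
#' calibration item has a realization within its bounds; every (expert, item)
#' pair has a strictly increasing quantile triple; the assessment matrix is
#' complete (incomplete panels are rejected rather than imputed, mirroring a
#' design where every panellist answers every panel item).
#'
#' @param study A `sej_study`.
#' @return Character vector of human-readable violations; empty when the
#'   study satisfies every invariant.  Never raises on a structurally parsed
#'   study.
#' @export
validate_study <- function(study) {
  out <- character(0)
  note <- function(...) out <<- c(out, sprintf(...))
  for (p in study$panels) {
    if (length(p$experts) < 1) note("panel %s: no experts", p$id)
    it <- p$items
    if (!any(it$kind == "calibration"))
      note("panel %s: no calibration items", p$id)
    for (j in seq_len(nrow(it))) {
      r <- it[j, ]
      if (r$kind == "calibration" && is.na(r$realization))
        note("panel %s item %s: calibration item without realization",
             p$id, r$item)
      if (!is.na(r$realization)) {
        if (!is.na(r$lower) && r$realization < r$lower)
          note("panel %s item %s: realization %g below lower bound %g",
               p$id, r$item, r$realization, r$lower)
        if (!is.na(r$upper) && r$realization > r$upper)
          note("panel %s item %s: realization %g above upper bound %g",
               p$id, r$item, r$realization, r$upper)
      }
    }
    a <- p$assessments
    bad <- !(a$q05 < a$q50 & a$q50 < a$q95)
    bad[is.na(bad)] <- TRUE
    for (j in which(bad))
      note("panel %s expert %s item %s: triple (%g, %g, %g) not strictly increasing",
           p$id, a$expert[j], a$item[j], a$q05[j], a$q50[j], a$q95[j])
    key <- paste(a$expert, a$item)
    if (anyDuplicated(key))
      note("panel %s: duplicate assessments for %s",
           p$id, paste(unique(key[duplicated(key)]), collapse = "; "))
    want <- as.vector(outer(p$experts, it$item, paste))
    missing <- setdiff(want, key)
    for (m in missing)
      note("panel %s: missing assessment for (expert item) %s", p$id, m)
    extra_e <- setdiff(unique(a$expert), p$experts)
    if (length(extra_e))
      note("panel %s: assessments by unknown expert(s) %s",
           p$id, paste(extra_e, collapse = ", "))
  }
  reg <- names(study$experts)
  if (anyDuplicated(reg))
    note("expert registry has duplicated ids: %s",
         paste(unique(reg[duplicated(reg)]), collapse = ", "))
  out
}

#' Extract one expert's triple for one item
#'
#' @param panel A `sej_panel`.
#' @param expert,item Ids.
#' @return Numeric vector `c(q05, q50, q95)`.
#' @keywords internal
get_triple <- function(panel, expert, item) {
  a <- panel$assessments
  i <- which(a$expert == expert & a$item == item)
  if (length(i) != 1)
    stop(sprintf("panel %s: no unique assessment for (%s, %s)",
                 panel$id, expert, item))
  c(q05 = a$q05[i], q50 = a$q50[i], q95 = a$q95[i])
}

#' Intrinsic-range configuration
#'
#' @param overshoot_k Fraction of the raw span added to each end of the
#'   envelope of all assessors' outer quantiles (and the realization) when
#'   forming the background support.  Default 0.10.
#' @param clip_to_bounds Clip the extended range to the item's natural bounds
#'   (e.g. `[0, 100]` for percentages) so the overshoot cannot create
#'   impossible values.  Default `TRUE`.
#' @return A list of class `sej_range_config`.
#' @export
range_config <- function(overshoot_k = 0.10, clip_to_bounds = TRUE) {
  stopifnot(is.numeric(overshoot_k), overshoot_k >= 0,
            is.logical(clip_to_bounds))
  structure(list(overshoot_k = overshoot_k, clip_to_bounds = clip_to_bounds),
            class = "sej_range_config")
}

#' Weighting configuration
#'
#' @param scheme `"equal"`, `"global"` (one weight per expert from overall
#'   accuracy x overall informativeness) or `"item"` (weights modulated per
#'   question by item-specific informativeness).
#' @param alpha Statistical-accuracy cut-off in `[0, 1]`; experts scoring
#'   below it receive zero weight.  Must be 0 for the equal scheme.
#' @param optimize If `TRUE`, `alpha` is chosen in-sample to maximise the
#'   pooled decision maker's combined score.
#' @param informativeness_item_set `"all_items"` (calibration plus target,
#'   the global-weights convention) or `"calibration_only"`.
#' @return A list of class `sej_weighting_config`.
#' @export
weighting_config <- function(scheme = c("global", "item", "equal"),
                             alpha = 0, optimize = TRUE,
                             informativeness_item_set = c("all_items",
                                                          "calibration_only")) {
  scheme <- match.arg(scheme)
  informativeness_item_set <- match.arg(informativeness_item_set)
  stopifnot(is.numeric(alpha), alpha >= 0, alpha <= 1)
  if (scheme == "equal" && alpha != 0)
    stop("alpha must be 0 for the equal-weight scheme")
  structure(list(scheme = scheme, alpha = alpha, optimize = optimize,
                 informativeness_item_set = informativeness_item_set),
            class = "sej_weighting_config")
}
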