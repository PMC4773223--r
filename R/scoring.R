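# Classical-Model performance scores for a single assessor: statistical
# accuracy (the calibration p-value), informativeness (Shannon relative
# information with respect to a uniform background on the intrinsic range),
# and their product, the combined score.

# Theoretical interquantile-bin probabilities for a 5/50/95% elicitation.
BIN_PROBS <- c(0.05, 0.45, 0.45, 0.05)

#' Intrinsic range of an item
#'
#' The support used for density reconstruction: the envelope of all
#' assessors' outer quantiles and the realization, extended by a fixed
#' overshoot fraction of the raw span on each side, then clipped to the
#' item's natural bounds.
#'
#' @param triples Numeric matrix or data frame with columns `q05`, `q50`,
#'   `q95`, one row per assessor.
#' @param realization Known value for calibration items; `NA` otherwise.
#' @param cfg A [range_config()].
#' @param bounds Length-2 numeric `c(lower, upper)`; `NA` entries mean
#'   unbounded on that side.
#' @return Numeric `c(L, U)` with `L < U`.
#' @export
intrinsic_range <- function(triples, realization = NA,
                            cfg = range_config(), bounds = c(NA, NA)) {
  triples <- as.matrix(as.data.frame(triples)[, c("q05", "q50", "q95")])
  vals <- c(triples[, "q05"], triples[, "q95"])
  if (!is.na(realization)) vals <- c(vals, realization)
  m <- min(vals); M <- max(vals)
  span <- M - m
  if (span <= 0) stop("degenerate range: all quantiles and realization coincide")
  L <- m - cfg$overshoot_k * span
  U <- M + cfg$overshoot_k * span
  if (cfg$clip_to_bounds) {
    if (!is.na(bounds[1])) L <- max(L, bounds[1])
    if (!is.na(bounds[2])) U <- min(U, bounds[2])
  }
  c(L = L, U = U)
}

#' Intrinsic ranges for every item of a panel
#'
#' @param panel A `sej_panel`.
#' @param cfg A [range_config()].
#' @return Named list, item id -> `c(L, U)`.
#' @export
panel_ranges <- function(panel, cfg = range_config()) {
  a <- panel$assessments
  out <- vector("list", nrow(panel$items))
  names(out) <- panel$items$item
  for (j in seq_len(nrow(panel$items))) {
    it <- panel$items[j, ]
    tr <- a[a$item == it$item, c("q05", "q50", "q95")]
    out[[j]] <- intrinsic_range(tr, realization = it$realization, cfg = cfg,
                                bounds = c(it$lower, it$upper))
  }
  out
}

#' Assign a realization to an interquantile bin
#'
#' Fixed tie convention (chosen for determinism): `r < q05` is bin 1,
#' `q05 <= r < q50` bin 2, `q50 <= r < q95` bin 3, `r >= q95` bin 4.
#'
#' @param r Realization(s).
#' @param q05,q50,q95 Quantiles (recycled against `r`).
#' @return Integer bin index in 1..4.
#' @export
which_bin <- function(r, q05, q50, q95) {
  1L + (r >= q05) + (r >= q50) + (r >= q95)
}

#' Interquantile-bin counts for one expert on a panel's calibration items
#'
#' @param panel A `sej_panel`.
#' @param expert Expert id.
#' @return A list of class `sej_counts`: `counts` (length-4 integer), `N`,
#'   `p` (theoretical bin probabilities), `s` (empirical distribution
#'   `counts / N`).
#' @export
bin_counts <- function(panel, expert) {
  it <- panel$items[panel$items$kind == "calibration", ]
  if (nrow(it) == 0) stop(sprintf("panel %s: no calibration items", panel$id))
  a <- panel$assessments
  a <- a[a$expert == expert & a$item %in% it$item, ]
  a <- a[match(it$item, a$item), ]
  if (anyNA(a$q05)) stop(sprintf("panel %s: incomplete assessments for %s",
                                 panel$id, expert))
  bins <- which_bin(it$realization, a$q05, a$q50, a$q95)
  calibration_counts(tabulate(bins, nbins = 4L))
}

#' Build a calibration-counts record from raw bin counts
#'
#' @param counts Length-4 non-negative integer vector (bins: below q05,
#'   between q05 and q50, between q50 and q95, at or above q95).
#' @return A list of class `sej_counts` (see [bin_counts()]).
#' @export
calibration_counts <- function(counts) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 4, all(counts >= 0))
  N <- sum(counts)
  if (N < 1) stop("no calibration items")
  structure(list(counts = counts, N = N, p = BIN_PROBS, s = counts / N),
            class = "sej_counts")
}

#' Discrete Shannon relative information
#'
#' \eqn{I(s; p) = \sum_i s_i \log(s_i / p_i)} with the convention
#' \eqn{0 \log 0 = 0}.  Non-negative; zero iff `s == p`.
#'
#' @param s Empirical distribution (sums to 1).
#' @param p Reference distribution, strictly positive (sums to 1).
#' @return Non-negative scalar (nats).
#' @export
relative_information_discrete <- function(s, p) {
  stopifnot(length(s) == length(p))
  if (any(p <= 0)) stop("reference distribution must be strictly positive")
  if (abs(sum(s) - 1) > 1e-9 || abs(sum(p) - 1) > 1e-9)
    stop("distributions must sum to 1")
  i <- s > 0
  sum(s[i] * log(s[i] / p[i]))
}

#' Statistical accuracy (calibration score)
#'
#' The p-value at which one would falsely reject the hypothesis that the
#' assessor's probability statements are statistically accurate: the
#' likelihood-ratio statistic \eqn{2 N I(s; p)} referred to a chi-square
#' distribution with 3 degrees of freedom (four bins, three free
#' proportions).  Equals 1 when the empirical bin distribution matches
#' (0.05, 0.45, 0.45, 0.05) exactly and decreases strictly in the statistic.
#'
#' @param counts A `sej_counts` record ([bin_counts()] /
#'   [calibration_counts()]).
#' @return Scalar in (0, 1].
#' @export
statistical_accuracy <- function(counts) {
  stopifnot(inherits(counts, "sej_counts"))
  stat <- 2 * counts$N * relative_information_discrete(counts$s, counts$p)
  stats::pchisq(stat, df = 3, lower.tail = FALSE)
}

#' Shannon relative information of one assessment against a uniform
#' background
#'
#' For the minimally-informative density consistent with the stated triple
#' on the intrinsic range `[L, U]` (masses 0.05/0.45/0.45/0.05 on the four
#' intervals), relative information against the uniform background reduces
#' to \eqn{\sum_i p_i \log(p_i / r_i)} where \eqn{r_i} is the interval width
#' divided by `U - L`.  Non-negative; zero iff widths are proportional to
#' the bin probabilities; invariant under joint affine rescaling of triple
#' and range.
#'
#' @param triple Numeric `c(q05, q50, q95)`.
#' @param range Numeric `c(L, U)` from [intrinsic_range()].
#' @return Non-negative scalar (nats).
#' @export
information_per_item <- function(triple, range) {
  L <- range[[1]]; U <- range[[2]]
  q <- as.numeric(triple)
  if (!(L <= q[1] && q[3] <= U))
    stop("triple outside intrinsic range")
  w <- diff(c(L, q, U))
  if (any(w <= 0)) stop("zero-width interval with positive mass")
  r <- w / (U - L)
  sum(BIN_PROBS * log(BIN_PROBS / r))
}

#' Overall informativeness of one expert on a panel
#'
#' Arithmetic mean of [information_per_item()] over the selected item set.
#'
#' @param panel A `sej_panel`.
#' @param expert Expert id.
#' @param ranges Named list of intrinsic ranges ([panel_ranges()]).
#' @param item_set `"all_items"` (default, the global-weights convention:
#'   calibration and target items) or `"calibration_only"`.
#' @return Non-negative scalar.
#' @export
informativeness <- function(panel, expert, ranges,
                            item_set = c("all_items", "calibration_only")) {
  item_set <- match.arg(item_set)
  it <- panel$items
  if (item_set == "calibration_only") it <- it[it$kind == "calibration", ]
  if (nrow(it) == 0) stop("empty item selection")
  vals <- vapply(it$item, function(id) {
    information_per_item(get_triple(panel, expert, id), ranges[[id]])
  }, numeric(1))
  mean(vals)
}

#' Per-item informativeness of one expert (for item weights)
#'
#' @inheritParams informativeness
#' @return Named numeric vector, one value per panel item.
#' @export
informativeness_by_item <- function(panel, expert, ranges) {
  vapply(panel$items$item, function(id) {
    information_per_item(get_triple(panel, expert, id), ranges[[id]])
  }, numeric(1))
}

#' Combined score
#'
#' The product of statistical accuracy and informativeness; proportional to
#' the assessor's performance-based weight.
#'
#' @param accuracy Scalar in (0, 1].
#' @param informativeness Non-negative scalar.
#' @return Non-negative scalar.
#' @export
combined_score <- function(accuracy, informativeness) {
  stopifnot(accuracy > 0, accuracy <= 1, informativeness >= 0)
  accuracy * informativeness
}

#' Score every expert on a panel
#'
#' @param panel A `sej_panel`.
#' @param ranges Intrinsic ranges; computed from `range_cfg` when `NULL`.
#' @param item_set Informativeness item set (see [informativeness()]).
#' @param range_cfg A [range_config()].
#' @return Data frame: `assessor`, `kind` ("expert"), `statistical_accuracy`,
#'   `informativeness`, `combined`.
#' @export
score_experts <- function(panel, ranges = NULL,
                          item_set = "all_items",
                          range_cfg = range_config()) {
  if (is.null(ranges)) ranges <- panel_ranges(panel, range_cfg)
  acc <- vapply(panel$experts, function(e)
    statistical_accuracy(bin_counts(panel, e)), numeric(1))
  inf <- vapply(panel$experts, function(e)
    informativeness(panel, e, ranges, item_set), numeric(1))
  data.frame(assessor = panel$experts, kind = "expert",
             statistical_accuracy = unname(acc),
             informativeness = unname(inf),
             combined = unname(acc * inf),
             row.names = NULL, stringsAsFactors = FALSE)
}
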