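# Pooling: reconstruct each expert's minimally-informative density from the
# stated quantiles, mix the densities with equal or performance-based
# weights, extract the pooled decision maker's (DM) quantiles exactly by
# inverting the piecewise-linear CDF, and score the DM with the same rules
# as an expert.  The accuracy cut-off alpha is optimised in-sample over the
# exhaustive candidate set of observed accuracy values.

#' Piecewise-uniform density
#'
#' @param breakpoints Strictly increasing numeric vector (length k + 1).
#' @param masses Non-negative numeric vector of length k summing to 1.
#' @return An object of class `sej_density`.
#' @export
piecewise_uniform <- function(breakpoints, masses) {
  stopifnot(length(breakpoints) == length(masses) + 1)
  if (any(diff(breakpoints) <= 0)) stop("breakpoints not strictly increasing")
  if (any(masses < 0)) stop("negative mass")
  if (abs(sum(masses) - 1) > 1e-9) stop("masses must sum to 1")
  structure(list(breakpoints = as.numeric(breakpoints),
                 masses = as.numeric(masses)),
            class = "sej_density")
}

#' Reconstruct an expert's density from a quantile triple
#'
#' The minimally-informative distribution consistent with the stated
#' quantiles on the intrinsic range: masses (0.05, 0.45, 0.45, 0.05) on the
#' intervals (L, q05), (q05, q50), (q50, q95), (q95, U), uniform within
#' each.
#'
#' @param triple Numeric `c(q05, q50, q95)`.
#' @param range Numeric `c(L, U)`.
#' @return A `sej_density`.
#' @export
expert_density <- function(triple, range) {
  b <- c(range[[1]], as.numeric(triple), range[[2]])
  if (any(diff(b) <= 0)) stop("zero-width interval with positive mass")
  piecewise_uniform(b, BIN_PROBS)
}

#' CDF of a piecewise-uniform density
#'
#' @param d A `sej_density`.
#' @param x Evaluation points (clamped to the support).
#' @return CDF values in `[0, 1]`.
#' @export
density_cdf <- function(d, x) {
  stats::approx(d$breakpoints, c(0, cumsum(d$masses)), xout = x,
                rule = 2, ties = "ordered")$y
}

#' Finite mixture of piecewise-uniform densities
#'
#' The mixture is represented on the union grid of all component
#' breakpoints; its CDF equals the weighted average of the component CDFs
#' at every point.
#'
#' @param components List of `sej_density` objects on a common support.
#' @param weights Non-negative weights summing to 1 (tolerance 1e-9).
#' @return A `sej_density`.
#' @export
mixture_density <- function(components, weights) {
  stopifnot(length(components) == length(weights))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(weights < 0)) stop("negative weight")
  keep <- weights > 0
  components <- components[keep]
  weights <- weights[keep]
  grid <- sort(unique(unlist(lapply(components, `[[`, "breakpoints"))))
  cdf <- numeric(length(grid))
  for (i in seq_along(components))
    cdf <- cdf + weights[i] * density_cdf(components[[i]], grid)
  # guard against accumulated rounding at the right end
  cdf[length(cdf)] <- 1
  piecewise_uniform(grid, pmax(diff(cdf), 0) / sum(pmax(diff(cdf), 0)))
}

#' Quantiles of a piecewise-uniform density
#'
#' Exact inversion of the piecewise-linear CDF (no sampling), so pooled
#' decision makers are deterministic.
#'
#' @param d A `sej_density`.
#' @param probs Probabilities; default the 5/50/95% markers.
#' @return Numeric vector of quantiles, strictly increasing for strictly
#'   increasing `probs` when the density is positive on its support.
#' @export
dm_quantiles <- function(d, probs = c(0.05, 0.50, 0.95)) {
  stopifnot(all(probs >= 0 & probs <= 1))
  cum <- c(0, cumsum(d$masses))
  cum[length(cum)] <- 1
  b <- d$breakpoints
  vapply(probs, function(p) {
    i <- findInterval(p, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(b) - 1L)
    m <- cum[i + 1] - cum[i]
    if (m <= 0) return(b[i])
    b[i] + (p - cum[i]) / m * (b[i + 1] - b[i])
  }, numeric(1))
}

#' Performance-based weights
#'
#' Global scheme: expert weight proportional to
#' `1{accuracy >= alpha} * accuracy * informativeness`, normalised over the
#' panel.  Item scheme: per-item weights proportional to
#' `1{accuracy >= alpha} * accuracy * item informativeness`, normalised per
#' item.
#'
#' @param scores Data frame from [score_experts()] (columns `assessor`,
#'   `statistical_accuracy`, `informativeness`).
#' @param alpha Accuracy cut-off.
#' @param scheme `"global"` or `"item"`.
#' @param info_by_item For the item scheme: matrix of per-item
#'   informativeness, experts in rows (rownames = assessor ids), items in
#'   columns.
#' @return Global: named numeric vector summing to 1.  Item: matrix with the
#'   same shape as `info_by_item`, each column summing to 1.
#' @export
performance_weights <- function(scores, alpha, scheme = c("global", "item"),
                                info_by_item = NULL) {
  scheme <- match.arg(scheme)
  acc <- scores$statistical_accuracy
  pass <- acc >= alpha
  if (!any(pass)) stop("empty weight support: all experts below alpha")
  if (scheme == "global") {
    w <- ifelse(pass, acc * scores$informativeness, 0)
    if (sum(w) <= 0) stop("empty weight support: all passing weights zero")
    stats::setNames(w / sum(w), scores$assessor)
  } else {
    if (is.null(info_by_item)) stop("item scheme requires info_by_item")
    info_by_item <- info_by_item[scores$assessor, , drop = FALSE]
    w <- ifelse(pass, acc, 0) * info_by_item
    cs <- colSums(w)
    if (any(cs <= 0)) stop("empty weight support on some item")
    sweep(w, 2, cs, "/")
  }
}

#' Score a set of DM quantile triples like an expert
#'
#' Identical scoring path as for experts: interquantile-bin counts of the
#' realizations against the DM's triples give the accuracy p-value;
#' informativeness uses the same intrinsic ranges as the experts (the DM
#' does not extend them).
#'
#' @param dm_triples Data frame with columns `item`, `q05`, `q50`, `q95`.
#' @param panel A `sej_panel`.
#' @param ranges Intrinsic ranges from [panel_ranges()].
#' @param label Assessor label for the returned row (e.g. `"ew"`).
#' @param item_set Informativeness item set.
#' @return One-row data frame matching [score_experts()] output.
#' @export
score_dm <- function(dm_triples, panel, ranges, label,
                     item_set = "all_items") {
  cal <- panel$items[panel$items$kind == "calibration", ]
  q <- dm_triples[match(cal$item, dm_triples$item), ]
  bins <- which_bin(cal$realization, q$q05, q$q50, q$q95)
  acc <- statistical_accuracy(calibration_counts(tabulate(bins, nbins = 4L)))
  sel <- panel$items
  if (item_set == "calibration_only") sel <- cal
  inf <- mean(vapply(sel$item, function(id) {
    r <- dm_triples[dm_triples$item == id, ]
    information_per_item(c(r$q05, r$q50, r$q95), ranges[[id]])
  }, numeric(1)))
  data.frame(assessor = label, kind = label,
             statistical_accuracy = acc, informativeness = inf,
             combined = acc * inf, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Build the DM densities and quantile triples for given weights.
# weights: named vector (global) or experts x items matrix (item scheme).
build_dm <- function(panel, ranges, weights, label, alpha,
                     item_set = "all_items") {
  items <- panel$items$item
  dens <- vector("list", length(items))
  names(dens) <- items
  qs <- matrix(NA_real_, length(items), 3,
               dimnames = list(items, c("q05", "q50", "q95")))
  per_item <- is.matrix(weights)
  for (id in items) {
    w <- if (per_item) weights[, id] else weights
    comp <- lapply(panel$experts[w > 0], function(e)
      expert_density(get_triple(panel, e, id), ranges[[id]]))
    d <- mixture_density(comp, w[w > 0])
    dens[[id]] <- d
    qs[id, ] <- dm_quantiles(d)
  }
  triples <- data.frame(item = items, q05 = qs[, 1], q50 = qs[, 2],
                        q95 = qs[, 3], row.names = NULL,
                        stringsAsFactors = FALSE)
  score <- score_dm(triples, panel, ranges, label, item_set)
  structure(list(label = label, alpha = alpha, weights = weights,
                 quantiles = triples, densities = dens, score = score),
            class = "sej_dm")
}

#' @export
print.sej_dm <- function(x, ...) {
  cat(sprintf("sej_dm '%s' (alpha = %g): accuracy %.4g, informativeness %.4g, combined %.4g\n",
              x$label, x$alpha, x$score$statistical_accuracy,
              x$score$informativeness, x$score$combined))
  invisible(x)
}

#' Equal-weight decision maker
#'
#' Averages the experts' reconstructed densities item by item with weights
#' `1/E`, then scores the pooled DM in-sample on the panel's calibration
#' items with the same rules as the experts.
#'
#' @param panel A `sej_panel`.
#' @param ranges Intrinsic ranges; computed with `range_cfg` when `NULL`.
#' @param item_set Informativeness item set for the DM's score.
#' @param range_cfg A [range_config()].
#' @return A `sej_dm`.
#' @export
equal_weight_dm <- function(panel, ranges = NULL, item_set = "all_items",
                            range_cfg = range_config()) {
  if (is.null(ranges)) ranges <- panel_ranges(panel, range_cfg)
  E <- length(panel$experts)
  w <- stats::setNames(rep(1 / E, E), panel$experts)
  build_dm(panel, ranges, w, "ew", alpha = 0, item_set = item_set)
}

#' Performance-weighted decision maker with in-sample threshold
#' optimisation
#'
#' Candidate cut-offs are 0 together with the distinct observed expert
#' accuracy values (a finer grid cannot change any DM's support).  For each
#' candidate the DM is built and scored in-sample; the DM with maximal
#' combined score is returned, ties broken toward the smallest alpha
#' (widest support).  With `optimize = FALSE` in `cfg` the DM at
#' `cfg$alpha` is returned directly.
#'
#' @param panel A `sej_panel`.
#' @param cfg A [weighting_config()] with scheme `"global"` or `"item"`.
#' @param ranges Intrinsic ranges; computed with `range_cfg` when `NULL`.
#' @param range_cfg A [range_config()].
#' @return A `sej_dm` with an `$optimization` data frame (candidate alpha
#'   and in-sample combined score) attached when optimisation ran.
#' @export
performance_weight_dm <- function(panel, cfg = weighting_config("global"),
                                  ranges = NULL,
                                  range_cfg = range_config()) {
  stopifnot(cfg$scheme %in% c("global", "item"))
  if (is.null(ranges)) ranges <- panel_ranges(panel, range_cfg)
  item_set <- cfg$informativeness_item_set
  label <- if (cfg$scheme == "global") "pwg" else "pwi"
  scores <- score_experts(panel, ranges, item_set)
  ibi <- NULL
  if (cfg$scheme == "item") {
    ibi <- t(vapply(panel$experts, function(e)
      informativeness_by_item(panel, e, ranges),
      numeric(nrow(panel$items))))
    rownames(ibi) <- panel$experts
    colnames(ibi) <- panel$items$item
  }
  one <- function(alpha) {
    w <- performance_weights(scores, alpha, cfg$scheme, ibi)
    build_dm(panel, ranges, w, label, alpha, item_set)
  }
  if (!cfg$optimize) return(one(cfg$alpha))
  cand <- sort(unique(c(0, scores$statistical_accuracy)))
  best <- NULL
  trace <- data.frame(alpha = cand, combined = NA_real_)
  for (i in seq_along(cand)) {
    dm <- one(cand[i])
    trace$combined[i] <- dm$score$combined
    if (is.null(best) || dm$score$combined > best$score$combined) best <- dm
  }
  best$optimization <- trace
  best
}

#' Score experts and all decision makers for one panel
#'
#' @param panel A `sej_panel`.
#' @param schemes DM labels to compute, subset of `c("ew", "pwg", "pwi")`.
#' @param item_set Informativeness item set.
#' @param range_cfg A [range_config()].
#' @param optimize Optimise the accuracy cut-off for the performance
#'   schemes.
#' @return List with `scores` (data frame: expert rows then DM rows, with a
#'   leading `panel` column) and `dms` (named list of `sej_dm`).
#' @export
score_panel <- function(panel, schemes = c("ew", "pwg", "pwi"),
                        item_set = "all_items",
                        range_cfg = range_config(), optimize = TRUE) {
  ranges <- panel_ranges(panel, range_cfg)
  rows <- score_experts(panel, ranges, item_set)
  dms <- list()
  for (s in schemes) {
    dm <- switch(s,
      ew  = equal_weight_dm(panel, ranges, item_set),
      pwg = performance_weight_dm(panel,
              weighting_config("global", optimize = optimize,
                               informativeness_item_set = item_set), ranges),
      pwi = performance_weight_dm(panel,
              weighting_config("item", optimize = optimize,
                               informativeness_item_set = item_set), ranges),
      stop("unknown scheme: ", s))
    dms[[s]] <- dm
    rows <- rbind(rows, dm$score)
  }
  rows <- cbind(panel = panel$id, rows, stringsAsFactors = FALSE)
  list(scores = rows, dms = dms)
}

#' Score a whole study
#'
#' Runs [score_panel()] over every panel and stacks the results into a
#' score table (one row per panel x assessor, assessors being the experts
#' and the requested DMs).
#'
#' @inheritParams score_panel
#' @param study A `sej_study`.
#' @return Data frame of class `sej_score_table`.
#' @export
score_study <- function(study, schemes = c("ew", "pwg", "pwi"),
                        item_set = "all_items",
                        range_cfg = range_config(), optimize = TRUE) {
  out <- do.call(rbind, lapply(study$panels, function(p)
    score_panel(p, schemes, item_set, range_cfg, optimize)$scores))
  rownames(out) <- NULL
  class(out) <- c("sej_score_table", "data.frame")
  out
}
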