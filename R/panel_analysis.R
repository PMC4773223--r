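# Cross-panel evaluation analytics: distinct-membership panel selection,
# performance-weight vs equal-weight comparison, expert-level score pooling,
# and the informativeness/accuracy rank-correlation structure (overall and
# running, with a permutation p-value for the directional test).

#' Panels with distinct expert membership
#'
#' Panels sharing an identical set of experts are represented once (the
#' first panel in id order); this is the unit for cross-panel comparisons,
#' since panels with the same membership produce strongly dependent pooled
#' solutions.
#'
#' @param x A `sej_study` or a score table (data frame with `panel`,
#'   `assessor`, `kind` columns, expert rows defining the membership).
#' @return Character vector of representative panel ids.
#' @export
distinct_panels <- function(x) {
  if (inherits(x, "sej_study")) {
    ids <- names(x$panels)
    sets <- lapply(x$panels, function(p) sort(unique(p$experts)))
  } else {
    stopifnot(is.data.frame(x))
    e <- x[x$kind == "expert", ]
    ids <- unique(x$panel)
    sets <- lapply(ids, function(pid)
      sort(unique(e$assessor[e$panel == pid])))
  }
  key <- vapply(sets, paste, character(1), collapse = "\r")
  ids[!duplicated(key)]
}

#' Spearman rank correlation with a one-sided permutation p-value
#'
#' Rho uses average ranks for ties.  The p-value tests the directional
#' hypothesis of negative association: the probability, under random
#' pairing, of a rank correlation at or below the observed one, estimated
#' by a seeded permutation test (with the `+1` small-sample correction).
#' With `n_perm = 0` a t-approximation is used instead.
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @param n_perm Number of permutations (default 100000).
#' @param seed Permutation seed (default 20160301).
#' @return List with elements `rho` and `p_one_sided`.
#' @export
spearman_rho <- function(x, y, n_perm = 1e5, seed = 20160301) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n_perm > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2)) * stats::sd(ry) * sqrt(n - 1)
    hits <- 0L
    done <- 0L
    chunk <- 2000L
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      perm <- matrix(ry[vapply(seq_len(b), function(i) sample.int(n),
                               integer(n))], nrow = n)
      rho_b <- colSums(rxc * (perm - mean(ry))) / denom
      hits <- hits + sum(rho_b <= rho)
      done <- done + b
    }
    p <- (1 + hits) / (n_perm + 1)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- stats::pt(tt, df = n - 2)
  }
  list(rho = rho, p_one_sided = p)
}

#' Running rank correlation between informativeness and accuracy
#'
#' Assessors are ordered by increasing statistical accuracy (ties broken by
#' id); for each starting index k the Spearman correlation between
#' informativeness and accuracy is recomputed over assessors k..n.  Windows
#' of fewer than 3 assessors are omitted.  An attenuation of the (negative)
#' correlation toward zero as k grows indicates that the least accurate
#' assessors drive the association.
#'
#' @param scores Data frame with columns `assessor`,
#'   `statistical_accuracy`, `informativeness` (one row per assessor).
#' @return Data frame with columns `k` and `rho`.
#' @export
running_rank_correlation <- function(scores) {
  n <- nrow(scores)
  if (n < 4) stop("need at least 4 assessors")
  o <- order(scores$statistical_accuracy, scores$assessor)
  acc <- scores$statistical_accuracy[o]
  inf <- scores$informativeness[o]
  ks <- seq_len(n - 2)
  rho <- vapply(ks, function(k)
    stats::cor(rank(acc[k:n]), rank(inf[k:n])), numeric(1))
  data.frame(k = ks, rho = rho)
}

#' Expert-level overall scores across panels
#'
#' An expert sitting on several panels gets one overall score.  With
#' `method = "pooled"` (default) their calibration items are pooled across
#' panels into a single set of bin counts and their informativeness is the
#' mean over all their items on all their panels; with `method = "average"`
#' their per-panel scores are averaged.
#'
#' @param study A `sej_study`.
#' @param method `"pooled"` or `"average"`.
#' @param item_set Informativeness item set.
#' @param range_cfg A [range_config()].
#' @return Data frame: `assessor`, `statistical_accuracy`,
#'   `informativeness`, `combined`.
#' @export
expert_overall_scores <- function(study, method = c("pooled", "average"),
                                  item_set = "all_items",
                                  range_cfg = range_config()) {
  method <- match.arg(method)
  experts <- sort(unique(unlist(lapply(study$panels, `[[`, "experts"))))
  ranges <- lapply(study$panels, panel_ranges, cfg = range_cfg)
  rows <- lapply(experts, function(e) {
    on_panels <- Filter(function(p) e %in% p$experts, study$panels)
    if (method == "pooled") {
      cnt <- Reduce(`+`, lapply(on_panels, function(p) bin_counts(p, e)$counts))
      acc <- statistical_accuracy(calibration_counts(cnt))
      infs <- unlist(lapply(on_panels, function(p) {
        it <- p$items
        if (item_set == "calibration_only") it <- it[it$kind == "calibration", ]
        vapply(it$item, function(id)
          information_per_item(get_triple(p, e, id), ranges[[p$id]][[id]]),
          numeric(1))
      }))
      inf <- mean(infs)
    } else {
      per <- vapply(on_panels, function(p) c(
        statistical_accuracy(bin_counts(p, e)),
        informativeness(p, e, ranges[[p$id]], item_set)), numeric(2))
      acc <- mean(per[1, ]); inf <- mean(per[2, ])
    }
    data.frame(assessor = e, statistical_accuracy = acc,
               informativeness = inf, combined = acc * inf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expert-level scores from a score table
#'
#' With only per-panel scores available (no raw elicitations), an expert's
#' overall score is the mean of their per-panel accuracy and
#' informativeness.
#'
#' @param table Score table data frame (`panel`, `assessor`, `kind`,
#'   `statistical_accuracy`, `informativeness`).
#' @return Data frame: `assessor`, `statistical_accuracy`,
#'   `informativeness`, `combined` (one row per distinct expert).
#' @export
expert_scores_from_table <- function(table) {
  e <- table[table$kind == "expert", ]
  acc <- tapply(e$statistical_accuracy, e$assessor, mean)
  inf <- tapply(e$informativeness, e$assessor, mean)
  out <- data.frame(assessor = names(acc),
                    statistical_accuracy = as.numeric(acc),
                    informativeness = as.numeric(inf[names(acc)]),
                    stringsAsFactors = FALSE)
  out$combined <- out$statistical_accuracy * out$informativeness
  rownames(out) <- NULL
  out[order(out$assessor), , drop = FALSE]
}

#' Performance-weight versus equal-weight summary
#'
#' Headline comparison over a set of panels: how often the
#' performance-weighted DM beats the equal-weight DM on combined score, how
#' much informativeness equal weighting gives up, and how accurate the
#' pooled solutions remain.
#'
#' @param table Score table data frame.
#' @param panels Panel ids to summarise; default the distinct-membership
#'   subset of `table`.
#' @param pw_label Which performance DM to compare (default `"pwg"`).
#' @param acc_threshold Accuracy threshold for the low-accuracy panel count
#'   (default 0.045).
#' @param expert_acc_level Accuracy level for the expert count (default
#'   0.05).
#' @return List: `n_panels`, `pw_win_pct` (share of panels where the PW
#'   DM's combined score strictly exceeds the EW DM's, in percent),
#'   `mean_ew_informativeness`, `mean_pw_informativeness`,
#'   `mean_expert_informativeness` (over expert rows on the selected
#'   panels), `n_panels_pw_acc_below` (PW accuracy below `acc_threshold`),
#'   `pct_ew_inf_below_0.5`, `n_experts` and `n_experts_acc_above` (distinct
#'   experts whose overall accuracy, per [expert_scores_from_table()],
#'   exceeds `expert_acc_level`), `mean_panel_size`.
#' @export
pw_vs_ew_summary <- function(table, panels = NULL, pw_label = "pwg",
                             acc_threshold = 0.045,
                             expert_acc_level = 0.05) {
  if (is.null(panels)) panels <- distinct_panels(table)
  t_sub <- table[table$panel %in% panels, ]
  pick <- function(kind) {
    r <- t_sub[t_sub$kind == kind, ]
    miss <- setdiff(panels, r$panel)
    if (length(miss))
      stop(sprintf("missing '%s' rows for panel(s): %s", kind,
                   paste(miss, collapse = ", ")))
    r[match(panels, r$panel), ]
  }
  pw <- pick(pw_label)
  ew <- pick("ew")
  ex <- t_sub[t_sub$kind == "expert", ]
  overall <- expert_scores_from_table(table)
  sizes <- tapply(ex$assessor, ex$panel, function(a) length(unique(a)))
  list(
    n_panels = length(panels),
    pw_win_pct = 100 * mean(pw$combined > ew$combined),
    mean_ew_informativeness = mean(ew$informativeness),
    mean_pw_informativeness = mean(pw$informativeness),
    mean_expert_informativeness = mean(ex$informativeness),
    n_panels_pw_acc_below = sum(pw$statistical_accuracy < acc_threshold),
    pct_ew_inf_below_0.5 = 100 * mean(ew$informativeness < 0.5),
    n_experts = nrow(overall),
    n_experts_acc_above = sum(overall$statistical_accuracy > expert_acc_level),
    mean_panel_size = mean(as.numeric(sizes))
  )
}

#' Expected false rejections among independent accurate panels
#'
#' If `n_panels` statistically accurate panels were independent, the number
#' of accuracy p-values expected below `level` is `n_panels * level`,
#' rounded to the nearest integer (halves away from zero).
#'
#' @param n_panels Positive integer.
#' @param level Significance level in (0, 1).
#' @return Integer count.
#' @export
expected_false_rejections <- function(n_panels, level = 0.05) {
  stopifnot(n_panels >= 1, level > 0, level < 1)
  as.integer(floor(n_panels * level + 0.5))
}
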