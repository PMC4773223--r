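# Small in-code fixtures used across the suite.

# A tiny valid panel: `E` experts, `n_cal` calibration items (+ optional
# targets), hand-set triples unless `assessments` given.
make_items <- function(n_cal, n_target = 0, realizations = NULL,
                       lower = NA, upper = NA) {
  n <- n_cal + n_target
  if (is.null(realizations)) realizations <- seq(2, length.out = n_cal)
  data.frame(
    item = sprintf("i%02d", seq_len(n)),
    kind = c(rep("calibration", n_cal), rep("target", n_target)),
    scale = "uniform", units = "u",
    lower = lower, upper = upper,
    realization = c(realizations, rep(NA_real_, n_target)),
    stringsAsFactors = FALSE)
}

make_assessments <- function(experts, items, triple_fun) {
  do.call(rbind, lapply(experts, function(e) {
    do.call(rbind, lapply(seq_along(items), function(j) {
      q <- triple_fun(e, j)
      data.frame(expert = e, item = items[j], q05 = q[1], q50 = q[2],
                 q95 = q[3], stringsAsFactors = FALSE)
    }))
  }))
}

tiny_panel <- function(E = 2, n_cal = 2, n_target = 0,
                       triple_fun = function(e, j) c(1, 2, 3) * j,
                       realizations = NULL, lower = NA, upper = NA,
                       id = "pA") {
  items <- make_items(n_cal, n_target, realizations, lower, upper)
  experts <- sprintf("e%02d", seq_len(E))
  panel(id, experts, items,
        make_assessments(experts, items$item, triple_fun))
}

# A random valid panel for property-style tests (call under a set seed).
random_panel <- function(E = 4, n_cal = 6, n_target = 2, id = "pR") {
  items <- make_items(n_cal, n_target,
                      realizations = runif(n_cal, 0, 10))
  experts <- sprintf("e%02d", seq_len(E))
  tf <- function(e, j) {
    m <- runif(1, 0, 10); w1 <- runif(1, 0.1, 2); w2 <- runif(1, 0.1, 2)
    c(m - w1, m, m + w2)
  }
  panel(id, experts, items, make_assessments(experts, items$item, tf))
}

# Independent chi-square(3 df) upper-tail oracle (closed form), used to
# cross-check the accuracy p-value.
chisq3_upper <- function(x) {
  2 * (1 - pnorm(sqrt(x))) + sqrt(2 * x / pi) * exp(-x / 2)
}

# Independent numerical CDF of a weighted mixture of expert densities,
# evaluated pointwise from first principles (per-expert piecewise-linear
# CDF written out directly).
oracle_expert_cdf <- function(triple, range, x) {
  b <- c(range[1], triple, range[2])
  p <- c(0, 0.05, 0.5, 0.95, 1)
  sapply(x, function(v) {
    if (v <= b[1]) return(0)
    if (v >= b[5]) return(1)
    i <- max(which(b <= v))
    p[i] + (p[i + 1] - p[i]) * (v - b[i]) / (b[i + 1] - b[i])
  })
}
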