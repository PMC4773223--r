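test_that("expert density places the canonical masses and CDF markers", {
  d <- expert_density(c(0.05, 0.5, 0.95), c(0, 1))
  expect_equal(d$breakpoints, c(0, 0.05, 0.5, 0.95, 1))
  expect_equal(d$masses, c(0.05, 0.45, 0.45, 0.05))
  # uniform density on [0,1]: CDF is the identity
  expect_equal(density_cdf(d, c(0.2, 0.7)), c(0.2, 0.7))
  set.seed(5)
  for (i in 1:20) {
    q <- sort(runif(3, 1, 9))
    d <- expert_density(q, c(0, 10))
    expect_equal(density_cdf(d, q[2]), 0.5)
    expect_equal(density_cdf(d, q[3]), 0.95)
    expect_equal(density_cdf(d, q[1]), 0.05)
  }
  expect_error(expert_density(c(0, 0.5, 0.95), c(0, 1)), "zero-width")
})

test_that("mixtures average component CDFs exactly", {
  d1 <- expert_density(c(1, 2, 3), c(0, 10))
  d2 <- expert_density(c(5, 7, 9), c(0, 10))
  # identical components: mixture is that component
  m0 <- mixture_density(list(d1, d1), c(0.3, 0.7))
  expect_equal(density_cdf(m0, seq(0, 10, 0.1)),
               density_cdf(d1, seq(0, 10, 0.1)))
  # degenerate weights pick out one component
  m1 <- mixture_density(list(d1, d2), c(1, 0))
  expect_equal(density_cdf(m1, seq(0, 10, 0.05)),
               density_cdf(d1, seq(0, 10, 0.05)))
  # 50/50 mixture vs independent pointwise CDF oracle on 1000 grid points
  m <- mixture_density(list(d1, d2), c(0.5, 0.5))
  x <- seq(0, 10, length.out = 1000)
  oracle <- 0.5 * oracle_expert_cdf(c(1, 2, 3), c(0, 10), x) +
            0.5 * oracle_expert_cdf(c(5, 7, 9), c(0, 10), x)
  expect_lt(max(abs(density_cdf(m, x) - oracle)), 1e-10)
  expect_error(mixture_density(list(d1, d2), c(0.5, 0.6)), "sum to 1")
})

test_that("mixture CDF equals the weighted average at random points", {
  set.seed(9)
  for (i in 1:10) {
    qs <- lapply(1:5, function(.) sort(runif(3, 1, 9)))
    ds <- lapply(qs, expert_density, range = c(0, 10))
    w <- runif(5); w <- w / sum(w)
    m <- mixture_density(ds, w)
    x <- runif(200, 0, 10)
    oracle <- Reduce(`+`, Map(function(q, wi)
      wi * oracle_expert_cdf(q, c(0, 10), x), qs, w))
    expect_lt(max(abs(density_cdf(m, x) - oracle)), 1e-10)
  }
})

test_that("quantile extraction inverts the CDF exactly", {
  u <- piecewise_uniform(c(0, 1), 1)
  expect_equal(dm_quantiles(u), c(0.05, 0.5, 0.95))
  # single-expert density returns the original triple
  set.seed(13)
  for (i in 1:25) {
    q <- sort(runif(3, 1, 9))
    expect_equal(dm_quantiles(expert_density(q, c(0, 10))), q,
                 tolerance = 1e-12)
  }
  # mixture quantiles match bisection on the oracle CDF to 1e-10
  d1 <- expert_density(c(1, 2, 3), c(0, 10))
  d2 <- expert_density(c(4, 6, 9), c(0, 10))
  m <- mixture_density(list(d1, d2), c(0.4, 0.6))
  oracle_cdf <- function(x)
    0.4 * oracle_expert_cdf(c(1, 2, 3), c(0, 10), x) +
    0.6 * oracle_expert_cdf(c(4, 6, 9), c(0, 10), x)
  for (p in c(0.05, 0.5, 0.95, 0.25, 0.8)) {
    lo <- 0; hi <- 10
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (oracle_cdf(mid) < p) lo <- mid else hi <- mid
    }
    expect_equal(dm_quantiles(m, p), (lo + hi) / 2, tolerance = 1e-10)
  }
})

test_that("performance weights follow the cut-off and renormalise", {
  sc <- data.frame(assessor = c("a", "b", "c"),
                   statistical_accuracy = c(0.8, 0.4, 0.02),
                   informativeness = c(1.0, 1.0, 3.0),
                   stringsAsFactors = FALSE)
  # alpha = 0: weights proportional to acc * inf (a:b = 2:1)
  w <- performance_weights(sc, 0, "global")
  expect_equal(unname(w["a"] / w["b"]), 2)
  expect_equal(sum(w), 1)
  # alpha between 2nd and 3rd accuracy: support of size 2
  w2 <- performance_weights(sc, 0.1, "global")
  expect_equal(unname(w2["c"]), 0)
  expect_equal(sum(w2), 1)
  expect_equal(unname(w2["a"] / w2["b"]), 2)
  # alpha above all but one: degenerate weight 1
  w3 <- performance_weights(sc, 0.5, "global")
  expect_equal(unname(w3), c(1, 0, 0))
  expect_error(performance_weights(sc, 0.9, "global"), "empty weight support")
  # item scheme: normalised per item with item-specific informativeness
  ibi <- matrix(c(1, 2, 1,
                  3, 1, 1), nrow = 3,
                dimnames = list(c("a", "b", "c"), c("i1", "i2")))
  wi <- performance_weights(sc, 0.1, "item", ibi)
  expect_equal(colSums(wi), c(i1 = 1, i2 = 1))
  expect_equal(unname(wi["a", "i1"] / wi["b", "i1"]), 0.8 / 0.8)
  expect_equal(unname(wi["a", "i2"] / wi["b", "i2"]),
               (0.8 * 3) / (0.4 * 1))
  expect_equal(unname(wi["c", ]), c(0, 0))
})

test_that("a panel of identical experts pools to each expert's scores", {
  p <- tiny_panel(E = 3, n_cal = 4, realizations = c(1.5, 2.5, 0.5, 3.5),
                  triple_fun = function(e, j) c(1, 2, 3))
  res <- score_panel(p, schemes = c("ew", "pwg"))
  ex <- res$scores[res$scores$kind == "expert", ]
  ew <- res$scores[res$scores$kind == "ew", ]
  expect_equal(ew$statistical_accuracy, ex$statistical_accuracy[1])
  expect_equal(ew$informativeness, ex$informativeness[1])
  # identical experts: optimiser ties resolve to alpha = 0, PW DM = EW DM
  expect_equal(res$dms$pwg$alpha, 0)
  expect_equal(res$dms$pwg$score$combined, ew$combined)
})

test_that("DM with a single surviving expert reproduces that expert", {
  set.seed(21)
  p <- random_panel(E = 4, n_cal = 8)
  ranges <- panel_ranges(p)
  sc <- score_experts(p, ranges)
  top <- sc$assessor[which.max(sc$statistical_accuracy)]
  cfg <- weighting_config("global", alpha = max(sc$statistical_accuracy),
                          optimize = FALSE)
  dm <- performance_weight_dm(p, cfg, ranges)
  expect_equal(dm$score$statistical_accuracy,
               sc$statistical_accuracy[sc$assessor == top])
  expect_equal(dm$score$informativeness,
               sc$informativeness[sc$assessor == top], tolerance = 1e-9)
  for (id in p$items$item)
    expect_equal(unlist(dm$quantiles[dm$quantiles$item == id, -1],
                        use.names = FALSE),
                 unname(sejcm:::get_triple(p, top, id)), tolerance = 1e-9)
})

test_that("threshold optimisation is the argmax over the candidate set", {
  set.seed(31)
  p <- random_panel(E = 5, n_cal = 10)
  ranges <- panel_ranges(p)
  dm <- performance_weight_dm(p, weighting_config("global"), ranges)
  # independent exhaustive search over the candidate set via the
  # non-optimising path
  sc <- score_experts(p, ranges)
  cand <- sort(unique(c(0, sc$statistical_accuracy)))
  combined <- sapply(cand, function(a)
    performance_weight_dm(p, weighting_config("global", alpha = a,
                                              optimize = FALSE),
                          ranges)$score$combined)
  expect_equal(dm$score$combined, max(combined))
  expect_equal(dm$alpha, cand[which.max(combined)])
  # never below the all-experts (alpha = 0) DM
  expect_gte(dm$score$combined, combined[1])
  # optimisation trace covers every candidate
  expect_equal(dm$optimization$alpha, cand)
  expect_equal(dm$optimization$combined, combined)
})

test_that("optimiser excludes wildly overconfident experts", {
  # one calibrated expert plus overconfident ones: the optimiser picks a
  # cut-off whose support is the calibrated expert
  g <- generate_study(sim_config(
    n_panels = 1, experts_per_panel = 5, n_calibration = 15, n_target = 0,
    archetype_mix = c(calibrated = 0.2, overconfident = 0.8,
                      underconfident = 0, biased = 0),
    seed = 99))
  p <- g$study$panels[[1]]
  calib <- g$truth$expert[g$truth$archetype == "calibrated"]
  dm <- performance_weight_dm(p, weighting_config("global"))
  w <- dm$weights
  # weight concentrates on the calibrated expert and the optimiser's
  # cut-off un-weights the worst overconfident experts entirely
  expect_gt(w[[calib]], 0.5)
  expect_gt(min(w[[calib]] / w[setdiff(names(w), calib)]), 5)
  expect_gte(sum(w[setdiff(names(w), calib)] == 0), 1)
})

test_that("mixture informativeness obeys the convexity bound", {
  set.seed(41)
  for (rep in 1:10) {
    p <- random_panel(E = 4, n_cal = 5, n_target = 1)
    ranges <- panel_ranges(p)
    w <- runif(4); w <- w / sum(w)
    for (id in p$items$item) {
      ds <- lapply(p$experts, function(e)
        expert_density(sejcm:::get_triple(p, e, id), ranges[[id]]))
      m <- mixture_density(ds, w)
      qm <- dm_quantiles(m)
      mix_inf <- information_per_item(qm, ranges[[id]])
      avg_inf <- sum(w * sapply(p$experts, function(e)
        information_per_item(sejcm:::get_triple(p, e, id), ranges[[id]])))
      expect_lte(mix_inf, avg_inf + 1e-9)
    }
  }
})

test_that("EW informativeness on disjoint experts is at most the average", {
  p <- tiny_panel(E = 2, n_cal = 2, realizations = c(2, 2),
                  triple_fun = function(e, j)
                    if (e == "e01") c(1, 1.5, 2) else c(8, 8.5, 9))
  res <- score_panel(p, schemes = "ew")
  ex <- res$scores[res$scores$kind == "expert", ]
  expect_lte(res$scores$informativeness[res$scores$kind == "ew"],
             mean(ex$informativeness))
})
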