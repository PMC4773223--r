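make_table <- function(panels, experts_per_panel = 3, f_acc = NULL) {
  # deterministic toy score table with expert + pwg + pwi + ew rows
  rows <- list()
  for (i in seq_along(panels)) {
    pid <- panels[i]
    for (j in seq_len(experts_per_panel)) {
      acc <- if (is.null(f_acc)) 0.03 * j else f_acc(i, j)
      rows[[length(rows) + 1]] <- data.frame(
        panel = pid, assessor = sprintf("ex%02d", j), kind = "expert",
        statistical_accuracy = acc, informativeness = 2 / j,
        combined = acc * 2 / j, stringsAsFactors = FALSE)
    }
    for (lab in c("pwg", "pwi", "ew")) {
      acc <- 0.5; inf <- if (lab == "ew") 0.4 else 1.1
      rows[[length(rows) + 1]] <- data.frame(
        panel = pid, assessor = lab, kind = lab,
        statistical_accuracy = acc, informativeness = inf,
        combined = acc * inf, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("distinct panels are selected by expert membership", {
  p1 <- tiny_panel(id = "a"); p2 <- tiny_panel(id = "b")
  p3 <- tiny_panel(E = 3, id = "c")
  st <- study(list(p1, p2, p3))  # a and b share the same expert ids
  expect_equal(distinct_panels(st), c("a", "c"))
  st2 <- study(list(tiny_panel(E = 2, id = "x"), tiny_panel(E = 3, id = "y")))
  expect_equal(distinct_panels(st2), c("x", "y"))
  # same logic from a score table
  tab <- make_table(c("a", "b"))
  tab$assessor[tab$panel == "b" & tab$kind == "expert"] <-
    sprintf("other%02d", 1:3)
  expect_equal(distinct_panels(tab), c("a", "b"))
  tab2 <- make_table(c("a", "b"))
  expect_equal(distinct_panels(tab2), "a")
})

test_that("spearman rho handles monotone data, ties and direction", {
  x <- 1:8
  expect_equal(spearman_rho(x, x * 2 + 1, n_perm = 0)$rho, 1)
  expect_equal(spearman_rho(x, -x, n_perm = 0)$rho, -1)
  # hand-computed average-rank value for a 5-point set with one tie:
  # ranks of y = (2, 1, 4, 4, 5) are (2, 1, 3.5, 3.5, 5) -> rho = 8.5/sqrt(95)
  r <- spearman_rho(1:5, c(2, 1, 4, 4, 5), n_perm = 0)
  expect_equal(r$rho, 8.5 / sqrt(95))
  # antisymmetry
  set.seed(3)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(spearman_rho(a, -b, n_perm = 0)$rho,
               -spearman_rho(a, b, n_perm = 0)$rho)
  expect_error(spearman_rho(1:5, rep(2, 5), n_perm = 0),
               "undefined correlation")
})

test_that("permutation p-value detects a negative association", {
  set.seed(17)
  x <- rnorm(40)
  y <- -x + rnorm(40, 0, 0.5)
  r <- spearman_rho(x, y, n_perm = 4000, seed = 1)
  expect_lt(r$rho, -0.5)
  expect_lt(r$p_one_sided, 0.01)
  # independent data: p not extreme, permutation close to t-approximation
  y2 <- rnorm(40)
  r2 <- spearman_rho(x, y2, n_perm = 4000, seed = 1)
  rt <- spearman_rho(x, y2, n_perm = 0)
  expect_equal(r2$rho, rt$rho)
  expect_lt(abs(r2$p_one_sided - rt$p_one_sided), 0.05)
  # seeded: reproducible
  expect_equal(spearman_rho(x, y, n_perm = 500, seed = 9)$p_one_sided,
               spearman_rho(x, y, n_perm = 500, seed = 9)$p_one_sided)
})

test_that("running rank correlation windows are laid out as specified", {
  sc <- data.frame(assessor = sprintf("e%d", 1:4),
                   statistical_accuracy = c(0.01, 0.2, 0.5, 0.9),
                   informativeness = c(3, 2.5, 1, 1.2))
  rr <- running_rank_correlation(sc)
  expect_equal(rr$k, 1:2)  # n = 4: exactly two windows of size >= 3
  expect_equal(rr$rho[1],
               spearman_rho(sc$statistical_accuracy,
                            sc$informativeness, n_perm = 0)$rho)
  expect_error(running_rank_correlation(sc[1:3, ]), "at least 4")
})

test_that("pw-vs-ew summary fields behave on constructed tables", {
  tab <- make_table(c("p1", "p2", "p3"))
  # make expert sets differ so all panels are distinct
  tab$assessor[tab$kind == "expert"] <-
    paste0(tab$assessor[tab$kind == "expert"],
           rep(c("a", "b", "c"), each = 3))
  s <- pw_vs_ew_summary(tab)
  expect_equal(s$n_panels, 3)
  expect_equal(s$pw_win_pct, 100)       # pwg combined 0.55 > ew 0.20
  expect_equal(s$mean_ew_informativeness, 0.4)
  expect_equal(s$pct_ew_inf_below_0.5, 100)
  expect_equal(s$mean_panel_size, 3)
  expect_equal(s$n_experts, 9)
  expect_equal(s$n_experts_acc_above, 6)  # accuracies 0.03/0.06/0.09 per panel
  # pwg == ew everywhere: strict comparison gives 0%
  tab2 <- tab
  tab2[tab2$kind == "pwg", c("statistical_accuracy", "informativeness",
                             "combined")] <-
    tab2[tab2$kind == "ew", c("statistical_accuracy", "informativeness",
                              "combined")]
  expect_equal(pw_vs_ew_summary(tab2)$pw_win_pct, 0)
  # invariance to row order
  perm <- sample(nrow(tab))
  s2 <- pw_vs_ew_summary(tab[perm, ])
  expect_equal(s2, s)
  # missing DM rows error names the panel
  tab3 <- tab[!(tab$panel == "p2" & tab$kind == "ew"), ]
  expect_error(pw_vs_ew_summary(tab3), "p2")
})

test_that("summaries agree between raw study and exported score table", {
  cfg <- sim_config(n_panels = 3, experts_per_panel = 6,
                    n_calibration = 8, n_target = 3, seed = 5)
  st <- generate_study(cfg)$study
  tab <- score_study(st)
  f <- tempfile(fileext = ".csv")
  write_score_table(tab, f)
  tab2 <- read_score_table(f, quiet = TRUE)
  expect_equal(pw_vs_ew_summary(tab), pw_vs_ew_summary(tab2))
  expect_equal(distinct_panels(tab), distinct_panels(tab2))
})

test_that("expected false rejections round half away from zero", {
  expect_identical(expected_false_rejections(112, 0.05), 6L)
  expect_identical(expected_false_rejections(100, 0.05), 5L)
  expect_identical(expected_false_rejections(20, 0.01), 0L)
  expect_identical(expected_false_rejections(10, 0.05), 1L)  # 0.5 rounds up
})

test_that("expert-level pooling across panels matches hand aggregation", {
  # same expert on two panels; pooled counts and mean item information
  tf <- function(e, j) c(1, 2, 3)
  p1 <- tiny_panel(E = 2, n_cal = 2, realizations = c(1.5, 0.5), id = "p1",
                   triple_fun = tf)
  p2 <- tiny_panel(E = 2, n_cal = 2, realizations = c(2.5, 9), id = "p2",
                   triple_fun = tf)
  st <- study(list(p1, p2))
  ov <- expert_overall_scores(st, method = "pooled")
  # bins: p1 -> (2, 3); p2 -> (3, 4): counts (1, 1, 1, 1) over N = 4
  expect_equal(ov$statistical_accuracy[ov$assessor == "e01"],
               statistical_accuracy(calibration_counts(c(1, 1, 1, 1))))
  ova <- expert_overall_scores(st, method = "average")
  per_panel <- c(statistical_accuracy(bin_counts(p1, "e01")),
                 statistical_accuracy(bin_counts(p2, "e01")))
  expect_equal(ova$statistical_accuracy[ova$assessor == "e01"],
               mean(per_panel))
})
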