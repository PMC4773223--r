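# Synthetic elicitation studies with the statistical structure the analysis
# assumes: many panels of ~13 experts, 10-15 calibration variables per
# panel, proportion-type items, and expert archetypes of heterogeneous
# calibration quality (calibrated / overconfident / underconfident /
# biased).
#
# Mechanism: items live on a logit scale and are mapped to percentages.
# The realization is a draw from the item's sampling distribution; each
# expert observes an independent noisy signal of it and states the 5/50/95%
# quantiles of the exact conditional (posterior) distribution, distorted by
# their archetype: the centre is shifted by `bias` item-sds and the spread
# multiplied by `dispersion`.  The calibrated archetype (bias 0, dispersion
# 1) therefore states quantiles that are true quantiles of the
# realization's distribution given their information, which is what makes
# its accuracy p-values uniform; dispersion < 1 produces overconfidence
# (narrow, informative, inaccurate), dispersion > 1 underconfidence.

#' Expert archetypes used by the generator
#'
#' @return Named list of `c(bias, dispersion)` pairs.
#' @export
default_archetypes <- function() {
  list(calibrated    = c(bias = 0, dispersion = 1),
       overconfident = c(bias = 0, dispersion = 0.3),
       underconfident = c(bias = 0, dispersion = 2),
       biased        = c(bias = 1, dispersion = 1))
}

#' Simulation configuration
#'
#' Defaults emulate a large multi-panel attribution elicitation: 112
#' panels, 13 experts per panel, 10-15 calibration variables (count drawn
#' per panel), proportion-type items on a logit latent scale, and an
#' archetype mix dominated by overconfident experts (the typical field
#' finding; few experts are well calibrated).
#'
#' @param n_panels Number of panels.
#' @param experts_per_panel Experts on each panel.
#' @param n_calibration Integer range `c(min, max)` (or a single count) of
#'   calibration variables per panel.
#' @param n_target Target questions per panel.
#' @param archetype_mix Named proportions over [default_archetypes()]
#'   (summing to 1); converted to per-panel counts by largest remainder, so
#'   every panel has the same deterministic composition.
#' @param archetypes Named list of `c(bias, dispersion)` per archetype.
#' @param signal_noise Standard deviation (in item-sd units) of the noise
#'   on each expert's private signal; controls disagreement between
#'   equally-skilled experts.
#' @param mu_sd Spread of item centres on the logit scale.
#' @param sigma_range Range of item sds on the logit scale.
#' @param seed Global seed; each panel derives its own substream from it,
#'   so increasing `n_panels` does not reshuffle existing panels.
#' @return List of class `sej_sim_config`.
#' @export
sim_config <- function(n_panels = 112, experts_per_panel = 13,
                       n_calibration = c(10, 15), n_target = 10,
                       archetype_mix = c(calibrated = 0.1,
                                         overconfident = 0.5,
                                         underconfident = 0.1,
                                         biased = 0.3),
                       archetypes = default_archetypes(),
                       signal_noise = 1, mu_sd = 1,
                       sigma_range = c(0.4, 1), seed = 1) {
  stopifnot(n_panels >= 1, experts_per_panel >= 1, n_target >= 0,
            all(n_calibration >= 1), signal_noise >= 0,
            abs(sum(archetype_mix) - 1) < 1e-9,
            all(names(archetype_mix) %in% names(archetypes)))
  disp <- vapply(archetypes, `[[`, numeric(1), "dispersion")
  stopifnot(all(disp > 0))
  structure(list(n_panels = n_panels, experts_per_panel = experts_per_panel,
                 n_calibration = n_calibration, n_target = n_target,
                 archetype_mix = archetype_mix, archetypes = archetypes,
                 signal_noise = signal_noise, mu_sd = mu_sd,
                 sigma_range = sigma_range, seed = as.integer(seed)),
            class = "sej_sim_config")
}

# Largest-remainder apportionment of n slots to proportions p.
apportion <- function(p, n) {
  base <- floor(p * n)
  rem <- p * n - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

# Deterministic per-panel seed substream derived from the global seed.
panel_seed <- function(seed, i) {
  ((as.double(seed %% 2147483647L) * 69069 + i) %% 2147483647) + 1
}

#' Generate a synthetic elicitation study
#'
#' @param cfg A [sim_config()].
#' @return List with `study` (a valid `sej_study`) and `truth` (data frame
#'   recording each expert's archetype, bias and dispersion).  Bit-identical
#'   for identical seeds; panels are generated on independent substreams so
#'   the first k panels do not depend on `n_panels`.
#' @export
generate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sej_sim_config"))
  counts <- apportion(cfg$archetype_mix, cfg$experts_per_panel)
  arch_of <- rep(names(counts), counts)
  tau <- cfg$signal_noise
  post_sd <- sqrt(tau^2 / (1 + tau^2))
  panels <- vector("list", cfg$n_panels)
  truth <- vector("list", cfg$n_panels)
  for (pi in seq_len(cfg$n_panels)) {
    set.seed(panel_seed(cfg$seed, pi))
    pid <- sprintf("p%03d", pi)
    n_cal <- if (length(cfg$n_calibration) > 1)
      sample(seq(cfg$n_calibration[1], cfg$n_calibration[2]), 1)
    else cfg$n_calibration
    n_items <- n_cal + cfg$n_target
    E <- cfg$experts_per_panel
    mu <- stats::rnorm(n_items, 0, cfg$mu_sd)
    sig <- stats::runif(n_items, cfg$sigma_range[1], cfg$sigma_range[2])
    z <- stats::rnorm(n_items, mu, sig)          # latent truth (logit scale)
    sig_noise <- matrix(stats::rnorm(n_items * E, 0, tau), n_items, E)
    item_ids <- sprintf("%s_i%02d", pid, seq_len(n_items))
    kind <- c(rep("calibration", n_cal), rep("target", cfg$n_target))
    realization <- ifelse(kind == "calibration", 100 * stats::plogis(z), NA)
    items <- data.frame(item = item_ids, kind = kind, scale = "uniform",
                        units = "%", lower = 0, upper = 100,
                        realization = realization,
                        stringsAsFactors = FALSE)
    expert_ids <- sprintf("%s_e%02d", pid, seq_len(E))
    rows <- vector("list", E)
    for (e in seq_len(E)) {
      a <- cfg$archetypes[[arch_of[e]]]
      zstd <- (z - mu) / sig
      u <- zstd + sig_noise[, e]
      centre <- mu + sig * (u / (1 + tau^2) + a[["bias"]])
      spread <- sig * a[["dispersion"]] * post_sd
      q05 <- 100 * stats::plogis(stats::qnorm(0.05, centre, spread))
      q50 <- 100 * stats::plogis(centre)
      q95 <- 100 * stats::plogis(stats::qnorm(0.95, centre, spread))
      rows[[e]] <- data.frame(expert = expert_ids[e], item = item_ids,
                              q05 = q05, q50 = q50, q95 = q95,
                              stringsAsFactors = FALSE)
    }
    panels[[pi]] <- panel(pid, expert_ids, items, do.call(rbind, rows),
                          hazard = sprintf("hazard-%02d", ((pi - 1) %% 14) + 1),
                          region = sprintf("region-%02d", ((pi - 1) %% 8) + 1))
    truth[[pi]] <- data.frame(panel = pid, expert = expert_ids,
                              archetype = arch_of,
                              bias = vapply(arch_of, function(an)
                                cfg$archetypes[[an]][["bias"]], numeric(1)),
                              dispersion = vapply(arch_of, function(an)
                                cfg$archetypes[[an]][["dispersion"]], numeric(1)),
                              stringsAsFactors = FALSE)
  }
  all_e <- unlist(lapply(panels, `[[`, "experts"))
  labels <- stats::setNames(sprintf("Expert %s", all_e), all_e)
  tr <- do.call(rbind, truth)
  rownames(tr) <- NULL
  list(study = study(panels, labels), truth = tr)
}

#' Generate a score table directly
#'
#' Convenience wrapper: [generate_study()] piped through [score_study()],
#' so analytics can be exercised without holding the raw elicitations.
#'
#' @param cfg A [sim_config()].
#' @param ... Passed to [score_study()].
#' @return A score table data frame.
#' @export
generate_score_table <- function(cfg = sim_config(), ...) {
  score_study(generate_study(cfg)$study, ...)
}

#' Accuracy p-values of a simulated archetype
#'
#' Lightweight replicate simulator on the standardised item scale (the
#' accuracy statistic is invariant to item location/scale, so only the
#' archetype and signal noise matter): one p-value per replicate panel of
#' `n_items` calibration items.
#'
#' @param n_items Calibration items per replicate.
#' @param n_rep Number of replicates.
#' @param bias,dispersion Archetype parameters.
#' @param signal_noise Signal noise, as in [sim_config()].
#' @param seed RNG seed.
#' @return Numeric vector of `n_rep` statistical-accuracy p-values.
#' @export
simulate_accuracy_pvalues <- function(n_items, n_rep, bias = 0,
                                      dispersion = 1, signal_noise = 1,
                                      seed = 1) {
  set.seed(seed)
  tau <- signal_noise
  post_sd <- sqrt(tau^2 / (1 + tau^2))
  vapply(seq_len(n_rep), function(r) {
    z <- stats::rnorm(n_items)
    u <- z + stats::rnorm(n_items, 0, tau)
    centre <- u / (1 + tau^2) + bias
    spread <- dispersion * post_sd
    q05 <- stats::qnorm(0.05, centre, spread)
    q50 <- centre
    q95 <- stats::qnorm(0.95, centre, spread)
    bins <- which_bin(z, q05, q50, q95)
    statistical_accuracy(calibration_counts(tabulate(bins, nbins = 4L)))
  }, numeric(1))
}
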