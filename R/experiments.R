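# Scaled-down parameter-recovery experiments on synthetic data: type-I
# control and power of the band test, direction recovery of the planted
# partner preference, and the Monte-Carlo power of the mass-cost pairing.
# These are the package's own validation harness; the methods vignette
# documents the problem sizes.

#' Type-I error of the band test under the movement null
#'
#' Each replicate simulates one group-season of movement (mean-reverting
#' walk), fits the a-LoCoH territory, places `n_callers * n_calls` calls at
#' uniformly chosen movement fixes (the movement null: no border bias) and
#' runs the pooled three-band chi-squared test against the 0.5/0.25/0.20
#' expectations. Returns the fraction of replicates rejecting at `alpha`.
#'
#' @param reps number of replicates.
#' @param n_callers,n_calls callers and calls per caller pooled per
#'   replicate.
#' @param n_fixes fixes per group-season (default 300).
#' @param theta,sigma movement parameters (see [sim_config()]).
#' @param a_fraction hull budget as a fraction of the max pairwise fix
#'   distance (default 0.25).
#' @param alpha significance level.
#' @param seed integer seed.
#' @return rejection rate in [0, 1].
#' @export
band_null_rejection_rate <- function(reps = 1000, n_callers = 10,
                                     n_calls = 25, n_fixes = 300,
                                     theta = 0.15, sigma = 120,
                                     a_fraction = 0.25, alpha = 0.05,
                                     seed = 1L) {
  reject <- logical(reps)
  total <- n_callers * n_calls
  for (r in seq_len(reps)) {
    fx <- simulate_movement(c(0, 0), n_fixes, theta, sigma,
                            seed = derive_seed(seed, 1000L + r))
    pts <- as.matrix(fx[, c("x", "y")])
    fit <- locoh(pts, a = a_fraction * choose_a(pts))
    set.seed(derive_seed(seed, 5000L + r))
    idx <- sample.int(n_fixes, total, replace = TRUE)
    band <- predict(fit, pts[idx, , drop = FALSE])
    obs <- table(band)[band_names()[1:3]]
    test <- chisq_gof(as.numeric(obs), expected_band_counts(total))
    reject[r] <- test$p < alpha
  }
  mean(reject)
}

#' Power of the band test with planted border bias
#'
#' Simulates two-group landscapes with a shared border and callers whose
#' calls go to the border inclusion zone with probability `border_bias`,
#' then runs the full pipeline and records how often the pooled band
#' chi-squared rejects. Landscapes are regenerated every
#' `reps_per_landscape` call replicates.
#'
#' @param reps total replicates.
#' @param border_bias planted border bias.
#' @param n_callers callers per replicate (split over the two groups).
#' @param n_calls calls per caller.
#' @param reps_per_landscape call replicates sharing one landscape.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return rejection rate in [0, 1].
#' @export
band_power_rate <- function(reps = 200, border_bias = 0.5, n_callers = 10,
                            n_calls = 25, reps_per_landscape = 20,
                            alpha = 0.05, seed = 1L) {
  reject <- logical(reps)
  ds <- NULL
  current_block <- -1L
  for (r in seq_len(reps)) {
    block <- (r - 1L) %/% reps_per_landscape
    if (block != current_block) {
      cfg <- sim_config(n_groups = 2, territory_spacing = 800,
                        n_calls = n_calls, border_bias = border_bias,
                        related_fraction = 0,
                        n_callers_per_group = ceiling(n_callers / 2),
                        group_size_range = c(2 + ceiling(n_callers / 2), 15),
                        seed = derive_seed(seed, 31L + block))
      ds <- simulate_dataset(cfg)
      current_block <- block
    }
    dsr <- resimulate_calls(ds, derive_seed(seed, 7000L + r))
    rep_out <- run_audience_analysis(dsr, analysis_config(a_fraction = 0.25),
                                     territories = attr(dsr, "territories"))
    reject[r] <- !is.null(rep_out$band_test$calls) &&
      rep_out$band_test$calls$p < alpha
  }
  mean(reject)
}

#' Direction recovery of the planted partner preference
#'
#' Simulates landscapes of territories in a linear chain with alternating
#' small and large neighbour compositions (so every interior caller faces a
#' genuine partner-count contrast) and callers whose border choice is
#' weighted by `(1 + partners)^partner_exponent`, runs the pipeline, and
#' checks whether the max-vs-min partner paired comparison shows the
#' planted direction (higher call rate per hectare at the max-partner
#' border, i.e. positive mean paired difference). The chain layout keeps
#' the two border strips of a caller geometrically comparable; a planted
#' preference on call counts can otherwise be inverted on the per-hectare
#' scale by an incidental area imbalance between a large side border and a
#' tiny corner border.
#'
#' @param reps replicates (each a fresh landscape).
#' @param n_groups groups per landscape (default 6).
#' @param partner_exponent planted preference exponent (default 3; any
#'   value of 2 or more plants a clear preference against the composition
#'   gradient below).
#' @param border_bias planted border bias (default 0.5).
#' @param n_calls calls per caller (default 25).
#' @param group_sizes composition pattern along the chain (default a
#'   repeating 3/8/13-member gradient, so adjacent neighbours always
#'   differ in composition; a period-2 alternation would give every
#'   interior caller two equal-sized neighbours and no contrast to
#'   recover).
#' @param seed integer seed.
#' @return fraction of replicates recovering the planted direction (among
#'   replicates where the comparison was estimable).
#' @export
partner_direction_rate <- function(reps = 50, n_groups = 6,
                                   partner_exponent = 3, border_bias = 0.5,
                                   n_calls = 25, group_sizes = c(3, 8, 13),
                                   seed = 1L) {
  ok <- logical(0)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_groups = n_groups, grid_ncol = n_groups,
                      territory_spacing = 650, max_radius = 360,
                      n_calls = n_calls, border_bias = border_bias,
                      partner_exponent = partner_exponent,
                      related_fraction = 0, group_sizes = group_sizes,
                      seed = derive_seed(seed, 61L + r))
    ds <- simulate_dataset(cfg)
    rep_out <- run_audience_analysis(ds, analysis_config(a_fraction = 0.25),
                                     territories = attr(ds, "territories"))
    tab <- rep_out$paired_tables$max_vs_min_partners
    if (is.null(tab) || nrow(tab) == 0L) next
    d <- tab$calls_per_ha_high - tab$calls_per_ha_low
    ok <- c(ok, mean(d) > 0)
  }
  if (!length(ok)) stop("no replicate yielded an estimable comparison", call. = FALSE)
  mean(ok)
}

#' Monte-Carlo power of the mass-cost comparison
#'
#' Simulates weighing sessions with a planted calling effect, runs
#' [weight_cost_pairs()] and [paired_t()], and returns the rejection rate,
#' alongside the closed-form noncentral-t power (the paired difference has
#' standard deviation `sqrt(2) * noise_sd` because both days carry
#' independent daily noise).
#'
#' @param reps replicates.
#' @param delta planted calling effect, grams (e.g. -2).
#' @param noise_sd daily mass-change noise, grams.
#' @param n_individuals individuals per replicate.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return list with `mc_power`, `closed_form_power`.
#' @export
weight_cost_power <- function(reps = 2000, delta = -2, noise_sd = 1,
                              n_individuals = 8, alpha = 0.05, seed = 1L) {
  ids <- sprintf("I%02d", seq_len(n_individuals))
  reject <- logical(reps)
  for (r in seq_len(reps)) {
    w <- simulate_weights(ids, calling_effect = delta, baseline_gain = 2,
                          noise_sd = noise_sd,
                          seed = derive_seed(seed, 9000L + r))
    pairs <- weight_cost_pairs(w)
    t <- paired_t(pairs$change_calling, pairs$change_noncalling)
    reject[r] <- t$p < alpha
  }
  list(mc_power = mean(reject),
       closed_form_power = paired_t_power(delta, sqrt(2) * noise_sd,
                                          n_individuals, alpha))
}
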