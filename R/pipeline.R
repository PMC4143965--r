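#' Density comparison pipeline
#'
#' Runs the fixed-box subsampling, the Kruskal-Wallis layer comparison,
#' Bonferroni-adjusted pairwise Mann-Whitney tests, and the
#' report-only Levene homoscedasticity check.
#'
#' @param study A [study_collection()].
#' @param n_rep Subsampling repetitions per layer.
#' @param seed Optional master seed.
#' @return List with `draws`, `kruskal`, `pairwise`, `levene`.
#' @export
run_density_analysis <- function(study, n_rep = 50, seed = NULL) {
  draws <- density_draws(study, n_rep = n_rep, seed = seed)
  list(draws = draws,
       kruskal = kruskal_wallis_draws(draws),
       pairwise = pairwise_mw_bonferroni(draws),
       levene = levene_check(draws))
}

#' Per-sample goodness-of-fit sweep
#'
#' Applies the leave-one-out envelope test ([loo_envelope_test()]) to
#' every sample of the study and tabulates the verdicts.
#'
#' @param study A [study_collection()] (every layer needs >= 2 samples).
#' @param n_central,n_envelope Simulation counts per test.
#' @param seed Optional master seed; each sample uses a derived sub-seed.
#' @return Data frame with `layer`, `sample_id`, `n`, `lambda_loo`,
#'   `reject`, `first_exceed_nm`.
#' @export
run_gof_sweep <- function(study, n_central = 99, n_envelope = 99,
                          seed = NULL) {
  rows <- lapply(seq_along(study$patterns), function(k) {
    p <- study$patterns[[k]]
    res <- loo_envelope_test(study, p$layer, p$sample_id, n_central,
                             n_envelope,
                             seed = if (is.null(seed)) NULL
                             else derive_seed(seed, k))
    data.frame(layer = p$layer, sample_id = p$sample_id, n = npoints(p),
               lambda_loo = loo_intensity(study, p$layer, p$sample_id),
               reject = res$reject,
               first_exceed_nm = if (res$reject) min(res$exceed_distances)
               else NA_real_)
  })
  do.call(rbind, rows)
}

#' Replicated-pattern comparisons
#'
#' Diggle bootstrap tests by animal, by layer, and one-vs-rest for each
#' layer.
#'
#' @param study A [study_collection()].
#' @param n_boot Bootstrap iterations.
#' @param seed Optional master seed.
#' @return List with `by_animal`, `by_layer`, `one_vs_rest` (named list of
#'   [diggle_test_curves()] results).
#' @export
run_replicated_analysis <- function(study, n_boot = 5000, seed = NULL) {
  layers <- sort(unique(study_layers(study)))
  list(by_animal = diggle_test(study, by = "animal", n_boot = n_boot,
                               seed = if (is.null(seed)) NULL
                               else derive_seed(seed, 1)),
       by_layer = diggle_test(study, by = "layer", n_boot = n_boot,
                              seed = if (is.null(seed)) NULL
                              else derive_seed(seed, 2)),
       one_vs_rest = stats::setNames(lapply(seq_along(layers), function(k)
         diggle_test(study, by = "layer", versus = layers[k],
                     n_boot = n_boot,
                     seed = if (is.null(seed)) NULL
                     else derive_seed(seed, 2 + k))), layers))
}

#' Global-model thinning cross-validation pipeline
#'
#' Fits the dense global RSA model on the requested layers and runs the
#' thinning cross-validation sweep.
#'
#' @inheritParams fit_global_model
#' @param seed Optional master seed.
#' @return List with `model` and `sweep` (see [thinning_cv_sweep()]).
#' @export
run_thinning_cv <- function(study, layers = c("II", "III", "IV", "V", "VI"),
                            volume_box = dense_box(), n_dense = 198,
                            seed = NULL) {
  model <- fit_global_model(study, layers, volume_box, n_dense,
                            seed = if (is.null(seed)) NULL
                            else derive_seed(seed, 1))
  list(model = model,
       sweep = thinning_cv_sweep(study, model,
                                 seed = if (is.null(seed)) NULL
                                 else derive_seed(seed, 2)))
}

#' Per-sample summary table of a study
#'
#' Volume, count and density per sample, with per-layer pooled rows,
#' mirroring the layout of published density tables.
#'
#' @param study A [study_collection()].
#' @param digits Density rounding for reporting (3 by default).
#' @return Data frame with `layer`, `sample_id`, `animal`, `volume_um3`,
#'   `n_synapses`, `density`.
#' @export
study_table <- function(study, digits = 3) {
  rows <- do.call(rbind, lapply(study$patterns, function(p)
    data.frame(layer = p$layer %||% NA, sample_id = p$sample_id,
               animal = p$animal %||% NA, volume_um3 = volume_um3(p$box),
               n_synapses = npoints(p),
               density = round(estimate_intensity(p), digits))))
  pooled <- do.call(rbind, lapply(split(rows, rows$layer), function(d)
    data.frame(layer = d$layer[1], sample_id = "pooled", animal = NA,
               volume_um3 = sum(d$volume_um3),
               n_synapses = sum(d$n_synapses),
               density = round(sum(d$n_synapses) / sum(d$volume_um3),
                               digits))))
  out <- rbind(rows, pooled)
  rownames(out) <- NULL
  out
}
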