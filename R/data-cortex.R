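#' Reference per-sample counts and volumes, rat somatosensory cortex
#'
#' Bundled reference table for 25 FIB/SEM neuropil samples spanning cortical
#' layers I-VI of P14 rat somatosensory cortex (three animals): reconstructed
#' tissue volume after shrinkage correction, number of synaptic junctions,
#' and the printed density (count / volume rounded to three decimals). These
#' per-sample counts and volumes are the inputs of the leave-one-out
#' intensity estimates and of the global-model intensity; the raw centroid
#' clouds themselves are not distributed.
#'
#' @return Data frame with columns `layer`, `sample`, `animal`,
#'   `volume_um3`, `n_synapses`, `density`.
#' @export
cortex_samples <- function() {
  data.frame(
    layer = rep(c("I", "II", "III", "IV", "V", "VI"),
                times = c(2, 3, 10, 3, 3, 4)),
    sample = c(1:2, 1:3, 1:10, 1:3, 1:3, 1:4),
    animal = c("w33", "w35",
               "w33", "w35", "w35",
               "w31", "w31", "w33", "w33", "w33", "w33", "w33", "w35",
               "w35", "w35",
               "w33", "w35", "w35",
               "w33", "w33", "w33",
               "w33", "w35", "w31", "w31"),
    volume_um3 = c(210.61, 177.20,
                   224.35, 139.51, 149.03,
                   149.13, 157.15, 186.45, 176.44, 176.28, 175.55, 191.28,
                   247.58, 178.40, 165.06,
                   154.59, 140.63, 123.81,
                   165.62, 218.01, 207.95,
                   185.32, 183.55, 179.97, 280.09),
    n_synapses = c(180, 128,
                   230, 127, 206,
                   147, 109, 173, 178, 167, 165, 189, 198, 201, 168,
                   172, 178, 162,
                   117, 198, 175,
                   92, 85, 102, 107),
    density = c(0.855, 0.722,
                1.025, 0.910, 1.382,
                0.986, 0.694, 0.928, 1.009, 0.947, 0.940, 0.988, 0.800,
                1.127, 1.018,
                1.113, 1.266, 1.308,
                0.706, 0.908, 0.842,
                0.496, 0.463, 0.567, 0.382))
}

#' Per-layer pooled means of the reference table
#'
#' Pooled (volume-weighted) density per layer together with the printed
#' per-layer mean volume, mean count and mean density.
#'
#' @return Data frame with columns `layer`, `mean_volume_um3`,
#'   `mean_count`, `mean_density` (printed values) and `pooled_density`
#'   (total count / total volume, full precision).
#' @export
cortex_layer_means <- function() {
  tab <- cortex_samples()
  pooled <- vapply(split(tab, tab$layer), function(d)
    sum(d$n_synapses) / sum(d$volume_um3), numeric(1))
  out <- data.frame(
    layer = c("I", "II", "III", "IV", "V", "VI"),
    mean_volume_um3 = c(193.91, 170.96, 180.33, 139.68, 197.19, 207.23),
    mean_count = c(154, 188, 170, 171, 163, 97),
    mean_density = c(0.794, 1.098, 0.940, 1.222, 0.828, 0.466))
  out$pooled_density <- pooled[out$layer]
  out
}

#' Global lognormal Feret-diameter law of the reference study
#'
#' Parameters of the lognormal distribution fitted to the Feret diameters
#' of all synapses of layers II-VI (log-nm scale): mu = 5.911,
#' sigma = 0.404, giving a mean diameter of about 401 nm.
#'
#' @return A [lognormal_size()].
#' @export
cortex_global_size <- function() lognormal_size(5.911, 0.404)

#' Leave-one-out intensities recomputed from the reference table
#'
#' For each sample of layers II-VI, the volume-weighted aggregate density
#' of the remaining samples of its layer (total count over total volume of
#' the others), as used to parameterise the thinned null models.
#'
#' @param digits Rounding of the reported estimate (3 by default, the
#'   reporting precision; `NULL` for full precision).
#' @return Data frame with columns `layer`, `sample`, `lambda_hat`.
#' @export
cortex_loo_intensities <- function(digits = 3) {
  tab <- cortex_samples()
  tab <- tab[tab$layer != "I", ]
  rows <- do.call(rbind, lapply(split(tab, tab$layer), function(d) {
    lh <- vapply(seq_len(nrow(d)), function(j)
      pooled_intensity(d$n_synapses[-j], d$volume_um3[-j]), numeric(1))
    data.frame(layer = d$layer, sample = d$sample, lambda_hat = lh)
  }))
  rows <- rows[order(match(rows$layer, c("II", "III", "IV", "V", "VI")),
                     rows$sample), ]
  rownames(rows) <- NULL
  if (!is.null(digits)) rows$lambda_hat <- round(rows$lambda_hat, digits)
  rows
}
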