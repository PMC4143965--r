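# Independent brute-force oracles and small fixture builders.

# Literal double-loop evaluation of the translation-corrected K estimator:
# K(d) = vol(B)^2 / N^2 * sum_{k != l} 1{||x_k - x_l|| <= d} / gamma_B(x_k - x_l)
k3_oracle <- function(p, grid) {
  xyz <- as.matrix(p$points[, c("x", "y", "z")])
  n <- nrow(xyz)
  sides <- p$box$side_lengths
  vals <- numeric(length(grid))
  for (k in seq_len(n - 1)) {
    for (l in (k + 1):n) {
      v <- xyz[k, ] - xyz[l, ]
      d <- sqrt(sum(v^2))
      gam <- prod(pmax(0, sides - abs(v)))
      vals <- vals + 2 * (d <= grid) / gam
    }
  }
  vals * prod(sides)^2 / n^2
}

# Exhaustive O(N^2) nearest-neighbour scan.
nn_oracle <- function(p) {
  xyz <- as.matrix(p$points[, c("x", "y", "z")])
  n <- nrow(xyz)
  vapply(seq_len(n), function(i)
    min(sqrt(colSums((t(xyz[-i, , drop = FALSE]) - xyz[i, ])^2))),
    numeric(1))
}

# Number of sphere pairs violating the exclusion constraint
# ||c_k - c_l|| >= factor * (D_k + D_l), by exhaustive pair scan.
overlap_violations <- function(p, factor = 0.5) {
  dm <- as.matrix(dist(p$points[, c("x", "y", "z")]))
  excl <- factor * outer(p$points$feret, p$points$feret, "+")
  sum(dm < excl - 1e-9 & upper.tri(dm))
}

# Uniform random pattern for estimator tests.
random_pattern <- function(n, sides = c(1000, 1200, 800)) {
  box <- box3d(sides)
  pp3_pattern(x = runif(n) * sides[1], y = runif(n) * sides[2],
              z = runif(n) * sides[3], box = box, sample_id = "rnd")
}

# Pattern with a prescribed count in a box of prescribed volume (um^3),
# used to rebuild count/volume bookkeeping from the reference table.
pattern_with_count <- function(n, volume_um3, layer = NULL,
                               sample_id = "s", animal = NULL) {
  sides <- c(7600, 5700, volume_um3 * 1e9 / (7600 * 5700))
  box <- box3d(sides)
  pp3_pattern(x = runif(n) * sides[1], y = runif(n) * sides[2],
              z = runif(n) * sides[3], box = box, layer = layer,
              animal = animal, sample_id = sample_id)
}

# Study mirroring the reference table's counts and volumes (coordinates
# are irrelevant for intensity bookkeeping).
reference_count_study <- function() {
  tab <- cortex_samples()
  study_collection(lapply(seq_len(nrow(tab)), function(i)
    pattern_with_count(tab$n_synapses[i], tab$volume_um3[i],
                       layer = tab$layer[i], sample_id = tab$sample[i],
                       animal = tab$animal[i])))
}
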