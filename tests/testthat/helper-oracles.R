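# independent segmentation oracle: objective of a boundary set under the
# block model with fixed off-block mean, by naive summation; exhaustive
# search over all boundary placements

oracle_gain <- function(y, boundaries, mu0) {
  cuts <- c(0, sort(boundaries), nrow(y))
  total <- 0
  for (s in seq_len(length(cuts) - 1)) {
    block <- y[(cuts[s] + 1):cuts[s + 1], (cuts[s] + 1):cuts[s + 1],
               drop = FALSE]
    z <- block - mu0
    total <- total + sum(z)^2 / length(z)
  }
  total
}

oracle_best <- function(y, k, mu0) {
  n <- nrow(y)
  best <- -Inf
  for (set in utils::combn(n - 1, k, simplify = FALSE)) {
    g <- oracle_gain(y, set, mu0)
    if (g > best) best <- g
  }
  best
}
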