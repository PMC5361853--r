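# Shared fixtures built in code. Scene sizes are kept small so the whole
# suite runs quickly; the generator is the same one users call.

small_scene <- function(scenario = "LLC", rows = 6L, cc = 0.3, seed = 1L,
                        size = c(80L, 120L)) {
  generate_field_image(scenario, row_count = rows, cc_target = cc,
                       size = size, seed = seed)
}

# deterministic flat-colour image
flat_image <- function(rgb, h = 8L, w = 8L) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  rgb_image(px)
}

random_image <- function(h = 12L, w = 15L, seed = 1L) {
  set.seed(seed)
  rgb_image(array(runif(h * w * 3), c(h, w, 3)))
}

random_mask <- function(h = 16L, w = 16L, p = 0.4, seed = 1L) {
  set.seed(seed)
  binary_mask(matrix(runif(h * w) < p, h, w))
}

# Brute-force Otsu: for every candidate bin edge, compute the between-class
# variance from first principles (class probabilities and means via loops
# over the histogram), and return the lowest maximising edge.
otsu_bruteforce <- function(values, n_bins = 256L) {
  rng <- range(values)
  bin <- pmin(floor((values - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, n_bins)
  n <- sum(counts)
  best <- -Inf
  best_k <- NA_integer_
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:k])
    n1 <- n - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- sum(counts[1:k] * (1:k)) / n0
    mu1 <- sum(counts[(k + 1):n_bins] * ((k + 1):n_bins)) / n1
    s <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (s > best + 1e-12) {
      best <- s
      best_k <- k
    }
  }
  rng[1] + best_k * diff(rng) / n_bins
}

# Double-loop pixel oracle for the segmentation quality factors.
quality_oracle <- function(S, R) {
  S <- unclass(S); R <- unclass(R)
  inter <- 0L; uni <- 0L; nref <- 0L; fp <- 0L
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
    s <- S[i, j] == 1L; r <- R[i, j] == 1L
    if (s && r) inter <- inter + 1L
    if (s || r) uni <- uni + 1L
    if (r) nref <- nref + 1L
    if (s && !r) fp <- fp + 1L
  }
  list(qseg = if (uni == 0L) 1 else inter / uni,
       sr = inter / nref, es = fp / nref)
}
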