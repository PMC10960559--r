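# Brute-force oracles, independent of the package's vectorized kernels:
# everything here is an explicit element-by-element loop over time points.

oracle_moment <- function(m, idx) {
  T <- ncol(m)
  acc <- 0
  for (t in seq_len(T)) {
    p <- 1
    for (j in idx) p <- p * m[j, t]
    acc <- acc + p
  }
  acc / T
}

oracle_cokurtosis <- function(m, i, j, k, l) {
  oracle_moment(m, c(i, j, k, l)) -
    oracle_moment(m, c(i, j)) * oracle_moment(m, c(k, l)) -
    oracle_moment(m, c(i, k)) * oracle_moment(m, c(j, l)) -
    oracle_moment(m, c(i, l)) * oracle_moment(m, c(j, k))
}

# uncentered normalized fourth moment of the two edge product signals
oracle_edge_raw <- function(m, e1, e2) {
  u <- m[e1[1], ] * m[e1[2], ]
  v <- m[e2[1], ] * m[e2[2], ]
  mean(u * v) / sqrt(mean(u^2) * mean(v^2))
}

oracle_edge_redundant <- function(m, e1, e2) {
  i <- e1[1]; j <- e1[2]; k <- e2[1]; l <- e2[2]
  num <- oracle_moment(m, c(i, j)) * oracle_moment(m, c(k, l)) +
    oracle_moment(m, c(i, k)) * oracle_moment(m, c(j, l)) +
    oracle_moment(m, c(i, l)) * oracle_moment(m, c(j, k))
  den <- sqrt((2 * oracle_moment(m, c(i, j))^2 +
                 oracle_moment(m, c(i, i)) * oracle_moment(m, c(j, j))) *
              (2 * oracle_moment(m, c(k, l))^2 +
                 oracle_moment(m, c(k, k)) * oracle_moment(m, c(l, l))))
  num / den
}

# z-score rows the way the estimators require (mean 1/T, variance 1/(T-1))
zrows <- function(m) {
  m <- m - rowMeans(m)
  m / sqrt(rowSums(m^2) / (ncol(m) - 1))
}

std_rts <- function(m) standardize(region_ts(m))

# small deterministic test matrix
toy_matrix <- function(nr, nc, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nrow = nr)
}

# synthetic multi-subject ensemble: independent Gaussian noise everywhere,
# optionally with a planted shared innovation in a subset of regions
gaussian_ensemble <- function(n_subj, n_regions, T, seed = 1) {
  set.seed(seed)
  subject_ensemble(lapply(seq_len(n_subj), function(s)
    region_ts(matrix(rnorm(n_regions * T), nrow = n_regions),
              region_ids = paste0("G", seq_len(n_regions)))))
}

# ensemble in which regions `planted` share a skew-normal (alpha) or t (nu)
# common innovation of strength psi; all other regions are independent noise
planted_ensemble <- function(n_subj, n_regions, T, planted, psi = 1,
                             alpha = NULL, nu = NULL, seed = 1,
                             homologous_pairs = NULL) {
  set.seed(seed)
  spec <- if (!is.null(alpha)) skew_normal_innovation(alpha)
          else student_t_innovation(nu)
  subject_ensemble(lapply(seq_len(n_subj), function(s) {
    m <- matrix(rnorm(n_regions * T), nrow = n_regions)
    u <- psi * sample_innovation(spec, T)
    for (i in planted) m[i, ] <- m[i, ] + u
    region_ts(m, region_ids = paste0("G", seq_len(n_regions)))
  }), homologous_pairs = homologous_pairs)
}
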