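# Shared fixture builders. Everything is generated in code at test time.

# A long clinical-style table from an explicit samples x variables matrix.
long_from_matrix <- function(values, animals, times, batch = "B1", sex = "F") {
  tibble::tibble(
    animal = rep(animals, each = ncol(values)),
    time = rep(times, each = ncol(values)),
    batch = rep(rep_len(batch, length(animals)), each = ncol(values)),
    sex = rep(rep_len(sex, length(animals)), each = ncol(values)),
    variable = rep(colnames(values) %||% paste0("v", seq_len(ncol(values))),
                   times = nrow(values)),
    value = as.vector(t(values))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A balanced random long table: n animals x times x p variables.
random_long <- function(n, times = c(0, 1, 4, 24), p = 3, seed = 1) {
  set.seed(seed)
  design <- acthkinetics::study_design(n, times = times, n_batches = 2L)
  tidyr::expand_grid(design, variable = paste0("v", seq_len(p))) %>%
    dplyr::mutate(value = rnorm(dplyr::n()))
}

# An expr_study straight from a gene x sample matrix on a balanced design.
expr_from_matrix <- function(values, n_animals, times = c(0, 1, 4, 24)) {
  design <- acthkinetics::study_design(n_animals, times = times, sexes = "F")
  samples <- design %>%
    dplyr::mutate(sample = paste(animal, time, sep = "_")) %>%
    dplyr::select(sample, animal, time, batch)
  colnames(values) <- samples$sample
  acthkinetics::expr_study(values, samples)
}

# Deterministic sign convention mirroring the package: the entry with the
# largest magnitude is made positive.
fix_sign_test <- function(v) {
  if (v[which.max(abs(v))] < 0) -v else v
}

# Brute-force BH step-up, kept deliberately naive.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact one-sided hypergeometric tail by direct summation of binomial
# coefficients: P(X >= k) drawing n from K whites / (N - K) blacks.
hyper_tail <- function(k, K, N, n) {
  j <- seq(k, min(n, K))
  if (!length(j)) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}
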