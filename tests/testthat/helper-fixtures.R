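# Shared fixtures: all built in code at test time.

make_sine <- function(freq, fs, n, phase = 0) {
  pcg_signal(sin(2 * pi * freq * (0:(n - 1)) / fs + phase), fs = fs)
}

random_signal <- function(n, fs = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pcg_signal(rnorm(n), fs = fs)
}

# Direct double-sum evaluation of one Stockwell voice: the independent
# O(N^2) oracle. Kernel: sum_k Z[(k+n) mod N] exp(-2 pi^2 k^2 / n^2)
# exp(+i 2 pi k m / N), implemented as an explicit complex matrix product
# with no shared code with st_voice().
direct_voice <- function(signal, n) {
  N <- signal$n_samples
  Z <- fft(signal$samples) / N
  k <- 0:(N - 1)
  g <- Z[((k + n) %% N) + 1] * exp(-2 * pi^2 * k^2 / n^2)
  E <- exp(2i * pi * outer(0:(N - 1), k) / N)
  as.vector(E %*% g)
}

# All voices n = 1..N-1 at once (columns), by one explicit matrix product.
direct_voices_matrix <- function(signal) {
  N <- signal$n_samples
  Z <- fft(signal$samples) / N
  k <- 0:(N - 1)
  E <- exp(2i * pi * outer(0:(N - 1), k) / N)
  G <- vapply(
    1:(N - 1),
    function(n) Z[((k + n) %% N) + 1] * exp(-2 * pi^2 * k^2 / n^2),
    complex(N)
  )
  E %*% G
}

# AUC by exhaustive pairwise comparison (ties count 1/2): oracle for the
# rank-based implementation.
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Literal term-by-term outcome-cost expression, written independently.
literal_cost <- function(N, M, TP, FN) {
  term_screen <- 35 * N
  term_alg <- 397 * M - 1718 * (M^2) / N + 11296 * (M^4) / (N^3)
  term_treat <- 10000 * TP
  term_miss <- 50000 * FN
  (term_screen + term_alg + term_treat + term_miss) / N
}

# A feature matrix whose first `n_inf` columns carry the labels with a
# >= 10x importance gap over pure-noise columns.
informative_matrix <- function(n_rows = 60, n_inf = 10, n_noise = 490,
                               noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n_rows)
  sig <- ifelse(y == "a", 1, -1)
  X <- cbind(
    matrix(sig, n_rows, n_inf) + matrix(rnorm(n_rows * n_inf, sd = noise_sd),
                                        n_rows, n_inf),
    matrix(rnorm(n_rows * n_noise), n_rows, n_noise)
  )
  list(X = X, y = y)
}

# Small cohort + config used by pipeline-level tests: short recordings keep
# unit tests quick; the full-scale defaults are exercised by the
# acceptance suite.
quick_sim_config <- function() sim_config(duration_range_s = c(5, 15))

quick_run_config <- function(task = "murmur", seed = 1L, ...) {
  run_config(
    task = task, seed = seed,
    k_features = 16L,
    balance = balance_config(k_neighbors = 2L, seed = seed),
    ...
  )
}
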