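# Shared small fixtures, built once per test run. Everything is generated in
# code; nothing is read from disk except in the explicit round-trip tests.

fixture_env <- new.env(parent = emptyenv())

# a small in-memory dataset: 6 groups of 10 variants at 32 px
tiny_groups <- function() {
  if (is.null(fixture_env$groups)) {
    fixture_env$groups <- synthesize_groups(n_groups = 6, n_variants = 10,
                                            size = 32, seed = 42)
  }
  fixture_env$groups
}

# a random image batch at a given size
rand_batch <- function(size, n, channels = 3, seed = 1) {
  withr::with_seed(seed, array(stats::runif(size * size * channels * n),
                               c(size, size, channels, n)))
}

# direct elementwise MSE oracle (explicit loop)
loop_mse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s / length(a)
}

# brute-force rank statistics used as independent oracles
mid_ranks <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

spearman_oracle <- function(x, y) pearson_oracle(mid_ranks(x), mid_ranks(y))

# Kendall tau-b by explicit all-pairs enumeration
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}
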