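# Shared fixtures and independent oracles, built in code at test time.

# small planted design used across module tests
small_sizes <- function() {
  planted_sizes(
    down = c(`1` = 30, `2` = 40, `3` = 20, `12` = 8, `13` = 6, `23` = 7,
             `123` = 20),
    up = c(`1` = 5, `2` = 4, `3` = 3, `12` = 1, `13` = 1, `23` = 1,
           `123` = 1))
}

small_config <- function(seed = 3, ...) {
  sim_config(n_genes = 500, seed = seed, planted_sizes = small_sizes(), ...)
}

# hypergeometric upper tail by term-by-term pmf enumeration with exact
# integer arithmetic (all binomials involved are far below 2^53 for the
# universe sizes used in tests)
oracle_hyper_terms <- function(o, n_i, n_j, n_u) {
  if (o == 0) return(1)
  ks <- o:min(n_i, n_j)
  num <- sum(choose(n_i, ks) * choose(n_u - n_i, n_j - ks))
  num / choose(n_u, n_j)
}

# hypergeometric upper tail by brute-force enumeration of every possible
# draw of the second list from the universe
oracle_hyper_enum <- function(o, n_i, n_j, n_u) {
  g_i <- seq_len(n_i)
  draws <- combn(n_u, n_j)
  mean(apply(draws, 2, function(gj) length(intersect(g_i, gj)) >= o))
}

# independent per-row mean / standard error via plain loops
oracle_row_stats <- function(values) {
  m <- s <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) {
    x <- values[i, ]
    x <- x[!is.na(x)]
    m[i] <- mean(x)
    s[i] <- sd(x) / sqrt(length(x))
  }
  list(m = m, s = s)
}

# pure-noise ratio matrix
noise_matrix <- function(n = 200, r = 6, sd = 0.5, seed = 1) {
  set.seed(seed)
  ratio_matrix(matrix(rnorm(n * r, 0, sd), n, r),
               clone_ids = sprintf("cl%04d", seq_len(n)),
               orientation = "null")
}

# planted matrix: first n_planted rows have mean -effect (down), rest null
planted_matrix <- function(n = 1000, n_planted = 50, effect = 1.5,
                           sd = 0.5, r = 6, seed = 42) {
  set.seed(seed)
  mu <- c(rep(-effect, n_planted), rep(0, n - n_planted))
  ratio_matrix(matrix(rnorm(n * r, mean = mu, sd = sd), n, r),
               clone_ids = sprintf("cl%04d", seq_len(n)),
               orientation = "planted")
}

negate_matrix <- function(m) {
  ratio_matrix(-m$values, orientation = m$orientation)
}
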