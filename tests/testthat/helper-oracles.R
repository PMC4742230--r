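# Independent oracle implementations, written as plain loops over the
# defining formulas so they share no code with the package internals.

# MATCH score: I(i) = sum_b f(i,b) ln(4 f(i,b)); raw = sum_i I(i) f(i, b_i);
# min-max normalised over per-position extremes.
oracle_match_score <- function(freqs, window) {
  bases <- c("A", "C", "G", "T")
  L <- ncol(freqs)
  info <- numeric(L)
  for (i in seq_len(L)) {
    for (b in 1:4) {
      f <- freqs[b, i]
      if (f > 0) info[i] <- info[i] + f * log(4 * f)
    }
  }
  chars <- strsplit(window, "")[[1]]
  cur <- 0; lo <- 0; hi <- 0
  for (i in seq_len(L)) {
    cur <- cur + info[i] * freqs[match(chars[i], bases), i]
    lo <- lo + info[i] * min(freqs[, i])
    hi <- hi + info[i] * max(freqs[, i])
  }
  if (hi - lo < 1e-12) return(1)
  unname((cur - lo) / (hi - lo))
}

# Upper-tail binomial by exhaustive summation.
oracle_binom_tail <- function(n, k, p) {
  if (k <= 0) return(1)
  total <- 0
  for (j in k:n) total <- total + choose(n, j) * p^j * (1 - p)^(n - j)
  total
}

# Upper-tail hypergeometric by enumeration over all draws of size n_hit
# from N genes (K of them annotated).
oracle_hyper_tail <- function(N, K, n_hit, k_hit) {
  if (k_hit <= 0) return(1)
  draws <- utils::combn(N, n_hit)
  annotated <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= k_hit)
}

# BH step-up by direct application of the rule.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

random_pwm <- function(L, id = "rnd") {
  m <- matrix(runif(4 * L), 4, L)
  pwm(m, id = id, pseudocount = 0)
}

random_window <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
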