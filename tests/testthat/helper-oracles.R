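# Independent oracles and small fixture builders shared across tests.

# brute-force crossnobis: explicit double sum over run pairs, no reuse of
# package internals
oracle_crossnobis <- function(betas) {
  n_runs <- dim(betas)[1]
  n_dig <- dim(betas)[2]
  n_nodes <- dim(betas)[3]
  d <- matrix(0, n_dig, n_dig)
  for (i in seq_len(n_dig)) for (j in seq_len(n_dig)) {
    if (i == j) next
    total <- 0
    npair <- 0
    for (A in seq_len(n_runs)) for (B in seq_len(n_runs)) {
      if (B <= A) next
      s <- 0
      for (v in seq_len(n_nodes)) {
        s <- s + (betas[A, i, v] - betas[A, j, v]) *
          (betas[B, i, v] - betas[B, j, v])
      }
      total <- total + s / n_nodes
      npair <- npair + 1
    }
    d[i, j] <- total / npair
  }
  d
}

# literal term-by-term evaluation of the circular correlation formula,
# with explicit loops and the arctangent circular mean
oracle_circcorr <- function(a1, a2) {
  n <- length(a1)
  cm <- function(a) {
    s <- 0; c <- 0
    for (k in seq_len(n)) { s <- s + sin(a[k]); c <- c + cos(a[k]) }
    atan2(s, c)
  }
  mu1 <- cm(a1); mu2 <- cm(a2)
  num <- 0; d1 <- 0; d2 <- 0
  for (k in seq_len(n)) {
    num <- num + sin(a1[k] - mu1) * sin(a2[k] - mu2)
    d1 <- d1 + sin(a1[k] - mu1)^2
    d2 <- d2 + sin(a2[k] - mu2)^2
  }
  num / sqrt(d1 * d2)
}

# participant-jittered field spec used for cohort-style fixtures: shared
# hand geometry per participant, chosen task gain/width/noise
jittered_spec <- function(p, gain = 1, width = 0.07, noise_sd = 0.2,
                          jitter_seed_offset = 0L) {
  set.seed(p + jitter_seed_offset)
  cen <- sort(pmin(pmax(c(0.1, 0.3, 0.5, 0.7, 0.9) + rnorm(5, 0, 0.015),
                        0.02), 0.98))
  digit_field_spec(centers = cen,
                   widths = rep(width, 5) * exp(rnorm(5, 0, 0.1)),
                   amplitudes = exp(rnorm(5, 0, 0.1)),
                   gain = gain, noise_sd = noise_sd)
}
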