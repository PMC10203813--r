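test_that("reference bank has 20 lag-shifted, cycle-tiled models", {
  bank <- build_reference_bank(tr = 2, cycles = 5)
  expect_equal(dim(bank$models), c(20, 100))
  # model 11 is model 1 circularly shifted by 10 lags (20 s = 10 TRs)
  shift10 <- c(tail(bank$boxcars[1, ], 10), head(bank$boxcars[1, ], 90))
  expect_equal(bank$boxcars[11, ], shift10)
  # boxcar tiling: at any timepoint exactly on_trs of the 20 boxcars are on
  expect_equal(colSums(bank$boxcars), rep(4, 100))
  expect_error(build_reference_bank(tr = 2, lag_seconds = 4), "lag step")
  expect_error(build_reference_bank(tr = 3), "whole number")
})

test_that("winner-take-all recovers the noise-free digit layout", {
  sh <- make_sheet(200)
  spec <- digit_field_spec(noise_sd = 0)
  bank <- build_reference_bank(2, 5)
  fwd <- simulate_localiser(sh, spec, direction = "forward", seed = 1)
  bwd <- simulate_localiser(sh, spec, direction = "backward", seed = 2)
  ca <- assign_digits(fwd, bwd, bank, q = 0.01)
  truth <- apply(true_patterns(sh, spec), 2, which.max)
  expect_equal(sum(ca$winner != truth), 0)
  # clusters are disjoint and contain only FDR-surviving winners
  all_members <- unlist(ca$cluster_members)
  expect_equal(anyDuplicated(all_members), 0)
  for (d in 1:5) {
    expect_true(all(ca$winner[ca$cluster_members[[d]]] == d))
    expect_true(all(ca$passed_fdr[cbind(ca$cluster_members[[d]], d)]))
  }
})

test_that("digit relabelling permutes winners identically", {
  sh <- make_sheet(60)
  spec <- digit_field_spec(noise_sd = 0.3)
  bank <- build_reference_bank(2, 5)
  fwd <- simulate_localiser(sh, spec, direction = "forward", seed = 5)
  bwd <- simulate_localiser(sh, spec, direction = "backward", seed = 6)
  w0 <- assign_digits(fwd, bwd, bank)$winner
  perm <- c(3, 5, 1, 2, 4)
  fwd2 <- fwd; fwd2$digit_order <- perm[fwd$digit_order]
  bwd2 <- bwd; bwd2$digit_order <- perm[bwd$digit_order]
  w1 <- assign_digits(fwd2, bwd2, bank)$winner
  expect_equal(w1, perm[w0])
})

test_that("forward/backward averaging cancels a common haemodynamic delay", {
  sh <- make_sheet(200)
  spec <- digit_field_spec(noise_sd = 0)
  bank <- build_reference_bank(2, 5)
  fwd <- simulate_localiser(sh, spec, direction = "forward", seed = 1)
  bwd <- simulate_localiser(sh, spec, direction = "backward", seed = 2)
  roll <- function(s, k) {
    n <- nrow(s$bold)
    s$bold <- s$bold[c((n - k + 1):n, 1:(n - k)), , drop = FALSE]
    s
  }
  w0 <- assign_digits(fwd, bwd, bank)$winner
  w1 <- assign_digits(roll(fwd, 1), roll(bwd, 1), bank)$winner
  expect_equal(w1, w0)
})

test_that("a pure-noise node essentially never survives the FDR threshold", {
  sh <- make_sheet(50)
  nullspec <- digit_field_spec(amplitudes = rep(1e-9, 5), noise_sd = 0.5)
  bank <- build_reference_bank(2, 5)
  set.seed(11)
  hits <- replicate(200, {
    s <- sample.int(1e6, 2)
    f <- simulate_localiser(sh, nullspec, direction = "forward", seed = s[1])
    b <- simulate_localiser(sh, nullspec, direction = "backward", seed = s[2])
    ca <- assign_digits(f, b, bank, q = 0.01)
    any(ca$passed_fdr[1, ])
  })
  expect_gte(mean(!hits), 0.99)
})

test_that("time-shuffled signal destroys the winner map", {
  sh <- make_sheet(100)
  spec <- digit_field_spec(noise_sd = 0.3)
  bank <- build_reference_bank(2, 5)
  fwd <- simulate_localiser(sh, spec, direction = "forward", seed = 3)
  bwd <- simulate_localiser(sh, spec, direction = "backward", seed = 4)
  truth <- apply(true_patterns(sh, spec), 2, which.max)
  set.seed(1)
  fwd$bold <- fwd$bold[sample(nrow(fwd$bold)), ]
  bwd$bold <- bwd$bold[sample(nrow(bwd$bold)), ]
  ca <- assign_digits(fwd, bwd, bank)
  expect_lt(mean(ca$winner == truth), 0.5)       # near chance (0.2)
  expect_lt(sum(lengths(ca$cluster_members)), 5) # essentially nothing survives
})

test_that("constant time series are excluded with a warning", {
  sh <- make_sheet(20)
  spec <- digit_field_spec(noise_sd = 0.2)
  bank <- build_reference_bank(2, 5)
  fwd <- simulate_localiser(sh, spec, direction = "forward", seed = 1)
  bwd <- simulate_localiser(sh, spec, direction = "backward", seed = 2)
  fwd$bold[, 3] <- 1
  bwd$bold[, 3] <- 1
  expect_warning(ca <- assign_digits(fwd, bwd, bank), "constant")
  expect_true(3 %in% ca$excluded)
  expect_true(is.na(ca$winner[3]))
  expect_error(assign_digits(fwd, bwd, bank, q = 2), "q must")
})

test_that("cluster TSV export writes node table and contiguous spans", {
  sh <- make_sheet(60)
  spec <- digit_field_spec(noise_sd = 0)
  bank <- build_reference_bank(2, 5)
  fwd <- simulate_localiser(sh, spec, direction = "forward", seed = 1)
  bwd <- simulate_localiser(sh, spec, direction = "backward", seed = 2)
  ca <- assign_digits(fwd, bwd, bank)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clusters_tsv(ca, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 60)
  expect_equal(tab$winner, ca$winner)
  spans <- read.delim(paste0(path, ".spans.tsv"))
  # noise-free winner map is ordered D1..D5 along the axis
  expect_equal(spans$digit, 1:5)
})
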