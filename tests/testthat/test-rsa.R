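test_that("prewhitening divides by sigma when the sample covariance is isotropic", {
  set.seed(2)
  n <- 120; p <- 10; sigma <- 0.4
  X <- matrix(rnorm(n * p), n, p)
  Xc <- sweep(X, 2, colMeans(X))
  Xs <- Xc %*% solve(chol(crossprod(Xc) / (n - 1))) * sigma
  res <- array(Xs, c(1, n, p))
  betas <- array(rnorm(2 * 5 * p), c(2, 5, p))
  wh <- prewhiten(betas, res, lambda = 0)
  expect_equal(wh, betas / sigma, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a high-variance node is downweighted in squared-distance contribution", {
  set.seed(3)
  nres <- 4000
  res <- array(0, c(1, nres, 2))
  res[1, , 1] <- rnorm(nres, sd = 1)
  res[1, , 2] <- rnorm(nres, sd = sqrt(10))   # 10x the variance
  betas <- array(1, c(2, 2, 2))
  betas[, 2, ] <- 2                            # unit pattern difference on both nodes
  wh <- prewhiten(betas, res, lambda = 0)
  contrib <- (wh[1, 1, ] - wh[1, 2, ])^2
  expect_equal(contrib[1] / contrib[2], 10, tolerance = 0.25)
})

test_that("whitening is idempotent up to shrinkage", {
  set.seed(4)
  p <- 6; n <- 2000
  L <- matrix(rnorm(p * p, sd = 0.4), p); diag(L) <- 1
  res <- array(matrix(rnorm(n * p), n) %*% t(L), c(1, n, p))
  betas <- array(rnorm(3 * 5 * p), c(3, 5, p))
  w1 <- prewhiten(betas, res, lambda = 0)
  res_w <- array(res[1, , ] %*% attr(w1, "whitener"), c(1, n, p))
  w2 <- prewhiten(array(w1, dim(w1)), res_w, lambda = 0)
  expect_equal(unclass(w2), unclass(w1), tolerance = 0.05, ignore_attr = TRUE)
  expect_error(prewhiten(betas, array(0, c(1, 10, p))), "all zero")
})

test_that("crossnobis matches a hand-computed small example exactly", {
  # 2 runs, 2 digits, 3 nodes, integer patterns
  b <- array(0, c(2, 2, 3))
  b[1, 1, ] <- c(1, 2, 0); b[1, 2, ] <- c(0, 1, 3)
  b[2, 1, ] <- c(2, 1, 1); b[2, 2, ] <- c(1, 0, 2)
  # delta_run1 = (1,1,-3); delta_run2 = (1,1,-1); dot = 1+1+3 = 5; /3 nodes
  rdm <- crossnobis(b)
  expect_equal(rdm[1, 2], 5 / 3)
  expect_equal(rdm[2, 1], 5 / 3)
  expect_equal(diag(unclass(rdm)), c(D1 = 0, D2 = 0))
})

test_that("crossnobis equals the brute-force double sum on random instances", {
  set.seed(5)
  for (i in 1:30) {
    b <- array(rnorm(4 * 3 * 8), c(sample(2:4, 1), 3, sample(2:8, 1)))
    expect_equal(unclass(crossnobis(b)), oracle_crossnobis(b),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("noise-free crossnobis reduces to scaled squared euclidean distance", {
  sh <- make_sheet(40)
  act <- simulate_activity(sh, digit_field_spec(noise_sd = 0), 4, seed = 1)
  rdm <- crossnobis(act$betas)
  truth <- true_patterns(sh, digit_field_spec(noise_sd = 0))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(rdm[i, j], sum((truth[i, ] - truth[j, ])^2) / 40,
                 tolerance = 1e-12)
  }
})

test_that("crossnobis is unbiased under identical true patterns", {
  set.seed(6)
  d <- replicate(400, {
    betas <- array(rnorm(3 * 2 * 12, mean = 1), c(3, 2, 12))
    crossnobis(betas)[1, 2]
  })
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)))
  expect_error(crossnobis(array(1, c(1, 2, 3))), ">= 2 runs")
})

test_that("rdm normalisation rescales without changing shape", {
  set.seed(7)
  m <- crossnobis(array(rnorm(3 * 5 * 10, mean = 1, sd = 2), c(3, 5, 10)))
  nm <- normalise_rdm(m)
  off <- nm[lower.tri(nm)]
  expect_equal(sqrt(mean(off^2)), 1)
  expect_equal(cor(off, m[lower.tri(m)]), 1)
  expect_equal(max(normalise_rdm(m, "max")[lower.tri(m)]), 1)
  expect_error(normalise_rdm(matrix(0, 5, 5)), "all-zero")
})

cohort_rdms <- function(n = 8, gain = 1, noise_sd = 0, sheet_nodes = 60,
                        seed_offset = 0) {
  sh <- make_sheet(sheet_nodes)
  lapply(seq_len(n), function(p) {
    spec <- jittered_spec(p, gain = gain, noise_sd = noise_sd)
    act <- simulate_activity(sh, spec, 3, seed = p + seed_offset)
    if (noise_sd > 0) {
      crossnobis(prewhiten(act$betas, act$residuals))
    } else {
      crossnobis(act$betas)
    }
  })
}

test_that("doubling gain quadruples information content but leaves typicality unchanged", {
  ra <- cohort_rdms(8, gain = 2)
  rp <- cohort_rdms(8, gain = 1)
  rs <- rdm_statistics(ra, rp)
  expect_equal(mean(rs$info_content$task_a) / mean(rs$info_content$task_b), 4,
               tolerance = 1e-10)
  expect_equal(rs$typicality$within_a, rs$typicality$between_a_with_b,
               tolerance = 1e-12)
  expect_gte(rs$typicality_tests$within_a_vs_between_a$p.value, 0.05)
  expect_lt(rs$info_test$p.value, 0.001)
})

test_that("a shared representational shape yields indistinguishable typicality", {
  set.seed(30)
  ok <- replicate(20, {
    ra <- cohort_rdms(6, gain = 1, noise_sd = 0.15,
                      seed_offset = sample.int(1e5, 1))
    rp <- cohort_rdms(6, gain = 1, noise_sd = 0.15,
                      seed_offset = sample.int(1e5, 1))
    rs <- rdm_statistics(ra, rp)
    rs$typicality_tests$within_a_vs_between_a$p.value > 0.05
  })
  expect_gte(mean(ok), 0.9)
})

test_that("an atypical participant is flagged by the 3-sigma rule", {
  # note: with one aberrant value among n, the most extreme z-score is
  # bounded by (n-1)/sqrt(n), so a 3-sigma rule needs n >= 11 to fire at all
  set.seed(9)
  base <- matrix(0, 5, 5)
  base[lower.tri(base)] <- c(1, 2, 3, 4, 1.5, 2.5, 3.5, 1.2, 2.2, 1.1)
  base <- base + t(base)
  jitter_rdm <- function() {
    e <- matrix(0, 5, 5)
    e[lower.tri(e)] <- rnorm(10, sd = 0.01)
    m <- base + e + t(e)
    structure(m, class = c("rdm", "matrix"))
  }
  ra <- replicate(15, jitter_rdm(), simplify = FALSE)
  rp <- replicate(15, jitter_rdm(), simplify = FALSE)
  # one participant carries an RDM anti-correlated with the group shape
  odd <- max(base) - base
  diag(odd) <- 0
  ra[[4]] <- structure(odd, class = c("rdm", "matrix"))
  rs <- rdm_statistics(ra, rp)
  expect_true(4 %in% rs$excluded)
  expect_false(is.null(rs$after_exclusion))
  expect_equal(nrow(rs$after_exclusion$typicality), 14)
  # exclusion is idempotent on the remaining cohort
  rs2 <- rdm_statistics(ra[-rs$excluded], rp[-rs$excluded])
  expect_length(rs2$excluded, 0)
})

test_that("MDS embeds a line of points exactly and aligns rotated copies", {
  pts <- c(0, 1, 2.5, 4, 7)
  rdm <- outer(pts, pts, function(a, b) (a - b)^2)
  mp <- mds_project(list(rdm), k = 1)
  expect_equal(as.matrix(dist(mp$coords))^2, rdm, tolerance = 1e-6,
               ignore_attr = TRUE)
  # a rotated/reflected/translated copy averages back onto the reference
  set.seed(10)
  X <- matrix(rnorm(10), 5, 2)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  D1 <- as.matrix(dist(X))^2
  mpa <- mds_project(list(D1, D1), k = 2)
  dd <- as.matrix(dist(mpa$coords))^2
  expect_equal(dd, D1, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("averaged MDS distances track the mean RDM on smooth cohorts", {
  rdms <- cohort_rdms(8, gain = 1, noise_sd = 0.05)
  mean_rdm <- Reduce(`+`, lapply(rdms, unclass)) / length(rdms)
  # five points embed exactly in four dimensions; fidelity is near-perfect
  mp4 <- mds_project(rdms, k = 4)
  emb4 <- as.matrix(dist(mp4$coords))^2
  expect_gt(cor(emb4[lower.tri(emb4)], mean_rdm[lower.tri(mean_rdm)]), 0.95)
  # the 2-D visualisation projection still preserves most of the structure
  mp <- mds_project(rdms, k = 2)
  emb <- as.matrix(dist(mp$coords))^2
  expect_gt(cor(emb[lower.tri(emb)], mean_rdm[lower.tri(mean_rdm)]), 0.85)
  # degenerate all-zero RDM is skipped with a warning
  expect_warning(mds_project(list(matrix(0, 5, 5), unclass(rdms[[1]]))),
                 "skipped")
})

test_that("RDM CSV round-trips with metadata", {
  m <- crossnobis(array(rnorm(2 * 5 * 6), c(2, 5, 6)), task = "active",
                  participant_id = "p03")
  path <- withr::local_tempfile(fileext = ".csv")
  write_rdm_csv(m, path)
  back <- as.matrix(read.csv(path, row.names = 1))
  expect_equal(back, unclass(m), tolerance = 1e-10, ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$task, "active")
})
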