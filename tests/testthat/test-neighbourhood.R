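make_clusters <- function(sheet, spec) {
  bank <- build_reference_bank(2, 5)
  fwd <- simulate_localiser(sheet, spec, direction = "forward", seed = 91)
  bwd <- simulate_localiser(sheet, spec, direction = "backward", seed = 92)
  assign_digits(fwd, bwd, bank)
}

test_that("noise-free cluster activity is maximal for the cluster's own digit", {
  sh <- make_sheet(150)
  spec <- digit_field_spec(noise_sd = 0)
  cl <- make_clusters(sh, spec)
  act <- simulate_activity(sh, spec, 4, seed = 1, task_label = "active")
  pas <- simulate_activity(sh, spec, 4, seed = 2, task_label = "passive")
  tb <- extract_cluster_activity(list(active = act, passive = pas), cl)
  sel <- selectivity_ratios(tb)
  expect_equal(unname(sel$hits), c(5L, 5L))
  # shift leaves the within-participant minimum at exactly zero
  expect_equal(min(tb$values, na.rm = TRUE), 0)
})

test_that("activity table scales with gain before the shift", {
  sh <- make_sheet(120)
  spec1 <- digit_field_spec(noise_sd = 0, gain = 1)
  spec2 <- digit_field_spec(noise_sd = 0, gain = 2)
  cl <- make_clusters(sh, spec1)
  t1 <- extract_cluster_activity(list(a = simulate_activity(sh, spec1, 2, seed = 1)), cl)
  t2 <- extract_cluster_activity(list(a = simulate_activity(sh, spec2, 2, seed = 1)), cl)
  raw1 <- t1$values + t1$shift_applied
  raw2 <- t2$values + t2$shift_applied
  expect_equal(raw2, 2 * raw1, tolerance = 1e-10)
})

test_that("constant activity collapses to all-zero shifted cells", {
  sh <- make_sheet(150)
  cl <- make_clusters(sh, digit_field_spec(noise_sd = 0))
  act <- simulate_activity(sh, digit_field_spec(noise_sd = 0), 2, seed = 1)
  act$betas[] <- 4.2
  tb <- extract_cluster_activity(list(a = act), cl)
  expect_true(all(tb$values == 0))
  expect_equal(tb$shift_applied, 4.2)
})

test_that("selectivity ratios follow the target-normalised difference formula", {
  tb <- structure(list(values = array(NA_real_, c(1, 5, 5),
                                      dimnames = list("a", paste0("C", 1:5),
                                                      paste0("D", 1:5))),
                       shift_applied = 0, tasks = "a"),
                  class = "cluster_activity")
  for (cl in 1:5) {
    row <- rep(2, 5)
    nb <- intersect(c(cl - 1, cl + 1), 1:5)
    row[nb] <- 5
    row[cl] <- 10
    tb$values[1, cl, ] <- row
  }
  sel <- selectivity_ratios(tb)
  expect_equal(unname(sel$neighbour_diff), 0.5)
  expect_equal(unname(sel$nonneighbour_diff), 0.8)
  # perfectly selective cluster profile gives both ratios = 1
  tb$values[] <- 0
  for (cl in 1:5) tb$values[1, cl, cl] <- 3
  sel2 <- selectivity_ratios(tb)
  expect_equal(unname(sel2$neighbour_diff), 1)
  expect_equal(unname(sel2$nonneighbour_diff), 1)
})

test_that("D1-D5 wrap variant changes only the edge clusters", {
  vals <- array(runif(25, 1, 2), c(1, 5, 5),
                dimnames = list("a", paste0("C", 1:5), paste0("D", 1:5)))
  for (cl in 1:5) vals[1, cl, cl] <- 5
  tb <- structure(list(values = vals, shift_applied = 0, tasks = "a"),
                  class = "cluster_activity")
  s0 <- selectivity_ratios(tb, d1d5_neighbours = FALSE)
  s1 <- selectivity_ratios(tb, d1d5_neighbours = TRUE)
  expect_equal(s0$per_cluster[1, 2:4, ], s1$per_cluster[1, 2:4, ])
  expect_false(isTRUE(all.equal(s0$per_cluster[1, 1, ], s1$per_cluster[1, 1, ])))
})

test_that("wider fields reduce neighbour selectivity across seeds", {
  sh <- make_sheet(120)
  cl <- make_clusters(sh, digit_field_spec(noise_sd = 0))
  nb_sel <- function(width, seed) {
    spec <- digit_field_spec(widths = rep(width, 5), noise_sd = 0.1)
    act <- simulate_activity(sh, spec, 4, seed = seed)
    tb <- extract_cluster_activity(list(a = act), cl)
    unname(selectivity_ratios(tb)$neighbour_diff)
  }
  for (seed in 1:5) {
    expect_gt(nb_sel(0.05, seed), nb_sel(0.1, seed))
  }
})

test_that("gaussian fields put non-neighbour selectivity above neighbour selectivity", {
  sh <- make_sheet(150)
  cl <- make_clusters(sh, digit_field_spec(noise_sd = 0))
  for (p in 1:8) {
    act <- simulate_activity(sh, jittered_spec(p, noise_sd = 0.1), 4, seed = 300 + p)
    sel <- selectivity_ratios(extract_cluster_activity(list(a = act), cl))
    expect_gt(unname(sel$nonneighbour_diff), unname(sel$neighbour_diff))
  }
})

test_that("paired-contrast 2x2 ANOVA matches the aov oracle", {
  set.seed(13)
  n <- 12
  cells <- list(y11 = rnorm(n, 1), y12 = rnorm(n, 0.8),
                y21 = rnorm(n, 0.3), y22 = rnorm(n, 0.5))
  an <- somatomap:::rm_anova_2x2(cells$y11, cells$y12, cells$y21, cells$y22)
  long <- data.frame(
    y = c(cells$y11, cells$y12, cells$y21, cells$y22),
    A = factor(rep(c("a1", "a1", "a2", "a2"), each = n)),
    B = factor(rep(c("b1", "b2", "b1", "b2"), each = n)),
    id = factor(rep(seq_len(n), 4))
  )
  fit <- summary(aov(y ~ A * B + Error(id / (A * B)), data = long))
  f_aov <- c(fit[["Error: id:A"]][[1]]["A", "F value"],
             fit[["Error: id:B"]][[1]]["B", "F value"],
             fit[["Error: id:A:B"]][[1]]["A:B", "F value"])
  expect_equal(unname(an[, "F"]), f_aov, tolerance = 1e-8)
})

test_that("task-identical cohorts show no task effect but a neighbourhood effect", {
  sh <- make_sheet(120)
  cl <- make_clusters(sh, digit_field_spec(noise_sd = 0))
  sels <- lapply(1:8, function(p) {
    spec <- jittered_spec(p, noise_sd = 0.15)
    a <- simulate_activity(sh, spec, 4, seed = 400 + p, task_label = "active")
    b <- simulate_activity(sh, spec, 4, seed = 800 + p, task_label = "passive")
    selectivity_ratios(extract_cluster_activity(list(active = a, passive = b), cl))
  })
  inf <- neighbourhood_inference(sels)
  expect_lt(inf$anova["task", "F"], inf$anova["neighbourhood", "F"] / 10)
  expect_gt(inf$anova["task", "p"], 0.05)
  expect_lt(inf$anova["neighbourhood", "p"], 0.001)
  expect_equal(nrow(inf$wilcoxon), 4)
  expect_equal(inf$alpha_followup, 0.0125)
  # within-task neighbour vs non-neighbour follow-ups are significant
  expect_lt(inf$wilcoxon$p[1], 0.0125)
  expect_lt(inf$wilcoxon$p[2], 0.0125)
})

test_that("narrower passive fields drive a neighbourhood-by-task interaction", {
  sh <- make_sheet(150)
  bank <- build_reference_bank(2, 5)
  detected <- logical(10)
  for (cohort in 1:10) {
    sels <- vector("list", 15)
    for (p in 1:15) {
      seed0 <- cohort * 1000 + p
      spA <- jittered_spec(p, width = 0.085, noise_sd = 0.2,
                           jitter_seed_offset = cohort * 37L)
      spP <- jittered_spec(p, width = 0.06, noise_sd = 0.2,
                           jitter_seed_offset = cohort * 37L)
      spL <- jittered_spec(p, width = 0.07, noise_sd = 0.5,
                           jitter_seed_offset = cohort * 37L)
      fwd <- simulate_localiser(sh, spL, direction = "forward", seed = seed0 + 1)
      bwd <- simulate_localiser(sh, spL, direction = "backward", seed = seed0 + 2)
      clp <- assign_digits(fwd, bwd, bank)
      a <- simulate_activity(sh, spA, 4, seed = seed0 + 3, task_label = "active")
      b <- simulate_activity(sh, spP, 4, seed = seed0 + 4, task_label = "passive")
      tb <- suppressWarnings(
        extract_cluster_activity(list(active = a, passive = b), clp))
      sels[[p]] <- suppressWarnings(selectivity_ratios(tb))
    }
    inf <- neighbourhood_inference(sels)
    detected[cohort] <- inf$anova["neighbourhood_x_task", "p"] < 0.05 &&
      mean(inf$cells$nb_b) > mean(inf$cells$nb_a)  # passive more selective
  }
  expect_gte(mean(detected), 0.8)
})

test_that("a doubled active gain shows up in the overall-activity comparison", {
  sh <- make_sheet(120)
  cl <- make_clusters(sh, digit_field_spec(noise_sd = 0))
  tabs <- lapply(1:8, function(p) {
    a <- simulate_activity(sh, jittered_spec(p, gain = 2), 4,
                           seed = 600 + p, task_label = "active")
    b <- simulate_activity(sh, jittered_spec(p, gain = 1), 4,
                           seed = 900 + p, task_label = "passive")
    extract_cluster_activity(list(active = a, passive = b), cl)
  })
  sels <- lapply(tabs, selectivity_ratios)
  inf <- neighbourhood_inference(sels, activity_tables = tabs)
  expect_lt(inf$overall_activity$p.value, 0.01)
  expect_gt(unname(inf$overall_activity$estimate), 0)
})
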