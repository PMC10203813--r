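#' Multivariate noise normalisation (prewhitening) of activity patterns
#'
#' Estimates the node-wise noise covariance from the GLM residuals (pooled
#' over runs), regularises it by shrinkage towards its diagonal, and
#' post-multiplies the beta patterns by the inverse matrix square root, so
#' that noisy (groups of) nodes are downweighted in all subsequent distances.
#'
#' The shrinkage intensity defaults to the analytic Schafer-Strimmer /
#' Ledoit-Wolf estimate for a diagonal target, clamped to \code{[0, 1]};
#' pass \code{lambda = 0} for no shrinkage.
#'
#' @param betas runs x digits x nodes array.
#' @param residuals runs x timepoints x nodes array (>= 2 timepoints).
#' @param lambda Shrinkage intensity in \code{[0, 1]}, or \code{"auto"}.
#' @return The whitened betas (same shape), with attributes
#'   \code{"lambda"} (the intensity used) and \code{"whitener"}
#'   (the nodes x nodes transform).
#' @export
prewhiten <- function(betas, residuals, lambda = "auto") {
  stopifnot(length(dim(betas)) == 3, length(dim(residuals)) == 3,
            dim(betas)[3] == dim(residuals)[3])
  if (dim(residuals)[2] < 2) stop("need >= 2 residual timepoints", call. = FALSE)
  n_nodes <- dim(betas)[3]
  X <- matrix(aperm(residuals, c(2, 1, 3)), ncol = n_nodes)  # (runs*T) x nodes
  if (all(X == 0)) stop("residuals are all zero; noise covariance undefined",
                        call. = FALSE)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / (n - 1)

  if (identical(lambda, "auto")) {
    # analytic shrinkage toward diag(S): sum of estimated variances of the
    # off-diagonal sample covariances over their squared magnitude
    num <- 0; den <- 0
    W <- Xc
    for (i in seq_len(n_nodes)) {
      wij <- W * W[, i]                        # n x nodes products
      vij <- colSums(sweep(wij, 2, colMeans(wij))^2) * n / (n - 1)^3
      keep <- seq_len(n_nodes) != i
      num <- num + sum(vij[keep])
      den <- den + sum(S[i, keep]^2)
    }
    lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  }
  stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
  Sigma <- (1 - lambda) * S + lambda * diag(diag(S), n_nodes)

  eg <- eigen(Sigma, symmetric = TRUE)
  evals <- pmax(eg$values, max(eg$values) * 1e-10)
  whitener <- eg$vectors %*% diag(1 / sqrt(evals), n_nodes) %*% t(eg$vectors)

  out <- betas
  for (r in seq_len(dim(betas)[1])) {
    out[r, , ] <- betas[r, , ] %*% whitener
  }
  attr(out, "lambda") <- lambda
  attr(out, "whitener") <- whitener
  out
}

#' Cross-validated squared Mahalanobis (crossnobis) distances
#'
#' Computes the 5x5 representational dissimilarity matrix of cross-validated
#' squared distances between (whitened) digit patterns:
#' \deqn{d_{ij} = \mathrm{mean}_{(A,B),\,A \ne B}
#'   \; (b_{iA} - b_{jA}) \cdot (b_{iB} - b_{jB}) / n_{nodes}}
#' over all unordered run pairs. Because pattern estimates from independent
#' runs carry independent noise, the estimator is unbiased: its expectation
#' is 0 when the true patterns are identical, and entries may be negative
#' under noise. The per-node divisor makes distances mask-size invariant.
#'
#' @param whitened runs x digits x nodes array (prewhitened betas, or raw
#'   betas for isotropic noise).
#' @param task,participant_id Optional labels attached to the result.
#' @return An \code{rdm}: a digits x digits symmetric matrix with zero
#'   diagonal and attributes \code{task} and \code{participant_id}.
#' @export
crossnobis <- function(whitened, task = NA, participant_id = NA) {
  stopifnot(length(dim(whitened)) == 3)
  n_runs <- dim(whitened)[1]
  n_dig <- dim(whitened)[2]
  n_nodes <- dim(whitened)[3]
  if (n_runs < 2) stop("crossnobis needs >= 2 runs", call. = FALSE)
  d <- matrix(0, n_dig, n_dig)
  pairs <- utils::combn(n_runs, 2)
  for (i in seq_len(n_dig - 1)) {
    for (j in (i + 1):n_dig) {
      acc <- 0
      for (p in seq_len(ncol(pairs))) {
        A <- pairs[1, p]; B <- pairs[2, p]
        dA <- whitened[A, i, ] - whitened[A, j, ]
        dB <- whitened[B, i, ] - whitened[B, j, ]
        acc <- acc + sum(dA * dB)
      }
      d[i, j] <- d[j, i] <- acc / (ncol(pairs) * n_nodes)
    }
  }
  dimnames(d) <- list(paste0("D", seq_len(n_dig)), paste0("D", seq_len(n_dig)))
  structure(d, class = c("rdm", "matrix"), task = task,
            participant_id = participant_id)
}

offdiag <- function(m) m[lower.tri(m)]

#' Normalise an RDM for averaging
#'
#' Divides all entries by a scale statistic of the off-diagonal distances so
#' cohort averages are not biased towards participants with larger overall
#' dissimilarity. Default scale: root-mean-square of the off-diagonal.
#'
#' @param rdm An \code{rdm} or plain matrix.
#' @param method \code{"rms"}, \code{"mean"} or \code{"max"} of the
#'   off-diagonal.
#' @return The rescaled matrix (attributes preserved).
#' @export
normalise_rdm <- function(rdm, method = c("rms", "mean", "max")) {
  method <- match.arg(method)
  v <- offdiag(rdm)
  s <- switch(method, rms = sqrt(mean(v^2)), mean = mean(v), max = max(v))
  if (s == 0) stop("cannot normalise an all-zero RDM", call. = FALSE)
  out <- rdm / s
  attributes(out) <- attributes(rdm)
  out
}

#' Cohort RDM statistics: information content, typicality, outlier exclusion
#'
#' For paired cohorts of per-participant RDMs from two tasks, computes:
#' (1) information content — the mean of the 10 off-diagonal distances per
#' participant and task, compared between tasks with a paired t-test;
#' (2) representational typicality — the Pearson (or Spearman) correlation of
#' each participant's RDM off-diagonal vector with the leave-one-out mean of
#' the normalised cohort RDMs, within task and between tasks, with paired
#' t-tests of every within/between combination; and (3) the outlier rule —
#' participants whose within-task typicality falls more than
#' \code{outlier_sigma} SDs below the group mean are excluded and the
#' statistics recomputed.
#'
#' @param rdms_a,rdms_b Lists of \code{rdm}s for task A and task B, aligned
#'   by participant.
#' @param normalise Normalisation method for averaging (see
#'   [normalise_rdm()]).
#' @param cor_method \code{"pearson"} (default) or \code{"spearman"}.
#' @param outlier_sigma Exclusion threshold in group SDs (default 3).
#' @return An \code{rdm_statistics} list: \code{info_content} (per
#'   participant x task), \code{info_test}, \code{typicality} (data frame
#'   with within/between columns), \code{typicality_tests}, \code{excluded}
#'   (indices), and \code{after_exclusion} (the same statistics recomputed,
#'   or NULL if nothing was excluded).
#' @export
rdm_statistics <- function(rdms_a, rdms_b, normalise = "rms",
                           cor_method = c("pearson", "spearman"),
                           outlier_sigma = 3) {
  cor_method <- match.arg(cor_method)
  n <- length(rdms_a)
  stopifnot(n == length(rdms_b), n >= 3)

  core <- function(rdms_a, rdms_b) {
    va <- vapply(rdms_a, offdiag, numeric(10))   # 10 x n
    vb <- vapply(rdms_b, offdiag, numeric(10))
    info <- data.frame(task_a = colMeans(va), task_b = colMeans(vb))
    info_test <- stats::t.test(info$task_a, info$task_b, paired = TRUE)

    norm_a <- vapply(lapply(rdms_a, normalise_rdm, method = normalise),
                     offdiag, numeric(10))
    norm_b <- vapply(lapply(rdms_b, normalise_rdm, method = normalise),
                     offdiag, numeric(10))
    loo_cor <- function(own, pool) {
      vapply(seq_len(ncol(own)), function(i) {
        ref <- rowMeans(pool[, -i, drop = FALSE])
        if (stats::sd(own[, i]) == 0 || stats::sd(ref) == 0) {
          warning("zero-variance RDM vector; typicality undefined")
          return(NA_real_)
        }
        stats::cor(own[, i], ref, method = cor_method)
      }, 0)
    }
    typ <- data.frame(
      within_a = loo_cor(norm_a, norm_a),
      within_b = loo_cor(norm_b, norm_b),
      between_a_with_b = loo_cor(norm_a, norm_b),
      between_b_with_a = loo_cor(norm_b, norm_a)
    )
    paired_p <- function(x, y) {
      d <- x - y
      if (all(abs(d - mean(d)) < 1e-14)) {
        # degenerate: differences (near-)constant; no evidence of a difference
        return(list(statistic = 0, p.value = 1))
      }
      h <- stats::t.test(x, y, paired = TRUE)
      list(statistic = unname(h$statistic), p.value = h$p.value)
    }
    tests <- list(
      within_a_vs_between_a = paired_p(typ$within_a, typ$between_a_with_b),
      within_b_vs_between_b = paired_p(typ$within_b, typ$between_b_with_a),
      within_a_vs_between_b = paired_p(typ$within_a, typ$between_b_with_a),
      within_b_vs_between_a = paired_p(typ$within_b, typ$between_a_with_b),
      within_a_vs_within_b = paired_p(typ$within_a, typ$within_b)
    )
    list(info_content = info, info_test = info_test, typicality = typ,
         typicality_tests = tests)
  }

  res <- core(rdms_a, rdms_b)
  low <- function(v) {
    mu <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(FALSE, length(v)))
    !is.na(v) & v < mu - outlier_sigma * s
  }
  excluded <- which(low(res$typicality$within_a) | low(res$typicality$within_b) |
                      is.na(res$typicality$within_a) |
                      is.na(res$typicality$within_b))
  after <- NULL
  if (length(excluded) > 0 && n - length(excluded) >= 3) {
    after <- core(rdms_a[-excluded], rdms_b[-excluded])
  }
  structure(c(res, list(excluded = excluded, after_exclusion = after,
                        normalise = normalise, cor_method = cor_method,
                        outlier_sigma = outlier_sigma)),
            class = "rdm_statistics")
}

#' MDS projection of a cohort of RDMs with Procrustes averaging
#'
#' Classical multidimensional scaling of each participant's RDM (negative
#' crossnobis entries are clipped to 0 for the embedding only), Procrustes
#' alignment (rotation/reflection and translation, no scaling) of every
#' configuration to the first participant's, and averaging. Output dimensions
#' are ordered by between-digit variance of the averaged configuration.
#'
#' @param rdms List of \code{rdm}s.
#' @param k Embedding dimension (default 2).
#' @return An \code{mds_projection} list: \code{coords} (digits x k averaged
#'   coordinates), \code{per_participant} (list of aligned configurations),
#'   \code{skipped} (degenerate RDM indices).
#' @export
mds_project <- function(rdms, k = 2) {
  stopifnot(length(rdms) >= 1)
  clip <- function(m) { m[m < 0] <- 0; m }
  configs <- list(); skipped <- integer(0)
  for (i in seq_along(rdms)) {
    m <- clip(unclass(rdms[[i]]))
    if (all(m == 0)) {
      warning("all-zero RDM skipped in MDS averaging (participant ", i, ")")
      skipped <- c(skipped, i)
      next
    }
    cfg <- stats::cmdscale(sqrt(m), k = k)  # sqrt: cmdscale expects distances
    configs[[length(configs) + 1L]] <- cfg
  }
  if (length(configs) == 0) stop("no embeddable RDMs", call. = FALSE)
  ref <- configs[[1]]
  aligned <- lapply(configs, function(cfg) {
    pr <- vegan::procrustes(ref, cfg, scale = FALSE)
    stats::predict(pr, cfg)
  })
  coords <- Reduce(`+`, aligned) / length(aligned)
  ord <- order(apply(coords, 2, stats::var), decreasing = TRUE)
  coords <- coords[, ord, drop = FALSE]
  rownames(coords) <- rownames(rdms[[1]])
  structure(list(coords = coords, per_participant = aligned,
                 skipped = skipped),
            class = "mds_projection")
}

#' Write / read an RDM as CSV with JSON metadata
#' @param rdm An \code{rdm}.
#' @param path Output CSV path; metadata goes to \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_rdm_csv <- function(rdm, path) {
  utils::write.csv(as.data.frame(unclass(rdm)), path, row.names = TRUE)
  jsonlite::write_json(
    list(task = attr(rdm, "task"), participant_id = attr(rdm, "participant_id")),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}
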