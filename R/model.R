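#' Parameters of the five-unit cortical model
#'
#' A parsimonious model of the SI hand area: five cortical units (one per
#' digit-specific cluster) receive pooled peripheral input from the five
#' digits and interact laterally, each unit exciting or inhibiting the
#' others. Stimulating digit \eqn{d} injects
#' \eqn{gain \cdot E[,d] \odot s} (enslavement-mixed, per-digit scaled
#' input) and the steady state solves
#' \eqn{r = [W r + input]_+} (rectification optional).
#'
#' @param W 5x5 lateral weight matrix (spectral radius < 1).
#' @param input_gain Positive task-level gain.
#' @param enslavement 5x5 nonnegative input-mixing matrix, diagonal-dominant
#'   row-wise.
#' @param input_scale Five positive per-digit input magnitudes.
#' @param rectify Apply output rectification (default FALSE: linear regime).
#' @return A \code{model_params} list.
#' @export
model_params <- function(W = matrix(0, 5, 5), input_gain = 1,
                         enslavement = diag(5), input_scale = rep(1, 5),
                         rectify = FALSE) {
  W <- as.matrix(W)
  stopifnot(all(dim(W) == c(5, 5)), input_gain > 0,
            length(input_scale) == 5, all(input_scale > 0))
  enslavement <- as.matrix(enslavement)
  stopifnot(all(dim(enslavement) == c(5, 5)), all(enslavement >= 0))
  offmax <- apply(enslavement - diag(diag(enslavement)), 1, max)
  if (any(diag(enslavement) < offmax)) {
    stop("enslavement diagonal must dominate its row", call. = FALSE)
  }
  if (spectral_radius(W) >= 1) {
    stop("unstable lateral network: spectral radius of W must be < 1",
         call. = FALSE)
  }
  structure(list(W = W, input_gain = input_gain, enslavement = enslavement,
                 input_scale = as.numeric(input_scale),
                 rectify = isTRUE(rectify)),
            class = "model_params")
}

spectral_radius <- function(W) max(Mod(eigen(W, only.values = TRUE)$values))

#' Steady-state response of the model to stimulation of one digit
#'
#' Solves \eqn{r = W r + u} (linear regime: \eqn{r = (I - W)^{-1} u}) or the
#' rectified fixed point \eqn{r = [W r + u]_+} by damped iteration, where
#' \eqn{u = gain \cdot (E[, d] \odot s)}.
#'
#' @param params A \code{model_params}.
#' @param stimulated_digit Digit 1-5.
#' @return Numeric vector of the five unit responses.
#' @export
model_forward <- function(params, stimulated_digit) {
  stopifnot(inherits(params, "model_params"),
            stimulated_digit %in% 1:5)
  u <- params$input_gain *
    (params$enslavement[, stimulated_digit] * params$input_scale)
  if (!params$rectify) {
    return(as.numeric(solve(diag(5) - params$W, u)))
  }
  r <- pmax(u, 0)
  for (it in seq_len(1000)) {
    r_new <- pmax(params$W %*% r + u, 0)
    if (max(abs(r_new - r)) < 1e-12) return(as.numeric(r_new))
    r <- r_new
  }
  warning("rectified fixed point did not fully converge")
  as.numeric(r)
}

#' Full 5x5 model response matrix and predicted RDM
#'
#' @param params A \code{model_params}.
#' @return A \code{model_response} list: \code{R} (units x stimulated digits)
#'   and \code{predicted_rdm} (squared Euclidean distances between response
#'   patterns, per unit).
#' @export
model_response <- function(params) {
  R <- sapply(1:5, function(d) model_forward(params, d))
  dimnames(R) <- list(paste0("unit", 1:5), paste0("D", 1:5))
  rdm <- matrix(0, 5, 5, dimnames = dimnames(R)[c(2, 2)])
  for (i in 1:4) for (j in (i + 1):5) {
    rdm[i, j] <- rdm[j, i] <- sum((R[, i] - R[, j])^2) / 5
  }
  structure(list(R = R, predicted_rdm = rdm), class = "model_response")
}

# pack/unpack free parameters for the optimiser
free_param_info <- function(free, base) {
  info <- list()
  if ("gain" %in% free) {
    info$gain <- list(n = 1L, lower = 0.01, upper = 10,
                      start = function() stats::runif(1, 0.2, 5))
  }
  if ("input_scale" %in% free) {
    info$input_scale <- list(n = 5L, lower = rep(0.01, 5), upper = rep(10, 5),
                             start = function() stats::runif(5, 0.2, 5))
  }
  if ("W" %in% free) {
    info$W <- list(n = 25L, lower = rep(-0.5, 25), upper = rep(0.9, 25),
                   start = function() stats::runif(25, -0.1, 0.2))
  }
  if ("enslavement_strength" %in% free) {
    info$enslavement_strength <- list(n = 1L, lower = 0, upper = 1,
                                      start = function() stats::runif(1))
  }
  info
}

apply_free <- function(base, free_info, theta) {
  p <- unclass(base)
  pos <- 1L
  for (nm in names(free_info)) {
    n <- free_info[[nm]]$n
    v <- theta[pos:(pos + n - 1L)]
    pos <- pos + n
    if (nm == "gain") p$input_gain <- v
    else if (nm == "input_scale") p$input_scale <- v
    else if (nm == "W") p$W <- matrix(v, 5, 5)
    else if (nm == "enslavement_strength") {
      p$enslavement <- (1 - v) * diag(5) + v * typical_enslavement()
    }
  }
  p
}

#' Fit model parameters to a 5x5 response profile
#'
#' Bounded least squares on the selected free parameters with seeded
#' multi-starts; all other parameters are taken from \code{base}. The
#' response matrix of the fitted model is matched to \code{target} by the
#' sum of squared errors; candidate lateral weights approaching instability
#' are penalised.
#'
#' @param target 5x5 matrix of responses (units/clusters x stimulated
#'   digits), e.g. one task's slice of a [extract_cluster_activity()] table
#'   (transposed to cluster x digit) or a model-generated profile.
#' @param free Character subset of
#'   \code{c("gain", "input_scale", "W", "enslavement_strength")}.
#' @param base A \code{model_params} supplying the fixed parameters.
#' @param n_starts Number of multi-starts (default 20).
#' @param seed Integer seed for the starts.
#' @return A \code{model_fit} list: \code{params} (best-fit
#'   \code{model_params}), \code{loss}, \code{theta}, \code{free},
#'   \code{losses} (per start).
#' @export
fit_to_profiles <- function(target, free, base = model_params(),
                            n_starts = 20L, seed = 1L) {
  target <- as.matrix(target)
  stopifnot(all(dim(target) == c(5, 5)), !anyNA(target))
  free <- match.arg(free, c("gain", "input_scale", "W",
                            "enslavement_strength"), several.ok = TRUE)
  info <- free_param_info(free, base)
  lower <- unlist(lapply(info, `[[`, "lower"), use.names = FALSE)
  upper <- unlist(lapply(info, `[[`, "upper"), use.names = FALSE)

  loss_fn <- function(theta) {
    p <- apply_free(base, info, theta)
    sr <- spectral_radius(p$W)
    if (sr >= 0.99) return(1e6 * (1 + sr))
    class(p) <- "model_params"
    R <- sapply(1:5, function(d) model_forward(p, d))
    sum((R - target)^2)
  }

  set.seed(as.integer(seed))
  best <- NULL
  losses <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    theta0 <- unlist(lapply(info, function(i) i$start()), use.names = FALSE)
    fit <- try(stats::optim(theta0, loss_fn, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500, factr = 1e4)),
               silent = TRUE)
    if (inherits(fit, "try-error")) { losses[s] <- Inf; next }
    losses[s] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimisation failed in every start", call. = FALSE)
  p <- apply_free(base, info, best$par)
  class(p) <- "model_params"
  structure(list(params = p, loss = best$value, theta = best$par,
                 free = free, losses = losses),
            class = "model_fit")
}

#' Compare gain, enslavement and digit-specific accounts of task differences
#'
#' Starting from a model fitted to the passive task profile, fits three
#' hypotheses about what changes in the active task: a single gain scalar
#' (gain modulation), a typical enslavement mixing of the pooled inputs
#' (with its strength and a gain free), or unconstrained digit-specific
#' input scales. Reports each hypothesis's residual loss and its predicted
#' active/passive ratio of mean RDM distance (gain modulation predicts
#' \eqn{g^2}).
#'
#' @param passive_fit A \code{model_params} fitted to the passive profile.
#' @param active_target 5x5 active-task response profile.
#' @param n_starts,seed Passed to [fit_to_profiles()].
#' @return A \code{hypothesis_report} list: \code{fits} (per hypothesis),
#'   \code{losses} (named vector), \code{rdm_ratio} (named vector),
#'   \code{best} (name of the lowest-loss hypothesis).
#' @export
compare_hypotheses <- function(passive_fit, active_target, n_starts = 20L,
                               seed = 1L) {
  stopifnot(inherits(passive_fit, "model_params"))
  hyps <- list(
    gain_only = "gain",
    enslavement_only = c("gain", "enslavement_strength"),
    digit_specific = "input_scale"
  )
  passive_rdm_mean <- mean(offdiag(model_response(passive_fit)$predicted_rdm))
  fits <- lapply(seq_along(hyps), function(i) {
    fit_to_profiles(active_target, free = hyps[[i]], base = passive_fit,
                    n_starts = n_starts, seed = seed + i)
  })
  names(fits) <- names(hyps)
  losses <- vapply(fits, `[[`, 0, "loss")
  ratio <- vapply(fits, function(f) {
    mean(offdiag(model_response(f$params)$predicted_rdm)) / passive_rdm_mean
  }, 0)
  structure(list(fits = fits, losses = losses, rdm_ratio = ratio,
                 best = names(which.min(losses))),
            class = "hypothesis_report")
}
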