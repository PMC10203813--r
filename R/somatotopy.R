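#' Weighted digit-preference index
#'
#' A node's digit preference: the average of digit identity (1-5) weighted by
#' the node's z-statistic for each digit. Negative z-values are clamped to
#' zero before weighting (the index presumes nonnegative weights). A node
#' whose weights are all zero has no defined preference and returns
#' \code{NA} with a warning.
#'
#' For example, z-statistics of 3 for D2 and D3 and 0 elsewhere give an
#' index of 2.5.
#'
#' @param z Numeric vector of five z-statistics (D1..D5).
#' @return Scalar in \code{[1, 5]}, or \code{NA_real_}.
#' @export
digit_preference_index <- function(z) {
  stopifnot(length(z) == 5, is.numeric(z))
  w <- pmax(z, 0)
  if (sum(w) == 0) {
    warning("all digit weights are zero; preference index undefined")
    return(NA_real_)
  }
  sum((1:5) * w) / sum(w)
}

#' Circular correlation of two angle vectors
#'
#' The circular correlation coefficient of Jammalamadaka & SenGupta:
#' \deqn{r = \frac{\sum_k \sin(a_k - \bar a)\sin(b_k - \bar b)}
#'   {\sqrt{\sum_k \sin^2(a_k-\bar a)\sum_k \sin^2(b_k-\bar b)}}}
#' with \eqn{\bar a,\bar b} the circular means (arctangent of the summed
#' sines and cosines).
#'
#' @param a1,a2 Equal-length angle vectors in radians, length >= 3.
#' @return Scalar in \code{[-1, 1]}.
#' @export
circular_correlation <- function(a1, a2) {
  stopifnot(length(a1) == length(a2), length(a1) >= 3)
  mu1 <- atan2(sum(sin(a1)), sum(cos(a1)))
  mu2 <- atan2(sum(sin(a2)), sum(cos(a2)))
  s1 <- sin(a1 - mu1)
  s2 <- sin(a2 - mu2)
  den <- sqrt(sum(s1^2) * sum(s2^2))
  if (den == 0) {
    stop("circular correlation undefined: a vector is concentrated at its circular mean",
         call. = FALSE)
  }
  sum(s1 * s2) / den
}

# map digit-preference indices and axis positions to angles.
# index d -> 2*pi*(d-1)/5: one digit step = 72 degrees, so D5 sits adjacent
# to a wrapped D1 (double-thumb topology). Positions are rescaled onto the
# D1..D5 arc, 2*pi*4/5, under the assumption that the observed map extent
# spans the five digits; the remaining fifth of the circle is the wrap gap
# through which a second thumb field returns to D1. (Mapping positions onto
# the full circle instead makes both circular means degenerate on canonical
# somatotopic data and destabilises the correlation.)
index_to_angle <- function(index) 2 * pi * (index - 1) / 5

position_to_angle <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate axis positions", call. = FALSE)
  2 * pi * (4 / 5) * (x - rng[1]) / diff(rng)
}

#' Somatotopic index analysis for one activity set
#'
#' Computes each node's digit-preference index from its five z-statistics and
#' correlates the indices with position along the dorsomedial-ventrolateral
#' axis using circular correlation. Nodes with all-zero (clamped) weights are
#' excluded.
#'
#' @param activity A \code{digit_activity} (its \code{zmaps} are used), or a
#'   5 x nodes z-map matrix.
#' @param sheet A \code{cortical_sheet} sharing the activity's nodes.
#' @param mask Optional node indices to include.
#' @return A \code{somatotopy_result} list: \code{index} (per node, NA where
#'   undefined), \code{r_circ}, \code{n_nodes_used}, \code{task}.
#' @export
somatotopy_score <- function(activity, sheet, mask = NULL) {
  zmaps <- if (inherits(activity, "digit_activity")) activity$zmaps else activity
  task <- if (inherits(activity, "digit_activity")) activity$task_label else NA
  stopifnot(nrow(zmaps) == 5, ncol(zmaps) == nrow(sheet))
  if (is.null(mask)) mask <- seq_len(nrow(sheet))
  idx <- rep(NA_real_, nrow(sheet))
  for (n in mask) {
    idx[n] <- suppressWarnings(digit_preference_index(zmaps[, n]))
  }
  if (sum(is.na(idx[mask])) > 0) {
    warning(sum(is.na(idx[mask])),
            " node(s) with no positive digit weight excluded from the somatotopic index")
  }
  ok <- mask[!is.na(idx[mask])]
  if (length(ok) < 3) stop("fewer than 3 nodes with a defined index", call. = FALSE)
  r <- circular_correlation(index_to_angle(idx[ok]),
                            position_to_angle(sheet$axis_pos[ok]))
  structure(list(index = idx, r_circ = r, n_nodes_used = length(ok),
                 task = task),
            class = "somatotopy_result")
}

#' Compare somatotopic organisation between tasks across a cohort
#'
#' Paired t-test of per-participant circular correlations between two tasks.
#'
#' @param r_task_a,r_task_b Numeric vectors of per-participant \code{r_circ}
#'   values for the two tasks (aligned by participant).
#' @return The paired \code{htest}.
#' @export
compare_somatotopy <- function(r_task_a, r_task_b) {
  stopifnot(length(r_task_a) == length(r_task_b))
  stats::t.test(r_task_a, r_task_b, paired = TRUE)
}
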