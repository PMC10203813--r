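#' Build a one-dimensional cortical sheet
#'
#' Constructs the node geometry all downstream analyses operate on: a set of
#' cortical surface nodes laid out along the dorsomedial-ventrolateral axis of
#' the primary somatosensory (SI) hand area. Positions are equally spaced on
#' \code{[0, 1]}, with 0 the dorsomedial end (thumb side in a canonical map is
#' at low positions) and 1 the ventrolateral end.
#'
#' @param n_nodes Number of surface nodes (at least 10).
#' @param seed Integer seed, kept for interface symmetry with the stochastic
#'   generators; the sheet itself is deterministic.
#' @param area_label Anatomical label attached to every node (used as a mask
#'   tag; the default mimics Brodmann area 3b).
#' @return A \code{cortical_sheet}: a data frame with columns \code{node_id},
#'   \code{axis_pos} and \code{area_label}.
#' @examples
#' sh <- make_sheet(11, seed = 0)
#' sh$axis_pos
#' @export
make_sheet <- function(n_nodes, seed = 0L, area_label = "BA3b") {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 10) {
    stop("n_nodes must be a single number >= 10", call. = FALSE)
  }
  n_nodes <- as.integer(n_nodes)
  sheet <- data.frame(
    node_id = seq_len(n_nodes),
    axis_pos = seq(0, 1, length.out = n_nodes),
    area_label = rep(area_label, n_nodes),
    stringsAsFactors = FALSE
  )
  class(sheet) <- c("cortical_sheet", "data.frame")
  sheet
}

#' Specify the generative digit-field model
#'
#' Defines the ground truth the synthetic cohort is drawn from: five Gaussian
#' digit fields ordered along the somatotopic axis, a task-level multiplicative
#' gain, an inter-digit enslavement mixing matrix applied to the pooled
#' per-digit inputs, and the run-to-run noise level. An optional "double
#' thumb" adds a second D1 field ventrolateral to D5, a feature of real hand
#' maps that motivates circular rather than linear somatotopy statistics.
#'
#' The true mean pattern for digit \eqn{d} at axis position \eqn{x} is
#' \deqn{gain \sum_e E[d,e]\, a_e \exp\{-(x - c_e)^2 / (2 w_e^2)\}}
#' with \eqn{E} the enslavement matrix, \eqn{a} the amplitudes, \eqn{c} the
#' centers and \eqn{w} the widths.
#'
#' @param centers Five field centers in \code{[0,1]}, strictly increasing.
#' @param widths Five positive spatial tuning SDs (axis units).
#' @param amplitudes Five positive peak amplitudes.
#' @param gain Positive task-level multiplier.
#' @param enslavement 5x5 nonnegative mixing matrix; each row's diagonal entry
#'   must be at least every off-diagonal entry in that row.
#' @param noise_sd Nonnegative run-to-run noise SD per node.
#' @param double_thumb If \code{TRUE}, D1 has a second field at
#'   \code{thumb2_center}.
#' @param thumb2_center Center of the second thumb field; must exceed the D5
#'   center.
#' @return A \code{digit_field_spec} list.
#' @export
digit_field_spec <- function(centers = c(0.1, 0.3, 0.5, 0.7, 0.9),
                             widths = rep(0.07, 5),
                             amplitudes = rep(1, 5),
                             gain = 1,
                             enslavement = diag(5),
                             noise_sd = 0.2,
                             double_thumb = FALSE,
                             thumb2_center = 1.0) {
  stopifnot(length(centers) == 5, length(widths) == 5, length(amplitudes) == 5)
  if (any(diff(centers) <= 0)) {
    stop("digit field centers must be strictly increasing D1 < ... < D5",
         call. = FALSE)
  }
  if (any(widths <= 0) || any(amplitudes <= 0)) {
    stop("widths and amplitudes must be positive", call. = FALSE)
  }
  if (gain <= 0) stop("gain must be positive", call. = FALSE)
  enslavement <- as.matrix(enslavement)
  if (!all(dim(enslavement) == c(5L, 5L)) || any(enslavement < 0)) {
    stop("enslavement must be a 5x5 nonnegative matrix", call. = FALSE)
  }
  offmax <- apply(enslavement - diag(diag(enslavement)), 1, max)
  if (any(diag(enslavement) < offmax)) {
    stop("enslavement diagonal must dominate every off-diagonal in its row",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (isTRUE(double_thumb) && thumb2_center <= centers[5]) {
    stop("second thumb center must lie beyond the D5 center", call. = FALSE)
  }
  structure(
    list(centers = as.numeric(centers), widths = as.numeric(widths),
         amplitudes = as.numeric(amplitudes), gain = gain,
         enslavement = enslavement, noise_sd = noise_sd,
         double_thumb = isTRUE(double_thumb),
         thumb2_center = thumb2_center),
    class = "digit_field_spec"
  )
}

#' Synthetic "typical" enslavement matrix
#'
#' A diagonal-dominant input-mixing matrix emulating the stylised facts of
#' digit enslavement during single-digit movements: the thumb moves most
#' independently, the ring and little fingers least, and co-activation falls
#' off with inter-digit distance. This is a synthetic stand-in constructed
#' from those qualitative constraints, not a measured matrix.
#'
#' @param strength Scalar in \code{[0, 1]} scaling all off-diagonal mixing.
#' @return A 5x5 nonnegative matrix with unit diagonal.
#' @export
typical_enslavement <- function(strength = 1) {
  stopifnot(strength >= 0, strength <= 1)
  # per-digit independence: D1 high, D4/D5 low
  neigh <- c(0.08, 0.15, 0.20, 0.30, 0.25)
  far <- c(0.02, 0.05, 0.08, 0.10, 0.08)
  E <- diag(5)
  for (d in 1:5) {
    for (e in 1:5) {
      if (e == d) next
      E[d, e] <- strength * if (abs(d - e) == 1) neigh[d] else far[d]
    }
  }
  E
}

# Gaussian field profiles, one row per digit, before enslavement/gain.
# The optional second thumb field is added into row 1.
digit_fields <- function(sheet, spec) {
  x <- sheet$axis_pos
  F <- matrix(0, nrow = 5, ncol = length(x))
  for (d in 1:5) {
    F[d, ] <- spec$amplitudes[d] *
      exp(-(x - spec$centers[d])^2 / (2 * spec$widths[d]^2))
  }
  if (spec$double_thumb) {
    F[1, ] <- F[1, ] + spec$amplitudes[1] *
      exp(-(x - spec$thumb2_center)^2 / (2 * spec$widths[1]^2))
  }
  F
}

#' True (noise-free) mean activity patterns
#'
#' Evaluates the generative model's mean pattern for each digit over a sheet:
#' gain times the enslavement-mixed Gaussian fields.
#'
#' @param sheet A \code{cortical_sheet}.
#' @param spec A \code{digit_field_spec}.
#' @return A 5 x nodes matrix; row \code{d} is the true pattern evoked by
#'   stimulating/moving digit \code{d}.
#' @export
true_patterns <- function(sheet, spec) {
  spec$gain * (spec$enslavement %*% digit_fields(sheet, spec))
}
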