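#' Canonical double-gamma haemodynamic response function
#'
#' The standard double-gamma HRF (response peak 6 s, undershoot peak 16 s,
#' unit dispersions, undershoot ratio 1/6), sampled on a regular grid and
#' scaled to unit peak.
#'
#' @param t Time points in seconds (nonnegative).
#' @return Numeric vector of HRF values at \code{t}.
#' @export
hrf_double_gamma <- function(t) {
  stopifnot(all(t >= 0))
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Circular convolution of a design column with the HRF sampled at TR.
# Travelling-wave runs cycle continuously, so steady-state (wrap-around)
# convolution is the natural model and keeps forward/backward symmetric.
convolve_circular <- function(x, tr) {
  n <- length(x)
  h <- hrf_double_gamma(seq(0, by = tr, length.out = n))
  Re(stats::fft(stats::fft(x) * stats::fft(h), inverse = TRUE)) / n
}

#' Simulate per-run digit activity patterns
#'
#' Draws a run-level activity set from a generative digit-field model: per-run
#' beta patterns are the true mean patterns (see [true_patterns()]) plus
#' i.i.d. Gaussian noise, GLM residuals are drawn with the same per-node
#' variance structure (so residual-based prewhitening is consistent with the
#' beta noise), and z-maps are the true patterns scaled by the nominal
#' across-run standard error plus unit sampling noise.
#'
#' @param sheet A \code{cortical_sheet}.
#' @param spec A \code{digit_field_spec}.
#' @param n_runs Number of imaging runs (at least 2; crossnobis needs run
#'   pairs).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param task_label \code{"active"} or \code{"passive"}.
#' @param participant_id Identifier carried through to outputs.
#' @param n_residual_timepoints Residual timepoints per run.
#' @param node_noise_scale Optional per-node multiplier on \code{noise_sd}
#'   (length = nodes), used to create heteroscedastic nodes that prewhitening
#'   should downweight. Default 1 everywhere.
#' @return A \code{digit_activity} list with elements \code{betas}
#'   (runs x 5 x nodes), \code{residuals} (runs x timepoints x nodes),
#'   \code{zmaps} (5 x nodes), \code{task_label}, \code{participant_id},
#'   \code{sheet} and \code{spec}.
#' @export
simulate_activity <- function(sheet, spec, n_runs = 4L, seed = 1L,
                              task_label = "active", participant_id = "p01",
                              n_residual_timepoints = 60L,
                              node_noise_scale = NULL) {
  if (n_runs < 2) stop("n_runs must be >= 2", call. = FALSE)
  stopifnot(inherits(sheet, "cortical_sheet"), inherits(spec, "digit_field_spec"))
  n_nodes <- nrow(sheet)
  if (is.null(node_noise_scale)) node_noise_scale <- rep(1, n_nodes)
  stopifnot(length(node_noise_scale) == n_nodes, all(node_noise_scale > 0))

  truth <- true_patterns(sheet, spec)      # 5 x nodes
  sd_node <- spec$noise_sd * node_noise_scale

  set.seed(as.integer(seed))
  betas <- array(0, dim = c(n_runs, 5L, n_nodes))
  for (r in seq_len(n_runs)) {
    noise <- matrix(stats::rnorm(5L * n_nodes), 5L, n_nodes) *
      rep(sd_node, each = 5L)
    betas[r, , ] <- truth + noise
  }
  residuals <- array(
    stats::rnorm(n_runs * n_residual_timepoints * n_nodes),
    dim = c(n_runs, n_residual_timepoints, n_nodes)
  )
  residuals <- residuals * rep(sd_node, each = n_runs * n_residual_timepoints)

  if (spec$noise_sd > 0) {
    zmaps <- truth / (spec$noise_sd / sqrt(n_runs)) +
      matrix(stats::rnorm(5L * n_nodes), 5L, n_nodes)
  } else {
    # noiseless limit: z-maps carry the true pattern itself
    zmaps <- truth
  }

  structure(
    list(betas = betas, residuals = residuals, zmaps = zmaps,
         task_label = task_label, participant_id = participant_id,
         sheet = sheet, spec = spec),
    class = "digit_activity"
  )
}

#' Simulate a travelling-wave localiser run
#'
#' Generates a BOLD time series for a phase-encoded digit localiser: five
#' digit blocks per cycle presented in forward (D1..D5) or backward (D5..D1)
#' order, cycles repeated back to back with no rest, each node responding with
#' its true per-digit activity (see [true_patterns()]) to the HRF-convolved
#' boxcar of that digit's blocks, plus Gaussian noise. Convolved regressors
#' are scaled to unit peak so a node's signal amplitude equals its true
#' response and the signal-to-noise ratio is \code{response / noise_sd}.
#'
#' @param sheet A \code{cortical_sheet}.
#' @param spec A \code{digit_field_spec}; \code{spec$noise_sd} is the BOLD
#'   noise SD.
#' @param tr_seconds Repetition time (seconds).
#' @param block_seconds Duration of one digit block; must be divisible by
#'   \code{tr_seconds}.
#' @param cycles Number of stimulation cycles.
#' @param direction \code{"forward"} or \code{"backward"}.
#' @param seed Integer seed.
#' @return A \code{localiser_series} list with \code{bold}
#'   (timepoints x nodes), \code{tr_seconds}, \code{block_seconds},
#'   \code{cycles}, \code{digit_order} and \code{direction}.
#' @export
simulate_localiser <- function(sheet, spec, tr_seconds = 2, block_seconds = 8,
                               cycles = 5L, direction = c("forward", "backward"),
                               seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(inherits(sheet, "cortical_sheet"), inherits(spec, "digit_field_spec"))
  if (block_seconds %% tr_seconds != 0) {
    stop("block duration must be divisible by the TR", call. = FALSE)
  }
  trs_per_block <- block_seconds / tr_seconds
  n_t <- as.integer(cycles * 5L * trs_per_block)
  digit_order <- if (direction == "forward") 1:5 else 5:1

  # one boxcar per digit, tiled over cycles, convolved circularly
  regressors <- matrix(0, nrow = n_t, ncol = 5L)
  for (slot in 1:5) {
    d <- digit_order[slot]
    box <- numeric(n_t)
    for (cy in seq_len(cycles)) {
      start <- (cy - 1L) * 5L * trs_per_block + (slot - 1L) * trs_per_block
      box[start + seq_len(trs_per_block)] <- 1
    }
    reg <- convolve_circular(box, tr_seconds)
    regressors[, d] <- reg / max(reg)
  }

  truth <- true_patterns(sheet, spec)      # 5 x nodes
  signal <- regressors %*% truth           # timepoints x nodes

  set.seed(as.integer(seed))
  bold <- signal + matrix(stats::rnorm(n_t * nrow(sheet), sd = spec$noise_sd),
                          n_t, nrow(sheet))
  structure(
    list(bold = bold, tr_seconds = tr_seconds, block_seconds = block_seconds,
         cycles = as.integer(cycles), digit_order = digit_order,
         direction = direction),
    class = "localiser_series"
  )
}

#' Write / read a digit activity set as TSV
#'
#' Long-format export (columns run, digit, node, beta) with a JSON sidecar
#' carrying the generating field spec, so a cohort can be archived and
#' reloaded as plain text.
#'
#' @param activity A \code{digit_activity}.
#' @param path Output TSV path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_activity_tsv <- function(activity, path) {
  stopifnot(inherits(activity, "digit_activity"))
  d <- dim(activity$betas)
  long <- expand.grid(run = seq_len(d[1]), digit = seq_len(d[2]),
                      node = seq_len(d[3]))
  long$beta <- as.vector(activity$betas)
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- activity$spec
  sidecar$enslavement <- unclass(sidecar$enslavement)
  jsonlite::write_json(
    list(task_label = activity$task_label,
         participant_id = activity$participant_id,
         spec = unclass(sidecar)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_activity_tsv
#' @param n_runs,n_digits,n_nodes Expected dimensions when reading.
#' @export
read_activity_tsv <- function(path, n_runs, n_digits = 5L, n_nodes) {
  long <- utils::read.delim(path)
  betas <- array(NA_real_, dim = c(n_runs, n_digits, n_nodes))
  betas[cbind(long$run, long$digit, long$node)] <- long$beta
  betas
}

#' Write a localiser series as TSV (time x node)
#' @param series A \code{localiser_series}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_localiser_tsv <- function(series, path) {
  stopifnot(inherits(series, "localiser_series"))
  df <- as.data.frame(series$bold)
  names(df) <- paste0("node", seq_len(ncol(df)))
  utils::write.table(cbind(t = seq_len(nrow(df)), df), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
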