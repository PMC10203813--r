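#' Build the travelling-wave reference model bank
#'
#' Constructs the 20 lagged reference models used to localise digit-specific
#' clusters: an 8 s "on" / 32 s "off" boxcar modelling one digit block within
#' a 40 s cycle, shifted 20 times by one 2 s lag, tiled over the cycles of a
#' run, and convolved with the canonical double-gamma HRF (circularly, since
#' cycles repeat without rest).
#'
#' @param tr Repetition time in seconds; must equal the lag step.
#' @param cycles Number of cycles per run.
#' @param on_seconds,off_seconds Block on/off durations (default 8 / 32).
#' @param lag_seconds Lag step (default = \code{tr}).
#' @return A \code{reference_bank} list: \code{models}
#'   (20 x timepoints, HRF-convolved, one row per lag), \code{boxcars}
#'   (unconvolved), plus the design constants.
#' @export
build_reference_bank <- function(tr = 2, cycles = 5L, on_seconds = 8,
                                 off_seconds = 32, lag_seconds = tr) {
  if (lag_seconds != tr) {
    stop("lag step must equal the TR", call. = FALSE)
  }
  cycle_seconds <- on_seconds + off_seconds
  n_lags <- cycle_seconds / lag_seconds
  if (n_lags != round(n_lags) || on_seconds %% tr != 0) {
    stop("cycle length must be a whole number of lags and the on period a whole number of TRs",
         call. = FALSE)
  }
  n_lags <- as.integer(n_lags)
  trs_per_cycle <- as.integer(cycle_seconds / tr)
  on_trs <- as.integer(on_seconds / tr)
  n_t <- trs_per_cycle * as.integer(cycles)

  base <- rep(c(rep(1, on_trs), rep(0, trs_per_cycle - on_trs)), cycles)
  boxcars <- matrix(0, nrow = n_lags, ncol = n_t)
  models <- matrix(0, nrow = n_lags, ncol = n_t)
  for (k in seq_len(n_lags)) {
    # circular shift by (k-1) lags within each cycle = over the whole series
    shifted <- c(utils::tail(base, k - 1L), utils::head(base, n_t - k + 1L))
    boxcars[k, ] <- shifted
    models[k, ] <- convolve_circular(shifted, tr)
  }
  structure(
    list(models = models, boxcars = boxcars, tr = tr,
         cycles = as.integer(cycles), on_seconds = on_seconds,
         off_seconds = off_seconds, lag_seconds = lag_seconds,
         n_lags = n_lags),
    class = "reference_bank"
  )
}

# lag (1-based index) -> digit, given the cycle's digit order.
# Four lags per digit, lag 1 aligned with the onset of the first block.
lag_to_digit <- function(n_lags, digit_order) {
  lags_per_digit <- n_lags / length(digit_order)
  digit_order[floor((seq_len(n_lags) - 1L) / lags_per_digit) + 1L]
}

#' Assign nodes to digits from forward and backward localiser runs
#'
#' The travelling-wave cluster analysis: each node's BOLD time course is
#' correlated with each of the 20 lagged reference models; r-values are
#' Fisher z-transformed; the four lags belonging to each digit are averaged
#' (with the backward run's lag-to-digit map reversed so lags point at the
#' same digits); forward and backward averages are combined; the node is
#' assigned to the digit with maximal averaged z (winner-take-all); and a
#' Benjamini-Hochberg FDR threshold at level \code{q} is applied per digit
#' across nodes. The statistic entering FDR is the normal approximation
#' \eqn{z\sqrt{n-3}} on the digit-averaged Fisher z (one-sided).
#'
#' @param series_fwd,series_bwd Forward/backward \code{localiser_series} on
#'   the same node set.
#' @param bank A \code{reference_bank}.
#' @param q FDR level in (0, 1).
#' @param mask Optional integer vector of node indices to analyse (the hand
#'   mask); default all nodes.
#' @return A \code{cluster_assignment} list: \code{winner} (digit per node,
#'   NA outside the mask or for excluded nodes), \code{zvals}
#'   (nodes x 5 digit-averaged Fisher z), \code{pvals}, \code{passed_fdr}
#'   (nodes x 5 logical), \code{cluster_members} (list of node indices per
#'   digit: winners surviving FDR for their winning digit), and
#'   \code{excluded} (constant-signal nodes).
#' @export
assign_digits <- function(series_fwd, series_bwd, bank, q = 0.01,
                          mask = NULL) {
  stopifnot(inherits(series_fwd, "localiser_series"),
            inherits(series_bwd, "localiser_series"),
            inherits(bank, "reference_bank"))
  if (!(q > 0 && q < 1)) stop("q must lie in (0, 1)", call. = FALSE)
  n_nodes <- ncol(series_fwd$bold)
  if (ncol(series_bwd$bold) != n_nodes) {
    stop("forward and backward runs must share the node set", call. = FALSE)
  }
  if (is.null(mask)) mask <- seq_len(n_nodes)
  n_t <- nrow(series_fwd$bold)
  if (ncol(bank$models) != n_t || nrow(series_bwd$bold) != n_t) {
    stop("reference bank and localiser runs must share the timepoint count",
         call. = FALSE)
  }

  digit_z <- function(series) {
    const <- apply(series$bold[, mask, drop = FALSE], 2, stats::sd) == 0
    r <- suppressWarnings(
      stats::cor(series$bold[, mask, drop = FALSE], t(bank$models)))
    z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    map <- lag_to_digit(bank$n_lags, series$digit_order)
    zd <- sapply(1:5, function(d) rowMeans(z[, map == d, drop = FALSE]))
    zd[const, ] <- NA_real_
    list(z = zd, const = const)
  }
  fw <- digit_z(series_fwd)
  bw <- digit_z(series_bwd)
  zvals_mask <- (fw$z + bw$z) / 2
  excluded_mask <- fw$const | bw$const
  if (any(excluded_mask)) {
    warning(sum(excluded_mask),
            " node(s) with constant time series excluded from assignment")
  }

  zvals <- matrix(NA_real_, n_nodes, 5L)
  zvals[mask, ] <- zvals_mask

  # winner-take-all; exact ties go to the lower digit number
  winner <- rep(NA_integer_, n_nodes)
  ok <- mask[!excluded_mask]
  winner[ok] <- apply(zvals[ok, , drop = FALSE], 1, which.max)

  # one-sided p on the averaged z, BH per digit within the mask
  n_eff <- n_t
  pvals <- matrix(NA_real_, n_nodes, 5L)
  pvals[mask, ] <- stats::pnorm(zvals[mask, , drop = FALSE] * sqrt(n_eff - 3),
                                lower.tail = FALSE)
  passed <- matrix(FALSE, n_nodes, 5L)
  for (d in 1:5) {
    idx <- mask[!is.na(pvals[mask, d])]
    if (length(idx)) {
      passed[idx, d] <- stats::p.adjust(pvals[idx, d], method = "BH") < q
    }
  }

  members <- lapply(1:5, function(d) {
    idx <- which(!is.na(winner) & winner == d)
    idx[passed[cbind(idx, rep.int(d, length(idx)))]]
  })
  names(members) <- paste0("D", 1:5)

  structure(
    list(winner = winner, zvals = zvals, pvals = pvals, passed_fdr = passed,
         cluster_members = members, excluded = mask[excluded_mask],
         q = q, mask = mask),
    class = "cluster_assignment"
  )
}

#' Write a cluster assignment as TSV
#'
#' One row per node: winner digit, per-digit averaged Fisher z and FDR flags.
#' A second file (\code{paste0(path, ".spans.tsv")}) summarises contiguous
#' runs of the winner map along the node axis, BED-style (digit, start node,
#' end node).
#'
#' @param assignment A \code{cluster_assignment}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_clusters_tsv <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  n <- length(assignment$winner)
  df <- data.frame(node = seq_len(n), winner = assignment$winner)
  for (d in 1:5) {
    df[[paste0("z_D", d)]] <- assignment$zvals[, d]
    df[[paste0("fdr_D", d)]] <- assignment$passed_fdr[, d]
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  w <- assignment$winner
  runs <- rle(ifelse(is.na(w), 0L, w))
  ends <- cumsum(runs$lengths)
  spans <- data.frame(digit = runs$values,
                      start = c(1L, utils::head(ends, -1) + 1L), end = ends)
  spans <- spans[spans$digit > 0, , drop = FALSE]
  utils::write.table(spans, paste0(path, ".spans.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
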