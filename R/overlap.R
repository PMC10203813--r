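#' Threshold a digit z-map within a mask
#'
#' Minimal thresholding of a surface z-map: the surviving node set is
#' \code{{n in mask : z[n] > z_thresh}} (strict inequality). An empty
#' surviving set is a valid map with area 0; downstream overlap code treats
#' it as missing data.
#'
#' @param zmap Numeric vector of z-statistics over nodes.
#' @param mask Integer node indices defining the (hand) mask.
#' @param z_thresh Threshold (default 2).
#' @param digit,task Optional labels carried on the result.
#' @return A \code{thresholded_map} list: \code{nodes} (surviving indices),
#'   \code{area} (node count), \code{digit}, \code{task}.
#' @export
threshold_map <- function(zmap, mask = seq_along(zmap), z_thresh = 2,
                          digit = NA, task = NA) {
  stopifnot(is.finite(z_thresh), length(mask) > 0)
  nodes <- mask[zmap[mask] > z_thresh]
  structure(list(nodes = nodes, area = length(nodes),
                 digit = digit, task = task),
            class = "thresholded_map")
}

#' Minimum-normalised (and traditional) Dice overlap
#'
#' Spatial overlap of two thresholded maps. The minimum-normalised variant
#' divides the intersection by the smaller of the two areas, so a map fully
#' contained in a larger one scores 1; the traditional variant is
#' \code{2|A n B| / (|A| + |B|)}. If either map is empty the overlap is
#' undefined and \code{NA} is returned with a warning (an empty map carries
#' no evidence of non-overlap).
#'
#' @param a,b \code{thresholded_map}s on the same node space.
#' @param variant \code{"min"} or \code{"traditional"}.
#' @return Scalar in \code{[0, 1]}, or \code{NA_real_}.
#' @export
dice_overlap <- function(a, b, variant = c("min", "traditional")) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "thresholded_map"), inherits(b, "thresholded_map"))
  if (min(a$area, b$area) == 0) {
    warning("Dice undefined for an empty map; returning NA")
    return(NA_real_)
  }
  inter <- length(intersect(a$nodes, b$nodes))
  if (variant == "min") inter / min(a$area, b$area)
  else 2 * inter / (a$area + b$area)
}

#' Cross-task 5x5 Dice matrix
#'
#' Thresholds the per-digit z-maps of two tasks and computes the Dice overlap
#' for every digit pair across tasks; rows index the first task's digits,
#' columns the second task's.
#'
#' @param zmaps_a,zmaps_b 5 x nodes z-map matrices (e.g. active and passive).
#' @param mask Node indices of the hand mask.
#' @param z_thresh Threshold (default 2).
#' @param variant Passed to [dice_overlap()].
#' @return 5x5 numeric matrix (may contain \code{NA}).
#' @export
dice_matrix <- function(zmaps_a, zmaps_b, mask = seq_len(ncol(zmaps_a)),
                        z_thresh = 2, variant = "min") {
  stopifnot(nrow(zmaps_a) == 5, nrow(zmaps_b) == 5,
            ncol(zmaps_a) == ncol(zmaps_b))
  maps_a <- lapply(1:5, function(d) threshold_map(zmaps_a[d, ], mask, z_thresh, d, "a"))
  maps_b <- lapply(1:5, function(d) threshold_map(zmaps_b[d, ], mask, z_thresh, d, "b"))
  m <- matrix(NA_real_, 5, 5, dimnames = list(paste0("D", 1:5), paste0("D", 1:5)))
  for (i in 1:5) for (j in 1:5) {
    m[i, j] <- suppressWarnings(dice_overlap(maps_a[[i]], maps_b[[j]], variant))
  }
  m
}

# one-sided paired t that degrades gracefully when the differences are
# constant (zero variance): t = 0 with p = 1 for all-zero differences,
# +/-Inf with p = 0/1 otherwise
paired_t_greater <- function(x, y) {
  d <- x - y
  if (stats::sd(d) == 0 || all(is.na(d))) {
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(statistic = tt,
                p.value = if (tt > 0) 0 else 1,
                estimate = mean(d), method = "degenerate paired t"))
  }
  h <- stats::t.test(x, y, paired = TRUE, alternative = "greater")
  list(statistic = unname(h$statistic), p.value = h$p.value,
       estimate = unname(h$estimate), method = h$method)
}

#' Group same / neighbour / non-neighbour overlap and test the ordering
#'
#' For each participant's cross-task Dice matrix, averages the diagonal
#' (same digit), the first off-diagonals (neighbouring digits,
#' |digit difference| = 1) and the remaining cells (non-neighbouring,
#' |difference| >= 2; D1-D5 counts as non-neighbouring). Group-level paired
#' one-sided t-tests compare same > neighbour and neighbour > non-neighbour,
#' each evaluated against a Bonferroni-adjusted alpha of .025 for the two
#' planned comparisons.
#'
#' @param matrices List of 5x5 Dice matrices, one per participant.
#' @return An \code{overlap_summary} list: \code{per_participant} data frame
#'   (same, neighbour, nonneighbour), \code{means}, and the two t-test
#'   results with the adjusted alpha.
#' @export
overlap_summary <- function(matrices) {
  stopifnot(length(matrices) >= 2)
  grp <- function(m) {
    dd <- abs(row(m) - col(m))
    if (anyNA(m)) {
      warning("missing Dice cells excluded from a participant's means")
    }
    c(same = mean(m[dd == 0], na.rm = TRUE),
      neighbour = mean(m[dd == 1], na.rm = TRUE),
      nonneighbour = mean(m[dd >= 2], na.rm = TRUE))
  }
  per <- as.data.frame(do.call(rbind, lapply(matrices, grp)))
  t1 <- paired_t_greater(per$same, per$neighbour)
  t2 <- paired_t_greater(per$neighbour, per$nonneighbour)
  structure(
    list(per_participant = per, means = colMeans(per, na.rm = TRUE),
         same_vs_neighbour = t1, neighbour_vs_nonneighbour = t2,
         alpha = 0.025),
    class = "overlap_summary"
  )
}
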