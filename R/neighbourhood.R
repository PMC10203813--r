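#' Mean per-digit activity within digit-specific clusters
#'
#' For one participant, extracts each digit's activity-versus-rest within
#' each localiser-defined digit-specific cluster: betas are averaged over
#' runs and over the cluster's member nodes, for both tasks, and then shifted
#' above zero by subtracting the participant's lowest cell value (one shift
#' per participant, common to both tasks). An empty cluster yields a missing
#' row with a warning.
#'
#' @param activities Named list of \code{digit_activity} objects, one per
#'   task (e.g. \code{list(active = ..., passive = ...)}).
#' @param clusters A \code{cluster_assignment} from the independent
#'   localiser.
#' @return A \code{cluster_activity} list: \code{values} (task x cluster x
#'   digit array, shifted), \code{shift_applied}, \code{tasks}.
#' @export
extract_cluster_activity <- function(activities, clusters) {
  stopifnot(inherits(clusters, "cluster_assignment"), length(activities) >= 1)
  tasks <- names(activities)
  vals <- array(NA_real_, dim = c(length(tasks), 5L, 5L),
                dimnames = list(tasks, paste0("C", 1:5), paste0("D", 1:5)))
  for (t in seq_along(tasks)) {
    act <- activities[[t]]
    stopifnot(inherits(act, "digit_activity"))
    mean_pattern <- apply(act$betas, c(2, 3), mean)   # 5 digits x nodes
    for (cl in 1:5) {
      members <- clusters$cluster_members[[cl]]
      if (length(members) == 0) {
        warning("cluster C", cl, " is empty; activity row left missing")
        next
      }
      vals[t, cl, ] <- rowMeans(mean_pattern[, members, drop = FALSE])
    }
  }
  shift <- min(vals, na.rm = TRUE)
  structure(
    list(values = vals - shift, shift_applied = shift, tasks = tasks),
    class = "cluster_activity"
  )
}

# neighbours / non-neighbours of a target digit; D1-D5 are non-neighbours
# unless d1d5_neighbours = TRUE (double-thumb variant).
digit_neighbours <- function(target, d1d5_neighbours = FALSE) {
  nb <- intersect(c(target - 1L, target + 1L), 1:5)
  if (d1d5_neighbours) {
    if (target == 1L) nb <- union(nb, 5L)
    if (target == 5L) nb <- union(nb, 1L)
  }
  nb
}

#' Target-vs-neighbour selectivity ratios
#'
#' Within each digit-specific cluster, the difference between the target
#' digit's activity and the mean activity of its neighbouring
#' (non-neighbouring) digits, divided by the target activity — e.g. for
#' cluster 3, ([D3 - mean(D2, D4)] / D3). Ratios are averaged over clusters
#' per task. Edge clusters have a single neighbour. Also counts
#' winner-take-all "hits": clusters whose target digit produces the maximal
#' activity.
#'
#' @param table A \code{cluster_activity}.
#' @param d1d5_neighbours Treat D1 and D5 as neighbours (default FALSE).
#' @return A \code{selectivity} list: \code{neighbour_diff} and
#'   \code{nonneighbour_diff} (named per task), \code{hits} (per task, 0-5),
#'   \code{per_cluster} (task x cluster x {neighbour, nonneighbour}).
#' @export
selectivity_ratios <- function(table, d1d5_neighbours = FALSE) {
  stopifnot(inherits(table, "cluster_activity"))
  tasks <- table$tasks
  per_cluster <- array(NA_real_, dim = c(length(tasks), 5L, 2L),
                       dimnames = list(tasks, paste0("C", 1:5),
                                       c("neighbour", "nonneighbour")))
  hits <- stats::setNames(integer(length(tasks)), tasks)
  for (t in seq_along(tasks)) {
    for (cl in 1:5) {
      row <- table$values[t, cl, ]
      if (anyNA(row)) next
      target <- row[cl]
      if (target == 0) {
        warning("target activity is zero in cluster C", cl,
                "; selectivity ratio dropped")
        next
      }
      nb <- digit_neighbours(cl, d1d5_neighbours)
      nn <- setdiff(1:5, c(cl, nb))
      per_cluster[t, cl, "neighbour"] <- (target - mean(row[nb])) / target
      per_cluster[t, cl, "nonneighbour"] <- (target - mean(row[nn])) / target
      if (which.max(row) == cl) hits[t] <- hits[t] + 1L
    }
  }
  structure(
    list(neighbour_diff = apply(per_cluster[, , "neighbour", drop = FALSE], 1,
                                mean, na.rm = TRUE),
         nonneighbour_diff = apply(per_cluster[, , "nonneighbour", drop = FALSE],
                                   1, mean, na.rm = TRUE),
         hits = hits, per_cluster = per_cluster, tasks = tasks),
    class = "selectivity"
  )
}

# 2x2 repeated-measures ANOVA from paired contrasts (exact for a 2x2
# within-subject design): each effect's F is the squared paired t on the
# corresponding within-subject contrast.
rm_anova_2x2 <- function(y11, y12, y21, y22) {
  contrast_F <- function(d) {
    n <- length(d)
    tt <- mean(d) / (stats::sd(d) / sqrt(n))
    c(F = tt^2, df1 = 1, df2 = n - 1,
      p = stats::pf(tt^2, 1, n - 1, lower.tail = FALSE))
  }
  rbind(
    factor1 = contrast_F((y11 + y12) / 2 - (y21 + y22) / 2),
    factor2 = contrast_F((y11 + y21) / 2 - (y12 + y22) / 2),
    interaction = contrast_F((y11 - y12) - (y21 - y22))
  )
}

#' Cohort-level neighbourhood-relationships inference
#'
#' The 2 (neighbourhood: neighbour vs non-neighbour) x 2 (task) repeated
#' measures analysis of the selectivity ratios: main effects and interaction
#' (computed exactly from paired contrasts), four follow-up Wilcoxon
#' matched-pairs signed-rank tests (neighbour vs non-neighbour within each
#' task; each neighbourhood level between tasks) at a Bonferroni-adjusted
#' alpha of .0125, Shapiro-Wilk normality screening of the four variables,
#' and a paired t-test of overall mean cluster activity between tasks.
#'
#' @param selectivities List of \code{selectivity} objects (one per
#'   participant), each with the same two tasks.
#' @param activity_tables Optional list of \code{cluster_activity} objects
#'   for the overall-activity comparison.
#' @return A \code{neighbourhood_inference} list: \code{anova} (matrix with
#'   rows task, neighbourhood, interaction), \code{wilcoxon} (data frame of
#'   the four follow-ups), \code{shapiro}, \code{overall_activity}
#'   (\code{htest} or NULL), \code{cells} (per-participant 2x2 means),
#'   \code{alpha_followup}.
#' @export
neighbourhood_inference <- function(selectivities, activity_tables = NULL) {
  stopifnot(length(selectivities) >= 5)
  tasks <- selectivities[[1]]$tasks
  stopifnot(length(tasks) == 2)
  cells <- data.frame(
    nb_a = vapply(selectivities, function(s) s$neighbour_diff[[tasks[1]]], 0),
    nb_b = vapply(selectivities, function(s) s$neighbour_diff[[tasks[2]]], 0),
    nn_a = vapply(selectivities, function(s) s$nonneighbour_diff[[tasks[1]]], 0),
    nn_b = vapply(selectivities, function(s) s$nonneighbour_diff[[tasks[2]]], 0)
  )
  complete <- stats::complete.cases(cells)
  if (any(!complete)) {
    warning(sum(!complete), " participant(s) with incomplete cells dropped")
    cells <- cells[complete, , drop = FALSE]
  }
  if (nrow(cells) < 5) stop("need >= 5 complete participants", call. = FALSE)

  an <- rm_anova_2x2(cells$nb_a, cells$nb_b, cells$nn_a, cells$nn_b)
  rownames(an) <- c("neighbourhood", "task", "neighbourhood_x_task")

  wtest <- function(x, y) {
    n <- length(x)
    stats::wilcox.test(x, y, paired = TRUE, exact = n <= 25, correct = TRUE)
  }
  wl <- list(
    nb_vs_nn_task1 = wtest(cells$nb_a, cells$nn_a),
    nb_vs_nn_task2 = wtest(cells$nb_b, cells$nn_b),
    nb_task1_vs_task2 = wtest(cells$nb_a, cells$nb_b),
    nn_task1_vs_task2 = wtest(cells$nn_a, cells$nn_b)
  )
  wilcoxon <- data.frame(
    comparison = names(wl),
    V = vapply(wl, function(h) unname(h$statistic), 0),
    p = vapply(wl, function(h) h$p.value, 0)
  )
  shapiro <- vapply(cells, function(v) stats::shapiro.test(v)$p.value, 0)

  overall <- NULL
  if (!is.null(activity_tables)) {
    m <- t(vapply(activity_tables,
                  function(tb) apply(tb$values, 1, mean, na.rm = TRUE),
                  numeric(2)))
    overall <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
  }
  structure(
    list(anova = an, wilcoxon = wilcoxon, shapiro = shapiro,
         overall_activity = overall, cells = cells, tasks = tasks,
         alpha_followup = 0.0125),
    class = "neighbourhood_inference"
  )
}
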