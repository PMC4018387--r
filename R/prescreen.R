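#' Two-sample t-test
#'
#' Classic two-sample t statistic with two-sided p-value; the default pooled
#' variant uses the pooled variance estimate with `n1 + n2 - 2` degrees of
#' freedom, `variant = "welch"` uses the Welch statistic. Degenerate inputs
#' follow an explicit contract: if both samples have zero variance the
#' result is `(0, 1)` when the means agree, and `(+/-Inf, 0)` with a warning
#' when they differ.
#'
#' @param x1,x2 Numeric vectors (class +1 and class -1 values of one
#'   feature), each of length >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A list with elements `statistic` and `p.value`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))
two_sample_t <- function(x1, x2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  res <- col_t_stats(matrix(x1, ncol = 1), matrix(x2, ncol = 1), variant)
  list(statistic = unname(res$statistic), p.value = unname(res$p.value))
}

# Vectorised column-wise two-sample t over feature matrices (class +1 rows in
# X1, class -1 rows in X2). Degenerate zero-variance columns follow the
# two_sample_t() contract.
col_t_stats <- function(X1, X2, variant = "pooled") {
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- apply(X1, 2, var); v2 <- apply(X2, 2, var)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- (m1 - m2) / se
  p <- 2 * pt(-abs(stat), df)
  degen <- se == 0
  if (any(degen)) {
    same <- degen & (m1 == m2)
    stat[same] <- 0; p[same] <- 1
    diff <- degen & (m1 != m2)
    if (any(diff)) {
      warn("Zero-variance feature(s) with differing class means; t set to +/-Inf, p to 0.")
      stat[diff] <- sign(m1[diff] - m2[diff]) * Inf
      p[diff] <- 0
    }
  }
  list(statistic = stat, p.value = p)
}

#' Feature preselection by asymmetric per-task keep rules
#'
#' Applies the t-test keep rules over already-computed per-task p-values.
#' A task keeps feature `j` if the p-value of `j` is at most `tau` in the
#' screening of *some* task whose pattern contains the task's own pattern
#' (including itself). For the canonical two-task instance (task 1 = both
#' modalities, task 2 = first modality only) this is exactly the asymmetric
#' pair of rules: task 1 keeps `j` iff `p1_j <= tau`; task 2 keeps `j` iff
#' `p1_j <= tau` or `p2_j <= tau`, so the modality-poorer task keeps more
#' features by borrowing significance from the richer task. Ties `p == tau`
#' are kept.
#'
#' @param pvalues_by_task List of numeric p-value vectors, one per task,
#'   each covering that task's features.
#' @param features_by_task List of global feature-id vectors, one per task,
#'   aligned with `pvalues_by_task`.
#' @param patterns List of character vectors: each task's set of sources.
#' @param tau Significance threshold in (0, 1); default 0.01.
#' @return An object of class `screening_result`: list with
#'   `pvalues_by_task`, `tau`, and `kept_by_task` (sorted local positions).
#' @export
preselect_features <- function(pvalues_by_task, features_by_task, patterns,
                               tau = 0.01) {
  stopifnot(tau > 0, tau < 1,
            length(pvalues_by_task) == length(features_by_task),
            length(pvalues_by_task) == length(patterns))
  n_task <- length(pvalues_by_task)
  kept <- vector("list", n_task)
  for (i in seq_len(n_task)) {
    pass_any <- rep(FALSE, length(features_by_task[[i]]))
    for (l in seq_len(n_task)) {
      if (!all(patterns[[i]] %in% patterns[[l]])) next
      pos <- match(features_by_task[[i]], features_by_task[[l]])
      hit <- !is.na(pos) & pvalues_by_task[[l]][pos] <= tau
      hit[is.na(hit)] <- FALSE
      pass_any <- pass_any | hit
    }
    kept[[i]] <- sort(which(pass_any))
    if (!length(kept[[i]])) {
      abort(paste0("screening removed all features of task ", i,
                   "; raise tau (currently ", tau, ")"))
    }
  }
  structure(list(pvalues_by_task = pvalues_by_task, tau = tau,
                 kept_by_task = kept),
            class = "screening_result")
}

#' Screen tasks with the two-sample t-test
#'
#' Computes per-task two-sided t-test p-values over each task's features
#' (training subjects only) and applies the asymmetric keep rules of
#' [preselect_features()].
#'
#' @param tasks List of `task_dataset` objects (training subjects).
#' @param tau Significance threshold; default 0.01.
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @return A `screening_result` (see [preselect_features()]); element
#'   `kept_by_task` gives local column positions to keep per task.
#' @export
screen_tasks <- function(tasks, tau = 0.01, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  pv <- lapply(tasks, function(t) {
    res <- col_t_stats(t$X1, t$X2, variant)
    setNames(res$p.value, names(t$global_index))
  })
  preselect_features(
    pvalues_by_task = pv,
    features_by_task = lapply(tasks, function(t) unname(t$global_index)),
    patterns = lapply(tasks, function(t) t$pattern),
    tau = tau
  )
}

#' Apply a screening result to tasks
#'
#' @param tasks List of `task_dataset` objects the screening was computed on
#'   (or test-subject tasks with the same feature layout).
#' @param screening A `screening_result` from [screen_tasks()].
#' @return The tasks with feature columns restricted to the kept sets.
#' @export
apply_screening <- function(tasks, screening) {
  purrr::map2(tasks, screening$kept_by_task, subset_task_features)
}
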