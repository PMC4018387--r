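#' Log-equispaced parameter grid
#'
#' `n` values from `lo` to `hi` inclusive with constant ratio
#' `(hi/lo)^(1/(n-1))` between consecutive values. The conventional
#' fidelity-bound grids are `make_log_grid(0.01, 1, 20)` (single-task) and
#' `make_log_grid(0.01, 10, 20)` (per-task bounds of the joint fit).
#'
#' @param lo,hi Positive endpoints, `lo < hi`.
#' @param n Number of grid points, at least 2.
#' @return Numeric vector of length `n`, strictly increasing.
#' @export
make_log_grid <- function(lo, hi, n) {
  if (!(lo > 0 && hi > lo)) abort("need 0 < lo < hi")
  if (n < 2) abort("need n >= 2")
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Stratified fold assignment by task and class
#'
#' Partitions the subjects of each (task, class) stratum independently into
#' `k` near-equal folds (sizes within a stratum differ by at most one), so
#' every outer training set preserves the task and class composition.
#' Deterministic given `seed`.
#'
#' @param tasks List of `task_dataset` objects.
#' @param k Number of folds; every stratum must have at least `k` subjects.
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `task_id`, `label`, `fold`.
#' @export
stratified_folds <- function(tasks, k, seed = 1) {
  strata <- list()
  for (t in tasks) {
    strata[[length(strata) + 1]] <-
      list(ids = rownames(t$X1), task = t$task_id, label = 1L)
    strata[[length(strata) + 1]] <-
      list(ids = rownames(t$X2), task = t$task_id, label = -1L)
  }
  small <- vapply(strata, function(s) length(s$ids) < k, logical(1))
  if (any(small)) {
    abort(paste0("stratum smaller than k = ", k,
                 " (task x class sizes: ",
                 paste(vapply(strata, function(s) length(s$ids), integer(1)),
                       collapse = ", "), "); use a smaller k"))
  }
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(strata, function(s) {
      ids <- sample(s$ids)
      tibble::tibble(subject_id = ids, task_id = s$task,
                     label = s$label,
                     fold = rep_len(seq_len(k), length(ids)))
    }))
  })
}

#' Confusion-count classification metrics
#'
#' @param tp,tn,fp,fn Nonnegative integer counts (vectorised).
#' @return A tibble with the counts and `accuracy = (TP+TN)/(TP+TN+FP+FN)`,
#'   `sensitivity = TP/(TP+FN)` (true-positive rate among the positive
#'   class), `specificity = TN/(TN+FP)`; a metric whose denominator is zero
#'   is `NA`.
#' @export
#' @examples
#' compute_metrics(3, 2, 2, 1)
compute_metrics <- function(tp, tn, fp, fn) {
  stopifnot(all(tp >= 0), all(tn >= 0), all(fp >= 0), all(fn >= 0))
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp)
  )
}

metrics_from_predictions <- function(pred) {
  counts <- function(d) compute_metrics(
    tp = sum(d$label == 1 & d$predicted == 1),
    tn = sum(d$label == -1 & d$predicted == -1),
    fp = sum(d$label == -1 & d$predicted == 1),
    fn = sum(d$label == 1 & d$predicted == -1)
  )
  dplyr::bind_rows(
    dplyr::mutate(counts(pred), scope = "overall", .before = 1),
    dplyr::bind_rows(lapply(split(pred, pred$task_id), function(d)
      dplyr::mutate(counts(d), scope = paste0("task", d$task_id[1]),
                    .before = 1)))
  )
}

# Precompute, per inner fold, everything that does not depend on the
# candidate parameters: screened training statistics, shared sets, and the
# screened held-out rows.
prepare_folds <- function(tasks, folds, tau, variant, link_norm) {
  k <- max(folds$fold)
  lapply(seq_len(k), function(f) {
    test_ids <- folds$subject_id[folds$fold == f]
    train_tasks <- lapply(tasks, subset_task_subjects,
                          ids = setdiff(folds$subject_id, test_ids))
    screening <- screen_tasks(train_tasks, tau = tau, variant = variant)
    train_scr <- apply_screening(train_tasks, screening)
    stats <- lapply(train_scr, pooled_stats)
    n <- length(train_scr)
    shared <- list()
    if (n >= 2) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        s <- shared_features(train_scr[[i]], train_scr[[j]])
        if (nrow(s)) shared[[length(shared) + 1]] <- s
      }
    }
    test <- lapply(seq_along(tasks), function(i) {
      ts <- subset_task_features(tasks[[i]], screening$kept_by_task[[i]])
      X <- rbind(ts$X1, ts$X2)
      lab <- c(rep(1L, nrow(ts$X1)), rep(-1L, nrow(ts$X2)))
      keep <- rownames(X) %in% test_ids
      list(X = X[keep, , drop = FALSE], label = lab[keep],
           ids = rownames(X)[keep])
    })
    list(stats = stats, shared = shared, test = test,
         screening = screening, patterns = lapply(tasks, `[[`, "pattern"))
  })
}

# Fit one parameter point on prepared fold data and return predictions for
# the held-out rows. Raises mlpd_infeasible for invalid points.
fit_and_predict <- function(fold, method, params, link_norm) {
  n_task <- length(fold$stats)
  lam <- params_lambdas(params, n_task)
  if (method == "mlpd") {
    fit <- fit_mlpd(fold$stats, lambdas = lam, gamma = params$gamma %||% NULL,
                    link_norm = link_norm, shared = fold$shared)
    preds <- lapply(seq_len(n_task), function(i) {
      te <- fold$test[[i]]
      if (!nrow(te$X)) return(NULL)
      out <- classify_mlpd(fit, te$X, task = i)
      tibble::tibble(subject_id = te$ids, task_id = i, label = te$label,
                     score = out$score, predicted = out$label)
    })
  } else {
    fits <- lapply(seq_len(n_task), function(i)
      fit_slpd(fold$stats[[i]], lambda = lam[i]))
    fit <- fits
    preds <- lapply(seq_len(n_task), function(i) {
      te <- fold$test[[i]]
      if (!nrow(te$X)) return(NULL)
      out <- classify_lpd(fits[[i]], te$X)
      tibble::tibble(subject_id = te$ids, task_id = i, label = te$label,
                     score = out$score, predicted = out$label)
    })
  }
  list(fit = fit, predictions = dplyr::bind_rows(preds))
}

params_lambdas <- function(params, n_task) {
  if (!is.null(params$lambda)) return(rep_len(params$lambda, n_task))
  cols <- paste0("lambda", seq_len(n_task))
  if (all(cols %in% names(params))) {
    return(vapply(cols, function(cl) params[[cl]], numeric(1)))
  }
  abort("parameter point must provide `lambda` or `lambda1..lambdaT`")
}

#' Inner cross-validated parameter selection
#'
#' Grid search over candidate parameter points by stratified `folds_inner`-
#' fold cross-validation *within the training subjects*: feature screening
#' is re-run on every inner training split, the model is refitted at each
#' candidate point, and the point with the highest mean inner accuracy is
#' selected. Ties break toward the smallest fidelity bounds (sparser
#' models), then the smallest `gamma`. Points whose LP is infeasible on any
#' inner split are skipped.
#'
#' @param tasks List of training `task_dataset` objects.
#' @param method `"slpd"` (independent per-task fits) or `"mlpd"` (joint).
#' @param grids Named list of numeric candidate vectors: either `lambda`
#'   (shared across tasks) or `lambda1 .. lambdaT`, plus optionally
#'   `gamma`. The candidate set is the full product.
#' @param folds_inner Number of inner folds (default 5).
#' @param tau Screening threshold.
#' @param variant t-test variant for screening.
#' @param link_norm Linking-penalty norm for `"mlpd"`.
#' @param seed Seed for the inner fold assignment.
#' @return A list with `params` (one-row tibble: the selected point) and
#'   `results` (tibble of all candidates with mean inner accuracy).
#' @export
inner_cv_select <- function(tasks, method = c("mlpd", "slpd"), grids,
                            folds_inner = 5, tau = 0.01,
                            variant = "pooled", link_norm = "l1", seed = 1) {
  method <- match.arg(method)
  candidates <- tidyr::expand_grid(!!!grids)
  candidates <- dplyr::arrange(
    candidates,
    dplyr::across(dplyr::all_of(sort(setdiff(names(candidates), "gamma")))),
    dplyr::across(dplyr::any_of("gamma"))
  )
  folds <- stratified_folds(tasks, folds_inner, seed = seed)
  prep <- prepare_folds(tasks, folds, tau, variant, link_norm)

  acc <- vapply(seq_len(nrow(candidates)), function(ci) {
    params <- as.list(candidates[ci, ])
    fold_acc <- numeric(length(prep))
    for (f in seq_along(prep)) {
      res <- tryCatch(fit_and_predict(prep[[f]], method, params, link_norm),
                      mlpd_infeasible = function(e) NULL)
      if (is.null(res)) return(NA_real_)
      fold_acc[f] <- mean(res$predictions$predicted ==
                            res$predictions$label)
    }
    mean(fold_acc)
  }, numeric(1))

  if (all(is.na(acc))) abort("all candidate parameter points are invalid")
  results <- dplyr::mutate(candidates, mean_accuracy = acc)
  best <- which.max(acc)  # first maximum = smallest lambdas, then gamma
  list(params = candidates[best, ], results = results)
}

#' One outer cross-validation run
#'
#' The full protocol for one repetition: decompose the dataset into tasks,
#' assign stratified outer folds, and for every outer fold screen features
#' on the training subjects, select parameters by inner cross-validation,
#' fit on the screened training subjects, and predict the held-out fold.
#' All randomness derives from `seed`.
#'
#' @param ds A [multisource_dataset()].
#' @param k Outer fold count (default 10).
#' @param method `"mlpd"` or `"slpd"`.
#' @param grids Candidate parameter grids as in [inner_cv_select()];
#'   default: the conventional 20-point log grids (0.01–1 shared lambda for
#'   `"slpd"`; 0.01–10 per-task lambdas for `"mlpd"`). The defaults are
#'   faithful but large; pass coarser grids for quick runs.
#' @param tau Screening threshold (default 0.01).
#' @param folds_inner Inner fold count (default 5).
#' @param gamma Fixed linking weight, or `NULL` for the `1 / max_i p_i`
#'   default, or include a `gamma` vector in `grids` to tune it.
#' @param min_per_class Passed to [decompose_tasks()].
#' @param variant,link_norm Screening and linking options.
#' @param seed Integer seed for fold assignment (outer and inner).
#' @return An object of class `cv_run`: list with `predictions` (tibble:
#'   `subject_id`, `task_id`, `fold`, `label`, `score`, `predicted`),
#'   `metrics` (overall and per task), and `fold_log` (per fold: selected
#'   parameters, kept-feature counts, screening p-values).
#' @export
cv_run <- function(ds, k = 10, method = c("mlpd", "slpd"), grids = NULL,
                   tau = 0.01, folds_inner = 5, gamma = NULL,
                   min_per_class = 2, variant = "pooled", link_norm = "l1",
                   seed = 1) {
  method <- match.arg(method)
  tasks <- decompose_tasks(ds, min_per_class = min_per_class)
  grids <- grids %||% default_grids(method, length(tasks), gamma)
  if (!is.null(gamma) && is.null(grids$gamma)) grids$gamma <- gamma

  folds <- stratified_folds(tasks, k, seed = seed)
  inner_seeds <- withr::with_seed(seed, sample.int(2^31 - 2, k))

  out_pred <- list(); fold_log <- list()
  for (f in seq_len(k)) {
    test_ids <- folds$subject_id[folds$fold == f]
    train_tasks <- lapply(tasks, subset_task_subjects,
                          ids = setdiff(folds$subject_id, test_ids))
    sel <- inner_cv_select(train_tasks, method = method, grids = grids,
                           folds_inner = folds_inner, tau = tau,
                           variant = variant, link_norm = link_norm,
                           seed = inner_seeds[f])
    screening <- screen_tasks(train_tasks, tau = tau, variant = variant)
    train_scr <- apply_screening(train_tasks, screening)
    stats <- lapply(train_scr, pooled_stats)
    shared <- list()
    if (length(train_scr) >= 2) {
      for (i in seq_len(length(train_scr) - 1))
        for (j in seq(i + 1, length(train_scr))) {
          s <- shared_features(train_scr[[i]], train_scr[[j]])
          if (nrow(s)) shared[[length(shared) + 1]] <- s
        }
    }
    test <- lapply(seq_along(tasks), function(i) {
      ts <- subset_task_features(tasks[[i]], screening$kept_by_task[[i]])
      X <- rbind(ts$X1, ts$X2)
      lab <- c(rep(1L, nrow(ts$X1)), rep(-1L, nrow(ts$X2)))
      keep <- rownames(X) %in% test_ids
      list(X = X[keep, , drop = FALSE], label = lab[keep],
           ids = rownames(X)[keep])
    })
    fold_data <- list(stats = stats, shared = shared, test = test)
    res <- fit_and_predict(fold_data, method, as.list(sel$params), link_norm)
    out_pred[[f]] <- dplyr::mutate(res$predictions, fold = f,
                                   .after = "task_id")
    fold_log[[f]] <- list(
      fold = f, params = sel$params,
      kept = vapply(screening$kept_by_task, length, integer(1)),
      pvalues_by_task = screening$pvalues_by_task
    )
  }
  predictions <- dplyr::bind_rows(out_pred)
  structure(
    list(predictions = predictions,
         metrics = metrics_from_predictions(predictions),
         fold_log = fold_log,
         settings = list(k = k, method = method, tau = tau, seed = seed,
                         grids = grids, link_norm = link_norm)),
    class = "cv_run"
  )
}

default_grids <- function(method, n_task, gamma = NULL) {
  if (method == "slpd") {
    list(lambda = make_log_grid(0.01, 1, 20))
  } else {
    g <- setNames(rep(list(make_log_grid(0.01, 10, 20)), n_task),
                  paste0("lambda", seq_len(n_task)))
    if (!is.null(gamma)) g$gamma <- gamma
    g
  }
}

#' @export
print.cv_run <- function(x, ...) {
  cat("<cv_run> ", x$settings$method, ", k = ", x$settings$k, ", ",
      nrow(x$predictions), " predictions\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Repeated cross-validation experiment
#'
#' Runs the full outer-CV protocol `reps` times (repetition `r` uses seed
#' `base_seed + r`, re-randomising both outer and inner folds) and reports
#' the mean and standard deviation of accuracy, sensitivity and specificity
#' over repetitions, overall and per task.
#'
#' @inheritParams cv_run
#' @param reps Number of repetitions (default 30).
#' @param base_seed Base seed; repetition `r` uses `base_seed + r`.
#' @param ... Passed to [cv_run()].
#' @return An object of class `cv_summary`: list with `per_rep` (tibble of
#'   per-repetition metrics) and `summary` (mean and sd per metric and
#'   scope).
#' @export
repeated_cv_experiment <- function(ds, k = 10, method = "mlpd", reps = 30,
                                   base_seed = 1, ...) {
  per_rep <- dplyr::bind_rows(lapply(seq_len(reps), function(r) {
    run <- cv_run(ds, k = k, method = method, seed = base_seed + r, ...)
    dplyr::mutate(run$metrics, rep = r, .before = 1)
  }))
  summary <- per_rep |>
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$scope, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (dplyr::n() > 1) stats::sd(.data$value, na.rm = TRUE) else
        NA_real_,
      .groups = "drop"
    )
  structure(list(per_rep = per_rep, summary = summary,
                 settings = list(k = k, method = method, reps = reps,
                                 base_seed = base_seed)),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat("<cv_summary> ", x$settings$method, ", k = ", x$settings$k,
      ", reps = ", x$settings$reps, "\n", sep = "")
  print(x$summary)
  invisible(x)
}
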