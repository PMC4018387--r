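#' Fit the multi-task linear programming discriminant (MLPD)
#'
#' Jointly estimates one sparse discriminant direction per task by solving
#' a single linear program: each task carries its own Dantzig-type fidelity
#' constraint `||Sigma_i beta_i - delta_i||_inf <= lambda_i`, and a linking
#' penalty `gamma * sum |(Sigma_i beta_i)_k - (Sigma_j beta_j)_k|` over
#' shared features `k` of every task pair pulls the estimated class-mean
#' differences of the tasks together on the features they share. With
#' `gamma = 0` the program decouples and each task's solution is the
#' single-task [fit_slpd()] rule.
#'
#' @param tasks Either a list of `task_dataset` objects (statistics and
#'   shared sets are derived automatically), or a list of `class_stats`
#'   (then `shared` must be supplied).
#' @param lambdas Per-task fidelity bounds, recycled to the number of tasks.
#' @param gamma Nonnegative linking weight; `NULL` (default) uses
#'   `1 / max_i p_i`, which scales the linking term against the l1 term.
#' @param link_norm `"l1"` (default) or `"linf"`; see [build_joint_lp()].
#' @param shared List of [shared_features()] sets; required when `tasks`
#'   are `class_stats`, derived over all task pairs otherwise.
#' @return An object of class `mlpd_fit`: list with `betas`, `mids`,
#'   `lambdas`, `gamma`, `objective` (total LP objective), `l1` (the
#'   `sum ||beta_i||_1` part), `linking` (the linking penalty evaluated at
#'   the optimum), `patterns`, `feature_index`, `shared`, `status`.
#'   Infeasible parameter points raise an `mlpd_infeasible` condition.
#' @export
#' @examples
#' cfg <- sim_config(block_dims = c(4, 3), seed = 7,
#'   patterns = list(list(sources = c("MRI", "PET"), n_pos = 30, n_neg = 30),
#'                   list(sources = "MRI", n_pos = 30, n_neg = 30)))
#' tasks <- decompose_tasks(simulate_dataset(cfg))
#' fit <- fit_mlpd(tasks, lambdas = 0.3)
#' glance(fit)
fit_mlpd <- function(tasks, lambdas, gamma = NULL,
                     link_norm = c("l1", "linf"), shared = NULL) {
  link_norm <- match.arg(link_norm)
  if (all(vapply(tasks, inherits, logical(1), "task_dataset"))) {
    stats <- lapply(tasks, pooled_stats)
    patterns <- lapply(tasks, function(t) t$pattern)
    if (is.null(shared)) {
      shared <- list()
      n <- length(tasks)
      if (n >= 2) {
        for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
          s <- shared_features(tasks[[i]], tasks[[j]])
          if (nrow(s)) shared[[length(shared) + 1]] <- s
        }
      }
    }
  } else if (all(vapply(tasks, inherits, logical(1), "class_stats"))) {
    stats <- tasks
    patterns <- rep(list(NULL), length(tasks))
    if (is.null(shared)) {
      abort("`shared` must be supplied when fitting from class_stats objects.")
    }
  } else {
    abort("`tasks` must be a list of task_dataset or class_stats objects.")
  }
  n_task <- length(stats)
  lambdas <- rep_len(lambdas, n_task)
  gamma <- gamma %||% (1 / max(vapply(stats, function(s)
    length(s$delta), integer(1))))
  stopifnot(gamma >= 0, all(lambdas >= 0))

  spec <- build_joint_lp(stats, shared, lambdas, gamma, link_norm)
  sol <- solve_lp(spec)
  if (sol$status == "infeasible") signal_infeasible(lambdas, gamma)
  if (sol$status != "optimal") {
    abort(paste0("LP solver failed with status: ", sol$status))
  }
  betas <- extract_betas(spec, sol$x, stats)
  l1 <- sum(vapply(betas, function(b) sum(abs(b)), numeric(1)))
  structure(
    list(betas = betas, mids = lapply(stats, `[[`, "mid"),
         lambdas = lambdas, gamma = gamma, link_norm = link_norm,
         objective = sol$objective, l1 = l1,
         linking = linking_penalty(stats, shared, betas, link_norm),
         patterns = patterns,
         feature_index = lapply(stats, `[[`, "global_index"),
         shared = shared, status = sol$status),
    class = "mlpd_fit"
  )
}

#' @export
print.mlpd_fit <- function(x, ...) {
  cat("<mlpd_fit> ", length(x$betas), " task(s), gamma = ",
      signif(x$gamma, 4), "\n", sep = "")
  for (i in seq_along(x$betas)) {
    cat("  task ", i,
        if (!is.null(x$patterns[[i]]))
          paste0(" [", paste(x$patterns[[i]], collapse = "+"), "]") else "",
        ": p = ", length(x$betas[[i]]), ", lambda = ", x$lambdas[i],
        ", nonzero = ", sum(abs(x$betas[[i]]) > 1e-8), "\n", sep = "")
  }
  cat("  objective = ", signif(x$objective, 6), " (l1 ", signif(x$l1, 6),
      " + gamma * linking ", signif(x$linking, 6), ")\n", sep = "")
  invisible(x)
}

#' Classify a subject with a fitted MLPD model
#'
#' Routes the subject to the task whose availability pattern matches the
#' subject's observed sources, then applies that task's linear rule:
#' score `(x - mid_i)' beta_i`, class +1 iff the score is strictly
#' positive (ties to -1).
#'
#' @param m An `mlpd_fit` fitted from `task_dataset` objects (so patterns
#'   are known), or with an explicit `task` index.
#' @param x Numeric vector (one subject) or matrix/data frame of subjects
#'   sharing one availability pattern.
#' @param pattern Character vector of observed source names; matched
#'   against the fitted tasks' patterns (order-insensitive). Ignored when
#'   `task` is given.
#' @param task Optional explicit task index.
#' @return A tibble with columns `task_id`, `score`, `label`.
#' @export
classify_mlpd <- function(m, x, pattern = NULL, task = NULL) {
  if (is.null(task)) {
    if (is.null(pattern)) abort("supply `pattern` or `task`")
    hit <- which(vapply(m$patterns, function(p)
      !is.null(p) && setequal(p, pattern), logical(1)))
    if (!length(hit)) {
      abort(paste0("no model for availability pattern {",
                   paste(pattern, collapse = ", "), "}"))
    }
    task <- hit[1]
  }
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != length(m$betas[[task]])) {
    abort(paste0("feature dimension mismatch for task ", task))
  }
  score <- drop(sweep(X, 2, m$mids[[task]]) %*% m$betas[[task]])
  tibble::tibble(task_id = task, score = score,
                 label = ifelse(score > 0, 1L, -1L))
}

#' Serialize / restore fitted models as JSON
#'
#' @param m An `slpd_fit` or `mlpd_fit`.
#' @param path Output JSON file.
#' @return `path` invisibly (`write_model`); a refitted-shape model object
#'   (`read_model`).
#' @export
write_model <- function(m, path) {
  payload <- if (inherits(m, "slpd_fit")) {
    list(type = "slpd", beta = as.list(m$beta), mid = as.list(m$mid),
         lambda = m$lambda, objective = m$objective,
         feature_index = as.list(m$feature_index))
  } else {
    list(type = "mlpd", gamma = m$gamma, lambdas = m$lambdas,
         objective = m$objective, link_norm = m$link_norm,
         tasks = lapply(seq_along(m$betas), function(i) list(
           pattern = m$patterns[[i]], beta = as.list(m$betas[[i]]),
           mid = as.list(m$mids[[i]]),
           feature_index = as.list(m$feature_index[[i]])
         )))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, as.numeric, numeric(1))
  if (identical(p$type, "slpd")) {
    structure(list(beta = num(p$beta), mid = num(p$mid),
                   lambda = p$lambda, objective = p$objective,
                   feature_index = num(p$feature_index),
                   status = "restored"),
              class = "slpd_fit")
  } else {
    structure(list(
      betas = lapply(p$tasks, function(t) num(t$beta)),
      mids = lapply(p$tasks, function(t) num(t$mid)),
      lambdas = num(p$lambdas), gamma = p$gamma, link_norm = p$link_norm,
      objective = p$objective,
      patterns = lapply(p$tasks, function(t)
        unlist(t$pattern, use.names = FALSE)),
      feature_index = lapply(p$tasks, function(t) num(t$feature_index)),
      shared = list(), status = "restored"
    ), class = "mlpd_fit")
  }
}
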