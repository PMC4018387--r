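#' Pooled two-class statistics of a task
#'
#' Computes the per-class mean vectors, their difference and midpoint, and
#' the pooled within-class sample covariance with maximum-likelihood divisor
#' `n = n1 + n2` (the within-class centered scatter of both classes over the
#' total sample size).
#'
#' @param t A `task_dataset` (see [decompose_tasks()]).
#' @return An object of class `class_stats`: list with `mu1`, `mu2`,
#'   `delta` (`mu1 - mu2`), `mid` (`(mu1 + mu2)/2`), `sigma` (p x p pooled
#'   covariance), `n1`, `n2`, and `global_index`.
#' @export
pooled_stats <- function(t) {
  stopifnot(inherits(t, "task_dataset"))
  mu1 <- colMeans(t$X1)
  mu2 <- colMeans(t$X2)
  C1 <- sweep(t$X1, 2, mu1)
  C2 <- sweep(t$X2, 2, mu2)
  n <- nrow(t$X1) + nrow(t$X2)
  sigma <- (crossprod(C1) + crossprod(C2)) / n
  sigma <- (sigma + t(sigma)) / 2
  structure(
    list(mu1 = mu1, mu2 = mu2, delta = mu1 - mu2, mid = (mu1 + mu2) / 2,
         sigma = sigma, n1 = nrow(t$X1), n2 = nrow(t$X2),
         global_index = t$global_index),
    class = "class_stats"
  )
}

#' @export
print.class_stats <- function(x, ...) {
  cat("<class_stats> p = ", length(x$delta), ", n = ", x$n1, " + ", x$n2,
      ", ||delta||_inf = ", signif(max(abs(x$delta)), 4), "\n", sep = "")
  invisible(x)
}

#' Fit the single-task linear programming discriminant (SLPD)
#'
#' Estimates the discriminant direction as the minimum-l1 vector whose
#' fitted mean difference is within `lambda` of the observed one in the
#' infinity norm:
#' \deqn{\hat\beta = \arg\min \|\beta\|_1 \quad \mathrm{s.t.} \quad
#'   \|\hat\Sigma \beta - \hat\delta\|_\infty \le \lambda,}
#' solved exactly as a linear program (positive/negative split, `2p`
#' inequality rows). `lambda` trades sparsity against fidelity and is
#' normally chosen by cross-validation ([inner_cv_select()]). When
#' `lambda >= ||delta||_inf`, the zero vector is feasible and optimal.
#'
#' @param x A `class_stats` object, or a `task_dataset` (statistics are
#'   computed via [pooled_stats()]).
#' @param lambda Nonnegative fidelity bound.
#' @return An object of class `slpd_fit`: list with `beta` (named vector),
#'   `mid`, `lambda`, `objective` (the l1 norm at the optimum),
#'   `feature_index`, `pattern`, and `status`. An infeasible LP (possible
#'   for singular `sigma` with small `lambda`) raises a condition of class
#'   `mlpd_infeasible`, which parameter tuning treats as an invalid point.
#' @export
#' @examples
#' t <- list(task_id = 1L, pattern = "A",
#'           X1 = matrix(rnorm(40, 1), 20), X2 = matrix(rnorm(40), 20),
#'           global_index = c(f1 = 1L, f2 = 2L))
#' class(t) <- "task_dataset"
#' fit <- fit_slpd(t, lambda = 0.1)
#' tidy(fit)
fit_slpd <- function(x, lambda) {
  s <- if (inherits(x, "task_dataset")) pooled_stats(x) else x
  stopifnot(inherits(s, "class_stats"), lambda >= 0)
  spec <- build_joint_lp(list(s), list(), lambdas = lambda, gamma = 0)
  sol <- solve_lp(spec)
  if (sol$status == "infeasible") signal_infeasible(lambda)
  if (sol$status != "optimal") {
    abort(paste0("LP solver failed with status: ", sol$status))
  }
  beta <- extract_betas(spec, sol$x, list(s))[[1]]
  structure(
    list(beta = beta, mid = s$mid, lambda = lambda,
         objective = sol$objective, feature_index = s$global_index,
         pattern = attr(x, "pattern") %||% x$pattern %||% NULL,
         status = sol$status),
    class = "slpd_fit"
  )
}

#' @export
print.slpd_fit <- function(x, ...) {
  cat("<slpd_fit> p = ", length(x$beta), ", lambda = ", x$lambda,
      ", ||beta||_1 = ", signif(x$objective, 5),
      ", nonzero = ", sum(abs(x$beta) > 1e-8), "\n", sep = "")
  invisible(x)
}

#' Classify subjects with a fitted LPD rule
#'
#' Scores a subject by `(x - mid)' beta` and assigns class +1 exactly when
#' the score is strictly positive; a score of zero (including the
#' all-zero discriminant) is assigned to class -1.
#'
#' @param m An `slpd_fit`.
#' @param x Numeric vector of length `p`, or a matrix / data frame with one
#'   subject per row.
#' @return A tibble with columns `score` and `label` (one row per subject).
#' @export
classify_lpd <- function(m, x) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != length(m$beta)) {
    abort(paste0("feature dimension mismatch: model has ", length(m$beta),
                 ", input has ", ncol(X)))
  }
  score <- drop(sweep(X, 2, m$mid) %*% m$beta)
  tibble::tibble(score = score, label = ifelse(score > 0, 1L, -1L))
}

#' @export
predict.slpd_fit <- function(object, newdata, ...) classify_lpd(object, newdata)
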