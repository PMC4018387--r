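# Linear-program assembly and solving for the discriminant fits.
#
# All problems are posed over nonnegative variables
#   v = (beta1+, beta1-, ..., betaT+, betaT-, slacks)
# with rows A v <= b. The l1 objective splits each discriminant vector as
# beta_i = beta_i+ - beta_i-; the infinity-norm fidelity constraint
# ||Sigma_i beta_i - delta_i||_inf <= lambda_i contributes 2 p_i rows; each
# linking term contributes slack variables bounding the absolute difference
# of (Sigma_i beta_i)_k across a task pair on shared features.

#' Assemble the joint multi-task discriminant linear program
#'
#' Encodes
#' \deqn{\min \sum_i \|\beta_i\|_1 +
#'   \gamma \sum_{(i,j)} \sum_{k \in S_{ij}}
#'   |(\hat\Sigma_i \beta_i)_k - (\hat\Sigma_j \beta_j)_k|
#'   \quad \mathrm{s.t.}\quad
#'   \|\hat\Sigma_i \beta_i - \hat\delta_i\|_\infty \le \lambda_i \ \forall i}
#' as a standard-form LP over nonnegative variables. `(\hat\Sigma_i
#' \beta_i)_k` on shared features uses the rows of `\hat\Sigma_i` indexed by
#' the shared set. With `link_norm = "linf"` the inner sum over `k` is
#' replaced by the maximum (one slack per pair instead of one per shared
#' feature).
#'
#' @param stats List of per-task [pooled_stats()] objects.
#' @param shared List of [shared_features()] sets (one per linked task
#'   pair); may be empty.
#' @param lambdas Numeric vector of per-task fidelity bounds, recycled to
#'   the number of tasks; all `>= 0`.
#' @param gamma Nonnegative linking weight.
#' @param link_norm `"l1"` (default; per-feature absolute differences) or
#'   `"linf"` (maximum difference per pair).
#' @return An object of class `lp_spec`: list with `objective`, `A`, `b`
#'   (all rows `A v <= b`, `v >= 0`), `col_labels`, `row_labels`, and
#'   layout metadata (`p`, `offsets`, `n_slack`).
#' @export
build_joint_lp <- function(stats, shared, lambdas, gamma,
                           link_norm = c("l1", "linf")) {
  link_norm <- match.arg(link_norm)
  n_task <- length(stats)
  lambdas <- rep_len(lambdas, n_task)
  stopifnot(all(lambdas >= 0), gamma >= 0, n_task >= 1)
  p <- vapply(stats, function(s) length(s$delta), integer(1))

  # variable layout: task i occupies offsets[i] + (1..2 p_i)
  offsets <- cumsum(c(0L, 2L * p))[seq_len(n_task)]
  n_beta <- 2L * sum(p)

  slack_cols <- list()
  for (s in shared) {
    pair <- attr(s, "task_pair")
    if (any(pair > n_task)) abort("shared set references an unknown task")
    if (any(s$pos_i > p[pair[1]]) || any(s$pos_j > p[pair[2]])) {
      abort("shared set positions exceed task dimensions")
    }
    k <- if (link_norm == "l1") nrow(s) else min(1L, nrow(s))
    slack_cols[[length(slack_cols) + 1]] <- k
  }
  n_slack <- sum(unlist(slack_cols), 0L)
  n_var <- n_beta + n_slack

  obj <- c(rep(1, n_beta), rep(gamma, n_slack))

  rows <- list(); rhs <- list(); rlab <- list()
  add <- function(r, b, lab) {
    rows[[length(rows) + 1]] <<- r
    rhs[[length(rhs) + 1]] <<- b
    rlab[[length(rlab) + 1]] <<- lab
  }

  beta_block <- function(i, M) {
    # columns of M applied to beta_i = beta_i+ - beta_i-, embedded in v
    out <- matrix(0, nrow(M), n_var)
    out[, offsets[i] + seq_len(p[i])] <- M
    out[, offsets[i] + p[i] + seq_len(p[i])] <- -M
    out
  }

  for (i in seq_len(n_task)) {
    S <- stats[[i]]$sigma
    d <- stats[[i]]$delta
    B <- beta_block(i, S)
    add(B, lambdas[i] + d, paste0("fid_t", i, "_hi_", seq_len(p[i])))
    add(-B, lambdas[i] - d, paste0("fid_t", i, "_lo_", seq_len(p[i])))
  }

  slack_at <- n_beta
  for (idx in seq_along(shared)) {
    s <- shared[[idx]]
    if (!nrow(s)) next
    pair <- attr(s, "task_pair")
    i <- pair[1]; j <- pair[2]
    Li <- beta_block(i, stats[[i]]$sigma[s$pos_i, , drop = FALSE])
    Lj <- beta_block(j, stats[[j]]$sigma[s$pos_j, , drop = FALSE])
    D <- Li - Lj
    m <- nrow(s)
    E <- matrix(0, m, n_var)
    if (link_norm == "l1") {
      E[cbind(seq_len(m), slack_at + seq_len(m))] <- 1
      slack_at <- slack_at + m
    } else {
      E[, slack_at + 1L] <- 1
      slack_at <- slack_at + 1L
    }
    add(D - E, rep(0, m), paste0("link_", i, "_", j, "_hi_", seq_len(m)))
    add(-D - E, rep(0, m), paste0("link_", i, "_", j, "_lo_", seq_len(m)))
  }

  A <- do.call(rbind, rows)
  structure(
    list(objective = obj, A = A, b = unlist(rhs),
         row_labels = unlist(rlab),
         col_labels = c(
           unlist(lapply(seq_len(n_task), function(i)
             paste0("t", i, "_", rep(c("bp", "bm"), each = p[i]), "_",
                    names(stats[[i]]$delta)))),
           if (n_slack) paste0("slack_", seq_len(n_slack))),
         p = p, offsets = offsets, n_slack = n_slack,
         gamma = gamma, lambdas = lambdas, link_norm = link_norm),
    class = "lp_spec"
  )
}

#' @export
print.lp_spec <- function(x, ...) {
  cat("<lp_spec> ", length(x$objective), " variables (",
      sum(2L * x$p), " beta splits + ", x$n_slack, " linking slacks), ",
      nrow(x$A), " inequality rows\n", sep = "")
  invisible(x)
}

#' Solve an assembled discriminant LP
#'
#' Thin wrapper around the two-phase simplex solver in \pkg{boot}. Rows
#' with negative right-hand side are flipped to `>=` form, as the solver
#' requires nonnegative bounds.
#'
#' @param spec An `lp_spec` from [build_joint_lp()].
#' @param n_iter Simplex iteration cap; defaults to `50 * (rows + cols)`.
#' @param eps Pivot tolerance passed to the solver.
#' @return List with `status` (`"optimal"`, `"infeasible"` or
#'   `"iteration_limit"`), `x` (the variable vector, for optimal status),
#'   and `objective`.
#' @export
solve_lp <- function(spec, n_iter = NULL, eps = 1e-10) {
  A <- spec$A
  n_iter <- n_iter %||% (50 * (nrow(A) + ncol(A)))
  run <- function(b, eps) {
    neg <- b < 0
    boot::simplex(
      a = spec$objective,
      A1 = if (any(!neg)) A[!neg, , drop = FALSE] else NULL,
      b1 = if (any(!neg)) b[!neg] else NULL,
      A2 = if (any(neg)) -A[neg, , drop = FALSE] else NULL,
      b2 = if (any(neg)) -b[neg] else NULL,
      maxi = FALSE, n.iter = n_iter, eps = eps
    )
  }
  # degenerate vertices (ties in the ratio test, exact-zero right-hand
  # sides) can stall the pivoting; retry with a tiny deterministic
  # relaxation of the constraint bounds, which moves the optimum by far
  # less than the solver tolerance
  attempts <- list(
    list(b = spec$b, eps = eps),
    list(b = spec$b + 1e-9 * (1 + abs(spec$b)), eps = eps),
    list(b = spec$b + 1e-7 * (1 + abs(spec$b)), eps = 1e-9)
  )
  sol <- NULL
  for (at in attempts) {
    sol <- tryCatch(run(at$b, at$eps), error = function(e) NULL)
    if (!is.null(sol) && sol$solved %in% c(-1, 1)) break
  }
  if (is.null(sol)) {
    return(list(status = "solver_error", x = NULL, objective = NA_real_))
  }
  status <- c("-1" = "infeasible", "0" = "iteration_limit",
              "1" = "optimal")[[as.character(sol$solved)]]
  list(status = status,
       x = if (status == "optimal") as.numeric(sol$soln[seq_along(spec$objective)]) else NULL,
       objective = if (status == "optimal") unname(sol$value) else NA_real_)
}

# Extract per-task beta vectors from an LP solution vector.
extract_betas <- function(spec, x, stats) {
  lapply(seq_along(spec$p), function(i) {
    pi <- spec$p[i]; off <- spec$offsets[i]
    setNames(x[off + seq_len(pi)] - x[off + pi + seq_len(pi)],
             names(stats[[i]]$delta))
  })
}

# Linking penalty of the fitted betas, evaluated exactly from the solution
# (not from the slack variables, which are only bounds when gamma = 0).
linking_penalty <- function(stats, shared, betas, link_norm = "l1") {
  total <- 0
  for (s in shared) {
    if (!nrow(s)) next
    pair <- attr(s, "task_pair")
    di <- drop(stats[[pair[1]]]$sigma[s$pos_i, , drop = FALSE] %*%
                 betas[[pair[1]]])
    dj <- drop(stats[[pair[2]]]$sigma[s$pos_j, , drop = FALSE] %*%
                 betas[[pair[2]]])
    total <- total + if (link_norm == "l1") sum(abs(di - dj)) else
      max(abs(di - dj))
  }
  total
}

signal_infeasible <- function(lambdas, gamma = NULL) {
  rlang::abort(
    class = "mlpd_infeasible",
    message = paste0(
      "LP infeasible for lambda = (",
      paste(signif(lambdas, 4), collapse = ", "),
      if (!is.null(gamma)) paste0("), gamma = ", signif(gamma, 4)) else ")",
      "; treat as invalid parameter point."
    )
  )
}
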