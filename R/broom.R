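#' Tidy fitted discriminant models
#'
#' `tidy()` returns one row per (task, feature) with the discriminant
#' coefficient; `glance()` returns a one-row model summary.
#'
#' @param x An `slpd_fit` or `mlpd_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.slpd_fit <- function(x, ...) {
  tibble::tibble(feature = names(x$beta),
                 global = as.integer(x$feature_index),
                 estimate = unname(x$beta))
}

#' @rdname tidy.slpd_fit
#' @exportS3Method generics::tidy
tidy.mlpd_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$betas), function(i)
    tibble::tibble(task_id = i, feature = names(x$betas[[i]]),
                   global = as.integer(x$feature_index[[i]]),
                   estimate = unname(x$betas[[i]]))))
}

#' @rdname tidy.slpd_fit
#' @exportS3Method generics::glance
glance.slpd_fit <- function(x, ...) {
  tibble::tibble(p = length(x$beta), lambda = x$lambda,
                 objective = x$objective,
                 nonzero = sum(abs(x$beta) > 1e-8), status = x$status)
}

#' @rdname tidy.slpd_fit
#' @exportS3Method generics::glance
glance.mlpd_fit <- function(x, ...) {
  tibble::tibble(
    n_tasks = length(x$betas), gamma = x$gamma,
    objective = x$objective, l1 = x$l1, linking = x$linking,
    nonzero = sum(vapply(x$betas, function(b)
      sum(abs(b) > 1e-8), integer(1))),
    status = x$status
  )
}

#' @rdname tidy.slpd_fit
#' @exportS3Method generics::tidy
tidy.cv_run <- function(x, ...) x$metrics

#' @rdname tidy.slpd_fit
#' @exportS3Method generics::glance
glance.cv_run <- function(x, ...) {
  dplyr::filter(x$metrics, .data$scope == "overall")
}

#' @rdname tidy.slpd_fit
#' @exportS3Method generics::tidy
tidy.cv_summary <- function(x, ...) x$summary

#' @rdname tidy.slpd_fit
#' @exportS3Method generics::glance
glance.cv_summary <- function(x, ...) {
  x$summary |>
    dplyr::filter(.data$scope == "overall") |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"))
}
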