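# Shared test fixtures and independent oracles, all built in code.

# A task_dataset straight from matrices.
make_task <- function(X1, X2, task_id = 1L, pattern = "A",
                      global_index = NULL) {
  p <- ncol(X1)
  if (is.null(colnames(X1))) {
    colnames(X1) <- colnames(X2) <- paste0("f", seq_len(p))
  }
  if (is.null(rownames(X1))) rownames(X1) <- paste0("a", seq_len(nrow(X1)))
  if (is.null(rownames(X2))) rownames(X2) <- paste0("b", seq_len(nrow(X2)))
  structure(
    list(task_id = as.integer(task_id), pattern = pattern,
         X1 = X1, X2 = X2,
         global_index = global_index %||%
           stats::setNames(seq_len(p), colnames(X1))),
    class = "task_dataset"
  )
}

`%||%` <- rlang::`%||%`

# class_stats with prescribed sigma / delta (mid defaults to zero).
make_stats <- function(sigma, delta, mid = NULL) {
  p <- length(delta)
  nm <- paste0("f", seq_len(p))
  structure(
    list(mu1 = stats::setNames(delta / 2, nm),
         mu2 = stats::setNames(-delta / 2, nm),
         delta = stats::setNames(delta, nm),
         mid = stats::setNames(mid %||% rep(0, p), nm),
         sigma = sigma, n1 = 10L, n2 = 10L,
         global_index = stats::setNames(seq_len(p), nm)),
    class = "class_stats"
  )
}

# Random well-conditioned statistics for property loops.
random_stats <- function(p, seed) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(p * p), p)
    make_stats(sigma = crossprod(M) / p + 0.05 * diag(p), delta = rnorm(p))
  })
}

# Independent generic LP oracle (pracma's simplex implementation) for
# min c'x s.t. A x <= b, x >= 0. Only trusted at small sizes; returns NA
# when the oracle itself breaks down numerically (degenerate pivot), which
# is a failure of the oracle, never of the solution under test.
lp_oracle <- function(spec) {
  # zero right-hand sides make the origin a degenerate vertex that stalls
  # pracma's pivoting; a 1e-9 relaxation breaks the tie and moves the
  # optimum by far less than the 1e-6 comparison tolerance
  b <- spec$b
  b[b == 0] <- 1e-9
  tryCatch(
    pracma::linprog(spec$objective, A = spec$A, b = b, maxiter = 5000)$fval,
    error = function(e) NA_real_
  )
}

# A 4-subject, two-source CSV written to a temp file; subject s3 is missing
# the whole PET block.
write_tiny_csv <- function(path = tempfile(fileext = ".csv"),
                           pet_na = "s3", partial = FALSE) {
  df <- data.frame(
    subject_id = paste0("s", 1:4),
    label = c("case", "ctrl", "case", "ctrl"),
    mri_a = c(1, 2, 3, 4), mri_b = c(5, 6, 7, 8),
    pet_a = c(0.1, 0.2, 0.3, 0.4), pet_b = c(1.1, 1.2, 1.3, 1.4)
  )
  df[df$subject_id %in% pet_na, c("pet_a", "pet_b")] <- NA
  if (partial) df[df$subject_id == "s2", "pet_b"] <- NA
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

tiny_sources <- list(MRI = c("mri_a", "mri_b"), PET = c("pet_a", "pet_b"))

# Small simulated two-task dataset for protocol tests.
toy_dataset <- function(seed = 11, n1 = c(20, 30), n2 = c(25, 15),
                        p = c(4, 3), rho = 0.6) {
  cfg <- sim_config(
    block_dims = p, rho = rho, seed = seed,
    support = seq_len(min(3, p[1])),
    patterns = list(
      list(sources = c("MRI", "PET"), n_pos = n1[1], n_neg = n2[1]),
      list(sources = "MRI", n_pos = n1[2], n_neg = n2[2])
    )
  )
  simulate_dataset(cfg)
}
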