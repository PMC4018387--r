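#' Configuration for the two-block Gaussian benchmark generator
#'
#' Describes a two-class Gaussian population over several feature blocks
#' ("sources") with a block-wise missingness design, emulating the
#' structure of a multi-modality neuroimaging cohort: two correlated
#' feature blocks (e.g. regional MRI volumes and PET intensities), a sparse
#' mean shift between the classes, and whole blocks absent for part of the
#' subjects.
#'
#' Cross-block dependence is generated by pairing feature `k` of block 1
#' with feature `k` of block 2 through a shared latent factor, giving
#' correlation `rho` within each pair and (for distinct pairs) independence,
#' so the canonical correlations between the blocks are `rho` for each of
#' the `min(p1, p2)` pairs. Alternatively a full covariance matrix `sigma`
#' may be supplied.
#'
#' Defaults follow the reference cohort's shape at toy feature scale:
#' pattern counts 76/126 (both blocks, classes +1/-1) and 91/100 (block 1
#' only), blocks of 10 features each, `rho = 0.7`, and a mean shift of 0.5
#' on the first 5 features of block 1 (Bayes accuracy about 0.78). A
#' full-scale design uses `block_dims = c(93, 93)`.
#'
#' @param block_dims Integer vector of per-source feature counts.
#' @param patterns List of availability patterns, each a list with
#'   `sources` (character), `n_pos`, `n_neg` (subjects per class).
#' @param rho Cross-block correlation of paired features, in `[0, 1)`.
#' @param delta_value Mean shift applied to each active feature.
#' @param support Global indices of active (mean-shifted) features.
#' @param sigma Optional full covariance matrix (overrides `rho`).
#' @param source_names Names of the sources; default `"MRI"`, `"PET"`, ...
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(block_dims = c(10, 10),
                       patterns = NULL,
                       rho = 0.7,
                       delta_value = 0.5,
                       support = seq_len(min(5, block_dims[1])),
                       sigma = NULL,
                       source_names = NULL,
                       seed = 1) {
  stopifnot(all(block_dims >= 1), rho >= 0, rho < 1)
  n_block <- length(block_dims)
  source_names <- source_names %||%
    c("MRI", "PET", paste0("SRC", seq_len(max(0, n_block - 2))))[seq_len(n_block)]
  patterns <- patterns %||% list(
    list(sources = source_names[seq_len(min(2, n_block))], n_pos = 76, n_neg = 126),
    list(sources = source_names[1], n_pos = 91, n_neg = 100)
  )
  p <- sum(block_dims)
  stopifnot(all(support >= 1), all(support <= p))

  if (is.null(sigma)) {
    sigma <- diag(p)
    if (n_block >= 2 && rho > 0) {
      off1 <- 0L
      off2 <- block_dims[1]
      for (k in seq_len(min(block_dims[1], block_dims[2]))) {
        sigma[off1 + k, off2 + k] <- rho
        sigma[off2 + k, off1 + k] <- rho
      }
    }
  } else {
    stopifnot(nrow(sigma) == p, ncol(sigma) == p)
    sigma <- (sigma + t(sigma)) / 2
  }
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    abort("sigma_true must be positive definite")
  }

  mu2 <- rep(0, p)
  mu1 <- mu2
  mu1[support] <- delta_value

  feat_names <- unlist(lapply(seq_len(n_block), function(b)
    paste0(source_names[b], "_", seq_len(block_dims[b]))))
  sources <- split(feat_names, rep(source_names, block_dims))[source_names]

  structure(
    list(block_dims = block_dims, patterns = patterns, rho = rho,
         mu1 = mu1, mu2 = mu2, sigma = sigma, support = support,
         sources = sources, source_names = source_names, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> blocks ", paste(x$block_dims, collapse = "+"),
      " (", paste(x$source_names, collapse = ", "), "), rho = ", x$rho,
      ", |support| = ", length(x$support), ", seed = ", x$seed, "\n", sep = "")
  for (pt in x$patterns) {
    cat("  pattern {", paste(pt$sources, collapse = "+"), "}: ",
        pt$n_pos, " / ", pt$n_neg, " subjects (+1 / -1)\n", sep = "")
  }
  invisible(x)
}

#' Simulate a block-missing two-class Gaussian dataset
#'
#' Draws each subject's full feature vector from `N(mu_c, sigma)` for its
#' class `c`, assigns subjects to availability patterns per the
#' configuration, blanks the absent blocks, and returns a valid
#' [multisource_dataset()]. Identical configurations (including `seed`)
#' produce identical datasets.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed overriding `cfg$seed` (convenient for
#'   replicate draws from one population).
#' @return A [multisource_dataset()].
#' @export
simulate_dataset <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- seed %||% cfg$seed
  p <- sum(cfg$block_dims)
  feat_names <- unlist(cfg$sources, use.names = FALSE)

  withr::with_seed(seed, {
    rows <- list()
    sid <- 0L
    for (pt in cfg$patterns) {
      for (cls in c(1L, -1L)) {
        n <- if (cls == 1L) pt$n_pos else pt$n_neg
        mu <- if (cls == 1L) cfg$mu1 else cfg$mu2
        X <- MASS::mvrnorm(n, mu = mu, Sigma = cfg$sigma)
        X <- matrix(X, nrow = n, ncol = p)
        colnames(X) <- feat_names
        absent <- setdiff(cfg$source_names, pt$sources)
        for (s in absent) X[, cfg$sources[[s]]] <- NA_real_
        df <- tibble::as_tibble(X)
        df$subject_id <- sprintf("S%05d", sid + seq_len(n))
        df$label <- cls
        sid <- sid + n
        rows[[length(rows) + 1]] <- df
      }
    }
    multisource_dataset(dplyr::bind_rows(rows), sources = cfg$sources)
  })
}

#' Bayes accuracy of the generating Gaussian model
#'
#' Closed-form optimal accuracy of the equal-prior, common-covariance
#' Gaussian classification problem: `Phi(Delta / 2)` with
#' `Delta^2 = delta' sigma^{-1} delta`, `delta = mu1 - mu2`. This is the
#' ceiling any classifier can reach on data from [simulate_dataset()], and
#' the oracle for consistency checks.
#'
#' @param cfg A [sim_config()].
#' @return A single number in `[0.5, 1]`.
#' @export
bayes_accuracy <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  delta <- cfg$mu1 - cfg$mu2
  sol <- tryCatch(solve(cfg$sigma, delta),
                  error = function(e) abort("sigma_true is singular"))
  pnorm(sqrt(sum(delta * sol)) / 2)
}

#' Canonical correlations between two feature blocks of a task
#'
#' Classical canonical correlation analysis between the first `split`
#' columns and the remaining columns of a task's stacked feature matrix
#' (both classes pooled), returned in descending order. Used as a
#' diagnostic of cross-modality dependence: strongly correlated blocks are
#' the regime where joint multi-task fitting is expected to help. When the
#' sample size does not exceed the total feature count, a ridge-regularised
#' variant is computed with a warning.
#'
#' @param t A `task_dataset` containing both blocks.
#' @param split Number of leading columns forming the first block.
#' @param ridge Regularisation added to the within-block correlation
#'   matrices in the degenerate regime.
#' @return Numeric vector of canonical correlations in `[0, 1]`, descending.
#' @export
canonical_correlation_diagnostic <- function(t, split, ridge = 1e-3) {
  X <- rbind(t$X1, t$X2)
  p <- ncol(X)
  stopifnot(split >= 1, split < p)
  A <- X[, seq_len(split), drop = FALSE]
  B <- X[, (split + 1):p, drop = FALSE]
  if (nrow(X) > p) {
    cc <- stats::cancor(A, B)$cor
  } else {
    warn("n <= total features; computing ridge-regularised canonical correlations")
    Saa <- stats::cov(A) + ridge * diag(ncol(A))
    Sbb <- stats::cov(B) + ridge * diag(ncol(B))
    Sab <- stats::cov(A, B)
    M <- solve(Saa, Sab) %*% solve(Sbb, t(Sab))
    ev <- eigen(M, only.values = TRUE)$values
    cc <- sqrt(pmax(0, pmin(1, Re(ev))))
  }
  sort(pmin(1, pmax(0, cc)), decreasing = TRUE)
}
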