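test_that("reading derives the availability mask from NA block patterns", {
  ds <- read_feature_table(write_tiny_csv(), tiny_sources,
                           positive = "case")
  expect_s3_class(ds, "multisource_dataset")
  expect_equal(unname(ds$availability[, "MRI"]), rep(TRUE, 4))
  expect_equal(unname(ds$availability[, "PET"]), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(ds$data$label, c(1L, -1L, 1L, -1L))
})

test_that("a partially missing block is rejected unless coerced", {
  path <- write_tiny_csv(partial = TRUE)
  expect_error(read_feature_table(path, tiny_sources, positive = "case"),
               "Block-consistency")
  expect_warning(
    ds <- read_feature_table(path, tiny_sources, positive = "case",
                             coerce_partial = TRUE),
    "Coercing"
  )
  expect_false(ds$availability["s2", "PET"])
  expect_true(all(is.na(ds$data[ds$data$subject_id == "s2",
                                tiny_sources$PET])))
})

test_that("unknown or non-binary label codes are rejected", {
  path <- write_tiny_csv()
  expect_error(read_feature_table(path, tiny_sources, positive = "sick"),
               "not found")
  expect_error(read_feature_table(path, tiny_sources), "positive")
})

test_that("write then read round-trips values, mask and labels", {
  ds <- toy_dataset(seed = 3)
  csv <- tempfile(fileext = ".csv")
  schema <- tempfile(fileext = ".yaml")
  write_feature_table(ds, csv, schema_path = schema)
  ds2 <- read_feature_table(csv, schema)
  expect_equal(ds2$data$label, ds$data$label)
  expect_equal(ds2$availability, ds$availability)
  expect_equal(as.matrix(ds2$data[-(1:2)]), as.matrix(ds$data[-(1:2)]),
               tolerance = 1e-12)
})

test_that("task decomposition recovers the two-task cohort shape", {
  ds <- simulate_dataset(sim_config(seed = 5))
  tasks <- decompose_tasks(ds)
  expect_length(tasks, 2)
  expect_setequal(tasks[[1]]$pattern, c("MRI", "PET"))
  expect_equal(tasks[[2]]$pattern, "MRI")
  expect_equal(c(nrow(tasks[[1]]$X1), nrow(tasks[[1]]$X2)), c(76, 126))
  expect_equal(c(nrow(tasks[[2]]$X1), nrow(tasks[[2]]$X2)), c(91, 100))
  expect_equal(ncol(tasks[[1]]$X1), 20)
  expect_equal(ncol(tasks[[2]]$X1), 10)
})

test_that("a fully complete dataset yields exactly one task", {
  cfg <- sim_config(block_dims = c(3, 3), seed = 2, patterns = list(
    list(sources = c("MRI", "PET"), n_pos = 10, n_neg = 12)))
  tasks <- decompose_tasks(simulate_dataset(cfg))
  expect_length(tasks, 1)
  expect_equal(nrow(tasks[[1]]$X1) + nrow(tasks[[1]]$X2), 22)
})

test_that("nested 3-source patterns decompose per brute-force grouping", {
  cfg <- sim_config(
    block_dims = c(2, 2, 2), seed = 9, rho = 0,
    source_names = c("A", "B", "C"),
    support = 1:2,
    patterns = list(
      list(sources = "A", n_pos = 5, n_neg = 5),
      list(sources = c("A", "B"), n_pos = 6, n_neg = 4),
      list(sources = c("A", "B", "C"), n_pos = 7, n_neg = 8)
    )
  )
  ds <- simulate_dataset(cfg)
  tasks <- decompose_tasks(ds)
  expect_length(tasks, 3)
  # deterministic ordering: descending source count
  expect_equal(vapply(tasks, function(t) ncol(t$X1), integer(1)),
               c(6L, 4L, 2L))
  # brute-force oracle: group subject ids by their NA pattern directly
  vals <- as.matrix(ds$data[-(1:2)])
  key <- apply(!is.na(vals), 1, paste, collapse = "")
  expect_equal(sort(table(key), decreasing = TRUE) |> as.integer() |> sort(),
               sort(vapply(tasks, function(t)
                 nrow(t$X1) + nrow(t$X2), integer(1))))
  # subject conservation
  expect_equal(sum(vapply(tasks, function(t)
    nrow(t$X1) + nrow(t$X2), integer(1))), nrow(ds$data))
})

test_that("decomposition is invariant to subject row order", {
  ds <- toy_dataset(seed = 21)
  tasks <- decompose_tasks(ds)
  perm <- withr::with_seed(1, sample(nrow(ds$data)))
  df <- ds$data[perm, ]
  df$label <- ifelse(df$label == 1, "1", "-1")
  ds2 <- multisource_dataset(df, ds$sources, positive = "1")
  tasks2 <- decompose_tasks(ds2)
  for (i in seq_along(tasks)) {
    expect_equal(tasks2[[i]]$pattern, tasks[[i]]$pattern)
    o1 <- order(rownames(tasks[[i]]$X1)); o2 <- order(rownames(tasks2[[i]]$X1))
    expect_equal(tasks2[[i]]$X1[o2, ], tasks[[i]]$X1[o1, ])
  }
})

test_that("no trainable pattern raises an error", {
  ds <- read_feature_table(write_tiny_csv(), tiny_sources, positive = "case")
  expect_error(decompose_tasks(ds, min_per_class = 5), "no trainable task")
})

test_that("shared feature sets match independent set intersection", {
  ds <- toy_dataset(seed = 13)
  tasks <- decompose_tasks(ds)
  s <- shared_features(tasks[[1]], tasks[[2]])
  expect_equal(attr(s, "m"), 4)  # the whole MRI block
  expect_equal(s$feature, names(tasks[[2]]$global_index))
  # intersection oracle on random 3-source patterns
  cfg <- sim_config(block_dims = c(2, 3, 2), seed = 17, rho = 0,
                    source_names = c("A", "B", "C"), support = 1:2,
                    patterns = list(
                      list(sources = c("A", "B"), n_pos = 5, n_neg = 5),
                      list(sources = c("B", "C"), n_pos = 5, n_neg = 5)))
  t2 <- decompose_tasks(simulate_dataset(cfg))
  s2 <- shared_features(t2[[1]], t2[[2]])
  expect_equal(attr(s2, "m"),
               length(intersect(t2[[1]]$global_index, t2[[2]]$global_index)))
  expect_equal(s2$global,
               sort(intersect(t2[[1]]$global_index, t2[[2]]$global_index)))
})

test_that("tasks over disjoint sources share nothing", {
  t1 <- make_task(matrix(rnorm(8), 4), matrix(rnorm(8), 4),
                  global_index = c(x1 = 1L, x2 = 2L))
  t2 <- make_task(matrix(rnorm(8), 4), matrix(rnorm(8), 4),
                  global_index = c(y1 = 3L, y2 = 4L))
  expect_equal(attr(shared_features(t1, t2), "m"), 0)
})

test_that("reorder_shared_first puts shared columns first in both tasks", {
  ds <- toy_dataset(seed = 31)
  tasks <- decompose_tasks(ds)
  # scramble task-1 columns so shared features are not first
  perm <- c(5, 1, 6, 2, 7, 3, 4)
  t1p <- mlpd:::permute_task(tasks[[1]], perm)
  s <- shared_features(t1p, tasks[[2]])
  out <- reorder_shared_first(t1p, tasks[[2]], s)
  m <- attr(out$shared, "m")
  expect_equal(out$shared$pos_i, seq_len(m))
  expect_equal(out$shared$pos_j, seq_len(m))
  expect_equal(out$task_i$global_index[seq_len(m)],
               out$task_j$global_index[seq_len(m)])
  # idempotence on already-ordered input
  again <- reorder_shared_first(out$task_i, out$task_j)
  expect_equal(again$task_i$X1, out$task_i$X1)
  expect_equal(again$task_j$X1, out$task_j$X1)
})

test_that("fits are invariant to the shared-first reordering", {
  ds <- toy_dataset(seed = 37)
  tasks <- decompose_tasks(ds)
  perm <- withr::with_seed(2, sample(7))
  t1p <- mlpd:::permute_task(tasks[[1]], perm)
  fit_orig <- fit_mlpd(list(tasks[[1]], tasks[[2]]), lambdas = 0.2,
                       gamma = 0.5)
  fit_perm <- fit_mlpd(list(t1p, tasks[[2]]), lambdas = 0.2, gamma = 0.5)
  out <- reorder_shared_first(t1p, tasks[[2]])
  fit_reord <- fit_mlpd(list(out$task_i, out$task_j), lambdas = 0.2,
                        gamma = 0.5)
  expect_equal(fit_perm$objective, fit_orig$objective, tolerance = 1e-8)
  expect_equal(fit_reord$objective, fit_orig$objective, tolerance = 1e-8)
  # fidelity residuals agree (beta itself may be LP-degenerate)
  s1 <- pooled_stats(out$task_i)
  res <- max(abs(s1$sigma %*% fit_reord$betas[[1]] - s1$delta))
  expect_lte(res, 0.2 + 1e-6)
})

test_that("restrict_sources and complete_cases build the comparison arms", {
  ds <- toy_dataset(seed = 41)
  mri_only <- restrict_sources(ds, "MRI")
  expect_equal(names(mri_only$sources), "MRI")
  expect_equal(nrow(mri_only$data), nrow(ds$data))
  expect_length(decompose_tasks(mri_only), 1)
  cc <- complete_cases(ds)
  expect_true(all(rowSums(cc$availability) == 2))
  expect_equal(nrow(cc$data), sum(rowSums(ds$availability) == 2))
})
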