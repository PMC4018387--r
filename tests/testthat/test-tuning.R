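test_that("log grids hit their endpoints with constant ratio", {
  g <- make_log_grid(0.01, 1, 20)
  expect_equal(g[1], 0.01)
  expect_equal(g[20], 1)
  ratios <- g[-1] / g[-20]
  expect_equal(ratios, rep(10^(2 / 19), 19), tolerance = 1e-10)
  g2 <- make_log_grid(0.01, 10, 20)
  expect_equal(c(g2[1], g2[20]), c(0.01, 10))
  expect_equal(make_log_grid(2, 8, 2), c(2, 8))
  expect_error(make_log_grid(1, 0.5, 5), "lo < hi")
  expect_error(make_log_grid(0.1, 1, 1), "n >= 2")
})

test_that("stratified folds are balanced within every task x class stratum", {
  ds <- simulate_dataset(sim_config(seed = 4))
  tasks <- decompose_tasks(ds)
  folds <- stratified_folds(tasks, k = 10, seed = 2)
  expect_equal(nrow(folds), 393)
  expect_equal(anyDuplicated(folds$subject_id), 0)
  sizes <- folds |>
    dplyr::count(.data$task_id, .data$label, .data$fold)
  by_stratum <- split(sizes$n, paste(sizes$task_id, sizes$label))
  for (s in by_stratum) expect_lte(max(s) - min(s), 1)
  # 76 subjects into 10 folds: six folds of 8 and four of 7
  s76 <- sort(sizes$n[sizes$task_id == 1 & sizes$label == 1])
  expect_equal(s76, c(rep(7, 4), rep(8, 6)))
})

test_that("fold assignment is deterministic in the seed", {
  tasks <- decompose_tasks(toy_dataset(seed = 6))
  f1 <- stratified_folds(tasks, 5, seed = 10)
  f2 <- stratified_folds(tasks, 5, seed = 10)
  f3 <- stratified_folds(tasks, 5, seed = 11)
  expect_identical(f1, f2)
  by_subj <- function(f) f$fold[order(f$subject_id)]
  expect_false(identical(by_subj(f1), by_subj(f3)))
})

test_that("a stratum equal to k gets one subject per fold, smaller errors", {
  t <- make_task(matrix(rnorm(12), 4), matrix(rnorm(12), 4))
  folds <- stratified_folds(list(t), k = 4, seed = 1)
  expect_equal(sort(folds$fold[folds$label == 1]), 1:4)
  expect_error(stratified_folds(list(t), k = 5, seed = 1), "smaller k")
})

test_that("metrics follow the confusion-count identities", {
  m <- compute_metrics(1, 1, 0, 0)
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(1, 1, 1))
  m2 <- compute_metrics(3, 2, 2, 1)
  expect_equal(m2$accuracy, 0.625)
  expect_equal(m2$sensitivity, 0.75)
  expect_equal(m2$specificity, 0.5)
  m3 <- compute_metrics(0, 5, 0, 0)
  expect_true(is.na(m3$sensitivity))
  expect_equal(m3$specificity, 1)
  expect_equal(m3$accuracy, 1)
  expect_error(compute_metrics(-1, 0, 0, 0))
})

test_that("a single-point grid is selected without choice", {
  tasks <- decompose_tasks(toy_dataset(seed = 14))
  sel <- inner_cv_select(tasks, method = "mlpd",
                         grids = list(lambda = 0.3), folds_inner = 3,
                         tau = 0.5, seed = 5)
  expect_equal(sel$params$lambda, 0.3)
  expect_equal(nrow(sel$results), 1)
})

test_that("inner selection finds a planted optimum and is deterministic", {
  # strong sparse signal: a moderate lambda separates well, a huge lambda
  # gives the zero rule (chance-level accuracy)
  cfg <- sim_config(block_dims = c(4, 4), rho = 0.3, delta_value = 1.5,
                    support = 1:3, seed = 50,
                    patterns = list(list(sources = c("MRI", "PET"),
                                         n_pos = 60, n_neg = 60)))
  tasks <- decompose_tasks(simulate_dataset(cfg))
  sel <- inner_cv_select(tasks, method = "slpd",
                         grids = list(lambda = c(0.1, 50)),
                         folds_inner = 5, tau = 0.9, seed = 3)
  expect_equal(sel$params$lambda, 0.1)
  expect_gt(diff(range(sel$results$mean_accuracy)), 0.2)
  sel2 <- inner_cv_select(tasks, method = "slpd",
                          grids = list(lambda = c(0.1, 50)),
                          folds_inner = 5, tau = 0.9, seed = 3)
  expect_identical(sel$results, sel2$results)
})

test_that("accuracy ties break toward the smaller lambda", {
  cfg <- sim_config(block_dims = c(3, 2), rho = 0, delta_value = 4,
                    support = 1:2, seed = 51,
                    patterns = list(list(sources = c("MRI", "PET"),
                                         n_pos = 30, n_neg = 30)))
  tasks <- decompose_tasks(simulate_dataset(cfg))
  # both small lambdas classify the well-separated classes perfectly
  sel <- inner_cv_select(tasks, method = "slpd",
                         grids = list(lambda = c(0.05, 0.1)),
                         folds_inner = 3, tau = 0.9, seed = 2)
  expect_equal(max(sel$results$mean_accuracy), 1)
  expect_equal(sel$params$lambda, 0.05)
})

test_that("an outer CV run is deterministic and conserves subjects", {
  ds <- toy_dataset(seed = 61, n1 = c(24, 24), n2 = c(24, 24))
  run <- cv_run(ds, k = 4, method = "mlpd",
                grids = list(lambda = c(0.1, 0.5)), folds_inner = 3,
                tau = 0.5, seed = 9)
  run2 <- cv_run(ds, k = 4, method = "mlpd",
                 grids = list(lambda = c(0.1, 0.5)), folds_inner = 3,
                 tau = 0.5, seed = 9)
  expect_identical(run$predictions, run2$predictions)
  expect_equal(nrow(run$predictions), nrow(ds$data))
  expect_equal(anyDuplicated(run$predictions$subject_id), 0)
  ov <- dplyr::filter(run$metrics, scope == "overall")
  expect_equal(ov$tp + ov$tn + ov$fp + ov$fn, nrow(ds$data))
})

test_that("screening and selection depend on outer-training subjects only", {
  ds <- toy_dataset(seed = 71, n1 = c(20, 20), n2 = c(20, 20))
  run <- cv_run(ds, k = 4, method = "mlpd",
                grids = list(lambda = 0.2), folds_inner = 3,
                tau = 0.6, seed = 13)
  tasks <- decompose_tasks(ds)
  folds <- stratified_folds(tasks, 4, seed = 13)
  for (f in c(1, 3)) {
    train_ids <- folds$subject_id[folds$fold != f]
    # recompute the screening from scratch after deleting the test rows
    train_tasks <- lapply(tasks, mlpd:::subset_task_subjects, ids = train_ids)
    scr <- screen_tasks(train_tasks, tau = 0.6)
    expect_equal(scr$pvalues_by_task,
                 run$fold_log[[f]]$pvalues_by_task, tolerance = 1e-12)
    expect_equal(vapply(scr$kept_by_task, length, integer(1)),
                 unname(run$fold_log[[f]]$kept))
  }
})

test_that("repeated runs aggregate by plain mean and sd", {
  ds <- toy_dataset(seed = 81, n1 = c(16, 16), n2 = c(16, 16))
  summ <- repeated_cv_experiment(ds, k = 4, method = "slpd", reps = 3,
                                 base_seed = 2,
                                 grids = list(lambda = c(0.1, 0.6)),
                                 folds_inner = 3, tau = 0.6)
  acc <- summ$per_rep$accuracy[summ$per_rep$scope == "overall"]
  got <- dplyr::filter(summ$summary, scope == "overall",
                       metric == "accuracy")
  expect_equal(got$mean, mean(acc))
  expect_equal(got$sd, stats::sd(acc))
  expect_equal(nrow(summ$per_rep), 3 * 3)  # overall + two tasks, three reps
  # reps = 1: no spread to report
  s1 <- repeated_cv_experiment(ds, k = 4, method = "slpd", reps = 1,
                               base_seed = 2,
                               grids = list(lambda = 0.1),
                               folds_inner = 3, tau = 0.6)
  expect_true(all(is.na(s1$summary$sd)))
})

test_that("the pipeline writes parseable artifacts and is reproducible", {
  ds <- toy_dataset(seed = 91, n1 = c(16, 16), n2 = c(16, 16))
  csv <- tempfile(fileext = ".csv"); schema <- tempfile(fileext = ".yaml")
  write_feature_table(ds, csv, schema_path = schema)
  outdir <- tempfile()
  config <- list(
    input = list(path = csv, sources = schema),
    method = "mlpd", k = 4, reps = 2, seed = 3, tau = 0.6,
    folds_inner = 3,
    grids = list(lambda = list(lo = 0.05, hi = 0.5, n = 2)),
    output_dir = outdir
  )
  res <- run_pipeline(config)
  expect_true(file.exists(res$paths$predictions))
  metrics <- jsonlite::read_json(res$paths$metrics, simplifyVector = TRUE)
  expect_true(all(c("summary", "per_rep") %in% names(metrics)))
  expect_true(all(metrics$summary$mean >= 0 & metrics$summary$mean <= 1))
  pred <- readr::read_csv(res$paths$predictions, show_col_types = FALSE)
  expect_true(all(c("subject_id", "task_id", "score", "predicted_label")
                  %in% names(pred)))
  # same config, fresh directory: identical predictions
  config$output_dir <- tempfile()
  res2 <- run_pipeline(config)
  expect_identical(readLines(res$paths$predictions),
                   readLines(res2$paths$predictions))
  # the single-modality single-task arm is a config change only
  config$restrict_sources <- "MRI"
  config$method <- "slpd"
  config$output_dir <- tempfile()
  res3 <- run_pipeline(config)
  expect_true(all(readr::read_csv(res3$paths$predictions,
                                  show_col_types = FALSE)$task_id == 1))
})

test_that("schema files can be read from YAML for the sources argument", {
  ds <- toy_dataset(seed = 95)
  csv <- tempfile(fileext = ".csv"); schema <- tempfile(fileext = ".yaml")
  write_feature_table(ds, csv, schema_path = schema)
  ds2 <- read_feature_table(csv, schema)
  expect_equal(ds2$sources, ds$sources)
})
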