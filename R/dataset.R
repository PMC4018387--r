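#' Multi-source dataset with block-wise missingness
#'
#' Bundles a subjects-by-features table with a schema that assigns feature
#' columns to named sources (modalities) and a per-subject availability mask.
#' A source is either entirely observed or entirely missing for a subject
#' ("block-wise" missingness); partially observed blocks are rejected unless
#' `coerce_partial = TRUE`, in which case the whole block is blanked.
#'
#' Labels are recoded internally to +1 / -1. If the label column is not
#' already coded that way, `positive` must name the level mapped to +1.
#'
#' @param data A data frame with one row per subject: an id column, a label
#'   column, and one numeric column per feature.
#' @param sources Named list mapping each source name to the character vector
#'   of its feature column names. Order of the list fixes the global feature
#'   order (features of the first source first).
#' @param label Name of the label column. Default `"label"`.
#' @param id Name of the subject identifier column. Default `"subject_id"`;
#'   if absent, row numbers are used.
#' @param positive The label level coded as +1 (the positive class, e.g.
#'   progressive MCI). Required unless labels are already +1/-1.
#' @param coerce_partial If `TRUE`, a block with some but not all entries
#'   missing is coerced to fully absent (with a warning) instead of raising
#'   an error.
#'
#' @return An object of class `multisource_dataset`: a list with elements
#'   `data` (tibble: `subject_id`, `label`, feature columns), `sources`,
#'   `availability` (subjects x sources logical matrix) and `label_map`.
#' @export
#' @examples
#' df <- tibble::tibble(
#'   subject_id = paste0("s", 1:4), label = c(1, -1, 1, -1),
#'   m1 = rnorm(4), m2 = rnorm(4), p1 = c(rnorm(2), NA, rnorm(1)),
#'   p2 = c(rnorm(2), NA, rnorm(1))
#' )
#' ds <- multisource_dataset(df, sources = list(MRI = c("m1", "m2"),
#'                                              PET = c("p1", "p2")))
#' ds$availability
multisource_dataset <- function(data, sources, label = "label",
                                id = "subject_id", positive = NULL,
                                coerce_partial = FALSE) {
  stopifnot(is.data.frame(data), is.list(sources), length(sources) >= 1)
  if (is.null(names(sources)) || any(names(sources) == "")) {
    abort("`sources` must be a named list of feature-column vectors.")
  }
  feats <- unlist(sources, use.names = FALSE)
  if (anyDuplicated(feats)) {
    abort("Feature names must be unique across sources.")
  }
  missing_cols <- setdiff(c(label, feats), names(data))
  if (length(missing_cols)) {
    abort(paste0("Columns absent from `data`: ",
                 paste(missing_cols, collapse = ", ")))
  }
  ids <- if (id %in% names(data)) as.character(data[[id]]) else
    as.character(seq_len(nrow(data)))
  if (anyDuplicated(ids)) abort("Subject identifiers must be unique.")

  lab_raw <- data[[label]]
  lvls <- sort(unique(as.character(lab_raw)))
  if (length(lvls) != 2) {
    abort(paste0("Label column must hold exactly two codes; found: ",
                 paste(lvls, collapse = ", ")))
  }
  if (is.null(positive)) {
    if (!setequal(lvls, c("-1", "1"))) {
      abort("Labels are not coded +1/-1; supply `positive` to declare the positive class.")
    }
    positive <- "1"
  } else {
    positive <- as.character(positive)
    if (!positive %in% lvls) {
      abort(paste0("`positive` level '", positive, "' not found in labels."))
    }
  }
  negative <- setdiff(lvls, positive)
  labels <- ifelse(as.character(lab_raw) == positive, 1L, -1L)

  vals <- as.matrix(data[feats])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids

  avail <- matrix(TRUE, nrow(vals), length(sources),
                  dimnames = list(ids, names(sources)))
  for (s in names(sources)) {
    block <- vals[, sources[[s]], drop = FALSE]
    n_na <- rowSums(is.na(block))
    partial <- n_na > 0 & n_na < length(sources[[s]])
    if (any(partial)) {
      if (!coerce_partial) {
        abort(paste0(
          "Block-consistency violation: subjects ",
          paste(head(ids[partial], 5), collapse = ", "),
          " have a partially missing '", s, "' block. ",
          "Use coerce_partial = TRUE to blank such blocks."
        ))
      }
      warn(paste0("Coercing partially missing '", s, "' block to absent for ",
                  sum(partial), " subject(s)."))
      vals[partial, sources[[s]]] <- NA_real_
      n_na[partial] <- length(sources[[s]])
    }
    avail[, s] <- n_na == 0
  }
  if (any(rowSums(avail) == 0)) {
    bad <- ids[rowSums(avail) == 0]
    abort(paste0("Subjects with no available source: ",
                 paste(head(bad, 5), collapse = ", ")))
  }

  out <- list(
    data = dplyr::bind_cols(
      tibble::tibble(subject_id = ids, label = labels),
      tibble::as_tibble(vals)
    ),
    sources = lapply(sources, as.character),
    availability = avail,
    label_map = c(positive = positive, negative = negative)
  )
  structure(out, class = "multisource_dataset")
}

#' @export
print.multisource_dataset <- function(x, ...) {
  cat("<multisource_dataset> ", nrow(x$data), " subjects, ",
      length(feature_names(x)), " features in ", length(x$sources),
      " source(s)\n", sep = "")
  for (s in names(x$sources)) {
    cat("  ", s, ": ", length(x$sources[[s]]), " features, available for ",
        sum(x$availability[, s]), " subjects\n", sep = "")
  }
  cat("  classes: +1 (", x$label_map[["positive"]], ") n=",
      sum(x$data$label == 1), "; -1 (", x$label_map[["negative"]], ") n=",
      sum(x$data$label == -1), "\n", sep = "")
  invisible(x)
}

feature_names <- function(ds) unlist(ds$sources, use.names = FALSE)

#' Read a feature table into a multi-source dataset
#'
#' Reads a CSV or TSV file (one row per subject; header row) and applies a
#' source schema. The schema may be given inline as a named list or as the
#' path to a YAML/JSON file with keys `sources` (name -> column list) and
#' optionally `label`, `id`, `positive`.
#'
#' @inheritParams multisource_dataset
#' @param path Path to a delimited text file; `.tsv`/`.txt` are read as
#'   tab-separated, anything else as comma-separated.
#' @param sources Named list, or path to a YAML/JSON schema file.
#' @return A [multisource_dataset()].
#' @export
read_feature_table <- function(path, sources, label = "label",
                               id = "subject_id", positive = NULL,
                               coerce_partial = FALSE) {
  if (is.character(sources) && length(sources) == 1 && file.exists(sources)) {
    schema <- read_schema(sources)
    label <- schema$label %||% label
    id <- schema$id %||% id
    positive <- schema$positive %||% positive
    sources <- schema$sources
  }
  reader <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
    readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  multisource_dataset(df, sources = sources, label = label, id = id,
                      positive = positive, coerce_partial = coerce_partial)
}

read_schema <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Write a multi-source dataset back to disk
#'
#' Writes the feature table as CSV (absent blocks as empty cells) and,
#' optionally, the source schema as YAML, so the pair can be re-read with
#' [read_feature_table()].
#'
#' @param ds A [multisource_dataset()].
#' @param path Output CSV path.
#' @param schema_path Optional path for a YAML schema file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ds, path, schema_path = NULL) {
  out <- ds$data
  out$label <- ifelse(out$label == 1, ds$label_map[["positive"]],
                      ds$label_map[["negative"]])
  readr::write_csv(out, path, na = "")
  if (!is.null(schema_path)) {
    yaml::write_yaml(
      list(sources = lapply(ds$sources, as.list), label = "label",
           id = "subject_id", positive = ds$label_map[["positive"]]),
      schema_path
    )
  }
  invisible(path)
}

#' Restrict a dataset to a subset of sources / to complete cases
#'
#' `restrict_sources()` drops all feature columns outside `sources` (subjects
#' left with no available source are dropped). `complete_cases()` keeps only
#' subjects for which every source is available. Together they express the
#' single-task comparison arms: a one-modality analysis of all subjects, and
#' a complete-case analysis.
#'
#' @param ds A [multisource_dataset()].
#' @param sources Character vector of source names to keep.
#' @return A [multisource_dataset()].
#' @export
restrict_sources <- function(ds, sources) {
  stopifnot(all(sources %in% names(ds$sources)))
  keep_sources <- ds$sources[sources]
  keep_subj <- rowSums(ds$availability[, sources, drop = FALSE]) > 0
  df <- ds$data[keep_subj, c("subject_id", "label",
                             unlist(keep_sources, use.names = FALSE))]
  df$label <- ifelse(df$label == 1, ds$label_map[["positive"]],
                     ds$label_map[["negative"]])
  multisource_dataset(df, sources = keep_sources,
                      positive = ds$label_map[["positive"]])
}

#' @rdname restrict_sources
#' @export
complete_cases <- function(ds) {
  keep <- rowSums(ds$availability) == length(ds$sources)
  df <- ds$data[keep, , drop = FALSE]
  df$label <- ifelse(df$label == 1, ds$label_map[["positive"]],
                     ds$label_map[["negative"]])
  multisource_dataset(df, sources = ds$sources,
                      positive = ds$label_map[["positive"]])
}

subset_subjects <- function(ds, subject_ids) {
  df <- ds$data[ds$data$subject_id %in% subject_ids, , drop = FALSE]
  df$label <- ifelse(df$label == 1, ds$label_map[["positive"]],
                     ds$label_map[["negative"]])
  multisource_dataset(df, sources = ds$sources,
                      positive = ds$label_map[["positive"]])
}

#' Decompose a block-missing dataset into per-pattern tasks
#'
#' Groups subjects by their availability pattern (the set of observed
#' sources) and forms one classification task per pattern that retains at
#' least `min_per_class` subjects in each class. Tasks are numbered
#' deterministically: descending number of sources, ties broken
#' lexicographically by pattern.
#'
#' @param ds A [multisource_dataset()].
#' @param min_per_class Minimum subjects per class for a pattern to become a
#'   task (default 2, so each class contributes at least one centered vector
#'   to the pooled covariance).
#' @return A list of `task_dataset` objects, each with elements `task_id`,
#'   `pattern` (source names), `X1` / `X2` (class +1 / -1 feature matrices,
#'   subjects in rows), and `global_index` (named integer vector mapping
#'   local column position to global feature position).
#' @export
decompose_tasks <- function(ds, min_per_class = 2) {
  stopifnot(inherits(ds, "multisource_dataset"), min_per_class >= 1)
  src_names <- names(ds$sources)
  pat_key <- apply(ds$availability, 1, function(a)
    paste(src_names[a], collapse = "+"))
  groups <- split(ds$data$subject_id, pat_key)

  keys <- names(groups)
  n_src <- lengths(strsplit(keys, "+", fixed = TRUE))
  keys <- keys[order(-n_src, keys)]

  all_feats <- feature_names(ds)
  vals <- as.matrix(ds$data[all_feats])
  rownames(vals) <- ds$data$subject_id
  labels <- setNames(ds$data$label, ds$data$subject_id)

  tasks <- list()
  for (key in keys) {
    subj <- groups[[key]]
    pat <- strsplit(key, "+", fixed = TRUE)[[1]]
    s1 <- subj[labels[subj] == 1]
    s2 <- subj[labels[subj] == -1]
    if (length(s1) < min_per_class || length(s2) < min_per_class) next
    feats <- unlist(ds$sources[src_names[src_names %in% pat]],
                    use.names = FALSE)
    gidx <- setNames(match(feats, all_feats), feats)
    tasks[[length(tasks) + 1]] <- new_task_dataset(
      task_id = length(tasks) + 1L, pattern = pat,
      X1 = vals[s1, feats, drop = FALSE], X2 = vals[s2, feats, drop = FALSE],
      global_index = gidx
    )
  }
  if (!length(tasks)) {
    abort(paste0("no trainable task: no availability pattern has at least ",
                 min_per_class, " subjects per class"))
  }
  tasks
}

new_task_dataset <- function(task_id, pattern, X1, X2, global_index) {
  stopifnot(nrow(X1) >= 1, nrow(X2) >= 1, ncol(X1) == ncol(X2),
            ncol(X1) == length(global_index),
            !anyNA(X1), !anyNA(X2), !anyDuplicated(global_index))
  structure(
    list(task_id = as.integer(task_id), pattern = pattern,
         X1 = X1, X2 = X2, global_index = global_index),
    class = "task_dataset"
  )
}

#' @export
print.task_dataset <- function(x, ...) {
  cat("<task_dataset> task ", x$task_id, " [",
      paste(x$pattern, collapse = "+"), "]: ",
      nrow(x$X1), " / ", nrow(x$X2), " subjects (+1 / -1), ",
      ncol(x$X1), " features\n", sep = "")
  invisible(x)
}

#' Shared features between two tasks
#'
#' Enumerates the global features present in both tasks, in global feature
#' order, as pairs of local column positions.
#'
#' @param t_i,t_j `task_dataset` objects from the same dataset.
#' @return A tibble of class `shared_feature_set` with columns `feature`,
#'   `global`, `pos_i`, `pos_j`, and attributes `task_pair` and `m` (the
#'   number of shared features; possibly zero).
#' @export
shared_features <- function(t_i, t_j) {
  common <- intersect(t_i$global_index, t_j$global_index)
  common <- sort(common)
  out <- tibble::tibble(
    feature = names(t_i$global_index)[match(common, t_i$global_index)],
    global = as.integer(common),
    pos_i = match(common, t_i$global_index),
    pos_j = match(common, t_j$global_index)
  )
  structure(out, class = c("shared_feature_set", class(out)),
            task_pair = c(t_i$task_id, t_j$task_id), m = nrow(out))
}

#' Reorder two tasks so shared features come first
#'
#' Permutes the feature columns of both tasks so that their shared features
#' occupy positions `1..m`, in the same (global) order in both tasks; the
#' remaining columns keep their original relative order. Any downstream fit
#' is invariant to this permutation; it only standardises bookkeeping.
#'
#' @inheritParams shared_features
#' @param s The [shared_features()] set of `(t_i, t_j)`; recomputed when
#'   omitted.
#' @return A list with elements `task_i`, `task_j` (reordered) and `shared`
#'   (the updated shared set, with `pos_i = pos_j = 1..m`).
#' @export
reorder_shared_first <- function(t_i, t_j, s = shared_features(t_i, t_j)) {
  perm_i <- c(s$pos_i, setdiff(seq_along(t_i$global_index), s$pos_i))
  perm_j <- c(s$pos_j, setdiff(seq_along(t_j$global_index), s$pos_j))
  ti <- permute_task(t_i, perm_i)
  tj <- permute_task(t_j, perm_j)
  list(task_i = ti, task_j = tj, shared = shared_features(ti, tj))
}

permute_task <- function(t, perm) {
  new_task_dataset(t$task_id, t$pattern,
                   t$X1[, perm, drop = FALSE], t$X2[, perm, drop = FALSE],
                   t$global_index[perm])
}

subset_task_features <- function(t, keep) {
  new_task_dataset(t$task_id, t$pattern,
                   t$X1[, keep, drop = FALSE], t$X2[, keep, drop = FALSE],
                   t$global_index[keep])
}

subset_task_subjects <- function(t, ids) {
  k1 <- rownames(t$X1) %in% ids
  k2 <- rownames(t$X2) %in% ids
  new_task_dataset(t$task_id, t$pattern,
                   t$X1[k1, , drop = FALSE], t$X2[k2, , drop = FALSE],
                   t$global_index)
}
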