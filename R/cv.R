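#' Stratified cross-validation folds
#'
#' Randomly partitions a dataset into `n_folds` disjoint test folds,
#' stratified by class so every fold contains both classes and per-fold
#' class ratios are within one instance of the global ratio. The companion
#' training set of each fold is the complement (80%/20% at the default 5
#' folds).
#'
#' @param dataset A [labeled_dataset()].
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed; identical seeds give identical folds.
#' @return A `fold_split`: list of `n_folds` `(train, test)` dataset
#'   pairs, with the per-record fold assignment in `attr(, "assignment")`.
#' @export
split_folds <- function(dataset, n_folds = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n_folds <- stopifnot_count(n_folds, "n_folds", min = 2L)
  cls <- split(seq_len(nrow(dataset)), dataset$label)
  if (length(cls) < 2L || any(lengths(cls) < n_folds)) {
    stop(sprintf(
      "too few instances for stratified %d-fold split (need >= %d per class)",
      n_folds, n_folds), call. = FALSE)
  }
  assignment <- integer(nrow(dataset))
  with_seed(seed, {
    for (ix in cls) {
      assignment[sample(ix)] <- rep_len(seq_len(n_folds), length(ix))
    }
  })
  folds <- lapply(seq_len(n_folds), function(f) {
    list(train = dataset_subset(dataset, assignment != f),
         test = dataset_subset(dataset, assignment == f))
  })
  attr(folds, "assignment") <- assignment
  class(folds) <- "fold_split"
  folds
}

#' Cross-validated evaluation of the nearest-neighbour classifier
#'
#' Runs stratified k-fold cross-validation (default 5CV, i.e. five 80/20
#' train/test splits): per fold, the classifier — including any feature
#' standardisation — is fitted on the training fold only and scored on the
#' held-out test fold, so no information leaks from test to train. Fold
#' metrics are aggregated two ways: pooled confusion counts across folds
#' (micro average, the primary report) and the mean of per-fold metrics
#' (macro average).
#'
#' @param dataset A [labeled_dataset()].
#' @param k,L,distance,scale,mode Model settings, see [allerknn()].
#' @param threshold Decision threshold for [compute_metrics()].
#' @param n_folds,seed Fold settings, see [split_folds()].
#' @param folds Optional precomputed `fold_split` (used by [k_scan()] to
#'   hold folds fixed across settings).
#' @return A `cv_result`: list with `pooled` (a `metrics_report` over the
#'   pooled counts), `folds` (per-fold reports), `macro` (mean per-fold
#'   metrics), and `predictions` (per-instance id, fold, label, score).
#' @export
cross_validate <- function(dataset, k = 3L, L = 5L,
                           distance = c("euclidean", "manhattan"),
                           scale = FALSE, mode = c("strict", "permissive"),
                           threshold = 0.5, n_folds = 5L, seed = 1L,
                           folds = NULL) {
  distance <- match.arg(distance)
  mode <- match.arg(mode)
  if (any(!dataset$valid)) {
    warning(sprintf("excluding %d record(s) flagged invalid",
                    sum(!dataset$valid)), call. = FALSE)
    dataset <- dataset_subset(dataset, dataset$valid)
  }
  folds <- folds %||% split_folds(dataset, n_folds = n_folds, seed = seed)
  assignment <- attr(folds, "assignment")
  X <- acc_features(dataset, L = L, mode = mode)

  preds <- vector("list", length(folds))
  reports <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- assignment != f
    te <- assignment == f
    fit <- allerknn(X[tr, , drop = FALSE], labels = dataset$label[tr],
                    routes = dataset$routes[tr], ids = dataset$id[tr],
                    k = k, L = L, distance = distance, scale = scale)
    p <- predict(fit, X[te, , drop = FALSE], threshold = threshold)
    preds[[f]] <- data.frame(id = dataset$id[te], fold = f,
                             label = dataset$label[te], score = p$score,
                             stringsAsFactors = FALSE)
    reports[[f]] <- compute_metrics(dataset$label[te], p$score, threshold)
  }
  all_pred <- do.call(rbind, preds)
  pooled <- compute_metrics(all_pred$label, all_pred$score, threshold)
  macro_of <- function(field) {
    mean(vapply(reports, function(r) r[[field]], 0))
  }
  macro <- vapply(c("sensitivity", "specificity", "ppv", "f1", "auc"),
                  macro_of, 0)
  structure(list(pooled = pooled, folds = reports, macro = macro,
                 predictions = all_pred,
                 settings = list(k = k, L = L, distance = distance,
                                 scale = scale, threshold = threshold,
                                 n_folds = length(folds), seed = seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf("%d-fold cross-validation, kNN k = %d (%s distance)\n",
              s$n_folds, s$k, s$distance))
  cat("Pooled (micro) metrics:\n")
  print(x$pooled)
  cat("Macro (mean per-fold):",
      paste(sprintf("%s=%.4f", names(x$macro), x$macro), collapse = " "),
      "\n")
  invisible(x)
}

#' Scan the neighbour count k
#'
#' Repeats cross-validation over a set of odd `k` values using *identical*
#' folds for every k, so the comparison is paired and differences are
#' attributable to k alone.
#'
#' @param dataset A [labeled_dataset()].
#' @param ks Odd neighbour counts to scan (default 1, 3, 5, 7, 9).
#' @param n_folds,seed Fold settings.
#' @param ... Further model settings passed to [cross_validate()].
#' @return A `k_scan` list: `table` (one row of pooled metrics per k),
#'   `results` (the full `cv_result` per k) and the shared fold
#'   `assignment`.
#' @export
k_scan <- function(dataset, ks = c(1L, 3L, 5L, 7L, 9L), n_folds = 5L,
                   seed = 1L, ...) {
  if (any(ks %% 2L == 0L)) {
    stop("all k values must be odd", call. = FALSE)
  }
  if (any(!dataset$valid)) dataset <- dataset_subset(dataset, dataset$valid)
  folds <- split_folds(dataset, n_folds = n_folds, seed = seed)
  results <- lapply(ks, function(k) {
    cross_validate(dataset, k = k, folds = folds, seed = seed, ...)
  })
  names(results) <- as.character(ks)
  table <- do.call(rbind, lapply(seq_along(ks), function(i) {
    cbind(k = ks[i], as.data.frame(results[[i]]$pooled))
  }))
  rownames(table) <- NULL
  structure(list(table = table, results = results,
                 assignment = attr(folds, "assignment")),
            class = "k_scan")
}

#' @export
print.k_scan <- function(x, ...) {
  cat("kNN neighbour-count scan (paired folds)\n")
  print(x$table[, c("k", "sensitivity", "specificity", "ppv", "f1", "auc")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cross-comparative analysis of route-specific models
#'
#' Fits one model per route of exposure (and one on the pooled total set)
#' and evaluates every model on every route's test data: diagonal cells use
#' the model's own held-out test folds (standard cross-validation, never
#' its training data); off-diagonal cells train on route A's training folds
#' and test on route B's test folds, pooling counts across folds. The
#' resulting grid shows how well allergenicity learned from one exposure
#' route transfers to the others.
#'
#' @param route_sets Named list of [labeled_dataset()]s with entries
#'   `food`, `inhalant`, `toxin` and optionally `total` (built as their
#'   union when absent; ids must then be globally unique).
#' @param k,L,distance,scale,threshold Model and decision settings.
#' @param n_folds,seed Fold settings (same seed drives every dataset's
#'   folds).
#' @return A `cross_compare_grid`: matrix-indexed list of
#'   `metrics_report`s plus a long-format data.frame `table`.
#' @export
cross_compare <- function(route_sets, k = 3L, L = 5L,
                          distance = c("euclidean", "manhattan"),
                          scale = FALSE, threshold = 0.5,
                          n_folds = 5L, seed = 1L) {
  distance <- match.arg(distance)
  need <- c("food", "inhalant", "toxin")
  if (!all(need %in% names(route_sets))) {
    stop("route_sets must contain 'food', 'inhalant' and 'toxin'",
         call. = FALSE)
  }
  if (is.null(route_sets$total)) {
    tot <- do.call(rbind, lapply(route_sets[need], as.data.frame))
    route_sets$total <- labeled_dataset(tot$id, tot$sequence, tot$label,
                                        tot$routes, tot$species,
                                        provenance = "union of route sets")
  }
  groups <- c(need, "total")
  route_sets <- lapply(route_sets[groups], function(d) {
    dataset_subset(d, d$valid)
  })
  feats <- lapply(route_sets, acc_features, L = L)
  folds <- lapply(route_sets, split_folds, n_folds = n_folds, seed = seed)
  assign <- lapply(folds, attr, "assignment")

  grid <- matrix(list(), length(groups), length(groups),
                 dimnames = list(model = groups, test = groups))
  for (m in groups) {
    for (t in groups) {
      lab <- character(0L)
      sco <- numeric(0L)
      for (f in seq_len(n_folds)) {
        tr <- assign[[m]] != f
        fit <- allerknn(feats[[m]][tr, , drop = FALSE],
                        labels = route_sets[[m]]$label[tr],
                        routes = route_sets[[m]]$routes[tr],
                        ids = route_sets[[m]]$id[tr],
                        k = k, L = L, distance = distance, scale = scale)
        te <- assign[[t]] == f
        p <- predict(fit, feats[[t]][te, , drop = FALSE],
                     threshold = threshold)
        lab <- c(lab, route_sets[[t]]$label[te])
        sco <- c(sco, p$score)
      }
      grid[[m, t]] <- compute_metrics(lab, sco, threshold)
    }
  }
  table <- do.call(rbind, lapply(groups, function(m) {
    do.call(rbind, lapply(groups, function(t) {
      cbind(model = m, test = t, as.data.frame(grid[[m, t]]))
    }))
  }))
  rownames(table) <- NULL
  structure(list(grid = grid, table = table,
                 settings = list(k = k, n_folds = n_folds, seed = seed)),
            class = "cross_compare_grid")
}

#' @export
print.cross_compare_grid <- function(x, ...) {
  cat("Cross-comparative analysis (rows: model, columns: test set)\n")
  groups <- rownames(x$grid)
  for (metric in c("sensitivity", "specificity")) {
    cat(sprintf("\n%s:\n", metric))
    m <- sapply(groups, function(t) {
      sapply(groups, function(g) x$grid[[g, t]][[metric]])
    })
    print(round(m, 4))
  }
  invisible(x)
}

#' Write a cross-comparison grid as TSV
#'
#' @param x A `cross_compare_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
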