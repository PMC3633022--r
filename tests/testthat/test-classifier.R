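fit_toy <- function(n = 100L, seed = 1L, ...) {
  ds <- generate_synthetic(synthetic_spec(
    n_per_class = n %/% 2L, length_range = c(30L, 80L), seed = seed))
  list(ds = ds, fit = allerknn(ds, ...))
}

test_that("fitting validates class balance, k parity and k range", {
  toy <- fit_toy(20L)
  ds <- toy$ds
  single <- dataset_subset(ds, ds$label == "allergen")
  expect_error(allerknn(single, k = 1L), "both classes")
  expect_error(allerknn(ds, k = 2L), "odd")
  expect_error(allerknn(ds, k = 21L), "exceeds")
  # minimal two-instance model is valid
  two <- dataset_subset(ds, c(1L, nrow(ds)))
  expect_s3_class(allerknn(two, k = 1L), "allerknn")
})

test_that("zero-variance features are excluded from scaling with a warning", {
  set.seed(2)
  X <- cbind(matrix(rnorm(40 * 44), 40), A = rep(1, 40))
  colnames(X) <- acc_layout(5L)
  labels <- rep(c("allergen", "non-allergen"), each = 20)
  expect_warning(fit <- allerknn(X, labels = labels, scale = TRUE),
                 "zero-variance")
  expect_identical(ncol(fit$x), 44L)
  expect_silent(p <- predict(fit, X[1:3, , drop = FALSE]))
  expect_length(p$score, 3L)
})

test_that("each training vector finds itself first at distance zero", {
  toy <- fit_toy(60L, seed = 5L)
  X <- acc_features(toy$ds)
  p <- predict(toy$fit, X)
  nb <- attr(p, "neighbours")
  for (i in seq_len(nrow(X))) {
    expect_identical(nb[[i]]$id[1L], toy$ds$id[i])
    expect_identical(nb[[i]]$distance[1L], 0)
  }
})

test_that("scores are allergen-neighbour fractions quantised to 1/k", {
  for (k in c(1L, 3L, 5L)) {
    toy <- fit_toy(40L, seed = k, k = k)
    set.seed(k)
    p <- predict(toy$fit, vapply(1:10, function(i) rand_seq(50), ""))
    expect_true(all(p$score %in% ((0:k) / k)))
    expect_true(all(vapply(attr(p, "neighbours"), nrow, 0L) == k))
    expect_true(all(vapply(attr(p, "neighbours"), function(nb) {
      !is.unsorted(nb$distance)
    }, TRUE)))
  }
})

test_that("the verdict follows the threshold rule on the score", {
  # 2 allergen + 1 non-allergen neighbours: score 2/3 >= 0.5 -> allergen
  X <- rbind(diag(3) * 0.01, c(10, 10, 10))
  X <- cbind(X, matrix(0, 4, 42))
  colnames(X) <- acc_layout(5L)
  labels <- c("allergen", "allergen", "non-allergen", "non-allergen")
  fit <- allerknn(X, labels = labels,
                  routes = c("food", "food", "", ""), k = 3L)
  q <- matrix(0, 1, 45, dimnames = list("q", acc_layout(5L)))
  p <- predict(fit, q)
  expect_equal(p$score, 2 / 3)
  expect_identical(p$verdict, "Probable Allergen")
  expect_identical(p$route, "food")
  # raising the threshold flips the verdict; route then stays unassigned
  p2 <- predict(fit, q, threshold = 0.9)
  expect_identical(p2$verdict, "Probable Non-allergen")
  expect_true(is.na(p2$route))
})

test_that("an exact training-allergen query is a distance-zero allergen", {
  toy <- fit_toy(30L, seed = 9L, k = 1L)
  al_idx <- which(toy$ds$label == "allergen")[1L]
  p <- predict(toy$fit, toy$ds$sequence[al_idx])
  expect_identical(p$verdict, "Probable Allergen")
  expect_equal(p$score, 1)
  expect_identical(attr(p, "neighbours")[[1L]]$distance[1L], 0)
})

test_that("predictions match the exhaustive-distance oracle", {
  set.seed(31)
  for (metric in c("euclidean", "manhattan")) {
    toy <- fit_toy(100L, seed = 17L, k = 3L, distance = metric)
    X <- acc_features(toy$ds)
    queries <- vapply(1:10, function(i) rand_seq(sample(30:80, 1)), "")
    p <- predict(toy$fit, queries)
    Q <- acc_features(queries)
    for (i in seq_along(queries)) {
      want <- knn_oracle(X, toy$ds$label, Q[i, ], k = 3L, metric = metric)
      expect_identical(p$verdict[i], want$verdict)
      expect_equal(p$score[i], want$score)
      expect_equal(attr(p, "neighbours")[[i]]$distance, want$dist)
    }
  }
})

test_that("distance ties break by training insertion order, deterministically", {
  X <- matrix(0, 4, 45, dimnames = list(NULL, acc_layout(5L)))
  X[4, ] <- 5  # rows 1-3 are identical, all at equal distance from queries
  fit <- allerknn(X, labels = c("allergen", "non-allergen", "allergen",
                                "non-allergen"),
                  ids = paste0("t", 1:4), k = 3L)
  q <- matrix(1, 1, 45, dimnames = list("q", acc_layout(5L)))
  p1 <- predict(fit, q)
  expect_identical(attr(p1, "neighbours")[[1L]]$id, c("t1", "t2", "t3"))
  expect_identical(p1, predict(fit, q))  # identical reruns, neighbour order included
})

test_that("route assignment counts tags and breaks ties as documented", {
  nb <- function(labels, routes, d = seq_along(labels)) {
    data.frame(id = paste0("n", seq_along(labels)), distance = d,
               label = labels, routes = routes, stringsAsFactors = FALSE)
  }
  # unanimity
  expect_identical(assign_route(nb(c("allergen", "allergen", "non-allergen"),
                                   c("food", "food", ""))), "food")
  # multi-route neighbours contribute one count per tag: toxin 2 vs 1 vs 1
  expect_identical(assign_route(nb(rep("allergen", 3),
                                   c("food", "inhalant,toxin", "toxin"))),
                   "toxin")
  # tie food=1 inhalant=1, nearest allergen carries inhalant
  expect_identical(assign_route(nb(c("non-allergen", "allergen", "allergen"),
                                   c("", "inhalant", "food"))), "inhalant")
  # full tie on one multi-route nearest neighbour: fixed order food < inhalant
  expect_identical(assign_route(nb("allergen", "inhalant,food")), "food")
  # no allergen neighbour: NA with a warning
  expect_warning(r <- assign_route(nb(rep("non-allergen", 3),
                                      rep("", 3))), "no allergen")
  expect_true(is.na(r))
})

test_that("models round-trip through the versioned flat file", {
  toy <- fit_toy(30L, seed = 23L, scale = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_knn_model(toy$fit, path)
  back <- read_knn_model(path)
  expect_equal(back$x, toy$fit$x)
  expect_identical(back$labels, toy$fit$labels)
  expect_identical(back$routes, toy$fit$routes)
  expect_identical(back$k, toy$fit$k)
  expect_equal(back$scaling$center, unname(toy$fit$scaling$center))
  # identical refit + rewrite is byte-identical
  path2 <- withr::local_tempfile(fileext = ".json")
  toy2 <- fit_toy(30L, seed = 23L, scale = TRUE)
  write_knn_model(toy2$fit, path2)
  expect_identical(readLines(path), readLines(path2))
  # loaded model predicts identically
  set.seed(1); q <- rand_seq(40)
  expect_identical(predict(back, q)$score, predict(toy$fit, q)$score)
})

test_that("corrupt or foreign model files fail with clear errors", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines("not json {", p)
  expect_error(read_knn_model(p), "cannot parse")
  jsonlite::write_json(list(format = "other"), p, auto_unbox = TRUE)
  expect_error(read_knn_model(p), "not an allerknn-model")
  toy <- fit_toy(10L)
  write_knn_model(toy$fit, p)
  obj <- jsonlite::read_json(p)
  obj$layout <- "acc-z9-L5/other"
  jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
  expect_error(read_knn_model(p), "layout mismatch")
})

test_that("baseline harness evaluates the requested methods", {
  ds <- generate_synthetic(synthetic_spec(n_per_class = 60L,
                                          length_range = c(40L, 100L),
                                          seed = 29L))
  folds <- split_folds(ds, n_folds = 5L, seed = 2L)
  tr <- folds[[1L]]$train
  te <- folds[[1L]]$test
  expect_error(run_baselines(tr, te, methods = "svm"), "unknown method")
  expect_error(run_baselines(tr, tr), "disjoint")
  reports <- run_baselines(tr, te, methods = c("knn", "nb"))
  expect_named(reports, c("knn", "nb"))
  expect_s3_class(reports$knn, "metrics_report")
  all4 <- run_baselines(tr, te)
  expect_named(all4, c("knn", "nb", "lr", "dt"))
  expect_true(all(vapply(all4, function(r) r$auc >= 0 && r$auc <= 1, TRUE)))
})

test_that("a linearly separable set is classified perfectly", {
  set.seed(37)
  X <- rbind(matrix(rnorm(50 * 45, mean = 8), 50),
             matrix(rnorm(50 * 45, mean = -8), 50))
  colnames(X) <- acc_layout(5L)
  labels <- rep(c("allergen", "non-allergen"), each = 50)
  ids <- sprintf("s%03d", 1:100)
  tr <- seq(1, 100, by = 2)
  # bypass sequences: score the matrices directly through the knn fit
  fit <- allerknn(X[tr, ], labels = labels[tr], ids = ids[tr], k = 3L)
  p <- predict(fit, X[-tr, ])
  m <- compute_metrics(labels[-tr], p$score)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
})
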