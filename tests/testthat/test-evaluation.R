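test_that("confusion-count metrics follow their defining formulas", {
  # 94 of 100 allergens and 94 of 100 non-allergens correct
  labels <- rep(c("allergen", "non-allergen"), each = 100)
  scores <- c(rep(1, 94), rep(0, 6), rep(0, 94), rep(1, 6))
  m <- compute_metrics(labels, scores)
  expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(94L, 6L, 94L, 6L))
  expect_equal(m$sensitivity, 0.94)
  expect_equal(m$specificity, 0.94)
  expect_equal(m$ppv, 0.94)
  expect_equal(m$f1, 0.94)
  expect_identical(m$n_evaluated, 200L)
  expect_identical(m$tp + m$tn + m$fp + m$fn, m$n_evaluated)
  # asymmetric counts: specificity is TN/(TN+FP), not the FP rate
  m2 <- compute_metrics(c(rep("allergen", 10), rep("non-allergen", 40)),
                        c(rep(1, 10), rep(1, 30), rep(0, 10)))
  expect_equal(m2$specificity, 10 / 40)
  expect_equal(m2$f1, 2 * 1 * 0.25 / 1.25)
})

test_that("single-class inputs yield NA metrics with a warning, never 0", {
  expect_warning(
    expect_warning(m <- compute_metrics(rep("allergen", 5),
                                        c(1, 1, 0, 1, 0)),
                   "specificity undefined"),
    "AUC undefined")
  expect_true(is.na(m$specificity))
  expect_equal(m$sensitivity, 0.6)
  expect_true(is.na(m$auc))
})

test_that("AUC is the Mann-Whitney statistic with half-credit ties", {
  labels <- rep(c("allergen", "non-allergen"), each = 5)
  expect_equal(compute_metrics(labels, c(rep(1, 5), rep(0, 5)))$auc, 1)
  expect_equal(compute_metrics(labels, c(rep(0, 5), rep(1, 5)))$auc, 0)
  expect_equal(compute_metrics(labels, rep(0.5, 10))$auc, 0.5)
  # randomised cases with heavy ties (coarse 1/k-style scores)
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    lab <- sample(c("allergen", "non-allergen"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    sc <- sample(seq(0, 1, by = 1 / 3), n, replace = TRUE)
    m <- compute_metrics(lab, sc)
    expect_equal(m$auc, auc_oracle(sc, lab == "allergen"))
  }
  # cross-check against an established implementation on one fixed case
  set.seed(43)
  lab <- sample(c("allergen", "non-allergen"), 40, replace = TRUE)
  sc <- sample(seq(0, 1, 0.25), 40, replace = TRUE)
  expect_equal(compute_metrics(lab, sc)$auc,
               as.numeric(pROC::auc(pROC::roc(
                 response = lab, predictor = sc, levels = c("non-allergen",
                                                            "allergen"),
                 direction = "<", quiet = TRUE))))
})

test_that("raising the threshold trades sensitivity for specificity monotonely", {
  set.seed(47)
  lab <- sample(c("allergen", "non-allergen"), 60, replace = TRUE,
                prob = c(0.5, 0.5))
  sc <- ifelse(lab == "allergen", rbeta(60, 3, 1.5), rbeta(60, 1.5, 3))
  ths <- seq(0, 1, by = 0.1)
  # ppv is legitimately undefined once the threshold exceeds every score
  ms <- lapply(ths, function(t) {
    suppressWarnings(compute_metrics(lab, sc, threshold = t))
  })
  sens <- vapply(ms, `[[`, 0, "sensitivity")
  spec <- vapply(ms, `[[`, 0, "specificity")
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("cross-validation pools fold counts without leakage", {
  ds <- generate_synthetic(synthetic_spec(n_per_class = 50L,
                                          length_range = c(40L, 90L),
                                          seed = 53L))
  cv <- cross_validate(ds, k = 3L, seed = 4L)
  expect_length(cv$folds, 5L)
  expect_identical(cv$pooled$n_evaluated, 100L)
  expect_identical(cv$pooled$tp, sum(vapply(cv$folds, `[[`, 0L, "tp")))
  expect_identical(cv$pooled$fp, sum(vapply(cv$folds, `[[`, 0L, "fp")))
  expect_identical(nrow(cv$predictions), 100L)
  expect_setequal(cv$predictions$id, ds$id)
  # same seed reproduces every fold report exactly
  cv2 <- cross_validate(ds, k = 3L, seed = 4L)
  expect_identical(cv$predictions, cv2$predictions)
  expect_equal(cv$folds, cv2$folds)
  # scaling variant fits parameters per training fold and still evaluates
  cv3 <- cross_validate(ds, k = 3L, seed = 4L, scale = TRUE)
  expect_identical(cv3$pooled$n_evaluated, 100L)
})

test_that("a separable feature geometry scores perfectly under CV", {
  set.seed(59)
  hydro <- biased_freqs(c("I", "L", "V", "F"), factor = 12)
  polar <- biased_freqs(c("D", "E", "K", "R"), factor = 12)
  ds <- generate_synthetic(synthetic_spec(
    n_per_class = 40L, length_range = c(80L, 120L),
    allergen_freqs = hydro, background_freqs = polar, seed = 61L))
  cv <- cross_validate(ds, k = 3L, seed = 6L)
  expect_equal(cv$pooled$sensitivity, 1)
  expect_equal(cv$pooled$specificity, 1)
  expect_equal(cv$pooled$auc, 1)
})

test_that("the k scan holds folds fixed and reports one row per k", {
  ds <- generate_synthetic(synthetic_spec(n_per_class = 40L,
                                          length_range = c(40L, 80L),
                                          seed = 67L))
  expect_error(k_scan(ds, ks = c(2L, 3L)), "odd")
  sc <- k_scan(ds, ks = c(1L, 3L, 5L, 7L, 9L), seed = 8L)
  expect_identical(sc$table$k, c(1L, 3L, 5L, 7L, 9L))
  expect_identical(nrow(sc$table), 5L)
  expect_true(all(is.finite(as.matrix(
    sc$table[, c("sensitivity", "specificity", "ppv", "f1", "auc")]))))
  # identical folds across k: each CV fold has the same test memberships
  base_ids <- lapply(1:5, function(f) {
    sort(sc$results[["1"]]$predictions$id[
      sc$results[["1"]]$predictions$fold == f])
  })
  for (kk in c("3", "5", "7", "9")) {
    ids_k <- lapply(1:5, function(f) {
      sort(sc$results[[kk]]$predictions$id[
        sc$results[[kk]]$predictions$fold == f])
    })
    expect_identical(ids_k, base_ids)
  }
  # single-k scan equals a direct cross-validation at that k
  one <- k_scan(ds, ks = 3L, seed = 8L)
  direct <- cross_validate(ds, k = 3L, seed = 8L)
  expect_equal(one$results[["3"]]$pooled, direct$pooled)
})

test_that("cross-comparison grid covers all model x test combinations", {
  sets <- synthetic_route_sets(n_per_class = 40L, seed = 71L,
                               length_range = c(40L, 80L))
  g <- cross_compare(sets, n_folds = 3L, seed = 10L)
  expect_identical(dim(g$grid), c(4L, 4L))
  expect_identical(rownames(g$grid), c("food", "inhalant", "toxin", "total"))
  expect_identical(nrow(g$table), 16L)
  # diagonal entries evaluate every instance of their own dataset once
  for (r in c("food", "inhalant", "toxin")) {
    expect_identical(g$grid[[r, r]]$n_evaluated, nrow(sets[[r]]))
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grid_tsv(g, path)
  expect_identical(nrow(read.delim(path)), 16L)
})

test_that("identically distributed route sets transfer without loss", {
  # all four sets drawn from one distribution: off-diagonal sensitivity
  # tracks the diagonal (exchangeability)
  one <- function(seed, route) {
    ds <- generate_synthetic(synthetic_spec(
      n_per_class = 60L, length_range = c(50L, 100L),
      route_mix = setNames(as.numeric(c("food", "inhalant",
                                        "toxin") == route),
                           c("food", "inhalant", "toxin")),
      p_multiroute = 0, seed = seed))
    ds$id <- paste(route, ds$id, sep = "_")
    labeled_dataset(ds$id, ds$sequence, ds$label, ds$routes, ds$species)
  }
  sets <- list(food = one(81L, "food"), inhalant = one(82L, "inhalant"),
               toxin = one(83L, "toxin"))
  g <- cross_compare(sets, n_folds = 3L, seed = 12L)
  for (m in c("food", "inhalant", "toxin")) {
    diag_sens <- g$grid[[m, m]]$sensitivity
    for (t in setdiff(c("food", "inhalant", "toxin"), m)) {
      expect_lt(abs(g$grid[[m, t]]$sensitivity - diag_sens), 0.1)
    }
  }
})
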