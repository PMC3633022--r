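#' Compare the nearest-neighbour model with standard baselines
#'
#' Trains the requested classifiers on the ACC feature vectors of a
#' training set and scores them on a disjoint test set with
#' [compute_metrics()]. `knn` is this package's own classifier; the
#' baselines delegate to standard implementations: naive Bayes
#' (`e1071::naiveBayes`), logistic regression (`stats::glm`, binomial) and
#' a decision tree (`rpart::rpart`). Each method yields an allergen score
#' in `[0, 1]` (neighbour fraction or class probability), so all are
#' evaluated identically, AUC included.
#'
#' @param training,test [labeled_dataset()]s, disjoint by id.
#' @param methods Subset of `"knn"`, `"nb"`, `"lr"`, `"dt"`.
#' @param k,L,distance,scale Settings for the `knn` entry.
#' @param threshold Decision threshold.
#' @return Named list of `metrics_report`, one per requested method.
#' @export
run_baselines <- function(training, test,
                          methods = c("knn", "nb", "lr", "dt"),
                          k = 3L, L = 5L, distance = "euclidean",
                          scale = FALSE, threshold = 0.5) {
  known <- c("knn", "nb", "lr", "dt")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    stop(sprintf("unknown method id(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (length(intersect(training$id, test$id))) {
    stop("training and test sets must be disjoint by id", call. = FALSE)
  }
  training <- dataset_subset(training, training$valid)
  test <- dataset_subset(test, test$valid)
  Xtr <- acc_features(training, L = L)
  Xte <- acc_features(test, L = L)
  ytr <- factor(training$label, levels = c("non-allergen", "allergen"))

  score_of <- list(
    knn = function() {
      fit <- allerknn(Xtr, labels = training$label, routes = training$routes,
                      ids = training$id, k = k, L = L, distance = distance,
                      scale = scale)
      predict(fit, Xte, threshold = threshold)$score
    },
    nb = function() {
      fit <- e1071::naiveBayes(x = Xtr, y = ytr)
      unname(stats::predict(fit, Xte, type = "raw")[, "allergen"])
    },
    lr = function() {
      df_tr <- data.frame(y = as.integer(ytr == "allergen"), Xtr)
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = df_tr, family = stats::binomial()))
      unname(suppressWarnings(
        stats::predict(fit, data.frame(Xte), type = "response")))
    },
    dt = function() {
      df_tr <- data.frame(y = ytr, Xtr)
      fit <- rpart::rpart(y ~ ., data = df_tr, method = "class")
      unname(stats::predict(fit, data.frame(Xte))[, "allergen"])
    }
  )
  reports <- lapply(methods, function(m) {
    compute_metrics(test$label, pmin(pmax(score_of[[m]](), 0), 1), threshold)
  })
  names(reports) <- methods
  reports
}
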