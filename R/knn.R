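#' Fit a k-nearest-neighbour allergen classifier on ACC features
#'
#' The core model: training sequences are encoded with the three Hellberg
#' z-descriptors, transformed into 45-component ACC vectors (at the default
#' lag count L = 5), and stored together with their class labels and route
#' tags. A query is classified by the majority label of its k nearest
#' training vectors (default k = 3) under the chosen distance. The model is
#' memory-based: "fitting" consists of featurising and (optionally)
#' standardising the training set.
#'
#' `k` must be odd so that two-class voting at the default threshold 0.5
#' always yields a strict majority. Feature standardisation is off by
#' default (distances are computed on raw ACC values); when `scale = TRUE`
#' a z-score standardisation is fitted on the training data only, and
#' zero-variance features are excluded with a warning.
#'
#' @param data A [labeled_dataset()], or a numeric feature matrix with
#'   9 * L columns (then `labels` is required).
#' @param labels,routes,ids Per-row class labels, comma-separated route
#'   tags and identifiers; ignored when `data` is a `labeled_dataset`.
#' @param k Neighbour count; odd, >= 1, <= number of training instances.
#' @param L Maximum ACC lag.
#' @param distance `"euclidean"` or `"manhattan"`.
#' @param scale Standardise features to training mean 0 / sd 1?
#' @param mode Residue-validation mode for featurisation.
#' @return An object of class `allerknn` with `print`, `summary`,
#'   `predict` and `plot` methods.
#' @examples
#' ds <- generate_synthetic(synthetic_spec(n_per_class = 30, seed = 7))
#' fit <- allerknn(ds, k = 3)
#' predict(fit, ds$sequence[1])
#' @export
allerknn <- function(data, labels = NULL, routes = NULL, ids = NULL,
                     k = 3L, L = 5L,
                     distance = c("euclidean", "manhattan"),
                     scale = FALSE, mode = c("strict", "permissive")) {
  distance <- match.arg(distance)
  mode <- match.arg(mode)
  k <- stopifnot_count(k, "k")
  L <- stopifnot_count(L, "L")

  if (inherits(data, "labeled_dataset")) {
    if (any(!data$valid)) {
      warning(sprintf("excluding %d record(s) flagged invalid",
                      sum(!data$valid)), call. = FALSE)
      data <- dataset_subset(data, data$valid)
    }
    X <- acc_features(data, L = L, mode = mode)
    labels <- data$label
    routes <- data$routes
    ids <- data$id
  } else if (is.matrix(data)) {
    X <- data
    if (is.null(labels)) stop("'labels' required with a feature matrix",
                              call. = FALSE)
    ids <- ids %||% rownames(X) %||% sprintf("train_%04d", seq_len(nrow(X)))
    routes <- routes %||% rep("", nrow(X))
  } else {
    stop("'data' must be a labeled_dataset or a feature matrix",
         call. = FALSE)
  }
  if (ncol(X) != 9L * L) {
    stop(sprintf("feature matrix must have %d columns (9 x L)", 9L * L),
         call. = FALSE)
  }
  if (nrow(X) == 0L) stop("empty training set", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (k %% 2L == 0L) {
    stop("'k' must be odd (strict majority in two-class voting)",
         call. = FALSE)
  }
  if (k > nrow(X)) stop("'k' exceeds the number of training instances",
                        call. = FALSE)

  scaling <- NULL
  if (isTRUE(scale)) {
    ctr <- colMeans(X)
    sds <- apply(X, 2L, stats::sd)
    keep <- sds > 0
    if (!all(keep)) {
      warning(sprintf("excluding %d zero-variance feature(s) from scaling: %s",
                      sum(!keep), paste(colnames(X)[!keep], collapse = ", ")),
              call. = FALSE)
    }
    scaling <- list(center = ctr[keep], sd = sds[keep], keep = unname(keep))
    X <- sweep(sweep(X[, keep, drop = FALSE], 2L, ctr[keep]), 2L,
               sds[keep], "/")
  }

  structure(list(x = X, labels = labels, routes = routes, ids = ids,
                 k = k, L = L, distance = distance, scaling = scaling,
                 mode = mode, layout = acc_layout_id(L)),
            class = "allerknn")
}

# versioned feature-layout identifier, validated on model load
acc_layout_id <- function(L) sprintf("acc-z3-L%d/pairmajor-v1", L)

#' Predict allergenicity for query sequences
#'
#' For each query the k nearest training vectors are found (distance ties
#' broken by training-set insertion order, so predictions are fully
#' deterministic). The score is the fraction of those neighbours labelled
#' allergen — a multiple of 1/k in `[0, 1]` — and the verdict is
#' `"Probable Allergen"` when the score reaches `threshold` (default 0.5,
#' i.e. simple majority at k = 3), else `"Probable Non-allergen"`. For
#' predicted allergens the most probable route of exposure is assigned
#' from the route tags of the allergen neighbours (see [assign_route()]).
#'
#' @param object An [allerknn()] model.
#' @param newdata Character vector of sequences, a [labeled_dataset()], or
#'   a feature matrix matching the model's layout.
#' @param threshold Decision threshold on the allergen-neighbour fraction.
#' @param ... Unused.
#' @return An `allerknn_prediction` data.frame with columns `id`,
#'   `verdict`, `score`, `route`; per-query neighbour tables (id, distance,
#'   label, routes, sorted by non-decreasing distance) are in
#'   `attr(, "neighbours")`.
#' @export
predict.allerknn <- function(object, newdata, threshold = 0.5, ...) {
  if (nrow(object$x) == 0L) stop("model has no training instances",
                                 call. = FALSE)
  if (threshold < 0 || threshold > 1) {
    stop("'threshold' must be in [0, 1]", call. = FALSE)
  }
  if (inherits(newdata, "labeled_dataset")) {
    Q <- acc_features(newdata, L = object$L, mode = object$mode)
  } else if (is.character(newdata)) {
    Q <- acc_features(newdata, L = object$L, mode = object$mode)
    rownames(Q) <- names(newdata) %||% sprintf("query_%d",
                                               seq_len(nrow(Q)))
  } else if (is.matrix(newdata)) {
    if (ncol(newdata) != 9L * object$L) {
      stop(sprintf("query matrix must have %d columns", 9L * object$L),
           call. = FALSE)
    }
    Q <- newdata
    if (is.null(rownames(Q))) {
      rownames(Q) <- sprintf("query_%d", seq_len(nrow(Q)))
    }
  } else {
    stop("'newdata' must be sequences, a labeled_dataset or a feature matrix",
         call. = FALSE)
  }
  if (!is.null(object$scaling)) {
    s <- object$scaling
    Q <- sweep(sweep(Q[, s$keep, drop = FALSE], 2L, s$center), 2L, s$sd, "/")
  }

  k <- object$k
  nb <- vector("list", nrow(Q))
  score <- numeric(nrow(Q))
  for (i in seq_len(nrow(Q))) {
    d <- row_distances(object$x, Q[i, ], object$distance)
    ord <- order(d, seq_along(d))[seq_len(k)]
    nb[[i]] <- data.frame(id = object$ids[ord], distance = d[ord],
                          label = object$labels[ord],
                          routes = object$routes[ord],
                          stringsAsFactors = FALSE)
    score[i] <- sum(object$labels[ord] == "allergen") / k
  }
  verdict <- ifelse(score >= threshold, "Probable Allergen",
                    "Probable Non-allergen")
  route <- rep(NA_character_, nrow(Q))
  # route assignment only makes sense when the training set is annotated
  if (any(nzchar(object$routes[object$labels == "allergen"]))) {
    for (i in which(verdict == "Probable Allergen")) {
      route[i] <- assign_route(nb[[i]])
    }
  }
  out <- data.frame(id = rownames(Q), verdict = verdict, score = score,
                    route = route, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "neighbours") <- setNames(nb, rownames(Q))
  attr(out, "threshold") <- threshold
  attr(out, "k") <- k
  class(out) <- c("allerknn_prediction", "data.frame")
  out
}

# distances from every row of X to vector q
row_distances <- function(X, q, distance) {
  D <- sweep(X, 2L, q)
  if (distance == "euclidean") sqrt(rowSums(D * D)) else rowSums(abs(D))
}

#' Assign the most probable route of exposure
#'
#' Given the neighbour table of a query predicted to be an allergen, counts
#' the route tags of the allergen-labelled neighbours (a multi-route
#' neighbour contributes one count per tag) and returns the route with the
#' highest count. Ties are broken by the route of the nearest allergen
#' neighbour carrying a tied route, then by the fixed order food <
#' inhalant < toxin. Returns `NA` with a warning when no allergen
#' neighbour is present (possible when a threshold below 0.5 admits
#' allergen verdicts without allergen neighbours).
#'
#' @param neighbours data.frame with columns `label` and `routes`
#'   (comma-separated tags), ordered by non-decreasing distance.
#' @return One of `"food"`, `"inhalant"`, `"toxin"`, or `NA`.
#' @export
assign_route <- function(neighbours) {
  al <- neighbours[neighbours$label == "allergen", , drop = FALSE]
  if (nrow(al) == 0L) {
    warning("no allergen neighbour: route of exposure undefined",
            call. = FALSE)
    return(NA_character_)
  }
  tag_list <- strsplit(al$routes, ",", fixed = TRUE)
  tags <- unlist(tag_list)
  tags <- tags[nzchar(tags)]
  if (!length(tags)) {
    warning("allergen neighbours carry no route tags", call. = FALSE)
    return(NA_character_)
  }
  counts <- vapply(ROUTES, function(r) sum(tags == r), 0L)
  tied <- ROUTES[counts == max(counts)]
  if (length(tied) == 1L) return(tied)
  for (i in seq_len(nrow(al))) {      # nearest allergen neighbour first
    hit <- intersect(ROUTES, intersect(tag_list[[i]], tied))
    if (length(hit)) return(hit[1L])  # ROUTES order = food < inhalant < toxin
  }
  tied[1L]
}

#' @export
print.allerknn <- function(x, ...) {
  cat("k-nearest-neighbour allergen classifier on ACC z-descriptor features\n")
  cat(sprintf("  training instances: %d (%d allergen / %d non-allergen)\n",
              nrow(x$x), sum(x$labels == "allergen"),
              sum(x$labels == "non-allergen")))
  cat(sprintf("  k = %d, distance = %s, features = %d (%s)%s\n",
              x$k, x$distance, ncol(x$x), x$layout,
              if (is.null(x$scaling)) "" else ", standardised"))
  invisible(x)
}

#' @export
summary.allerknn <- function(object, ...) {
  rc <- vapply(ROUTES, function(r) {
    sum(grepl(r, object$routes[object$labels == "allergen"], fixed = TRUE))
  }, 0L)
  structure(list(n = nrow(object$x),
                 n_allergen = sum(object$labels == "allergen"),
                 n_non_allergen = sum(object$labels == "non-allergen"),
                 route_counts = rc, k = object$k,
                 distance = object$distance,
                 scaled = !is.null(object$scaling),
                 layout = object$layout),
            class = "summary.allerknn")
}

#' @export
print.summary.allerknn <- function(x, ...) {
  cat("allerknn model summary\n")
  cat(sprintf("  instances: %d (%d allergen, %d non-allergen)\n",
              x$n, x$n_allergen, x$n_non_allergen))
  cat("  allergen route tags:",
      paste(sprintf("%s=%d", names(x$route_counts), x$route_counts),
            collapse = " "), "\n")
  cat(sprintf("  k = %d, distance = %s, scaled = %s\n  layout = %s\n",
              x$k, x$distance, x$scaled, x$layout))
  invisible(x)
}

#' Plot the training feature space of a fitted model
#'
#' Projects the stored ACC vectors onto their first two principal
#' components and colours points by class — a quick visual check of the
#' class separation available to the nearest-neighbour rule.
#'
#' @param x An [allerknn()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.allerknn <- function(x, ...) {
  pc <- stats::prcomp(x$x, scale. = FALSE)
  is_al <- x$labels == "allergen"
  graphics::plot(pc$x[, 1:2], col = ifelse(is_al, "firebrick", "steelblue"),
                 pch = ifelse(is_al, 17, 1),
                 xlab = "PC1", ylab = "PC2",
                 main = "ACC feature space (training set)", ...)
  graphics::legend("topright", legend = c("allergen", "non-allergen"),
                   col = c("firebrick", "steelblue"), pch = c(17, 1),
                   bty = "n")
  invisible(x)
}

#' @export
print.allerknn_prediction <- function(x, ...) {
  nb <- attr(x, "neighbours")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s: %s (score %.3f%s)\n", x$id[i], x$verdict[i],
                x$score[i],
                if (!is.na(x$route[i])) {
                  sprintf(", route of exposure: %s", x$route[i])
                } else ""))
    tab <- nb[[i]]
    for (j in seq_len(nrow(tab))) {
      cat(sprintf("    %d. %s  d=%.4f  %s%s\n", j, tab$id[j],
                  tab$distance[j], tab$label[j],
                  if (nzchar(tab$routes[j])) paste0(" [", tab$routes[j], "]")
                  else ""))
    }
  }
  invisible(x)
}
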