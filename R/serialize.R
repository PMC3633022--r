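MODEL_FORMAT <- "allerknn-model"
MODEL_VERSION <- 1L

#' Save a fitted model to a versioned flat file
#'
#' Serialises an [allerknn()] model as JSON: format tag, version, feature
#' layout identifier, configuration, scaling parameters and the training
#' instances. Numeric values are written at full precision, so re-training
#' on identical data and saving again yields a byte-identical file.
#'
#' @param model An [allerknn()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_knn_model()]
#' @export
write_knn_model <- function(model, path) {
  stopifnot(inherits(model, "allerknn"))
  obj <- list(
    format = MODEL_FORMAT,
    version = MODEL_VERSION,
    layout = model$layout,
    k = model$k, L = model$L,
    distance = model$distance, mode = model$mode,
    scaling = if (is.null(model$scaling)) NULL else list(
      center = unname(model$scaling$center),
      sd = unname(model$scaling$sd),
      keep = model$scaling$keep),
    ids = model$ids, labels = model$labels, routes = model$routes,
    features = colnames(model$x),
    x = unname(apply(model$x, 1L, as.numeric, simplify = FALSE))
  )
  # I(17) = 17 significant digits: doubles survive the round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a model from a versioned flat file
#'
#' Validates the format tag, version and feature-layout identifier before
#' reconstructing the model; a corrupted or foreign file is a clear error.
#'
#' @param path File written by [write_knn_model()].
#' @return An [allerknn()] model.
#' @export
read_knn_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("cannot parse model file '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  if (!identical(obj$format, MODEL_FORMAT)) {
    stop(sprintf("'%s' is not an %s file", path, MODEL_FORMAT),
         call. = FALSE)
  }
  if (!identical(as.integer(obj$version), MODEL_VERSION)) {
    stop(sprintf("unsupported model version %s (expected %d)",
                 obj$version, MODEL_VERSION), call. = FALSE)
  }
  if (!identical(obj$layout, acc_layout_id(as.integer(obj$L)))) {
    stop(sprintf("feature layout mismatch: file has '%s'", obj$layout),
         call. = FALSE)
  }
  X <- if (is.matrix(obj$x)) obj$x else do.call(rbind, obj$x)
  dimnames(X) <- list(obj$ids, obj$features)
  scaling <- NULL
  if (!is.null(obj$scaling)) {
    scaling <- list(center = obj$scaling$center, sd = obj$scaling$sd,
                    keep = obj$scaling$keep)
  }
  structure(list(x = X, labels = obj$labels, routes = obj$routes,
                 ids = obj$ids, k = as.integer(obj$k),
                 L = as.integer(obj$L), distance = obj$distance,
                 scaling = scaling, mode = obj$mode, layout = obj$layout),
            class = "allerknn")
}
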