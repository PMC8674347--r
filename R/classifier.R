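#' Train the random-forest pixel classifier
#'
#' Fits a probability random forest ([ranger::ranger()]) on a preprocessed
#' training library: the features are the scaled intensities on the common
#' grid (478 at defaults), no derived features. Out-of-bag (OOB) class
#' predictions give the model's OOB error and confusion matrix; a pixel's
#' confidence at prediction time is the fraction of trees voting for the
#' winning class.
#'
#' @param lib a preprocessed [raman_library()] (see [preprocess_library()]).
#' @param n_trees number of trees (default 1500).
#' @param seed integer seed; training is reproducible given the seed
#'   (single-threaded growth).
#' @return An object of class `raman_classifier` with fields `forest`,
#'   `n_trees`, `classes`, `oob_error`, `confusion` (rows = truth, columns =
#'   OOB prediction; rows sum to per-class training counts), `wavenumbers`
#'   and `seed`.
#' @export
train_classifier <- function(lib, n_trees = 1500, seed = 1L) {
  stopifnot(inherits(lib, "raman_library"))
  if (length(lib$classes) < 2L) {
    stop("training requires at least 2 classes", call. = FALSE)
  }
  df <- as.data.frame(lib$intensities)
  names(df) <- paste0("wn", seq_len(ncol(df)))
  df$.class <- factor(lib$labels, levels = lib$classes)
  forest <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, probability = TRUE,
    seed = as.integer(seed), num.threads = 1L
  )
  oob_prob <- forest$predictions            # rows in training order
  oob_class <- lib$classes[max.col(oob_prob, ties.method = "first")]
  truth <- lib$labels
  confusion <- table(factor(truth, levels = lib$classes),
                     factor(oob_class, levels = lib$classes),
                     dnn = c("truth", "oob_prediction"))
  structure(
    list(forest = forest, n_trees = n_trees, classes = lib$classes,
         oob_error = mean(oob_class != truth),
         confusion = unclass(confusion),
         wavenumbers = lib$wavenumbers, seed = as.integer(seed)),
    class = "raman_classifier"
  )
}

#' @export
print.raman_classifier <- function(x, ...) {
  cat(sprintf("<raman_classifier> %d trees, %d classes, OOB error %.4f\n",
              x$n_trees, length(x$classes), x$oob_error))
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.raman_classifier <- function(object, ...) {
  print(object)
  cat("\nOOB confusion matrix (rows = truth):\n")
  print(object$confusion)
  conf <- report_confusion(object)
  cat("\nper-class OOB error:\n")
  print(round(conf$class_error, 4))
  invisible(conf)
}

#' OOB confusion matrix and per-class error fractions
#'
#' @param m a `raman_classifier`.
#' @return A list with `confusion` (counts; rows sum to per-class training
#'   counts) and `class_error` (fraction of each class's training spectra
#'   misassigned out-of-bag).
#' @export
report_confusion <- function(m) {
  stopifnot(inherits(m, "raman_classifier"))
  conf <- m$confusion
  n <- rowSums(conf)
  err <- ifelse(n > 0, (n - diag(conf)) / n, NA_real_)
  names(err) <- rownames(conf)
  list(confusion = conf, class_error = err)
}

#' Classify every pixel of a preprocessed map
#'
#' Each non-degenerate pixel is pushed through the forest; its class is the
#' majority vote and its confidence the winning vote fraction. Pixels below
#' the review threshold are flagged for operator review (they are still
#' counted downstream unless dropped explicitly). Degenerate pixels (missed
#' acquisitions; constant spectra) bypass the forest entirely: class NMP,
#' confidence 0, review TRUE.
#'
#' @param object a `raman_classifier`.
#' @param map a preprocessed [raman_map()] on the model's wavenumber grid.
#' @param review_threshold confidence below which a pixel is flagged
#'   (default 0.5).
#' @param ... unused.
#' @return A data.frame with one row per pixel: `x`, `y`, `class`,
#'   `confidence`, `review`, `degenerate`.
#' @export
predict.raman_classifier <- function(object, map, review_threshold = 0.5,
                                     ...) {
  stopifnot(inherits(map, "raman_map"))
  if (length(map$wavenumbers) != length(object$wavenumbers) ||
      any(abs(map$wavenumbers - object$wavenumbers) > 1e-9)) {
    stop("map wavenumber axis does not match the model's training grid; preprocess the map first",
         call. = FALSE)
  }
  n <- nrow(map$intensities)
  cls <- rep("NMP", n)
  conf <- numeric(n)
  live <- which(!map$degenerate)
  if (length(live) > 0L) {
    df <- as.data.frame(map$intensities[live, , drop = FALSE])
    names(df) <- paste0("wn", seq_len(ncol(df)))
    pr <- stats::predict(object$forest, data = df,
                         num.threads = 1L)$predictions
    idx <- max.col(pr, ties.method = "first")
    cls[live] <- object$classes[idx]
    conf[live] <- pr[cbind(seq_along(live), idx)]
  }
  data.frame(
    x = map$x, y = map$y, class = cls, confidence = conf,
    review = conf < review_threshold | map$degenerate,
    degenerate = map$degenerate,
    stringsAsFactors = FALSE
  )
}
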