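# Class levels in canonical order, restricted to classes actually present.
class_levels <- function(labels) {
  present <- unique(as.character(labels))
  c(intersect(TWEET_CLASSES, present), setdiff(present, TWEET_CLASSES))
}

#' Multinomial Naive Bayes
#'
#' A multinomial Naive Bayes classifier over non-negative count features with
#' add-one (Laplace) smoothing and log-priors from class frequencies.
#'
#' @param fm A `feature_matrix` of non-negative counts.
#' @param labels Class labels, one per row.
#' @param laplace Additive smoothing constant.
#' @return A fitted model of class `bd_nb`.
#' @export
train_nb <- function(fm, labels, laplace = 1) {
  m <- fm$m
  if (length(m@x) > 0 && min(m@x) < 0) {
    stop("multinomial NB requires non-negative count features", call. = FALSE)
  }
  labels <- factor(as.character(labels), levels = class_levels(labels))
  stopifnot(nrow(m) == length(labels))
  y <- Matrix::sparseMatrix(i = seq_len(nrow(m)), j = as.integer(labels),
                            x = 1, dims = c(nrow(m), nlevels(labels)))
  counts <- as.matrix(Matrix::crossprod(y, m))  # classes x features
  flp <- log(counts + laplace) -
    log(rowSums(counts) + laplace * ncol(counts))
  prior <- log(as.numeric(table(labels)) / length(labels))
  structure(list(kind = "nb", classes = levels(labels),
                 feature_log_prob = flp, class_log_prior = prior,
                 features = colnames(m), laplace = laplace,
                 n_train = nrow(m)),
            class = c("bd_nb", "bd_model"))
}

#' @export
predict.bd_nb <- function(object, fm, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  m <- if (inherits(fm, "feature_matrix")) fm$m else fm
  if (!identical(colnames(m), object$features)) {
    stop("feature columns do not match the fitted model", call. = FALSE)
  }
  scores <- as.matrix(m %*% t(object$feature_log_prob))
  scores <- sweep(scores, 2, object$class_log_prior, "+")
  colnames(scores) <- object$classes
  if (type == "class") {
    factor(object$classes[max.col(scores, ties.method = "first")],
           levels = object$classes)
  } else {
    softmax_rows(scores)
  }
}

softmax_rows <- function(scores) {
  z <- scores - apply(scores, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' RBF-kernel SVM with class weights
#'
#' A support vector machine with the radial basis function kernel, cost
#' `c = 100`, one-vs-one multiclass, and per-class weights (default:
#' inverse frequency, `N / (K * N_c)`) that upweight the minority classes.
#' Probability estimates, needed for precision-recall curves, come from
#' pairwise-coupled sigmoid calibration; the calibrated argmax may rarely
#' disagree with the decision-rule label. Feature vectors must be scaled
#' (see [scale_fit_transform()]); unscaled input is refused.
#'
#' @param fm A scaled `feature_matrix`.
#' @param labels Class labels, one per row.
#' @param cost SVM cost parameter.
#' @param class_weights `"inverse"`, or a named numeric vector of per-class
#'   weights.
#' @param gamma RBF kernel width; defaults to `1 / n_features`.
#' @return A fitted model of class `bd_svm`.
#' @export
train_svm <- function(fm, labels, cost = 100, class_weights = "inverse",
                      gamma = NULL) {
  if (is.null(fm$bounds)) {
    stop("SVM features must be scaled first (scale_fit_transform); ",
         "scaling bounds are missing", call. = FALSE)
  }
  labels <- factor(as.character(labels), levels = class_levels(labels))
  if (identical(class_weights, "inverse")) {
    tab <- table(labels)
    class_weights <- length(labels) / (nlevels(labels) * as.numeric(tab))
    names(class_weights) <- names(tab)
  }
  gamma <- gamma %||% (1 / ncol(fm$m))
  fit <- e1071::svm(x = fm$m, y = labels, kernel = "radial", cost = cost,
                    gamma = gamma, class.weights = class_weights,
                    probability = TRUE, scale = FALSE)
  structure(list(kind = "svm", classes = levels(labels), fit = fit,
                 cost = cost, gamma = gamma, class_weights = class_weights,
                 features = colnames(fm$m), n_train = nrow(fm$m)),
            class = c("bd_svm", "bd_model"))
}

#' @export
predict.bd_svm <- function(object, fm, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  m <- if (inherits(fm, "feature_matrix")) fm$m else fm
  if (!identical(colnames(m), object$features)) {
    stop("feature columns do not match the fitted model", call. = FALSE)
  }
  # class labels come from the one-vs-one decision rule; probabilities from
  # the pairwise-coupled calibration (their argmax may rarely disagree)
  pred <- predict(object$fit, m, probability = (type == "prob"))
  if (type == "class") {
    factor(as.character(pred), levels = object$classes)
  } else {
    pr <- attr(pred, "probabilities")
    pr[, object$classes, drop = FALSE]
  }
}

#' @exportS3Method generics::tidy
tidy.bd_nb <- function(x, ...) {
  tibble::tibble(
    class = rep(x$classes, each = length(x$features)),
    feature = rep(x$features, times = length(x$classes)),
    log_prob = as.numeric(t(x$feature_log_prob))
  )
}

#' @exportS3Method generics::glance
glance.bd_nb <- function(x, ...) {
  tibble::tibble(kind = "nb", n_train = x$n_train,
                 n_features = length(x$features),
                 n_classes = length(x$classes), laplace = x$laplace)
}

#' @exportS3Method generics::tidy
tidy.bd_svm <- function(x, ...) {
  nsv <- x$fit$nSV
  tibble::tibble(class = x$fit$levels[seq_along(nsv)], n_support = nsv,
                 weight = unname(x$class_weights[x$fit$levels[seq_along(nsv)]]))
}

#' @exportS3Method generics::glance
glance.bd_svm <- function(x, ...) {
  tibble::tibble(kind = "svm", n_train = x$n_train,
                 n_features = length(x$features),
                 n_classes = length(x$classes), cost = x$cost,
                 gamma = x$gamma, n_support_total = x$fit$tot.nSV)
}

#' Save and load fitted models
#'
#' Thin serialization wrappers. NB and SVM round-trips are bit-identical in
#' prediction; the LSTM is identical within floating tolerance.
#'
#' @param model A fitted model.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
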