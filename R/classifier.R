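#' Fit the logistic NS/AF classifier
#'
#' Fits a logistic regression of rhythm class (NS = 0, AF = 1) on the
#' covariate vectors of RR windows, then selects the probability threshold
#' tau on the training ROC curve as the point closest to the ideal corner
#' (0, 1) in (false-positive rate, sensitivity) space. Features are z-scored
#' with training statistics before fitting (an affine change of basis that
#' leaves the attainable decision boundaries untouched but stabilizes the
#' optimizer), and a tiny ridge penalty on the slopes keeps the maximum
#' likelihood problem well-posed under complete separation; set
#' `ridge = 0` for the pure MLE.
#'
#' @param x numeric matrix or data frame of covariates, one row per window.
#' @param labels class labels: 0/1, logical, or factor/character with
#'   levels NS/AF. Both classes must be present.
#' @param ridge L2 penalty on standardized slopes (not the intercept).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return An object of class `af_logit` with components `coefficients`
#'   (intercept + one slope per feature, on the standardized scale),
#'   `feature_names`, `center`, `scale`, `tau`, `roc` (training ROC curve),
#'   `ridge`, `n`, `converged`.
#' @seealso [predict.af_logit()], [cross_validate()], [roc_curve()]
#' @export
fit_af_classifier <- function(x, labels, ridge = 1e-6, max_iter = 100,
                              tol = 1e-10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- encode_labels(labels)
  if (nrow(x) != length(y)) stop("x and labels disagree in length")
  if (!all(is.finite(x))) stop("covariates must be finite")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1     # constant feature: harmless, slope stays 0
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  X <- cbind(`(Intercept)` = 1, z)
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X * w, X) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  probs <- stats::plogis(drop(X %*% beta))
  roc <- roc_curve(probs, y)
  model <- structure(list(coefficients = stats::setNames(beta, colnames(X)),
                          feature_names = colnames(x),
                          center = center, scale = scale,
                          tau = NA_real_, roc = roc, ridge = ridge,
                          n = nrow(x), converged = converged),
                     class = "af_logit")
  model$tau <- optimal_threshold(roc)
  model
}

encode_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    ok <- labels %in% c("NS", "AF")
    if (!all(ok)) stop("character labels must be 'NS' or 'AF'")
    return(as.integer(labels == "AF"))
  }
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1 or NS/AF")
  y
}

#' @export
print.af_logit <- function(x, ...) {
  cat(sprintf("Logistic NS/AF classifier: %d features, n = %d, tau = %.4f\n",
              length(x$feature_names), x$n, x$tau))
  cat("Standardized coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.af_logit <- function(object, ...) {
  auc <- roc_auc(object$roc)
  cat(sprintf("Logistic NS/AF classifier (n = %d, ridge = %g, %s)\n",
              object$n, object$ridge,
              if (object$converged) "converged" else "not converged"))
  cat(sprintf("Training AUC %.4f, threshold tau = %.4f\n", auc, object$tau))
  cat("\nStandardized coefficients:\n")
  print(round(object$coefficients, 4))
  invisible(object)
}

#' @export
coef.af_logit <- function(object, ...) object$coefficients

#' Predict from a fitted NS/AF classifier
#'
#' @param object an `af_logit` model.
#' @param newdata covariate matrix/data frame with the training features
#'   (by name), or a named numeric vector for a single window.
#' @param type `"prob"` for AF probabilities, `"class"` for hard NS/AF
#'   calls using the model's threshold (AF iff probability strictly exceeds
#'   tau).
#' @param ... unused.
#' @return Numeric probabilities in (0, 1), or a factor with levels NS/AF.
#' @export
predict.af_logit <- function(object, newdata,
                             type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing))
      stop("missing feature(s): ", paste(missing, collapse = ", "))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) != length(object$feature_names)) {
    stop("newdata has the wrong number of features")
  }
  z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  eta <- drop(cbind(1, z) %*% object$coefficients)
  p <- stats::plogis(eta)
  if (type == "prob") return(p)
  factor(ifelse(p > object$tau, "AF", "NS"), levels = c("NS", "AF"))
}

#' @export
plot.af_logit <- function(x, ...) {
  plot(x$roc, ...)
  i <- which.min(sqrt(x$roc$fpr^2 + (1 - x$roc$se)^2))
  graphics::points(x$roc$fpr[i], x$roc$se[i], pch = 19, col = "red")
  graphics::legend("bottomright", sprintf("tau = %.3f", x$tau),
                   pch = 19, col = "red", bty = "n")
  invisible(x)
}

#' ROC curve from probabilities and labels
#'
#' Sweeps the classification rule "AF iff probability > threshold" over all
#' distinct probabilities (plus the 0 and 1 sentinels) and records the
#' (threshold, FPR, sensitivity) triplets. As the threshold decreases both
#' FPR and sensitivity are non-decreasing.
#'
#' @param probs predicted AF probabilities.
#' @param labels 0/1 (or NS/AF) true classes; both must be present.
#' @return An object of class `roc_curve`: data frame with `threshold`,
#'   `fpr`, `se`.
#' @export
roc_curve <- function(probs, labels) {
  y <- encode_labels(labels)
  if (length(probs) != length(y)) stop("probs and labels disagree in length")
  if (length(unique(y)) < 2) stop("both classes must be present")
  thr <- sort(unique(c(0, 1, probs)))
  pos <- sum(y == 1); neg <- sum(y == 0)
  pts <- t(vapply(thr, function(tau) {
    pred <- probs > tau
    c(fpr = sum(pred & y == 0) / neg, se = sum(pred & y == 1) / pos)
  }, numeric(2)))
  structure(data.frame(threshold = thr, fpr = pts[, "fpr"], se = pts[, "se"]),
            class = c("roc_curve", "data.frame"))
}

#' @export
plot.roc_curve <- function(x, ...) {
  o <- order(x$fpr, x$se)
  graphics::plot(x$fpr[o], x$se[o], type = "l", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "false positive rate",
                 ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Area under an ROC curve (trapezoidal)
#' @param roc a `roc_curve`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  o <- order(roc$fpr, roc$se)
  fpr <- roc$fpr[o]; se <- roc$se[o]
  sum(diff(fpr) * (utils::head(se, -1) + utils::tail(se, -1)) / 2)
}

#' ROC-optimal probability threshold
#'
#' The operating threshold closest to the ideal corner (0, 1):
#' `tau = argmin sqrt(FPR^2 + (1 - Se)^2)`. Ties are broken toward the
#' largest threshold, the more conservative choice (fewer false AF calls).
#'
#' @param roc a `roc_curve`.
#' @return The selected threshold.
#' @export
optimal_threshold <- function(roc) {
  if (!nrow(roc)) stop("empty ROC curve")
  d <- sqrt(roc$fpr^2 + (1 - roc$se)^2)
  best <- which(d == min(d))
  max(roc$threshold[best])
}

#' Sensitivity, specificity and accuracy of hard calls
#'
#' `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `ACC = (TP+TN)/n`, with AF as the
#' positive class. Ratios with a zero denominator are reported as `NA` with
#' a warning.
#'
#' @param predicted 0/1 (or NS/AF) predicted classes.
#' @param labels 0/1 (or NS/AF) true classes, same length.
#' @return List with `se`, `sp`, `acc` and the confusion `counts`
#'   (tp, tn, fp, fn).
#' @export
evaluate_predictions <- function(predicted, labels) {
  p <- encode_labels(predicted)
  y <- encode_labels(labels)
  if (length(p) != length(y)) stop("predicted and labels disagree in length")
  tp <- sum(p == 1 & y == 1); tn <- sum(p == 0 & y == 0)
  fp <- sum(p == 1 & y == 0); fn <- sum(p == 0 & y == 1)
  ratio <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NA_real_ }
    else num / den
  }
  list(se = ratio(tp, tp + fn, "sensitivity"),
       sp = ratio(tn, tn + fp, "specificity"),
       acc = (tp + tn) / length(y),
       counts = c(tp = tp, tn = tn, fp = fp, fn = fn))
}

#' Stratified k-fold cross-validation of the NS/AF classifier
#'
#' Shuffles each class separately with the given seed, deals the windows
#' into k stratified folds, and for each fold fits the classifier — and
#' selects its threshold — on the remaining folds only, then classifies the
#' held-out fold. The aggregate metrics pool the test-fold confusion counts.
#'
#' @param x covariate matrix, one row per window.
#' @param labels true classes.
#' @param k number of folds (each class must have at least k members).
#' @param seed integer seed for the fold shuffle.
#' @param ridge passed to [fit_af_classifier()].
#' @return List with `folds` (per-fold data frame: se, sp, acc, tau),
#'   `aggregate` (pooled se/sp/acc + counts), `k`, `seed`.
#' @export
cross_validate <- function(x, labels, k = 10, seed = 1, ridge = 1e-6) {
  x <- as.matrix(x)
  y <- encode_labels(labels)
  if (k < 2) stop("k must be at least 2")
  if (min(table(y)) < k) stop("each class needs at least k windows")
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    train <- fold != f
    model <- fit_af_classifier(x[train, , drop = FALSE], y[train],
                               ridge = ridge)
    pred <- predict(model, x[!train, , drop = FALSE], type = "class")
    ev <- suppressWarnings(evaluate_predictions(pred, y[!train]))
    pooled <- pooled + ev$counts
    rows[[f]] <- data.frame(fold = f, se = ev$se, sp = ev$sp, acc = ev$acc,
                            tau = model$tau)
  }
  agg <- list(se = pooled[["tp"]] / (pooled[["tp"]] + pooled[["fn"]]),
              sp = pooled[["tn"]] / (pooled[["tn"]] + pooled[["fp"]]),
              acc = (pooled[["tp"]] + pooled[["tn"]]) / sum(pooled),
              counts = pooled)
  list(folds = do.call(rbind, rows), aggregate = agg, k = k, seed = seed)
}

#' Serialize / load a fitted classifier as JSON
#'
#' @param model an `af_logit`.
#' @param path file path.
#' @return `write_classifier_json` returns `path` invisibly;
#'   `read_classifier_json` returns an `af_logit` (without the training
#'   ROC curve).
#' @export
write_classifier_json <- function(model, path) {
  stopifnot(inherits(model, "af_logit"))
  jsonlite::write_json(list(coefficients = as.list(model$coefficients),
                            feature_names = model$feature_names,
                            center = as.list(model$center),
                            scale = as.list(model$scale),
                            tau = model$tau, ridge = model$ridge,
                            n = model$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(obj$coefficients),
                 feature_names = obj$feature_names,
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 tau = obj$tau, roc = NULL, ridge = obj$ridge, n = obj$n,
                 converged = TRUE),
            class = "af_logit")
}
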