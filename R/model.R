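#' Binarize a 6-point motion-sickness score
#'
#' Scores 0-1 ("no motion sickness at all" / "slight") map to class 0,
#' scores 2-5 ("some" through "unbearable") to class 1.
#'
#' @param score integer vector with values in 0..5.
#' @return integer vector of 0/1 labels.
#' @export
#' @examples
#' binarize_score(c(0, 1, 2, 5))  # 0 0 1 1
binarize_score <- function(score) {
  if (any(!is.finite(score)) || any(score != round(score)) ||
      any(score < 0) || any(score > 5))
    stop("score must be an integer in 0..5")
  as.integer(score >= 2)
}

#' SVM training and cross-validation settings
#'
#' @param c soft-margin penalty C (> 0).
#' @param gamma RBF kernel width, a positive real or `"scale"` for
#'   `1 / (n_features * mean feature variance)` computed on the training fold.
#' @param standardize center/scale features using training-fold statistics
#'   only (recommended: RBF kernels are scale-sensitive).
#' @param k_folds number of cross-validation folds (>= 2).
#' @param seed integer seed for the shuffled fold assignment.
#' @return list of class `svm_config`.
#' @export
svm_config <- function(c = 1, gamma = "scale", standardize = TRUE,
                       k_folds = 5, seed = 1) {
  stopifnot_scalar_num(c, "c", positive = TRUE)
  if (!(identical(gamma, "scale") ||
        (is.numeric(gamma) && length(gamma) == 1 && gamma > 0)))
    stop("gamma must be a positive real or \"scale\"")
  if (!is.numeric(k_folds) || k_folds < 2 || k_folds != round(k_folds))
    stop("k_folds must be an integer >= 2")
  structure(list(c = c, gamma = gamma, standardize = isTRUE(standardize),
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "svm_config")
}

feature_columns <- function(data) {
  cols <- grep("^pse_", names(data), value = TRUE)
  if (!length(cols)) stop("no feature columns (pse_*) in data")
  cols
}

# Balanced fold sizes for n samples in k folds: the first n %% k folds get
# one extra sample.
fold_sizes <- function(n, k) n %/% k + as.integer(seq_len(k) <= n %% k)

#' Cross-validate an RBF-SVM motion-sickness classifier
#'
#' Seeded shuffled k-fold cross-validation. Per fold, feature
#' standardization statistics are computed on the training portion only, an
#' RBF-kernel SVM is trained (via `e1071::svm`, i.e. libsvm), and the held-out
#' fold is predicted. Confusion counts are pooled over all folds into a
#' single matrix for the whole dataset.
#'
#' @param data data frame with feature columns `pse_I..pse_V` (any `pse_*`
#'   set) and a 0/1 `label` column; both classes must be present.
#' @param cfg an [svm_config()].
#' @return list of class `evaluation_report`: `tp`, `fp`, `tn`, `fn`, the
#'   derived metrics (`accuracy`, `precision`, `recall`, `f1`), `per_fold`
#'   counts, `seed`, and a config echo.
#' @export
cross_validate_svm <- function(data, cfg = svm_config()) {
  if (!inherits(cfg, "svm_config")) stop("cfg must be an svm_config")
  cols <- feature_columns(data)
  if (!"label" %in% names(data)) stop("data must contain a `label` column")
  y <- as.integer(data$label)
  n <- nrow(data)
  if (n < cfg$k_folds)
    stop(sprintf("fewer samples (%d) than folds (%d)", n, cfg$k_folds))
  if (length(unique(y)) < 2)
    stop("single-class data: both labels must be present")
  X <- as.matrix(data[, cols, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature values")

  perm <- local_seed(cfg$seed, sample.int(n))
  sizes <- fold_sizes(n, cfg$k_folds)
  fold_of <- integer(n)
  fold_of[perm] <- rep.int(seq_len(cfg$k_folds), sizes)

  per_fold <- vector("list", cfg$k_folds)
  counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (f in seq_len(cfg$k_folds)) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    xtr <- X[tr, , drop = FALSE]; xte <- X[te, , drop = FALSE]
    if (cfg$standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    }
    g <- if (identical(cfg$gamma, "scale")) {
      v <- mean(apply(xtr, 2, stats::var))
      if (v <= 0) 1 / ncol(xtr) else 1 / (ncol(xtr) * v)
    } else cfg$gamma
    ytr <- factor(y[tr], levels = c(0, 1))
    if (nlevels(droplevels(ytr)) < 2)
      stop(sprintf("fold %d training set is single-class; use fewer folds", f))
    fit <- e1071::svm(x = xtr, y = ytr, kernel = "radial", cost = cfg$c,
                      gamma = g, scale = FALSE)
    pred <- as.integer(as.character(predict(fit, xte)))
    fc <- c(tp = sum(pred == 1 & y[te] == 1),
            fp = sum(pred == 1 & y[te] == 0),
            tn = sum(pred == 0 & y[te] == 0),
            fn = sum(pred == 0 & y[te] == 1))
    per_fold[[f]] <- as.list(fc)
    counts <- counts + fc
  }
  met <- confusion_metrics(unname(counts["tp"]), unname(counts["fp"]),
                           unname(counts["tn"]), unname(counts["fn"]))
  structure(c(as.list(counts), met,
              list(per_fold = per_fold, seed = cfg$seed,
                   config = unclass(cfg))),
            class = "evaluation_report")
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall, and F1 from pooled true/false
#' positive/negative counts. Ratios with a zero denominator are reported as
#' `NA` (absent), not as 0.
#'
#' @param tp,fp,tn,fn nonnegative integer counts; their sum must be positive.
#' @return list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
#' @examples
#' confusion_metrics(tp = 36, fp = 4, tn = 32, fn = 6)$accuracy  # 68/78
confusion_metrics <- function(tp, fp, tn, fn) {
  cnt <- c(tp, fp, tn, fn)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be nonnegative integers")
  total <- sum(cnt)
  if (total == 0) stop("all-zero confusion counts")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Pooled cross-validated confusion matrix:\n")
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(c("true 0", "true 1"),
                              c("pred 0", "pred 1")))
  m[1, ] <- c(x$tn, x$fp); m[2, ] <- c(x$fn, x$tp)
  print(m)
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Pearson correlation of each band's entropy with the binary label
#'
#' @param data data frame with `pse_*` feature columns and a `label` column;
#'   at least 3 rows, label not constant.
#' @return named numeric vector of Pearson coefficients, in band order;
#'   constant feature columns give `NA`.
#' @export
feature_label_correlation <- function(data) {
  cols <- feature_columns(data)
  if (nrow(data) < 3) stop("need at least 3 samples for correlation")
  y <- as.numeric(data$label)
  if (stats::sd(y) == 0) stop("label is constant; correlation undefined")
  out <- vapply(cols, function(cn) {
    x <- as.numeric(data[[cn]])
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, y)
  }, numeric(1))
  names(out) <- sub("^pse_", "", cols)
  out
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
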