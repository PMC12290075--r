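# Immunofluorescence rare-cell calling: slide-wide CK threshold, CD45
# logistic classifier with repeated cross-validation, CTC enumeration.

#' Call cytokeratin-positive cells by the slide-wide threshold rule
#'
#' A cell is CK+ when its mean CK intensity is strictly greater than the
#' slide-wide mean plus `n_sd` slide-wide (population) standard deviations,
#' computed over all cells on that slide. The call is invariant to affine
#' rescaling of a slide's intensities.
#'
#' @param table Data.frame with columns `slide` and `ck`.
#' @param n_sd Number of standard deviations above the slide mean.
#' @return Logical vector, one element per row of `table`.
#' @export
call_ck_positive <- function(table, n_sd = 6) {
  stopifnot(all(c("slide", "ck") %in% names(table)))
  out <- logical(nrow(table))
  for (sl in unique(table$slide)) {
    idx <- which(table$slide == sl)
    if (length(idx) < 2L) {
      stop_invalid("insufficient data: slide ", sl, " has fewer than 2 cells")
    }
    x <- table$ck[idx]
    out[idx] <- x > mean(x) + n_sd * sd_pop(x)
  }
  out
}

# Ridge-stabilized logistic regression (IRLS) of y (0/1) on a single
# covariate. The tiny ridge penalty (on the standardized slope only) keeps
# coefficients finite under complete separation.
.ridge_logit <- function(x, y, lambda = 1e-6, max_iter = 100L, tol = 1e-10) {
  mu_x <- mean(x)
  sd_x <- stats::sd(x)
  if (!is.finite(sd_x) || sd_x == 0) sd_x <- 1
  z <- (x - mu_x) / sd_x
  X <- cbind(1, z)
  beta <- c(log((mean(y) + 0.5 / length(y)) / (1 - mean(y) + 0.5 / length(y))), 0)
  P <- diag(c(0, lambda))
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    zz <- eta + (y - p) / w
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X + P, XtW %*% zz))
    dev <- -2 * sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300))) +
      lambda * beta[2]^2
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) break
    dev_old <- dev
  }
  # back to the raw intensity scale
  c(intercept = unname(beta[1] - beta[2] * mu_x / sd_x),
    slope = unname(beta[2] / sd_x))
}

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit the CD45 logistic classifier with repeated cross-validation
#'
#' Splits the annotated cells into a stratified training set
#' (`train_fraction`, default two-thirds) and a held-out test set, fits a
#' ridge-stabilized logistic regression of CD45 positivity on mean CD45
#' intensity, and reports stratified `folds`-fold cross-validation accuracy
#' (repeated `repeats` times) on the training set plus accuracy on the
#' held-out test set.
#'
#' @param labeled Data.frame with columns `cd45` and `label`; `label` must
#'   take exactly the two values `positive` and one other.
#' @param train_fraction Fraction of cells in the training split.
#' @param folds,repeats Cross-validation folds and repeats.
#' @param seed Integer seed (split, folds and fits are reproducible).
#' @param positive Label value treated as CD45 positive.
#' @param lambda Ridge penalty on the standardized slope.
#' @return A `cd45_classifier`: list with `coefficients` (intercept, slope on
#'   the raw intensity scale), `positive`, `negative`, `cv` (data.frame of
#'   per-fold accuracies), `cv_accuracy` (their mean), `test_accuracy`,
#'   `train_fraction`, and the index vectors of the split.
#' @export
fit_cd45_classifier <- function(labeled, train_fraction = 2 / 3, folds = 5L,
                                repeats = 5L, seed = 1L,
                                positive = "CD45+/CK+", lambda = 1e-6) {
  stopifnot(all(c("cd45", "label") %in% names(labeled)))
  labs <- unique(as.character(labeled$label))
  if (length(labs) != 2L) stop_invalid("need exactly two label classes")
  if (!positive %in% labs) stop_invalid("`positive` label not present")
  negative <- setdiff(labs, positive)
  y_all <- as.integer(labeled$label == positive)
  x_all <- labeled$cd45
  if (min(table(y_all)) < folds) {
    stop_invalid("need at least `folds` cells per class")
  }
  with_seed(seed, {
    # stratified train/test split
    train_idx <- unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(y_all == cl)
      sample(idx, round(train_fraction * length(idx)))
    }))
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_along(y_all), train_idx)
    x <- x_all[train_idx]
    y <- y_all[train_idx]
    if (min(table(y)) < folds) stop_invalid("need at least `folds` cells per class in training split")

    cv <- do.call(rbind, lapply(seq_len(repeats), function(r) {
      fold <- .stratified_folds(y, folds)
      acc <- vapply(seq_len(folds), function(f) {
        tr <- fold != f
        cf <- .ridge_logit(x[tr], y[tr], lambda = lambda)
        pred <- as.integer(stats::plogis(cf[1] + cf[2] * x[!tr]) > 0.5)
        mean(pred == y[!tr])
      }, 0)
      data.frame(repeat_ = r, fold = seq_len(folds), accuracy = acc)
    }))

    cf <- .ridge_logit(x, y, lambda = lambda)
    test_pred <- as.integer(stats::plogis(cf[1] + cf[2] * x_all[test_idx]) > 0.5)
    model <- structure(
      list(coefficients = cf, positive = positive, negative = negative,
           cv = cv, cv_accuracy = mean(cv$accuracy),
           test_accuracy = mean(test_pred == y_all[test_idx]),
           train_fraction = train_fraction, folds = folds, repeats = repeats,
           lambda = lambda, seed = as.integer(seed),
           train_idx = train_idx, test_idx = test_idx),
      class = "cd45_classifier"
    )
    model
  })
}

#' @export
print.cd45_classifier <- function(x, ...) {
  cat("CD45 logistic classifier\n")
  cat(sprintf("  logit(p) = %.4g + %.4g * CD45\n",
              x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  CV accuracy (%d-fold x %d): %.4f\n",
              x$folds, x$repeats, x$cv_accuracy))
  cat(sprintf("  held-out test accuracy: %.4f\n", x$test_accuracy))
  invisible(x)
}

#' Classify cells as CD45 positive or negative
#'
#' Labels a cell CD45+ when the fitted model's predicted probability is
#' strictly greater than 0.5 (a cell exactly at the decision boundary is
#' negative).
#'
#' @param model A fitted `cd45_classifier`.
#' @param table Data.frame with a `cd45` column.
#' @return Character vector of labels (`model$positive` / `model$negative`).
#' @export
classify_cd45 <- function(model, table) {
  if (!inherits(model, "cd45_classifier") ||
      !all(is.finite(model$coefficients))) {
    stop_invalid("model is not a fitted cd45_classifier")
  }
  p <- stats::plogis(model$coefficients[1] + model$coefficients[2] * table$cd45)
  ifelse(p > 0.5, model$positive, model$negative)
}

#' Persist / restore a CD45 classifier as JSON
#'
#' @param model A `cd45_classifier`.
#' @param path File path.
#' @return `read_cd45_classifier` returns the model; the writer returns
#'   `path` invisibly.
#' @export
write_cd45_classifier <- function(model, path) {
  obj <- model[c("coefficients", "positive", "negative", "cv_accuracy",
                 "test_accuracy", "train_fraction", "folds", "repeats",
                 "lambda", "seed")]
  obj$cv <- model$cv
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cd45_classifier
#' @export
read_cd45_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- stats::setNames(as.numeric(obj$coefficients),
                                      c("intercept", "slope"))
  obj$cv <- as.data.frame(obj$cv)
  class(obj) <- "cd45_classifier"
  obj
}

#' Enumerate CTC phenotypes per mL of blood
#'
#' From per-cell CK and CD45 calls (logical vectors) or precomputed counts,
#' reports CK+ cells per mL, the CD45+/CK+ and CD45-/CK+ subsets per mL, and
#' the CD45+ fraction of the CK+ population.
#'
#' @param ck_positive Logical vector of CK calls, or a single CK+ count.
#' @param cd45_positive Logical vector of CD45 calls (aligned with
#'   `ck_positive`), or a single count of CD45+/CK+ cells.
#' @param volume_ml Blood volume the cells came from (mL, > 0).
#' @return Data.frame with `n_ck_pos`, `n_ck_cd45_pos`, `n_ck_cd45_neg`,
#'   `ck_per_ml`, `ck_cd45_pos_per_ml`, `ck_cd45_neg_per_ml` and
#'   `cd45_fraction` (NA when there are no CK+ cells).
#' @examples
#' enumerate_ctc(6419, 6268, volume_ml = 1)  # cd45_fraction > 0.97
#' @export
enumerate_ctc <- function(ck_positive, cd45_positive, volume_ml = 1) {
  if (volume_ml <= 0) stop_invalid("`volume_ml` must be positive")
  if (is.logical(ck_positive)) {
    stopifnot(is.logical(cd45_positive),
              length(ck_positive) == length(cd45_positive))
    n_ck <- sum(ck_positive)
    n_dp <- sum(ck_positive & cd45_positive)
  } else {
    n_ck <- as.numeric(ck_positive)
    n_dp <- as.numeric(cd45_positive)
    if (n_dp > n_ck) stop_invalid("CD45+/CK+ count exceeds CK+ count")
  }
  data.frame(
    n_ck_pos = n_ck,
    n_ck_cd45_pos = n_dp,
    n_ck_cd45_neg = n_ck - n_dp,
    ck_per_ml = n_ck / volume_ml,
    ck_cd45_pos_per_ml = n_dp / volume_ml,
    ck_cd45_neg_per_ml = (n_ck - n_dp) / volume_ml,
    cd45_fraction = if (n_ck > 0) n_dp / n_ck else NA_real_
  )
}
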