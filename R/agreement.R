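#' Confusion matrix of true versus assigned grade bands
#'
#' @param true,assigned Vectors of band labels of equal length; every value
#'   must occur in `labels`.  Unclassified records must be filtered (or given
#'   an explicit extra label) by the caller.
#' @param labels Ordered band labels, severity-ascending; rows (true) and
#'   columns (assigned) share this order.
#' @return An object of class `mrs_confusion`: an integer matrix with cell
#'   (i, j) counting records whose true band is `labels[i]` and assigned band
#'   `labels[j]`.
#' @export
#' @examples
#' cm <- confusion_matrix(c("0-2", "3"), c("0-2", "3"),
#'                        grade_scheme("tree1")$labels)
#' classification_accuracy(cm)
confusion_matrix <- function(true, assigned, labels) {
  if (length(true) != length(assigned))
    stop("'true' and 'assigned' differ in length", call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicate band labels", call. = FALSE)
  bad <- setdiff(unique(c(true, assigned)), labels)
  if (length(bad))
    stop("value(s) not among band labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tf <- factor(true, levels = labels)
  af <- factor(assigned, levels = labels)
  m <- unclass(table(true = tf, assigned = af))
  storage.mode(m) <- "integer"
  structure(m, class = c("mrs_confusion", class(m)))
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("confusion matrix must be square", call. = FALSE)
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  invisible(cm)
}

#' Overall classification accuracy
#'
#' Proportion of records on the diagonal of the confusion matrix.
#'
#' @param cm A square confusion matrix (rows = true band).
#' @return A proportion in \[0, 1\].
#' @export
classification_accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' No-information rate
#'
#' Accuracy achievable by always predicting the most prevalent true band:
#' the largest row sum divided by n.  Used as the usability baseline for a
#' classifier's accuracy.
#'
#' @inheritParams classification_accuracy
#' @return A proportion in \[0, 1\].
#' @export
no_information_rate <- function(cm) {
  check_cm(cm)
  max(rowSums(cm)) / sum(cm)
}

#' Fleiss-Cohen quadratic agreement weights
#'
#' Weight matrix `w(i, j) = 1 - (i - j)^2 / (k - 1)^2` (0-based indices), so
#' exact agreement weighs 1, extreme disagreement 0, and near-misses count
#' partially - the appropriate weighting for an ordinal scale such as the
#' mRS.
#'
#' @param k Number of bands (>= 2).
#' @return A `k x k` numeric matrix.
#' @export
quadratic_weights <- function(k) {
  if (k < 2) stop("need at least 2 bands", call. = FALSE)
  i <- matrix(0:(k - 1), k, k)
  1 - (i - t(i))^2 / (k - 1)^2
}

#' Weighted Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement `Kw = (Po_w - Pe_w) / (1 - Pe_w)` where
#' `Po_w = sum(w * p_obs)` and `Pe_w = sum(w * outer(row, col))` are the
#' weighted observed and expected agreement.  The standard error is the
#' large-sample (Fleiss-Cohen-Everitt) variance of weighted kappa under the
#' alternative, giving the Wald interval `Kw +/- z * SE`, truncated to
#' \[-1, 1\].
#'
#' @param cm A square confusion matrix (rows = true band, columns =
#'   assigned band, identical label order).
#' @param weights Weight matrix matching `cm`; defaults to
#'   [quadratic_weights()] of the matching size.  Pass `diag(k)` for
#'   unweighted Cohen's kappa.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `kappa_result`: list with `estimate`, `se`,
#'   `conf_int` (length-2), `conf_level`, `weights`, `interpretation`
#'   (Landis-Koch label) and `n`.
#' @export
#' @examples
#' cm <- matrix(c(10, 2, 0, 3, 8, 2, 0, 1, 9), 3, 3, byrow = TRUE)
#' weighted_kappa(cm)
weighted_kappa <- function(cm, weights = NULL, conf_level = 0.95) {
  check_cm(cm)
  k <- nrow(cm)
  if (is.null(weights)) weights <- quadratic_weights(k)
  if (!is.matrix(weights) || any(dim(weights) != k))
    stop("weight matrix does not match the confusion matrix", call. = FALSE)
  n <- sum(cm)
  p <- cm / n
  r <- rowSums(p)
  s <- colSums(p)
  po <- sum(weights * p)
  pe <- sum(weights * outer(r, s))
  if (isTRUE(all.equal(pe, 1)))
    stop("degenerate margins: expected weighted agreement is 1, kappa undefined",
         call. = FALSE)
  kw <- (po - pe) / (1 - pe)
  # large-sample variance (Fleiss, Cohen & Everitt 1969)
  wr <- as.vector(weights %*% s)   # row-conditional expected weight
  wc <- as.vector(t(weights) %*% r)
  term <- (weights * (1 - pe) -
             (matrix(wr, k, k) + matrix(wc, k, k, byrow = TRUE)) * (1 - po))^2
  v <- (sum(p * term) - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(-1, kw + c(-1, 1) * z * se))
  structure(list(estimate = kw, se = se, conf_int = ci,
                 conf_level = conf_level, weights = weights,
                 interpretation = interpret_kappa(kw), n = n),
            class = "kappa_result")
}

#' Landis-Koch interpretation of a kappa value
#'
#' Verbal agreement bands: slight (Kw <= 0.20), fair (0.21-0.40), moderate
#' (0.41-0.60), substantial (0.61-0.80) and almost perfect (>= 0.81).  The
#' estimate is rounded half-up to two decimals before banding, so values in
#' the unprinted gaps (e.g. 0.805) resolve by their printed representation.
#'
#' @param kw A kappa estimate in \[-1, 1\].
#' @return One of `"slight"`, `"fair"`, `"moderate"`, `"substantial"`,
#'   `"almost perfect"`.
#' @export
interpret_kappa <- function(kw) {
  if (is.na(kw) || kw < -1 || kw > 1)
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  r2 <- floor(abs(kw) * 100 + 0.5) / 100 * sign(kw)  # round half-up
  if (r2 <= 0.20) "slight"
  else if (r2 <= 0.40) "fair"
  else if (r2 <= 0.60) "moderate"
  else if (r2 <= 0.80) "substantial"
  else "almost perfect"
}

#' Under- and over-estimation proportions
#'
#' Splits the off-diagonal mass of a severity-ordered confusion matrix into
#' the proportion of records assigned a lower (better) band than their true
#' band (`under`) and a higher (worse) band (`over`).  With rows = true band
#' in severity-ascending order, `over` is the above-diagonal mass: the
#' assigned band indicates worse disability than the reference.
#'
#' @inheritParams classification_accuracy
#' @return Named numeric vector `c(under = , over = )`;
#'   `accuracy + under + over == 1`.
#' @export
misclassification_profile <- function(cm) {
  check_cm(cm)
  n <- sum(cm)
  c(under = sum(cm[lower.tri(cm)]) / n,
    over = sum(cm[upper.tri(cm)]) / n)
}

#' Full agreement report for a classifier
#'
#' Bundles the confusion matrix with classification accuracy, the
#' no-information rate, quadratic weighted kappa (with CI and Landis-Koch
#' interpretation) and the under/over-estimation split.
#'
#' @inheritParams weighted_kappa
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(cm, weights = NULL, conf_level = 0.95) {
  check_cm(cm)
  mp <- misclassification_profile(cm)
  structure(list(
    confusion = cm,
    n = sum(cm),
    accuracy = classification_accuracy(cm),
    nir = no_information_rate(cm),
    kappa = weighted_kappa(cm, weights, conf_level),
    under = unname(mp["under"]),
    over = unname(mp["over"])
  ), class = "agreement_report")
}

#' @export
print.kappa_result <- function(x, digits = 3, ...) {
  cat(sprintf("Weighted kappa: %.*f (SE %.*f), %d%% CI %.*f to %.*f - %s agreement (n = %d)\n",
              digits, x$estimate, digits, x$se,
              round(100 * x$conf_level), digits, x$conf_int[1],
              digits, x$conf_int[2], x$interpretation, x$n))
  invisible(x)
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("Agreement report (n = ", x$n, ")\n", sep = "")
  print(unclass(x$confusion))
  cat(sprintf("Accuracy: %.*f   No-information rate: %.*f\n",
              digits, x$accuracy, digits, x$nir))
  cat(sprintf("Under-estimated: %.*f   Over-estimated: %.*f\n",
              digits, x$under, digits, x$over))
  print(x$kappa, digits = digits)
  invisible(x)
}

#' Serialize an agreement report to JSON
#'
#' @param report An `agreement_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  out <- list(
    n = report$n,
    confusion = list(labels = rownames(report$confusion),
                     counts = unclass(report$confusion)),
    accuracy = report$accuracy,
    no_information_rate = report$nir,
    under = report$under,
    over = report$over,
    kappa = list(estimate = report$kappa$estimate,
                 se = report$kappa$se,
                 conf_level = report$kappa$conf_level,
                 conf_int = report$kappa$conf_int,
                 interpretation = report$kappa$interpretation)
  )
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
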