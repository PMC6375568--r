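# ROC analysis with accuracy-maximizing cut-off selection, confusion
# metrics, DeLong's paired AUC comparison, and covariate-adjusted group
# comparison. Conventions: candidate thresholds are the midpoints between
# adjacent distinct observed values plus -Inf/+Inf sentinels; a subject is
# called positive when its value is strictly above the threshold; AUC is the
# trapezoidal area, identical to the Mann-Whitney statistic with half-credit
# for ties.

#' ROC curve of an index against a binary label
#'
#' @param values numeric index values, higher meaning more disease-like.
#' @param labels binary labels, `TRUE`/positive-class for diseased.
#' @param positive the positive-class label when `labels` is not logical
#'   (default `"HCM"`).
#' @return A `roc_report`: `thresholds`, `sensitivity` and `specificity`
#'   arrays (%), `auc`, counts `n_pos`/`n_neg`, and (after
#'   [optimal_cutoff()]) the optimum fields.
#' @examples
#' r <- roc_curve(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
#' r$auc
#' @export
roc_curve <- function(values, labels, positive = "HCM") {
  if (length(values) != length(labels))
    stop_cmr("'values' and 'labels' lengths differ")
  if (any(!is.finite(values))) stop_cmr("missing or non-finite index values")
  pos <- if (is.logical(labels)) labels else labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop_cmr("both classes must be present (got %d positive, %d negative)",
             n_pos, n_neg)
  ux <- sort(unique(values))
  thr <- c(-Inf, if (length(ux) > 1L) (ux[-1L] + ux[-length(ux)]) / 2, Inf)
  tp <- vapply(thr, function(t) sum(pos & values > t), integer(1))
  fp <- vapply(thr, function(t) sum(!pos & values > t), integer(1))
  sens <- 100 * tp / n_pos
  spec <- 100 * (n_neg - fp) / n_neg
  # trapezoid over the ROC polyline (FPR decreasing along thr)
  fpr <- fp / n_neg; tpr <- tp / n_pos
  auc <- sum(-diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 tp = tp, fp = fp, auc = auc,
                 n_pos = n_pos, n_neg = n_neg), class = "roc_report")
}

#' Accuracy-maximizing cut-off
#'
#' Picks the candidate threshold maximizing the proportion of subjects
#' correctly classified, breaking ties toward the smallest threshold (the
#' more sensitive choice), and populates the optimum fields of the report:
#' confusion counts and sensitivity/specificity/PPV/NPV/accuracy at the
#' optimum.
#'
#' @param roc a [roc_curve()] report.
#' @return The report with `optimal_threshold`, `confusion` (TP/FP/FN/TN)
#'   and `at_optimum` (a [confusion_metrics()] result) added.
#' @export
optimal_cutoff <- function(roc) {
  if (!inherits(roc, "roc_report")) stop_cmr("need a 'roc_report'")
  total <- roc$n_pos + roc$n_neg
  tn <- roc$n_neg - roc$fp
  acc <- (roc$tp + tn) / total
  best <- which.max(acc)                      # which.max takes the first tie
  roc$optimal_threshold <- roc$thresholds[best]
  fn <- roc$n_pos - roc$tp[best]
  roc$confusion <- c(TP = roc$tp[best], FP = roc$fp[best],
                     FN = fn, TN = tn[best])
  roc$at_optimum <- confusion_metrics(roc$tp[best], roc$fp[best], fn,
                                      tn[best])
  roc
}

#' Confusion-matrix metrics
#'
#' Sensitivity, specificity, positive and negative predictive value and the
#' proportion correctly classified, as percentages. A metric whose
#' denominator is zero is returned as `NA` (undefined), never as 0.
#'
#' @param tp,fp,fn,tn non-negative confusion counts.
#' @return List of class `confusion_metrics` with `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `correctly_classified` (all %) and the
#'   counts.
#' @examples
#' confusion_metrics(143, 0, 47, 108)  # PPV 100%, NPV ~70%
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  k <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(k < 0) || any(k != round(k)))
    stop_cmr("confusion counts must be non-negative integers")
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    sensitivity = frac(tp, tp + fn),
    specificity = frac(tn, tn + fp),
    ppv = frac(tp, tp + fp),
    npv = frac(tn, tn + fn),
    correctly_classified = frac(tp + tn, sum(k)),
    counts = k), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, digits = 1, ...) {
  f <- function(v) if (is.na(v)) "undefined" else
    sprintf(paste0("%.", digits, "f%%"), v)
  cat(sprintf("sensitivity %s  specificity %s  PPV %s  NPV %s  correct %s\n",
              f(x$sensitivity), f(x$specificity), f(x$ppv), f(x$npv),
              f(x$correctly_classified)))
  invisible(x)
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  if (!is.null(x$optimal_threshold)) {
    cat(sprintf("  optimal cut-off > %.4g: ", x$optimal_threshold))
    print(x$at_optimum)
  }
  invisible(x)
}

#' @export
plot.roc_report <- function(x, ...) {
  graphics::plot(100 - x$specificity, x$sensitivity, type = "s",
                 xlab = "100 - specificity (%)", ylab = "sensitivity (%)",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# Mann-Whitney placement components: psi(x, y) with half-credit ties
delong_components <- function(x_pos, x_neg) {
  m <- length(x_pos); n <- length(x_neg)
  psi <- outer(x_pos, x_neg, function(a, b)
    (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' DeLong's paired comparison of two AUCs
#'
#' Compares the AUCs of two indices measured on the same subjects using the
#' structural-components estimate of the variance of the AUC difference,
#' with a two-sided normal test.
#'
#' @param values_a,values_b paired index values on the same subjects.
#' @param labels binary labels (see [roc_curve()]).
#' @param positive positive-class label.
#' @return List: `auc_a`, `auc_b`, `auc_diff`, `z`, `p_value`.
#' @export
delong_compare <- function(values_a, values_b, labels, positive = "HCM") {
  if (length(values_a) != length(values_b) ||
      length(values_a) != length(labels))
    stop_cmr("paired inputs must have equal length")
  pos <- if (is.logical(labels)) labels else labels == positive
  if (!any(pos) || all(pos)) stop_cmr("both classes must be present")
  ca <- delong_components(values_a[pos], values_a[!pos])
  cb <- delong_components(values_b[pos], values_b[!pos])
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff <= 1e-16) {
    z <- 0; p <- if (abs(d) < 1e-12) 1 else NA_real_
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, auc_diff = d, z = z, p_value = p,
       var_diff = var_diff)
}

#' Covariate-adjusted group comparison
#'
#' Within each stratum, fits a least-squares regression of the outcome on a
#' two-level group indicator plus age and heart rate, and reports the
#' adjusted group difference (the group coefficient), its standard error and
#' the coefficient t-test p-value.
#'
#' @param outcome numeric outcome values.
#' @param group two-level group labels (factor or character).
#' @param age,heart_rate adjustment covariates.
#' @param strata optional stratification labels (e.g. sex); one comparison
#'   per stratum.
#' @return A `group_comparison` data frame: stratum, groups compared,
#'   estimate (second level minus first), se, p_value, n, covariates used.
#' @export
adjusted_group_compare <- function(outcome, group, age, heart_rate,
                                   strata = NULL) {
  n <- length(outcome)
  if (length(group) != n || length(age) != n || length(heart_rate) != n)
    stop_cmr("input lengths differ")
  if (is.null(strata)) strata <- rep("all", n)
  out <- lapply(split(seq_len(n), strata), function(ix) {
    # radix order keeps the level order (hence the sign of the estimate)
    # locale-independent
    g <- factor(group[ix],
                levels = sort(unique(as.character(group[ix])),
                              method = "radix"))
    if (nlevels(g) < 2L)
      stop_cmr("stratum '%s' has fewer than 2 groups", strata[ix][1L])
    d <- data.frame(y = outcome[ix], g = g, age = age[ix],
                    hr = heart_rate[ix])
    fit <- stats::lm(y ~ g + age + hr, data = d)
    if (any(is.na(stats::coef(fit))))
      stop_cmr("rank-deficient design in stratum '%s'", strata[ix][1L])
    sm <- summary(fit)$coefficients
    row <- grep("^g", rownames(sm))[1L]
    data.frame(stratum = as.character(strata[ix][1L]),
               comparison = paste(levels(g)[2L], "vs", levels(g)[1L]),
               estimate = sm[row, 1L], se = sm[row, 2L],
               p_value = sm[row, 4L], n = length(ix),
               covariates = "age, heart_rate", stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, c(out, make.row.names = FALSE)),
            class = c("group_comparison", "data.frame"))
}
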