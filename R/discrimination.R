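#' ROC analysis of a single index
#'
#' Computes the ROC curve of a continuous index against binary labels
#' with the criterion "positive if value > c". The orientation is chosen
#' automatically so the AUC is at least 0.5 (and recorded): when the
#' positive class tends to have smaller values the criterion becomes
#' "value < c". The AUC is the trapezoidal area, equivalently the
#' concordance probability with ties counting one half. The 95% CI and
#' the p-value for AUC = 0.5 use the DeLong variance estimator. The
#' Youden-optimal cut-off, sensitivity and specificity (percent) are
#' included.
#'
#' @param values numeric index, one per subject.
#' @param labels binary labels: logical, 0/1, or a factor/character whose
#'   positive class is `positive`.
#' @param positive positive-class label; defaults to TRUE/1 or the second
#'   factor level.
#' @return an object of class `roc_result`: auc, ci_low, ci_high,
#'   p_value, direction (">" or "<"), cutoff, sensitivity, specificity,
#'   youden, curve (data.frame fpr, tpr, threshold), n_pos, n_neg.
#' @export
roc_curve <- function(values, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  if (length(values) != length(y)) stop("values and labels differ in length")
  if (anyNA(values) || anyNA(y)) stop("values/labels contain missing entries")
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos < 3L || n_neg < 3L)
    stop("need at least 3 subjects in each class")

  auc_of <- function(v) {
    r <- rank(v)
    (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  direction <- ">"
  v <- values
  if (auc_of(values) < 0.5) {
    direction <- "<"
    v <- -values
  }
  auc <- auc_of(v)
  if (length(unique(values)) == 1L)
    warning("all index values identical: degenerate ROC curve (AUC 0.5)")

  pos <- v[y == 1L]
  neg <- v[y == 0L]
  # DeLong placement values
  v10 <- vapply(pos, function(x) (sum(neg < x) + 0.5 * sum(neg == x)) / n_neg,
                numeric(1))
  v01 <- vapply(neg, function(x) (sum(pos > x) + 0.5 * sum(pos == x)) / n_pos,
                numeric(1))
  var_auc <- stats::var(v10) / n_pos + stats::var(v01) / n_neg
  se <- sqrt(max(var_auc, 0))
  if (se > 0) {
    z <- (auc - 0.5) / se
    p_value <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  } else {
    p_value <- if (auc == 0.5) 1 else 0
    ci <- c(auc, auc)
  }

  # curve over all distinct thresholds, criterion "v > c"; the -Inf cut
  # supplies the (1, 1) endpoint
  cuts <- c(Inf, sort(unique(v), decreasing = TRUE), -Inf)
  tpr <- vapply(cuts, function(cc) mean(pos > cc), numeric(1))
  fpr <- vapply(cuts, function(cc) mean(neg > cc), numeric(1))
  curve <- data.frame(fpr = fpr, tpr = tpr,
                      threshold = if (direction == ">") cuts else -cuts)

  res <- structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                        p_value = p_value, direction = direction,
                        cutoff = NA_real_, sensitivity = NA_real_,
                        specificity = NA_real_, youden = NA_real_,
                        curve = curve, n_pos = n_pos, n_neg = n_neg,
                        .values = v, .labels = y),
                   class = "roc_result")
  yj <- youden_cutoff(res)
  res$cutoff <- yj$cutoff
  res$sensitivity <- yj$sensitivity
  res$specificity <- yj$specificity
  res$youden <- yj$youden
  res
}

as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two classes")
  if (is.null(positive)) positive <- levels(f)[2]
  if (!positive %in% levels(f))
    stop("positive class '", positive, "' not found in labels")
  as.integer(f == positive)
}

#' Youden-optimal cut-off
#'
#' Maximizes J = sensitivity + specificity - 1 over the observed
#' criterion values (plus -Inf), with ties broken by higher sensitivity,
#' then by lower cut-off. The cut-off is reported on the original value
#' scale; with direction "<" the criterion is "value < cutoff".
#'
#' @param result a `roc_result`.
#' @return list: cutoff, sensitivity (%), specificity (%), youden.
#' @export
youden_cutoff <- function(result) {
  stopifnot(inherits(result, "roc_result"))
  v <- result$.values
  y <- result$.labels
  pos <- v[y == 1L]
  neg <- v[y == 0L]
  cuts <- sort(unique(c(-Inf, v)))
  sens <- vapply(cuts, function(cc) mean(pos > cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(neg <= cc), numeric(1))
  j <- sens + spec - 1
  best <- order(-j, -sens, cuts)[1]
  cutoff <- cuts[best]
  if (result$direction == "<") cutoff <- -cutoff
  list(cutoff = cutoff, sensitivity = 100 * sens[best],
       specificity = 100 * spec[best], youden = j[best])
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (95%% CI %.3f-%.3f), p = %.4g\n", x$auc, x$ci_low,
    x$ci_high, x$p_value))
  cat(sprintf(
    "  Youden cut-off %s %.4g: sensitivity %.1f%%, specificity %.1f%% (n+ = %d, n- = %d)\n",
    x$direction, x$cutoff, x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Fit a logistic-regression composite model
#'
#' Maximum-likelihood logistic regression
#' z_i = a0 + a1 X_i1 + ... + aN X_iN, P_i = 1 / (1 + exp(-z_i)),
#' fitted by iteratively reweighted least squares with no penalty.
#' Columns are standardized internally for conditioning; coefficients are
#' reported on the original scale. Convergence requires the maximum
#' absolute score to fall below 1e-8 (at most 100 iterations). Perfect
#' separation (diverging coefficients) raises an error rather than
#' returning a silent non-MLE.
#'
#' @param x subjects x N numeric matrix of indexes.
#' @param y binary labels (see [roc_curve()]).
#' @param positive positive-class label.
#' @return object of class `lr_model`: a0, coefficients, z (linear
#'   predictor), fitted (P_i), converged, iterations.
#' @export
fit_logistic <- function(x, y, positive = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  yb <- as_binary_labels(y, positive)
  if (length(unique(yb)) < 2L) stop("both classes must be present")
  if (nrow(x) != length(yb)) stop("x rows and y length differ")
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  if (any(sdev == 0)) stop("constant index column(s): ",
                           paste(colnames(x)[sdev == 0], collapse = ", "))
  xs <- cbind(1, sweep(sweep(x, 2, mu), 2, sdev, "/"))
  beta <- rep(0, ncol(xs))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(xs %*% beta)
    p <- stats::plogis(eta)
    score <- crossprod(xs, yb - p)
    if (max(abs(score)) < 1e-8) { converged <- TRUE; break }
    if (iter > 100L) break
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (yb - p) / w
    fit <- stats::lm.wfit(xs, z, w)
    beta <- fit$coefficients
    if (any(!is.finite(beta)) || max(abs(beta)) > 1e4)
      stop("perfect separation detected (coefficients diverge); ",
           "consider a penalized fit")
  }
  # a standardized coefficient beyond ~30 means fitted probabilities pinned
  # at 0/1: the MLE does not exist (separation), even if the score converged
  if (max(abs(beta)) > 30)
    stop("perfect separation detected (coefficients diverge); ",
         "consider a penalized fit")
  if (!converged)
    warning("IRLS did not reach score tolerance 1e-8 in 100 iterations")
  coef_orig <- beta[-1] / sdev
  a0 <- beta[1] - sum(beta[-1] * mu / sdev)
  eta <- drop(a0 + x %*% coef_orig)
  structure(list(a0 = unname(a0),
                 coefficients = stats::setNames(coef_orig, colnames(x)),
                 z = eta, fitted = stats::plogis(eta),
                 converged = converged, iterations = iter),
            class = "lr_model")
}

#' @export
print.lr_model <- function(x, ...) {
  cat(sprintf("Logistic composite model (%d predictors, %s in %d iterations)\n",
              length(x$coefficients),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(c("(constant)" = x$a0, x$coefficients))
  invisible(x)
}

#' Predicted probabilities from a composite model
#'
#' @param object an `lr_model`.
#' @param newdata subjects x N matrix on the original index scale.
#' @param ... unused.
#' @return vector of probabilities P_i.
#' @export
predict.lr_model <- function(object, newdata, ...) {
  stats::plogis(drop(object$a0 + as.matrix(newdata) %*% object$coefficients))
}

#' ROC of the logistic composite index
#'
#' Evaluates the fitted model's predicted probabilities as a single
#' composite index and runs the same ROC analysis as for individual
#' indexes.
#'
#' @param model an `lr_model` fitted on (`x`, `y`).
#' @param x subjects x N index matrix.
#' @param y binary labels.
#' @param positive positive-class label.
#' @return a `roc_result`.
#' @export
composite_roc <- function(model, x, y, positive = NULL) {
  roc_curve(predict(model, x), y, positive = positive)
}

#' Per-comparison ROC report
#'
#' For one pairwise group comparison, runs single-index ROC analysis of
#' the degree centrality at each selected node and, when two or more
#' nodes are given, the logistic-regression composite of all of them
#' (labelled "LR"). Mirrors the usual biomarker table: AUC, 95% CI,
#' cut-off, sensitivity, specificity, p.
#'
#' @param dc subjects x nodes matrix.
#' @param pheno phenotype data.frame with subject_id and group.
#' @param pair two group labels; the first is the positive class.
#' @param nodes node labels to evaluate.
#' @return list with `table` (data.frame) and `roc` (named list of
#'   `roc_result`, including "LR" when computed).
#' @export
roc_report <- function(dc, pheno, pair, nodes) {
  pheno <- align_pheno(dc, pheno)
  sel <- pheno$group %in% pair
  y <- factor(pheno$group[sel], levels = c(pair[2], pair[1]))
  x <- as.matrix(dc)[sel, nodes, drop = FALSE]
  rocs <- list()
  for (nd in colnames(x)) rocs[[nd]] <- roc_curve(x[, nd], y)
  if (ncol(x) >= 2L) {
    model <- fit_logistic(x, y)
    rocs[["LR"]] <- composite_roc(model, x, y)
  }
  tab <- do.call(rbind, lapply(names(rocs), function(nm) {
    r <- rocs[[nm]]
    data.frame(index = nm, auc = r$auc, ci_low = r$ci_low,
               ci_high = r$ci_high,
               cutoff = if (nm == "LR") NA_real_ else r$cutoff,
               sensitivity = r$sensitivity, specificity = r$specificity,
               p_value = r$p_value, stringsAsFactors = FALSE)
  }))
  list(table = tab, roc = rocs)
}
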