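# Classifier evaluation: confusion matrices, Matthews correlation
# coefficient, per-class metrics, Spearman rank correlation, grid-search
# weight training, category-stratified accuracy and best-method-per-category
# meta prediction.  The positive class ("Class 1") is the neutral label
# throughout; Class 0 metrics (destabilizing as positive) are also reported.

LABELS <- c("neutral", "destabilizing")

#' Confusion matrix for binary neutral/destabilizing calls
#'
#' @param truth,pred Character vectors over `"neutral"` / `"destabilizing"`.
#' @param positive The positive class (default `"neutral"`, i.e. Class 1).
#' @return A `cp_confusion` list with `TP`, `FP`, `TN`, `FN`, `positive`.
#' @export
confusion_matrix <- function(truth, pred, positive = "neutral") {
  stopifnot(length(truth) == length(pred))
  if (!all(truth %in% LABELS) || !all(pred %in% LABELS))
    stop("labels must be 'neutral' or 'destabilizing'")
  p <- pred == positive
  t <- truth == positive
  confusion_counts(TP = sum(p & t), FP = sum(p & !t),
                   TN = sum(!p & !t), FN = sum(!p & t),
                   positive = positive)
}

#' @rdname confusion_matrix
#' @param TP,FP,TN,FN Counts (all >= 0), e.g. taken from a published
#'   confusion table.
#' @export
confusion_counts <- function(TP, FP, TN, FN, positive = "neutral") {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN, positive = positive),
            class = "cp_confusion")
}

#' @export
print.cp_confusion <- function(x, ...) {
  cat(sprintf("<cp_confusion> (positive = %s) TP=%d FP=%d TN=%d FN=%d\n",
              x$positive, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in
#' `[-1, 1]`.  When any marginal is zero the denominator vanishes and the
#' value is undefined: `NA` is returned with attribute `undefined = TRUE`.
#'
#' @param cm A `cp_confusion` object.
#' @return MCC (numeric scalar, possibly `NA`).
#' @export
mcc <- function(cm) {
  with(cm, {
    den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
    if (den == 0) return(structure(NA_real_, undefined = TRUE))
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / den
  })
}

safe_div <- function(a, b) if (b == 0) NA_real_ else a / b

#' Per-class classification metrics
#'
#' Standard definitions, reported for both class views: Class 1 treats the
#' confusion matrix's positive class (neutral) as positive; Class 0 swaps
#' the roles.  Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP), F1 = harmonic mean of precision and sensitivity,
#' accuracy = (TP+TN)/total.  Divisions by zero yield `NA`.
#'
#' @param cm A `cp_confusion` object.
#' @return List: `mcc`, `accuracy`, and per-class `sensitivity`,
#'   `specificity`, `precision`, `f1` (named vectors with entries `class1`
#'   and `class0`).
#' @export
classification_metrics <- function(cm) {
  one <- function(TP, FP, TN, FN) {
    sens <- safe_div(TP, TP + FN)
    spec <- safe_div(TN, TN + FP)
    prec <- safe_div(TP, TP + FP)
    f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
  }
  c1 <- one(cm$TP, cm$FP, cm$TN, cm$FN)
  c0 <- one(cm$TN, cm$FN, cm$TP, cm$FP)  # swap class roles
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  list(mcc = as.numeric(mcc(cm)),
       accuracy = safe_div(cm$TP + cm$TN, total),
       sensitivity = c(class1 = unname(c1["sensitivity"]),
                       class0 = unname(c0["sensitivity"])),
       specificity = c(class1 = unname(c1["specificity"]),
                       class0 = unname(c0["specificity"])),
       precision = c(class1 = unname(c1["precision"]),
                     class0 = unname(c0["precision"])),
       f1 = c(class1 = unname(c1["f1"]), class0 = unname(c0["f1"])))
}

#' Spearman rank correlation
#'
#' `rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))` with `d` the rank differences.
#' Tied values receive midranks; since the plain formula assumes distinct
#' ranks, tied inputs are evaluated as the Pearson correlation of the
#' midranks (the two coincide exactly when there are no ties).
#'
#' @param actual,predicted Numeric vectors of equal length `n >= 2`.
#' @return rho, or `NA` with attribute `undefined = TRUE` when either
#'   vector is constant.
#' @export
spearman_rho <- function(actual, predicted) {
  n <- length(actual)
  stopifnot(n == length(predicted), n >= 2)
  rx <- rank(actual, ties.method = "average")
  ry <- rank(predicted, ties.method = "average")
  if (length(unique(rx)) == 1L || length(unique(ry)) == 1L)
    return(structure(NA_real_, undefined = TRUE))
  ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  if (!ties) {
    d <- rx - ry
    return(1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }
  # Pearson on midranks, written out
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

#' Grid-search training of weights and threshold
#'
#' Exhaustive scan of the linear-combination coefficients (each sampled over
#' `weight_range` in steps of `weight_step`; defaults give 13 values per
#' axis) and the classification threshold (`threshold_range` in steps of
#' `threshold_step`; default 21 values), maximising the MCC of the induced
#' neutral/destabilizing calls.  Ties are broken toward the
#' lexicographically smallest `(w_s, w_h, w_f, threshold)`.
#'
#' @param features Data frame or matrix with columns `S`, `H`, `F` (one row
#'   per mutation).
#' @param truth Character vector of true labels.
#' @param weight_range,weight_step Weight axis sampling (default 0-3 by
#'   0.25).
#' @param threshold_range,threshold_step Threshold sampling (default 0-2 by
#'   0.1).
#' @param return_surface If TRUE, the full score surface (one row per grid
#'   point with its MCC) is attached as `$surface`.
#' @return List: `weights` (a [score_weights()] object), `mcc`, `grid_dim`
#'   (named vector with the number of values per axis), and optionally
#'   `surface`.
#' @export
grid_search_weights <- function(features, truth,
                                weight_range = c(0, 3), weight_step = 0.25,
                                threshold_range = c(0, 2),
                                threshold_step = 0.1,
                                return_surface = FALSE) {
  X <- as.matrix(as.data.frame(features)[, c("S", "H", "F")])
  storage.mode(X) <- "double"
  if (!all(truth %in% LABELS)) stop("labels must be neutral/destabilizing")
  y <- truth == "neutral"
  if (all(y) || !any(y))
    stop("need at least one mutation of each class")

  wvals <- seq(weight_range[1], weight_range[2], by = weight_step)
  tvals <- seq(threshold_range[1], threshold_range[2], by = threshold_step)
  # lexicographic order: w_s slowest, threshold fastest
  W <- as.matrix(expand.grid(w_f = wvals, w_h = wvals, w_s = wvals))
  W <- W[, c("w_s", "w_h", "w_f"), drop = FALSE]
  ord <- order(W[, 1], W[, 2], W[, 3])
  W <- W[ord, , drop = FALSE]

  scores <- X %*% t(W)  # n x n_triples
  npos <- sum(y)
  nneg <- sum(!y)
  best <- list(mcc = -Inf, i = NA, t = NA)
  surface <- if (return_surface) vector("list", length(tvals)) else NULL
  for (k in seq_along(tvals)) {
    P <- scores > tvals[k]
    TP <- colSums(P[y, , drop = FALSE])
    FP <- colSums(P[!y, , drop = FALSE])
    FN <- npos - TP
    TN <- nneg - FP
    den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
    m <- ifelse(den == 0, NA_real_, (TP * TN - FP * FN) / den)
    if (return_surface)
      surface[[k]] <- data.frame(w_s = W[, 1], w_h = W[, 2], w_f = W[, 3],
                                 threshold = tvals[k], mcc = m)
    m2 <- ifelse(is.na(m), -Inf, m)
    i <- which.max(m2)  # first max = smallest triple within this threshold
    # lexicographic tie-break on (w_s, w_h, w_f, threshold): the triple is
    # more significant than the threshold, and k only increases, so update
    # on a strictly better MCC or an equal MCC at a smaller triple index
    if (m2[i] > best$mcc || (m2[i] == best$mcc && !is.na(best$i) &&
                             i < best$i)) {
      best <- list(mcc = m2[i], i = i, t = tvals[k])
    }
  }
  out <- list(
    weights = score_weights(W[best$i, 1], W[best$i, 2], W[best$i, 3],
                            threshold = best$t),
    mcc = best$mcc,
    grid_dim = c(w_s = length(wvals), w_h = length(wvals),
                 w_f = length(wvals), threshold = length(tvals)))
  if (return_surface) out$surface <- do.call(rbind, surface)
  out
}

#' Category-stratified accuracy
#'
#' Fraction of correct predictions per category (e.g. depth zone, wild-type
#' amino acid, or wild-type/mutant pair).
#'
#' @param truth,pred Label vectors.
#' @param category Character vector of category assignments (same length).
#' @return Data frame: `category`, `n`, `correct`, `accuracy`.
#' @export
stratified_accuracy <- function(truth, pred, category) {
  stopifnot(length(truth) == length(pred),
            length(truth) == length(category))
  correct <- truth == pred
  cats <- sort(unique(category))
  out <- data.frame(
    category = cats,
    n = vapply(cats, function(g) sum(category == g), integer(1)),
    correct = vapply(cats, function(g) sum(correct[category == g]),
                     integer(1)),
    stringsAsFactors = FALSE)
  out$accuracy <- out$correct / out$n
  rownames(out) <- NULL
  out
}

#' Best-method-per-category meta prediction
#'
#' For every category (wild-type amino acid, or wild-type/mutant pair
#' crossed with depth zone) the individual method with the highest category
#' accuracy is selected; ties go to the method with the better overall MCC.
#' The meta prediction routes each mutation to its category's method and is
#' scored on the same set (an in-sample construction that bounds, rather
#' than estimates, attainable performance).
#'
#' @param truth Label vector.
#' @param predictions Data frame: one column of labels per method.
#' @param category Category assignment per mutation.
#' @return List: `selection` (data frame `category`, `method`, `accuracy`,
#'   `tie`, `fallback`), `meta_pred` (label vector), `cm` (meta confusion
#'   matrix), `mcc`, `method_mcc` (overall MCC per method).
#' @export
meta_select <- function(truth, predictions, category) {
  predictions <- as.data.frame(predictions, stringsAsFactors = FALSE)
  methods <- names(predictions)
  if (length(methods) < 2L) stop("need at least two methods")
  overall_mcc <- vapply(methods, function(m) {
    as.numeric(mcc(confusion_matrix(truth, predictions[[m]])))
  }, numeric(1))
  best_overall <- methods[order(-overall_mcc)][1]

  cats <- sort(unique(category))
  sel <- data.frame(category = cats, method = NA_character_,
                    accuracy = NA_real_, tie = FALSE, fallback = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cats)) {
    in_cat <- category == cats[i]
    if (!any(in_cat)) {  # unreachable for categories drawn from the data,
      sel$method[i] <- best_overall  # kept for externally supplied levels
      sel$fallback[i] <- TRUE
      next
    }
    acc <- vapply(methods, function(m) {
      mean(predictions[[m]][in_cat] == truth[in_cat])
    }, numeric(1))
    top <- which(acc == max(acc))
    sel$tie[i] <- length(top) > 1L
    if (length(top) > 1L) {
      top <- top[which.max(overall_mcc[top])]
    }
    sel$method[i] <- methods[top]
    sel$accuracy[i] <- acc[methods[top]]
  }
  meta_pred <- character(length(truth))
  for (i in seq_along(cats)) {
    in_cat <- category == cats[i]
    meta_pred[in_cat] <- predictions[[sel$method[i]]][in_cat]
  }
  cm <- confusion_matrix(truth, meta_pred)
  list(selection = sel, meta_pred = meta_pred, cm = cm,
       mcc = as.numeric(mcc(cm)),
       method_mcc = stats::setNames(overall_mcc, methods))
}

#' Mutational-sensitivity score to label
#'
#' Experimental mutational-sensitivity (MS) grades map to binary labels:
#' MS = 2 (no perceptible phenotypic difference from wild type) is neutral,
#' MS > 2 is destabilizing.
#'
#' @param ms Numeric vector of MS grades (>= 2).
#' @return Label vector.
#' @export
ms_to_label <- function(ms) {
  if (any(ms < 2)) stop("MS grades start at 2")
  ifelse(ms == 2, "neutral", "destabilizing")
}
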