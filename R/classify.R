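# Group-comparison schemes, MLP/SVM training with classical data-mining
# toolkit conventions, stratified
# cross-validation, and the full per-class metric panel (TP/FP rate,
# precision, recall, F, MCC, ROC and PRC areas, confusion matrix).

#' Build the group-comparison schemes
#'
#' For `g >= 3` groups returns, in order: one all-groups scheme, `g`
#' one-vs-rest schemes (`"X vs Others"`), and `choose(g, 2)` pairwise
#' schemes — 11 schemes for the four study groups. For exactly two groups
#' the single pairwise scheme is returned.
#'
#' @param groups character vector of distinct group labels (>= 2).
#' @return list of `comparison_scheme` objects, each with `name` and
#'   `mapping` (named character: group -> scheme class, `NA` = excluded).
#' @examples
#' length(build_comparisons(c("addict", "first", "second", "normal")))  # 11
#' @export
build_comparisons <- function(groups = c("addict", "first", "second", "normal")) {
  groups <- unique(as.character(groups))
  g <- length(groups)
  if (g < 2L) stop_input("need at least two group labels")
  scheme <- function(name, mapping)
    structure(list(name = name, mapping = mapping), class = "comparison_scheme")
  out <- list()
  if (g >= 3L) {
    out[[length(out) + 1L]] <-
      scheme("All", stats::setNames(groups, groups))
    for (gr in groups) {
      m <- stats::setNames(rep("Others", g), groups)
      m[gr] <- gr
      out[[length(out) + 1L]] <- scheme(paste(gr, "vs Others"), m)
    }
  }
  pairs <- utils::combn(groups, 2)
  for (j in seq_len(ncol(pairs))) {
    m <- stats::setNames(rep(NA_character_, g), groups)
    m[pairs[1, j]] <- pairs[1, j]
    m[pairs[2, j]] <- pairs[2, j]
    out[[length(out) + 1L]] <- scheme(paste(pairs[1, j], "vs", pairs[2, j]), m)
  }
  out
}

#' @export
print.comparison_scheme <- function(x, ...) {
  inc <- !is.na(x$mapping)
  cat(sprintf("<comparison_scheme> %s: %s\n", x$name,
              paste(sprintf("%s->%s", names(x$mapping)[inc], x$mapping[inc]),
                    collapse = ", ")))
  invisible(x)
}

# Apply a scheme to raw group labels -> factor with excluded groups as NA.
apply_scheme <- function(labels, scheme) {
  m <- scheme$mapping[as.character(labels)]
  factor(unname(m), levels = unique(stats::na.omit(unname(scheme$mapping))))
}

#' Metric panel from a confusion matrix
#'
#' Per class `i` (one-vs-rest on the c x c matrix, rows = true class,
#' columns = predicted): `TP = cm[i,i]`, `FN = rowsum - TP`,
#' `FP = colsum - TP`, `TN = total - TP - FN - FP`; TP rate (= recall)
#' `TP/(TP+FN)`, FP rate `FP/(FP+TN)`, precision `TP/(TP+FP)`,
#' `F = 2PR/(P+R)`, and the Matthews correlation coefficient. Undefined 0/0
#' ratios are reported as 0. Weighted averages use true-class frequencies.
#'
#' @param cm square matrix of non-negative integer counts; rows are true
#'   classes, columns predicted. Dimnames, if present, name the classes.
#' @return object of class `metric_panel`: `per_class` data.frame,
#'   `weighted` named vector, `confusion` matrix.
#' @examples
#' metrics_from_confusion(matrix(c(18, 1, 1, 30), 2, byrow = TRUE))
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0) || any(cm != floor(cm)))
    stop_input("'cm' must be a square matrix of non-negative integer counts")
  total <- sum(cm)
  if (total <= 0) stop_input("'cm' has no counts")
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  div0 <- function(num, den) ifelse(den == 0, 0, num / den)
  per <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    prec <- div0(tp, tp + fp)
    rec <- div0(tp, tp + fn)
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    data.frame(class = classes[i],
               tp_rate = rec,
               fp_rate = div0(fp, fp + tn),
               precision = prec,
               recall = rec,
               f_measure = div0(2 * prec * rec, prec + rec),
               mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  wts <- rowSums(cm) / total
  weighted <- vapply(per[, -1], function(col) sum(wts * col), numeric(1))
  structure(list(per_class = per, weighted = weighted, confusion = cm,
                 n = total), class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, digits = 2, ...) {
  cat(sprintf("<metric_panel> n = %d\n", x$n))
  tab <- x$per_class
  tab[-1] <- round(tab[-1], digits)
  print(tab, row.names = FALSE)
  cat("weighted:", paste(sprintf("%s=%.*f", names(x$weighted), digits,
                                 x$weighted), collapse = " "), "\n")
  invisible(x)
}

# ROC area (pROC) and PRC area (step integration over the pooled scores),
# one-vs-rest per class, appended to a metric panel.
add_score_areas <- function(panel, truth, prob) {
  classes <- panel$per_class$class
  roc <- prc <- numeric(length(classes))
  for (i in seq_along(classes)) {
    resp <- as.integer(truth == classes[i])
    sc <- prob[, classes[i]]
    if (length(unique(resp)) < 2L) { roc[i] <- prc[i] <- 0; next }
    roc[i] <- as.numeric(pROC::auc(pROC::roc(resp, sc, quiet = TRUE,
                                             direction = "<", levels = c(0, 1))))
    prc[i] <- prc_area(resp, sc)
  }
  panel$per_class$roc_area <- roc
  panel$per_class$prc_area <- prc
  wts <- rowSums(panel$confusion) / panel$n
  panel$weighted <- c(panel$weighted,
                      roc_area = sum(wts * roc), prc_area = sum(wts * prc))
  panel
}

# Area under the precision-recall curve: step integration, precision summed
# over the recall increments of the descending-score sweep.
prc_area <- function(resp, score) {
  ord <- order(score, decreasing = TRUE)
  resp <- resp[ord]
  tp <- cumsum(resp)
  fp <- cumsum(1 - resp)
  pos <- sum(resp)
  if (pos == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / pos
  # collapse tied scores to their last point
  keep <- c(diff(score[ord]) != 0, TRUE)
  prec <- prec[keep]; rec <- rec[keep]
  sum(diff(c(0, rec)) * prec)
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}
standardize_apply <- function(x, s) scale(x, center = s$center, scale = s$scale)

#' Train an MLP classifier (classical toolkit-convention defaults)
#'
#' One hidden layer with `ceiling((p + #classes) / 2)` logistic units, inputs
#' standardized, softmax output, 500 training iterations. Deterministic under
#' the caller's RNG state (weight initialization is random).
#'
#' @param x numeric matrix / data.frame of predictors.
#' @param y class labels (>= 2 classes).
#' @param hidden hidden-unit count; default the (p + classes)/2 rule.
#' @param maxit training iterations (default 500).
#' @param decay weight decay (default 0).
#' @return object of class `eegfd_mlp`.
#' @export
train_mlp <- function(x, y, hidden = NULL, maxit = 500, decay = 0) {
  x <- as.matrix(as.data.frame(x))
  if (!all(is.finite(x))) stop_input("non-finite features")
  y <- factor(y)
  if (nlevels(y) < 2L) stop_input("need at least two classes")
  s <- standardize_fit(x)
  xs <- standardize_apply(x, s)
  hidden <- hidden %||% ceiling((ncol(x) + nlevels(y)) / 2)
  fit <- nnet::nnet(xs, nnet::class.ind(y), size = hidden, softmax = TRUE,
                    maxit = maxit, decay = decay, trace = FALSE,
                    MaxNWts = 100000)
  structure(list(fit = fit, scaler = s, levels = levels(y)),
            class = "eegfd_mlp")
}

#' @export
predict.eegfd_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- standardize_apply(as.matrix(as.data.frame(newdata)), object$scaler)
  p <- stats::predict(object$fit, xs)
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  factor(object$levels[max.col(p, ties.method = "first")], levels = object$levels)
}

#' Train an SVM classifier (RBF kernel, library defaults)
#'
#' Radial-basis SVM with default kernel scale (`gamma = 1/p`) and cost 1,
#' one-vs-one for multi-class, with pairwise-coupled probability estimates
#' (approximate, used for ROC/PRC areas).
#'
#' @inheritParams train_mlp
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost soft-margin cost (default 1).
#' @return object of class `eegfd_svm`.
#' @export
train_svm <- function(x, y, kernel = c("radial", "linear"), cost = 1) {
  kernel <- match.arg(kernel)
  x <- as.matrix(as.data.frame(x))
  if (!all(is.finite(x))) stop_input("non-finite features")
  y <- factor(y)
  if (nlevels(y) < 2L) stop_input("need at least two classes")
  fit <- e1071::svm(x, y, kernel = kernel, cost = cost, probability = TRUE)
  structure(list(fit = fit, levels = levels(y)), class = "eegfd_svm")
}

#' @export
predict.eegfd_svm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(as.data.frame(newdata))
  pr <- stats::predict(object$fit, newdata, probability = TRUE)
  if (type == "class") return(factor(as.character(pr), levels = object$levels))
  p <- attr(pr, "probabilities")
  p[, object$levels, drop = FALSE]
}

#' Stratified cross-validated classification for one scheme
#'
#' Applies the comparison scheme to the labels (dropping excluded groups),
#' splits the instances into stratified folds, and within each training fold
#' fits the optional partition-membership transform and the classifier;
#' held-out predictions are pooled into one confusion matrix and metric
#' panel. All fold-level fitting (partition, scaling, model) sees training
#' data only. Deterministic given `seed`.
#'
#' @param features n x p numeric table (raw attributes).
#' @param labels group labels, length n.
#' @param scheme a `comparison_scheme` (default: all groups as-is).
#' @param model `"mlp"` or `"svm"`.
#' @param k folds (default 10); reduced with a warning if the rarest class
#'   has fewer members.
#' @param seed integer seed.
#' @param transform `"none"`, `"crisp"`, or `"graded"` partition-membership
#'   preprocessing fitted per training fold.
#' @param ... passed to [train_mlp()] / [train_svm()].
#' @return a `metric_panel` with ROC/PRC areas; attribute `"folds"` records
#'   the fold count used.
#' @export
cross_validate <- function(features, labels, scheme = NULL,
                           model = c("mlp", "svm"), k = 10, seed = 1,
                           transform = c("none", "crisp", "graded"), ...) {
  model <- match.arg(model)
  transform <- match.arg(transform)
  features <- as.data.frame(features)
  y_all <- if (is.null(scheme)) factor(labels) else apply_scheme(labels, scheme)
  inc <- !is.na(y_all)
  x <- features[inc, , drop = FALSE]
  y <- droplevels(y_all[inc])
  if (nlevels(y) < 2L) stop_input("scheme leaves fewer than two classes")
  min_class <- min(table(y))
  if (min_class < k) {
    warning(sprintf("smallest class has %d members; reducing folds from %d",
                    min_class, k))
    k <- max(2L, min_class)
  }
  with_seed(seed, {
    fold <- integer(nrow(x))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    pred <- factor(rep(NA_character_, nrow(x)), levels = levels(y))
    prob <- matrix(NA_real_, nrow(x), nlevels(y),
                   dimnames = list(NULL, levels(y)))
    for (f in seq_len(k)) {
      tr <- fold != f
      xtr <- x[tr, , drop = FALSE]
      xte <- x[!tr, , drop = FALSE]
      if (transform != "none") {
        pm <- fit_partition(xtr, y[tr], mode = transform)
        xtr <- transform_dataset(xtr, model = pm)
        xte <- transform_dataset(xte, model = pm)
      }
      fitted <- if (model == "mlp") train_mlp(xtr, y[tr], ...) else
        train_svm(xtr, y[tr], ...)
      pred[!tr] <- stats::predict(fitted, xte, type = "class")
      prob[!tr, ] <- stats::predict(fitted, xte, type = "prob")
    }
    cm <- table(true = y, predicted = pred)
    panel <- metrics_from_confusion(unclass(cm))
    panel <- add_score_areas(panel, y, prob)
    attr(panel, "folds") <- k
    panel
  })
}

#' Run every comparison scheme
#'
#' [cross_validate()] over all schemes from [build_comparisons()], for one or
#' more models, returning a summary table plus all panels. The best model per
#' scheme is flagged by weighted F-measure (selection rule stated in the
#' output column `best`).
#'
#' @inheritParams cross_validate
#' @param models character vector among `"mlp"`, `"svm"`.
#' @return list: `panels` (nested scheme -> model), `summary` data.frame.
#' @export
classify_all_schemes <- function(features, labels, models = c("mlp", "svm"),
                                 k = 10, seed = 1,
                                 transform = c("crisp", "none", "graded")) {
  transform <- match.arg(transform)
  schemes <- build_comparisons(sort(unique(as.character(labels))))
  panels <- list()
  rows <- list()
  for (s in schemes) {
    panels[[s$name]] <- list()
    for (m in models) {
      pn <- withCallingHandlers(
        cross_validate(features, labels, scheme = s, model = m, k = k,
                       seed = child_seed(seed, "classify"),
                       transform = transform),
        warning = function(w) invokeRestart("muffleWarning"))
      panels[[s$name]][[m]] <- pn
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = s$name, model = m, transform = transform,
        n = pn$n, folds = attr(pn, "folds"),
        weighted_f = pn$weighted[["f_measure"]],
        weighted_mcc = pn$weighted[["mcc"]],
        weighted_roc = pn$weighted[["roc_area"]],
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  summary$best <- ave(summary$weighted_f, summary$scheme,
                      FUN = function(v) v == max(v)) == 1
  list(panels = panels, summary = summary)
}
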