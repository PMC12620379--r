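# Fuzzy partition-membership feature processing.
#
# A partition generator (a Gini decision tree) carves the feature space into
# axis-aligned cells (the leaves). Each instance is then re-expressed as its
# vector of membership degrees in those cells: crisp mode gives the one-hot
# leaf indicator; graded mode softens every split with a logistic activation
# so membership is a genuine fuzzy degree in [0,1]. In both modes the leaf
# degrees of an instance sum to one, so the transform is a fuzzy partition of
# unity over the feature space.

#' Fit a partition generator on a labelled feature table
#'
#' Fits a classification tree (Gini impurity, configurable minimum leaf size
#' and depth, no pruning) and extracts its split structure into a
#' `partition_model`: an ordered set of leaf cells, each defined by the
#' conjunction of threshold predicates along its path. Deterministic given
#' the data and settings.
#'
#' A single-class input cannot be partitioned and yields a one-cell model
#' with a `degenerate-partition` warning.
#'
#' @param features numeric data.frame or matrix, n x p.
#' @param labels class labels, length n (>= 2 distinct values for a
#'   non-degenerate partition).
#' @param min_leaf minimum instances per leaf (default 2).
#' @param max_depth maximum tree depth (default 30, effectively unlimited).
#' @param mode `"crisp"` (hard cells) or `"graded"` (logistic-softened
#'   splits). The mode is carried in the model and used by [membership()].
#' @param bandwidth `"auto"` (0.25 x per-feature interquartile range, the
#'   softness scale of each split in graded mode) or a positive number used
#'   for every split.
#' @return object of class `partition_model` with elements `nodes`
#'   (data.frame of tree nodes), `n_cells`, `feature_names`, `mode`,
#'   `bandwidths`.
#' @export
fit_partition <- function(features, labels, min_leaf = 2, max_depth = 30,
                          mode = c("crisp", "graded"), bandwidth = "auto") {
  mode <- match.arg(mode)
  features <- as.data.frame(features)
  if (nrow(features) == 0L || ncol(features) == 0L)
    stop_input("empty feature table")
  if (length(labels) != nrow(features))
    stop_input("labels length must match the number of rows")
  fnames <- colnames(features)
  safe <- paste0("f", seq_along(fnames))   # immune to non-syntactic names
  colnames(features) <- safe
  y <- factor(labels)

  if (nlevels(y) < 2L) {
    warning("degenerate-partition: single class, returning a one-cell model")
    return(new_partition_model(nodes = NULL, fnames = fnames, mode = mode,
                               features = features, bandwidth = bandwidth))
  }
  df <- cbind(features, .class = y)
  fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        minsplit = 2L * min_leaf, minbucket = min_leaf,
                        cp = 0, maxdepth = max_depth, xval = 0,
                        maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
  nodes <- parse_rpart(fit)
  new_partition_model(nodes, fnames, mode, features, bandwidth)
}

# Turn an rpart frame + splits matrix into a flat node table.
# rpart node numbering: children of node n are 2n and 2n+1.
parse_rpart <- function(fit) {
  fr <- fit$frame
  ids <- as.integer(rownames(fr))
  is_leaf <- fr$var == "<leaf>"
  if (all(is_leaf)) return(NULL)
  sp <- fit$splits
  # with maxcompete = maxsurrogate = 0, internal frame rows map 1:1 to split rows
  srow <- cumsum(!is_leaf)
  nodes <- data.frame(
    id = ids,
    is_leaf = is_leaf,
    var = NA_integer_,
    threshold = NA_real_,
    lt_goes_left = NA,
    leaf_index = NA_integer_
  )
  for (i in seq_along(ids)) {
    if (!is_leaf[i]) {
      r <- srow[i]
      nodes$var[i] <- match(as.character(fr$var[i]), attr(fit$terms, "term.labels"))
      nodes$threshold[i] <- sp[r, "index"]
      # ncat == -1: x < threshold goes left; +1: x >= threshold goes left
      nodes$lt_goes_left[i] <- sp[r, "ncat"] < 0
    }
  }
  nodes$leaf_index[is_leaf] <- seq_len(sum(is_leaf))
  nodes
}

new_partition_model <- function(nodes, fnames, mode, features, bandwidth) {
  n_cells <- if (is.null(nodes)) 1L else sum(nodes$is_leaf)
  bw <- NULL
  if (!is.null(nodes)) {
    if (identical(bandwidth, "auto")) {
      iqr <- vapply(seq_along(fnames),
                    function(j) stats::IQR(features[[j]]), numeric(1))
      scale <- 0.25 * iqr
      # guard degenerate features: fall back to 0.25 * sd, then a small constant
      sdv <- vapply(seq_along(fnames),
                    function(j) stats::sd(features[[j]]), numeric(1))
      scale[scale <= 0] <- 0.25 * sdv[scale <= 0]
      scale[scale <= 0 | !is.finite(scale)] <- 1e-6
      bw <- scale[nodes$var]
    } else {
      if (!is.numeric(bandwidth) || bandwidth <= 0)
        stop_invalid("'bandwidth' must be \"auto\" or a positive number")
      bw <- rep(bandwidth, nrow(nodes))
    }
    bw[nodes$is_leaf] <- NA_real_
  }
  structure(list(nodes = nodes, n_cells = n_cells, feature_names = fnames,
                 mode = mode, bandwidths = bw),
            class = "partition_model")
}

#' @export
print.partition_model <- function(x, ...) {
  cat(sprintf("<partition_model> %d cell(s), %s membership, %d features\n",
              x$n_cells, x$mode, length(x$feature_names)))
  invisible(x)
}

#' Membership degrees of one instance
#'
#' Crisp mode: degree 1 for the unique leaf cell containing the instance,
#' 0 elsewhere. Graded mode: the degree of a leaf is the product along its
#' path of logistic split activations `sigma(+/-(x_f - t) / bandwidth)`; at a
#' threshold both sides receive 0.5, and as bandwidth shrinks the degrees
#' converge to the crisp assignment. In both modes the degrees over all
#' leaves sum to 1.
#'
#' @param instance numeric vector of length p (model feature order).
#' @param model a [fit_partition()] model.
#' @return numeric vector of length `model$n_cells` named `cell_1 ...`;
#'   attribute `"nonzero"` lists the indices of nonzero degrees (the sparse
#'   representation).
#' @export
membership <- function(instance, model) {
  stopifnot(inherits(model, "partition_model"))
  instance <- as.numeric(instance)
  if (length(instance) != length(model$feature_names))
    stop_input(sprintf("instance has %d values, model expects %d",
                       length(instance), length(model$feature_names)))
  deg <- numeric(model$n_cells)
  if (model$n_cells == 1L) {
    deg[1] <- 1
  } else {
    nodes <- model$nodes
    row_of <- match(seq_len(max(nodes$id)), nodes$id)
    walk <- function(id, weight) {
      i <- row_of[id]
      if (nodes$is_leaf[i]) {
        deg[nodes$leaf_index[i]] <<- deg[nodes$leaf_index[i]] + weight
        return(invisible())
      }
      x <- instance[nodes$var[i]]
      t <- nodes$threshold[i]
      if (model$mode == "crisp") {
        left <- if (nodes$lt_goes_left[i]) x < t else x >= t
        walk(if (left) 2L * id else 2L * id + 1L, weight)
      } else {
        bw <- model$bandwidths[i]
        a_left <- stats::plogis(if (nodes$lt_goes_left[i]) (t - x) / bw else (x - t) / bw)
        if (a_left > 0) walk(2L * id, weight * a_left)
        if (a_left < 1) walk(2L * id + 1L, weight * (1 - a_left))
      }
    }
    walk(1L, 1)
  }
  names(deg) <- paste0("cell_", seq_along(deg))
  attr(deg, "nonzero") <- which(deg > 0)
  deg
}

#' Partition-membership transform of a dataset
#'
#' Maps every row of a feature table to its vector of cell membership
#' degrees, preserving row count and appending the class attribute unchanged.
#' Crisp models produce a one-hot leaf encoding; graded models a dense fuzzy
#' embedding whose rows still sum to 1.
#'
#' @param features n x p table in the model's feature order.
#' @param labels class labels carried through (may be `NULL`).
#' @param model a [fit_partition()] model.
#' @return data.frame with columns `cell_1 ... cell_K` and, if given,
#'   `class`.
#' @export
transform_dataset <- function(features, labels = NULL, model) {
  stopifnot(inherits(model, "partition_model"))
  features <- as.matrix(as.data.frame(features))
  if (ncol(features) != length(model$feature_names))
    stop_input("feature count does not match the fitted model")
  m <- t(apply(features, 1, function(r) as.numeric(membership(r, model))))
  if (model$n_cells == 1L) m <- matrix(m, ncol = 1L)  # apply() drops dims
  colnames(m) <- paste0("cell_", seq_len(model$n_cells))
  out <- as.data.frame(m)
  if (!is.null(labels)) {
    if (length(labels) != nrow(out))
      stop_input("labels length must match the number of rows")
    out$class <- labels
  }
  out
}

#' Write a membership table in sparse coordinate format
#'
#' One line per nonzero degree: `row, cell, degree` (plus a class column per
#' row when labels are present in the table).
#'
#' @param transformed output of [transform_dataset()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_membership_coo <- function(transformed, path) {
  cells <- grep("^cell_", names(transformed))
  m <- as.matrix(transformed[, cells, drop = FALSE])
  nz <- which(m != 0, arr.ind = TRUE)
  out <- data.frame(row = nz[, 1], cell = nz[, 2], degree = m[nz])
  out <- out[order(out$row, out$cell), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
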