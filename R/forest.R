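#' Number of candidate attributes per tree node
#'
#' The number of features examined at each decision node is
#' `max(1, floor(log2(M + 1)))` for M features in total, the classic forest
#' default.
#'
#' @param m_features Total feature count M (>= 1).
#' @return Integer m, with 1 <= m <= M.
#' @export
attributes_per_node <- function(m_features) {
  if (any(m_features < 1)) stop("M must be >= 1", call. = FALSE)
  pmin(as.integer(m_features), pmax(1L, as.integer(floor(log2(m_features + 1)))))
}

node_impurity <- function(cnt_rows, n_rows, split = "gain") {
  p <- cnt_rows / n_rows
  if (split == "gini") {
    1 - rowSums(p^2)
  } else {
    -rowSums(ifelse(p > 0, p * log2(p), 0))
  }
}

# Best (feature, threshold) among `feats` for rows `idx`, by impurity
# decrease. Thresholds are midpoints between consecutive distinct sorted
# values. Returns NULL when no candidate improves on the parent.
best_split <- function(X, yi, idx, feats, K, split) {
  n <- length(idx)
  y_node <- yi[idx]
  cnt_parent <- tabulate(y_node, K)
  imp_parent <- node_impurity(matrix(cnt_parent, 1), n, split)
  best <- list(gain = 1e-12, feature = NA_integer_, threshold = NA_real_)
  for (f in feats) {
    x <- X[idx, f]
    o <- order(x, method = "radix")
    xs <- x[o]
    ys <- y_node[o]
    pos <- which(diff(xs) > 0)
    if (length(pos) == 0L) next
    cum <- vapply(seq_len(K), function(k) cumsum(ys == k),
                  numeric(n))
    left_cnt <- cum[pos, , drop = FALSE]
    nl <- pos
    nr <- n - pos
    right_cnt <- matrix(cnt_parent, length(pos), K, byrow = TRUE) - left_cnt
    gain <- imp_parent -
      (nl / n) * node_impurity(left_cnt, nl, split) -
      (nr / n) * node_impurity(right_cnt, nr, split)
    k <- which.max(gain)
    if (gain[k] > best$gain) {
      best <- list(gain = gain[k], feature = f,
                   threshold = (xs[pos[k]] + xs[pos[k] + 1]) / 2)
    }
  }
  if (is.na(best$feature)) NULL else best
}

# Grow one unpruned tree on rows `rows` (bootstrap indices). Consumes the
# current RNG stream for per-node feature draws. Flat representation:
# parallel vectors + a counts matrix for leaves (zero rows for internals).
grow_tree <- function(X, yi, rows, m, K, split) {
  env <- new.env(parent = emptyenv())
  env$feature <- integer()
  env$threshold <- numeric()
  env$left <- integer()
  env$right <- integer()
  env$counts <- list()
  M <- ncol(X)
  build <- function(idx) {
    id <- length(env$feature) + 1L
    env$feature[id] <- NA_integer_
    env$threshold[id] <- NA_real_
    env$left[id] <- 0L
    env$right[id] <- 0L
    cnt <- tabulate(yi[idx], K)
    env$counts[[id]] <- cnt
    if (max(cnt) < length(idx)) { # impure: try to split
      feats <- sample.int(M, m)
      sp <- best_split(X, yi, idx, feats, K, split)
      if (!is.null(sp)) {
        go_left <- X[idx, sp$feature] <= sp$threshold
        env$feature[id] <- sp$feature
        env$threshold[id] <- sp$threshold
        env$left[id] <- build(idx[go_left])
        env$right[id] <- build(idx[!go_left])
      }
    }
    id
  }
  build(rows)
  list(feature = env$feature, threshold = env$threshold,
       left = env$left, right = env$right,
       counts = do.call(rbind, env$counts))
}

tree_leaf_proba <- function(tree, X) {
  n <- nrow(X)
  K <- ncol(tree$counts)
  P <- matrix(0, n, K)
  stack <- list(list(node = 1L, rows = seq_len(n)))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(top$rows) == 0L) next
    nd <- top$node
    if (tree$left[nd] == 0L) { # leaf
      cnt <- tree$counts[nd, ]
      P[top$rows, ] <- matrix(cnt / sum(cnt), length(top$rows), K, byrow = TRUE)
    } else {
      go_left <- X[top$rows, tree$feature[nd]] <= tree$threshold[nd]
      stack[[length(stack) + 1L]] <- list(node = tree$left[nd],
                                          rows = top$rows[go_left])
      stack[[length(stack) + 1L]] <- list(node = tree$right[nd],
                                          rows = top$rows[!go_left])
    }
  }
  P
}

resolve_features <- function(data, label, id_cols) {
  feats <- setdiff(names(data), c(label, id_cols))
  num <- vapply(data[feats], is.numeric, TRUE)
  feats[num]
}

#' Train a random forest of unpruned bagged trees
#'
#' Each tree is grown on a bootstrap sample (n draws with replacement) of
#' the training pairs. At every decision node, `mtry` candidate features are
#' drawn uniformly without replacement and the split maximising the impurity
#' decrease (information gain by default) over midpoint thresholds is taken;
#' recursion stops only at pure nodes or nodes where no candidate split
#' improves — there is no pruning, depth cap or minimum leaf size. Leaves
#' store raw class counts, so prediction can average leaf class ratios over
#' trees. Training is deterministic given `seed`.
#'
#' @param data Tibble of training pairs: one label column plus numeric
#'   feature columns (as produced by [make_pair_dataset()]).
#' @param label Name of the label column (default `"label"`).
#' @param trees Number of trees T (default 10).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param mtry Candidate features per node; default
#'   [attributes_per_node()]`(M)`.
#' @param split Split criterion, `"gain"` (information gain, default) or
#'   `"gini"`.
#' @param id_cols Non-feature columns to ignore (default
#'   `c("sid_a", "sid_b", "identity_pair_key")`).
#'
#' @return An object of class `sse_forest`: trees, class alphabet, feature
#'   names, `mtry`, seed, out-of-bag accuracy and layout version.
#' @export
train_forest <- function(data, label = "label", trees = 10L, seed = 1L,
                         mtry = NULL, split = c("gain", "gini"),
                         id_cols = c("sid_a", "sid_b", "identity_pair_key")) {
  split <- match.arg(split)
  stopifnot(nrow(data) > 0L, trees >= 1L, label %in% names(data))
  feats <- resolve_features(data, label, id_cols)
  X <- as.matrix(data[feats])
  if (anyNA(X)) stop("missing values in features", call. = FALSE)
  y <- data[[label]]
  classes <- if (is.factor(y)) {
    levels(y)
  } else if (all(y %in% PAIR_CLASSES)) {
    PAIR_CLASSES[PAIR_CLASSES %in% y]
  } else {
    sort(unique(as.character(y)))
  }
  yi <- match(as.character(y), classes)
  if (anyNA(yi)) {
    stop("labels outside the class set (note: the NA pair type is the ",
         "string \"NA\", not a missing value)", call. = FALSE)
  }
  K <- length(classes)
  n <- nrow(X)
  if (is.null(mtry)) mtry <- attributes_per_node(ncol(X))
  stopifnot(mtry >= 1L, mtry <= ncol(X))

  oob_P <- matrix(0, n, K)
  oob_hits <- integer(n)
  tree_list <- withr::with_seed(seed, {
    lapply(seq_len(trees), function(t) {
      boot <- sample.int(n, n, replace = TRUE)
      tr <- grow_tree(X, yi, boot, mtry, K, split)
      oob <- setdiff(seq_len(n), unique(boot))
      if (length(oob) > 0L) {
        oob_P[oob, ] <<- oob_P[oob, , drop = FALSE] +
          tree_leaf_proba(tr, X[oob, , drop = FALSE])
        oob_hits[oob] <<- oob_hits[oob] + 1L
      }
      tr
    })
  })
  covered <- oob_hits > 0L
  oob_acc <- if (any(covered)) {
    mean(max.col(oob_P[covered, , drop = FALSE], ties.method = "first") ==
           yi[covered])
  } else {
    NA_real_
  }
  structure(
    list(trees = tree_list, classes = classes, feature_names = feats,
         mtry = as.integer(mtry), n_train = n, seed = as.integer(seed),
         split = split, oob_accuracy = oob_acc, layout_version = "1"),
    class = "sse_forest"
  )
}

#' @export
print.sse_forest <- function(x, ...) {
  cat("Random forest for SCOP pair classification\n")
  cat(sprintf("  trees: %d, mtry: %d (of %d features), split: %s\n",
              length(x$trees), x$mtry, length(x$feature_names), x$split))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained on %d pairs, OOB accuracy %.3f\n",
              x$n_train, x$oob_accuracy))
  invisible(x)
}

#' Predict pair types with leaf-ratio averaging
#'
#' Each tree routes the feature vector to a leaf and reports the leaf's
#' class ratios (instances of each class over all instances that reached
#' the leaf); the forest probability is the unweighted mean of these T leaf
#' distributions, and the predicted label is the argmax (ties broken by
#' class-alphabet order).
#'
#' @param object An `sse_forest` model.
#' @param newdata Tibble containing the model's feature columns (extra
#'   columns are ignored).
#' @param ... Unused.
#'
#' @return A tibble with one row per input row: probability columns
#'   `p_<class>` (summing to 1), the argmax `label`, and its probability
#'   `p`.
#' @export
predict.sse_forest <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing) > 0L) {
    stop("newdata lacks model features: ", paste(head(missing, 3), collapse = ", "),
         if (length(missing) > 3) ", ...", call. = FALSE)
  }
  X <- as.matrix(newdata[object$feature_names])
  P <- Reduce(`+`, lapply(object$trees, function(t) tree_leaf_proba(t, X))) /
    length(object$trees)
  lab_i <- max.col(P, ties.method = "first")
  out <- as_tibble(as.data.frame(P))
  names(out) <- paste0("p_", object$classes)
  out$label <- object$classes[lab_i]
  out$p <- P[cbind(seq_len(nrow(P)), lab_i)]
  out
}

tree_depth <- function(tree) {
  depth <- function(nd) {
    if (tree$left[nd] == 0L) 1L
    else 1L + max(depth(tree$left[nd]), depth(tree$right[nd]))
  }
  depth(1L)
}

#' @rdname train_forest
#' @param x An `sse_forest` model.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per tree (`tree`, `n_nodes`,
#'   `n_leaves`, `depth`); `glance()`: a one-row model summary.
#' @method tidy sse_forest
#' @export
tidy.sse_forest <- function(x, ...) {
  tibble(
    tree = seq_along(x$trees),
    n_nodes = vapply(x$trees, function(t) length(t$feature), 1L),
    n_leaves = vapply(x$trees, function(t) sum(t$left == 0L), 1L),
    depth = vapply(x$trees, tree_depth, 1L)
  )
}

#' @rdname train_forest
#' @method glance sse_forest
#' @export
glance.sse_forest <- function(x, ...) {
  tibble(
    trees = length(x$trees), mtry = x$mtry,
    n_features = length(x$feature_names), n_train = x$n_train,
    n_classes = length(x$classes), oob_accuracy = x$oob_accuracy,
    seed = x$seed, layout_version = x$layout_version
  )
}

#' Serialize a forest model to JSON text
#'
#' Trees are written as nested records (flat node arrays plus leaf count
#' matrices) with the class alphabet, feature names and layout version, so
#' a model written by one session can be reloaded and must predict
#' identically.
#'
#' @param model An `sse_forest`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(model, path) {
  doc <- list(
    format = "sseforest-model", format_version = 1L,
    layout_version = model$layout_version,
    classes = model$classes, feature_names = model$feature_names,
    mtry = model$mtry, n_train = model$n_train, seed = model$seed,
    split = model$split, oob_accuracy = model$oob_accuracy,
    trees = lapply(model$trees, function(t) {
      list(feature = t$feature, threshold = t$threshold,
           left = t$left, right = t$right, counts = t$counts)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Load a forest model written by [write_forest_json()]
#'
#' @param path Path to a model JSON file.
#' @return An `sse_forest`.
#' @export
read_forest_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "sseforest-model")) {
    stop("not an sseforest model file", call. = FALSE)
  }
  trees <- if (is.data.frame(doc$trees)) {
    # jsonlite simplifies a list of homogeneous records to a data frame
    lapply(seq_len(nrow(doc$trees)), function(i) {
      list(feature = as.integer(doc$trees$feature[[i]]),
           threshold = as.numeric(doc$trees$threshold[[i]]),
           left = as.integer(doc$trees$left[[i]]),
           right = as.integer(doc$trees$right[[i]]),
           counts = matrix(as.numeric(doc$trees$counts[[i]]),
                           ncol = length(doc$classes)))
    })
  } else {
    lapply(doc$trees, function(t) {
      list(feature = as.integer(t$feature), threshold = as.numeric(t$threshold),
           left = as.integer(t$left), right = as.integer(t$right),
           counts = matrix(as.numeric(unlist(t$counts)),
                           ncol = length(doc$classes), byrow = TRUE))
    })
  }
  structure(
    list(trees = trees, classes = doc$classes,
         feature_names = doc$feature_names, mtry = as.integer(doc$mtry),
         n_train = as.integer(doc$n_train), seed = as.integer(doc$seed),
         split = doc$split, oob_accuracy = doc$oob_accuracy,
         layout_version = doc$layout_version),
    class = "sse_forest"
  )
}
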