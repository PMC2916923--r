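#' Confusion matrix of actual vs predicted pair types
#'
#' Rows are actual classes, columns predicted; `counts[i, j]` is the number
#' of pairs of actual class i predicted as class j.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param classes Ordered class alphabet (default [PAIR_CLASSES] restricted
#'   to the labels present).
#' @return A `confusion_matrix` object (an integer K x K matrix with class
#'   dimnames).
#' @export
confusion <- function(actual, predicted,
                      classes = PAIR_CLASSES[PAIR_CLASSES %in% c(actual, predicted)]) {
  stopifnot(length(actual) == length(predicted))
  actual <- as.character(actual); predicted <- as.character(predicted)
  unknown <- setdiff(c(actual, predicted), classes)
  if (length(unknown) > 0L) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- table(factor(actual, levels = classes),
             factor(predicted, levels = classes))
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(actual = classes, predicted = classes))
  class(out) <- c("confusion_matrix", "matrix")
  out
}

#' Wrap a printed confusion matrix
#'
#' For regression against published tables: turn a plain counts matrix
#' (rows actual, columns predicted, with class dimnames) into a
#' `confusion_matrix`.
#'
#' @param counts Square numeric matrix with identical row/column names.
#' @return A `confusion_matrix`.
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts),
            identical(rownames(counts), colnames(counts)),
            all(counts >= 0))
  out <- matrix(as.integer(counts), nrow = nrow(counts),
                dimnames = list(actual = rownames(counts),
                                predicted = colnames(counts)))
  class(out) <- c("confusion_matrix", "matrix")
  out
}

#' Overall accuracy of a confusion matrix
#'
#' The fraction of pairs on the diagonal (correctly predicted).
#'
#' @param cm A `confusion_matrix`.
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

#' One-vs-rest counts for a class
#'
#' @param cm A `confusion_matrix`.
#' @param class A class name present in `cm`.
#' @return Named numeric vector `tp`, `fp`, `fn`, `tn` summing to the matrix
#'   total.
#' @export
per_class_counts <- function(cm, class) {
  stopifnot(class %in% rownames(cm))
  tp <- cm[class, class]
  fp <- sum(cm[, class]) - tp
  fn <- sum(cm[class, ]) - tp
  c(tp = tp, fp = fp, fn = fn, tn = sum(cm) - tp - fp - fn)
}

#' Matthews correlation coefficient
#'
#' Binary (one-vs-rest) MCC:
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in \[-1, 1\];
#' a perfect predictor scores 1 and a random one 0. When any margin of the
#' 2x2 table is zero the coefficient is undefined and 0 is returned with a
#' warning.
#'
#' @param tp,fp,fn,tn One-vs-rest counts.
#' @return Scalar in \[-1, 1\].
#' @export
mcc <- function(tp, fp, fn, tn) {
  # margin products overflow 32-bit integers on realistic set sizes
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) {
    warning("degenerate margin in MCC; returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Per-class precision, recall and MCC of a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return A `metric_report`: a tibble with one row per class (`class`,
#'   `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `mcc`) carrying the
#'   overall accuracy and total as attributes (see `glance()`).
#' @export
metric_report <- function(cm) {
  rows <- lapply(rownames(cm), function(k) {
    ct <- per_class_counts(cm, k)
    tibble(
      class = k,
      tp = ct[["tp"]], fp = ct[["fp"]], fn = ct[["fn"]], tn = ct[["tn"]],
      precision = ct[["tp"]] / (ct[["tp"]] + ct[["fp"]]),
      recall = ct[["tp"]] / (ct[["tp"]] + ct[["fn"]]),
      mcc = mcc(ct[["tp"]], ct[["fp"]], ct[["fn"]], ct[["tn"]])
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "accuracy") <- accuracy(cm)
  attr(out, "total") <- sum(cm)
  class(out) <- c("metric_report", class(out))
  out
}

#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("actual", "predicted", "n")
  as_tibble(df)
}

#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble(total = sum(x), accuracy = accuracy(x), n_classes = nrow(x))
}

#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "metric_report")
  out
}

#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tibble(accuracy = attr(x, "accuracy"), total = attr(x, "total"),
         n_classes = nrow(x))
}

#' Bin predictions by probability
#'
#' Predicted levels are binned on the prediction probability p into
#' `p < 0.5`, `p = 0.5`, `0.5 < p < 0.9` and `p >= 0.9`. Because averaged
#' leaf ratios produce values like 0.4999999999, equality at the 0.5
#' boundary is tested after rounding p to 10 decimal places.
#'
#' @param predictions Tibble with columns `label` (predicted level) and `p`
#'   (its probability), as returned by [predict.sse_forest()].
#' @return A tibble with one row per predicted level: `label`, `total`,
#'   `p_lt_0.5`, `p_eq_0.5`, `p_mid`, `p_ge_0.9`.
#' @export
bin_probabilities <- function(predictions) {
  stopifnot(all(predictions$p >= 0 & predictions$p <= 1))
  p <- round(predictions$p, 10)
  bin <- dplyr::case_when(
    p < 0.5 ~ "p_lt_0.5",
    p == 0.5 ~ "p_eq_0.5",
    p < 0.9 ~ "p_mid",
    TRUE ~ "p_ge_0.9"
  )
  lvls <- unique(c(PAIR_CLASSES[PAIR_CLASSES %in% predictions$label],
                   setdiff(predictions$label, PAIR_CLASSES)))
  tab <- table(factor(predictions$label, levels = lvls),
               factor(bin, levels = c("p_lt_0.5", "p_eq_0.5", "p_mid", "p_ge_0.9")))
  out <- as_tibble(as.data.frame.matrix(tab))
  dplyr::bind_cols(tibble(label = lvls, total = as.integer(rowSums(tab))), out)
}

deeper_level <- function(level) {
  c("CL" = "FO", "FO" = "SF", "SF" = "FA")[[level]]
}

lineage_at <- function(sccs, level) {
  lin <- parse_sccs(sccs)
  switch(level, CL = lin$cl, FO = lin$fo, SF = lin$sf, FA = lin$fa)
}

#' Propose classifications for an unassigned target domain
#'
#' Given the forest predictions of a target against a set of classified
#' template domains, applies the probability decision rules:
#' \enumerate{
#'   \item per template, take the argmax level and its probability; NA
#'     predictions propose nothing;
#'   \item within one template lineage, if any template pair predicts a
#'     deeper level, the deepest predicted level is reported for that
#'     lineage;
#'   \item if at least `min_templates` templates of the lineage have
#'     shared-level probability below 0.8 while their probability for the
#'     next deeper level exceeds 0.2, the suggestion is promoted to that
#'     deeper level;
#'   \item suggestions with p >= 0.5 are tier `"accepted"`, p >= 0.9
#'     `"high"`, otherwise `"candidate"`.
#' }
#' Several lineages may be reported for one target (multi-domain case).
#' The output is invariant to the order of the template rows.
#'
#' @param target_id Identifier of the target domain.
#' @param template_predictions Tibble with one row per (target, template)
#'   pair: `template` (id), `sccs` (template lineage) and probability
#'   columns `p_CL`, `p_FO`, `p_SF`, `p_FA` (and optionally `p_NA`).
#' @param min_templates Minimum number of low-confidence template pairs
#'   required by the promotion rule (default 2).
#' @return A tibble of suggestions sorted by decreasing p: `target`,
#'   `level`, `node` (lineage prefix at the suggested level), `sunid` if a
#'   `sunid` column was supplied, `templates` (comma-joined supporting ids),
#'   `p`, `tier`, `promoted`.
#' @export
classify_target <- function(target_id, template_predictions, min_templates = 2L) {
  tp <- template_predictions
  empty <- tibble(target = character(), level = character(),
                  node = character(), templates = character(),
                  p = numeric(), tier = character(), promoted = logical())
  if (nrow(tp) == 0L) return(empty)
  stopifnot(all(c("template", "sccs", "p_CL", "p_FO", "p_SF", "p_FA") %in% names(tp)))
  tp <- dplyr::arrange(tp, .data$sccs, .data$template) # order invariance
  pm <- as.matrix(tp[paste0("p_", PAIR_CLASSES[PAIR_CLASSES %in%
                                                 sub("^p_", "", names(tp))])])
  colnames(pm) <- sub("^p_", "", colnames(pm))
  true_levels <- c("CL", "FO", "SF", "FA")
  sugg <- lapply(split(seq_len(nrow(tp)), tp$sccs), function(rows) {
    sub <- pm[rows, , drop = FALSE]
    arg <- colnames(sub)[max.col(sub, ties.method = "first")]
    shared <- arg[arg %in% true_levels]
    if (length(shared) == 0L) return(NULL)
    # rule (ii): deepest argmax level across templates of this lineage
    level <- shared[which.max(.level_depth[shared])]
    p_level <- max(sub[, level])
    supporting <- rows
    promoted <- FALSE
    # rule (iii): promotion to the next deeper level
    if (level != "FA") {
      deeper <- deeper_level(level)
      low_conf <- sub[, level] < 0.8 & sub[, deeper] > 0.2
      if (sum(low_conf) >= min_templates) {
        level <- deeper
        p_level <- max(sub[low_conf, deeper])
        promoted <- TRUE
      }
    }
    sccs <- tp$sccs[rows[1]]
    out <- tibble(
      target = target_id,
      level = level,
      node = lineage_at(sccs, level),
      templates = paste(sort(unique(tp$template[supporting])), collapse = ","),
      p = p_level,
      tier = if (p_level >= 0.9) "high" else if (p_level >= 0.5) "accepted" else "candidate",
      promoted = promoted
    )
    if ("sunid" %in% names(tp)) out$sunid <- tp$sunid[rows[1]]
    out
  })
  sugg <- dplyr::bind_rows(sugg)
  if (nrow(sugg) == 0L) return(empty)
  dplyr::arrange(sugg, dplyr::desc(.data$p), .data$node)
}

#' Detect triangle-equality violations among predicted pair types
#'
#' Transitivity check: if pairs (i, j) and (j, k) are both predicted to
#' share a level, pair (i, k) should be predicted to share it too. A triple
#' with all three edges predicted is a violation when exactly two edges
#' carry the same shared level (one of CL/FO/SF/FA) and the third differs.
#' An NA edge asserts no shared level, so two NA edges impose nothing on
#' the third.
#'
#' @param predictions Tibble with columns `sid_a`, `sid_b`, `label`.
#' @return A tibble of violating triples: `i`, `j`, `k` (ids), their three
#'   edge labels `label_ij`, `label_jk`, `label_ik`.
#' @export
triangle_violations <- function(predictions) {
  ids <- sort(unique(c(predictions$sid_a, predictions$sid_b)))
  key <- canonical_pair_key(predictions$sid_a, predictions$sid_b)
  lab <- setNames(as.character(predictions$label), key)
  out <- list()
  n <- length(ids)
  if (n >= 3L) {
    for (a in 1:(n - 2)) {
      for (b in (a + 1):(n - 1)) {
        kab <- canonical_pair_key(ids[a], ids[b])
        if (is.na(lab[kab])) next
        for (c in (b + 1):n) {
          kac <- canonical_pair_key(ids[a], ids[c])
          kbc <- canonical_pair_key(ids[b], ids[c])
          e <- c(lab[kab], lab[kbc], lab[kac])
          if (anyNA(e)) next
          reps <- table(e)
          if (length(reps) == 2L) {
            shared <- names(reps)[reps == 2L]
            if (length(shared) == 1L && shared != "NA") {
              out[[length(out) + 1L]] <- tibble(
                i = ids[a], j = ids[b], k = ids[c],
                label_ij = e[1], label_jk = e[2], label_ik = e[3]
              )
            }
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    tibble(i = character(), j = character(), k = character(),
           label_ij = character(), label_jk = character(),
           label_ik = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Suggest hierarchy edits from confidently misclassified pairs
#'
#' Misclassified pairs with p >= 0.9 are confident predictions that may
#' indicate the classification itself should change. A prediction deeper
#' than the recorded shared level suggests merging the two nodes at the
#' predicted level; a prediction shallower than the recorded level suggests
#' a new element at the deeper (recorded) level.
#'
#' @param results Tibble with columns `sid_a`, `sid_b`, `sccs_a`, `sccs_b`,
#'   `actual`, `predicted`, `p`.
#' @param p_min Confidence threshold (default 0.9).
#' @return A tibble: `sid_a`, `sid_b`, `actual`, `predicted`, `p`, `action`
#'   (`"merge"` or `"new_sublevel"`), `node_a`, `node_b` (lineage prefixes
#'   at the predicted level for mergers, at the actual level otherwise).
#' @export
merger_suggestions <- function(results, p_min = 0.9) {
  r <- dplyr::filter(results,
                     .data$predicted != .data$actual,
                     .data$p >= p_min,
                     .data$predicted != "NA")
  if (nrow(r) == 0L) {
    return(tibble(sid_a = character(), sid_b = character(),
                  actual = character(), predicted = character(),
                  p = numeric(), action = character(),
                  node_a = character(), node_b = character()))
  }
  deeper <- unname(.level_depth[r$predicted] > .level_depth[r$actual])
  level_for_node <- ifelse(deeper, r$predicted, r$actual)
  tibble(
    sid_a = r$sid_a, sid_b = r$sid_b,
    actual = r$actual, predicted = r$predicted, p = r$p,
    action = ifelse(deeper, "merge", "new_sublevel"),
    node_a = vapply(seq_len(nrow(r)),
                    function(i) lineage_at(r$sccs_a[i], level_for_node[i]), ""),
    node_b = vapply(seq_len(nrow(r)),
                    function(i) lineage_at(r$sccs_b[i], level_for_node[i]), "")
  )
}
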