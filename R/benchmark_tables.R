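#' Published benchmark confusion matrices (SCOP 1.69 -> 1.73)
#'
#' The confusion matrices of the original inter-version benchmark of this
#' classifier: a forest trained on SCOP 1.69 three-SSE domain pairs and
#' tested on the non-overlapping SCOP 1.73 pairs, either with all five pair
#' types (`strategy = 1`, 6929 training / 6606 test pairs) or with NA-pairs
#' removed from both sides (`strategy = 2`, 4071 / 4114). These printed
#' counts are the input for metric regression: [metric_report()] on them
#' reproduces the published per-class precision/recall/MCC and the 85% / 93%
#' overall accuracies.
#'
#' @param strategy 1 or 2.
#' @return A `confusion_matrix` (rows actual, columns predicted).
#' @export
benchmark_confusion <- function(strategy = 1) {
  stopifnot(strategy %in% c(1, 2))
  if (strategy == 1) {
    m <- matrix(c(
      2813, 10,  0,  12, 511,
        92, 125,  1,  30,  30,
        21,  2,  56,  23,   0,
        30,  5,  13, 336,   4,
       216,  3,   0,   9, 2264
    ), nrow = 5, byrow = TRUE,
    dimnames = list(c("CL", "FO", "SF", "FA", "NA"),
                    c("CL", "FO", "SF", "FA", "NA")))
  } else {
    m <- matrix(c(
      3327,  4,  1,  14,
       134, 115,  6,  23,
        21,  1,  56,  24,
        44,  3,  12, 329
    ), nrow = 4, byrow = TRUE,
    dimnames = list(c("CL", "FO", "SF", "FA"),
                    c("CL", "FO", "SF", "FA")))
  }
  as_confusion(m)
}

#' Published probability-bin table for NA-pair reclassification
#'
#' Counts of NA-pairs predicted to each true level, binned by prediction
#' probability, for the two reclassification scenarios of the original
#' benchmark: strategy 3 (NA-pairs of the 1.69 set, 2858 pairs) and
#' strategy 4 (NA-pairs unique to the 1.73 set, 4653 pairs).
#'
#' @param strategy 3 or 4.
#' @return A tibble with columns `label`, `total`, `p_lt_0.5`, `p_eq_0.5`,
#'   `p_mid`, `p_ge_0.9`.
#' @export
benchmark_probability_bins <- function(strategy = 3) {
  stopifnot(strategy %in% c(3, 4))
  if (strategy == 3) {
    tibble(
      label = c("CL", "FO", "SF", "FA"),
      total = c(2806L, 29L, 2L, 21L),
      p_lt_0.5 = c(14L, 0L, 2L, 0L),
      p_eq_0.5 = c(130L, 6L, 0L, 8L),
      p_mid = c(1235L, 9L, 0L, 12L),
      p_ge_0.9 = c(1427L, 14L, 0L, 1L)
    )
  } else {
    tibble(
      label = c("CL", "FO", "SF", "FA"),
      total = c(4558L, 55L, 3L, 37L),
      p_lt_0.5 = c(37L, 0L, 3L, 0L),
      p_eq_0.5 = c(162L, 5L, 0L, 9L),
      p_mid = c(1917L, 37L, 0L, 20L),
      p_ge_0.9 = c(2442L, 13L, 0L, 8L)
    )
  }
}
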