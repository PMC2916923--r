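test_that("confusion counts actual x predicted", {
  cm <- confusion("CL", "CL")
  expect_equal(cm["CL", "CL"], 1L)
  cm2 <- confusion(c("CL", "FA"), c("FA", "CL"))
  expect_equal(sum(diag(cm2)), 0L)
  expect_equal(sum(cm2), 2L)
  expect_error(confusion("CL", "XX", classes = "CL"), "unknown label")
})

test_that("published benchmark matrices have the printed test-set sizes", {
  expect_equal(sum(benchmark_confusion(1)), 6606)
  expect_equal(sum(benchmark_confusion(2)), 4114)
})

test_that("accuracy is trace over total", {
  ident <- diag(3L, 5)
  dimnames(ident) <- list(PAIR_CLASSES, PAIR_CLASSES)
  expect_equal(accuracy(as_confusion(ident)), 1.0)
  expect_equal(round(accuracy(benchmark_confusion(1)), 2), 0.85)
  expect_equal(round(accuracy(benchmark_confusion(2)), 2), 0.93)
  expect_error(accuracy(as_confusion(matrix(0L, 2, 2,
    dimnames = list(c("CL", "FA"), c("CL", "FA"))))), "empty")
})

test_that("per-class one-vs-rest counts partition the matrix total", {
  cm1 <- benchmark_confusion(1)
  fa <- per_class_counts(cm1, "FA")
  expect_equal(unname(fa), c(336, 74, 52, 6144))
  sf <- per_class_counts(cm1, "SF")
  expect_equal(sf[["tp"]], 56)
  expect_equal(sf[["fp"]], 14)
  for (k in rownames(cm1)) {
    expect_equal(sum(per_class_counts(cm1, k)), sum(cm1))
  }
  # single-class matrix: no negatives possible
  single <- as_confusion(matrix(7L, 1, 1, dimnames = list("FA", "FA")))
  expect_equal(unname(per_class_counts(single, "FA")[c("fp", "fn")]), c(0, 0))
})

test_that("mcc matches hand-checked values and handles degeneracy", {
  expect_equal(mcc(10, 0, 0, 90), 1.0)
  expect_equal(round(mcc(336, 74, 52, 6144), 2), 0.83)
  expect_equal(round(mcc(125, 20, 153, 6308), 2), 0.61)
  expect_warning(z <- mcc(0, 0, 5, 5), "degenerate")
  expect_equal(z, 0)
})

test_that("metric_report equals metrics recomputed from counts", {
  cm <- benchmark_confusion(1)
  rep <- metric_report(cm)
  for (i in seq_len(nrow(rep))) {
    ct <- per_class_counts(cm, rep$class[i])
    expect_equal(rep$precision[i], ct[["tp"]] / (ct[["tp"]] + ct[["fp"]]))
    expect_equal(rep$recall[i], ct[["tp"]] / (ct[["tp"]] + ct[["fn"]]))
    expect_equal(rep$mcc[i], mcc(ct[["tp"]], ct[["fp"]], ct[["fn"]], ct[["tn"]]))
    # Rec * (TP + FN) = TP exactly
    expect_equal(rep$recall[i] * (rep$tp[i] + rep$fn[i]), rep$tp[i])
  }
  expect_equal(glance(rep)$accuracy, accuracy(cm))
  expect_equal(glance(rep)$total, 6606)
})

test_that("probability bins use the printed boundary semantics", {
  preds <- tibble::tibble(
    label = rep("CL", 6),
    p = c(0.49, 0.5, 0.5 - 1e-13, 0.51, 0.9, 0.89999)
  )
  bins <- bin_probabilities(preds)
  expect_equal(bins$p_lt_0.5, 1L)   # 0.49
  expect_equal(bins$p_eq_0.5, 2L)   # 0.5 and the rounding-guarded value
  expect_equal(bins$p_mid, 2L)      # 0.51, 0.89999
  expect_equal(bins$p_ge_0.9, 1L)   # 0.9
  expect_equal(bins$total, 6L)
})

test_that("bin totals equal per-level prediction counts", {
  withr::with_seed(6, {
    preds <- tibble::tibble(
      label = sample(c("CL", "FO", "FA"), 300, replace = TRUE),
      p = runif(300)
    )
  })
  bins <- bin_probabilities(preds)
  expect_equal(bins$total,
               bins$p_lt_0.5 + bins$p_eq_0.5 + bins$p_mid + bins$p_ge_0.9)
  counts <- table(preds$label)
  expect_equal(bins$total, as.integer(counts[bins$label]))
})

test_that("published probability-bin tables are internally consistent", {
  for (s in 3:4) {
    b <- benchmark_probability_bins(s)
    expect_equal(b$total, b$p_lt_0.5 + b$p_eq_0.5 + b$p_mid + b$p_ge_0.9)
  }
  expect_equal(sum(benchmark_probability_bins(3)$total), 2858)
  expect_equal(sum(benchmark_probability_bins(4)$total), 4653)
})

test_that("a single confident template yields an accepted family suggestion", {
  tp <- tibble::tibble(
    template = "t1", sccs = "a.7.6.1",
    p_CL = 0.05, p_FO = 0.02, p_SF = 0.03, p_FA = 0.9, p_NA = 0
  )
  s <- classify_target("q1", tp)
  expect_equal(nrow(s), 1)
  expect_equal(s$level, "FA")
  expect_equal(s$node, "a.7.6.1")
  expect_equal(s$tier, "high")
  expect_false(s$promoted)
})

test_that("low-confidence shared level with deeper support is promoted", {
  tp <- tibble::tibble(
    template = c("t1", "t2"), sccs = "a.7.6.1",
    p_CL = 0.05, p_FO = 0.7, p_SF = 0.25, p_FA = 0, p_NA = 0
  )
  s <- classify_target("q1", tp)
  expect_equal(s$level, "SF")
  expect_equal(s$node, "a.7.6")
  expect_true(s$promoted)
  expect_equal(s$p, 0.25)

  # a single low-confidence template is not enough
  s1 <- classify_target("q1", tp[1, ])
  expect_equal(s1$level, "FO")
  expect_false(s1$promoted)
})

test_that("a deeper prediction from any template sets the lineage level", {
  tp <- tibble::tibble(
    template = c("t1", "t2"), sccs = "a.7.6.1",
    p_CL = c(0.1, 0.05), p_FO = c(0.85, 0.1), p_SF = c(0.02, 0.05),
    p_FA = c(0.03, 0.8), p_NA = 0
  )
  s <- classify_target("q1", tp)
  expect_equal(s$level, "FA")
  expect_equal(s$p, 0.8)
})

test_that("templates from different lineages yield multiple suggestions", {
  tp <- tibble::tibble(
    template = c("t1", "t2"),
    sccs = c("a.7.6.1", "b.6.1.2"),
    p_CL = 0.1, p_FO = 0.7, p_SF = 0.1, p_FA = 0.1, p_NA = 0
  )
  s <- classify_target("q1", tp)
  expect_equal(nrow(s), 2)
  expect_setequal(s$node, c("a.7", "b.6"))
  # order invariance
  s_rev <- classify_target("q1", tp[2:1, ])
  expect_equal(s, s_rev)
})

test_that("NA-dominant templates and empty input propose nothing", {
  tp <- tibble::tibble(
    template = "t1", sccs = "a.7.6.1",
    p_CL = 0.1, p_FO = 0.1, p_SF = 0.05, p_FA = 0.05, p_NA = 0.7
  )
  expect_equal(nrow(classify_target("q1", tp)), 0)
  expect_equal(nrow(classify_target("q1", tp[0, ])), 0)
})

test_that("triangle violations flag inconsistent shared levels", {
  edges <- function(l12, l13, l23) {
    tibble::tibble(sid_a = c("d1", "d1", "d2"), sid_b = c("d2", "d3", "d3"),
                   label = c(l12, l13, l23))
  }
  expect_equal(nrow(triangle_violations(edges("FO", "FO", "FO"))), 0)
  v <- triangle_violations(edges("FO", "FO", "NA"))
  expect_equal(nrow(v), 1)
  # two NA edges do not assert a shared level for the third
  expect_equal(nrow(triangle_violations(edges("NA", "NA", "FO"))), 0)
  # incomplete triangles are not evaluated
  open <- tibble::tibble(sid_a = c("d1", "d1"), sid_b = c("d2", "d3"),
                         label = c("FO", "FO"))
  expect_equal(nrow(triangle_violations(open)), 0)
})

test_that("confident misclassifications become merger or sublevel records", {
  res <- tibble::tibble(
    sid_a = c("d1", "d2", "d3", "d4"),
    sid_b = c("t1", "t2", "t3", "t4"),
    sccs_a = c("i.1.1.1", "a.7.6.1", "a.7.6.1", "a.7.6.1"),
    sccs_b = c("a.7.6.1", "a.7.6.1", "a.7.6.2", "a.7.6.1"),
    actual = c("NA", "FA", "SF", "FA"),
    predicted = c("FA", "FA", "FA", "CL"),
    p = c(0.9, 0.99, 0.95, 0.92)
  )
  sugg <- merger_suggestions(res)
  expect_equal(nrow(sugg), 3) # the correct FA prediction yields no record
  merge_fa <- sugg[sugg$sid_a == "d1", ]
  expect_equal(merge_fa$action, "merge")
  expect_equal(merge_fa$node_a, "i.1.1.1")
  expect_equal(merge_fa$node_b, "a.7.6.1")
  expect_equal(sugg[sugg$sid_a == "d3", ]$action, "merge")
  expect_equal(sugg[sugg$sid_a == "d3", ]$node_b, "a.7.6.2")
  expect_equal(sugg[sugg$sid_a == "d4", ]$action, "new_sublevel")
  # below the confidence threshold nothing is suggested
  res$p <- 0.8
  expect_equal(nrow(merger_suggestions(res)), 0)
})
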