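hand_example <- function() {
  # reference: 80 A, 20 B; prediction: 70 A correct + 10 -> B,
  # 15 B correct + 5 -> A
  ids <- sprintf("c%03d", 1:100)
  ref <- setNames(rep(c("A", "B"), c(80, 20)), ids)
  pred <- ref
  pred[71:80] <- "B"
  pred[81:85] <- "A"
  list(pred = pred, ref = ref)
}

test_that("confusion counts match the hand-tabulated example", {
  h <- hand_example()
  cc <- confusion_counts(h$pred, h$ref)
  a <- cc[cc$cell_type == "A", ]
  expect_equal(c(a$TP, a$FN, a$FP, a$TN), c(70, 10, 5, 15))
  b <- cc[cc$cell_type == "B", ]
  expect_equal(c(b$TP, b$FN, b$FP, b$TN), c(15, 5, 10, 70))
  expect_equal(cc$proportion, c(0.8, 0.2))
})

test_that("weighted metrics agree with an independent hand calculation", {
  h <- hand_example()
  m <- evaluate_annotation(h$pred, h$ref)
  expect_identical(m$weighted_recall, 0.875 * 0.8 + 0.75 * 0.2) # = 0.85
  wp <- (70 / 75) * 0.8 + (15 / 25) * 0.2
  expect_equal(m$weighted_precision, wp, tolerance = 1e-12)
  expect_equal(m$weighted_f1, 2 * wp * 0.85 / (wp + 0.85), tolerance = 1e-12)
  expect_equal(m$accuracy, (70 + 15 + 15 + 70) / 200, tolerance = 1e-12)
})

test_that("edge labelings behave: perfect, all-Unknown, single type", {
  ids <- paste0("c", 1:50)
  ref <- setNames(rep(c("A", "B"), 25), ids)
  perf <- evaluate_annotation(ref, ref)
  expect_equal(c(perf$accuracy, perf$weighted_recall,
                 perf$weighted_precision, perf$weighted_f1), rep(1, 4))

  unk <- evaluate_annotation(setNames(rep("Unknown", 50), ids), ref)
  expect_equal(unk$weighted_recall, 0)
  cc <- confusion_counts(setNames(rep("Unknown", 50), ids), ref)
  expect_equal(cc$TP, c(0, 0))
  expect_equal(cc$FN, c(25, 25))

  one <- setNames(rep("A", 30), paste0("s", 1:30))
  pred <- one; pred[1:6] <- "B"
  m1 <- evaluate_annotation(pred, one)
  expect_equal(m1$weighted_recall, 24 / 30)   # plain recall
})

test_that("reference exclusion list drops cells before counting", {
  ids <- paste0("c", 1:30)
  ref <- setNames(rep(c("A", "dirt", "B"), each = 10), ids)
  pred <- setNames(rep(c("A", "B", "B"), each = 10), ids)
  cc <- confusion_counts(pred, ref, exclude_labels = "dirt")
  expect_equal(sum(cc$TP + cc$FP + cc$FN + cc$TN) / nrow(cc), 20)
  expect_equal(sum(cc$proportion), 1)
})

test_that("metrics stay in bounds and respect the harmonic-mean relation", {
  set.seed(10)
  ids <- paste0("c", 1:200)
  for (rep in 1:20) {
    ref <- setNames(sample(c("A", "B", "C"), 200, TRUE, c(.6, .3, .1)), ids)
    pred <- setNames(sample(c("A", "B", "C", "Unknown"), 200, TRUE), ids)
    m <- evaluate_annotation(pred, ref)
    vals <- c(m$accuracy, m$weighted_recall, m$weighted_precision,
              m$weighted_f1)
    expect_true(all(vals >= 0 & vals <= 1))
    if (m$weighted_precision > 0 && m$weighted_recall > 0)
      expect_lte(m$weighted_f1,
                 min(m$weighted_precision, m$weighted_recall) * 2 *
                   max(m$weighted_precision, m$weighted_recall) /
                   (min(m$weighted_precision, m$weighted_recall) +
                      max(m$weighted_precision, m$weighted_recall)) + 1e-12)
  }
})

test_that("label shuffling drives weighted recall to the chance level", {
  set.seed(20)
  ids <- paste0("c", 1:2000)
  props <- c(A = 0.5, B = 0.3, C = 0.2)
  ref <- setNames(rep(names(props), props * 2000), ids)
  wr <- replicate(50, {
    evaluate_annotation(setNames(sample(ref), ids), ref)$weighted_recall
  })
  expect_equal(mean(wr), sum(props^2), tolerance = 0.02)
})

test_that("enrichment flags unique markers of real populations", {
  set.seed(30)
  sim <- simulate_cells(n_cells = 800,
                        cell_type_fractions = c(A = 0.5, B = 0.5),
                        n_markers = 6, seed = 30)
  mat <- znormalize(sim$features)
  truth <- setNames(sim$truth$label, sim$truth$cell_id)
  res <- marker_enrichment(mat, truth, sim$signatures)
  expect_setequal(res$marker, c("M01", "M02", "M03", "M04"))
  expect_true(all(res$log2fc > 1))
  expect_true(all(res$p_adjusted < 0.05))
  expect_true(all(res$p_adjusted >= res$p_value))

  # a marker expressed identically everywhere is not enriched
  v <- named_matrix(abs(rnorm(400)), 100, markers = c("mA", "mB", "mC", "mD"))
  w <- named_matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 4, markers = c("X", "Y"))
  rownames(w) <- colnames(v)
  labs <- setNames(rep(c("X", "Y"), 50), rownames(v))
  null_res <- marker_enrichment(fm(v), labs, suppressWarnings(signature_matrix(w)))
  expect_true(all(abs(null_res$log2fc) < 0.5))
  expect_true(all(null_res$p_value > 0.01))
})

test_that("shared signature markers are excluded and empty types skipped", {
  w <- named_matrix(c(1, 1, 0, 0, 1, 1), 3, markers = c("X", "Y"))
  rownames(w) <- c("m1", "m2", "m3")
  sig <- signature_matrix(w)        # m2 shared by X and Y
  v <- named_matrix(rnorm(30), 10, markers = c("m1", "m2", "m3"))
  labs <- setNames(rep("X", 10), rownames(v))  # Y has no assigned cells
  expect_warning(res <- marker_enrichment(fm(v), labs, sig), "skipped")
  expect_false("m2" %in% res$marker)
  expect_false("m3" %in% res$marker)
})

test_that("reported adjusted p-values follow the BH step-up rule", {
  set.seed(40)
  for (rep in 1:5) {
    n <- 120; m <- 8
    v <- named_matrix(rnorm(n * m) + rep(runif(m, 0, 2), each = n), n)
    w <- diag(m)[, 1:4]
    dimnames(w) <- list(colnames(v), paste0("T", 1:4))
    sig <- suppressWarnings(signature_matrix(w))
    labs <- setNames(sample(paste0("T", 1:4), n, TRUE), rownames(v))
    res <- marker_enrichment(fm(v), labs, sig)
    expect_equal(res$p_adjusted, bh_stepup(res$p_value), tolerance = 1e-12)
    # monotone in BH rank
    o <- order(res$p_value)
    expect_true(all(diff(res$p_adjusted[o]) >= -1e-12))
  }
})
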