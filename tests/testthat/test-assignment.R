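two_type_sig <- function() {
  w <- named_matrix(c(1, 0, 0, 1), 2, markers = c("X", "Y"))
  rownames(w) <- c("mX", "mY")
  signature_matrix(w)
}

test_that("categorization follows row sums of the positivity matrix", {
  B <- rbind(c(0L, 1L, 0L), c(1L, 1L, 0L), c(0L, 0L, 0L))
  dimnames(B) <- list(c("a", "b", "c"), c("T1", "T2", "T3"))
  asg <- categorize(B)
  expect_equal(asg$category, c("clean", "mixed", "unknown"))
  expect_equal(asg$label, c("T2", "Unknown", "Unknown"))
  expect_equal(attr(asg, "candidates")[[2]], c("T1", "T2"))
  # conservation before deconvolution
  expect_equal(sum(table(asg$category)), nrow(B))
})

test_that("deconvolution votes among clean anchors in the marker subspace", {
  sig <- two_type_sig()
  # anchors: three X at 0, three Y at 10; mixed cell at 2 -> all 3 nearest X
  v <- named_matrix(c(0, 0, 0, 10, 10, 10, 2,
                      0, 0, 0, 10, 10, 10, 2), 7,
                    cells = sprintf("c%d", 1:7), markers = c("mX", "mY"))
  mat <- fm(v)
  B <- cbind(X = c(1L, 1L, 1L, 0L, 0L, 0L, 1L),
             Y = c(0L, 0L, 0L, 1L, 1L, 1L, 1L))
  rownames(B) <- rownames(v)
  asg <- deconvolve(categorize(B), mat, sig, k_neighbors = 3)
  expect_equal(asg$label[7], "X")
  expect_equal(asg$category[7], "mixed_resolved")
  # clean labels untouched
  expect_equal(asg$label[1:6], c("X", "X", "X", "Y", "Y", "Y"))

  # zero-distance anchor with k = 1
  asg1 <- deconvolve(categorize(B), mat, sig, k_neighbors = 1)
  expect_equal(asg1$label[7], "X")
  expect_error(deconvolve(categorize(B), mat, sig, k_neighbors = 0),
               "at least 1")
})

test_that("mixed sets without anchors stay unresolved", {
  sig <- two_type_sig()
  v <- named_matrix(rnorm(6), 3, cells = c("a", "b", "c"),
                    markers = c("mX", "mY"))
  B <- cbind(X = c(1L, 1L, 1L), Y = c(1L, 1L, 1L))
  rownames(B) <- rownames(v)
  asg <- deconvolve(categorize(B), fm(v), sig)
  expect_true(all(asg$category == "unresolved_mixed"))
  expect_true(all(asg$label == "Unknown"))
})

test_that("deconvolution distances ignore markers outside the candidate set", {
  set.seed(44)
  w <- named_matrix(c(1, 0, 0, 0, 1, 0), 3, markers = c("X", "Y"))
  rownames(w) <- c("mX", "mY", "mJunk")
  sig <- suppressWarnings(signature_matrix(w))
  v <- named_matrix(rnorm(30), 10, markers = c("mX", "mY", "mJunk"))
  B <- cbind(X = rep(c(1L, 0L, 1L), c(4, 4, 2)),
             Y = rep(c(0L, 1L, 1L), c(4, 4, 2)))
  rownames(B) <- rownames(v)
  asg1 <- deconvolve(categorize(B), fm(v), sig, k_neighbors = 3)
  v2 <- v; v2[, "mJunk"] <- v2[, "mJunk"] + rnorm(10, 50)
  asg2 <- deconvolve(categorize(B), fm(v2), sig, k_neighbors = 3)
  expect_identical(asg1$label, asg2$label)
})

test_that("KNN resolution matches a brute-force all-pairs oracle", {
  set.seed(77)
  sim <- simulate_cells(n_cells = 500,
                        cell_type_fractions = c(A = 0.4, B = 0.35, C = 0.25),
                        n_markers = 10, doublet_fraction = 0.15, seed = 77)
  mat <- znormalize(sim$features)
  sig <- sim$signatures
  ctr <- compute_ctr(mat, sig)
  # thresholds from the truth quantiles just to create mixed cells
  th <- apply(ctr, 2, stats::quantile, 0.6)
  B <- binarize(ctr, th)
  pre <- categorize(B)
  post <- deconvolve(pre, mat, sig, k_neighbors = 10)
  mixed <- which(pre$category == "mixed")
  expect_gt(length(mixed), 0)
  clean <- pre$category == "clean"
  cand <- attr(pre, "candidates")
  for (i in mixed) {
    xi <- cand[[i]]
    mk <- rownames(sig)[rowSums(sig[, xi, drop = FALSE] > 0) > 0]
    anch <- which(clean & pre$label %in% xi)
    lab <- brute_knn_labels(mat$values[anch, mk, drop = FALSE],
                            pre$label[anch],
                            mat$values[i, mk, drop = FALSE], 10, xi)
    expect_equal(post$label[i], lab)
  }
})

test_that("the full pipeline recovers all simulated types deterministically", {
  sim <- simulate_cells(n_cells = 2000,
                        cell_type_fractions = c(A = 0.3, B = 0.25, C = 0.2,
                                                D = 0.15, E = 0.1),
                        n_markers = 14, seed = 1)
  fit <- suppressWarnings(markgate(sim$features, sim$signatures,
                                   band = c(0.01, 0.05), verbose = FALSE))
  expect_true(all(c("A", "B", "C", "D", "E") %in% fit$assignment$label))
  # conservation: every cell has exactly one final label
  expect_equal(nrow(fit$assignment), 2000)
  expect_true(all(fit$assignment$label != "" & !is.na(fit$assignment$label)))
  # clean labels survive deconvolution
  pre <- categorize(fit$positivity)
  ci <- pre$category == "clean"
  expect_identical(fit$assignment$label[ci], pre$label[ci])
  # pre-deconvolution categories partition n
  expect_equal(sum(fit$pre_deconvolution), 2000)

  fit2 <- suppressWarnings(markgate(sim$features, sim$signatures,
                                    band = c(0.01, 0.05), verbose = FALSE))
  expect_identical(fit$assignment, fit2$assignment)
  expect_identical(coef(fit), coef(fit2))
})

test_that("a signature type absent from the tissue is flagged degenerate", {
  sim <- simulate_cells(n_cells = 2000,
                        cell_type_fractions = c(A = 0.3, B = 0.25, C = 0.2,
                                                D = 0.15, E = 0.1),
                        n_markers = 14, seed = 6)
  w <- unclass(sim$signatures)
  w <- cbind(w, Ghost = 0)
  w["M13", "Ghost"] <- 1          # a pure-noise marker defines the ghost type
  sig <- suppressWarnings(signature_matrix(w))
  fit <- suppressWarnings(markgate(sim$features, sig, band = c(0.01, 0.05),
                                   verbose = FALSE))
  expect_true(fit$thresholds$degenerate[fit$thresholds$cell_type == "Ghost"])
  expect_equal(sum(fit$positivity[, "Ghost"]), 0L)
  expect_false(any(fit$assignment$label == "Ghost"))
})

test_that("predict applies learned thresholds to new cells", {
  sim <- simulate_cells(n_cells = 1000,
                        cell_type_fractions = c(A = 0.5, B = 0.5),
                        n_markers = 8, seed = 12)
  mat <- znormalize(sim$features)
  half <- seq(1, 1000, by = 2)     # interleaved so both types are in each half
  train <- fm(mat$values[half, ])
  test_ <- fm(mat$values[-half, ])
  fit <- suppressWarnings(markgate(train, sim$signatures,
                                   band = c(0.01, 0.05), verbose = FALSE))
  pred <- predict(fit, test_)
  acc <- mean(pred$label == sim$truth$label[-half])
  expect_gt(acc, 0.9)
})
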