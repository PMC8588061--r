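test_that("design matrix enumerates exactly the 15 distinct-predictor products", {
  X <- build_design_matrix(matrix(c(1, 2, 3, 4), nrow = 1))
  expect_equal(ncol(X), 15)
  expect_equal(ncol(X), choose(4, 1) + choose(4, 2) + choose(4, 3) +
                 choose(4, 4))
  # brute-force subset enumeration reproduces the row (same term order)
  expect_equal(as.numeric(X), oracle_interaction_products(c(1, 2, 3, 4)))
  expect_equal(unname(X[1, 15]), 24)  # x1*x2*x3*x4
  expect_equal(as.numeric(build_design_matrix(matrix(0, 1, 4))),
               rep(0, 15))
  # fixed documented order
  expect_equal(colnames(X),
               c("x1", "x2", "x3", "x4", "x1:x2", "x1:x3", "x1:x4",
                 "x2:x3", "x2:x4", "x3:x4", "x1:x2:x3", "x1:x2:x4",
                 "x1:x3:x4", "x2:x3:x4", "x1:x2:x3:x4"))
  expect_error(build_design_matrix(matrix(c(1, NA, 3, 4), nrow = 1)),
               "row 1, predictor x2")
})

make_features <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(H = runif(n, 420, 560), SpO2 = runif(n, 94, 99),
             HR = runif(n, 60, 100), BF = runif(n, 5, 25))
}

test_that("MPR4 recovers generating coefficients exactly at zero noise", {
  feats <- make_features(120)
  truth <- c(2, 0.01, 0.03, -0.02, 0.05, 1e-4, -2e-4, 3e-4, 1e-4, -1e-4,
             2e-4, 1e-6, -1e-6, 2e-6, 1e-6, -1e-8)
  y <- drop(cbind(1, build_design_matrix(feats)) %*% truth)
  m <- fit_mpr4(feats, y)
  expect_equal(unname(m$coefficients), truth, tolerance = 1e-6)
  expect_equal(unname(predict(m, feats)), y, tolerance = 1e-8)
})

test_that("MPR4 handles degenerate targets and enforces the sample-size rule", {
  feats <- make_features(100)
  m <- fit_mpr4(feats, rep(7, 100))
  expect_equal(unname(m$coefficients), c(7, rep(0, 15)), tolerance = 1e-8)
  expect_error(fit_mpr4(make_features(45), runif(45, 4, 10)),
               "three times the number of variables")
  # n = 46 is the smallest admissible size
  expect_s3_class(fit_mpr4(make_features(46), runif(46, 4, 10)), "mpr4")
})

test_that("MPR4 rejects rank-deficient designs naming the collinear columns", {
  feats <- make_features(100)
  feats$SpO2 <- 2 * feats$HR   # x2 collinear with x3
  expect_error(fit_mpr4(feats, runif(100, 4, 10)), "collinear")
})

test_that("MPR4 prediction is a row-wise map", {
  feats <- make_features(60)
  m <- fit_mpr4(feats, runif(60, 4, 10))
  expect_equal(unname(predict(m, feats[1, ])),
               unname(predict(m, feats)[1]))
  set.seed(2)
  perm <- sample(60)
  expect_equal(predict(m, feats[perm, ]), predict(m, feats)[perm])
  # all-zero record maps to the intercept
  expect_equal(unname(predict(m, matrix(0, 1, 4))),
               unname(m$coefficients[1]))
})

test_that("residual sum of squares is non-increasing as interaction terms are added", {
  feats <- make_features(80, seed = 3)
  y <- runif(80, 4, 10)
  X <- build_design_matrix(feats)
  rss <- vapply(1:15, function(k) {
    sum(stats::lm.fit(cbind(1, X[, 1:k, drop = FALSE]), y)$residuals^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("BPNN is sized by the Kolmogorov rule and is seed-reproducible", {
  feats <- make_features(80)
  y <- 5 + feats$H / 100
  b1 <- suppressWarnings(fit_bpnn(feats, y, seed = 11, max_epochs = 30))
  b2 <- suppressWarnings(fit_bpnn(feats, y, seed = 11, max_epochs = 30))
  expect_equal(b1$nhid, 2 * 4 + 1)
  expect_identical(b1$W1, b2$W1)
  expect_identical(b1$w2, b2$w2)
  expect_identical(unclass(b1), unclass(b2))
  b3 <- suppressWarnings(fit_bpnn(feats, y, seed = 12, max_epochs = 30))
  expect_false(identical(b1$W1, b3$W1))
})

test_that("BPNN fits a noiseless linear target to under 1% training mARD", {
  feats <- make_features(200, seed = 5)
  y <- 2 * feats$H / 100 + feats$HR / 20
  b <- suppressWarnings(fit_bpnn(feats, y, seed = 2))
  expect_lt(mard(y, predict(b, feats)), 1)
})

test_that("BPNN forward pass matches an independent matrix transcription", {
  feats <- make_features(50, seed = 9)
  y <- runif(50, 4, 10)
  b <- suppressWarnings(fit_bpnn(feats, y, seed = 3, max_epochs = 40))
  X <- as.matrix(feats[c("H", "SpO2", "HR", "BF")])
  Xs <- sweep(sweep(X, 2, b$x_center), 2, b$x_scale, "/")
  manual <- drop(tanh(Xs %*% t(b$W1) +
                        matrix(b$b1, 50, b$nhid, byrow = TRUE)) %*% b$w2 +
                   b$b2) * b$y_scale + b$y_center
  expect_equal(unname(predict(b, feats)), unname(manual), tolerance = 1e-12)
})

test_that("optimization never worsens the seeded initial loss", {
  feats <- make_features(60, seed = 13)
  y <- 4 + feats$BF / 10
  b <- suppressWarnings(fit_bpnn(feats, y, seed = 21, max_epochs = 50,
                                 validation_fraction = 0, n_starts = 1))
  # reconstruct the seeded initial weights and their training SSE
  set.seed(21)
  par0 <- runif(4 * 9 + 9 + 9 + 1, -0.5, 0.5)
  X <- as.matrix(feats[c("H", "SpO2", "HR", "BF")])
  Xs <- sweep(sweep(X, 2, b$x_center), 2, b$x_scale, "/")
  ys <- (y - b$y_center) / b$y_scale
  W1 <- matrix(par0[1:36], 9, 4); b1 <- par0[37:45]
  w2 <- par0[46:54]; b2 <- par0[55]
  sse0 <- sum((ys - drop(tanh(Xs %*% t(W1) +
                                matrix(b1, 60, 9, byrow = TRUE)) %*% w2 +
                           b2))^2)
  expect_lte(b$sse, sse0)
})

test_that("a zero network predicts its output bias and flags extrapolation", {
  b <- structure(list(W1 = matrix(0, 9, 4), b1 = rep(0, 9),
                      w2 = rep(0, 9), b2 = 0.5, nin = 4L, nhid = 9L,
                      x_center = rep(0, 4), x_scale = rep(1, 4),
                      y_center = 0, y_scale = 1,
                      x_range = rbind(rep(0, 4), rep(1, 4))),
                 class = "bpnn")
  expect_equal(unname(predict(b, matrix(0.5, 3, 4))), rep(0.5, 3))
  expect_warning(predict(b, matrix(100, 1, 4)), "extrapolat")
})

test_that("hold-out split is a seeded disjoint partition with the study default", {
  feats <- make_features(211)
  sp <- holdout_split(feats, seed = 4)
  expect_equal(nrow(sp$train), 118)
  expect_equal(nrow(sp$train) + nrow(sp$test), 211)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:211)
  sp2 <- holdout_split(feats, seed = 4)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_false(identical(sp$train_idx, holdout_split(feats, seed = 5)$train_idx))
  expect_error(holdout_split(feats, train_fraction = 1), "between 0 and 1")
  # integer form
  spn <- holdout_split(100, 0.7, seed = 1)
  expect_length(spn$train, 70)
})

test_that("models survive a structured-text round trip", {
  feats <- make_features(60)
  y <- runif(60, 4, 10)
  m <- fit_mpr4(feats, y)
  f <- tempfile(fileext = ".yaml")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(predict(m2, feats), predict(m, feats), tolerance = 1e-8)
  b <- suppressWarnings(fit_bpnn(feats, y, seed = 1, max_epochs = 20))
  write_model(b, f)
  b2 <- read_model(f)
  expect_equal(predict(b2, feats), predict(b, feats), tolerance = 1e-6)
  expect_true(file.size(f) > 0)
  expect_error(write_model(list(), f), "mpr4 and bpnn")
})
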