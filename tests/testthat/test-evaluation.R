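test_that("mARD matches hand arithmetic and is scale invariant", {
  expect_equal(mard(c(4, 5), c(4, 5)), 0)
  expect_equal(mard(c(4, 5), c(5, 4)), 22.5)
  set.seed(1)
  x <- runif(50, 4, 10); y <- x * runif(50, 0.9, 1.1)
  expect_equal(mard(3 * x, 3 * y), mard(x, y))
  expect_error(mard(c(0, 5), c(1, 5)), "> 0")
})

test_that("correlation is standard Pearson with degenerate guards", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  # definitional covariance / variance transcription
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(corr_coefficient(x, y), oracle)
  expect_equal(corr_coefficient(x, x), 1)
  expect_equal(corr_coefficient(x, -x), -1)
  expect_equal(corr_coefficient(2 * x + 1, y), corr_coefficient(x, y))
  expect_error(corr_coefficient(c(1, 1), c(1, 2)), "zero variance")
})

test_that("both MAD conventions behave as documented", {
  expect_equal(mad_printed(c(5, 5, 5)), 0)
  expect_equal(mad_printed(c(1, 3)), 1)
  expect_equal(mad_printed(c(1, 2, 6)), 2)
  expect_equal(mad_conventional(c(4, 5), c(5, 4)), 1)
  # the printed form never sees the reference
  expect_equal(mad_printed(c(1, 2, 6)), mad_printed(c(1, 2, 6)))
})

test_that("RMSE matches hand arithmetic and dominates conventional MAD", {
  expect_equal(rmse(c(4, 5), c(4, 5)), 0)
  expect_equal(rmse(c(0.1, 0.1), c(3.1, 4.1)), sqrt(25 / 2))
  set.seed(2)
  x <- runif(100, 4, 10); y <- x + rnorm(100, 0, 0.5)
  expect_gte(rmse(x, y), mad_conventional(x, y))
})

test_that("SEP is the residual spread, blind to constant bias", {
  x <- c(4, 5, 6)
  expect_equal(sep(x, x + 2), 0)
  expect_equal(sep(c(5, 5), c(4, 6)), sqrt(2))
  set.seed(3)
  xx <- runif(30, 4, 10); yy <- xx + rnorm(30, 0, 0.3)
  expect_equal(sep(xx, yy + 1.7), sep(xx, yy))
  # definitional transcription, both divisors
  e <- yy - xx
  expect_equal(sep(xx, yy), sqrt(sum((e - mean(e))^2) / (length(e) - 1)))
  expect_equal(sep(xx, yy, divisor = "n"),
               sqrt(sum((e - mean(e))^2) / length(e)))
  expect_error(sep(5, 6), "n >= 2")
})

test_that("error metrics scale linearly while mARD and CORR are scale free", {
  set.seed(4)
  x <- runif(40, 4, 10); y <- x * runif(40, 0.85, 1.15)
  for (c0 in c(0.5, 18.016)) {
    expect_equal(rmse(c0 * x, c0 * y), c0 * rmse(x, y))
    expect_equal(mad_conventional(c0 * x, c0 * y),
                 c0 * mad_conventional(x, y))
    expect_equal(sep(c0 * x, c0 * y), c0 * sep(x, y))
    expect_equal(mard(c0 * x, c0 * y), mard(x, y))
    expect_equal(corr_coefficient(c0 * x, c0 * y), corr_coefficient(x, y))
  }
})

test_that("perfect predictions land entirely in Clarke zone A", {
  x <- c(4.5, 6, 8, 9.5)
  z <- clarke_zones(x, x)
  expect_true(all(z == "A"))
  expect_equal(unname(attr(z, "percentages")["A"]), 100)
})

test_that("the zone A boundary sits at 20% relative deviation, inclusive", {
  ref <- 150 / MGDL_PER_MMOLL  # normoglycemic reference, mmol/L
  z <- clarke_zones(rep(ref, 3), ref * c(1.199, 1.200, 1.201))
  expect_equal(as.character(z), c("A", "A", "B"))
  zlow <- clarke_zones(rep(ref, 2), ref * c(0.801, 0.799))
  expect_equal(as.character(zlow), c("A", "B"))
  # hypoglycemic branch: both below 70 mg/dL is A regardless of deviation
  expect_equal(as.character(clarke_zones(3, 1.5)), "A")
})

test_that("golden points classify to their recorded zones", {
  gold <- read.csv(system.file("extdata", "clarke_golden_points.csv",
                               package = "glucoheat"))
  z <- clarke_zones(gold$ref_mgdl, gold$pred_mgdl, units = "mg/dL")
  expect_equal(as.character(z), gold$zone)
  # and agree with the independently coded grid geometry
  expect_equal(as.character(z), oracle_clarke(gold$ref_mgdl, gold$pred_mgdl))
})

test_that("zone assignment matches the independent transcription on random pairs", {
  set.seed(5)
  x <- runif(2000, 20, 400)
  y <- runif(2000, 20, 400)
  z <- clarke_zones(x, y, units = "mg/dL")
  expect_equal(as.character(z), oracle_clarke(x, y))
  expect_equal(sum(attr(z, "percentages")), 100, tolerance = 1e-9)
})

test_that("one canonical point per zone gives 20% everywhere", {
  ref <- c(100, 150, 160, 250, 200)
  pred <- c(100, 190, 30, 100, 50)
  tab <- clarke_zone_table(ref, pred, units = "mg/dL")
  expect_equal(tab$percent, rep(20, 5))
  expect_equal(sum(tab$percent), 100)
  expect_error(clarke_zones(c(-1, 5), c(5, 5)), "positive")
})

test_that("the combined evaluation report is internally consistent", {
  set.seed(6)
  x <- runif(60, 4.1, 10)
  y <- x * (1 + rnorm(60, 0, 0.05))
  rep <- evaluate_predictions(x, y)
  expect_equal(rep$mARD, mard(x, y))
  expect_equal(rep$CORR, corr_coefficient(x, y))
  expect_equal(rep$RMSE, rmse(x, y))
  expect_equal(rep$SEP, sep(x, y))
  expect_equal(sum(rep$clarke$percent), 100, tolerance = 1e-9)
  expect_equal(sum(rep$clarke$n), 60)
  expect_output(print(rep), "mARD")
})
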