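test_that("reference thresholds interpolate order statistics at
           position 1 + (n-1)p", {
  expect_equal(reference_threshold(1:100, "UP"), 95.05)
  expect_equal(reference_threshold(1:100, "DOWN"), 5.95)
  expect_equal(reference_threshold(rep(2, 25), "UP"), 2)
  expect_equal(reference_threshold(rep(2, 25), "DOWN"), 2)
  expect_warning(reference_threshold(1:10, "UP"), "unstable")
  expect_error(reference_threshold(numeric(0), "UP"), "control")
})

test_that("binarization is strict at the threshold and handles direction,
           missing values, and the literal down rule", {
  expect_identical(binarize(2, 2, "UP"), 0L)          # tie scores 0
  expect_identical(binarize(2 * 1.01, 2, "UP"), 1L)
  expect_identical(binarize(1.5, 2, "DOWN"), 1L)      # below 5th pctile
  expect_identical(binarize(2.5, 2, "DOWN"), 0L)
  expect_identical(binarize(NA_real_, 2, "UP"), 0L)   # missing -> no risk
  # literal reading: above the lower bound
  expect_identical(binarize(2.5, 2, "DOWN", down_rule = "above_lower"), 1L)
})

test_that("logistic weights equal the log odds ratio, with documented
           separation and degeneracy handling", {
  s <- c(rep(1, 15), rep(0, 5), rep(1, 2), rep(0, 18))
  y <- c(rep(1, 20), rep(0, 20))
  w <- fit_weight(s, y)
  expect_equal(as.numeric(w), log(27), tolerance = 1e-6)
  expect_identical(attr(w, "flag"), "OK")

  bal <- fit_weight(rep(c(1, 0, 1, 0), each = 10),
                    rep(c(1, 1, 0, 0), each = 10))
  expect_equal(as.numeric(bal), 0, tolerance = 1e-8)

  # complete separation: Haldane-Anscombe corrected log-OR
  ysep <- rep(c(1, 0), each = 12)
  wsep <- fit_weight(ysep, ysep)
  expect_identical(attr(wsep, "flag"), "SEPARATION")
  expect_equal(as.numeric(wsep), log((12.5 * 12.5) / (0.5 * 0.5)))

  wdeg <- fit_weight(rep(0L, 24), ysep)
  expect_identical(attr(wdeg, "flag"), "DEGENERATE")
  expect_equal(as.numeric(wdeg), 0)
})

test_that("iterative logistic fit matches the closed-form log-OR on random
           non-separated tables", {
  set.seed(13)
  done <- 0
  while (done < 100) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, runif(1, 0.3, 0.7))
    s <- rbinom(n, 1, plogis(-0.5 + 1.2 * y))
    a <- sum(y & s); b <- sum(y & !s); cc <- sum(!y & s); d <- sum(!y & !s)
    if (min(a, b, cc, d) == 0) next
    w <- fit_weight(s, y)
    expect_equal(as.numeric(w), log(a * d / (b * cc)), tolerance = 1e-6)
    done <- done + 1
  }
})

test_that("the risk score is the exact weighted sum and respects its
           contracts", {
  expect_equal(risk_score(c(0, 0, 0), c(3, -1, 7)), 0)
  expect_equal(risk_score(c(1, 0, 1), c(1, 2, 3)), 4)
  perm <- sample(5)
  s <- c(1, 0, 1, 1, 0); w <- c(0.5, 1, 1.5, 2, 2.5)
  expect_equal(risk_score(s[perm], w[perm]), risk_score(s, w))
  expect_error(risk_score(c(1, 0), 1), "length")
})

test_that("a fitted model stores directions, thresholds and weights, and
           its control exceedance sits near the 5% design point", {
  set.seed(2)
  n <- 400
  x <- cbind(
    up = c(2^rnorm(n, 1), 2^rnorm(n)),       # cases higher
    dn = c(2^rnorm(n, -1), 2^rnorm(n)))      # cases lower
  y <- rep(c(1, 0), each = n)
  fit <- risk_model(x, y)
  expect_s3_class(fit, "risk_model")
  expect_identical(unname(fit$direction), c("UP", "DOWN"))
  expect_equal(unname(fit$threshold),
               unname(c(quantile(x[y == 0, 1], 0.95, type = 7),
                        quantile(x[y == 0, 2], 0.05, type = 7))))
  # by construction ~5% of training controls exceed their interval
  expect_equal(unname(fit$control_exceedance), c(0.05, 0.05),
               tolerance = 0.035)
  expect_true(all(coef(fit) > 0))  # correctly specified directions
  # RSF is the exact weighted sum of the binarized matrix
  s <- predict(fit, x, type = "binary")
  expect_identical(predict(fit, x), as.numeric(s %*% coef(fit)))
})

test_that("prediction applies the frozen model without re-estimation", {
  set.seed(3)
  x <- cbind(m = c(2^rnorm(50, 1), 2^rnorm(50)))
  y <- rep(c(1, 0), each = 50)
  fit <- risk_model(x, y)
  before <- fit[c("direction", "threshold", "weight")]
  xnew <- cbind(m = 2^rnorm(30, 5))  # wildly shifted new data
  rsf <- predict(fit, xnew)
  expect_identical(fit[c("direction", "threshold", "weight")], before)
  expect_true(all(rsf %in% c(0, fit$weight)))  # single marker: RSF ~ s
  # single-marker model: ranking by RSF equals ranking by s
  s <- predict(fit, xnew, type = "binary")[, 1]
  expect_identical(order(rsf), order(s * fit$weight))
})

test_that("model serialization round-trips and reproduces predictions", {
  set.seed(4)
  x <- cbind(a = c(2^rnorm(40, 1), 2^rnorm(40)),
             b = c(2^rnorm(40, -0.8), 2^rnorm(40)))
  y <- rep(c(1, 0), each = 40)
  fit <- risk_model(x, y)
  path <- tempfile(fileext = ".json")
  write_risk_model(fit, path)
  back <- read_risk_model(path)
  expect_identical(back$direction, fit$direction)
  expect_identical(back$threshold, fit$threshold)
  expect_identical(back$weight, fit$weight)
  expect_identical(predict(back, x), predict(fit, x))
})

test_that("weights are recovered non-negative when directions are correctly
           specified", {
  set.seed(6)
  ok <- logical(200)
  for (r in 1:200) {
    n <- 60
    x <- cbind(up = c(2^rnorm(n, 1.2), 2^rnorm(n)),
               dn = c(2^rnorm(n, -1.2), 2^rnorm(n)))
    fit <- risk_model(x, rep(c(1, 0), each = n))
    ok[r] <- all(coef(fit) >= 0)
  }
  expect_gte(mean(ok), 0.95)
})
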