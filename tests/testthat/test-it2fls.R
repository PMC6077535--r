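mk_params <- function(cons = cbind(c(250, 300, 350), c(260, 310, 360)),
                      sigma = 40) {
  ant <- array(0, dim = c(4, 3, 3))
  for (i in 1:4)
    for (j in 1:3) {
      m <- 60 + 120 * (j - 1)
      ant[i, j, ] <- c(m - 10, m + 10, sigma)
    }
  it2f_params(ant, cons)
}

test_that("parameter objects validate, encode, and round-trip", {
  p <- mk_params()
  expect_equal(it2f_dim(), 42L)
  v <- it2f_encode(p)
  expect_length(v, 42)
  p2 <- it2f_decode(v)
  expect_equal(p2$antecedents, p$antecedents)
  expect_equal(p2$consequents, p$consequents)

  # decode repairs swapped pairs instead of rejecting them
  v_swapped <- v
  v_swapped[1:2] <- v[2:1]
  expect_equal(it2f_decode(v_swapped)$antecedents, p$antecedents)

  bad_ant <- p$antecedents; bad_ant[1, 1, 3] <- -1
  expect_error(it2f_params(bad_ant, p$consequents), "sigma")
  bad_cons <- p$consequents; bad_cons[1, ] <- c(400, 300)
  expect_error(it2f_params(p$antecedents, bad_cons), "c_l")

  js <- it2f_params_to_json(p)
  p3 <- it2f_params_from_json(js)
  expect_identical(p3$antecedents, p$antecedents)
  expect_identical(p3$consequents, p$consequents)
})

test_that("fuzzification implements the uncertain-mean Gaussian FoU", {
  ant <- array(0, dim = c(4, 3, 3))
  for (i in 1:4) for (j in 1:3) ant[i, j, ] <- c(90, 90, 20)
  ant[1, 1, ] <- c(80, 100, 20)
  p <- it2f_params(ant, cbind(rep(300, 3), rep(300, 3)))

  g <- it2f_fuzzify(c(90, 90, 90, 90), p)
  # inside the uncertain-mean band the upper grade is 1
  expect_equal(g$upper[1, 1], 1)
  # collapsed FoU at the center gives the degenerate interval [1, 1]
  expect_equal(g$lower[2, 1], 1)
  expect_equal(g$upper[2, 1], 1)
  # lower grade uses the farthest edge of the band
  expect_equal(g$lower[1, 1], exp(-(90 - 80)^2 / (2 * 20^2)))

  far <- it2f_fuzzify(c(350, 350, 350, 350), p)
  expect_lt(max(far$upper[, 1]), 1e-6) # > 6 sigma from every mean

  # upper >= lower everywhere
  set.seed(1)
  for (x in runif(20, 0, 360)) {
    gg <- it2f_fuzzify(rep(x, 4), mk_params())
    expect_true(all(gg$upper >= gg$lower - 1e-12))
  }
})

test_that("firing intervals are the product t-norm of the grades", {
  g <- list(lower = matrix(1, 4, 3), upper = matrix(1, 4, 3))
  expect_equal(it2f_firing(g), cbind(f_low = rep(1, 3), f_high = rep(1, 3)))

  g$lower[2, 1] <- 0
  expect_equal(it2f_firing(g)[1, "f_low"], c(f_low = 0))

  g2 <- list(lower = matrix(c(.5, .5, 1, 1), 4, 3), # rule grades per input
             upper = matrix(c(.8, .8, 1, 1), 4, 3))
  fr <- it2f_firing(g2)
  expect_equal(unname(fr[1, ]), c(0.25, 0.64))
})

test_that("type reduction matches the exhaustive vertex oracle", {
  set.seed(2024)
  worst <- 0
  for (i in 1:2000) {
    n <- sample(2:5, 1)
    firing <- random_firing(n)
    cons <- random_consequents(n)
    got <- type_reduce_cos(firing, cons)
    ref <- brute_force_cos(firing, cons)
    worst <- max(worst, max(abs(got - ref)))
    expect_true(got[1] <= got[2] + 1e-12)
  }
  expect_lt(worst, 1e-9)
})

test_that("type reduction handles closed-form and degenerate cases", {
  # single rule: the output interval is the consequent interval
  expect_equal(unname(type_reduce_cos(cbind(0.3, 0.7),
                                      matrix(c(300, 320), 1))),
               c(300, 320))

  # type-1 limit: degenerate consequents and firings -> weighted mean
  f <- c(.2, .5, .3)
  cons <- cbind(c(250, 300, 350), c(250, 300, 350))
  y <- type_reduce_cos(cbind(f, f), cons)
  expect_equal(unname(y), rep(sum(f * cons[, 1]) / sum(f), 2))
  expect_equal(it2f_defuzzify(y[1], y[2]), sum(f * cons[, 1]) / sum(f))

  expect_error(type_reduce_cos(cbind(c(0, 0), c(0, 0)),
                               random_consequents(2)),
               class = "bcicalib_no_rule")
})

test_that("defuzzification is the interval midpoint", {
  expect_equal(it2f_defuzzify(300, 320), 310)
  expect_equal(it2f_defuzzify(310, 310), 310)
  expect_error(it2f_defuzzify(320, 300))
})

test_that("prediction respects constant models, shifts, and convexity", {
  p_const <- mk_params(cons = cbind(rep(310, 3), rep(310, 3)))
  for (x in list(c(60, 60, 60, 60), c(100, 150, 200, 250)))
    expect_equal(it2f_predict(x, p_const)$value, 310)

  # adding delta to all consequent endpoints adds delta to the output
  p <- mk_params()
  p_shift <- it2f_params(p$antecedents, p$consequents + 25)
  x <- c(70, 180, 290, 40)
  expect_equal(it2f_predict(x, p_shift)$value,
               it2f_predict(x, p)$value + 25)

  # output always within [min c_l, max c_r]
  set.seed(9)
  for (i in 1:50) {
    pr <- it2f_decode(runif(42, default_it2f_bounds()[, 1],
                            default_it2f_bounds()[, 2]))
    x <- runif(4, 0, 360)
    fr <- it2f_firing(it2f_fuzzify(x, pr))
    if (all(fr[, 2] <= 0)) next
    y <- it2f_predict(x, pr)$value
    expect_gte(y, min(pr$consequents[, 1]) - 1e-9)
    expect_lte(y, max(pr$consequents[, 2]) + 1e-9)
  }
})

test_that("zero-width FoU reproduces a type-1 Sugeno system exactly", {
  ant <- array(0, dim = c(4, 3, 3))
  for (i in 1:4)
    for (j in 1:3) ant[i, j, ] <- c(120 * (j - 1) + 30, 120 * (j - 1) + 30, 50)
  cons <- cbind(c(260, 320, 380), c(260, 320, 380))
  p <- it2f_params(ant, cons)
  type1 <- function(x) {
    w <- vapply(1:3, function(j)
      prod(exp(-(x - ant[, j, 1])^2 / (2 * ant[, j, 3]^2))), numeric(1))
    sum(w * cons[, 1]) / sum(w)
  }
  set.seed(4)
  for (i in 1:20) {
    x <- runif(4, 0, 360)
    expect_equal(it2f_predict(x, p)$value, type1(x), tolerance = 1e-9)
  }
})

test_that("batch prediction equals the single-instance path", {
  set.seed(6)
  b <- default_it2f_bounds()
  for (rep in 1:5) {
    p <- it2f_decode(runif(42, b[, 1], b[, 2]))
    X <- matrix(runif(120, 0, 360), 30, 4)
    single <- apply(X, 1, function(r) it2f_predict(r, p)$value)
    expect_equal(it2f_predict_batch(X, p), single, tolerance = 1e-10)
  }
})
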