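test_that("membership functions evaluate their closed forms", {
  tri <- mf_triangular(100, 150, 200)
  expect_equal(membership_degree(tri, 150), 1)
  expect_equal(membership_degree(tri, 100), 0)
  expect_equal(membership_degree(tri, 125), 0.5)
  g <- mf_gaussian(15, 5)
  expect_equal(membership_degree(g, 20), exp(-0.5))
  expect_equal(membership_degree(g, 15), 1)
  tz <- mf_trapezoidal(0, 0, 150, 300)
  expect_equal(membership_degree(tz, c(0, 150, 225, 300)), c(1, 1, 0.5, 0))
})

test_that("invalid membership parameters fail at construction, never later", {
  expect_error(mf_triangular(2, 1, 3), "a <= b <= c")
  expect_error(mf_gaussian(0, 0), "sigma > 0")
  expect_error(mf_trapezoidal(0, 2, 1, 3), "a <= b <= c <= d")
  expect_error(mf_triangular(1, 1, 1), "non-degenerate")
})

test_that("membership degrees stay in [0, 1] across shapes and extremes", {
  set.seed(77)
  mfs <- list(mf_triangular(-3, 0, 10), mf_gaussian(50, 0.3),
              mf_trapezoidal(-5, -1, 2, 2), mf_triangular(0, 0, 1))
  xs <- c(runif(200, -1e3, 1e3), -1e9, 1e9, 0)
  for (mf in mfs) {
    d <- membership_degree(mf, xs)
    expect_true(all(d >= 0 & d <= 1))
  }
})

simple_system <- function() {
  a <- linguistic_variable("a", c(0, 10),
                           list(lo = mf_triangular(0, 0, 5),
                                hi = mf_triangular(5, 10, 10)))
  b <- linguistic_variable("b", c(0, 10),
                           list(lo = mf_triangular(0, 0, 5),
                                hi = mf_triangular(5, 10, 10)))
  out <- linguistic_variable("y", c(0, 100),
                             list(small = mf_triangular(0, 20, 40),
                                  large = mf_triangular(60, 80, 100)))
  rules <- list(
    fuzzy_rule(list(list(var = "a", is = "lo"), list(var = "b", is = "lo")),
               list(var = "y", is = "small"), id = "S1"),
    fuzzy_rule(list(list(var = "a", is = "hi"), list(var = "b", is = "hi")),
               list(var = "y", is = "large"), id = "S2"),
    fuzzy_rule(list(list(var = "a", is = "lo"), list(var = "b", is = "hi", not = TRUE)),
               list(var = "y", is = "large"), id = "S3"))
  rule_base(rules, list(a, b), out)
}

test_that("rule activation is min over antecedents with complemented negation", {
  rb <- simple_system()
  # a=0 -> lo degree 1; b=2.5 -> lo degree 0.5
  expect_equal(evaluate_rule(rb$rules[[1]], list(a = 0, b = 2.5), rb), 0.5)
  # negated antecedent: b hi degree at 7.5 is 0.5 -> contributes 0.5
  expect_equal(evaluate_rule(rb$rules[[3]], list(a = 0, b = 7.5), rb), 0.5)
  # all-ones and plain min
  expect_equal(evaluate_rule(rb$rules[[2]], list(a = 10, b = 10), rb), 1)
  expect_error(evaluate_rule(rb$rules[[1]], list(a = 0), rb), "b")
})

test_that("inputs outside the universe are clamped with a warning", {
  rb <- simple_system()
  expect_warning(v <- evaluate_rule(rb$rules[[1]], list(a = -5, b = 0), rb),
                 "clamped")
  expect_equal(v, 1)
})

test_that("aggregation clips consequents and takes the pointwise max", {
  rb <- simple_system()
  # only S2 at full activation: aggregate equals the consequent set
  agg <- aggregate_rules(rb, list(a = 10, b = 10))
  xs <- seq(0, 100, by = 0.5)
  expect_equal(agg$fun(xs),
               membership_degree(rb$output$sets$large, xs))
  # partial activation flat-tops the triangle
  agg2 <- aggregate_rules(rb, list(a = 0, b = 2.5))  # S1 at 0.5, S3 at 0.5+
  mu <- agg2$fun(c(20, 0, 40))
  expect_equal(mu[1], 0.5)  # clipped peak
  # two rules on disjoint supports: piecewise max against a dense grid oracle
  acts <- agg2$activations
  manual <- pmax(pmin(acts[["S1"]], membership_degree(rb$output$sets$small, xs)),
                 pmin(acts[["S3"]], membership_degree(rb$output$sets$large, xs)))
  expect_equal(agg2$fun(xs), manual)
})

test_that("centroid defuzzification matches geometry and quadrature", {
  # symmetric triangle centered at 50: centroid 50 at every clipping level
  out <- linguistic_variable("y", c(0, 100), list(mid = mf_triangular(30, 50, 70)))
  for (alpha in c(1, 0.7, 0.25, 0.01)) {
    agg <- structure(list(universe = c(0, 100),
                          fun = function(x) pmin(alpha, membership_degree(out$sets$mid, x))),
                     class = "fuzzy_aggregate")
    expect_equal(defuzzify_centroid(agg, 0.1), 50, tolerance = 1e-9)
  }
  # rectangular membership on [20, 40] -> midpoint
  rect <- structure(list(universe = c(0, 100),
                         fun = function(x) as.numeric(x >= 20 & x <= 40)),
                    class = "fuzzy_aggregate")
  expect_equal(defuzzify_centroid(rect, 0.1), 30, tolerance = 1e-9)
  # clipped asymmetric triangle vs a 10x finer quadrature
  asym <- function(x) pmin(0.6, membership_degree(mf_triangular(10, 20, 70), x))
  agg3 <- structure(list(universe = c(0, 100), fun = asym),
                    class = "fuzzy_aggregate")
  xs <- seq(0, 100, by = 0.01)
  expect_equal(defuzzify_centroid(agg3, 0.1), sum(xs * asym(xs)) / sum(asym(xs)),
               tolerance = 0.1)
  # zero aggregate is an explicit error
  zero <- structure(list(universe = c(0, 100), fun = function(x) 0 * x),
                    class = "fuzzy_aggregate")
  expect_error(defuzzify_centroid(zero, 0.1), "no rule fired")
})

test_that("defuzzified outputs always lie inside the universe", {
  rb <- simple_system()
  set.seed(13)
  for (i in 1:50) {
    inp <- list(a = runif(1, 0, 10), b = runif(1, 0, 10))
    agg <- aggregate_rules(rb, inp)
    v <- tryCatch(defuzzify_centroid(agg, 0.1), error = function(e) NA)
    if (!is.na(v)) {
      expect_gte(v, 0); expect_lte(v, 100)
    }
  }
})

test_that("halving the centroid grid changes the result by less than 0.05", {
  rb <- build_confidence_system(camfuse_config())
  set.seed(19)
  for (i in 1:10) {
    inputs <- list("RightCam BB" = runif(1, 0, 720),
                   "LeftCam BB" = runif(1, 0, 720),
                   "IOU overlap" = runif(1, 0, 100))
    agg <- aggregate_rules(rb, inputs)
    expect_lt(abs(defuzzify_centroid(agg, 0.1) - defuzzify_centroid(agg, 0.05)),
              0.05)
  }
})

test_that("rule bases reject dangling references", {
  rb <- simple_system()
  expect_error(rule_base(list(fuzzy_rule(list(list(var = "zz", is = "lo")),
                                         list(var = "y", is = "small"))),
                         rb$inputs, rb$output), "unknown input")
  expect_error(rule_base(list(fuzzy_rule(list(list(var = "a", is = "zz")),
                                         list(var = "y", is = "small"))),
                         rb$inputs, rb$output), "no set")
  expect_error(rule_base(list(fuzzy_rule(list(list(var = "a", is = "lo")),
                                         list(var = "y", is = "zz"))),
                         rb$inputs, rb$output), "no set")
})
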