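test_that("neutral fraction from sweep timing follows 2^t2/(t1+2^t2)", {
  expect_equal(neutral_fraction_from_times(0, 5), 1)
  expect_equal(neutral_fraction_from_times(0, 0), 1)
  expect_equal(neutral_fraction_from_times(4, 2), 0.5)
  expect_equal(neutral_fraction_from_times(3, 0), 1 / 4)
  expect_error(neutral_fraction_from_times(-1, 2))
})

test_that("model CDF has the 1/f tail and the clonal atom at one half", {
  p <- evo_model_params(w = 1, f_min = 0.1)
  expect_equal(af_cdf(0.05, p), 0)
  expect_equal(af_cdf(p$f_min, p), 0)        # bracket vanishes at f_min
  expect_equal(af_cdf(0.5, p), 1)
  # fully neutral limit: CDF reaches 1 already just below 0.5 (nu = 0.25)
  expect_equal(af_cdf(0.4999, p), 0.125 * (10 - 1 / 0.4999))
  expect_equal(0.125 * (10 - 2), 1)
  # half-neutral model leaves mass 1 - w at the atom
  p5 <- evo_model_params(w = 0.5, f_min = 0.1)
  expect_equal(1 - af_cdf(0.4999999, p5), 0.5, tolerance = 1e-5)
  expect_error(af_cdf(0.6, p), "support")
})

test_that("inverse-CDF sampling reproduces the model distribution", {
  # pure clonal: every draw is the atom
  expect_true(all(sample_afs(evo_model_params(0), n = 100, seed = 1) == 0.5))

  # empirical CDF matches the analytic one in the fully neutral model
  p <- evo_model_params(w = 1, f_min = 0.1)
  x <- sample_afs(p, n = 1e5, seed = 2)
  grid <- seq(0.1, 0.499, length.out = 50)
  emp <- vapply(grid, function(g) mean(x <= g), numeric(1))
  expect_lt(max(abs(emp - af_cdf(grid, p))), 2 / sqrt(1e5) * 1.5)

  # atom mass: fraction of non-clonal draws converges to w
  for (w in c(0.3, 0.7)) {
    x <- sample_afs(evo_model_params(w), n = 1e4, seed = 3)
    frac <- mean(x != 0.5)
    expect_lt(abs(frac - w), 3 * sqrt(w * (1 - w) / 1e4))
  }

  # deterministic under a seed
  expect_identical(sample_afs(p, n = 50, seed = 9),
                   sample_afs(p, n = 50, seed = 9))
})

test_that("closed-form MATH is continuous, clonal-zero and degenerate", {
  # delta_w at f_min = 0.1
  ci <- closed_form_intermediates(0.8, 0.1)
  expect_equal(ci$delta_w, (sqrt(1.32) - 1) / 1.6, tolerance = 1e-12)
  expect_equal(ci$nu, 2 * 0.8 * 0.1 / 0.8)

  # clonal regime is exactly zero
  expect_equal(math_closed_form(c(0, 0.2, 0.5), 0.1), c(0, 0, 0))

  # continuity at both branch boundaries over a grid of f_min
  for (fm in c(0.05, 0.1, 0.2, 0.3)) {
    dw <- closed_form_intermediates(1, fm)$delta_w
    for (b in c(0.5, 0.5 + dw)) {
      lo <- math_closed_form(b, fm)
      hi <- math_closed_form(min(b + 1e-12, 1), fm)
      expect_lt(abs(hi - lo), 1e-8)
    }
  }

  # hand value at w = 1, f_min = 0.1
  expect_equal(math_closed_form(1, 0.1),
               148.26 * (sqrt(0.0625 + 1 / 36) - 0.25) * 6,
               tolerance = 1e-12)

  # the neutral regime is not one-to-one: the score peaks at 1/2 + delta_w
  dw <- closed_form_intermediates(1, 0.1)$delta_w
  peak <- math_closed_form(0.5 + dw, 0.1)
  expect_gt(peak, math_closed_form(0.99, 0.1))
  expect_gt(peak, math_closed_form(0.52, 0.1))
  # so two distinct w share a MATH score (evolutionary degeneracy)
  f <- function(w) math_closed_form(w, 0.1) - 60
  w_left <- uniroot(f, c(0.51, 0.5 + dw), tol = 1e-12)$root
  w_right <- uniroot(f, c(0.5 + dw, 1), tol = 1e-12)$root
  expect_equal(math_closed_form(w_left, 0.1),
               math_closed_form(w_right, 0.1), tolerance = 1e-6)
  expect_gt(w_right - w_left, 0.05)
})

test_that("Monte-Carlo MATH agrees with the closed form", {
  set.seed(79)
  for (w in c(0.6, 0.8, 1)) {
    x <- sample_afs(evo_model_params(w), n = 1e5, seed = 80 + w * 10)
    expect_lt(abs(math_score(x) - math_closed_form(w, 0.1)), 1.0)
  }
})

test_that("Gaussian read noise has the binomial-approximation variance", {
  # sd at f = 0.5, N = 100 is 0.05
  x <- add_read_noise(rep(0.5, 1e5), read_depth = 100, seed = 83)
  expect_lt(abs(sd(x) - 0.05), 0.002)
  expect_lt(abs(mean(x) - 0.5), 0.002)

  # huge depth: noise vanishes
  y <- add_read_noise(rep(0.3, 1000), read_depth = 1e9, seed = 84)
  expect_lt(max(abs(y - 0.3)), 1e-3)

  # clipping keeps draws inside (0, 1)
  z <- add_read_noise(rep(0.01, 1000), read_depth = 10, seed = 85)
  expect_true(all(z >= 1e-3 & z <= 1 - 1e-3))

  # optional re-application of the measurement cutoff
  zf <- add_read_noise(rep(0.11, 1000), read_depth = 50, seed = 86,
                       refilter_f_min = 0.1)
  expect_true(all(zf >= 0.1))

  # noise lifts MATH above zero in the clonal regime
  base <- sample_afs(evo_model_params(0.3), n = 301, seed = 87)
  expect_equal(math_score(base), 0)
  noised <- add_read_noise(base, read_depth = 100, seed = 88)
  expect_gt(math_score(noised), 0)
})

test_that("degeneracy surface: equal w gives bitwise-equal MATH", {
  g <- degeneracy_surface(seq(0, 10, length.out = 20),
                          seq(0, 6, length.out = 20))
  expect_equal(nrow(g), 400)
  # t1 = 0 row: w identically 1
  expect_true(all(g$w[g$t1 == 0] == 1))
  # pointwise recomputation
  expect_identical(g$math,
                   math_closed_form(neutral_fraction_from_times(g$t1, g$t2)))
  # equal w => identical MATH, bitwise
  for (w in unique(g$w[duplicated(g$w)])) {
    expect_length(unique(g$math[g$w == w]), 1)
  }
})
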