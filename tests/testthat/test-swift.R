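test_that("log_compress maps the unit range onto [0, ln 2]", {
  G <- gray_image(matrix(c(0, 1, 0.5, 0.25), 2, 2), "unit")
  u <- log_compress(G)
  expect_equal(u[1, 1], 0)
  expect_equal(u[2, 1], log(2))
  expect_equal(u[1, 2], log(1.5))
  expect_true(all(u >= 0 & u <= log(2)))
})

test_that("adjustment_sigma is the corrected sample standard deviation", {
  expect_equal(adjustment_sigma(matrix(0.3, 5, 5)), 0)
  expect_equal(adjustment_sigma(matrix(c(0, 2), 1, 2)), sqrt(2))
  u <- rand_unit(16, 16, seed = 8)
  direct <- sqrt(sum((u - mean(u))^2) / (length(u) - 1))
  expect_equal(adjustment_sigma(u), direct, tolerance = 1e-12)
  expect_error(adjustment_sigma(matrix(1, 1, 1)),
               class = "ncfuse_validation_error")
})

test_that("adjustment_eta is u^lambda / lambda!", {
  expect_equal(adjustment_eta(matrix(1, 1, 2), 3L), matrix(1 / 6, 1, 2))
  expect_equal(adjustment_eta(matrix(0, 2, 2), 3L), matrix(0, 2, 2))
  expect_equal(adjustment_eta(matrix(0.5, 1, 2), 3L)[1, 1], 0.125 / 6)
  # monotone non-decreasing in u for u >= 0
  u <- seq(0, log(2), length.out = 50)
  expect_true(all(diff(adjustment_eta(matrix(u, 1), 3L)[1, ]) >= 0))
  expect_error(adjustment_eta(matrix(1, 2, 2), 0L),
               class = "ncfuse_validation_error")
})

test_that("tone_map honours both parse modes", {
  # fraction mode: zero numerator -> f = 1
  u <- matrix(atan(0.3), 2, 2)
  eta <- adjustment_eta(u, 3L)
  f <- tone_map(u, sigma = 0.3, eta = eta, swift_params())
  expect_equal(f, matrix(1, 2, 2), tolerance = 1e-12)
  # fraction mode: huge gamma -> no enhancement anywhere
  u2 <- matrix(seq(0.01, log(2), length.out = 16), 4, 4)
  f2 <- tone_map(u2, 0.2, adjustment_eta(u2, 3L),
                 swift_params(gamma = 1e9))
  expect_equal(f2, matrix(1, 4, 4), tolerance = 1e-6)
  # both modes match an element-wise oracle on a 4x4 grid
  sig <- 0.17
  eta2 <- adjustment_eta(u2, 3L)
  frac <- tone_map(u2, sig, eta2, swift_params(parse_mode = "fraction"))
  expect_equal(frac, exp((tan(u2) - sig) / (1 * (exp(u2) - eta2))),
               tolerance = 1e-12)
  lit <- tone_map(u2, sig, eta2, swift_params(gamma = 1.3, parse_mode = "literal"))
  expect_equal(lit, exp(tan(u2) - sig * exp(u2) - eta2)^1.3, tolerance = 1e-12)
})

test_that("fraction-mode denominator cannot vanish on the reachable domain", {
  u <- seq(0, log(2), length.out = 10000)
  expect_true(all(exp(u) - u^3 / 6 > 0.9))
})

test_that("rescale_dynamic_range restores [0, 1]", {
  out <- rescale_dynamic_range(matrix(c(2, 4, 3, 2), 2, 2))
  expect_equal(min(as.matrix(out)), 0)
  expect_equal(max(as.matrix(out)), 1)
  expect_equal(as.matrix(out)[1, 1], 0)
  expect_equal(as.matrix(out)[2, 1], 1)
  # degenerate constant input -> mid-gray
  expect_equal(as.matrix(rescale_dynamic_range(matrix(7, 3, 3))),
               matrix(0.5, 3, 3))
})

test_that("swift_enhance composes the chain deterministically", {
  const <- gray_image(matrix(0.4, 5, 5), "unit")
  enh <- swift_enhance(const)
  expect_equal(as.matrix(enh$image), matrix(0.5, 5, 5))
  expect_equal(enh$intermediates$sigma_adj, 0)

  G <- gray_image(rand_unit(16, 16, seed = 14), "unit")
  e1 <- swift_enhance(G); e2 <- swift_enhance(G)
  expect_identical(as.matrix(e1$image), as.matrix(e2$image))
  # non-constant input spans the full unit range after rescaling
  expect_equal(min(as.matrix(e1$image)), 0)
  expect_equal(max(as.matrix(e1$image)), 1)
})

test_that("swift keeps the phantom's contrast (frozen regression)", {
  pair <- fixture_pair_default()
  G <- normalize_image(pair$ct)
  enh <- swift_enhance(G)
  sd_in <- stats::sd(as.matrix(G))
  sd_out <- stats::sd(as.matrix(enh$image))
  expect_gte(sd_out, 0.5 * sd_in)
  expect_equal(sd_out, 0.322016, tolerance = 1e-6)
})
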