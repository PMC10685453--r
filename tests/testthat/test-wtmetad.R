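# Well-tempered metadynamics engine: tempering rule, grid bias evaluation
# against a brute-force oracle, c(t) properties, run self-consistency.

test_that("next kernel height follows the tempering rule", {
  led <- empty_ledger(d = 1, bias_factor = 20, thermo = thermo310)
  expect_identical(next_height(led, 0, w0 = 1.2), 1.2)

  led1 <- hills_ledger(2, 0, 0.5, 1.2, bias_factor = 20,
                       thermo = thermo310, pace = 2)
  expect_equal(next_height(led1, 0, w0 = 1.2),
               1.2 * exp(-1.2 / (19 * thermo310$kT)), tolerance = 1e-12)
  # untempered limit: gamma -> infinity leaves heights at w0
  ledinf <- hills_ledger(2, 0, 0.5, 1.2, bias_factor = 1e9,
                         thermo = thermo310, pace = 2)
  expect_equal(next_height(ledinf, 0, w0 = 1.2), 1.2, tolerance = 1e-6)
  expect_error(hills_ledger(2, 0, 0.5, 1.2, bias_factor = 0.9,
                            thermo = thermo310, pace = 2), "gamma")
})

test_that("grid bias matches single-kernel closed forms", {
  led <- hills_ledger(2, 0, 0.5, 1.2, bias_factor = 20,
                      thermo = thermo310, pace = 2)
  g <- evaluate_bias(led, bias_grid(-5, 5, 201))
  z <- g$axes[[1]]
  expect_equal(g$values[z == 0], 1.2, tolerance = 1e-14)
  expect_equal(g$values[z == 0.5], 1.2 * exp(-0.5), tolerance = 1e-14)
  empty <- evaluate_bias(empty_ledger(), bias_grid(-5, 5, 21))
  expect_true(all(empty$values == 0))
})

test_that("grid accumulation equals brute-force summation", {
  for (d in 1:2) {
    led <- random_ledger(if (d == 1) 1000 else 200, d = d)
    n <- if (d == 1) 401 else 81
    g <- evaluate_bias(led, bias_grid(rep(-6, d), rep(6, d), rep(n, d)))
    pts <- as.matrix(do.call(expand.grid, g$axes))
    expect_lt(max(abs(as.numeric(g$values) - brute_bias(led, pts))), 1e-10)
    # truncated fast path stays within its documented error
    gt <- evaluate_bias(led, bias_grid(rep(-6, d), rep(6, d), rep(n, d)),
                        truncation = 6)
    expect_lt(max(abs(gt$values - g$values)), 1e-5)
  }
})

test_that("c(t) obeys shift identity and matches quadrature", {
  g <- bias_grid(-5, 5, 501)
  expect_equal(update_c_of_t(g, 20, thermo310), 0, tolerance = 1e-12)
  g$values[] <- 3.7
  expect_equal(update_c_of_t(g, 20, thermo310), 3.7, tolerance = 1e-10)
  g$values[] <- 3.7
  expect_equal(update_c_of_t(g, 5, thermo310), 3.7, tolerance = 1e-10)

  # single-Gaussian bias vs adaptive quadrature oracle
  led <- hills_ledger(2, 0.7, 0.5, 1.1, bias_factor = 20,
                      thermo = thermo310, pace = 2)
  gb <- evaluate_bias(led, bias_grid(-5, 5, 2001))
  beta <- thermo310$beta
  V <- function(z) 1.1 * exp(-(z - 0.7)^2 / 0.5)
  num <- integrate(function(z) exp(20 / 19 * beta * V(z)), -5, 5,
                   rel.tol = 1e-12)$value
  den <- integrate(function(z) exp(1 / 19 * beta * V(z)), -5, 5,
                   rel.tol = 1e-12)$value
  expect_equal(update_c_of_t(gb, 20, thermo310), log(num / den) / beta,
               tolerance = 1e-6)
})

test_that("a WTMetaD run is internally consistent", {
  res <- wtmetad_run_1d()
  led <- res$ledger
  n <- length(led)
  expect_gt(n, 1000)
  # replay: each stored height is reproducible from the ledger prefix
  set.seed(4)
  for (k in sample(2:n, 50)) {
    prefix <- hills_ledger(led$time[1:(k - 1)],
                           led$center[1:(k - 1), , drop = FALSE],
                           led$sigma[1:(k - 1), , drop = FALSE],
                           led$height[1:(k - 1)],
                           led$bias_factor, led$thermo, led$pace)
    expect_equal(next_height(prefix, led$center[k, ], w0 = 1.2),
                 led$height[k], tolerance = 2e-2)
  }
  expect_identical(next_height(empty_ledger(), 0, 1.2), led$height[1])
  # heights bounded by the tempering envelope
  Vmax <- max(evaluate_bias(led, bias_grid(-12, 12, 481))$values)
  expect_true(all(led$height <= 1.2 + 1e-12))
  expect_true(all(led$height >= 1.2 * exp(-Vmax / (19 * thermo310$kT)) - 1e-12))
  # c(t) rises steadily on a bounded domain; the log-ratio estimator admits
  # a small early-time ripple, so allow a few-thousandths-of-kT slack
  dc <- diff(res$reweight$c_of_t)
  expect_true(all(dc > -5e-3))
  expect_gt(sum(dc), 50)
  late <- res$reweight$c_of_t[-seq_len(length(dc) %/% 2)]
  expect_true(all(diff(late) > -1e-4))
})

test_that("zero depositions reduce to the unbiased trajectory", {
  sf <- double_well_1d()
  dm <- diffusion_model("constant", 0.5)
  plain <- simulate_overdamped(sf, dm, thermo310, dt = 0.01, n_steps = 5e3,
                               seed = 31, stride = 10)
  biased <- run_wtmetad(sf, dm, thermo310, dt = 0.01, n_steps = 5e3,
                        seed = 31, stride = 10, pace = 1e6,
                        grid_spacing = 0.5)
  expect_identical(plain$values, biased$trajectory$values)
  expect_identical(length(biased$ledger), 0L)
})

test_that("long-time bias converges to the tempered negative of F", {
  res <- wtmetad_run_1d()
  sf <- double_well_1d()
  g <- evaluate_bias(res$ledger, bias_grid(-12, 12, 481), truncation = 6)
  z <- g$axes[[1]]
  inner <- abs(z) < 9
  Ftrue <- sf$f(z)
  pred <- -(1 - 1 / 20) * (Ftrue - min(Ftrue))
  dev <- (g$values - max(g$values)) - (pred - max(pred))
  expect_lt(max(abs(dev[inner])), 1.5)
})
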