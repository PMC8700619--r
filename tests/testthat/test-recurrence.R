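test_that("phase-space diameter is the exact maximal pairwise distance", {
  a <- matrix(c(0, 0), 1, 2)
  b <- matrix(c(3, 4), 1, 2)
  expect_equal(phase_space_diameter(a, b), 5)
  p <- matrix(c(1, 1), 1, 2)
  expect_equal(phase_space_diameter(p, p), 0)
  set.seed(41)
  x <- matrix(rnorm(150), 50, 3)
  y <- matrix(rnorm(150), 50, 3)
  expect_equal(phase_space_diameter(x, y), oracle_diameter(rbind(x, y)),
               tolerance = 1e-12)
})

test_that("diameter-rule epsilon is the exact fraction of the diameter", {
  a <- matrix(c(0, 0), 1, 2); b <- matrix(c(3, 4), 1, 2)
  expect_equal(epsilon_from_diameter(a, b, 0.10), 0.5)
  expect_equal(epsilon_from_diameter(a, b, 1.0), 5)
  p <- matrix(1, 2, 2)
  expect_error(epsilon_from_diameter(p, p), "degenerate")
})

test_that("cross-recurrence matrix uses an inclusive threshold and transposes", {
  x <- matrix(rnorm(30), 15, 2)
  cr <- cross_recurrence_matrix(x, x, epsilon = 0.5)
  expect_true(all(diag(cr$cells) == 1))          # zero self-distance
  expect_identical(cross_recurrence_matrix(matrix(0), matrix(10), 1)$cells,
                   matrix(0L))
  set.seed(42)
  a <- matrix(rnorm(40), 20, 2); b <- matrix(rnorm(44), 22, 2)
  ab <- cross_recurrence_matrix(a, b, 1)
  ba <- cross_recurrence_matrix(b, a, 1)
  expect_identical(ab$cells, t(ba$cells))
  # inclusive tie: distance exactly epsilon counts
  expect_identical(cross_recurrence_matrix(matrix(0), matrix(1), 1)$cells,
                   matrix(1L))
})

test_that("recurrence rate equals the direct cell count", {
  expect_equal(recurrence_rate(matrix(1L, 2, 3)), 1)
  m <- matrix(0L, 3, 3); m[cbind(1:3, c(1, 2, 1))] <- 1L
  expect_equal(recurrence_rate(m), 1 / 3)
  set.seed(8)
  r <- matrix(rbinom(400, 1, 0.3), 20)
  expect_equal(recurrence_rate(r), oracle_rr(r))
})

test_that("RR is non-decreasing in epsilon", {
  set.seed(101)
  a <- matrix(rnorm(90), 30, 3); b <- matrix(rnorm(90), 30, 3)
  eps <- sort(runif(50, 0, 4))
  rrs <- vapply(eps, function(e)
    recurrence_rate(cross_recurrence_matrix(a, b, e)), numeric(1))
  expect_true(all(diff(rrs) >= 0))
})

test_that("epsilon calibration lands on an achievable step closest to target", {
  set.seed(55)
  x <- make_sine(160, 40, noise_sd = 0.3)
  y <- make_sine(160, 40, noise_sd = 0.3, phase = 1)
  ta <- delay_embed(zscore(x), 3, 5)
  tb <- delay_embed(zscore(y), 3, 5)
  cal <- calibrate_epsilon(ta, tb, target_rr = 0.1, rr_tolerance = 1e-3)
  m <- nrow(ta) * nrow(tb)
  expect_equal(cal$achieved_rr * m, round(cal$achieved_rr * m),
               tolerance = 1e-9)                       # exact step value
  expect_lte(abs(cal$achieved_rr - 0.1), 1e-3)
  # recomputing the rate at the calibrated epsilon reproduces achieved_rr
  cr <- cross_recurrence_matrix(ta, tb, cal$epsilon)
  expect_equal(recurrence_rate(cr), cal$achieved_rr, tolerance = 1e-12)
  # a target adjacent to 1 pushes epsilon to the maximal distance
  cal1 <- suppressWarnings(calibrate_epsilon(ta, tb, target_rr = 1 - 1e-9))
  expect_equal(cal1$achieved_rr, 1)
  # degenerate: all distances equal
  expect_error(calibrate_epsilon(matrix(0, 3, 1), matrix(1, 3, 1), 0.1),
               "degenerate")
})

test_that("calibration equals a sort-based scan on random pairs", {
  for (r in 1:25) {
    set.seed(700 + r)
    a <- matrix(rnorm(36), 12, 3); b <- matrix(rnorm(36), 12, 3)
    target <- runif(1, 0.05, 0.5)
    cal <- calibrate_epsilon(a, b, target, rr_tolerance = 1)
    d <- as.vector(recurnet:::cpp_cross_dist(a, b, FALSE))
    u <- sort(unique(d))
    rrs <- vapply(u, function(e) mean(d <= e), numeric(1))
    i <- which.min(abs(rrs - target))
    expect_equal(cal$epsilon, u[i], tolerance = 0)
    expect_equal(cal$achieved_rr, rrs[i], tolerance = 0)
  }
})

test_that("diagonal line histograms match naive per-diagonal enumeration", {
  expect_identical(diagonal_line_histogram(diag(1L, 3)), c("3" = 1L))
  expect_identical(diagonal_line_histogram(matrix(1L, 3, 3)),
                   c("2" = 2L, "3" = 1L))
  expect_identical(length(diagonal_line_histogram(matrix(0L, 3, 3))), 0L)
  set.seed(61)
  for (r in 1:20) {
    m <- matrix(rbinom(25 * 25, 1, runif(1, 0.1, 0.6)), 25)
    expect_identical(diagonal_line_histogram(m), oracle_diag_hist(m))
  }
  # rectangular
  m <- matrix(rbinom(15 * 24, 1, 0.4), 15)
  expect_identical(diagonal_line_histogram(m), oracle_diag_hist(m))
})

test_that("diagonal entropy follows the Shannon definition", {
  expect_equal(diagonal_entropy(c("4" = 1)), 0)
  expect_equal(diagonal_entropy(c("2" = 5, "3" = 5)), log(2))
  expect_equal(diagonal_entropy(c("2" = 5, "3" = 5), base = "log2"), 1)
  set.seed(3)
  h <- setNames(sample(1:20, 6), as.character(2:7))
  expect_lte(diagonal_entropy(h), log(6))
  expect_equal(diagonal_entropy(h), diagonal_entropy(h * 13),
               tolerance = 1e-12)                 # count-scale invariance
  expect_equal(diagonal_entropy(integer(0)), 0)
})

test_that("crqa_pair is symmetric and separates periodic from noise pairs", {
  set.seed(88)
  x <- make_sine(150, 30, noise_sd = 0.2)
  y <- make_sine(150, 30, noise_sd = 0.2, phase = 0.7)
  par <- list(tau = 5, m = 3)
  m1 <- crqa_pair(x, y, par)
  m2 <- crqa_pair(y, x, par)
  expect_equal(m1$rr, m2$rr, tolerance = 1e-12)
  expect_equal(m1$entropy, m2$entropy, tolerance = 1e-12)
  expect_equal(m1$epsilon_ent, m2$epsilon_ent, tolerance = 1e-12)
  # identical profiles recur along the main diagonal
  self <- crqa_pair(x, x, par)
  expect_gt(self$rr, 0)
  # under fixed RR, a periodic identical pair spreads its (long, edge-
  # truncated) diagonal lines over many length classes, whereas white noise
  # concentrates lines at the shortest lengths: periodic pairs carry the
  # HIGHER diagonal entropy
  ent_sine <- ent_noise <- numeric(20)
  for (r in 1:20) {
    set.seed(900 + r)
    s <- make_sine(150, 30, noise_sd = 0.01)
    ent_sine[r] <- suppressWarnings(crqa_pair(s, s, par)$entropy)
    w1 <- rnorm(150); w2 <- rnorm(150)
    ent_noise[r] <- crqa_pair(w1, w2, par)$entropy
  }
  expect_gt(mean(ent_sine), mean(ent_noise))
})
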