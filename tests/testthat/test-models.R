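test_that("sparse-recovery inference matches an independent ISTA oracle", {
  # d = 0 with a contraction-valid W: the zero fixed point
  A <- rand_mat(4, 10, 61)
  w <- ista_weights(A, tau = 0.2)
  res0 <- sparse_recovery_infer(w, A, rep(0, 4))
  expect_equal(res0$x, rep(0, 10))

  # 4 x 10 instance: limit agrees with a hand-rolled ISTA limit
  set.seed(62)
  xs <- rep(0, 10); xs[c(3, 8)] <- c(2, -1)
  d <- as.vector(A %*% xs)
  res <- sparse_recovery_infer(w, A, d, tol = 1e-13, max_iter = 30000)
  cstep <- 0.99 / make_matrix_map(A)$norm_bound^2
  x_ref <- rep(0, 10)
  for (k in 1:30000) {
    g <- x_ref - cstep * as.numeric(t(A) %*% (A %*% x_ref - d))
    xn <- sign(g) * pmax(abs(g) - cstep * 0.2, 0)
    if (max(abs(xn - x_ref)) < 1e-15) { x_ref <- xn; break }
    x_ref <- xn
  }
  expect_equal(res$x, x_ref, tolerance = 1e-8)
  # fixed-point residual honoured at return
  expect_true(res$state$converged)
})

test_that("IDM inference agrees with the convex oracle and respects feasibility", {
  skip_if_not_installed("pracma")
  set.seed(63)
  A <- matrix(rnorm(8 * 20), 8, 20)
  s <- rep(0, 20); s[c(4, 11)] <- c(1, 2)
  d <- as.vector(A %*% s)
  res <- idm_infer(idm_weights(diag(20)), A, d, tol = 1e-11, max_iter = 60000)
  xo <- bp_oracle(A, d)
  expect_lt(sqrt(sum((res$x - xo)^2)) / sqrt(sum(xo^2)), 1e-3)
  expect_lt(sqrt(sum((A %*% res$x - d)^2)), 1e-6 * (1 + sqrt(sum(d^2))))
  # objective within 1e-3 relative of the oracle optimum
  expect_lt(abs(sum(abs(res$x)) - sum(abs(xo))) / sum(abs(xo)), 1e-3)
  # support of the recovered signal matches the oracle's
  expect_identical(which(abs(res$x) > 1e-4), which(abs(xo) > 1e-4))

  # zero measurements: zero is the feasible minimizer
  res0 <- idm_infer(idm_weights(diag(20)), A, rep(0, 8))
  expect_equal(res0$x, rep(0, 20))
})

test_that("CT inference enforces the box bit-exactly and the fidelity ball", {
  geom <- radon_geometry(8, 5, 11)
  rad <- build_radon_map(geom)
  ph <- generate_phantom(8, seed = 31)
  d <- map_forward(rad, as.vector(t(ph)))

  # identity prox (no learned regularization), delta = 0-ish clean data
  idprox <- structure(list(weights = list(kind = "id"), dim = 64,
                           apply = identity, lipschitz_certified = TRUE),
                      class = "learned_prox")
  res <- ct_infer(ct_weights(idprox, delta = 1e-8), rad, d,
                  tol = 1e-10, max_iter = 20000)
  expect_true(all(res$x >= 0 & res$x <= 1))
  expect_lt(sqrt(sum((map_forward(rad, res$x) - d)^2)), 1e-8 + 1e-4)

  # noisy data with the discrepancy-principle delta
  dn <- add_beam_noise(d, 0.015, seed = 32)
  pr <- learned_prox(64, image_side = 8, seed = 33)
  resn <- ct_infer(ct_weights(pr), rad, dn, tol = 1e-9, max_iter = 6000)
  expect_identical(range(pmin(pmax(resn$x, 0), 1)), range(resn$x))  # clamp exact
  expect_lte(sqrt(sum((map_forward(rad, resn$x) - dn)^2)), resn$delta + 1e-6)
})

test_that("inference is deterministic and tightening tol reduces the residual", {
  ds <- generate_dictionary_dataset(20, 5, 8, 2, 1, seed = 9)
  w <- idm_init_weights(20, seed = 9)
  r1 <- idm_infer(w, ds$A, ds$D[, 1], tol = 1e-8, max_iter = 4000)
  r2 <- idm_infer(w, ds$A, ds$D[, 1], tol = 1e-8, max_iter = 4000)
  expect_identical(r1$x, r2$x)

  resids <- vapply(c(1e-2, 1e-4, 1e-6), function(tl) {
    idm_infer(w, ds$A, ds$D[, 1], tol = tl, max_iter = 50000)$state$residual
  }, numeric(1))
  expect_true(all(diff(resids) < 0))
})

test_that("CT reconstruction beats unfiltered backprojection on noisy sinograms", {
  geom <- radon_geometry(16, 8, 23)
  rad <- build_radon_map(geom)
  pr <- learned_prox(256, image_side = 16, seed = 41)
  wts <- ct_weights(pr)
  psnr_gain <- numeric(5)
  for (i in 1:5) {
    ph <- generate_phantom(16, seed = 400 + i)
    d <- add_beam_noise(map_forward(rad, as.vector(t(ph))), 0.015, seed = 500 + i)
    res <- ct_infer(wts, rad, d, tol = 1e-8, max_iter = 2500)
    est <- matrix(res$x, 16, 16, byrow = TRUE)
    bp <- map_adjoint(rad, d); bp <- project_box(bp / max(bp), 0, 1)
    psnr_gain[i] <- psnr(ph, est) - psnr(ph, matrix(bp, 16, 16, byrow = TRUE))
  }
  expect_true(all(psnr_gain > 0))
})
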