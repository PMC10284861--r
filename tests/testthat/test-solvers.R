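test_that("fixed-point iteration contracts geometrically and stops correctly", {
  st <- iterate_to_fixed_point(function(x) x / 2, 1, tol = 1e-6, max_iter = 100)
  expect_true(st$converged)
  expect_lt(abs(st$x), 1e-5)
  # residuals halve every step
  ratios <- st$history[-1] / st$history[-st$k]
  expect_true(all(abs(ratios - 0.5) < 1e-12))
  expect_equal(length(st$history), st$k)
  expect_equal(st$residual, st$history[st$k])

  # identity: every point is fixed, returns after one iteration
  st2 <- iterate_to_fixed_point(identity, c(1, 2), tol = 1e-8)
  expect_equal(st2$k, 1L)
  expect_equal(st2$residual, 0)
  expect_equal(st2$x, c(1, 2))

  expect_error(iterate_to_fixed_point(function(x) x * 1e200, 1, tol = 1e-6, max_iter = 10),
               "diverged at iteration")
})

test_that("averaged operators built from a contraction converge (Banach)", {
  set.seed(21)
  for (s in 1:5) {
    Q <- rand_mat(6, 6, 100 + s)
    Q <- 0.9 * Q / svd(Q)$d[1]      # 0.9-contraction
    b <- rnorm(6)
    T_fn <- function(x) 0.5 * x + 0.5 * (Q %*% x + b)
    st <- iterate_to_fixed_point(T_fn, rnorm(6), tol = 1e-10, max_iter = 2000)
    expect_true(st$converged)
    expect_lt(sqrt(sum((T_fn(st$x) - st$x)^2)), 2e-9 * (1 + sqrt(sum(st$x^2))))
    # residual decay for averaged maps: much smaller after 200 than after 20
    expect_lt(st$history[min(200, st$k)], st$history[20])
  }
})

test_that("the shrink-based model operator reproduces ISTA and least squares", {
  # A = W = I, theta = 0: x - (x - d) = d in one application
  n <- 4
  I <- make_matrix_map(diag(n))
  d <- rnorm(n)
  T_fn <- make_pg_operator(I, I, d, 0)
  expect_equal(T_fn(rnorm(n)), d)

  # theta = 0, W = c A^T: fixed points satisfy the normal equations
  A <- rand_mat(4, 6, 33)
  cstep <- 0.9 / svd(A)$d[1]^2
  W <- make_matrix_map(cstep * t(A))
  d <- rnorm(4)
  T0 <- make_pg_operator(W, make_matrix_map(A), d, 0)
  st <- iterate_to_fixed_point(T0, rep(0, 6), tol = 1e-13, max_iter = 20000)
  expect_lt(max(abs(t(A) %*% (A %*% st$x - d))), 1e-8)

  # with theta > 0 the iterates match a hand-rolled ISTA step by step
  A3 <- rand_mat(2, 3, 44)
  d3 <- rnorm(2)
  c3 <- 0.8 / svd(A3)$d[1]^2
  tau <- 0.3
  T1 <- make_pg_operator(make_matrix_map(c3 * t(A3)), make_matrix_map(A3),
                         d3, c3 * tau)
  x_pkg <- rep(0, 3); x_ref <- rep(0, 3)
  for (k in 1:50) {
    x_pkg <- T1(x_pkg)
    g <- x_ref - c3 * as.numeric(t(A3) %*% (A3 %*% x_ref - d3))
    x_ref <- sign(g) * pmax(abs(g) - c3 * tau, 0)
    expect_equal(x_pkg, x_ref, tolerance = 1e-10)
  }

  expect_error(make_pg_operator(W, make_matrix_map(A3), d3, 0.1), "shape")
})

test_that("an L-ADMM step is stationary at a solution and side-effect free", {
  n <- 3
  I <- identity_map(n)
  d <- c(1, -2, 0.5)
  prob <- ladmm_problem(K = I, M = I, d = d, delta = 0,
                        prox_f = function(v, t) v,  # f = 0
                        prox_h = function(v, t) v)
  st <- ladmm_init(prob, d)
  st$p <- d; st$w <- d
  st2 <- ladmm_step(st, prob)
  expect_equal(st2$x, d, tolerance = 1e-14)
  expect_equal(st2$p, d, tolerance = 1e-14)
  expect_equal(st2$nu1, rep(0, n))
  # input state untouched
  expect_equal(st$x, d)
})

test_that("L-ADMM solves the tiny basis-pursuit instance exactly", {
  # min |x|_1 s.t. 2 x1 + x2 = 2 has unique vertex solution (1, 0)
  A <- matrix(c(2, 1), 1, 2)
  res <- idm_infer(idm_weights(diag(2)), A, 2, tol = 1e-12, max_iter = 5000)
  expect_equal(res$x, c(1, 0), tolerance = 1e-4)
  expect_true(res$state$converged)
})

test_that("L-ADMM limits match the LP oracle on random basis-pursuit instances", {
  skip_if_not_installed("pracma")
  set.seed(77)
  for (t in 1:5) {
    A <- matrix(rnorm(8 * 20), 8, 20)
    s <- rep(0, 20); s[sample(20, 2)] <- rnorm(2)
    d <- as.vector(A %*% s)
    res <- idm_infer(idm_weights(diag(20)), A, d, tol = 1e-11, max_iter = 60000)
    xo <- bp_oracle(A, d)
    expect_lt(sqrt(sum((res$x - xo)^2)) / sqrt(sum(xo^2)), 1e-3)
  }
})

test_that("delta = 0 with f = 0 forces feasibility: the limit is d", {
  I <- identity_map(4)
  d <- rnorm(4)
  prob <- ladmm_problem(K = I, M = I, d = d, delta = 0,
                        prox_f = function(v, t) v)
  fps <- ladmm_solve(prob, tol = 1e-12, max_iter = 10000)
  expect_equal(fps$x, d, tolerance = 1e-6)
})

test_that("unconverged runs are flagged, not fatal", {
  I <- identity_map(3)
  prob <- ladmm_problem(K = I, M = I, d = c(1, 1, 1), delta = 0, prox_f = prox_l1)
  fps <- ladmm_solve(prob, tol = 1e-14, max_iter = 3)
  expect_false(fps$converged)
  expect_equal(fps$k, 3L)
})

test_that("L-ADMM limits are invariant under row relabeling of the system", {
  set.seed(55)
  A <- matrix(rnorm(5 * 12), 5, 12)
  s <- rep(0, 12); s[c(2, 9)] <- c(1.5, -1)
  d <- as.vector(A %*% s)
  res1 <- idm_infer(idm_weights(diag(12)), A, d, tol = 1e-11, max_iter = 40000)
  perm <- c(4, 1, 5, 2, 3)
  res2 <- idm_infer(idm_weights(diag(12)), A[perm, ], d[perm],
                    tol = 1e-11, max_iter = 40000)
  expect_equal(res1$x, res2$x, tolerance = 1e-5)
})

test_that("divergence in an L-ADMM update names the culprit", {
  I <- identity_map(2)
  prob <- ladmm_problem(K = I, M = I, d = c(1, 1), delta = 0,
                        prox_f = function(v, t) v * NaN)
  expect_error(ladmm_step(ladmm_init(prob), prob), "p update")
})

test_that("batched IDM inference follows the single-instance iterates", {
  ds <- generate_dictionary_dataset(20, 5, 8, 2, 3, seed = 5)
  w <- idm_weights(diag(20))
  many <- idm_infer_many(w, ds$A, ds$D, tol = 1e-30, max_iter = 400, chunk = 400)
  for (i in 1:3) {
    one <- idm_infer(w, ds$A, ds$D[, i], tol = 1e-30, max_iter = 400)
    expect_equal(many$X[, i], one$x, tolerance = 1e-10)
  }
})
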