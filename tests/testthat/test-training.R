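test_that("the JFB backward tape does not grow with fixed-point depth", {
  T_fn <- function(x) 0.5 * x + 1
  f5 <- jfb_forward(T_fn, d = 1, cfg = train_config(fp_tol = 1e-14, fp_max_iter = 5L))
  f500 <- jfb_forward(T_fn, d = 1, cfg = train_config(fp_tol = 1e-14, fp_max_iter = 500L))
  expect_gt(f500$forward_state$k, f5$forward_state$k)   # deeper solve happened
  expect_identical(f5$tape_size, f500$tape_size)        # same stored graph
  # x_final is one application of the map at x_K
  expect_equal(f500$x_final, T_fn(f500$x_K))
})

test_that("JFB differentiates the single step at the fixed point, not the unrolled chain", {
  w <- 0.6; x0 <- 1; target <- 0.2; Kit <- 8L
  step <- function(x, p) p[1] * x
  loss <- function(x1) (x1 - target)^2
  x_K <- w^Kit * x0   # no-grad phase, exactly Kit applications
  g_jfb <- jfb_gradient(step, x_K, w, loss, eps = 1e-7)
  # independent oracle: one-step finite differences at x_K
  eps <- 1e-7
  g_fd <- (loss((w + eps) * x_K) - loss((w - eps) * x_K)) / (2 * eps)
  expect_lt(abs(g_jfb - g_fd), 1e-6)
  # analytic single-step derivative
  expect_lt(abs(g_jfb - 2 * (w * x_K - target) * x_K), 1e-6)
  # the fully unrolled derivative differs (JFB is the preconditioned gradient)
  g_unrolled <- 2 * (w^(Kit + 1) * x0 - target) * (Kit + 1) * w^Kit * x0
  expect_gt(abs(g_jfb - g_unrolled), 1e-3)
})

test_that("JFB equals the exact gradient for a state-independent step", {
  # T(x; w) = w: spectral radius 0 in the state, one-step dependence
  target <- 1.5
  step <- function(x, p) p[1]
  loss <- function(x1) (x1 - target)^2
  g <- jfb_gradient(step, x_K = 99, params = 0.3, loss, eps = 1e-6)
  expect_lt(abs(g - 2 * (0.3 - target)), 1e-8)
})

test_that("with fp_max_iter = 1 JFB coincides with one-step backpropagation", {
  T_fn <- function(x) 0.5 * x + 1
  f1 <- jfb_forward(T_fn, d = 2, cfg = train_config(fp_tol = 1e-14, fp_max_iter = 1L))
  expect_equal(f1$x_K, T_fn(0))
  expect_equal(f1$x_final, T_fn(T_fn(0)))
})

test_that("training the sparse-recovery model reduces inference MSE", {
  # 3-variable system with a known lasso-style solution
  set.seed(71)
  A <- matrix(rnorm(2 * 3), 2, 3)
  Xs <- matrix(0, 3, 60)
  Xs[cbind(sample(1:3, 60, TRUE), 1:60)] <- rnorm(60)
  D <- A %*% Xs
  model <- implicit_model("sparse_recovery", ista_weights(A, tau = 0.3), A)
  mse_of <- function(m) {
    mean(vapply(1:60, function(i) {
      mean((sparse_recovery_infer(m$weights, m$A, D[, i])$x - Xs[, i])^2)
    }, numeric(1)))
  }
  before <- mse_of(model)
  tr <- train(model, list(D = D, X = Xs),
              train_config(epochs = 40L, batch_size = 20L, lr = 5e-3,
                           fp_tol = 1e-8, fp_max_iter = 200L, seed = 71))
  expect_lt(mse_of(tr$model), before)
  expect_lt(utils::tail(tr$history$loss, 1), tr$history$loss[1])
})

test_that("training is reproducible bit-for-bit under a fixed seed", {
  ds <- generate_dictionary_dataset(20, 5, 8, 2, 40, seed = 5)
  model <- implicit_model("idm", idm_init_weights(20, seed = 5), ds$A)
  cfg <- train_config(epochs = 3L, batch_size = 20L, lr = 3e-3,
                      fp_max_iter = 60L, seed = 99)
  t1 <- train(model, ds, cfg)
  t2 <- train(model, ds, cfg)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$model$weights$K, t2$model$weights$K)
})

test_that("the analytic IDM gradient matches finite differences of the tracked step", {
  set.seed(72)
  n <- 8; m <- 4; B <- 3
  K <- diag(n) + 0.05 * matrix(rnorm(n * n), n, n)
  M <- matrix(rnorm(m * n), m, n); M <- M / svd(M)$d[1]
  D <- matrix(rnorm(m * B), m, B)
  Xstar <- matrix(rnorm(n * B), n, B)
  lam <- 0.9; alpha <- 0.9; beta <- 0.45
  st <- l2ocert:::ladmm_batch(K, M, D, 30, lam, alpha, beta, delta = 0)
  gr <- l2ocert:::.jfb_grad_idm(K, M, D, st, Xstar, lam, alpha, beta, mu = 0, rho = 0)
  loss_of <- function(Kp) {
    s1 <- l2ocert:::ladmm_batch(Kp, M, D, 1, lam, alpha, beta, delta = 0, init = st)
    mean((s1$X - Xstar)^2)
  }
  eps <- 1e-6
  for (idx in list(c(1, 1), c(3, 5), c(8, 8), c(2, 7))) {
    Kp <- K; Km <- K
    Kp[idx[1], idx[2]] <- Kp[idx[1], idx[2]] + eps
    Km[idx[1], idx[2]] <- Km[idx[1], idx[2]] - eps
    fd <- (loss_of(Kp) - loss_of(Km)) / (2 * eps)
    expect_lt(abs(gr$grad[idx[1], idx[2]] - fd), 1e-6 * (1 + abs(fd)))
  }
})

test_that("CT prox training runs and reduces the epoch loss", {
  geom <- radon_geometry(8, 4, 11)
  rad <- build_radon_map(geom)
  ds <- generate_ct_dataset(geom, count = 3, seed = 73, radon = rad)
  pr <- learned_prox(64, image_side = 8, seed = 73)
  model <- implicit_model("ct", ct_weights(pr), rad, tol = 1e-6, max_iter = 200L)
  tr <- train(model, ds, train_config(epochs = 3L, lr = 5e-3, fp_tol = 1e-6,
                                      fp_max_iter = 150L, seed = 73))
  expect_equal(nrow(tr$history), 3L)
  expect_true(all(is.finite(tr$history$loss)))
  expect_lt(utils::tail(tr$history$loss, 1), tr$history$loss[1])
  expect_true(tr$model$weights$prox$lipschitz_certified)
})

test_that("empty datasets are rejected", {
  ds <- generate_dictionary_dataset(20, 5, 8, 2, 3, seed = 5)
  model <- implicit_model("idm", idm_init_weights(20, seed = 5), ds$A)
  expect_error(train(model, list(D = matrix(0, 8, 0), X = matrix(0, 20, 0))),
               "empty")
})
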