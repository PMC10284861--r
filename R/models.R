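#' Identity linear map
#'
#' @param n dimension.
#' @return a [linear_map()] with forward and adjoint equal to the identity.
#' @export
identity_map <- function(n) {
  n <- check_count(n, "n")
  linear_map(n, n, function(v) v, function(v) v, norm_bound = 1)
}

# ---------------------------------------------------------------------------
# Sparse recovery:  fixed points of  x -> shrink(x - W(Ax - d), theta)
# ---------------------------------------------------------------------------

#' Weights of the sparse-recovery operator
#'
#' The model operator is `T(x; d) = shrink(x - W(Ax - d), theta)`; its weights
#' are the step matrix `W` (absorbing the proximal-gradient step size and any
#' data-driven quadratic terms), the shrink threshold `theta`, and the sparsity
#' weight `tau` that `theta` absorbs (`theta = step * tau` in the classical
#' iteration).
#'
#' @param W a [linear_map()] from measurement space (length `m`) to signal
#'   space (length `n`), or an `n x m` matrix.
#' @param theta nonnegative shrink threshold.
#' @param tau positive sparsity weight (book-keeping; the operator only uses
#'   `theta`).
#' @return object of class `sparse_recovery_weights`.
#' @export
sparse_recovery_weights <- function(W, theta, tau = 1) {
  if (!inherits(W, "linear_map")) W <- make_matrix_map(W)
  check_scalar(theta, "theta", lower = 0)
  check_scalar(tau, "tau", lower = 0, strict = TRUE)
  structure(list(W = W, theta = theta, tau = tau), class = "sparse_recovery_weights")
}

#' Classical (untrained) sparse-recovery weights for a given system
#'
#' `W = c * t(A)` with `c = 0.99 / |A|^2` and `theta = c * tau`: the ISTA
#' iteration for the lasso objective `tau*||x||_1 + ||Ax - d||^2 / 2` scaled to
#' a contraction-valid step.
#'
#' @param A a [linear_map()] or matrix of measurements.
#' @param tau positive sparsity weight.
#' @return `sparse_recovery_weights`.
#' @export
ista_weights <- function(A, tau = 0.1) {
  if (!inherits(A, "linear_map")) A <- make_matrix_map(A)
  cstep <- 0.99 / A$norm_bound^2
  Wmat <- cstep * t(as.matrix(A$matrix))
  sparse_recovery_weights(make_matrix_map(Wmat), theta = cstep * tau, tau = tau)
}

#' Sparse-recovery inference
#'
#' Iterates the shrink-based model operator to its fixed point.  With `W`
#' frozen at a scaled adjoint this reproduces ISTA/lasso solutions; with
#' trained `W` it is a learned sparse-recovery model whose inference still
#' solves a fixed-point condition.
#'
#' @param weights [sparse_recovery_weights()].
#' @param A measurement [linear_map()] (or matrix).
#' @param d measurement vector.
#' @param tol,max_iter solver controls, see [iterate_to_fixed_point()].
#' @return list with the fixed point `x` and the solver `state`
#'   (`fixed_point_state`).
#' @export
sparse_recovery_infer <- function(weights, A, d, tol = 1e-10, max_iter = 5000L) {
  stopifnot(inherits(weights, "sparse_recovery_weights"))
  if (!inherits(A, "linear_map")) A <- make_matrix_map(A)
  T_fn <- make_pg_operator(weights$W, A, d, weights$theta)
  st <- iterate_to_fixed_point(T_fn, numeric(A$in_dim), tol = tol, max_iter = max_iter)
  list(x = st$x, state = st)
}

# ---------------------------------------------------------------------------
# Implicit dictionary model:  argmin ||Kx||_1  s.t.  Ax = d
# ---------------------------------------------------------------------------

#' Weights of the implicit dictionary model
#'
#' The single weight is a square sparsifying transform `K`: inference solves
#' `argmin ||Kx||_1 s.t. Ax = d`.  When `K` is invertible its inverse is a
#' dictionary and `Kx` the sparse code of the signal `x`.
#'
#' @param K square numeric matrix (`n x n`).
#' @return object of class `idm_weights`.
#' @export
idm_weights <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("`K` must be square", call. = FALSE)
  stop_if_not_finite(K, "K")
  structure(list(K = K), class = "idm_weights")
}

#' Default untrained sparsifying transform
#'
#' Identity plus seeded Gaussian noise of scale 0.01, spectrally normalized —
#' a starting point close to plain basis pursuit.
#'
#' @param n signal dimension.
#' @param seed integer seed.
#' @return `idm_weights`.
#' @export
idm_init_weights <- function(n, seed = 1L) {
  K <- diag(n) + with_seed(seed, matrix(stats::rnorm(n * n, sd = 0.01), n, n))
  K <- K / estimate_norm(make_matrix_map(K), iters = 60L, seed = 2L)
  idm_weights(K)
}

# shared solver-facing normalization: scale M (and data) to unit operator norm
.normalized_system <- function(A) {
  if (!inherits(A, "linear_map")) A <- make_matrix_map(A)
  nA <- max(A$norm_bound, .Machine$double.eps)
  list(map = linear_map(A$in_dim, A$out_dim,
                        forward = function(v) A$forward(v) / nA,
                        adjoint = function(v) A$adjoint(v) / nA,
                        norm_bound = 1.0,
                        matrix = if (is.null(A$matrix)) NULL else A$matrix / nA),
       scale = nA)
}

#' Implicit dictionary model inference
#'
#' Solves `argmin ||Kx||_1 s.t. Ax = d` by linearized ADMM (exact-feasibility
#' ball of radius 0).  The measurement operator and data are internally
#' rescaled to unit operator norm, which leaves the problem unchanged but
#' gives the step-size rule useful magnitudes.
#'
#' @param weights [idm_weights()].
#' @param A measurement map or matrix.
#' @param d measurement vector.
#' @param tol,max_iter solver controls (residual on the whole ADMM state).
#' @param feasibility_tol acceptable absolute violation of `Ax = d` (scaled by
#'   `1 + ||d||`) before the run is flagged unconverged.
#' @return list with solution `x`, solver `state`, and the code `code = K x`.
#' @export
idm_infer <- function(weights, A, d, tol = 1e-9, max_iter = 6000L,
                      feasibility_tol = 1e-6) {
  stopifnot(inherits(weights, "idm_weights"))
  ns <- .normalized_system(A)
  Kmap <- make_matrix_map(weights$K)
  prob <- ladmm_problem(K = Kmap, M = ns$map, d = d / ns$scale, delta = 0,
                        prox_f = prox_l1)
  fps <- ladmm_solve(prob, x0 = numeric(Kmap$in_dim), tol = tol, max_iter = max_iter)
  feas <- l2norm(map_forward(ns$map, fps$x) - prob$d) * ns$scale
  if (feas > feasibility_tol * (1 + l2norm(d))) fps$converged <- FALSE
  list(x = fps$x, state = fps, code = as.numeric(weights$K %*% fps$x))
}

#' Batched implicit dictionary inference
#'
#' Solves the IDM problem for many measurement vectors at once by advancing
#' all instances as matrix columns (they share `K` and `A`, so each iteration
#' is a handful of matrix products).  The per-column iterates coincide with
#' those of [idm_infer()] started from zero; stopping is checked in chunks on
#' the whole-state change of the worst column.
#'
#' @param weights [idm_weights()].
#' @param A measurement map or matrix.
#' @param D matrix of measurements, one instance per column.
#' @param tol relative state-change tolerance.
#' @param max_iter total iteration cap.
#' @param chunk iterations between convergence checks.
#' @return list with solutions `X` (columns), codes `C = K X`, per-column
#'   `feasibility` (`||A x - d||`), iterations used, and a `converged` flag.
#' @export
idm_infer_many <- function(weights, A, D, tol = 1e-8, max_iter = 4000L,
                           chunk = 200L) {
  stopifnot(inherits(weights, "idm_weights"))
  ns <- .normalized_system(A)
  if (is.null(ns$map$matrix)) stop("`A` must expose an explicit matrix", call. = FALSE)
  M <- as.matrix(ns$map$matrix)
  D <- as.matrix(D) / ns$scale
  K <- weights$K
  L <- 1.01 * max(make_matrix_map(K)$norm_bound, 1)^2
  lam <- 1 / L; alpha <- lam; beta <- lam / 2
  st <- NULL
  done <- 0L
  converged <- FALSE
  while (done < max_iter) {
    it <- min(chunk, max_iter - done)
    prev <- st
    st <- ladmm_batch(K, M, D, it, lam, alpha, beta, delta = 0, init = st)
    done <- done + it
    if (!is.null(prev)) {
      chg <- sqrt(colSums((st$X - prev$X)^2) + colSums((st$P - prev$P)^2) +
                    colSums((st$N1 - prev$N1)^2) + colSums((st$N2 - prev$N2)^2))
      sz <- 1 + sqrt(colSums(st$X^2) + colSums(st$P^2) +
                       colSums(st$N1^2) + colSums(st$N2^2))
      # state change accumulated over the chunk bounds the per-step residual
      if (max(chg / sz) <= tol * it) { converged <- TRUE; break }
    }
  }
  feas <- sqrt(colSums((M %*% st$X - D)^2)) * ns$scale
  list(X = st$X, C = K %*% st$X, feasibility = feas, iters = done,
       converged = converged)
}

# ---------------------------------------------------------------------------
# CT reconstruction:  argmin_{x in [0,1]^n} f_Omega(Kx)  s.t. ||Ax - d|| <= delta
# ---------------------------------------------------------------------------

#' Weights of the constrained CT reconstruction model
#'
#' @param prox a [learned_prox()] acting on the range of `K` (the data-driven
#'   regularizer is represented directly by its proximal operator).
#' @param K sparsifying transform as a [linear_map()]; identity when `NULL`.
#' @param alpha,beta,lam optional trained step sizes (default rule when
#'   `NULL`).
#' @param delta nonnegative fidelity tolerance; when `NULL` it defaults at
#'   inference time to `0.015 * ||d||`, the discrepancy-principle choice for
#'   1.5 percent per-beam noise.
#' @return object of class `ct_weights`.
#' @export
ct_weights <- function(prox, K = NULL, alpha = NULL, beta = NULL, lam = NULL,
                       delta = NULL) {
  stopifnot(inherits(prox, "learned_prox"))
  if (!is.null(K)) stopifnot(inherits(K, "linear_map"))
  if (!is.null(delta)) check_scalar(delta, "delta", lower = 0)
  structure(list(prox = prox, K = K, alpha = alpha, beta = beta, lam = lam,
                 delta = delta),
            class = "ct_weights")
}

#' Constrained CT reconstruction inference
#'
#' Solves `argmin_{x in [0,1]^n} f(Kx) s.t. ||Ax - d|| <= delta` with the
#' learned proximal standing in for `prox_f`.  The primal update is the final
#' operation of every iteration and is a box projection, so the returned image
#' lies in `[0, 1]` exactly, whatever the solver state.
#'
#' @param weights [ct_weights()].
#' @param A system map (e.g. from [build_radon_map()]).
#' @param d sinogram vector.
#' @param tol,max_iter solver controls.
#' @param x0 optional start; default is the adjoint image `t(A) d` rescaled
#'   into `[0, 1]`.
#' @return list with image vector `x`, solver `state`, and the `delta` used.
#' @export
ct_infer <- function(weights, A, d, tol = 1e-7, max_iter = 3000L, x0 = NULL) {
  stopifnot(inherits(weights, "ct_weights"))
  ns <- .normalized_system(A)
  delta <- if (is.null(weights$delta)) 0.015 * l2norm(d) else weights$delta
  Kmap <- if (is.null(weights$K)) identity_map(ns$map$in_dim) else weights$K
  prox_fn <- weights$prox$apply
  prob <- ladmm_problem(
    K = Kmap, M = ns$map, d = d / ns$scale, delta = delta / ns$scale,
    prox_f = function(v, t) prox_fn(v),
    prox_h = function(v, t) project_box(v, 0, 1),
    alpha = weights$alpha, beta = weights$beta, lam = weights$lam)
  if (is.null(x0)) {
    bp <- map_adjoint(ns$map, d / ns$scale)
    mx <- max(bp)
    x0 <- project_box(if (mx > 0) bp / mx else bp, 0, 1)
  }
  fps <- ladmm_solve(prob, x0 = x0, tol = tol, max_iter = max_iter)
  list(x = fps$x, state = fps, delta = delta)
}

# ---------------------------------------------------------------------------
# Uniform inference front end
# ---------------------------------------------------------------------------

#' Bundle weights, a system and solver controls into an implicit model
#'
#' @param kind one of `"sparse_recovery"`, `"idm"`, `"ct"`.
#' @param weights the matching weights object.
#' @param A the measurement/system map.
#' @param tol,max_iter solver configuration used by [infer()].
#' @return object of class `implicit_model`.
#' @export
implicit_model <- function(kind = c("sparse_recovery", "idm", "ct"), weights, A,
                           tol = NULL, max_iter = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
                     sparse_recovery = list(tol = 1e-10, max_iter = 5000L),
                     idm = list(tol = 1e-9, max_iter = 6000L),
                     ct = list(tol = 1e-7, max_iter = 3000L))
  if (!inherits(A, "linear_map")) A <- make_matrix_map(A)
  structure(list(kind = kind, weights = weights, A = A,
                 tol = if (is.null(tol)) defaults$tol else tol,
                 max_iter = if (is.null(max_iter)) defaults$max_iter else max_iter),
            class = "implicit_model")
}

#' @export
print.implicit_model <- function(x, ...) {
  cat(sprintf("<implicit_model kind=%s, system %d x %d, tol %.1g, max_iter %d>\n",
              x$kind, x$A$out_dim, x$A$in_dim, x$tol, x$max_iter))
  invisible(x)
}

#' Run an implicit model on one input
#'
#' Inference solves the model's optimization problem: the returned value is the
#' fixed point of the model's iteration together with the solver state, and is
#' deterministic given the weights, the input and the solver configuration.
#'
#' @param model an [implicit_model()].
#' @param d input vector (measurements / sinogram).
#' @param ... passed through to the kind-specific inference function.
#' @return list with at least `x` and `state`.
#' @export
infer <- function(model, d, ...) {
  stopifnot(inherits(model, "implicit_model"))
  switch(model$kind,
         sparse_recovery = sparse_recovery_infer(model$weights, model$A, d,
                                                 tol = model$tol,
                                                 max_iter = model$max_iter, ...),
         idm = idm_infer(model$weights, model$A, d, tol = model$tol,
                         max_iter = model$max_iter, ...),
         ct = ct_infer(model$weights, model$A, d, tol = model$tol,
                       max_iter = model$max_iter, ...))
}
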