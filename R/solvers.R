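#' Iterate a map to a fixed point
#'
#' Runs `x_{k+1} = T(x_k)` until the iterate residual `||x_k - x_{k-1}||` falls
#' below `tol * (1 + ||x_k||)` or `max_iter` is reached.  Inference of every
#' implicit model in this package is such a fixed-point computation: for an
#' averaged operator the sequence converges to a solution of the model's
#' optimization problem, and tightening `tol` approximates that limit to
#' arbitrary precision.
#'
#' @param T_fn function mapping a numeric vector to a numeric vector.
#' @param x0 start vector.
#' @param tol positive relative tolerance on the iterate residual.
#' @param max_iter iteration cap.
#' @return an object of class `fixed_point_state`: a list with the final
#'   iterate `x`, iteration count `k`, last `residual`, the full residual
#'   `history` (length `k`), and a `converged` flag.
#' @examples
#' st <- iterate_to_fixed_point(function(x) x / 2, 1, tol = 1e-6)
#' st$k; st$x
#' @export
iterate_to_fixed_point <- function(T_fn, x0, tol = 1e-8, max_iter = 1000L) {
  check_scalar(tol, "tol", lower = 0, strict = TRUE)
  max_iter <- check_count(max_iter, "max_iter")
  x <- as.numeric(x0)
  history <- numeric(0)
  res <- Inf
  k <- 0L
  for (k in seq_len(max_iter)) {
    xn <- as.numeric(T_fn(x))
    if (!all(is.finite(xn)))
      stop(sprintf("fixed-point iteration diverged at iteration %d (non-finite iterate)", k),
           call. = FALSE)
    res <- l2norm(xn - x)
    history <- c(history, res)
    x <- xn
    if (is.finite(res) && res <= tol * (1 + l2norm(x))) break
  }
  structure(list(x = x, k = k, residual = res, history = history,
                 converged = is.finite(res) && res <= tol * (1 + l2norm(x))),
            class = "fixed_point_state")
}

#' @export
print.fixed_point_state <- function(x, ...) {
  cat(sprintf("<fixed_point_state: %d iterations, residual %.3g, %s>\n",
              x$k, x$residual, if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Plot the residual history of a fixed-point run
#'
#' @param x a `fixed_point_state`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fixed_point_state <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, log = "y", type = "l",
                 xlab = "iteration", ylab = "iterate residual", ...)
}

#' Proximal-gradient model operator for sparse recovery
#'
#' Builds the operator `x -> shrink(x - W (A x - d), theta)` whose fixed points
#' solve an l1-regularized least-squares problem when `W` is a scaled adjoint
#' of `A`.  With tunable `W` and `theta` this is the classic learned sparse
#' recovery iteration (LISTA-style): the step matrix and threshold are weights.
#'
#' @param W a [linear_map()] from measurement space back to signal space.
#' @param A a [linear_map()] from signal space to measurement space.
#' @param d measurement vector (length `A$out_dim`).
#' @param theta nonnegative shrink threshold.
#' @return a function of one vector argument, suitable for
#'   [iterate_to_fixed_point()].
#' @export
make_pg_operator <- function(W, A, d, theta) {
  stopifnot(inherits(W, "linear_map"), inherits(A, "linear_map"))
  check_scalar(theta, "theta", lower = 0)
  if (W$out_dim != A$in_dim || W$in_dim != A$out_dim || length(d) != A$out_dim)
    stop("shape mismatch: need W: m -> n compatible with A: n -> m and d of length m",
         call. = FALSE)
  force(d)
  function(x) shrink(x - map_forward(W, map_forward(A, x) - d), theta)
}

# ---------------------------------------------------------------------------
# Linearized ADMM for   min f(Kx) + h(x)  s.t.  ||Mx - d|| <= delta
# ---------------------------------------------------------------------------

#' Specify a linearized-ADMM problem
#'
#' The problem solved is `min f(Kx) + h(x)` subject to `||Mx - d|| <= delta`,
#' with `f` and `h` supplied through their proximal operators.  Default step
#' sizes follow the conservative rule `lambda = alpha = 1/L` with
#' `L = 1.01 * max(|K|, |M|)^2` and `beta = lambda / 2`, which keeps the
#' iteration averaged on all tested instances (operator norms are taken from
#' the maps' certified bounds).  Pass `alpha`, `beta`, `lam` explicitly to
#' override, e.g. when they are trained.
#'
#' @param K,M [linear_map()]s with a common domain (the primal variable).
#' @param d data vector in the range of `M`.
#' @param delta nonnegative noise tolerance (radius of the fidelity ball).
#' @param prox_f proximal operator of `f`: `function(v, t)` returning
#'   `prox_{t f}(v)` on the range of `K`.
#' @param prox_h proximal operator of `h` (`NULL` for `h = 0`).
#' @param alpha,beta,lam positive step sizes; computed by the default rule when
#'   `NULL`.
#' @return an object of class `ladmm_problem`.
#' @export
ladmm_problem <- function(K, M, d, delta, prox_f, prox_h = NULL,
                          alpha = NULL, beta = NULL, lam = NULL) {
  stopifnot(inherits(K, "linear_map"), inherits(M, "linear_map"), is.function(prox_f))
  if (K$in_dim != M$in_dim) stop("K and M must share their domain", call. = FALSE)
  if (length(d) != M$out_dim) stop("`d` must have length M$out_dim", call. = FALSE)
  check_scalar(delta, "delta", lower = 0)
  if (is.null(lam)) {
    L <- 1.01 * max(K$norm_bound, M$norm_bound)^2
    lam <- 1 / L
  }
  if (is.null(alpha)) alpha <- lam
  if (is.null(beta)) beta <- lam / 2
  check_scalar(alpha, "alpha", lower = 0, strict = TRUE)
  check_scalar(beta, "beta", lower = 0, strict = TRUE)
  check_scalar(lam, "lam", lower = 0, strict = TRUE)
  structure(list(K = K, M = M, d = as.numeric(d), delta = delta,
                 prox_f = prox_f,
                 prox_h = if (is.null(prox_h)) function(v, t) v else prox_h,
                 alpha = alpha, beta = beta, lam = lam),
            class = "ladmm_problem")
}

#' Initial linearized-ADMM state
#'
#' Auxiliaries start at their consistency values `p = Kx0`, `w = Mx0` with zero
#' duals, a deterministic warm start.
#'
#' @param prob an [ladmm_problem()].
#' @param x0 primal start (defaults to the zero vector).
#' @return an object of class `ladmm_state` with fields `p`, `w`, `nu1`, `nu2`,
#'   `x`.
#' @export
ladmm_init <- function(prob, x0 = NULL) {
  stopifnot(inherits(prob, "ladmm_problem"))
  if (is.null(x0)) x0 <- numeric(prob$K$in_dim)
  structure(list(p = map_forward(prob$K, x0),
                 w = map_forward(prob$M, x0),
                 nu1 = numeric(prob$K$out_dim),
                 nu2 = numeric(prob$M$out_dim),
                 x = as.numeric(x0)),
            class = "ladmm_state")
}

.check_update <- function(v, name, k = NULL) {
  if (!all(is.finite(v)))
    stop(sprintf("linearized ADMM diverged in the %s update%s", name,
                 if (is.null(k)) "" else sprintf(" at iteration %d", k)),
         call. = FALSE)
  v
}

#' One linearized-ADMM iteration
#'
#' Applies the six updates in order — `p` (prox of f), `w` (ball projection),
#' the two dual ascents, the linearized gradient `r`, and finally the primal
#' `x` (prox of h) — so that the primal update is the last operation of the
#' step.  The input state is not modified.
#'
#' @param state an [ladmm_init()] state.
#' @param prob an [ladmm_problem()].
#' @return the updated `ladmm_state`.
#' @export
ladmm_step <- function(state, prob) {
  stopifnot(inherits(state, "ladmm_state"), inherits(prob, "ladmm_problem"))
  al <- prob$alpha; be <- prob$beta; la <- prob$lam
  Kx <- map_forward(prob$K, state$x)
  Mx <- map_forward(prob$M, state$x)
  p_new <- .check_update(prob$prox_f(state$p + la * (state$nu1 + al * (Kx - state$p)), la), "p")
  w_new <- .check_update(project_ball(state$w + la * (state$nu2 + al * (Mx - state$w)),
                                      prob$d, prob$delta), "w")
  nu1_new <- .check_update(state$nu1 + al * (Kx - p_new), "nu1")
  nu2_new <- .check_update(state$nu2 + al * (Mx - w_new), "nu2")
  r <- .check_update(map_adjoint(prob$K, 2 * nu1_new - state$nu1) +
                       map_adjoint(prob$M, 2 * nu2_new - state$nu2), "r")
  x_new <- .check_update(prob$prox_h(state$x - be * r, be), "x")
  structure(list(p = p_new, w = w_new, nu1 = nu1_new, nu2 = nu2_new, x = x_new),
            class = "ladmm_state")
}

.pack_state <- function(s) c(s$p, s$w, s$nu1, s$nu2, s$x)

.unpack_state <- function(v, dims) {
  ends <- cumsum(dims)
  starts <- c(1, utils::head(ends, -1) + 1)
  structure(list(p = v[starts[1]:ends[1]], w = v[starts[2]:ends[2]],
                 nu1 = v[starts[3]:ends[3]], nu2 = v[starts[4]:ends[4]],
                 x = v[starts[5]:ends[5]]),
            class = "ladmm_state")
}

#' Run linearized ADMM to a fixed point
#'
#' Wraps [ladmm_step()] in [iterate_to_fixed_point()] on the concatenated
#' state tuple `(p, w, nu1, nu2, x)`; the stopping residual is the norm of the
#' change of the whole tuple in relative form, which avoids premature stops
#' when only the primal stalls.  A run that hits `max_iter` is returned with
#' `converged = FALSE` rather than raising — the convergence certificate layer
#' is the intended place to surface unconverged inferences.
#'
#' @param prob an [ladmm_problem()].
#' @param x0 primal start vector (defaults to zero).
#' @param tol positive relative tolerance on the state residual.
#' @param max_iter iteration cap.
#' @return a `fixed_point_state` whose `x` is the primal solution; the full
#'   `ladmm_state` is attached as `$state`, and `$feasibility` records
#'   `||Mx - d|| - delta` (negative or tiny when the ball constraint holds).
#' @export
ladmm_solve <- function(prob, x0 = NULL, tol = 1e-8, max_iter = 5000L) {
  stopifnot(inherits(prob, "ladmm_problem"))
  s0 <- ladmm_init(prob, x0)
  dims <- c(length(s0$p), length(s0$w), length(s0$nu1), length(s0$nu2), length(s0$x))
  T_fn <- function(v) .pack_state(ladmm_step(.unpack_state(v, dims), prob))
  fps <- iterate_to_fixed_point(T_fn, .pack_state(s0), tol = tol, max_iter = max_iter)
  st <- .unpack_state(fps$x, dims)
  fps$x <- st$x
  fps$state <- st
  fps$feasibility <- l2norm(map_forward(prob$M, st$x) - prob$d) - prob$delta
  fps
}

# ---------------------------------------------------------------------------
# Batched L-ADMM on explicit matrices (internal; used by training loops where
# instances share K and M and can be advanced as matrix columns).
# ---------------------------------------------------------------------------

ladmm_batch <- function(K, M, D, iters, lam, alpha, beta, delta = 0,
                        prox_h = NULL, init = NULL) {
  n <- ncol(M); B <- ncol(D)
  if (is.null(init)) {
    X <- matrix(0, n, B); P <- K %*% X; W <- M %*% X
    N1 <- matrix(0, nrow(K), B); N2 <- matrix(0, nrow(M), B)
  } else {
    X <- init$X; P <- init$P; W <- init$W; N1 <- init$N1; N2 <- init$N2
  }
  shrink_m <- function(V, t) sign(V) * pmax(abs(V) - t, 0)
  for (k in seq_len(iters)) {
    KX <- K %*% X; MX <- M %*% X
    P1 <- shrink_m(P + lam * (N1 + alpha * (KX - P)), lam)
    if (delta <= 0) {
      W1 <- D
    } else {
      Wa <- W + lam * (N2 + alpha * (MX - W))
      dn <- sqrt(colSums((Wa - D)^2))
      scl <- ifelse(dn > delta, delta / pmax(dn, 1e-300), 1)
      W1 <- D + sweep(Wa - D, 2, scl, "*")
    }
    N1n <- N1 + alpha * (KX - P1)
    N2n <- N2 + alpha * (MX - W1)
    R <- crossprod(K, 2 * N1n - N1) + crossprod(M, 2 * N2n - N2)
    X <- X - beta * R
    if (!is.null(prox_h)) X <- prox_h(X, beta)
    P <- P1; W <- W1; N1 <- N1n; N2 <- N2n
  }
  list(X = as.matrix(X), P = as.matrix(P), W = as.matrix(W),
       N1 = as.matrix(N1), N2 = as.matrix(N2))
}
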