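#' Training configuration
#'
#' @param epochs,batch_size positive integers.
#' @param lr positive Adam learning rate.
#' @param fp_tol positive fixed-point tolerance used during the no-gradient
#'   forward phase.
#' @param fp_max_iter iteration cap of the no-gradient phase (training-time
#'   cap; inference may use a larger one).
#' @param seed integer seed controlling batch shuffling and any initialisation
#'   drawn inside training; identical seeds give bit-identical loss histories.
#' @param loss loss identifier; `"mse"` is the only built-in.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 50L, lr = 1e-3,
                         fp_tol = 1e-6, fp_max_iter = 100L, seed = 1L,
                         loss = "mse") {
  structure(list(epochs = check_count(epochs, "epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 lr = check_scalar(lr, "lr", lower = 0, strict = TRUE),
                 fp_tol = check_scalar(fp_tol, "fp_tol", lower = 0, strict = TRUE),
                 fp_max_iter = check_count(fp_max_iter, "fp_max_iter"),
                 seed = check_count(seed, "seed", lower = -.Machine$integer.max),
                 loss = loss),
            class = "train_config")
}

#' Jacobian-free forward pass
#'
#' Runs the model's iteration map to an approximate fixed point with no
#' derivative tracking, then applies the map once more as the "tracked" step.
#' Training differentiates only that final application, so the backward tape
#' stores a fixed set of intermediates — its size does not grow with the
#' number of fixed-point iterations, which is the memory contract that makes
#' implicit models trainable at all.
#'
#' @param model an [implicit_model()] of kind `sparse_recovery`, or directly a
#'   function `x -> T(x)` (then `d` is ignored).
#' @param d input vector for the model.
#' @param cfg a [train_config()] (supplies `fp_tol`, `fp_max_iter`).
#' @return list with `x_K` (approximate fixed point entering the tracked
#'   step), `x_final` (one further application), `tape` (the stored
#'   intermediates of the tracked step), and `tape_size`.
#' @export
jfb_forward <- function(model, d = NULL, cfg = train_config()) {
  T_fn <- if (is.function(model)) {
    model
  } else if (inherits(model, "implicit_model") && model$kind == "sparse_recovery") {
    make_pg_operator(model$weights$W, model$A, d, model$weights$theta)
  } else {
    stop("jfb_forward needs a function or a sparse_recovery implicit_model", call. = FALSE)
  }
  x0 <- if (is.function(model)) {
    if (is.null(d)) 0 else numeric(length(d))
  } else numeric(model$A$in_dim)
  # no-gradient phase: nothing is retained beyond the current iterate
  st <- iterate_to_fixed_point(T_fn, x0, tol = cfg$fp_tol, max_iter = cfg$fp_max_iter)
  x_K <- st$x
  # tracked phase: exactly one application; the tape is what backward needs
  x_final <- as.numeric(T_fn(x_K))
  tape <- list(input = x_K, output = x_final)
  list(x_K = x_K, x_final = x_final, tape = tape, tape_size = length(tape),
       forward_state = st)
}

#' Jacobian-free gradient of a parameterised one-step map
#'
#' Central finite differences of `loss_fn(step_fn(x_K, params))` in `params`,
#' i.e. the derivative of a single application of the iteration map evaluated
#' at the approximate fixed point — the JFB gradient.  Intended for small
#' parameter vectors (learned step sizes, small convolution kernels); the
#' analytic trainers below use closed-form backward passes instead.
#'
#' @param step_fn function `(x, params) -> next iterate`.
#' @param x_K the fixed point at which to differentiate.
#' @param params numeric parameter vector.
#' @param loss_fn function of the next iterate returning a scalar loss.
#' @param eps finite-difference step.
#' @return gradient vector, `length(params)`.
#' @export
jfb_gradient <- function(step_fn, x_K, params, loss_fn, eps = 1e-6) {
  g <- numeric(length(params))
  for (i in seq_along(params)) {
    pp <- params; pp[i] <- pp[i] + eps
    pm <- params; pm[i] <- pm[i] - eps
    g[i] <- (loss_fn(step_fn(x_K, pp)) - loss_fn(step_fn(x_K, pm))) / (2 * eps)
  }
  g
}

# --- Adam ------------------------------------------------------------------

.adam_init <- function(shape_like) list(m = shape_like * 0, v = shape_like * 0, t = 0L)

.adam_step <- function(state, grad, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  state$update <- lr * mhat / (sqrt(vhat) + eps)
  state
}

# --- dataset coercion ------------------------------------------------------

.as_training_matrices <- function(dataset) {
  if (inherits(dataset, "dictionary_dataset"))
    return(list(D = dataset$D, X = dataset$X))
  if (inherits(dataset, "ct_dataset"))
    return(list(D = dataset$sino_noisy,
                X = vapply(dataset$phantoms, function(p) as.vector(t(p)),
                           numeric(length(dataset$phantoms[[1]])))))
  if (is.list(dataset) && !is.null(dataset$D) && !is.null(dataset$X))
    return(list(D = as.matrix(dataset$D), X = as.matrix(dataset$X)))
  stop("`dataset` must be a dictionary_dataset, ct_dataset, or list(D=, X=)",
       call. = FALSE)
}

#' Train an implicit model with Jacobian-free backpropagation
#'
#' Minimises the configured loss over the dataset with Adam, differentiating
#' only through the final application of the model's iteration map at each
#' forward solve (JFB).  Instances sharing the model's operators are advanced
#' together as matrix columns, so one batch costs one batched fixed-point
#' solve plus one closed-form backward step.
#'
#' Kind-specific behaviour:
#' * `sparse_recovery`: trains `(W, theta)` of the shrink operator on MSE.
#' * `idm`: trains the sparsifying transform `K`.  The default objective is
#'   reconstruction MSE plus a transform-learning sparsity term
#'   `mu * mean(|K x_true|_1)/n` and a rank-preserving penalty
#'   `rho * |K K' K - K|_F^2 / n^2` (singular values pushed towards 0 or 1);
#'   `K` is spectrally renormalized after every step since the model is
#'   invariant to its scale.
#' * `ct`: trains the learned-prox convolution kernels by finite-difference
#'   JFB over their ~20 parameters; spectral normalization is re-imposed
#'   after every step so the prox stays 1-Lipschitz.
#'
#' @param model an [implicit_model()].
#' @param dataset a `dictionary_dataset`, `ct_dataset`, or `list(D=, X=)` with
#'   inputs and targets as matrix columns.
#' @param cfg a [train_config()].
#' @param mu sparsity-term weight for `idm` (0 disables).
#' @param rho rank-penalty weight for `idm` (0 disables).
#' @param verbose print per-epoch losses.
#' @return list with the trained `model` and `history`, a data.frame of
#'   per-epoch mean losses.
#' @export
train <- function(model, dataset, cfg = train_config(), mu = 0.05, rho = 0.5,
                  verbose = FALSE) {
  stopifnot(inherits(model, "implicit_model"))
  mats <- .as_training_matrices(dataset)
  if (ncol(mats$D) == 0L) stop("`dataset` is empty", call. = FALSE)
  switch(model$kind,
         idm = .train_idm(model, mats, cfg, mu, rho, verbose),
         sparse_recovery = .train_sr(model, mats, cfg, verbose),
         ct = .train_ct(model, dataset, cfg, verbose))
}

# ---------------------------------------------------------------------------
# IDM trainer: analytic JFB backward through one L-ADMM step w.r.t. K
# ---------------------------------------------------------------------------

.jfb_grad_idm <- function(K, M, D, st, Xstar, lam, alpha, beta, mu, rho) {
  X <- st$X; P <- st$P; N1 <- st$N1; N2 <- st$N2
  B <- ncol(X); n <- nrow(X)
  KX <- K %*% X; MX <- M %*% X
  Aarg <- P + lam * (N1 + alpha * (KX - P))
  P1 <- sign(Aarg) * pmax(abs(Aarg) - lam, 0)
  N1n <- N1 + alpha * (KX - P1)
  N2n <- N2 + alpha * (MX - D)
  S1 <- 2 * N1n - N1
  R <- crossprod(K, S1) + crossprod(M, 2 * N2n - N2)
  X1 <- X - beta * R
  G <- (2 / (B * n)) * (X1 - Xstar)
  Rbar <- -beta * G
  KR <- K %*% Rbar
  mask <- (abs(Aarg) > lam) * 1
  gK <- S1 %*% t(Rbar) + (2 * alpha) * (KR %*% t(X)) +
    (lam * alpha) * ((mask * (-2 * alpha * KR)) %*% t(X))
  loss <- mean((X1 - Xstar)^2)
  if (mu > 0) {
    KXs <- K %*% Xstar
    gK <- gK + (mu / (B * n)) * sign(KXs) %*% t(Xstar)
    loss <- loss + (mu / (B * n)) * sum(abs(KXs))
  }
  if (rho > 0) {
    E <- K %*% crossprod(K) - K
    gK <- gK + (rho * 2 / n^2) *
      (E %*% crossprod(K) + K %*% crossprod(E, K) + tcrossprod(K) %*% E - E)
    loss <- loss + (rho / n^2) * sum(E^2)
  }
  list(grad = gK, loss = loss)
}

.train_idm <- function(model, mats, cfg, mu, rho, verbose) {
  K <- model$weights$K
  n <- nrow(K)
  A <- model$A
  nA <- A$norm_bound
  M <- as.matrix(A$matrix) / nA
  D <- mats$D / nA
  Xs <- mats$X
  Ntr <- ncol(D)
  L <- 1.01; lam <- 1 / L; alpha <- 1 / L; beta <- 1 / (2 * L)  # |K|,|M| <= 1
  K <- K / max(1, estimate_norm(make_matrix_map(K), 60L, seed = 3L))
  ad <- .adam_init(K)
  bs <- min(cfg$batch_size, Ntr)
  nb <- ceiling(Ntr / bs)
  hist_loss <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    # piecewise lr decay: full rate, then 1/3, then 1/10
    lr <- cfg$lr * if (ep > 0.8 * cfg$epochs) 0.1 else if (ep > 0.4 * cfg$epochs) 1 / 3 else 1
    ord <- with_seed(cfg$seed * 1000L + ep, sample.int(Ntr))
    eploss <- 0
    for (ib in seq_len(nb)) {
      idx <- ord[((ib - 1) * bs + 1):min(ib * bs, Ntr)]
      st <- ladmm_batch(K, M, D[, idx, drop = FALSE], cfg$fp_max_iter,
                        lam, alpha, beta, delta = 0)
      if (!all(is.finite(st$X))) {
        warning(sprintf("skipping diverged training batch (epoch %d)", ep))
        next
      }
      gr <- .jfb_grad_idm(K, M, D[, idx, drop = FALSE], st,
                          Xs[, idx, drop = FALSE], lam, alpha, beta, mu, rho)
      ad <- .adam_step(ad, gr$grad, lr)
      K <- K - ad$update
      K <- K / max(1, estimate_norm(make_matrix_map(K), 40L, seed = 3L))
      eploss <- eploss + gr$loss
    }
    hist_loss[ep] <- eploss / nb
    if (verbose) message(sprintf("epoch %d  loss %.6g", ep, hist_loss[ep]))
  }
  model$weights <- idm_weights(K)
  list(model = model,
       history = data.frame(epoch = seq_len(cfg$epochs), loss = hist_loss))
}

# ---------------------------------------------------------------------------
# Sparse-recovery trainer: analytic JFB backward through one shrink step
# ---------------------------------------------------------------------------

.train_sr <- function(model, mats, cfg, verbose) {
  W <- as.matrix(model$weights$W$matrix)
  theta <- model$weights$theta
  A <- as.matrix(model$A$matrix)
  D <- mats$D; Xs <- mats$X
  Ntr <- ncol(D); n <- nrow(Xs)
  adW <- .adam_init(W); adT <- .adam_init(0)
  bs <- min(cfg$batch_size, Ntr)
  nb <- ceiling(Ntr / bs)
  hist_loss <- numeric(cfg$epochs)
  shr <- function(V, t) sign(V) * pmax(abs(V) - t, 0)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed * 1000L + ep, sample.int(Ntr))
    eploss <- 0
    for (ib in seq_len(nb)) {
      idx <- ord[((ib - 1) * bs + 1):min(ib * bs, Ntr)]
      Db <- D[, idx, drop = FALSE]; Xb <- Xs[, idx, drop = FALSE]
      B <- ncol(Db)
      # no-grad phase
      X <- matrix(0, n, B)
      ok <- TRUE
      for (k in seq_len(cfg$fp_max_iter)) {
        Xn <- shr(X - W %*% (A %*% X - Db), theta)
        if (!all(is.finite(Xn))) { ok <- FALSE; break }
        if (max(abs(Xn - X)) <= cfg$fp_tol) { X <- Xn; break }
        X <- Xn
      }
      if (!ok) {
        warning(sprintf("skipping diverged training batch (epoch %d)", ep))
        next
      }
      # tracked step + closed-form backward
      Resid <- A %*% X - Db
      U <- X - W %*% Resid
      X1 <- shr(U, theta)
      G <- (2 / (B * n)) * (X1 - Xb)
      mask <- (abs(U) > theta) * 1
      Ubar <- mask * G
      gW <- -Ubar %*% t(Resid)
      gT <- -sum(sign(U) * Ubar)
      adW <- .adam_step(adW, gW, cfg$lr)
      adT <- .adam_step(adT, gT, cfg$lr)
      W <- W - adW$update
      theta <- max(0, theta - adT$update)
      eploss <- eploss + mean((X1 - Xb)^2)
    }
    hist_loss[ep] <- eploss / nb
    if (verbose) message(sprintf("epoch %d  loss %.6g", ep, hist_loss[ep]))
  }
  model$weights <- sparse_recovery_weights(make_matrix_map(W), theta,
                                           model$weights$tau)
  list(model = model,
       history = data.frame(epoch = seq_len(cfg$epochs), loss = hist_loss))
}

# ---------------------------------------------------------------------------
# CT trainer: finite-difference JFB over the learned-prox kernel parameters
# ---------------------------------------------------------------------------

.ct_pack_params <- function(w) c(w$k1, w$k2, w$b1, w$b2)

.ct_unpack_params <- function(p, w) {
  w$k1 <- p[1:9]; w$k2 <- p[10:18]; w$b1 <- p[19]; w$b2 <- p[20]
  w
}

.train_ct <- function(model, dataset, cfg, verbose) {
  stopifnot(inherits(dataset, "ct_dataset"))
  wts <- model$weights
  if (wts$prox$weights$kind != "conv")
    stop("ct training supports the convolutional learned prox", call. = FALSE)
  A <- model$A
  targets <- vapply(dataset$phantoms, function(p) as.vector(t(p)),
                    numeric(A$in_dim))
  targets <- matrix(targets, nrow = A$in_dim)
  D <- dataset$sino_noisy
  Ntr <- ncol(D)
  params <- .ct_pack_params(wts$prox$weights)
  ad <- .adam_init(params)
  hist_loss <- numeric(cfg$epochs)
  infer_state <- function(prox, d) {
    w2 <- wts; w2$prox <- prox
    res <- ct_infer(w2, A, d, tol = cfg$fp_tol, max_iter = cfg$fp_max_iter)
    res$state$state  # full ladmm_state at the approximate fixed point
  }
  step_with <- function(st, p, d) {
    pw <- .ct_unpack_params(p, wts$prox$weights)
    prox <- rebuild_learned_prox(pw, wts$prox$dim)
    w2 <- wts; w2$prox <- prox
    ns <- .normalized_system(A)
    delta <- if (is.null(wts$delta)) 0.015 * l2norm(d) else wts$delta
    Kmap <- if (is.null(wts$K)) identity_map(ns$map$in_dim) else wts$K
    prob <- ladmm_problem(Kmap, ns$map, d / ns$scale, delta / ns$scale,
                          prox_f = function(v, t) prox$apply(v),
                          prox_h = function(v, t) project_box(v, 0, 1))
    ladmm_step(st, prob)$x
  }
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed * 1000L + ep, sample.int(Ntr))
    eploss <- 0
    for (i in ord) {
      d <- D[, i]; xstar <- targets[, i]
      prox <- rebuild_learned_prox(.ct_unpack_params(params, wts$prox$weights),
                                   wts$prox$dim)
      st <- infer_state(prox, d)
      loss_fn <- function(x1) mean((x1 - xstar)^2)
      g <- jfb_gradient(function(x, p) step_with(st, p, d), NULL, params,
                        function(x1) loss_fn(x1), eps = 1e-5)
      ad <- .adam_step(ad, g, cfg$lr)
      params <- params - ad$update
      eploss <- eploss + loss_fn(step_with(st, params, d))
    }
    hist_loss[ep] <- eploss / Ntr
    if (verbose) message(sprintf("epoch %d  loss %.6g", ep, hist_loss[ep]))
  }
  wts$prox <- rebuild_learned_prox(.ct_unpack_params(params, wts$prox$weights),
                                   wts$prox$dim)
  model$weights <- wts
  list(model = model,
       history = data.frame(epoch = seq_len(cfg$epochs), loss = hist_loss))
}
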