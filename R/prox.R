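#' Soft-thresholding (shrink) operator
#'
#' `shrink(x, theta) = sign(x) * max(|x| - theta, 0)`, the proximal operator of
#' `theta * ||.||_1`.  Componentwise, 1-Lipschitz and firmly nonexpansive, so it
#' is a valid building block for averaged fixed-point iterations.  `sign(0)` is
#' taken as 0, which keeps the map continuous.
#'
#' @param x numeric vector.
#' @param theta nonnegative threshold.
#' @return numeric vector of the same length; each output entry has the sign of
#'   the input entry or is zero.
#' @examples
#' shrink(c(2, -0.3), 0.5)  # 1.5, 0
#' @export
shrink <- function(x, theta) {
  check_scalar(theta, "theta", lower = 0)
  sign(x) * pmax(abs(x) - theta, 0)
}

#' Proximal operator of the weighted l1 norm
#'
#' `prox_l1(x, w) = argmin_z w*||z||_1 + ||z - x||^2/2`, which is exactly
#' [shrink()] with threshold `w`.
#'
#' @param x numeric vector.
#' @param weight nonnegative l1 weight.
#' @return numeric vector.
#' @export
prox_l1 <- function(x, weight) {
  check_scalar(weight, "weight", lower = 0)
  shrink(x, weight)
}

#' Euclidean projection onto a ball
#'
#' Projects `w` onto the closed Euclidean ball of radius `delta` centred at
#' `center`.  Interior points are returned unchanged; outside points are pulled
#' radially onto the sphere.  `delta = 0` collapses the ball to its centre.
#'
#' @param w numeric vector to project.
#' @param center ball centre, same length as `w`.
#' @param delta nonnegative radius.
#' @return the unique closest point of the ball.
#' @export
project_ball <- function(w, center, delta) {
  check_scalar(delta, "delta", lower = 0)
  if (length(w) != length(center))
    stop("`w` and `center` must have the same length", call. = FALSE)
  diff <- w - center
  nd <- l2norm(diff)
  # points within rounding error of the sphere count as inside, which makes
  # the projection exactly idempotent
  if (nd <= delta * (1 + 32 * .Machine$double.eps)) return(w)
  center + diff * (delta / nd)
}

#' Componentwise projection onto a box
#'
#' Clamps every entry of `x` into `[lo, hi]`.  Used to enforce known pixel
#' ranges such as `[0, 1]`.
#'
#' @param x numeric vector.
#' @param lo,hi scalar bounds with `lo <= hi`.
#' @return clamped vector.
#' @export
project_box <- function(x, lo = 0, hi = 1) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo > hi)
    stop("`lo` must be <= `hi`", call. = FALSE)
  pmin(pmax(x, lo), hi)
}

# ---------------------------------------------------------------------------
# Learned proximal operator
# ---------------------------------------------------------------------------

# 3x3 convolution on a side x side image (row-major vector) as a sparse matrix.
.conv3_matrix <- function(side, kernel) {
  stopifnot(length(kernel) == 9L)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  n <- side * side
  px <- expand.grid(c = seq_len(side), r = seq_len(side))  # row-major order
  ii <- list(); jj <- list(); vv <- list()
  for (k in seq_len(9L)) {
    r2 <- px$r + offs$dr[k]; c2 <- px$c + offs$dc[k]
    keep <- r2 >= 1 & r2 <= side & c2 >= 1 & c2 <= side
    ii[[k]] <- which(keep)
    jj[[k]] <- (r2[keep] - 1) * side + c2[keep]
    vv[[k]] <- rep.int(kernel[k], sum(keep))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv), dims = c(n, n))
}

.spectral_normalize <- function(W, iters = 30L, seed = 5L) {
  nrm <- estimate_norm(make_matrix_map(W), iters = iters, seed = seed)
  if (nrm > 1) W / (1.000001 * nrm) else W
}

#' Data-driven proximal operator with a certified Lipschitz bound
#'
#' A small residual network standing in for the proximal operator of a learned
#' regularizer: `apply(x) = x/2 + g(x)/2` with
#' `g(x) = W2 tanh(W1 x + b1) + b2`.  Both affine layers are spectrally
#' normalized to operator norm at most 1 and `tanh` is 1-Lipschitz, so `g` is
#' 1-Lipschitz and the combined map is averaged with constant 1/2 — the
#' property the convergence theory of averaged fixed-point iterations needs.
#'
#' For image signals (`image_side` given) the layers are 3x3 convolutions with
#' 9 free weights each; otherwise they are dense `dim x dim` matrices.
#'
#' @param dim signal length.
#' @param image_side optional image side; when given, `dim` must equal
#'   `image_side^2` and convolutional layers are used.
#' @param seed integer seed for the weight initialisation.
#' @param scale standard deviation of the initial weights before
#'   normalization.
#' @return an object of class `learned_prox` with fields `weights` (named list),
#'   `apply` (function), and `lipschitz_certified = TRUE`.
#' @export
learned_prox <- function(dim, image_side = NULL, seed = 1L, scale = 0.1) {
  dim <- check_count(dim, "dim")
  if (!is.null(image_side)) {
    image_side <- check_count(image_side, "image_side")
    if (image_side^2 != dim) stop("`dim` must equal image_side^2", call. = FALSE)
    k1 <- with_seed(seed, stats::rnorm(9, sd = scale))
    k2 <- with_seed(seed + 1L, stats::rnorm(9, sd = scale))
    weights <- list(kind = "conv", image_side = image_side,
                    k1 = k1, k2 = k2, b1 = 0, b2 = 0, seed = seed)
  } else {
    W1 <- with_seed(seed, matrix(stats::rnorm(dim * dim, sd = scale / sqrt(dim)), dim, dim))
    W2 <- with_seed(seed + 1L, matrix(stats::rnorm(dim * dim, sd = scale / sqrt(dim)), dim, dim))
    weights <- list(kind = "dense", W1 = W1, W2 = W2, b1 = 0, b2 = 0, seed = seed)
  }
  rebuild_learned_prox(weights, dim)
}

# (Re)assemble the apply closure from raw weights; spectral normalization is
# applied here so it can be re-imposed after every training step.
rebuild_learned_prox <- function(weights, dim) {
  if (weights$kind == "conv") {
    W1 <- .spectral_normalize(.conv3_matrix(weights$image_side, weights$k1))
    W2 <- .spectral_normalize(.conv3_matrix(weights$image_side, weights$k2))
  } else {
    W1 <- .spectral_normalize(weights$W1)
    W2 <- .spectral_normalize(weights$W2)
  }
  apply_fn <- function(x) {
    g <- as.numeric(W2 %*% tanh(as.numeric(W1 %*% x) + weights$b1)) + weights$b2
    0.5 * x + 0.5 * g
  }
  structure(list(weights = weights, dim = dim, apply = apply_fn,
                 lipschitz_certified = TRUE),
            class = "learned_prox")
}

#' @export
print.learned_prox <- function(x, ...) {
  cat(sprintf("<learned_prox dim %d (%s layers), 1-Lipschitz certified>\n",
              x$dim, x$weights$kind))
  invisible(x)
}

#' Proximal residual of a point under a proximal operator
#'
#' `||x - prox(x)||`: zero exactly when `x` is a fixed point of the operator,
#' i.e. a local minimizer of the regularizer the operator encodes.  This is the
#' data-driven regularization property value used by certificates.
#'
#' @param x numeric vector.
#' @param prox a `learned_prox`, or any function mapping a vector to a vector.
#' @return nonnegative scalar.
#' @export
learned_prox_residual <- function(x, prox) {
  f <- if (inherits(prox, "learned_prox")) prox$apply else prox
  px <- f(x)
  if (length(px) != length(x)) stop("prox output length mismatch", call. = FALSE)
  l2norm(x - px)
}

#' Serialize / restore learned proximal weights
#'
#' Weights are written as JSON (with full double precision) together with a
#' sidecar-style header recording shapes, the spectral-normalization flag and
#' the initialisation seed.
#'
#' @param prox a `learned_prox`.
#' @param path file path.
#' @return `save_learned_prox` returns `path` invisibly;
#'   `load_learned_prox` returns the restored `learned_prox`.
#' @export
save_learned_prox <- function(prox, path) {
  stopifnot(inherits(prox, "learned_prox"))
  payload <- list(meta = list(kind = prox$weights$kind, dim = prox$dim,
                              spectral_norm = TRUE, seed = prox$weights$seed),
                  weights = prox$weights)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_learned_prox
#' @export
load_learned_prox <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- payload$weights
  if (w$kind == "dense") { w$W1 <- as.matrix(w$W1); w$W2 <- as.matrix(w$W2) }
  rebuild_learned_prox(w, payload$meta$dim)
}
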