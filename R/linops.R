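#' Linear operator abstraction
#'
#' A `linear_map` bundles a forward action, its adjoint, the two dimensions and
#' a certified upper bound on the operator norm.  Solvers only ever touch
#' operators through this interface, so a dense matrix, a sparse Radon system
#' and a convolution all look alike to them.  The norm bound is what the
#' step-size rules consume.
#'
#' @param in_dim,out_dim positive integers, domain and range dimension.
#' @param forward,adjoint functions mapping a numeric vector to a numeric
#'   vector.  The adjoint must satisfy `<forward(u), v> == <u, adjoint(v)>`.
#' @param norm_bound nonnegative upper bound on the operator norm.  If `NA` it
#'   is filled in by power iteration (see [estimate_norm()]).
#' @param matrix optional explicit matrix backing the map (kept for adjoint
#'   verification and export, not required).
#' @return an object of class `linear_map`.
#' @seealso [make_matrix_map()], [build_radon_map()], [estimate_norm()]
#' @export
linear_map <- function(in_dim, out_dim, forward, adjoint, norm_bound = NA_real_,
                       matrix = NULL) {
  in_dim <- check_count(in_dim, "in_dim")
  out_dim <- check_count(out_dim, "out_dim")
  stopifnot(is.function(forward), is.function(adjoint))
  map <- structure(
    list(in_dim = in_dim, out_dim = out_dim, forward = forward,
         adjoint = adjoint, norm_bound = norm_bound, matrix = matrix),
    class = "linear_map")
  if (is.na(norm_bound)) map$norm_bound <- estimate_norm(map, iters = 60L, seed = 1L)
  map
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf("<linear_map %d -> %d, norm bound %.4g%s>\n", x$in_dim, x$out_dim,
              x$norm_bound, if (is.null(x$matrix)) "" else ", explicit matrix"))
  invisible(x)
}

#' Apply a linear map or its adjoint
#'
#' @param map a [linear_map()].
#' @param v numeric vector of length `in_dim` (`map_forward`) or `out_dim`
#'   (`map_adjoint`).
#' @return numeric vector.
#' @export
map_forward <- function(map, v) {
  stopifnot(inherits(map, "linear_map"))
  if (length(v) != map$in_dim)
    stop(sprintf("expected input of length %d, got %d", map$in_dim, length(v)), call. = FALSE)
  as.numeric(map$forward(v))
}

#' @rdname map_forward
#' @export
map_adjoint <- function(map, v) {
  stopifnot(inherits(map, "linear_map"))
  if (length(v) != map$out_dim)
    stop(sprintf("expected input of length %d, got %d", map$out_dim, length(v)), call. = FALSE)
  as.numeric(map$adjoint(v))
}

#' Wrap an explicit matrix as a linear map
#'
#' Forward is the matrix-vector product, the adjoint the transpose product.
#' Works for base matrices and any `Matrix` sparse class.
#'
#' @param A numeric matrix (dense or sparse), all entries finite.
#' @param norm_bound optional known bound; computed by power iteration when
#'   missing.
#' @return a [linear_map()].
#' @examples
#' m <- make_matrix_map(diag(3))
#' map_forward(m, c(1, 2, 3))
#' @export
make_matrix_map <- function(A, norm_bound = NA_real_) {
  if (inherits(A, "Matrix")) {
    if (any(!is.finite(A@x))) stop("`A` must contain only finite values", call. = FALSE)
  } else {
    A <- as.matrix(A)
    stop_if_not_finite(A, "A")
  }
  linear_map(
    in_dim = ncol(A), out_dim = nrow(A),
    forward = function(v) as.numeric(A %*% v),
    adjoint = function(v) as.numeric(Matrix::crossprod(A, v)),
    norm_bound = norm_bound, matrix = A)
}

#' Power-iteration estimate of an operator norm
#'
#' Runs power iteration on the normal operator `adjoint(forward(.))` from a
#' seeded random start and returns `sqrt` of the dominant eigenvalue estimate.
#' The estimate is nondecreasing in `iters` for a fixed seed.  Callers that
#' store the result into `norm_bound` multiply by a 1.01 safety factor so
#' step-size conditions hold strictly.
#'
#' @param map a [linear_map()].
#' @param iters number of power iterations (>= 1).
#' @param seed integer seed for the start vector.
#' @return nonnegative scalar estimate of the spectral norm.
#' @export
estimate_norm <- function(map, iters = 50L, seed = 1L) {
  stopifnot(inherits(map, "linear_map"))
  iters <- check_count(iters, "iters")
  v <- with_seed(seed, stats::rnorm(map$in_dim))
  nv <- l2norm(v)
  if (nv == 0) return(0)
  v <- v / nv
  est <- 0
  for (k in seq_len(iters)) {
    w <- map$adjoint(map$forward(v))
    nw <- l2norm(w)
    if (nw == 0) return(0)
    est <- max(est, sqrt(nw))   # Rayleigh growth is monotone from below
    v <- w / nw
  }
  # final Rayleigh quotient: |map v| for the normalized iterate
  max(est, l2norm(map$forward(v)))
}

#' Parallel-beam acquisition geometry
#'
#' `n_angles` view angles equally spaced on `[0, pi)`, `n_beams` parallel rays
#' per view, offsets equally spaced across the image diagonal (cell-centred, so
#' offsets are `(b - (n_beams+1)/2) * side*sqrt(2)/n_beams`).  The image is a
#' `image_side x image_side` pixel grid centred at the origin with unit pixels.
#'
#' @param image_side,n_angles,n_beams positive integers.
#' @return an object of class `radon_geometry`.
#' @export
radon_geometry <- function(image_side, n_angles, n_beams) {
  structure(list(image_side = check_count(image_side, "image_side"),
                 n_angles = check_count(n_angles, "n_angles"),
                 n_beams = check_count(n_beams, "n_beams")),
            class = "radon_geometry")
}

#' @export
print.radon_geometry <- function(x, ...) {
  cat(sprintf("<radon_geometry %dx%d image, %d angles x %d beams -> %d rays>\n",
              x$image_side, x$image_side, x$n_angles, x$n_beams,
              x$n_angles * x$n_beams))
  invisible(x)
}

# Exact pixel-line intersection lengths (Siddon-style) for one ray.
# Ray: point(t) = tau*(cos phi, sin phi) + t*(-sin phi, cos phi).
# Returns row-major pixel indices and chord lengths.
.ray_trace <- function(side, phi, tau) {
  half <- side / 2
  cphi <- cos(phi); sphi <- sin(phi)
  dx <- -sphi; dy <- cphi
  x0 <- tau * cphi; y0 <- tau * sphi
  tmax <- half * sqrt(2) + 1
  ts <- c(-tmax, tmax)
  grid <- (-half):half
  if (abs(dx) > 1e-12) ts <- c(ts, (grid - x0) / dx)
  if (abs(dy) > 1e-12) ts <- c(ts, (grid - y0) / dy)
  ts <- sort(ts[ts >= -tmax & ts <= tmax])
  ts <- ts[c(TRUE, diff(ts) > 1e-12)]
  if (length(ts) < 2L) return(NULL)
  mid <- (ts[-1L] + ts[-length(ts)]) / 2
  len <- diff(ts)
  mx <- x0 + mid * dx
  my <- y0 + mid * dy
  col <- floor(mx + half) + 1
  row <- floor(half - my) + 1
  keep <- row >= 1 & row <= side & col >= 1 & col <= side & len > 1e-12
  if (!any(keep)) return(NULL)
  list(idx = (row[keep] - 1) * side + col[keep], len = len[keep])
}

#' Build the sparse Radon system matrix for a parallel-beam geometry
#'
#' Each matrix row is one ray, ordered angle-major (all beams of angle 1, then
#' angle 2, ...).  Entries are exact intersection lengths of the ray with each
#' pixel, so the forward map is the discrete line-integral Radon transform and
#' the adjoint (transpose) is unfiltered backprojection.  The construction is
#' deterministic for a fixed geometry.
#'
#' The sparse-angle setup used for chest-CT style experiments (`128 x 128`
#' image, 30 angles, 183 beams) yields a `5490 x 16384` system.
#'
#' @param geom a [radon_geometry()].
#' @return a [linear_map()] whose `matrix` field is the sparse system matrix
#'   (`Matrix::dgCMatrix`, rows `n_angles * n_beams`, columns `image_side^2`,
#'   row-major pixel order).
#' @export
build_radon_map <- function(geom) {
  stopifnot(inherits(geom, "radon_geometry"))
  side <- geom$image_side
  n_rays <- geom$n_angles * geom$n_beams
  diag_len <- side * sqrt(2)
  taus <- (seq_len(geom$n_beams) - (geom$n_beams + 1) / 2) * (diag_len / geom$n_beams)
  phis <- (seq_len(geom$n_angles) - 1) * pi / geom$n_angles
  ri <- vector("list", n_rays); ci <- ri; vi <- ri
  row <- 0L
  for (a in seq_len(geom$n_angles)) {
    for (b in seq_len(geom$n_beams)) {
      row <- row + 1L
      tr <- .ray_trace(side, phis[a], taus[b])
      if (is.null(tr)) next
      ri[[row]] <- rep.int(row, length(tr$idx))
      ci[[row]] <- tr$idx
      vi[[row]] <- tr$len
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(ci), x = unlist(vi),
                            dims = c(n_rays, side * side))
  map <- make_matrix_map(A)
  map$geometry <- geom
  map
}

#' Export a sparse system matrix as plain-text triplets
#'
#' Writes a CSV of `(row, col, value)` triplets preceded by a JSON header line
#' carrying the shape, so the operator can be rebuilt outside R.
#'
#' @param map a [linear_map()] with an explicit sparse `matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_triplets <- function(map, path) {
  stopifnot(inherits(map, "linear_map"), !is.null(map$matrix))
  M <- methods::as(methods::as(map$matrix, "generalMatrix"), "TsparseMatrix")
  header <- jsonlite::toJSON(list(nrow = nrow(M), ncol = ncol(M), nnz = length(M@x)),
                             auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines("row,col,value", con)
  writeLines(sprintf("%d,%d,%.17g", M@i + 1L, M@j + 1L, M@x), con)
  invisible(path)
}
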