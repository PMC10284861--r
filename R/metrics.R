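#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` with peak 1 for images in `[0, 1]`.  Identical
#' images have zero MSE and return `Inf`.
#'
#' @param reference,estimate numeric matrices (or vectors) of equal shape;
#'   the reference is assumed to live in `[0, 1]`.
#' @param peak peak signal value.
#' @return PSNR in decibels.
#' @export
psnr <- function(reference, estimate, peak = 1) {
  if (length(reference) != length(estimate))
    stop("shapes must match", call. = FALSE)
  mse <- mean((as.numeric(reference) - as.numeric(estimate))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# valid-region local means of a matrix under a w x w uniform window,
# computed with banded summation matrices
.local_mean <- function(M, w) {
  nr <- nrow(M); nc <- ncol(M)
  Ur <- matrix(0, nr - w + 1, nr)
  for (i in seq_len(nr - w + 1)) Ur[i, i:(i + w - 1)] <- 1
  Uc <- matrix(0, nc - w + 1, nc)
  for (i in seq_len(nc - w + 1)) Uc[i, i:(i + w - 1)] <- 1
  (Ur %*% M %*% t(Uc)) / (w * w)
}

#' Structural similarity index
#'
#' Mean local SSIM over a sliding `win x win` uniform window (default 7),
#' stabilising constants `C1 = (0.01 peak)^2`, `C2 = (0.03 peak)^2`, sample
#' (N-1) normalization for the local variances, and the mean taken over
#' windows fully inside the image.  These conventions match the standard
#' reference implementation for uniform windows.
#'
#' @param reference,estimate numeric matrices of equal shape, sides at least
#'   `win`.
#' @param win odd window size.
#' @param peak data range of the reference.
#' @return SSIM value in `[-1, 1]` (1 for identical images).
#' @export
ssim <- function(reference, estimate, win = 7L, peak = 1) {
  X <- as.matrix(reference); Y <- as.matrix(estimate)
  if (!all(dim(X) == dim(Y))) stop("shapes must match", call. = FALSE)
  if (min(dim(X)) < win)
    stop(sprintf("image sides must be at least the window size (%d)", win), call. = FALSE)
  NP <- win * win
  cov_norm <- NP / (NP - 1)
  C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
  ux <- .local_mean(X, win); uy <- .local_mean(Y, win)
  vx <- cov_norm * (.local_mean(X * X, win) - ux^2)
  vy <- cov_norm * (.local_mean(Y * Y, win) - uy^2)
  vxy <- cov_norm * (.local_mean(X * Y, win) - ux * uy)
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(S)
}
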