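#' Synthetic dictionary-recovery dataset
#'
#' Emulates the sparse-representation recovery setting: signals
#' `x = M s` with a hidden dense transform `M` (`n x r`, columns normalized)
#' and sparse codes `s`, observed through an under-determined Gaussian
#' measurement matrix `A` (`m x n`, `m < n`) as `d = A x`.  One `(M, A)` pair
#' is drawn per dataset; codes are fresh per instance with uniformly chosen
#' supports and standard Gaussian magnitudes.  Least-squares inversion of `d`
#' alone cannot recover such signals — that failure is the reason the implicit
#' dictionary model exists.
#'
#' Full-scale defaults are `n = 250`, `r = 50`, `m = 100` with 5-sparse codes.
#'
#' @param n signal dimension.
#' @param r code dimension (`r < n`).
#' @param m number of measurements (`m < n`).
#' @param sparsity nonzeros per code (`<= r`).
#' @param count number of instances.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return object of class `dictionary_dataset`: list with matrices `M`
#'   (`n x r`), `A` (`m x n`), `X` (`n x count`, true signals), `S`
#'   (`r x count`, true codes), `D` (`m x count`, measurements), and the
#'   generation parameters.
#' @export
generate_dictionary_dataset <- function(n = 250L, r = 50L, m = 100L,
                                        sparsity = 5L, count = 100L, seed = 1L) {
  n <- check_count(n, "n"); r <- check_count(r, "r"); m <- check_count(m, "m")
  count <- check_count(count, "count")
  sparsity <- check_count(sparsity, "sparsity", lower = 0L)
  if (sparsity > r) stop("`sparsity` must be <= `r`", call. = FALSE)
  if (m >= n) stop("`m` must be < `n` (under-determined system)", call. = FALSE)
  with_seed(seed, {
    M <- matrix(stats::rnorm(n * r), n, r)
    M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
    A <- matrix(stats::rnorm(m * n), m, n)
    S <- matrix(0, r, count)
    if (sparsity > 0)
      for (i in seq_len(count)) S[sample.int(r, sparsity), i] <- stats::rnorm(sparsity)
    X <- M %*% S
    structure(list(M = M, A = A, S = S, X = X, D = A %*% X,
                   n = n, r = r, m = m, sparsity = sparsity,
                   count = count, seed = seed),
              class = "dictionary_dataset")
  })
}

#' @export
print.dictionary_dataset <- function(x, ...) {
  cat(sprintf("<dictionary_dataset: %d instances, n=%d r=%d m=%d, %d-sparse codes, seed %d>\n",
              x$count, x$n, x$r, x$m, x$sparsity, x$seed))
  invisible(x)
}

#' Random ellipse phantom
#'
#' Superimposes `n_ellipses` random ellipses (random centres, axes, rotation,
#' signed intensities) on an empty image and clips to `[0, 1]`.  A synthetic
#' stand-in for anatomical phantoms with piecewise-smooth structure.
#'
#' @param image_side image side in pixels (>= 4).
#' @param n_ellipses number of ellipses.
#' @param seed integer seed.
#' @return `image_side x image_side` numeric matrix with values in `[0, 1]`.
#' @export
generate_phantom <- function(image_side, n_ellipses = 6L, seed = 1L) {
  image_side <- check_count(image_side, "image_side", lower = 4L)
  n_ellipses <- check_count(n_ellipses, "n_ellipses", lower = 0L)
  img <- matrix(0, image_side, image_side)
  if (n_ellipses == 0L) return(img)
  # pixel-centre coordinates in [-1, 1]
  cc <- (seq_len(image_side) - 0.5) / image_side * 2 - 1
  xg <- matrix(cc, image_side, image_side, byrow = TRUE)
  yg <- matrix(rev(cc), image_side, image_side)
  with_seed(seed, {
    for (e in seq_len(n_ellipses)) {
      if (e == 1L) {
        # a guaranteed positive "body" ellipse: every phantom has support
        cx <- stats::runif(1, -0.2, 0.2); cy <- stats::runif(1, -0.2, 0.2)
        ax <- stats::runif(1, 0.45, 0.85); ay <- stats::runif(1, 0.45, 0.85)
        val <- stats::runif(1, 0.3, 1)
      } else {
        cx <- stats::runif(1, -0.6, 0.6); cy <- stats::runif(1, -0.6, 0.6)
        ax <- stats::runif(1, 0.1, 0.7); ay <- stats::runif(1, 0.1, 0.7)
        val <- stats::runif(1, -0.5, 1)
      }
      th <- stats::runif(1, 0, pi)
      xr <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
      yr <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
      img <- img + val * ((xr / ax)^2 + (yr / ay)^2 <= 1)
    }
  })
  pmin(pmax(img, 0), 1)
}

#' Per-beam multiplicative Gaussian noise
#'
#' Each beam measurement is perturbed as `out_i = sino_i * (1 + e_i)` with
#' `e_i ~ N(0, level^2)` — "level" fraction Gaussian noise on each individual
#' beam.  Zero-valued beams stay exactly zero.
#'
#' @param sinogram numeric vector of beam measurements.
#' @param level nonnegative relative noise level (0.015 is 1.5 percent).
#' @param seed integer seed.
#' @return noisy sinogram vector.
#' @export
add_beam_noise <- function(sinogram, level = 0.015, seed = 1L) {
  check_scalar(level, "level", lower = 0)
  if (level == 0) return(sinogram)
  eps <- with_seed(seed, stats::rnorm(length(sinogram), sd = level))
  sinogram * (1 + eps)
}

#' Geometry presets for the CT experiment
#'
#' `"full"` is the full sparse-angle setup (128 x 128 image, 30 angles, 183
#' beams: 5490 rays against 16384 unknowns); `"desk"` is a reduced geometry
#' (32 x 32, 10 angles, 47 beams) with the same under-determined character,
#' sized for routine test runs.
#'
#' @param preset `"full"` or `"desk"`.
#' @return a [radon_geometry()].
#' @export
ct_preset_geometry <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  switch(preset,
         full = radon_geometry(128L, 30L, 183L),
         desk = radon_geometry(32L, 10L, 47L))
}

#' Synthetic sparse-angle CT dataset
#'
#' Generates random ellipse phantoms, their clean sinograms under the given
#' parallel-beam geometry, and noisy sinograms with per-beam multiplicative
#' Gaussian noise.
#'
#' @param geometry a [radon_geometry()] or a preset name (see
#'   [ct_preset_geometry()]).
#' @param count number of instances.
#' @param noise_level per-beam relative noise level.
#' @param seed integer seed.
#' @param radon optionally a prebuilt [build_radon_map()] for `geometry`
#'   (built once here when `NULL`).
#' @return object of class `ct_dataset`: list with the `radon` map, `geometry`,
#'   `phantoms` (list of matrices), `sino_clean` and `sino_noisy` (matrices,
#'   one column per instance), and `noise_level`.
#' @export
generate_ct_dataset <- function(geometry = "desk", count = 10L,
                                noise_level = 0.015, seed = 1L, radon = NULL) {
  if (is.character(geometry)) geometry <- ct_preset_geometry(geometry)
  stopifnot(inherits(geometry, "radon_geometry"))
  count <- check_count(count, "count")
  if (is.null(radon)) radon <- build_radon_map(geometry)
  phantoms <- lapply(seq_len(count), function(i)
    generate_phantom(geometry$image_side, n_ellipses = 6L, seed = seed * 10000L + i))
  sino_clean <- vapply(phantoms,
                       function(ph) map_forward(radon, as.vector(t(ph))),
                       numeric(radon$out_dim))
  sino_clean <- matrix(sino_clean, nrow = radon$out_dim)
  sino_noisy <- vapply(seq_len(count), function(i)
    add_beam_noise(sino_clean[, i], noise_level, seed = seed * 20000L + i),
    numeric(radon$out_dim))
  sino_noisy <- matrix(sino_noisy, nrow = radon$out_dim)
  structure(list(radon = radon, geometry = geometry, phantoms = phantoms,
                 sino_clean = sino_clean, sino_noisy = sino_noisy,
                 noise_level = noise_level, count = count, seed = seed),
            class = "ct_dataset")
}

#' @export
print.ct_dataset <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<ct_dataset: %d instances, %dx%d image, %d angles x %d beams, %.1f%% noise, seed %d>\n",
              x$count, g$image_side, g$image_side, g$n_angles, g$n_beams,
              100 * x$noise_level, x$seed))
  invisible(x)
}

#' Export a dictionary dataset as plain text
#'
#' Writes `M.csv`, `A.csv`, `S.csv`, `X.csv`, `D.csv` and a `manifest.json`
#' (shapes, seed, parameters) into a directory.
#'
#' @param ds a `dictionary_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_dictionary_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "dictionary_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("M", "A", "S", "X", "D"))
    utils::write.table(ds[[nm]], file.path(dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(ds[c("n", "r", "m", "sparsity", "count", "seed")],
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
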