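# shared fixtures, all generated in code

rand_mat <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc)
}

# independent basis-pursuit oracle: min ||x||_1 s.t. Ax = d as the LP
# min 1'(u + v) s.t. A(u - v) = d, u, v >= 0 (interior-point via pracma)
bp_oracle <- function(A, d) {
  n <- ncol(A)
  lp <- pracma::linprog(rep(1, 2 * n), Aeq = cbind(A, -A), beq = as.vector(d),
                        maxiter = 5000)
  lp$x[1:n] - lp$x[(n + 1):(2 * n)]
}

# chord length of the line {tau*(cos a, sin a) + t*(-sin a, cos a)} with the
# square [-h, h]^2 (slab intersection; independent geometric oracle)
chord_length <- function(h, angle, tau) {
  p <- tau * c(cos(angle), sin(angle))
  u <- c(-sin(angle), cos(angle))
  tmin <- -Inf; tmax <- Inf
  for (i in 1:2) {
    if (abs(u[i]) < 1e-14) {
      if (abs(p[i]) > h) return(0)
    } else {
      t1 <- (-h - p[i]) / u[i]; t2 <- (h - p[i]) / u[i]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  max(0, tmax - tmin)
}

# small dictionary problem shared by training tests (reduced scale)
reduced_dictionary <- function(seed = 11) {
  tr <- generate_dictionary_dataset(60, 12, 24, 3, 500, seed = seed)
  te <- generate_dictionary_dataset(60, 12, 24, 3, 100, seed = seed + 1L)
  te$M <- tr$M; te$A <- tr$A
  te$X <- te$M %*% te$S
  te$D <- te$A %*% te$X
  list(train = tr, test = te)
}
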