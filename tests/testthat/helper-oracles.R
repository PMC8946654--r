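# Shared oracles and cached simulation runs for the test suite.

# Second-order finite-difference solve of -lap(u) = 1 with no-slip walls:
# the independent reference for the duct series profile.
fd_poisson_profile <- function(width, height, n = 201L) {
  y <- seq(0, width, length.out = n)
  z <- seq(0, height, length.out = n)
  hy <- y[2] - y[1]; hz <- z[2] - z[1]
  m <- n - 2L; N <- m * m
  idx <- function(i, j) (j - 1L) * m + i
  ii <- rep(seq_len(m), times = m); jj <- rep(seq_len(m), each = m)
  trips <- list(
    cbind(idx(ii, jj), idx(ii, jj), 2 / hy^2 + 2 / hz^2))
  left <- ii > 1L
  trips[[2]] <- cbind(idx(ii[left], jj[left]),
                      idx(ii[left] - 1L, jj[left]), -1 / hy^2)
  right <- ii < m
  trips[[3]] <- cbind(idx(ii[right], jj[right]),
                      idx(ii[right] + 1L, jj[right]), -1 / hy^2)
  down <- jj > 1L
  trips[[4]] <- cbind(idx(ii[down], jj[down]),
                      idx(ii[down], jj[down] - 1L), -1 / hz^2)
  up <- jj < m
  trips[[5]] <- cbind(idx(ii[up], jj[up]),
                      idx(ii[up], jj[up] + 1L), -1 / hz^2)
  tr <- do.call(rbind, trips)
  A <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                            dims = c(N, N))
  u <- Matrix::solve(A, rep(1, N))
  mat <- matrix(0, n, n)
  mat[2:(n - 1L), 2:(n - 1L)] <- matrix(as.numeric(u), m, m)
  # normalise to unit sectional mean (trapezoid weights)
  wgt <- rep(1, n); wgt[c(1, n)] <- 0.5
  W <- outer(wgt, wgt)
  list(y = y, z = z, u = mat / (sum(mat * W) / sum(W)))
}

# Tiny-step explicit-Euler integration of m dv/dt = F(x) - gamma (v - u_f):
# brute-force oracle for the exponential Newtonian stepper.
euler_oracle <- function(x0, v0, mass, gamma, force_of, t_end, dt = 1e-7,
                         u_fluid = 0) {
  x <- x0; v <- v0; t <- 0
  nstep <- round(t_end / dt)
  for (i in seq_len(nstep)) {
    a <- (force_of(x) + gamma * (u_fluid - v)) / mass
    x <- x + v * dt
    v <- v + a * dt
  }
  list(x = x, v = v)
}

# Memoised expensive ensemble runs shared across test files.
.run_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .run_cache)) {
    assign(name, force(expr), envir = .run_cache)
  }
  get(name, envir = .run_cache)
}

mixed_ensemble <- function(seed = 42L, n = 50L) {
  make_cell_ensemble(c(CTC = n, WBC = n, RBC = n), 500e-6, 70e-6,
                     seed = seed)
}

s4_re40_passive <- function() cached("s4_re40", {
  run_passive_stage(mixed_ensemble(), build_channel("S4"),
                    fluid_properties(), 40)
})
s4_re65_passive <- function() cached("s4_re65", {
  run_passive_stage(mixed_ensemble(), build_channel("S4"),
                    fluid_properties(), 65)
})
s4_re40_hybrid <- function() cached("s4_re40_hybrid", {
  run_hybrid_pipeline(device_fixture("S4@Re40"))
})
s3_re65_hybrid <- function() cached("s3_re65_hybrid", {
  run_hybrid_pipeline(device_fixture("S3@Re65"))
})
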