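# shared in-code fixtures

# default generator truth used across kinetics tests
default_truth <- function(...) kinetic_truth(...)

# dense-grid oracle for the half-time of the two-component model
grid_half_time <- function(A1, r1, k2, c_nM, dt = 1e-4) {
  t_max <- 1
  while (eval_model(t_max, A1, r1, k2, c_nM) < 0.5) {
    t_max <- t_max * 2
    if (t_max > 1e5) stop("oracle: model never reaches 0.5")
  }
  tt <- seq(0, t_max, by = dt)
  tt[which(eval_model(tt, A1, r1, k2, c_nM) >= 0.5)[1]]
}

# rigid-body transform of a C-alpha coordinate table (rotation about z + xyz shift)
rigid_transform <- function(coords, theta = 0.7, shift = c(10, -5, 3)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta),  cos(theta), 0,
                0,           0,          1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(coords[, c("x", "y", "z")]) %*% t(R)
  out <- coords
  out$x <- xyz[, 1] + shift[1]
  out$y <- xyz[, 2] + shift[2]
  out$z <- xyz[, 3] + shift[3]
  out
}
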