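# Shared fixtures and independent oracles used across the suite.

# Chip table rows as plain values for readability in tests.
rc_params <- function(chip) {
  tab <- filter_chip_table()
  as.list(tab[chip, ])
}

# Filter chip in an isolation configuration: buffer branch resistance
# much larger than the filter resistance so junction loading is
# negligible and the capacitor node behaves as a textbook first-order
# system with tau ~= R_f * C.
isolated_filter_config <- function(chip = "RC2", rb_factor = 1e3,
                                   mixer = NULL) {
  p <- rc_params(chip)
  r <- p$tau_s / p$capacitance_m3_per_pa
  system_config(
    high_reservoir = reservoir(0.10, concentration = 1),
    low_reservoir = reservoir(0.05, concentration = 1),
    buffer_reservoir = reservoir(0.05, concentration = 0),
    filter_resistor = fluidic_resistor(r),
    filter_capacitor = fluidic_capacitor(p$capacitance_m3_per_pa,
                                         cavity_diameter = p$diameter_m),
    buffer_resistor = fluidic_resistor(rb_factor * r),
    mixer = mixer,
    withdrawal_rate = 2.5e-11)
}

# Brute-force 2-D Poiseuille cross-section oracle: solve
# mu * laplacian(u) = -G (G = 1 Pa/m) on the rectangle with no-slip
# walls by sparse finite differences; R = G * L / Q.
fd_duct_resistance <- function(length, width, depth, viscosity = 1e-3,
                               n_short = 40L) {
  ny <- n_short
  nx <- max(n_short, round(n_short * width / depth))
  dx <- width / (nx + 1)
  dy <- depth / (ny + 1)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  id <- function(i, j) (j - 1L) * nx + i
  rows <- id(g$i, g$j)
  entries <- list(data.frame(r = rows, c = rows,
                             v = 2 / dx^2 + 2 / dy^2))
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    ii <- g$i + d[1]; jj <- g$j + d[2]
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    entries[[length(entries) + 1L]] <-
      data.frame(r = rows[ok], c = id(ii[ok], jj[ok]),
                 v = -1 / if (d[1] != 0L) dx^2 else dy^2)
  }
  e <- do.call(rbind, entries)
  A <- Matrix::sparseMatrix(i = e$r, j = e$c, x = e$v,
                            dims = c(nx * ny, nx * ny))
  u <- as.numeric(Matrix::solve(A, rep(1 / viscosity, nx * ny)))
  q <- sum(u) * dx * dy
  length / q
}

# Explicit finite-difference oracle for transverse diffusion of the
# half-step with no-flux walls, at dimensionless time t_tilde.
fd_half_step_profile <- function(t_tilde, n_points = 101L) {
  x <- seq(0, 1, length.out = n_points)
  dx <- x[2] - x[1]
  u <- as.numeric(x < 0.5) + 0.5 * (abs(x - 0.5) < dx / 2)
  dt <- 0.4 * dx^2
  nsteps <- ceiling(t_tilde / dt)
  dt <- t_tilde / nsteps
  r <- dt / dx^2
  for (k in seq_len(nsteps)) {
    un <- u
    un[2:(n_points - 1)] <- u[2:(n_points - 1)] +
      r * (u[3:n_points] - 2 * u[2:(n_points - 1)] + u[1:(n_points - 2)])
    un[1] <- u[1] + 2 * r * (u[2] - u[1])
    un[n_points] <- u[n_points] + 2 * r * (u[n_points - 1] - u[n_points])
    u <- un
  }
  u
}

# First-order low-pass gain magnitude.
lpf_gain <- function(f, tau) 1 / sqrt(1 + (2 * pi * f * tau)^2)
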