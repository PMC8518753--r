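# Independent oracles used across the suite.

# Hand-coded rate equations for the ten-species network, written directly
# from the mechanism (not via the stoichiometry matrix). Used to verify the
# generated right-hand side.
hand_coded_rhs <- function(conc, k, relax = FALSE, clamp_h2 = FALSE) {
  c1 <- conc[["1"]]; c1a <- conc[["1a"]]; c2 <- conc[["2"]]
  c3 <- conc[["3"]]; c3a <- conc[["3a"]]; c4 <- conc[["4"]]
  c4a <- conc[["4a"]]
  k6 <- if (relax) k[["k6"]] else 0
  d <- c(
    "1"   = -k[["k1"]] * c1 * c2,
    "1a"  = +k[["k1"]] * c1 * c2 - k[["k2"]] * c1a * c3 +
            k[["k3"]] * c3a * c2 - k[["k4"]] * c1a * c4 +
            k[["k5"]] * c4a * c2,
    "2"   = -k[["k1"]] * c1 * c2 - k[["k3"]] * c3a * c2 -
            k[["k5"]] * c4a * c2,
    "3"   = -k[["k2"]] * c1a * c3,
    "3a"  = +k[["k2"]] * c1a * c3 - k[["k3"]] * c3a * c2,
    "4"   = +k[["k3"]] * c3a * c2 - k[["k4"]] * c1a * c4 - k6 * c4,
    "4a"  = +k[["k4"]] * c1a * c4 - k[["k5"]] * c4a * c2,
    "4rx" = +k6 * c4,
    "5"   = +k[["k5"]] * c4a * c2,
    "6"   = +k[["k1"]] * c1 * c2
  )
  if (clamp_h2) d[["2"]] <- 0
  d
}

# Fixed-step classical Runge-Kutta integrator: brute-force oracle for the
# adaptive integration.
rk4_integrate <- function(rhs_fun, y0, t_end, dt) {
  y <- y0
  t <- 0
  nstep <- round(t_end / dt)
  for (s in seq_len(nstep)) {
    k1 <- rhs_fun(y)
    k2 <- rhs_fun(y + dt / 2 * k1)
    k3 <- rhs_fun(y + dt / 2 * k2)
    k4 <- rhs_fun(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# default kinetic test fixtures
tube_network <- function(...) {
  build_network(calibrated_rate_constants(), hydrogen_clamp = 20, ...)
}
tube_initial <- function() phip_state(c("1" = 5, "3" = 20, "2" = 20))

# small chip mesh for fast transport tests (coarser than the default)
small_geometry <- function(...) {
  build_geometry(dx_mm = 0.5, n_across_channel = 6L, n_across_upper = 4L, ...)
}
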