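test_that("geometry construction validates the layout", {
  geo <- build_geometry()
  expect_equal(geo$membrane_mm, c(2, 27))
  expect_equal(geo$chamber_mm, c(48, 50))
  # liquid volume: channel plus the widened chamber pocket, close to the
  # real device's 8.5 uL
  expect_equal(geo$liquid_volume_uL,
               (55 * 0.1 + 2 * 0.4) * 1.4, tolerance = 1e-9)
  # upstream-shifted chamber
  up <- build_geometry(chamber_shift_mm = -12.5)
  expect_equal(up$chamber_mm, c(35.5, 37.5))
  expect_equal(up$membrane_mm, geo$membrane_mm)
  # degenerate and inconsistent layouts are rejected
  expect_error(build_geometry(membrane_length_mm = 0), "positive")
  expect_error(build_geometry(chamber_shift_mm = -30), "overlap")
  expect_error(build_geometry(chamber_shift_mm = -47.9), "downstream")
  expect_error(build_geometry(chamber_shift_mm = 10), "outside")
})

test_that("prescribed flow is plane Poiseuille with exact flux conservation", {
  geo <- build_geometry()
  fl <- compute_flow_field(geo, 8.4)
  Q <- 8.4e-9 / 60
  # mean axial velocity in the channel: Q / (w d) = 1.0e-3 m/s
  w <- 0.1e-3; d <- 1.4e-3
  expect_equal(sum(fl$Fx[10, ]) / (w * d), 1.0e-3, tolerance = 1e-12)
  # face fluxes follow the parabolic profile at the cell centres
  ych <- geo$y_mid_mm[1:geo$n_ch] * 1e-3
  shape <- 6 * (ych / w) * (1 - ych / w)
  expect_equal(fl$Fx[10, 1:geo$n_ch] / sum(fl$Fx[10, ]),
               shape / sum(shape), tolerance = 1e-12)
  # centreline cells run at 1.5x the mean (cell-averaged, so slightly less)
  expect_equal(max(fl$u_cell_m_s, na.rm = TRUE) / 1.0e-3, 1.5,
               tolerance = 0.03)
  # incompressibility: identical flux through random cross-sections
  set.seed(1)
  for (f in sample(geo$nx + 1, 10)) {
    expect_equal(cross_section_flux(fl, f), Q, tolerance = 1e-3 * 1e-2)
  }
  # the membrane subdomain carries no flow
  mem <- geo$cells[!geo$cells$liquid, ]
  expect_true(all(is.na(fl$u_cell_m_s[mem$id])))
})

test_that("pure-diffusion equilibrium: zero flow saturates the liquid", {
  geo <- small_geometry()
  net0 <- build_network(c(k1 = 0))
  sol <- solve_steady_transport(geo, network = net0,
                                config = chip_config(0, inlet_mM = c()))
  expect_lt(max(abs(sol$conc[, "2"] - 20)), 1e-6)
  expect_equal(chamber_mean(sol, "2"), 20, tolerance = 1e-8)
  # flat profile
  prof <- pathway_profile(sol, "2")
  expect_lt(diff(range(prof$concentration_mM)), 1e-6)
})

test_that("global hydrogen mass balance closes with reactions off", {
  geo <- small_geometry()
  net0 <- build_network(c(k1 = 0))
  for (q in c(2, 10)) {
    sol <- solve_steady_transport(geo, network = net0,
                                  config = chip_config(q, inlet_mM = c()))
    mb <- hydrogen_mass_balance(sol)
    expect_equal(mb$membrane_influx + mb$inlet_flux, mb$outlet_flux,
                 tolerance = 5e-3)
  }
})

test_that("hydrogen field is bounded and saturates as the narrative says", {
  geo <- small_geometry()
  net0 <- build_network(c(k1 = 0))
  # very low flow: saturation reached before the membrane segment ends
  lo <- solve_steady_transport(geo, network = net0,
                               config = chip_config(0.5, inlet_mM = c()))
  prof <- pathway_profile(lo, "2")
  mem_end <- geo$membrane_mm[2]
  before_end <- prof$concentration_mM[prof$x_mm > mem_end - 6 &
                                        prof$x_mm < mem_end]
  expect_true(all(before_end > 0.99 * 20))
  # maximum principle: 0 <= h <= h_pdms
  expect_true(all(lo$conc[, "2"] >= -1e-6))
  expect_true(all(lo$conc[, "2"] <= 20 + 1e-6))
  # profile monotone non-decreasing along the membrane segment
  memprof <- prof[prof$x_mm > geo$membrane_mm[1] & prof$x_mm < mem_end, ]
  expect_true(all(diff(memprof$concentration_mM) > -1e-9))
  # high flow: everywhere below saturation
  hi <- solve_steady_transport(geo, network = net0,
                               config = chip_config(20, inlet_mM = c()))
  expect_true(all(pathway_profile(hi, "2")$concentration_mM < 20))
  expect_true(all(hi$conc[, "2"] <= 20 + 1e-6))
})

test_that("chamber mean is a volume-weighted average", {
  geo <- small_geometry()
  net0 <- build_network(c(k1 = 0))
  sol <- solve_steady_transport(geo, network = net0,
                                config = chip_config(0, inlet_mM = c()))
  # uniform field averages to itself
  expect_equal(chamber_mean(sol, "2"), 20, tolerance = 1e-8)
  # an axially linear field averages to its value at the chamber midpoint
  # (quadrature oracle: the cell layout is symmetric about the midpoint)
  cells <- geo$cells
  sol2 <- sol
  sol2$conc[, "3"] <- 1 + 2 * cells$x_mm
  mid <- mean(geo$chamber_mm)
  expect_equal(chamber_mean(sol2, "3"), 1 + 2 * mid, tolerance = 1e-12)
  # zero field averages to zero
  expect_equal(chamber_mean(sol, "4"), 0, tolerance = 1e-12)
  expect_error(chamber_mean(sol, "7"), "unknown species")
})

test_that("chip solver agrees with the tube ODE in the clamped plug-flow limit", {
  # transverse diffusion mixes the 0.1 mm channel in ~2.5 s, far faster than
  # residence, so with hydrogen clamped the chip reduces to the tube model
  # evaluated at the residence time
  geo <- build_geometry(dx_mm = 0.5)
  net <- build_network(calibrated_rate_constants(), hydrogen_clamp = 20)
  q <- 2
  sol <- solve_steady_transport(geo, network = net,
                                config = chip_config(q))
  expect_true(all(abs(sol$conc[, "2"] - 20) < 1e-9, na.rm = TRUE))
  # residence time to the chamber midpoint
  cells <- geo$cells
  mid <- mean(geo$chamber_mm)
  vol_up <- sum(cells$volume_m3[cells$liquid & cells$x_mm < mid])
  t_res <- vol_up / (q * 1e-9 / 60)
  traj <- integrate_network(net, tube_initial(),
                            times = c(0, t_res))
  ode <- traj$conc[2, ]
  for (sp in c("3", "4", "5", "1", "1a")) {
    expect_equal(chamber_mean(sol, sp), ode[[sp]], tolerance = 0.08,
                 label = paste("chamber", sp))
  }
})

test_that("clamped low-flow limit reaches the ODE steady state", {
  geo <- small_geometry()
  net <- build_network(calibrated_rate_constants(), hydrogen_clamp = 20)
  sol <- solve_steady_transport(geo, network = net,
                                config = chip_config(0.05), max_iter = 400)
  # residence ~ 3 hours: full conversion, fully activated catalyst
  expect_equal(chamber_mean(sol, "5"), 20, tolerance = 0.02)
  expect_equal(chamber_mean(sol, "1a"), 5, tolerance = 0.02)
  expect_equal(chamber_mean(sol, "6"), 5, tolerance = 0.02)
})

test_that("mesh refinement leaves the chamber mean essentially unchanged", {
  net0 <- build_network(c(k1 = 0))
  base <- solve_steady_transport(build_geometry(), network = net0,
                                 config = chip_config(10, inlet_mM = c()))
  fine <- solve_steady_transport(
    build_geometry(dx_mm = 0.125, n_across_channel = 16L,
                   n_across_upper = 16L),
    network = net0, config = chip_config(10, inlet_mM = c()))
  expect_equal(chamber_mean(fine, "2"), chamber_mean(base, "2"),
               tolerance = 0.02)
})

test_that("field export is tidy and complete", {
  geo <- small_geometry()
  sol <- solve_steady_transport(geo, network = build_network(c(k1 = 0)),
                                config = chip_config(5, inlet_mM = c()))
  df <- field_to_df(sol, species = "2")
  expect_named(df, c("x_mm", "y_mm", "species", "concentration_mM"))
  expect_identical(nrow(df), nrow(geo$cells))  # hydrogen lives everywhere
  df3 <- field_to_df(sol, species = "3")
  expect_identical(nrow(df3), geo$n_liquid)   # others only in the liquid
})
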