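test_that("network construction enforces the mechanism's structure", {
  net <- build_network(calibrated_rate_constants())
  S <- net$stoich
  expect_identical(dim(S), c(10L, 6L))
  # every reaction conserves total catalyst and the organic backbone
  cat_rows <- c("1", "1a", "3a", "4a")
  bb_rows <- c("3", "3a", "4", "4a", "4rx", "5")
  expect_true(all(colSums(S[cat_rows, ]) == 0))
  expect_true(all(colSums(S[bb_rows, ]) == 0))
  # reactions 1-5 bimolecular, reaction 6 unimolecular 4 -> 4rx
  expect_equal(unname(colSums(net$orders[, 1:5])), rep(2, 5))
  expect_equal(unname(colSums(net$orders[, 6, drop = FALSE])), 1)
  expect_equal(S[, 6], c("1" = 0, "1a" = 0, "2" = 0, "3" = 0, "3a" = 0,
                         "4" = -1, "4a" = 0, "4rx" = 1, "5" = 0, "6" = 0))
  # relaxation off forces k6 = 0; on keeps it
  expect_identical(net$rate_constants[["k6"]], 0)
  net6 <- build_network(calibrated_rate_constants(k6 = 0.14),
                        relaxation_enabled = TRUE)
  expect_identical(net6$rate_constants[["k6"]], 0.14)
  # validation
  expect_error(build_network(c(k2 = -1)), "k2")
  expect_error(build_network(c(k9 = 1)), "unknown")
  # all-zero constants give an identically zero right-hand side
  net0 <- build_network(c(k1 = 0))
  expect_equal(unname(mass_action_rhs(phip_state(c("1" = 5, "2" = 20)), net0)),
               rep(0, 10))
})

test_that("rhs and fluxes reproduce hand arithmetic", {
  net <- build_network(calibrated_rate_constants())
  st <- phip_state(c("1" = 5, "2" = 20, "3" = 20))
  d <- mass_action_rhs(st, net)
  # only catalyst activation runs at t = 0: k1 * 5 * 20 = 0.15 mM/s
  expect_equal(d[["1"]], -0.15)
  expect_equal(d[["1a"]], 0.15)
  expect_equal(d[["6"]], 0.15)
  expect_equal(d[["3"]], 0)
  v <- reaction_fluxes(st, net)
  expect_equal(unname(v), c(0.15, 0, 0, 0, 0, 0))
  # substrate binding flux: k2 * [1a] * [3]
  v2 <- reaction_fluxes(phip_state(c("1a" = 1, "3" = 10)), net)
  expect_equal(v2[["r2"]], 5.016)
  expect_equal(unname(reaction_fluxes(phip_state(), net)), rep(0, 6))
  # clamping zeroes only the hydrogen derivative
  netc <- build_network(calibrated_rate_constants(), hydrogen_clamp = 20)
  dc <- mass_action_rhs(st, netc)
  expect_identical(dc[["2"]], 0)
  expect_equal(dc[setdiff(names(dc), "2")], d[setdiff(names(d), "2")])
  expect_error(mass_action_rhs(c(1, 2, 3), net), "species")
})

test_that("generated rhs matches the hand-coded rate equations", {
  set.seed(42)
  k <- calibrated_rate_constants(k6 = 0.14)
  for (relax in c(FALSE, TRUE)) {
    for (clamp in c(FALSE, TRUE)) {
      net <- build_network(k, relaxation_enabled = relax,
                           hydrogen_clamp = if (clamp) 20 else NULL)
      for (rep in 1:250) {
        st <- phip_state(stats::setNames(runif(10, 0, 30), phip_species()$id))
        expect_lt(max(abs(mass_action_rhs(st, net) -
                            hand_coded_rhs(st, k, relax, clamp))), 1e-12)
      }
    }
  }
})

test_that("integration conserves catalyst and backbone and reaches full conversion", {
  traj <- integrate_network(tube_network(), tube_initial(),
                            times = seq(0, 5000, by = 25))
  cat_tot <- rowSums(traj$conc[, c("1", "1a", "3a", "4a")])
  bb_tot <- rowSums(traj$conc[, c("3", "3a", "4", "4a", "4rx", "5")])
  expect_lt(max(abs(cat_tot - 5)) / 5, 1e-6)
  expect_lt(max(abs(bb_tot - 20)) / 20, 1e-6)
  # clamped hydrogen stays constant exactly
  expect_true(all(traj$conc[, "2"] == 20))
  # long-time limit: everything hydrogenated to propyl acetate, catalyst
  # fully activated
  final <- traj$conc[nrow(traj$conc), ]
  expect_lt(abs(final[["5"]] - 20) / 20, 0.02)
  expect_lt(abs(final[["1a"]] - 5) / 5, 0.02)
  expect_lt(abs(final[["6"]] - 5) / 5, 0.02)
  expect_lt(max(final[c("1", "3", "3a", "4", "4a")]), 0.4)
  # concentrations stay non-negative (within clipping tolerance)
  expect_true(all(traj$conc >= 0))
  # first row is the initial condition
  expect_equal(unname(traj$conc[1, ]), unname(tube_initial()))
  expect_error(integrate_network(tube_network(), phip_state(c("1" = -1)),
                                 c(0, 1)), "non-negative|>= 0")
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle", {
  net <- tube_network()
  k <- calibrated_rate_constants()
  rhs <- function(y) hand_coded_rhs(stats::setNames(y, phip_species()$id),
                                    k, relax = FALSE, clamp_h2 = TRUE)
  y_rk4 <- rk4_integrate(rhs, unname(tube_initial()), t_end = 100, dt = 1e-3)
  traj <- integrate_network(net, tube_initial(), times = c(0, 50, 100))
  expect_lt(max(abs(traj$conc[3, ] - y_rk4)), 1e-4)
})

test_that("network YAML serialisation round-trips", {
  net <- build_network(calibrated_rate_constants(k6 = 0.14),
                       relaxation_enabled = TRUE, hydrogen_clamp = 20)
  txt <- network_to_yaml(net)
  net2 <- network_from_yaml(text = txt)
  expect_equal(net2$rate_constants, net$rate_constants)
  expect_equal(net2$stoich, net$stoich)
  expect_equal(net2$hydrogen_clamp, net$hydrogen_clamp)
  # tidy trajectory export covers the full grid
  traj <- integrate_network(net, tube_initial(), c(0, 10, 20))
  df <- trajectory_to_df(traj)
  expect_identical(nrow(df), 30L)
  expect_named(df, c("time_s", "species", "concentration_mM"))
})
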