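# module tests run on a coarse mesh for speed; the default-resolution runs
# live in the acceptance suite
test_that("uptake curve declines monotonically with flow rate", {
  geo <- small_geometry()
  sw <- hydrogen_uptake_curve(c(1, 2, 5, 10, 20), geometry = geo)
  expect_identical(nrow(sw), 5L)
  expect_true(all(sw$species == "2"))
  expect_true(all(diff(sw$chamber_mM) < 0))
  expect_length(attr(sw, "failed"), 0)
  # determinism: a duplicated grid point yields identical values
  dup <- hydrogen_uptake_curve(c(5, 5), geometry = geo)
  expect_identical(dup$chamber_mM[1], dup$chamber_mM[2])
})

test_that("optimum finder refines with a quadratic and flags boundaries", {
  # synthetic exact parabola: vertex recovered exactly
  q <- seq(2, 10, by = 1)
  y <- 3 - (q - 5.3)^2 * 0.1
  sw <- data.frame(flow_uL_min = q, species = "4", chamber_mM = y,
                   scenario = "synthetic")
  opt <- find_optimal_flow(sw)
  expect_equal(opt$flow_uL_min, 5.3, tolerance = 1e-12)
  expect_equal(opt$peak_mM, 3, tolerance = 1e-12)
  expect_false(opt$boundary)
  # monotone sweep: boundary flag, no interpolation
  mono <- data.frame(flow_uL_min = q, species = "4", chamber_mM = q,
                     scenario = "synthetic")
  expect_true(find_optimal_flow(mono)$boundary)
  expect_error(find_optimal_flow(sw[1:3, ]), "5 grid points")
})

test_that("scenario definitions carry the right overrides", {
  expect_identical(phip_scenario("baseline")$label, "baseline")
  expect_equal(phip_scenario("k1_x10")$rate_constants, c(k1 = 0.015))
  expect_equal(phip_scenario("h2_40mM")$h_pdms_mM, 40)
  up <- phip_scenario("chamber_upstream")
  expect_equal(up$h_pdms_mM, 40)
  expect_equal(up$chamber_shift_mm, -12.5)
  expect_error(phip_scenario("bogus"))
})

test_that("product sweep is reproducible and responds to the relaxation sink", {
  geo <- small_geometry()
  grid <- c(2.5, 4, 6, 9, 12)
  sw1 <- product_vs_flow(grid, geometry = geo)
  sw2 <- product_vs_flow(grid, geometry = geo)
  expect_identical(sw1$chamber_mM, sw2$chamber_mM)  # bitwise determinism
  expect_identical(sort(unique(sw1$species)), sort(phip_species()$id))
  # switching the relaxation sink off lifts the low-flow product: without
  # relaxation nothing destroys allyl acetate on its way to the chamber
  # (except slow further hydrogenation)
  p_on <- sw1$chamber_mM[sw1$species == "4" & sw1$flow_uL_min == 2.5]
  sw0 <- product_vs_flow(c(2.5, 5, 10), geometry = geo, k6 = 0)
  p_off <- sw0$chamber_mM[sw0$species == "4" & sw0$flow_uL_min == 2.5]
  expect_gt(p_off, 5 * p_on)
  expect_gt(p_off, 0.5)
})

test_that("tenfold faster activation depletes the chamber hydrogen", {
  geo <- small_geometry()
  grid <- c(3, 6, 12)
  base <- product_vs_flow(grid, geometry = geo)
  fast <- product_vs_flow(grid, scenario = phip_scenario("k1_x10"),
                          geometry = geo)
  # the very stiff low-flow end may be reported as a flagged failure on this
  # coarse test mesh; compare hydrogen on the flows both sweeps solved
  common <- intersect(base$flow_uL_min, fast$flow_uL_min)
  expect_gte(length(common), 2)
  h_base <- base$chamber_mM[base$species == "2" & base$flow_uL_min %in% common]
  h_fast <- fast$chamber_mM[fast$species == "2" & fast$flow_uL_min %in% common]
  expect_true(all(h_fast < h_base))
})

test_that("run_scenario reports the peak and the baseline delta", {
  geo <- small_geometry()
  grid <- c(2.5, 4, 5, 6, 8, 10)
  base <- product_vs_flow(grid, geometry = geo)
  res <- run_scenario("h2_40mM", flow_rates = grid, baseline = base,
                      geometry = small_geometry())
  expect_identical(res$scenario, "h2_40mM")
  expect_gt(res$peak_mM, res$baseline_peak_mM)
  expect_equal(res$delta_vs_baseline_mM, res$peak_mM - res$baseline_peak_mM)
  # a baseline run compares to itself
  selfres <- run_scenario("baseline", flow_rates = grid, geometry = geo)
  expect_equal(selfres$delta_vs_baseline_mM, 0)
})

test_that("sweep CSV export round-trips", {
  sw <- data.frame(flow_uL_min = c(2, 2), species = c("4", "2"),
                   chamber_mM = c(0.5, 3.2), scenario = "baseline")
  f <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, f)
  back <- utils::read.csv(f, colClasses = c(species = "character"))
  expect_equal(back$chamber_mM, sw$chamber_mM)
  unlink(f)
})

test_that("bundled reference prediction points load", {
  ref <- reference_predictions()
  expect_true(all(c("quantity", "value", "units") %in% names(ref)))
  expect_true("optimal_flow_baseline" %in% ref$quantity)
})
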