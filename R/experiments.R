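#' Device-improvement scenarios
#'
#' Named configurations explored with the chip model: `baseline` (calibrated
#' constants, 20 mM membrane hydrogen, default chamber position), `k1_x10`
#' (catalyst-activation constant increased tenfold to 0.015 1/(mM s)),
#' `h2_40mM` (membrane hydrogen boundary doubled to 40 mM) and
#' `chamber_upstream` (chamber relocated 12.5 mm upstream while keeping the
#' 40 mM hydrogen boundary).
#'
#' @param label One of `"baseline"`, `"k1_x10"`, `"h2_40mM"`,
#'   `"chamber_upstream"`.
#' @return A `phip_scenario` with the label and its overrides
#'   (`rate_constants`, `h_pdms_mM`, `chamber_shift_mm`).
#' @export
phip_scenario <- function(label = c("baseline", "k1_x10", "h2_40mM",
                                    "chamber_upstream")) {
  label <- match.arg(label)
  ov <- switch(label,
    baseline = list(),
    k1_x10 = list(rate_constants = c(k1 = 0.015)),
    h2_40mM = list(h_pdms_mM = 40),
    chamber_upstream = list(h_pdms_mM = 40, chamber_shift_mm = -12.5)
  )
  structure(c(list(label = label), ov), class = "phip_scenario")
}

.sweep_record <- function(solution, flow, scenario,
                          species = .species_ids()) {
  data.frame(
    flow_uL_min = flow,
    species = species,
    chamber_mM = vapply(species, function(sp) chamber_mean(solution, sp), 0),
    scenario = scenario,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Hydrogen uptake into the flowing liquid vs flow rate
#'
#' Predicts how much hydrogen dissolves into methanol as it passes the
#' membrane, in the absence of catalyst and substrate: all rate constants
#' and all inlet concentrations are zero, only the membrane boundary supplies
#' hydrogen. The chamber-mean hydrogen concentration is reported per flow
#' rate; the curve is monotone non-increasing in flow rate.
#'
#' @param flow_rates Flow-rate grid, uL/min.
#' @param geometry A `chip_geometry`; default [build_geometry()].
#' @param h_pdms_mM Membrane boundary hydrogen, mM.
#' @param ... Passed to [solve_steady_transport()].
#' @return A sweep data frame: `flow_uL_min`, `species`, `chamber_mM`,
#'   `scenario`, plus a `failed` attribute listing flow rates whose solve
#'   failed (normally none).
#' @export
hydrogen_uptake_curve <- function(flow_rates, geometry = build_geometry(),
                                  h_pdms_mM = 20, ...) {
  net <- build_network(rep(0, 6) |> stats::setNames(paste0("k", 1:6)))
  rows <- list(); failed <- numeric(0)
  for (q in flow_rates) {
    cfg <- chip_config(q, h_pdms_mM = h_pdms_mM, inlet_mM = c())
    sol <- tryCatch(
      solve_steady_transport(geometry, network = net, config = cfg, ...),
      error = function(e) e)
    if (inherits(sol, "error")) {
      failed <- c(failed, q)
      next
    }
    rows[[length(rows) + 1]] <- .sweep_record(sol, q, "uptake", "2")
  }
  out <- do.call(rbind, rows)
  attr(out, "failed") <- failed
  out
}

#' Hyperpolarised-product concentration vs flow rate
#'
#' Runs the full kinetic chip model over a grid of flow rates: calibrated
#' rate constants (with any scenario overrides), relaxation sink
#' `k6 = 0.14` 1/s on free allyl acetate, inlet 20 mM propargyl acetate and
#' 5 mM catalyst precursor, membrane hydrogen boundary per scenario. Chamber
#' means of all ten species are recorded at each flow rate; consecutive
#' solves are warm-started from the previous one.
#'
#' @param flow_rates Flow-rate grid, uL/min (ascending recommended).
#' @param scenario A `phip_scenario` (default baseline).
#' @param geometry Optional `chip_geometry`; by default built from the
#'   scenario's chamber shift.
#' @param k6 Relaxation rate constant, 1/s.
#' @param rate_constants Base chemical rate constants `k1..k5`.
#' @param inlet_mM Inlet composition.
#' @param ... Passed to [solve_steady_transport()].
#' @return A sweep data frame (`flow_uL_min`, `species`, `chamber_mM`,
#'   `scenario`) with a `failed` attribute.
#' @export
product_vs_flow <- function(flow_rates, scenario = phip_scenario("baseline"),
                            geometry = NULL, k6 = 0.14,
                            rate_constants = calibrated_rate_constants()[1:5],
                            inlet_mM = c("1" = 5, "3" = 20), ...) {
  stopifnot(inherits(scenario, "phip_scenario"))
  ks <- rate_constants
  if (!is.null(scenario$rate_constants)) {
    ks[names(scenario$rate_constants)] <- scenario$rate_constants
  }
  net <- build_network(c(ks, k6 = k6), relaxation_enabled = TRUE)
  shift <- if (is.null(scenario$chamber_shift_mm)) 0
           else scenario$chamber_shift_mm
  if (is.null(geometry)) geometry <- build_geometry(chamber_shift_mm = shift)
  h_pdms <- if (is.null(scenario$h_pdms_mM)) 20 else scenario$h_pdms_mM
  rows <- list(); failed <- numeric(0)
  prev <- NULL
  # solve from high to low flow: the short-residence end is mild and each
  # solution warm-starts the next, which keeps the stiff low-flow solves in
  # the Newton basin
  flow_rates <- sort(flow_rates, decreasing = TRUE)
  solve_q <- function(q, init) {
    solve_steady_transport(geometry, network = net,
                           config = chip_config(q, h_pdms_mM = h_pdms,
                                                inlet_mM = inlet_mM),
                           init = init, ...)
  }
  for (q in flow_rates) {
    sol <- tryCatch(solve_q(q, prev), error = function(e) e)
    if (inherits(sol, "error")) {
      # stiff solve: retry by ramping down from a benign high flow
      sol <- tryCatch({
        ramp <- NULL
        for (qq in sort(unique(c(q * c(8, 4, 2), 12)), decreasing = TRUE)) {
          if (qq <= q || qq > 50) next
          ramp <- solve_q(qq, ramp)
        }
        solve_q(q, ramp)
      }, error = function(e) e)
    }
    if (inherits(sol, "error")) {
      failed <- c(failed, q)
      prev <- NULL
      next
    }
    prev <- sol
    rows[[length(rows) + 1]] <- .sweep_record(sol, q, scenario$label)
  }
  if (!length(rows)) {
    stop("no flow rate converged; failures at ",
         paste(failed, collapse = ", "), " uL/min")
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$flow_uL_min, out$species), ]
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  out
}

#' Locate the optimal flow rate from a sweep
#'
#' Finds the flow rate maximising the chamber-mean concentration of a
#' species. The grid argmax is refined by fitting a quadratic through the
#' top three grid points (the printed optimum lies between grid points at
#' any realistic sweep resolution). If the maximum sits on the grid
#' boundary, no interpolation is attempted and the result carries
#' `boundary = TRUE`.
#'
#' @param sweep Sweep data frame from [product_vs_flow()] or
#'   [hydrogen_uptake_curve()].
#' @param species Species id to maximise (default `"4"`, hyperpolarised
#'   allyl acetate).
#' @return List with `flow_uL_min` (refined optimum), `peak_mM` (quadratic
#'   peak value, or the grid value at a boundary), `grid_flow_uL_min`,
#'   `grid_peak_mM` and `boundary`.
#' @export
find_optimal_flow <- function(sweep, species = "4") {
  sub <- sweep[sweep$species == species, ]
  if (nrow(sub) < 5) stop("sweep must contain at least 5 grid points")
  sub <- sub[order(sub$flow_uL_min), ]
  m <- which.max(sub$chamber_mM)
  grid_q <- sub$flow_uL_min[m]
  grid_y <- sub$chamber_mM[m]
  if (m == 1 || m == nrow(sub)) {
    return(list(flow_uL_min = grid_q, peak_mM = grid_y,
                grid_flow_uL_min = grid_q, grid_peak_mM = grid_y,
                boundary = TRUE))
  }
  x <- sub$flow_uL_min[(m - 1):(m + 1)]
  y <- sub$chamber_mM[(m - 1):(m + 1)]
  co <- stats::coef(stats::lm(y ~ x + I(x^2)))
  if (!is.finite(co[3]) || co[3] >= 0) {
    # degenerate (flat or non-concave) top: fall back to the grid argmax
    return(list(flow_uL_min = grid_q, peak_mM = grid_y,
                grid_flow_uL_min = grid_q, grid_peak_mM = grid_y,
                boundary = FALSE))
  }
  qstar <- -co[2] / (2 * co[3])
  ystar <- co[1] + co[2] * qstar + co[3] * qstar^2
  list(flow_uL_min = unname(qstar), peak_mM = unname(ystar),
       grid_flow_uL_min = grid_q, grid_peak_mM = grid_y, boundary = FALSE)
}

#' Run a device-improvement scenario and compare with baseline
#'
#' Applies the scenario overrides, sweeps the flow-rate grid, and reports
#' the peak hyperpolarised-product concentration together with its change
#' relative to the baseline peak.
#'
#' @param scenario A `phip_scenario` or scenario label.
#' @param flow_rates Flow-rate grid, uL/min.
#' @param baseline Optional precomputed baseline sweep (recomputed if
#'   missing and the scenario is not itself the baseline).
#' @param ... Passed to [product_vs_flow()].
#' @return List with the scenario `sweep`, the refined `optimum` (from
#'   [find_optimal_flow()]), `peak_mM`, `baseline_peak_mM` and
#'   `delta_vs_baseline_mM`.
#' @export
run_scenario <- function(scenario, flow_rates = seq(2, 20, by = 0.5),
                         baseline = NULL, ...) {
  if (is.character(scenario)) scenario <- phip_scenario(scenario)
  sweep <- product_vs_flow(flow_rates, scenario = scenario, ...)
  opt <- find_optimal_flow(sweep, "4")
  base_peak <- NA_real_
  if (scenario$label == "baseline") {
    base_peak <- opt$peak_mM
  } else {
    if (is.null(baseline)) {
      baseline <- product_vs_flow(flow_rates,
                                  scenario = phip_scenario("baseline"), ...)
    }
    base_peak <- find_optimal_flow(baseline, "4")$peak_mM
  }
  list(scenario = scenario$label, sweep = sweep, optimum = opt,
       peak_mM = opt$peak_mM, baseline_peak_mM = base_peak,
       delta_vs_baseline_mM = opt$peak_mM - base_peak)
}

#' Write a sweep as tidy CSV
#'
#' @param sweep Sweep data frame.
#' @param path Output CSV path.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE, quote = FALSE)
  invisible(sweep)
}

#' Reference prediction points for regression testing
#'
#' Loads the bundled CSV of published 2D-model prediction points (chamber
#' hydrogen at 20 uL/min, the saturation flow-rate bound, the optimal flow
#' rate, scenario peak concentrations) used by the regression tests.
#'
#' @return Data frame `quantity`, `value`, `units`.
#' @export
reference_predictions <- function() {
  utils::read.csv(system.file("extdata", "reference_predictions.csv",
                              package = "phipflow"),
                  stringsAsFactors = FALSE)
}
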