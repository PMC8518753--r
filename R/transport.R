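#' Transport configuration for the chip model
#'
#' @param flow_uL_min Volumetric flow rate, uL/min (0 to 50).
#' @param D_m2_s Diffusion coefficient, m2/s, used for every species and for
#'   hydrogen inside the membrane; default 1e-9.
#' @param h_pdms_mM Hydrogen concentration held at the outer boundary of the
#'   PDMS membrane, mM; default 20 (the 5-bar solubility in methanol).
#' @param inlet_mM Named inlet concentrations, mM; defaults to 5 mM catalyst
#'   precursor and 20 mM propargyl acetate, everything else 0.
#' @param fluid_density_kg_m3,temperature_K Recorded fluid properties (the
#'   prescribed Stokes-regime flow does not depend on them).
#' @return A `chip_config` list.
#' @export
chip_config <- function(flow_uL_min,
                        D_m2_s = 1e-9,
                        h_pdms_mM = 20,
                        inlet_mM = c("1" = 5, "3" = 20),
                        fluid_density_kg_m3 = 789,
                        temperature_K = 298.15) {
  if (!is.finite(flow_uL_min) || flow_uL_min < 0 || flow_uL_min > 50) {
    stop("flow_uL_min must lie in [0, 50]")
  }
  if (D_m2_s <= 0) stop("D_m2_s must be > 0")
  if (h_pdms_mM < 0) stop("h_pdms_mM must be >= 0")
  structure(
    list(flow_uL_min = flow_uL_min, D_m2_s = D_m2_s, h_pdms_mM = h_pdms_mM,
         inlet_mM = phip_state(inlet_mM),
         fluid_density_kg_m3 = fluid_density_kg_m3,
         temperature_K = temperature_K),
    class = "chip_config"
  )
}

# Finite-volume operators on the chip mesh: upwinded advection + central
# diffusion for the liquid domain (all species) and the extended
# liquid+membrane domain (hydrogen), with inlet/outlet/membrane boundary
# terms. Matrix rows are net OUTflow coefficients, so the steady balance of
# species s reads  M_s c_s = b_s + V R_s(c).
.assemble_transport <- function(geometry, flow, D) {
  g <- geometry
  nx <- g$nx; ny <- g$ny
  d <- g$depth_mm * 1e-3
  dx <- g$dx_mm * 1e-3
  dy <- g$dy_mm * 1e-3
  L <- g$liq_id
  Mm <- g$mem_id
  n_liq <- g$n_liquid
  n_mem <- g$n_membrane
  n_h <- n_liq + n_mem

  ii <- jj <- integer(0); xx <- numeric(0)
  add_pair <- function(a, b, gg, F) {
    Fp <- pmax(F, 0); Fm <- pmax(-F, 0)
    ii <<- c(ii, a, a, b, b)
    jj <<- c(jj, a, b, b, a)
    xx <<- c(xx, gg + Fp, -(gg + Fm), gg + Fm, -(gg + Fp))
  }

  # liquid x-faces
  A1 <- L[seq_len(nx - 1), , drop = FALSE]
  A2 <- L[2:nx, , drop = FALSE]
  sel <- which(!is.na(A1) & !is.na(A2))
  a <- A1[sel]; b <- A2[sel]
  jrow <- ((sel - 1) %/% (nx - 1)) + 1
  fcol <- ((sel - 1) %% (nx - 1)) + 2
  add_pair(a, b, D * dy[jrow] * d / dx, flow$Fx[cbind(fcol, jrow)])

  # liquid y-faces
  B1 <- L[, seq_len(ny - 1), drop = FALSE]
  B2 <- L[, 2:ny, drop = FALSE]
  sel <- which(!is.na(B1) & !is.na(B2))
  a <- B1[sel]; b <- B2[sel]
  irow <- ((sel - 1) %% nx) + 1
  jlow <- ((sel - 1) %/% nx) + 1
  add_pair(a, b, D * dx * d / ((dy[jlow] + dy[jlow + 1]) / 2),
           flow$Fy[cbind(irow, jlow + 1)])

  # inlet: pure upwind inflow carrying the boundary concentration
  w_in <- numeric(n_liq)
  rows <- which(!is.na(L[1, ]))
  inlet_cells <- L[1, rows]
  w_in[inlet_cells] <- flow$Fx[1, rows]

  # outlet: upwind outflow of the cell concentration, zero diffusive flux
  rows <- which(!is.na(L[nx, ]))
  outlet_cells <- L[nx, rows]
  Fout <- flow$Fx[nx + 1, rows]
  ii <- c(ii, outlet_cells); jj <- c(jj, outlet_cells); xx <- c(xx, Fout)

  M_liq <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                dims = c(n_liq, n_liq))

  # hydrogen domain: liquid block plus the membrane (diffusion only)
  ii2 <- jj2 <- integer(0); xx2 <- numeric(0)
  add_pair2 <- function(a, b, gg) {
    ii2 <<- c(ii2, a, a, b, b)
    jj2 <<- c(jj2, a, b, b, a)
    xx2 <<- c(xx2, gg, -gg, gg, -gg)
  }
  # membrane x-faces
  A1 <- Mm[seq_len(nx - 1), , drop = FALSE]
  A2 <- Mm[2:nx, , drop = FALSE]
  sel <- which(!is.na(A1) & !is.na(A2))
  if (length(sel)) {
    jrow <- ((sel - 1) %/% (nx - 1)) + 1
    add_pair2(n_liq + A1[sel], n_liq + A2[sel], D * dy[jrow] * d / dx)
  }
  # membrane y-faces
  B1 <- Mm[, seq_len(ny - 1), drop = FALSE]
  B2 <- Mm[, 2:ny, drop = FALSE]
  sel <- which(!is.na(B1) & !is.na(B2))
  if (length(sel)) {
    jlow <- ((sel - 1) %/% nx) + 1
    add_pair2(n_liq + B1[sel], n_liq + B2[sel],
              D * dx * d / ((dy[jlow] + dy[jlow + 1]) / 2))
  }
  # membrane/channel interface: diffusive coupling, hydrogen only
  jtop <- g$n_ch
  icols <- which(!is.na(L[, jtop]) & !is.na(Mm[, jtop + 1]))
  iface <- data.frame(
    liq = L[icols, jtop],
    mem = n_liq + Mm[icols, jtop + 1],
    g = D * dx * d / ((dy[jtop] + dy[jtop + 1]) / 2)
  )
  add_pair2(iface$liq, iface$mem, iface$g)
  # outer membrane boundary: Dirichlet h_pdms through a half-cell conductance
  icols <- which(!is.na(Mm[, ny]))
  b_mem <- numeric(n_h)
  gtop <- D * dx * d / (dy[ny] / 2)
  top_cells <- n_liq + Mm[icols, ny]
  ii2 <- c(ii2, top_cells); jj2 <- c(jj2, top_cells)
  xx2 <- c(xx2, rep(gtop, length(top_cells)))
  b_mem[top_cells] <- gtop

  M_h2 <- Matrix::sparseMatrix(i = c(ii, ii2), j = c(jj, jj2),
                               x = c(xx, xx2), dims = c(n_h, n_h))

  list(M_liq = M_liq, M_h2 = M_h2, w_in = w_in, b_mem = b_mem,
       interface = iface,
       outlet = data.frame(cell = outlet_cells, F = Fout),
       inlet = data.frame(cell = inlet_cells, F = w_in[inlet_cells]))
}

#' Solve the steady convection-diffusion-reaction problem on the chip
#'
#' Solves the steady balance `div(u c_i) - D lap(c_i) = R_i(c)` for all ten
#' species on the chip mesh by damped Newton iteration with pseudo-transient
#' continuation. Boundary conditions: Dirichlet inlet composition carried in
#' by the flow, zero-diffusive-flux outflow at the outlet, no-flux walls, a
#' Dirichlet hydrogen concentration `h_pdms` on the outer membrane boundary,
#' and diffusion-only hydrogen transport inside the membrane (all other
#' species see the membrane interface as a wall). Kinetic source terms come
#' from the mass-action network with hydrogen FREE; if the network clamps
#' hydrogen, the hydrogen field is pinned to the clamp value instead (used
#' for the well-mixed equivalence checks against the tube model).
#'
#' @param geometry A `chip_geometry`.
#' @param flow A `chip_flow` on the same mesh (or `NULL` to compute it from
#'   the config flow rate).
#' @param network A `phip_network` (rate constants in 1/(mM s) apply
#'   unchanged because mM = mol/m3).
#' @param config A `chip_config`.
#' @param init Optional warm-start: a previous `chip_solution` on the same
#'   mesh, or a raw state vector.
#' @param tol Relative residual tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations.
#' @param verbose Print residual history.
#' @return A `chip_solution`: cell table plus an (n_cells x 10) concentration
#'   matrix (mM; NA where a species is not defined, i.e. non-hydrogen inside
#'   the membrane), the residual norm, and assembly internals used by the
#'   mass-balance diagnostics.
#' @export
solve_steady_transport <- function(geometry, flow = NULL, network, config,
                                   init = NULL, tol = 1e-8, max_iter = 100,
                                   verbose = FALSE) {
  g <- geometry
  stopifnot(inherits(g, "chip_geometry"), inherits(config, "chip_config"))
  if (is.null(flow)) flow <- compute_flow_field(g, config$flow_uL_min)
  ks <- network$rate_constants
  if (flow$Q_m3_s == 0 && any(ks[1:5] > 0)) {
    stop("reactive runs require a positive flow rate")
  }
  ids <- .species_ids()
  n_liq <- g$n_liquid
  n_mem <- g$n_membrane
  ops <- .assemble_transport(g, flow, config$D_m2_s)
  clamp <- network$hydrogen_clamp

  nuk <- ifelse(ids == "2", n_liq + n_mem, n_liq)
  off <- cumsum(c(0, nuk))[seq_along(ids)]
  names(off) <- ids
  ntot <- sum(nuk)

  # per-species transport blocks and rhs; Dirichlet (pinned) rows are scaled
  # to the transport-operator magnitude so the residual norm weighs all
  # equations comparably
  pin <- mean(Matrix::diag(ops$M_liq))
  blocks <- vector("list", length(ids))
  b <- numeric(ntot)
  quiescent <- flow$Q_m3_s == 0
  for (s in seq_along(ids)) {
    id <- ids[s]
    if (id == "2") {
      if (!is.null(clamp)) {
        blocks[[s]] <- Matrix::Diagonal(n_liq + n_mem, pin)
        b[off[s] + seq_len(n_liq + n_mem)] <- pin * clamp
      } else {
        blocks[[s]] <- ops$M_h2
        b[off[s] + seq_len(n_liq)] <- ops$w_in * config$inlet_mM[[id]]
        b[off[s] + seq_len(n_liq + n_mem)] <-
          b[off[s] + seq_len(n_liq + n_mem)] + ops$b_mem * config$h_pdms_mM
      }
    } else if (quiescent) {
      # no flow and no reactions: composition is the uniform inlet state
      blocks[[s]] <- Matrix::Diagonal(n_liq, pin)
      b[off[s] + seq_len(n_liq)] <- pin * config$inlet_mM[[id]]
    } else {
      blocks[[s]] <- ops$M_liq
      b[off[s] + seq_len(n_liq)] <- ops$w_in * config$inlet_mM[[id]]
    }
  }
  M <- Matrix::bdiag(blocks)

  Vliq <- g$cells$volume_m3[seq_len(n_liq)]
  Vglob <- numeric(ntot)
  for (s in seq_along(ids)) {
    Vglob[off[s] + seq_len(n_liq)] <- Vliq
  }
  Vglob[off[["2"]] + n_liq + seq_len(n_mem)] <-
    g$cells$volume_m3[n_liq + seq_len(n_mem)]

  # reaction structure (liquid cells only)
  S <- network$stoich
  reactants <- lapply(1:6, function(r) which(network$orders[, r] > 0))
  prods <- lapply(1:6, function(r) which(S[, r] != 0))
  h2_idx <- match("2", ids)
  react_rows_skip <- if (!is.null(clamp)) h2_idx else 0L

  liquid_conc <- function(cv) {
    C <- matrix(0, n_liq, length(ids))
    for (s in seq_along(ids)) C[, s] <- cv[off[s] + seq_len(n_liq)]
    C
  }
  reaction_vec <- function(C) {
    v <- matrix(0, n_liq, 6)
    for (r in 1:6) {
      rs <- reactants[[r]]
      v[, r] <- ks[[r]] * if (length(rs) == 2) C[, rs[1]] * C[, rs[2]]
                          else C[, rs]
    }
    R <- v %*% t(S)
    out <- numeric(ntot)
    for (s in seq_along(ids)) {
      if (s == react_rows_skip) next
      out[off[s] + seq_len(n_liq)] <- Vliq * R[, s]
    }
    out
  }
  reaction_jac <- function(C) {
    ji <- jjx <- integer(0); jv <- numeric(0)
    cell <- seq_len(n_liq)
    for (r in 1:6) {
      if (ks[[r]] == 0) next
      rs <- reactants[[r]]
      for (q in rs) {
        dv <- if (length(rs) == 2) ks[[r]] * C[, rs[rs != q][1]]
              else rep(ks[[r]], n_liq)
        for (i in prods[[r]]) {
          if (i == react_rows_skip) next
          ji <- c(ji, off[i] + cell)
          jjx <- c(jjx, off[q] + cell)
          jv <- c(jv, -Vliq * S[i, r] * dv)
        }
      }
    }
    if (!length(ji)) return(NULL)
    Matrix::sparseMatrix(i = ji, j = jjx, x = jv, dims = c(ntot, ntot))
  }

  # initial iterate: warm start, else the reactions-off linear solution
  if (inherits(init, "chip_solution")) init <- init$state
  cvec <- if (!is.null(init)) {
    if (length(init) != ntot) stop("warm start has wrong dimension")
    as.numeric(init)
  } else {
    as.numeric(Matrix::solve(M, b))
  }

  ref <- max(sqrt(sum(b^2)), 1e-30)
  resid <- function(cv) as.numeric(M %*% cv - b - reaction_vec(liquid_conc(cv)))
  Fv <- resid(cvec)
  rn <- sqrt(sum(Fv^2)) / ref
  history <- rn
  # Damped Newton with pseudo-transient continuation: when a plain Newton
  # step with backtracking fails, fall back to implicit-Euler pseudo-time
  # steps (diagonal V/dt augmentation). The pseudo-timestep follows switched
  # evolution relaxation: it grows as the steady residual falls, so the
  # iteration turns back into Newton near the solution.
  dt_inv <- 0
  iter <- 0
  while (rn >= tol && iter < max_iter) {
    iter <- iter + 1
    C <- liquid_conc(cvec)
    J <- M
    RJ <- reaction_jac(C)
    if (!is.null(RJ)) J <- J + RJ
    if (dt_inv > 0) J <- J + Matrix::Diagonal(x = Vglob * dt_inv)
    delta <- tryCatch(as.numeric(Matrix::solve(J, -Fv)),
                      error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) {
      dt_inv <- if (dt_inv == 0) 1 else dt_inv * 10
      if (dt_inv > 1e14) stop("steady solver: singular Jacobian")
      next
    }
    if (dt_inv == 0) {
      accepted <- FALSE
      lambda <- 1
      for (ls in 1:10) {
        cand <- cvec + lambda * delta
        cand[cand < 0 & cand > -1e-8] <- 0
        Fc <- resid(cand)
        rc <- sqrt(sum(Fc^2)) / ref
        if (is.finite(rc) && (rc < rn * (1 - 1e-4 * lambda) || rc < tol)) {
          cvec <- cand; Fv <- Fc; rn <- rc; accepted <- TRUE
          break
        }
        lambda <- lambda / 2
      }
      if (!accepted) dt_inv <- 1  # engage pseudo-transient damping
    } else {
      cand <- pmax(cvec + delta, 0)  # concentrations are non-negative
      Fc <- resid(cand)
      rc <- sqrt(sum(Fc^2)) / ref
      if (is.finite(rc) && rc < 10 * rn) {
        cvec <- cand; Fv <- Fc
        dt_inv <- dt_inv * max(min(rc / rn, 1), 1e-3)
        rn <- rc
        if (dt_inv < 1e-4) dt_inv <- 0  # hand back to plain Newton
      } else {
        dt_inv <- dt_inv * 10
        if (dt_inv > 1e14) {
          stop(sprintf(
            "steady solver stalled at relative residual %.3g (history: %s)",
            rn, paste(signif(utils::tail(history, 5), 3), collapse = ", ")))
        }
      }
    }
    history <- c(history, rn)
    if (verbose) message(sprintf("iter %d: rel residual %.3e (1/dt %.1e)",
                                 iter, rn, dt_inv))
  }
  if (rn >= tol) {
    stop(sprintf(
      "steady solver did not converge in %d iterations; residual %.3g (history: %s)",
      max_iter, rn, paste(signif(utils::tail(history, 6), 3), collapse = ", ")))
  }

  # unpack to the cell table
  n_cells <- nrow(g$cells)
  conc <- matrix(NA_real_, n_cells, length(ids), dimnames = list(NULL, ids))
  for (s in seq_along(ids)) {
    conc[seq_len(n_liq), s] <- cvec[off[s] + seq_len(n_liq)]
  }
  conc[n_liq + seq_len(n_mem), "2"] <- cvec[off[["2"]] + n_liq + seq_len(n_mem)]

  structure(
    list(geometry = g, flow = flow, network = network, config = config,
         conc = conc, state = cvec, offsets = off,
         residual = rn, iterations = iter, ops = ops),
    class = "chip_solution"
  )
}

#' @export
print.chip_solution <- function(x, ...) {
  cat(sprintf(
    "chip_solution: %g uL/min, residual %.2e after %d Newton iterations\n",
    x$config$flow_uL_min, x$residual, x$iterations))
  cat(sprintf("  chamber H2 %.3f mM, chamber allyl acetate %.4f mM\n",
              chamber_mean(x, "2"), chamber_mean(x, "4")))
  invisible(x)
}

#' Volume-weighted mean concentration in the detection chamber
#'
#' The chamber read-out: mean over all liquid cells whose axial position
#' falls in the chamber interval (the widened pocket plus the channel strip
#' beneath it), weighted by cell volume.
#'
#' @param solution A `chip_solution`.
#' @param species Species id (one of the ten network species).
#' @return Concentration in mM.
#' @export
chamber_mean <- function(solution, species) {
  if (!species %in% .species_ids()) stop("unknown species: ", species)
  cells <- solution$geometry$cells
  sel <- cells$in_chamber
  stats::weighted.mean(solution$conc[sel, species], cells$volume_m3[sel])
}

#' Width-averaged axial concentration profile
#'
#' @param solution A `chip_solution`.
#' @param species Species id.
#' @return Data frame `x_mm`, `concentration_mM` (volume-weighted mean over
#'   the local liquid cross-section).
#' @export
pathway_profile <- function(solution, species) {
  if (!species %in% .species_ids()) stop("unknown species: ", species)
  cells <- solution$geometry$cells
  sel <- which(cells$liquid)
  v <- cells$volume_m3[sel] * solution$conc[sel, species]
  num <- tapply(v, cells$i[sel], sum)
  den <- tapply(cells$volume_m3[sel], cells$i[sel], sum)
  data.frame(x_mm = solution$geometry$x_mid_mm[as.integer(names(num))],
             concentration_mM = as.numeric(num / den))
}

#' Hydrogen mass balance diagnostics
#'
#' Integrated hydrogen fluxes: diffusive influx across the membrane/channel
#' interface, advective outflux at the outlet, and advective influx at the
#' inlet (mol/s). At steady state with reactions off, membrane influx plus
#' inlet influx equals the outlet outflux.
#'
#' @param solution A `chip_solution`.
#' @return List with `membrane_influx`, `outlet_flux`, `inlet_flux` (mol/s).
#' @export
hydrogen_mass_balance <- function(solution) {
  off2 <- solution$offsets[["2"]]
  cv <- solution$state
  ifc <- solution$ops$interface
  membrane_influx <- sum(ifc$g * (cv[off2 + ifc$mem] - cv[off2 + ifc$liq]))
  out <- solution$ops$outlet
  outlet_flux <- sum(out$F * cv[off2 + out$cell])
  inl <- solution$ops$inlet
  inlet_flux <- sum(inl$F * solution$config$inlet_mM[["2"]])
  list(membrane_influx = membrane_influx, outlet_flux = outlet_flux,
       inlet_flux = inlet_flux)
}

#' Tidy long-format view of a field solution
#'
#' @param solution A `chip_solution`.
#' @param species Species ids to include; default all ten.
#' @return Data frame `x_mm`, `y_mm`, `species`, `concentration_mM` (rows
#'   where a species is undefined are dropped).
#' @export
field_to_df <- function(solution, species = .species_ids()) {
  cells <- solution$geometry$cells
  out <- do.call(rbind, lapply(species, function(sp) {
    data.frame(x_mm = cells$x_mm, y_mm = cells$y_mm, species = sp,
               concentration_mM = solution$conc[, sp],
               stringsAsFactors = FALSE)
  }))
  out[!is.na(out$concentration_mM), ]
}
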