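#' Build the 2D chip geometry and its finite-volume mesh
#'
#' The simulation domain is the unrolled reaction pathway of the microfluidic
#' chip: a straight liquid channel (default 55 mm long, 0.1 mm wide) with a
#' gas-permeable PDMS membrane window along one wall (25 mm long, 0.4 mm
#' thick) and a widened detection chamber (2 mm long, 0.5 mm wide) near the
#' outlet. An out-of-plane depth (1.4 mm) converts areas to volumes. The
#' membrane subdomain sits on top of the channel (hydrogen diffuses through
#' it from a Dirichlet outer boundary); the chamber is a pocket in which the
#' liquid cross-section widens from the channel width to the chamber width.
#'
#' Axial positions are not part of the fabricated-chip description, so they
#' are parameters: by default the membrane spans x = 2-27 mm and the chamber
#' x = 48-50 mm, which gives a liquid volume close to the real device's
#' 8.5 uL and a realistic pre-chamber residence volume. A signed
#' `chamber_shift_mm` relocates the chamber (e.g. -12.5 mm for the
#' "chamber moved upstream" scenario).
#'
#' The mesh is structured and rectilinear: uniform axial spacing `dx_mm`,
#' `n_across_channel` cells across the channel width and `n_across_upper`
#' cells across the membrane/pocket height. Region boundaries must fall on
#' mesh faces.
#'
#' @param channel_length_mm,channel_width_mm Reaction pathway dimensions.
#' @param membrane_length_mm,membrane_thickness_mm,membrane_start_mm PDMS
#'   membrane window dimensions and axial start.
#' @param chamber_length_mm,chamber_width_mm,chamber_start_mm Detection
#'   chamber dimensions and axial start (before any shift).
#' @param chamber_shift_mm Signed axial relocation of the chamber, mm.
#' @param depth_mm Out-of-plane depth, mm.
#' @param dx_mm Axial cell size, mm.
#' @param n_across_channel Cells across the channel width (>= 4).
#' @param n_across_upper Cells across the membrane thickness / pocket height.
#' @return A `chip_geometry` holding the parameters, the cell table
#'   (`cells`), index matrices for liquid and membrane cells, and the liquid
#'   volume in uL.
#' @export
#' @examples
#' geo <- build_geometry()
#' geo
build_geometry <- function(channel_length_mm = 55, channel_width_mm = 0.1,
                           membrane_length_mm = 25,
                           membrane_thickness_mm = 0.4,
                           membrane_start_mm = 2,
                           chamber_length_mm = 2, chamber_width_mm = 0.5,
                           chamber_start_mm = 48, chamber_shift_mm = 0,
                           depth_mm = 1.4,
                           dx_mm = 0.25, n_across_channel = 8L,
                           n_across_upper = 8L) {
  dims <- c(channel_length_mm, channel_width_mm, membrane_length_mm,
            membrane_thickness_mm, chamber_length_mm, chamber_width_mm,
            depth_mm, dx_mm)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("all geometry dimensions must be positive")
  }
  if (n_across_channel < 4) stop("need >= 4 cells across the channel width")
  mem <- membrane_start_mm + c(0, membrane_length_mm)
  cham <- chamber_start_mm + chamber_shift_mm + c(0, chamber_length_mm)
  if (mem[1] < 0 || mem[2] > channel_length_mm) {
    stop("membrane extends outside the channel")
  }
  if (cham[1] < 0 || cham[2] > channel_length_mm) {
    stop("chamber extends outside the channel")
  }
  if (cham[1] < mem[1]) {
    stop("chamber must lie downstream of the membrane start")
  }
  if (cham[1] < mem[2] && cham[2] > mem[1]) {
    stop("chamber must not overlap the membrane")
  }
  if (chamber_width_mm < channel_width_mm) {
    stop("chamber must be at least as wide as the channel")
  }
  pocket_h <- chamber_width_mm - channel_width_mm
  if (pocket_h > membrane_thickness_mm + 1e-12) {
    stop("chamber pocket height must not exceed the membrane thickness ",
         "(shared upper mesh band)")
  }

  nx <- round(channel_length_mm / dx_mm)
  if (abs(nx * dx_mm - channel_length_mm) > 1e-9) {
    stop("dx_mm must divide the channel length")
  }
  on_face <- function(x) abs(x / dx_mm - round(x / dx_mm)) < 1e-9
  if (!all(on_face(c(mem, cham)))) {
    stop("membrane and chamber boundaries must fall on mesh faces; ",
         "adjust dx_mm")
  }

  n_ch <- as.integer(n_across_channel)
  n_up <- as.integer(n_across_upper)
  ny <- n_ch + n_up
  dy <- c(rep(channel_width_mm / n_ch, n_ch),
          rep(membrane_thickness_mm / n_up, n_up))
  y_face <- cumsum(c(0, dy))
  y_mid <- (y_face[-1] + y_face[-(ny + 1)]) / 2
  x_face <- seq(0, channel_length_mm, by = dx_mm)
  x_mid <- (x_face[-1] + x_face[-(nx + 1)]) / 2

  mem_col <- x_mid > mem[1] & x_mid < mem[2]
  cham_col <- x_mid > cham[1] & x_mid < cham[2]
  # pocket rows: upper cells whose centre lies below the chamber width
  pocket_row <- seq_len(ny) > n_ch & y_mid < channel_width_mm + pocket_h

  region <- matrix(NA_character_, nx, ny)
  region[, seq_len(n_ch)] <- "channel"
  region[mem_col, (n_ch + 1):ny] <- "membrane"
  for (j in which(pocket_row)) region[cham_col, j] <- "chamber"

  idx <- which(!is.na(region), arr.ind = TRUE)
  cells <- data.frame(
    i = idx[, 1], j = idx[, 2],
    x_mm = x_mid[idx[, 1]], y_mm = y_mid[idx[, 2]],
    dx_mm = dx_mm, dy_mm = dy[idx[, 2]],
    region = region[idx],
    stringsAsFactors = FALSE
  )
  cells$liquid <- cells$region != "membrane"
  cells$in_chamber <- cells$liquid & cells$x_mm > cham[1] & cells$x_mm < cham[2]
  cells$volume_m3 <- cells$dx_mm * cells$dy_mm * depth_mm * 1e-9
  cells <- cells[order(!cells$liquid, cells$i, cells$j), ]
  rownames(cells) <- NULL
  cells$id <- seq_len(nrow(cells))

  liq_id <- mem_id <- matrix(NA_integer_, nx, ny)
  liq <- cells[cells$liquid, ]
  liq_id[cbind(liq$i, liq$j)] <- seq_len(nrow(liq))
  memc <- cells[!cells$liquid, ]
  mem_id[cbind(memc$i, memc$j)] <- seq_len(nrow(memc))

  structure(
    list(
      channel_length_mm = channel_length_mm,
      channel_width_mm = channel_width_mm,
      membrane_mm = mem, membrane_thickness_mm = membrane_thickness_mm,
      chamber_mm = cham, chamber_width_mm = chamber_width_mm,
      depth_mm = depth_mm,
      nx = nx, ny = ny, n_ch = n_ch, n_up = n_up,
      dx_mm = dx_mm, dy_mm = dy, x_face_mm = x_face, y_face_mm = y_face,
      x_mid_mm = x_mid, y_mid_mm = y_mid,
      cells = cells, liq_id = liq_id, mem_id = mem_id,
      n_liquid = nrow(liq), n_membrane = nrow(memc),
      liquid_volume_uL = sum(liq$volume_m3) * 1e9
    ),
    class = "chip_geometry"
  )
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat(sprintf(
    "chip_geometry: %g x %g mm channel, membrane %g-%g mm (%g mm thick),\n",
    x$channel_length_mm, x$channel_width_mm, x$membrane_mm[1],
    x$membrane_mm[2], x$membrane_thickness_mm))
  cat(sprintf("  chamber %g-%g mm (%g mm wide), depth %g mm\n",
              x$chamber_mm[1], x$chamber_mm[2], x$chamber_width_mm,
              x$depth_mm))
  cat(sprintf("  mesh %d x %d (dx %g mm), %d liquid + %d membrane cells\n",
              x$nx, x$ny, x$dx_mm, x$n_liquid, x$n_membrane))
  cat(sprintf("  liquid volume %.2f uL\n", x$liquid_volume_uL))
  invisible(x)
}

#' Prescribed laminar flow field on the chip mesh
#'
#' The channel Reynolds number is far below 1, so the velocity field is
#' prescribed analytically rather than solved: a plane-Poiseuille parabolic
#' profile across the local liquid width, scaled so the volumetric flux
#' through every cross-section equals the inlet flow rate. In the widened
#' chamber the profile spans the full chamber width (the mean velocity drops
#' accordingly); the membrane subdomain carries no flow. Face-normal
#' volumetric flows are reconstructed to be exactly divergence-free on the
#' mesh: axial face flows follow the parabolic profile (normalised per
#' cross-section), and transverse face flows are obtained from cell-by-cell
#' continuity, which closes with zero flow at the walls.
#'
#' @param geometry A `chip_geometry`.
#' @param flow_uL_min Volumetric flow rate, uL/min (>= 0; 0 gives a
#'   quiescent field).
#' @return A `chip_flow` with face volumetric flows `Fx` ((nx+1) x ny, m3/s,
#'   positive downstream) and `Fy` (nx x (ny+1), positive upward), the cell
#'   mean axial velocity, and the flow rate.
#' @export
compute_flow_field <- function(geometry, flow_uL_min) {
  g <- geometry
  stopifnot(inherits(g, "chip_geometry"), flow_uL_min >= 0)
  Q <- flow_uL_min * 1e-9 / 60  # m3/s
  d <- g$depth_mm * 1e-3
  dy_m <- g$dy_mm * 1e-3
  nx <- g$nx; ny <- g$ny
  Fx <- matrix(0, nx + 1, ny)
  if (Q > 0) {
    for (f in seq_len(nx + 1)) {
      # liquid rows active on both sides of the face (boundary faces use the
      # adjacent column); always a contiguous stack starting at the wall y=0
      left <- if (f == 1) g$liq_id[1, ] else g$liq_id[f - 1, ]
      right <- if (f == nx + 1) g$liq_id[nx, ] else g$liq_id[f, ]
      rows <- which(!is.na(left) & !is.na(right))
      yf <- g$y_face_mm * 1e-3
      W <- yf[max(rows) + 1]  # local liquid width, m
      ym <- g$y_mid_mm[rows] * 1e-3
      u <- 6 * (ym / W) * (1 - ym / W)      # parabolic shape
      flux <- u * dy_m[rows] * d
      Fx[f, rows] <- Q * flux / sum(flux)   # normalise: exact flux Q
    }
  }
  Fy <- matrix(0, nx, ny + 1)
  for (i in seq_len(nx)) {
    rows <- which(!is.na(g$liq_id[i, ]))
    for (j in rows) {
      Fy[i, j + 1] <- Fy[i, j] + Fx[i, j] - Fx[i + 1, j]
    }
    # continuity must close at the top of the liquid stack
    top <- max(rows)
    if (abs(Fy[i, top + 1]) > 1e-12 * max(Q, 1e-30)) {
      stop("flow reconstruction failed to close continuity")
    }
    Fy[i, top + 1] <- 0
  }
  umean <- rep(NA_real_, nrow(g$cells))
  liq <- g$cells[g$cells$liquid, ]
  umean[liq$id] <- (Fx[cbind(liq$i, liq$j)] + Fx[cbind(liq$i + 1, liq$j)]) /
    (2 * dy_m[liq$j] * d)
  structure(
    list(Fx = Fx, Fy = Fy, flow_uL_min = flow_uL_min, Q_m3_s = Q,
         u_cell_m_s = umean),
    class = "chip_flow"
  )
}

#' @export
print.chip_flow <- function(x, ...) {
  cat(sprintf("chip_flow: %g uL/min (%.3g m3/s)\n", x$flow_uL_min, x$Q_m3_s))
  invisible(x)
}

#' Volumetric flux through a cross-section
#'
#' Diagnostic used to verify incompressibility: sums the axial face flows at
#' a given face index.
#'
#' @param flow A `chip_flow`.
#' @param face Axial face index (1 = inlet, nx+1 = outlet).
#' @return Volumetric flux in m3/s.
#' @export
cross_section_flux <- function(flow, face) {
  sum(flow$Fx[face, ])
}
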