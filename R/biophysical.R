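#' Parameters of the biophysical glucose-transport model
#'
#' The 18 transport parameters describing glucose movement from the blood
#' capillary through the interstitial fluid (ISF) and the sweat gland to the
#' skin surface, plus the normalised experimental sweat velocity and the
#' passive sweat velocity constant. Defaults are the literature values used
#' throughout the package.
#'
#' @param P_c Capillary hydrostatic pressure (mmHg).
#' @param L_pc Capillary hydraulic conductivity (m s^-1 mmHg^-1).
#' @param k_DE Glucose clearance constant in the dermis (s^-1).
#' @param V_p Capillary effective volume (m^3).
#' @param V_ISF ISF effective volume (m^3).
#' @param P_ISF ISF hydrostatic pressure (mmHg); may be negative.
#' @param D_sg_wall Glucose diffusion coefficient in the gland wall (m^2 s^-1).
#' @param D_ISF Glucose diffusion coefficient in the ISF (m^2 s^-1).
#' @param D_sw Glucose diffusion coefficient in water (m^2 s^-1).
#' @param d Sweat-gland luminal diameter (m).
#' @param A_ISF ISF cross-sectional area (m^2).
#' @param dP Pressure difference across the sweat gland (mmHg).
#' @param K_wg Water-to-glucose volumetric flow ratio (dimensionless).
#' @param L Sweat-gland length (m).
#' @param h_sg Sweat-gland wall thickness (m).
#' @param A_c Capillary surface area (m^2).
#' @param r_uptake Cellular glucose uptake rate (mol m^-3 s^-1).
#' @param eta Water viscosity (Pa s).
#' @param u_sweat_n Experimental sweat velocity normalised by the passive
#'   velocity (dimensionless; 1 = passive sweating).
#' @param u_passive Passive sweat velocity constant (m s^-1).
#' @return An object of class `biophysical_params` (named list).
#' @export
biophysical_params <- function(P_c = 30,
                               L_pc = 6.5e-10,
                               k_DE = 6.51e-4,
                               V_p = 3.02e-13,
                               V_ISF = 6.0e-13,
                               P_ISF = -3,
                               D_sg_wall = 6.46e-10,
                               D_ISF = 2.64e-10,
                               D_sw = 6.7e-10,
                               d = 5e-6,
                               A_ISF = 2.2e-8,
                               dP = 10,
                               K_wg = 12,
                               L = 4e-3,
                               h_sg = 5e-5,
                               A_c = 1.5e-8,
                               r_uptake = 2.78e-2,
                               eta = 1e-3,
                               u_sweat_n = 1,
                               u_passive = 3e-4) {
  p <- list(P_c = P_c, L_pc = L_pc, k_DE = k_DE, V_p = V_p, V_ISF = V_ISF,
            P_ISF = P_ISF, D_sg_wall = D_sg_wall, D_ISF = D_ISF, D_sw = D_sw,
            d = d, A_ISF = A_ISF, dP = dP, K_wg = K_wg, L = L, h_sg = h_sg,
            A_c = A_c, r_uptake = r_uptake, eta = eta, u_sweat_n = u_sweat_n,
            u_passive = u_passive)
  validate_biophysical_params(p)
  class(p) <- "biophysical_params"
  p
}

validate_biophysical_params <- function(p) {
  must_pos <- c("P_c", "L_pc", "k_DE", "V_p", "V_ISF", "D_sg_wall", "D_ISF",
                "D_sw", "d", "A_ISF", "dP", "L", "h_sg", "A_c", "eta",
                "u_sweat_n", "u_passive")
  for (nm in must_pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) || p[[nm]] <= 0) {
      stop(sprintf("invalid parameter: `%s` must be a single positive number", nm),
           call. = FALSE)
    }
  }
  for (nm in c("K_wg", "r_uptake")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) || p[[nm]] < 0) {
      stop(sprintf("invalid parameter: `%s` must be non-negative", nm), call. = FALSE)
    }
  }
  if (p$d >= p$L) stop("invalid parameter: luminal diameter `d` must be smaller than gland length `L`",
                       call. = FALSE)
  if (p$P_c <= p$P_ISF) stop("invalid parameter: `P_c` must exceed `P_ISF` (filtration regime)",
                             call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params A `biophysical_params` object.
#' @param ... Named scalar replacements, e.g. `d = 6e-6`.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "biophysical_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  params[names(repl)] <- repl
  validate_biophysical_params(params)
  params
}

#' Simulation grid for the transport model
#'
#' Spatial and temporal discretisation of the one-dimensional method-of-lines
#' solver. The ISF compartment is a segment of length `V_ISF/A_ISF`; the
#' gland a segment of length `L`.
#'
#' @param n_isf Number of ISF cells (>= 10).
#' @param n_sg Number of gland cells (>= 20).
#' @param dt Time step (s).
#' @param t_end Simulated duration (s).
#' @param pulse_width Width of the rectangular delta-surrogate pulse (s).
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(n_isf = 40, n_sg = 160, dt = 0.25, t_end = 3600,
                     pulse_width = 1) {
  if (n_isf < 10) stop("`n_isf` must be at least 10", call. = FALSE)
  if (n_sg < 20) stop("`n_sg` must be at least 20", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (!(t_end > pulse_width && pulse_width > 0)) {
    stop("need t_end > pulse_width > 0", call. = FALSE)
  }
  structure(list(n_isf = as.integer(n_isf), n_sg = as.integer(n_sg),
                 dt = dt, t_end = t_end, pulse_width = pulse_width),
            class = "sim_grid")
}

#' Water flows through the transport chain
#'
#' Computes the pressure-driven water fluxes: the Starling filtration flow
#' from capillary to ISF, the ISF water velocity, the Poiseuille hydraulic
#' resistance of the gland duct, the Darcy water flow through the gland, and
#' the resulting luminal sweat velocity (scaled by the normalised
#' experimental sweat velocity).
#'
#' @param params A `biophysical_params` object.
#' @return A `flow_state` list with fields `Q_water_cap` (m^3 s^-1), `u_ISF`
#'   (m s^-1), `R_gland` (Pa s m^-3), `Q_water_sg` (m^3 s^-1), `A_sg` (m^2),
#'   `u_sg` (m s^-1) and `u_sg_n` (u_sg normalised by the passive velocity).
#' @examples
#' water_flows(biophysical_params())
#' @export
water_flows <- function(params) {
  stopifnot(inherits(params, "biophysical_params"))
  p <- params
  Q_water_cap <- p$L_pc * p$A_c * (p$P_c - p$P_ISF)
  u_ISF <- Q_water_cap / p$A_ISF
  R_gland <- 128 * p$eta * p$L / (pi * p$d^4)
  Q_water_sg <- p$dP * MMHG_TO_PA / R_gland
  A_sg <- pi * p$d^2 / 4
  u_sg <- Q_water_sg / A_sg * p$u_sweat_n
  structure(list(Q_water_cap = Q_water_cap, u_ISF = u_ISF, R_gland = R_gland,
                 Q_water_sg = Q_water_sg, A_sg = A_sg, u_sg = u_sg,
                 u_sg_n = u_sg / p$u_passive),
            class = "flow_state")
}

MMHG_TO_PA <- 133.322

#' Dilution factor of the sweat-rate water influx
#'
#' The multiplicative factor `1 / (1 + K_wg * u_sg_n)` mapping the undiluted
#' gland glucose concentration to its diluted value at the skin surface.
#'
#' @param params A `biophysical_params` object (supplies `K_wg`).
#' @param u_sg_n Gland water velocity normalised by the passive velocity
#'   (dimensionless, >= 0). Defaults to the value derived from `params`.
#' @return Dimensionless factor in (0, 1].
#' @export
dilution_factor <- function(params, u_sg_n = water_flows(params)$u_sg_n) {
  stopifnot(inherits(params, "biophysical_params"))
  if (params$K_wg < 0) stop("invalid parameter: `K_wg` must be non-negative", call. = FALSE)
  if (u_sg_n < 0) stop("`u_sg_n` must be non-negative", call. = FALSE)
  1 / (1 + params$K_wg * u_sg_n)
}

# Assemble the tridiagonal semi-discrete transport operator M (finite-volume,
# cell-centred; central diffusion, first-order upwind advection) together
# with the source loading vector. State ordering: ISF cells 1..n1, gland
# cells n1+1..n1+n2; the diffusive wall coupling links cells n1 and n1+1 so
# the operator stays tridiagonal.
build_transport_system <- function(params, grid) {
  p <- params
  fl <- water_flows(p)
  n1 <- grid$n_isf
  n2 <- grid$n_sg
  n <- n1 + n2
  L_isf <- p$V_ISF / p$A_ISF
  dx1 <- L_isf / n1
  dx2 <- p$L / n2
  u1 <- fl$u_ISF
  u2 <- fl$u_sg
  D1 <- p$D_ISF
  D2 <- p$D_sw
  kw <- p$D_sg_wall / p$h_sg          # wall transfer velocity (m s^-1)
  a_exch <- p$k_DE * p$V_p / p$V_ISF  # capillary exchange rate (s^-1)

  dl <- numeric(n); dd <- numeric(n); du <- numeric(n)

  # ISF segment: zero diffusive flux at both ends, upwind advection with
  # zero-concentration inflow, advective outflow at the distal end,
  # uniform capillary exchange source a_exch * (Cp - C)
  for (i in seq_len(n1)) {
    diff_l <- if (i > 1) D1 / dx1^2 else 0
    diff_r <- if (i < n1) D1 / dx1^2 else 0
    dd[i] <- -(diff_l + diff_r) - u1 / dx1 - a_exch
    if (i > 1) dl[i] <- diff_l + u1 / dx1
    if (i < n1) du[i] <- diff_r
  }
  # diffusive wall flux leaving the distal ISF cell (volume A_ISF * dx1)
  wall_isf <- kw * fl$A_sg / (p$A_ISF * dx1)
  dd[n1] <- dd[n1] - wall_isf
  du[n1] <- du[n1] + wall_isf

  # gland segment: wall influx at the inlet cell, upwind advection with
  # zero-concentration water inflow, advective outflow at the outlet,
  # zero diffusive flux boundaries
  for (j in seq_len(n2)) {
    i <- n1 + j
    diff_l <- if (j > 1) D2 / dx2^2 else 0
    diff_r <- if (j < n2) D2 / dx2^2 else 0
    dd[i] <- -(diff_l + diff_r) - u2 / dx2
    if (j > 1) dl[i] <- diff_l + u2 / dx2
    if (j < n2) du[i] <- diff_r
  }
  wall_sg <- kw / dx2
  dd[n1 + 1] <- dd[n1 + 1] - wall_sg
  dl[n1 + 1] <- dl[n1 + 1] + wall_sg

  svec <- c(rep(a_exch, n1), rep(0, n2))
  list(dl = dl, dd = dd, du = du, svec = svec, n1 = n1, n2 = n2,
       dx1 = dx1, dx2 = dx2, flows = fl, kw = kw)
}

# Core time marcher. cp_values: capillary concentration at t = dt, 2 dt, ...
# record: integer node indices. Returns list(times, mat).
march_transport <- function(params, grid, cp_values, clamp_sink = TRUE,
                            record = NULL) {
  sys <- build_transport_system(params, grid)
  n <- sys$n1 + sys$n2
  if (is.null(record)) record <- n  # outlet cell
  dt <- grid$dt
  A_dl <- -dt * sys$dl
  A_dd <- 1 - dt * sys$dd
  A_du <- -dt * sys$du
  mat <- .be_march(A_dl, A_dd, A_du, rep(0, n), sys$svec, cp_values,
                   params$r_uptake, sys$n1, clamp_sink, dt, as.integer(record))
  list(times = seq(0, by = dt, length.out = length(cp_values) + 1L),
       mat = mat, sys = sys)
}

# capillary input sampled at the implicit-step times t_1..t_nt
cp_on_grid <- function(blood, grid) {
  nt <- round(grid$t_end / grid$dt)
  tk <- seq_len(nt) * grid$dt
  if (nrow(blood) > 1L) {
    t_tol <- 1e-9 * max(1, grid$t_end)
    if (blood$times[1] > t_tol || max(blood$times) < grid$t_end - t_tol) {
      stop("blood series must cover [0, t_end]", call. = FALSE)
    }
  }
  interp_series(blood, tk)
}

#' Simulate sweat glucose at the skin surface
#'
#' Forward simulation of the transport chain: a prescribed blood (capillary)
#' glucose concentration drives the capillary-to-ISF exchange; glucose then
#' moves by convection and diffusion through the ISF, crosses the gland wall
#' by Fickian diffusion, is advected along the gland lumen, and is finally
#' diluted by the sweat-rate water influx. The solver is an implicit
#' (backward-Euler) method of lines on the grid defined by [sim_grid()];
#' the cellular uptake sink is clamped so concentrations stay non-negative.
#'
#' @param params A `biophysical_params` object.
#' @param blood A `concentration_series` covering `[0, t_end]` (a one-point
#'   series is treated as a constant input).
#' @param grid A `sim_grid`.
#' @param clamp_sink Clamp the zeroth-order uptake sink at zero concentration
#'   (default `TRUE`). `FALSE` gives the unclamped linear system used
#'   internally for impulse-response extraction.
#' @return A `concentration_series` (label `"sweat"`) of the diluted outlet
#'   concentration on the simulation time grid, in mol m^-3.
#' @examples
#' g <- sim_grid(t_end = 600)
#' sw <- simulate_sweat(biophysical_params(r_uptake = 0),
#'                      concentration_series(0, 5.5, "blood"), g)
#' @export
simulate_sweat <- function(params, blood, grid = sim_grid(), clamp_sink = TRUE) {
  stopifnot(inherits(params, "biophysical_params"),
            inherits(blood, "concentration_series"),
            inherits(grid, "sim_grid"))
  cp <- cp_on_grid(blood, grid)
  res <- march_transport(params, grid, cp, clamp_sink = clamp_sink)
  out <- res$mat[, 1] * dilution_factor(params)
  if (clamp_sink) out <- pmax(out, 0)
  concentration_series(res$times, pmax(out, 0), "sweat")
}

#' Impulse response of the transport system
#'
#' Characterises the (linearised) transport chain by its response to a unit
#' concentration-time-area pulse in the capillary input. A rectangular pulse
#' of width `pulse_width` is superimposed on a zero baseline; both runs use
#' the unclamped linear system, so the affine trajectory contributed by the
#' constant uptake sink cancels exactly under baseline subtraction. The
#' result is normalised by the realised discrete pulse area.
#'
#' @param params A `biophysical_params` object.
#' @param grid A `sim_grid`; `pulse_width` must be at least `dt`.
#' @return An object of class `impulse_response`: list with `times` (s),
#'   `values` (s^-1 times the dimensionless concentration transfer), `gain`
#'   (trapezoidal area = sweat-per-blood steady-state transfer) and `grid`.
#' @examples
#' h <- impulse_response(biophysical_params(), sim_grid(t_end = 600))
#' h$gain
#' @export
impulse_response <- function(params, grid = sim_grid()) {
  stopifnot(inherits(params, "biophysical_params"), inherits(grid, "sim_grid"))
  if (grid$pulse_width < grid$dt) {
    stop("`pulse_width` must be at least `dt`", call. = FALSE)
  }
  nt <- round(grid$t_end / grid$dt)
  n_pulse <- max(1L, round(grid$pulse_width / grid$dt))
  cp_pulse <- c(rep(1 / grid$pulse_width, n_pulse), rep(0, nt - n_pulse))
  # By linearity of the unclamped system with a zero baseline, the
  # baseline-subtracted pulse response equals a single sink-free run driven
  # by the pulse alone (the sink's affine offset is identical in both runs
  # and cancels exactly), so only one march is needed.
  p0 <- params
  p0$r_uptake <- 0
  run_pulse <- march_transport(p0, grid, cp_pulse, clamp_sink = FALSE)
  area_discrete <- n_pulse * grid$dt / grid$pulse_width
  h <- run_pulse$mat[, 1] * dilution_factor(params) / area_discrete
  h <- pmax(h, 0)
  structure(list(times = run_pulse$times, values = h,
                 gain = trapz_area(run_pulse$times, h), grid = grid),
            class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  ipk <- which.max(x$values)
  cat(sprintf("<impulse_response> gain = %.4g, peak %.3g s^-1 at t = %.4g s, t_end = %g s\n",
              x$gain, x$values[ipk], x$times[ipk], max(x$times)))
  invisible(x)
}

# Gland-segment molar flux diagnostics for conservation checks: wall influx
# into the inlet cell and advective outflow at the outlet, per unit time.
transport_fluxes <- function(params, blood, grid, clamp_sink = FALSE) {
  cp <- cp_on_grid(blood, grid)
  n <- grid$n_isf + grid$n_sg
  res <- march_transport(params, grid, cp, clamp_sink = clamp_sink,
                         record = c(grid$n_isf, grid$n_isf + 1L, n))
  sys <- res$sys
  influx <- sys$kw * sys$flows$A_sg * (res$mat[, 1] - res$mat[, 2])
  outflux <- sys$flows$u_sg * sys$flows$A_sg * res$mat[, 3]
  list(times = res$times, influx = influx, outflux = outflux)
}
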