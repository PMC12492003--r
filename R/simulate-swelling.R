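# Forward model of the oocyte swelling assay.
#
# State: oocyte volume V (cm^3) and absorbed permeant solute n_sol (mol).
# Water flux follows the osmotic gradient, solute flux its own gradient:
#
#   dV/dt     = P_water * S * Vw * (n_osm/V - osm_out)
#   dn_sol/dt = P_solute * S * (sol_out - n_sol/V)
#
# where n_osm = impermeant internal osmolytes + absorbed solute.  A
# 4th-order fixed-step (classical Runge-Kutta) integrator is used.
#
# The published solute estimator presumes osmotic quasi-equilibrium (water
# much faster than solute).  With a finite realistic P_water that limit is
# approached with time constant tau = (V/S)/(P_water*Vw*osm) -- minutes
# for a 1.2 mm oocyte -- so the generator supports `truePWater = Inf`, the
# water-equilibrated limit in which V is algebraically slaved to solute
# content; this is the solute-mode default and the regime the estimator is
# derived for.  Finite values quantify the water-limitation bias.

rk4Step <- function(y, t, h, deriv) {
  k1 <- deriv(t, y)
  k2 <- deriv(t + h / 2, y + h / 2 * k1)
  k3 <- deriv(t + h / 2, y + h / 2 * k2)
  k4 <- deriv(t + h, y + h * k3)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate an oocyte swelling trace
#'
#' Integrates the osmotic/solute flux ODEs and returns the observed
#' relative-volume time series, optionally with i.i.d. Gaussian
#' measurement noise.  Deterministic given \code{seed}.
#'
#' @param geometry an \code{\linkS4class{OocyteGeometry}}.
#' @param design an \code{\linkS4class{AssayDesign}} (water or solute
#'   mode).
#' @param truePWater water permeability, cm/s.  \code{Inf} (solute-mode
#'   default) = water-equilibrated limit.
#' @param truePSolute solute permeability, cm/s (solute mode).
#' @param dt integration/sampling step, s (default 0.01, i.e. a 100 Hz
#'   video-imaging observation rate in both assay modes).
#' @param duration trace length, s (default 120 in water mode, 600 in
#'   solute mode).
#' @param noiseSd sd of additive Gaussian noise on observed V/V0
#'   (default 0 = noiseless; 0.005 emulates projected-area measurement
#'   error).
#' @param surfaceMode "fixed" (S frozen at S0, matching the estimator's
#'   assumption; default) or "spherical" (S grows with V, to quantify
#'   model-mismatch bias).
#' @param seed RNG seed for the noise (required when noiseSd > 0).
#' @param oocyteId,constructId ids stamped on the output rows.
#' @return Data frame with columns \code{oocyte_id}, \code{construct_id},
#'   \code{time_s}, \code{rel_volume}; attribute \code{"truth"} carries
#'   the generating parameters.
#' @export
simulateSwelling <- function(geometry, design,
                             truePWater = if (design@mode == "solute") Inf
                                          else 5e-3,
                             truePSolute = 0,
                             dt = 0.01,
                             duration = if (design@mode == "solute") 600
                                        else 120,
                             noiseSd = 0,
                             surfaceMode = c("fixed", "spherical"),
                             seed = NULL,
                             oocyteId = "oo1", constructId = "sim") {
  stopifnot(methods::is(geometry, "OocyteGeometry"),
            methods::is(design, "AssayDesign"))
  surfaceMode <- match.arg(surfaceMode)
  if (dt <= 0 || duration < dt) stop("need dt > 0 and duration >= dt")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  v0 <- geometry@vo; s0 <- geometry@s
  soluteMode <- design@mode == "solute"
  osmOut <- design@osmOut
  nSol0 <- design@solIn * v0
  nImp <- design@osmIn * v0 - nSol0      # impermeant internal osmolytes
  surf <- function(v) if (surfaceMode == "fixed") s0
                      else pi^(1 / 3) * (6 * v)^(2 / 3)
  times <- seq(0, duration, by = dt)
  if (is.infinite(truePWater)) {
    if (!soluteMode)
      stop("truePWater = Inf is only meaningful in solute mode")
    # water-equilibrated limit: osm_total * V = nImp + nSol at all times
    deriv <- function(t, y) {
      v <- (nImp + y) / design@osmTotal
      truePSolute * surf(v) * (design@solOut - y / v)
    }
    nSol <- numeric(length(times)); nSol[1] <- nSol0
    for (i in seq_along(times)[-1]) {
      nSol[i] <- rk4Step(nSol[i - 1], times[i - 1], dt, deriv)
    }
    v <- (nImp + nSol) / design@osmTotal
  } else {
    deriv <- function(t, y) {
      v <- y[1]; ns <- y[2]
      if (v <= 0) stop("integration instability: volume reached zero")
      s <- surf(v)
      dv <- truePWater * s * V_W * ((nImp + ns) / v - osmOut)
      dns <- if (soluteMode) truePSolute * s * (design@solOut - ns / v) else 0
      c(dv, dns)
    }
    y <- matrix(0, length(times), 2)
    y[1, ] <- c(v0, nSol0)
    for (i in seq_along(times)[-1]) {
      y[i, ] <- rk4Step(y[i - 1, ], times[i - 1], dt, deriv)
      if (y[i, 1] <= 0) stop("integration instability: volume reached zero")
    }
    v <- y[, 1]
  }
  rel <- v / v0
  if (noiseSd > 0) {
    if (is.null(seed)) stop("a seed is required when noiseSd > 0")
    rel <- rel + withLocalSeed(seed, stats::rnorm(length(rel), 0, noiseSd))
  }
  out <- data.frame(oocyte_id = oocyteId, construct_id = constructId,
                    time_s = times, rel_volume = rel)
  attr(out, "truth") <- list(truePWater = truePWater,
                             truePSolute = truePSolute,
                             mode = design@mode, dt = dt,
                             duration = duration, noiseSd = noiseSd,
                             surfaceMode = surfaceMode)
  out
}
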