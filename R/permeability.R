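# Permeability estimation from oocyte swelling kinetics.
#
# Both estimators take the fitted initial rate of relative volume change,
# d(V/V0)/dt, together with the initial geometry and the bath design:
#
#   P_water  = [V0 * d(V/V0)/dt] / [S * Vw * (osm_in - osm_out)]
#   P_solute = osm_total * [V0 * d(V/V0)/dt] / [S * (sol_out - sol_in)]
#
# with Vw = 18 cm^3/mol the molar volume of water.  Canonical units:
# cm, s, mol/cm^3; results are in cm/s.

#' Default initial-rate fit window
#'
#' The first 60 s or the first 20\% of the trace, whichever is shorter:
#' long enough for a stable OLS slope, short enough that bath dilution has
#' not yet bent the trace.
#'
#' @param times time vector, s.
#' @return Window length in seconds.
#' @export
defaultFitWindow <- function(times) min(60, 0.2 * max(times))

#' Initial slope of a relative-volume trace
#'
#' Ordinary least-squares slope of V/V0 against time over [0, window].
#'
#' @param times time points, s (strictly increasing, starting at 0).
#' @param relVolume relative volume V/V0 at each time point.
#' @param window fit window, s; default \code{\link{defaultFitWindow}}.
#' @return List: \code{slope} (1/s), \code{r2}, \code{window}, \code{n}
#'   (points used).
#' @export
fitInitialSlope <- function(times, relVolume, window = NULL) {
  stopifnot(length(times) == length(relVolume))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (is.null(window)) window <- defaultFitWindow(times)
  sel <- times <= window + 1e-12
  if (sum(sel) < 3L)
    stop(sprintf("need >= 3 points inside the %.3g s window, have %d",
                 window, sum(sel)))
  x <- times[sel]; y <- relVolume[sel]
  xc <- x - mean(x); yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc * xc)
  sst <- sum(yc^2)
  r2 <- if (sst > 0) (slope^2 * sum(xc^2)) / sst else 1
  list(slope = slope, r2 = r2, window = window, n = sum(sel))
}

permeabilityResult <- function(kind, value, slope, window, r2) {
  data.frame(kind = kind, value = value, slope = slope,
             fit_window = window, fit_r2 = r2)
}

#' Osmotic water permeability from an initial swelling rate
#'
#' @param slope fitted initial rate d(V/V0)/dt, 1/s.
#' @param geometry an \code{\linkS4class{OocyteGeometry}}.
#' @param design a water-mode \code{\linkS4class{AssayDesign}}.
#' @param window,r2 fit metadata carried into the result.
#' @return One-row data frame: \code{kind} ("P_water"), \code{value}
#'   (cm/s), \code{slope}, \code{fit_window}, \code{fit_r2}.  Positive for
#'   swelling in a hypoosmotic bath.
#' @export
pWater <- function(slope, geometry, design, window = NA_real_, r2 = NA_real_) {
  stopifnot(methods::is(geometry, "OocyteGeometry"),
            methods::is(design, "AssayDesign"))
  if (design@mode != "water") stop("pWater needs a water-mode AssayDesign")
  grad <- design@osmIn - design@osmOut
  if (grad == 0) stop("no osmotic gradient")
  value <- (geometry@vo * slope) / (geometry@s * V_W * grad)
  permeabilityResult("P_water", value, slope, window, r2)
}

#' Solute permeability from an initial swelling rate
#'
#' @inheritParams pWater
#' @param design a solute-mode \code{\linkS4class{AssayDesign}}.
#' @return One-row data frame as in \code{\link{pWater}}, with \code{kind}
#'   "P_glycerol", "P_urea" or "P_boric_acid".
#' @export
pSolute <- function(slope, geometry, design, window = NA_real_, r2 = NA_real_) {
  stopifnot(methods::is(geometry, "OocyteGeometry"),
            methods::is(design, "AssayDesign"))
  if (design@mode != "solute") stop("pSolute needs a solute-mode AssayDesign")
  grad <- design@solOut - design@solIn
  if (grad == 0) stop("no solute gradient")
  value <- design@osmTotal * (geometry@vo * slope) / (geometry@s * grad)
  permeabilityResult(paste0("P_", design@soluteName), value, slope, window, r2)
}

#' Estimate permeabilities for a table of swelling traces
#'
#' Fits the initial slope of each oocyte's trace and applies the
#' estimator matching the design mode.
#'
#' @param traces data frame with columns \code{oocyte_id},
#'   \code{construct_id}, \code{time_s}, \code{rel_volume} (the trace CSV
#'   layout).
#' @param design an \code{\linkS4class{AssayDesign}} shared by the traces.
#' @param geometry an \code{\linkS4class{OocyteGeometry}} shared by the
#'   traces.
#' @param window fit window, s (default \code{\link{defaultFitWindow}}).
#' @return Data frame with one row per oocyte: ids, \code{kind},
#'   \code{value}, \code{slope}, \code{fit_window}, \code{fit_r2}.
#' @export
estimateTracePermeabilities <- function(traces, design, geometry,
                                        window = NULL) {
  need <- c("oocyte_id", "construct_id", "time_s", "rel_volume")
  if (!all(need %in% names(traces)))
    stop(sprintf("traces must have columns: %s", paste(need, collapse = ", ")))
  out <- lapply(split(traces, traces$oocyte_id), function(tr) {
    tr <- tr[order(tr$time_s), ]
    fit <- fitInitialSlope(tr$time_s, tr$rel_volume, window)
    res <- if (design@mode == "water")
      pWater(fit$slope, geometry, design, fit$window, fit$r2)
    else
      pSolute(fit$slope, geometry, design, fit$window, fit$r2)
    cbind(data.frame(oocyte_id = tr$oocyte_id[1],
                     construct_id = tr$construct_id[1]), res)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
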