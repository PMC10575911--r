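#' Thermal resistance of a layer
#'
#' Conduction-only temperature-drop coefficient of a slab,
#' \eqn{R_i = d_i / \kappa_i} (°C m^2/W).
#'
#' @param layer a [tissue_layer()], or a [layer_stack()] (returns the
#'   per-layer vector).
#' @return thermal resistance(s) in °C m^2/W.
#' @export
thermal_resistance <- function(layer) {
  if (inherits(layer, "layer_stack"))
    return(vapply(layer$layers, thermal_resistance, numeric(1)))
  stopifnot(inherits(layer, "tissue_layer"))
  layer$thickness / layer$kappa
}

#' Scalar dosimetric metrics at one frequency
#'
#' Runs the coupled EM + bioheat solve and reports the transmittance
#' (APD/IPD), the heating factor (surface \eqn{\Delta T} divided by surface
#' APD, °C m^2/W), the surface temperature elevation at the given IPD, and
#' the per-layer thermal resistances. Transmittance and heating factor are
#' intensive: they do not depend on `p`.
#'
#' @param stack a [layer_stack()].
#' @param f frequency in Hz.
#' @param p incident power density in W/m^2.
#' @param db dielectric database.
#' @return an object of class `dose_metrics`.
#' @export
metrics_at <- function(stack, f, p = 1000, db = default_dielectrics()) {
  prof <- delta_T(stack, f, p, db)
  structure(list(frequency = f, ipd = p,
                 apd = prof$em$apd,
                 transmittance = prof$em$transmittance,
                 surface_delta_t = prof$surface,
                 heating_factor = prof$surface / prof$em$apd,
                 thermal_resistance = thermal_resistance(stack),
                 profile = prof),
            class = "dose_metrics")
}

#' @method print dose_metrics
#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf("dose metrics at %.4g GHz (IPD %.4g W/m^2):\n", x$frequency / 1e9, x$ipd))
  cat(sprintf("  transmittance (APD/IPD) : %.4f\n", x$transmittance))
  cat(sprintf("  APD                     : %.4g W/m^2\n", x$apd))
  cat(sprintf("  surface delta T         : %.4f degC\n", x$surface_delta_t))
  cat(sprintf("  heating factor          : %.5f degC m^2/W\n", x$heating_factor))
  invisible(x)
}

#' Frequency sweep of APD and surface temperature elevation
#'
#' One EM + thermal solve per grid frequency.
#'
#' @param stack a [layer_stack()].
#' @param f frequencies in Hz, strictly increasing.
#' @param p incident power density in W/m^2.
#' @param db dielectric database.
#' @return data.frame (class `mmw_sweep`) with columns `frequency`, `apd`,
#'   `transmittance`, `surface_delta_t`, `heating_factor`.
#' @export
sweep_frequency <- function(stack, f, p = 1000, db = default_dielectrics()) {
  if (any(diff(f) <= 0)) stop("'f' must be strictly increasing")
  rows <- lapply(f, function(fi) {
    mm <- metrics_at(stack, fi, p, db)
    data.frame(frequency = fi, apd = mm$apd, transmittance = mm$transmittance,
               surface_delta_t = mm$surface_delta_t,
               heating_factor = mm$heating_factor)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mmw_sweep", "data.frame")
  attr(out, "axis") <- "frequency"
  out
}

#' Blood-perfusion sensitivity sweep of one layer
#'
#' Recomputes the surface temperature elevation while the perfusion term B
#' of one named layer is swept over a grid (all other layers keep their
#' stack values). The default grid is 13 log-spaced points over
#' 300-36300 W/(m^3 °C), the reported rodent physiological range.
#'
#' @param stack a [layer_stack()].
#' @param layer name of the swept layer.
#' @param B perfusion grid, W/(m^3 °C), strictly increasing, >= 0.
#' @param f frequency in Hz.
#' @param p incident power density in W/m^2.
#' @param db dielectric database.
#' @return data.frame (class `mmw_sweep`) with columns `perfusion`,
#'   `surface_delta_t`.
#' @export
sweep_perfusion <- function(stack, layer,
                            B = exp(seq(log(300), log(36300), length.out = 13)),
                            f = 30e9, p = 1000, db = default_dielectrics()) {
  if (any(B < 0)) stop("'B' must be >= 0")
  if (any(diff(B) <= 0)) stop("'B' must be strictly increasing")
  dt <- vapply(B, function(b)
    delta_T(set_perfusion(stack, layer, b), f, p, db)$surface, numeric(1))
  out <- data.frame(perfusion = B, surface_delta_t = dt)
  class(out) <- c("mmw_sweep", "data.frame")
  attr(out, "axis") <- "perfusion"
  attr(out, "layer") <- layer
  out
}

#' Cross-model dispersion of APD and surface temperature elevation
#'
#' Relative standard deviation (population SD over mean, in percent) of the
#' surface APD and of the surface \eqn{\Delta T} across two or more stacks
#' at one frequency.
#'
#' @param stacks list of [layer_stack()] objects (>= 2).
#' @param f frequency in Hz.
#' @param p incident power density in W/m^2.
#' @param db dielectric database.
#' @return list with `rsd_apd` and `rsd_delta_t` (percent), plus the
#'   per-stack `apd` and `surface_delta_t` vectors.
#' @export
model_dispersion <- function(stacks, f, p = 1000, db = default_dielectrics()) {
  if (!is.list(stacks) || length(stacks) < 2L)
    stop("'stacks' must be a list of at least 2 layer stacks")
  apd <- numeric(length(stacks)); dt0 <- numeric(length(stacks))
  for (i in seq_along(stacks)) {
    prof <- delta_T(stacks[[i]], f, p, db)
    apd[i] <- prof$em$apd; dt0[i] <- prof$surface
  }
  rsd <- function(x) 100 * sqrt(mean((x - mean(x))^2)) / mean(x)
  list(rsd_apd = rsd(apd), rsd_delta_t = rsd(dt0),
       apd = apd, surface_delta_t = dt0)
}

#' Layer-by-layer dosimetry report
#'
#' For each layer: thickness, steady-state temperature elevation and net
#' power flux (APD) at its top surface, and thermal resistance
#' \eqn{R_i = d_i/\kappa_i}.
#'
#' @param stack a [layer_stack()].
#' @param f frequency in Hz.
#' @param p incident power density in W/m^2.
#' @param db dielectric database.
#' @return data.frame with columns `tissue`, `thickness_um`, `delta_t_top`,
#'   `apd_top`, `thermal_resistance`.
#' @export
layer_report <- function(stack, f = 30e9, p = 1000, db = default_dielectrics()) {
  prof <- delta_T(stack, f, p, db)
  tops <- layer_tops(stack)
  idx <- seq_along(stack$layers)
  data.frame(
    tissue = vapply(stack$layers, `[[`, character(1), "name"),
    thickness_um = 1e6 * vapply(stack$layers, `[[`, numeric(1), "thickness"),
    delta_t_top = delta_t_at(prof, tops),
    apd_top = poynting_at(prof$em, tops, layer = idx),
    thermal_resistance = thermal_resistance(stack))
}

#' Coupled millimeter-wave dosimetry solve
#'
#' The package front door: runs the plane-wave absorption solve and the
#' analytic steady-state bioheat solve for one stack at one or more
#' frequencies and collects the standard dosimetric summaries.
#'
#' @param stack a [layer_stack()], or a fixture label accepted by
#'   [fixture_stack()].
#' @param frequency frequencies in Hz.
#' @param ipd incident power density in W/m^2.
#' @param db dielectric database.
#' @return an object of class `mmw_dosimetry`: `metrics` (one
#'   `dose_metrics` per frequency), `table` (one row per frequency), the
#'   `stack`, and `ipd`.
#' @examples
#' fit <- solve_dosimetry("rat_head", frequency = 30e9, ipd = 1000)
#' summary(fit)
#' @export
solve_dosimetry <- function(stack, frequency, ipd = 1000,
                            db = default_dielectrics()) {
  if (is.character(stack)) stack <- fixture_stack(stack)
  stopifnot(inherits(stack, "layer_stack"))
  metrics <- lapply(frequency, function(f) metrics_at(stack, f, ipd, db))
  tab <- do.call(rbind, lapply(metrics, function(m)
    data.frame(frequency = m$frequency, apd = m$apd,
               transmittance = m$transmittance,
               surface_delta_t = m$surface_delta_t,
               heating_factor = m$heating_factor)))
  structure(list(stack = stack, ipd = ipd, metrics = metrics, table = tab),
            class = "mmw_dosimetry")
}

#' @method print mmw_dosimetry
#' @export
print.mmw_dosimetry <- function(x, ...) {
  cat(sprintf("mmw dosimetry: %d layers, IPD %.4g W/m^2, %d frequency point(s)\n",
              length(x$stack$layers), x$ipd, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @method summary mmw_dosimetry
#' @export
summary.mmw_dosimetry <- function(object, ...) {
  cat("Layer stack\n")
  print(as.data.frame(object$stack), row.names = FALSE)
  cat("\nDosimetric metrics\n")
  print(object$table, row.names = FALSE)
  cat(sprintf("\nheating factor range: %.5f - %.5f degC m^2/W\n",
              min(object$table$heating_factor),
              max(object$table$heating_factor)))
  invisible(object)
}

#' @export
as.data.frame.mmw_dosimetry <- function(x, ...) x$table

#' Plot a dosimetry solve
#'
#' Depth profiles of SAR and temperature elevation at the first solved
#' frequency (base graphics).
#'
#' @param x an `mmw_dosimetry` object.
#' @param which `"depth"` (SAR and delta-T profiles) or `"frequency"`
#'   (metrics versus frequency; needs >= 2 frequencies).
#' @param n number of depth samples.
#' @param ... ignored.
#' @export
plot.mmw_dosimetry <- function(x, which = c("depth", "frequency"), n = 400, ...) {
  which <- match.arg(which)
  if (which == "depth") {
    prof <- x$metrics[[1]]$profile
    z <- seq(0, prof$total_thickness, length.out = n)
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(z * 1e3, sar_at(prof$em, z), type = "l", xlab = "depth (mm)",
                   ylab = "SAR (W/kg)",
                   main = sprintf("%.4g GHz, IPD %.4g W/m^2",
                                  prof$em$frequency / 1e9, x$ipd))
    graphics::plot(z * 1e3, delta_t_at(prof, z), type = "l",
                   xlab = "depth (mm)", ylab = expression(Delta * T ~ (degree * C)))
    graphics::abline(v = 1e3 * cumsum(vapply(x$stack$layers, `[[`,
                                             numeric(1), "thickness")),
                     lty = 3, col = "grey")
  } else {
    if (nrow(x$table) < 2) stop("frequency plot needs >= 2 solved frequencies")
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(x$table$frequency / 1e9, x$table$transmittance, type = "b",
                   xlab = "frequency (GHz)", ylab = "transmittance")
    graphics::plot(x$table$frequency / 1e9, x$table$surface_delta_t, type = "b",
                   xlab = "frequency (GHz)",
                   ylab = expression(Delta * T(0) ~ (degree * C)))
  }
  invisible(x)
}
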