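#' Normal-incidence plane-wave solution through a layer stack
#'
#' Solves the one-dimensional multilayer reflection/transmission problem for
#' a plane wave incident from air onto the exposed surface (z = 0), using a
#' numerically stable impedance-transformation recursion. The deepest layer
#' is treated as semi-infinite for the electromagnetic problem (no
#' reflection from the model bottom). Per-layer complex amplitudes are
#' normalised to a unit incident field; the incident-power scaling
#' \eqn{|E_{inc}|^2 = 2 p \eta_0} enters only in SAR/APD quantities.
#'
#' In layer i with local depth \eqn{\zeta = z - z_i} the field is
#' \eqn{E_i(\zeta) = \tau_i e^{-\gamma_i\zeta} + \upsilon_i e^{+\gamma_i\zeta}},
#' with \eqn{\upsilon = 0} in the terminal layer.
#'
#' @param stack a [layer_stack()].
#' @param f frequency in Hz (validated band 6-100 GHz for the fixtures;
#'   accepted on (1, 300] GHz).
#' @param p incident power density (IPD) in W/m^2 (> 0).
#' @param db dielectric database (named list of models).
#' @return an object of class `em_solution`: frequency, `ipd`, overall
#'   reflection coefficient, `apd` (W/m^2), `transmittance`, `eta0`, and a
#'   per-layer list `waves` with `tau`, `upsilon`, `gamma`, `alpha`, `beta`,
#'   `eta`, `sigma`, `rho`, standing-wave coefficients `X`, `Y`, the
#'   bottom-interface reflection coefficient `gb`, `z_top` and `thickness`.
#' @export
solve_stack_em <- function(stack, f, p = 1000, db = default_dielectrics()) {
  stopifnot(inherits(stack, "layer_stack"))
  if (length(f) != 1L || !is.finite(f) || f <= 1e9 || f > 300e9)
    stop("'f' must be a single frequency in (1, 300] GHz, in Hz")
  if (length(p) != 1L || !is.finite(p) || p <= 0)
    stop("'p' (incident power density) must be > 0")
  lyr <- stack$layers
  n <- length(lyr)
  d <- vapply(lyr, `[[`, numeric(1), "thickness")
  if (any(d <= 0)) stop("all layers must have positive thickness")

  eps <- vapply(lyr, function(l)
    complex_permittivity(resolve_dielectric(db, l$dielectric_ref), f),
    complex(1))
  prop <- lapply(eps, propagation_constants, f = f)
  gam <- vapply(prop, `[[`, complex(1), "gamma")
  eta <- vapply(prop, `[[`, complex(1), "eta")
  sig <- vapply(seq_len(n), function(i) effective_conductivity(eps[i], f),
                numeric(1))

  # Bottom-up impedance recursion. gb[i]: reflection coefficient at the
  # bottom interface of layer i for a downward wave in layer i (referenced
  # at z_{i+1}); zin[i]: input impedance looking into layer i at its top.
  gb <- complex(n); zin <- complex(n)
  zin[n] <- eta[n]; gb[n] <- 0
  if (n >= 2) for (i in (n - 1):1) {
    gb[i] <- (zin[i + 1] - eta[i]) / (zin[i + 1] + eta[i])
    ph <- gb[i] * exp(-2 * gam[i] * d[i])
    zin[i] <- eta[i] * (1 + ph) / (1 - ph)
  }
  refl <- (zin[1] - .eta0) / (zin[1] + .eta0)

  # Top-down amplitudes, unit incident field; only decaying exponentials.
  tau <- complex(n); ups <- complex(n)
  e_top <- 1 + refl
  for (i in seq_len(n)) {
    r <- if (i < n) gb[i] * exp(-2 * gam[i] * d[i]) else 0
    tau[i] <- e_top / (1 + r)
    ups[i] <- tau[i] * r
    e_top <- tau[i] * exp(-gam[i] * d[i]) * (1 + gb[i])
  }
  cross <- tau * Conj(ups)

  waves <- lapply(seq_len(n), function(i) {
    list(name = lyr[[i]]$name,
         tau = tau[i], upsilon = ups[i], gb = gb[i],
         gamma = gam[i], alpha = Re(gam[i]), beta = Im(gam[i]), eta = eta[i],
         sigma = sig[i], rho = lyr[[i]]$rho,
         X = 2 * Re(cross[i]), Y = 2 * Im(cross[i]),
         z_top = c(0, cumsum(d))[i], thickness = d[i])
  })
  structure(list(frequency = f, ipd = p, eta0 = .eta0,
                 reflection = refl, apd = p * (1 - Mod(refl)^2),
                 transmittance = 1 - Mod(refl)^2, waves = waves,
                 total_thickness = sum(d)),
            class = "em_solution")
}

#' @method print em_solution
#' @export
print.em_solution <- function(x, ...) {
  cat(sprintf("plane-wave solution at %.4g GHz, IPD %.4g W/m^2\n",
              x$frequency / 1e9, x$ipd))
  cat(sprintf("  |reflection| = %.4f, transmittance = %.4f, APD = %.4g W/m^2\n",
              Mod(x$reflection), x$transmittance, x$apd))
  invisible(x)
}

# Map depths to layer indices; z on [0, L], interfaces belong to the deeper
# layer except z = L which stays in the terminal layer.
.layer_index <- function(sol, z) {
  tops <- vapply(sol$waves, `[[`, numeric(1), "z_top")
  i <- findInterval(z, tops)
  i[z >= sol$total_thickness] <- length(sol$waves)
  i
}

# Unit-field squared magnitude |E_u(zeta)|^2 inside layer i, overflow-safe:
# the backward term is evaluated as |tau*gb|^2 exp(2*alpha*(zeta - 2d)).
.unit_field_sq <- function(w, zeta) {
  fwd <- Mod(w$tau)^2 * exp(-2 * w$alpha * zeta)
  bwd <- Mod(w$tau * w$gb)^2 * exp(2 * w$alpha * (zeta - 2 * w$thickness))
  if (Mod(w$upsilon) == 0) bwd <- 0 * zeta
  fwd + bwd + w$X * cos(2 * w$beta * zeta) + w$Y * sin(2 * w$beta * zeta)
}

#' Specific absorption rate at depth
#'
#' \eqn{\mathrm{SAR}(z) = \sigma(z) |E(z)|^2 / (2\rho(z))} with peak-phasor
#' fields; piecewise smooth, discontinuous only at layer interfaces (where
#' the value of the deeper layer is reported).
#'
#' @param sol an `em_solution`.
#' @param z depth(s) in metres on `[0, total thickness]`.
#' @param layer optional layer index override (same length as `z`), used to
#'   evaluate one-sided values exactly at interfaces.
#' @return SAR in W/kg, same length as `z`.
#' @export
sar_at <- function(sol, z, layer = NULL) {
  stopifnot(inherits(sol, "em_solution"))
  if (any(z < 0) || any(z > sol$total_thickness + 1e-15))
    stop("'z' must lie within the stack, [0, total thickness]")
  idx <- if (is.null(layer)) .layer_index(sol, z) else layer
  out <- numeric(length(z))
  for (i in unique(idx)) {
    w <- sol$waves[[i]]
    sel <- idx == i
    zeta <- z[sel] - w$z_top
    out[sel] <- sol$ipd * sol$eta0 * w$sigma / w$rho * .unit_field_sq(w, zeta)
  }
  out
}

#' Net power flux (Poynting vector) at depth
#'
#' Forward-minus-backward time-averaged power flux
#' \eqn{\tfrac12 \mathrm{Re}[E(z) H^*(z)]} in +z, in W/m^2. At z = 0 this is
#' the absorbed power density (APD).
#'
#' @inheritParams sar_at
#' @return flux in W/m^2.
#' @export
poynting_at <- function(sol, z, layer = NULL) {
  stopifnot(inherits(sol, "em_solution"))
  if (any(z < 0) || any(z > sol$total_thickness + 1e-15))
    stop("'z' must lie within the stack, [0, total thickness]")
  idx <- if (is.null(layer)) .layer_index(sol, z) else layer
  out <- numeric(length(z))
  for (i in unique(idx)) {
    w <- sol$waves[[i]]
    sel <- idx == i
    zeta <- z[sel] - w$z_top
    ef <- w$tau * exp(-w$gamma * zeta)
    eb <- w$upsilon * exp(w$gamma * zeta)
    out[sel] <- sol$ipd * sol$eta0 * Re((ef + eb) * Conj((ef - eb) / w$eta))
  }
  out
}

#' Absorbed power density at the exposed surface
#'
#' The net Poynting flux entering the tissue at z = 0; equals
#' \eqn{p (1 - |\Gamma_0|^2)} with \eqn{\Gamma_0} the overall reflection
#' coefficient of the stack.
#'
#' @param sol an `em_solution`.
#' @return APD in W/m^2.
#' @export
apd_surface <- function(sol) {
  stopifnot(inherits(sol, "em_solution"))
  sol$apd
}

#' Export a SAR depth profile as CSV
#'
#' Columns: `z` (m), `tissue`, `sar` (W/kg) and `cumulative_absorbed`
#' (W/m^2, power deposited between the surface and z).
#'
#' @param sol an `em_solution`.
#' @param path output CSV path.
#' @param n number of depth samples.
#' @return the data.frame, invisibly.
#' @export
export_sar_profile <- function(sol, path, n = 400) {
  z <- seq(0, sol$total_thickness, length.out = n)
  idx <- .layer_index(sol, z)
  df <- data.frame(
    z = z,
    tissue = vapply(sol$waves, `[[`, character(1), "name")[idx],
    sar = sar_at(sol, z),
    cumulative_absorbed = sol$apd - poynting_at(sol, z))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
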