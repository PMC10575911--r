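#' Multi-term Cole-Cole dielectric relaxation model
#'
#' Constructs a tissue dielectric dispersion model of the Cole-Cole form
#' \deqn{\hat\varepsilon(\omega) = \varepsilon_\infty +
#'   \sum_n \frac{\Delta\varepsilon_n}{1 + (j\omega\tau_n)^{1-\alpha_n}} -
#'   j\frac{\sigma_s}{\omega\varepsilon_0}}
#' under the \eqn{e^{+j\omega t}} time convention, so that lossy media have
#' \eqn{\hat\varepsilon = \varepsilon' - j\varepsilon''} with
#' \eqn{\varepsilon'' \ge 0}.
#'
#' @param eps_inf high-frequency relative permittivity (>= 1, dimensionless).
#' @param delta_eps vector of relaxation amplitudes (dimensionless, >= 0).
#' @param tau vector of relaxation times (seconds, > 0), same length as
#'   `delta_eps`.
#' @param alpha_broadening vector of Cole-Cole broadening exponents in
#'   `[0, 1)`; 0 gives a pure Debye term.
#' @param sigma_static static ionic conductivity (S/m, >= 0).
#' @return an object of class `cole_cole_model`.
#' @seealso [complex_permittivity()], [default_dielectrics()]
#' @export
cole_cole_model <- function(eps_inf, delta_eps = numeric(), tau = numeric(),
                            alpha_broadening = numeric(), sigma_static = 0) {
  stopifnot(length(eps_inf) == 1L, is.finite(eps_inf))
  if (eps_inf < 1) stop("'eps_inf' must be >= 1")
  n <- length(delta_eps)
  if (length(tau) != n || length(alpha_broadening) != n)
    stop("'delta_eps', 'tau' and 'alpha_broadening' must have equal length")
  if (any(delta_eps < 0)) stop("'delta_eps' must be >= 0")
  if (n && any(tau <= 0)) stop("'tau' must be > 0")
  if (n && any(alpha_broadening < 0 | alpha_broadening >= 1))
    stop("'alpha_broadening' must lie in [0, 1)")
  if (sigma_static < 0) stop("'sigma_static' must be >= 0")
  structure(list(eps_inf = eps_inf, delta_eps = as.numeric(delta_eps),
                 tau = as.numeric(tau),
                 alpha_broadening = as.numeric(alpha_broadening),
                 sigma_static = sigma_static),
            class = "cole_cole_model")
}

#' Tabulated dielectric model
#'
#' A direct `(frequency, eps_real, sigma)` table, linearly interpolated in
#' frequency. Intended for substituting measured tissue values for the
#' packaged Cole-Cole database.
#'
#' @param frequency frequencies (Hz), strictly increasing.
#' @param eps_real relative permittivity \eqn{\varepsilon'} at each frequency.
#' @param sigma effective conductivity (S/m) at each frequency.
#' @return an object of class `dielectric_table`.
#' @export
dielectric_table <- function(frequency, eps_real, sigma) {
  stopifnot(length(frequency) >= 2L,
            length(eps_real) == length(frequency),
            length(sigma) == length(frequency))
  if (any(diff(frequency) <= 0)) stop("'frequency' must be strictly increasing")
  if (any(frequency <= 0)) stop("'frequency' must be > 0")
  if (any(eps_real < 1)) stop("'eps_real' must be >= 1")
  if (any(sigma < 0)) stop("'sigma' must be >= 0")
  structure(list(frequency = as.numeric(frequency),
                 eps_real = as.numeric(eps_real),
                 sigma = as.numeric(sigma)),
            class = "dielectric_table")
}

#' Complex relative permittivity of a dielectric model
#'
#' Evaluates \eqn{\hat\varepsilon(f) = \varepsilon' - j\varepsilon''} for a
#' dielectric model at frequency `f`.
#'
#' @param model a `cole_cole_model` or `dielectric_table`.
#' @param f frequency in Hz (> 0); vectorised.
#' @return complex vector, \eqn{\varepsilon'' \ge 0} for passive media.
#' @export
complex_permittivity <- function(model, f) UseMethod("complex_permittivity")

#' @export
complex_permittivity.cole_cole_model <- function(model, f) {
  if (any(!is.finite(f)) || any(f <= 0))
    stop("'f' must be a positive frequency in Hz")
  w <- 2 * pi * f
  eps <- complex(real = rep(model$eps_inf, length(f)), imaginary = 0)
  for (n in seq_along(model$delta_eps)) {
    ex <- 1 - model$alpha_broadening[n]
    eps <- eps + model$delta_eps[n] / (1 + (1i * w * model$tau[n])^ex)
  }
  eps - 1i * model$sigma_static / (w * .eps0)
}

#' @export
complex_permittivity.dielectric_table <- function(model, f) {
  if (any(!is.finite(f)) || any(f <= 0))
    stop("'f' must be a positive frequency in Hz")
  if (any(f < model$frequency[1]) || any(f > model$frequency[length(model$frequency)]))
    stop("'f' outside the tabulated frequency range")
  er <- stats::approx(model$frequency, model$eps_real, xout = f)$y
  sg <- stats::approx(model$frequency, model$sigma, xout = f)$y
  complex(real = er, imaginary = -sg / (2 * pi * f * .eps0))
}

#' Effective conductivity from a complex permittivity
#'
#' \eqn{\sigma = \omega \varepsilon_0 \varepsilon''}: the total (dipolar plus
#' ionic) loss expressed as an equivalent conductivity.
#'
#' @param eps complex relative permittivity \eqn{\varepsilon' - j\varepsilon''}.
#' @param f frequency in Hz (> 0).
#' @return conductivity in S/m.
#' @export
effective_conductivity <- function(eps, f) {
  if (any(!is.finite(f)) || any(f <= 0))
    stop("'f' must be a positive frequency in Hz")
  2 * pi * f * .eps0 * (-Im(eps))
}

#' Plane-wave propagation constants in a nonmagnetic medium
#'
#' Computes the attenuation constant \eqn{\alpha} (Np/m), phase constant
#' \eqn{\beta} (rad/m) and complex intrinsic wave impedance \eqn{\eta}
#' (ohm) from \eqn{\gamma = j\omega\sqrt{\mu_0\varepsilon_0\hat\varepsilon}}
#' with the branch chosen so that \eqn{\alpha \ge 0} (fields decaying as
#' \eqn{e^{-\gamma z}} into the medium) and \eqn{\mathrm{Re}(\eta) > 0}.
#'
#' @param eps complex relative permittivity (scalar).
#' @param f frequency in Hz (> 0).
#' @return an object of class `propagation_triple`: list with `alpha`,
#'   `beta`, `eta` (complex) and `gamma` (complex).
#' @export
propagation_constants <- function(eps, f) {
  if (length(f) != 1L || !is.finite(f) || f <= 0)
    stop("'f' must be a single positive frequency in Hz")
  if (-Im(eps) < 0)
    stop("active medium (negative loss) not supported: Im(eps) must be <= 0")
  w <- 2 * pi * f
  # principal sqrt: eps in lower half plane => arg(sqrt) in (-pi/2, 0]
  gamma <- 1i * w * sqrt(.mu0 * .eps0) * sqrt(as.complex(eps))
  if (Re(gamma) < 0) gamma <- -gamma
  eta <- sqrt(as.complex(.mu0 / (.eps0 * eps)))
  if (Re(eta) < 0) eta <- -eta
  structure(list(alpha = Re(gamma), beta = Im(gamma), eta = eta, gamma = gamma),
            class = "propagation_triple")
}

#' Packaged tissue dielectric database
#'
#' Loads the Cole-Cole parameter table shipped with the package (dry skin,
#' infiltrated fat, muscle, cortical bone, grey matter; literature
#' parametric-model values) and caches it for the session. Rodent dWAT is
#' mapped to the fat model and panniculus carnosus to the muscle model.
#'
#' @param path optional path to an alternative database file in the same
#'   YAML format.
#' @return named list of dielectric models.
#' @export
default_dielectrics <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_env$dielectrics)) return(.pkg_env$dielectrics)
    path <- system.file("extdata", "tissue_dielectrics.yaml",
                        package = "mmwdosim", mustWork = TRUE)
    db <- read_dielectrics(path)
    .pkg_env$dielectrics <- db
    return(db)
  }
  read_dielectrics(path)
}

#' Read a dielectric database file
#'
#' Each top-level key is a tissue label; records are either
#' `model: cole_cole` (fields `eps_inf`, `terms` with `delta_eps`/`tau`/
#' `alpha`, `sigma_static`) or `model: table` (fields `frequency_ghz`,
#' `eps_real`, `sigma`).
#'
#' @param path file path.
#' @return named list of dielectric models.
#' @export
read_dielectrics <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    rec <- raw[[nm]]
    kind <- rec$model
    if (identical(kind, "cole_cole")) {
      terms <- rec$terms
      if (is.null(terms)) terms <- list()
      cole_cole_model(
        eps_inf = rec$eps_inf,
        delta_eps = vapply(terms, `[[`, numeric(1), "delta_eps"),
        tau = vapply(terms, `[[`, numeric(1), "tau"),
        alpha_broadening = vapply(terms, `[[`, numeric(1), "alpha"),
        sigma_static = if (is.null(rec$sigma_static)) 0 else rec$sigma_static)
    } else if (identical(kind, "table")) {
      dielectric_table(frequency = unlist(rec$frequency_ghz) * 1e9,
                       eps_real = unlist(rec$eps_real),
                       sigma = unlist(rec$sigma))
    } else {
      stop(sprintf("tissue '%s': unknown dielectric model type '%s'",
                   nm, as.character(kind)))
    }
  })
  names(out) <- names(raw)
  out
}

#' Merge a dielectric override database into a base database
#'
#' Records in `override` replace records of the same tissue label in `base`;
#' new labels are appended. Typical use: substitute measured skin values
#' (as a `dielectric_table`) for the packaged parametric model.
#'
#' @param base,override named lists of dielectric models.
#' @return merged named list.
#' @export
merge_dielectrics <- function(base, override) {
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}

# Resolve a tissue label into a dielectric model, with a clear error.
resolve_dielectric <- function(db, ref) {
  m <- db[[ref]]
  if (is.null(m))
    stop(sprintf("dielectric_ref '%s' not found in the dielectric database (available: %s)",
                 ref, paste(names(db), collapse = ", ")))
  m
}
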