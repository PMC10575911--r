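# Closed-form steady-state solution of the 1-D Pennes bioheat equation
#
#   kappa_i T_i'' + rho_i SAR_i(z) + A_i - B_i (T_i - T_blood) = 0
#
# on each layer, with a convective (Robin) balance at the exposed surface,
# temperature/flux continuity at interior interfaces, and a core-temperature
# clamp at the bottom. Per layer the solution is written as
#
#   T_i(z_i + zeta) = a(zeta) T_i(z_i) + b(zeta) T_i'(z_i) + c(zeta)
#
# where (a, b) are the homogeneous propagators (linear for B = 0,
# cosh/sinh for B > 0) and c collects the known particular parts: the
# metabolic/perfusion offset and the electromagnetic source term S_i(zeta),
# which satisfies kappa S'' - B S = -rho SAR with S(0) = S'(0) = 0.

# Response of kappa S'' - B S = -e^{k zeta}, S(0) = S'(0) = 0, m = sqrt(B/kappa).
# Returns list(val, der), vectorised over zeta; k may be complex.
.src_response <- function(k, m, kappa, zeta) {
  if (m == 0) {
    kz <- k * zeta
    if (abs(k) == 0) return(list(val = -zeta^2 / (2 * kappa), der = -zeta / kappa))
    small <- Mod(kz) < 1e-4
    e1 <- exp(kz) - 1 - kz          # ~ (kz)^2/2
    e1[small] <- kz[small]^2 / 2 * (1 + kz[small] / 3 + kz[small]^2 / 12 +
                                      kz[small]^3 / 60)
    d1 <- exp(kz) - 1
    d1[small] <- kz[small] * (1 + kz[small] / 2 + kz[small]^2 / 6 +
                                kz[small]^3 / 24)
    return(list(val = -e1 / (kappa * k^2), der = -d1 / (kappa * k)))
  }
  dk2 <- k^2 - m^2
  if (Mod(dk2) <= 1e-6 * max(Mod(k)^2, m^2)) {
    # removable singularity at k = +-m: limit form F'(k)/(2k)
    k0 <- if (Re(k) >= 0 || Im(k) != 0) m else -m
    ek <- exp(k0 * zeta)
    val <- -(zeta * ek - sinh(m * zeta) / m) / (2 * k0 * kappa)
    der <- -(ek + k0 * zeta * ek - cosh(m * zeta)) / (2 * k0 * kappa)
    return(list(val = val, der = der))
  }
  ek <- exp(k * zeta)
  ch <- cosh(m * zeta); sh <- sinh(m * zeta)
  val <- -(ek - ch - (k / m) * sh) / (kappa * dk2)
  der <- -(k * ek - m * sh - k * ch) / (kappa * dk2)
  list(val = val, der = der)
}

#' Electromagnetic particular term of one layer
#'
#' Builds the particular solution \eqn{S_i(\zeta)} (and its derivative) of
#' the layer bioheat ODE driven by the plane-wave absorption profile,
#' \eqn{\kappa S'' - B S + \rho\,\mathrm{SAR}(\zeta) = 0} with
#' \eqn{S(0) = S'(0) = 0} (zero state at the layer top). The absorption
#' profile combines decaying/growing exponentials and a standing-wave
#' oscillation, each handled in closed form; near-degenerate denominators
#' (\eqn{4\alpha^2\kappa \approx B}) switch to a limit evaluation.
#'
#' @param layer a [tissue_layer()].
#' @param wave the layer's entry in `em_solution$waves`.
#' @param p incident power density (W/m^2) of the EM solve.
#' @return list of vectorised functions `S(zeta)` and `Sprime(zeta)`
#'   (zeta in metres from the layer top).
#' @export
particular_term <- function(layer, wave, p) {
  kappa <- layer$kappa
  m <- sqrt(layer$perfusion / kappa)
  pref <- wave$sigma * p * .eta0
  if (pref == 0) {
    zero <- function(zeta) rep(0, length(zeta))
    return(list(S = zero, Sprime = zero))
  }
  a2 <- Mod(wave$tau)^2
  b2 <- Mod(wave$upsilon)^2
  cxy <- complex(real = wave$X, imaginary = -wave$Y)
  al <- wave$alpha; be <- wave$beta
  S <- function(zeta) {
    r1 <- .src_response(-2 * al, m, kappa, zeta)
    r3 <- .src_response(2i * be, m, kappa, zeta)
    out <- a2 * Re(r1$val) + Re(cxy * r3$val)
    if (b2 > 0) out <- out + b2 * Re(.src_response(2 * al, m, kappa, zeta)$val)
    pref * out
  }
  Sp <- function(zeta) {
    r1 <- .src_response(-2 * al, m, kappa, zeta)
    r3 <- .src_response(2i * be, m, kappa, zeta)
    out <- a2 * Re(r1$der) + Re(cxy * r3$der)
    if (b2 > 0) out <- out + b2 * Re(.src_response(2 * al, m, kappa, zeta)$der)
    pref * out
  }
  list(S = S, Sprime = Sp)
}

# Homogeneous propagators and known particular part of one layer.
# Returns functions a, ap, b, bp, c, cp of zeta.
.layer_coeffs <- function(layer, t_blood, src = NULL) {
  kappa <- layer$kappa; B <- layer$perfusion; A <- layer$metabolic_rate
  S  <- if (is.null(src)) function(zeta) rep(0, length(zeta)) else src$S
  Sp <- if (is.null(src)) function(zeta) rep(0, length(zeta)) else src$Sprime
  if (B == 0) {
    list(a = function(z) rep(1, length(z)), ap = function(z) rep(0, length(z)),
         b = function(z) z, bp = function(z) rep(1, length(z)),
         c = function(z) S(z) - A * z^2 / (2 * kappa),
         cp = function(z) Sp(z) - A * z / kappa)
  } else {
    m <- sqrt(B / kappa); K <- t_blood + A / B
    list(a = function(z) cosh(m * z), ap = function(z) m * sinh(m * z),
         b = function(z) sinh(m * z) / m, bp = function(z) cosh(m * z),
         c = function(z) K * (1 - cosh(m * z)) + S(z),
         cp = function(z) -K * m * sinh(m * z) + Sp(z))
  }
}

#' Assemble and solve the steady-state bioheat interface system
#'
#' Solves for the 2N unknowns (temperature and temperature gradient at the
#' top of each layer) from the surface Robin balance
#' \eqn{h (T(0) - T_{air}) = \kappa_1 T'(0)}, N-1 temperature- and N-1
#' flux-continuity conditions at interior interfaces, and the core Dirichlet
#' condition \eqn{T(L) = T_{body}}.
#'
#' @param stack a [layer_stack()].
#' @param em an `em_solution` for the exposed solve, or `NULL` for the
#'   unexposed baseline (S = 0).
#' @return an object of class `thermal_solution` with per-layer top
#'   temperatures/gradients and a piecewise evaluator (see
#'   [temperature_at()]).
#' @export
assemble_and_solve <- function(stack, em = NULL) {
  stopifnot(inherits(stack, "layer_stack"))
  lyr <- stack$layers; n <- length(lyr)
  d <- vapply(lyr, `[[`, numeric(1), "thickness")
  kap <- vapply(lyr, `[[`, numeric(1), "kappa")
  if (!is.null(em)) {
    stopifnot(inherits(em, "em_solution"))
    if (length(em$waves) != n) stop("'em' was solved for a different stack")
    src <- lapply(seq_len(n), function(i)
      particular_term(lyr[[i]], em$waves[[i]], em$ipd))
  } else src <- vector("list", n)
  co <- lapply(seq_len(n), function(i)
    .layer_coeffs(lyr[[i]], stack$t_blood, src[[i]]))

  # unknowns u = (T_1, D_1, ..., T_n, D_n)
  M <- matrix(0, 2 * n, 2 * n); rhs <- numeric(2 * n)
  tc <- function(i) 2 * i - 1; dc <- function(i) 2 * i
  M[1, tc(1)] <- stack$h; M[1, dc(1)] <- -kap[1]; rhs[1] <- stack$h * stack$t_air
  r <- 1
  for (i in seq_len(n - 1)) {
    ci <- co[[i]]
    r <- r + 1  # temperature continuity at z_{i+1}
    M[r, tc(i)] <- ci$a(d[i]); M[r, dc(i)] <- ci$b(d[i])
    M[r, tc(i + 1)] <- -1; rhs[r] <- -ci$c(d[i])
    r <- r + 1  # heat-flux continuity
    M[r, tc(i)] <- kap[i] * ci$ap(d[i]); M[r, dc(i)] <- kap[i] * ci$bp(d[i])
    M[r, dc(i + 1)] <- -kap[i + 1]; rhs[r] <- -kap[i] * ci$cp(d[i])
  }
  cn <- co[[n]]
  r <- r + 1
  M[r, tc(n)] <- cn$a(d[n]); M[r, dc(n)] <- cn$b(d[n])
  rhs[r] <- stack$t_body - cn$c(d[n])

  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-14)
    stop(sprintf("bioheat interface system is numerically singular (rcond = %.3g)", rc))
  u <- solve(M, rhs)

  structure(list(stack = stack, em = em,
                 t_top = u[tc(seq_len(n))], dt_top = u[dc(seq_len(n))],
                 coeffs = co, z_top = c(0, cumsum(d))[seq_len(n)],
                 thickness = d, total_thickness = sum(d),
                 baseline = is.null(em), rcond = rc),
            class = "thermal_solution")
}

#' Evaluate a thermal solution at depth
#'
#' @param sol a `thermal_solution`.
#' @param z depth(s) in metres on `[0, total thickness]`.
#' @return temperature(s) in °C.
#' @export
temperature_at <- function(sol, z) {
  stopifnot(inherits(sol, "thermal_solution"))
  if (any(z < -1e-15) || any(z > sol$total_thickness + 1e-12))
    stop("'z' must lie within the stack")
  i <- findInterval(z, sol$z_top)
  i[i < 1] <- 1
  i[z >= sol$total_thickness] <- length(sol$z_top)
  out <- numeric(length(z))
  for (k in unique(i)) {
    sel <- i == k
    zeta <- z[sel] - sol$z_top[k]
    ck <- sol$coeffs[[k]]
    out[sel] <- ck$a(zeta) * sol$t_top[k] + ck$b(zeta) * sol$dt_top[k] +
      ck$c(zeta)
  }
  out
}

#' @method print thermal_solution
#' @export
print.thermal_solution <- function(x, ...) {
  cat(sprintf("steady-state bioheat solution (%s): T(0) = %.4f degC, T(L) = %.4f degC\n",
              if (x$baseline) "baseline" else
                sprintf("exposed, %.4g GHz", x$em$frequency / 1e9),
              x$t_top[1], temperature_at(x, x$total_thickness)))
  invisible(x)
}

#' Steady-state temperature elevation profile
#'
#' Solves the exposed and unexposed (baseline) problems with the identical
#' assembly and returns their difference
#' \eqn{\Delta T(z) = T_{exposed}(z) - T_{baseline}(z)}; the core clamp
#' forces \eqn{\Delta T(L) = 0}.
#'
#' @param stack a [layer_stack()].
#' @param f frequency in Hz.
#' @param p incident power density in W/m^2.
#' @param db dielectric database.
#' @return an object of class `delta_t_profile`: fields `em` (the
#'   `em_solution`), `exposed`, `baseline` (thermal solutions), and
#'   `surface` (\eqn{\Delta T(0)} in °C). Evaluate with [delta_t_at()].
#' @export
delta_T <- function(stack, f, p = 1000, db = default_dielectrics()) {
  if (length(p) != 1L || !is.finite(p) || p < 0)
    stop("'p' (incident power density) must be >= 0")
  baseline <- assemble_and_solve(stack, NULL)
  if (p == 0) {  # no exposure: elevation is identically zero
    em <- solve_stack_em(stack, f, 1, db)
    em$ipd <- 0; em$apd <- 0
    for (i in seq_along(em$waves)) {
      em$waves[[i]]$tau <- 0i; em$waves[[i]]$upsilon <- 0i
      em$waves[[i]]$X <- 0; em$waves[[i]]$Y <- 0
    }
    exposed <- baseline
    exposed$em <- em
  } else {
    em <- solve_stack_em(stack, f, p, db)
    exposed <- assemble_and_solve(stack, em)
  }
  structure(list(em = em, exposed = exposed, baseline = baseline,
                 surface = exposed$t_top[1] - baseline$t_top[1],
                 total_thickness = exposed$total_thickness),
            class = "delta_t_profile")
}

#' Evaluate a temperature-elevation profile at depth
#'
#' @param prof a `delta_t_profile` from [delta_T()].
#' @param z depth(s) in metres.
#' @return \eqn{\Delta T(z)} in °C.
#' @export
delta_t_at <- function(prof, z) {
  stopifnot(inherits(prof, "delta_t_profile"))
  temperature_at(prof$exposed, z) - temperature_at(prof$baseline, z)
}

#' @method print delta_t_profile
#' @export
print.delta_t_profile <- function(x, ...) {
  cat(sprintf("temperature elevation at %.4g GHz, IPD %.4g W/m^2: dT(0) = %.4f degC\n",
              x$em$frequency / 1e9, x$em$ipd, x$surface))
  invisible(x)
}

#' Export a temperature depth profile as CSV
#'
#' Columns: `z` (m), `tissue`, `t_baseline`, `t_exposed`, `delta_t` (°C).
#'
#' @param prof a `delta_t_profile`.
#' @param path output CSV path.
#' @param n number of depth samples.
#' @return the data.frame, invisibly.
#' @export
export_temperature_profile <- function(prof, path, n = 400) {
  z <- seq(0, prof$total_thickness, length.out = n)
  i <- findInterval(z, prof$exposed$z_top)
  i[i < 1] <- 1
  nms <- vapply(prof$exposed$stack$layers, `[[`, character(1), "name")
  df <- data.frame(z = z, tissue = nms[i],
                   t_baseline = temperature_at(prof$baseline, z),
                   t_exposed = temperature_at(prof$exposed, z),
                   delta_t = delta_t_at(prof, z))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
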