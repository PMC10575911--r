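# Independent steady-state finite-difference solver of the Pennes equation,
# used to verify the closed-form interface solution. Node-centred grid with
# every layer interface as a shared node; the flux between adjacent nodes
# uses the (uniform) conductivity of the interval between them, which for
# interface half-cells is the standard conservative harmonic-mean treatment
# of a discontinuous kappa.

#' Build a finite-difference grid for a layer stack
#'
#' Uniform spacing within each layer, chosen per layer as
#' `min(thickness / 8, max_dx)` (with `max_dx_deep` for layers thicker than
#' `deep_cutoff`), so every interface is a node and every layer has at least
#' 4 interior nodes.
#'
#' @param stack a [layer_stack()].
#' @param max_dx target spacing (m) in thin (skin) layers.
#' @param max_dx_deep target spacing (m) in layers thicker than `deep_cutoff`.
#' @param deep_cutoff thickness (m) separating the two regimes.
#' @return an object of class `fd_grid`: node depths `z` (first node 0,
#'   last at the total thickness), and `interval_layer`, the layer index of
#'   each inter-node interval.
#' @export
fd_grid <- function(stack, max_dx = 1e-6, max_dx_deep = 2.5e-5,
                    deep_cutoff = 2.5e-3) {
  d <- vapply(stack$layers, `[[`, numeric(1), "thickness")
  z <- 0; il <- integer(0)
  for (i in seq_along(d)) {
    dx <- if (d[i] > deep_cutoff) max_dx_deep else max_dx
    nint <- max(5L, ceiling(d[i] / dx))
    zi <- z[length(z)] + seq_len(nint) * (d[i] / nint)
    zi[length(zi)] <- z[length(z)] + d[i]  # exact interface
    z <- c(z, zi)
    il <- c(il, rep.int(i, nint))
  }
  structure(list(z = z, interval_layer = il), class = "fd_grid")
}

#' Finite-difference steady-state bioheat solve
#'
#' Conservative tridiagonal discretisation of the steady Pennes equation on
#' `grid`, with the Robin balance at the surface node and a Dirichlet core
#' clamp at the last node. Source terms (SAR, metabolism, perfusion) are
#' evaluated pointwise and side-correctly at interface nodes, weighted by
#' the adjacent half-cells.
#'
#' @param stack a [layer_stack()].
#' @param sar `NULL` for the unexposed baseline, or a function
#'   `sar(z, layer_index)` returning W/kg (e.g. wrapping [sar_at()]).
#' @param grid an [fd_grid()].
#' @return list with node depths `z` and nodal temperatures `t` (°C).
#' @export
solve_fd <- function(stack, sar = NULL, grid = fd_grid(stack)) {
  stopifnot(inherits(stack, "layer_stack"), inherits(grid, "fd_grid"))
  lyr <- stack$layers
  nint_per <- tabulate(grid$interval_layer, nbins = length(lyr))
  if (any(nint_per < 5L))
    stop(sprintf("grid under-resolves layer '%s' (needs >= 4 interior nodes)",
                 lyr[[which(nint_per < 5L)[1]]]$name))
  z <- grid$z; il <- grid$interval_layer
  m <- length(z)
  hgt <- diff(z)
  kapi <- vapply(lyr, `[[`, numeric(1), "kappa")[il]   # per interval
  rhov <- vapply(lyr, `[[`, numeric(1), "rho")
  Av   <- vapply(lyr, `[[`, numeric(1), "metabolic_rate")
  Bv   <- vapply(lyr, `[[`, numeric(1), "perfusion")
  sarf <- if (is.null(sar)) function(zz, li) rep(0, length(zz)) else sar

  # per-node side contributions; node j has left interval j-1, right interval j
  qside <- function(nodes, side_int) {
    li <- il[side_int]
    rhov[li] * sarf(z[nodes], li) + Av[li]
  }
  main <- numeric(m); lower <- numeric(m - 1); upper <- numeric(m - 1)
  rhs <- numeric(m)
  # surface node (Robin)
  wr <- hgt[1] / 2
  main[1] <- -kapi[1] / hgt[1] - stack$h - wr * Bv[il[1]]
  upper[1] <- kapi[1] / hgt[1]
  rhs[1] <- -stack$h * stack$t_air - wr * (qside(1, 1) + Bv[il[1]] * stack$t_blood)
  # interior nodes
  if (m > 2) {
    j <- 2:(m - 1)
    hl <- hgt[j - 1]; hr <- hgt[j]
    kl <- kapi[j - 1]; kr <- kapi[j]
    Bl <- Bv[il[j - 1]]; Br <- Bv[il[j]]
    ql <- qside(j, j - 1); qr <- qside(j, j)
    lower[j - 1] <- kl / hl
    upper[j] <- kr / hr
    main[j] <- -(kl / hl + kr / hr) - (hl / 2) * Bl - (hr / 2) * Br
    rhs[j] <- -(hl / 2) * (ql + Bl * stack$t_blood) -
      (hr / 2) * (qr + Br * stack$t_blood)
  }
  # core node (Dirichlet)
  main[m] <- 1; lower[m - 1] <- 0; rhs[m] <- stack$t_body

  Msp <- Matrix::bandSparse(m, m, k = c(-1, 0, 1),
                            diagonals = list(lower, main, upper))
  tt <- as.numeric(Matrix::solve(Msp, rhs))
  list(z = z, t = tt)
}

#' Finite-difference temperature elevation
#'
#' Difference of the exposed and baseline finite-difference solves on the
#' same grid; the companion verification route to [delta_T()].
#'
#' @param stack a [layer_stack()].
#' @param em an `em_solution` for the stack.
#' @param grid an [fd_grid()].
#' @return list with `z` and `delta_t` at the nodes.
#' @export
delta_T_fd <- function(stack, em, grid = fd_grid(stack)) {
  sarfun <- function(zz, li) sar_at(em, zz, layer = rep_len(li, length(zz)))
  exposed <- solve_fd(stack, sarfun, grid)
  baseline <- solve_fd(stack, NULL, grid)
  list(z = grid$z, delta_t = exposed$t - baseline$t)
}
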