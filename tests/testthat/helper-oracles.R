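# Shared test helpers: an independent brute-force electromagnetic oracle,
# a random stack generator, constant-permittivity media, and a closed-form
# per-layer absorbed-power integral.

.test_eta0 <- 376.730313668

# Brute-force plane-wave oracle: assembles the full dense complex linear
# system of E/H continuity at every interface (no impedance recursion, no
# reuse of the solver's algebra). Unknowns: overall reflection coefficient,
# then per-layer forward/backward amplitudes (no backward wave in the
# terminal, semi-infinite layer).
oracle_em <- function(stack, f, db = default_dielectrics()) {
  lyr <- stack$layers
  n <- length(lyr)
  d <- vapply(lyr, `[[`, numeric(1), "thickness")
  eps <- vapply(lyr, function(l) complex_permittivity(db[[l$dielectric_ref]], f),
                complex(1))
  pc <- lapply(eps, propagation_constants, f = f)
  gam <- vapply(pc, `[[`, complex(1), "gamma")
  eta <- vapply(pc, `[[`, complex(1), "eta")
  # unknowns x = (G, tau_1, ups_1, ..., tau_{n-1}, ups_{n-1}, tau_n)
  iG <- 1L
  itau <- function(i) if (i < n) 2L * i else 2L * n
  iups <- function(i) 2L * i + 1L
  M <- matrix(0i, 2L * n, 2L * n)
  rhs <- complex(2L * n)
  # air interface at z = 0: 1 + G = tau_1 + ups_1;  (1 - G)/eta0 = (tau_1 - ups_1)/eta_1
  M[1, iG] <- -1; M[1, itau(1)] <- 1; M[1, iups(1)] <- 1; rhs[1] <- 1
  M[2, iG] <- 1 / .test_eta0
  M[2, itau(1)] <- 1 / eta[1]; M[2, iups(1)] <- -1 / eta[1]
  rhs[2] <- 1 / .test_eta0
  for (i in seq_len(n - 1)) {
    em <- exp(-gam[i] * d[i]); ep <- exp(gam[i] * d[i])
    r <- 2L * i + 1L
    M[r, itau(i)] <- em; M[r, iups(i)] <- ep
    M[r, itau(i + 1)] <- -1
    if (i + 1 < n) M[r, iups(i + 1)] <- -1
    r <- r + 1L
    M[r, itau(i)] <- em / eta[i]; M[r, iups(i)] <- -ep / eta[i]
    M[r, itau(i + 1)] <- -1 / eta[i + 1]
    if (i + 1 < n) M[r, iups(i + 1)] <- 1 / eta[i + 1]
  }
  x <- solve(M, rhs)
  list(reflection = x[iG],
       tau = x[vapply(seq_len(n), itau, integer(1))],
       upsilon = c(x[vapply(seq_len(n - 1), iups, integer(1))], 0i))
}

# Random but physically plausible test stack: 3-5 layers with tissue
# dielectrics, moderate thicknesses and Pennes parameters.
random_stack <- function(seed) {
  set.seed(seed)
  refs <- c("skin_dry", "fat_infiltrated", "muscle", "bone_cortical",
            "brain_grey_matter")
  n <- sample(3:5, 1)
  layers <- lapply(seq_len(n), function(i)
    tissue_layer(sprintf("layer%d", i),
                 thickness = stats::runif(1, 1e-4, 1.5e-3),
                 kappa = stats::runif(1, 0.2, 0.6),
                 rho = stats::runif(1, 900, 2000),
                 metabolic_rate = stats::runif(1, 0, 11000),
                 perfusion = stats::runif(1, 0, 12000),
                 dielectric_ref = sample(refs, 1)))
  layer_stack(layers, h = stats::runif(1, 0.5, 8))
}

# A one-tissue database with frequency-flat eps' and sigma.
const_db <- function(eps_real, sigma = 0) {
  list(medium = dielectric_table(frequency = c(1e8, 1e12),
                                 eps_real = rep(eps_real, 2),
                                 sigma = rep(sigma, 2)))
}

# Simple n-layer stack of one uniform medium.
uniform_stack <- function(n = 2, thickness = 5e-4, kappa = 0.5, rho = 1000,
                          A = 0, B = 0, h = 0.5, t_air = 23, t_blood = 37,
                          t_body = 37, ref = "medium") {
  layers <- lapply(seq_len(n), function(i)
    tissue_layer(sprintf("slab%d", i), thickness, kappa, rho, A, B, ref))
  layer_stack(layers, h = h, t_air = t_air, t_blood = t_blood, t_body = t_body)
}

# Closed-form integral of the volumetric absorbed power over layer i of an
# em_solution (terminal layer integrated to infinity). Independent algebra
# from both sar_at and poynting_at.
layer_absorbed <- function(sol, i) {
  w <- sol$waves[[i]]
  pref <- sol$ipd * sol$eta0 * w$sigma
  if (pref == 0) return(0)
  a <- w$alpha; b <- w$beta; d <- w$thickness
  terminal <- i == length(sol$waves)
  if (terminal) return(pref * Mod(w$tau)^2 / (2 * a))
  fwd <- Mod(w$tau)^2 * (1 - exp(-2 * a * d)) / (2 * a)
  bwd <- Mod(w$tau * w$gb)^2 * (exp(-2 * a * d) - exp(-4 * a * d)) / (2 * a)
  osc <- w$X * sin(2 * b * d) / (2 * b) + w$Y * (1 - cos(2 * b * d)) / (2 * b)
  pref * (fwd + bwd + osc)
}
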