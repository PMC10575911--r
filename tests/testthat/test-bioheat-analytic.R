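# Closed-form steady-state bioheat solution.

test_that("zero incident power gives an identically zero elevation", {
  s <- fixture_stack("rat_head")
  prof <- delta_T(s, 30e9, 0)
  z <- seq(0, total_thickness(s), length.out = 60)
  expect_equal(prof$surface, 0)
  expect_equal(delta_t_at(prof, z), rep(0, 60))
})

test_that("a lossless medium produces a zero particular term", {
  db <- const_db(4, 0)
  s <- uniform_stack(n = 2, thickness = 1e-3, B = 5000)
  sol <- solve_stack_em(s, 30e9, 1000, db)
  pt <- particular_term(s$layers[[1]], sol$waves[[1]], 1000)
  zeta <- seq(0, 1e-3, length.out = 11)
  expect_equal(pt$S(zeta), rep(0, 11))
  expect_equal(pt$Sprime(zeta), rep(0, 11))
})

test_that("unperfused terminal layer matches the single-exponential closed form", {
  s <- fixture_stack("rat_head")
  # make the terminal layer unperfused so the B = 0 branch is exercised
  s$layers[[6]]$perfusion <- 0
  sol <- solve_stack_em(s, 30e9, 1000)
  w <- sol$waves[[6]]
  lyr <- s$layers[[6]]
  pt <- particular_term(lyr, w, 1000)
  zeta <- seq(0, 2e-3, length.out = 21)
  # kappa S'' = -rho SAR0 e^{-2 alpha zeta}, S(0) = S'(0) = 0
  q0 <- 1000 * .test_eta0 * w$sigma * Mod(w$tau)^2   # rho * SAR at layer top
  a <- w$alpha
  exact <- -q0 / (4 * a^2 * lyr$kappa) * (exp(-2 * a * zeta) - 1 + 2 * a * zeta)
  expect_equal(pt$S(zeta), exact, tolerance = 1e-10)
})

test_that("the reported S' is the derivative of the reported S", {
  s <- fixture_stack("rat_dorsal")
  sol <- solve_stack_em(s, 60e9, 1000)
  h <- 1e-9
  for (i in seq_along(s$layers)) {
    pt <- particular_term(s$layers[[i]], sol$waves[[i]], 1000)
    zeta <- seq(0.1, 0.9, length.out = 7) * s$layers[[i]]$thickness
    num <- (pt$S(zeta + h) - pt$S(zeta - h)) / (2 * h)
    scale <- max(abs(pt$Sprime(zeta)), 1e-12)
    expect_equal(pt$Sprime(zeta), num, tolerance = 1e-5 * max(1, scale) / scale)
  }
})

test_that("the exposed temperature field satisfies the bioheat ODE pointwise", {
  s <- fixture_stack("rat_head")
  em <- solve_stack_em(s, 30e9, 1000)
  sol <- assemble_and_solve(s, em)
  tops <- c(0, cumsum(vapply(s$layers, `[[`, numeric(1), "thickness")))
  for (i in seq_along(s$layers)) {
    lyr <- s$layers[[i]]
    d <- lyr$thickness
    h <- min(d / 50, 1e-5)
    z <- tops[i] + seq(2 * h, d - 2 * h, length.out = 25)
    t_lo <- temperature_at(sol, z - h)
    t_mid <- temperature_at(sol, z)
    t_hi <- temperature_at(sol, z + h)
    curv <- (t_hi - 2 * t_mid + t_lo) / h^2
    q <- lyr$rho * sar_at(em, z, layer = rep(i, length(z)))
    resid <- lyr$kappa * curv + q + lyr$metabolic_rate -
      lyr$perfusion * (t_mid - s$t_blood)
    scale <- max(abs(q) + lyr$metabolic_rate +
                   lyr$perfusion * abs(t_mid - s$t_blood))
    expect_lt(max(abs(resid)), 1e-3 * max(scale, 1))
  }
})

test_that("boundary and interface conditions hold to machine-level accuracy", {
  s <- fixture_stack("rat_dorsal")
  em <- solve_stack_em(s, 30e9, 1000)
  for (sol in list(assemble_and_solve(s, em), assemble_and_solve(s, NULL))) {
    kap <- vapply(s$layers, `[[`, numeric(1), "kappa")
    d <- vapply(s$layers, `[[`, numeric(1), "thickness")
    # Robin balance at the surface
    expect_equal(s$h * (sol$t_top[1] - s$t_air), kap[1] * sol$dt_top[1],
                 tolerance = 1e-9)
    # Dirichlet clamp at the core
    expect_equal(temperature_at(sol, sol$total_thickness), s$t_body,
                 tolerance = 1e-10)
    # continuity of T and kappa T' at every interior interface
    for (i in seq_len(length(d) - 1)) {
      ci <- sol$coeffs[[i]]
      t_bot <- ci$a(d[i]) * sol$t_top[i] + ci$b(d[i]) * sol$dt_top[i] +
        ci$c(d[i])
      f_bot <- kap[i] * (ci$ap(d[i]) * sol$t_top[i] +
                           ci$bp(d[i]) * sol$dt_top[i] + ci$cp(d[i]))
      expect_equal(t_bot, sol$t_top[i + 1], tolerance = 1e-9)
      expect_equal(f_bot, kap[i + 1] * sol$dt_top[i + 1], tolerance = 1e-7)
    }
  }
})

test_that("elevation is linear in incident power, nonnegative, and clamped at depth", {
  s <- fixture_stack("rat_head")
  z <- seq(0, total_thickness(s), length.out = 80)
  p1 <- delta_T(s, 30e9, 500)
  p2 <- delta_T(s, 30e9, 2000)
  expect_equal(4 * delta_t_at(p1, z), delta_t_at(p2, z), tolerance = 1e-9)
  expect_true(all(delta_t_at(p2, z) >= -1e-10))
  expect_equal(delta_t_at(p2, total_thickness(s)), 0, tolerance = 1e-10)
})

test_that("a source-free baseline obeys the maximum principle", {
  s <- fixture_stack("rat_head")
  for (i in seq_along(s$layers)) s$layers[[i]]$metabolic_rate <- 0
  sol <- assemble_and_solve(s, NULL)
  z <- seq(0, total_thickness(s), length.out = 200)
  tt <- temperature_at(sol, z)
  expect_true(all(tt >= s$t_air - 1e-9 & tt <= s$t_body + 1e-9))
})

test_that("the packaged baseline sits in a physiological range", {
  sol <- assemble_and_solve(fixture_stack("rat_head"), NULL)
  expect_gt(sol$t_top[1], 30)
  expect_lt(sol$t_top[1], 39)
})

test_that("mismatched EM and thermal stacks are rejected", {
  em <- solve_stack_em(fixture_stack("rat_head"), 30e9)
  expect_error(assemble_and_solve(fixture_stack("human_forearm"), em),
               "different stack")
})

test_that("temperature profile export writes the documented columns", {
  prof <- delta_T(fixture_stack("rat_head"), 30e9, 1000)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- export_temperature_profile(prof, path, n = 40)
  expect_true(file.exists(path))
  expect_equal(nrow(utils::read.csv(path)), 40)
})
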