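# Layer and stack construction, fixtures, sampling and config I/O.

test_that("fixture stacks have the documented totals and boundary defaults", {
  head <- fixture_stack("rat_head")
  dorsal <- fixture_stack("rat_dorsal")
  forearm <- fixture_stack("human_forearm")
  expect_equal(total_thickness(head), 11507.8e-6, tolerance = 1e-12)
  expect_equal(total_thickness(dorsal), 11578.9e-6, tolerance = 1e-12)
  expect_equal(total_thickness(forearm), 28322e-6, tolerance = 1e-12)
  for (s in list(head, dorsal, forearm)) {
    expect_equal(s$h, 0.5)
    expect_equal(s$t_air, 23)
    expect_equal(s$t_blood, 37)
    expect_equal(s$t_body, 37)
  }
})

test_that("rat-head fixture table is frozen at the packaged values", {
  df <- as.data.frame(fixture_stack("rat_head"))
  expect_equal(df$tissue, c("epidermis", "dermis", "dWAT",
                            "panniculus_carnosus", "bone", "brain"))
  expect_equal(df$thickness_um, c(22.8, 563.4, 191.5, 230.1, 1000, 9500),
               tolerance = 1e-12)
  expect_equal(df$kappa, c(0.42, 0.42, 0.25, 0.50, 0.37, 0.57))
  expect_equal(df$rho, c(1109, 1109, 911, 1090, 1990, 1038))
  expect_equal(df$metabolic_rate, c(7486, 7486, 4063, 1858, 7945, 10837))
  expect_equal(df$perfusion, c(0, 1160, 5629, 9380, 12317, 6800))
  expect_equal(df$dielectric_ref,
               c("skin_dry", "skin_dry", "fat_infiltrated", "muscle",
                 "bone_cortical", "brain_grey_matter"))
})

test_that("rat-dorsal fixture table is frozen at the packaged values", {
  df <- as.data.frame(fixture_stack("rat_dorsal"))
  expect_equal(df$thickness_um, c(26.1, 908.0, 577.3, 567.5, 4750, 4750),
               tolerance = 1e-12)
  expect_equal(df$perfusion, c(0, 1160, 5629, 9380, 3801, 12317))
})

test_that("every fixture dielectric_ref resolves in the packaged database", {
  db <- default_dielectrics()
  for (part in c("rat_head", "rat_dorsal", "human_forearm")) {
    refs <- vapply(fixture_stack(part)$layers, `[[`, character(1),
                   "dielectric_ref")
    expect_true(all(refs %in% names(db)))
  }
})

test_that("constructors validate their arguments with named messages", {
  expect_error(tissue_layer("x", -1, 0.4, 1000, 0, 0, "skin_dry"), "thickness")
  expect_error(tissue_layer("x", 1e-4, 0, 1000, 0, 0, "skin_dry"), "kappa")
  expect_error(tissue_layer("x", 1e-4, 0.4, 1000, -1, 0, "skin_dry"),
               "metabolic_rate")
  expect_error(tissue_layer("x", 1e-4, 0.4, 1000, 0, -1, "skin_dry"),
               "perfusion")
  l <- tissue_layer("x", 1e-4, 0.4, 1000, 0, 0, "skin_dry")
  expect_error(layer_stack(list(l)), "at least 2")
  expect_error(layer_stack(list(l, l), h = 0), "h")
  expect_error(fixture_stack("rat_tail"), "rat_tail")
})

test_that("thickness sampler is deterministic, truncated, and leaves deep layers", {
  s1 <- sample_stack("rat_head", seed = 42)
  s2 <- sample_stack("rat_head", seed = 42)
  s3 <- sample_stack("rat_head", seed = 43)
  th <- function(s) vapply(s$layers, `[[`, numeric(1), "thickness")
  expect_identical(th(s1), th(s2))
  expect_false(identical(th(s1), th(s3)))
  # deep layers keep fixture values
  expect_equal(th(s1)[5:6], c(1.0e-3, 9.5e-3))
  # truncation bound over many draws
  dist <- thickness_distributions("rat_head")
  for (k in 1:200) {
    x <- th(sample_stack("rat_head", seed = k))[1:4]
    expect_true(all(x >= pmax(dist$mean - 3 * dist$sd, 1e-6) - 1e-15))
  }
})

test_that("zero-variance distributions reproduce the means exactly", {
  dist <- thickness_distributions("rat_dorsal")
  dist$sd <- 0
  s <- sample_stack("rat_dorsal", distributions = dist, seed = 5)
  th <- vapply(s$layers, `[[`, numeric(1), "thickness")
  expect_equal(th[1:4], dist$mean, tolerance = 1e-15)
})

test_that("sampling does not disturb the caller's RNG stream", {
  set.seed(999)
  a <- stats::runif(1)
  set.seed(999)
  invisible(sample_stack("rat_head", seed = 7))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("stack configs round-trip through the YAML format", {
  s <- fixture_stack("rat_dorsal")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_stack(s, path)
  s2 <- read_stack(path)
  expect_equal(as.data.frame(s2), as.data.frame(s), tolerance = 1e-12)
  expect_equal(s2$h, s$h)
  expect_equal(s2$t_air, s$t_air)
})

test_that("config reading reports the offending field and layer", {
  base <- write_stack(fixture_stack("rat_head"))
  path <- withr::local_tempfile(fileext = ".yaml")

  writeLines(sub("thickness: 2.28e-05", "thickness: -5 um", base, fixed = TRUE),
             path)
  expect_error(read_stack(path), "epidermis")

  writeLines(sub("^h: .*", "", base), path)
  expect_error(read_stack(path), "'h'")

  writeLines(sub("dielectric_ref: skin_dry", "dielectric_ref: unobtainium",
                 base, fixed = TRUE), path)
  expect_error(read_stack(path), "unobtainium")
})

test_that("thickness strings with um/mm units are parsed", {
  txt <- write_stack(fixture_stack("rat_head"))
  txt <- sub("thickness: 0.0095", "thickness: 9.5 mm", txt, fixed = TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(txt, path)
  s <- read_stack(path)
  expect_equal(s$layers[[6]]$thickness, 9.5e-3, tolerance = 1e-12)
})

test_that("set_perfusion replaces exactly one layer's B", {
  s <- fixture_stack("rat_head")
  s2 <- set_perfusion(s, "brain", 300)
  expect_equal(s2$layers[[6]]$perfusion, 300)
  expect_equal(s2$layers[[5]]$perfusion, s$layers[[5]]$perfusion)
  expect_error(set_perfusion(s, "gills", 1), "gills")
})
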