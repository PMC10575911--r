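#' A single tissue slab
#'
#' One layer of a one-dimensional tissue stack: geometry, thermal parameters
#' of the Pennes bioheat equation, and a label resolving into the dielectric
#' database.
#'
#' @param name layer label (e.g. `"dermis"`).
#' @param thickness slab thickness in metres (> 0).
#' @param kappa thermal conductivity, W/(m °C) (> 0).
#' @param rho mass density, kg/m^3 (> 0).
#' @param metabolic_rate basal metabolic heat production A, W/m^3 (>= 0).
#' @param perfusion blood-perfusion heat-exchange term B, W/(m^3 °C) (>= 0).
#' @param dielectric_ref tissue label in the dielectric database.
#' @return an object of class `tissue_layer`.
#' @export
tissue_layer <- function(name, thickness, kappa, rho, metabolic_rate,
                         perfusion, dielectric_ref) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  chk <- function(x, what, strict = TRUE) {
    if (length(x) != 1L || !is.finite(x) || (if (strict) x <= 0 else x < 0))
      stop(sprintf("layer '%s': '%s' must be %s", name, what,
                   if (strict) "a positive number" else "a non-negative number"))
  }
  chk(thickness, "thickness"); chk(kappa, "kappa"); chk(rho, "rho")
  chk(metabolic_rate, "metabolic_rate", strict = FALSE)
  chk(perfusion, "perfusion", strict = FALSE)
  if (!is.character(dielectric_ref) || length(dielectric_ref) != 1L)
    stop(sprintf("layer '%s': 'dielectric_ref' must be a string", name))
  structure(list(name = name, thickness = thickness, kappa = kappa, rho = rho,
                 metabolic_rate = metabolic_rate, perfusion = perfusion,
                 dielectric_ref = dielectric_ref),
            class = "tissue_layer")
}

#' An ordered stack of tissue layers with boundary settings
#'
#' Layers are ordered exposure side first. The exposed surface couples to
#' ambient air through a convective (Robin) boundary with heat-transfer
#' coefficient `h`; the deep end is clamped at the body core temperature.
#'
#' @param layers list of [tissue_layer()] objects (at least 2).
#' @param h surface heat-transfer coefficient, W/(m^2 °C) (> 0).
#' @param t_air ambient air temperature, °C.
#' @param t_blood arterial blood temperature, °C.
#' @param t_body body core temperature (deep boundary), °C.
#' @return an object of class `layer_stack`.
#' @export
layer_stack <- function(layers, h = 0.5, t_air = 23, t_blood = 37,
                        t_body = 37) {
  if (!is.list(layers) || length(layers) < 2L)
    stop("'layers' must be a list of at least 2 tissue_layer objects")
  ok <- vapply(layers, inherits, logical(1), "tissue_layer")
  if (!all(ok)) stop("all elements of 'layers' must be tissue_layer objects")
  if (length(h) != 1L || !is.finite(h) || h <= 0) stop("'h' must be > 0")
  for (v in c(t_air, t_blood, t_body))
    if (length(v) != 1L || !is.finite(v)) stop("temperatures must be finite")
  structure(list(layers = layers, h = h, t_air = t_air, t_blood = t_blood,
                 t_body = t_body),
            class = "layer_stack")
}

#' @method print layer_stack
#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("layer stack: %d layers, total thickness %.4g mm\n",
              length(x$layers), 1e3 * total_thickness(x)))
  cat(sprintf("  h = %g W/(m^2 degC), T_air = %g, T_blood = %g, T_body = %g degC\n",
              x$h, x$t_air, x$t_blood, x$t_body))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' @export
as.data.frame.layer_stack <- function(x, ...) {
  data.frame(
    tissue = vapply(x$layers, `[[`, character(1), "name"),
    thickness_um = 1e6 * vapply(x$layers, `[[`, numeric(1), "thickness"),
    kappa = vapply(x$layers, `[[`, numeric(1), "kappa"),
    rho = vapply(x$layers, `[[`, numeric(1), "rho"),
    metabolic_rate = vapply(x$layers, `[[`, numeric(1), "metabolic_rate"),
    perfusion = vapply(x$layers, `[[`, numeric(1), "perfusion"),
    dielectric_ref = vapply(x$layers, `[[`, character(1), "dielectric_ref"),
    stringsAsFactors = FALSE)
}

#' Total thickness of a stack in metres
#' @param stack a `layer_stack`.
#' @return total thickness (m).
#' @export
total_thickness <- function(stack) {
  sum(vapply(stack$layers, `[[`, numeric(1), "thickness"))
}

# Depth of the top of each layer (m), exposure surface at z = 0.
layer_tops <- function(stack) {
  d <- vapply(stack$layers, `[[`, numeric(1), "thickness")
  c(0, cumsum(d)[-length(d)])
}

# --- packaged fixtures ------------------------------------------------------
# Histology (skin block) + X-ray CT (deep block) layer tables for precise rat
# models, and the four-layer human forearm model used for comparison.
# Thickness in metres; kappa W/(m degC); rho kg/m^3; A W/m^3; B W/(m^3 degC).

.fixture_tables <- list(
  rat_head = list(
    list("epidermis",           22.8e-6, 0.42, 1109,  7486,     0, "skin_dry"),
    list("dermis",             563.4e-6, 0.42, 1109,  7486,  1160, "skin_dry"),
    list("dWAT",               191.5e-6, 0.25,  911,  4063,  5629, "fat_infiltrated"),
    list("panniculus_carnosus",230.1e-6, 0.50, 1090,  1858,  9380, "muscle"),
    list("bone",                 1.0e-3, 0.37, 1990,  7945, 12317, "bone_cortical"),
    list("brain",                9.5e-3, 0.57, 1038, 10837,  6800, "brain_grey_matter")),
  rat_dorsal = list(
    list("epidermis",           26.1e-6, 0.42, 1109,  7486,     0, "skin_dry"),
    list("dermis",             908.0e-6, 0.42, 1109,  7486,  1160, "skin_dry"),
    list("dWAT",               577.3e-6, 0.25,  911,  4063,  5629, "fat_infiltrated"),
    list("panniculus_carnosus",567.5e-6, 0.50, 1090,  1858,  9380, "muscle"),
    list("muscle",              4.75e-3, 0.50, 1090,  1858,  3801, "muscle"),
    list("bone",                4.75e-3, 0.37, 1990,  7945, 12317, "bone_cortical")),
  human_forearm = list(
    list("epidermis",          102.0e-6, 0.42, 1109,  7486,     0, "skin_dry"),
    list("dermis",            1080.0e-6, 0.42, 1109,  7486,  1160, "skin_dry"),
    list("subcutaneous_fat",  3890.0e-6, 0.25,  911,  4063,  5629, "fat_infiltrated"),
    list("muscle",            23250e-6,  0.50, 1090,  1858,  3801, "muscle"))
)

# Per-layer thickness statistics (mean, sd in metres) from the histological
# measurements of the four skin layers (three sites per stained section).
.thickness_stats <- list(
  rat_head = data.frame(
    tissue = c("epidermis", "dermis", "dWAT", "panniculus_carnosus"),
    mean = c(22.8e-6, 563.4e-6, 191.5e-6, 230.1e-6),
    sd = c(2.4e-6, 62.8e-6, 28.0e-6, 25.3e-6),
    stringsAsFactors = FALSE),
  rat_dorsal = data.frame(
    tissue = c("epidermis", "dermis", "dWAT", "panniculus_carnosus"),
    mean = c(26.1e-6, 908.0e-6, 577.3e-6, 567.5e-6),
    sd = c(2.6e-6, 22.4e-6, 45.0e-6, 60.7e-6),
    stringsAsFactors = FALSE)
)

.fixture_labels <- function() names(.fixture_tables)

#' Packaged layer-stack fixtures
#'
#' Builds one of the packaged tissue stacks: the six-layer precise rat head
#' or rat dorsal model (epidermis, dermis, dWAT, panniculus carnosus over
#' bone/brain or muscle/bone), or the four-layer human forearm model.
#' Boundary defaults are `h = 0.5` W/(m^2 °C), `t_air = 23` °C and
#' `t_blood = t_body = 37` °C.
#'
#' @param body_part one of `"rat_head"`, `"rat_dorsal"`, `"human_forearm"`.
#' @return a [layer_stack()].
#' @export
fixture_stack <- function(body_part = c("rat_head", "rat_dorsal",
                                        "human_forearm")) {
  if (!is.character(body_part) || !body_part[1] %in% .fixture_labels())
    stop(sprintf("unknown body part '%s'; valid labels: %s",
                 as.character(body_part[1]),
                 paste(.fixture_labels(), collapse = ", ")))
  body_part <- body_part[1]
  rows <- .fixture_tables[[body_part]]
  layers <- lapply(rows, function(r)
    tissue_layer(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]], r[[6]], r[[7]]))
  layer_stack(layers)
}

#' Measured thickness distributions of the rat skin layers
#'
#' Mean and standard deviation (metres) of each histologically measured skin
#' layer, as used by [sample_stack()].
#'
#' @param body_part `"rat_head"` or `"rat_dorsal"`.
#' @return data.frame with columns `tissue`, `mean`, `sd`.
#' @export
thickness_distributions <- function(body_part = c("rat_head", "rat_dorsal")) {
  body_part <- match.arg(body_part)
  .thickness_stats[[body_part]]
}

#' Sample a stack with stochastic skin-layer thicknesses
#'
#' Draws the four skin-layer thicknesses from per-layer normal distributions
#' (truncated below at `mean - 3*sd` and floored at 1 micron) while keeping
#' the deep layers at their fixture values. Deterministic for a fixed seed.
#'
#' @param body_part `"rat_head"` or `"rat_dorsal"`.
#' @param distributions data.frame as from [thickness_distributions()];
#'   columns `tissue`, `mean`, `sd` (metres).
#' @param seed integer RNG seed.
#' @return a [layer_stack()].
#' @export
sample_stack <- function(body_part = c("rat_head", "rat_dorsal"),
                         distributions = thickness_distributions(body_part),
                         seed) {
  body_part <- match.arg(body_part)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  if (any(distributions$sd < 0)) stop("'sd' must be >= 0")
  if (any(distributions$mean <= 0)) stop("'mean' must be > 0")
  stack <- fixture_stack(body_part)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  for (k in seq_len(nrow(distributions))) {
    nm <- distributions$tissue[k]
    mu <- distributions$mean[k]; sd <- distributions$sd[k]
    idx <- match(nm, vapply(stack$layers, `[[`, character(1), "name"))
    if (is.na(idx)) stop(sprintf("no layer named '%s' in the %s fixture", nm, body_part))
    if (sd == 0) { x <- mu } else {
      lo <- mu - 3 * sd
      repeat { x <- stats::rnorm(1, mu, sd); if (x >= lo) break }
    }
    stack$layers[[idx]]$thickness <- max(x, 1e-6)
  }
  stack
}

#' Replace the perfusion term of one layer
#'
#' @param stack a `layer_stack`.
#' @param layer layer name.
#' @param perfusion new B value, W/(m^3 °C) (>= 0).
#' @return modified stack.
#' @export
set_perfusion <- function(stack, layer, perfusion) {
  idx <- match(layer, vapply(stack$layers, `[[`, character(1), "name"))
  if (is.na(idx))
    stop(sprintf("no layer named '%s' (layers: %s)", layer,
                 paste(vapply(stack$layers, `[[`, character(1), "name"),
                       collapse = ", ")))
  if (perfusion < 0) stop("'perfusion' must be >= 0")
  stack$layers[[idx]]$perfusion <- perfusion
  stack
}

# --- stack config I/O -------------------------------------------------------

# Parse a thickness field: plain number = metres; "x um"/"x mm"/"x m" also ok.
parse_thickness <- function(x, where) {
  if (is.numeric(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^\\s*(-?[0-9.eE+-]+)\\s*(um|mm|m)\\s*$", x))[[1]]
    if (length(m) == 3L) {
      v <- suppressWarnings(as.numeric(m[2]))
      if (is.finite(v))
        return(v * switch(m[3], um = 1e-6, mm = 1e-3, m = 1))
    }
  }
  stop(sprintf("%s: cannot parse thickness '%s' (use metres or 'x um/mm/m')",
               where, as.character(x)))
}

#' Read a layer-stack config file
#'
#' YAML mapping with scalar fields `h`, `t_air`, `t_blood`, `t_body` and a
#' `layers` sequence; every layer must declare `name`, `thickness` (metres,
#' or a string with `um`/`mm`/`m` units), `kappa`, `rho`, `metabolic_rate`,
#' `perfusion` and `dielectric_ref`. All invariants are validated on read.
#'
#' @param path config file path.
#' @param db dielectric database used to validate `dielectric_ref` labels.
#' @return a [layer_stack()].
#' @export
read_stack <- function(path, db = default_dielectrics()) {
  cfg <- yaml::read_yaml(path)
  for (fld in c("h", "t_air", "t_blood", "t_body"))
    if (is.null(cfg[[fld]]))
      stop(sprintf("stack config: missing field '%s'", fld))
  if (is.null(cfg$layers) || length(cfg$layers) < 2L)
    stop("stack config: 'layers' must list at least 2 layers")
  layers <- lapply(seq_along(cfg$layers), function(i) {
    rec <- cfg$layers[[i]]
    where <- sprintf("layers[%d]%s", i,
                     if (!is.null(rec$name)) sprintf(" ('%s')", rec$name) else "")
    for (fld in c("name", "thickness", "kappa", "rho", "metabolic_rate",
                  "perfusion", "dielectric_ref"))
      if (is.null(rec[[fld]]))
        stop(sprintf("%s: missing field '%s'", where, fld))
    th <- parse_thickness(rec$thickness, where)
    if (!is.finite(th) || th <= 0)
      stop(sprintf("%s: thickness must be > 0", where))
    lyr <- tissue_layer(rec$name, th, rec$kappa, rec$rho, rec$metabolic_rate,
                        rec$perfusion, rec$dielectric_ref)
    resolve_dielectric(db, lyr$dielectric_ref)  # fail early on unknown labels
    lyr
  })
  layer_stack(layers, h = cfg$h, t_air = cfg$t_air, t_blood = cfg$t_blood,
              t_body = cfg$t_body)
}

#' Write a layer stack to a config file (or string)
#'
#' @param stack a `layer_stack`.
#' @param path output file; if `NULL`, the YAML text is returned.
#' @return the YAML text, invisibly when written to a file.
#' @export
write_stack <- function(stack, path = NULL) {
  cfg <- list(h = stack$h, t_air = stack$t_air, t_blood = stack$t_blood,
              t_body = stack$t_body,
              layers = lapply(stack$layers, function(l)
                list(name = l$name, thickness = l$thickness, kappa = l$kappa,
                     rho = l$rho, metabolic_rate = l$metabolic_rate,
                     perfusion = l$perfusion,
                     dielectric_ref = l$dielectric_ref)))
  txt <- yaml::as.yaml(cfg, precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Export a stack's layer table as CSV
#'
#' @param stack a `layer_stack`.
#' @param path output CSV path.
#' @return the exported data.frame, invisibly.
#' @export
export_stack_csv <- function(stack, path) {
  df <- as.data.frame(stack)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
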