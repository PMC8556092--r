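#' Water-equivalent thickness factors
#'
#' Per-material scaling rules converting a physical layer thickness to its
#' water-equivalent thickness (WET). PMMA scales by 1.16; graphite scales by
#' its mass density times 1.16/1.19 (i.e. the PMMA factor per unit density);
#' lacquer and water count at face value. These constants reproduce the
#' worked wall calculations for the PTW 34080 (2.0648 mm) and PTW 34070
#' (4.022 mm) chambers bit-exactly and can be overridden for other
#' conversion protocols.
#'
#' @return Named list with elements `pmma_factor` (dimensionless, default
#'   1.16) and `pmma_density` (g/cm^3, default 1.19). Graphite WET is
#'   `thickness * density * pmma_factor / pmma_density`.
#' @export
wet_factors <- function() {
  list(pmma_factor = 1.16, pmma_density = 1.19)
}

.materials <- c("PMMA", "graphite", "lacquer", "water")

#' Construct a chamber wall/window layer
#'
#' @param material One of `"PMMA"`, `"graphite"`, `"lacquer"`, `"water"`
#'   (case-insensitive).
#' @param thickness Physical thickness in mm; must be >= 0.
#' @param density Mass density in g/cm^3. Defaults: PMMA 1.19,
#'   graphite 1.85, lacquer and water 1.0.
#' @return An object of class `material_layer`.
#' @examples
#' material_layer("PMMA", 3.35)
#' material_layer("graphite", 0.02)
#' @export
material_layer <- function(material, thickness, density = NULL) {
  m <- .materials[match(tolower(material), tolower(.materials))]
  if (is.na(m)) {
    stop("unknown material '", material, "'; expected one of: ",
         paste(.materials, collapse = ", "), call. = FALSE)
  }
  stopifnot(is.numeric(thickness), length(thickness) == 1L, thickness >= 0)
  if (is.null(density)) {
    density <- switch(m, PMMA = 1.19, graphite = 1.85, 1.0)
  }
  stopifnot(is.numeric(density), length(density) == 1L, density > 0)
  structure(list(material = m, thickness = thickness, density = density),
            class = "material_layer")
}

#' @export
print.material_layer <- function(x, ...) {
  cat(sprintf("<material_layer> %s: %.4g mm (rho = %.3g g/cm^3), WET %.4f mm\n",
              x$material, x$thickness, x$density, layer_wet(x)))
  invisible(x)
}

#' Water-equivalent thickness of one layer
#'
#' Applies the per-material scaling rule: PMMA thickness x 1.16; graphite
#' thickness x density x (1.16/1.19); lacquer and water x 1.
#'
#' @param layer A [material_layer()].
#' @param factors Conversion constants, see [wet_factors()].
#' @return Water-equivalent thickness in mm.
#' @examples
#' layer_wet(material_layer("PMMA", 3.35))     # 3.886
#' layer_wet(material_layer("graphite", 0.02)) # 0.0361
#' @export
layer_wet <- function(layer, factors = wet_factors()) {
  if (!inherits(layer, "material_layer")) {
    layer <- do.call(material_layer, as.list(layer))
  }
  switch(layer$material,
    PMMA     = layer$thickness * factors$pmma_factor,
    graphite = layer$thickness * layer$density *
               (factors$pmma_factor / factors$pmma_density),
    lacquer  = layer$thickness,
    water    = layer$thickness,
    stop("unknown material '", layer$material, "'", call. = FALSE)
  )
}

#' Water-equivalent thickness of a layer stack
#'
#' Sum of [layer_wet()] over an ordered stack; additive and
#' order-independent. The bundled PTW 34080 window (0.62 mm PMMA wall +
#' 1.16 mm PMMA electrode) yields 2.0648 mm and the PTW 34070 window
#' (3.35 mm PMMA + 0.02 mm graphite + 0.1 mm lacquer) yields 4.022 mm.
#'
#' @param layers List of [material_layer()] objects (may be empty).
#' @inheritParams layer_wet
#' @return Total water-equivalent thickness in mm.
#' @examples
#' stack_wet(list(
#'   material_layer("PMMA", 3.35),
#'   material_layer("graphite", 0.02),
#'   material_layer("lacquer", 0.1)
#' ))
#' @export
stack_wet <- function(layers, factors = wet_factors()) {
  if (length(layers) == 0L) return(0)
  sum(vapply(layers, layer_wet, numeric(1), factors = factors))
}

#' Construct an ionization chamber specification
#'
#' @param name Chamber model name, e.g. `"PTW 30013"`.
#' @param kind `"plane_parallel"` or `"cylindrical"`.
#' @param window_layers List of [material_layer()] (entrance window or wall
#'   stack along the beam); must be non-empty.
#' @param inner_radius Cavity inner radius in mm (cylindrical chambers
#'   only; 3.05 mm for the PTW 30013 Farmer chamber).
#' @param active_volume Active volume in cm^3 (optional).
#' @param pom_convention Free-text point-of-measurement convention.
#' @param pom_offset Offset of the point of measurement in mm along the
#'   chamber axis relative to the convention's reference (e.g. 13 mm behind
#'   the tip for the Farmer chamber).
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(name, kind = c("plane_parallel", "cylindrical"),
                         window_layers, inner_radius = NULL,
                         active_volume = NULL, pom_convention = "",
                         pom_offset = 0) {
  kind <- match.arg(kind)
  if (length(window_layers) == 0L) {
    stop("window_layers must be non-empty", call. = FALSE)
  }
  window_layers <- lapply(window_layers, function(l) {
    if (inherits(l, "material_layer")) l else do.call(material_layer, as.list(l))
  })
  if (kind == "cylindrical") {
    stopifnot(is.numeric(inner_radius), inner_radius > 0)
  }
  structure(list(name = name, kind = kind, window_layers = window_layers,
                 inner_radius = inner_radius, active_volume = active_volume,
                 pom_convention = pom_convention, pom_offset = pom_offset),
            class = "chamber_spec")
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf("<chamber_spec> %s (%s)\n", x$name, x$kind))
  if (!is.null(x$inner_radius)) {
    cat(sprintf("  inner radius: %.3g mm\n", x$inner_radius))
  }
  cat(sprintf("  point of measurement: %s\n", x$pom_convention))
  for (l in x$window_layers) {
    cat(sprintf("  layer %-8s %6.3f mm -> WET %.4f mm\n",
                l$material, l$thickness, layer_wet(l)))
  }
  cat(sprintf("  total WET: %.4f mm\n", chamber_wet(x)))
  invisible(x)
}

#' Total wall/window WET of a chamber
#'
#' @param chamber A [chamber_spec()].
#' @inheritParams layer_wet
#' @return Water-equivalent thickness in mm of the chamber's layer stack.
#' @export
chamber_wet <- function(chamber, factors = wet_factors()) {
  stack_wet(chamber$window_layers, factors)
}

#' Bundled chamber specifications
#'
#' Reads the chamber definitions shipped with the package: the PTW Bragg
#' peak chambers 34080 (reference) and 34070 (in-field) and the PTW 30013
#' Farmer chamber. The 34080 stack follows the worked wall calculation
#' (0.62 mm PMMA window + 1.16 mm PMMA electrode incl. graphite coat,
#' scaled together by 1.16); the 34070 and 30013 stacks scale graphite
#' separately by density. Both published conventions are reproduced
#' as printed, per chamber.
#'
#' @param path Optional path to an alternative YAML chamber file with the
#'   same schema.
#' @return Named list of [chamber_spec()] objects.
#' @examples
#' chs <- builtin_chambers()
#' chamber_wet(chs[["PTW 34080"]]) # 2.0648
#' @export
builtin_chambers <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chambers.yaml", package = "peffkit")
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(rec) {
    layers <- lapply(rec$window_layers, function(l) {
      material_layer(l$material, l$thickness, l$density)
    })
    chamber_spec(name = rec$name, kind = rec$kind, window_layers = layers,
                 inner_radius = rec$inner_radius,
                 active_volume = rec$active_volume,
                 pom_convention = rec$pom_convention %||% "",
                 pom_offset = rec$pom_offset %||% 0)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
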