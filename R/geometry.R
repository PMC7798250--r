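#' Shape-based compartment geometry
#'
#' Cellular compartments are idealised as simple shapes: nuclei as perfect
#' spheres (the measured nuclear cross-section is read as the great-circle
#' cross-section, so `r = sqrt(A_cs / pi)`), root epidermis cells as cuboids
#' with constant width and depth. Units are fixed package-wide: lengths in
#' um, areas in um^2, volumes in um^3 (= fL), concentrations in umol/L
#' (uM), time in s. Area-scaled rate constants carry um/s.
#'
#' @name geometry
NULL

#' Sphere geometry
#'
#' Construct a sphere from its radius. Volume, surface area and great-circle
#' cross-section are derived quantities; `surface = 4 * cross_section`
#' exactly for any sphere.
#'
#' @param r radius (um), non-negative.
#' @return An object of class `sphere_geometry` with fields `r`, `volume`,
#'   `surface`, `cross_section`.
#' @examples
#' s <- sphere_geometry(1)
#' s$volume   # 4*pi/3
#' s$surface  # 4*pi
#' @export
sphere_geometry <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0)
    stop("sphere radius must be a single non-negative number, got ",
         deparse(r), call. = FALSE)
  structure(
    list(r = r,
         volume = 4 / 3 * pi * r^3,
         surface = 4 * pi * r^2,
         cross_section = pi * r^2),
    class = "sphere_geometry")
}

#' Sphere from its great-circle cross-section
#'
#' Recovers a sphere from a measured cross-sectional area, the way nuclear
#' volume and surface are derived from a nuclear cross-section measured in a
#' microscopy image: `r = sqrt(A_cs / pi)`.
#'
#' @param cross_section cross-sectional area (um^2), positive.
#' @return A `sphere_geometry`.
#' @examples
#' sphere_from_cross_section(200)$volume  # ~2.13e3 um^3
#' @export
sphere_from_cross_section <- function(cross_section) {
  if (!is.numeric(cross_section) || length(cross_section) != 1L ||
      is.na(cross_section) || cross_section <= 0)
    stop("cross_section must be a single positive number", call. = FALSE)
  sphere_geometry(sqrt(cross_section / pi))
}

#' Sphere from its volume
#'
#' `r = (3 V / (4 pi))^(1/3)`; used when only a compartment volume is
#' reported and the bounding membrane area is needed.
#'
#' @param volume volume (um^3), positive.
#' @return A `sphere_geometry`.
#' @examples
#' sphere_from_volume(1.2e4)$surface  # ~2534 um^2
#' @export
sphere_from_volume <- function(volume) {
  if (!is.numeric(volume) || length(volume) != 1L ||
      is.na(volume) || volume <= 0)
    stop("volume must be a single positive number", call. = FALSE)
  sphere_geometry((3 * volume / (4 * pi))^(1 / 3))
}

#' Scale a sphere by a radius factor
#'
#' Multiplies the radius by `factor`; surface then scales by `factor^2` and
#' volume by `factor^3`. Used for scenarios such as a 50% increase of both
#' nuclear and cell radius.
#'
#' @param geom a `sphere_geometry`.
#' @param factor positive radius multiplier (dimensionless).
#' @return A `sphere_geometry`.
#' @export
scale_sphere <- function(geom, factor) {
  stopifnot(inherits(geom, "sphere_geometry"))
  if (!is.numeric(factor) || length(factor) != 1L ||
      is.na(factor) || factor <= 0)
    stop("radius factor must be a single positive number", call. = FALSE)
  sphere_geometry(geom$r * factor)
}

#' Cuboid geometry
#'
#' Root epidermis cells are idealised as cuboids of length `L` (the axial
#' growth direction), width `w` and depth `d`. The vertical interface area
#' shared with the axially adjacent cell is `w * d` and does not change as
#' the cell elongates.
#'
#' @param L,w,d edge lengths (um), all positive.
#' @return An object of class `cuboid_geometry` with fields `L`, `w`, `d`,
#'   `volume`, `vertical_interface`, `total_surface`.
#' @export
cuboid_geometry <- function(L, w, d) {
  dims <- c(L = L, w = w, d = d)
  if (!is.numeric(dims) || length(dims) != 3L || anyNA(dims) || any(dims <= 0))
    stop("cuboid dimensions must all be positive", call. = FALSE)
  structure(
    list(L = L, w = w, d = d,
         volume = L * w * d,
         vertical_interface = w * d,
         total_surface = 2 * (L * w + L * d + w * d)),
    class = "cuboid_geometry")
}

#' Compartment geometry: volume plus named membrane areas
#'
#' The geometric facts a kinetic model needs about a compartment: its volume
#' and the areas of named membrane interfaces. Usually derived from a shape
#' (see [as_compartment_geometry()]), but values can also be supplied
#' directly when no shape is assumed.
#'
#' @param volume compartment volume (um^3), positive.
#' @param membrane_areas named numeric vector or list of interface areas
#'   (um^2), all positive. May be empty for compartments with no modelled
#'   membrane.
#' @param provenance character tag: the shape the values derive from, or
#'   `"direct"`.
#' @return An object of class `compartment_geometry`.
#' @export
compartment_geometry <- function(volume, membrane_areas = numeric(),
                                 provenance = "direct") {
  if (!is.numeric(volume) || length(volume) != 1L ||
      is.na(volume) || volume <= 0)
    stop("compartment volume must be a single positive number", call. = FALSE)
  membrane_areas <- unlist(membrane_areas)
  if (length(membrane_areas)) {
    if (is.null(names(membrane_areas)) || any(names(membrane_areas) == ""))
      stop("membrane areas must be named", call. = FALSE)
    if (!is.numeric(membrane_areas) || anyNA(membrane_areas) ||
        any(membrane_areas <= 0))
      stop("membrane areas must all be positive", call. = FALSE)
  }
  structure(
    list(volume = volume,
         membrane_areas = membrane_areas,
         provenance = provenance),
    class = "compartment_geometry")
}

#' Convert a shape to a compartment geometry
#'
#' @param x a `sphere_geometry` or `cuboid_geometry`.
#' @param ... unused.
#' @return A `compartment_geometry`. Spheres expose a `"surface"` interface;
#'   cuboids expose `"vertical_interface"` and `"total_surface"`.
#' @export
as_compartment_geometry <- function(x, ...) UseMethod("as_compartment_geometry")

#' @export
as_compartment_geometry.sphere_geometry <- function(x, ...) {
  compartment_geometry(x$volume, c(surface = x$surface), provenance = "sphere")
}

#' @export
as_compartment_geometry.cuboid_geometry <- function(x, ...) {
  compartment_geometry(
    x$volume,
    c(vertical_interface = x$vertical_interface,
      total_surface = x$total_surface),
    provenance = "cuboid")
}

#' @export
as_compartment_geometry.compartment_geometry <- function(x, ...) x

#' Root epidermis cell geometry
#'
#' A root cell as a cuboid: volume `L*w*d`, vertical interface `w*d` (the
#' face shared with the axially adjacent cell), total surface
#' `2(Lw + Ld + wd)`. Root cells grow almost exclusively in length, so the
#' vertical interface stays constant while the volume grows linearly in `L`.
#'
#' @param L cell length (um).
#' @param w,d cell width and depth (um); default 5 um each.
#' @return A `compartment_geometry` with provenance `"cuboid"`.
#' @examples
#' root_cell_geometry(8)$volume     # 200 um^3
#' root_cell_geometry(220)$membrane_areas[["vertical_interface"]]  # still 25
#' @export
root_cell_geometry <- function(L, w = 5, d = 5) {
  as_compartment_geometry(cuboid_geometry(L, w, d))
}

#' Read a geometry table from a YAML config file
#'
#' Each top-level key names a compartment; its value is either
#' `{shape: sphere, cross_section | volume | radius: <num>}`,
#' `{shape: cuboid, L: , w: , d: }`, or
#' `{volume: <num>, areas: {name: value, ...}}` for direct values.
#'
#' @param path path to a YAML file.
#' @return A named list of `compartment_geometry` objects.
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg) || is.null(names(cfg)))
    stop("geometry config must map compartment ids to shape entries",
         call. = FALSE)
  out <- lapply(names(cfg), function(id) {
    entry <- cfg[[id]]
    shape <- entry$shape %||% "direct"
    if (identical(shape, "sphere")) {
      s <- if (!is.null(entry$radius)) sphere_geometry(entry$radius)
      else if (!is.null(entry$cross_section))
        sphere_from_cross_section(entry$cross_section)
      else if (!is.null(entry$volume)) sphere_from_volume(entry$volume)
      else stop("sphere entry '", id,
                "' needs one of radius/cross_section/volume", call. = FALSE)
      as_compartment_geometry(s)
    } else if (identical(shape, "cuboid")) {
      as_compartment_geometry(cuboid_geometry(entry$L, entry$w, entry$d))
    } else if (identical(shape, "direct")) {
      compartment_geometry(entry$volume, entry$areas %||% numeric())
    } else {
      stop("unknown shape '", shape, "' for compartment '", id, "'",
           call. = FALSE)
    }
  })
  names(out) <- names(cfg)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
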