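#' Brick lattice description of the calibration phantom
#'
#' The phantom is a stack of interlocking toy bricks; marker positions are
#' computed from the lattice pitches rather than measured. Horizontal
#' positions are multiples of the stud pitch, vertical positions multiples
#' of the layer pitch. The defaults describe the 6x2-stud, eight-layer
#' phantom used for calibration: a caliper-measured width of 47.7 mm over
#' six studs gives a stud pitch of 7.95 mm, and eight layers spanning
#' 76.2 mm give a layer pitch of 9.525 mm.
#'
#' @param stud_pitch Horizontal lattice unit (mm).
#' @param layer_pitch Vertical lattice unit (mm).
#' @param n_layers Number of brick layers.
#' @param footprint_studs Integer vector (n_x, n_z): stud counts of the
#'   footprint.
#' @return An object of class \code{brick_lattice}.
#' @export
brick_lattice <- function(stud_pitch = 47.7 / 6, layer_pitch = 76.2 / 8,
                          n_layers = 8, footprint_studs = c(6, 2)) {
  stopifnot(stud_pitch > 0, layer_pitch > 0, n_layers >= 1,
            length(footprint_studs) == 2, all(footprint_studs >= 2))
  structure(list(stud_pitch = stud_pitch, layer_pitch = layer_pitch,
                 n_layers = as.integer(n_layers),
                 footprint_studs = as.integer(footprint_studs)),
            class = "brick_lattice")
}

#' Marker placement in the brick lattice
#'
#' A marker bears in one of the hollow cylinders on the underside of a
#' brick. Cylinders sit at stud-grid midpoints: cylinder (cx, cz) is
#' centered between studs (cx, cz) and (cx+1, cz+1), so valid indices are
#' 0 .. n_x-2 and 0 .. n_z-2.
#'
#' @param layer_index 0-based brick layer of the bearing brick.
#' @param cyl_x,cyl_z 0-based cylinder indices within the footprint.
#' @param depth_fraction Depth of the marker center below the layer top, in
#'   units of the marker diameter. The default 1.5 corresponds to a sphere
#'   pressed exactly one diameter deep: its top lies one diameter below the
#'   cylinder mouth, its center one further radius down.
#' @return An object of class \code{marker_placement}.
#' @export
marker_placement <- function(layer_index, cyl_x, cyl_z = 0,
                             depth_fraction = 1.5) {
  stopifnot(layer_index >= 0, cyl_x >= 0, cyl_z >= 0, depth_fraction > 0)
  structure(list(layer_index = as.integer(layer_index),
                 cyl_x = as.integer(cyl_x), cyl_z = as.integer(cyl_z),
                 depth_fraction = depth_fraction),
            class = "marker_placement")
}

#' Build a marker phantom from a lattice and placements
#'
#' Marker coordinates are pure lattice arithmetic. Horizontally a cylinder
#' (cx, cz) is centered at ((cx+1) - n_x/2, (cz+1) - n_z/2) stud pitches
#' from the footprint center. Vertically the marker center sits
#' \code{depth_fraction} marker diameters below the top of its layer. The
#' phantom frame origin is the geometric center of the brick bounding box,
#' with y vertical.
#'
#' @param lattice A [brick_lattice()].
#' @param placements List of [marker_placement()] objects.
#' @param marker_diameter Marker (bead) diameter in mm; the steel beads of
#'   the reference phantom measure 4.95 mm.
#' @return An object of class \code{phantom_model} with elements
#'   \code{markers} (data.frame id, x_mm, y_mm, z_mm),
#'   \code{marker_diameter}, \code{dims} (bounding width, height, depth in
#'   mm) and \code{lattice}.
#' @export
build_phantom <- function(lattice, placements, marker_diameter = 4.95) {
  stopifnot(inherits(lattice, "brick_lattice"), marker_diameter > 0)
  nx <- lattice$footprint_studs[1]
  nz <- lattice$footprint_studs[2]
  width <- nx * lattice$stud_pitch
  depth <- nz * lattice$stud_pitch
  height <- lattice$n_layers * lattice$layer_pitch
  rows <- lapply(seq_along(placements), function(k) {
    p <- placements[[k]]
    stopifnot(inherits(p, "marker_placement"))
    if (p$layer_index >= lattice$n_layers)
      stop("placement layer_index ", p$layer_index, " outside lattice (",
           lattice$n_layers, " layers)")
    if (p$cyl_x > nx - 2 || p$cyl_z > nz - 2)
      stop("placement cylinder (", p$cyl_x, ", ", p$cyl_z,
           ") outside footprint")
    x <- (p$cyl_x + 1) * lattice$stud_pitch - width / 2
    z <- (p$cyl_z + 1) * lattice$stud_pitch - depth / 2
    y_top <- (p$layer_index + 1) * lattice$layer_pitch
    y <- y_top - p$depth_fraction * marker_diameter - height / 2
    data.frame(id = k, x_mm = x, y_mm = y, z_mm = z)
  })
  markers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), x_mm = numeric(), y_mm = numeric(),
               z_mm = numeric())
  structure(list(markers = markers, marker_diameter = marker_diameter,
                 dims = c(width = width, height = height, depth = depth),
                 lattice = lattice,
                 placements = placements),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("phantom_model: %d markers (diameter %.3g mm), %0.4g x %0.4g x %0.4g mm (w x h x d)\n",
              nrow(x$markers), x$marker_diameter,
              x$dims["width"], x$dims["height"], x$dims["depth"]))
  print(x$markers)
  invisible(x)
}

phantom_marker_matrix <- function(phantom) {
  as.matrix(phantom$markers[, c("x_mm", "y_mm", "z_mm")])
}

#' Default five-marker calibration phantom
#'
#' Eight layers tall (76.2 mm), a single 6x2-brick footprint 47.7 mm wide,
#' and five markers in distinct layers placed towards the phantom facets so
#' their projection trajectories cover the detector field of view.
#'
#' @param lattice A [brick_lattice()]; defaults to the standard lattice.
#' @return A [build_phantom()] model with 5 markers.
#' @export
default_phantom <- function(lattice = brick_lattice()) {
  placements <- list(
    marker_placement(0, 0),
    marker_placement(2, 4),
    marker_placement(4, 0),
    marker_placement(6, 4),
    marker_placement(7, 1)
  )
  build_phantom(lattice, placements)
}

#' Check a phantom against the marker-placement rules
#'
#' Two rules: (a) no two markers may share a vertical brick layer (marker
#' projections would overlap near the half-turn view), an error-level
#' violation; (b) markers should lie close to the phantom facets to spread
#' their trajectories over the detector, a warning-level violation when the
#' horizontal distance from a marker to the nearest facet exceeds
#' \code{facet_fraction} of the larger footprint dimension.
#'
#' @param model A [build_phantom()] model.
#' @param lattice A [brick_lattice()]; defaults to the model's own.
#' @param facet_fraction Allowed facet distance as a fraction of the larger
#'   footprint side.
#' @return A data.frame of violations with columns \code{type} ("layer" or
#'   "facet"), \code{marker_ids}, \code{detail}; zero rows when compliant.
#' @export
validate_placement <- function(model, lattice = model$lattice,
                               facet_fraction = 0.25) {
  out <- list()
  layers <- vapply(model$placements, function(p) p$layer_index, integer(1))
  if (length(layers)) {
    dup <- split(seq_along(layers), layers)
    for (g in dup) {
      if (length(g) > 1) {
        out[[length(out) + 1]] <- data.frame(
          type = "layer",
          marker_ids = paste(g, collapse = ","),
          detail = sprintf("markers share layer %d",
                           layers[g[1]]))
      }
    }
  }
  width <- model$dims["width"]; depth <- model$dims["depth"]
  lim <- facet_fraction * max(width, depth)
  for (k in seq_len(nrow(model$markers))) {
    m <- model$markers[k, ]
    dist_facet <- min(width / 2 - abs(m$x_mm), depth / 2 - abs(m$z_mm))
    if (dist_facet > lim) {
      out[[length(out) + 1]] <- data.frame(
        type = "facet",
        marker_ids = as.character(m$id),
        detail = sprintf("marker %d is %.3g mm from the nearest facet (limit %.3g)",
                         m$id, dist_facet, lim))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(type = character(), marker_ids = character(),
               detail = character())
}
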