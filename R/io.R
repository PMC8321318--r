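#' Read and write 16-bit TIFF images
#'
#' Intensities in counts are scaled by \code{1/max_counts} into the unit
#' range expected by 16-bit TIFF and back on reading.
#'
#' @param img Numeric intensity matrix (counts).
#' @param path File path.
#' @param max_counts Full-scale value mapped to the maximum 16-bit code.
#' @return \code{read_image_tiff} returns the intensity matrix;
#'   \code{write_image_tiff} returns \code{path} invisibly.
#' @export
write_image_tiff <- function(img, path, max_counts = 65535) {
  x <- pmin(pmax(img / max_counts, 0), 1)
  tiff::writeTIFF(x, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, max_counts = 65535) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x * max_counts
}

# CSV writers/readers: UTF-8, LF, 17 significant digits for doubles.
write_table_csv <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]]))
      fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write measurement / truth tables as CSV
#'
#' The truth table written by [write_dataset()] and the measurement table
#' written here share a schema, so either can feed
#' [calibrate_geometry()].
#'
#' @param m A measurement table.
#' @param path CSV path.
#' @return The table (readers) or \code{path} invisibly (writers).
#' @export
write_measurements_csv <- function(m, path) {
  write_table_csv(m, path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- read_table_csv(path)
  if (!"valid" %in% names(df)) {
    df$valid <- if ("in_fov" %in% names(df)) as.logical(df$in_fov) else TRUE
  }
  df$valid <- as.logical(df$valid)
  df
}

pose_to_list <- function(p) {
  list(dx_mm = p$dx, dy_mm = p$dy, dz_mm = p$dz,
       theta_deg = p$theta, phi_deg = p$phi, eta_deg = p$eta)
}

pose_from_list <- function(l) {
  rigid_pose(l$dx_mm, l$dy_mm, l$dz_mm, l$theta_deg, l$phi_deg, l$eta_deg)
}

pair_to_list <- function(p) {
  list(sod_mm = p$sod, sdd_mm = p$sdd, dsod_mm = p$dsod,
       detector = list(n_u = p$detector_spec$n_u,
                       n_v = p$detector_spec$n_v,
                       pixel_size_mm = p$detector_spec$pixel_size),
       detector_pose = pose_to_list(p$detector_pose))
}

pair_from_list <- function(l) {
  source_detector_pair(l$sod_mm, l$sdd_mm,
                       detector_spec(l$detector$n_u, l$detector$n_v,
                                     l$detector$pixel_size_mm),
                       dsod = l$dsod_mm,
                       detector_pose = pose_from_list(l$detector_pose))
}

#' Read and write a stereo geometry as JSON
#'
#' All keys carry explicit unit suffixes (\code{sod_mm},
#' \code{alpha_deg}, ...). Round-trips are lossless to double precision.
#'
#' @param geom A [stereo_geometry()].
#' @param path JSON file path.
#' @return The geometry (reader) or \code{path} invisibly (writer).
#' @export
write_geometry_json <- function(geom, path) {
  obj <- list(pair1 = pair_to_list(geom$pair1),
              pair2 = pair_to_list(geom$pair2),
              alpha_deg = geom$alpha,
              phantom_pose = pose_to_list(geom$phantom_pose))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  stereo_geometry(pair_from_list(l$pair1), pair_from_list(l$pair2),
                  alpha = l$alpha_deg,
                  phantom_pose = pose_from_list(l$phantom_pose))
}

#' Read and write a phantom description as JSON, markers as CSV
#'
#' @param model A [build_phantom()] model.
#' @param path Output path (JSON description / CSV marker table).
#' @return The model (readers) or \code{path} invisibly (writers).
#' @export
write_phantom_json <- function(model, path) {
  l <- model$lattice
  obj <- list(
    lattice = list(stud_pitch_mm = l$stud_pitch,
                   layer_pitch_mm = l$layer_pitch,
                   n_layers = l$n_layers,
                   footprint_studs = l$footprint_studs),
    marker_diameter_mm = model$marker_diameter,
    placements = lapply(model$placements, function(p)
      list(layer_index = p$layer_index, cyl_x = p$cyl_x, cyl_z = p$cyl_z,
           depth_fraction = p$depth_fraction)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  lat <- brick_lattice(o$lattice$stud_pitch_mm, o$lattice$layer_pitch_mm,
                       o$lattice$n_layers,
                       unlist(o$lattice$footprint_studs))
  pl <- lapply(o$placements, function(p)
    marker_placement(p$layer_index, p$cyl_x, p$cyl_z, p$depth_fraction))
  build_phantom(lat, pl, o$marker_diameter_mm)
}

#' @rdname write_phantom_json
#' @export
write_marker_csv <- function(model, path) {
  write_table_csv(model$markers, path)
}

#' Read and write a calibration result as JSON
#'
#' Stores the estimated parameter vector (values, mask, bounds), the
#' per-stage cost history, a residual summary and the convergence state.
#' The reader restores the parameter vector and metadata (residual records
#' live in the companion CSV written by [cmd_calibrate()]).
#'
#' @param result A \code{calibration_result} from [calibrate_geometry()].
#' @param path JSON file path.
#' @return Reader: list with \code{beta}, \code{cost}, \code{converged},
#'   \code{outer_iterations}, \code{n_free}, \code{history}.
#' @export
write_result_json <- function(result, path) {
  b <- result$beta
  obj <- list(
    beta = as.list(b$values),
    units = as.list(b$units),
    fixed = names(b$values)[b$fixed],
    lower = as.list(b$lower),
    upper = as.list(b$upper),
    cost_mm = result$cost,
    converged = result$converged,
    outer_iterations = result$outer_iterations,
    n_free = result$n_free,
    history = result$history,
    residual_summary = list(
      n_records = nrow(result$residuals),
      median_mm = stats::median(result$residuals$residual_mm),
      max_mm = max(result$residuals$residual_mm)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- parameter_vector(unlist(o$beta),
                           lower = unlist(o$lower), upper = unlist(o$upper))
  if (length(o$fixed)) beta <- fix_parameters(beta, unlist(o$fixed))
  list(beta = beta, cost = o$cost_mm, converged = o$converged,
       outer_iterations = o$outer_iterations, n_free = o$n_free,
       history = o$history)
}

#' Write a run manifest
#'
#' Every command-line run records its inputs, outputs, seed, configuration
#' hash and tool version in one JSON manifest.
#'
#' @param path Manifest path.
#' @param command Command name.
#' @param inputs,outputs Character vectors of paths.
#' @param seed Integer seed or NULL.
#' @param config The configuration list used (hashed into the manifest).
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, command, inputs, outputs, seed = NULL,
                           config = NULL) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  obj <- list(command = command,
              tool = "stereocal",
              version = as.character(utils::packageVersion("stereocal")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed,
              inputs = as.list(inputs),
              outputs = as.list(outputs),
              config_hash = sprintf("%08x",
                                    sum(utf8ToInt(as.character(cfg_json)) *
                                          seq_len(nchar(cfg_json)) %% 97)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory containing \code{sys*_ang*.tif},
#'   \code{flat_sys*.tif} and \code{truth.csv}.
#' @param with_images Read the TIFF stacks (set FALSE to load only the
#'   truth table).
#' @return A list shaped like a [simulate_dataset()] result (without
#'   geometry/phantom).
#' @export
read_dataset <- function(dir, with_images = TRUE) {
  truth <- read_table_csv(file.path(dir, "truth.csv"))
  truth$in_fov <- as.logical(truth$in_fov)
  angles <- sort(unique(truth$angle_deg))
  images <- NULL; flat <- NULL
  if (with_images) {
    images <- lapply(c(1L, 2L), function(i)
      lapply(seq_along(angles) - 1L, function(n) {
        f <- file.path(dir, sprintf("sys%d_ang%04d.tif", i, n))
        if (file.exists(f)) read_image_tiff(f) else NULL
      }))
    flat <- lapply(c(1L, 2L), function(i) {
      f <- file.path(dir, sprintf("flat_sys%d.tif", i))
      if (file.exists(f)) read_image_tiff(f) else NULL
    })
  }
  list(images = images, flatfield = flat, truth = truth, angles = angles)
}
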