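#' Flatfield and log correction of a radiograph
#'
#' Converts raw transmission intensities to line integrals:
#' corrected = -ln((raw - dark) / (flat - dark)), with the dark frame
#' defaulting to zero. Output is clipped below at 0, so open-beam pixels
#' map to 0 and beads become positive peaks.
#'
#' @param raw,flat Numeric matrices of identical shape.
#' @param dark Optional dark frame (same shape); default 0.
#' @return Corrected image matrix (line-integral units).
#' @export
flatfield_log_correct <- function(raw, flat, dark = NULL) {
  if (is.null(dark)) dark <- 0 * raw
  if (!all(dim(raw) == dim(flat)) || !all(dim(raw) == dim(dark)))
    stop("raw, flat and dark images must have identical shapes")
  denom <- flat - dark
  if (any(denom <= 0))
    stop("flatfield must exceed the dark frame everywhere")
  tr <- (raw - dark) / denom
  out <- -log(pmax(tr, .Machine$double.eps))
  out[out < 0] <- 0
  out
}

#' Synthetic bead template
#'
#' Chord-length profile of a sphere of the given projected radius, sampled
#' at pixel centers: the expected line-integral footprint of a bead in a
#' corrected radiograph. Used as the matching template.
#'
#' @param radius_px Projected bead radius in pixels (>= 2).
#' @return A square odd-sized numeric matrix.
#' @export
bead_template <- function(radius_px) {
  stopifnot(radius_px >= 2)
  h <- ceiling(radius_px) + 2
  ax <- (-h):h
  rho2 <- outer(ax^2, ax^2, "+")
  t <- 2 * sqrt(pmax(radius_px^2 - rho2, 0))
  t
}

# 2D cross-correlation of image with template, "same" size, zero padding,
# template center aligned to each pixel. FFT-based.
xcorr2 <- function(img, tmpl) {
  H <- nrow(img); W <- ncol(img)
  h <- nrow(tmpl); w <- ncol(tmpl)
  PH <- H + h - 1L; PW <- W + w - 1L
  A <- matrix(0, PH, PW); A[1:H, 1:W] <- img
  B <- matrix(0, PH, PW)
  B[1:h, 1:w] <- tmpl[h:1, w:1]   # reversed template: conv == corr
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
    (PH * PW)
  r0 <- (h - 1L) / 2; c0 <- (w - 1L) / 2
  full[(1 + r0):(H + r0), (1 + c0):(W + c0)]
}

#' Find bead candidates by normalized cross-correlation
#'
#' Correlates the corrected image with a synthetic bead template
#' ([bead_template()]) under local normalization (zero-normalized cross
#' correlation), keeps peaks above \code{threshold}, and suppresses
#' non-maxima within one template diameter of a stronger peak.
#'
#' @param image Corrected image matrix (beads positive).
#' @param template_radius Expected projected bead radius in pixels (>= 2).
#' @param threshold Minimum correlation score in [0, 1); default 0.5.
#' @return data.frame with 0-based pixel coordinates \code{col},
#'   \code{row} and \code{score}, strongest first; zero rows when nothing
#'   matches.
#' @export
find_candidates <- function(image, template_radius, threshold = 0.5) {
  stopifnot(template_radius >= 2)
  tmpl <- bead_template(template_radius)
  n <- length(tmpl)
  tz <- tmpl - mean(tmpl)
  tnorm <- sqrt(sum(tz^2))
  ones <- matrix(1, nrow(tmpl), ncol(tmpl))
  s1 <- xcorr2(image, ones)
  s2 <- xcorr2(image * image, ones)
  num <- xcorr2(image, tz)
  varloc <- pmax(s2 - s1 * s1 / n, 0)
  sd <- sqrt(varloc)
  score <- num / (sd * tnorm)
  score[sd < 1e-12 * max(sd, 1e-300)] <- 0
  score[!is.finite(score)] <- 0

  hits <- which(score >= threshold, arr.ind = TRUE)
  if (nrow(hits) == 0)
    return(data.frame(col = numeric(), row = numeric(), score = numeric()))
  sc <- score[hits]
  o <- order(-sc)
  hits <- hits[o, , drop = FALSE]
  sc <- sc[o]
  keep <- logical(length(sc))
  min_d2 <- (2 * template_radius)^2
  acc_r <- numeric(0); acc_c <- numeric(0)
  for (i in seq_along(sc)) {
    if (length(acc_r) == 0 ||
        all((hits[i, 1] - acc_r)^2 + (hits[i, 2] - acc_c)^2 > min_d2)) {
      keep[i] <- TRUE
      acc_r <- c(acc_r, hits[i, 1]); acc_c <- c(acc_c, hits[i, 2])
    }
  }
  data.frame(col = hits[keep, 2] - 1, row = hits[keep, 1] - 1,
             score = sc[keep])
}

#' Sub-pixel center refinement by background-subtracted centroid
#'
#' Within a square window around the candidate, the background is taken as
#' the median of the window's one-pixel border ring, subtracted, clipped at
#' zero, and the intensity-weighted centroid computed.
#'
#' @param image Corrected image matrix (beads positive).
#' @param col,row Candidate center, 0-based pixel coordinates.
#' @param window_radius Half-width of the refinement window (pixels).
#' @return A list with \code{col}, \code{row} (0-based, fractional) and
#'   \code{valid}; invalid when the window is clipped by the image edge or
#'   contains no signal above background.
#' @export
refine_center <- function(image, col, row, window_radius) {
  r0 <- round(row); c0 <- round(col)
  rows <- (r0 - window_radius):(r0 + window_radius) + 1L
  cols <- (c0 - window_radius):(c0 + window_radius) + 1L
  if (min(rows) < 1 || min(cols) < 1 ||
      max(rows) > nrow(image) || max(cols) > ncol(image))
    return(list(col = NA_real_, row = NA_real_, valid = FALSE))
  win <- image[rows, cols]
  m <- nrow(win)
  ring <- c(win[1, ], win[m, ], win[2:(m - 1), 1], win[2:(m - 1), m])
  bg <- stats::median(ring)
  w <- pmax(win - bg, 0)
  tot <- sum(w)
  if (tot <= 1e-12)
    return(list(col = NA_real_, row = NA_real_, valid = FALSE))
  rr <- rowSums(w) ; cc <- colSums(w)
  off <- (-window_radius):window_radius
  list(col = c0 + sum(off * cc) / tot,
       row = r0 + sum(off * rr) / tot,
       valid = TRUE)
}

#' Assign detected candidates to markers across all views
#'
#' For every (system, angle) view the detected candidates are put in
#' one-to-one correspondence with the markers via the model predictions of
#' an initial geometry: the assignment minimizing the total candidate to
#' predicted-position distance (optimal bipartite assignment, Hungarian
#' method) is computed, and pairs farther apart than the gating radius are
#' dropped. Markers whose predicted projections approach each other within
#' the gating radius in a view are ambiguous there (the beads overlap on
#' the detector and no deblending is attempted) and are dropped for that
#' view only. Every (system, angle, marker) triple yields a record;
#' unmatched or gated markers get \code{valid = FALSE}.
#'
#' @param candidates data.frame of refined candidates with columns
#'   \code{system}, \code{angle_index}, \code{angle_deg}, \code{col},
#'   \code{row} (0-based pixels) and optionally \code{score}.
#' @param predicted Reference table from [project_all()] under the initial
#'   geometry.
#' @param spec1,spec2 [detector_spec()] per system, for the px/mm
#'   conversion.
#' @param gate_px Gating radius in pixels.
#' @return A measurement table (coordinates in mm) with columns
#'   \code{system}, \code{angle_index}, \code{angle_deg},
#'   \code{marker_id}, \code{u_mm}, \code{v_mm}, \code{u_px},
#'   \code{v_px}, \code{valid}, \code{score}.
#' @export
match_correspondences <- function(candidates, predicted, spec1, spec2,
                                  gate_px = Inf) {
  views <- unique(predicted[, c("system", "angle_index", "angle_deg")])
  out <- vector("list", nrow(views))
  for (vi in seq_len(nrow(views))) {
    s <- views$system[vi]; n <- views$angle_index[vi]
    spec <- if (s == 1L) spec1 else spec2
    pred <- predicted[predicted$system == s & predicted$angle_index == n, ]
    cand <- candidates[candidates$system == s &
                         candidates$angle_index == n, , drop = FALSE]
    rec <- data.frame(system = s, angle_index = n,
                      angle_deg = views$angle_deg[vi],
                      marker_id = pred$marker_id,
                      u_mm = NA_real_, v_mm = NA_real_,
                      u_px = NA_real_, v_px = NA_real_,
                      valid = FALSE, score = NA_real_)
    usable <- pred$in_fov & pred$valid
    if (any(usable) && is.finite(gate_px)) {
      # overlap veto: predictions closer than the gate are ambiguous
      apx <- mm_to_px(pred$u_mm[usable], pred$v_mm[usable], spec)
      if (nrow(apx) > 1) {
        DD <- as.matrix(stats::dist(cbind(apx$col, apx$row)))
        diag(DD) <- Inf
        usable[usable] <- apply(DD, 1, min) > gate_px
      }
    }
    if (nrow(cand) > 0 && any(usable)) {
      ppx <- mm_to_px(pred$u_mm[usable], pred$v_mm[usable], spec)
      D <- sqrt(outer(ppx$col, cand$col, "-")^2 +
                  outer(ppx$row, cand$row, "-")^2)
      D <- matrix(D, nrow = sum(usable))
      nm <- nrow(D); nc <- ncol(D)
      if (nm <= nc) {
        sol <- as.integer(clue::solve_LSAP(D))
        mk <- seq_len(nm); cd <- sol
      } else {
        sol <- as.integer(clue::solve_LSAP(t(D)))
        cd <- seq_len(nc); mk <- sol
      }
      widx <- which(usable)
      for (j in seq_along(mk)) {
        if (D[mk[j], cd[j]] <= gate_px) {
          i <- widx[mk[j]]
          mmv <- px_to_mm(cand$col[cd[j]], cand$row[cd[j]], spec)
          rec$u_mm[i] <- mmv$u_mm; rec$v_mm[i] <- mmv$v_mm
          rec$u_px[i] <- cand$col[cd[j]]; rec$v_px[i] <- cand$row[cd[j]]
          rec$valid[i] <- TRUE
          rec$score[i] <- if ("score" %in% names(cand))
            cand$score[cd[j]] else NA_real_
        }
      }
    }
    out[[vi]] <- rec
  }
  res <- do.call(rbind, out)
  res[order(res$system, res$angle_index, res$marker_id), ]
}

#' Detect marker centers in a simulated or loaded dataset
#'
#' The full measurement pipeline: flatfield/log correction, template
#' matching, sub-pixel centroid refinement, and correspondence assignment
#' against the projections predicted by an initial geometry.
#'
#' @param ds A [simulate_dataset()] result with images (or an equivalent
#'   list built by [read_dataset()]).
#' @param geom_init Initial [stereo_geometry()] used to predict marker
#'   positions for the correspondence step.
#' @param phantom The [build_phantom()] model.
#' @param template_radius Projected bead radius in pixels; default derived
#'   from the nominal magnification sdd/sod and the marker diameter.
#' @param threshold Candidate score threshold.
#' @param gate_factor Gating radius in units of the template radius
#'   (default 5).
#' @param window_radius Refinement window half-width; default
#'   template_radius + 2 px.
#' @return A measurement table as from [match_correspondences()].
#' @export
detect_dataset <- function(ds, geom_init, phantom, template_radius = NULL,
                           threshold = 0.5, gate_factor = 5,
                           window_radius = NULL) {
  if (is.null(ds$images))
    stop("dataset contains no images (exact_centers mode?)")
  cand_all <- list()
  for (i in c(1L, 2L)) {
    pair <- geometry_pair(geom_init, i)
    tr <- template_radius
    if (is.null(tr))
      tr <- max(2, phantom$marker_diameter / 2 * pair$sdd / pair$sod /
                  pair$detector_spec$pixel_size)
    wr <- if (is.null(window_radius)) ceiling(tr) + 2 else window_radius
    flat <- ds$flatfield[[i]]
    for (n in seq_along(ds$angles)) {
      cor <- flatfield_log_correct(ds$images[[i]][[n]], flat)
      cand <- find_candidates(cor, tr, threshold)
      if (nrow(cand) == 0) next
      ref <- lapply(seq_len(nrow(cand)), function(j)
        refine_center(cor, cand$col[j], cand$row[j], wr))
      ok <- vapply(ref, `[[`, logical(1), "valid")
      if (!any(ok)) next
      cand_all[[length(cand_all) + 1]] <- data.frame(
        system = i, angle_index = n - 1L, angle_deg = ds$angles[n],
        col = vapply(ref[ok], `[[`, numeric(1), "col"),
        row = vapply(ref[ok], `[[`, numeric(1), "row"),
        score = cand$score[ok])
    }
  }
  candidates <- if (length(cand_all)) do.call(rbind, cand_all) else
    data.frame(system = integer(), angle_index = integer(),
               angle_deg = numeric(), col = numeric(), row = numeric(),
               score = numeric())
  predicted <- project_all(geom_init, phantom, ds$angles)
  tr1 <- if (is.null(template_radius))
    max(2, phantom$marker_diameter / 2 * geom_init$pair1$sdd /
          geom_init$pair1$sod / geom_init$pair1$detector_spec$pixel_size)
  else template_radius
  match_correspondences(candidates, predicted,
                        geom_init$pair1$detector_spec,
                        geom_init$pair2$detector_spec,
                        gate_px = gate_factor * tr1)
}
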