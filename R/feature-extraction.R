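#' Segment a single frame
#'
#' The cell appears dark on a bright background. The frame is thresholded
#' (Otsu or fixed), the largest connected foreground component is kept with
#' holes filled, and a sub-pixel closed contour is taken as the iso-intensity
#' line of the image at the threshold level around that component. A blank
#' frame is signalled distinctly (not an error) so callers can drop the
#' event with a logged reason.
#'
#' @param image Numeric matrix with finite intensities (values in `[0, 1]`).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Required when `method = "fixed"`.
#' @return A list of class `segmentation`: `ok` (logical), `reason` (when not
#'   ok), `mask` (binary matrix), `contour` (n x 2 matrix of sub-pixel
#'   (x = col, y = row) points), `threshold`, `area_px`, `centroid`.
#' @export
segment_frame <- function(image, method = c("otsu", "fixed"),
                          threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image) || !all(is.finite(image)))
    stopf("image must be a finite numeric matrix")
  th <- if (method == "otsu") {
    rng <- range(image)
    if (diff(rng) < 1e-6)
      return(structure(list(ok = FALSE, reason = "no_cell"),
                       class = "segmentation"))
    EBImage::otsu(EBImage::Image(image), range = rng)
  } else {
    if (is.null(threshold)) stopf("fixed method requires a threshold")
    threshold
  }
  fg <- image < th                      # dark cell on bright background
  if (!any(fg))
    return(structure(list(ok = FALSE, reason = "no_cell"),
                     class = "segmentation"))
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- EBImage::fillHull(lab == keep)
  mask <- matrix(as.numeric(mask) > 0, nrow(image), ncol(image))

  contour <- iso_contour(image, th, mask)
  if (is.null(contour))
    return(structure(list(ok = FALSE, reason = "no_contour"),
                     class = "segmentation"))
  pm <- polygon_moments(contour)
  structure(list(ok = TRUE, mask = mask, contour = contour, threshold = th,
                 area_px = pm$area, centroid = pm$centroid),
            class = "segmentation")
}

# Sub-pixel closed contour of `image` at iso-level `th`, chosen as the
# closed contour line of largest enclosed area whose centroid lies in the
# foreground mask. Coordinates are (x = col, y = row) in pixel units.
iso_contour <- function(image, th, mask) {
  cl <- grDevices::contourLines(x = seq_len(nrow(image)),
                                y = seq_len(ncol(image)),
                                z = image, levels = th)
  if (!length(cl)) return(NULL)
  best <- NULL; best_area <- 0
  for (cc in cl) {
    # contourLines returns x along rows, y along cols; recast as (col, row)
    poly <- cbind(cc$y, cc$x)
    if (nrow(poly) < 8L) next
    closed <- sqrt(sum((poly[1L, ] - poly[nrow(poly), ])^2)) < 2
    if (!closed) next
    a <- abs(polygon_area(poly))
    if (a > best_area) { best_area <- a; best <- poly }
  }
  if (is.null(best)) return(NULL)
  # drop duplicated closing vertex if present
  if (sqrt(sum((best[1L, ] - best[nrow(best), ])^2)) < 1e-9)
    best <- best[-nrow(best), , drop = FALSE]
  best
}

#' Radial boundary trace of a closed contour
#'
#' Transforms a closed boundary from Cartesian to polar coordinates about
#' its area centroid: the radius r(theta) is sampled at `n_angles` uniformly
#' spaced angles by casting rays from the centroid and linearly
#' interpolating along the intersected contour edge. The shape is assumed
#' star-convex about its centroid (true for the near-elliptical cells this
#' trace is built for); a centroid outside the contour is signalled as a
#' degenerate shape.
#'
#' @param contour n x 2 matrix of ordered boundary points (closed implicitly).
#' @param n_angles Number of uniformly spaced angles in `[0, 2*pi)`.
#' @return A list of class `boundary_trace`: `centroid`, `theta`, `radii`,
#'   `n_angles`.
#' @export
contour_to_trace <- function(contour, n_angles = 360L) {
  stopifnot(is.matrix(contour), ncol(contour) == 2L)
  if (nrow(contour) < 8L) stopf("contour must have at least 8 points")
  pm <- polygon_moments(contour)
  ctr <- pm$centroid
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  p1 <- contour
  p2 <- contour[c(2:nrow(contour), 1L), , drop = FALSE]
  ex <- p1[, 1L] - ctr[1L]; ey <- p1[, 2L] - ctr[2L]
  dx <- p2[, 1L] - p1[, 1L]; dy <- p2[, 2L] - p1[, 2L]
  radii <- vapply(theta, function(th) {
    ux <- cos(th); uy <- sin(th)
    den <- dx * uy - dy * ux
    ok <- abs(den) > 1e-12
    s <- (ey * ux - ex * uy) / den          # position along the edge
    r <- (dx[ok] * ey[ok] - dy[ok] * ex[ok]) / den[ok]  # distance along ray
    hit <- ok
    hit[ok] <- s[ok] >= -1e-9 & s[ok] <= 1 + 1e-9 & r > 1e-9
    if (!any(hit)) return(NA_real_)
    max((dx * ey - dy * ex)[hit] / den[hit])
  }, 0)
  if (anyNA(radii))
    stopf("degenerate shape: centroid not star-visible from the boundary")
  structure(list(centroid = ctr, theta = theta, radii = radii,
                 n_angles = as.integer(n_angles)),
            class = "boundary_trace")
}

#' Polygon reconstructed from a boundary trace
#'
#' @param trace A `boundary_trace`.
#' @return n x 2 matrix of (x, y) vertices.
#' @export
trace_to_polygon <- function(trace) {
  cbind(trace$centroid[1L] + trace$radii * cos(trace$theta),
        trace$centroid[2L] + trace$radii * sin(trace$theta))
}

#' Deformability of a segmented shape
#'
#' The ratio of major to minor axis lengths of the ellipse with the same
#' second central moments of area as the shape. Computed exactly from the
#' closed contour polygon, so it is rotation invariant and robust to
#' boundary pixelation.
#'
#' @param shape A `segmentation`, a `boundary_trace`, or an n x 2 contour
#'   matrix.
#' @return Dimensionless ratio >= 1.
#' @export
deformability <- function(shape) {
  poly <- shape_polygon(shape)
  mu <- polygon_moments(poly)$mu
  ev <- eigen(mu, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] <= 0) stopf("degenerate shape: zero-variance axis")
  sqrt(ev[1L] / ev[2L])
}

shape_polygon <- function(shape) {
  if (inherits(shape, "segmentation")) {
    if (!isTRUE(shape$ok)) stopf("cannot use a failed segmentation")
    shape$contour
  } else if (inherits(shape, "boundary_trace")) {
    trace_to_polygon(shape)
  } else if (is.matrix(shape) && ncol(shape) == 2L) {
    shape
  } else stopf("unsupported shape object")
}

# Moment-equivalent major axis length (same units as the polygon coords).
major_axis_length <- function(poly) {
  mu <- polygon_moments(poly)$mu
  4 * sqrt(eigen(mu, symmetric = TRUE, only.values = TRUE)$values[1L])
}

#' Boundary morphology metrics from a radial trace
#'
#' The trace r(theta) is compared against its circular (wrap-around) moving
#' average: roughness is `SD(r - moving_average) / mean(r)` and the
#' intersection count is the number of sign changes of the residual over the
#' closed trace, a transition through exact zero counting once. A k-lobed
#' boundary perturbation yields 2k intersections. Both metrics are invariant
#' to the starting angle.
#'
#' @param trace A `boundary_trace` (or bare numeric vector of radii).
#' @param window Odd moving-average window, `3 <= window <= n_angles / 2`.
#' @return Named numeric vector `c(roughness, intersections)`.
#' @export
morphology_metrics <- function(trace, window = 31L) {
  r <- if (inherits(trace, "boundary_trace")) trace$radii else as.numeric(trace)
  morphology_metrics_radii(r, window)
}

morphology_metrics_radii <- function(r, window) {
  n <- length(r)
  if (window %% 2L != 1L) stopf("window must be odd")
  if (window < 3L || window > n / 2) stopf("window must be in [3, n/2]")
  half <- (window - 1L) %/% 2L
  padded <- c(r[(n - half + 1L):n], r, r[1L:half])
  ma <- stats::filter(padded, rep(1 / window, window), sides = 2L)
  ma <- as.numeric(ma[(half + 1L):(half + n)])
  resid <- r - ma
  rough <- stats::sd(resid) / mean(r)
  s <- sign(resid)
  s <- s[s != 0]
  crossings <- if (length(s) < 2L) 0L else sum(s != c(s[-1L], s[1L]))
  c(roughness = rough, intersections = as.integer(crossings))
}

#' Extract the 15-parameter biophysical profile of one cell event
#'
#' Segments every frame, computes per-frame moment-equivalent ellipse axes,
#' and applies the canonical parameter definitions: size and circularity
#' from the pre-junction frames, deformability at arrival / mean / max /
#' final, time-to-maximum-deformability, maximum strain rate, maximum and
#' residual strain, morphology metrics from the last pre-junction frame and
#' the maximum-deformation frame, and the area ratio. Junction residence is
#' taken from `junction_exit_index` when the event carries one; otherwise it
#' runs from arrival to the maximum-deformability frame.
#'
#' @param event A `cell_event`.
#' @param window Odd moving-average window for the morphology metrics.
#' @param min_segmented Minimum fraction of frames that must segment for the
#'   event to be accepted.
#' @return Named numeric vector over `DC_PARAMETERS` with attribute
#'   `event_id`. Rejected events raise a condition of class
#'   `defcyto_rejected` whose message carries the reason code.
#' @export
extract_profile <- function(event, window = 31L, min_segmented = 0.8) {
  stopifnot(inherits(event, "cell_event"))
  nf <- length(event$frames)
  j0 <- event$junction_arrival_index          # 0-based
  if (j0 < 1L || j0 >= nf)
    reject(event$event_id, "no_pre_or_junction_frames")
  segs <- lapply(event$frames, function(f) {
    tryCatch(segment_frame(f), error = function(e)
      structure(list(ok = FALSE, reason = conditionMessage(e)),
                class = "segmentation"))
  })
  ok <- vapply(segs, function(s) isTRUE(s$ok), NA)
  if (mean(ok) < min_segmented)
    reject(event$event_id, "too_many_failed_segmentations")
  if (!all(ok[(j0 + 1L):nf]) || !any(ok[1:j0]))
    reject(event$event_id, "segmentation_failed_on_required_frame")

  px <- event$pixel_size
  area_um2 <- vapply(segs, function(s)
    if (isTRUE(s$ok)) s$area_px * px^2 else NA_real_, 0)
  major_um <- vapply(segs, function(s)
    if (isTRUE(s$ok)) major_axis_length(s$contour) * px else NA_real_, 0)
  D <- vapply(segs, function(s)
    if (isTRUE(s$ok)) deformability(s) else NA_real_, 0)

  pre <- which(ok[1:j0])                      # 1-based indices of pre frames
  A <- stats::median(2 * sqrt(area_um2[pre] / pi))
  perim_um <- vapply(segs[pre], function(s)
    polygon_perimeter(s$contour) * px, 0)
  C1 <- stats::median(4 * pi * area_um2[pre] / perim_um^2)

  strain <- (major_um - A) / A
  exit0 <- event$junction_exit_index          # 0-based, optional
  if (is.null(exit0)) {
    # fall back: junction residence ends at the deformability peak
    rel <- (j0 + 1L):nf
    exit0 <- rel[which.max(D[rel])] - 1L
  }
  jun <- (j0 + 1L):(min(exit0, nf - 1L) + 1L) # 1-based junction frames
  i_d3 <- jun[which.max(D[jun])]
  dt <- event$frame_interval
  dD <- diff(strain[jun]) / dt
  profile <- c(
    A = A, C1 = C1,
    D1 = D[j0 + 1L], D2 = mean(D[jun]), D3 = D[i_d3], D4 = D[nf],
    T1 = (i_d3 - (j0 + 1L)) * dt,
    T2 = if (length(dD)) max(dD) else 0,
    S1 = max(strain[jun]), S2 = strain[nf],
    M1 = NA_real_, M2 = NA_real_, M3 = NA_real_, M4 = NA_real_,
    AR1 = area_um2[i_d3] / stats::median(area_um2[pre]))
  tr_pre <- contour_to_trace(segs[[pre[length(pre)]]]$contour)
  tr_d3 <- contour_to_trace(segs[[i_d3]]$contour)
  m_pre <- morphology_metrics(tr_pre, window)
  m_d3 <- morphology_metrics(tr_d3, window)
  profile[c("M1", "M2")] <- m_pre
  profile[c("M3", "M4")] <- m_d3
  attr(profile, "event_id") <- event$event_id
  profile
}

reject <- function(event_id, reason) {
  cond <- structure(class = c("defcyto_rejected", "error", "condition"),
                    list(message = reason, call = NULL,
                         event_id = event_id))
  stop(cond)
}

#' Extract profiles for a batch of events
#'
#' @param events List of `cell_event` objects.
#' @param window Odd moving-average window passed to [extract_profile()].
#' @return A feature table (data frame) with `event_id` plus the 15
#'   parameters, one row per accepted event in input order; rejected events
#'   are recorded in attribute `rejections` (data frame of `event_id`,
#'   `reason`). Warns when every event is rejected.
#' @export
batch_extract <- function(events, window = 31L) {
  stopifnot(length(events) >= 1L)
  rows <- list(); rej <- list()
  for (ev in events) {
    prof <- tryCatch(extract_profile(ev, window = window),
                     defcyto_rejected = function(c) c)
    if (inherits(prof, "defcyto_rejected")) {
      rej[[length(rej) + 1L]] <- data.frame(event_id = prof$event_id,
                                            reason = conditionMessage(prof))
    } else {
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(event_id = attr(prof, "event_id")),
              as.data.frame(as.list(prof)))
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(event_id = character(0)),
          as.data.frame(matrix(numeric(0), 0L, length(DC_PARAMETERS),
                               dimnames = list(NULL, DC_PARAMETERS))))
  rownames(tab) <- NULL
  if (!length(rows)) warnf("all %d events were rejected", length(events))
  attr(tab, "rejections") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(event_id = character(0), reason = character(0))
  tab
}
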