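#' Specify a synthetic viscoelastic cell
#'
#' A cell is modelled as an incompressible ellipse undergoing Kelvin--Voigt
#' creep: while it resides in the extensional-flow junction the major-axis
#' strain grows as \eqn{\epsilon(t) = \epsilon_{max}(1 - e^{-t/\tau})}, and
#' after exit it relaxes as
#' \eqn{\epsilon(t) = \epsilon_{exit}[(1 - \rho) + \rho e^{-t/\tau_r}]}
#' where \eqn{\rho} is the recoverable fraction of the attained strain.
#' Area is conserved (the minor axis shrinks as the major grows), so a strain
#' \eqn{\epsilon} corresponds to a deformability \eqn{D = (1+\epsilon)^2}.
#' Static low-order Fourier modes on the radial boundary function give
#' analytic control over the morphology (roughness / intersection) metrics.
#'
#' @param initial_diameter Undeformed equivalent diameter in micrometres.
#' @param max_strain Asymptotic creep strain \eqn{\epsilon_{max} \ge 0}.
#' @param creep_time Creep time constant \eqn{\tau} in microseconds (> 0).
#'   Stretch timescales in the junction are of order a few microseconds.
#' @param recovery_fraction Fraction of the attained strain that relaxes
#'   after exit, in `[0, 1]`. `1` means fully elastic recovery.
#' @param recovery_time Relaxation time constant in microseconds (> 0).
#' @param boundary_modes List of `c(k, amplitude)` pairs: angular frequency
#'   `k >= 2` and amplitude as a fraction of the local radius (< 0.3 so the
#'   boundary stays simple and star-convex).
#' @param rng_seed Integer seed used when the event is rendered with noise.
#' @return An object of class `viscoelastic_cell_spec`.
#' @export
viscoelastic_cell_spec <- function(initial_diameter = 15,
                                   max_strain = 0.5,
                                   creep_time = 2,
                                   recovery_fraction = 0.8,
                                   recovery_time = 4,
                                   boundary_modes = list(),
                                   rng_seed = 1L) {
  if (initial_diameter <= 0) stopf("initial_diameter must be positive")
  if (max_strain < 0) stopf("max_strain must be nonnegative")
  if (creep_time <= 0) stopf("creep_time must be positive")
  if (recovery_time <= 0) stopf("recovery_time must be positive")
  if (recovery_fraction < 0 || recovery_fraction > 1)
    stopf("recovery_fraction must lie in [0, 1]")
  for (m in boundary_modes) {
    if (length(m) != 2L || m[1L] < 2 || m[1L] != round(m[1L]))
      stopf("boundary mode frequency must be an integer >= 2")
    if (abs(m[2L]) >= 0.3)
      stopf("boundary mode amplitude must be < 0.3 of the radius")
  }
  structure(list(initial_diameter = initial_diameter,
                 max_strain = max_strain,
                 creep_time = creep_time,
                 recovery_fraction = recovery_fraction,
                 recovery_time = recovery_time,
                 boundary_modes = boundary_modes,
                 rng_seed = as.integer(rng_seed)),
            class = "viscoelastic_cell_spec")
}

#' Specify how an event is rendered to frames
#'
#' @param pixel_size Micrometres per pixel; must leave the cell at least
#'   10 px across for segmentability.
#' @param frame_interval Microseconds between frames.
#' @param n_pre_frames,n_junction_frames,n_post_frames Frame counts before,
#'   during and after junction residence (each >= 1).
#' @param psf_sigma Gaussian point-spread sigma in pixels (0 disables blur).
#' @param noise_sd Additive Gaussian noise SD as a fraction of the intensity
#'   range.
#' @param image_shape Integer `c(rows, cols)` of each frame.
#' @param initial_diameter_hint Diameter (micrometres) used to validate the
#'   10 px segmentability floor at construction time.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(pixel_size = 0.4,
                        frame_interval = 1,
                        n_pre_frames = 3L,
                        n_junction_frames = 6L,
                        n_post_frames = 3L,
                        psf_sigma = 1,
                        noise_sd = 0.02,
                        image_shape = c(96L, 96L),
                        initial_diameter_hint = 15) {
  counts <- c(n_pre_frames, n_junction_frames, n_post_frames)
  if (any(counts < 1L)) stopf("all frame counts must be >= 1")
  if (pixel_size <= 0) stopf("pixel_size must be positive")
  if (initial_diameter_hint / pixel_size < 10)
    stopf("pixel_size too coarse: cell diameter would be < 10 px")
  if (any(image_shape < 8L)) stopf("image_shape too small")
  structure(list(pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 n_pre_frames = as.integer(n_pre_frames),
                 n_junction_frames = as.integer(n_junction_frames),
                 n_post_frames = as.integer(n_post_frames),
                 psf_sigma = psf_sigma,
                 noise_sd = noise_sd,
                 image_shape = as.integer(image_shape)),
            class = "render_spec")
}

# Creep strain during junction residence, t in microseconds from arrival.
creep_strain <- function(t, max_strain, creep_time) {
  max_strain * (1 - exp(-t / creep_time))
}

# Relaxation strain, t in microseconds from junction exit.
relax_strain <- function(t, strain_exit, recovery_fraction, recovery_time) {
  strain_exit * ((1 - recovery_fraction) +
                   recovery_fraction * exp(-t / recovery_time))
}

#' Simulate the per-frame shape trajectory of a cell event
#'
#' Evaluates the creep/recovery law at every frame time and returns the
#' axis lengths of the area-conserving ellipse. Pre-junction frames carry
#' zero strain; junction frames follow the creep law with time measured from
#' arrival; post-junction frames relax from the exit strain toward the
#' unrecovered residual.
#'
#' @param spec A [viscoelastic_cell_spec()].
#' @param render A [render_spec()].
#' @return A data frame with one row per frame: `frame` (0-based index),
#'   `time_us`, `phase` (`"pre"`, `"junction"`, `"post"`), `strain`,
#'   `major_um` and `minor_um` (full axis lengths). The boundary modes are
#'   attached as attribute `boundary_modes`.
#' @export
simulate_trajectory <- function(spec, render) {
  stopifnot(inherits(spec, "viscoelastic_cell_spec"),
            inherits(render, "render_spec"))
  n_pre <- render$n_pre_frames
  n_jun <- render$n_junction_frames
  n_post <- render$n_post_frames
  n <- n_pre + n_jun + n_post
  idx <- seq_len(n) - 1L
  phase <- rep(c("pre", "junction", "post"), times = c(n_pre, n_jun, n_post))
  dt <- render$frame_interval
  strain <- numeric(n)
  jun <- which(phase == "junction")
  t_jun <- (jun - jun[1L]) * dt
  strain[jun] <- creep_strain(t_jun, spec$max_strain, spec$creep_time)
  strain_exit <- strain[jun[length(jun)]]
  post <- which(phase == "post")
  if (length(post)) {
    t_post <- (post - jun[length(jun)]) * dt
    strain[post] <- relax_strain(t_post, strain_exit,
                                 spec$recovery_fraction, spec$recovery_time)
  }
  a0 <- spec$initial_diameter / 2
  major <- a0 * (1 + strain)          # semi-axes; area pi*a*b conserved
  minor <- a0^2 / major
  out <- data.frame(frame = idx, time_us = idx * dt, phase = phase,
                    strain = strain, major_um = 2 * major,
                    minor_um = 2 * minor, stringsAsFactors = FALSE)
  attr(out, "boundary_modes") <- spec$boundary_modes
  attr(out, "spec") <- spec
  out
}

# Radius of the perturbed ellipse boundary at angles theta (radians), for
# semi-axes a, b and Fourier boundary modes. Units follow a and b.
boundary_radius <- function(theta, a, b, modes) {
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (length(modes)) {
    pert <- rep(0, length(theta))
    for (m in modes) pert <- pert + m[2L] * sin(m[1L] * theta)
    r <- r * (1 + pert)
  }
  r
}

# Dense polygon sampled from the continuous boundary of one trajectory frame,
# in micrometres, centred at the origin, major axis along x.
frame_boundary_polygon <- function(traj_row, modes, n_vertices = 2048L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- boundary_radius(theta, traj_row$major_um / 2, traj_row$minor_um / 2,
                       modes)
  cbind(r * cos(theta), r * sin(theta))
}

# Ground-truth biophysical profile computed from the continuous (noise-free)
# shapes of a trajectory, using dense polygon quadrature rather than pixels.
trajectory_ground_truth <- function(traj, render, window = 31L,
                                    n_angles = 360L) {
  modes <- attr(traj, "boundary_modes")
  dt <- render$frame_interval
  pre <- which(traj$phase == "pre")
  jun <- which(traj$phase == "junction")
  n <- nrow(traj)

  shape_stats <- function(i) {
    pm <- polygon_moments(frame_boundary_polygon(traj[i, ], modes))
    ev <- eigen(pm$mu, symmetric = TRUE, only.values = TRUE)$values
    list(area = pm$area,
         perim = polygon_perimeter(frame_boundary_polygon(traj[i, ], modes)),
         D = sqrt(ev[1L] / ev[2L]),
         major = 4 * sqrt(ev[1L]))
  }
  st <- lapply(seq_len(n), shape_stats)
  area <- vapply(st, `[[`, 0, "area")
  D <- vapply(st, `[[`, 0, "D")
  major <- vapply(st, `[[`, 0, "major")

  A <- stats::median(2 * sqrt(area[pre] / pi))
  C1 <- stats::median(4 * pi * area[pre] /
                        vapply(st[pre], `[[`, 0, "perim")^2)
  strain <- (major - A) / A
  i_d3 <- jun[which.max(D[jun])]
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  trace_of <- function(i) {
    boundary_radius(theta, traj$major_um[i] / 2, traj$minor_um[i] / 2, modes)
  }
  m_pre <- morphology_metrics_radii(trace_of(pre[length(pre)]), window)
  m_d3 <- morphology_metrics_radii(trace_of(i_d3), window)
  profile <- c(A = A, C1 = C1,
               D1 = D[jun[1L]], D2 = mean(D[jun]), D3 = D[i_d3], D4 = D[n],
               T1 = (i_d3 - jun[1L]) * dt,
               T2 = max(diff(strain[jun]) / dt, 0),
               S1 = max(strain[jun]), S2 = strain[n],
               M1 = m_pre[["roughness"]], M2 = m_pre[["intersections"]],
               M3 = m_d3[["roughness"]], M4 = m_d3[["intersections"]],
               AR1 = area[i_d3] / stats::median(area[pre]))
  profile
}

#' Render a simulated trajectory to a noisy frame stack
#'
#' Each frame rasterizes the filled perturbed ellipse (dark cell on a bright
#' background, fixed contrast 0.6) with 2x2 subpixel coverage sampling,
#' blurs it with a Gaussian point-spread function and adds Gaussian noise.
#' The event carries a ground-truth profile computed analytically from the
#' continuous, noise-free shapes.
#'
#' @param traj Output of [simulate_trajectory()].
#' @param render A [render_spec()].
#' @param seed Integer noise seed; the same seed yields bit-identical frames.
#' @param event_id Identifier stored on the event.
#' @return A `cell_event`: list with `frames` (list of matrices in `[0, 1]`),
#'   `frame_interval`, `pixel_size`, `junction_arrival_index`,
#'   `junction_exit_index` (0-based) and `ground_truth`.
#' @export
render_event <- function(traj, render, seed = 1L, event_id = "event") {
  stopifnot(inherits(render, "render_spec"), nrow(traj) >= 1L)
  modes <- attr(traj, "boundary_modes")
  shape <- render$image_shape
  px <- render$pixel_size
  ctr <- (shape + 1) / 2                      # image centre, pixel coords
  max_r_px <- max(traj$major_um) / 2 / px * (1 + 0.3)
  if (max_r_px + 3 * render$psf_sigma + 1 > min(shape) / 2)
    stopf("cell exceeds image bounds: enlarge image_shape or pixel_size")

  # subpixel sample offsets for 2x2 coverage sampling
  offs <- c(-0.25, 0.25)
  rows <- seq_len(shape[1L]); cols <- seq_len(shape[2L])
  frames <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(nrow(traj)), function(i) {
      a <- traj$major_um[i] / 2 / px
      b <- traj$minor_um[i] / 2 / px
      cov <- matrix(0, shape[1L], shape[2L])
      for (dy in offs) for (dx in offs) {
        x <- outer(rep(1, shape[1L]), cols + dx - ctr[2L])   # x along cols
        y <- outer(rows + dy - ctr[1L], rep(1, shape[2L]))
        th <- atan2(y, x)
        rr <- sqrt(x^2 + y^2)
        cov <- cov + (rr <= boundary_radius(th, a, b, modes))
      }
      img <- 1 - 0.6 * cov / 4
      if (render$psf_sigma > 0)
        img <- matrix(EBImage::imageData(
          EBImage::gblur(EBImage::Image(img), sigma = render$psf_sigma)),
          nrow(img), ncol(img))
      if (render$noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, render$noise_sd),
                            nrow(img), ncol(img))
      pmin(pmax(img, 0), 1)
    })
  })
  gt <- trajectory_ground_truth(traj, render)
  structure(list(event_id = event_id,
                 frames = frames,
                 frame_interval = render$frame_interval,
                 pixel_size = px,
                 junction_arrival_index = render$n_pre_frames,
                 junction_exit_index =
                   render$n_pre_frames + render$n_junction_frames - 1L,
                 ground_truth = gt),
            class = "cell_event")
}

#' @export
print.cell_event <- function(x, ...) {
  cat(sprintf("<cell_event %s: %d frames %dx%d, %.2f um/px, %.2f us/frame>\n",
              x$event_id, length(x$frames), nrow(x$frames[[1L]]),
              ncol(x$frames[[1L]]), x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Simulate and render one cell event in a single call
#'
#' @inheritParams render_event
#' @param spec A [viscoelastic_cell_spec()].
#' @param render A [render_spec()].
#' @return A `cell_event`.
#' @export
simulate_event <- function(spec, render, event_id = "event",
                           seed = spec$rng_seed) {
  render_event(simulate_trajectory(spec, render), render,
               seed = seed, event_id = event_id)
}
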