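#' Synthetic scan scenes with analytic ground truth
#'
#' A synthetic scene specifies a parametric anatomy surface (flat skin
#' patch, cylindrical limb, or spherical torso segment), a wound patch on
#' it, and a meshing resolution. The wound patch area is known in closed
#' form from the specification alone — before any mesh exists — which is
#' what makes the generator usable as an oracle for the whole measurement
#' pipeline:
#' \itemize{
#'   \item plane disc of radius r: `pi * r^2`
#'   \item cylindrical patch spanning angle `phi_span` and axial length
#'     `patch_length` on a cylinder of radius R: `R * phi_span *
#'     patch_length`
#'   \item spherical cap of angular radius theta on a sphere of radius R:
#'     `2 * pi * R^2 * (1 - cos(theta))`
#' }
#' The triangulation inserts the wound boundary into its knot set (the cap
#' ring, the patch edges, the disc circle are mesh polylines), so the
#' labelled region's polyhedral area differs from the closed form only by
#' quadratic chordal error, not by a linear boundary band.
#'
#' @param anatomy `"plane"`, `"cylinder_limb"` or `"sphere_torso"`.
#' @param anatomy_params Named list of dimensions in mm. Defaults:
#'   plane `width = 100, height = 100`; cylinder `radius = 40,
#'   length = 200`; sphere `radius = 100`.
#' @param wound_spec Named list describing the patch. Defaults: plane
#'   `radius = 20`; cylinder `phi_span = pi / 2, patch_length = 50`
#'   (centred); sphere `theta = 0.3` (cap at the pole).
#' @param resolution Target triangle edge length in mm. The default 1.0 mm
#'   is a few times the native resolution of clinical structured-light
#'   scanners and keeps meshes desk-scale.
#' @param seed Integer seed used for any stochastic step (scan noise).
#' @param skin_color,wound_color RGB triples used when painting; defaults
#'   are linearly separable by the default colour rule.
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(anatomy = c("plane", "cylinder_limb",
                                        "sphere_torso"),
                            anatomy_params = list(),
                            wound_spec = list(),
                            resolution = 1.0,
                            seed = 1L,
                            skin_color = c(0.9, 0.75, 0.6),
                            wound_color = c(0.8, 0.2, 0.2)) {
  anatomy <- match.arg(anatomy)
  defaults <- switch(anatomy,
    plane = list(params = list(width = 100, height = 100),
                 wound = list(radius = 20)),
    cylinder_limb = list(params = list(radius = 40, length = 200),
                         wound = list(phi_span = pi / 2, patch_length = 50)),
    sphere_torso = list(params = list(radius = 100),
                        wound = list(theta = 0.3))
  )
  params <- utils::modifyList(defaults$params, anatomy_params)
  wound <- utils::modifyList(defaults$wound, wound_spec)
  if (resolution <= 0) {
    bp_abort("resolution must be positive.", "bp_error_input")
  }
  scene <- structure(
    list(anatomy = anatomy, anatomy_params = params, wound_spec = wound,
         resolution = resolution, seed = as.integer(seed),
         skin_color = skin_color, wound_color = wound_color),
    class = "synthetic_scene"
  )
  check_scene_geometry(scene)
  scene
}

check_scene_geometry <- function(scene) {
  p <- scene$anatomy_params
  w <- scene$wound_spec
  bad <- switch(scene$anatomy,
    plane = w$radius < 0 || w$radius >= min(p$width, p$height) / 2,
    cylinder_limb = w$phi_span < 0 || w$phi_span >= 2 * pi ||
      w$patch_length < 0 || w$patch_length >= p$length,
    sphere_torso = w$theta < 0 || w$theta >= pi
  )
  if (bad) {
    bp_abort("wound patch must lie strictly inside the anatomy surface.",
             "bp_error_geometry")
  }
  invisible(scene)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %s, resolution %.3g mm, wound %.4f cm^2 (analytic)\n",
    x$anatomy, x$resolution, ground_truth_area_cm2(x)))
  invisible(x)
}

#' @rdname synthetic_scene
#' @param scene A `synthetic_scene`.
#' @return `ground_truth_area_cm2()`: the closed-form wound patch area in
#'   cm^2, computable without meshing.
#' @export
ground_truth_area_cm2 <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  p <- scene$anatomy_params
  w <- scene$wound_spec
  mm2 <- switch(scene$anatomy,
    plane = pi * w$radius^2,
    cylinder_limb = p$radius * w$phi_span * w$patch_length,
    sphere_torso = 2 * pi * p$radius^2 * (1 - cos(w$theta))
  )
  mm2 / 100
}

# insert a value into a knot vector, snapping to an existing knot when the
# gap would create a sliver narrower than `tol`
insert_knot <- function(knots, value, tol) {
  d <- abs(knots - value)
  i <- which.min(d)
  if (d[i] < tol) knots[i] <- value else knots <- sort(c(knots, value))
  knots
}

grid_faces <- function(nrow_rings, nphi, ring_index, wrap = TRUE) {
  # ring_index(i): vertex index of entry k (1..nphi) in ring i
  kk <- seq_len(if (wrap) nphi else nphi - 1L)
  k2 <- if (wrap) c(seq_len(nphi)[-1L], 1L) else kk + 1L
  out <- vector("list", nrow_rings - 1L)
  for (i in seq_len(nrow_rings - 1L)) {
    a <- ring_index(i)[kk];  b <- ring_index(i)[k2]
    c2 <- ring_index(i + 1L)[k2]; d2 <- ring_index(i + 1L)[kk]
    out[[i]] <- rbind(cbind(a, b, c2), cbind(a, c2, d2))
  }
  do.call(rbind, out)
}

min_wound_extent_mm <- function(scene) {
  p <- scene$anatomy_params
  w <- scene$wound_spec
  switch(scene$anatomy,
    plane = w$radius,
    cylinder_limb = if (w$phi_span == 0 || w$patch_length == 0) 0 else
      min(p$radius * w$phi_span, w$patch_length),
    sphere_torso = p$radius * w$theta
  )
}

#' Triangulate the anatomy surface of a scene
#'
#' Builds the scene's parametric surface at the requested resolution. The
#' construction is fully deterministic (no randomness is involved until
#' scan noise is applied) and the wound patch boundary is part of the knot
#' set. The flat patch is meshed as a polar fan whose boundary polygon
#' includes the rectangle corners, so its total area is exactly
#' `width * height`; curved anatomies carry the usual quadratic chordal
#' deficit.
#'
#' @param scene A [synthetic_scene()].
#' @return An unlabelled [triangle_mesh()].
#' @export
make_anatomy <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  ext <- min_wound_extent_mm(scene)
  if (ext > 0 && ext < scene$resolution) {
    bp_abort("mesh resolution is coarser than the wound feature.",
             "bp_error_resolution")
  }
  switch(scene$anatomy,
    plane = make_plane(scene),
    cylinder_limb = make_cylinder(scene),
    sphere_torso = make_sphere(scene)
  )
}

make_plane <- function(scene) {
  p <- scene$anatomy_params
  res <- scene$resolution
  rw <- scene$wound_spec$radius
  w2 <- p$width / 2; h2 <- p$height / 2
  rho <- function(phi) 1 / pmax(abs(cos(phi)) / w2, abs(sin(phi)) / h2)
  rmax <- sqrt(w2^2 + h2^2)
  nphi <- max(16L, ceiling(2 * pi * rmax / res))
  phi <- seq(-pi, pi, length.out = nphi + 1L)[-(nphi + 1L)]
  for (ca in atan2(c(h2, h2, -h2, -h2), c(w2, -w2, -w2, w2))) {
    phi <- insert_knot(phi, ca, tol = 0.25 * 2 * pi / nphi)
  }
  nphi <- length(phi)
  radii_in <- if (rw > 0) rw * seq_len(max(1L, ceiling(rw / res))) /
    max(1L, ceiling(rw / res)) else numeric(0)
  rb <- rho(phi)
  n_out <- max(1L, ceiling((max(rb) - rw) / res))
  # ring radii: inner discs (aligned so the last inner ring is exactly the
  # wound circle), then ruled interpolation out to the rectangle boundary
  rings <- c(
    lapply(radii_in, function(r) rep(r, nphi)),
    lapply(seq_len(n_out), function(j) rw + (j / n_out) * (rb - rw))
  )
  nring <- length(rings)
  verts <- rbind(
    c(0, 0, 0),
    do.call(rbind, lapply(rings, function(r) cbind(r * cos(phi),
                                                   r * sin(phi), 0)))
  )
  ring_index <- function(i) 1L + (i - 1L) * nphi + seq_len(nphi)
  k2 <- c(seq_len(nphi)[-1L], 1L)
  fan <- cbind(1L, ring_index(1L), ring_index(1L)[k2])
  faces <- rbind(fan, grid_faces(nring, nphi, ring_index))
  triangle_mesh(verts, faces)
}

make_cylinder <- function(scene) {
  p <- scene$anatomy_params
  res <- scene$resolution
  R <- p$radius; L <- p$length
  dphi <- scene$wound_spec$phi_span; lp <- scene$wound_spec$patch_length
  nphi <- max(16L, ceiling(2 * pi * R / res))
  phi <- seq(-pi, pi, length.out = nphi + 1L)[-(nphi + 1L)]
  if (dphi > 0) {
    tol <- 0.25 * 2 * pi / nphi
    phi <- insert_knot(phi, -dphi / 2, tol)
    phi <- insert_knot(phi, dphi / 2, tol)
  }
  nphi <- length(phi)
  nz <- max(1L, ceiling(L / res))
  z <- seq(0, L, length.out = nz + 1L)
  if (lp > 0) {
    tolz <- 0.25 * L / nz
    z <- insert_knot(z, (L - lp) / 2, tolz)
    z <- insert_knot(z, (L + lp) / 2, tolz)
  }
  nz1 <- length(z)
  verts <- cbind(
    R * cos(rep(phi, times = nz1)),
    R * sin(rep(phi, times = nz1)),
    rep(z, each = nphi)
  )
  ring_index <- function(i) (i - 1L) * nphi + seq_len(nphi)
  triangle_mesh(verts, grid_faces(nz1, nphi, ring_index))
}

make_sphere <- function(scene) {
  p <- scene$anatomy_params
  res <- scene$resolution
  R <- p$radius
  theta_cap <- scene$wound_spec$theta
  ntheta <- max(8L, ceiling(pi * R / res))
  th <- seq(0, pi, length.out = ntheta + 1L)
  if (theta_cap > 0) {
    th <- insert_knot(th, theta_cap, tol = 0.25 * pi / ntheta)
  }
  th <- th[th > 0 & th < pi]
  nth <- length(th)
  nphi <- max(16L, ceiling(2 * pi * R / res))
  phi <- seq(-pi, pi, length.out = nphi + 1L)[-(nphi + 1L)]
  ring <- function(theta) cbind(R * sin(theta) * cos(phi),
                                R * sin(theta) * sin(phi),
                                rep(R * cos(theta), nphi))
  verts <- rbind(
    c(0, 0, R),
    do.call(rbind, lapply(th, ring)),
    c(0, 0, -R)
  )
  ring_index <- function(i) 1L + (i - 1L) * nphi + seq_len(nphi)
  south <- nrow(verts)
  k2 <- c(seq_len(nphi)[-1L], 1L)
  faces <- rbind(
    cbind(1L, ring_index(1L), ring_index(1L)[k2]),
    grid_faces(nth, nphi, ring_index),
    cbind(south, ring_index(nth)[k2], ring_index(nth))
  )
  triangle_mesh(verts, faces)
}

#' Paint the wound patch onto an anatomy mesh
#'
#' Labels every vertex inside the scene's wound patch with `1` and colours
#' wound vertices in the scene's wound tone against the skin tone, mimicking
#' the texture cue a human segmenter works from. Because the patch boundary
#' is a knot polyline of the triangulation, the `all_vertices` face rule
#' recovers the full polyhedral patch. The analytic patch area is available
#' from [ground_truth_area_cm2()] independently of any mesh.
#'
#' @param mesh The mesh built by [make_anatomy()] for the same scene.
#' @param scene The [synthetic_scene()].
#' @return The mesh with `labels` and `colors` set.
#' @export
paint_wound <- function(mesh, scene) {
  stopifnot(inherits(mesh, "triangle_mesh"),
            inherits(scene, "synthetic_scene"))
  check_scene_geometry(scene)
  v <- mesh$vertices
  p <- scene$anatomy_params
  w <- scene$wound_spec
  tol <- 1e-9
  inside <- switch(scene$anatomy,
    plane = {
      if (w$radius <= 0) rep(FALSE, nrow(v)) else
        sqrt(v[, 1]^2 + v[, 2]^2) <= w$radius * (1 + 1e-9) + 1e-9
    },
    cylinder_limb = {
      if (w$phi_span <= 0 || w$patch_length <= 0) rep(FALSE, nrow(v)) else {
        phiv <- atan2(v[, 2], v[, 1])
        zlo <- (p$length - w$patch_length) / 2
        zhi <- (p$length + w$patch_length) / 2
        abs(phiv) <= w$phi_span / 2 + tol &
          v[, 3] >= zlo - 1e-9 * p$length & v[, 3] <= zhi + 1e-9 * p$length
      }
    },
    sphere_torso = {
      if (w$theta <= 0) rep(FALSE, nrow(v)) else
        atan2(sqrt(v[, 1]^2 + v[, 2]^2), v[, 3]) <= w$theta + tol
    }
  )
  mesh$labels <- as.integer(inside)
  colors <- matrix(rep(scene$skin_color, each = nrow(v)), ncol = 3L)
  colors[inside, ] <- matrix(rep(scene$wound_color, each = sum(inside)),
                             ncol = 3L)
  mesh$colors <- colors
  mesh
}

#' Apply scanner-like depth noise to a mesh
#'
#' Displaces every vertex along the local surface normal by a smooth
#' Gaussian random field, mimicking the residual depth error of a
#' registered structured-light scan: such error is spatially correlated
#' (registration and reconstruction leave smooth undulations, not
#' per-vertex speckle), so the field is synthesised as a sum of random
#' cosine waves with correlation length `correlation_mm` and marginal
#' standard deviation `sigma_mm`. Setting `correlation_mm = 0` degrades to
#' independent per-vertex jitter, which roughens the surface and biases
#' areas upward — useful to model raw unsmoothed depth speckle. Noise is
#' applied after labelling, so the labelled vertex set is unaffected;
#' tangential jitter is deliberately not applied because it would move the
#' labelled boundary. Deterministic for a given seed.
#'
#' @param mesh A (typically painted) [triangle_mesh()].
#' @param scene The scene, used for its analytic surface normals.
#' @param sigma_mm Standard deviation of the normal offsets (mm).
#' @param seed Integer seed; defaults to the scene's.
#' @param correlation_mm Spatial correlation length of the error field
#'   (mm); default 10.
#' @return The jittered mesh.
#' @export
apply_scan_noise <- function(mesh, scene, sigma_mm, seed = scene$seed,
                             correlation_mm = 10) {
  stopifnot(inherits(mesh, "triangle_mesh"),
            inherits(scene, "synthetic_scene"))
  if (sigma_mm < 0) bp_abort("sigma_mm must be >= 0.", "bp_error_input")
  if (sigma_mm == 0) return(mesh)
  v <- mesh$vertices
  normals <- switch(scene$anatomy,
    plane = matrix(rep(c(0, 0, 1), each = nrow(v)), ncol = 3L),
    cylinder_limb = {
      r <- sqrt(v[, 1]^2 + v[, 2]^2)
      r[r == 0] <- 1
      cbind(v[, 1] / r, v[, 2] / r, 0)
    },
    sphere_torso = {
      r <- sqrt(rowSums(v^2))
      r[r == 0] <- 1
      v / r
    }
  )
  disp <- withr::with_seed(as.integer(seed), {
    if (correlation_mm <= 0) {
      rnorm(nrow(v), 0, sigma_mm)
    } else {
      # sum of K random plane waves; wavevector magnitude set by the
      # correlation length, marginal sd = sigma_mm
      K <- 24L
      dirs <- matrix(rnorm(3L * K), ncol = 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      kmag <- 2 * pi / correlation_mm
      phase <- stats::runif(K, 0, 2 * pi)
      field <- v %*% t(dirs * kmag)
      sigma_mm * sqrt(2 / K) * as.vector(cos(sweep(field, 2L, phase, "+")) %*%
                                           rep(1, K))
    }
  })
  mesh$vertices <- v + normals * disp
  mesh
}

#' Healing trajectory specification
#'
#' Prescribes how a synthetic wound's true area evolves over the scan days:
#' `exponential` gives `A(d) = a0 * exp(-rate * (d - d1))` (rapid initial
#' decline flattening into a plateau, the shape repeatedly seen in real
#' healing series), `linear` gives `A(d) = a0 - rate * (d - d1)`, where
#' `d1` is the first scan day.
#'
#' @param model `"exponential"` or `"linear"`.
#' @param a0_cm2 Baseline wound area (cm^2).
#' @param rate Decay rate: per day (exponential) or cm^2/day (linear).
#' @param scan_days Strictly increasing integer days, first day is baseline.
#' @param noise_sigma_mm Vertex jitter applied to every scan (mm).
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(model = c("exponential", "linear"),
                            a0_cm2, rate, scan_days,
                            noise_sigma_mm = 0) {
  model <- match.arg(model)
  scan_days <- as.integer(scan_days)
  if (length(scan_days) < 1L || any(diff(scan_days) <= 0) ||
      scan_days[1L] < 1L) {
    bp_abort("scan_days must be strictly increasing integers >= 1.",
             "bp_error_input")
  }
  if (a0_cm2 < 0) bp_abort("a0_cm2 must be >= 0.", "bp_error_domain")
  spec <- structure(
    list(model = model, a0_cm2 = a0_cm2, rate = rate,
         scan_days = scan_days, noise_sigma_mm = noise_sigma_mm),
    class = "trajectory_spec"
  )
  if (any(trajectory_areas(spec) < 0)) {
    bp_abort("trajectory yields negative areas on the scan days.",
             "bp_error_input")
  }
  spec
}

#' @rdname trajectory_spec
#' @param spec A `trajectory_spec`.
#' @return `trajectory_areas()`: the true areas (cm^2) on the scan days.
#' @export
trajectory_areas <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  t <- spec$scan_days - spec$scan_days[1L]
  a <- switch(spec$model,
    exponential = spec$a0_cm2 * exp(-spec$rate * t),
    linear = spec$a0_cm2 - spec$rate * t
  )
  a[abs(a) < 1e-12] <- 0
  a
}

scene_with_wound_area <- function(scene, area_cm2) {
  mm2 <- area_cm2 * 100
  p <- scene$anatomy_params
  w <- scene$wound_spec
  w2 <- switch(scene$anatomy,
    plane = list(radius = sqrt(mm2 / pi)),
    cylinder_limb = {
      s <- sqrt(mm2 / (p$radius * w$phi_span * w$patch_length))
      list(phi_span = w$phi_span * s, patch_length = w$patch_length * s)
    },
    sphere_torso = {
      c1 <- 1 - mm2 / (2 * pi * p$radius^2)
      if (c1 < -1) {
        bp_abort("target wound area exceeds the sphere surface.",
                 "bp_error_geometry")
      }
      list(theta = acos(c1))
    }
  )
  scene$wound_spec <- utils::modifyList(scene$wound_spec, w2)
  check_scene_geometry(scene)
  scene
}

#' Generate a longitudinal series of labelled scan meshes
#'
#' For each scan day, shrinks the scene's wound patch parameter so the
#' patch's closed-form area equals the trajectory's `A(day)` exactly, then
#' meshes, paints and (optionally) jitters the surface. Shrinking the patch
#' parameter — rather than morphing a mesh — keeps an exact analytic oracle
#' at every time point. A day whose target area is zero yields a mesh with
#' no wound labels; a positive target area too small for the meshing
#' resolution raises a trajectory-resolution error.
#'
#' @param scene A [synthetic_scene()].
#' @param trajectory A [trajectory_spec()].
#' @return A tibble of class `synthetic_series` with columns `day`,
#'   `true_area_cm2` and a `mesh` list-column of painted
#'   [triangle_mesh()] objects; the scene and trajectory ride along as
#'   attributes.
#' @export
generate_series <- function(scene, trajectory) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(trajectory, "trajectory_spec"))
  areas <- trajectory_areas(trajectory)
  meshes <- vector("list", length(areas))
  for (i in seq_along(areas)) {
    sc <- scene_with_wound_area(scene, areas[i])
    if (areas[i] > 0 && min_wound_extent_mm(sc) < scene$resolution) {
      bp_abort(sprintf(
        "wound area %.3f cm^2 on day %d is below the smallest patch the %.3g mm resolution can represent.",
        areas[i], trajectory$scan_days[i], scene$resolution),
        "bp_error_resolution")
    }
    m <- paint_wound(make_anatomy(sc), sc)
    if (trajectory$noise_sigma_mm > 0) {
      m <- apply_scan_noise(m, sc, trajectory$noise_sigma_mm,
                            seed = scene$seed + i)
    }
    meshes[[i]] <- m
  }
  out <- tibble(day = trajectory$scan_days, true_area_cm2 = areas,
                mesh = meshes)
  structure(out, class = c("synthetic_series", class(out)),
            scene = scene, trajectory = trajectory)
}

#' Run the measurement pipeline over a synthetic series
#'
#' Extracts the wound area of every scan in a generated series through the
#' same segmentation + area-summation path used for real scans: label-driven
#' ROI selection followed by [surface_area()]. Scans whose target area is
#' zero report 0.
#'
#' @param series A [generate_series()] result.
#' @param inclusion_rule Passed to [roi_from_labels()].
#' @return A tibble with `day`, `true_area_cm2`, `measured_area_cm2`.
#' @export
extract_series_areas <- function(series,
                                 inclusion_rule = "all_vertices") {
  stopifnot(inherits(series, "synthetic_series"))
  measured <- map_dbl(series$mesh, function(m) {
    if (is.null(m$labels) || !any(m$labels > 0L)) return(0)
    roi <- roi_from_labels(m, 1L, inclusion_rule = inclusion_rule)
    roi$area_cm2
  })
  tibble(day = series$day, true_area_cm2 = series$true_area_cm2,
         measured_area_cm2 = measured)
}

#' Recover an exponential healing rate from measured areas
#'
#' Log-linear least squares on the measured areas:
#' `log A = log a0 - k * (day - day1)`. Used to check end-to-end trajectory
#' recovery against the generator's prescribed decay rate.
#'
#' @param day Scan days.
#' @param area_cm2 Measured areas (must be positive).
#' @return A one-row tibble: `k_per_day`, `a0_cm2`, `r_squared`.
#' @export
fit_exponential_decay <- function(day, area_cm2) {
  if (length(day) < 2L) {
    bp_abort("need at least two scans to fit a decay rate.",
             "bp_error_insufficient_data")
  }
  if (any(area_cm2 <= 0)) {
    bp_abort("areas must be positive to fit an exponential decay.",
             "bp_error_domain")
  }
  t <- day - day[1L]
  fit <- lm(log(area_cm2) ~ t)
  tibble(
    k_per_day = -unname(coef(fit)[2L]),
    a0_cm2 = exp(unname(coef(fit)[1L])),
    r_squared = summary(fit)$r.squared
  )
}
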