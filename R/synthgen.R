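#' Parameters for a synthetic high-content scene
#'
#' Bundles everything the generator needs to lay out cells, mitochondria and
#' lysosomes, sample per-frame engulfment (mitophagy) states, and render a
#' noisy multi-z time-lapse. Defaults emulate a day-27 control field:
#' 50 cells, ~20 mitochondria per cell, a basal engulfment probability of
#' 0.09 per mitochondrion per frame, frames every 18 minutes and 7 z planes.
#'
#' @param n_cells number of cells in the field.
#' @param cell_radius geometric mean cell radius, micrometres.
#' @param cell_roundness_target target isoperimetric roundness
#'   (perimeter^2 / (4 pi area), circle = 1). Values below the floor imposed
#'   by `cell_elongation_ratio` are achieved as closely as the ellipse allows.
#' @param cell_elongation_ratio target major/minor axis ratio (>= 1).
#' @param mito_per_cell_mean Poisson mean of mitochondria per cell.
#' @param mito_area_mean mean mitochondrion area, square micrometres.
#' @param mito_intensity_mean mean in-focus mitochondrial fluorescence (a.u.).
#' @param lyso_per_cell_mean Poisson mean of lysosomes per cell.
#' @param lyso_radius lysosome radius, micrometres.
#' @param basal_engulf_prob per-mitochondrion per-frame probability of being
#'   inside a lysosome (basal mitophagy rate).
#' @param induced_engulf_curve optional numeric vector, one engulfment
#'   probability per frame, used instead of `basal_engulf_prob` (the induced
#'   condition). Must have length `n_frames`.
#' @param n_frames number of time-lapse frames.
#' @param frame_interval minutes between frames.
#' @param n_z number of z planes rendered.
#' @param pixel_size micrometres per pixel.
#' @param noise_model list with `gaussian_sd` (additive read noise, a.u.) and
#'   `poisson_scale` (photon noise; 0 disables, larger = less noisy).
#' @param background camera background offset (a.u.).
#' @param nucleus_intensity,lyso_intensity in-focus object intensities (a.u.).
#' @param cyto_haze named numeric: diffuse cytoplasmic signal added to the
#'   mitochondria and lysosome channels inside each cell (residual dye).
#' @param seed integer seed; fixed seed gives bit-identical scenes.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(n_cells = 50,
                         cell_radius = 12,
                         cell_roundness_target = 1.3,
                         cell_elongation_ratio = 2,
                         mito_per_cell_mean = 20,
                         mito_area_mean = 1.0,
                         mito_intensity_mean = 3000,
                         lyso_per_cell_mean = 5,
                         lyso_radius = 1.2,
                         basal_engulf_prob = 0.09,
                         induced_engulf_curve = NULL,
                         n_frames = 10,
                         frame_interval = 18,
                         n_z = 7,
                         pixel_size = 0.3,
                         noise_model = list(gaussian_sd = 40, poisson_scale = 0),
                         background = 100,
                         nucleus_intensity = 4000,
                         lyso_intensity = 3500,
                         cyto_haze = c(mitochondria = 500, lysosomes = 300),
                         seed = 1L) {
  p <- list(
    n_cells = as.integer(n_cells), cell_radius = cell_radius,
    cell_roundness_target = cell_roundness_target,
    cell_elongation_ratio = cell_elongation_ratio,
    mito_per_cell_mean = mito_per_cell_mean,
    mito_area_mean = mito_area_mean,
    mito_intensity_mean = mito_intensity_mean,
    lyso_per_cell_mean = lyso_per_cell_mean,
    lyso_radius = lyso_radius,
    basal_engulf_prob = basal_engulf_prob,
    induced_engulf_curve = induced_engulf_curve,
    n_frames = as.integer(n_frames), frame_interval = frame_interval,
    n_z = as.integer(n_z), pixel_size = pixel_size,
    noise_model = noise_model, background = background,
    nucleus_intensity = nucleus_intensity, lyso_intensity = lyso_intensity,
    cyto_haze = cyto_haze, seed = as.integer(seed)
  )
  validate_scene_params(p)
  class(p) <- "scene_params"
  p
}

validate_scene_params <- function(p) {
  stopifnot(p$n_cells >= 0, p$mito_per_cell_mean >= 0, p$lyso_per_cell_mean >= 0,
            p$n_frames >= 1, p$n_z >= 1)
  if (p$frame_interval <= 0) stop("frame_interval must be > 0")
  if (p$pixel_size <= 0) stop("pixel_size must be > 0")
  if (p$cell_roundness_target < 1) stop("cell_roundness_target must be >= 1")
  if (p$cell_elongation_ratio < 1) stop("cell_elongation_ratio must be >= 1")
  if (p$basal_engulf_prob < 0 || p$basal_engulf_prob > 1)
    stop("basal_engulf_prob must be a probability in [0, 1]")
  if (!is.null(p$induced_engulf_curve)) {
    if (length(p$induced_engulf_curve) != p$n_frames)
      stop("induced_engulf_curve must have length n_frames")
    if (any(p$induced_engulf_curve < 0 | p$induced_engulf_curve > 1))
      stop("induced_engulf_curve entries must be probabilities in [0, 1]")
  }
  if (is.null(p$noise_model$gaussian_sd) || is.null(p$noise_model$poisson_scale))
    stop("noise_model must have gaussian_sd and poisson_scale")
  if (p$noise_model$gaussian_sd < 0 || p$noise_model$poisson_scale < 0)
    stop("noise parameters must be >= 0")
  invisible(TRUE)
}

# even-odd point-in-polygon test, vectorized over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    if (denom == 0) denom <- .Machine$double.eps
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# star-convex cell outline: anisotropically scaled, wobbled circle.
# amp is calibrated by bisection so the analytic polygon hits the requested
# isoperimetric roundness (when reachable above the ellipse floor).
cell_outline <- function(center, r_px, elong, roundness_target,
                         wobble_freq, wobble_phase, theta0, n_vert = 72) {
  a <- r_px * sqrt(elong)
  b <- r_px / sqrt(elong)
  th <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  shape_at <- function(amp) {
    rho <- 1 + amp * cos(wobble_freq * th + wobble_phase)
    ex <- a * rho * cos(th)
    ey <- b * rho * sin(th)
    x <- center[1] + ex * cos(theta0) - ey * sin(theta0)
    y <- center[2] + ex * sin(theta0) + ey * cos(theta0)
    cbind(x = x, y = y)
  }
  roundness_of <- function(v) {
    polygon_perimeter(v[, 1], v[, 2])^2 /
      (4 * pi * polygon_area(v[, 1], v[, 2]))
  }
  lo <- 0; hi <- 0.35
  if (roundness_of(shape_at(0)) >= roundness_target) {
    amp <- 0
  } else {
    for (it in 1:30) {
      mid <- (lo + hi) / 2
      if (roundness_of(shape_at(mid)) < roundness_target) lo <- mid else hi <- mid
    }
    amp <- (lo + hi) / 2
  }
  list(vertices = shape_at(amp), amp = amp, a = a, b = b, theta = theta0,
       center = center)
}

cell_local_axes <- function(cell, margin_px) {
  keep_amp <- 1 - cell$amp
  a_eff <- cell$a * keep_amp - margin_px
  b_eff <- cell$b * keep_amp - margin_px
  if (a_eff <= 0 || b_eff <= 0)
    stop("impossible geometry: object margin ", round(margin_px, 1),
         " px exceeds the cell minor axis; enlarge cell_radius or shrink objects")
  c(a_eff, b_eff)
}

local_to_world <- function(cell, ex, ey) {
  cbind(x = cell$center[1] + ex * cos(cell$theta) - ey * sin(cell$theta),
        y = cell$center[2] + ex * sin(cell$theta) + ey * cos(cell$theta))
}

# jittered-lattice placement inside the shrunk cell ellipse: deterministic
# capacity, worst-case pairwise separation = spacing - 2 * jitter
sample_positions_lattice <- function(n, cell, margin_px, spacing, jitter = 1) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  ax <- cell_local_axes(cell, margin_px + jitter)
  off <- stats::runif(2, 0, spacing)
  gx <- seq(-ax[1], ax[1], by = spacing) + off[1]
  gy <- seq(-ax[2], ax[2], by = spacing) + off[2]
  pts <- expand.grid(ex = gx, ey = gy)
  keep <- (pts$ex / ax[1])^2 + (pts$ey / ax[2])^2 <= 1
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < n)
    stop("impossible geometry: cell can hold at most ", nrow(pts),
         " objects at spacing ", round(spacing, 1), " px but ", n,
         " were requested; enlarge cell_radius or reduce counts")
  pts <- pts[sample.int(nrow(pts), n), , drop = FALSE]
  local_to_world(cell,
                 pts$ex + stats::runif(n, -jitter, jitter),
                 pts$ey + stats::runif(n, -jitter, jitter))
}

# rejection-sample object centres inside the shrunk cell ellipse; objects
# have individual packing radii (pairwise distance >= r_i + r_j + gap) and
# are placed largest-first, which packs markedly better at high density.
sample_positions <- function(n, cell, radii, gap = 2, avoid = NULL,
                             avoid_sep = 0, max_tries = 20000) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  radii <- rep_len(radii, n)
  ord <- order(radii, decreasing = TRUE)
  pts <- matrix(NA_real_, n, 2)
  placed <- 0
  tries <- 0
  while (placed < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("impossible geometry: could not place ", n,
           " objects at the requested density (cell too crowded); ",
           "reduce counts or enlarge cell_radius")
    rk <- radii[ord[placed + 1]]
    ax <- cell_local_axes(cell, rk + gap)
    u <- stats::runif(1, 0, 2 * pi)
    r <- sqrt(stats::runif(1))
    w <- local_to_world(cell, ax[1] * r * cos(u), ax[2] * r * sin(u))
    ok <- TRUE
    if (placed > 0) {
      d2 <- (pts[seq_len(placed), 1] - w[1])^2 +
        (pts[seq_len(placed), 2] - w[2])^2
      ok <- all(d2 >= (radii[ord[seq_len(placed)]] + rk + gap)^2)
    }
    if (ok && !is.null(avoid) && nrow(avoid) > 0) {
      d2 <- (avoid[, 1] - w[1])^2 + (avoid[, 2] - w[2])^2
      ok <- all(d2 >= (avoid_sep + rk)^2)
    }
    if (ok) {
      placed <- placed + 1
      pts[placed, ] <- w
      tries <- 0
    }
  }
  pts[ord, ] <- pts[seq_len(n), ]
  colnames(pts) <- c("x", "y")
  pts
}

#' Generate a ground-truthed synthetic scene
#'
#' Lays out star-convex cells on a jittered grid (no cell touches the field
#' border), places mitochondria and lysosomes inside each cell with
#' separation constraints so rendered objects never merge, and samples a
#' per-mitochondrion per-frame engulfment state: Bernoulli with probability
#' `basal_engulf_prob` (or the per-frame `induced_engulf_curve`). Engulfment
#' is reversible between frames, so the cross-sectional engulfed fraction
#' equals the engulfment probability at every frame. Each engulfed
#' mitochondrion is assigned its own host lysosome and is rendered wholly
#' inside it.
#'
#' Geometry and engulfment use one RNG stream seeded from `params$seed`;
#' rendering noise uses a separate per-frame stream, so the geometry is
#' stable when only noise parameters change.
#'
#' @param params a [scene_params()] object.
#' @return object of class `synthetic_scene` with the field dimensions, cell
#'   polygons, organelle tables, engulfment state matrices and the exact
#'   per-cell per-frame `ground_truth_fractions`.
#' @export
generate_scene <- function(params) {
  validate_scene_params(params)
  p <- params
  ps <- p$pixel_size
  set.seed(p$seed %% 2147483647L)

  r_px <- p$cell_radius / ps
  a_px <- r_px * sqrt(p$cell_elongation_ratio)
  spacing <- ceiling(2 * a_px * 1.08 + 8)
  ncol_g <- ceiling(sqrt(p$n_cells))
  nrow_g <- ceiling(p$n_cells / ncol_g)
  field <- c(Y = nrow_g * spacing + spacing, X = ncol_g * spacing + spacing)

  mito_area_px <- p$mito_area_mean / ps^2
  lyso_r_px <- p$lyso_radius / ps

  probs <- if (!is.null(p$induced_engulf_curve)) p$induced_engulf_curve
           else rep(p$basal_engulf_prob, p$n_frames)

  cells <- vector("list", p$n_cells)
  mito_rows <- list(); lyso_rows <- list()
  engulf <- list(); hosts <- list()
  gt <- matrix(NA_real_, p$n_cells, p$n_frames)
  mito_id0 <- 0L; lyso_id0 <- 0L

  for (ci in seq_len(p$n_cells)) {
    gy <- (ci - 1) %/% ncol_g
    gx <- (ci - 1) %% ncol_g
    center <- c(
      x = spacing * (gx + 1) + stats::runif(1, -0.04, 0.04) * spacing,
      y = spacing * (gy + 1) + stats::runif(1, -0.04, 0.04) * spacing
    )
    outline <- cell_outline(
      center, r_px, p$cell_elongation_ratio, p$cell_roundness_target,
      wobble_freq = sample(4:7, 1), wobble_phase = stats::runif(1, 0, 2 * pi),
      theta0 = stats::runif(1, 0, 2 * pi)
    )
    nuc_r <- 0.32 * r_px

    n_mito <- stats::rpois(1, p$mito_per_cell_mean)
    # engulfment states first, so the lysosome count can host the peak load
    E <- matrix(FALSE, n_mito, p$n_frames)
    if (n_mito > 0)
      for (t in seq_len(p$n_frames))
        E[, t] <- stats::runif(n_mito) < probs[t]
    need_lyso <- if (n_mito > 0) max(colSums(E)) else 0L
    n_lyso <- max(stats::rpois(1, p$lyso_per_cell_mean), need_lyso)

    # mitochondria geometry: 2:1 ellipses, gamma-distributed areas
    # area floor of 6 px: objects below the resolution limit would not be
    # counted by any segmentation, so the generator does not create them
    areas <- if (n_mito > 0)
      stats::rgamma(n_mito, shape = 6, scale = mito_area_px / 6) else numeric(0)
    bb <- sqrt(pmin(pmax(areas, 6), 3 * mito_area_px) / (2 * pi))
    aa <- 2 * bb

    # lysosomes on a jittered lattice (never merge); free mitochondria by
    # rejection sampling, kept clear of each other and of lysosome interiors
    # (partial mito-lysosome overlap would be fine under the 100% rule, but
    # keeping centres out of lysosomes makes the ground truth unambiguous)
    lyso_pos <- sample_positions_lattice(
      n_lyso, outline, margin_px = lyso_r_px + 2,
      spacing = 2 * lyso_r_px + 3, jitter = 0.5
    )
    mito_pos <- sample_positions(
      n_mito, outline, radii = aa, gap = 2, avoid = lyso_pos,
      avoid_sep = lyso_r_px
    )

    # host lysosome per engulfed mitochondrion, distinct within a frame
    H <- matrix(NA_integer_, n_mito, p$n_frames)
    if (n_mito > 0) {
      for (t in seq_len(p$n_frames)) {
        eng <- which(E[, t])
        if (length(eng) > 0)
          H[eng, t] <- sample.int(n_lyso, length(eng))
      }
      gt[ci, ] <- colSums(E) / n_mito
    }

    cells[[ci]] <- list(
      id = ci, center = center, vertices = outline$vertices,
      a = outline$a, b = outline$b, theta = outline$theta, amp = outline$amp,
      nucleus_radius = nuc_r, n_mito = n_mito, n_lyso = n_lyso
    )
    if (n_mito > 0)
      mito_rows[[ci]] <- data.frame(
        cell = ci, mito = mito_id0 + seq_len(n_mito),
        x = mito_pos[, 1], y = mito_pos[, 2], a = aa, b = bb,
        phi = stats::runif(n_mito, 0, pi),
        intensity = pmax(p$mito_intensity_mean *
                           (1 + stats::rnorm(n_mito, 0, 0.1)),
                         p$mito_intensity_mean * 0.5),
        z0 = sample(seq_len(p$n_z), n_mito, replace = TRUE,
                    prob = z_focus_prior(p$n_z))
      )
    if (n_lyso > 0)
      lyso_rows[[ci]] <- data.frame(
        cell = ci, lyso = lyso_id0 + seq_len(n_lyso),
        x = lyso_pos[, 1], y = lyso_pos[, 2], r = lyso_r_px,
        intensity = pmax(p$lyso_intensity * (1 + stats::rnorm(n_lyso, 0, 0.1)),
                         p$lyso_intensity * 0.5),
        z0 = sample(seq_len(p$n_z), n_lyso, replace = TRUE,
                    prob = z_focus_prior(p$n_z))
      )
    engulf[[ci]] <- E
    hosts[[ci]] <- H
    mito_id0 <- mito_id0 + n_mito
    lyso_id0 <- lyso_id0 + n_lyso
  }

  scene <- list(
    params = p, field_dim = field, cells = cells,
    mito = if (length(mito_rows)) do.call(rbind, mito_rows) else
      data.frame(cell = integer(0), mito = integer(0), x = numeric(0),
                 y = numeric(0), a = numeric(0), b = numeric(0),
                 phi = numeric(0), intensity = numeric(0), z0 = integer(0)),
    lyso = if (length(lyso_rows)) do.call(rbind, lyso_rows) else
      data.frame(cell = integer(0), lyso = integer(0), x = numeric(0),
                 y = numeric(0), r = numeric(0), intensity = numeric(0),
                 z0 = integer(0)),
    engulf = engulf, hosts = hosts,
    ground_truth_fractions = gt
  )
  class(scene) <- "synthetic_scene"
  scene
}

# objects concentrate near the focal mid-plane
z_focus_prior <- function(n_z) {
  mid <- (n_z + 1) / 2
  w <- exp(-0.5 * ((seq_len(n_z) - mid) / max(1, n_z / 5))^2)
  w / sum(w)
}

#' Exact per-cell, per-frame engulfed fraction of a scene
#'
#' @param scene a `synthetic_scene`.
#' @return matrix cells x frames; `NA` for cells with zero mitochondria.
#' @export
ground_truth_fractions <- function(scene) scene$ground_truth_fractions

# --- rendering ------------------------------------------------------------

# linear pixel indices of a filled rotated ellipse (pixel-centre test)
ellipse_pixels <- function(cx, cy, a, b, phi, ny, nx) {
  r <- max(a, b) + 1
  ys <- max(1, floor(cy - r)):min(ny, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(nx, ceiling(cx + r))
  if (length(ys) == 0 || length(xs) == 0) return(integer(0))
  py <- rep(ys - 0.5, times = length(xs))
  px <- rep(xs - 0.5, each = length(ys))
  dx <- px - cx; dy <- py - cy
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  hit <- (u^2 + v^2) <= 1
  (rep(xs, each = length(ys))[hit] - 1L) * ny + rep(ys, times = length(xs))[hit]
}

add_ellipse <- function(img, cx, cy, a, b, phi, value) {
  idx <- ellipse_pixels(cx, cy, a, b, phi, nrow(img), ncol(img))
  img[idx] <- img[idx] + value
  img
}

# linear pixel indices of a filled polygon (pixel-centre even-odd test)
polygon_pixels <- function(vx, vy, ny, nx) {
  ys <- max(1, floor(min(vy))):min(ny, ceiling(max(vy)))
  xs <- max(1, floor(min(vx))):min(nx, ceiling(max(vx)))
  if (length(ys) == 0 || length(xs) == 0) return(integer(0))
  py <- rep(ys - 0.5, times = length(xs))
  px <- rep(xs - 0.5, each = length(ys))
  hit <- point_in_polygon(px, py, vx, vy)
  (rep(xs, each = length(ys))[hit] - 1L) * ny + rep(ys, times = length(xs))[hit]
}

add_polygon <- function(img, vx, vy, value) {
  idx <- polygon_pixels(vx, vy, nrow(img), ncol(img))
  img[idx] <- img[idx] + value
  img
}

# z attenuation: gaussian in plane distance, 1 at the object's focal plane,
# so the per-pixel max over z recovers the in-focus image exactly
z_weight <- function(z, z0, sigma = 1.1) exp(-0.5 * ((z - z0) / sigma)^2)

# per-object-focal-plane component images for the static content of a scene
render_static <- function(scene) {
  p <- scene$params
  ny <- as.integer(scene$field_dim[["Y"]]); nx <- as.integer(scene$field_dim[["X"]])
  mid <- as.integer(ceiling(p$n_z / 2))
  blank <- function() matrix(0, ny, nx)

  # cells and nuclei never overlap, so index accumulation is exact
  nuc_idx <- integer(0)
  cell_idx <- integer(0)
  for (cl in scene$cells) {
    nuc_idx <- c(nuc_idx, ellipse_pixels(cl$center[1], cl$center[2],
                                         cl$nucleus_radius, cl$nucleus_radius,
                                         0, ny, nx))
    cell_idx <- c(cell_idx, polygon_pixels(cl$vertices[, 1], cl$vertices[, 2],
                                           ny, nx))
  }
  haze_m <- blank(); haze_m[cell_idx] <- unname(p$cyto_haze["mitochondria"])
  haze_l <- blank(); haze_l[cell_idx] <- unname(p$cyto_haze["lysosomes"])

  lys <- list()
  if (nrow(scene$lyso) > 0) {
    for (z0 in sort(unique(scene$lyso$z0))) {
      sub <- scene$lyso[scene$lyso$z0 == z0, , drop = FALSE]
      idx <- integer(0); val <- numeric(0)
      for (k in seq_len(nrow(sub))) {
        i <- ellipse_pixels(sub$x[k], sub$y[k], sub$r[k], sub$r[k], 0, ny, nx)
        idx <- c(idx, i); val <- c(val, rep(sub$intensity[k], length(i)))
      }
      lys[[as.character(z0)]] <- list(idx = idx, val = val)
    }
  }
  list(nucleus_mid = list(idx = nuc_idx,
                          val = rep(p$nucleus_intensity, length(nuc_idx))),
       mid = mid, lyso_by_z = lys,
       haze_mito = haze_m, haze_lyso = haze_l)
}

# one channel's composed in-focus content at plane z (background included);
# components are sparse (pixel index, value) lists keyed by focal plane
compose_plane <- function(base, comps, z, background) {
  img <- base + background
  for (key in names(comps)) {
    w <- z_weight(z, as.integer(key))
    if (w > 1e-4) {
      idx <- comps[[key]]$idx
      img[idx] <- img[idx] + comps[[key]]$val * w
    }
  }
  img
}

#' Render the per-channel maximum projection of one frame
#'
#' Identical content to [render_frame()] followed by [max_project()] (noise
#' is applied per z plane before the maximum), but never materializes the
#' full z stack — the memory- and time-frugal path the live pipeline uses.
#'
#' @inheritParams render_frame
#' @return array `[C, Y, X]` with channel dimnames.
#' @export
render_projection <- function(scene, frame, static = NULL) {
  p <- scene$params
  stopifnot(frame >= 1, frame <= p$n_frames)
  if (is.null(static)) static <- render_static(scene)
  ny <- as.integer(scene$field_dim[["Y"]]); nx <- as.integer(scene$field_dim[["X"]])
  mito_comps <- render_mito_frame(scene, frame)
  nuc_comp <- list(); nuc_comp[[as.character(static$mid)]] <-
    static$nucleus_mid
  set.seed((as.numeric(p$seed) * 1009 + 777 + frame * 31) %% 2147483647)
  out <- array(0, dim = c(3, ny, nx),
               dimnames = list(c("nuclei", "mitochondria", "lysosomes"),
                               NULL, NULL))
  acc <- list(NULL, NULL, NULL)
  for (z in seq_len(p$n_z)) {
    planes <- list(
      compose_plane(matrix(0, ny, nx), nuc_comp, z, p$background),
      compose_plane(static$haze_mito * z_weight(z, static$mid), mito_comps,
                    z, p$background),
      compose_plane(static$haze_lyso * z_weight(z, static$mid),
                    static$lyso_by_z, z, p$background)
    )
    for (c in 1:3) {
      pl <- clip16(apply_noise(planes[[c]], p$noise_model))
      acc[[c]] <- if (is.null(acc[[c]])) pl else pmax(acc[[c]], pl)
    }
  }
  for (c in 1:3) out[c, , ] <- acc[[c]]
  out
}

# in-focus mitochondria channel components for one frame, by focal plane.
# engulfed mitochondria are drawn condensed at their host lysosome's centre
# (scaled to fit wholly inside the lysosome with a safety margin) and share
# its focal plane.
render_mito_frame <- function(scene, frame) {
  p <- scene$params
  ny <- as.integer(scene$field_dim[["Y"]]); nx <- as.integer(scene$field_dim[["X"]])
  comps <- list()
  md <- scene$mito
  if (nrow(md) == 0) return(comps)
  lyso_r_px <- p$lyso_radius / p$pixel_size
  fit <- lyso_r_px - 2

  # resolve drawn position/size/plane per mitochondrion, then group fills
  cx <- md$x; cy <- md$y; a <- md$a; b <- md$b; z0 <- md$z0
  row0 <- 0L
  for (ci in seq_along(scene$cells)) {
    n_mito <- scene$cells[[ci]]$n_mito
    if (n_mito == 0) next
    E <- scene$engulf[[ci]][, frame]
    H <- scene$hosts[[ci]][, frame]
    eng <- which(E)
    if (length(eng) > 0) {
      ld <- scene$lyso[scene$lyso$cell == ci, , drop = FALSE]
      gi <- row0 + eng
      s <- pmin(1, fit / a[gi])
      cx[gi] <- ld$x[H[eng]]; cy[gi] <- ld$y[H[eng]]
      a[gi] <- a[gi] * s; b[gi] <- b[gi] * s
      z0[gi] <- ld$z0[H[eng]]
    }
    row0 <- row0 + n_mito
  }
  idx_by_z <- list(); val_by_z <- list()
  for (k in seq_len(nrow(md))) {
    key <- as.character(z0[k])
    px <- ellipse_pixels(cx[k], cy[k], a[k], b[k], md$phi[k], ny, nx)
    idx_by_z[[key]] <- c(idx_by_z[[key]], px)
    val_by_z[[key]] <- c(val_by_z[[key]], rep(md$intensity[k], length(px)))
  }
  for (key in names(idx_by_z))
    comps[[key]] <- list(idx = idx_by_z[[key]], val = val_by_z[[key]])
  comps
}

apply_noise <- function(plane, noise_model) {
  if (noise_model$poisson_scale > 0) {
    s <- noise_model$poisson_scale
    plane[] <- stats::rpois(length(plane), pmax(plane, 0) * s) / s
  }
  if (noise_model$gaussian_sd > 0)
    plane <- plane + stats::rnorm(length(plane), 0, noise_model$gaussian_sd)
  plane
}

clip16 <- function(plane) {
  mx <- max(plane)
  if (mx > 65535) {
    warning(sum(plane > 65535),
            " pixels saturated at the 16-bit ceiling and were clipped")
    plane <- pmin(plane, 65535)
  }
  if (min(plane) < 0) plane <- pmax(plane, 0)
  plane
}

#' Render one frame of a synthetic scene
#'
#' @param scene a `synthetic_scene`.
#' @param frame frame index (1-based).
#' @param static optional cached output of the internal static renderer;
#'   pass the same object across frames to avoid recomputation.
#' @return array `[Z, C, Y, X]` with channels nuclei, mitochondria, lysosomes.
#' @export
render_frame <- function(scene, frame, static = NULL) {
  p <- scene$params
  stopifnot(frame >= 1, frame <= p$n_frames)
  if (is.null(static)) static <- render_static(scene)
  dims <- scene$field_dim
  mito_comps <- render_mito_frame(scene, frame)
  # build planes contiguously as [Y, X, Z, C], then permute to [Z, C, Y, X]
  tmp <- array(0, dim = c(as.integer(dims[["Y"]]), as.integer(dims[["X"]]), p$n_z, 3))
  # deterministic per (seed, frame) noise stream, independent of call order
  set.seed((as.numeric(p$seed) * 1009 + 777 + frame * 31) %% 2147483647)
  nuc_comp <- list(); nuc_comp[[as.character(static$mid)]] <-
    static$nucleus_mid
  ny <- as.integer(scene$field_dim[["Y"]]); nx <- as.integer(scene$field_dim[["X"]])
  for (z in seq_len(p$n_z)) {
    nuc <- compose_plane(matrix(0, ny, nx), nuc_comp, z, p$background)
    mito <- compose_plane(static$haze_mito * z_weight(z, static$mid),
                          mito_comps, z, p$background)
    lys <- compose_plane(static$haze_lyso * z_weight(z, static$mid),
                         static$lyso_by_z, z, p$background)
    tmp[, , z, 1] <- clip16(apply_noise(nuc, p$noise_model))
    tmp[, , z, 2] <- clip16(apply_noise(mito, p$noise_model))
    tmp[, , z, 3] <- clip16(apply_noise(lys, p$noise_model))
  }
  out <- aperm(tmp, c(3, 4, 1, 2))
  dimnames(out) <- list(NULL, c("nuclei", "mitochondria", "lysosomes"),
                        NULL, NULL)
  out
}

#' Render the full time-lapse of a synthetic scene
#'
#' @param scene a `synthetic_scene`.
#' @return an [image_stack()] with pixels `[T, Z, C, Y, X]`.
#' @export
render_timelapse <- function(scene) {
  p <- scene$params
  dims <- scene$field_dim
  static <- render_static(scene)
  px <- array(0, dim = c(p$n_frames, p$n_z, 3, as.integer(dims[["Y"]]), as.integer(dims[["X"]])))
  for (t in seq_len(p$n_frames))
    px[t, , , , ] <- render_frame(scene, t, static = static)
  image_stack(px, pixel_size = p$pixel_size, frame_interval = p$frame_interval,
              channel_names = c("nuclei", "mitochondria", "lysosomes"))
}

#' Render a fixed-assay multichannel projection from a scene
#'
#' Builds noise-free-geometry fixed-stain channels on top of a scene's
#' layout: `tomm20` mirrors the mitochondria channel scaled by
#' `tomm20_scale`; `lc3` mirrors the lysosome channel (autophagosome
#' puncta); `marker` fills the cytoplasm of the cells listed in
#' `marker_cells`; `caspase` places `spot_counts[cell]` bright puncta inside
#' each cell. The same noise model as the live render is applied per plane
#' and the maximum projection over z is returned.
#'
#' @param scene a `synthetic_scene`.
#' @param frame which frame's engulfment state to use.
#' @param tomm20_scale multiplier on mitochondrial intensity for the Tomm20
#'   channel (group differences in Tomm20 amount).
#' @param marker_cells integer cell ids rendered marker-positive.
#' @param marker_intensity in-focus marker fill intensity (a.u.).
#' @param spot_counts integer vector, one per cell: caspase-3 spots to place.
#' @param spot_intensity,spot_radius spot rendering parameters.
#' @return array `[C, Y, X]` with channels nuclei, tomm20, lc3, marker,
#'   caspase (a max projection, ready for the segmentation functions).
#' @export
render_fixed <- function(scene, frame = 1, tomm20_scale = 1,
                         marker_cells = integer(0), marker_intensity = 2000,
                         spot_counts = NULL, spot_intensity = 5000,
                         spot_radius = 2) {
  p <- scene$params
  dims <- scene$field_dim
  static <- render_static(scene)
  mito_comps <- render_mito_frame(scene, frame)
  blank <- function() matrix(0, dims["Y"], dims["X"])

  tomm <- blank()
  for (key in names(mito_comps)) {
    cm <- mito_comps[[key]]
    tomm[cm$idx] <- tomm[cm$idx] + cm$val
  }
  tomm <- (tomm + static$haze_mito) * tomm20_scale
  lc3 <- blank()
  for (key in names(static$lyso_by_z)) {
    cm <- static$lyso_by_z[[key]]
    lc3[cm$idx] <- lc3[cm$idx] + cm$val
  }
  lc3 <- lc3 + static$haze_lyso

  marker <- blank()
  for (ci in marker_cells) {
    cl <- scene$cells[[ci]]
    marker <- add_polygon(marker, cl$vertices[, 1], cl$vertices[, 2],
                          marker_intensity)
  }

  set.seed((as.numeric(p$seed) * 2017 + 97 + frame) %% 2147483647)
  casp <- blank()
  if (!is.null(spot_counts)) {
    stopifnot(length(spot_counts) == length(scene$cells))
    for (ci in seq_along(scene$cells)) {
      k <- spot_counts[ci]
      if (k == 0) next
      pos <- sample_positions(k, scene$cells[[ci]],
                              radii = rep(spot_radius + 2, k), gap = 4)
      for (j in seq_len(k))
        casp <- add_ellipse(casp, pos[j, 1], pos[j, 2], spot_radius,
                            spot_radius, 0, spot_intensity)
    }
  }

  nuc <- blank()
  nuc[static$nucleus_mid$idx] <- static$nucleus_mid$val
  chans <- list(nuclei = nuc, tomm20 = tomm, lc3 = lc3,
                marker = marker, caspase = casp)
  out <- array(0, dim = c(5, dims["Y"], dims["X"]),
               dimnames = list(names(chans), NULL, NULL))
  for (i in seq_along(chans))
    out[i, , ] <- clip16(apply_noise(chans[[i]] + p$background, p$noise_model))
  out
}

#' Generate a synthetic ATP luminescence plate
#'
#' Wells are drawn from a gamma distribution (positive-valued) around each
#' condition mean with coefficient of variation `cv`; `cv = 0` returns the
#' means exactly. Deterministic for a fixed seed.
#'
#' @param group_means named numeric: mean luminescence per condition; names
#'   must be a subset of untreated, oligomycin, 2DG, both and must include
#'   untreated (the partition is undefined without it).
#' @param cv coefficient of variation of well noise (fraction, >= 0).
#' @param n_wells wells per condition.
#' @param seed integer seed.
#' @param timepoint optional differentiation day label.
#' @param group optional genotype label.
#' @return `atp_plate` data.frame with columns well, condition, luminescence
#'   (plus timepoint/group when given).
#' @export
generate_atp_plate <- function(group_means, cv, n_wells, seed = 1L,
                               timepoint = NA, group = NA) {
  allowed <- c("untreated", "oligomycin", "2DG", "both")
  if (is.null(names(group_means)) || !all(names(group_means) %in% allowed))
    stop("group_means must be named with conditions among: ",
         paste(allowed, collapse = ", "))
  if (!"untreated" %in% names(group_means))
    stop("missing untreated condition: the ATP partition is undefined without it")
  if (cv < 0) stop("cv must be >= 0")
  if (any(group_means < 0)) stop("luminescence means must be >= 0")
  set.seed(as.integer(seed) %% 2147483647L)
  rows <- lapply(names(group_means), function(cond) {
    m <- group_means[[cond]]
    lum <- if (cv == 0 || m == 0) rep(m, n_wells) else
      stats::rgamma(n_wells, shape = 1 / cv^2, scale = m * cv^2)
    data.frame(well = paste0(cond, "_", seq_len(n_wells)),
               condition = cond, luminescence = lum)
  })
  plate <- do.call(rbind, rows)
  plate$timepoint <- timepoint
  plate$group <- group
  class(plate) <- c("atp_plate", "data.frame")
  plate
}
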