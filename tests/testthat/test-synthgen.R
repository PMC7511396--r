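test_that("engulfment probability extremes give all-zero and all-one fractions", {
  sc0 <- generate_scene(tiny_params(seed = 3, basal_engulf_prob = 0))
  expect_true(all(ground_truth_fractions(sc0) == 0, na.rm = TRUE))
  sc1 <- generate_scene(tiny_params(seed = 3, basal_engulf_prob = 1))
  expect_true(all(ground_truth_fractions(sc1) == 1, na.rm = TRUE))
})

test_that("ground-truth engulfed fraction matches the sampling rate within 2 SE", {
  # binomial oracle: mean of N iid Bernoulli(p) draws
  p <- 0.09
  sc <- generate_scene(scene_params(n_cells = 50, mito_per_cell_mean = 20,
                                    n_frames = 10, basal_engulf_prob = p,
                                    seed = 101))
  counts <- vapply(sc$engulf, nrow, integer(1))
  n_draws <- sum(counts) * sc$params$n_frames
  eng <- sum(vapply(sc$engulf, sum, numeric(1)))
  se <- sqrt(p * (1 - p) / n_draws)
  expect_lt(abs(eng / n_draws - p), 2 * se)
})

test_that("ground truth equals engulfed/mito count exactly on every frame", {
  sc <- generate_scene(tiny_params(seed = 9, basal_engulf_prob = 0.3))
  gt <- ground_truth_fractions(sc)
  for (ci in seq_along(sc$cells)) {
    n <- sc$cells[[ci]]$n_mito
    if (n == 0) next
    expect_equal(gt[ci, ], colSums(sc$engulf[[ci]]) / n)
  }
})

test_that("expected engulfed fraction increases with the engulfment probability", {
  means <- vapply(c(0.05, 0.2, 0.45, 0.7), function(p) {
    sc <- generate_scene(scene_params(n_cells = 12, mito_per_cell_mean = 10,
                                      n_frames = 4, basal_engulf_prob = p,
                                      seed = 77))
    mean(ground_truth_fractions(sc), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("fixed seed gives bit-identical scenes and renders; seeds differ pixelwise", {
  p <- tiny_params(seed = 21)
  expect_identical(generate_scene(p), generate_scene(p))
  sc <- generate_scene(p)
  expect_identical(render_frame(sc, 1), render_frame(sc, 1))
  sc2 <- generate_scene(tiny_params(seed = 22))
  fr1 <- render_frame(sc, 1)
  fr2 <- render_frame(sc2, 1)
  expect_false(identical(fr1, fr2))
  # same summary statistics within sampling error (same generative law)
  expect_lt(abs(mean(fr1) - mean(fr2)) / mean(fr1), 0.1)
})

test_that("geometry is unchanged when only the noise model changes", {
  a <- generate_scene(tiny_params(seed = 5))
  b <- generate_scene(tiny_params(seed = 5,
                                  noise_model = list(gaussian_sd = 120,
                                                     poisson_scale = 20)))
  expect_identical(a$mito, b$mito)
  expect_identical(a$lyso, b$lyso)
  expect_identical(a$engulf, b$engulf)
})

test_that("noise-free render thresholded at half object intensity recovers masks", {
  sc <- generate_scene(tiny_params(seed = 13, noise_model = noise_free,
                                   basal_engulf_prob = 0))
  proj <- render_projection(sc, 1)
  mito_img <- proj["mitochondria", , ]
  ny <- sc$field_dim["Y"]; nx <- sc$field_dim["X"]
  truth <- matrix(FALSE, ny, nx)
  for (k in seq_len(nrow(sc$mito)))
    truth[mitoquant:::ellipse_pixels(sc$mito$x[k], sc$mito$y[k], sc$mito$a[k],
                                     sc$mito$b[k], sc$mito$phi[k],
                                     ny, nx)] <- TRUE
  thr <- sc$params$background + unname(sc$params$cyto_haze["mitochondria"]) +
    0.5 * min(sc$mito$intensity)
  expect_identical(unname(mito_img > thr), truth)
})

test_that("a single known mitochondrion is brightest at its coordinates", {
  sc <- generate_scene(tiny_params(n_cells = 1, mito_per_cell_mean = 0,
                                   lyso_per_cell_mean = 0, seed = 2,
                                   noise_model = noise_free))
  sc$mito <- data.frame(cell = 1L, mito = 1L, x = 60.5, y = 70.5, a = 3,
                        b = 1.5, phi = 0,
                        intensity = 3000,
                        z0 = as.integer(ceiling(sc$params$n_z / 2)))
  sc$cells[[1]]$n_mito <- 1L
  sc$engulf[[1]] <- matrix(FALSE, 1, sc$params$n_frames)
  sc$hosts[[1]] <- matrix(NA_integer_, 1, sc$params$n_frames)
  proj <- render_projection(sc, 1)
  img <- proj["mitochondria", , ]
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_true(any(abs(peak[, 1] - 71) <= 2 & abs(peak[, 2] - 61) <= 2))
})

test_that("engulfed mitochondria are rendered wholly inside their host lysosome", {
  sc <- generate_scene(tiny_params(seed = 31, basal_engulf_prob = 0.5,
                                   noise_model = noise_free))
  ny <- sc$field_dim["Y"]; nx <- sc$field_dim["X"]
  row0 <- 0L
  for (ci in seq_along(sc$cells)) {
    n <- sc$cells[[ci]]$n_mito
    if (n == 0) next
    E <- sc$engulf[[ci]][, 1]; H <- sc$hosts[[ci]][, 1]
    ld <- sc$lyso[sc$lyso$cell == ci, , drop = FALSE]
    for (k in which(E)) {
      m <- sc$mito[row0 + k, ]
      host <- ld[H[k], ]
      fit <- sc$params$lyso_radius / sc$params$pixel_size - 2
      s <- min(1, fit / m$a)
      mpx <- mitoquant:::ellipse_pixels(host$x, host$y, m$a * s, m$b * s,
                                        m$phi, ny, nx)
      lpx <- mitoquant:::ellipse_pixels(host$x, host$y, host$r, host$r, 0,
                                        ny, nx)
      expect_true(all(mpx %in% lpx))
    }
    row0 <- row0 + n
  }
})

test_that("requested cell elongation is achieved within 10% in the raster", {
  for (E in c(1.5, 2, 3)) {
    sc <- generate_scene(tiny_params(n_cells = 4, mito_per_cell_mean = 0,
                                     lyso_per_cell_mean = 0, seed = 8,
                                     cell_elongation_ratio = E,
                                     cell_roundness_target = 1))
    ny <- sc$field_dim["Y"]; nx <- sc$field_dim["X"]
    for (cl in sc$cells) {
      lab <- matrix(0L, ny, nx)
      lab[mitoquant:::polygon_pixels(cl$vertices[, 1], cl$vertices[, 2],
                                     ny, nx)] <- 1L
      g <- mitoquant:::label_geometry(lab)
      expect_lt(abs(g$elongation / E - 1), 0.1)
    }
  }
})

test_that("impossible geometry fails with an explicit constraint error", {
  expect_error(
    generate_scene(tiny_params(n_cells = 1, cell_radius = 3,
                               mito_per_cell_mean = 80, seed = 1)),
    "impossible geometry")
  expect_error(
    generate_scene(tiny_params(n_cells = 1, cell_radius = 1.2,
                               lyso_per_cell_mean = 10, seed = 1)),
    "impossible geometry")
})

test_that("parameter invariants are enforced", {
  expect_error(tiny_params(basal_engulf_prob = 1.2), "probability")
  expect_error(tiny_params(frame_interval = 0), "frame_interval")
  expect_error(tiny_params(induced_engulf_curve = c(0.1, 0.2, 0.3)),
               "length n_frames")
  expect_error(tiny_params(cell_elongation_ratio = 0.5), "elongation")
})

test_that("ATP plate generator: cv = 0 reproduces means exactly, cv > 0 obeys the CLT", {
  means <- c(untreated = 15.1, oligomycin = 3.5, "2DG" = 8.5)
  pl <- generate_atp_plate(means, cv = 0, n_wells = 6, seed = 4)
  for (cond in names(means))
    expect_equal(pl$luminescence[pl$condition == cond],
                 rep(unname(means[cond]), 6))
  # CLT oracle: sample mean within 3 SE of each group mean
  pl2 <- generate_atp_plate(means, cv = 0.1, n_wells = 100, seed = 4)
  for (cond in names(means)) {
    m <- unname(means[cond])
    se <- 0.1 * m / sqrt(100)
    expect_lt(abs(mean(pl2$luminescence[pl2$condition == cond]) - m), 3 * se)
  }
  expect_identical(generate_atp_plate(means, 0.1, 12, seed = 9),
                   generate_atp_plate(means, 0.1, 12, seed = 9))
})

test_that("ATP plate generator refuses a plate without untreated wells", {
  expect_error(generate_atp_plate(c(oligomycin = 3.5), cv = 0, n_wells = 4),
               "untreated")
})

test_that("equal condition means partition to 0% for both pathways", {
  pl <- generate_atp_plate(c(untreated = 5, oligomycin = 5, "2DG" = 5),
                           cv = 0, n_wells = 4)
  part <- atp_partition(pl)
  expect_equal(part$pct_oxphos, 0)
  expect_equal(part$pct_glycolysis, 0)
})
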