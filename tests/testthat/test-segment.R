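make_stack <- function(px, ...) image_stack(px, pixel_size = 0.3, ...)

test_that("max projection is the identity on single-plane stacks", {
  px <- array(runif(1 * 1 * 2 * 20 * 30, 0, 100), dim = c(1, 1, 2, 20, 30))
  st <- make_stack(px, channel_names = c("a", "b"))
  proj <- max_project(st, 1)
  expect_equal(proj["a", , ], px[1, 1, 1, , ])
  expect_equal(proj["b", , ], px[1, 1, 2, , ])
})

test_that("max projection picks the plane-wise maximum", {
  px <- array(0, dim = c(1, 3, 1, 1, 1))
  px[1, , 1, 1, 1] <- c(0, 5, 3)
  expect_equal(unname(max_project(make_stack(px), 1)[1, 1, 1]), 5)
})

test_that("max projection dominates every plane pixelwise (exhaustive oracle)", {
  set.seed(42)
  px <- array(runif(2 * 5 * 2 * 15 * 17, 0, 1000), dim = c(2, 5, 2, 15, 17))
  st <- make_stack(px, channel_names = c("a", "b"))
  for (t in 1:2) {
    proj <- max_project(st, t)
    for (z in 1:5) for (c in 1:2)
      expect_true(all(proj[c, , ] >= px[t, z, c, , ]))
    # and is attained: max over z equals the projection
    expect_equal(proj[1, , ], apply(px[t, , 1, , ], c(2, 3), max))
  }
  expect_error(max_project(st, 3), "frame out of range")
})

test_that("nucleus count is exact on a noise-free scene and zero on blank input", {
  sc <- generate_scene(tiny_params(seed = 14, noise_model = noise_free))
  proj <- render_projection(sc, 1)
  nuc <- segment_nuclei(proj)
  expect_equal(max(nuc), sc$params$n_cells)
  blank <- array(0, dim = c(1, 40, 40), dimnames = list("nuclei", NULL, NULL))
  expect_equal(max(segment_nuclei(blank)), 0)
})

test_that("nucleus counts at default noise stay within 5% of truth on average", {
  counts <- vapply(1:20, function(s) {
    sc <- generate_scene(tiny_params(seed = 300 + s))
    max(segment_nuclei(render_projection(sc, 1)))
  }, numeric(1))
  expect_lt(abs(mean(counts) / 6 - 1), 0.05)
})

test_that("each well-separated cell region contains its nucleus and they are disjoint", {
  sc <- generate_scene(tiny_params(n_cells = 2, seed = 6))
  seg <- segment_scene_frame(sc)
  expect_equal(max(seg$cells), 2)
  for (id in 1:2) {
    nuc_px <- which(seg$nuclei == id)
    expect_true(all(seg$cells[nuc_px] == id))
  }
})

test_that("an isolated cell's mask covers at least 90% of the ground-truth polygon", {
  sc <- generate_scene(tiny_params(n_cells = 1, seed = 19))
  seg <- segment_scene_frame(sc)
  ny <- nrow(seg$cells); nx <- ncol(seg$cells)
  cl <- sc$cells[[1]]
  truth <- mitoquant:::polygon_pixels(cl$vertices[, 1], cl$vertices[, 2],
                                      ny, nx)
  inter <- sum(seg$cells[truth] == 1)
  expect_gt(inter / length(truth), 0.9)
})

test_that("cell partition is invariant to nucleus label permutation", {
  sc <- generate_scene(tiny_params(n_cells = 4, seed = 23,
                                   noise_model = noise_free))
  proj <- render_projection(sc, 1)
  nuc <- segment_nuclei(proj)
  n <- max(nuc)
  perm <- c(3L, 1L, 4L, 2L)
  nuc_perm <- nuc
  nuc_perm[nuc > 0] <- perm[nuc[nuc > 0]]
  attr(nuc_perm, "class_name") <- "nucleus"
  a <- segment_cells(proj, nuc)
  b <- segment_cells(proj, nuc_perm)
  b_unperm <- b
  b_unperm[b > 0] <- order(perm)[b[b > 0]]
  expect_equal(unname(a == 0), unname(b == 0))
  expect_true(all(a[a > 0] == b_unperm[b_unperm > 0]))
})

test_that("organelle counts per cell are exact on noise-free scenes", {
  sc <- generate_scene(tiny_params(seed = 16, noise_model = noise_free))
  seg <- segment_scene_frame(sc)
  expect_equal(max(seg$mito), nrow(sc$mito))
  expect_equal(max(seg$lyso), nrow(sc$lyso))
  # per-cell counts match after matching segmented cells to generator cells
  # by nucleus centre
  truth_counts <- table(factor(sc$mito$cell, levels = seq_along(sc$cells)))
  got <- mito_stats_per_cell(seg$mito, seg$cells)
  centers <- t(vapply(sc$cells, function(cl) cl$center, numeric(2)))
  lab_at <- seg$cells[cbind(round(centers[, 2]), round(centers[, 1]))]
  expect_equal(got$mito_count[match(lab_at, got$cell_id)],
               as.integer(truth_counts))
})

test_that("organelle counts at default noise are within 5% of truth on average", {
  rel <- vapply(1:8, function(s) {
    sc <- generate_scene(tiny_params(seed = 500 + s))
    seg <- segment_scene_frame(sc)
    max(seg$mito) / nrow(sc$mito)
  }, numeric(1))
  expect_lt(abs(mean(rel) - 1), 0.05)
})

test_that("objects below min_area are excluded", {
  cells <- matrix(1L, 30, 30)
  attr(cells, "class_name") <- "cell"
  img <- matrix(0, 30, 30)
  img[10, 10] <- 5000          # 1 px: below min_area = 3
  img[20:21, 20:22] <- 5000    # 6 px: kept
  proj <- array(img, dim = c(1, 30, 30),
                dimnames = list("mitochondria", NULL, NULL))
  lab <- segment_organelles(proj, cells, "mitochondrion", min_area = 3,
                            tophat_radius = 4)
  expect_equal(max(lab), 1)
  expect_true(all(which(lab == 1) %in%
                    which(row(img) %in% 20:21 & col(img) %in% 20:22)))
  expect_error(segment_organelles(proj, cells, "ribosome"), "arg")
})

test_that("spot detection is exact on constructed scenes and zero on blank channels", {
  sc <- generate_scene(tiny_params(seed = 25, mito_per_cell_mean = 5))
  truth_spots <- c(2L, 0L, 1L, 3L, 0L, 1L)
  fx <- render_fixed(sc, spot_counts = truth_spots)
  st <- segment_scene_frame(sc)
  sp <- detect_spots(fx, st$cells, "caspase")
  # match segmented cell ids to generator cells via nucleus centres
  centers <- t(vapply(sc$cells, function(cl) cl$center, numeric(2)))
  lab_at <- st$cells[cbind(round(centers[, 2]), round(centers[, 1]))]
  expect_equal(sp$spot_count[match(lab_at, sp$cell_id)], truth_spots)
  expect_equal(sp$positive[match(lab_at, sp$cell_id)], truth_spots >= 1)
  blank <- fx
  blank["caspase", , ] <- sc$params$background
  sp0 <- detect_spots(blank, st$cells, "caspase")
  expect_true(all(sp0$spot_count == 0))
})

test_that("marker positivity recovers the generated fraction", {
  # all-on and all-off extremes
  sc <- generate_scene(tiny_params(seed = 33))
  st <- segment_scene_frame(sc)
  fx_all <- render_fixed(sc, marker_cells = seq_along(sc$cells))
  expect_equal(as.numeric(marker_positive_fraction(fx_all, st$cells,
                                                   "marker")), 100)
  fx_none <- render_fixed(sc, marker_cells = integer(0))
  expect_equal(as.numeric(marker_positive_fraction(fx_none, st$cells,
                                                   "marker")), 0)
  expect_error(marker_positive_fraction(fx_all, matrix(0L, 10, 10), "marker"),
               "at least one")
})

test_that("a population generated 89.9% marker-positive is recovered within binomial error", {
  # three replicate fields, 16 cells each, each cell positive w.p. 0.899
  p_true <- 0.899
  set.seed(1203)
  got <- vapply(1:3, function(s) {
    sc <- generate_scene(tiny_params(n_cells = 16, seed = 880 + s))
    pos <- which(stats::runif(16) < p_true)
    fx <- render_fixed(sc, marker_cells = pos)
    st <- segment_scene_frame(sc)
    c(as.numeric(marker_positive_fraction(fx, st$cells, "marker")),
      length(pos))
  }, numeric(2))
  n <- sum(got[2, ])
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(got[1, ]) / 100 - p_true), 2 * se + 1e-9)
})

test_that("label maps share the projection grid and organelles stay within cells", {
  sc <- generate_scene(tiny_params(seed = 44))
  seg <- segment_scene_frame(sc)
  expect_equal(dim(seg$nuclei), dim(seg$cells))
  expect_equal(dim(seg$mito), dim(seg$cells))
  sel <- seg$mito > 0
  expect_true(all(seg$cells[sel] > 0))
  cell_of <- attr(seg$mito, "cell_of")
  expect_true(all(cell_of[seg$mito[sel]] == seg$cells[sel]))
})
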