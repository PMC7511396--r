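lab_map <- function(m) {
  storage.mode(m) <- "integer"
  m
}

test_that("a mitochondrion wholly inside a lysosome is one event at overlap 1.0", {
  mito <- lab_map(matrix(0, 20, 20)); mito[9:11, 9:11] <- 1
  lyso <- lab_map(matrix(0, 20, 20)); lyso[7:13, 7:13] <- 1
  ev <- detect_mitophagy_events(mito, lyso)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$overlap_fraction, 1)
  expect_equal(ev$lyso_label, 1L)
})

test_that("50% overlap is not an event at the default threshold but is at 0.5", {
  mito <- lab_map(matrix(0, 20, 20)); mito[9:10, 9:12] <- 1
  lyso <- lab_map(matrix(0, 20, 20)); lyso[9:10, 11:14] <- 1  # covers half
  expect_equal(nrow(detect_mitophagy_events(mito, lyso)), 0)
  ev <- detect_mitophagy_events(mito, lyso, overlap_threshold = 0.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$overlap_fraction, 0.5)
})

test_that("containment agrees with brute force on all 2^9 masks at all offsets", {
  # lysosome: fixed 3x3 block; mitochondrion: every non-empty 3x3 mask at
  # every placement on a 7x7 grid; oracle = pixel-set containment
  lyso <- lab_map(matrix(0, 7, 7)); lyso[3:5, 3:5] <- 1
  lyso_set <- which(lyso == 1)
  for (bits in 1:511) {
    cfg <- as.integer(intToBits(bits))[1:9]
    for (oy in 0:4) for (ox in 0:4) {
      mito <- matrix(0L, 7, 7)
      mito[oy + 1:3, ox + 1:3] <- cfg
      mset <- which(mito == 1)
      expected <- all(mset %in% lyso_set)
      got <- nrow(detect_mitophagy_events(mito, lyso)) == 1
      if (got != expected)
        fail(sprintf("mismatch at bits=%d oy=%d ox=%d", bits, oy, ox))
    }
  }
  succeed()
})

test_that("event count is monotone non-increasing in the overlap threshold", {
  set.seed(7)
  mito <- lab_map(matrix(0, 40, 40))
  for (i in 1:8) {
    y <- sample(3:36, 1); x <- sample(3:36, 1)
    mito[y + 0:1, x + 0:1] <- i
  }
  lyso <- lab_map(matrix(0, 40, 40))
  lyso[sample(1600, 500)] <- 1
  counts <- vapply(c(0.25, 0.5, 0.75, 1),
                   function(th) nrow(detect_mitophagy_events(
                     mito, lyso, overlap_threshold = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("single-lysosome containment is stricter than class-union containment", {
  # mitochondrion straddling two touching lysosomes: union covers it fully,
  # no single label does
  mito <- lab_map(matrix(0, 10, 10)); mito[5, 4:7] <- 1
  lyso <- lab_map(matrix(0, 10, 10))
  lyso[3:7, 2:5] <- 1; lyso[3:7, 6:9] <- 2
  expect_equal(nrow(detect_mitophagy_events(mito, lyso)), 0)
  ev <- detect_mitophagy_events(mito, lyso, single_lysosome = FALSE)
  expect_equal(nrow(ev), 1)
})

test_that("per-cell fraction handles the trivial extremes and zero-mito exclusion", {
  counts <- data.frame(cell_id = 1:3, mito_count = c(20L, 20L, 0L))
  no_ev <- data.frame(cell_id = integer(0), mito_label = integer(0))
  expect_message(r0 <- mitophagy_fraction_per_cell(no_ev, counts), "zero")
  expect_equal(r0$m, c(0, 0))
  all_ev <- data.frame(cell_id = rep(1L, 20), mito_label = 1:20)
  r1 <- suppressMessages(mitophagy_fraction_per_cell(all_ev, counts))
  expect_equal(r1$m[r1$cell_id == 1], 1)
  # the same mitochondrion seen twice is one distinct event
  dup <- data.frame(cell_id = c(1L, 1L), mito_label = c(5L, 5L))
  r2 <- suppressMessages(mitophagy_fraction_per_cell(dup, counts))
  expect_equal(r2$m[r2$cell_id == 1], 1 / 20)
})

test_that("pipeline fraction equals generator ground truth exactly on noise-free renders", {
  sc <- generate_scene(tiny_params(seed = 71, basal_engulf_prob = 0.2,
                                   noise_model = noise_free, n_frames = 3))
  static <- mitoquant:::render_static(sc)
  for (t in 1:3) {
    seg <- segment_scene_frame(sc, t, static = static)
    ev <- detect_mitophagy_events(seg$mito, seg$lyso, frame = t)
    expect_equal(nrow(ev), truth_engulfed(sc, t))
  }
})

test_that("live fraction tracks ground truth within 10% relative at default noise", {
  sc <- generate_scene(scene_params(n_cells = 12, mito_per_cell_mean = 15,
                                    n_frames = 4, basal_engulf_prob = 0.25,
                                    seed = 83))
  static <- mitoquant:::render_static(sc)
  got <- truth <- 0
  for (t in 1:4) {
    seg <- segment_scene_frame(sc, t, static = static)
    got <- got + nrow(detect_mitophagy_events(seg$mito, seg$lyso, frame = t))
    truth <- truth + truth_engulfed(sc, t)
  }
  expect_lt(abs(got / truth - 1), 0.1)
})

test_that("time-course assembly orders frames in minutes and summarizes per frame", {
  fr <- expand.grid(cell_id = 1:5, frame = 1:4)
  fr$m <- 0.1
  tc <- assemble_timecourse(fr, condition = "basal", frame_interval = 18)
  expect_equal(tc$minutes, c(0, 18, 36, 54))
  expect_equal(tc$mean_m, rep(0.1, 4))       # constant input -> flat series
  expect_equal(tc$n, rep(5L, 4))
  expect_error(assemble_timecourse(fr[fr$frame == 1, ]), "at least 2 frames")
})

test_that("unequal frame counts across fields truncate to the shortest with a warning", {
  f1 <- expand.grid(cell_id = 1:3, frame = 1:5); f1$m <- 0.2
  f2 <- expand.grid(cell_id = 1:3, frame = 1:3); f2$m <- 0.4
  expect_warning(tc <- assemble_timecourse(list(f1, f2)), "truncat")
  expect_equal(nrow(tc), 3)
  expect_equal(tc$mean_m, rep(0.3, 3))
})

test_that("induced series reproduces the generator's rise-then-fall ordering", {
  # step up then decay, as when mitophagy cannot be sustained after induction
  curve <- c(0.05, 0.35, 0.35, 0.22, 0.12)
  sc <- generate_scene(scene_params(n_cells = 15, mito_per_cell_mean = 15,
                                    n_frames = 5,
                                    induced_engulf_curve = curve, seed = 97))
  static <- mitoquant:::render_static(sc)
  per_frame <- vapply(1:5, function(t) {
    seg <- segment_scene_frame(sc, t, static = static)
    ev <- detect_mitophagy_events(seg$mito, seg$lyso, frame = t)
    counts <- mito_stats_per_cell(seg$mito, seg$cells)
    mean(suppressMessages(
      mitophagy_fraction_per_cell(ev, counts[, c("cell_id", "mito_count")]))$m)
  }, numeric(1))
  peak <- which.max(per_frame)
  expect_true(peak %in% c(2, 3))             # rises after induction
  expect_lt(per_frame[5], per_frame[peak])   # then falls
  expect_gt(per_frame[peak], per_frame[1])
})

test_that("Tomm20 readout is linear, zero on blank channels, and group ratios recover", {
  sc <- generate_scene(tiny_params(seed = 55))
  seg <- segment_scene_frame(sc)
  fx1 <- render_fixed(sc, tomm20_scale = 1)
  fx15 <- render_fixed(sc, tomm20_scale = 1.5)
  r1 <- tomm20_loss_readout(fx1, seg$cells)
  r15 <- tomm20_loss_readout(fx15, seg$cells)
  expect_lt(abs(mean(r15$tomm20_amount) / mean(r1$tomm20_amount) / 1.5 - 1),
            0.1)
  # doubling all intensities doubles the readout (background scales too)
  fx2 <- fx1; fx2["tomm20", , ] <- 2 * fx1["tomm20", , ]
  r2 <- tomm20_loss_readout(fx2, seg$cells)
  expect_equal(r2$tomm20_amount, 2 * r1$tomm20_amount)
  blank <- fx1; blank["tomm20", , ] <- 0
  expect_true(all(tomm20_loss_readout(blank, seg$cells)$tomm20_amount == 0))
})

test_that("LC3/Tomm20 colocalization counts contained objects and 0 when disjoint", {
  # constructed masks through the same containment rule
  cells <- matrix(1L, 30, 30)
  mito <- lab_map(matrix(0, 30, 30))
  mito[5:6, 5:6] <- 1; mito[15:16, 15:16] <- 2; mito[25:26, 25:26] <- 3
  lyso <- lab_map(matrix(0, 30, 30))
  lyso[4:7, 4:7] <- 1; lyso[14:17, 14:17] <- 2; lyso[24:27, 24:27] <- 3
  ev <- detect_mitophagy_events(mito, lyso)
  expect_equal(nrow(ev), 3)
  disjoint <- lab_map(matrix(0, 30, 30)); disjoint[1:2, 28:29] <- 1
  expect_equal(nrow(detect_mitophagy_events(mito, disjoint)), 0)
  # end-to-end on a rendered fixed stain: colocalized count equals the
  # engulfed count of the frame
  sc <- generate_scene(tiny_params(seed = 72, basal_engulf_prob = 0.3))
  seg <- segment_scene_frame(sc)
  fx <- render_fixed(sc, frame = 1)
  co <- lc3_tomm20_colocalization(fx, seg$cells)
  expect_equal(sum(co$colocalized), truth_engulfed(sc, 1))
})

test_that("fixed and live assays rank groups identically on the same scenes", {
  run_both <- function(p_basal, seed) {
    sc <- generate_scene(tiny_params(seed = seed, basal_engulf_prob = p_basal,
                                     n_frames = 2))
    seg <- segment_scene_frame(sc)
    ev <- detect_mitophagy_events(seg$mito, seg$lyso, frame = 1)
    counts <- mito_stats_per_cell(seg$mito, seg$cells)
    live <- mean(suppressMessages(mitophagy_fraction_per_cell(
      ev, counts[, c("cell_id", "mito_count")]))$m)
    fx <- render_fixed(sc, frame = 1)
    co <- lc3_tomm20_colocalization(fx, seg$cells)
    fixed <- mean(co$fraction, na.rm = TRUE)
    c(live = live, fixed = fixed)
  }
  hi <- run_both(0.3, 201)
  lo <- run_both(0.05, 202)
  expect_gt(hi["live"], lo["live"])
  expect_gt(hi["fixed"], lo["fixed"])
})
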