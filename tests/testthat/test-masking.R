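# a hand-made segmentation object is enough for mask construction
fake_segmentation <- function(interior) {
  structure(list(interior = interior, pm = matrix(0L, nrow(interior), ncol(interior)),
                 outside = interior == 0L, line = interior < 0L,
                 cell_ids = sort(unique(interior[interior > 0])),
                 border_flag = stats::setNames(logical(1), "1"), outside_label = 2L),
            class = "cell_segmentation")
}

test_that("membrane threshold is the configured multiple of the background mean", {
  n <- matrix(5, 10, 10); t <- matrix(5, 10, 10)
  bg <- estimate_background(channel_stack(n, t), c(0L, 0L, 4L, 4L))
  expect_equal(f66_membrane_threshold(bg), 40) # 4 x (5 + 5)
  expect_equal(f66_membrane_threshold(bg, multiplier = 2), 20)
  expect_equal(f66_membrane_threshold(bg, relief_channel = "n"), 20)
  expect_error(f66_membrane_threshold(bg, multiplier = 0), "> 0")
  zero <- estimate_background(channel_stack(matrix(0, 4, 4), matrix(0, 4, 4)),
                              c(0L, 0L, 4L, 4L))
  expect_equal(f66_membrane_threshold(zero), 0)
})

test_that("exactly the pixels above 4x background survive on a toy interior", {
  # 8x8 image, 6x6 interior block with 9 bright pixels (relief 50), rest dim
  n <- matrix(2.5, 8, 8); t <- matrix(2.5, 8, 8)
  n[3:5, 3:5] <- 25; t[3:5, 3:5] <- 25 # 9 pixels at relief 50
  n[7:8, 1:4] <- 5; t[7:8, 1:4] <- 5   # background area: relief 10
  stack <- channel_stack(n, t)
  interior <- matrix(0L, 8, 8); interior[2:7, 2:7] <- 1L
  seg <- fake_segmentation(interior)
  bg <- estimate_background(stack, c(6L, 0L, 8L, 4L))
  expect_equal(f66_membrane_threshold(bg), 40)
  masks <- build_compartment_masks(stack, seg, bg, run_config())
  expect_equal(sum(masks$intracellular > 0), 9)
})

test_that("maxentropy split matches the exhaustively evaluated criterion", {
  # two spikes, equal mass: every separating split ties; lowest bin wins
  h <- numeric(256); h[11] <- 500; h[201] <- 500
  expect_equal(maxentropy_threshold(h)$bin, 12) # first bin above the low spike
  expect_equal(kapur_oracle(h), 12)

  # uniform histogram: symmetric criterion peaks at the midpoint split
  u <- rep(4, 256)
  expect_equal(maxentropy_threshold(u)$bin, 129)
  expect_equal(kapur_oracle(u), 129)

  # bimodal mixture: threshold strictly between the modes, equal to oracle
  set.seed(7)
  v <- c(rnorm(5000, 30, 8), rnorm(5000, 180, 15))
  h2 <- graphics::hist(v, breaks = seq(min(v) - 1, max(v) + 1, length.out = 257),
                       plot = FALSE)$counts
  res <- maxentropy_threshold(h2)
  expect_equal(res$bin, kapur_oracle(h2))
  mode1 <- which.max(h2[1:100]); mode2 <- 100 + which.max(h2[101:256])
  expect_gt(res$bin, mode1)
  expect_lt(res$bin, mode2)

  # random histograms, varying bin counts
  set.seed(31)
  for (i in 1:20) {
    k <- sample(c(8, 32, 64, 256), 1)
    h3 <- rpois(k, lambda = sample(1:20, 1))
    if (sum(h3 > 0) < 2) next
    expect_equal(maxentropy_threshold(h3)$bin, kapur_oracle(h3))
  }

  expect_error(maxentropy_threshold(c(0, 5, 0)), "one bin")
  expect_error(maxentropy_threshold(7), ">= 2 bins")
})

test_that("organelle and membrane masks follow their thresholds on clean data", {
  img <- noise_free_cell()
  cfg <- run_config(organelle_label = "lysosome")
  seg <- segment_cells(img$stack, img$seeds, cfg)
  bg <- estimate_background(img$stack, img$seeds$background_roi)
  masks <- build_compartment_masks(img$stack, seg, bg, cfg)
  expect_identical(masks$organelle > 0, img$truth$organelle_mask > 0)
  expect_equal(masks$marker_threshold_provenance, "auto")
  # intracellular-membrane mask = organelle + endomembrane + the bright
  # juxtamembrane flank inside the basin
  inner_flank <- (img$truth$interior_mask > 0) &
    !binary_erode(img$truth$interior_mask > 0, 1, 4)
  expected <- (img$truth$organelle_mask > 0) |
    (img$truth$endomembrane_mask > 0) | inner_flank
  expect_identical(masks$intracellular > 0, expected)
})

test_that("mask invariants: subset of interior, monotone in the threshold", {
  ds <- generate_experiment("skbr3", "lysosome", 1, seed = 88,
                            params = synthetic_params(image_size = 128))
  entry <- ds$images[[1]]
  cfg <- run_config(organelle_label = "lysosome")
  seg <- segment_cells(entry$stack, entry$seeds, cfg)
  bg <- estimate_background(entry$stack, entry$seeds$background_roi)
  auto <- build_compartment_masks(entry$stack, seg, bg, cfg)
  expect_true(all(seg$interior[auto$organelle > 0] > 0))
  expect_true(all(seg$interior[auto$intracellular > 0] > 0))
  expect_equal(sum(auto$organelle > 0 & seg$pm > 0), 0)
  # raising the threshold never adds pixels
  lo <- build_compartment_masks(entry$stack, seg, bg,
                                run_config(organelle_label = "lysosome",
                                           marker_threshold_override = auto$marker_threshold))
  hi <- build_compartment_masks(entry$stack, seg, bg,
                                run_config(organelle_label = "lysosome",
                                           marker_threshold_override = auto$marker_threshold * 1.5))
  expect_equal(lo$marker_threshold_provenance, "override")
  expect_true(all(which(hi$organelle > 0) %in% which(lo$organelle > 0)))
  hi_f66 <- build_compartment_masks(entry$stack, seg, bg,
                                    run_config(f66_threshold_multiplier = 6))
  expect_true(all(which(hi_f66$intracellular > 0) %in% which(auto$intracellular > 0)))
})

test_that("the maxentropy class partition is invariant to intensity rescaling", {
  ds <- generate_experiment("skbr3", "lysosome", 1, seed = 12,
                            params = synthetic_params(image_size = 128))
  entry <- ds$images[[1]]
  cfg <- run_config(organelle_label = "lysosome")
  seg <- segment_cells(entry$stack, entry$seeds, cfg)
  bg <- estimate_background(entry$stack, entry$seeds$background_roi)
  m1 <- build_compartment_masks(entry$stack, seg, bg, cfg)
  scaled <- entry$stack
  scaled$marker <- scaled$marker * 3.7
  m2 <- build_compartment_masks(scaled, seg, bg, cfg)
  expect_identical(m1$organelle, m2$organelle)
  expect_equal(m2$marker_threshold, m1$marker_threshold * 3.7)
})

test_that("recovered organelle mask overlaps truth strongly under noise", {
  # marker amplitude 120 over shot+read noise => SNR well above 5
  ds <- generate_experiment("skbr3", "lysosome", 3, seed = 55,
                            params = synthetic_params(image_size = 160))
  for (entry in ds$images) {
    cfg <- run_config(organelle_label = "lysosome")
    seg <- segment_cells(entry$stack, entry$seeds, cfg)
    bg <- estimate_background(entry$stack, entry$seeds$background_roi)
    masks <- build_compartment_masks(entry$stack, seg, bg, cfg)
    a <- masks$organelle > 0
    b <- entry$truth$organelle_mask > 0
    jaccard <- sum(a & b) / sum(a | b)
    expect_gte(jaccard, 0.8)
  }
})

test_that("missing or degenerate marker input fails loudly", {
  img <- noise_free_cell()
  stack_nomarker <- channel_stack(img$stack$n, img$stack$t)
  cfg <- run_config(organelle_label = "lysosome")
  seg <- segment_cells(stack_nomarker, img$seeds, cfg)
  bg <- estimate_background(stack_nomarker, img$seeds$background_roi)
  expect_error(build_compartment_masks(stack_nomarker, seg, bg, cfg),
               "no marker channel")
  # constant marker inside the interiors: single-bin histogram
  flat <- channel_stack(img$stack$n, img$stack$t,
                        matrix(0, nrow(img$stack$n), ncol(img$stack$n)))
  expect_error(build_compartment_masks(flat, seg, bg, cfg), "one bin")
})
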