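zero_background <- function() {
  structure(list(n = list(mean = 0, sd = 0), t = list(mean = 0, sd = 0),
                 marker = NULL, n_pixels = 1L),
            class = "background_estimate")
}

raw_ratio_map <- function(values) {
  v <- as.matrix(values)
  structure(list(value = v, valid = !is.na(v), epsilon = 1), class = "ratio_map")
}

test_that("pixelwise ratios follow the background-subtracted definition", {
  n <- matrix(5, 4, 4); t <- matrix(5, 4, 4)
  rm1 <- ratio_map(channel_stack(n, t), zero_background())
  expect_true(all(rm1$value == 1))

  n2 <- matrix(10, 2, 2); t2 <- matrix(30, 2, 2)
  rm2 <- ratio_map(channel_stack(n2, t2), zero_background())
  expect_equal(rm2$value[1, 1], 3.0)

  # denominator at zero is invalid and excluded from statistics
  bg <- structure(list(n = list(mean = 10, sd = 0), t = list(mean = 0, sd = 0),
                       marker = NULL, n_pixels = 1L), class = "background_estimate")
  n3 <- matrix(c(10, 50, 50, 50), 2, 2); t3 <- matrix(20, 2, 2)
  rm3 <- ratio_map(channel_stack(n3, t3), bg)
  expect_false(rm3$valid[1, 1])
  expect_true(is.na(rm3$value[1, 1]))
  st <- region_stats(rm3, matrix(TRUE, 2, 2))
  expect_equal(st$n_pixels, 3)
  expect_equal(st$median, 0.5)
  expect_error(ratio_map(channel_stack(n3, t3), bg, epsilon = 0), "> 0")
})

test_that("region statistics use the shared quantile convention", {
  expect_equal(region_stats(raw_ratio_map(c(1, 2, 3)), matrix(TRUE, 3, 1))$median, 2)
  st <- region_stats(raw_ratio_map(c(1, 2, 3, 4)), matrix(TRUE, 4, 1))
  expect_equal(st$median, 2.5) # even count: mean of central order statistics
  expect_equal(st$q1, 1.75)
  expect_equal(st$q3, 3.25)
  expect_warning(out <- region_stats(raw_ratio_map(c(1, 2)), matrix(TRUE, 2, 1),
                                     min_pixels = 10), "dropped")
  expect_null(out)
})

test_that("the sample median of many draws concentrates at the population median", {
  set.seed(101)
  draws <- rnorm(1e4, 2.5, 0.4)
  st <- region_stats(raw_ratio_map(matrix(draws, 100, 100)), matrix(TRUE, 100, 100))
  # 5 sigma of the asymptotic median sd sqrt(pi/2)*0.4/100
  expect_lt(abs(st$median - 2.5), 0.0251)
})

test_that("plasma-membrane normalization is the per-cell quotient", {
  expect_equal(normalize_to_pm(2.2, 2.2), 1)
  expect_equal(normalize_to_pm(2.488, 3.441), 0.7231, tolerance = 1e-4)
  expect_error(normalize_to_pm(2.5, 0), "> 0")
})

test_that("noise-free measurements equal the generator truth exactly", {
  img <- noise_free_cell(pm_ratio = 3.4, organelle_ratio = 2.5)
  res <- analyze(img$stack, img$seeds, run_config(organelle_label = "lysosome"))
  m <- res$measurements
  expect_equal(m$median_ratio[m$compartment == "PM"], 3.4, tolerance = 1e-12)
  expect_equal(m$median_ratio[m$compartment == "lysosome"], 2.5, tolerance = 1e-12)
  expect_equal(m$normalized_ratio[m$compartment == "lysosome"], 2.5 / 3.4,
               tolerance = 1e-12)
  expect_equal(m$normalized_ratio[m$compartment == "PM"], 1)
  expect_true(all(m$q1 <= m$median_ratio & m$median_ratio <= m$q3))
})

test_that("an empty organelle mask drops that compartment with a warning", {
  img <- noise_free_cell()
  cfg <- run_config(organelle_label = "lysosome",
                    marker_threshold_override = max(img$stack$marker) + 1)
  seg <- segment_cells(img$stack, img$seeds, cfg)
  bg <- estimate_background(img$stack, img$seeds$background_roi)
  masks <- build_compartment_masks(img$stack, seg, bg, cfg)
  expect_warning( # pixel-count warning, then the compartment-drop warning
    expect_warning(m <- measure_cells(img$stack, seg, masks, bg, cfg),
                   "fewer than min_pixels"),
    "compartment dropped")
  expect_setequal(m$compartment, c("PM", "intracellular_all"))
})

test_that("every ratio statistic is invariant to a common intensity rescaling", {
  img <- noise_free_cell()
  cfg <- run_config(organelle_label = "lysosome")
  base <- analyze(img$stack, img$seeds, cfg)$measurements
  scaled_stack <- img$stack
  for (ch in c("n", "t")) scaled_stack[[ch]] <- scaled_stack[[ch]] * 7.3
  scaled <- analyze(scaled_stack, img$seeds, cfg)$measurements
  expect_equal(scaled$median_ratio, base$median_ratio, tolerance = 1e-12)
  expect_equal(scaled$q1, base$q1, tolerance = 1e-12)
  expect_equal(scaled$normalized_ratio, base$normalized_ratio, tolerance = 1e-12)
})

test_that("relabeling cells only permutes the measurement records", {
  p <- synthetic_params(image_size = 160, cells_per_image = 2L, noise = FALSE)
  make <- function(ids) {
    set.seed(3)
    tr <- data.frame(cell_id = ids, pm_ratio = c(3.4, 3.6),
                     organelle_ratio = c(2.5, 2.2), endo_ratio = c(2.2, 2.3))
    generate_cell_image(p, tr, "lysosome")
  }
  a <- make(c(1L, 2L))
  b <- make(c(2L, 1L))
  cfg <- run_config(organelle_label = "lysosome")
  ma <- analyze(a$stack, a$seeds, cfg)$measurements
  mb <- analyze(b$stack, b$seeds, cfg)$measurements
  key <- function(m) m[order(m$median_ratio, m$compartment),
                       c("compartment", "median_ratio", "normalized_ratio", "n_pixels")]
  ka <- key(ma); kb <- key(mb)
  rownames(ka) <- rownames(kb) <- NULL
  expect_equal(ka, kb, tolerance = 1e-12)
  # the id swap really moved the values between cells
  pm_of <- function(m, id) m$median_ratio[m$cell_id == id & m$compartment == "PM"]
  expect_equal(pm_of(ma, 1), pm_of(mb, 2), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pm_of(ma, 1), pm_of(mb, 1))))
})
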