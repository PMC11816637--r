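test_that("with noise off the rendered images are exact expectations", {
  img <- noise_free_cell(pm_ratio = 3.0, organelle_ratio = 2.0)
  pm <- img$truth$pm_mask > 0
  ratio <- (img$stack$t - 20) / (img$stack$n - 20)
  expect_true(all(ratio[pm] == 3.0))
  org <- img$truth$organelle_mask > 0
  expect_true(all(ratio[org] == 2.0))
  # marker bright only on the organelle
  expect_true(all(img$stack$marker[org] > 10))
  expect_true(all(img$stack$marker[!org] == 10))
})

test_that("generation is reproducible and the truth stream is noise-independent", {
  a <- generate_experiment("skbr3", "lysosome", 3, seed = 5,
                           params = synthetic_params(image_size = 96))
  b <- generate_experiment("skbr3", "lysosome", 3, seed = 5,
                           params = synthetic_params(image_size = 96))
  expect_identical(a$images[[2]]$stack$n, b$images[[2]]$stack$n)
  expect_identical(a$truth_table, b$truth_table)

  quiet <- generate_experiment("skbr3", "lysosome", 3, seed = 5,
                               params = synthetic_params(image_size = 96),
                               noise = FALSE)
  expect_identical(quiet$truth_table, a$truth_table) # same truths ...
  expect_false(identical(quiet$images[[1]]$stack$n, a$images[[1]]$stack$n)) # ... different images

  c2 <- generate_experiment("skbr3", "lysosome", 3, seed = 6,
                            params = synthetic_params(image_size = 96))
  expect_false(identical(c2$truth_table, a$truth_table))
})

test_that("drawn true ratios recover the packaged population moments", {
  ds <- generate_experiment("skbr3", "lysosome", 100, seed = 31,
                            params = synthetic_params(image_size = 96),
                            noise = FALSE)
  m <- mean(ds$truth_table$organelle_ratio)
  # 5 standard errors of the mean of 100 draws with sd 0.424
  expect_lt(abs(m - 2.488), 5 * 0.424 / 10)
  mpm <- mean(ds$truth_table$pm_ratio)
  expect_lt(abs(mpm - 3.441), 5 * 0.263 / 10)
  expect_true(all(ds$truth_table$organelle_ratio > 0.1))
})

test_that("within-cell ratio correlation tightens the normalized-ratio spread", {
  p <- synthetic_params(image_size = 64)
  ind <- generate_experiment("skbr3", "lysosome", 120, seed = 61, params = p,
                             noise = FALSE)$truth_table
  cor0 <- cor(ind$pm_ratio, ind$organelle_ratio)
  expect_lt(abs(cor0), 0.25) # independent by default
  dep <- generate_experiment("skbr3", "lysosome", 120, seed = 61, params = p,
                             noise = FALSE, ratio_correlation = 0.9)$truth_table
  expect_gt(cor(dep$pm_ratio, dep$organelle_ratio), 0.7)
  spread <- function(d) sd(d$organelle_ratio / d$pm_ratio)
  expect_lt(spread(dep), spread(ind))
})

test_that("empty datasets and unknown parameter sets behave as specified", {
  empty <- generate_experiment("skbr3", "lysosome", 0, seed = 1)
  expect_length(empty$images, 0)
  expect_equal(nrow(empty$truth_table), 0)
  expect_error(generate_experiment("cos7", "lysosome", 1, seed = 1))
  expect_error(generate_experiment("skbr3", "nucleus", 1, seed = 1))
})

test_that("generated data conform to the io and segmentation schemas", {
  for (org in c("lysosome", "golgi", "er", "mitochondria")) {
    ds <- generate_experiment("hela", org, 1, seed = 14,
                              params = synthetic_params(image_size = 128))
    entry <- ds$images[[1]]
    expect_silent(validate_channel_stack(entry$stack))
    expect_silent(validate_seed_set(entry$seeds, dim = dim(entry$stack$n)))
    truth <- entry$truth
    interior <- truth$interior_mask > 0
    expect_true(all(interior[truth$organelle_mask > 0]))
    expect_true(all(interior[truth$endomembrane_mask > 0]))
    expect_equal(sum(truth$pm_mask > 0 & interior), 0)
    expect_gt(sum(truth$organelle_mask > 0), 0)
  }
})

test_that("datasets written to disk re-analyze identically to in-memory ones", {
  ds <- generate_experiment("skbr3", "golgi", 2, seed = 9,
                            params = synthetic_params(image_size = 96))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "image_001.tif")))
  expect_true(file.exists(file.path(dir, "image_002.seeds.json")))
  stack <- read_channel_stack(file.path(dir, "image_001.tif"),
                              list(n = 1, t = 2, marker = 3))
  expect_equal(stack$n, round(ds$images[[1]]$stack$n))
  seeds <- read_seed_set(file.path(dir, "image_001.seeds.json"))
  expect_identical(seeds$cell_seeds, ds$images[[1]]$seeds$cell_seeds)
})
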