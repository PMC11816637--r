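# Shared small fixtures, built in code at test time.

# circular bright ring (value hi) on a dim plateau (value lo)
ring_relief <- function(size = 16, center = c(8.5, 8.5), r_in = 3.5, r_out = 5.5,
                        lo = 10, hi = 100) {
  d <- sqrt(outer((seq_len(size) - center[1])^2,
                  (seq_len(size) - center[2])^2, `+`))
  relief <- matrix(lo, size, size)
  ring <- d >= r_in & d <= r_out
  relief[ring] <- hi
  attr(relief, "ring") <- ring
  relief
}

seed_matrix <- function(size, at) {
  s <- matrix(0L, size[1], size[2])
  for (i in seq_along(at)) s[at[[i]][1], at[[i]][2]] <- i
  s
}

# one noise-free synthetic cell with known ratios
noise_free_cell <- function(organelle = "lysosome", image_size = 96,
                            pm_ratio = 3.4, organelle_ratio = 2.5,
                            endo_ratio = 2.2, geometry_seed = 11) {
  p <- synthetic_params(image_size = image_size, noise = FALSE)
  set.seed(geometry_seed)
  truth <- data.frame(cell_id = 1L, pm_ratio = pm_ratio,
                      organelle_ratio = organelle_ratio,
                      endo_ratio = endo_ratio)
  generate_cell_image(p, truth, organelle)
}
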