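# Shared fixtures, built once per test run. All synthetic, all seeded.

.fixtures <- new.env(parent = emptyenv())

# noiseless desk-scale imaging: the generator/decoder consistency oracle
fix_noiseless <- function() {
  if (is.null(.fixtures$nl)) {
    cfg <- imaging_config("desk", noise = "none")
    lib <- build_patch_library(20, cfg, seed = 11)
    .fixtures$nl <- list(cfg = cfg, lib = lib, layout = grid_layout(cfg))
  }
  .fixtures$nl
}

# moderate-noise desk-scale imaging (the default study condition)
fix_noisy <- function() {
  if (is.null(.fixtures$ns)) {
    cfg <- imaging_config("desk")
    lib <- build_patch_library(50, cfg, seed = 12)
    .fixtures$ns <- list(cfg = cfg, lib = lib, layout = grid_layout(cfg))
  }
  .fixtures$ns
}

# a tiny CNN geometry that trains in seconds; used for mechanics tests
tiny_cnn_config <- function(...) {
  cnn_config("desk", n = 5, input_shape = c(20L, 20L),
             filters = c(3L, 4L, 5L), kernels = c(3L, 2L, 2L),
             strides = c(2L, 1L, 1L), pools = c(2L, 2L, 2L),
             pool_strides = c(2L, 2L, 1L), fc_nodes = 11L, ...)
}
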