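# Shared fixture builders: everything is generated in code at test time.

# A one-ROI phantom with zero between-voxel SD (every ROI voxel shares the
# structure's reference parameters) on a small grid.
noiseless_phantom <- function(structure = "retrodiscal_tissue",
                              group = "no_displacement",
                              nx = 4L, ny = 4L, seed = 1L) {
  spec <- phantom_spec(
    dim = c(nx + 1L, ny + 1L, 1L),
    rois = list(list(
      label = 1L, structure = structure,
      tissue = tissue_spec(structure, group, zero_sd = TRUE),
      region = list(x = c(1L, nx), y = c(1L, ny), z = 1L)
    )),
    noise = "none", seed = seed
  )
  make_phantom(spec)
}

# Reference biexponential curve for a tissue row (zero SD), plus its truth.
tissue_curve <- function(structure, group = "no_displacement",
                         tes = default_echo_times()) {
  tis <- tissue_spec(structure, group, zero_sd = TRUE)
  params <- biexp_params(tis$mean_frac_short, 1 - tis$mean_frac_short,
                         tis$mean_t2_short, tis$mean_t2_long)
  list(params = params, signal = biexp_signal(params, tes), tissue = tis,
       tes = tes)
}
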