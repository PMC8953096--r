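#!/usr/bin/env Rscript

# Step 4: model-adequacy report. For one representative noisy retrodiscal
# decay curve, compares the best monoexponential and biexponential fits
# and plots both against the eight measured echoes -- the monoexponential
# curve misses the fast early decay and carries the higher weighted MSE.
# Also summarizes the voxelwise MSE ratio across the noisy phantom maps.

suppressPackageStartupMessages({
  library(biexpT2)
  library(ggplot2)
})

tes <- default_echo_times()
tis <- tissue_spec("retrodiscal_tissue", "no_displacement", zero_sd = TRUE)
truth <- biexp_params(tis$mean_frac_short, 1 - tis$mean_frac_short,
                      tis$mean_t2_short, tis$mean_t2_long)
clean <- biexp_signal(truth, tes)
set.seed(4L)
observed <- clean + stats::rnorm(length(tes), 0, 0.01 * clean[1])

bi <- fit_biexp(observed, tes)
mono <- fit_mono(observed, tes)
message(sprintf("biexponential fit: t2s = %.2f ms, t2l = %.2f ms, MSE = %.3e",
                bi$params$t2_short, bi$params$t2_long, bi$mse))
message(sprintf("monoexponential fit: t2 = %.2f ms, MSE = %.3e (%.0fx higher)",
                mono$params$t2, mono$mse, mono$mse / bi$mse))

grid <- seq(1, max(tes), length.out = 200)
curves <- rbind(
  data.frame(te = grid, model = "biexponential",
             signal = biexp_signal(bi$params, grid)),
  data.frame(te = grid, model = "monoexponential",
             signal = mono_signal(mono$params, grid))
)
fig <- ggplot() +
  geom_line(data = curves, aes(te, signal, linetype = model)) +
  geom_point(data = data.frame(te = tes, signal = observed),
             aes(te, signal), shape = 15, size = 2) +
  scale_linetype_manual(values = c(biexponential = "solid",
                                   monoexponential = "dashed")) +
  labs(x = "echo time [ms]", y = "signal [a.u.]",
       title = "Mono- vs biexponential fit of one retrodiscal voxel") +
  theme_minimal()
dir.create("results", showWarnings = FALSE)
ggsave("results/mono_vs_biexp_fit.pdf", fig, width = 6, height = 4)
message("wrote results/mono_vs_biexp_fit.pdf")

maps_dir <- "results/maps_noisy"
if (dir.exists(maps_dir)) {
  stack <- read_maps(maps_dir)
  v <- stack$validity & is.finite(stack$mse_mono) & is.finite(stack$mse_biexp)
  ratio <- stack$mse_mono[v] / stack$mse_biexp[v]
  message(sprintf(
    "noisy phantom: mono/bi MSE ratio median %.1f (IQR %.1f-%.1f, n = %d)",
    stats::median(ratio), stats::quantile(ratio, 0.25),
    stats::quantile(ratio, 0.75), sum(v)))
}
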