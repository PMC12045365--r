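# Two-host-model simulation used for group-level recovery checks.
# Deltas use the closed-form expected null (all-cell median), so no
# permutation ensemble is needed at the group level.
simulate_group_summaries <- function(seed0, lambda_a, lambda_b, n_per = 6,
                                     n_cells = 1000, width = 160,
                                     height = 160) {
  rows <- vector("list", 2 * n_per)
  for (m in 1:2) {
    lam <- if (m == 1) lambda_a else lambda_b
    for (s in seq_len(n_per)) {
      cfg <- synthetic_config(width = width, height = height, pixel_size = 2,
                              n_stroma_seeds = 5, stroma_thickness = 5,
                              target_stroma_fraction = 0.15,
                              n_cells = n_cells, positive_fraction = 0.1,
                              bias_length = lam, seed = seed0 + m * 1000 + s)
      ds <- generate_dataset(cfg, sample_id = sprintf("m%d_s%d", m, s),
                             treatment = "treated",
                             host_model = c("modelA", "modelB")[m])
      prof <- cell_distances(ds$sample)
      obs <- summarize_profile(prof, "positive")
      nul <- summarize_profile(prof, "all")
      rows[[(m - 1) * n_per + s]] <- data.frame(
        sample_id = ds$sample$sample_id, treatment = "treated",
        host_model = ds$sample$host_model,
        n_cells = nul$n, k_positive = obs$n,
        obs_median = obs$median, obs_mean = obs$mean,
        null_median = nul$median, null_mean = nul$mean,
        delta_median = obs$median - nul$median,
        delta_mean = obs$mean - nul$mean)
    }
  }
  do.call(rbind, rows)
}
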