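#!/usr/bin/env Rscript

# Nucleolar line-profile analysis: recover constructed Nup reductions over
# the nucleolar-facing nuclear envelope from marker-aligned, resampled and
# averaged two-channel profiles (50 noisy synthetic nuclei per level).

suppressMessages(library(npcorg))
dir.create("results", showWarnings = FALSE)

summary_rows <- list()
profile_rows <- list()
for (red in c(0, 0.2, 0.5)) {
  scenes <- lapply(1:50, function(i)
    generate_nucleolar_scene(nup_reduction_frac = red, noise_sd = 0.1,
                             seed = round(red * 1000) + i))
  al <- align_and_average(lapply(scenes, `[[`, "profiles"))
  r <- nup_reduction_at_center(al)
  cat(sprintf("constructed reduction %.1f: value at centre %.3f (SD %.3f, n = %d)\n",
              red, r$value, r$sd, r$n))
  summary_rows[[length(summary_rows) + 1]] <-
    data.frame(constructed_reduction = red, value_at_center = r$value,
               sd = r$sd, n = r$n)
  profile_rows[[length(profile_rows) + 1]] <-
    data.frame(constructed_reduction = red, position_nm = al$position_nm,
               mean_intensity = al$mean, sd_intensity = al$sd)
}
write_csv_with_header(do.call(rbind, summary_rows),
                      "results/nucleolar_reduction_summary.csv",
                      run_config(seed = 1))
write_csv_with_header(do.call(rbind, profile_rows),
                      "results/nucleolar_aligned_profiles.csv",
                      run_config(seed = 1))
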