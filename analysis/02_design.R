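#!/usr/bin/env Rscript
# Expand the factorial flight design (5 sleeping sites x 8 flights,
# 2 heights x 2 camera angles x 3 speeds) into blinded video records and
# show how faster speeds are simulated by frame subsampling.

library(tirsurvey)
dir.create("results", showWarnings = FALSE)

design <- expand_design(5, 8, heights = c(40, 50), angles = c(-45, -90),
                        speeds = c(2, 4, 6), seed = 1)
write_table_csv(design, "results/design.csv")
cat(sprintf("%d video records, %d per flight\n", nrow(design),
            nrow(design) / length(unique(design$flight_id))))
cat(sprintf("Transect durations: %s s at %s m/s\n",
            paste(round(transect_duration(220, c(2, 4, 6)), 1), collapse = "/"),
            paste(c(2, 4, 6), collapse = "/")))

base <- frame_sequence(round(110 * 30), fps = 30)  # 110 s flown at 2 m/s
for (v in c(2, 4, 6)) {
  fr <- simulate_speed(base, 2, v)
  cat(sprintf("  %d m/s: %d frames at %.0f fps nominal\n",
              v, length(fr$frame_times_s), fr$nominal_fps))
}
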