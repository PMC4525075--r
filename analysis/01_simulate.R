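#!/usr/bin/env Rscript
# Generate the full synthetic study dataset: per-worm headings for fed and
# starved populations, two-choice assay counts, a per-isolate performance
# table, and calcium-imaging traces. Everything downstream reads the CSVs
# this writes under results/data/.

suppressPackageStartupMessages(library(wormcompass))

seed <- 20260920
out <- "results/data"

# --- heading samples at the study's population sizes -----------------------
# fed worms prefer 132 deg to the field, starved 304.6 deg; kappa = 1
# approximates the dispersion of the unimodal heading histograms
fed <- sample_headings(1268, mean_direction = 132, kappa = 1, seed = seed,
                       strain = "N2", satiation = "fed")
starved <- sample_headings(1079, mean_direction = 304.6, kappa = 1,
                           seed = seed + 1, strain = "N2",
                           satiation = "starved")
headings <- rbind(
  data.frame(assay_id = "pooled_fed", strain = "N2", satiation = "fed",
             angle_deg = fed$angles),
  data.frame(assay_id = "pooled_starved", strain = "N2",
             satiation = "starved", angle_deg = starved$angles))
write_report(headings, file.path(out, "headings.csv"), seed = seed,
             params = list(kappa = 1))
message(sprintf("headings: %d fed + %d starved worms", 1268, 1079))

# --- magnet-assay counts ---------------------------------------------------
# about two thirds of arriving worms choose the magnet goal; 10 replicate
# assays of ~48 worms, plus a no-magnet control choosing at random
counts <- rbind(
  simulate_assay_counts(10, choice_probability = 2 / 3, worms_per_assay = 48,
                        seed = seed + 2, strain = "N2", assay_type = "magnet"),
  simulate_assay_counts(10, choice_probability = 0.5, worms_per_assay = 48,
                        seed = seed + 3, strain = "N2",
                        assay_type = "no_magnet"))
counts$assay_id <- sprintf("%s_%s", counts$assay_type, counts$assay_id)
write_report(counts, file.path(out, "assay_counts.csv"), seed = seed)
message(sprintf("assay counts: %d assays", nrow(counts)))

# --- isolate performance table --------------------------------------------
# index coupled to the vertical field component; last isolate held out for
# the prediction exercise
fields <- synthetic_isolate_fields(11)
isolates <- simulate_isolate_table(fields, slope = 0.8, intercept = 0,
                                   noise_sd = 0.05, predictor = "vertical",
                                   seed = seed + 4)
write_report(isolates, file.path(out, "isolates.csv"), seed = seed,
             params = list(slope = 0.8, noise_sd = 0.05))
message(sprintf("isolates: %d (%s held out)", nrow(isolates),
                isolates$strain[isolates$holdout]))

# --- calcium traces --------------------------------------------------------
# 7 worms, three stimuli each; a 2% first response adapting to 1%,
# exponential bleaching (tau = 60 s), 0.2% frame noise at 8 Hz.
# Single-stimulus 50-s runs are the standard protocol; the repeated-stimulus
# runs here concatenate three epochs into one long recording for the
# adaptation profile.
eps <- data.frame(onset_s = c(12.5, 62.5, 112.5), duration_s = 6,
                  amplitude_pct = c(2, 1, 1))
sims <- lapply(1:7, function(w)
  simulate_trace(eps, f0 = 100, bleach_tau = 60, noise_sd = 0.2,
                 sample_rate = 8, total_duration = 150, seed = seed + 10 + w,
                 worm_id = sprintf("worm_%02d", w)))
write_report(do.call(rbind, lapply(sims, `[[`, "trace")),
             file.path(out, "traces.csv"), seed = seed)
write_report(do.call(rbind, lapply(sims, `[[`, "epochs")),
             file.path(out, "epochs.csv"), seed = seed)
message(sprintf("traces: %d worms x %d stimuli", length(sims), nrow(eps)))
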