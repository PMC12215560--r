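#!/usr/bin/env Rscript
# Generate the synthetic datasets used by the downstream analysis scripts:
# stimulation-trial voltage recordings, BT/ST reconstructions, laminar
# afferent profiles and a two-channel calcium session. Everything is
# seeded, so rerunning reproduces identical files.

library(l23pipe)

seed <- 20260921L
out <- "results/data"
dir.create(file.path(out, "swc"), showWarnings = FALSE, recursive = TRUE)

## voltage trials: a POm-like stimulation session with NMDA-spike trials
## and plateau events
sim_v <- simulate_voltage_trials(voltage_sim_config(
  n_trials = 30, p_nmda = 0.5, dsdp_rate = 0.6, seed = seed
))
write_voltage_trials(sim_v$trials, file.path(out, "voltage_trials.tsv"))
write.table(sim_v$truth, file.path(out, "voltage_truth.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

## morphologies: 20 BT + 20 ST reconstructions as SWC
sim_m <- simulate_morphologies(20, 20, seed = seed)
for (i in seq_along(sim_m$trees)) {
  write_swc(sim_m$trees[[i]],
            sprintf("%s/swc/neuron_%02d_%s.swc", out, i,
                    sim_m$truth$label[i]))
}
write.table(sim_m$truth, file.path(out, "morphology_truth.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

## laminar afferent templates
for (aff in c("POm", "VPM", "M1", "S2")) {
  write_laminar_profile(simulate_laminar_profile(aff, seed = seed),
                        file.path(out, paste0("profile_", aff, ".tsv")))
}

## calcium session: 3 movement-coupled neurons, shared axial artifact
sim_c <- simulate_calcium_recording(3, 0, duration = 300, coupling = 2,
                                    artifact_amp = 0.2, seed = seed)
for (i in seq_along(sim_c$rois)) {
  write_roi_recording(sim_c$rois[[i]],
                      sprintf("%s/roi_%02d.tsv", out, i))
}
write.table(data.frame(frame = seq_along(sim_c$movement),
                       movement = sim_c$movement),
            file.path(out, "movement.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("wrote", length(sim_v$trials), "voltage trials,",
    length(sim_m$trees), "reconstructions,",
    length(sim_c$rois), "calcium ROIs to", out, "\n")
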