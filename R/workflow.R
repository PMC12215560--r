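#' Build a workflow run configuration
#'
#' Central place for every stage parameter, all defaulting to the values
#' used throughout the package: 3-SD detection threshold, 100-ms low-pass,
#' 10-ms minimum event duration, 200-ms DSDP cut, bimodality threshold 0.5,
#' neuropil r 0.7, 30th-percentile F0, 1000 permutations at alpha 0.01 with
#' d > 0.2, 128 trees. Configurations round-trip losslessly through JSON.
#'
#' @param workflow one of `"ephys"`, `"calcium"`, `"morpho"`.
#' @param params named list overriding stage parameters and simulator
#'   settings for the workflow.
#' @param seed integer seed driving every random stage.
#' @param outdir output directory (created if missing).
#' @param inputs optional named list of input paths (e.g. `swc_dir`,
#'   `trials`); when absent the synthetic generators supply the inputs.
#' @return an object of class `run_config`.
#' @export
run_config <- function(workflow, params = list(), seed = 1L,
                       outdir = tempfile("l23run"), inputs = list()) {
  defaults <- list(
    threshold_sd = 3, lowpass_ms = 100, min_duration_ms = 10, dsdp_ms = 200,
    bc_threshold = 0.5, neuropil_r = 0.7, f0_percentile = 30,
    n_perm = 1000, alpha = 0.01, d_min = 0.2, num_trees = 128, n_folds = 5,
    # simulator settings
    n_trials = 30, dsdp_rate = 0.6, p_nmda = 0.5,
    n_bt = 10, n_st = 10,
    n_upper = 2, n_lower = 2, duration = 300, rate = 0.2,
    effect = 1.8, coupling = 2
  )
  p <- utils::modifyList(defaults, params)
  stopifnot(
    p$threshold_sd > 0, p$lowpass_ms > 0, p$min_duration_ms > 0,
    p$dsdp_ms > 0, p$bc_threshold > 0,
    p$alpha > 0, p$alpha < 1, p$n_perm >= 100,
    p$neuropil_r >= 0, p$neuropil_r <= 1,
    p$f0_percentile > 0, p$f0_percentile < 100,
    p$num_trees >= 1, p$n_folds >= 2
  )
  structure(list(workflow = workflow, params = p, seed = as.integer(seed),
                 outdir = outdir, inputs = inputs),
            class = "run_config")
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run an end-to-end workflow
#'
#' Executes one of three stage chains and writes its tables, a
#' machine-readable JSON manifest (workflow, parameters, seed, package
#' version, input digests, output list) and a short human-readable report.
#' At fixed config and seed the numerical outputs and the manifest are
#' identical across runs; timestamps appear only in the report.
#'
#' * `ephys`: simulate stimulation trials, detect and classify events,
#'   summarize DSDP statistics, classify NMDA-spike trials.
#' * `calcium`: simulate before/after two-channel sessions, run the
#'   correction chain, call modulation per neuron, decode movement and
#'   compute noise power.
#' * `morpho`: load (or simulate) reconstructions, compute features,
#'   cluster BT/ST, score overlap against the four afferent templates.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!config$workflow %in% c("ephys", "calcium", "morpho")) {
    stop("unknown workflow: ", config$workflow)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  outputs <- switch(config$workflow,
    ephys = run_ephys_workflow(config),
    calcium = run_calcium_workflow(config),
    morpho = run_morpho_workflow(config)
  )
  digests <- if (length(config$inputs)) {
    as.list(tools::md5sum(unlist(config$inputs)))
  } else {
    list()
  }
  manifest <- list(
    workflow = config$workflow, params = p, seed = config$seed,
    package_version = as.character(utils::packageVersion("l23pipe")),
    input_digests = digests, outputs = outputs$files,
    summary = outputs$summary
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("l23pipe %s workflow run, %s", config$workflow, Sys.time()),
    sprintf("seed: %d", config$seed), "",
    outputs$report
  ), file.path(config$outdir, "report.txt"))
  invisible(manifest)
}

run_ephys_workflow <- function(config) {
  p <- config$params
  sim <- simulate_voltage_trials(voltage_sim_config(
    n_trials = p$n_trials, dsdp_rate = p$dsdp_rate, p_nmda = p$p_nmda,
    seed = config$seed
  ))
  events <- lapply(sim$trials, function(tr) {
    classify_events(detect_events(
      tr, threshold_sd = p$threshold_sd, lowpass_ms = p$lowpass_ms,
      min_duration_ms = p$min_duration_ms
    ), dsdp_ms = p$dsdp_ms)
  })
  cfg0 <- voltage_sim_config()
  post_window <- cfg0$trial_length - (max(cfg0$stim_times) +
                                        cfg0$stim_duration + 0.05)
  summ <- summarize_dsdp(events, post_window)
  amps <- vapply(sim$trials, evoked_amplitude, 0)
  nm <- nmda_classify(amps, bc_threshold = p$bc_threshold)
  ev_tab <- do.call(rbind, lapply(seq_along(events), function(i) {
    if (nrow(events[[i]]) == 0) return(NULL)
    cbind(trial = i, events[[i]])
  }))
  if (is.null(ev_tab)) {
    ev_tab <- data.frame(trial = integer(0), onset = numeric(0),
                         duration = numeric(0), mean_amplitude = numeric(0),
                         class = character(0))
  }
  f_ev <- write_tsv(ev_tab, file.path(config$outdir, "events.tsv"))
  stats <- c(summ, nm[c("bc", "is_bimodal", "nmda_fraction",
                        "nmda_mean_amplitude", "nmda_strength")])
  f_js <- file.path(config$outdir, "dsdp_summary.json")
  jsonlite::write_json(stats, f_js, auto_unbox = TRUE, digits = NA)
  list(
    files = c(f_ev, f_js),
    summary = stats,
    report = c(
      sprintf("trials: %d, events detected: %d (%d DSDPs)",
              length(sim$trials), nrow(ev_tab),
              sum(ev_tab$class == "dsdp")),
      sprintf("DSDP probability %.3f, total duration %.3f s, frequency %.3f Hz",
              summ$probability, summ$total_duration, summ$frequency),
      sprintf("bimodality coefficient %.3f (bimodal: %s), NMDA strength %.2f mV",
              nm$bc, nm$is_bimodal, nm$nmda_strength)
    )
  )
}

#' Peak evoked amplitude of the stimulus window
#'
#' Peak of the lightly smoothed trace above the whole-trace median, between
#' the first stimulus and 150 ms after the last one — the per-trial
#' amplitude fed to [nmda_classify()].
#'
#' @param trial a [voltage_trial()] with stimulus times.
#' @param lowpass_ms smoothing window in ms (default 20, light enough to
#'   preserve PSP peaks).
#' @return evoked amplitude in mV.
#' @export
evoked_amplitude <- function(trial, lowpass_ms = 20) {
  fs <- trial$sampling_rate
  sm <- moving_average(trial$samples, round(lowpass_ms / 1000 * fs))
  i0 <- round(trial$stim_times[1] * fs) + 1L
  i1 <- min(round((max(trial$stim_times) + 0.15) * fs), length(sm))
  max(sm[i0:i1]) - median(trial$samples)
}

run_calcium_workflow <- function(config) {
  p <- config$params
  before <- simulate_calcium_recording(
    n_upper = p$n_upper, n_lower = p$n_lower, duration = p$duration,
    rate = p$rate, coupling = p$coupling, seed = config$seed
  )
  after <- simulate_calcium_recording(
    n_upper = p$n_upper, n_lower = p$n_lower, duration = p$duration,
    rate = p$rate * p$effect, coupling = p$coupling, seed = config$seed + 1L
  )
  cp <- correction_params(neuropil_r = p$neuropil_r,
                          f0_percentile = p$f0_percentile)
  rows <- lapply(seq_along(before$rois), function(i) {
    rb <- before$rois[[i]]
    ra <- after$rois[[i]]
    db <- correct_roi(rb, cp)$dff
    da <- correct_roi(ra, cp)$dff
    call <- modulation_call(db, da, n_perm = p$n_perm, alpha = p$alpha,
                            d_min = p$d_min, seed = config$seed + i)
    rates <- infer_rates(c(db, da), rb$frame_rate)
    n_b <- length(db)
    m20 <- before$movement
    mv <- approx(seq_along(m20) / 20, m20,
                 xout = seq_len(n_b) / rb$frame_rate, rule = 2)$y
    # decode on the before-session rates against the session's movement
    feats <- build_features(
      approx(seq_len(n_b) / rb$frame_rate, rates[seq_len(n_b)],
             xout = seq(1 / 20, n_b / rb$frame_rate, by = 1 / 20),
             rule = 2)$y
    )
    dec <- decode_movement(feats,
                           movement = before$movement[seq_len(nrow(feats))],
                           n_folds = p$n_folds, num_trees = p$num_trees,
                           seed = config$seed + i)
    data.frame(
      neuron = rb$id, depth = rb$depth, cohen_d = call$cohen_d,
      p_value = call$p_value, direction = call$direction,
      modulation_index = call$modulation_index, pp_before = dec$pp,
      noise_power_before = noise_power(db, rb$frame_rate),
      noise_power_after = noise_power(da, ra$frame_rate)
    )
  })
  calls <- do.call(rbind, rows)
  f_calls <- write_tsv(calls, file.path(config$outdir, "modulation_calls.tsv"))
  summary <- list(
    n_neurons = nrow(calls),
    n_modulated = sum(calls$direction != "none"),
    mean_pp = mean(calls$pp_before)
  )
  list(
    files = f_calls, summary = summary,
    report = c(
      sprintf("neurons: %d, called modulated: %d", summary$n_neurons,
              summary$n_modulated),
      sprintf("mean prediction power (before): %.3f", summary$mean_pp)
    )
  )
}

run_morpho_workflow <- function(config) {
  p <- config$params
  if (!is.null(config$inputs$swc_dir)) {
    paths <- list.files(config$inputs$swc_dir, "\\.swc$", full.names = TRUE)
    if (length(paths) == 0) stop("no SWC files in ", config$inputs$swc_dir)
    trees <- lapply(paths, read_swc)
    truth <- NULL
  } else {
    sim <- simulate_morphologies(p$n_bt, p$n_st, seed = config$seed)
    trees <- sim$trees
    truth <- sim$truth
  }
  feats <- do.call(rbind, lapply(trees, compute_features))
  cl <- cluster_bt_st(feats, seed = config$seed)
  feats$label <- cl$labels
  if (!is.null(truth)) feats$true_label <- truth$label
  edges <- seq(0, 800, 25)
  afferents <- c("POm", "VPM", "M1", "S2")
  prof_ax <- lapply(afferents, simulate_laminar_profile, bin_edges = edges,
                    seed = config$seed)
  names(prof_ax) <- afferents
  ov <- do.call(rbind, lapply(seq_along(trees), function(i) {
    dp <- dendritic_density_profile(trees[[i]], edges)
    data.frame(neuron = i, label = cl$labels[i],
               t(vapply(prof_ax, overlap_dot, 0, dendrite_profile = dp)))
  }))
  f_feat <- write_tsv(cbind(neuron = seq_len(nrow(feats)), feats),
                      file.path(config$outdir, "morpho_features.tsv"))
  f_ov <- write_tsv(ov, file.path(config$outdir, "overlap_scores.tsv"))
  acc <- if (!is.null(truth)) mean(cl$labels == truth$label) else NA_real_
  list(
    files = c(f_feat, f_ov),
    summary = list(n_bt = sum(cl$labels == "BT"),
                   n_st = sum(cl$labels == "ST"),
                   label_accuracy = acc),
    report = c(
      sprintf("neurons: %d (BT %d / ST %d)", nrow(feats),
              sum(cl$labels == "BT"), sum(cl$labels == "ST")),
      if (!is.null(truth)) sprintf("label accuracy vs ground truth: %.2f", acc),
      sprintf("mean POm overlap BT %.4f vs ST %.4f",
              mean(ov$POm[ov$label == "BT"]), mean(ov$POm[ov$label == "ST"]))
    )
  )
}

#' Validate input files before running a workflow
#'
#' Schema-level checks with actionable messages; reports rather than
#' raises. Kinds: `"swc"` (7 columns, single root, no cycles), `"voltage"`
#' (metadata header, monotone time column, finite samples), `"roi"`
#' (matched channel lengths, finite), `"movement"` (3 numeric columns,
#' finite).
#'
#' @param paths character vector of file paths.
#' @param kinds character vector of expected kinds, recycled.
#' @return data frame with columns `path`, `kind`, `valid`, `message`.
#' @export
validate_inputs <- function(paths, kinds) {
  kinds <- rep_len(kinds, length(paths))
  rows <- lapply(seq_along(paths), function(i) {
    msg <- "ok"
    ok <- TRUE
    res <- tryCatch({
      switch(kinds[i],
        swc = read_swc(paths[i]),
        voltage = {
          d <- read.table(paths[i], header = TRUE, comment.char = "#",
                          sep = "\t")
          if (is.unsorted(d[[1]], strictly = TRUE)) {
            stop("time column is not strictly increasing")
          }
          if (!all(is.finite(as.matrix(d)))) stop("non-finite samples")
          d
        },
        roi = read_roi_recording(paths[i]),
        movement = {
          d <- read_movement_xy(paths[i])
          if (!all(is.finite(as.matrix(d)))) stop("non-finite coordinates")
          d
        },
        stop("unknown input kind: ", kinds[i])
      )
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      ok <- FALSE
      msg <- res
    }
    data.frame(path = paths[i], kind = kinds[i], valid = ok, message = msg)
  })
  do.call(rbind, rows)
}
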