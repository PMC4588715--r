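# Plain-text session container: a directory mirroring the hierarchical
# layout trials / spikes/<unit> / lfp/<channel> / eye / ground_truth.

#' Write a session to a plain-text container directory
#'
#' Serializes an `sf_session` as a directory of portable text files:
#' `trials.csv`, `spikes/unit<u>.csv` (trial, time), `lfp/channel<c>.csv`
#' (long format: trial, t, value, plus the rate and `t0` per trial),
#' `eye/trace.csv` and `eye/events.csv`, and `ground_truth.json` holding
#' the config, coupling profiles and observer parameters. Intended for
#' session exchange and inspection; traces are stored at full precision.
#'
#' @param session an `sf_session`
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "sf_session"))
  dir.create(file.path(dir, "spikes"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "lfp"), showWarnings = FALSE)
  dir.create(file.path(dir, "eye"), showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  for (u in seq_along(session$spikes)) {
    st <- session$spikes[[u]]
    df <- data.frame(trial = rep(seq_along(st), lengths(st)),
                     time = unlist(st, use.names = FALSE))
    utils::write.csv(df, file.path(dir, "spikes", sprintf("unit%d.csv", u)),
                     row.names = FALSE)
  }
  for (ch in seq_along(session$lfp)) {
    tr <- session$lfp[[ch]]
    df <- data.frame(
      trial = rep(seq_along(tr), vapply(tr, function(l) length(l$samples), integer(1))),
      t = unlist(lapply(tr, lfp_time), use.names = FALSE),
      value = unlist(lapply(tr, `[[`, "samples"), use.names = FALSE))
    utils::write.csv(df, file.path(dir, "lfp", sprintf("channel%d.csv", ch)),
                     row.names = FALSE)
  }
  eye_df <- do.call(rbind, lapply(seq_along(session$eye), function(i) {
    e <- session$eye[[i]]
    data.frame(trial = i, t = e$t0 + (seq_along(e$x) - 1) / e$rate,
               x = e$x, y = e$y)
  }))
  utils::write.csv(eye_df, file.path(dir, "eye", "trace.csv"),
                   row.names = FALSE)
  ev_df <- do.call(rbind, lapply(seq_along(session$eye), function(i) {
    ev <- session$eye[[i]]$events
    if (nrow(ev) == 0) return(NULL)
    cbind(trial = i, ev)
  }))
  if (is.null(ev_df)) ev_df <- data.frame(trial = integer(0), time = numeric(0),
                                          amplitude = numeric(0),
                                          direction = numeric(0))
  utils::write.csv(ev_df, file.path(dir, "eye", "events.csv"),
                   row.names = FALSE)
  gt <- list(config = unclass(session$config),
             profiles = lapply(session$ground_truth$profiles, unclass),
             observer = unclass(session$ground_truth$observer),
             channel_positions = session$channel_positions,
             unit_positions = session$unit_positions)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session from a plain-text container directory
#'
#' Inverse of [write_session()]. Missing mandatory components raise a
#' schema error naming the absent path.
#'
#' @param dir container directory
#' @return an `sf_session`
#' @export
read_session <- function(dir) {
  need <- c("trials.csv", "ground_truth.json")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop(sprintf("session schema error: missing %s", file.path(dir, f)))
    }
  }
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = FALSE)
  num <- function(x) if (is.null(x)) NULL else unlist(x, use.names = FALSE)
  cfg <- lapply(gt$config, num)
  config <- session_config(
    n_blocks = cfg$n_blocks, trials_per_block = cfg$trials_per_block,
    orientations = cfg$orientations, fixation_ms = cfg$fixation_ms,
    target_ms = cfg$target_ms, delay_ms = cfg$delay_ms,
    test_ms = cfg$test_ms, delay_jitter_ms = cfg$delay_jitter_ms,
    lfp_rate = cfg$lfp_rate, n_channels = cfg$n_channels,
    n_units = cfg$n_units, seed = cfg$seed)
  n_tr <- nrow(trials)
  spike_files <- sort(list.files(file.path(dir, "spikes"), full.names = TRUE))
  if (length(spike_files) == 0L) {
    stop("session schema error: missing spikes/ group")
  }
  spikes <- lapply(spike_files, function(f) {
    df <- utils::read.csv(f)
    out <- split(df$time, factor(df$trial, levels = seq_len(n_tr)))
    lapply(out, as.numeric)
  })
  lfp_files <- sort(list.files(file.path(dir, "lfp"), full.names = TRUE))
  if (length(lfp_files) == 0L) {
    stop("session schema error: missing lfp/ group")
  }
  lfp <- lapply(lfp_files, function(f) {
    df <- utils::read.csv(f)
    lapply(split(df, factor(df$trial, levels = seq_len(n_tr))), function(d) {
      lfp_trace(d$value, rate = config$lfp_rate, t0 = d$t[1])
    })
  })
  eye <- NULL
  if (file.exists(file.path(dir, "eye", "trace.csv"))) {
    tr <- utils::read.csv(file.path(dir, "eye", "trace.csv"))
    ev <- utils::read.csv(file.path(dir, "eye", "events.csv"))
    eye <- lapply(seq_len(n_tr), function(i) {
      d <- tr[tr$trial == i, , drop = FALSE]
      evi <- ev[ev$trial == i, c("time", "amplitude", "direction"),
                drop = FALSE]
      structure(list(x = d$x, y = d$y, rate = config$lfp_rate,
                     t0 = d$t[1], events = evi), class = "eye_trace")
    })
  }
  profiles <- lapply(gt$profiles, function(p) {
    epochs <- if (is.null(p$coupling_epochs)) NULL else
      lapply(p$coupling_epochs, function(e) unlist(e, use.names = FALSE))
    coupling_profile(band = num(p$band), kappa = p$kappa,
                     preferred_phase = p$preferred_phase,
                     base_rate = p$base_rate, osc_freq = p$osc_freq,
                     oscillation_amplitude = p$oscillation_amplitude,
                     noise_sd = p$noise_sd, noise_exponent = p$noise_exponent,
                     coupling_epochs = epochs)
  })
  observer <- observer_model(FA = num(gt$observer$FA), a = num(gt$observer$a),
                             b = num(gt$observer$b),
                             n_blocks = gt$observer$n_blocks)
  structure(list(config = config, trials = trials, lfp = lfp,
                 spikes = spikes, eye = eye,
                 channel_positions = num(gt$channel_positions),
                 unit_positions = num(gt$unit_positions),
                 ground_truth = list(profiles = profiles,
                                     observer = observer)),
            class = "sf_session")
}
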