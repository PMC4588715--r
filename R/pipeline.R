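# Session-level orchestration: block segmentation, per-pair SFC and phase
# statistics, behavioral summaries, delay-period analysis, and the
# cross-session SFC-behavior correlation.

#' Segment trials into consecutive fixed-size blocks
#'
#' Labels trials with consecutive 96-trial blocks in presentation order;
#' a trailing remainder shorter than one block is dropped with a message.
#'
#' @param trials data.frame in presentation order
#' @param block_size trials per block
#' @return the trials of complete blocks with a `block` column
#' @export
segment_blocks <- function(trials, block_size = 96) {
  n <- nrow(trials)
  if (n < block_size) stop(sprintf("need at least %d trials", block_size))
  n_blocks <- n %/% block_size
  keep <- n_blocks * block_size
  if (keep < n) message(sprintf("dropping %d trailing trials", n - keep))
  out <- trials[seq_len(keep), , drop = FALSE]
  out$block <- rep(seq_len(n_blocks), each = block_size)
  out
}

#' Discriminability index d'
#'
#' Absolute difference of the mean firing rates divided by the
#' root-mean-square standard deviation:
#' `d' = |mean_A - mean_B| / sqrt((var_A + var_B) / 2)`.
#' Zero pooled variance with unequal means gives `Inf` with a warning.
#'
#' @param rates_a,rates_b per-trial firing rates under the two conditions
#' @return scalar d' (>= 0)
#' @export
compute_dprime <- function(rates_a, rates_b) {
  if (length(rates_a) < 2L || length(rates_b) < 2L) {
    stop("need >= 2 trials per condition")
  }
  num <- abs(mean(rates_a) - mean(rates_b))
  den <- sqrt((var(rates_a) + var(rates_b)) / 2)
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero pooled variance with unequal means: d' is infinite")
    return(Inf)
  }
  num / den
}

#' Relative change with respect to a reference
#'
#' `(x - ref) / ref`, the per-pair normalization used for block-wise SFC
#' and threshold changes.
#'
#' @param x value(s)
#' @param ref reference value
#' @return relative change (dimensionless; multiply by 100 for percent)
#' @export
relative_change <- function(x, ref) {
  (x - ref) / ref
}

# spike times restricted to a union of windows
clip_spikes <- function(spikes, windows) {
  keep <- rep(FALSE, length(spikes))
  for (w in windows) keep <- keep | (spikes >= w[1] & spikes <= w[2])
  spikes[keep]
}

# per-trial stimulus analysis windows (150-350 ms after each stimulus onset)
stim_windows <- function(trials_row, offset = c(0.150, 0.350)) {
  list(offset, trials_row$test_on + offset)
}

#' Block-wise statistics of per-pair band values
#'
#' Paired nonparametric comparisons of blocks 2..n against block 1
#' (Wilcoxon signed-rank), the across-block omnibus Kruskal-Wallis test,
#' and relative-change summaries (per-pair `(block_k - block_1)/block_1`,
#' with median, mean and s.e.m. across pairs). With fewer than `min_pairs`
#' pairs only the descriptive part is returned. Per-band p-values are
#' reported uncorrected by default; `holm = TRUE` applies a Holm
#' adjustment over the block comparisons.
#'
#' @param values data.frame with columns `pair_id`, `block`, `value` (one
#'   band), or a pairs x blocks numeric matrix
#' @param min_pairs minimum pairs for inferential statistics
#' @param holm apply Holm correction across the block-wise tests
#' @return list with `summary` (per block: n, median, mean, sem, relative
#'   change), `wilcoxon` (per block vs block 1), `pooled` (blocks 2..n
#'   pooled vs block 1), `kruskal` (omnibus), `inferential` flag
#' @export
block_change_statistics <- function(values, min_pairs = 10, holm = FALSE) {
  if (is.matrix(values)) {
    values <- data.frame(pair_id = rep(seq_len(nrow(values)), ncol(values)),
                         block = rep(seq_len(ncol(values)), each = nrow(values)),
                         value = as.vector(values))
  }
  stopifnot(all(c("pair_id", "block", "value") %in% names(values)))
  wide <- stats::reshape(values[, c("pair_id", "block", "value")],
                         idvar = "pair_id", timevar = "block",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("value.", "", colnames(mat))
  mat <- mat[, order(as.numeric(colnames(mat))), drop = FALSE]
  mat <- mat[complete.cases(mat), , drop = FALSE]
  n_pairs <- nrow(mat)
  blocks <- as.numeric(colnames(mat))
  rel <- sweep(mat, 1, mat[, 1], "-") / mat[, 1]
  sem <- function(x) sd(x) / sqrt(length(x))
  summary_df <- data.frame(
    block = blocks,
    n = n_pairs,
    median = apply(mat, 2, median),
    mean = colMeans(mat),
    sem = apply(mat, 2, sem),
    rel_median = apply(rel, 2, median),
    rel_mean = colMeans(rel),
    rel_sem = apply(rel, 2, sem))
  inferential <- n_pairs >= min_pairs
  wilcoxon <- NULL; kruskal <- NULL; pooled <- NULL
  if (inferential && ncol(mat) >= 2) {
    degenerate <- all(abs(mat - mat[1, 1]) < .Machine$double.eps^0.5)
    if (degenerate) {
      warning("all values identical: tests degenerate")
    } else {
      ps <- numeric(ncol(mat) - 1)
      stats_v <- numeric(ncol(mat) - 1)
      for (j in 2:ncol(mat)) {
        wt <- suppressWarnings(wilcox.test(mat[, j], mat[, 1], paired = TRUE))
        ps[j - 1] <- wt$p.value
        stats_v[j - 1] <- unname(wt$statistic)
      }
      if (holm) ps <- p.adjust(ps, "holm")
      wilcoxon <- data.frame(block = blocks[-1], V = stats_v, p.value = ps)
      later <- rowMeans(mat[, -1, drop = FALSE])
      pw <- suppressWarnings(wilcox.test(later, mat[, 1], paired = TRUE))
      pooled <- list(V = unname(pw$statistic), p.value = pw$p.value)
      kw <- kruskal.test(split(as.vector(mat), rep(blocks, each = n_pairs)))
      kruskal <- list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p.value = kw$p.value)
    }
  }
  list(summary = summary_df, wilcoxon = wilcoxon, pooled = pooled,
       kruskal = kruskal, inferential = inferential)
}

#' Correlation between behavioral and coherence changes across sessions
#'
#' Pearson correlation between the session-by-session change in
#' discrimination threshold and the mean change in band coherence (blocks
#' 2-4 vs block 1, averaged over the session's spike-LFP pairs). Learning
#' predicts a negative correlation in the theta band: larger coherence
#' increases go with larger threshold decreases.
#'
#' @param sessions data.frame with columns `d_threshold` and `d_sfc`
#'   (theta), plus optional `d_sfc_<band>` columns for per-band breakdowns
#' @param min_sessions minimum number of complete sessions
#' @return list with `r`, `p.value`, `n`, and `by_band` (data.frame for
#'   any per-band columns)
#' @export
sfc_behavior_correlation <- function(sessions, min_sessions = 5) {
  stopifnot(all(c("d_threshold", "d_sfc") %in% names(sessions)))
  ok <- is.finite(sessions$d_threshold) & is.finite(sessions$d_sfc)
  d <- sessions[ok, , drop = FALSE]
  if (nrow(d) < min_sessions) {
    stop(sprintf("need >= %d sessions with valid changes", min_sessions))
  }
  if (sd(d$d_threshold) == 0 || sd(d$d_sfc) == 0) {
    stop("constant change vector: correlation undefined")
  }
  ct <- cor.test(d$d_threshold, d$d_sfc)
  bands <- grep("^d_sfc_", names(d), value = TRUE)
  by_band <- NULL
  if (length(bands)) {
    by_band <- do.call(rbind, lapply(bands, function(bn) {
      x <- d[[bn]]
      if (sd(x) == 0) {
        return(data.frame(band = sub("d_sfc_", "", bn), r = NA, p.value = NA))
      }
      bt <- cor.test(d$d_threshold, x)
      data.frame(band = sub("d_sfc_", "", bn), r = unname(bt$estimate),
                 p.value = bt$p.value)
    }))
  }
  list(r = unname(ct$estimate), p.value = ct$p.value, n = nrow(d),
       by_band = by_band)
}

# per-pair, per-block band SFC with spike-count equalization across blocks;
# returns long data.frame plus the equalized spike count
pair_block_sfc <- function(spikes_by_block, lfp_by_block, windows_by_block,
                           bands, cfg, seed, dof_scale = 1, sqrt_q = FALSE) {
  clipped <- lapply(seq_along(spikes_by_block), function(b) {
    mapply(clip_spikes, spikes_by_block[[b]], windows_by_block[[b]],
           SIMPLIFY = FALSE)
  })
  eq <- subsample_spikes(clipped, seed = seed)
  rows <- list()
  for (b in seq_along(eq)) {
    est <- compute_sfc(eq[[b]], lfp_by_block[[b]], cfg = cfg)
    zc <- z_transform_sfc(est, dof_scale = dof_scale, sqrt_q = sqrt_q)
    for (bn in names(bands)) {
      idx <- est$frequencies >= bands[[bn]]$low &
        est$frequencies <= bands[[bn]]$high
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, band = bn,
        sfc = mean(est$sfc[idx], na.rm = TRUE),
        z = mean(zc$z[idx], na.rm = TRUE),
        n_spikes = est$n_spikes)
    }
  }
  do.call(rbind, rows)
}

#' Delay-period spike-field coherence
#'
#' Splits each trial's target-test delay into three equal windows (early,
#' middle, late; 333 ms each for the canonical 1000-ms delay) and computes
#' the block-wise band SFC within each window with spike counts equalized
#' across blocks, plus the relative change of blocks 2..n versus block 1.
#' A stimulus-locked coupling regime shows no block effect here.
#'
#' @param spikes_by_block,lfp_by_block lists over blocks of per-trial spike
#'   vectors / [lfp_trace()]s
#' @param delay_span `c(start, end)` of the delay in seconds relative to
#'   target onset (target offset to test onset)
#' @param band a [band_definition()] (theta by default)
#' @param cfg an [mt_config()]
#' @param seed subsampling seed
#' @return data.frame with `window` (early/middle/late), `block`, `sfc`,
#'   and `rel_change` versus block 1
#' @export
delay_period_sfc <- function(spikes_by_block, lfp_by_block,
                             delay_span = c(0.3, 1.3),
                             band = sfc_bands()$theta, cfg = mt_config(),
                             seed = 1) {
  if (diff(delay_span) < 0.999) {
    warning("delay shorter than 1 s: windows rescaled to one third each")
  }
  edges <- seq(delay_span[1], delay_span[2], length.out = 4)
  labels <- c("early", "middle", "late")
  rows <- list()
  for (w in 1:3) {
    win <- c(edges[w], edges[w + 1])
    clipped <- lapply(spikes_by_block, function(blk) {
      lapply(blk, clip_spikes, windows = list(win))
    })
    res <- tryCatch({
      eq <- subsample_spikes(clipped, seed = seed + w)
      vapply(seq_along(eq), function(b) {
        est <- compute_sfc(eq[[b]], lfp_by_block[[b]], cfg = cfg)
        band_average_sfc(est, band)
      }, numeric(1))
    }, spikefield_empty_block = function(e) rep(NA_real_, length(clipped)))
    rows[[w]] <- data.frame(window = labels[w],
                            block = seq_along(spikes_by_block),
                            sfc = res,
                            rel_change = relative_change(res, res[1]))
  }
  do.call(rbind, rows)
}

# concatenated theta-phase series per trial for one channel
session_phases <- function(lfp_trials, spec = band_filter_spec("theta")) {
  lens <- vapply(lfp_trials, function(l) length(l$samples), integer(1))
  conc <- unlist(lapply(lfp_trials, `[[`, "samples"), use.names = FALSE)
  rate <- lfp_trials[[1]]$rate
  filt <- band_filter(lfp_trace(conc, rate = rate, t0 = 0), spec)
  phase <- instantaneous_phase(filt)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  lapply(seq_along(lfp_trials), function(i) {
    lfp_trace(phase[starts[i]:ends[i]], rate = rate, t0 = lfp_trials[[i]]$t0)
  })
}

#' Run the full analysis on one session
#'
#' Orchestrates conditioning, spike-field coherence, phase locking,
#' behavior and statistics for a session object:
#' artifact rejection per channel; Weibull thresholds per 96-trial block
#' plus the match-trial strategy control; per-unit block firing rates and
#' pairwise orientation d'; per spike-LFP pair the block-wise band SFC and
#' z (spike counts equalized across blocks, analysis restricted to the
#' 150-350 ms windows after target and test onsets); theta spike-phase
#' distributions per block with Rayleigh/omnibus tests, the across-block
#' common-median test and pairwise Kuiper tests; delay-period SFC in three
#' windows; block-change statistics per band; and the session-level
#' changes (`d_threshold`, `d_sfc` per band: blocks 2-4 vs block 1) that
#' feed [sfc_behavior_correlation()]. Deterministic given `seed`.
#'
#' @param session an `sf_session` from [generate_session()]
#' @param bands named list of [band_definition()]s for SFC statistics
#' @param cfg an [mt_config()]
#' @param seed seed for spike subsampling and shuffle controls
#' @param correct_only restrict neural analyses to correct trials
#' @param microsaccade_screen drop trials whose eye trace triggers the
#'   fixation-instability abort
#' @param out_dir optional directory for result tables (CSV/JSON)
#' @return object of class `session_result`
#' @export
run_session <- function(session, bands = sfc_bands(), cfg = mt_config(),
                        seed = 1, correct_only = FALSE,
                        microsaccade_screen = FALSE, out_dir = NULL) {
  stopifnot(inherits(session, "sf_session"))
  trials <- session$trials
  required <- c("trial", "block", "dtheta", "correct", "test_on")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("session schema error: missing trial fields ",
         paste(missing_cols, collapse = ", "))
  }
  n_blocks <- max(trials$block)

  # ---- trial screening -------------------------------------------------
  keep <- rep(TRUE, nrow(trials))
  if (correct_only) keep <- keep & trials$correct
  if (microsaccade_screen) {
    aborts <- vapply(session$eye, function(e) {
      detect_microsaccades(e)$abort
    }, logical(1))
    keep <- keep & !aborts
  }
  qc <- list()
  for (ch in seq_along(session$lfp)) {
    part <- reject_artifacts(session$lfp[[ch]])
    ch_keep <- rep(FALSE, nrow(trials))
    ch_keep[part$kept] <- TRUE
    qc[[ch]] <- data.frame(channel = ch, kept = length(part$kept),
                           discarded = length(part$discarded))
    keep <- keep & ch_keep
  }
  qc <- do.call(rbind, qc)
  kept_idx <- which(keep)

  # ---- behavior --------------------------------------------------------
  thresholds <- block_thresholds(trials)
  match_rates <- match_rate_by_block(trials)
  sliding <- tryCatch(sliding_threshold(trials), error = function(e) NULL)

  # ---- neuron metrics --------------------------------------------------
  test_win <- 0.3
  neuron <- list()
  for (u in seq_along(session$spikes)) {
    rates <- vapply(seq_len(nrow(trials)), function(i) {
      sum(session$spikes[[u]][[i]] >= trials$test_on[i] &
            session$spikes[[u]][[i]] <= trials$test_on[i] + test_win) / test_win
    }, numeric(1))
    per_block <- vapply(seq_len(n_blocks), function(b) {
      mean(rates[trials$block == b & keep])
    }, numeric(1))
    oris <- sort(unique(trials$dtheta))
    combos <- utils::combn(oris, 2)
    dps <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      data.frame(unit = u, block = b,
                 ori_a = combos[1, ], ori_b = combos[2, ],
                 dprime = vapply(seq_len(ncol(combos)), function(j) {
                   ra <- rates[trials$block == b & keep &
                                 trials$dtheta == combos[1, j]]
                   rb <- rates[trials$block == b & keep &
                                 trials$dtheta == combos[2, j]]
                   if (length(ra) < 2 || length(rb) < 2) return(NA_real_)
                   suppressWarnings(compute_dprime(ra, rb))
                 }, numeric(1)))
    }))
    neuron[[u]] <- list(unit = u, mean_rate = per_block, dprime = dps)
  }

  # ---- per-pair SFC ----------------------------------------------------
  block_trials <- lapply(seq_len(n_blocks), function(b) {
    intersect(which(trials$block == b), kept_idx)
  })
  windows_by_block <- lapply(block_trials, function(idx) {
    lapply(idx, function(i) stim_windows(trials[i, ]))
  })
  pair_rows <- list()
  delay_tabs <- list()
  pair_id <- 0L
  for (u in seq_along(session$spikes)) {
    for (ch in seq_along(session$lfp)) {
      pair_id <- pair_id + 1L
      spikes_by_block <- lapply(block_trials, function(idx) {
        session$spikes[[u]][idx]
      })
      lfp_by_block <- lapply(block_trials, function(idx) {
        session$lfp[[ch]][idx]
      })
      dist <- abs(session$unit_positions[u] - session$channel_positions[ch])
      tab <- tryCatch(
        pair_block_sfc(spikes_by_block, lfp_by_block, windows_by_block,
                       bands, cfg, seed = split_seed(seed, "subsample", pair_id)),
        spikefield_empty_block = function(e) NULL)
      if (is.null(tab)) {
        message(sprintf("pair %d (unit %d x channel %d) excluded: empty block",
                        pair_id, u, ch))
        next
      }
      tab$pair_id <- pair_id; tab$unit <- u; tab$channel <- ch
      tab$distance <- dist; tab$near <- dist < 2
      tab$same_electrode <- isTRUE(all.equal(dist, 0))
      pair_rows[[length(pair_rows) + 1L]] <- tab
      delay_tabs[[length(delay_tabs) + 1L]] <- cbind(
        pair_id = pair_id,
        delay_period_sfc(spikes_by_block, lfp_by_block,
                         delay_span = c(0.3, median(trials$test_on)),
                         band = bands$theta, cfg = cfg,
                         seed = split_seed(seed, "delay", pair_id)))
    }
  }
  pairs <- do.call(rbind, pair_rows)
  delay <- do.call(rbind, delay_tabs)

  # ---- theta phase locking (first unit x its coupled channel) ----------
  phase_report <- NULL
  if (length(kept_idx) >= 2) {
    ch1 <- min(1L, length(session$lfp))
    phases <- session_phases(session$lfp[[1]][kept_idx])
    spk <- session$spikes[[1]][kept_idx]
    phase_by_block <- lapply(seq_len(n_blocks), function(b) {
      in_b <- which(trials$block[kept_idx] == b)
      ang <- unlist(lapply(in_b, function(j) {
        wins <- stim_windows(trials[kept_idx[j], ])
        c(spike_phases(spk[[j]], phases[[j]], window = wins[[1]])$angles,
          spike_phases(spk[[j]], phases[[j]], window = wins[[2]])$angles)
      }))
      structure(list(angles = ang, n = length(ang),
                     window = c(0.15, 0.35)), class = "phase_distribution")
    })
    per_block <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      ut <- uniformity_tests(phase_by_block[[b]])
      data.frame(block = b, n = ut$n,
                 rayleigh_z = if (ut$computable) ut$rayleigh$Z else NA,
                 rayleigh_p = if (ut$computable) ut$rayleigh$p.value else NA,
                 omnibus_p = if (ut$computable) ut$omnibus$p.value else NA)
    }))
    comparison <- tryCatch(compare_phase_distributions(phase_by_block),
                           error = function(e) NULL)
    phase_report <- list(per_block = per_block, comparison = comparison)
  }

  # ---- block-change statistics per band --------------------------------
  stats_by_band <- lapply(names(bands), function(bn) {
    d <- pairs[pairs$band == bn, c("pair_id", "block", "sfc")]
    names(d)[3] <- "value"
    block_change_statistics(d)
  })
  names(stats_by_band) <- names(bands)

  # ---- session-level changes ------------------------------------------
  thr_ok <- thresholds$converged & is.finite(thresholds$threshold)
  d_threshold <- if (thr_ok[1] && any(thr_ok[-1])) {
    relative_change(mean(thresholds$threshold[-1][thr_ok[-1]]),
                    thresholds$threshold[1])
  } else NA_real_
  d_sfc <- vapply(names(bands), function(bn) {
    d <- pairs[pairs$band == bn, ]
    per_pair <- vapply(split(d, d$pair_id), function(p) {
      p <- p[order(p$block), ]
      if (!is.finite(p$sfc[1]) || p$sfc[1] == 0) return(NA_real_)
      relative_change(mean(p$sfc[-1]), p$sfc[1])
    }, numeric(1))
    mean(per_pair, na.rm = TRUE)
  }, numeric(1))

  result <- structure(list(
    thresholds = thresholds, match_rates = match_rates, sliding = sliding,
    neuron = neuron, pairs = pairs, delay = delay,
    phase = phase_report, stats = stats_by_band, qc = qc,
    d_threshold = d_threshold, d_sfc = d_sfc,
    n_trials_kept = length(kept_idx), seed = seed),
    class = "session_result")
  if (!is.null(out_dir)) write_session_result(result, out_dir)
  result
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %d trials kept, %d pair-band rows\n",
              x$n_trials_kept, if (is.null(x$pairs)) 0L else nrow(x$pairs)))
  cat("block thresholds (deg):",
      paste(sprintf("%.2f", x$thresholds$threshold), collapse = ", "), "\n")
  cat(sprintf("relative threshold change (blocks 2+ vs 1): %.1f%%\n",
              100 * x$d_threshold))
  cat("relative theta SFC change:",
      sprintf("%.1f%%", 100 * x$d_sfc[["theta"]]), "\n")
  invisible(x)
}

#' Write session result tables
#'
#' Emits the session artifacts as plain-text files: `thresholds.csv`,
#' `sfc_long.csv` (pair_id, block, band, sfc, z), `delay_sfc.csv`,
#' `qc.csv`, and `report.json` with the phase tests and session-level
#' changes.
#'
#' @param result a `session_result`
#' @param out_dir output directory (created if needed)
#' @return invisibly, the output paths
#' @export
write_session_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    thresholds = file.path(out_dir, "thresholds.csv"),
    sfc = file.path(out_dir, "sfc_long.csv"),
    delay = file.path(out_dir, "delay_sfc.csv"),
    qc = file.path(out_dir, "qc.csv"),
    report = file.path(out_dir, "report.json"))
  utils::write.csv(result$thresholds, paths["thresholds"], row.names = FALSE)
  utils::write.csv(result$pairs, paths["sfc"], row.names = FALSE)
  utils::write.csv(result$delay, paths["delay"], row.names = FALSE)
  utils::write.csv(result$qc, paths["qc"], row.names = FALSE)
  report <- list(
    d_threshold = result$d_threshold,
    d_sfc = as.list(result$d_sfc),
    phase_per_block = result$phase$per_block,
    n_trials_kept = result$n_trials_kept)
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Analyze a cohort of sessions
#'
#' Runs [run_session()] on each session and correlates the behavioral and
#' theta-coherence changes across sessions.
#'
#' @param sessions list of `sf_session` objects
#' @param ... passed to [run_session()]
#' @return list with `summaries` (one row per session) and `correlation`
#'   (from [sfc_behavior_correlation()])
#' @export
run_cohort <- function(sessions, ...) {
  summaries <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    r <- run_session(sessions[[i]], ...)
    out <- data.frame(session = i, d_threshold = r$d_threshold,
                      d_sfc = r$d_sfc[["theta"]])
    for (bn in names(r$d_sfc)) out[[paste0("d_sfc_", bn)]] <- r$d_sfc[[bn]]
    out
  }))
  correlation <- tryCatch(sfc_behavior_correlation(summaries),
                          error = function(e) NULL)
  list(summaries = summaries, correlation = correlation)
}
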