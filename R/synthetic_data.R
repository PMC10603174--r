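# Synthetic electrophysiology trials and behavioral cohorts generated from
# a ground truth, plus plain-text serialization of tracks and cascades.

#' Generate synthetic single-sensillum trials from a ground-truth cascade
#'
#' Each trial passes a stimulus pattern through the truth encoder: the LFP
#' is the stage-1 convolution plus Gaussian noise, the rate is the
#' rectified stage-2 convolution of that (noisy) LFP plus the 4.7 spikes/s
#' baseline and Gaussian noise.  Optionally emits inhomogeneous-Poisson
#' spike times drawn from the clean rate.
#'
#' @param truth a [make_ground_truth()] object (its `encoder` and `noise`
#'   are used)
#' @param stimulus_patterns list of stimulus vectors at 100 Hz
#' @param n_trials trials per pattern
#' @param noise_sd optional list with `lfp` and `rate` SDs overriding the
#'   truth noise levels (use 0 for noiseless trials)
#' @param seed RNG seed
#' @param spikes also draw Poisson spike times
#' @return list of trials; each has `t`, `stimulus`, `lfp`, `rate`,
#'   `pattern`, `trial`, and optionally `spike_times`
#' @export
generate_ephys_trials <- function(truth, stimulus_patterns, n_trials = 1,
                                  noise_sd = NULL, seed = NULL,
                                  spikes = FALSE) {
  stopifnot(n_trials >= 1)
  casc <- truth$encoder
  if (is.null(noise_sd))
    noise_sd <- list(lfp = truth$noise$lfp_sd, rate = truth$noise$rate_sd)
  if (is.numeric(noise_sd) && length(noise_sd) == 1)
    noise_sd <- list(lfp = noise_sd, rate = noise_sd)
  if (noise_sd$lfp < 0 || noise_sd$rate < 0) stop("negative noise_sd")
  with_seed(seed, {
    out <- list()
    for (p in seq_along(stimulus_patterns)) {
      s <- stimulus_patterns[[p]]
      n <- length(s)
      lfp_clean <- conv_causal(s, casc$filter1)
      for (tr in seq_len(n_trials)) {
        lfp <- lfp_clean + stats::rnorm(n, 0, noise_sd$lfp)
        rate <- conv_causal(lfp, casc$filter2) + casc$baseline
        rate <- pmax(rate + stats::rnorm(n, 0, noise_sd$rate), 0)
        trial <- list(t = (seq_len(n) - 1) / casc$fs, stimulus = s,
                      lfp = lfp, rate = rate, pattern = p, trial = tr)
        if (spikes) {
          # thinning against the clean rectified rate
          clean <- pmax(conv_causal(lfp_clean, casc$filter2) +
                          casc$baseline, 0)
          rmax <- max(clean) + 1e-9
          cand <- cumsum(stats::rexp(ceiling(rmax * n / casc$fs * 1.5 + 20),
                                     rmax))
          cand <- cand[cand < n / casc$fs]
          keep <- stats::runif(length(cand)) <
            clean[pmin(floor(cand * casc$fs) + 1, n)] / rmax
          trial$spike_times <- cand[keep]
        }
        out[[length(out) + 1]] <- trial
      }
    }
    out
  })
}

#' Generate a synthetic behavioral cohort from a ground truth
#'
#' Convenience wrapper: runs the agent simulator with the ground truth's
#' encoder and sampling rules, so the cohort's latent (f, df) series and
#' sampled kinematics are known exactly and downstream estimators can be
#' tested by recovery.
#'
#' @param truth a [make_ground_truth()]
#' @param arena an [make_arena_model()]
#' @param config an [agent_config()]
#' @param seed master seed
#' @return a `trackset` (see [simulate_cohort()])
#' @export
generate_behavior_cohort <- function(truth, arena,
                                     config = agent_config(), seed = 1) {
  simulate_cohort(config, arena, truth$encoder, policy_from_truth(truth),
                  seed = seed)
}

#' Write a trackset to tidy CSV with a JSON sidecar
#'
#' One row per frame (`fly_id`, `t_s`, `x_norm`, `y_norm`, `head_x_norm`,
#' `head_y_norm`, `state`); configuration and seed go to `<path>.json`.
#'
#' @param ts a `trackset`
#' @param path CSV path
#' @export
write_trackset <- function(ts, path) {
  rows <- lapply(seq_along(ts$flies), function(k) {
    tr <- ts$flies[[k]]$track
    data.frame(fly_id = k, t_s = tr$t, x_norm = tr$x, y_norm = tr$y,
               head_x_norm = tr$head_x, head_y_norm = tr$head_y,
               state = tr$state)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- list(seed = ts$seed,
               first_entries = ts$first_entries,
               config = ts$config[!vapply(ts$config, is.function,
                                          logical(1))])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trackset CSV written by [write_trackset()]
#'
#' @param path CSV path
#' @param arena_radius_cm arena radius for unit conversion
#' @return list of `fly_track` objects
#' @export
read_trackset <- function(path, arena_radius_cm = 4) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$fly_id), function(d) {
    tr <- make_track(d$t_s, d$x_norm, d$y_norm, d$head_x_norm,
                     d$head_y_norm, fly_id = d$fly_id[1],
                     arena_radius_cm = arena_radius_cm)
    if ("state" %in% names(d)) tr$state <- d$state
    tr
  })
}

#' Serialize an encoder cascade to JSON
#'
#' @param cascade an `orn_cascade`
#' @param path output path
#' @export
write_cascade <- function(cascade, path) {
  jsonlite::write_json(
    list(filter1 = cascade$filter1, filter2 = cascade$filter2,
         baseline = cascade$baseline, fs = cascade$fs,
         rectify = cascade$rectify),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cascade
#' @export
read_cascade <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_cascade(x$filter1, x$filter2, baseline = x$baseline, fs = x$fs,
              rectify = x$rectify)
}

#' Write or read electrophysiology trials as tidy CSV
#'
#' One row per sample with `pattern`, `trial`, `t_s`, `stimulus`, `lfp`,
#' `rate` columns.
#'
#' @param trials a list of trials from [generate_ephys_trials()]
#' @param path CSV path
#' @export
write_ephys_trials <- function(trials, path) {
  rows <- lapply(trials, function(tr)
    data.frame(pattern = tr$pattern, trial = tr$trial, t_s = tr$t,
               stimulus = tr$stimulus, lfp = tr$lfp, rate = tr$rate))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ephys_trials
#' @export
read_ephys_trials <- function(path) {
  df <- utils::read.csv(path)
  unname(lapply(split(df, interaction(df$pattern, df$trial, drop = TRUE)),
                function(d) list(t = d$t_s, stimulus = d$stimulus,
                                 lfp = d$lfp, rate = d$rate,
                                 pattern = d$pattern[1],
                                 trial = d$trial[1])))
}
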