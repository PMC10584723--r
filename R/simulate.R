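#' Default ground-truth half-amplitude map
#'
#' Per-condition true serial-dependence half-amplitudes (morph steps) used
#' by the simulator when none are supplied. The defaults place attraction
#' where the human experiments found it — Experiment 1: 3.6 steps at
#' (ISI 1 s, delay 1 s) and 5.9 at (ISI 1 s, delay 6 s); Experiment 2:
#' 2.1 at (target Face 2, delay 1 s) and 2.4 at (target Face 2, delay
#' 6 s) — and zero everywhere else.
#'
#' @param experiment 1 or 2.
#' @return named numeric vector over [condition_keys()].
#' @export
default_amplitudes <- function(experiment) {
  keys <- condition_keys(experiment)
  amp <- stats::setNames(rep(0, length(keys)), keys)
  if (match_experiment(experiment) == 1L) {
    amp["isi1_delay1"] <- 3.6
    amp["isi1_delay6"] <- 5.9
  } else {
    amp["postcue2_delay1"] <- 2.1
    amp["postcue2_delay6"] <- 2.4
  }
  amp
}

#' Configuration for the synthetic observer
#'
#' Bundles the design and observer parameters of the generative model used
#' for parameter-recovery and calibration studies. The observer reproduces
#' the target face with a DoG-shaped bias toward the inducer plus wrapped
#' Gaussian response noise, lapses uniformly at random with probability
#' `lapse_rate` (half of the lapse trials also draw a response time above
#' the 15 s cutoff so both lapse filters are exercised), and otherwise
#' responds with lognormal response times (median ~5 s).
#'
#' `noise_sd` defaults to 16 morph steps, calibrated (see
#' [calibrate_noise()]) so that categorical classification accuracy falls
#' in the ~70-74% range reported for human observers.
#'
#' @param experiment 1 or 2.
#' @param n_participants number of simulated participants.
#' @param sessions_per_participant sessions each (180 trials/session for
#'   Experiment 1, 300 for Experiment 2).
#' @param amplitude true half-amplitudes: `NULL` for
#'   [default_amplitudes()], a single number applied to every condition,
#'   or a named vector covering every condition key.
#' @param bias_sigma width (morph steps) of the generating DoG curve.
#' @param noise_sd SD (morph steps) of the wrapped Gaussian response noise.
#' @param lapse_rate probability of a uniform-random lapse response.
#' @param rt_meanlog,rt_sdlog lognormal response-time parameters.
#' @param seed integer seed; simulation is deterministic given the config.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(experiment = 1, n_participants = 20,
                       sessions_per_participant = 1, amplitude = NULL,
                       bias_sigma = 20, noise_sd = 16, lapse_rate = 0.05,
                       rt_meanlog = log(5), rt_sdlog = 0.4, seed = 1L) {
  experiment <- match_experiment(experiment)
  keys <- condition_keys(experiment)
  if (is.null(amplitude)) {
    amplitude <- default_amplitudes(experiment)
  } else if (is.null(names(amplitude))) {
    if (length(amplitude) != 1L)
      stop("unnamed `amplitude` must be a single number")
    amplitude <- stats::setNames(rep(amplitude, length(keys)), keys)
  } else {
    missing <- setdiff(keys, names(amplitude))
    if (length(missing))
      stop("`amplitude` map is missing condition keys: ",
           paste(missing, collapse = ", "))
    amplitude <- amplitude[keys]
  }
  stopifnot(bias_sigma > 0, noise_sd >= 0,
            lapse_rate >= 0, lapse_rate < 1)
  structure(
    list(experiment = experiment, n_participants = n_participants,
         sessions_per_participant = sessions_per_participant,
         amplitude = amplitude, bias_sigma = bias_sigma,
         noise_sd = noise_sd, lapse_rate = lapse_rate,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
         seed = as.integer(seed)),
    class = "sim_config")
}

session_schedule <- function(experiment) {
  if (experiment == 1L) {
    cells <- expand.grid(isi_s = exp1_isi_levels,
                         delay_s = exp1_delay_levels)
    cells$postcue <- NA_integer_
    cells[rep(seq_len(nrow(cells)), each = 9L), , drop = FALSE]
  } else {
    cells <- expand.grid(postcue = 1:2, delay_s = exp2_delay_levels)
    cells$isi_s <- 1
    cells[rep(seq_len(nrow(cells)), each = 50L), , drop = FALSE]
  }
}

#' Simulate a full experiment from a synthetic observer
#'
#' Generates trial records following the experimental designs: balanced
#' pseudorandom condition schedules (Experiment 1: 180 trials/session,
#' each of the 20 ISI x delay cells exactly 9 times; Experiment 2: 300
#' trials/session, each of the 6 postcue x delay cells exactly 50 times),
#' Face 1 and Face 2 drawn independently and uniformly from the wheel,
#' and responses from the biased observer described in [sim_config()].
#' The generating bias is parameterised directly by its half-amplitude so
#' the simulator's truth and the analysis estimate share units.
#'
#' @param config a [sim_config()].
#' @param wheel a [morph_wheel()].
#' @return data.frame of trial records in the standard schema
#'   (`participant, session, trial, isi_s, delay_s, face1, face2, postcue,
#'   response, rt_s`).
#' @examples
#' cfg <- sim_config(experiment = 1, n_participants = 2, seed = 7)
#' trials <- simulate_experiment(cfg)
#' nrow(trials)  # 360
#' @export
simulate_experiment <- function(config, wheel = morph_wheel()) {
  stopifnot(inherits(config, "sim_config"))
  n_pos <- wheel$n_positions
  sched0 <- session_schedule(config$experiment)
  alpha_map <- config$amplitude / dog_peak_coef(config$bias_sigma)

  with_seed(config$seed, {
    out <- vector("list",
                  config$n_participants * config$sessions_per_participant)
    k <- 0L
    for (p in seq_len(config$n_participants)) {
      for (s in seq_len(config$sessions_per_participant)) {
        sched <- sched0[sample.int(nrow(sched0)), , drop = FALSE]
        nt <- nrow(sched)
        face1 <- sample.int(n_pos, nt, replace = TRUE) - 1L
        face2 <- sample.int(n_pos, nt, replace = TRUE) - 1L
        swap <- !is.na(sched$postcue) & sched$postcue == 1L
        target  <- ifelse(swap, face1, face2)
        inducer <- ifelse(swap, face2, face1)
        delta <- signed_distance(target, inducer, wheel)
        key <- if (config$experiment == 1L)
          sprintf("isi%g_delay%g", sched$isi_s, sched$delay_s)
        else
          sprintf("postcue%d_delay%g", sched$postcue, sched$delay_s)
        bias <- dog_value(delta, 0, config$bias_sigma, 1) *
          alpha_map[key]
        noise <- stats::rnorm(nt, 0, config$noise_sd)
        response <- (round(target + bias + noise)) %% n_pos
        rt <- stats::rlnorm(nt, config$rt_meanlog, config$rt_sdlog)
        lapse <- stats::runif(nt) < config$lapse_rate
        if (any(lapse)) {
          nl <- sum(lapse)
          response[lapse] <- sample.int(n_pos, nl, replace = TRUE) - 1L
          slow <- stats::runif(nl) < 0.5
          rt[lapse][slow] <- 15 + stats::rexp(sum(slow), rate = 1 / 3)
        }
        k <- k + 1L
        out[[k]] <- data.frame(
          participant = sprintf("p%02d", p),
          session = s,
          trial = seq_len(nt),
          isi_s = sched$isi_s,
          delay_s = sched$delay_s,
          face1 = face1,
          face2 = face2,
          postcue = sched$postcue,
          response = as.integer(response),
          rt_s = rt,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Calibrate response noise to a target classification accuracy
#'
#' Finds, by bisection, the wrapped-Gaussian response-noise SD at which
#' the simulated observer's categorical classification accuracy matches a
#' target (e.g. the ~72% typical of human observers on this task).
#' Accuracy is evaluated on filtered trials from a zero-amplitude
#' simulation, with a fixed seed per evaluation so the accuracy-vs-noise
#' curve is deterministic and monotone decreasing.
#'
#' @param target_accuracy_pct target accuracy in percent, in (33.34, 100).
#' @param config a [sim_config()] supplying lapse rate, design, and seed.
#' @param tol acceptable accuracy mismatch in percentage points
#'   (default 0.5).
#' @param n_trials approximate number of simulated trials per evaluation.
#' @param sd_range search bracket for the noise SD.
#' @param wheel a [morph_wheel()].
#' @return the calibrated noise SD in morph steps, with the achieved
#'   accuracy as attribute `"accuracy_pct"`.
#' @export
calibrate_noise <- function(target_accuracy_pct, config = sim_config(),
                            tol = 0.5, n_trials = 20000,
                            sd_range = c(0.01, 150),
                            wheel = morph_wheel()) {
  if (target_accuracy_pct <= 100 / 3 + 0.01 || target_accuracy_pct > 100)
    stop("`target_accuracy_pct` must be in (33.34, 100]")
  trials_per_sess <- if (config$experiment == 1L) 180 else 300
  n_part <- max(1L, ceiling(n_trials / trials_per_sess))
  acc_at <- function(sd) {
    cfg <- config
    cfg$noise_sd <- sd
    cfg$amplitude[] <- 0
    cfg$n_participants <- n_part
    cfg$sessions_per_participant <- 1L
    trials <- simulate_experiment(cfg, wheel)
    d <- derive_trials(trials, wheel, cfg$experiment)
    f <- filter_trials(d)
    classification_accuracy(f$kept, wheel, n_boot = 0)$accuracy_pct
  }
  lo <- sd_range[1]; hi <- sd_range[2]
  a_lo <- acc_at(lo); a_hi <- acc_at(hi)
  if (target_accuracy_pct > a_lo + tol)
    stop("target accuracy unattainable: even noiseless accuracy is ",
         round(a_lo, 1), "%")
  if (target_accuracy_pct < a_hi - tol)
    stop("target accuracy unattainable: accuracy floor is ",
         round(a_hi, 1), "%")
  mid <- lo; acc <- a_lo
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    acc <- acc_at(mid)
    if (abs(acc - target_accuracy_pct) <= tol) break
    if (acc > target_accuracy_pct) lo <- mid else hi <- mid
  }
  structure(mid, accuracy_pct = acc)
}
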