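#' Whistle specification
#'
#' Parametric description of one synthetic whistle: a polynomial frequency
#' contour in the 5-20 kHz band, optional harmonics at near-integer
#' multiples, and optional delayed multipath replicas.
#'
#' @param start_time Emission time (s) within the scene.
#' @param duration Contour duration (s), > 0.
#' @param contour_coeffs Polynomial coefficients of `f0(t)` in Hz
#'   (intercept first, `t` in seconds over `[0, duration]`), degree <= 6.
#' @param n_harmonics Number of harmonics (>= 0); harmonic `m` (for
#'   `m = 2 .. n_harmonics + 1`) sits at `m * harmonic_rate_true * f0(t)`.
#' @param harmonic_rate_true Dimensionless per-harmonic frequency ratio
#'   (1 = ideal harmonics).
#' @param multipath_delays Numeric vector of delays (s), each in `(0, inf)`.
#' @param multipath_gains Linear amplitude factors in `(0, 1)`, one per delay.
#' @param amplitude Linear amplitude of the basic contour.
#' @return A `whistle_spec` object. Errors with an explicit violation report
#'   if the contour leaves the 5-20 kHz band.
#' @export
whistle_spec <- function(start_time, duration, contour_coeffs,
                         n_harmonics = 0L, harmonic_rate_true = 1,
                         multipath_delays = numeric(0),
                         multipath_gains = numeric(0), amplitude = 1) {
  if (duration <= 0) stop("whistle_spec: duration must be > 0")
  if (length(contour_coeffs) > 7L)
    stop("whistle_spec: contour degree must be <= 6")
  if (length(multipath_delays) != length(multipath_gains))
    stop("whistle_spec: delays and gains must have equal length")
  if (any(multipath_gains <= 0 | multipath_gains >= 1))
    stop("whistle_spec: multipath gains must be strictly in (0, 1)")
  if (any(multipath_delays <= 0))
    stop("whistle_spec: multipath delays must be > 0")
  tt <- seq(0, duration, length.out = max(16L, ceiling(duration * 1000)))
  f <- poly_eval(contour_coeffs, tt)
  if (any(f < 5000) || any(f > 20000)) {
    bad <- range(f)
    stop(sprintf(
      "whistle_spec: contour leaves [5000, 20000] Hz (range %.1f-%.1f Hz at t in [0, %.3f] s)",
      bad[1], bad[2], duration
    ))
  }
  structure(
    list(start_time = start_time, duration = duration,
         contour_coeffs = as.numeric(contour_coeffs),
         n_harmonics = as.integer(n_harmonics),
         harmonic_rate_true = harmonic_rate_true,
         multipath_delays = as.numeric(multipath_delays),
         multipath_gains = as.numeric(multipath_gains),
         amplitude = amplitude),
    class = "whistle_spec"
  )
}

poly_eval <- function(coeffs, t) {
  f <- numeric(length(t))
  for (k in seq_along(coeffs)) f <- f + coeffs[k] * t^(k - 1)
  f
}

# antiderivative of the contour polynomial (phase in cycles)
poly_integral <- function(coeffs, t) {
  ph <- numeric(length(t))
  for (k in seq_along(coeffs)) ph <- ph + coeffs[k] * t^k / k
  ph
}

#' Synthesize one whistle waveform
#'
#' Renders the basic contour, its harmonics (amplitude halved per order,
#' skipped if they would alias), and delayed attenuated multipath replicas.
#' The instantaneous frequency of the basic contour follows
#' `contour_coeffs`; harmonic `m` follows `m * harmonic_rate_true * f0(t)`.
#' Edges are shaped with 5 ms raised-cosine ramps.
#'
#' @param spec A [whistle_spec()].
#' @param sample_rate Sample rate in Hz.
#' @return An [audio_segment()] starting at `spec$start_time`, covering the
#'   whistle and its longest multipath tail.
#' @export
synth_whistle <- function(spec, sample_rate) {
  stopifnot(inherits(spec, "whistle_spec"))
  fs <- sample_rate
  n <- max(2L, round(spec$duration * fs))
  t <- (0:(n - 1)) / fs
  env <- cosine_ramp(n, fs, ramp = 0.005)
  base_phase <- poly_integral(spec$contour_coeffs, t)
  x <- spec$amplitude * env * sin(2 * pi * base_phase)
  if (spec$n_harmonics > 0L) {
    fmax <- max(poly_eval(spec$contour_coeffs, t))
    for (m in 2:(spec$n_harmonics + 1L)) {
      if (m * spec$harmonic_rate_true * fmax >= 0.98 * fs / 2) next
      x <- x + spec$amplitude * 0.5^(m - 1) * env *
        sin(2 * pi * m * spec$harmonic_rate_true * base_phase)
    }
  }
  if (length(spec$multipath_delays) > 0L) {
    dmax <- max(spec$multipath_delays)
    out <- c(x, numeric(ceiling(dmax * fs) + 1L))
    for (k in seq_along(spec$multipath_delays)) {
      off <- round(spec$multipath_delays[k] * fs)
      idx <- (off + 1):(off + n)
      out[idx] <- out[idx] + spec$multipath_gains[k] * x
    }
    x <- out
  }
  audio_segment(x, fs, spec$start_time)
}

cosine_ramp <- function(n, fs, ramp = 0.005) {
  nr <- min(floor(n / 2), max(1L, round(ramp * fs)))
  env <- rep(1, n)
  up <- 0.5 - 0.5 * cos(pi * (0:(nr - 1)) / nr)
  env[1:nr] <- up
  env[(n - nr + 1):n] <- rev(up)
  env
}

#' Vessel underwater-radiated-noise specification
#'
#' The three manual-tagging cues: broadband noise, an engine-harmonic comb,
#' and one amplitude-modulated narrowband thruster line.
#'
#' @param intervals Two-column matrix or data frame of (start, end) seconds,
#'   sorted and non-overlapping.
#' @param broadband_level Broadband noise level, dB re unit amplitude.
#' @param engine_fundamental Engine fundamental (Hz).
#' @param n_engine_harmonics Number of comb lines.
#' @param thruster_mod_freq Thruster AM rate (Hz).
#' @param thruster_carrier Thruster line carrier (Hz; in-band by default so
#'   the cue is visible on the analysis spectrogram).
#' @return A `vessel_noise_spec` object.
#' @export
vessel_noise_spec <- function(intervals, broadband_level = -26,
                              engine_fundamental = 90,
                              n_engine_harmonics = 8,
                              thruster_mod_freq = 4,
                              thruster_carrier = 6000) {
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2L) stop("vessel_noise_spec: intervals need 2 columns")
  if (nrow(intervals) > 0L) {
    if (any(intervals[, 2] <= intervals[, 1]))
      stop("vessel_noise_spec: interval end must exceed start")
    if (nrow(intervals) > 1L) {
      o <- order(intervals[, 1])
      intervals <- intervals[o, , drop = FALSE]
      if (any(intervals[-1, 1] < intervals[-nrow(intervals), 2]))
        stop("vessel_noise_spec: intervals must be non-overlapping")
    }
  }
  structure(
    list(intervals = unname(intervals), broadband_level = broadband_level,
         engine_fundamental = engine_fundamental,
         n_engine_harmonics = as.integer(n_engine_harmonics),
         thruster_mod_freq = thruster_mod_freq,
         thruster_carrier = thruster_carrier),
    class = "vessel_noise_spec"
  )
}

#' Scene configuration for the synthetic generator
#'
#' @param day_index Integer day number.
#' @param day_length Scene duration in seconds.
#' @param sample_rate Sample rate in Hz (>= 40 kHz so the 20 kHz band edge
#'   is representable).
#' @param class_label `"with_vessel"` or `"no_vessel"` (used for bookkeeping
#'   and defaults; vessel noise itself comes from `vessel`).
#' @param whistle_rate Whistle emissions per minute.
#' @param overlap_prob Probability that a whistle is answered by an
#'   overlapping whistle from a second animal.
#' @param vessel A [vessel_noise_spec()] or `NULL`.
#' @param ambient_level Ambient Gaussian noise level, dB re unit amplitude.
#' @param transient_rate Snapping-shrimp-like transients per minute.
#' @param harmonic_prob Probability a whistle carries harmonics.
#' @param multipath_prob Probability a whistle carries a multipath replica.
#' @param seed RNG seed; fully determines the scene.
#' @return A `scene_config` object.
#' @export
scene_config <- function(day_index = 1L, day_length = 30, sample_rate = 48000,
                         class_label = c("no_vessel", "with_vessel"),
                         whistle_rate = 6, overlap_prob = 0.15,
                         vessel = NULL, ambient_level = -40,
                         transient_rate = 10, harmonic_prob = 0.35,
                         multipath_prob = 0.3, seed = 1L) {
  class_label <- match.arg(class_label)
  if (sample_rate < 2 * 20000)
    stop("scene_config: sample_rate must be >= 40 kHz")
  if (whistle_rate < 0 || transient_rate < 0)
    stop("scene_config: rates must be >= 0")
  if (whistle_rate > 0 && day_length < 5)
    stop("scene_config: day_length too short for the requested whistle rate")
  structure(as.list(environment()), class = "scene_config")
}

random_contour <- function(duration, fmin = 6000, fmax = 18000) {
  # degree-2 contour kept comfortably inside the band
  f0 <- runif(1, fmin + 1000, fmax - 1000)
  sweep <- runif(1, -4000, 4000) # Hz/s
  curv <- runif(1, -3000, 3000) # Hz/s^2
  co <- c(f0, sweep, curv)
  tt <- seq(0, duration, length.out = 32)
  f <- poly_eval(co, tt)
  # reflect back into the band if the sweep escapes
  if (max(f) > 19500) co[1] <- co[1] - (max(f) - 19500)
  if (min(poly_eval(co, tt)) < 5500) co[1] <- co[1] + (5500 - min(poly_eval(co, tt)))
  co
}

random_whistle_spec <- function(start_time, cfg, amp_db_range = c(-20, 0)) {
  duration <- min(2.5, max(0.08, rlnorm(1, log(0.4), 0.5)))
  co <- random_contour(duration)
  nh <- if (runif(1) < cfg$harmonic_prob) sample(1:2, 1) else 0L
  has_mp <- runif(1) < cfg$multipath_prob
  whistle_spec(
    start_time = start_time, duration = duration, contour_coeffs = co,
    n_harmonics = nh,
    harmonic_rate_true = rnorm(1, 1, 0.003),
    multipath_delays = if (has_mp) runif(1, 0.02, 0.15) else numeric(0),
    multipath_gains = if (has_mp) runif(1, 0.35, 0.7) else numeric(0),
    amplitude = 10^(runif(1, amp_db_range[1], amp_db_range[2]) / 20)
  )
}

#' Synthesize a full acoustic scene with ground truth
#'
#' Sums Poisson-emitted whistles (with harmonics, multipath and overlapping
#' answers), vessel noise on its intervals, ambient Gaussian noise and
#' impulsive transients. The same `(config, seed)` reproduces the scene
#' bit-for-bit.
#'
#' @param config A [scene_config()].
#' @return A list with `waveform` (an [audio_segment()]) and `ground_truth`
#'   (see Details). `ground_truth$whistles` is a tibble of emitted whistle
#'   specs with cluster ids; `ground_truth$vessel_intervals` the vessel
#'   interval matrix; `ground_truth$class_label` the scene class.
#' @export
synth_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_local_seed(config$seed, {
    fs <- config$sample_rate
    n <- round(config$day_length * fs)
    x <- numeric(n)
    specs <- list()
    cluster_of <- integer(0)
    n_wh <- if (config$whistle_rate > 0)
      rpois(1, config$whistle_rate * config$day_length / 60) else 0L
    if (n_wh > 0) {
      times <- sort(runif(n_wh, 0, max(0.1, config$day_length - 3)))
      cl <- 0L
      for (t0 in times) {
        cl <- cl + 1L
        sp <- random_whistle_spec(t0, config)
        specs[[length(specs) + 1L]] <- sp
        cluster_of <- c(cluster_of, cl)
        if (runif(1) < config$overlap_prob) {
          cl <- cl + 1L
          t1 <- t0 + runif(1, 0, 0.6 * sp$duration)
          sp2 <- random_whistle_spec(t1, config)
          specs[[length(specs) + 1L]] <- sp2
          cluster_of <- c(cluster_of, cl)
        }
      }
      for (k in seq_along(specs)) {
        seg <- synth_whistle(specs[[k]], fs)
        i0 <- round(specs[[k]]$start_time * fs) + 1L
        idx <- i0:min(n, i0 + length(seg$samples) - 1L)
        x[idx] <- x[idx] + seg$samples[seq_along(idx)]
      }
    }
    if (!is.null(config$vessel)) {
      x <- x + render_vessel_noise(config$vessel, n, fs)
    }
    if (config$transient_rate > 0) {
      n_tr <- rpois(1, config$transient_rate * config$day_length / 60)
      if (n_tr > 0) {
        for (tt in runif(n_tr, 0, config$day_length - 0.01)) {
          i0 <- round(tt * fs) + 1L
          len <- round(0.0004 * fs)
          idx <- i0:min(n, i0 + len - 1L)
          a <- runif(1, 2, 6)
          x[idx] <- x[idx] + a * exp(-(seq_along(idx) - 1) / (0.00008 * fs)) *
            sign(rnorm(length(idx)))
        }
      }
    }
    x <- x + 10^(config$ambient_level / 20) * rnorm(n)
    gt_whistles <- if (length(specs) > 0) {
      tibble::tibble(
        id = seq_along(specs),
        cluster_id = cluster_of,
        start_time = vapply(specs, `[[`, numeric(1), "start_time"),
        duration = vapply(specs, `[[`, numeric(1), "duration"),
        n_harmonics = vapply(specs, `[[`, integer(1), "n_harmonics"),
        harmonic_rate_true = vapply(specs, `[[`, numeric(1), "harmonic_rate_true"),
        n_multipath = vapply(specs, function(s) length(s$multipath_delays), integer(1)),
        amplitude = vapply(specs, `[[`, numeric(1), "amplitude"),
        class_label = config$class_label
      )
    } else {
      tibble::tibble(
        id = integer(), cluster_id = integer(), start_time = numeric(),
        duration = numeric(), n_harmonics = integer(),
        harmonic_rate_true = numeric(), n_multipath = integer(),
        amplitude = numeric(), class_label = character()
      )
    }
    list(
      waveform = audio_segment(x, fs, 0),
      ground_truth = list(
        whistles = gt_whistles,
        specs = specs,
        vessel_intervals = if (is.null(config$vessel)) matrix(numeric(0), 0, 2)
          else config$vessel$intervals,
        class_label = config$class_label,
        day_index = config$day_index,
        seed = config$seed
      )
    )
  })
}

render_vessel_noise <- function(vs, n, fs) {
  out <- numeric(n)
  t_all <- (0:(n - 1)) / fs
  bb_amp <- 10^(vs$broadband_level / 20)
  for (r in seq_len(nrow(vs$intervals))) {
    i0 <- max(1L, round(vs$intervals[r, 1] * fs) + 1L)
    i1 <- min(n, round(vs$intervals[r, 2] * fs))
    if (i1 <= i0) next
    idx <- i0:i1
    t <- t_all[idx]
    seg <- bb_amp * rnorm(length(idx))
    for (m in seq_len(vs$n_engine_harmonics)) {
      seg <- seg + (4 * bb_amp / m) * sin(2 * pi * m * vs$engine_fundamental * t +
                                          runif(1, 0, 2 * pi))
    }
    seg <- seg + 3 * bb_amp * (1 + 0.8 * sin(2 * pi * vs$thruster_mod_freq * t)) *
      sin(2 * pi * vs$thruster_carrier * t + runif(1, 0, 2 * pi))
    out[idx] <- out[idx] + seg
  }
  out
}

#' Ground-truth pixel paths for a scene
#'
#' Converts each emitted contour (basic, harmonics, multipath replicas) into
#' the 0-based spectrogram pixel path it should occupy under the given STFT
#' parameters, for detector recall scoring.
#'
#' @param ground_truth The `ground_truth` element returned by [synth_scene()].
#' @param spec A `spectrogram` of the scene's waveform (provides the axes).
#' @return A tibble with `whistle_id`, `cluster_id`, `role`, `path_id`, and
#'   list columns `columns`/`bins` (0-based).
#' @export
gt_pixel_paths <- function(ground_truth, spec) {
  hop_s <- spec$time_axis[2] - spec$time_axis[1]
  binw <- spec$freq_axis[2] - spec$freq_axis[1]
  f0_axis <- spec$freq_axis[1]
  J <- ncol(spec$values); I <- nrow(spec$values)
  rows <- list()
  pid <- 0L
  for (k in seq_along(ground_truth$specs)) {
    sp <- ground_truth$specs[[k]]
    wid <- ground_truth$whistles$id[k]
    cid <- ground_truth$whistles$cluster_id[k]
    contours <- list(list(role = "basic", mult = 1, delay = 0))
    if (sp$n_harmonics > 0L)
      for (m in 2:(sp$n_harmonics + 1L))
        contours <- c(contours, list(list(role = "harmonic",
                                          mult = m * sp$harmonic_rate_true,
                                          delay = 0)))
    for (d in seq_along(sp$multipath_delays))
      contours <- c(contours, list(list(role = "multipath", mult = 1,
                                        delay = sp$multipath_delays[d])))
    for (cc in contours) {
      jj <- seq(floor((sp$start_time + cc$delay) / hop_s),
                floor((sp$start_time + cc$delay + sp$duration) / hop_s))
      jj <- jj[jj >= 0 & jj < J]
      if (length(jj) == 0L) next
      tt <- jj * hop_s - sp$start_time - cc$delay
      tt <- pmin(pmax(tt, 0), sp$duration)
      f <- cc$mult * poly_eval(sp$contour_coeffs, tt)
      ii <- round((f - f0_axis) / binw)
      keep <- ii >= 0 & ii < I
      if (sum(keep) < 2L) next
      pid <- pid + 1L
      rows[[pid]] <- tibble::tibble(
        whistle_id = wid, cluster_id = cid, role = cc$role, path_id = pid,
        columns = list(as.integer(jj[keep])), bins = list(as.integer(ii[keep]))
      )
    }
  }
  if (length(rows) == 0L)
    return(tibble::tibble(whistle_id = integer(), cluster_id = integer(),
                          role = character(), path_id = integer(),
                          columns = list(), bins = list()))
  dplyr::bind_rows(rows)
}
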