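test_that("bandpass keeps in-band tones, rejects out-of-band, is idempotent", {
  tin <- tone_segment(10000)
  out <- bandpass(tin, 5000, 20000)
  expect_lt(abs(10 * log10(core_power(out) / core_power(tin))), 1)

  tout <- tone_segment(2000)
  stopped <- bandpass(tout, 5000, 20000)
  expect_lt(10 * log10(core_power(stopped) / core_power(tout)), -60)

  # tone pair: only the in-band tone survives
  fs <- fs_test
  t <- (0:(fs - 1)) / fs
  pair <- audio_segment(sin(2 * pi * 2000 * t) + sin(2 * pi * 10000 * t), fs)
  filt <- bandpass(pair, 5000, 20000)
  mid <- filt$samples[round(0.2 * fs):round(0.8 * fs)]
  spec <- Mod(stats::fft(mid))[1:(length(mid) / 2)]
  peak_freq <- (which.max(spec) - 1) * fs / length(mid)
  expect_lt(abs(peak_freq - 10000), 100)

  # idempotence within 0.1 dB
  twice <- bandpass(out, 5000, 20000)
  expect_lt(abs(10 * log10(core_power(twice) / core_power(out))), 0.1)

  expect_error(bandpass(tin, 20000, 5000), "low < high")
  expect_error(bandpass(tin, 5000, 30000), "sample_rate/2")
})

test_that("wavelet transient suppression attenuates impulses, preserves tones", {
  fs <- 96000
  t <- (0:(fs - 1)) / fs
  tone <- sin(2 * pi * 10000 * t)

  # zero in, zero out
  z <- wavelet_denoise(audio_segment(rep(0, 4096), fs))
  expect_equal(max(abs(z$samples)), 0)

  # pure tone essentially untouched
  pure <- wavelet_denoise(audio_segment(tone, fs))
  expect_gt(stats::cor(pure$samples, tone), 0.99)
  expect_lt(abs(10 * log10(mean(pure$samples^2) / mean(tone^2))), 1)

  # tone + 10 isolated impulses 20 dB above the tone
  x <- tone
  set.seed(31)
  pos <- sample(1000:(fs - 1000), 10)
  x[pos] <- x[pos] + 10
  den <- wavelet_denoise(audio_segment(x, fs))
  peak_before <- max(abs(x[pos]))
  peak_after <- max(abs(den$samples[pos]))
  expect_lt(20 * log10(peak_after / peak_before), -10)
  mask <- rep(TRUE, fs)
  for (p in pos) mask[max(1, p - 60):min(fs, p + 60)] <- FALSE
  expect_lt(abs(10 * log10(mean(den$samples[mask]^2) / mean(tone[mask]^2))), 1)
})

test_that("NLMS line enhancer raises tone SNR and suppresses pure noise", {
  fs <- 16000
  n <- 5 * fs
  f0 <- 4000
  snr_fft <- function(x) {
    X <- Mod(stats::fft(x))^2
    fr <- (0:(length(x) - 1)) * fs / length(x)
    sig <- fr > f0 - 50 & fr < f0 + 50
    half <- fr > 0 & fr < fs / 2
    10 * log10(sum(X[sig & half]) / sum(X[half & !sig]))
  }
  # zero input -> zero outputs
  z <- nlms_cancel(audio_segment(rep(0, 2000), fs))
  expect_equal(max(abs(z$enhanced$samples)), 0)
  expect_equal(max(abs(z$error_signal$samples)), 0)

  gains <- vapply(1:3, function(s) {
    set.seed(s)
    x <- sqrt(2) * sin(2 * pi * f0 * (0:(n - 1)) / fs) + stats::rnorm(n)
    out <- nlms_cancel(audio_segment(x, fs))
    late <- (n / 2):n
    snr_fft(out$enhanced$samples[late]) - snr_fft(x[late])
  }, numeric(1))
  expect_gt(mean(gains), 10)

  # white noise only: unpredictable, output power collapses
  set.seed(99)
  w <- stats::rnorm(n)
  out <- nlms_cancel(audio_segment(w, fs))
  late <- (n / 2):n
  expect_lt(mean(out$enhanced$samples[late]^2) / mean(w[late]^2), 0.1)

  expect_error(nlms_config(step_size = 2.5), "step_size")
  expect_error(nlms_config(delay = 0), "delay")
})

test_that("NLMS benefit is monotone in input SNR (averaged over seeds)", {
  fs <- 16000
  n <- 2 * fs
  f0 <- 4000
  out_snr <- function(in_snr_db, seed) {
    set.seed(seed)
    a <- sqrt(2) * 10^(in_snr_db / 20)
    x <- a * sin(2 * pi * f0 * (0:(n - 1)) / fs) + stats::rnorm(n)
    out <- nlms_cancel(audio_segment(x, fs))
    late <- (n / 2):n
    X <- Mod(stats::fft(out$enhanced$samples[late]))^2
    fr <- (0:(length(late) - 1)) * fs / length(late)
    sig <- fr > f0 - 50 & fr < f0 + 50
    half <- fr > 0 & fr < fs / 2
    10 * log10(sum(X[sig & half]) / sum(X[half & !sig]))
  }
  snr_levels <- c(-5, 0, 5, 10)
  means <- vapply(snr_levels, function(s)
    mean(vapply(1:20, function(seed) out_snr(s, seed), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("spectrogram places tones and chirps correctly and conserves energy", {
  seg <- tone_segment(10000, dur = 1)
  sp <- make_spectrogram(seg)
  ridge <- apply(sp$values[, 5:(ncol(sp$values) - 5)], 2, which.max)
  expect_equal(length(unique(ridge)), 1L)
  expect_lt(abs(sp$freq_axis[ridge[1]] - 10000), sp$freq_axis[2] - sp$freq_axis[1])

  # linear chirp 8 -> 12 kHz: ridge rises monotonically
  fs <- fs_test
  t <- (0:(fs - 1)) / fs
  ch <- audio_segment(sin(2 * pi * (8000 * t + 2000 * t^2)), fs)
  spc <- make_spectrogram(ch)
  ridc <- apply(spc$values[, 5:(ncol(spc$values) - 5)], 2, which.max)
  expect_true(all(diff(ridc) >= 0))

  # silence
  sil <- make_spectrogram(audio_segment(rep(1e-30, fs_test), fs_test))
  expect_lt(max(sil$values), 1e-8)

  # Parseval-style: band energy vs windowed time-domain energy within 5%
  ratio <- sum(sp$values^2) * 2 / sp$nfft / sp$windowed_energy
  expect_lt(abs(ratio - 1), 0.05)

  expect_error(make_spectrogram(audio_segment(rep(0.1, 100), fs_test)),
               "shorter than one window")
  expect_error(stft_params(window = 128, hop = 256), "window must be >= hop")
})

test_that("trace SNR matches its formula and flags bad input", {
  # synthetic spectrogram: path pixels at 10x magnitude (100x power)
  I <- 20; J <- 30
  v <- matrix(1, I, J)
  path <- rep(10L, J)
  v[cbind(path + 1L, seq_len(J))] <- 10
  sp <- structure(
    list(values = v, freq_axis = 5000 + (0:(I - 1)) * 46.875,
         time_axis = (0:(J - 1)) / 187.5, stft_params = NULL,
         sample_rate = 96000, windowed_energy = NA, nfft = 2048),
    class = "spectrogram"
  )
  tr <- mk_trace(0:(J - 1), path)
  expect_equal(trace_snr(sp, tr), 20)

  # path equal to background -> 0 dB
  v0 <- matrix(2, I, J)
  sp0 <- sp; sp0$values <- v0
  expect_equal(trace_snr(sp0, tr), 0)

  out_of_bounds <- mk_trace(0:(J - 1), rep(25L, J))
  expect_error(trace_snr(sp, out_of_bounds), "outside")

  # injected whistle: estimate matches the contrast the generator knows,
  # measured independently from clean-signal and noise-only spectrograms
  fs <- fs_test
  t <- (0:(2 * fs - 1)) / fs
  set.seed(4)
  noise <- stats::rnorm(length(t), sd = 0.2)
  whistle <- numeric(length(t))
  idx <- round(0.5 * fs):round(1.0 * fs)
  tt <- (idx - idx[1]) / fs
  whistle[idx] <- 0.3 * sin(2 * pi * (9000 * tt + 1500 * tt^2))
  spn <- make_spectrogram(audio_segment(noise + whistle, fs))
  det <- detect_traces(spn)
  expect_gte(length(det$traces), 1L)
  tr <- det$traces[[1]]
  snr_est <- trace_snr(spn, tr)
  # oracle: ridge pixel power from the clean render, background from noise
  sp_sig <- make_spectrogram(audio_segment(whistle, fs))
  sp_noise <- make_spectrogram(audio_segment(noise, fs))
  ridge_pow <- mean(sp_sig$values[cbind(tr$bins + 1L, tr$columns + 1L)]^2)
  bg_pow <- mean(sp_noise$values^2)
  expected_db <- 10 * log10(ridge_pow / bg_pow)
  expect_lt(abs(snr_est - expected_db), 2)
})
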