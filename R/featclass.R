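#' Harmonic spectral rate of a whistle cluster
#'
#' For each harmonic trace with integer harmonic number `m` (the rounded
#' mean frequency ratio to the basic trace), the per-column ratio
#' `f_h(j) / (m * f0(j))` is averaged over the temporal overlap with the
#' basic trace; the feature is the mean over harmonics. A cluster without
#' harmonics returns 1 by convention. Harmonics with no temporal overlap are
#' skipped with a warning.
#'
#' @param cluster_traces List of `whistle_trace`s forming one cluster.
#' @param roles Character vector of roles for `cluster_traces` (one must be
#'   `"basic"`).
#' @param axes The source `spectrogram` (or list with `freq_axis`).
#' @return Dimensionless harmonic rate.
#' @export
harmonic_rate <- function(cluster_traces, roles, axes) {
  bidx <- which(roles == "basic")
  if (length(bidx) != 1L) stop("harmonic_rate: cluster needs one basic trace")
  basic <- cluster_traces[[bidx]]
  hidx <- which(roles == "harmonic")
  if (length(hidx) == 0L) return(1)
  rates <- numeric(0)
  for (h in hidx) {
    tr <- cluster_traces[[h]]
    cols <- intersect(basic$columns, tr$columns)
    if (length(cols) == 0L) {
      warning("harmonic_rate: harmonic with no temporal overlap skipped")
      next
    }
    f0 <- axes$freq_axis[basic$bins[match(cols, basic$columns)] + 1L]
    fh <- axes$freq_axis[tr$bins[match(cols, tr$columns)] + 1L]
    m <- round(mean(fh / f0))
    if (m < 1) m <- 1
    rates <- c(rates, mean(fh / (m * f0)))
  }
  if (length(rates) == 0L) return(1)
  mean(rates)
}

#' Compute the five whistle features per cluster
#'
#' One record per cluster, anchored on its basic trace: `duration` (basic
#' trace span, start to end, no averaging), `whistle_number` (basic whistles
#' with timestamps inside the centered 60 s buffer, the whistle itself
#' included), `number_of_overlaps` (traces of other clusters whose time
#' support intersects the basic trace), `number_of_clusters` (traces in the
#' cluster), and `harmonic_rate`. SNR is measured on the spectrogram via
#' [trace_snr()].
#'
#' @param assignment A [cluster_assignment()] over `traces`.
#' @param traces List of `whistle_trace`s the assignment indexes.
#' @param spec The source `spectrogram` (axes + SNR measurement).
#' @param day_index Day number attached to the records.
#' @param window Whistle-number buffer width in seconds (default 60,
#'   centered).
#' @return A tibble of whistle records.
#' @export
compute_features <- function(assignment, traces, spec, day_index = 1L,
                             window = 60) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (length(traces) != length(assignment$membership))
    stop("compute_features: traces/assignment mismatch")
  member <- assignment$membership
  roles <- assignment$roles
  hop_s <- spec$time_axis[2] - spec$time_axis[1]
  t_start <- vapply(traces, function(t) spec$time_axis[min(t$columns) + 1L],
                    numeric(1))
  t_end <- vapply(traces, function(t)
    spec$time_axis[max(t$columns) + 1L] + hop_s, numeric(1))
  clusters <- unique(member)
  basic_of <- vapply(clusters, function(k) {
    idx <- which(member == k & roles == "basic")
    if (length(idx) != 1L) stop("compute_features: cluster without unique basic")
    idx
  }, integer(1))
  basic_ts <- t_start[basic_of]
  out <- purrr::map_dfr(seq_along(clusters), function(ci) {
    k <- clusters[ci]
    b <- basic_of[ci]
    idx <- which(member == k)
    others <- which(member != k)
    n_overlap <- sum(t_start[others] < t_end[b] & t_end[others] > t_start[b])
    wn <- sum(abs(basic_ts - basic_ts[ci]) <= window / 2)
    tibble::tibble(
      cluster = k,
      duration = length(traces[[b]]$columns) * hop_s,
      whistle_number = wn,
      number_of_overlaps = n_overlap,
      number_of_clusters = length(idx),
      harmonic_rate = harmonic_rate(traces[idx], roles[idx], spec),
      snr = trace_snr(spec, traces[[b]]),
      timestamp = basic_ts[ci],
      day_index = day_index,
      is_daytime = (basic_ts[ci] %% 86400) >= 6 * 3600 &
                   (basic_ts[ci] %% 86400) < 18 * 3600
    )
  })
  out
}

#' Vessel interval log
#'
#' @param start,end Numeric vectors of interval bounds in dataset seconds;
#'   must be sorted and non-overlapping with `end > start`.
#' @return A tibble with class `vessel_log`.
#' @export
vessel_log <- function(start, end) {
  if (length(start) != length(end)) stop("vessel_log: length mismatch")
  if (any(end <= start)) stop("vessel_log: end must exceed start")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1] < end[-length(end)]))
    stop("vessel_log: intervals must be non-overlapping")
  structure(tibble::tibble(start = start, end = end),
            class = c("vessel_log", "tbl_df", "tbl", "data.frame"))
}

dist_to_intervals <- function(t, start, end) {
  if (length(start) == 0L) return(rep(Inf, length(t)))
  vapply(t, function(x) min(pmax(0, pmax(start - x, x - end))), numeric(1))
}

#' Label whistle records by vessel presence
#'
#' A record is `with_vessel` if a vessel interval lies within `with_buffer`
#' seconds of its timestamp (zero if inside an interval), `no_vessel` if no
#' interval lies within `no_buffer` seconds, and `excluded` otherwise.
#'
#' @param records Tibble of whistle records with a `timestamp` column.
#' @param vessels A [vessel_log()] (or tibble with `start`, `end`).
#' @param with_buffer With-vessel buffer in seconds (default 60 = 1 min).
#' @param no_buffer No-vessel buffer in seconds (default 300 = 5 min).
#' @return `records` with a `label` factor column
#'   (`with_vessel`/`no_vessel`/`excluded`).
#' @export
label_whistles <- function(records, vessels, with_buffer = 60,
                           no_buffer = 300) {
  if (with_buffer >= no_buffer)
    stop("label_whistles: with_buffer must be < no_buffer")
  d <- dist_to_intervals(records$timestamp, vessels$start, vessels$end)
  records$label <- factor(
    dplyr::case_when(
      d <= with_buffer ~ "with_vessel",
      d >= no_buffer ~ "no_vessel",
      TRUE ~ "excluded"
    ),
    levels = c("with_vessel", "no_vessel", "excluded")
  )
  records
}

#' Filter records by SNR
#'
#' Keeps records whose SNR strictly exceeds the threshold (the boundary
#' value is dropped).
#'
#' @param records Tibble with an `snr` column (dB).
#' @param threshold SNR threshold in dB (default 15).
#' @return Filtered tibble.
#' @export
snr_filter <- function(records, threshold = 15) {
  dplyr::filter(records, .data$snr > threshold)
}

#' Ratio-of-means feature statistic
#'
#' `rho(i)`: the mean of feature `i` over `with_vessel` records divided by
#' its mean over `no_vessel` records. The delta-method standard error is
#' attached as attribute `"se"`.
#'
#' @param records Labelled records tibble (see [label_whistles()]).
#' @param feature Feature column name.
#' @return Scalar ratio with attribute `se`.
#' @export
rho_statistic <- function(records, feature) {
  if (!feature %in% names(records)) stop("rho_statistic: unknown feature")
  xw <- records[[feature]][records$label == "with_vessel"]
  xn <- records[[feature]][records$label == "no_vessel"]
  if (length(xw) == 0L || length(xn) == 0L)
    stop("rho_statistic: both classes must be non-empty")
  mw <- mean(xw); mn <- mean(xn)
  if (mn == 0) stop("rho_statistic: no_vessel mean is zero")
  rho <- mw / mn
  se <- abs(rho) * sqrt(stats::var(xw) / (length(xw) * mw^2) +
                        stats::var(xn) / (length(xn) * mn^2))
  structure(rho, se = se)
}

#' Day/night classification-performance ratios
#'
#' From per-record test predictions of [evaluate_lodo()], computes per-day
#' TP and TN rates separately for daytime (06:00-18:00) and nighttime
#' records and their day/night ratios; degenerate strata (empty, or missing
#' the relevant class) yield `NA` and are flagged.
#'
#' @param report An `eval_report` from [evaluate_lodo()].
#' @return A list with `by_day` (tibble of stratified rates and ratios) and
#'   `averages` (mean TP and TN day/night ratios over non-degenerate days).
#' @export
day_night_report <- function(report) {
  pred <- report$predictions
  rate <- function(df, truth_lab) {
    sel <- df$truth == truth_lab
    if (!any(sel)) return(NA_real_)
    mean(df$pred[sel] == truth_lab)
  }
  by_day <- pred |>
    dplyr::group_by(.data$day_index) |>
    dplyr::group_modify(function(df, key) {
      day <- df[df$is_daytime, ]
      night <- df[!df$is_daytime, ]
      tibble::tibble(
        tp_day = rate(day, "with_vessel"), tp_night = rate(night, "with_vessel"),
        tn_day = rate(day, "no_vessel"), tn_night = rate(night, "no_vessel")
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      tp_ratio = .data$tp_day / .data$tp_night,
      tn_ratio = .data$tn_day / .data$tn_night,
      degenerate = !is.finite(.data$tp_ratio) | !is.finite(.data$tn_ratio)
    )
  list(
    by_day = by_day,
    averages = c(
      tp_ratio = mean(by_day$tp_ratio[is.finite(by_day$tp_ratio)]),
      tn_ratio = mean(by_day$tn_ratio[is.finite(by_day$tn_ratio)])
    )
  )
}

#' Feature histograms by vessel label
#'
#' @param records Labelled records tibble.
#' @param features Feature columns to plot.
#' @return A ggplot with one facet per feature.
#' @export
plot_features <- function(records,
                          features = c("duration", "whistle_number",
                                       "number_of_overlaps",
                                       "number_of_clusters",
                                       "harmonic_rate")) {
  df <- records |>
    dplyr::filter(.data$label != "excluded") |>
    tidyr::pivot_longer(dplyr::all_of(features), names_to = "feature")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$label)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "whistles", fill = NULL)
}
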