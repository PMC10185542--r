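# Pulse-wave analysis: preprocessing that mirrors the DAQ chain (30 Hz
# zero-phase low-pass) and extraction of the scalar indices of the central
# aortic waveform: SBP, DBP, PP, the two MAP variants, augmentation
# pressure/index, dicrotic notch and foot times.

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so the passband is flat, the DC gain is exactly
#' one and no phase is introduced (foot and peak timings are preserved).
#' The signal is mirror-padded before filtering to suppress edge
#' transients, and its mean is removed and restored so a constant input
#' passes through unchanged.
#'
#' @param waveform a [pressure_waveform()].
#' @param cutoff cutoff frequency, Hz; must be below the Nyquist rate.
#' @return the filtered [pressure_waveform()].
#' @export
lowpass_filter <- function(waveform, cutoff = 30) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  stop_if_not_positive(cutoff = cutoff)
  fs <- waveform$sample_rate
  if (cutoff >= fs / 2) {
    stop("`cutoff` must be below the Nyquist frequency", call. = FALSE)
  }
  x <- waveform$samples
  m <- mean(x)
  xc <- x - m
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * fs / cutoff))
  xp <- c(rev(xc[seq_len(pad) + 1L]), xc, rev(xc[n - seq_len(pad)]))
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  yp <- signal::filtfilt(bf, xp)
  y <- yp[(pad + 1L):(pad + n)] + m
  pressure_waveform(y, fs, waveform$sensor_position, waveform$t0)
}

#' Mean arterial pressure by the clinical formula
#'
#' `MAP = (SBP + 2 * DBP) / 3`, the standard approximation of the time
#' average of the arterial waveform (diastole occupies roughly two thirds
#' of the beat).
#'
#' @param sbp systolic pressure, mmHg.
#' @param dbp diastolic pressure, mmHg; must not exceed `sbp`.
#' @return mean arterial pressure, mmHg.
#' @export
#' @examples
#' map_formula(120, 80)  # 93.33
map_formula <- function(sbp, dbp) {
  if (any(sbp < dbp)) stop("`sbp` must be >= `dbp`", call. = FALSE)
  (sbp + 2 * dbp) / 3
}

#' Augmentation index
#'
#' `AIx = 100 * AP / PP`: the augmentation pressure contributed by the
#' reflected wave as a percentage of pulse pressure.
#'
#' @param ap augmentation pressure, mmHg, with `0 <= ap <= pp`.
#' @param pp pulse pressure, mmHg (> 0).
#' @return augmentation index, percent.
#' @export
#' @examples
#' aix(5.3, 40)  # 13.25
aix <- function(ap, pp) {
  if (any(pp <= 0)) stop("`pp` must be positive", call. = FALSE)
  if (any(ap < 0) || any(ap > pp)) {
    stop("`ap` must lie in [0, pp]", call. = FALSE)
  }
  100 * ap / pp
}

#' Aortic from carotid-femoral wave speed
#'
#' The aortic path excludes the narrow, fast femoral section, so the aortic
#' wave speed is about 87 % of the clinically measured carotid-femoral
#' value: `aPWV = 0.87 * cfPWV`.
#'
#' @param cfpwv carotid-femoral wave speed, m/s (> 0).
#' @return aortic wave speed, m/s.
#' @export
#' @examples
#' cfpwv_to_apwv(7.52)  # ~6.54
cfpwv_to_apwv <- function(cfpwv) {
  if (any(cfpwv <= 0)) stop("`cfpwv` must be positive", call. = FALSE)
  0.87 * cfpwv
}

# dominant beat period by autocorrelation of the mean-removed signal;
# searched between 0.25 s (240 BPM) and 2 s (30 BPM)
estimate_period <- function(x, fs) {
  xc <- x - mean(x)
  max_lag <- min(length(x) - 1L, round(2 * fs))
  ac <- stats::acf(xc, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  lo <- round(0.25 * fs)
  if (lo + 1L >= length(ac)) return(NA_real_)
  (which.max(ac[(lo + 1L):length(ac)]) + lo - 1L) / fs
}

# strict local maxima above an amplitude threshold, thinned so only the
# highest peak per beat period survives (secondary/dicrotic humps are
# suppressed even when tall)
find_systolic_peaks <- function(x, fs) {
  n <- length(x)
  if (n < 5L) return(integer(0))
  thr <- min(x) + 0.4 * (max(x) - min(x))
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[x[cand] >= thr]
  if (!length(cand)) return(integer(0))
  period <- estimate_period(x, fs)
  min_gap <- if (is.na(period)) round(0.3 * fs) else round(0.55 * period * fs)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  sort(keep)
}

# per-beat feet as sample indices: the lowest point between consecutive
# systolic peaks (i.e. preceding each upstroke); optionally the
# intersecting-tangent foot
foot_indices <- function(x, fs, method = c("lowest", "tangent")) {
  method <- match.arg(method)
  pk <- find_systolic_peaks(x, fs)
  if (length(pk) < 2L) return(integer(0))
  feet <- integer(0)
  for (k in seq_len(length(pk) - 1L)) {
    seg <- pk[k]:pk[k + 1L]
    i_min <- seg[which.min(x[seg])]
    if (method == "lowest") {
      feet <- c(feet, i_min)
    } else {
      # intersecting tangent: crossing of the horizontal through the
      # minimum with the tangent at the steepest upstroke point
      up <- i_min:pk[k + 1L]
      d <- diff(x[up])
      i_st <- up[which.max(d)]
      slope <- (x[i_st + 1L] - x[i_st - 1L]) / 2
      if (slope <= 0) {
        feet <- c(feet, i_min)
      } else {
        i_cross <- i_st - (x[i_st] - x[i_min]) / slope
        feet <- c(feet, as.integer(round(max(i_min, i_cross))))
      }
    }
  }
  feet
}

#' Foot times of a waveform
#'
#' The foot of each beat: by default the per-beat lowest point preceding
#' the upstroke (`"lowest"`), matching how transit times are read off
#' measured waveforms; `"tangent"` gives the intersecting-tangent
#' alternative.
#'
#' @param waveform a [pressure_waveform()].
#' @param method foot definition.
#' @return numeric vector of foot times, s (empty if fewer than two beats
#'   are present).
#' @export
foot_times <- function(waveform, method = c("lowest", "tangent")) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  idx <- foot_indices(waveform$samples, waveform$sample_rate,
                      match.arg(method))
  waveform$t0 + (idx - 1L) / waveform$sample_rate
}

# five-point central-difference derivatives (spec'd stencil)
deriv5 <- function(x, dt) {
  n <- length(x)
  d <- rep(NA_real_, n)
  i <- 3:(n - 2)
  d[i] <- (x[i - 2] - 8 * x[i - 1] + 8 * x[i + 1] - x[i + 2]) / (12 * dt)
  d
}

#' Extract pulse-wave features
#'
#' Applies the 30 Hz zero-phase low-pass (unless `filter = FALSE`),
#' segments the signal into beats by detected feet, and extracts per-beat
#' features, returned beat-averaged:
#' \describe{
#'   \item{sbp, dbp, pp}{beat maximum, minimum and their difference, mmHg.}
#'   \item{map_formula}{`(SBP + 2 DBP)/3`.}
#'   \item{map_integral}{true time average over the beat.}
#'   \item{ap, aix}{augmentation pressure (pressure difference between the
#'     systolic shoulder -- the inflection produced by the arriving
#'     reflected wave -- and the systolic peak) and `100 * AP / PP`. The
#'     shoulder is the second-derivative zero crossing adjacent to the
#'     peak within systole; when no inflection is found, `ap` and `aix`
#'     are `NA`, not zero.}
#'   \item{notch_time}{time of the dicrotic notch (first early-diastolic
#'     local minimum after the peak), s from the start of the record, or
#'     `NA`.}
#'   \item{foot_time}{time of the first detected foot, s.}
#' }
#' Partial beats at the edges of the record are discarded.
#'
#' @param waveform a [pressure_waveform()] covering at least two detectable
#'   upstrokes (one full foot-to-foot beat).
#' @param filter logical; apply the low-pass preprocessing first.
#' @param cutoff low-pass cutoff, Hz.
#' @param foot_method foot definition, see [foot_times()].
#' @return an object of class `waveform_features`; the per-beat values are
#'   in the `per_beat` element.
#' @export
#' @examples
#' w <- generate_fixture("sinusoid", seed = 1)
#' f <- extract_features(w)
#' c(f$sbp, f$dbp, f$map_integral)  # 120, 80, 100
extract_features <- function(waveform, filter = TRUE, cutoff = 30,
                             foot_method = c("lowest", "tangent")) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  foot_method <- match.arg(foot_method)
  w <- if (filter) lowpass_filter(waveform, cutoff) else waveform
  x <- w$samples
  fs <- w$sample_rate
  feet <- foot_indices(x, fs, foot_method)
  if (length(feet) < 2L) {
    stop("no complete beat detected (need at least two feet)", call. = FALSE)
  }
  dt <- 1 / fs
  beats <- lapply(seq_len(length(feet) - 1L), function(k) {
    i0 <- feet[k]
    i1 <- feet[k + 1L]
    seg <- x[i0:i1]
    sbp <- max(seg)
    dbp <- min(seg)
    pp <- sbp - dbp
    i_pk <- i0 + which.max(seg) - 1L
    beat_len <- i1 - i0

    # systolic shoulder: 2nd-derivative zero crossing adjacent to the peak,
    # searched from the steepest-upstroke point to 45 % of the beat
    ap <- NA_real_
    sys_end <- i0 + round(0.45 * beat_len)
    d1 <- deriv5(x, dt)
    up <- i0:i_pk
    i_steep <- up[which.max(d1[up])]
    lo <- min(i_steep + 2L, sys_end)
    win <- lo:sys_end
    if (length(win) > 4L) {
      d2 <- deriv5_of(d1, win, dt)
      sgn <- sign(d2)
      cross <- which(sgn[-length(sgn)] != sgn[-1] & !is.na(sgn[-length(sgn)]))
      if (length(cross)) {
        cand <- win[cross]
        before <- cand[cand < i_pk]
        after <- cand[cand > i_pk]
        # a reflected wave either augments the peak (inflection before it)
        # or re-raises the pressure after it; a monotone post-peak decay
        # means no reflection shoulder, and AP is reported absent
        post <- min(i_pk + 4L, sys_end):sys_end
        re_rise <- any(d1[post] > 0, na.rm = TRUE)
        i_sh <- if (length(before)) max(before) else
          if (re_rise && length(after)) min(after) else NA_integer_
        if (!is.na(i_sh)) ap <- max(0, x[i_pk] - x[i_sh])
      }
    }

    # dicrotic notch: first local minimum after the peak, in early diastole
    notch <- NA_real_
    dia <- i_pk:min(i1 - 2L, i_pk + round(0.45 * beat_len))
    if (length(dia) > 4L) {
      dseg <- x[dia]
      dd <- diff(dseg)
      loc <- which(dd[-length(dd)] < 0 & dd[-1] >= 0) + 1L
      loc <- loc[loc > 2L]
      if (length(loc)) notch <- w$t0 + (dia[loc[1L]] - 1L) * dt
    }

    list(sbp = sbp, dbp = dbp, pp = pp,
         map_formula = map_formula(sbp, dbp),
         map_integral = mean(x[i0:(i1 - 1L)]),
         ap = ap, aix = if (!is.na(ap) && pp > 0) 100 * ap / pp else NA_real_,
         notch_time = notch,
         foot_time = w$t0 + (i0 - 1L) * dt,
         peak_time = w$t0 + (i_pk - 1L) * dt)
  })

  per_beat <- do.call(rbind, lapply(beats, function(b)
    data.frame(b[c("sbp", "dbp", "pp", "map_formula", "map_integral",
                   "ap", "aix", "notch_time", "foot_time", "peak_time")])))
  avg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  structure(
    list(sbp = avg(per_beat$sbp), dbp = avg(per_beat$dbp),
         pp = avg(per_beat$pp),
         map_formula = avg(per_beat$map_formula),
         map_integral = avg(per_beat$map_integral),
         ap = avg(per_beat$ap), aix = avg(per_beat$aix),
         notch_time = per_beat$notch_time[1L],
         foot_time = per_beat$foot_time[1L],
         n_beats = nrow(per_beat), per_beat = per_beat),
    class = "waveform_features"
  )
}

# five-point stencil applied to an (already differentiated) series,
# restricted to a window; returns the window's values
deriv5_of <- function(d1, win, dt) {
  n <- length(d1)
  i <- win
  i <- pmin(pmax(i, 3L), n - 2L)
  (d1[i - 2] - 8 * d1[i - 1] + 8 * d1[i + 1] - d1[i + 2]) / (12 * dt)
}

#' @export
print.waveform_features <- function(x, ...) {
  cat(sprintf("<waveform_features> (%d beats averaged)\n", x$n_beats))
  cat(sprintf("  SBP %.1f  DBP %.1f  PP %.1f mmHg\n", x$sbp, x$dbp, x$pp))
  cat(sprintf("  MAP %.1f (formula) / %.1f (integral) mmHg\n",
              x$map_formula, x$map_integral))
  if (!is.na(x$ap)) {
    cat(sprintf("  AP %.1f mmHg  AIx %.1f%%\n", x$ap, x$aix))
  } else {
    cat("  AP/AIx: no systolic inflection found\n")
  }
  invisible(x)
}
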