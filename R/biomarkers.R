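#' Phase features of a one-cycle waveform
#'
#' Identifies the peak-systolic value, the systolic-upstroke foot (by the
#' intersecting-tangents rule: the horizontal baseline through the cycle
#' minimum intersected with the tangent at the point of maximum upstroke
#' slope), the end-diastolic value (the sample immediately preceding the
#' upstroke foot, the clinical convention for V_EDV), and the cycle mean.
#' The series is treated as circular, so the cycle may start at any phase.
#'
#' @param time Sample times over one period (s), uniform.
#' @param values Waveform samples (same length as `time`, >= 50 samples).
#' @return A list with `Y_PS`, `t_PS`, `Y_ED`, `t_ED`, `Y_b`, `t_b`,
#'   `Y_mean` and `flat` (TRUE when no upstroke is identifiable, in which
#'   case the foot and timing fields are `NA`). Times are unwrapped so that
#'   `t_b <= t_PS < t_ED` within one period of each other.
#' @export
phase_features <- function(time, values) {
  n <- length(values)
  stopifnot(length(time) == n, n >= 50)
  period <- (time[2] - time[1]) * n
  y_mean <- mean(values) # trapezoidal mean of a uniform circular grid
  i_ps <- which.max(values)
  y_ps <- values[i_ps]
  rng <- y_ps - min(values)
  if (rng <= 1e-12 * max(abs(y_ps), 1e-300)) {
    return(list(Y_PS = y_ps, t_PS = time[i_ps], Y_ED = y_ps, t_ED = NA_real_,
                Y_b = y_ps, t_b = NA_real_, Y_mean = y_mean, flat = TRUE))
  }
  # circular index helper
  cidx <- function(i) ((i - 1) %% n) + 1
  # walk backwards from the peak to the preceding local minimum
  i_min <- i_ps
  for (step in 1:(n - 1)) {
    j <- cidx(i_ps - step)
    if (values[j] <= values[cidx(j - 1)] && values[j] <= values[cidx(j + 1)]) {
      i_min <- j
      break
    }
  }
  y_base <- values[i_min]
  # maximum slope on the upstroke (between the preceding minimum and peak)
  up <- integer(0)
  j <- i_min
  while (j != i_ps) {
    up <- c(up, j)
    j <- cidx(j + 1)
  }
  if (length(up) < 2) {
    up <- c(cidx(i_ps - 2), cidx(i_ps - 1))
  }
  dt <- period / n
  slopes <- (values[cidx(up + 1)] - values[up]) / dt
  k <- up[which.max(slopes)]
  m <- max(slopes)
  # unwrapped time of the max-slope point, placed before the peak
  t_ps <- time[i_ps]
  back_steps <- (i_ps - k) %% n
  t_k <- t_ps - back_steps * dt
  # intersecting tangents: baseline y = y_base with tangent of slope m
  t_b <- t_k - (values[k] - y_base) / m
  y_b <- y_base
  # end diastole: sample immediately preceding the foot
  i_ed <- cidx(i_min - 1)
  back_ed <- (i_ps - i_ed) %% n
  t_ed <- t_ps + (period - back_ed * dt) # the next cycle's pre-foot sample
  list(Y_PS = y_ps, t_PS = t_ps, Y_ED = values[i_ed], t_ED = t_ed,
       Y_b = y_b, t_b = t_b, Y_mean = y_mean, flat = FALSE)
}

#' Resistive index
#'
#' `RI = (V_PSV - V_EDV) / V_PSV`.
#'
#' @param v_psv Peak-systolic velocity (> 0).
#' @param v_edv End-diastolic velocity.
#' @return Dimensionless index.
#' @export
resistive_index <- function(v_psv, v_edv) {
  if (any(v_psv <= 0)) stop("V_PSV must be positive", call. = FALSE)
  (v_psv - v_edv) / v_psv
}

#' Pulsatility index
#'
#' `PI = (V_PSV - V_EDV) / V_Mean`.
#'
#' @param v_psv Peak-systolic velocity.
#' @param v_edv End-diastolic velocity.
#' @param v_mean Cycle-mean velocity (> 0).
#' @return Dimensionless index.
#' @export
pulsatility_index <- function(v_psv, v_edv, v_mean) {
  if (any(v_mean <= 0)) stop("V_Mean must be positive", call. = FALSE)
  (v_psv - v_edv) / v_mean
}

#' Systolic acceleration slope
#'
#' `(Y_PS - Y_b) / (t_PS - t_b)` from the phase features.
#'
#' @param features Result of [phase_features()].
#' @return Slope in waveform units per second (`NA` for a flat waveform).
#' @export
systolic_acceleration_slope <- function(features) {
  if (isTRUE(features$flat)) return(NA_real_)
  if (features$t_PS == features$t_b) {
    stop("degenerate upstroke: t_PS equals t_b", call. = FALSE)
  }
  (features$Y_PS - features$Y_b) / (features$t_PS - features$t_b)
}

#' Diastolic deceleration slope
#'
#' `(Y_PS - Y_ED) / (t_PS - t_ED)`; negative for a decaying diastole since
#' `t_ED > t_PS`.
#'
#' @param features Result of [phase_features()].
#' @return Slope in waveform units per second (`NA` for a flat waveform).
#' @export
diastolic_deceleration_slope <- function(features) {
  if (isTRUE(features$flat)) return(NA_real_)
  if (features$t_ED == features$t_PS) {
    stop("degenerate diastole: t_ED equals t_PS", call. = FALSE)
  }
  (features$Y_PS - features$Y_ED) / (features$t_PS - features$t_ED)
}

# quantity name -> slot of a waveform set
.panel_quantities <- c("RBF Rate" = "flow", "Velocity" = "velocity",
                       "Pressure" = "pressure", "PWV" = "wave_speed",
                       "Area" = "area")

#' Candidate biomarker vocabulary
#'
#' @param quantities Quantity display names.
#' @return Character vector of the 27 biomarker names per location:
#'   five phase/slope features per quantity plus RI and PI.
#' @export
biomarker_names <- function(quantities = names(.panel_quantities)) {
  c(as.vector(outer(c("Systolic", "Diastolic", "Mean", "Acceleration",
                      "Deceleration"), quantities, paste)),
    "RI", "PI")
}

#' Extract the biomarker panel from one subject's waveforms
#'
#' Computes, for each renal location (main, segmental, interlobar, arcuate)
#' and side, the phase values (systolic, diastolic, mean), the acceleration
#' and deceleration slopes of the flow (RBF rate), velocity, pressure, PWV
#' and area waveforms, plus RI and PI from the velocity waveform. Locations
#' with several vessels of the same generation (segmental, interlobar,
#' arcuate) report the feature averaged across those vessels.
#'
#' @param sw A `subject_waves` object from [simulate_subject()] containing
#'   all renal vessels, or any named list of waveform sets whose names
#'   follow the renal id convention plus a `time` vector.
#' @param locations Renal generations to extract.
#' @return A data frame with columns `side`, `location`, `name`, `value`.
#' @export
biomarker_panel <- function(sw, locations = c("main", "segmental",
                                              "interlobar", "arcuate")) {
  locs <- names(sw$waves)
  out <- list()
  for (side in c("left", "right")) {
    sfx <- if (side == "left") "l" else "r"
    gen_ids <- list(
      main = paste0("renal_", sfx),
      segmental = grep(sprintf("^renal_%s_seg\\d+$", sfx), locs, value = TRUE),
      interlobar = grep(sprintf("^renal_%s_seg\\d+_il\\d+$", sfx), locs, value = TRUE),
      arcuate = grep(sprintf("^renal_%s_seg\\d+_il\\d+_arc\\d+$", sfx), locs,
                     value = TRUE)
    )
    for (loc in intersect(names(gen_ids), locations)) {
      ids <- intersect(gen_ids[[loc]], locs)
      if (length(ids) == 0) {
        stop("waveforms missing for ", side, " ", loc, " location",
             call. = FALSE)
      }
      acc <- NULL
      for (id in ids) {
        w <- sw$waves[[id]]
        vals <- numeric(0)
        for (qn in names(.panel_quantities)) {
          f <- phase_features(sw$time, w[[.panel_quantities[[qn]]]])
          # a flat waveform has no identifiable upstroke; its slopes are
          # reported as zero so the feature table stays complete
          acc_s <- systolic_acceleration_slope(f)
          dec_s <- diastolic_deceleration_slope(f)
          vals <- c(vals, stats::setNames(
            c(f$Y_PS, f$Y_ED, f$Y_mean,
              if (is.na(acc_s)) 0 else acc_s,
              if (is.na(dec_s)) 0 else dec_s),
            paste(c("Systolic", "Diastolic", "Mean", "Acceleration",
                    "Deceleration"), qn)))
        }
        fv <- phase_features(sw$time, w$velocity)
        vals <- c(vals,
                  RI = resistive_index(fv$Y_PS, fv$Y_ED),
                  PI = pulsatility_index(fv$Y_PS, fv$Y_ED, fv$Y_mean))
        acc <- if (is.null(acc)) vals else acc + vals
      }
      acc <- acc / length(ids)
      out[[length(out) + 1]] <- data.frame(
        side = side, location = loc, name = names(acc), value = unname(acc),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Collapse a per-side biomarker panel to per-subject features
#'
#' Averages each biomarker over the left and right kidneys (the default
#' input to the trial analyses) and returns one named row.
#'
#' @param panel Data frame from [biomarker_panel()].
#' @param locations Locations to keep.
#' @return Named numeric vector with names `location.name`.
#' @export
panel_features <- function(panel, locations = c("main", "segmental",
                                                "interlobar", "arcuate")) {
  p <- panel[panel$location %in% locations, ]
  key <- paste(p$location, p$name, sep = ".")
  tapply(p$value, key, mean)
}
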