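# Synthetic class-conditional waveform families. These exercise the
# biomarker extraction and trial statistics in milliseconds, with known
# ground truth, and are never a stand-in for the physiological model: they
# emulate only the statistical structure the analysis assumes (independent
# Gaussian parameter variation with class mean shifts and a realistic
# waveform morphology).

.surrogate_param_names <- c("v_base", "v_amp", "p_base", "p_amp",
                            "c_base", "c_amp", "a_base", "a_amp")

#' Specification of a surrogate two-class waveform cohort
#'
#' Each subject's waveforms are built from a two-Gaussian-lobe template
#' (sharp systolic lobe plus a slower diastolic lobe over a baseline),
#' with the template parameters drawn from independent Gaussians. Class 1
#' shifts selected parameter means by `delta` standard deviations.
#'
#' @param n_per_class Subjects per class (>= 2).
#' @param delta Named numeric vector of standardized class-1 mean shifts;
#'   names from `v_base`, `v_amp` (velocity baseline and systolic
#'   amplitude), `p_base`, `p_amp` (pressure), `c_base`, `c_amp` (PWV),
#'   `a_base`, `a_amp` (area). `v_base` is the PI- and RI-controlling
#'   parameter: raising the diastolic velocity baseline lowers both
#'   indices monotonically.
#' @param cv Coefficient of variation of the template parameters: a
#'   scalar applied to all, or a named vector (unnamed parameters get 0),
#'   so that a single parameter can carry all the between-subject
#'   variance.
#' @param n_samples Samples per cycle.
#' @param period Cycle duration (s).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `surrogate_spec`.
#' @export
surrogate_spec <- function(n_per_class = 100, delta = c(v_base = 0),
                           cv = 0.08, n_samples = 200, period = 0.8,
                           seed = 1) {
  stopifnot(n_per_class >= 2, all(cv >= 0), n_samples >= 50, period > 0)
  unknown <- setdiff(c(names(delta), names(cv)), .surrogate_param_names)
  if (length(unknown) > 0) {
    stop("unknown surrogate parameter: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  d <- stats::setNames(numeric(length(.surrogate_param_names)),
                       .surrogate_param_names)
  d[names(delta)] <- delta
  if (is.null(names(cv))) {
    cv <- stats::setNames(rep(cv[1], length(.surrogate_param_names)),
                          .surrogate_param_names)
  } else {
    cv_full <- stats::setNames(numeric(length(.surrogate_param_names)),
                               .surrogate_param_names)
    cv_full[names(cv)] <- cv
    cv <- cv_full
  }
  structure(list(n_per_class = n_per_class, delta = d, cv = cv,
                 n_samples = n_samples, period = period, seed = seed),
            class = "surrogate_spec")
}

# two-lobe template on [0, period)
.surrogate_template <- function(t, period) {
  exp(-(t - 0.16 * period)^2 / (2 * (0.055 * period)^2)) +
    0.22 * exp(-(t - 0.45 * period)^2 / (2 * (0.16 * period)^2))
}

#' Generate a surrogate waveform cohort
#'
#' @param spec A [surrogate_spec()].
#' @return A list with `subjects` (a list of waveform containers usable by
#'   [biomarker_panel()]), `labels` (0/1), and `truth` (the sampled
#'   template parameters per subject).
#' @export
generate_surrogate <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- 2 * spec$n_per_class
  labels <- rep(c(0L, 1L), each = spec$n_per_class)
  mu <- c(v_base = 0.12, v_amp = 0.45, p_base = 10700, p_amp = 5300,
          c_base = 5.0, c_amp = 0.5, a_base = 2.4e-5, a_amp = 1.2e-6)
  t <- (seq_len(spec$n_samples) - 1) / spec$n_samples * spec$period
  shape <- .surrogate_template(t, spec$period)
  truth <- matrix(NA_real_, n, length(mu), dimnames = list(NULL, names(mu)))
  # the renal id vocabulary expected by biomarker_panel
  ids <- unlist(lapply(c("l", "r"), function(s) {
    c(paste0("renal_", s),
      sprintf("renal_%s_seg%d", s, 1:2),
      sprintf("renal_%s_seg%d_il1", s, 1:2),
      sprintf("renal_%s_seg%d_il1_arc1", s, 1:2))
  }))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    m <- mu * (1 + (labels[i] == 1L) * spec$delta * spec$cv)
    p <- stats::rnorm(length(mu), m, spec$cv * mu)
    p[spec$cv == 0] <- m[spec$cv == 0]
    p <- pmax(p, 0.05 * mu)
    names(p) <- names(mu)
    truth[i, ] <- p
    velocity <- p[["v_base"]] + p[["v_amp"]] * shape
    area <- p[["a_base"]] + p[["a_amp"]] * shape
    waves1 <- list(
      velocity = velocity,
      area = area,
      flow = velocity * area,
      pressure = p[["p_base"]] + p[["p_amp"]] * shape,
      wave_speed = p[["c_base"]] + p[["c_amp"]] * shape
    )
    subjects[[i]] <- list(time = t,
                          waves = stats::setNames(rep(list(waves1), length(ids)),
                                                  ids),
                          period = spec$period, surrogate = TRUE)
  }
  list(subjects = subjects, labels = labels,
       truth = as.data.frame(truth))
}

#' Assemble a trial dataset from a surrogate cohort
#'
#' Runs the real [biomarker_panel()] on every surrogate subject and
#' collects the per-subject features into a [trial_dataset()].
#'
#' @param surr Output of [generate_surrogate()].
#' @param locations Renal locations to keep.
#' @return A `trial_dataset`.
#' @export
surrogate_to_panel <- function(surr, locations = "main") {
  feats <- lapply(surr$subjects, function(s) {
    panel_features(biomarker_panel(s, locations = locations),
                   locations = locations)
  })
  X <- do.call(rbind, feats)
  trial_dataset(X, surr$labels)
}
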