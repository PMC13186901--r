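# Sex-, age- and disease-specific parameterization of virtual subjects.
#
# Subjects are defined as multiplicative factor sets over the reference
# network: global factors (cardiac output, viscosity), per-vessel wall and
# geometry factors, and per-terminal peripheral resistance/compliance
# factors. Sex and age enter as deterministic normalization factors;
# inter-individual variability as independent Gaussian draws around them;
# disease as the printed normalized columns applied on top.

.param_names <- c("cardiac_output", "viscosity", "length", "radius",
                  "youngs_modulus", "wall_thickness", "pvr_systemic",
                  "pvr_renal", "pvc")

#' Age groups of the virtual population
#' @return Character vector of the six decade labels.
#' @export
age_groups <- function() {
  c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79")
}

#' Default sex/age normalization tables, sampling SDs and disease columns
#'
#' Sex factors are normalized male/female property ratios relative to the
#' non-sex-specific reference model; the renal peripheral resistance
#' anchors (0.85 in males, 1.15 in females) are exact, the remaining
#' curves are packaged defaults from standard aging-model conventions
#' (stiffening and peripheral resistance rise with age, cardiac output and
#' compliance decline) standing in for the source tables. All values are
#' editable.
#'
#' @return A list with elements `sex` (data frame, parameters by sex),
#'   `age` (parameters by age group), `sds` (sampling coefficients of
#'   variation per parameter), `disease` (normalized disease columns) and
#'   `filter` (per sex/age SBP/DBP reference means and SDs plus the RI
#'   inclusion interval).
#' @export
normalization_tables <- function() {
  sex <- data.frame(
    male   = c(1.08, 1.02, 1.00, 1.03, 1.05, 1.05, 0.95, 0.85, 1.05),
    female = c(0.92, 0.98, 1.00, 0.97, 0.95, 0.95, 1.05, 1.15, 0.95),
    row.names = .param_names)
  i <- 0:5
  age <- data.frame(
    cardiac_output = 1 - 0.03 * i,
    viscosity      = 1 + 0.01 * i,
    length         = rep(1, 6),
    radius         = 1 + 0.015 * i,
    youngs_modulus = 1 + 0.09 * i,
    wall_thickness = 1 + 0.04 * i,
    pvr_systemic   = 1 + 0.04 * i,
    pvr_renal      = 1 + 0.09 * i,
    pvc            = 1 - 0.06 * i,
    row.names = age_groups())
  # Sampling spread calibrated once so the retained cohort's resistive
  # index dispersion matches clinical report levels (RI SD ~ 0.04); the
  # blood-pressure spread is then ~2.8x the filter reference SD
  sds <- c(cardiac_output = 0.22, viscosity = 0.08, length = 0,
           radius = 0.14, youngs_modulus = 0.15, wall_thickness = 0.15,
           pvr_systemic = 0.35, pvr_renal = 0.35, pvc = 0.30)
  disease <- data.frame(
    dm_htn = c(0.83, 1.20, 1.00, 0.97, 1.25, 1.12, 1.17, 1.17, 0.77),
    dkd    = c(0.83, 1.20, 1.00, 0.97, 1.25, 1.12, 1.17, 1.35, 0.77),
    hkd    = c(0.83, 1.20, 1.00, 0.97, 1.25, 1.12, 1.17, 1.29, 0.77),
    row.names = .param_names)
  # renal-vessel-only overrides for the proximal wall remodeling of
  # hypertensive kidney disease (Table rows differ between systemic and
  # renal blocks only for HKD)
  disease_renal_wall <- data.frame(
    dm_htn = c(radius = 0.97, youngs_modulus = 1.25, wall_thickness = 1.12),
    dkd    = c(radius = 0.97, youngs_modulus = 1.25, wall_thickness = 1.12),
    hkd    = c(radius = 0.95, youngs_modulus = 1.40, wall_thickness = 1.23))
  # Normative filter anchors: centered on the reference subject of each
  # sex/age cell (the deterministic model prediction), with population
  # SDs of 10/7 mmHg; they stand in for the experimental reference table
  # and are fully editable.
  filt <- list(
    sbp_mean = rbind(
      male   = c(135.3, 136.8, 137.7, 138.1, 138.0, 137.4),
      female = c(127.6, 129.2, 130.1, 130.5, 130.5, 130.0)),
    dbp_mean = rbind(
      male   = c(79.7, 80.5, 81.1, 81.2, 81.1, 80.7),
      female = c(79.1, 79.8, 80.3, 80.6, 80.6, 80.3)),
    sbp_sd = 10, dbp_sd = 7, z_threshold = 2.575,
    ri_interval = c(0.47, 0.80))
  colnames(filt$sbp_mean) <- colnames(filt$dbp_mean) <- age_groups()
  list(sex = sex, age = age, sds = sds, disease = disease,
       disease_renal_wall = disease_renal_wall, filter = filt)
}

#' Deterministic reference subject for a sex/age cell
#'
#' Combines the sex and age normalization factors multiplicatively per
#' parameter; no random variation.
#'
#' @param sex "male" or "female".
#' @param age_group One of [age_groups()].
#' @param tables Normalization tables, see [normalization_tables()].
#' @return An object of class `subject_parameters` with unit per-vessel
#'   noise.
#' @export
build_reference_subject <- function(sex = c("male", "female"),
                                    age_group = "50-59",
                                    tables = normalization_tables()) {
  sex <- match.arg(sex)
  if (!age_group %in% rownames(tables$age)) {
    stop("unknown age group: ", age_group, call. = FALSE)
  }
  f <- stats::setNames(tables$sex[[sex]][match(.param_names,
                                               rownames(tables$sex))] *
                         unlist(tables$age[age_group, .param_names]),
                       .param_names)
  structure(list(sex = sex, age_group = age_group, factors = f,
                 disease_state = "healthy", seed = NA_integer_,
                 vessel_noise = NULL, terminal_noise = NULL),
            class = "subject_parameters")
}

#' Sample one virtual subject around a reference
#'
#' Draws independent Gaussian per-vessel noise for radius, Young's
#' modulus and wall thickness, per-terminal noise for peripheral
#' resistance and compliance, and global noise for cardiac output and
#' viscosity, all truncated at 0.2 times the reference to preclude
#' non-physical values. Identical seeds reproduce the subject bit for
#' bit.
#'
#' @param reference A `subject_parameters` from
#'   [build_reference_subject()].
#' @param network The network the subject will be instantiated on (its
#'   vessel and terminal ids dimension the noise tables).
#' @param sds Named per-parameter coefficients of variation.
#' @param seed Integer seed.
#' @return A `subject_parameters` with noise tables attached.
#' @export
sample_virtual_subject <- function(reference, network,
                                   sds = normalization_tables()$sds,
                                   seed = 1) {
  stopifnot(inherits(reference, "subject_parameters"))
  if (any(sds < 0)) stop("SDs must be non-negative", call. = FALSE)
  v <- network$vessels
  term <- network$terminals
  .with_seed(seed, {
    draw <- function(n, cv) {
      if (cv == 0) rep(1, n) else pmax(stats::rnorm(n, 1, cv), 0.2)
    }
    subj <- reference
    subj$seed <- as.integer(seed)
    subj$global_noise <- c(
      cardiac_output = draw(1, sds[["cardiac_output"]]),
      viscosity = draw(1, sds[["viscosity"]]))
    subj$vessel_noise <- data.frame(
      id = v$id,
      radius = draw(nrow(v), sds[["radius"]]),
      youngs_modulus = draw(nrow(v), sds[["youngs_modulus"]]),
      wall_thickness = draw(nrow(v), sds[["wall_thickness"]]),
      length = draw(nrow(v), sds[["length"]]),
      stringsAsFactors = FALSE)
    is_renal <- term$vessel %in% v$id[v$region == "renal"]
    subj$terminal_noise <- data.frame(
      vessel = term$vessel,
      pvr = ifelse(is_renal, draw(nrow(term), sds[["pvr_renal"]]),
                   draw(nrow(term), sds[["pvr_systemic"]])),
      pvc = draw(nrow(term), sds[["pvc"]]),
      stringsAsFactors = FALSE)
    subj
  })
}

#' Apply a disease parameterization to a subject
#'
#' Multiplies the subject's normalization factors by the disease columns.
#' Legal transitions are healthy to the diabetic-hypertensive systemic
#' state (`dm_htn`), and from there to diabetic (`dkd`) or hypertensive
#' (`hkd`) kidney disease. The renal peripheral resistance column is
#' authoritative for the 1D terminal coupling (1.17 / 1.35 / 1.29); the
#' kidney-disease microvascular mechanisms (arteriolar tone, nephron
#' loss, interlobular constriction) additionally reshape the bed circuit
#' used for glomerular filtration, see [subject_bed()].
#'
#' @param subject A `subject_parameters`.
#' @param disease "dm_htn", "dkd" or "hkd".
#' @param tables Normalization tables.
#' @return A new `subject_parameters`.
#' @export
apply_disease <- function(subject, disease = c("dm_htn", "dkd", "hkd"),
                          tables = normalization_tables()) {
  disease <- match.arg(disease)
  stopifnot(inherits(subject, "subject_parameters"))
  legal <- (subject$disease_state == "healthy" && disease == "dm_htn") ||
    (subject$disease_state == "dm_htn" && disease %in% c("dkd", "hkd"))
  if (!legal) {
    stop("illegal disease transition: ", subject$disease_state, " -> ",
         disease, call. = FALSE)
  }
  # factors are defined relative to healthy; later stages replace the
  # dm_htn column by the full-disease column
  col <- tables$disease[[if (disease == "dm_htn") "dm_htn" else disease]]
  names(col) <- rownames(tables$disease)
  prev <- if (subject$disease_state == "healthy") {
    stats::setNames(rep(1, length(.param_names)), .param_names)
  } else {
    tables$disease[["dm_htn"]]
  }
  names(prev) <- .param_names
  subject$factors <- subject$factors * col / prev
  subject$disease_state <- if (disease == "dm_htn") "dm_htn" else
    paste0("dm_htn_", disease)
  subject$disease <- disease
  subject$renal_wall <- tables$disease_renal_wall[[disease]]
  names(subject$renal_wall) <- rownames(tables$disease_renal_wall)
  subject
}

#' Instantiate a subject's arterial network
#'
#' Applies the subject's sex/age/disease factors and sampled noise to a
#' base network: global wall/geometry factors per region, per-vessel
#' noise, and terminal resistance/compliance factors.
#'
#' @param subject A `subject_parameters`.
#' @param base_network The reference [arterial_network()].
#' @return An `arterial_network` for this subject.
#' @export
instantiate_subject <- function(subject, base_network) {
  stopifnot(inherits(subject, "subject_parameters"))
  f <- subject$factors
  net <- scale_network(base_network,
                       c(length = f[["length"]], radius = f[["radius"]],
                         youngs_modulus = f[["youngs_modulus"]],
                         wall_thickness = f[["wall_thickness"]]),
                       scope = "all")
  # disease-specific renal wall remodeling (replaces the systemic wall
  # column on renal vessels)
  if (!is.null(subject$renal_wall)) {
    rw <- subject$renal_wall
    sysd <- c(radius = 0.97, youngs_modulus = 1.25, wall_thickness = 1.12)
    adj <- rw / sysd
    net <- scale_network(net, c(radius = adj[["radius"]],
                                youngs_modulus = adj[["youngs_modulus"]],
                                wall_thickness = adj[["wall_thickness"]]),
                         scope = "renal")
  }
  net <- scale_network(net, c(pvr = f[["pvr_systemic"]], pvc = f[["pvc"]]),
                       scope = "systemic")
  net <- scale_network(net, c(pvr = f[["pvr_renal"]], pvc = f[["pvc"]]),
                       scope = "renal")
  scale_network_per_vessel(net, subject$vessel_noise, subject$terminal_noise)
}

#' Subject cardiac output and viscosity
#'
#' @param subject A `subject_parameters`.
#' @param co_ref Reference cardiac output (m^3/s).
#' @param viscosity_ref Reference blood viscosity (Pa s).
#' @return List with `cardiac_output` and `viscosity`.
#' @export
subject_globals <- function(subject, co_ref = 5.3 / 60000,
                            viscosity_ref = 3.5e-3) {
  g <- if (is.null(subject$global_noise)) c(cardiac_output = 1, viscosity = 1)
       else subject$global_noise
  list(cardiac_output = co_ref * subject$factors[["cardiac_output"]] *
         g[["cardiac_output"]],
       viscosity = viscosity_ref * subject$factors[["viscosity"]] *
         g[["viscosity"]])
}

#' Microvascular bed of a subject for filtration analysis
#'
#' Builds the bed circuit consistent with the subject's renal peripheral
#' resistance factor: all components are scaled uniformly by the
#' sex/age/noise factor (and the systemic diabetic-hypertensive column
#' when diseased), then the kidney-disease mechanisms are applied
#' mechanistically -- afferent dilation/efferent constriction plus 57%
#' nephron loss for the diabetic kidney, or the interlobular constriction
#' solved for a 10% bed resistance rise for the hypertensive kidney.
#'
#' @param subject A `subject_parameters`.
#' @param surviving_fraction Fraction of nephrons surviving under
#'   diabetic nephron loss.
#' @param hkd_pvr_ratio Target bed resistance ratio of the hypertensive
#'   interlobular constriction.
#' @return A `microvascular_bed`.
#' @export
subject_bed <- function(subject, surviving_fraction = 0.43,
                        hkd_pvr_ratio = 1.10) {
  sexage <- subject$factors[["pvr_renal"]]
  disease <- subject$disease_state
  # remove the kidney-disease part of the factor: the bed gets it
  # mechanistically
  base_scale <- if (disease == "healthy") sexage else {
    sexage / (if (disease == "dm_htn") 1.17 else
              if (disease == "dm_htn_dkd") 1.35 else 1.29) * 1.17
  }
  comp <- nephron_components() * base_scale
  bed <- microvascular_bed(nephron_circuit(comp),
                           interlobular_resistance() * base_scale)
  if (disease == "dm_htn_dkd") {
    bed <- apply_dkd_arterioles(bed)
    bed <- apply_nephron_loss(bed, surviving_fraction)
  } else if (disease == "dm_htn_hkd") {
    s <- solve_hkd_interlobular_scale(bed, hkd_pvr_ratio)
    bed <- apply_interlobular_scale(bed, s)
  }
  bed
}

#' Brachial pressure and renal summary of a simulated subject
#'
#' @param sw A `subject_waves` with brachial and renal segmental
#'   locations.
#' @param brachial Location id of the brachial artery measurement.
#' @return List with `sbp`, `dbp` (mmHg) and `ri` (mean resistive index
#'   across the ten segmental arteries).
#' @export
subject_summary <- function(sw, brachial = "brachial_l_p") {
  pb <- sw$waves[[brachial]]$pressure / 133.322
  seg <- grep("^renal_[lr]_seg\\d+$", names(sw$waves), value = TRUE)
  ris <- vapply(seg, function(id) {
    f <- phase_features(sw$time, sw$waves[[id]]$velocity)
    resistive_index(f$Y_PS, f$Y_ED)
  }, 0)
  list(sbp = max(pb), dbp = min(pb), ri = mean(ris))
}

#' Physiological inclusion filter
#'
#' Retains a subject when its systolic and diastolic brachial pressures
#' lie within `z_threshold` reference SDs of the sex/age reference means
#' and its segmental resistive index lies inside the clinical normal
#' interval.
#'
#' @param summary List with `sbp`, `dbp` (mmHg), `ri`, e.g. from
#'   [subject_summary()].
#' @param sex,age_group Cell of the filter reference table.
#' @param criteria The `filter` element of [normalization_tables()].
#' @return List with `keep` (logical) and `reasons` (character vector of
#'   violated criteria, empty when kept).
#' @export
physiological_filter <- function(summary, sex, age_group,
                                 criteria = normalization_tables()$filter) {
  reasons <- character(0)
  z <- criteria$z_threshold
  if (abs(summary$sbp - criteria$sbp_mean[sex, age_group]) >
      z * criteria$sbp_sd) reasons <- c(reasons, "SBP")
  if (abs(summary$dbp - criteria$dbp_mean[sex, age_group]) >
      z * criteria$dbp_sd) reasons <- c(reasons, "DBP")
  if (summary$ri < criteria$ri_interval[1] ||
      summary$ri > criteria$ri_interval[2]) reasons <- c(reasons, "RI")
  list(keep = length(reasons) == 0, reasons = reasons)
}
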