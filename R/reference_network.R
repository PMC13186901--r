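# Packaged reference systemic arterial tree.
#
# The tree is a 75-segment adult systemic network with 29 lumped outlets,
# assembled from standard published adult arterial tree conventions
# (aorta, head and arm vessels, visceral branches, leg vessels). It is a
# packaged default standing in for subject-specific dimension tables: all
# cohort-level analyses in this package depend on its topology, its outlet
# impedance distribution and the renal subtree, not on any individual
# segment dimension, and every value can be overridden through the YAML
# network file.

.reference_vessel_table <- function() {
  # id, parent, length mm, radius mm, wall mm, E kPa, region
  tab <- rbind(
    c("aorta_asc",        NA,                 40, 14.50, 1.60,  400, "systemic"),
    c("aortic_arch_a",    "aorta_asc",        20, 11.20, 1.30,  400, "systemic"),
    c("brachiocephalic",  "aortic_arch_a",    34,  6.20, 0.80,  400, "systemic"),
    c("aortic_arch_b",    "aortic_arch_a",    39, 10.70, 1.25,  400, "systemic"),
    c("subclavian_r",     "brachiocephalic",  34,  4.20, 0.67,  300, "systemic"),
    c("carotid_r",        "brachiocephalic",  94,  3.70, 0.63,  400, "systemic"),
    c("carotid_l",        "aortic_arch_b",   139,  3.70, 0.63,  400, "systemic"),
    c("subclavian_l",     "aortic_arch_b",    42,  4.20, 0.67,  300, "systemic"),
    c("thoracic_aorta_a", "aortic_arch_b",    52, 10.00, 1.20,  400, "systemic"),
    c("vertebral_r",      "subclavian_r",    149,  1.90, 0.45,  800, "systemic"),
    c("axillary_r",       "subclavian_r",     61,  3.60, 0.62,  300, "systemic"),
    c("carotid_int_r",    "carotid_r",       178,  1.80, 0.45,  800, "systemic"),
    c("carotid_ext_r",    "carotid_r",       177,  1.50, 0.42,  800, "systemic"),
    c("carotid_int_l",    "carotid_l",       178,  1.80, 0.45,  800, "systemic"),
    c("carotid_ext_l",    "carotid_l",       177,  1.50, 0.42,  800, "systemic"),
    c("vertebral_l",      "subclavian_l",    148,  1.90, 0.45,  800, "systemic"),
    c("axillary_l",       "subclavian_l",     56,  3.60, 0.62,  300, "systemic"),
    c("brachial_r",       "axillary_r",      220,  3.20, 0.55,  300, "systemic"),
    c("brachial_l",       "axillary_l",      220,  3.20, 0.55,  300, "systemic"),
    c("radial_r",         "brachial_r",      235,  1.60, 0.43,  450, "systemic"),
    c("ulnar_r_a",        "brachial_r",       67,  2.10, 0.46,  450, "systemic"),
    c("radial_l",         "brachial_l",      235,  1.60, 0.43,  450, "systemic"),
    c("ulnar_l_a",        "brachial_l",       67,  2.10, 0.46,  450, "systemic"),
    c("interosseous_r",   "ulnar_r_a",        79,  0.90, 0.28,  800, "systemic"),
    c("ulnar_r_b",        "ulnar_r_a",       171,  1.90, 0.46,  450, "systemic"),
    c("interosseous_l",   "ulnar_l_a",        79,  0.90, 0.28,  800, "systemic"),
    c("ulnar_l_b",        "ulnar_l_a",       171,  1.90, 0.46,  450, "systemic"),
    c("intercostal",      "thoracic_aorta_a", 80,  3.15, 0.49,  400, "systemic"),
    c("thoracic_aorta_b", "thoracic_aorta_a",104,  8.35, 1.05,  400, "systemic"),
    c("abdominal_aorta_a","thoracic_aorta_b", 53,  7.60, 0.90,  400, "systemic"),
    c("celiac",           "abdominal_aorta_a",20,  3.90, 0.64,  400, "systemic"),
    c("abdominal_aorta_b","abdominal_aorta_a",15,  7.30, 0.90,  400, "systemic"),
    c("hepatic",          "celiac",           66,  2.80, 0.49,  400, "systemic"),
    c("splenic",          "celiac",           63,  2.75, 0.54,  400, "systemic"),
    c("gastric",          "celiac",           71,  1.80, 0.45,  400, "systemic"),
    c("mesenteric_sup",   "abdominal_aorta_b",59,  4.35, 0.69,  400, "systemic"),
    c("abdominal_aorta_c","abdominal_aorta_b",15,  7.00, 0.85,  400, "systemic"),
    c("renal_r",          "abdominal_aorta_c",32,  2.75, 0.53,  400, "renal"),
    c("abdominal_aorta_d","abdominal_aorta_c",15,  6.75, 0.85,  400, "systemic"),
    c("renal_l",          "abdominal_aorta_d",32,  2.75, 0.53,  400, "renal"),
    c("abdominal_aorta_e","abdominal_aorta_d",106, 6.10, 0.80,  400, "systemic"),
    c("lumbar",           "abdominal_aorta_e",60,  2.00, 0.45,  800, "systemic"),
    c("mesenteric_inf",   "abdominal_aorta_e",50,  1.60, 0.43,  400, "systemic"),
    c("abdominal_aorta_f","abdominal_aorta_e",15,  5.80, 0.75,  400, "systemic"),
    c("iliac_common_r",   "abdominal_aorta_f",58,  3.70, 0.60,  400, "systemic"),
    c("iliac_common_l",   "abdominal_aorta_f",58,  3.70, 0.60,  400, "systemic"),
    c("iliac_ext_r",      "iliac_common_r",  144,  3.20, 0.53,  400, "systemic"),
    c("iliac_int_r",      "iliac_common_r",   50,  2.00, 0.40, 1600, "systemic"),
    c("iliac_ext_l",      "iliac_common_l",  144,  3.20, 0.53,  400, "systemic"),
    c("iliac_int_l",      "iliac_common_l",   50,  2.00, 0.40, 1600, "systemic"),
    c("femoral_r",        "iliac_ext_r",     443,  2.60, 0.50,  800, "systemic"),
    c("femoral_deep_r",   "iliac_ext_r",     126,  2.30, 0.47,  800, "systemic"),
    c("femoral_l",        "iliac_ext_l",     443,  2.60, 0.50,  800, "systemic"),
    c("femoral_deep_l",   "iliac_ext_l",     126,  2.30, 0.47,  800, "systemic"),
    c("popliteal_r",      "femoral_r",        85,  2.30, 0.47,  800, "systemic"),
    c("popliteal_l",      "femoral_l",        85,  2.30, 0.47,  800, "systemic"),
    c("tibial_ant_r",     "popliteal_r",     343,  1.30, 0.39, 1600, "systemic"),
    c("tibial_post_r",    "popliteal_r",     321,  1.55, 0.45, 1600, "systemic"),
    c("tibial_ant_l",     "popliteal_l",     343,  1.30, 0.39, 1600, "systemic"),
    c("tibial_post_l",    "popliteal_l",     321,  1.55, 0.45, 1600, "systemic")
  )
  v <- data.frame(
    id = tab[, 1], name = gsub("_", " ", tab[, 1]), parent = tab[, 2],
    region = tab[, 7], generation = NA_character_,
    length = as.numeric(tab[, 3]) / 1000,
    radius = as.numeric(tab[, 4]) / 1000,
    wall_thickness = as.numeric(tab[, 5]) / 1000,
    youngs_modulus = as.numeric(tab[, 6]) * 1000,
    stringsAsFactors = FALSE
  )
  # Split selected long vessels into proximal/distal halves. This refines
  # the series discretisation of the tree without changing its outlets.
  splits <- c("femoral_r", "femoral_l", "brachial_r", "brachial_l",
              "carotid_r", "carotid_l", "thoracic_aorta_b",
              "abdominal_aorta_e", "tibial_post_r", "tibial_post_l",
              "tibial_ant_r", "tibial_ant_l", "radial_r", "radial_l",
              "iliac_ext_r")
  for (s in splits) {
    i <- which(v$id == s)
    prox <- v[i, ]; dist <- v[i, ]
    prox$id <- paste0(s, "_p"); prox$name <- paste(v$name[i], "proximal")
    dist$id <- paste0(s, "_d"); dist$name <- paste(v$name[i], "distal")
    prox$length <- v$length[i] / 2; dist$length <- v$length[i] / 2
    dist$parent <- prox$id
    dist$radius <- v$radius[i] * 0.97 # mild distal taper
    v$parent[v$parent == s & !is.na(v$parent)] <- dist$id
    v <- rbind(v[-i, ], prox, dist)
  }
  rownames(v) <- NULL
  v
}

# Target cycle-mean flow fraction of each outlet (sums to 1). The two renal
# outlets carry 9.5% each, consistent with the renal microvascular bed
# resistance; the remaining fractions follow standard regional perfusion
# shares and are normalized to the non-renal remainder.
.reference_outlet_fractions <- function() {
  renal <- c(renal_r = 0.095, renal_l = 0.095)
  w <- c(
    carotid_int_r = 3.2, carotid_int_l = 3.2,
    carotid_ext_r = 1.5, carotid_ext_l = 1.5,
    vertebral_r = 1.3, vertebral_l = 1.3,
    radial_r_d = 1.4, radial_l_d = 1.4,
    ulnar_r_b = 1.6, ulnar_l_b = 1.6,
    interosseous_r = 0.3, interosseous_l = 0.3,
    intercostal = 4.0, lumbar = 2.0,
    hepatic = 4.5, splenic = 4.5, gastric = 2.0,
    mesenteric_sup = 11.0, mesenteric_inf = 2.5,
    iliac_int_r = 2.3, iliac_int_l = 2.3,
    femoral_deep_r = 2.3, femoral_deep_l = 2.3,
    tibial_ant_r_d = 1.4, tibial_ant_l_d = 1.4,
    tibial_post_r_d = 1.8, tibial_post_l_d = 1.8
  )
  c(renal, w / sum(w) * (1 - sum(renal)))
}

#' Packaged reference systemic (and renal) arterial network
#'
#' Returns the package's default adult arterial tree: 75 systemic 1D
#' segments with 29 lumped outlets; with `renal = TRUE` (the default) the
#' two main renal arteries are extended with the full renal trees
#' (5 segmental, 10 interlobar and 20 arcuate arteries per kidney), each
#' arcuate terminated by a microvascular bed.
#'
#' Outlet resistances distribute a total peripheral resistance consistent
#' with a mean arterial pressure in the high 80s mmHg at a cardiac output
#' of 5.3 L/min over standard regional flow fractions; each outlet's
#' proximal resistance is the characteristic impedance of its feeding
#' vessel. Wall stiffness and terminal compliance were tuned once so the
#' reference subject reproduces a physiological operating point (diastolic
#' brachial pressure near 80 mmHg, renal blood flow near 1 L/min, and a
#' segmental resistive index near 0.62 for a young male).
#'
#' @param renal Attach the bilateral renal trees?
#' @param bed Microvascular bed used for the arcuate terminals.
#' @param total_compliance Total peripheral (terminal) compliance in
#'   m^3/Pa, distributed over outlets proportionally to flow fraction.
#' @param map_target,co_ref Mean arterial pressure (Pa) and cardiac output
#'   (m^3/s) defining the total peripheral resistance.
#' @param venous_pressure Reference venous pressure (Pa).
#' @return An `arterial_network`.
#' @export
reference_network <- function(renal = TRUE, bed = microvascular_bed(),
                              total_compliance = 1.6e-8,
                              map_target = 11500, co_ref = 5.3 / 60000,
                              venous_pressure = 666.5) {
  v <- .reference_vessel_table()
  frac <- .reference_outlet_fractions()
  leaves <- setdiff(v$id, v$parent[!is.na(v$parent)])
  stopifnot(setequal(leaves, names(frac)))
  r_net <- (map_target - venous_pressure) / co_ref
  rho <- 1060
  rows <- lapply(names(frac), function(id) {
    i <- which(v$id == id)
    r_tot <- r_net / frac[[id]]
    a0 <- pi * v$radius[i]^2
    c0 <- sqrt(v$youngs_modulus[i] * v$wall_thickness[i] / (2 * rho * v$radius[i]))
    r1 <- min(rho * c0 / a0, 0.2 * r_tot)
    cc <- if (id %in% c("renal_r", "renal_l")) {
      20 * bed$compliance # 20 arcuate beds per kidney
    } else {
      total_compliance * frac[[id]]
    }
    data.frame(vessel = id, type = "windkessel", R1 = r1, R2 = r_tot - r1,
               C = cc, stringsAsFactors = FALSE)
  })
  net <- arterial_network(v, do.call(rbind, rows), "aorta_asc")
  if (renal) net <- attach_renal_trees(net, bed = bed)
  net
}
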