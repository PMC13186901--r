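#' Hagen-Poiseuille resistance of a cylindrical vessel
#'
#' Resistance of fully developed laminar flow in a rigid cylinder,
#' `8 * mu * L / (pi * r^4)`.
#'
#' @param viscosity Dynamic viscosity (Pa s). Must be positive.
#' @param length Vessel length (m). Must be non-negative; a zero length
#'   returns zero resistance.
#' @param radius Lumen radius (m). Must be positive.
#' @return Resistance in Pa s / m^3.
#' @examples
#' poiseuille_resistance(4e-3, 370e-6, 22.9e-6) # interlobular arteriole
#' @export
poiseuille_resistance <- function(viscosity, length, radius) {
  if (any(viscosity <= 0)) stop("viscosity must be positive", call. = FALSE)
  if (any(radius <= 0)) stop("radius must be positive", call. = FALSE)
  if (any(length < 0)) stop("length must be non-negative", call. = FALSE)
  8 * viscosity * length / (pi * radius^4)
}

# Geometry of the Poiseuille-derived microcirculatory components.
# Dimensions in SI; viscosity is whole blood (4 mPa s) upstream of the
# glomerular filter and plasma (2 mPa s) downstream.
.nephron_geometry <- data.frame(
  component = c("interlobular", "afferent", "renal_tubule", "efferent"),
  viscosity = c(4.0e-3, 4.0e-3, 2.0e-3, 2.0e-3),
  length    = c(370e-6, 112e-6, 18000e-6, 120e-6),
  radius    = c(22.9e-6, 10.7e-6, 16.4e-6, 7.97e-6),
  stringsAsFactors = FALSE
)

# Components whose resistance is set by published ratios to the afferent
# arteriole rather than by geometry; stored as fixed configuration constants.
.nephron_ratio_resistances <- c(
  glomerular_capillary = 3.92e12,
  glomerular_filter    = 3.35e14,
  reabsorption         = 3.31e14,
  peritubular_capillary = 3.60e13,
  ureter               = 7.96e15
)

#' Default single-nephron circuit components
#'
#' Returns the eight component resistances of the single-nephron equivalent
#' circuit. The afferent arteriole, renal tubule and efferent arteriole are
#' computed by [poiseuille_resistance()] from their geometry; the glomerular
#' capillary, glomerular filter, reabsorption, peritubular capillary and
#' ureter pathways are ratio-derived constants.
#'
#' @param viscosity_scale Multiplier applied to both the blood and plasma
#'   viscosities entering the Poiseuille-derived components (e.g. 1.20 for
#'   the diabetic-hypertensive blood viscosity increase). Ratio-derived
#'   components are scaled by the same factor, treating them as viscous.
#' @return Named numeric vector of resistances (Pa s / m^3) with names
#'   `afferent`, `glomerular_capillary`, `glomerular_filter`, `renal_tubule`,
#'   `reabsorption`, `efferent`, `peritubular_capillary`, `ureter`.
#' @export
nephron_components <- function(viscosity_scale = 1) {
  stopifnot(viscosity_scale > 0)
  g <- .nephron_geometry
  pois <- stats::setNames(
    poiseuille_resistance(g$viscosity * viscosity_scale, g$length, g$radius),
    g$component
  )
  c(
    afferent = unname(pois["afferent"]),
    glomerular_capillary = unname(.nephron_ratio_resistances["glomerular_capillary"]) * viscosity_scale,
    glomerular_filter = unname(.nephron_ratio_resistances["glomerular_filter"]) * viscosity_scale,
    renal_tubule = unname(pois["renal_tubule"]),
    reabsorption = unname(.nephron_ratio_resistances["reabsorption"]) * viscosity_scale,
    efferent = unname(pois["efferent"]),
    peritubular_capillary = unname(.nephron_ratio_resistances["peritubular_capillary"]) * viscosity_scale,
    ureter = unname(.nephron_ratio_resistances["ureter"]) * viscosity_scale
  )
}

#' Default interlobular arteriole resistance
#'
#' @param viscosity_scale Multiplier on blood viscosity.
#' @return Resistance in Pa s / m^3.
#' @export
interlobular_resistance <- function(viscosity_scale = 1) {
  g <- .nephron_geometry[.nephron_geometry$component == "interlobular", ]
  poiseuille_resistance(g$viscosity * viscosity_scale, g$length, g$radius)
}

.nephron_component_names <- c(
  "afferent", "glomerular_capillary", "glomerular_filter", "renal_tubule",
  "reabsorption", "efferent", "peritubular_capillary", "ureter"
)

#' Construct a single-nephron equivalent circuit
#'
#' The circuit has a fixed bridge topology: the afferent arteriole feeds the
#' glomerular node, from which two branches depart -- the blood path
#' (glomerular capillary then efferent arteriole to the peritubular node)
#' and the filtrate path (glomerular filter then renal tubule to the tubular
#' node, then ureter to the venous outlet). The reabsorption pathway bridges
#' the tubular node back to the peritubular node, and the peritubular
#' capillary drains the peritubular node to the outlet.
#'
#' @param components Named numeric vector of the eight component resistances,
#'   as returned by [nephron_components()]. `Inf` is permitted and removes a
#'   branch (zero conductance); zeros are rejected because they short nodes.
#' @return An object of class `nephron_circuit`.
#' @export
nephron_circuit <- function(components = nephron_components()) {
  missing <- setdiff(.nephron_component_names, names(components))
  if (length(missing) > 0) {
    stop("missing nephron components: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  components <- components[.nephron_component_names]
  bad <- names(components)[components <= 0 | is.na(components)]
  if (length(bad) > 0) {
    stop("non-positive resistance for component: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(components = components), class = "nephron_circuit")
}

#' Solve the single-nephron circuit by nodal analysis
#'
#' Applies Kirchhoff's current law at the glomerular, tubular and peritubular
#' nodes and solves the resulting linear system for the node pressures.
#'
#' @param circuit A [nephron_circuit()].
#' @param inlet_pressure Pressure upstream of the afferent arteriole (Pa).
#' @param outlet_pressure Venous outlet pressure (Pa). Must be lower than
#'   the inlet pressure.
#' @return A list with `node_pressures` (glomerular, tubular, peritubular),
#'   `branch_flows` (m^3/s, one per component), `equivalent_resistance`
#'   (pressure drop over inlet flow, Pa s / m^3), `filtration_flow` (flow
#'   through the glomerular filter, m^3/s) and `filtration_fraction`.
#' @export
solve_nephron <- function(circuit, inlet_pressure, outlet_pressure = 0) {
  stopifnot(inherits(circuit, "nephron_circuit"))
  if (inlet_pressure <= outlet_pressure) {
    stop("inlet_pressure must exceed outlet_pressure", call. = FALSE)
  }
  r <- circuit$components
  # series lumps within branches
  r_blood <- r[["glomerular_capillary"]] + r[["efferent"]]
  r_filt <- r[["glomerular_filter"]] + r[["renal_tubule"]]
  g <- function(x) if (is.infinite(x)) 0 else 1 / x
  g_af <- g(r[["afferent"]]); g_b <- g(r_blood); g_f <- g(r_filt)
  g_re <- g(r[["reabsorption"]]); g_pc <- g(r[["peritubular_capillary"]])
  g_ur <- g(r[["ureter"]])
  # unknown node pressures: G (glomerular), T (tubular), P (peritubular)
  A <- rbind(
    c(g_af + g_b + g_f, -g_f, -g_b),
    c(-g_f, g_f + g_ur + g_re, -g_re),
    c(-g_b, -g_re, g_b + g_re + g_pc)
  )
  b <- c(inlet_pressure * g_af, outlet_pressure * g_ur, outlet_pressure * g_pc)
  # row equilibration: conductances span many decades
  d <- diag(A)
  if (all(d > 0)) {
    A <- A / d
    b <- b / d
  }
  p <- tryCatch(solve(A, b), error = function(e) {
    stop("singular nodal system (check for shorted or isolated components)",
         call. = FALSE)
  })
  names(p) <- c("glomerular", "tubular", "peritubular")
  q_in <- (inlet_pressure - p[["glomerular"]]) * g_af
  q_filt <- (p[["glomerular"]] - p[["tubular"]]) * g_f
  flows <- c(
    afferent = q_in,
    glomerular_capillary = (p[["glomerular"]] - p[["peritubular"]]) * g_b,
    glomerular_filter = q_filt,
    renal_tubule = q_filt,
    reabsorption = (p[["tubular"]] - p[["peritubular"]]) * g_re,
    efferent = (p[["glomerular"]] - p[["peritubular"]]) * g_b,
    peritubular_capillary = (p[["peritubular"]] - outlet_pressure) * g_pc,
    ureter = (p[["tubular"]] - outlet_pressure) * g_ur
  )
  list(
    node_pressures = p,
    branch_flows = flows,
    equivalent_resistance = (inlet_pressure - outlet_pressure) / q_in,
    filtration_flow = unname(q_filt),
    filtration_fraction = unname(q_filt / q_in)
  )
}

#' Construct the microvascular bed downstream of one arcuate artery
#'
#' The bed is a two-level parallel hierarchy: `n_nephrons_per_interlobular`
#' identical nephron circuits in parallel behind each interlobular arteriole,
#' and `n_interlobular_per_arcuate` such interlobular units in parallel
#' behind the arcuate terminus.
#'
#' @param nephron A [nephron_circuit()].
#' @param interlobular_resistance Resistance of one interlobular arteriole
#'   (Pa s / m^3).
#' @param n_interlobular_per_arcuate Number of interlobular arterioles per
#'   arcuate artery.
#' @param n_nephrons_per_interlobular Number of glomeruli fed by each
#'   interlobular arteriole.
#' @param surviving_fraction Fraction of nephrons remaining functional, in
#'   (0, 1]. Nephron loss scales the effective nephron count.
#' @param compliance Peripheral compliance of the bed (m^3 / Pa), used by
#'   the 1D outlet coupling.
#' @return An object of class `microvascular_bed`.
#' @export
microvascular_bed <- function(nephron = nephron_circuit(),
                              interlobular_resistance = renaltwin::interlobular_resistance(),
                              n_interlobular_per_arcuate = 650,
                              n_nephrons_per_interlobular = 60,
                              surviving_fraction = 1,
                              compliance = 2.53e-11) {
  stopifnot(
    inherits(nephron, "nephron_circuit"),
    interlobular_resistance > 0,
    n_interlobular_per_arcuate >= 1,
    n_nephrons_per_interlobular >= 1,
    surviving_fraction > 0, surviving_fraction <= 1,
    compliance > 0
  )
  structure(list(
    nephron = nephron,
    interlobular_resistance = interlobular_resistance,
    n_interlobular_per_arcuate = n_interlobular_per_arcuate,
    n_nephrons_per_interlobular = n_nephrons_per_interlobular,
    surviving_fraction = surviving_fraction,
    compliance = compliance
  ), class = "microvascular_bed")
}

#' Equivalent resistance of the nephron block behind one interlobular arteriole
#'
#' @param bed A [microvascular_bed()].
#' @return Resistance of `n_nephrons_per_interlobular * surviving_fraction`
#'   nephrons in parallel (Pa s / m^3).
#' @export
nephron_block_resistance <- function(bed) {
  stopifnot(inherits(bed, "microvascular_bed"))
  single <- solve_nephron(bed$nephron, 1, 0)$equivalent_resistance
  single / (bed$n_nephrons_per_interlobular * bed$surviving_fraction)
}

#' Equivalent resistance downstream of one arcuate artery
#'
#' Reduces the two-level parallel hierarchy: each interlobular unit is the
#' interlobular arteriole in series with its parallel nephron block; the
#' arcuate terminus sees all interlobular units in parallel.
#'
#' @param bed A [microvascular_bed()].
#' @return Resistance in Pa s / m^3.
#' @export
bed_equivalent_resistance <- function(bed) {
  stopifnot(inherits(bed, "microvascular_bed"))
  unit <- bed$interlobular_resistance + nephron_block_resistance(bed)
  unit / bed$n_interlobular_per_arcuate
}

#' Apply the diabetic arteriolar changes to a bed
#'
#' Afferent dilation and efferent constriction rescale the respective
#' Poiseuille resistances by the inverse fourth power of the lumen radius
#' scale; all other components are untouched.
#'
#' @param bed A [microvascular_bed()].
#' @param afferent_radius_scale Lumen radius multiplier for the afferent
#'   arteriole (default 1.10, a 10 percent dilation).
#' @param efferent_radius_scale Lumen radius multiplier for the efferent
#'   arteriole (default 0.93, a 7 percent constriction).
#' @return A new `microvascular_bed`.
#' @export
apply_dkd_arterioles <- function(bed, afferent_radius_scale = 1.10,
                                 efferent_radius_scale = 0.93) {
  stopifnot(inherits(bed, "microvascular_bed"),
            afferent_radius_scale > 0, efferent_radius_scale > 0)
  comp <- bed$nephron$components
  comp[["afferent"]] <- comp[["afferent"]] / afferent_radius_scale^4
  comp[["efferent"]] <- comp[["efferent"]] / efferent_radius_scale^4
  bed$nephron <- nephron_circuit(comp)
  bed
}

#' Apply nephron loss to a bed
#'
#' @param bed A [microvascular_bed()].
#' @param surviving_fraction Fraction of nephrons remaining, in (0, 1].
#'   Applied multiplicatively to the bed's current surviving fraction.
#' @return A new `microvascular_bed`.
#' @export
apply_nephron_loss <- function(bed, surviving_fraction) {
  stopifnot(inherits(bed, "microvascular_bed"))
  if (surviving_fraction <= 0 || surviving_fraction > 1) {
    stop("surviving_fraction must be in (0, 1]", call. = FALSE)
  }
  bed$surviving_fraction <- bed$surviving_fraction * surviving_fraction
  bed
}

#' Interlobular radius scale reproducing a target bed resistance ratio
#'
#' Finds the lumen-radius multiplier `s` of the interlobular arteriole such
#' that the bed equivalent resistance with interlobular resistance divided
#' by `s^4` equals `target_pvr_ratio` times the unmodified bed resistance.
#' Used to derive the hypertensive interlobular constriction from a target
#' peripheral-resistance scaling.
#'
#' @param bed The baseline [microvascular_bed()] (e.g. the
#'   diabetic-hypertensive systemic baseline).
#' @param target_pvr_ratio Desired ratio of modified to baseline bed
#'   resistance; must be >= 1.
#' @param bracket Search interval for the radius scale.
#' @return The radius scale factor (a number <= 1 for ratios > 1).
#' @export
solve_hkd_interlobular_scale <- function(bed, target_pvr_ratio = 1.10,
                                         bracket = c(0.3, 1.0)) {
  stopifnot(inherits(bed, "microvascular_bed"), target_pvr_ratio >= 1)
  if (target_pvr_ratio == 1) return(1.0)
  base <- bed_equivalent_resistance(bed)
  f <- function(s) {
    b <- bed
    b$interlobular_resistance <- bed$interlobular_resistance / s^4
    bed_equivalent_resistance(b) / base - target_pvr_ratio
  }
  if (f(bracket[1]) < 0) {
    stop("target PVR ratio unreachable within radius-scale bracket [",
         bracket[1], ", ", bracket[2], "]", call. = FALSE)
  }
  stats::uniroot(f, interval = bracket, tol = 1e-12)$root
}

#' Scale the interlobular arteriole radius of a bed
#'
#' @param bed A [microvascular_bed()].
#' @param radius_scale Lumen radius multiplier; resistance scales by its
#'   inverse fourth power.
#' @return A new `microvascular_bed`.
#' @export
apply_interlobular_scale <- function(bed, radius_scale) {
  stopifnot(inherits(bed, "microvascular_bed"), radius_scale > 0)
  bed$interlobular_resistance <- bed$interlobular_resistance / radius_scale^4
  bed
}

#' Glomerular filtration rate of a set of microvascular beds
#'
#' Solves the bed at the supplied steady perfusion pressure: the interlobular
#' drop is resolved first (the nephron block sees the interlobular-unit
#' intermediate pressure), then the single-nephron circuit is solved and its
#' filter-branch flow summed over all functioning nephrons and beds.
#'
#' @param bed A [microvascular_bed()].
#' @param inlet_pressure Cycle-mean pressure at the arcuate terminus (Pa).
#' @param outlet_pressure Venous pressure (Pa); default 5 mmHg.
#' @param n_beds Number of beds summed (40 for two kidneys of 20 arcuate
#'   arteries each).
#' @return A list with `gfr` (ml/min across all beds), `filtration_fraction`,
#'   `bed_inflow` (m^3/s per bed) and `total_inflow` (m^3/s across beds).
#' @export
compute_gfr <- function(bed, inlet_pressure, outlet_pressure = 666.5,
                        n_beds = 40) {
  stopifnot(inherits(bed, "microvascular_bed"), n_beds >= 1)
  if (inlet_pressure <= outlet_pressure) {
    stop("inlet_pressure must exceed outlet_pressure", call. = FALSE)
  }
  r_block <- nephron_block_resistance(bed)
  unit_r <- bed$interlobular_resistance + r_block
  q_unit <- (inlet_pressure - outlet_pressure) / unit_r
  # pressure at the interlobular/afferent junction
  p_mid <- inlet_pressure - q_unit * bed$interlobular_resistance
  sol <- solve_nephron(bed$nephron, p_mid, outlet_pressure)
  n_neph <- bed$n_nephrons_per_interlobular * bed$surviving_fraction *
    bed$n_interlobular_per_arcuate
  q_filt_bed <- sol$filtration_flow * n_neph
  q_in_bed <- q_unit * bed$n_interlobular_per_arcuate
  list(
    gfr = q_filt_bed * n_beds * 1e6 * 60, # m^3/s -> ml/min
    filtration_fraction = sol$filtration_fraction,
    bed_inflow = q_in_bed,
    total_inflow = q_in_bed * n_beds
  )
}
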