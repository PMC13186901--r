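#' Numerical configuration for the 1D solver
#'
#' @param target_dx Target cell size (m); each vessel gets at least
#'   `min_cells` cells.
#' @param min_cells Minimum cells per vessel.
#' @param cfl Courant number in (0, 1].
#' @param rho Blood density (kg/m^3).
#' @param nu_poisson Wall Poisson ratio entering the tube-law stiffness
#'   `beta = sqrt(pi) E h / (1 - nu^2)`. The default 0 makes the reference
#'   wave speed exactly Moens-Korteweg, `c0 = sqrt(E h / (2 rho r0))`.
#' @param gamma_profile Velocity-profile exponent of the friction term
#'   (9 approximates the blunt profiles of large arteries; 2 is parabolic).
#' @param heart_rate Beats per minute.
#' @param max_cycles Maximum cardiac cycles to iterate.
#' @param periodicity_tolerance Relative L2 change of the inlet pressure
#'   between consecutive cycles accepted as converged.
#' @param n_out Samples per cycle in returned waveforms.
#' @param p_ref Reference (diastolic) pressure at which vessel areas equal
#'   their reference areas (Pa).
#' @param venous_pressure Windkessel outflow pressure (Pa).
#' @return A list of class `numerics_config`.
#' @export
numerics_config <- function(target_dx = 0.015, min_cells = 3, cfl = 0.8,
                            rho = 1060, nu_poisson = 0, gamma_profile = 9,
                            heart_rate = 75, max_cycles = 10,
                            periodicity_tolerance = 1e-3, n_out = 200,
                            p_ref = 10400, venous_pressure = 666.5) {
  stopifnot(cfl > 0, cfl <= 1, rho > 0, max_cycles >= 2,
            heart_rate > 0, n_out >= 50)
  structure(list(target_dx = target_dx, min_cells = min_cells, cfl = cfl,
                 rho = rho, nu_poisson = nu_poisson,
                 gamma_profile = gamma_profile, heart_rate = heart_rate,
                 max_cycles = max_cycles,
                 periodicity_tolerance = periodicity_tolerance,
                 n_out = n_out, p_ref = p_ref,
                 venous_pressure = venous_pressure),
            class = "numerics_config")
}

#' Parametric aortic inflow waveform
#'
#' A two-lobe template: a dominant systolic ejection lobe, a brief
#' end-systolic reverse wave at valve closure, and zero diastolic flow. The
#' waveform is scaled so its cycle mean equals the requested cardiac
#' output.
#'
#' @param cardiac_output Cycle-mean flow (m^3/s).
#' @param heart_rate Beats per minute.
#' @param n Samples over one period.
#' @param systole_fraction Fraction of the cycle occupied by the ejection
#'   lobe.
#' @param reverse_fraction Duration of the reverse lobe as a fraction of
#'   the cycle.
#' @param reverse_amplitude Peak reverse flow relative to peak forward
#'   flow.
#' @return A list with `time` (s) and `flow` (m^3/s) over one period.
#' @export
aortic_inflow <- function(cardiac_output, heart_rate = 75, n = 512,
                          systole_fraction = 0.36, reverse_fraction = 0.06,
                          reverse_amplitude = 0.08) {
  period <- 60 / heart_rate
  t <- (seq_len(n) - 1) / n * period
  ts <- systole_fraction * period
  tr <- reverse_fraction * period
  q <- numeric(n)
  sys <- t < ts
  q[sys] <- sin(pi * t[sys] / ts)^2 * (1 + 0.25 * sin(2 * pi * t[sys] / ts))
  rev <- t >= ts & t < ts + tr
  q[rev] <- -reverse_amplitude * sin(pi * (t[rev] - ts) / tr)^2
  q <- q * cardiac_output / mean(q)
  list(time = t, flow = q, period = period)
}

#' Characteristic impedance of a vessel
#'
#' `Z0 = rho c0 / A0` with the reference wave speed from the tube law.
#'
#' @param radius,wall_thickness,youngs_modulus Vessel properties (SI).
#' @param rho Blood density.
#' @param nu_poisson Wall Poisson ratio.
#' @return Impedance in Pa s / m^3.
#' @export
characteristic_impedance <- function(radius, wall_thickness, youngs_modulus,
                                     rho = 1060, nu_poisson = 0) {
  a0 <- pi * radius^2
  beta <- sqrt(pi) * wall_thickness * youngs_modulus / (1 - nu_poisson^2)
  c0 <- sqrt(beta / (2 * rho * a0)) * a0^0.25
  rho * c0 / a0
}

#' Instantaneous wave speed from an area series
#'
#' Evaluates `c(A) = sqrt(A / rho * dP/dA)` for the elastic tube law, i.e.
#' `c = sqrt(beta / (2 rho A0)) * A^(1/4)`.
#'
#' @param area Numeric vector of lumen areas (m^2), all positive.
#' @param radius,wall_thickness,youngs_modulus Reference vessel properties.
#' @param rho Blood density.
#' @param nu_poisson Wall Poisson ratio.
#' @return Wave-speed series (m/s).
#' @export
wave_speed_series <- function(area, radius, wall_thickness, youngs_modulus,
                              rho = 1060, nu_poisson = 0) {
  if (any(area <= 0)) stop("areas must be positive", call. = FALSE)
  a0 <- pi * radius^2
  beta <- sqrt(pi) * wall_thickness * youngs_modulus / (1 - nu_poisson^2)
  sqrt(beta / (2 * rho * a0)) * area^0.25
}

#' Simulate one subject over converged cardiac cycles
#'
#' Integrates the 1D mass/momentum equations over the network with the
#' given aortic inflow, iterating cardiac cycles until the inlet pressure
#' is periodic, and returns last-cycle waveforms at the midpoints of the
#' requested vessels.
#'
#' @param network An [arterial_network()].
#' @param inflow A list with `time` and `flow` over one period, e.g. from
#'   [aortic_inflow()]; its mean is the subject's cardiac output.
#' @param numerics A [numerics_config()].
#' @param locations Character vector of vessel ids at which waveforms are
#'   recorded (default: all renal vessels plus the brachial artery and the
#'   aortic root).
#' @param viscosity Blood dynamic viscosity (Pa s).
#' @return A list of class `subject_waves` with elements `time`,
#'   `waves` (named list per location: `pressure`, `flow`, `velocity`,
#'   `area`, `wave_speed`), `inlet_pressure`, `period`, `cycles`,
#'   `converged`.
#' @export
simulate_subject <- function(network, inflow, numerics = numerics_config(),
                             locations = NULL, viscosity = 3.5e-3) {
  v <- network$vessels
  if (is.null(locations)) {
    locations <- unique(c(v$id[v$region == "renal"],
                          intersect(c("brachial_l_p", "brachial_l", "aorta_asc"),
                                    v$id)))
  }
  missing_loc <- setdiff(locations, v$id)
  if (length(missing_loc) > 0) {
    stop("unknown waveform location: ", paste(missing_loc, collapse = ", "),
         call. = FALSE)
  }
  idx <- stats::setNames(seq_len(nrow(v)) - 1L, v$id)
  kids <- network_children(network)
  has_kids <- names(kids)[vapply(kids, length, 1L) > 0]
  junc_parent <- unname(idx[has_kids])
  junc_children <- lapply(has_kids, function(p) unname(idx[kids[[p]]]))
  term <- network$terminals
  leaf_vessel <- unname(idx[term$vessel])
  ncells <- pmax(numerics$min_cells, ceiling(v$length / numerics$target_dx))
  period <- 60 / numerics$heart_rate
  # steady resistive pre-solve: initial windkessel pressures at the
  # cycle-mean operating point shorten the transient to periodicity
  est <- steady_network_flows(network, mean(inflow$flow), viscosity,
                              numerics$gamma_profile,
                              numerics$venous_pressure)
  pc0 <- numerics$venous_pressure +
    est$terminal_flow[match(term$vessel, names(est$terminal_flow))] * term$R2
  beta_v <- sqrt(pi) * v$wall_thickness * v$youngs_modulus /
    (1 - numerics$nu_poisson^2)
  a0_v <- pi * v$radius^2
  a_init <- (sqrt(a0_v) + a0_v * (est$inlet_pressure - numerics$p_ref) / beta_v)^2
  a_init <- pmin(pmax(a_init, 0.5 * a0_v), 2 * a0_v)
  q_init <- unname(est$vessel_flow[v$id])

  res <- solve_network_1d_cpp(
    len = v$length, r0 = v$radius, wallh = v$wall_thickness,
    emod = v$youngs_modulus, ncells = as.integer(ncells),
    junc_parent = as.integer(junc_parent), junc_children = junc_children,
    leaf_vessel = as.integer(leaf_vessel), tR1 = term$R1, tR2 = term$R2,
    tC = term$C, Pc0 = pc0, Ainit = a_init, Qinit = q_init,
    root = unname(idx[network$inlet]),
    inflow = inflow$flow, period = period,
    rho = numerics$rho, nu_poisson = numerics$nu_poisson, mu = viscosity,
    gamma_profile = numerics$gamma_profile, p_ref = numerics$p_ref,
    p_out = numerics$venous_pressure, cfl = numerics$cfl,
    max_cycles = numerics$max_cycles, tol = numerics$periodicity_tolerance,
    out_vessels = as.integer(unname(idx[locations])), n_out = numerics$n_out)

  if (res$failed_vessel >= 0) {
    stop("solver instability (non-finite state) in vessel '",
         v$id[res$failed_vessel + 1], "' at t = ",
         signif(res$failed_time, 4), " s", call. = FALSE)
  }
  waves <- stats::setNames(vector("list", length(locations)), locations)
  for (i in seq_along(locations)) {
    vi <- which(v$id == locations[i])
    area <- res$area[, i]
    flow <- res$flow[, i]
    waves[[i]] <- list(
      location = locations[i],
      pressure = res$pressure[, i],
      flow = flow,
      velocity = flow / area,
      area = area,
      wave_speed = wave_speed_series(area, v$radius[vi], v$wall_thickness[vi],
                                     v$youngs_modulus[vi], numerics$rho,
                                     numerics$nu_poisson)
    )
  }
  structure(list(time = res$time, waves = waves,
                 inlet_pressure = res$inlet_pressure, period = period,
                 cycles = res$cycles, converged = res$converged,
                 residuals = res$residuals),
            class = "subject_waves")
}

#' Steady-flow solution of the network as a resistive tree
#'
#' Reduces the tree bottom-up with laminar-friction vessel resistances
#' `R = 2 (gamma + 2) pi mu L / A0^2` in series with terminal resistances,
#' then distributes the cycle-mean inflow down the tree by conductance.
#' Used to initialize the windkessel states near the periodic operating
#' point, and useful as a zero-harmonic sanity check.
#'
#' @param network An [arterial_network()].
#' @param q_mean Cycle-mean inflow (m^3/s).
#' @param viscosity Blood viscosity (Pa s).
#' @param gamma_profile Velocity-profile exponent of the friction model.
#' @param venous_pressure Outflow pressure (Pa).
#' @return A list with `total_resistance` (Pa s/m^3), `inlet_pressure`
#'   (Pa), `terminal_flow` (named vector, m^3/s) and `vessel_flow`.
#' @export
steady_network_flows <- function(network, q_mean, viscosity = 3.5e-3,
                                 gamma_profile = 9, venous_pressure = 666.5) {
  v <- network$vessels
  kids <- network_children(network)
  term <- network$terminals
  r_ves <- stats::setNames(
    2 * (gamma_profile + 2) * pi * viscosity * v$length / (pi * v$radius^2)^2,
    v$id)
  r_term <- stats::setNames(term$R1 + term$R2, term$vessel)
  r_sub <- stats::setNames(rep(NA_real_, nrow(v)), v$id)
  # bottom-up order: sort by tree depth, deepest first
  depth <- stats::setNames(integer(nrow(v)), v$id)
  parent_of <- stats::setNames(v$parent, v$id)
  for (id in v$id) {
    d <- 0L; cur <- parent_of[[id]]
    while (!is.na(cur)) { d <- d + 1L; cur <- parent_of[[cur]] }
    depth[[id]] <- d
  }
  for (id in names(sort(depth, decreasing = TRUE))) {
    ch <- kids[[id]]
    down <- if (length(ch) == 0) r_term[[id]] else 1 / sum(1 / r_sub[ch])
    r_sub[[id]] <- r_ves[[id]] + down
  }
  q_ves <- stats::setNames(rep(0, nrow(v)), v$id)
  q_ves[[network$inlet]] <- q_mean
  for (id in names(sort(depth))) {
    ch <- kids[[id]]
    if (length(ch) > 0) {
      g <- 1 / r_sub[ch]
      q_ves[ch] <- q_ves[[id]] * g / sum(g)
    }
  }
  leaves <- network_leaves(network)
  list(total_resistance = unname(r_sub[[network$inlet]]),
       inlet_pressure = venous_pressure + q_mean * r_sub[[network$inlet]],
       terminal_flow = q_ves[leaves],
       vessel_flow = q_ves)
}
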