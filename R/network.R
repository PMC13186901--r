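#' Construct an arterial network
#'
#' An arterial network is a rooted tree of 1D vessel segments plus a lumped
#' terminal element (windkessel or microvascular bed) at every leaf. All
#' quantities are SI internally (m, Pa).
#'
#' @param vessels Data frame with columns `id`, `name`, `parent` (NA for the
#'   root), `region` ("systemic" or "renal"), `generation` (NA, or one of
#'   "main", "segmental", "interlobar", "arcuate" for renal vessels),
#'   `length`, `radius`, `wall_thickness` (m) and `youngs_modulus` (Pa).
#' @param terminals Data frame with columns `vessel`, `type` ("windkessel"
#'   or "bed"), `R1`, `R2` (Pa s / m^3) and `C` (m^3 / Pa).
#' @param inlet Id of the root vessel.
#' @return An object of class `arterial_network`.
#' @export
arterial_network <- function(vessels, terminals, inlet) {
  net <- structure(
    list(vessels = as.data.frame(vessels), terminals = as.data.frame(terminals),
         inlet = inlet),
    class = "arterial_network"
  )
  validate_network(net)
  net
}

#' Validate an arterial network
#'
#' Checks positivity of dimensions, rooted-tree topology (reporting any
#' cycle by the vessel ids on it), one terminal per leaf, and -- when renal
#' generations are present -- the per-kidney generation counts
#' (1 main, 5 segmental, 10 interlobar, 20 arcuate).
#'
#' @param net An `arterial_network`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_network <- function(net) {
  v <- net$vessels
  needed <- c("id", "name", "parent", "region", "generation",
              "length", "radius", "wall_thickness", "youngs_modulus")
  missing_cols <- setdiff(needed, names(v))
  if (length(missing_cols) > 0) {
    stop("vessel table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(v$id)) {
    stop("duplicate vessel ids: ",
         paste(unique(v$id[duplicated(v$id)]), collapse = ", "), call. = FALSE)
  }
  for (fld in c("length", "radius", "wall_thickness", "youngs_modulus")) {
    bad <- v$id[!is.finite(v[[fld]]) | v[[fld]] <= 0]
    if (length(bad) > 0) {
      stop("non-positive ", fld, " for vessel ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  bad_r <- v$id[v$radius >= 0.05]
  if (length(bad_r) > 0) {
    stop("implausible lumen radius (>= 0.05 m) for vessel ",
         paste(bad_r, collapse = ", "), call. = FALSE)
  }
  if (!net$inlet %in% v$id) {
    stop("inlet vessel '", net$inlet, "' not in vessel table", call. = FALSE)
  }
  unknown_parent <- v$id[!is.na(v$parent) & !(v$parent %in% v$id)]
  if (length(unknown_parent) > 0) {
    stop("unknown parent for vessel ", paste(unknown_parent, collapse = ", "),
         call. = FALSE)
  }
  # walk to the root from every vessel; a repeat marks a cycle
  parent_of <- stats::setNames(v$parent, v$id)
  for (id in v$id) {
    seen <- character(0)
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) {
        cyc <- seen[which(seen == cur):length(seen)]
        stop("cycle in parent/children topology: ",
             paste(c(cyc, cur), collapse = " -> "), call. = FALSE)
      }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  roots <- v$id[is.na(v$parent)]
  if (!identical(roots, net$inlet)) {
    stop("network must have exactly one root (the inlet); found: ",
         paste(roots, collapse = ", "), call. = FALSE)
  }
  leaves <- setdiff(v$id, v$parent[!is.na(v$parent)])
  term <- net$terminals
  if (anyDuplicated(term$vessel)) {
    stop("multiple terminals attached to vessel ",
         paste(unique(term$vessel[duplicated(term$vessel)]), collapse = ", "),
         call. = FALSE)
  }
  no_term <- setdiff(leaves, term$vessel)
  if (length(no_term) > 0) {
    stop("leaf vessel without terminal: ", paste(no_term, collapse = ", "),
         call. = FALSE)
  }
  not_leaf <- setdiff(term$vessel, leaves)
  if (length(not_leaf) > 0) {
    stop("terminal attached to non-leaf vessel: ",
         paste(not_leaf, collapse = ", "), call. = FALSE)
  }
  bad_t <- term$vessel[term$R1 <= 0 | term$R2 <= 0 | term$C <= 0]
  if (length(bad_t) > 0) {
    stop("non-positive terminal parameter for vessel ",
         paste(bad_t, collapse = ", "), call. = FALSE)
  }
  # renal generation counts, per kidney, once the tree is built out
  ren <- v[v$region == "renal" & !is.na(v$generation), ]
  if (any(ren$generation %in% c("segmental", "interlobar", "arcuate"))) {
    side <- ifelse(grepl("_l", ren$id, fixed = TRUE), "left", "right")
    for (s in unique(side)) {
      counts <- table(factor(ren$generation[side == s],
                             levels = c("main", "segmental", "interlobar", "arcuate")))
      expect <- c(main = 1, segmental = 5, interlobar = 10, arcuate = 20)
      if (!all(counts == expect)) {
        stop("renal generation counts for ", s, " kidney are ",
             paste(counts, collapse = "/"), ", expected 1/5/10/20",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Children map of a network
#' @param net An `arterial_network`.
#' @return Named list: vessel id -> character vector of child ids.
#' @export
network_children <- function(net) {
  v <- net$vessels
  kids <- split(v$id[!is.na(v$parent)], v$parent[!is.na(v$parent)])
  out <- stats::setNames(vector("list", nrow(v)), v$id)
  out[names(kids)] <- kids
  out
}

#' Leaf vessels of a network
#' @param net An `arterial_network`.
#' @return Character vector of ids of vessels with no children.
#' @export
network_leaves <- function(net) {
  v <- net$vessels
  setdiff(v$id, v$parent[!is.na(v$parent)])
}

#' @export
print.arterial_network <- function(x, ...) {
  v <- x$vessels
  cat("<arterial_network> ", nrow(v), " vessels (",
      sum(v$region == "systemic"), " systemic, ", sum(v$region == "renal"),
      " renal), ", nrow(x$terminals), " terminals (",
      sum(x$terminals$type == "bed"), " microvascular beds)\n", sep = "")
  cat("inlet:", x$inlet, "\n")
  invisible(x)
}

# ---- YAML I/O --------------------------------------------------------------
# File dialect uses hand-edit friendly units: lengths in mm, Young's modulus
# in kPa. Terminal parameters stay SI (Pa s/m^3, m^3/Pa) because they have no
# convenient small unit. Numbers are serialized with full double precision.

#' Read an arterial network from a YAML file
#'
#' The file dialect stores vessel geometry in mm and Young's modulus in kPa
#' (converted to SI on load), a `terminals:` list with SI windkessel values,
#' and an `inlet:` mapping. See the packaged `network_schema.json`.
#'
#' @param path Path to a YAML network file.
#' @return A validated `arterial_network`.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$vessels) || is.null(doc$terminals) || is.null(doc$inlet)) {
    stop("not a network file (need top-level vessels, terminals, inlet): ",
         path, call. = FALSE)
  }
  vs <- do.call(rbind, lapply(doc$vessels, function(x) {
    data.frame(
      id = x$id, name = x$name %||% x$id,
      parent = x$parent %||% NA_character_,
      region = x$region %||% "systemic",
      generation = x$generation %||% NA_character_,
      length = x$length_mm / 1000,
      radius = x$radius_mm / 1000,
      wall_thickness = x$wall_thickness_mm / 1000,
      youngs_modulus = x$youngs_modulus_kPa * 1000,
      stringsAsFactors = FALSE
    )
  }))
  ts <- do.call(rbind, lapply(doc$terminals, function(x) {
    data.frame(vessel = x$vessel, type = x$type %||% "windkessel",
               R1 = x$R1, R2 = x$R2, C = x$C, stringsAsFactors = FALSE)
  }))
  arterial_network(vs, ts, doc$inlet$vessel)
}

#' Write an arterial network to a YAML file
#'
#' Inverse of [load_network()]; numbers are written with 17 significant
#' digits so that a write/load round trip reproduces every field exactly.
#'
#' @param net An `arterial_network`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_network <- function(net, path) {
  v <- net$vessels
  vessels <- lapply(seq_len(nrow(v)), function(i) {
    row <- list(
      id = v$id[i], name = v$name[i],
      length_mm = v$length[i] * 1000,
      radius_mm = v$radius[i] * 1000,
      wall_thickness_mm = v$wall_thickness[i] * 1000,
      youngs_modulus_kPa = v$youngs_modulus[i] / 1000,
      region = v$region[i]
    )
    if (!is.na(v$parent[i])) row$parent <- v$parent[i]
    if (!is.na(v$generation[i])) row$generation <- v$generation[i]
    row
  })
  t <- net$terminals
  terminals <- lapply(seq_len(nrow(t)), function(i) {
    list(vessel = t$vessel[i], type = t$type[i],
         R1 = t$R1[i], R2 = t$R2[i], C = t$C[i])
  })
  doc <- list(inlet = list(vessel = net$inlet),
              vessels = vessels, terminals = terminals)
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Renal tree ------------------------------------------------------------

#' Default renal tree generation geometry
#'
#' Per-generation vessel dimensions for the renal arterial tree. The values
#' are packaged defaults representative of adult renal anatomy; they stand
#' in for dimension tables that are not part of this package and are fully
#' overridable.
#'
#' @return Data frame with one row per generation (main, segmental,
#'   interlobar, arcuate) and columns `length`, `radius`, `wall_thickness`
#'   (m) and `youngs_modulus` (Pa).
#' @export
renal_default_geometry <- function() {
  data.frame(
    generation = c("main", "segmental", "interlobar", "arcuate"),
    length = c(32e-3, 20e-3, 15e-3, 8e-3),
    radius = c(2.75e-3, 1.30e-3, 0.95e-3, 0.65e-3),
    wall_thickness = c(0.53e-3, 0.35e-3, 0.30e-3, 0.25e-3),
    youngs_modulus = c(4.0e5, 6.0e5, 6.0e5, 6.0e5),
    stringsAsFactors = FALSE
  )
}

#' Build one kidney's arterial tree fragment
#'
#' Builds the renal tree of one kidney: 1 main renal artery feeding 5
#' segmental arteries, each segmental feeding 2 interlobar arteries, and
#' each interlobar bifurcating into `arcuate_count_per_interlobar` arcuate
#' arteries (2 by default, giving 20 arcuate leaves). Every arcuate leaf is
#' terminated by a microvascular bed element.
#'
#' @param side "left" or "right"; determines vessel id suffixes.
#' @param arcuate_count_per_interlobar Arcuate branches per interlobar
#'   terminus.
#' @param base_geometry Per-generation geometry, see
#'   [renal_default_geometry()].
#' @param bed A [microvascular_bed()] providing the terminal resistance and
#'   compliance of each arcuate outlet.
#' @param char_impedance_split If `TRUE`, the bed terminal's proximal
#'   resistance is set to the arcuate characteristic impedance (reflection
#'   minimizing) with the remainder distal; otherwise a 5/95 split is used.
#' @param parent Optional id of an existing vessel the main renal artery
#'   hangs from (NA for a standalone fragment).
#' @return A list with elements `vessels` and `terminals` (data frames in
#'   the [arterial_network()] layout).
#' @export
build_renal_tree <- function(side = c("left", "right"),
                             arcuate_count_per_interlobar = 2,
                             base_geometry = renal_default_geometry(),
                             bed = microvascular_bed(),
                             char_impedance_split = TRUE,
                             parent = NA_character_) {
  side <- match.arg(side)
  stopifnot(arcuate_count_per_interlobar >= 1)
  gens <- c("main", "segmental", "interlobar", "arcuate")
  if (!all(gens %in% base_geometry$generation)) {
    stop("base_geometry must provide rows for generations: ",
         paste(setdiff(gens, base_geometry$generation), collapse = ", "),
         call. = FALSE)
  }
  geo <- function(g, f) base_geometry[[f]][base_geometry$generation == g]
  sfx <- if (side == "left") "l" else "r"
  row <- function(id, name, parent, gen) {
    data.frame(id = id, name = name, parent = parent, region = "renal",
               generation = gen,
               length = geo(gen, "length"), radius = geo(gen, "radius"),
               wall_thickness = geo(gen, "wall_thickness"),
               youngs_modulus = geo(gen, "youngs_modulus"),
               stringsAsFactors = FALSE)
  }
  main_id <- paste0("renal_", sfx)
  out <- list(row(main_id, paste(side, "main renal artery"), parent, "main"))
  arcuate_ids <- character(0)
  for (s in 1:5) {
    seg_id <- sprintf("renal_%s_seg%d", sfx, s)
    out[[length(out) + 1]] <- row(seg_id, sprintf("%s segmental artery %d", side, s),
                                  main_id, "segmental")
    for (i in 1:2) {
      il_id <- sprintf("renal_%s_seg%d_il%d", sfx, s, i)
      out[[length(out) + 1]] <- row(il_id, sprintf("%s interlobar artery %d.%d", side, s, i),
                                    seg_id, "interlobar")
      for (a in seq_len(arcuate_count_per_interlobar)) {
        ar_id <- sprintf("renal_%s_seg%d_il%d_arc%d", sfx, s, i, a)
        out[[length(out) + 1]] <- row(ar_id,
                                      sprintf("%s arcuate artery %d.%d.%d", side, s, i, a),
                                      il_id, "arcuate")
        arcuate_ids <- c(arcuate_ids, ar_id)
      }
    }
  }
  vessels <- do.call(rbind, out)
  r_bed <- bed_equivalent_resistance(bed)
  if (char_impedance_split) {
    rho <- 1060
    a0 <- pi * geo("arcuate", "radius")^2
    c0 <- sqrt(geo("arcuate", "youngs_modulus") * geo("arcuate", "wall_thickness") /
                 (2 * rho * geo("arcuate", "radius")))
    r1 <- min(rho * c0 / a0, 0.5 * r_bed)
  } else {
    r1 <- 0.05 * r_bed
  }
  terminals <- data.frame(vessel = arcuate_ids, type = "bed",
                          R1 = r1, R2 = r_bed - r1,
                          C = bed$compliance, stringsAsFactors = FALSE)
  list(vessels = vessels, terminals = terminals)
}

#' Attach bilateral renal trees to a systemic network
#'
#' Replaces the windkessel terminal of each main renal artery (ids
#' `renal_l`, `renal_r`) by the full renal tree of that kidney, terminating
#' every arcuate artery with a microvascular bed.
#'
#' @param net A systemic `arterial_network` whose renal mains are leaves.
#' @param bed A [microvascular_bed()] used for all arcuate terminals.
#' @param base_geometry Renal generation geometry.
#' @return A new `arterial_network` (36 renal vessels and 20 beds per
#'   kidney).
#' @export
attach_renal_trees <- function(net, bed = microvascular_bed(),
                               base_geometry = renal_default_geometry()) {
  vessels <- net$vessels
  terminals <- net$terminals
  for (side in c("left", "right")) {
    sfx <- if (side == "left") "l" else "r"
    main_id <- paste0("renal_", sfx)
    if (!main_id %in% vessels$id) {
      stop("systemic network has no vessel '", main_id, "'", call. = FALSE)
    }
    frag <- build_renal_tree(side, base_geometry = base_geometry, bed = bed,
                             parent = main_id)
    frag_v <- frag$vessels[frag$vessels$id != main_id, ]
    vessels$generation[vessels$id == main_id] <- "main"
    vessels$region[vessels$id == main_id] <- "renal"
    vessels <- rbind(vessels, frag_v)
    terminals <- terminals[terminals$vessel != main_id, ]
    terminals <- rbind(terminals, frag$terminals)
  }
  arterial_network(vessels, terminals, net$inlet)
}

# ---- Scaling ---------------------------------------------------------------

#' Scale network properties by multiplicative factors
#'
#' Multiplies vessel geometry/wall properties and terminal windkessel values
#' of the scoped vessels by the given factors, returning a new network. The
#' operation is multiplicative and composable: scaling by `f` then `g`
#' equals scaling by `f * g`.
#'
#' @param net An `arterial_network`.
#' @param factors Named numeric vector; recognised names are `length`,
#'   `radius`, `youngs_modulus`, `wall_thickness`, `pvr` (multiplies both
#'   terminal resistances) and `pvc` (terminal compliance). All must be
#'   positive. Omitted names default to 1.
#' @param scope One of "systemic", "renal", "all".
#' @return A new `arterial_network`.
#' @export
scale_network <- function(net, factors, scope = c("all", "systemic", "renal")) {
  scope <- match.arg(scope)
  known <- c("length", "radius", "youngs_modulus", "wall_thickness", "pvr", "pvc")
  unknown <- setdiff(names(factors), known)
  if (length(unknown) > 0) {
    stop("unknown scaling factor: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(factors <= 0)) stop("scaling factors must be positive", call. = FALSE)
  f <- function(nm) if (nm %in% names(factors)) factors[[nm]] else 1
  v <- net$vessels
  in_scope <- if (scope == "all") rep(TRUE, nrow(v)) else v$region == scope
  for (nm in c("length", "radius", "youngs_modulus", "wall_thickness")) {
    v[[nm]][in_scope] <- v[[nm]][in_scope] * f(nm)
  }
  t <- net$terminals
  t_scope <- t$vessel %in% v$id[in_scope]
  t$R1[t_scope] <- t$R1[t_scope] * f("pvr")
  t$R2[t_scope] <- t$R2[t_scope] * f("pvr")
  t$C[t_scope] <- t$C[t_scope] * f("pvc")
  arterial_network(v, t, net$inlet)
}

#' Apply per-vessel multiplicative factors to a network
#'
#' Unlike [scale_network()], which applies one factor to every scoped
#' vessel, this applies an individual factor per vessel (and per terminal),
#' as used when instantiating a sampled virtual subject.
#'
#' @param net An `arterial_network`.
#' @param vessel_factors Data frame with column `id` plus any of `length`,
#'   `radius`, `youngs_modulus`, `wall_thickness` containing per-vessel
#'   multipliers (missing vessels keep factor 1).
#' @param terminal_factors Data frame with column `vessel` plus any of
#'   `pvr`, `pvc`.
#' @return A new `arterial_network`.
#' @export
scale_network_per_vessel <- function(net, vessel_factors = NULL,
                                     terminal_factors = NULL) {
  v <- net$vessels
  if (!is.null(vessel_factors)) {
    m <- match(v$id, vessel_factors$id)
    for (nm in intersect(names(vessel_factors),
                         c("length", "radius", "youngs_modulus", "wall_thickness"))) {
      fac <- ifelse(is.na(m), 1, vessel_factors[[nm]][m])
      fac[is.na(fac)] <- 1
      v[[nm]] <- v[[nm]] * fac
    }
  }
  t <- net$terminals
  if (!is.null(terminal_factors)) {
    m <- match(t$vessel, terminal_factors$vessel)
    if ("pvr" %in% names(terminal_factors)) {
      fac <- ifelse(is.na(m), 1, terminal_factors$pvr[m]); fac[is.na(fac)] <- 1
      t$R1 <- t$R1 * fac; t$R2 <- t$R2 * fac
    }
    if ("pvc" %in% names(terminal_factors)) {
      fac <- ifelse(is.na(m), 1, terminal_factors$pvc[m]); fac[is.na(fac)] <- 1
      t$C <- t$C * fac
    }
  }
  arterial_network(v, t, net$inlet)
}
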