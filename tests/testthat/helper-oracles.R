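# Independent oracles used across the suite. These deliberately avoid the
# package's own reduction/statistics code paths.

# Nodal solve of an arbitrary resistor netlist. `edges` is a data frame
# with columns n1, n2 (node labels) and R; `fixed` a named vector of
# prescribed node pressures. Returns node pressures and the current drawn
# from each fixed node.
oracle_solve_netlist <- function(edges, fixed) {
  nodes <- unique(c(edges$n1, edges$n2))
  free <- setdiff(nodes, names(fixed))
  G <- matrix(0, length(free), length(free), dimnames = list(free, free))
  b <- stats::setNames(numeric(length(free)), free)
  for (k in seq_len(nrow(edges))) {
    g <- 1 / edges$R[k]
    if (!is.finite(g)) next
    a <- edges$n1[k]; d <- edges$n2[k]
    for (pair in list(c(a, d), c(d, a))) {
      x <- pair[1]; yy <- pair[2]
      if (x %in% free) {
        G[x, x] <- G[x, x] + g
        if (yy %in% free) G[x, yy] <- G[x, yy] - g
        else b[x] <- b[x] + g * fixed[[yy]]
      }
    }
  }
  p <- solve(G, b)
  all_p <- c(p, fixed)
  current <- vapply(names(fixed), function(nf) {
    sum(vapply(seq_len(nrow(edges)), function(k) {
      if (edges$n1[k] == nf) (all_p[[edges$n1[k]]] - all_p[[edges$n2[k]]]) / edges$R[k]
      else if (edges$n2[k] == nf) (all_p[[edges$n2[k]]] - all_p[[edges$n1[k]]]) / edges$R[k]
      else 0
    }, 0))
  }, 0)
  list(pressures = all_p, source_current = current)
}

# Fully expanded netlist of a microvascular bed: ni interlobular units in
# parallel, each an interlobular resistor feeding nn complete nephron
# bridge circuits in parallel.
oracle_bed_netlist <- function(comp, r_il, ni, nn) {
  edges <- NULL
  add <- function(e, n1, n2, R) rbind(e, data.frame(n1 = n1, n2 = n2, R = R,
                                                    stringsAsFactors = FALSE))
  for (i in seq_len(ni)) {
    ji <- sprintf("J%d", i)
    edges <- add(edges, "IN", ji, r_il)
    for (j in seq_len(nn)) {
      g <- sprintf("G%d_%d", i, j); tt <- sprintf("T%d_%d", i, j)
      pp <- sprintf("P%d_%d", i, j)
      edges <- add(edges, ji, g, comp[["afferent"]])
      edges <- add(edges, g, pp, comp[["glomerular_capillary"]] + comp[["efferent"]])
      edges <- add(edges, g, tt, comp[["glomerular_filter"]] + comp[["renal_tubule"]])
      edges <- add(edges, tt, pp, comp[["reabsorption"]])
      edges <- add(edges, tt, "OUT", comp[["ureter"]])
      edges <- add(edges, pp, "OUT", comp[["peritubular_capillary"]])
    }
  }
  edges
}

oracle_bed_resistance <- function(comp, r_il, ni, nn, dp = 1000) {
  edges <- oracle_bed_netlist(comp, r_il, ni, nn)
  sol <- oracle_solve_netlist(edges, c(IN = dp, OUT = 0))
  dp / sol$source_current[["IN"]]
}

# Exhaustive Mann-Whitney AUC over all class-1 x class-0 pairs.
oracle_auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s1) * length(s0))
}

# Steady series/parallel reduction of an arterial tree with laminar
# friction resistances (independent of the package's reduction).
oracle_tree_resistance <- function(net, viscosity, gamma_profile) {
  v <- net$vessels
  term <- net$terminals
  rv <- stats::setNames(2 * (gamma_profile + 2) * pi * viscosity * v$length /
                          (pi * v$radius^2)^2, v$id)
  rt <- stats::setNames(term$R1 + term$R2, term$vessel)
  reduce <- function(id) {
    ch <- v$id[!is.na(v$parent) & v$parent == id]
    down <- if (length(ch) == 0) rt[[id]]
            else 1 / sum(vapply(ch, function(c) 1 / reduce(c), 0))
    rv[[id]] + down
  }
  reduce(net$inlet)
}

# Small single-vessel test network.
make_tube_network <- function(length = 0.5, radius = 5e-3, h = 0.75e-3,
                              E = 4e5, R2 = 1.5e8, C = 1e-8,
                              split = FALSE) {
  if (!split) {
    v <- data.frame(id = "tube", name = "tube", parent = NA_character_,
                    region = "systemic", generation = NA_character_,
                    length = length, radius = radius, wall_thickness = h,
                    youngs_modulus = E, stringsAsFactors = FALSE)
    leaf <- "tube"
  } else {
    v <- data.frame(id = c("tube_a", "tube_b"),
                    name = c("tube a", "tube b"),
                    parent = c(NA_character_, "tube_a"),
                    region = "systemic", generation = NA_character_,
                    length = length / 2, radius = radius, wall_thickness = h,
                    youngs_modulus = E, stringsAsFactors = FALSE)
    leaf <- "tube_b"
  }
  z0 <- characteristic_impedance(radius, h, E)
  term <- data.frame(vessel = leaf, type = "windkessel", R1 = z0, R2 = R2,
                     C = C, stringsAsFactors = FALSE)
  arterial_network(v, term, v$id[1])
}
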