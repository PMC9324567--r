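# Capsule placement template.
#
# At the geometric fidelity used for population-scale runs, a cell's tile
# placement lives on a fixed capsule frame: two octagonal poles, two rings
# of three octagonal side tiles, two octagonal septum faces at mid-cell,
# and three auxiliary rod scaffold slots. Slot occupancy is the
# authoritative structure; the bond graph is derived from occupancy by a
# fixed adjacency map, and slot poses supply the 3D positions used for
# radius-r reagent capture, Brownian confinement and rendering.

RING <- c("a", "b", "c")
SLOT_RING1 <- paste0("r1", RING)
SLOT_RING2 <- paste0("r2", RING)
SLOT_RODS  <- paste0("rod", 1:3)
SLOT_WALL  <- c("poleA", SLOT_RING1, SLOT_RING2, "poleB")
SLOT_ALL   <- c(SLOT_WALL, "f1", "f2", SLOT_RODS)

#' Capsule placement template
#'
#' The closed-cell placement model used by the bacterial system: an
#' octagonal capsule with slots `poleA`, `r1a..c` (first side ring),
#' `r2a..c` (second side ring, inserted at the septal end), `poleB`,
#' septum faces `f1`, `f2`, and rod scaffold slots `rod1..3`. Each slot
#' carries a glue label; creation rules address slots through their
#' `at_glue` field.
#'
#' @param interior_radius Radius of the sphere confining interior
#'   floating objects (tile-edge units).
#' @param leak_rate Per-iteration escape probability of an interior
#'   floating object per unit open wall fraction.
#' @param rebond_rate Per-iteration probability that a severed bond
#'   between two still-present adjacent tiles re-adheres (glues still
#'   match and remain in contact).
#' @param interior_capacity Maximum number of floating objects a cell
#'   interior holds; protion transport stalls against a full interior
#'   (the crowding feedback through which growth self-controls).
#' @return An object of class `capsule_template`.
#' @export
capsule_template <- function(interior_radius = 1.5, leak_rate = 0.4,
                             rebond_rate = 0.16, interior_capacity = 8) {
  pos <- rbind(
    poleA = c(0, 0, -1.4),
    r1a = 1.2 * c(cos(0), sin(0), 0) + c(0, 0, -0.6),
    r1b = 1.2 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0) + c(0, 0, -0.6),
    r1c = 1.2 * c(cos(4 * pi / 3), sin(4 * pi / 3), 0) + c(0, 0, -0.6),
    r2a = 1.2 * c(cos(0), sin(0), 0) + c(0, 0, 0.6),
    r2b = 1.2 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0) + c(0, 0, 0.6),
    r2c = 1.2 * c(cos(4 * pi / 3), sin(4 * pi / 3), 0) + c(0, 0, 0.6),
    poleB = c(0, 0, 1.4),
    f1 = c(0, 0, -0.12),
    f2 = c(0, 0, 0.12),
    rod1 = 0.7 * c(cos(pi / 3), sin(pi / 3), 0),
    rod2 = 0.7 * c(cos(pi), sin(pi), 0),
    rod3 = 0.7 * c(cos(5 * pi / 3), sin(5 * pi / 3), 0)
  )
  glue <- c(poleA = "septum", r1a = "rim1", r1b = "rim1", r1c = "rim1",
            r2a = "rim2", r2b = "rim2", r2c = "rim2",
            poleB = "septum", f1 = "septum", f2 = "septum",
            rod1 = "scafA", rod2 = "scafB", rod3 = "scafC")
  side <- c(poleA = "out", r1a = "out", r1b = "out", r1c = "out",
            r2a = "out", r2b = "out", r2c = "out", poleB = "in",
            f1 = "in", f2 = "in", rod1 = "in", rod2 = "in", rod3 = "in")
  structure(list(name = "capsule", positions = pos, slot_glue = glue,
                 slot_side = side, interior_radius = interior_radius,
                 leak_rate = leak_rate, rebond_rate = rebond_rate,
                 interior_capacity = interior_capacity),
            class = "capsule_template")
}

# Fresh empty cell record on a capsule frame.
new_cell <- function(id, anchor) {
  occ <- rep(NA_character_, length(SLOT_ALL))
  names(occ) <- SLOT_ALL
  list(id = id, anchor = anchor, occ = occ,
       protion_ok = stats::setNames(rep(FALSE, 6), c(SLOT_RING1, SLOT_RING2)),
       severed = character(0))
}

cell_center <- function(cell) cell$anchor$position

# World position of a slot on a given cell.
slot_world <- function(tpl, cell, slot) {
  to_world(cell$anchor, tpl$positions[slot, ])
}

# Reagent-capture point of a slot. Interior-side reactions capture at
# the slot's inner face (pulled towards the cell centre) so the capture
# ball lies inside the confinement sphere; exterior reactions capture at
# the slot position itself.
capture_site <- function(tpl, cell, slot, side) {
  p <- slot_world(tpl, cell, slot)
  if (identical(side, "in")) {
    ctr <- cell_center(cell)
    ctr + 0.6 * (p - ctr)
  } else {
    p
  }
}

ring1_full <- function(cell) !anyNA(cell$occ[SLOT_RING1])
ring2_full <- function(cell) !anyNA(cell$occ[SLOT_RING2])
ring2_engaged <- function(cell) any(!is.na(cell$occ[SLOT_RING2]))

# Fraction of wall positions currently missing. The second ring counts
# only once insertion has begun (a short daughter capsule is closed).
open_fraction <- function(cell) {
  core <- c("poleA", SLOT_RING1, "poleB")
  missing <- sum(is.na(cell$occ[core]))
  total <- length(core)
  if (ring2_engaged(cell)) {
    missing <- missing + sum(is.na(cell$occ[SLOT_RING2]))
    total <- total + length(SLOT_RING2)
  }
  missing / total
}

# A bond severed between two still-present tiles leaves the wall ajar:
# the compartment only counts as closed once every such bond has healed.
severed_live_bonds <- function(cell) {
  if (!length(cell$severed)) return(character(0))
  ends <- strsplit(cell$severed, "|", fixed = TRUE)
  live <- vapply(ends, function(e)
    !is.na(cell$occ[e[1]]) && !is.na(cell$occ[e[2]]), logical(1))
  cell$severed[live]
}

cell_closed <- function(cell) {
  open_fraction(cell) == 0 && length(severed_live_bonds(cell)) == 0
}

scaffold_complete <- function(cell) !anyNA(cell$occ[SLOT_RODS])

septum_complete <- function(cell) {
  cell_closed(cell) && ring2_full(cell) &&
    !is.na(cell$occ["f1"]) && !is.na(cell$occ["f2"])
}

# Division becomes applicable when the septum is complete and the
# auxiliary rod scaffold has been cleared by the destruction rule.
division_ready <- function(cell) {
  septum_complete(cell) && all(is.na(cell$occ[SLOT_RODS]))
}

eval_guard <- function(guard, cell) {
  switch(guard,
         none = TRUE,
         closed = cell_closed(cell),
         scaffold_complete = scaffold_complete(cell),
         septum_complete = septum_complete(cell),
         stop("unknown guard '", guard, "'", call. = FALSE))
}

# Derived bond adjacency of a cell: list of slot pairs among occupied
# slots, with septal-end insertion rewiring handled implicitly (a ring-1
# tile bonds to poleB directly while its ring-2 neighbour slot is empty).
bond_key <- function(s1, s2) paste(pmin(s1, s2), pmax(s1, s2), sep = "|")

cell_bonds <- function(cell) {
  occ <- !is.na(cell$occ)
  pairs <- list()
  add <- function(s1, s2) {
    if (occ[[s1]] && occ[[s2]]) pairs[[length(pairs) + 1]] <<- c(s1, s2)
  }
  for (i in 1:3) {
    r1 <- SLOT_RING1[i]; r2 <- SLOT_RING2[i]
    add("poleA", r1)
    add(r1, SLOT_RING1[if (i == 3) 1 else i + 1])
    if (occ[[r2]]) {
      add(r1, r2)
      add(r2, SLOT_RING2[if (i == 3) 1 else i + 1])
      add(r2, "poleB")
    } else {
      add(r1, "poleB")
    }
  }
  add("f1", "f2")
  add("f1", "r1a")
  add("f2", "r2a")
  if (!length(pairs)) return(matrix(character(0), ncol = 2))
  m <- do.call(rbind, pairs)
  keys <- bond_key(m[, 1], m[, 2])
  m[!keys %in% cell$severed, , drop = FALSE]
}

# Slots a creation rule could fill on this cell (occupancy logic encodes
# the developmental ordering; the rule's at_glue picks the slot family).
eligible_slots <- function(tpl, cell, rule) {
  occ <- !is.na(cell$occ)
  out <- character(0)
  cand <- names(tpl$slot_glue)[tpl$slot_glue == rule$at_glue]
  for (s in cand) {
    if (occ[[s]]) next
    ok <- switch(s,
      # ring-1 growth proceeds from either pole so a lost seed pole can
      # be rebuilt from the remaining wall
      r1a = , r1b = , r1c = occ[["poleA"]] || occ[["poleB"]] ||
        ring2_engaged(cell),
      r2a = , r2b = , r2c = ring1_full(cell),
      poleA = ring1_full(cell),
      poleB = ring2_full(cell),
      f1 = scaffold_complete(cell) && cell_closed(cell),
      f2 = scaffold_complete(cell) && cell_closed(cell),
      # the completed septum occupies the mid-plane: no scaffold rebuild
      rod1 = cell_closed(cell) && ring2_full(cell) && !septum_complete(cell),
      rod2 = occ[["rod1"]] && !septum_complete(cell),
      rod3 = occ[["rod1"]] && !septum_complete(cell),
      FALSE)
    if (isTRUE(ok) && isTRUE(eval_guard(rule$guard %||% "none", cell))) {
      out <- c(out, s)
    }
  }
  out
}

# Split an adult cell into two daughters, re-anchored on fresh capsule
# frames offset along the mother's long axis. Every tile is retained:
# daughter A keeps poleA + ring 1 with septum face f1 as its new pole;
# daughter B keeps ring 2 + poleB with f2 as its new pole. The ring of a
# daughter occupies its ring-1 slots; severed-bond records do not carry
# across (daughter frames re-derive bonds).
split_cell <- function(tpl, cell, id_a, id_b) {
  axis <- quat_to_matrix(cell$anchor$quaternion)[, 3]
  jit <- function() stats::runif(3, -0.9, 0.9) * c(1, 1, 0)
  pa <- pose(cell$anchor$position - 2.2 * axis + jit(), cell$anchor$quaternion)
  pb <- pose(cell$anchor$position + 2.2 * axis + jit(), cell$anchor$quaternion)
  a <- new_cell(id_a, pa)
  b <- new_cell(id_b, pb)
  a$occ["poleA"] <- cell$occ[["poleA"]]
  a$occ[SLOT_RING1] <- cell$occ[SLOT_RING1]
  a$occ["poleB"] <- cell$occ[["f1"]]
  a$protion_ok[SLOT_RING1] <- cell$protion_ok[SLOT_RING1]
  b$occ["poleA"] <- cell$occ[["f2"]]
  b$occ[SLOT_RING1] <- cell$occ[SLOT_RING2]
  b$occ["poleB"] <- cell$occ[["poleB"]]
  b$protion_ok[SLOT_RING1] <- cell$protion_ok[SLOT_RING2]
  list(a, b)
}
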