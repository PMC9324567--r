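# The M-system formalism: floating-object / tile / protion specifications,
# the glue relation, the four reaction-rule variants, and the assembled
# system object with cross-reference validation.

#' Floating object specification
#'
#' Floating objects are small shapeless atomic objects of positive volume
#' that drift through the environment by Brownian motion and take part in
#' reactions. In the bacterial model the two floating species are the
#' nutrient `a` and the division signal `s`.
#'
#' @param name Unique label.
#' @param radius Occupied-volume proxy (>= 0).
#' @param mobility Per-iteration step length as a multiple of the
#'   interaction radius.
#' @param env_concentration Supply density (objects per unit volume) the
#'   environment boundary maintains; 0 for objects never supplied.
#' @return An object of class `floating_spec`.
#' @export
floating_spec <- function(name, radius = 0.05, mobility = 1,
                          env_concentration = 0) {
  stopifnot(is.character(name), length(name) == 1, radius >= 0,
            mobility >= 0, env_concentration >= 0)
  structure(list(name = name, radius = radius, mobility = mobility,
                 env_concentration = env_concentration),
            class = "floating_spec")
}

#' Protion specification
#'
#' A protion is a protein-like catalyst fixed at an unchangeable position
#' on its host tile. It enables reactions and transports floating objects
#' through the tile, like an ion channel through a membrane.
#'
#' @param name Label.
#' @param site Length-3 point in the host tile's local frame.
#' @return An object of class `protion_spec`.
#' @export
protion_spec <- function(name, site = c(0, 0, 0)) {
  stopifnot(is.character(name), length(name) == 1, length(site) == 3)
  structure(list(name = name, site = as.numeric(site)),
            class = "protion_spec")
}

#' Tile specification
#'
#' @param name Unique label.
#' @param shape A [tile_shape()].
#' @param connectors List of [connector()]s with distinct sites.
#' @param protions List of [protion_spec()]s carried by every instance of
#'   this tile.
#' @return An object of class `tile_spec`.
#' @export
tile_spec <- function(name, shape, connectors = list(), protions = list()) {
  stopifnot(is.character(name), length(name) == 1,
            inherits(shape, "tile_shape"))
  if (length(connectors) > 1) {
    sites <- vapply(connectors, function(co) paste(round(co$site, 9), collapse = ","),
                    character(1))
    if (anyDuplicated(sites)) {
      stop("connector sites must be distinct on tile '", name, "'", call. = FALSE)
    }
  }
  structure(list(name = name, shape = shape, connectors = connectors,
                 protions = protions),
            class = "tile_spec")
}

#' Glue relation
#'
#' The symmetric relation deciding which glue labels match. A glue
#' matches itself only if the pair `(g, g)` is listed.
#'
#' @param pairs Two-column character matrix (or data frame) of unordered
#'   glue-label pairs.
#' @return An object of class `glue_relation`.
#' @examples
#' gr <- glue_relation(rbind(c("gx", "gy"), c("gx", "gx")))
#' glue_matches(gr, "gy", "gx")  # TRUE
#' glue_matches(gr, "gy", "gy")  # FALSE
#' @export
glue_relation <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0) {
    pairs <- matrix(character(0), ncol = 2)
  }
  stopifnot(ncol(pairs) == 2)
  keys <- apply(pairs, 1, function(p) paste(sort(p), collapse = "\r"))
  structure(list(pairs = pairs, keys = unique(keys)),
            class = "glue_relation")
}

#' @rdname glue_relation
#' @param gr A `glue_relation`.
#' @param g1,g2 Glue labels.
#' @export
glue_matches <- function(gr, g1, g2) {
  paste(pmin(g1, g2), pmax(g1, g2), sep = "\r") %in% gr$keys
}

# ---- Rule variants -------------------------------------------------------
# All four variants instantiate the reaction form u -> v on multisets of
# floating objects, protions and tiles.

#' Metabolic rule: transport through a protion channel
#'
#' Consumes a multiset of floating objects on one side of a tile bearing
#' the named protion and produces a multiset on the other side. In the
#' bacterial model this is inward nutrient transport `a(out) -> a(in) +
#' s(in)`: each imported nutrient releases one unit of the division
#' signal on the interior side.
#'
#' @param protion Protion label at which the rule fires.
#' @param consumed Character vector (multiset) of floating labels, at
#'   least one.
#' @param consumed_side,produced_side `"out"` or `"in"`.
#' @param produced Character multiset of floating labels.
#' @return An object of class `metabolic_rule` / `ms_rule`.
#' @export
metabolic_rule <- function(protion, consumed, produced,
                           consumed_side = "out", produced_side = "in") {
  stopifnot(length(consumed) >= 1)
  consumed_side <- match.arg(consumed_side, c("out", "in"))
  produced_side <- match.arg(produced_side, c("out", "in"))
  structure(list(kind = "metabolic", protion = protion,
                 consumed = as.character(consumed),
                 produced = as.character(produced),
                 consumed_side = consumed_side,
                 produced_side = produced_side),
            class = c("metabolic_rule", "ms_rule"))
}

#' Creation rule: tile synthesis from floating objects
#'
#' Creates one tile of the named specification, attached at a connector
#' whose glue matches `at_glue`, consuming the given floating objects
#' (tiles can only be created via reactions involving floating objects,
#' so `consumed` must be nonempty).
#'
#' @param tile Tile spec name to create.
#' @param at_glue Glue label the new tile attaches by.
#' @param consumed Nonempty character multiset of floating labels.
#' @param side `"out"` or `"in"`: which side of the membrane the
#'   reagents must lie on.
#' @param guard Optional structural guard name (see
#'   [rule_guards()]); `"none"` by default.
#' @return An object of class `creation_rule` / `ms_rule`.
#' @export
creation_rule <- function(tile, at_glue, consumed, side = "out",
                          guard = "none") {
  stopifnot(length(consumed) >= 1)
  side <- match.arg(side, c("out", "in"))
  structure(list(kind = "creation", tile = tile, at_glue = at_glue,
                 consumed = as.character(consumed), side = side,
                 guard = guard),
            class = c("creation_rule", "ms_rule"))
}

#' Destruction rule: tile annihilation
#'
#' Removes a tile of the named specification, optionally consuming and
#' producing floating objects at its position.
#'
#' @param tile Tile spec name to annihilate; may be a vector of names
#'   when one rule annihilates a whole tile class (e.g. the auxiliary
#'   rods).
#' @param consumed,produced Character multisets of floating labels
#'   (either may be empty).
#' @param guard Optional structural guard name.
#' @return An object of class `destruction_rule` / `ms_rule`.
#' @export
destruction_rule <- function(tile, consumed = character(0),
                             produced = character(0), guard = "none") {
  structure(list(kind = "destruction", tile = tile,
                 consumed = as.character(consumed),
                 produced = as.character(produced), guard = guard),
            class = c("destruction_rule", "ms_rule"))
}

#' Division rule: septum fission
#'
#' Concludes cell division when septum formation is complete. The
#' trigger is structural: the septum must form a closed interface in the
#' bond graph such that severing the interface bonds leaves exactly two
#' closed daughter compartments. Applying the rule severs those bonds,
#' retains every tile, and increases the cell count by one.
#'
#' @param trigger Guard name; the shipped bacterial model uses
#'   `"septum_complete"`.
#' @return An object of class `division_rule` / `ms_rule`.
#' @export
division_rule <- function(trigger = "septum_complete") {
  structure(list(kind = "division", trigger = trigger),
            class = c("division_rule", "ms_rule"))
}

#' Structural guard vocabulary
#'
#' Guards are declarative structural preconditions evaluated on the cell
#' an instance would act in: `"none"`, `"closed"` (the wall is a closed
#' compartment), `"scaffold_complete"` (the auxiliary rod ring is
#' assembled), `"septum_complete"` (both septum faces are in place).
#'
#' @return Character vector of the recognised guard names.
#' @export
rule_guards <- function() {
  c("none", "closed", "scaffold_complete", "septum_complete")
}

# ---- The assembled system ------------------------------------------------

#' Assemble an M system
#'
#' @param floating_specs List of [floating_spec()]s.
#' @param tile_specs List of [tile_spec()]s.
#' @param glue_relation A [glue_relation()].
#' @param rules List of rule objects (the four variants).
#' @param interaction_radius Reaction/displacement radius r (> 0), in
#'   tile-edge units.
#' @param environment List with `bounds` (2 x 3 matrix `rbind(lower,
#'   upper)`) and `nutrient_budget` (named numeric per floating label;
#'   `Inf` for the unlimited-supply protocol).
#' @param seed_tiles List of `list(tile = <spec name>, pose = <pose>)`
#'   initial placements.
#' @param template Optional placement template for closed-cell models
#'   (see [capsule_template()]); `NULL` for free self-assembly.
#' @return An object of class `msystem`.
#' @export
msystem <- function(floating_specs, tile_specs, glue_relation, rules,
                    interaction_radius, environment, seed_tiles = list(),
                    template = NULL) {
  stopifnot(interaction_radius > 0)
  fl_names <- vapply(floating_specs, `[[`, character(1), "name")
  ti_names <- vapply(tile_specs, `[[`, character(1), "name")
  if (anyDuplicated(fl_names)) stop("floating object names must be unique", call. = FALSE)
  if (anyDuplicated(ti_names)) stop("tile spec names must be unique", call. = FALSE)
  names(floating_specs) <- fl_names
  names(tile_specs) <- ti_names
  pr_names <- unique(unlist(lapply(tile_specs, function(ts)
    vapply(ts$protions, `[[`, character(1), "name"))))

  for (i in seq_along(rules)) {
    ru <- rules[[i]]
    labs <- c(ru$consumed, ru$produced)
    bad <- setdiff(labs, fl_names)
    if (length(bad)) {
      stop("rule ", i, " (", ru$kind, ") references undeclared floating object(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (ru$kind %in% c("creation", "destruction") &&
        !all(ru$tile %in% ti_names)) {
      stop("rule ", i, " (", ru$kind, ") references undeclared tile '",
           paste(setdiff(ru$tile, ti_names), collapse = ", "), "'",
           call. = FALSE)
    }
    if (ru$kind == "metabolic" && !ru$protion %in% pr_names) {
      stop("rule ", i, " (metabolic) references undeclared protion '",
           ru$protion, "'", call. = FALSE)
    }
    g <- if (ru$kind == "division") ru$trigger else ru$guard %||% "none"
    if (!g %in% rule_guards()) {
      stop("rule ", i, " uses unknown guard '", g, "'", call. = FALSE)
    }
  }
  env <- environment
  stopifnot(is.matrix(env$bounds), all(dim(env$bounds) == c(2, 3)))
  if (is.null(env$nutrient_budget)) env$nutrient_budget <- numeric(0)
  for (st in seed_tiles) {
    if (!st$tile %in% ti_names) {
      stop("seed tile references undeclared tile '", st$tile, "'", call. = FALSE)
    }
  }
  structure(list(floating_specs = floating_specs, tile_specs = tile_specs,
                 glue_relation = glue_relation, rules = rules,
                 interaction_radius = interaction_radius,
                 environment = env, seed_tiles = seed_tiles,
                 template = template),
            class = "msystem")
}

#' @export
print.msystem <- function(x, ...) {
  kinds <- table(vapply(x$rules, `[[`, character(1), "kind"))
  cat("<msystem>\n")
  cat("  floating objects:", paste(names(x$floating_specs), collapse = ", "), "\n")
  cat("  tile specs:      ", paste(names(x$tile_specs), collapse = ", "), "\n")
  cat("  rules:           ", length(x$rules), "(",
      paste(names(kinds), as.integer(kinds), collapse = ", "), ")\n")
  cat("  interaction radius:", x$interaction_radius, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Multiset helper: does `pool` (character vector) contain multiset `need`?
multiset_contains <- function(pool, need) {
  if (!length(need)) return(TRUE)
  tn <- table(need)
  tp <- table(pool)
  all(names(tn) %in% names(tp)) && all(tp[names(tn)] >= tn)
}
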