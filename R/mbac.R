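# The concrete bacterial model: four 2D wall/septum tile types, three
# auxiliary rod-shaped tile types, floating objects a (nutrient) and
# s (division signal), one transport protion, and nine rules
# (1 metabolic + 6 creation + 1 destruction + 1 division).
#
# Developmental cycle of one cell on the capsule template:
#   seed pole -> first side ring -> second side ring -> far pole
#   (closure) -> nutrient import builds up the division signal ->
#   rod scaffold at mid-cell -> two septum faces -> rods annihilated ->
#   division severs the septum interface into two closed daughters.
# Maturity is nowhere preset as an iteration number: division readiness
# emerges from the septum completing, which requires signal accumulated
# through membrane transport.

#' Species calibration parameters
#'
#' Species models differ only in the diffusion (mobility) constants of
#' the two floating objects and the nutrient budget of the limited-supply
#' protocol; the rule set is identical.
#'
#' @param name Species label.
#' @param diffusion_a,diffusion_s Per-iteration step lengths of nutrient
#'   and signal objects as multiples of the interaction radius (> 0).
#' @param nutrient_budget Total nutrient objects the environment may
#'   supply (`Inf` for the unlimited protocol).
#' @param target_iterations Simulated minutes of the species' census
#'   protocol (one iteration = one minute).
#' @return An object of class `species_params`.
#' @export
species_params <- function(name, diffusion_a, diffusion_s,
                           nutrient_budget, target_iterations) {
  stopifnot(diffusion_a > 0, diffusion_s > 0, nutrient_budget >= 0,
            target_iterations >= 1)
  structure(list(name = name, diffusion_a = diffusion_a,
                 diffusion_s = diffusion_s,
                 nutrient_budget = nutrient_budget,
                 target_iterations = as.integer(target_iterations)),
            class = "species_params")
}

#' Calibrated species presets
#'
#' Parameters calibrated (grid search over the diffusion constants and
#' nutrient budget, `scripts/calibrate.R`) so that 100 seeded runs of the
#' limited-nutrient protocol reproduce the target mean final populations:
#' about 74 cells at 100 iterations (E. coli), 76 at 150 (S. lactis) and
#' 85 at 400 (L. acidophilus).
#'
#' @param species `"ecoli"`, `"slactis"` or `"lacidophilus"`.
#' @return A [species_params()] object.
#' @examples
#' mbac_preset("ecoli")$target_iterations  # 100
#' @export
mbac_preset <- function(species = c("ecoli", "slactis", "lacidophilus")) {
  species <- match.arg(species)
  switch(species,
    ecoli = species_params("ecoli", diffusion_a = 2.5, diffusion_s = 1.5,
                           nutrient_budget = 720, target_iterations = 100),
    slactis = species_params("slactis", diffusion_a = 1.05,
                             diffusion_s = 0.75,
                             nutrient_budget = 875, target_iterations = 150),
    lacidophilus = species_params("lacidophilus", diffusion_a = 0.40,
                                  diffusion_s = 0.35,
                                  nutrient_budget = 1120,
                                  target_iterations = 400))
}

# Environment constants shared by all species (the species differ only by
# diffusion and budget): box half-width, supply concentration, radius r.
MBAC_BOX_HALF <- 6
MBAC_CONC_A <- 0.25
MBAC_RADIUS <- 1

#' Build the bacterial M system
#'
#' Assembles the full system for a species: 4 types of 2D tiles (pole
#' cap, two side-wall types carrying the transport protion, septum
#' face), 3 auxiliary rod tile types controlling division, floating
#' objects `a` (nutrient) and `s` (signal), one protion, and nine rules.
#'
#' @param params A [species_params()], e.g. from [mbac_preset()].
#' @param unlimited_nutrients Override the budget with `Inf` (the injury
#'   experiment protocol).
#' @return An [msystem()] seeded with a single pole-cap tile at the
#'   origin.
#' @examples
#' sys <- build_mbac(mbac_preset("ecoli"))
#' length(sys$rules)  # 9
#' @export
build_mbac <- function(params = mbac_preset("ecoli"),
                       unlimited_nutrients = FALSE) {
  if (!inherits(params, "species_params")) {
    stop("`params` must be a species_params object", call. = FALSE)
  }
  octo <- tile_shape_regular_polygon(8)
  rod <- tile_shape("rod1D", rbind(c(0, 0, 0), c(0.6, 0, 0)))
  channel <- protion_spec("pch", c(0, 0, 0))
  rim <- function(glue) list(connector(c(0.5, -0.5 / tan(pi / 8), 0), glue))
  tiles <- list(
    tile_spec("cap", octo, rim("wall")),
    tile_spec("sideA", octo, rim("rim1"), list(channel)),
    tile_spec("sideB", octo, rim("rim2"), list(channel)),
    tile_spec("septum_face", octo, rim("septum")),
    tile_spec("rod_seed", rod, list(connector(c(0, 0, 0), "scafA"))),
    tile_spec("rod_arm", rod, list(connector(c(0, 0, 0), "scafB"))),
    tile_spec("rod_bridge", rod, list(connector(c(0, 0, 0), "scafC")))
  )
  floats <- list(
    floating_spec("a", radius = 0.05, mobility = params$diffusion_a,
                  env_concentration = MBAC_CONC_A),
    floating_spec("s", radius = 0.05, mobility = params$diffusion_s,
                  env_concentration = 0)
  )
  glues <- c("wall", "rim1", "rim2", "septum", "scafA", "scafB", "scafC")
  gr <- glue_relation(cbind(glues, glues))
  rules <- list(
    # one metabolic rule: inward nutrient transport releasing one unit of
    # division signal per imported nutrient
    metabolic_rule("pch", consumed = "a", produced = c("a", "s")),
    # six creation rules
    creation_rule("sideA", "rim1", "a", side = "out"),
    creation_rule("sideB", "rim2", "a", side = "out"),
    creation_rule("rod_seed", "scafA", "s", side = "in"),
    creation_rule("rod_arm", "scafB", "s", side = "in"),
    creation_rule("rod_bridge", "scafC", "s", side = "in"),
    creation_rule("septum_face", "septum", c("a", "a"), side = "in"),
    # one destruction rule annihilating the auxiliary rods
    destruction_rule(c("rod_seed", "rod_arm", "rod_bridge"),
                     guard = "septum_complete"),
    # one division rule
    division_rule("septum_complete")
  )
  budget <- if (unlimited_nutrients) Inf else params$nutrient_budget
  env <- list(bounds = rbind(rep(-MBAC_BOX_HALF, 3), rep(MBAC_BOX_HALF, 3)),
              nutrient_budget = c(a = budget))
  msystem(floats, tiles, gr, rules,
          interaction_radius = MBAC_RADIUS, environment = env,
          seed_tiles = list(list(tile = "cap", pose = pose(c(0, 0, 0)))),
          template = capsule_template())
}

#' Is a cell an adult?
#'
#' Adulthood is reached when the cell's configuration lies in the
#' homeostatic part of the developmental cycle: here, when the septum is
#' complete and the rod scaffold has been cleared, i.e. division is
#' applicable.
#'
#' @param cell A cell record from a configuration.
#' @return Logical.
#' @export
is_adult_cell <- function(cell) division_ready(cell)

#' Grow a single cell to adulthood
#'
#' Runs the system (unlimited nutrients recommended) until the first
#' cell reaches the pre-division adult state, and returns the
#' configuration at that point (before division applies).
#'
#' @param sys An [msystem()] from [build_mbac()].
#' @param seed Integer seed.
#' @param max_iter Iteration cap.
#' @return A list with `cfg` (the adult configuration), `cell_id` (the
#'   adult cell) and `iterations` (time to adulthood, minutes).
#' @export
grow_to_adult <- function(sys, seed = 1, max_iter = 400) {
  tr <- ms_run(sys, max_iter, seed = seed,
               stop_when = function(cfg) any(vapply(cfg$cells, division_ready,
                                                    logical(1))))
  cfg <- tr$final
  adult <- which(vapply(cfg$cells, division_ready, logical(1)))
  if (!length(adult)) {
    stop("no cell reached adulthood within ", max_iter, " iterations",
         call. = FALSE)
  }
  list(cfg = cfg, cell_id = cfg$cells[[adult[1]]]$id,
       iterations = cfg$iteration)
}

#' List the injurable components of a cell
#'
#' Enumerates the distinct components eligible as injury targets: every
#' placed tile, every intact protion, and every bond of the derived bond
#' graph. An adult pre-division cell exposes exactly 34 components
#' (10 tiles + 6 protions + 18 bonds).
#'
#' @param cfg A configuration.
#' @param cell_id Cell id (default: the first cell).
#' @return A tibble with columns `component` (unique id), `kind`
#'   (`"tile"`, `"protion"` or `"bond"`) and `target` (slot name or bond
#'   key).
#' @export
injury_targets <- function(cfg, cell_id = NULL) {
  if (is.null(cell_id)) cell_id <- cfg$cells[[1]]$id
  ci <- cell_index(cfg, cell_id)
  if (!length(ci)) stop("no cell with id ", cell_id, call. = FALSE)
  cl <- cfg$cells[[ci]]
  tiles <- names(cl$occ)[!is.na(cl$occ)]
  prot <- names(cl$protion_ok)[cl$protion_ok & !is.na(cl$occ[names(cl$protion_ok)])]
  bonds <- cell_bonds(cl)
  bond_keys <- if (nrow(bonds)) bond_key(bonds[, 1], bonds[, 2]) else character(0)
  out <- tibble::tibble(
    kind = c(rep("tile", length(tiles)), rep("protion", length(prot)),
             rep("bond", length(bond_keys))),
    target = c(tiles, prot, bond_keys))
  out$component <- seq_len(nrow(out))
  out[, c("component", "kind", "target")]
}
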