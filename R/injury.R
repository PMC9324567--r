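# Injury operators and the survival / recovery-time experiment drivers.
#
# An injury is a transition the system could not make by a valid
# application of any single rule: removing a tile (leaving a hole in the
# membrane), removing a protion (the host tile keeps its place but loses
# its transport channel), breaking a bond without destroying the tiles,
# or the sudden appearance of floating objects inside a membrane. No
# repair-specific rule exists anywhere in the model: recovery, when it
# happens, uses only the nine growth rules.

#' Construct an injury
#'
#' @param kind `"remove_tile"`, `"remove_protion"`, `"break_bond"` or
#'   `"inject_floats"`.
#' @param target Slot name (tiles/protions), bond key `"slot1|slot2"`
#'   (bonds), or for `inject_floats` a character multiset of floating
#'   labels.
#' @param cell_id Cell to injure (default: first cell).
#' @return An object of class `injury`.
#' @export
injury <- function(kind = c("remove_tile", "remove_protion", "break_bond",
                            "inject_floats"),
                   target, cell_id = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, target = target, cell_id = cell_id),
            class = "injury")
}

#' Inflict an injury on a configuration
#'
#' The resulting configuration may lie outside the set reachable by
#' valid rule applications.
#'
#' @param cfg A configuration.
#' @param inj An [injury()].
#' @param sys The [msystem()] (needed to place injected floats).
#' @return The injured configuration.
#' @export
inflict <- function(cfg, inj, sys) {
  cell_id <- inj$cell_id %||% cfg$cells[[1]]$id
  ci <- cell_index(cfg, cell_id)
  if (!length(ci)) stop("no cell with id ", cell_id, call. = FALSE)
  cl <- cfg$cells[[ci]]
  if (inj$kind == "remove_tile") {
    if (!inj$target %in% names(cl$occ) || is.na(cl$occ[inj$target])) {
      stop("remove_tile: no tile at slot '", inj$target, "' of cell ",
           cell_id, call. = FALSE)
    }
    cl$occ[inj$target] <- NA_character_
    if (inj$target %in% names(cl$protion_ok)) cl$protion_ok[inj$target] <- FALSE
    cfg$cells[[ci]] <- cl
  } else if (inj$kind == "remove_protion") {
    if (!inj$target %in% names(cl$protion_ok) ||
        !isTRUE(cl$protion_ok[inj$target])) {
      stop("remove_protion: no intact protion at slot '", inj$target,
           "' of cell ", cell_id, call. = FALSE)
    }
    cl$protion_ok[inj$target] <- FALSE
    cfg$cells[[ci]] <- cl
  } else if (inj$kind == "break_bond") {
    bonds <- cell_bonds(cl)
    keys <- if (nrow(bonds)) bond_key(bonds[, 1], bonds[, 2]) else character(0)
    if (!inj$target %in% keys) {
      stop("break_bond: no bond '", inj$target, "' in cell ", cell_id,
           call. = FALSE)
    }
    cl$severed <- union(cl$severed, inj$target)
    cfg$cells[[ci]] <- cl
  } else if (inj$kind == "inject_floats") {
    labels <- as.character(inj$target)
    if (length(labels)) {
      bad <- setdiff(labels, names(sys$floating_specs))
      if (length(bad)) {
        stop("inject_floats: undeclared floating object(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      ctr <- cell_center(cl)
      off <- matrix(stats::runif(3 * length(labels), -0.5, 0.5), ncol = 3)
      cfg <- add_floats(cfg, labels,
                        matrix(ctr, length(labels), 3, byrow = TRUE) + off,
                        rep(cell_id, length(labels)))
      # injected objects enter from outside the rule system; they are
      # recorded as injected so conservation checks stay balanced
      for (lab in labels) {
        cfg$ledger$injected[[lab]] <- cfg$ledger$injected[[lab]] + 1
      }
    }
  }
  cfg
}

# Draw one random injury: kind uniform over the four kinds, target
# uniform over the components currently eligible for that kind; if a
# kind has no eligible target left, another kind is drawn.
sample_injury <- function(cfg, cell_id, payload = c("s", "s", "s")) {
  ci <- cell_index(cfg, cell_id)
  cl <- cfg$cells[[ci]]
  kinds <- sample(c("remove_tile", "remove_protion", "break_bond",
                    "inject_floats"))
  for (kind in kinds) {
    if (kind == "remove_tile") {
      elig <- names(cl$occ)[!is.na(cl$occ)]
      if (length(elig)) {
        return(injury("remove_tile", sample(elig, 1), cell_id))
      }
    } else if (kind == "remove_protion") {
      elig <- names(cl$protion_ok)[cl$protion_ok &
                                     !is.na(cl$occ[names(cl$protion_ok)])]
      if (length(elig)) {
        return(injury("remove_protion", sample(elig, 1), cell_id))
      }
    } else if (kind == "break_bond") {
      bonds <- cell_bonds(cl)
      if (nrow(bonds)) {
        keys <- bond_key(bonds[, 1], bonds[, 2])
        return(injury("break_bond", sample(keys, 1), cell_id))
      }
    } else {
      return(injury("inject_floats", payload, cell_id))
    }
  }
  NULL
}

# Inflict k simultaneous random injuries on one cell: k of its
# injurable components are drawn without replacement and each is
# damaged according to its kind (tiles removed, protions removed,
# bonds broken). k >= the component count destroys the whole cell.
inflict_simultaneous <- function(cfg, sys, cell_id, k) {
  tg <- injury_targets(cfg, cell_id)
  k <- min(k, nrow(tg))
  if (k == 0) return(cfg)
  pick <- tg[sample.int(nrow(tg), k), ]
  # removing tiles first would invalidate bond/protion targets drawn on
  # them; the simultaneous semantics applies all damage to the original
  # state, so bonds and protions are damaged before their host tiles go
  ord <- order(match(pick$kind, c("bond", "protion", "tile")))
  for (i in ord) {
    kind <- switch(pick$kind[i], tile = "remove_tile",
                   protion = "remove_protion", bond = "break_bond")
    inj <- injury(kind, pick$target[i], cell_id)
    cfg <- tryCatch(inflict(cfg, inj, sys), error = function(e) cfg)
  }
  cfg
}

# Mean uninjured generation time (iterations from a single seeded tile
# to the first completed division) under unlimited nutrients.
mean_generation_time <- function(sys, n_runs = 10, seed = 1,
                                 max_iter = 400) {
  times <- vapply(seq_len(n_runs), function(i) {
    tr <- ms_run(sys, max_iter, seed = seed + i,
                 stop_when = function(cfg) cfg$n_divisions >= 1)
    if (tr$final$n_divisions >= 1) tr$final$iteration else NA_real_
  }, numeric(1))
  mean(times, na.rm = TRUE)
}

#' Survival experiment
#'
#' Runs replicate injured growth experiments under unlimited nutrients
#' and estimates the probability that the cell still reaches adulthood
#' and reproduction (a completed division) within the run cap of three
#' times the uninjured mean generation time.
#'
#' Two schedules are supported: `"simultaneous_predivision"` inflicts
#' all `n_injuries` at once on the adult cell just before division;
#' `"random_times"` spreads them over uniformly random iterations of the
#' growth phase prior to division.
#'
#' @param sys An [msystem()] built with unlimited nutrients
#'   (`build_mbac(..., unlimited_nutrients = TRUE)`).
#' @param n_injuries Number of random injuries (total count across all
#'   four kinds).
#' @param schedule `"simultaneous_predivision"` or `"random_times"`.
#' @param n_runs Replicates (the census protocol uses 100).
#' @param seed Integer seed.
#' @param generation_time Optional precomputed uninjured mean generation
#'   time (iterations); measured on the fly when `NULL`.
#' @return A one-row tibble: `n_injuries`, `n_runs`, `p_survive`,
#'   `mean_recovery_ratio` (NA when no run survived).
#' @export
survival_experiment <- function(sys, n_injuries,
                                schedule = c("simultaneous_predivision",
                                             "random_times"),
                                n_runs = 100, seed = 1,
                                generation_time = NULL) {
  schedule <- match.arg(schedule)
  set.seed(seed)
  if (is.null(generation_time)) {
    generation_time <- mean_generation_time(sys, seed = seed * 1000 %% 104729)
  }
  cap <- ceiling(3 * generation_time)
  survived <- logical(n_runs)
  ratio <- rep(NA_real_, n_runs)
  run_seeds <- sample.int(2^30, n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(run_seeds[i])
    if (schedule == "simultaneous_predivision") {
      ad <- tryCatch(grow_to_adult_quiet(sys), error = function(e) NULL)
      if (is.null(ad)) next
      cfg <- inflict_simultaneous(ad$cfg, sys, ad$cell_id, n_injuries)
      base <- cfg$n_divisions
      tr <- ms_run(sys, cap, cfg = cfg,
                   stop_when = function(c) c$n_divisions > base)
      survived[i] <- tr$final$n_divisions > base
      if (survived[i]) {
        recovery <- tr$final$iteration - ad$iterations
        # an uninjured adult would have divided on the next iteration
        ratio[i] <- (ad$iterations + recovery) / (ad$iterations + 1)
      }
    } else {
      # random times during growth, prior to division
      times <- sort(sample.int(max(1, ceiling(generation_time)), n_injuries,
                               replace = TRUE))
      cfg <- ms_init(sys)
      t <- 0L
      dead <- FALSE
      while (t < cap && cfg$n_divisions < 1) {
        due <- times[times == t]
        for (j in seq_along(due)) {
          if (!length(cfg$cells)) { dead <- TRUE; break }
          cfg <- inflict_simultaneous(cfg, sys, cfg$cells[[1]]$id, 1)
        }
        if (dead) break
        cfg <- ms_step(cfg, sys)
        t <- t + 1L
      }
      survived[i] <- cfg$n_divisions >= 1
      if (survived[i]) ratio[i] <- t / max(1, generation_time)
    }
  }
  tibble::tibble(
    n_injuries = n_injuries,
    n_runs = n_runs,
    p_survive = mean(survived),
    mean_recovery_ratio = if (any(survived)) mean(ratio[survived]) else NA_real_
  )
}

# grow_to_adult without reseeding (uses the ambient RNG stream)
grow_to_adult_quiet <- function(sys, max_iter = 400) {
  tr <- ms_run(sys, max_iter,
               stop_when = function(cfg) any(vapply(cfg$cells, division_ready,
                                                    logical(1))))
  cfg <- tr$final
  adult <- which(vapply(cfg$cells, division_ready, logical(1)))
  if (!length(adult)) stop("no adult reached", call. = FALSE)
  list(cfg = cfg, cell_id = cfg$cells[[adult[1]]]$id,
       iterations = cfg$iteration)
}

#' Survival sweep over injury counts
#'
#' @param sys Unlimited-nutrient system.
#' @param n_injuries Integer vector of injury counts to test.
#' @param n_runs Replicates per count.
#' @param seed Integer seed.
#' @param schedule Passed to [survival_experiment()].
#' @return A tibble with one row per injury count.
#' @export
survival_sweep <- function(sys, n_injuries = 0:34, n_runs = 100, seed = 1,
                           schedule = "simultaneous_predivision") {
  gt <- mean_generation_time(sys, seed = seed)
  purrr::map_dfr(seq_along(n_injuries), function(i) {
    survival_experiment(sys, n_injuries[i], schedule = schedule,
                        n_runs = n_runs, seed = seed + 7919 * i,
                        generation_time = gt)
  })
}

#' Recovery-time experiment
#'
#' Ratio of the injured generation time to the uninjured generation
#' time, averaged over surviving runs only.
#'
#' @inheritParams survival_experiment
#' @return A one-row tibble; `mean_recovery_ratio` is `NA` (explicitly
#'   undefined) when no run survives.
#' @export
recovery_time_experiment <- function(sys, n_injuries, n_runs = 100,
                                     seed = 1, generation_time = NULL) {
  survival_experiment(sys, n_injuries,
                      schedule = "simultaneous_predivision",
                      n_runs = n_runs, seed = seed,
                      generation_time = generation_time)
}
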