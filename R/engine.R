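# Discrete-time simulation engine: each iteration first displaces every
# floating object by one Brownian step, then applies a maximal
# conflict-free subset of applicable rule instances in randomised order
# (each object consumed at most once, each slot filled at most once).

#' Initial configuration of an M system
#'
#' Seeds the cells from `sys$seed_tiles` (each seed tile anchors one cell
#' frame at its pose) and injects the environment's initial supply of
#' floating objects up to the concentration targets, charged against the
#' nutrient budget.
#'
#' @param sys An [msystem()] carrying a placement template.
#' @return An object of class `configuration`.
#' @export
ms_init <- function(sys) {
  tpl <- sys$template
  if (is.null(tpl)) {
    stop("the continuous engine requires a placement template", call. = FALSE)
  }
  cells <- list()
  for (i in seq_along(sys$seed_tiles)) {
    st <- sys$seed_tiles[[i]]
    cl <- new_cell(i, st$pose)
    cl$occ["poleA"] <- st$tile
    cells[[i]] <- cl
  }
  labels <- names(sys$floating_specs)
  cfg <- structure(list(
    cells = cells,
    floats = list(label = character(0),
                  pos = matrix(numeric(0), ncol = 3),
                  cell = integer(0)),
    iteration = 0L,
    next_cell_id = length(cells) + 1L,
    n_divisions = 0L,
    budget_left = budget_of(sys),
    ledger = list(injected = stats::setNames(numeric(length(labels)), labels),
                  consumed = stats::setNames(numeric(length(labels)), labels),
                  produced = stats::setNames(numeric(length(labels)), labels))
  ), class = "configuration")
  inject_floats_env(cfg, sys)
}

budget_of <- function(sys) {
  labels <- names(sys$floating_specs)
  b <- stats::setNames(rep(Inf, length(labels)), labels)
  nb <- sys$environment$nutrient_budget
  b[names(nb)] <- as.numeric(nb)
  b
}

#' @export
print.configuration <- function(x, ...) {
  cat("<configuration> iteration", x$iteration, "|", length(x$cells),
      "cell(s) |", count_tiles(x), "tiles |",
      length(x$floats$label), "floating objects\n")
  invisible(x)
}

count_tiles <- function(cfg) {
  sum(vapply(cfg$cells, function(cl) sum(!is.na(cl$occ)), integer(1)))
}

float_count <- function(cfg, label) sum(cfg$floats$label == label)

add_floats <- function(cfg, label, pos, cell) {
  n <- length(label)
  if (!n) return(cfg)
  cfg$floats$label <- c(cfg$floats$label, label)
  cfg$floats$pos <- rbind(cfg$floats$pos, pos)
  cfg$floats$cell <- c(cfg$floats$cell, as.integer(cell))
  cfg
}

drop_floats <- function(cfg, idx) {
  if (!length(idx)) return(cfg)
  keep <- setdiff(seq_along(cfg$floats$label), idx)
  cfg$floats$label <- cfg$floats$label[keep]
  cfg$floats$pos <- cfg$floats$pos[keep, , drop = FALSE]
  cfg$floats$cell <- cfg$floats$cell[keep]
  cfg
}

# Top up environment floating objects towards each label's concentration
# target, limited by the remaining nutrient budget.
inject_floats_env <- function(cfg, sys) {
  vol <- prod(sys$environment$bounds[2, ] - sys$environment$bounds[1, ])
  for (fs in sys$floating_specs) {
    if (fs$env_concentration <= 0) next
    target <- round(fs$env_concentration * vol)
    cur <- sum(cfg$floats$label == fs$name & cfg$floats$cell == 0L)
    n <- max(0, target - cur)
    n <- min(n, floor(cfg$budget_left[[fs$name]]))
    if (n > 0) {
      cfg <- add_floats(cfg, rep(fs$name, n),
                        runif_box(n, sys$environment$bounds), rep(0L, n))
      cfg$budget_left[[fs$name]] <- cfg$budget_left[[fs$name]] - n
      cfg$ledger$injected[[fs$name]] <- cfg$ledger$injected[[fs$name]] + n
    }
  }
  cfg
}

# Brownian phase: displace every floating object by one step of length
# mobility * r; environment objects reflect at the box walls, interior
# objects reflect inside their cell's confinement sphere. Objects inside
# a cell with an open wall may escape to the environment.
brownian_phase <- function(cfg, sys) {
  n <- length(cfg$floats$label)
  if (n == 0) return(cfg)
  tpl <- sys$template
  r <- sys$interaction_radius
  mob <- vapply(sys$floating_specs, `[[`, numeric(1), "mobility")
  step <- mob[cfg$floats$label] * r
  env_i <- which(cfg$floats$cell == 0L)
  if (length(env_i)) {
    cfg$floats$pos[env_i, ] <- brownian_step(
      cfg$floats$pos[env_i, , drop = FALSE], step[env_i],
      bounds = sys$environment$bounds)
  }
  int_i <- which(cfg$floats$cell != 0L)
  if (length(int_i)) {
    p <- brownian_step(cfg$floats$pos[int_i, , drop = FALSE], step[int_i])
    centers <- t(vapply(cfg$cells, cell_center, numeric(3)))
    ids <- vapply(cfg$cells, `[[`, integer(1), "id")
    row <- match(cfg$floats$cell[int_i], ids)
    ctr <- centers[row, , drop = FALSE]
    d <- p - ctr
    dn <- sqrt(rowSums(d^2))
    out <- dn > tpl$interior_radius
    if (any(out)) {
      # radial reflection back into the confinement sphere
      refl <- pmax(2 * tpl$interior_radius - dn[out], 0.05)
      p[out, ] <- ctr[out, , drop = FALSE] + d[out, , drop = FALSE] *
        (refl / dn[out])
    }
    cfg$floats$pos[int_i, ] <- p
    # leakage through open walls
    openf <- vapply(cfg$cells, open_fraction, numeric(1))[row]
    esc <- stats::runif(length(int_i)) < tpl$leak_rate * openf
    if (any(esc)) {
      cfg$floats$cell[int_i[esc]] <- 0L
      cfg$floats$pos[int_i[esc], ] <- reflect_into_box(
        cfg$floats$pos[int_i[esc], , drop = FALSE], sys$environment$bounds)
    }
  }
  cfg
}

# ---- Rule instance enumeration -------------------------------------------

# Indices of available floats with `label`, in compartment `cell_id`
# (0 = environment), within radius r of point `site`.
floats_near <- function(cfg, label, cell_id, site, r, taken) {
  cand <- which(cfg$floats$label == label & cfg$floats$cell == cell_id & !taken)
  if (!length(cand)) return(integer(0))
  d2 <- rowSums(sweep(cfg$floats$pos[cand, , drop = FALSE], 2, site)^2)
  ok <- d2 <= r^2
  cand[ok][order(d2[ok])]
}

# Bind the consumed multiset of a rule at a site: nearest available
# floats per label; NULL when some label is short.
bind_reagents <- function(cfg, consumed, cell_id, site, r, taken) {
  if (!length(consumed)) return(integer(0))
  labs <- unique(consumed)
  out <- integer(0)
  for (lab in labs) {
    k <- sum(consumed == lab)
    got <- floats_near(cfg, lab, cell_id, site, r, taken)
    if (length(out)) got <- setdiff(got, out)
    if (length(got) < k) return(NULL)
    out <- c(out, got[seq_len(k)])
  }
  out
}

#' Enumerate applicable rule instances
#'
#' Returns every (rule, site, bound reagents) combination whose reactants
#' all lie within the interaction radius of the reaction site and satisfy
#' the rule's side and structural-guard constraints. Reagent bindings are
#' the nearest available objects; bindings of distinct instances may
#' overlap (conflicts are resolved during [ms_step()]).
#'
#' @param cfg A [ms_init()] configuration.
#' @param sys The [msystem()].
#' @return A list of instances, each a list with elements `rule`
#'   (index into `sys$rules`), `kind`, `cell` (cell id), `slot` (for
#'   creation/destruction), and `floats` (indices of bound reagents).
#' @export
applicable_instances <- function(cfg, sys) {
  tpl <- sys$template
  r <- sys$interaction_radius
  taken <- rep(FALSE, length(cfg$floats$label))
  out <- list()
  emit <- function(...) out[[length(out) + 1]] <<- list(...)
  for (cl in cfg$cells) {
    closed <- cell_closed(cl)
    for (ri in seq_along(sys$rules)) {
      ru <- sys$rules[[ri]]
      if (ru$kind == "metabolic") {
        # transport stalls against a full interior
        if (ru$produced_side == "in" &&
            sum(cfg$floats$cell == cl$id) >= tpl$interior_capacity) next
        host <- names(cl$protion_ok)[cl$protion_ok & !is.na(cl$occ[names(cl$protion_ok)])]
        for (s in host) {
          site <- capture_site(tpl, cl, s, ru$consumed_side)
          src <- if (ru$consumed_side == "out") 0L else cl$id
          fl <- bind_reagents(cfg, ru$consumed, src, site, r, taken)
          if (!is.null(fl)) emit(rule = ri, kind = "metabolic", cell = cl$id,
                                 slot = s, floats = fl)
        }
      } else if (ru$kind == "creation") {
        for (s in eligible_slots(tpl, cl, ru)) {
          site <- capture_site(tpl, cl, s, ru$side)
          src <- if (ru$side == "out") 0L else cl$id
          fl <- bind_reagents(cfg, ru$consumed, src, site, r, taken)
          if (!is.null(fl)) emit(rule = ri, kind = "creation", cell = cl$id,
                                 slot = s, floats = fl)
        }
      } else if (ru$kind == "destruction") {
        if (!eval_guard(ru$guard %||% "none", cl)) next
        hit <- names(cl$occ)[!is.na(cl$occ) & cl$occ %in% ru$tile]
        for (s in hit) {
          site <- capture_site(tpl, cl, s, "in")
          fl <- bind_reagents(cfg, ru$consumed, cl$id, site, r, taken)
          if (!is.null(fl)) emit(rule = ri, kind = "destruction",
                                 cell = cl$id, slot = s, floats = fl)
        }
      } else if (ru$kind == "division") {
        if (division_ready(cl)) {
          emit(rule = ri, kind = "division", cell = cl$id, slot = NA_character_,
               floats = integer(0))
        }
      }
    }
  }
  out
}

cell_index <- function(cfg, id) {
  which(vapply(cfg$cells, `[[`, integer(1), "id") == id)
}

# Apply one bound instance; assumes availability was re-checked.
apply_instance <- function(cfg, sys, inst) {
  tpl <- sys$template
  ru <- sys$rules[[inst$rule]]
  ci <- cell_index(cfg, inst$cell)
  cl <- cfg$cells[[ci]]
  ledger_consume <- function(cfg, labels) {
    for (lab in labels) cfg$ledger$consumed[[lab]] <- cfg$ledger$consumed[[lab]] + 1
    cfg
  }
  ledger_produce <- function(cfg, labels) {
    for (lab in labels) cfg$ledger$produced[[lab]] <- cfg$ledger$produced[[lab]] + 1
    cfg
  }
  if (ru$kind == "metabolic") {
    site <- slot_world(tpl, cl, inst$slot)
    cfg <- ledger_consume(cfg, cfg$floats$label[inst$floats])
    cfg <- drop_floats(cfg, inst$floats)
    if (length(ru$produced)) {
      dest <- if (ru$produced_side == "in") cl$id else 0L
      inner <- cell_center(cl) + 0.5 * (site - cell_center(cl))
      ppos <- matrix(rep(inner, length(ru$produced)), ncol = 3, byrow = TRUE)
      cfg <- add_floats(cfg, ru$produced, ppos, rep(dest, length(ru$produced)))
      cfg <- ledger_produce(cfg, ru$produced)
    }
  } else if (ru$kind == "creation") {
    cfg <- ledger_consume(cfg, cfg$floats$label[inst$floats])
    cfg <- drop_floats(cfg, inst$floats)
    ci <- cell_index(cfg, inst$cell)
    cl <- cfg$cells[[ci]]
    cl$occ[inst$slot] <- ru$tile
    if (inst$slot %in% names(cl$protion_ok) &&
        length(sys$tile_specs[[ru$tile]]$protions)) {
      cl$protion_ok[inst$slot] <- TRUE
    }
    cfg$cells[[ci]] <- cl
  } else if (ru$kind == "destruction") {
    cfg <- ledger_consume(cfg, cfg$floats$label[inst$floats])
    cfg <- drop_floats(cfg, inst$floats)
    ci <- cell_index(cfg, inst$cell)
    cl <- cfg$cells[[ci]]
    site <- slot_world(tpl, cl, inst$slot)
    cl$occ[inst$slot] <- NA_character_
    if (inst$slot %in% names(cl$protion_ok)) cl$protion_ok[inst$slot] <- FALSE
    cfg$cells[[ci]] <- cl
    if (length(ru$produced)) {
      ppos <- matrix(rep(site, length(ru$produced)), ncol = 3, byrow = TRUE)
      cfg <- add_floats(cfg, ru$produced, ppos, rep(cl$id, length(ru$produced)))
      cfg <- ledger_produce(cfg, ru$produced)
    }
  } else if (ru$kind == "division") {
    cfg <- apply_division(cfg, inst, sys)
  }
  cfg
}

#' Apply a division instance
#'
#' Severs the septum interface of the target cell, yielding two closed
#' daughter compartments; every tile is retained and the cell count
#' increases by exactly one. If the trigger predicate does not hold the
#' configuration is returned unchanged with a warning.
#'
#' @param cfg Configuration.
#' @param instance An instance from [applicable_instances()] with
#'   `kind == "division"` (only its `cell` element is used).
#' @param sys The [msystem()].
#' @return The post-division configuration.
#' @export
apply_division <- function(cfg, instance, sys) {
  ci <- cell_index(cfg, instance$cell)
  if (!length(ci)) stop("no cell with id ", instance$cell, call. = FALSE)
  cl <- cfg$cells[[ci]]
  if (!division_ready(cl)) {
    warning("division trigger does not hold for cell ", cl$id,
            "; configuration unchanged")
    return(cfg)
  }
  tpl <- sys$template
  id_a <- cl$id                 # daughter A inherits the mother's id
  id_b <- cfg$next_cell_id
  daughters <- split_cell(tpl, cl, id_a, id_b)
  # clamp daughter anchors into the environment box
  lo <- sys$environment$bounds[1, ] + 1
  hi <- sys$environment$bounds[2, ] - 1
  for (k in 1:2) {
    daughters[[k]]$anchor$position <-
      pmin(pmax(daughters[[k]]$anchor$position, lo), hi)
  }
  # interior objects split by which side of the septum plane they lie on
  int_i <- which(cfg$floats$cell == cl$id)
  if (length(int_i)) {
    ax <- quat_to_matrix(cl$anchor$quaternion)[, 3]
    zloc <- as.numeric((cfg$floats$pos[int_i, , drop = FALSE] -
                          matrix(cell_center(cl), length(int_i), 3,
                                 byrow = TRUE)) %*% ax)
    to_b <- zloc > 0
    cfg$floats$cell[int_i[to_b]] <- id_b
    if (any(!to_b)) {
      shift_a <- matrix(cell_center(daughters[[1]]) - cell_center(cl),
                        sum(!to_b), 3, byrow = TRUE)
      cfg$floats$pos[int_i[!to_b], ] <-
        cfg$floats$pos[int_i[!to_b], , drop = FALSE] + shift_a
    }
    if (any(to_b)) {
      shift_b <- matrix(cell_center(daughters[[2]]) - cell_center(cl),
                        sum(to_b), 3, byrow = TRUE)
      cfg$floats$pos[int_i[to_b], ] <-
        cfg$floats$pos[int_i[to_b], , drop = FALSE] + shift_b
    }
  }
  cfg$cells[[ci]] <- daughters[[1]]
  cfg$cells[[length(cfg$cells) + 1]] <- daughters[[2]]
  cfg$next_cell_id <- cfg$next_cell_id + 1L
  cfg$n_divisions <- cfg$n_divisions + 1L
  cfg
}

# Spontaneous re-adhesion of severed bonds whose tiles are both present:
# glues still match and remain in contact, so agitation re-bonds them.
rebond_phase <- function(cfg, sys) {
  rate <- sys$template$rebond_rate
  for (ci in seq_along(cfg$cells)) {
    sv <- cfg$cells[[ci]]$severed
    if (!length(sv)) next
    ends <- strsplit(sv, "|", fixed = TRUE)
    present <- vapply(ends, function(e)
      !is.na(cfg$cells[[ci]]$occ[e[1]]) && !is.na(cfg$cells[[ci]]$occ[e[2]]),
      logical(1))
    heal <- present & stats::runif(length(sv)) < rate
    if (any(heal)) cfg$cells[[ci]]$severed <- sv[!heal]
  }
  cfg
}

#' Advance a configuration by one iteration
#'
#' One discrete time step: (1) Brownian displacement of every floating
#' object; (2) application of a maximal conflict-free subset of
#' applicable rule instances in uniformly random order, each object
#' consumed at most once and each placement slot filled at most once;
#' (3) environment nutrient injection up to the concentration target;
#' (4) iteration counter advanced by one.
#'
#' @param cfg Configuration.
#' @param sys The [msystem()].
#' @return The next configuration.
#' @export
ms_step <- function(cfg, sys) {
  cfg <- brownian_phase(cfg, sys)
  cfg <- rebond_phase(cfg, sys)
  insts <- applicable_instances(cfg, sys)
  if (length(insts)) {
    ord <- sample.int(length(insts))
    filled <- character(0)
    # Greedy conflict-free application. Float indices shift as floats are
    # consumed/produced, so instances are re-bound at application time.
    for (k in ord) {
      inst <- insts[[k]]
      ru <- sys$rules[[inst$rule]]
      ci <- cell_index(cfg, inst$cell)
      if (!length(ci)) next
      cl <- cfg$cells[[ci]]
      key <- paste(inst$cell, inst$slot, sep = "#")
      if (inst$kind == "creation") {
        if (key %in% filled) next
        if (!inst$slot %in% eligible_slots(sys$template, cl, ru)) next
      }
      if (inst$kind == "destruction") {
        if (key %in% filled) next
        if (is.na(cl$occ[inst$slot]) || !cl$occ[inst$slot] %in% ru$tile) next
        if (!eval_guard(ru$guard %||% "none", cl)) next
      }
      if (inst$kind == "metabolic") {
        if (!isTRUE(cl$protion_ok[inst$slot]) || is.na(cl$occ[inst$slot])) next
        if (ru$produced_side == "in" &&
            sum(cfg$floats$cell == cl$id) >= sys$template$interior_capacity) next
      }
      if (inst$kind == "division") {
        if (!division_ready(cl)) next
        cfg <- apply_instance(cfg, sys, inst)
        next
      }
      cap_side <- switch(inst$kind,
                         metabolic = ru$consumed_side,
                         creation = ru$side,
                         destruction = "in")
      site <- capture_site(sys$template, cl, inst$slot, cap_side)
      src <- switch(inst$kind,
                    metabolic = if (ru$consumed_side == "out") 0L else cl$id,
                    creation = if (ru$side == "out") 0L else cl$id,
                    destruction = cl$id)
      taken <- rep(FALSE, length(cfg$floats$label))
      fl <- bind_reagents(cfg, ru$consumed, src, site,
                          sys$interaction_radius, taken)
      if (is.null(fl)) next
      inst$floats <- fl
      cfg <- apply_instance(cfg, sys, inst)
      if (inst$kind %in% c("creation", "destruction")) filled <- c(filled, key)
    }
  }
  cfg <- inject_floats_env(cfg, sys)
  cfg$iteration <- cfg$iteration + 1L
  cfg
}

census_row <- function(cfg) {
  tibble::tibble(iteration = cfg$iteration,
                 cells = length(cfg$cells),
                 tiles = count_tiles(cfg),
                 a_count = float_count(cfg, "a"),
                 s_count = float_count(cfg, "s"))
}

#' Run an M system
#'
#' Simulates `n_iter` iterations from the initial (or a supplied)
#' configuration and records a per-iteration census. Deterministic given
#' `seed`.
#'
#' @param sys The [msystem()].
#' @param n_iter Number of iterations (>= 0); one iteration corresponds
#'   to one simulated minute.
#' @param seed Optional integer seed; when given, the run is bit
#'   reproducible.
#' @param cfg Optional starting configuration (default [ms_init()]).
#' @param stop_when Optional predicate `function(cfg)`; the run stops
#'   early when it first returns `TRUE` (used by injury experiments to
#'   detect a completed division).
#' @return A list of class `ms_trajectory` with elements `census` (a
#'   tibble with columns iteration, cells, tiles, a_count, s_count) and
#'   `final` (the final configuration).
#' @export
ms_run <- function(sys, n_iter, seed = NULL, cfg = NULL, stop_when = NULL) {
  if (n_iter < 0) stop("n_iter must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cfg)) cfg <- ms_init(sys)
  rows <- vector("list", n_iter + 1)
  rows[[1]] <- census_row(cfg)
  it <- 0L
  while (it < n_iter) {
    cfg <- ms_step(cfg, sys)
    it <- it + 1L
    rows[[it + 1]] <- census_row(cfg)
    if (!is.null(stop_when) && isTRUE(stop_when(cfg))) break
  }
  structure(list(census = dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))]),
                 final = cfg),
            class = "ms_trajectory")
}

#' @export
print.ms_trajectory <- function(x, ...) {
  last <- x$census[nrow(x$census), ]
  cat("<ms_trajectory>", nrow(x$census) - 1, "iterations;",
      "final census:", last$cells, "cells,", last$tiles, "tiles\n")
  invisible(x)
}
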