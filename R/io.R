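# Serialization: model documents (JSON dialect), census tables (CSV),
# transition digraphs (whitespace edge lists, GraphML), configuration
# snapshots (JSON, Wavefront OBJ), and named test fixtures.

pose_to_list <- function(p) {
  list(position = p$position, quaternion = p$quaternion)
}

pose_from_list <- function(l) pose(as.numeric(l$position),
                                   as.numeric(l$quaternion))

#' Serialize an M system to a model document
#'
#' @param sys An [msystem()].
#' @return A named list (the JSON document structure).
#' @export
model_document <- function(sys) {
  list(
    floating_objects = lapply(unname(sys$floating_specs), function(f)
      list(name = f$name, radius = f$radius, mobility = f$mobility,
           env_concentration = f$env_concentration)),
    glue_relation = apply(sys$glue_relation$pairs, 1, function(p)
      sort(unname(p)), simplify = FALSE),
    tiles = lapply(unname(sys$tile_specs), function(ts) list(
      name = ts$name,
      shape = list(kind = ts$shape$kind,
                   vertices = apply(ts$shape$vertices, 1, as.numeric,
                                    simplify = FALSE)),
      connectors = lapply(ts$connectors, function(co) list(
        site = apply(co$site, 1, as.numeric, simplify = FALSE),
        glue = co$glue, attach_angle = co$attach_angle)),
      protions = lapply(ts$protions, function(pr) list(
        name = pr$name, site = pr$site)))),
    rules = lapply(sys$rules, function(ru) unclass(ru)),
    environment = list(
      bounds = list(lower = sys$environment$bounds[1, ],
                    upper = sys$environment$bounds[2, ]),
      nutrient_budget = as.list(sys$environment$nutrient_budget),
      interaction_radius = sys$interaction_radius),
    seed_tiles = lapply(sys$seed_tiles, function(st)
      list(tile = st$tile, pose = pose_to_list(st$pose))),
    template = if (is.null(sys$template)) NULL else
      list(name = sys$template$name,
           interior_radius = sys$template$interior_radius,
           leak_rate = sys$template$leak_rate,
           rebond_rate = sys$template$rebond_rate)
  )
}

#' Write a model document to a JSON file
#'
#' @param sys An [msystem()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(sys, path) {
  jsonlite::write_json(model_document(sys), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

json_field <- function(doc, name, where) {
  if (is.null(doc[[name]])) {
    stop("model document: missing field '", where, "'", call. = FALSE)
  }
  doc[[name]]
}

#' Load an M system from a model JSON file
#'
#' Validation failures report the JSON path of the offending field.
#'
#' @param path Path to a model JSON written by [write_model()].
#' @return A validated [msystem()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path)
  floats <- lapply(json_field(doc, "floating_objects", "$.floating_objects"),
                   function(f) floating_spec(f$name, f$radius, f$mobility,
                                             f$env_concentration))
  gr_pairs <- json_field(doc, "glue_relation", "$.glue_relation")
  gr <- glue_relation(do.call(rbind, lapply(gr_pairs, unlist)))
  tiles <- lapply(json_field(doc, "tiles", "$.tiles"), function(ts) {
    shp <- tile_shape(ts$shape$kind,
                      do.call(rbind, lapply(ts$shape$vertices, unlist)))
    cons <- lapply(ts$connectors, function(co)
      connector(do.call(rbind, lapply(co$site, unlist)), co$glue,
                co$attach_angle))
    prs <- lapply(ts$protions, function(pr)
      protion_spec(pr$name, unlist(pr$site)))
    tile_spec(ts$name, shp, cons, prs)
  })
  rules <- lapply(seq_along(json_field(doc, "rules", "$.rules")), function(i) {
    ru <- doc$rules[[i]]
    at <- paste0("$.rules[", i, "]")
    kind <- ru$kind %||% stop("model document: missing field '", at, ".kind'",
                              call. = FALSE)
    switch(kind,
      metabolic = metabolic_rule(ru$protion, unlist(ru$consumed),
                                 unlist(ru$produced) %||% character(0),
                                 ru$consumed_side, ru$produced_side),
      creation = creation_rule(ru$tile, ru$at_glue, unlist(ru$consumed),
                               ru$side, ru$guard %||% "none"),
      destruction = destruction_rule(unlist(ru$tile),
                                     unlist(ru$consumed) %||% character(0),
                                     unlist(ru$produced) %||% character(0),
                                     ru$guard %||% "none"),
      division = division_rule(ru$trigger %||% "septum_complete"),
      stop("model document: unknown rule kind at '", at, "'", call. = FALSE))
  })
  envd <- json_field(doc, "environment", "$.environment")
  env <- list(bounds = rbind(unlist(envd$bounds$lower),
                             unlist(envd$bounds$upper)),
              nutrient_budget = unlist(envd$nutrient_budget) %||% numeric(0))
  seeds <- lapply(doc$seed_tiles, function(st)
    list(tile = st$tile, pose = pose_from_list(st$pose)))
  tpl <- if (!is.null(doc$template)) {
    if (!identical(doc$template$name, "capsule")) {
      stop("model document: unknown template '", doc$template$name,
           "' at '$.template.name'", call. = FALSE)
    }
    capsule_template(doc$template$interior_radius, doc$template$leak_rate,
                     doc$template$rebond_rate)
  } else NULL
  msystem(floats, tiles, gr, rules,
          interaction_radius = envd$interaction_radius,
          environment = env, seed_tiles = seeds, template = tpl)
}

#' Write / read a census table
#'
#' Fixed CSV columns: run, iteration, cells, tiles, a_count, s_count.
#'
#' @param census A census tibble.
#' @param path File path.
#' @return The census (read) or `path` invisibly (write).
#' @export
write_census <- function(census, path) {
  readr::write_csv(census, path)
  invisible(path)
}

#' @rdname write_census
#' @export
read_census <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a transition digraph as a whitespace edge list
#'
#' Format: one `from to` pair per line; a leading comment line
#' `# root: <id>` records the root; isolated nodes are listed on lines
#' of their own.
#'
#' @param g A [transition_digraph()].
#' @param path File path.
#' @return The digraph (read) or `path` invisibly (write).
#' @export
write_edgelist <- function(g, path) {
  iso <- setdiff(g$nodes, as.vector(g$arcs))
  lines <- c(paste("# root:", g$root),
             if (nrow(g$arcs)) paste(g$arcs[, 1], g$arcs[, 2]),
             iso)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  root <- NULL
  rl <- grepl("^# root:", lines)
  if (any(rl)) root <- trimws(sub("^# root:", "", lines[rl][1]))
  lines <- lines[!grepl("^#", lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  arcs <- do.call(rbind, parts[lengths(parts) == 2])
  iso <- unlist(parts[lengths(parts) == 1])
  if (is.null(arcs)) arcs <- matrix(character(0), ncol = 2)
  transition_digraph(arcs, nodes = unique(c(iso, as.vector(t(arcs)))),
                     root = root)
}

#' Write a transition digraph as GraphML
#'
#' @param g A [transition_digraph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' Export a configuration snapshot
#'
#' JSON carries the full state (cells, slot occupancy, floats); OBJ
#' carries one face per placed polygon tile (octagon faces at their slot
#' poses), suitable for external 3D rendering.
#'
#' @param cfg A configuration.
#' @param sys Its [msystem()].
#' @param path Output path.
#' @param format `"json"` or `"obj"`.
#' @return `path`, invisibly.
#' @export
export_snapshot <- function(cfg, sys, path, format = c("json", "obj")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      iteration = cfg$iteration,
      n_divisions = cfg$n_divisions,
      cells = lapply(cfg$cells, function(cl) list(
        id = cl$id, anchor = pose_to_list(cl$anchor),
        slots = as.list(cl$occ[!is.na(cl$occ)]),
        protions = as.list(cl$protion_ok),
        severed_bonds = cl$severed)),
      floats = list(label = cfg$floats$label,
                    cell = cfg$floats$cell,
                    pos = apply(cfg$floats$pos, 1, as.numeric,
                                simplify = FALSE)))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  # OBJ: one face per placed polygon tile
  lines <- c("# morphosys configuration snapshot")
  nv <- 0
  for (cl in cfg$cells) {
    for (s in names(cl$occ)[!is.na(cl$occ)]) {
      spec <- sys$tile_specs[[cl$occ[[s]]]]
      if (spec$shape$kind != "polygon2D") next
      ctr <- slot_world(sys$template, cl, s)
      vv <- sweep(spec$shape$vertices, 2, c(ctr - c(0, 0, 0)), "+")
      for (i in seq_len(nrow(vv))) {
        lines <- c(lines, paste("v", vv[i, 1], vv[i, 2], vv[i, 3]))
      }
      lines <- c(lines, paste(c("f", nv + seq_len(nrow(vv))), collapse = " "))
      nv <- nv + nrow(vv)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a named fixture
#'
#' Shipped fixtures: `"fig_single_hcomponent"` (a configuration space
#' whose nodes all belong to one h-component, including two nodes
#' unreachable from the root), `"fig_three_hcomponents"` (three 2-cycle
#' h-components below a 2-node morphogenetic phase),
#' `"fig_cycle_closure"` (the whole graph is the closure of one cycle),
#' `"toy_line3"` / `"toy_reversible"` (toy lattice systems), and
#' `"gompertz_demo"` (a noiseless synthetic Gompertz census with known
#' parameters A = 4, mu = 0.5, lambda = 10 in log-count units).
#'
#' @param name Fixture name.
#' @param dir Output directory (created if needed); when `NULL` the
#'   fixture object is returned without writing.
#' @return The fixture object (digraph, toy system or census tibble).
#' @export
make_fixture <- function(name, dir = NULL) {
  fx <- switch(name,
    fig_single_hcomponent = {
      # one big h-component: root cycle C0..C3 with offshoots C4-C6
      # re-entering, plus C7, C8 unreachable from the root but feeding in
      arcs <- rbind(c("C0", "C1"), c("C1", "C2"), c("C2", "C3"),
                    c("C3", "C0"), c("C2", "C4"), c("C4", "C5"),
                    c("C5", "C0"), c("C4", "C6"), c("C6", "C1"),
                    c("C7", "C8"), c("C8", "C2"))
      transition_digraph(arcs, root = "C0")
    },
    fig_three_hcomponents = {
      arcs <- rbind(c("C0", "C1"),
                    c("C1", "C2"), c("C1", "C4"), c("C1", "C6"),
                    c("C2", "C3"), c("C3", "C2"),
                    c("C4", "C5"), c("C5", "C4"),
                    c("C6", "C7"), c("C7", "C6"))
      transition_digraph(arcs, root = "C0")
    },
    fig_cycle_closure = {
      arcs <- rbind(c("C0", "C1"), c("C1", "C2"), c("C2", "C0"),
                    c("C2", "C3"), c("C3", "C4"), c("C4", "C0"))
      transition_digraph(arcs, root = "C0")
    },
    toy_line3 = toy_msystem(3, "attach"),
    toy_reversible = toy_msystem(2, c("attach", "detach")),
    gompertz_demo = {
      tt <- seq(0, 60, by = 2)
      y <- zw_gompertz(tt, A = 4, mu = 0.5, lambda = 10)
      growth_census(tibble::tibble(run = 1L, iteration = tt,
                                   cells = exp(y)))
    },
    stop("unknown fixture '", name, "'", call. = FALSE))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (inherits(fx, "transition_digraph")) {
      write_edgelist(fx, file.path(dir, paste0(name, ".edges")))
    } else if (inherits(fx, "growth_census")) {
      readr::write_csv(fx, file.path(dir, paste0(name, ".csv")))
    } else if (inherits(fx, "toy_msystem")) {
      jsonlite::write_json(unclass(fx), file.path(dir, paste0(name, ".json")),
                           auto_unbox = TRUE)
    }
  }
  fx
}

#' Run manifest
#'
#' Records everything needed to reproduce an emitted artifact
#' bit-for-bit: model hash, seed, iteration/run counts, package version.
#'
#' @param model_path Path of the model JSON used.
#' @param iterations,runs,seed Protocol numbers.
#' @param outputs Character vector of output paths.
#' @param species Optional species preset name.
#' @return A named list of class `run_manifest`.
#' @export
run_manifest <- function(model_path, iterations, runs, seed, outputs,
                         species = NULL) {
  hash <- if (file.exists(model_path)) {
    unname(tools::md5sum(model_path))
  } else NA_character_
  structure(list(model = model_path, model_md5 = hash,
                 iterations = iterations, runs = runs, seed = seed,
                 outputs = outputs, species = species,
                 package_version = as.character(utils::packageVersion("morphosys"))),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
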