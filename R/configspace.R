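# Graph-theoretic self-healing framework on configuration-space
# digraphs. Nodes are (equivalence classes of) configurations; arcs are
# one-rule transitions. The configuration space may contain nodes
# unreachable from the root that still feed into it.
#
# The homeostatic phase is built inductively: the transitive closure of
# every directed cycle seeds an h-component (overlapping closures
# merge); every leaf node seeds an h-component; and every node whose
# transitive closure intersects exactly one h-component joins that
# component. Nodes left over form the morphogenetic phase. Once entered,
# an h-component cannot be exited by following arcs.

#' Construct a transition digraph
#'
#' @param arcs Two-column character matrix (or data frame) of directed
#'   arcs `(from, to)`.
#' @param nodes Optional character vector of node ids (defaults to the
#'   ids appearing in `arcs`); isolated nodes must be listed here.
#' @param root Root node id (the initial configuration); defaults to the
#'   first node.
#' @return An object of class `transition_digraph`.
#' @examples
#' g <- transition_digraph(rbind(c("C0", "C1"), c("C1", "C0")))
#' @export
transition_digraph <- function(arcs, nodes = NULL, root = NULL) {
  arcs <- as.matrix(arcs)
  if (length(arcs) == 0) arcs <- matrix(character(0), ncol = 2)
  storage.mode(arcs) <- "character"
  stopifnot(ncol(arcs) == 2)
  nodes <- unique(c(nodes, as.vector(t(arcs))))
  if (!length(nodes)) stop("digraph needs at least one node", call. = FALSE)
  root <- root %||% nodes[1]
  if (!root %in% nodes) stop("root must be a declared node", call. = FALSE)
  if (!all(arcs %in% nodes)) stop("arcs reference undeclared nodes", call. = FALSE)
  structure(list(nodes = nodes, arcs = arcs, root = root),
            class = "transition_digraph")
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$arcs, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
}

#' @export
print.transition_digraph <- function(x, ...) {
  cat("<transition_digraph>", length(x$nodes), "nodes,", nrow(x$arcs),
      "arcs, root", x$root, "\n")
  invisible(x)
}

#' Homeostatic decomposition of a transition digraph
#'
#' Computes the fixpoint of the three inductive clauses: cycle closures
#' seed h-components (overlapping closures merged), leaves seed
#' singleton h-components, and nodes whose descendant set intersects a
#' single h-component are absorbed into it. Remaining nodes form the
#' morphogenetic phase.
#'
#' @param g A [transition_digraph()].
#' @return An object of class `ms_decomposition`: a list with
#'   `h_components` (list of disjoint node-id vectors), `morphogenetic`
#'   (node-id vector) and `membership` (named integer, 0 for
#'   morphogenetic nodes).
#' @examples
#' g <- transition_digraph(rbind(c("C0", "C1"),
#'                               c("C1", "C2"), c("C2", "C3"), c("C3", "C2")))
#' decompose_digraph(g)
#' @export
decompose_digraph <- function(g) {
  ig <- as_igraph(g)
  n <- length(g$nodes)
  comp_of <- stats::setNames(rep(NA_integer_, n), g$nodes)
  next_id <- 1L

  # cyclic strongly connected components (size > 1 or with a self-loop)
  scc <- igraph::components(ig, mode = "strong")
  loops <- unique(igraph::ends(ig, igraph::E(ig))[
    igraph::which_loop(ig), 1])
  for (k in seq_len(scc$no)) {
    members <- g$nodes[scc$membership == k]
    cyclic <- length(members) > 1 || members[1] %in% loops
    if (!cyclic) next
    closure <- g$nodes[igraph::subcomponent(ig, members[1], mode = "out")]
    ids <- unique(stats::na.omit(comp_of[closure]))
    id <- if (length(ids)) ids[1] else { next_id <- next_id + 1L; next_id - 1L }
    comp_of[closure] <- id
    # overlapping closures merge into one component
    for (other in setdiff(ids, id)) comp_of[comp_of == other] <- id
  }
  # leaves
  outdeg <- igraph::degree(ig, mode = "out", loops = TRUE)
  for (v in g$nodes[outdeg == 0]) {
    if (is.na(comp_of[v])) {
      comp_of[v] <- next_id
      next_id <- next_id + 1L
    }
  }
  # absorption: unassigned nodes lie in trivial acyclic SCCs, so the
  # condensation order is a topological order; walk it leaf-to-root and
  # join a node to the unique component among its successors' results
  # (morphogenetic as soon as two distinct components are reachable)
  MORPHO <- -1L
  adj <- igraph::adjacent_vertices(ig, igraph::V(ig), mode = "out")
  names(adj) <- g$nodes
  # Every unassigned node lies in a trivial acyclic SCC, so repeatedly
  # resolving nodes whose successors are all resolved terminates (every
  # maximal path ends in a cycle or a leaf, both already seeded).
  repeat {
    changed <- FALSE
    for (v in g$nodes[is.na(comp_of)]) {
      succ <- setdiff(g$nodes[as.integer(adj[[v]])], v)
      ids <- unique(comp_of[succ])
      if (any(is.na(ids))) next
      comp_of[v] <- if (length(ids) == 1 && ids[1] != MORPHO) ids[1] else MORPHO
      changed <- TRUE
    }
    if (!changed) break
  }
  comp_of[is.na(comp_of)] <- MORPHO
  hc <- split(names(comp_of)[comp_of > 0], comp_of[comp_of > 0])
  names(hc) <- NULL
  membership <- comp_of
  membership[membership == MORPHO] <- 0L
  # renumber components 1..k in node order
  hc <- hc[order(vapply(hc, function(x) min(match(x, g$nodes)), integer(1)))]
  for (k in seq_along(hc)) membership[hc[[k]]] <- k
  structure(list(h_components = hc,
                 morphogenetic = names(membership)[membership == 0],
                 membership = membership),
            class = "ms_decomposition")
}

#' @export
print.ms_decomposition <- function(x, ...) {
  cat("<ms_decomposition>", length(x$h_components), "h-component(s);",
      length(x$morphogenetic), "morphogenetic node(s)\n")
  invisible(x)
}

#' Injury degree: undirected distance between two configurations
#'
#' @param g A [transition_digraph()].
#' @param x,y Node ids.
#' @return Integer path length; `Inf` when disconnected.
#' @export
injury_degree <- function(g, x, y) {
  if (!x %in% g$nodes || !y %in% g$nodes) {
    stop("unknown node(s): ", paste(setdiff(c(x, y), g$nodes), collapse = ", "),
         call. = FALSE)
  }
  d <- igraph::distances(as_igraph(g), v = x, to = y, mode = "all")
  as.numeric(d[1, 1])
}

#' Is an injury sustainable?
#'
#' An injury `(x, y)` is sustainable iff both endpoints belong to the
#' same h-component.
#'
#' @param dec A [decompose_digraph()] result.
#' @param x,y Node ids.
#' @return Logical.
#' @export
is_sustainable <- function(dec, x, y) {
  mx <- dec$membership[x]
  my <- dec$membership[y]
  if (is.na(mx) || is.na(my)) {
    stop("unknown node(s) in decomposition", call. = FALSE)
  }
  mx > 0 && mx == my
}

#' Self-healing degree of a configuration space
#'
#' The system is self-healing of degree `m` if it sustains a random
#' injury of degree at most `m` to a uniformly random homeostatic node
#' with probability at least 0.5 (and self-healing of any degree when
#' that holds without a distance bound). The random-injury model draws
#' the landing configuration uniformly among homeostatic nodes within
#' undirected distance `m` of the injured node (all homeostatic nodes,
#' connected or not, in the unbounded case); with two equal disjoint
#' h-components this sits exactly on the 0.5 boundary, which is
#' reported with `tie = TRUE`. Exact enumeration is used up to 1000
#' nodes, Monte Carlo sampling beyond.
#'
#' @param g A [transition_digraph()].
#' @param dec Its decomposition.
#' @param max_m Largest degree to examine.
#' @param n_samples Monte Carlo sample count for large graphs.
#' @return A list: `self_healing` (logical; FALSE with `degree = NA`
#'   when the homeostatic phase is empty), `degree` (largest m with
#'   sustain probability >= 0.5, `Inf` when the system is self-healing
#'   of any degree, 0 when not even degree 1 is sustained), `any_degree`
#'   logical, `tie` (TRUE when some probability equals 0.5 exactly), and
#'   `prob` (tibble of degree, sustain probability).
#' @export
self_healing_degree <- function(g, dec, max_m = NULL, n_samples = 10000) {
  hnodes <- names(dec$membership)[dec$membership > 0]
  if (!length(hnodes)) {
    return(list(self_healing = FALSE, degree = NA_real_, any_degree = FALSE,
                tie = FALSE, prob = tibble::tibble(degree = numeric(0),
                                                   p_sustain = numeric(0))))
  }
  ig <- as_igraph(g)
  D <- igraph::distances(ig, v = hnodes, to = hnodes, mode = "all")
  finite_max <- suppressWarnings(max(D[is.finite(D) & D > 0], 0))
  max_m <- max_m %||% max(finite_max, 1)
  ms <- seq_len(max_m)
  exact <- length(g$nodes) <= 1000
  p_of <- function(i, elig) {
    if (!length(elig)) return(1)  # no possible landing: vacuously sustained
    if (exact) {
      mean(dec$membership[elig] == dec$membership[hnodes[i]])
    } else {
      smp <- sample(elig, min(length(elig),
                              ceiling(n_samples / length(hnodes))),
                    replace = TRUE)
      mean(dec$membership[smp] == dec$membership[hnodes[i]])
    }
  }
  p_m <- vapply(ms, function(m) {
    mean(vapply(seq_along(hnodes), function(i)
      p_of(i, hnodes[D[i, ] <= m]), numeric(1)))
  }, numeric(1))
  # unbounded degree: landing uniform over the whole homeostatic phase
  p_any <- mean(vapply(seq_along(hnodes), function(i)
    p_of(i, hnodes), numeric(1)))
  tol <- 1e-12
  any_degree <- p_any >= 0.5 - tol
  degree <- if (any_degree) Inf else if (any(p_m >= 0.5 - tol)) max(ms[p_m >= 0.5 - tol]) else 0
  list(self_healing = degree > 0,
       degree = degree,
       any_degree = any_degree,
       tie = any(abs(c(p_m, p_any) - 0.5) <= tol),
       prob = tibble::tibble(degree = c(ms, Inf), p_sustain = c(p_m, p_any)))
}

#' Dominating h-component criterion
#'
#' A system whose largest h-component occupies at least 71% of all nodes
#' in its configuration space is self-healing of any degree: a random
#' homeostatic node lies in the dominating component with probability at
#' least 0.71, an injury lands there independently with the same bound,
#' and 0.71^2 > 0.5.
#'
#' @param dec A decomposition.
#' @return Logical: does the dominating-component criterion hold?
#' @export
proposition1_holds <- function(dec) {
  n <- length(dec$membership)
  if (!length(dec$h_components)) return(FALSE)
  biggest <- max(lengths(dec$h_components))
  biggest / n >= 0.71
}

#' Smallest dominating percentage guaranteeing self-healing
#'
#' The smallest integer percentage p such that (p/100)^2 > 0.5.
#'
#' @return 71.
#' @export
proposition1_threshold <- function() {
  p <- 1
  while (!((p / 100)^2 > 0.5)) p <- p + 1
  p
}

# ---- Toy discrete systems and configuration-space enumeration ----------

#' Toy discrete M system on a line of slots
#'
#' Finite-state stand-in used to enumerate configuration spaces exactly:
#' tiles occupy slots on a 1D line, an `attach` rule fills any empty
#' slot adjacent to an occupied one, a `detach` rule removes any
#' occupied endpoint (a slot with at most one occupied neighbour) as
#' long as at least one tile remains.
#'
#' @param n_slots Number of slots (>= 1).
#' @param rules Character subset of `c("attach", "detach")`.
#' @param root_slots Initially occupied slot indices (default slot 1).
#' @return An object of class `toy_msystem`.
#' @export
toy_msystem <- function(n_slots, rules = "attach", root_slots = 1) {
  stopifnot(n_slots >= 1, all(rules %in% c("attach", "detach")),
            all(root_slots %in% seq_len(n_slots)))
  structure(list(n_slots = n_slots, rules = rules, root_slots = root_slots),
            class = "toy_msystem")
}

toy_state_id <- function(occ) paste(as.integer(occ), collapse = "")

toy_successors <- function(toy, occ) {
  n <- toy$n_slots
  out <- list()
  if ("attach" %in% toy$rules) {
    for (i in seq_len(n)) {
      if (occ[i]) next
      nb <- c(if (i > 1) occ[i - 1], if (i < n) occ[i + 1])
      if (any(nb)) {
        s <- occ; s[i] <- TRUE
        out[[length(out) + 1]] <- s
      }
    }
  }
  if ("detach" %in% toy$rules && sum(occ) >= 2) {
    for (i in seq_len(n)) {
      if (!occ[i]) next
      nb <- c(if (i > 1) occ[i - 1], if (i < n) occ[i + 1])
      if (sum(nb) <= 1) {
        s <- occ; s[i] <- FALSE
        out[[length(out) + 1]] <- s
      }
    }
  }
  out
}

#' Enumerate the configuration space of a toy system
#'
#' Breadth-first search over one-rule transitions from the root state,
#' merging equivalent configurations (identical occupancy) into unique
#' nodes. Extra off-path nodes and arcs (the inverse-closure part of the
#' space) may be supplied by the caller.
#'
#' @param toy A [toy_msystem()].
#' @param depth_cap Maximum BFS depth; if reached the returned graph is
#'   flagged partial (`attr(g, "partial")`).
#' @param extra_arcs Optional two-column matrix of additional arcs.
#' @return A [transition_digraph()] rooted at the initial state.
#' @export
enumerate_configspace <- function(toy, depth_cap = 10000,
                                  extra_arcs = NULL) {
  occ0 <- rep(FALSE, toy$n_slots)
  occ0[toy$root_slots] <- TRUE
  root <- toy_state_id(occ0)
  seen <- stats::setNames(list(occ0), root)
  frontier <- list(occ0)
  arcs <- list()
  depth <- 0
  partial <- FALSE
  while (length(frontier)) {
    if (depth >= depth_cap) { partial <- TRUE; break }
    nxt <- list()
    for (occ in frontier) {
      from <- toy_state_id(occ)
      for (s in toy_successors(toy, occ)) {
        to <- toy_state_id(s)
        arcs[[length(arcs) + 1]] <- c(from, to)
        if (is.null(seen[[to]])) {
          seen[[to]] <- s
          nxt[[length(nxt) + 1]] <- s
        }
      }
    }
    frontier <- nxt
    depth <- depth + 1
  }
  am <- if (length(arcs)) unique(do.call(rbind, arcs)) else matrix(character(0), ncol = 2)
  if (!is.null(extra_arcs)) am <- unique(rbind(am, as.matrix(extra_arcs)))
  g <- transition_digraph(am, nodes = names(seen), root = root)
  attr(g, "partial") <- partial
  g
}
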