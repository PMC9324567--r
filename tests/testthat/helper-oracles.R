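# Shared test helpers: a random digraph generator and a brute-force
# h-component decomposition oracle that literally iterates the three
# inductive clauses (independent of the package implementation and of
# igraph).

random_digraph <- function(n, p, labels = paste0("n", seq_len(n))) {
  arcs <- which(matrix(stats::runif(n * n) < p, n, n) &
                  !diag(TRUE, n), arr.ind = TRUE)
  m <- cbind(labels[arcs[, 1]], labels[arcs[, 2]])
  transition_digraph(if (nrow(m)) m else matrix(character(0), ncol = 2),
                     nodes = labels, root = labels[1])
}

# Reachability (including self) by plain BFS on an adjacency list.
brute_desc <- function(adj, v) {
  seen <- v
  queue <- v
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (y in adj[[x]]) {
      if (!y %in% seen) { seen <- c(seen, y); queue <- c(queue, y) }
    }
  }
  seen
}

# Literal three-clause fixpoint: cycle closures (merged on overlap),
# leaf singletons, then absorption of nodes whose descendant set meets
# exactly one component.
oracle_decompose <- function(g) {
  nodes <- g$nodes
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    unique(g$arcs[g$arcs[, 1] == v, 2]))
  desc <- lapply(stats::setNames(nodes, nodes), function(v) brute_desc(adj, v))
  on_cycle <- vapply(nodes, function(v)
    any(vapply(adj[[v]], function(y) v %in% desc[[y]], logical(1))) ||
      v %in% adj[[v]], logical(1))
  comps <- list()
  for (v in nodes[on_cycle]) comps[[length(comps) + 1]] <- desc[[v]]
  # merge overlapping closures until disjoint
  repeat {
    merged <- FALSE
    for (i in seq_along(comps)) {
      for (j in seq_along(comps)) {
        if (j <= i) next
        if (length(intersect(comps[[i]], comps[[j]]))) {
          comps[[i]] <- union(comps[[i]], comps[[j]])
          comps[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  assigned <- unlist(comps)
  for (v in nodes) {
    if (!length(adj[[v]]) && !v %in% assigned) {
      comps[[length(comps) + 1]] <- v
      assigned <- c(assigned, v)
    }
  }
  repeat {
    changed <- FALSE
    for (v in setdiff(nodes, assigned)) {
      hits <- which(vapply(comps, function(cc)
        length(intersect(desc[[v]], cc)) > 0, logical(1)))
      if (length(hits) == 1) {
        comps[[hits]] <- c(comps[[hits]], v)
        assigned <- c(assigned, v)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(h_components = comps, morphogenetic = setdiff(nodes, assigned))
}

# Canonical form of a partition for comparison.
partition_key <- function(h_components, morphogenetic) {
  comps <- lapply(h_components, function(x) sort(unlist(x)))
  comps <- comps[order(vapply(comps, `[`, character(1), 1))]
  list(comps = comps, morpho = sort(morphogenetic))
}

# A fast unlimited-nutrient bacterial test system.
mbac_test_system <- function(unlimited = TRUE, budget = 720) {
  p <- mbac_preset("ecoli")
  if (!unlimited) p$nutrient_budget <- budget
  build_mbac(p, unlimited_nutrients = unlimited)
}
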