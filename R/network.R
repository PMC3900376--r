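# Thresholded force-difference network: residues are nodes, an edge connects
# two residues when some spanning atom pair (default) carries a force
# difference strictly above the cutoff. The component of interest is the one
# with the largest vertex count; the cutoff is chosen by scanning for the
# largest value that keeps every source connected to every target.

#' Build the force-difference graph
#'
#' A residue pair becomes an edge iff its force difference exceeds the cutoff
#' strictly. In `"atomic_max"` mode (default) the residue pair is thresholded
#' on the maximum |dF_ij| over spanning atom pairs, which is also the edge
#' weight; `"residue_sum"` mode thresholds on |sum of signed dF_ij|.
#'
#' @param diff a `force_difference`.
#' @param residues integer residue index per atom.
#' @param cutoff_pn force cutoff in pN (edges require weight > cutoff).
#' @param mode edge rule, see above.
#' @param min_separation optional minimum |u - v| sequence separation for an
#'   edge (0 = no filter, the default).
#' @return an igraph graph with integer residue ids as vertex names and a
#'   `weight_pn` edge attribute; cutoff and mode stored as graph attributes.
#' @export
build_force_graph <- function(diff, residues, cutoff_pn = 90,
                              mode = c("atomic_max", "residue_sum"),
                              min_separation = 0) {
  mode <- match.arg(mode)
  stopifnot(cutoff_pn >= 0)
  if (length(residues) != attr(diff, "n_atoms")) {
    stop("residue map length must equal the atom count of the difference")
  }
  ru <- residues[diff$i]
  rv <- residues[diff$j]
  keep <- which(ru != rv)
  key <- paste(pmin(ru, rv), pmax(ru, rv))[keep]
  if (length(keep)) {
    val <- if (mode == "atomic_max") {
      tapply(abs(diff$delta_pn[keep]), key, max)
    } else {
      abs(tapply(diff$delta_pn[keep], key, sum))
    }
    uv <- do.call(rbind, strsplit(names(val), " "))
    u <- as.integer(uv[, 1]); v <- as.integer(uv[, 2])
  } else {
    val <- numeric(); u <- integer(); v <- integer()
  }
  sel <- as.vector(val) > cutoff_pn
  if (min_separation > 0) sel <- sel & (abs(u - v) >= min_separation)
  nodes <- sort(unique(residues))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(nodes))
  if (any(sel)) {
    g <- igraph::add_edges(g, rbind(as.character(u[sel]), as.character(v[sel])),
                           attr = list(weight_pn = as.vector(val)[sel]))
  }
  g <- igraph::set_graph_attr(g, "cutoff_pn", cutoff_pn)
  igraph::set_graph_attr(g, "mode", mode)
}

graph_nodes <- function(g) as.integer(igraph::V(g)$name)

#' Largest connected component by vertex count
#'
#' Isolated vertices do not form a component of interest; among components
#' with at least one edge (or, failing that, all components), the one with
#' the maximal vertex count wins, ties broken by the smallest minimum residue
#' index.
#'
#' @param graph graph from [build_force_graph()].
#' @return list with `graph` (induced subgraph), `nodes` (integer residue
#'   ids) and `vertex_count`.
#' @export
largest_component <- function(graph) {
  comp <- igraph::components(graph)
  deg <- igraph::degree(graph)
  sizes <- comp$csize
  has_edge <- vapply(seq_along(sizes), function(cc) {
    any(deg[comp$membership == cc] > 0)
  }, logical(1))
  cand <- if (any(has_edge)) which(has_edge) else integer()
  if (!length(cand)) {
    return(list(graph = igraph::make_empty_graph(0, directed = FALSE),
                nodes = integer(), vertex_count = 0L))
  }
  best_size <- max(sizes[cand])
  tied <- cand[sizes[cand] == best_size]
  min_node <- vapply(tied, function(cc) {
    min(as.integer(igraph::V(graph)$name[comp$membership == cc]))
  }, integer(1))
  win <- tied[which.min(min_node)]
  vids <- which(comp$membership == win)
  sub <- igraph::induced_subgraph(graph, vids)
  list(graph = sub, nodes = sort(graph_nodes(sub)),
       vertex_count = as.integer(best_size))
}

#' Scan force cutoffs for source-to-target connectivity
#'
#' For each cutoff on the grid, builds the graph, takes the largest
#' component, and tests whether every source residue reaches every target
#' residue inside it. The recommended cutoff is the largest grid value at
#' which full connectivity holds; if none, the result is flagged broken.
#'
#' @param diff a `force_difference`.
#' @param residues residue index per atom.
#' @param sources,targets integer residue sets.
#' @param grid increasing numeric cutoff grid, pN.
#' @param mode edge rule, see [build_force_graph()].
#' @return list with `table` (cutoff, vertex_count, n_components, n_spurious,
#'   connected), `recommended` (pN or NA), `broken`.
#' @export
scan_cutoffs <- function(diff, residues, sources, targets,
                         grid = seq(30, 240, by = 30),
                         mode = "atomic_max") {
  if (!length(grid) || !length(sources) || !length(targets)) {
    stop("grid, sources and targets must be nonempty")
  }
  grid <- sort(grid)
  rows <- lapply(grid, function(cutoff) {
    g <- build_force_graph(diff, residues, cutoff, mode = mode)
    lc <- largest_component(g)
    deg <- igraph::degree(g)
    comp <- igraph::components(g)
    with_edges <- unique(comp$membership[deg > 0])
    connected <- length(lc$nodes) > 0 && all(sources %in% lc$nodes) &&
      all(targets %in% lc$nodes) &&
      all(vapply(sources, function(s) {
        all(is.finite(igraph::distances(lc$graph, as.character(s),
                                        as.character(targets))))
      }, logical(1)))
    data.frame(cutoff_pn = cutoff, vertex_count = lc$vertex_count,
               n_components = length(with_edges),
               n_spurious = max(0L, length(with_edges) - 1L),
               connected = connected)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$cutoff_pn[tab$connected]
  list(table = tab,
       recommended = if (length(ok)) max(ok) else NA_real_,
       broken = !length(ok))
}

#' Extract shortest source-to-target pathways
#'
#' All hop-count shortest paths from each source residue to its nearest
#' reachable target(s); unreachable source/target pairs are listed
#' separately.
#'
#' @param graph graph from [build_force_graph()] (or a component subgraph).
#' @param sources,targets integer residue sets.
#' @return list with `paths` (list of integer residue chains), `hops` (named
#'   by "source->target"), `unreachable` (data.frame source, target).
#' @export
extract_pathways <- function(graph, sources, targets) {
  nodes <- graph_nodes(graph)
  paths <- list(); hops <- numeric(); unreach <- list()
  for (s in sources) {
    reach_t <- intersect(targets, nodes)
    d <- if (s %in% nodes && length(reach_t)) {
      drop(igraph::distances(graph, as.character(s), as.character(reach_t)))
    } else numeric()
    d <- stats::setNames(as.numeric(d), reach_t)
    finite <- d[is.finite(d)]
    for (t in setdiff(targets, as.integer(names(finite)))) {
      unreach[[length(unreach) + 1L]] <- data.frame(source = s, target = t)
    }
    if (!length(finite)) next
    nearest <- as.integer(names(finite)[finite == min(finite)])
    for (t in nearest) {
      sp <- igraph::all_shortest_paths(graph, as.character(s),
                                       as.character(t))$vpaths
      for (p in sp) {
        chain <- as.integer(igraph::V(graph)$name[p])
        paths[[length(paths) + 1L]] <- chain
        hops[paste0(s, "->", t)] <- length(chain) - 1L
      }
    }
  }
  list(paths = paths, hops = hops,
       unreachable = if (length(unreach)) do.call(rbind, unreach) else
         data.frame(source = integer(), target = integer()))
}

#' Graph edge list as a data.frame
#' @param graph graph from [build_force_graph()].
#' @return data.frame (u, v, weight_pn).
#' @export
graph_edge_list <- function(graph) {
  e <- igraph::as_edgelist(graph)
  data.frame(u = as.integer(e[, 1]), v = as.integer(e[, 2]),
             weight_pn = if (igraph::ecount(graph))
               igraph::E(graph)$weight_pn else numeric())
}
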