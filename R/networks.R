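# Emergent information-diffusion networks built from exchange events:
# directed multigraphs whose nodes are agents and whose edges are
# individual exchange events.

#' Build a diffusion network from exchange events
#'
#' One directed edge per exchange event with `hour` in the half-open
#' window `[hour_start, hour_end)`; nodes appear only through events
#' (isolated agents are excluded).
#'
#' @param events exchange-event table (`hour`, `giver_id`, `receiver_id`,
#'   `place_id`, `resource_id`)
#' @param window numeric `c(hour_start, hour_end)`, half-open
#' @return a `crx_network` list with the igraph `graph` and the edge table
#' @export
build_network <- function(events, window = c(0, Inf)) {
  if (window[2] <= window[1]) abort_config("inverted or empty window")
  ev <- as.data.table(events)
  ev <- ev[hour >= window[1] & hour < window[2]]
  if (nrow(ev) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    verts <- sort(unique(c(ev$giver_id, ev$receiver_id)))
    g <- igraph::graph_from_data_frame(
      ev[, .(from = as.character(giver_id), to = as.character(receiver_id),
             hour, place_id, resource_id)],
      directed = TRUE, vertices = data.frame(name = as.character(verts)))
  }
  structure(list(graph = g, edges = ev, window = window),
            class = "crx_network")
}

#' @export
print.crx_network <- function(x, ...) {
  cat(sprintf("<crx_network> %d nodes, %d edges (hours [%s, %s))\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              format(x$window[1]), format(x$window[2])))
  invisible(x)
}

#' Total-degree distribution of a diffusion network
#'
#' Total degree is in-degree plus out-degree per node (multi-edges each
#' count); the distribution sums to the node count.
#' @param net a `crx_network`
#' @return data.table (`degree`, `n_nodes`)
#' @export
degree_distribution <- function(net) {
  if (igraph::vcount(net$graph) == 0L)
    return(data.table(degree = integer(), n_nodes = integer()))
  deg <- igraph::degree(net$graph, mode = "all", loops = TRUE)
  tb <- table(deg)
  data.table(degree = as.integer(names(tb)), n_nodes = as.integer(tb))
}

#' Summary statistics of a diffusion network
#' @param net a `crx_network`
#' @return one-row data.table: node and edge counts, mean and max total
#'   degree, weak component count
#' @export
network_summary <- function(net) {
  g <- net$graph
  nv <- as.integer(igraph::vcount(g))
  ne <- as.integer(igraph::ecount(g))
  deg <- if (nv) igraph::degree(g, mode = "all") else numeric()
  data.table(n_nodes = nv, n_edges = ne,
             mean_degree = if (nv) mean(deg) else NA_real_,
             max_degree = if (nv) max(deg) else NA_integer_,
             n_components = if (nv) igraph::count_components(g, mode = "weak")
                            else 0L)
}

#' Attach a node attribute and optionally induce per-stratum subgraphs
#'
#' @param net a `crx_network`
#' @param agents agent table resolving every node id
#' @param attribute one of the agent columns, or `"age_band"`
#' @param induce return induced subgraphs per stratum
#' @return the network with the attribute attached (and `$strata`, a named
#'   list of induced `crx_network`s, when `induce = TRUE`)
#' @export
stratify_network <- function(net, agents, attribute = "age_band",
                             induce = FALSE) {
  ids <- as.integer(igraph::V(net$graph)$name)
  if (length(ids)) {
    i <- match(ids, agents$agent_id)
    if (anyNA(i)) abort_config("network node missing from agent table")
    val <- if (attribute == "age_band") as.character(age_band(agents$age[i]))
           else if (attribute %in% names(agents)) as.character(agents[[attribute]][i])
           else abort_config("unknown attribute '%s'", attribute)
    net$graph <- igraph::set_vertex_attr(net$graph, attribute, value = val)
  } else val <- character()
  if (induce) {
    net$strata <- lapply(split(seq_along(ids), val), function(sel) {
      sub <- igraph::induced_subgraph(net$graph, sel)
      keep_ids <- ids[sel]
      structure(list(graph = sub,
                     edges = net$edges[giver_id %in% keep_ids &
                                         receiver_id %in% keep_ids],
                     window = net$window),
                class = "crx_network")
    })
  }
  net
}

#' Export the edge list as CSV
#' @param net a `crx_network`
#' @param path output path
#' @param simplify collapse repeated giver-receiver pairs into one row with
#'   an `n_events` count (the multigraph is the default representation)
#' @return invisibly, `path`
#' @export
write_edgelist <- function(net, path, simplify = FALSE) {
  ev <- net$edges
  if (simplify)
    ev <- ev[, .(n_events = .N), by = .(giver_id, receiver_id)]
  data.table::fwrite(ev, path)
  invisible(path)
}

#' Export the network as GraphML (with any attached node attributes)
#' @param net a `crx_network`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
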