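#' Build the cluster transition network at one resolution
#'
#' An edge between two conformational substates counts the consecutive-frame
#' pairs (within a trajectory; never across trajectory boundaries) whose keys
#' differ. Edges are undirected with summed counts by default; with
#' `directed = TRUE` direction is retained. Each edge is classified
#' `intra_parent` when both endpoints merge to the same cluster at the next
#' coarser resolution, `inter_parent` otherwise.
#'
#' @param hierarchy A `cluster_hierarchy`.
#' @param resolution Band at which to build the network.
#' @param directed Keep transition direction? Default `FALSE`.
#' @return An object of class `transition_network`: `nodes` (key, W, count,
#'   N_conn, degree, harbors_reference), `edges` (from, to, count, class),
#'   `resolution`, `directed`.
#' @export
build_network <- function(hierarchy, resolution, directed = FALSE) {
  tab <- hierarchy$tables[[resolution]]
  if (is.null(tab)) stop("resolution ", resolution, " not in hierarchy")
  fk <- hierarchy$frame_keys
  keys <- fk[[resolution]]
  tid <- fk$trajectory_id
  n <- length(keys)
  same_traj <- tid[-n] == tid[-1]
  changed <- keys[-n] != keys[-1]
  sel <- same_traj & changed
  from <- keys[-n][sel]
  to <- keys[-1][sel]
  if (!directed && length(from)) {
    a <- pmin(from, to); b <- pmax(from, to)
    from <- a; to <- b
  }
  edges <- tibble::tibble(from = from, to = to) |>
    dplyr::count(.data$from, .data$to, name = "count")
  # classify against the coarser level via the parent mapping
  pmap <- stats::setNames(tab$parent_key, as.character(tab$key))
  edges$class <- ifelse(
    pmap[as.character(edges$from)] == pmap[as.character(edges$to)],
    "intra_parent", "inter_parent")
  conn <- tibble::tibble(key = c(edges$from, edges$to),
                         count = rep(edges$count, 2)) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(N_conn = sum(.data$count), degree = dplyr::n(),
                     .groups = "drop")
  nodes <- tab |>
    dplyr::left_join(conn, by = "key") |>
    dplyr::mutate(N_conn = dplyr::coalesce(.data$N_conn, 0L),
                  degree = dplyr::coalesce(.data$degree, 0L),
                  N_conn_over_W = .data$N_conn / .data$W)
  structure(list(nodes = nodes, edges = edges, resolution = resolution,
                 directed = directed,
                 n_pairs = sum(same_traj)),
            class = "transition_network")
}

#' Build a transition network directly from a frame key series
#'
#' Lower-level companion of [build_network()] for key series that do not come
#' from a cluster hierarchy (no parent level is available, so edges are
#' classified `"unclassified"`).
#'
#' @param trajectory_id Trajectory id per frame.
#' @param keys Cluster key per frame (frames ordered within trajectory).
#' @param directed Keep transition direction? Default `FALSE`.
#' @return A `transition_network`.
#' @export
network_from_keys <- function(trajectory_id, keys, directed = FALSE) {
  stopifnot(length(trajectory_id) == length(keys), length(keys) >= 2)
  n <- length(keys)
  same_traj <- trajectory_id[-n] == trajectory_id[-1]
  changed <- keys[-n] != keys[-1]
  sel <- same_traj & changed
  from <- keys[-n][sel]
  to <- keys[-1][sel]
  if (!directed && length(from)) {
    a <- pmin(from, to); b <- pmax(from, to)
    from <- a; to <- b
  }
  edges <- tibble::tibble(from = from, to = to) |>
    dplyr::count(.data$from, .data$to, name = "count")
  edges$class <- "unclassified"
  conn <- tibble::tibble(key = c(edges$from, edges$to),
                         count = rep(edges$count, 2)) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(N_conn = sum(.data$count), degree = dplyr::n(),
                     .groups = "drop")
  nodes <- cluster_frames(keys) |>
    dplyr::mutate(parent_key = .data$key, harbors_reference = FALSE) |>
    dplyr::left_join(conn, by = "key") |>
    dplyr::mutate(N_conn = dplyr::coalesce(.data$N_conn, 0L),
                  degree = dplyr::coalesce(.data$degree, 0L),
                  N_conn_over_W = .data$N_conn / .data$W)
  structure(list(nodes = nodes, edges = edges, resolution = NA_character_,
                 directed = directed, n_pairs = sum(same_traj)),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  cat("<transition_network> ", x$resolution, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), if (x$directed) " directed" else " undirected",
      " edges (", sum(x$edges$count), " transitions)\n", sep = "")
  invisible(x)
}

#' @rdname build_network
#' @param x,object A `transition_network`.
#' @param ... Unused.
#' @method tidy transition_network
#' @export
tidy.transition_network <- function(x, ...) {
  dplyr::mutate(x$edges, resolution = x$resolution, .before = 1,
                from = as.character(.data$from), to = as.character(.data$to))
}

#' @rdname build_network
#' @method glance transition_network
#' @export
glance.transition_network <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(resolution = x$resolution,
                                  n_nodes = nrow(x$nodes),
                                  n_edges = nrow(x$edges),
                                  n_transitions = sum(x$edges$count)),
                   hub_score(x))
}

#' Hub-likeness summary of a transition network
#'
#' @param net A `transition_network`.
#' @return A one-row tibble: `max_degree_share` (fraction of distinct edges
#'   incident to the highest-degree node; 1 for a perfect star),
#'   `mean_degree`, `degree_variance`, and `dominant_node_W` (weight of the
#'   highest-degree node).
#' @export
hub_score <- function(net) {
  if (nrow(net$edges) == 0) stop("empty network: no inter-cluster transitions")
  deg <- net$nodes$degree
  hub <- which.max(deg)
  hub_key <- net$nodes$key[hub]
  share <- sum(net$edges$from == hub_key | net$edges$to == hub_key) /
    nrow(net$edges)
  tibble::tibble(max_degree_share = share,
                 mean_degree = mean(deg),
                 degree_variance = stats::var(deg),
                 dominant_node_W = net$nodes$W[hub])
}

#' Kinetic-trap diagnostics for flagged clusters
#'
#' For each cluster harboring a reference structure, reports its total
#' transition count `N_conn`, the weight-normalized `N_conn / W`, and the
#' percentile of that quantity among the `n_neighbors` clusters closest in
#' statistical weight. Low percentiles mark kinetic traps: clusters with
#' anomalously few transitions for their weight.
#'
#' @param net A `transition_network` whose nodes carry `harbors_reference`
#'   flags (see [flag_reference_clusters()]), or pass explicit `keys`.
#' @param keys Optional explicit cluster keys to score instead of the flags.
#' @param n_neighbors Number of nearest-weight comparison clusters
#'   (default 20).
#' @return A tibble: `key`, `W`, `N_conn`, `N_conn_over_W`, `percentile`
#'   (0-100 within the comparison set); empty when nothing is flagged.
#' @export
trap_score <- function(net, keys = NULL, n_neighbors = 20) {
  nodes <- net$nodes
  if (is.null(keys)) keys <- nodes$key[nodes$harbors_reference]
  if (length(keys) == 0) {
    return(tibble::tibble(key = character(0), W = numeric(0),
                          N_conn = integer(0), N_conn_over_W = numeric(0),
                          percentile = numeric(0)))
  }
  purrr::map_dfr(keys, function(k) {
    i <- match(k, nodes$key)
    if (is.na(i)) stop("cluster key not in network: ", k)
    others <- nodes[-i, ]
    nb <- others[order(abs(others$W - nodes$W[i])), ]
    nb <- utils::head(nb, n_neighbors)
    ref <- c(nb$N_conn_over_W, nodes$N_conn_over_W[i])
    pct <- 100 * (rank(ref, ties.method = "average")[length(ref)] - 0.5) /
      length(ref)
    tibble::tibble(key = as.character(k), W = nodes$W[i],
                   N_conn = nodes$N_conn[i],
                   N_conn_over_W = nodes$N_conn_over_W[i],
                   percentile = pct)
  })
}

#' Convert a transition network to an igraph graph
#'
#' Node attributes: `W`, `count`, `harbors_reference`; edge attributes:
#' `count`, `class`.
#'
#' @param net A `transition_network`.
#' @param min_W Drop nodes below this statistical weight (default 0: keep
#'   all; the plotting default elsewhere is 1e-4, keeping only significant
#'   substates).
#' @return An igraph object.
#' @export
as_igraph <- function(net, min_W = 0) {
  nodes <- net$nodes[net$nodes$W >= min_W, ]
  keep <- as.character(nodes$key)
  edges <- net$edges[as.character(net$edges$from) %in% keep &
                       as.character(net$edges$to) %in% keep, ]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$from),
                   to = as.character(edges$to),
                   count = edges$count, class = edges$class,
                   stringsAsFactors = FALSE),
    directed = net$directed,
    vertices = data.frame(name = keep, W = nodes$W, count = nodes$count,
                          harbors_reference = nodes$harbors_reference,
                          stringsAsFactors = FALSE))
  g
}

#' Export / import a transition network as GraphML
#'
#' @param net A `transition_network`.
#' @param path File path.
#' @param min_W Node significance filter passed to [as_igraph()].
#' @return `write_network_graphml()`: `path`, invisibly.
#'   `read_network_graphml()`: an igraph object with the same nodes, edges,
#'   counts and classes.
#' @export
write_network_graphml <- function(net, path, min_W = 0) {
  g <- as_igraph(net, min_W = min_W)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' @rdname build_network
#' @method autoplot transition_network
#' @export
autoplot.transition_network <- function(object, min_W = 1e-4, ...) {
  g <- as_igraph(object, min_W = min_W)
  lay <- igraph::layout_with_fr(g)
  vd <- tibble::tibble(x = lay[, 1], y = lay[, 2],
                       W = igraph::V(g)$W,
                       harbors_reference = igraph::V(g)$harbors_reference)
  el <- igraph::as_edgelist(g, names = FALSE)
  ed <- tibble::tibble(x = lay[el[, 1], 1], y = lay[el[, 1], 2],
                       xend = lay[el[, 2], 1], yend = lay[el[, 2], 2],
                       class = igraph::E(g)$class)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$class),
                          linewidth = 0.3) +
    ggplot2::geom_point(data = vd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$W,
                                     shape = .data$harbors_reference)) +
    ggplot2::scale_colour_manual(values = c(intra_parent = "steelblue",
                                            inter_parent = "seagreen")) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste("CS transition network at", object$resolution))
}
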