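# Sociogram export: classical multidimensional scaling of geodesic
# distances for node placement, and graph serialization to GraphML, DOT, and
# JSON with role/provenance attributes and a fixed role color map.

graph_parts <- function(net) {
  if (inherits(net, "ego_network")) {
    nodes <- tibble::tibble(
      id = as.character(net$alters$rank),
      label = net$alters$label,
      role_class = net$alters$role_class
    )
    edges <- tibble::tibble(
      from = as.character(net$edges$a), to = as.character(net$edges$b),
      weight = as.integer(net$edges$weight), implied = FALSE
    )
  } else if (inherits(net, "duo_network")) {
    nodes <- tibble::tibble(
      id = net$nodes$unified_id,
      label = net$nodes$label,
      role_class = net$nodes$role_class,
      provenance = net$nodes$provenance,
      is_parent = net$nodes$is_parent
    )
    edges <- tibble::tibble(
      from = net$edges$node_a, to = net$edges$node_b,
      weight = ifelse(is.na(net$edges$weight), 0L,
                      as.integer(net$edges$weight)),
      implied = net$edges$implied
    )
  } else {
    stop("expected an ego_network or duo_network", call. = FALSE)
  }
  list(nodes = nodes, edges = edges)
}

#' Convert a network to an igraph object
#'
#' Node attributes carry the label, role class, and (for duocentric
#' networks) provenance and parent flag; edge attributes carry the ordinal
#' weight and whether the tie is generator-implied.
#'
#' @param net An [ego_network()] or [merge_duocentric()] network.
#' @return An undirected [igraph::igraph] graph.
#' @export
as_igraph <- function(net) {
  p <- graph_parts(net)
  igraph::graph_from_data_frame(p$edges, directed = FALSE,
                                vertices = p$nodes)
}

#' Sociogram layout by classical multidimensional scaling
#'
#' Positions nodes so that graph-theoretically close nodes sit close in the
#' plane: classical MDS ([stats::cmdscale()]) of the geodesic (shortest
#' path) distance matrix. Geodesic distance is undefined across
#' disconnected components, so each component is scaled independently: the
#' largest sits at the origin and every other component — isolated alters
#' included — is placed on a surrounding ring wide enough that component
#' bounding boxes cannot overlap. Coordinates are dimensionless and
#' deterministic.
#'
#' @param net An [ego_network()] or [merge_duocentric()] network.
#' @return Tibble with columns `node`, `x`, `y`.
#' @export
layout_mds <- function(net) {
  p <- graph_parts(net)
  n <- nrow(p$nodes)
  if (n == 0) stop("cannot lay out an empty network", call. = FALSE)
  if (n == 1) return(tibble::tibble(node = p$nodes$id, x = 0, y = 0))
  g <- as_igraph(net)
  comp <- igraph::components(g)
  member_ids <- split(names(comp$membership), comp$membership)

  scale_component <- function(ids) {
    m <- length(ids)
    if (m == 1) {
      return(matrix(0, 1, 2, dimnames = list(ids, c("x", "y"))))
    }
    d <- igraph::distances(g, v = ids, to = ids)
    fit <- stats::cmdscale(stats::as.dist(d), k = min(2L, m - 1L))
    out <- matrix(0, m, 2, dimnames = list(ids, c("x", "y")))
    out[, seq_len(ncol(fit))] <- fit
    out
  }
  layouts <- lapply(member_ids, scale_component)
  radii <- vapply(layouts, function(l) max(sqrt(rowSums(l^2))), numeric(1))
  main <- order(-vapply(member_ids, length, integer(1)))[1]

  coords <- matrix(0, nrow = n, ncol = 2,
                   dimnames = list(p$nodes$id, c("x", "y")))
  coords[rownames(layouts[[main]]), ] <- layouts[[main]]
  sats <- setdiff(seq_along(layouts), main)
  if (length(sats) > 0) {
    ring_r <- radii[main] + max(radii[sats]) + 1
    theta <- 2 * pi * (seq_along(sats) - 1) / length(sats) + pi / 4
    for (k in seq_along(sats)) {
      l <- layouts[[sats[k]]]
      l[, 1] <- l[, 1] + ring_r * cos(theta[k])
      l[, 2] <- l[, 2] + ring_r * sin(theta[k])
      coords[rownames(l), ] <- l
    }
  }
  tibble::tibble(node = rownames(coords),
                 x = unname(coords[, 1]), y = unname(coords[, 2]))
}

#' Role color map for sociograms
#'
#' @return Named character vector of hex colors over [role_classes()].
#' @export
default_role_colors <- function() {
  c(family = "#1b9e77", community = "#7570b3", professional = "#d95f02")
}

#' Export a sociogram
#'
#' Writes the network with layout coordinates, role colors, and (for
#' duocentric networks) provenance attributes to GraphML, Graphviz DOT, or a
#' JSON form that [import_graph_json()] reads back losslessly.
#'
#' @param net An [ego_network()] or [merge_duocentric()] network.
#' @param path Output file.
#' @param format `"graphml"`, `"dot"`, or `"json"`.
#' @param layout Layout tibble from [layout_mds()] (computed if `NULL`);
#'   must cover every node.
#' @param colors Role color map (default [default_role_colors()]).
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "dot", "json"),
                         layout = NULL, colors = default_role_colors()) {
  format <- match.arg(format)
  p <- graph_parts(net)
  layout <- layout %||% layout_mds(net)
  if (!all(p$nodes$id %in% layout$node)) {
    stop("layout does not cover all nodes", call. = FALSE)
  }
  idx <- match(p$nodes$id, layout$node)
  p$nodes$x <- layout$x[idx]
  p$nodes$y <- layout$y[idx]
  p$nodes$color <- unname(colors[p$nodes$role_class])
  if (format == "json") {
    jsonlite::write_json(
      list(nodes = p$nodes, edges = p$edges), path,
      dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    dplyr::mutate(p$edges, implied = as.integer(.data$implied)),
    directed = FALSE, vertices = p$nodes
  )
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Read back a JSON sociogram export
#'
#' @param path File written by [export_graph()] with `format = "json"`.
#' @return List with `nodes` and `edges` tibbles.
#' @export
import_graph_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(nodes = tibble::as_tibble(raw$nodes),
       edges = tibble::as_tibble(raw$edges))
}
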