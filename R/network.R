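# Assemblage-level class-sharing network: nodes are assemblages, ties are
# shared classes weighted by the Sorensen index.

#' Per-assemblage class profiles
#'
#' Reduces a classified specimen table to one profile per assemblage: its
#' region and the set of distinct class codes present.
#'
#' @param classified Data frame with columns `assemblage_id`, `region`,
#'   `class_code`.
#' @return An object of class `assemblage_profiles`: named list with
#'   `class_sets` (list of character vectors) and `region` (named character
#'   vector).
#' @export
assemblage_profiles <- function(classified) {
  need <- c("assemblage_id", "region", "class_code")
  if (!all(need %in% names(classified)))
    stop("classified table needs columns ", paste(need, collapse = ", "))
  sp <- split(classified, classified$assemblage_id)
  regs <- vapply(sp, function(d) {
    r <- unique(d$region)
    if (length(r) != 1L)
      stop("assemblage ", d$assemblage_id[1], " spans multiple regions")
    r
  }, "")
  structure(list(class_sets = lapply(sp, function(d) unique(d$class_code)),
                 region = regs),
            class = "assemblage_profiles")
}

#' Sorensen weight between two assemblage class sets
#'
#' The number of shared classes divided by the average class richness of the
#' two assemblages: \eqn{|A \cap B| / [(|A| + |B|)/2]}, algebraically the
#' classic Sorensen index \eqn{2 |A \cap B| / (|A| + |B|)}. A tie exists iff
#' the intersection is non-empty.
#'
#' @param a,b Character vectors of class codes (non-empty).
#' @return Weight in `[0, 1]`.
#' @export
#' @examples
#' sorensen_weight(c("x", "y", "z"), c("x", "y", "w", "v"))  # 2 / 3.5
sorensen_weight <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("empty class set")
  length(intersect(a, b)) / ((length(a) + length(b)) / 2)
}

#' Build the class-sharing network
#'
#' Constructs an undirected graph with one node per assemblage and a tie
#' between every pair sharing at least one class, weighted by the Sorensen
#' index. Node attributes carry region and class richness; edge attributes
#' carry the shared-class count and the weight.
#'
#' @param profiles An [assemblage_profiles()] object.
#' @return An `igraph` graph.
#' @export
build_class_network <- function(profiles) {
  stopifnot(inherits(profiles, "assemblage_profiles"))
  ids <- names(profiles$class_sets)
  if (length(ids) < 2) stop("need at least 2 assemblages")
  if (anyDuplicated(ids)) stop("duplicate assemblage_id")
  pairs <- utils::combn(ids, 2)
  shared <- apply(pairs, 2, function(p)
    length(intersect(profiles$class_sets[[p[1]]],
                     profiles$class_sets[[p[2]]])))
  keep <- shared > 0
  edges <- pairs[, keep, drop = FALSE]
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "region", value = unname(profiles$region[ids]))
  g <- igraph::set_vertex_attr(g, "richness",
                               value = lengths(profiles$class_sets[ids]))
  if (any(keep)) {
    g <- igraph::add_edges(g, as.vector(edges))
    w <- vapply(which(keep), function(j)
      sorensen_weight(profiles$class_sets[[pairs[1, j]]],
                      profiles$class_sets[[pairs[2, j]]]), 1)
    g <- igraph::set_edge_attr(g, "shared", value = shared[keep])
    g <- igraph::set_edge_attr(g, "weight", value = w)
  }
  g
}

#' Network density
#'
#' `mode = "binary"` (default) reports the proportion of possible undirected
#' ties present, edge count over C(N, 2). `mode = "weighted"` reports the
#' mean Sorensen weight over all unordered pairs (absent ties count 0), the
#' convention of valued-network density in classic social-network software.
#'
#' @param net An `igraph` network from [build_class_network()].
#' @param mode `"binary"` or `"weighted"`.
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(net, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  nv <- igraph::vcount(net)
  if (nv < 2) stop("density needs at least 2 nodes")
  possible <- nv * (nv - 1) / 2
  if (mode == "binary") igraph::ecount(net) / possible
  else sum(igraph::E(net)$weight) / possible
}

#' Connected components and isolates
#'
#' Components are maximal sets of assemblages linked by chains of shared
#' classes; isolates are assemblages sharing no class with any other.
#'
#' @param net An `igraph` network from [build_class_network()].
#' @return List with `components` (list of node-name vectors, largest
#'   first), `isolates` (node names), `n_components`, `n_isolates`.
#' @export
components_and_isolates <- function(net) {
  comp <- igraph::components(net)
  groups <- split(igraph::V(net)$name, comp$membership)
  groups <- groups[order(-vapply(groups, length, 1L))]
  iso <- unlist(groups[vapply(groups, length, 1L) == 1L], use.names = FALSE)
  list(components = unname(groups),
       isolates = if (is.null(iso)) character(0) else iso,
       n_components = length(groups),
       n_isolates = length(iso))
}

#' Classes shared between the two regions
#'
#' Counts the distinct class codes present in at least one assemblage of
#' each region (the intersection of the regional class unions).
#'
#' @param profiles An [assemblage_profiles()] object with exactly the two
#'   region labels, or a classified specimen table.
#' @return Integer count of cross-region shared classes.
#' @export
cross_region_shared_classes <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- assemblage_profiles(profiles)
  regs <- unique(profiles$region)
  if (length(regs) < 2) return(0L)
  unions <- lapply(regs, function(r)
    unique(unlist(profiles$class_sets[profiles$region == r])))
  length(Reduce(intersect, unions))
}

#' Write the network edge list and graph file
#'
#' Emits a CSV edge list (`source`, `target`, `shared_count`,
#' `sorensen_weight`), a node attribute table (`assemblage_id`, `region`,
#' `richness`) and, optionally, a GraphML file for network software.
#'
#' @param net An `igraph` network from [build_class_network()].
#' @param edge_path CSV path for the edge list.
#' @param node_path Optional CSV path for node attributes.
#' @param graphml_path Optional GraphML output path.
#' @return `edge_path`, invisibly.
#' @export
write_edge_list <- function(net, edge_path, node_path = NULL,
                            graphml_path = NULL) {
  el <- igraph::as_edgelist(net)
  d <- data.frame(source = el[, 1], target = el[, 2],
                  shared_count = if (igraph::ecount(net))
                    igraph::E(net)$shared else integer(0),
                  sorensen_weight = if (igraph::ecount(net))
                    igraph::E(net)$weight else numeric(0),
                  stringsAsFactors = FALSE)
  utils::write.csv(d, edge_path, row.names = FALSE)
  if (!is.null(node_path)) {
    nd <- data.frame(assemblage_id = igraph::V(net)$name,
                     region = igraph::V(net)$region,
                     richness = igraph::V(net)$richness,
                     stringsAsFactors = FALSE)
    utils::write.csv(nd, node_path, row.names = FALSE)
  }
  if (!is.null(graphml_path))
    igraph::write_graph(net, graphml_path, format = "graphml")
  invisible(edge_path)
}
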