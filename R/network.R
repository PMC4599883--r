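#' Construct an anatomical network
#'
#' An anatomical network is a simple, undirected, unweighted graph whose nodes
#' are anatomical parts (bones/cartilages and muscles) and whose edges are the
#' physical contacts between them: articulations between bones, tendinous
#' fusions between muscles, and muscle-bone attachments.
#'
#' @param adjacency square symmetric binary matrix of contacts. Row/column
#'   names, when present, must agree and match `labels`.
#' @param labels character vector of unique node identifiers. Defaults to the
#'   row names of `adjacency`.
#' @param node_class per-node class, `"bone_cartilage"` or `"muscle"`. A named
#'   vector is matched by label; an unnamed vector is taken in node order.
#' @param region optional per-node region, `"proximal"` or `"distal"` (`NA`
#'   allowed). Same matching rules as `node_class`.
#' @param meta optional named list of network-level metadata. Recognised keys:
#'   `limb` ("UL"/"LL"), `side` ("left"/"right"), `condition`
#'   ("adult"/"newborn"/"T18"), `system`
#'   ("skeletal"/"muscular"/"musculoskeletal").
#' @return An object of class `anatomical_network`: a list with elements
#'   `labels`, `adjacency` (binary matrix with dimnames), `node_class`,
#'   `region` (named vectors) and `meta`.
#' @examples
#' A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' A["a", "b"] <- A["b", "a"] <- 1
#' net <- anatomical_network(A, node_class = rep("bone_cartilage", 3))
#' net
#' @seealso [read_adjacency_csv()], [extract_subsystem()], [network_params()]
#' @export
anatomical_network <- function(adjacency, labels = rownames(adjacency),
                               node_class = NULL, region = NULL, meta = list()) {
  adjacency <- as.matrix(adjacency)
  if (is.null(labels)) {
    labels <- paste0("v", seq_len(nrow(adjacency)))
  }
  labels <- trimws(as.character(labels))
  validate_adjacency(adjacency, labels)
  dimnames(adjacency) <- list(labels, labels)
  storage.mode(adjacency) <- "double"

  node_class <- align_node_attr(node_class, labels, "node_class")
  if (any(is.na(node_class))) {
    stop_limbnet("node_class must be defined for every node",
                 "limbnet_error_node_class")
  }
  bad <- !node_class %in% c("bone_cartilage", "muscle")
  if (any(bad)) {
    stop_limbnet(
      sprintf("invalid node_class value(s): %s",
              paste(unique(node_class[bad]), collapse = ", ")),
      "limbnet_error_node_class")
  }
  region <- align_node_attr(region, labels, "region")
  region[!is.na(region) & region == ""] <- NA_character_
  bad <- !is.na(region) & !region %in% c("proximal", "distal")
  if (any(bad)) {
    stop_limbnet(
      sprintf("invalid region value(s): %s",
              paste(unique(region[bad]), collapse = ", ")),
      "limbnet_error_region")
  }

  structure(
    list(labels = labels, adjacency = adjacency,
         node_class = node_class, region = region, meta = meta),
    class = "anatomical_network")
}

# classed errors so callers (and tests) can distinguish failure modes
stop_limbnet <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "limbnet_validation_error",
                                     "error", "condition")))
}

validate_adjacency <- function(A, labels) {
  if (nrow(A) != ncol(A)) {
    stop_limbnet(sprintf("adjacency matrix is not square (%d x %d)",
                         nrow(A), ncol(A)),
                 "limbnet_error_nonsquare")
  }
  if (length(labels) != nrow(A)) {
    stop_limbnet("number of labels does not match matrix dimension",
                 "limbnet_error_nonsquare")
  }
  if (anyDuplicated(labels)) {
    stop_limbnet(sprintf("duplicate node label(s): %s",
                         paste(unique(labels[duplicated(labels)]),
                               collapse = ", ")),
                 "limbnet_error_duplicate_label")
  }
  vals <- suppressWarnings(as.numeric(A))
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    stop_limbnet("adjacency entries must all be 0 or 1",
                 "limbnet_error_nonbinary")
  }
  A <- matrix(vals, nrow(A))
  if (!isTRUE(all.equal(A, t(A)))) {
    idx <- which(A != t(A), arr.ind = TRUE)[1, ]
    stop_limbnet(
      sprintf("adjacency matrix is asymmetric, e.g. A[%d,%d] != A[%d,%d]",
              idx[1], idx[2], idx[2], idx[1]),
      "limbnet_error_asymmetric")
  }
  if (any(diag(A) != 0)) {
    stop_limbnet("adjacency diagonal must be all zero (no self-contacts)",
                 "limbnet_error_diagonal")
  }
  invisible(TRUE)
}

align_node_attr <- function(x, labels, what) {
  n <- length(labels)
  if (is.null(x)) return(stats::setNames(rep(NA_character_, n), labels))
  x <- as.character(x)
  if (!is.null(names(x))) {
    miss <- setdiff(labels, names(x))
    if (length(miss) && what == "node_class") {
      stop_limbnet(sprintf("%s missing for node(s): %s", what,
                           paste(miss, collapse = ", ")),
                   "limbnet_error_node_class")
    }
    out <- stats::setNames(x[labels], labels)
  } else {
    if (length(x) != n) {
      stop_limbnet(sprintf("%s has length %d, expected %d", what,
                           length(x), n),
                   paste0("limbnet_error_", what))
    }
    out <- stats::setNames(x, labels)
  }
  out
}

#' Number of nodes and edges
#'
#' @param net an [anatomical_network()].
#' @return `n_nodes()`: the node count N; `n_edges()`: the edge count K
#'   (half the sum of the adjacency matrix).
#' @export
n_nodes <- function(net) length(net$labels)

#' @rdname n_nodes
#' @export
n_edges <- function(net) sum(net$adjacency) / 2

#' @export
print.anatomical_network <- function(x, ...) {
  sys <- x$meta$system %||% "anatomical"
  cat(sprintf("<anatomical_network> %s system: %d nodes, %d edges\n",
              sys, n_nodes(x), n_edges(x)))
  tab <- table(x$node_class)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (any(!is.na(x$region))) {
    rt <- table(x$region, useNA = "no")
    cat("  regions:", paste(sprintf("%s=%d", names(rt), rt), collapse = ", "),
        "\n")
  }
  extra <- x$meta[setdiff(names(x$meta), "system")]
  if (length(extra)) {
    cat("  meta:", paste(sprintf("%s=%s", names(extra), unlist(extra)),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert an anatomical network to an igraph graph
#'
#' Node class and region are carried along as vertex attributes.
#'
#' @param net an [anatomical_network()].
#' @return an undirected simple [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  igraph::V(g)$node_class <- unname(net$node_class)
  igraph::V(g)$region <- unname(net$region)
  g
}

induced_subnetwork <- function(net, keep) {
  # keep: logical or label vector; preserves node order of the parent
  if (is.character(keep)) keep <- net$labels %in% keep
  labels <- net$labels[keep]
  anatomical_network(net$adjacency[keep, keep, drop = FALSE],
                     labels = labels,
                     node_class = net$node_class[keep],
                     region = net$region[keep],
                     meta = net$meta)
}

#' Extract the skeletal, muscular or musculoskeletal subsystem
#'
#' The skeletal system is the induced subgraph on bone/cartilage nodes, the
#' muscular system the induced subgraph on muscle nodes, and the
#' musculoskeletal system the full network.
#'
#' @param net an [anatomical_network()], typically musculoskeletal.
#' @param system one of `"skeletal"`, `"muscular"`, `"musculoskeletal"`.
#' @return an [anatomical_network()] with `meta$system` set accordingly.
#' @export
extract_subsystem <- function(net, system = c("skeletal", "muscular",
                                              "musculoskeletal")) {
  if (!is.character(system) || length(system) != 1 ||
      !system %in% c("skeletal", "muscular", "musculoskeletal")) {
    stop_limbnet(sprintf("unknown system '%s'", paste(system, collapse = ",")),
                 "limbnet_error_unknown_system")
  }
  keep <- switch(system,
    skeletal = net$node_class == "bone_cartilage",
    muscular = net$node_class == "muscle",
    musculoskeletal = rep(TRUE, n_nodes(net)))
  out <- induced_subnetwork(net, keep)
  out$meta$system <- system
  out
}

#' Split a network into proximal and distal subnetworks
#'
#' @param net an [anatomical_network()].
#' @param regions optional [region_map()] (named character vector
#'   label -> "proximal"/"distal"). Defaults to the network's own `region`
#'   tags, which must then cover every node.
#' @return a list with elements `proximal` and `distal`, each an induced
#'   subnetwork; their node counts sum to `n_nodes(net)`.
#' @export
split_by_region <- function(net, regions = NULL) {
  if (is.null(regions)) {
    regions <- net$region
  } else {
    regions <- region_map(regions)
  }
  miss <- setdiff(net$labels, names(regions)[!is.na(regions)])
  miss <- union(miss, net$labels[is.na(regions[net$labels])])
  if (length(miss)) {
    stop_limbnet(sprintf("region map does not cover node(s): %s",
                         paste(miss, collapse = ", ")),
                 "limbnet_error_uncovered_label")
  }
  reg <- regions[net$labels]
  list(proximal = induced_subnetwork(net, reg == "proximal"),
       distal = induced_subnetwork(net, reg == "distal"))
}

#' Region map constructor
#'
#' A region map assigns each node label to the proximal (girdle + stylopod,
#' and muscles attached to them) or distal (zeugopod + autopod) region of a
#' limb.
#'
#' @param x a named character vector, or a data.frame whose first two columns
#'   are label and region.
#' @return a named character vector with values in
#'   `c("proximal", "distal")`, class `region_map`.
#' @export
region_map <- function(x) {
  if (is.data.frame(x)) {
    x <- stats::setNames(as.character(x[[2]]), trimws(as.character(x[[1]])))
  }
  vals <- as.character(x)
  bad <- !is.na(vals) & !vals %in% c("proximal", "distal")
  if (any(bad)) {
    stop_limbnet(sprintf("invalid region value(s): %s",
                         paste(unique(vals[bad]), collapse = ", ")),
                 "limbnet_error_region")
  }
  structure(stats::setNames(vals, names(x)), class = "region_map")
}
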