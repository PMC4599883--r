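#' Global network parameters
#'
#' Computes the five descriptors used to characterise anatomical networks,
#' plus the node and edge counts:
#' \describe{
#'   \item{D}{density of connections, `2K / (N (N - 1))`.}
#'   \item{C}{mean clustering coefficient: the local clustering
#'     `2 tau_i / (k_i (k_i - 1))` (triangles through node i over wedges),
#'     defined as 0 for nodes of degree < 2, averaged over all N nodes.}
#'   \item{L}{mean shortest path length over all unordered node pairs joined
#'     by some path; unreachable pairs are excluded, so sparse disconnected
#'     systems (e.g. muscular networks of mostly isolated muscles) still get
#'     a finite value. `NA` when the network has no edges.}
#'   \item{diameter}{the longest of all (finite) shortest paths.}
#'   \item{H}{degree heterogeneity, the coefficient of variation
#'     `sigma_K / mu_K` of the degree sequence (population standard
#'     deviation); 0 exactly when all degrees are equal.}
#' }
#'
#' @param net an [anatomical_network()] with at least one node.
#' @return an object of class `network_params`: a list with elements `N`,
#'   `K`, `D`, `C`, `L`, `diameter`, `H`.
#' @examples
#' net <- planted_partition_graph(c(4, 4), p_in = 1, p_out = 0, seed = 1)$network
#' network_params(net)
#' @export
network_params <- function(net) {
  N <- n_nodes(net)
  if (N == 0) {
    stop_limbnet("network has no nodes", "limbnet_error_empty")
  }
  K <- n_edges(net)
  g <- as_igraph(net)
  D <- if (N > 1) 2 * K / (N * (N - 1)) else 0
  C <- if (K > 0) {
    igraph::transitivity(g, type = "localaverage", isolates = "zero")
  } else 0
  if (K > 0) {
    L <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    diam <- igraph::diameter(g, directed = FALSE, unconnected = TRUE)
  } else {
    L <- NA_real_
    diam <- NA_real_
  }
  deg <- rowSums(net$adjacency)
  mu <- mean(deg)
  sig <- sqrt(mean((deg - mu)^2))
  H <- if (sig == 0) 0 else sig / mu
  structure(list(N = N, K = K, D = D, C = C, L = L, diameter = diam, H = H),
            class = "network_params")
}

#' @export
print.network_params <- function(x, digits = 3, ...) {
  cat(sprintf(
    "N=%d K=%d D=%.*f C=%.*f L=%s diameter=%s H=%.*f\n",
    x$N, x$K, digits, x$D, digits, x$C,
    if (is.na(x$L)) "NA" else formatC(x$L, digits = digits, format = "f"),
    if (is.na(x$diameter)) "NA" else format(x$diameter),
    digits, x$H))
  invisible(x)
}

#' Degree-indexed profiles P(k) and C(k)
#'
#' `P(k) = n_k / N` is the probability of finding a node with k connections;
#' `C(k)` is the mean local clustering coefficient of the nodes with k
#' connections. Both are indexed by the degrees actually present in the
#' network, and P sums to 1.
#'
#' @param net an [anatomical_network()] with at least one node.
#' @return a list with `k` (sorted observed degrees), `P` and `Cprof`
#'   (numeric vectors named by degree).
#' @export
degree_profiles <- function(net) {
  N <- n_nodes(net)
  if (N == 0) stop_limbnet("network has no nodes", "limbnet_error_empty")
  deg <- rowSums(net$adjacency)
  loc <- local_clustering(net)
  ks <- sort(unique(deg))
  P <- vapply(ks, function(k) sum(deg == k) / N, numeric(1))
  Cprof <- vapply(ks, function(k) mean(loc[deg == k]), numeric(1))
  list(k = ks,
       P = stats::setNames(P, ks),
       Cprof = stats::setNames(Cprof, ks))
}

local_clustering <- function(net) {
  g <- as_igraph(net)
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[is.nan(loc)] <- 0
  stats::setNames(loc, net$labels)
}

#' Weak-tie report: candidate structurally critical nodes
#'
#' "Weak ties" are the elements that hold otherwise separate parts of the
#' network together; they combine low local clustering with high betweenness
#' centrality. For every node the report gives its clustering coefficient,
#' its (unnormalised) shortest-path betweenness, and the effect of deleting
#' it: how many fragments its component breaks into, how many elements are
#' cut off from the largest remaining fragment of that component, and the
#' resulting global component count. Candidates are ranked by decreasing
#' betweenness, ties broken by increasing clustering, then label order.
#'
#' @param net an [anatomical_network()] with at least two nodes.
#' @return a data.frame with one row per node (`label`, `clustering`,
#'   `betweenness`, `n_fragments`, `newly_disconnected`,
#'   `components_after`, `rank`), ordered by rank.
#' @export
weak_tie_report <- function(net) {
  N <- n_nodes(net)
  if (N < 2) stop_limbnet("need at least 2 nodes", "limbnet_error_empty")
  g <- as_igraph(net)
  loc <- local_clustering(net)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  comp <- igraph::components(g)
  n_frag <- integer(N)
  newly_disc <- integer(N)
  comp_after <- integer(N)
  for (i in seq_len(N)) {
    gi <- igraph::delete_vertices(g, i)
    ci <- igraph::components(gi)
    comp_after[i] <- ci$no
    memb <- comp$membership[-i]
    in_comp <- memb == comp$membership[i]
    if (!any(in_comp)) {            # node was isolated
      n_frag[i] <- 0
      newly_disc[i] <- 0
    } else {
      frag_sizes <- table(ci$membership[in_comp])
      n_frag[i] <- length(frag_sizes)
      newly_disc[i] <- sum(frag_sizes) - max(frag_sizes)
    }
  }
  ord <- order(-btw, loc, net$labels)
  out <- data.frame(label = net$labels, clustering = unname(loc),
                    betweenness = unname(btw), n_fragments = n_frag,
                    newly_disconnected = newly_disc,
                    components_after = comp_after,
                    stringsAsFactors = FALSE)
  out$rank <- order(ord)
  out[ord, , drop = FALSE]
}

#' Tabulate parameters for a set of networks
#'
#' One row per network with columns `network`, `N`, `K`, `D`, `C`, `L`,
#' `Diameter`, `H`, matching the layout of published parameter tables.
#'
#' @param nets a named list of [anatomical_network()] objects.
#' @return a data.frame.
#' @export
params_table <- function(nets) {
  stopifnot(is.list(nets))
  if (is.null(names(nets))) names(nets) <- paste0("net", seq_along(nets))
  rows <- lapply(names(nets), function(nm) {
    p <- network_params(nets[[nm]])
    data.frame(network = nm, N = p$N, K = p$K, D = p$D, C = p$C, L = p$L,
               Diameter = p$diameter, H = p$H, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
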