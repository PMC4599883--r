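#' Random-walk (walktrap) merge dendrogram
#'
#' Agglomerative community detection driven by short random walks. For each
#' connected component, the t-step transition probabilities from every node
#' are computed (`P^t`, with `P = D^-1 A`); the squared distance between two
#' communities C1, C2 is
#' `r^2 = sum_k (P^t_{C1,k} - P^t_{C2,k})^2 / d_k`,
#' where `P^t_{C,k}` is the mean walk probability from the community to node
#' k and `d_k` the degree of k. Starting from singletons, the pair of
#' *adjacent* (edge-connected) communities whose merge minimises the
#' Ward-style variation
#' `delta sigma = (1/n) |C1||C2|/(|C1|+|C2|) r^2(C1, C2)`
#' is merged, until each component is a single community. After a merge the
#' distances to common neighbours follow the Lance-Williams-style update of
#' the walktrap algorithm; distances to communities adjacent to only one of
#' the merged pair are computed directly from the community probability
#' vectors (the two routes give identical values).
#'
#' Isolated nodes carry no walk and remain singletons; components are
#' processed independently, so no merge ever crosses a component boundary.
#' Ties in delta sigma are broken deterministically towards the pair with
#' the lowest (smaller, then larger) community index.
#'
#' @param net an [anatomical_network()].
#' @param steps random-walk length t (default 3).
#' @return an object of class `walktrap_dendrogram`: list with
#'   \describe{
#'     \item{merges}{m x 2 matrix of community indices; leaves are 1..N in
#'       node order, internal communities are numbered N+1, ... in merge
#'       order.}
#'     \item{heights}{delta sigma at each merge.}
#'     \item{labels}{node labels.}
#'     \item{component}{component membership of each node.}
#'     \item{merge_component}{component of each merge.}
#'   }
#' @seealso [best_partition()], [cut_dendrogram()]
#' @export
walktrap_dendrogram <- function(net, steps = 3) {
  if (!is.numeric(steps) || length(steps) != 1 || steps < 1) {
    stop_limbnet("steps must be a positive integer",
                 "limbnet_error_steps")
  }
  steps <- as.integer(steps)
  N <- n_nodes(net)
  if (N == 0) stop_limbnet("network has no nodes", "limbnet_error_empty")
  A <- net$adjacency
  comp <- igraph::components(as_igraph(net))$membership

  merges <- matrix(integer(0), ncol = 2)
  heights <- numeric(0)
  merge_comp <- integer(0)
  next_id <- N + 1L
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    if (length(idx) < 2) next
    res <- walktrap_component(A[idx, idx, drop = FALSE], idx, steps, next_id)
    merges <- rbind(merges, res$merges)
    heights <- c(heights, res$heights)
    merge_comp <- c(merge_comp, rep(cid, nrow(res$merges)))
    next_id <- next_id + nrow(res$merges)
  }
  structure(list(merges = merges, heights = heights, labels = net$labels,
                 component = unname(comp), merge_component = merge_comp,
                 steps = steps, n = N),
            class = "walktrap_dendrogram")
}

# Agglomeration within one connected component. idx maps local node
# positions to global leaf ids; new communities are numbered from next_id.
walktrap_component <- function(A, idx, steps, next_id) {
  m <- nrow(A)
  # lazy walk: every node carries a unit self-loop, as in the published
  # walktrap implementation; keeps the walk aperiodic
  A <- A + diag(1, m)
  deg <- rowSums(A)
  P <- A / deg
  Pt <- P
  if (steps > 1) for (t in 2:steps) Pt <- Pt %*% P

  size <- rep(1, m)
  pvec <- Pt                     # row c = probability vector of community c
  ids <- as.integer(idx)         # dendrogram id of each live community slot
  active <- rep(TRUE, m)
  nbr <- A > 0                   # community adjacency (logical matrix)

  dsig <- function(a, b) {
    (1 / m) * (size[a] * size[b] / (size[a] + size[b])) *
      sum((pvec[a, ] - pvec[b, ])^2 / deg)
  }
  D <- matrix(NA_real_, m, m)
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) if (nbr[a, b]) D[a, b] <- dsig(a, b)
  }

  merges <- matrix(integer(2 * (m - 1)), ncol = 2)
  heights <- numeric(m - 1)
  for (step in seq_len(m - 1)) {
    dmin <- min(D[upper.tri(D)], na.rm = TRUE)
    cand <- which(!is.na(D) & D <= dmin + 1e-12, arr.ind = TRUE)
    # deterministic tie-break on (smaller, larger) community ids
    key_small <- pmin(ids[cand[, 1]], ids[cand[, 2]])
    key_large <- pmax(ids[cand[, 1]], ids[cand[, 2]])
    pick <- order(key_small, key_large)[1]
    a <- cand[pick, 1]; b <- cand[pick, 2]

    merges[step, ] <- c(ids[a], ids[b])
    heights[step] <- D[a, b]
    dab <- D[a, b]

    # merge b into slot a
    new_size <- size[a] + size[b]
    pvec[a, ] <- (size[a] * pvec[a, ] + size[b] * pvec[b, ]) / new_size
    for (k in which(active)) {
      if (k == a || k == b) next
      if (!nbr[a, k] && !nbr[b, k]) next
      if (nbr[a, k] && nbr[b, k] && !is.na(D[min(a, k), max(a, k)]) &&
          !is.na(D[min(b, k), max(b, k)])) {
        dak <- D[min(a, k), max(a, k)]
        dbk <- D[min(b, k), max(b, k)]
        dnew <- ((size[a] + size[k]) * dak + (size[b] + size[k]) * dbk -
                   size[k] * dab) / (new_size + size[k])
      } else {
        size_a_old <- size[a]
        size[a] <- new_size    # dsig uses updated size/pvec
        dnew <- dsig(a, k)
        size[a] <- size_a_old
      }
      D[min(a, k), max(a, k)] <- dnew
    }
    size[a] <- new_size
    nbr[a, ] <- nbr[a, ] | nbr[b, ]
    nbr[, a] <- nbr[a, ]
    nbr[a, a] <- FALSE
    active[b] <- FALSE
    D[b, ] <- NA_real_
    D[, b] <- NA_real_
    ids[a] <- next_id
    next_id <- next_id + 1L
  }
  list(merges = merges, heights = heights)
}

#' @export
print.walktrap_dendrogram <- function(x, ...) {
  cat(sprintf(
    "<walktrap_dendrogram> %d nodes, %d merges over %d component(s), t=%d\n",
    x$n, nrow(x$merges), length(unique(x$component)), x$steps))
  invisible(x)
}

#' Partition at a given merge level of a dendrogram
#'
#' Applies the first `n_merges` merges (in recorded order) and returns the
#' resulting flat partition. `n_merges = 0` gives all singletons;
#' `n_merges = nrow(dend$merges)` gives one block per connected component.
#'
#' @param dend a [walktrap_dendrogram()].
#' @param n_merges number of merges to apply.
#' @return a named integer membership vector (label -> module id, modules
#'   numbered consecutively in node order).
#' @export
cut_dendrogram <- function(dend, n_merges) {
  n <- dend$n
  parent <- seq_len(n + nrow(dend$merges))
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n_merges > 0) {
    for (s in seq_len(n_merges)) {
      a <- find(dend$merges[s, 1])
      b <- find(dend$merges[s, 2])
      parent[a] <- n + s
      parent[b] <- n + s
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(roots, unique(roots)), dend$labels)
}

#' Newman modularity Q of a partition
#'
#' `Q = (1/2K) sum_ij (A_ij - k_i k_j / 2K) delta(m_i, m_j)`, summed over
#' ordered node pairs including the diagonal. Q is the difference between
#' the observed fraction of connections inside modules and the fraction
#' expected in a random network with the same degrees; it ranges from -1 to
#' 1 and equals 0 exactly for the all-in-one-module partition.
#'
#' @param net an [anatomical_network()].
#' @param partition a `module_partition`, or a membership vector named by
#'   node label (unnamed vectors are taken in node order). Must cover every
#'   node.
#' @return the Q value. A network without edges gives 0 with a warning.
#' @export
modularity_q <- function(net, partition) {
  memb <- as_membership(partition, net$labels)
  K <- n_edges(net)
  if (K == 0) {
    warning("network has no edges; Q defined as 0")
    return(0)
  }
  deg <- rowSums(net$adjacency)
  q <- 0
  for (mod in unique(memb)) {
    in_m <- memb == mod
    l_m <- sum(net$adjacency[in_m, in_m]) / 2
    d_m <- sum(deg[in_m])
    q <- q + l_m / K - (d_m / (2 * K))^2
  }
  q
}

as_membership <- function(partition, labels) {
  if (inherits(partition, "module_partition")) {
    partition <- partition$membership
  }
  if (!is.null(names(partition))) {
    miss <- setdiff(labels, names(partition))
    if (length(miss)) {
      stop_limbnet(sprintf("partition does not cover node(s): %s",
                           paste(miss, collapse = ", ")),
                   "limbnet_error_uncovered_label")
    }
    partition <- partition[labels]
  } else if (length(partition) != length(labels)) {
    stop_limbnet("partition length does not match node count",
                 "limbnet_error_uncovered_label")
  }
  stats::setNames(match(partition, unique(partition)), labels)
}

#' Module partition object
#'
#' @param membership named membership vector (label -> module id).
#' @param Q modularity of the partition (optional).
#' @return an object of class `module_partition` with elements
#'   `membership`, `n_modules`, `Q`.
#' @export
module_partition <- function(membership, Q = NA_real_) {
  ids <- match(membership, unique(membership))
  structure(list(membership = stats::setNames(ids, names(membership)),
                 n_modules = length(unique(ids)), Q = Q),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules over %d nodes, Q = %s\n",
              x$n_modules, length(x$membership),
              if (is.na(x$Q)) "NA" else sprintf("%.4f", x$Q)))
  sizes <- sort(table(x$membership), decreasing = TRUE)
  cat("  module sizes:", paste(as.integer(sizes), collapse = " "), "\n")
  invisible(x)
}

#' Maximum-modularity partition of a walktrap dendrogram
#'
#' Evaluates modularity Q at every cut level of the dendrogram — from all
#' singletons to one block per connected component — and returns the
#' partition with the highest Q. Because Q decomposes over connected
#' components (a module never spans components), each component's cut level
#' is chosen independently by maximising its additive contribution to the
#' global Q; ties are broken towards fewer modules. Isolated nodes are
#' singleton modules.
#'
#' @param dend a [walktrap_dendrogram()] built on `net`.
#' @param net the same [anatomical_network()].
#' @return a [module_partition()] with its Q.
#' @examples
#' sim <- planted_partition_graph(rep(8, 3), p_in = 1, p_out = 0, seed = 1)
#' part <- best_partition(walktrap_dendrogram(sim$network), sim$network)
#' part$n_modules  # 3
#' @export
best_partition <- function(dend, net) {
  if (!identical(dend$labels, net$labels)) {
    stop_limbnet("dendrogram was not built on this network",
                 "limbnet_error_uncovered_label")
  }
  n <- dend$n
  K <- n_edges(net)
  A <- net$adjacency
  deg <- rowSums(A)
  membership <- seq_len(n)                 # start from singletons

  if (K > 0 && nrow(dend$merges) > 0) {
    for (cid in unique(dend$merge_component)) {
      rows <- which(dend$merge_component == cid)
      # incremental per-level contribution to global Q within this component
      node_of <- as.list(seq_len(n))       # community id -> node indices
      contrib <- numeric(length(rows) + 1)
      cum <- sum(-(deg[dend$component == cid] / (2 * K))^2)
      contrib[1] <- cum
      for (s in seq_along(rows)) {
        mrow <- dend$merges[rows[s], ]
        na_ <- node_of[[mrow[1]]]
        nb_ <- node_of[[mrow[2]]]
        l_ab <- sum(A[na_, nb_, drop = FALSE])
        d_a <- sum(deg[na_]); d_b <- sum(deg[nb_])
        # merging: + l_ab/K - 2 d_a d_b / (2K)^2
        cum <- cum + l_ab / K - 2 * d_a * d_b / (2 * K)^2
        contrib[s + 1] <- cum
        node_of[[n + rows[s]]] <- c(na_, nb_)
      }
      best <- max(contrib)
      level <- max(which(contrib >= best - 1e-12)) - 1  # ties: fewer modules
      if (level > 0) {
        for (s in seq_len(level)) {
          mrow <- dend$merges[rows[s], ]
          a_nodes <- node_of[[mrow[1]]]
          b_nodes <- node_of[[mrow[2]]]
          membership[c(a_nodes, b_nodes)] <- min(membership[a_nodes])
        }
      }
    }
  }
  memb <- stats::setNames(match(membership, unique(membership)), dend$labels)
  module_partition(memb, Q = modularity_q(net, memb))
}

#' Export a dendrogram as Newick text and a CSV merge list
#'
#' One Newick tree per connected component (isolated nodes are single-leaf
#' trees), with delta-sigma merge heights as internal node labels, plus a
#' merge list with columns `community_a`, `community_b`, `merged_as`,
#' `height`.
#'
#' @param dend a [walktrap_dendrogram()].
#' @param newick_path,csv_path optional output paths; omitted outputs are
#'   returned but not written.
#' @return invisibly, a list with `newick` (character vector) and `merges`
#'   (data.frame).
#' @export
export_dendrogram <- function(dend, newick_path = NULL, csv_path = NULL) {
  n <- dend$n
  txt <- character(n + nrow(dend$merges))
  txt[seq_len(n)] <- gsub("[,;:()\\s]", "_", dend$labels, perl = TRUE)
  if (nrow(dend$merges) > 0) {
    for (s in seq_len(nrow(dend$merges))) {
      a <- dend$merges[s, 1]; b <- dend$merges[s, 2]
      txt[n + s] <- sprintf("(%s,%s)%g", txt[a], txt[b], dend$heights[s])
    }
  }
  roots <- unique(vapply(seq_len(n), function(i) {
    r <- i
    while (TRUE) {
      up <- which(dend$merges[, 1] == r | dend$merges[, 2] == r)
      if (!length(up)) break
      r <- n + up[1]
    }
    r
  }, integer(1)))
  newick <- paste0(txt[roots], ";")
  merges_df <- data.frame(community_a = dend$merges[, 1],
                          community_b = dend$merges[, 2],
                          merged_as = n + seq_len(nrow(dend$merges)),
                          height = dend$heights)
  if (!is.null(newick_path)) writeLines(newick, newick_path)
  if (!is.null(csv_path)) {
    utils::write.csv(merges_df, csv_path, row.names = FALSE)
  }
  invisible(list(newick = newick, merges = merges_df))
}

#' Write a partition as a two-column CSV (label, module)
#'
#' @param partition a [module_partition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(partition, path) {
  utils::write.csv(
    data.frame(label = names(partition$membership),
               module = unname(partition$membership)),
    path, row.names = FALSE)
  invisible(path)
}
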