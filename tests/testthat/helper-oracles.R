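# Fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately avoid the code paths they check: distances by hand-
# rolled BFS, triangles by adjacency enumeration, modularity by the double
# loop, module matching by exhaustive assignment.

make_net <- function(A, labels = NULL, node_class = NULL, region = NULL,
                     meta = list()) {
  n <- nrow(A)
  if (is.null(labels)) labels <- sprintf("v%02d", seq_len(n))
  if (is.null(node_class)) node_class <- rep("bone_cartilage", n)
  anatomical_network(A, labels = labels, node_class = node_class,
                     region = region, meta = meta)
}

edges_net <- function(n, edges, ...) {
  A <- matrix(0, n, n)
  for (e in edges) A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  make_net(A, ...)
}

path3_net <- function() edges_net(3, list(c(1, 2), c(2, 3)),
                                  labels = c("a", "b", "c"))

complete_net <- function(n) {
  A <- matrix(1, n, n); diag(A) <- 0
  make_net(A)
}

two_k3_net <- function() {
  edges_net(6, list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
            labels = letters[1:6])
}

rand_net <- function(n, m) {
  # uniform simple graph via igraph; caller controls the RNG seed
  g <- igraph::sample_gnm(n, m)
  make_net(as.matrix(igraph::as_adjacency_matrix(g)))
}

# Ravasz-style deterministic hierarchical graph: 5 copies of K5, peripheral
# nodes of the outer copies wired to the root of the central copy.
rb_hierarchical_net <- function() {
  A <- matrix(0, 25, 25)
  for (c in 0:4) {
    idx <- c * 5 + 1:5
    A[idx, idx] <- 1
  }
  diag(A) <- 0
  for (c in 1:4) {
    per <- c * 5 + 2:5
    A[1, per] <- A[per, 1] <- 1
  }
  make_net(A)
}

bf_params <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  deg <- rowSums(A)
  tri <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) 0 else sum(A[nb, nb]) / 2
  }, numeric(1))
  Ci <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in which(A[v, ] > 0)) {
        if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
      }
    }
    dist[s, ] <- d
  }
  up <- dist[upper.tri(dist)]
  fin <- up[is.finite(up)]
  sig <- sqrt(mean((deg - mean(deg))^2))
  list(N = n, K = sum(A) / 2, D = if (n > 1) sum(A) / (n * (n - 1)) else 0,
       C = mean(Ci),
       L = if (length(fin)) mean(fin) else NA_real_,
       diameter = if (length(fin)) max(fin) else NA_real_,
       H = if (sig == 0) 0 else sig / mean(deg))
}

bf_modularity <- function(net, memb) {
  A <- net$adjacency
  deg <- rowSums(A)
  K <- sum(A) / 2
  n <- nrow(A)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        q <- q + unname(A[i, j] - deg[i] * deg[j] / (2 * K))
      }
    }
  }
  q / (2 * K)
}

# exhaustive one-to-one assignment total on a contingency table
bf_match_total <- function(tab) {
  nr <- nrow(tab); nc <- ncol(tab)
  best <- 0
  rec <- function(r, used, acc) {
    if (r > nr) { best <<- max(best, acc); return() }
    rec(r + 1, used, acc)
    for (j in seq_len(nc)) {
      if (!(j %in% used)) rec(r + 1, c(used, j), acc + tab[r, j])
    }
  }
  rec(1, integer(0), 0)
  best
}

set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p; q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

random_membership <- function(labels, k) {
  stats::setNames(sample.int(k, length(labels), replace = TRUE), labels)
}
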