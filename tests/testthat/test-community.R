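test_that("walktrap never merges across connected components", {
  net <- two_k3_net()
  dend <- walktrap_dendrogram(net)
  expect_equal(nrow(dend$merges), 4)  # 2 merges per triangle
  # every merge belongs to exactly one component
  for (s in seq_len(nrow(dend$merges))) {
    leaves <- dend$merges[s, ]
    comps <- unique(dend$component[leaves[leaves <= 6]])
    expect_length(comps, 1)
  }
  expect_error(walktrap_dendrogram(net, steps = 0),
               class = "limbnet_error_steps")
})

test_that("a single edge yields one merge with a finite height", {
  net <- edges_net(2, list(c(1, 2)), labels = c("a", "b"))
  dend <- walktrap_dendrogram(net)
  expect_equal(nrow(dend$merges), 1)
  # the two endpoints are structurally identical, so the merge cost is 0
  expect_true(is.finite(dend$heights))
  expect_gte(dend$heights, 0)
})

test_that("the barbell graph merges each clique before the bridge", {
  # two K5 joined by one edge
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1; diag(A) <- 0
  A[5, 6] <- A[6, 5] <- 1
  net <- make_net(A)
  dend <- walktrap_dendrogram(net)
  # last merge joins the two clique communities
  last <- cut_dendrogram(dend, nrow(dend$merges) - 1)
  expect_equal(length(unique(last)), 2)
  expect_equal(unname(last[1:5]), rep(last[[1]], 5))
  expect_equal(unname(last[6:10]), rep(last[[6]], 5))
  part <- best_partition(dend, net)
  expect_equal(part$n_modules, 2)
  # agrees with the independent reference implementation
  ref <- igraph::cluster_walktrap(as_igraph(net), steps = 3)
  expect_equal(part$n_modules, length(ref))
  expect_equal(part$Q, igraph::modularity(ref), tolerance = 1e-12)
})

test_that("modularity matches the double-loop formula evaluation", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(3:10, 1)
    net <- rand_net(n, sample(1:(n * (n - 1) / 2), 1))
    memb <- random_membership(net$labels, sample(1:4, 1))
    expect_equal(modularity_q(net, memb),
                 bf_modularity(net, unname(memb)),
                 tolerance = 1e-12)
  }
})

test_that("forced modularity values hold exactly", {
  set.seed(19)
  for (i in 1:5) {
    net <- rand_net(8, sample(4:20, 1))
    one <- stats::setNames(rep(1L, 8), net$labels)
    expect_equal(modularity_q(net, one), 0)
  }
  net <- two_k3_net()
  split <- stats::setNames(rep(1:2, each = 3), net$labels)
  expect_equal(modularity_q(net, split), 0.5)
  edgeless <- make_net(matrix(0, 3, 3))
  expect_warning(q0 <- modularity_q(
    edgeless, stats::setNames(1:3, edgeless$labels)))
  expect_equal(q0, 0)
})

test_that("max-Q cut recovers forced structures", {
  net <- two_k3_net()
  part <- best_partition(walktrap_dendrogram(net), net)
  expect_equal(part$n_modules, 2)
  expect_equal(part$Q, 0.5)

  # muscular-network topology: 4 contact pairs + 49 isolated muscles
  A <- matrix(0, 57, 57)
  for (i in 1:4) A[2 * i - 1, 2 * i] <- A[2 * i, 2 * i - 1] <- 1
  mus <- make_net(A, node_class = rep("muscle", 57))
  part <- best_partition(walktrap_dendrogram(mus), mus)
  expect_equal(part$n_modules, 53)  # 4 pairs + 49 singleton modules
  sizes <- table(part$membership)
  expect_equal(sum(sizes == 2), 4)
  expect_equal(sum(sizes == 1), 49)
})

test_that("planted modules are recovered exactly in the easy regime", {
  sim <- planted_partition_graph(rep(20, 4), p_in = 0.5, p_out = 0.02,
                                 seed = 5)
  part <- best_partition(walktrap_dendrogram(sim$network), sim$network)
  expect_equal(part$n_modules, 4)
  expect_equal(nmi_similarity(part, sim$partition)$nmi, 1)
})

test_that("best partition never scores below the trivial one-module cut", {
  set.seed(23)
  for (i in 1:10) {
    net <- rand_net(12, sample(6:30, 1))
    part <- best_partition(walktrap_dendrogram(net), net)
    expect_gte(part$Q, 0)
  }
})

test_that("heuristic Q gap to the exhaustive optimum is small and no worse than the reference", {
  set.seed(11)
  gap_mine <- c(); gap_ref <- c()
  for (i in 1:20) {
    n <- sample(5:8, 1)
    repeat {
      net <- rand_net(n, sample(n:(n * (n - 1) / 2), 1))
      if (n_edges(net) > 0) break
    }
    part <- best_partition(walktrap_dendrogram(net), net)
    ref <- igraph::cluster_walktrap(as_igraph(net), steps = 3)
    qmax <- -Inf
    for (p in set_partitions(as.integer(n))) {
      memb <- integer(n)
      for (k in seq_along(p)) memb[p[[k]]] <- k
      qmax <- max(qmax, modularity_q(net,
                                     stats::setNames(memb, net$labels)))
    }
    gap_mine <- c(gap_mine, qmax - part$Q)
    gap_ref <- c(gap_ref, qmax - igraph::modularity(ref))
  }
  expect_lte(stats::quantile(gap_mine, 0.9), 0.05)
  expect_lte(max(gap_mine), max(gap_ref) + 1e-9)
})

test_that("dendrogram and partition exports are well-formed", {
  net <- two_k3_net()
  dend <- walktrap_dendrogram(net)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  csv <- withr::local_tempfile(fileext = ".csv")
  out <- export_dendrogram(dend, newick_path = nwk, csv_path = csv)
  expect_length(out$newick, 2)  # one tree per component
  expect_true(all(grepl(";$", readLines(nwk))))
  merges <- utils::read.csv(csv)
  expect_named(merges, c("community_a", "community_b", "merged_as",
                         "height"))
  part <- best_partition(dend, net)
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write_partition_csv(part, pcsv)
  tab <- utils::read.csv(pcsv)
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("label", "module"))
})
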