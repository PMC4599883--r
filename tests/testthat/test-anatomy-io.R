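test_that("a triangle adjacency CSV reads into a 3-node, 3-edge network", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",femur,tibia,patella",
               "femur,0,1,1",
               "tibia,1,0,1",
               "patella,1,1,0"), path)
  net <- read_adjacency_csv(path, node_class = rep("bone_cartilage", 3))
  expect_s3_class(net, "anatomical_network")
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 3)
  expect_equal(net$labels, c("femur", "tibia", "patella"))
})

test_that("each invariant violation raises its own named validation error", {
  lab <- c("a", "b", "c")
  sq <- function(A) { dimnames(A) <- list(lab[seq_len(nrow(A))],
                                          lab[seq_len(ncol(A))]); A }
  asym <- sq(matrix(0, 3, 3)); asym[1, 2] <- 1
  expect_error(anatomical_network(asym, node_class = rep("muscle", 3)),
               class = "limbnet_error_asymmetric")
  expect_error(anatomical_network(matrix(0, 2, 3)),
               class = "limbnet_error_nonsquare")
  nb <- sq(matrix(0, 3, 3)); nb[1, 2] <- nb[2, 1] <- 2
  expect_error(anatomical_network(nb, node_class = rep("muscle", 3)),
               class = "limbnet_error_nonbinary")
  dg <- sq(matrix(0, 3, 3)); diag(dg) <- 1
  expect_error(anatomical_network(dg, node_class = rep("muscle", 3)),
               class = "limbnet_error_diagonal")
  expect_error(
    anatomical_network(sq(matrix(0, 3, 3)), labels = c("a", "a", "b"),
                       node_class = rep("muscle", 3)),
    class = "limbnet_error_duplicate_label")
  expect_error(
    anatomical_network(sq(matrix(0, 3, 3)), labels = lab),
    class = "limbnet_error_node_class")
  # all validation errors share a common superclass
  expect_error(anatomical_network(asym, node_class = rep("muscle", 3)),
               class = "limbnet_validation_error")
})

test_that("write/read round-trip is the identity on labels, adjacency and classes", {
  sim <- planted_partition_graph(c(4, 4, 4), p_in = 0.9, p_out = 0.05,
                                 seed = 1)
  net <- sim$network
  net$region[] <- rep(c("proximal", "distal"), each = 6)
  net$meta <- list(system = "musculoskeletal", limb = "UL", side = "left")
  path <- withr::local_tempfile(fileext = ".csv")
  write_adjacency_csv(net, path)
  back <- read_adjacency_csv(path, metadata = paste0(
    sub("\\.csv$", "", path), ".meta.csv"))
  expect_identical(back$labels, net$labels)
  expect_identical(back$adjacency, net$adjacency)
  expect_identical(back$node_class, net$node_class)
  expect_identical(back$region, net$region)
  expect_identical(back$meta$limb, "UL")

  # empty 5-node network round-trips to a zero matrix
  empty <- make_net(matrix(0, 5, 5))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_adjacency_csv(empty, p2, metadata = NA)
  back2 <- read_adjacency_csv(p2, node_class = rep("bone_cartilage", 5))
  expect_true(all(back2$adjacency == 0))
  expect_equal(n_nodes(back2), 5)
})

test_that("repeated writes of the same network are byte-identical", {
  net <- planted_partition_graph(c(5, 5), 0.8, 0.1, seed = 1)$network
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_adjacency_csv(net, p1, metadata = NA)
  write_adjacency_csv(net, p2, metadata = NA)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("subsystem extraction keeps only the requested tissue layer", {
  # two bones joined by an articulation, one muscle attached to both
  net <- edges_net(3, list(c(1, 2), c(1, 3), c(2, 3)),
                   labels = c("bone1", "bone2", "muscle1"),
                   node_class = c("bone_cartilage", "bone_cartilage",
                                  "muscle"))
  sk <- extract_subsystem(net, "skeletal")
  expect_equal(sk$labels, c("bone1", "bone2"))
  expect_equal(n_edges(sk), 1)
  mu <- extract_subsystem(net, "muscular")
  expect_equal(mu$labels, "muscle1")
  expect_equal(n_edges(mu), 0)
  expect_identical(extract_subsystem(net, "musculoskeletal")$adjacency,
                   net$adjacency)
  expect_error(extract_subsystem(net, "nervous"),
               class = "limbnet_error_unknown_system")
  # node counts of the two layers always sum to the whole
  full <- limb_like_network(seed = 3)
  expect_equal(n_nodes(extract_subsystem(full, "skeletal")) +
                 n_nodes(extract_subsystem(full, "muscular")),
               n_nodes(full))
})

test_that("induced subgraphs never contain edges absent from the parent", {
  full <- limb_like_network(seed = 5)
  for (sys in c("skeletal", "muscular")) {
    sub <- extract_subsystem(full, sys)
    expect_true(all(sub$adjacency <=
                      full$adjacency[sub$labels, sub$labels]))
  }
})

test_that("region splitting partitions the node set", {
  net <- path3_net()
  rm_all_prox <- region_map(stats::setNames(rep("proximal", 3), net$labels))
  sp <- split_by_region(net, rm_all_prox)
  expect_equal(n_nodes(sp$proximal), 3)
  expect_equal(n_nodes(sp$distal), 0)

  rm_chain <- region_map(c(a = "proximal", b = "distal", c = "distal"))
  sp <- split_by_region(net, rm_chain)
  expect_equal(n_nodes(sp$proximal), 1)
  expect_equal(n_edges(sp$proximal), 0)
  expect_equal(n_nodes(sp$distal), 2)
  expect_equal(n_edges(sp$distal), 1)

  expect_error(split_by_region(net, region_map(c(a = "proximal"))),
               class = "limbnet_error_uncovered_label")

  # limb-like generator: the digit chains all land in the distal half
  limb <- limb_like_network(seed = 2)
  sp <- split_by_region(limb)
  expect_equal(n_nodes(sp$proximal) + n_nodes(sp$distal), n_nodes(limb))
  digits <- grep("^digit", limb$labels, value = TRUE)
  expect_true(all(digits %in% sp$distal$labels))
})

test_that("GraphML export preserves node classes and regions", {
  net <- limb_like_network(n_digits = 2, n_muscles = 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), n_nodes(net))
  expect_setequal(unique(igraph::V(g)$node_class),
                  unique(net$node_class))
  expect_true("region" %in% igraph::vertex_attr_names(g))
})

test_that("bundled limb table resolves anatomical labels to classes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",Humerus,Radius,Biceps brachii",
               "Humerus,0,1,1",
               "Radius,1,0,1",
               "Biceps brachii,1,1,0"), path)
  net <- read_adjacency_csv(path)
  expect_equal(unname(net$node_class),
               c("bone_cartilage", "bone_cartilage", "muscle"))
  expect_equal(unname(net$region["Humerus"]), "proximal")
  expect_equal(unname(net$region["Radius"]), "distal")
})
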