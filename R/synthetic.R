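#' Planted-partition benchmark graph
#'
#' Generates a random graph with known community structure: nodes are split
#' into modules of the given sizes, and each unordered node pair receives an
#' edge independently with probability `p_in` (same module) or `p_out`
#' (different modules). The planted assignment is returned as ground truth
#' for module-recovery experiments.
#'
#' @param sizes integer vector of module sizes (each >= 1).
#' @param p_in within-module edge probability.
#' @param p_out between-module edge probability; must satisfy
#'   `0 <= p_out < p_in <= 1`.
#' @param seed integer RNG seed; the output is reproducible given the seed.
#' @return list with `network` (an [anatomical_network()]; all nodes tagged
#'   `bone_cartilage`) and `partition` (the planted [module_partition()]).
#' @export
planted_partition_graph <- function(sizes, p_in, p_out, seed = 1L) {
  if (any(sizes < 1)) {
    stop_limbnet("module sizes must be >= 1", "limbnet_error_spec")
  }
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop_limbnet("need 0 <= p_out < p_in <= 1", "limbnet_error_spec")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  A <- matrix(0, n, n)
  same <- outer(block, block, "==")
  up <- upper.tri(A)
  prob <- ifelse(same[up], p_in, p_out)
  A[up] <- as.numeric(stats::runif(sum(up)) < prob)
  A <- A + t(A)
  labels <- sprintf("n%02d", seq_len(n))
  net <- anatomical_network(A, labels = labels,
                            node_class = rep("bone_cartilage", n),
                            meta = list(system = "synthetic"))
  list(network = net,
       partition = module_partition(stats::setNames(block, labels)))
}

#' Synthetic limb-like musculoskeletal network
#'
#' Emulates the topology the analysis is built for. The skeletal layer is a
#' connected, sparse, tree-like graph: a girdle block, a single stylopod
#' bone, a two-bone zeugopod, a wrist/ankle block, and serial digit chains
#' (one metapodial plus a chain of phalanges per digit). The muscular layer
#' is mostly isolated muscles with rare fusion edges. Muscles attach to at
#' least two bones; with probability `span_prob` a muscle spans a joint
#' (attaches to two adjacent bones), which is what creates the high triangle
#' density of musculoskeletal networks. Girdle and stylopod bones, and
#' muscles attached to them, are tagged proximal; everything else distal.
#'
#' With the defaults the skeletal layer has 33 bones and a connection
#' density below 0.1, the muscular layer has 57 muscles with only a handful
#' of contacts, and the musculoskeletal layer has roughly 180-190 contacts —
#' the sparsity regime of real human limb networks.
#'
#' @param n_digits number of digits.
#' @param phalanges phalanges per digit (including the metapodial chain).
#' @param girdle_size number of girdle bones.
#' @param wrist_size number of bones in the wrist/ankle block.
#' @param n_muscles number of muscles; 0 gives a purely skeletal network.
#' @param extra_attach_prob probability that a muscle takes a third bone
#'   attachment.
#' @param fusion_p probability that a muscle is fused to (shares a tendon
#'   with) a previously placed muscle.
#' @param span_prob probability that a muscle's two main attachments span a
#'   joint (adjacent bones).
#' @param seed integer RNG seed.
#' @return a musculoskeletal [anatomical_network()] with node classes and
#'   regions tagged.
#' @export
limb_like_network <- function(n_digits = 5, phalanges = 3, girdle_size = 2,
                              wrist_size = 8, n_muscles = 57,
                              extra_attach_prob = 0.3, fusion_p = 0.07,
                              span_prob = 0.7, seed = 1L) {
  if (n_digits < 1 || phalanges < 1 || girdle_size < 1 || wrist_size < 2) {
    stop_limbnet("invalid limb spec", "limbnet_error_spec")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  girdle <- sprintf("girdle%d", seq_len(girdle_size))
  stylopod <- "stylopod"
  zeugopod <- c("zeugopod1", "zeugopod2")
  wrist <- sprintf("wrist%d", seq_len(wrist_size))
  meta_b <- sprintf("metapodial%d", seq_len(n_digits))
  phal <- unlist(lapply(seq_len(n_digits), function(d) {
    sprintf("digit%d_phalanx%d", d, seq_len(phalanges))
  }))
  bones <- c(girdle, stylopod, zeugopod, wrist, meta_b, phal)

  edges <- list()
  add_edge <- function(a, b) edges[[length(edges) + 1]] <<- c(a, b)
  if (girdle_size > 1) {
    for (i in seq_len(girdle_size - 1)) add_edge(girdle[i], girdle[i + 1])
  }
  add_edge(girdle[1], stylopod)
  add_edge(stylopod, zeugopod[1]); add_edge(stylopod, zeugopod[2])
  add_edge(zeugopod[1], zeugopod[2])
  add_edge(zeugopod[1], wrist[1]); add_edge(zeugopod[2], wrist[2])
  for (i in seq_len(wrist_size - 1)) add_edge(wrist[i], wrist[i + 1])
  # a few extra wrist contacts: real carpal/tarsal blocks are not pure chains
  n_extra <- min(3, choose(wrist_size, 2) - (wrist_size - 1))
  if (n_extra > 0) {
    cand <- which(upper.tri(matrix(0, wrist_size, wrist_size)), arr.ind = TRUE)
    cand <- cand[cand[, 2] - cand[, 1] > 1, , drop = FALSE]
    pick <- cand[sample(nrow(cand), n_extra), , drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      add_edge(wrist[pick[r, 1]], wrist[pick[r, 2]])
    }
  }
  for (d in seq_len(n_digits)) {
    w <- wrist[1 + (d - 1) %% wrist_size]
    add_edge(w, meta_b[d])
    chain <- c(meta_b[d], sprintf("digit%d_phalanx%d", d, seq_len(phalanges)))
    for (i in seq_len(length(chain) - 1)) add_edge(chain[i], chain[i + 1])
  }

  muscles <- if (n_muscles > 0) sprintf("muscle%02d", seq_len(n_muscles)) else character(0)
  labels <- c(bones, muscles)
  nb <- length(bones)
  A <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (e in edges) A[e[1], e[2]] <- A[e[2], e[1]] <- 1

  for (m in muscles) {
    anchor <- sample(bones, 1)
    nbrs <- bones[A[anchor, bones] > 0]
    insertion <- if (length(nbrs) && stats::runif(1) < span_prob) {
      sample(nbrs, 1)
    } else {
      sample(setdiff(bones, anchor), 1)
    }
    att <- c(anchor, insertion)
    if (stats::runif(1) < extra_attach_prob) {
      att <- c(att, sample(setdiff(bones, att), 1))
    }
    A[m, att] <- A[att, m] <- 1
    prev <- muscles[seq_len(match(m, muscles) - 1)]
    if (length(prev) && stats::runif(1) < fusion_p) {
      other <- sample(prev, 1)
      A[m, other] <- A[other, m] <- 1
    }
  }

  node_class <- stats::setNames(
    c(rep("bone_cartilage", nb), rep("muscle", length(muscles))), labels)
  prox_bones <- c(girdle, stylopod)
  region <- stats::setNames(rep("distal", length(labels)), labels)
  region[prox_bones] <- "proximal"
  for (m in muscles) {
    if (any(A[m, prox_bones] > 0)) region[m] <- "proximal"
  }
  anatomical_network(A, labels = labels, node_class = node_class,
                     region = region,
                     meta = list(system = "musculoskeletal",
                                 condition = "synthetic"))
}
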