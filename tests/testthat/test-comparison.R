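test_that("co-classification ratio behaves on forced cases", {
  p <- module_partition(stats::setNames(c(1, 1, 2, 2, 3), letters[1:5]))
  same <- partition_similarity(p, p)
  expect_equal(same$ratio, 1)
  expect_equal(same$n_common, 5)

  all_one <- module_partition(stats::setNames(rep(1, 5), letters[1:5]))
  singletons <- module_partition(stats::setNames(1:5, letters[1:5]))
  res <- partition_similarity(all_one, singletons)
  expect_equal(res$n_coclassified, 1)
  expect_equal(res$ratio, 0.2)

  # reassigning 2 of 20 shared elements drops the ratio to 0.9
  base <- stats::setNames(rep(1:4, each = 5), sprintf("e%02d", 1:20))
  moved <- base
  moved[c("e01", "e06")] <- c(4, 4)
  res <- partition_similarity(module_partition(base),
                              module_partition(moved))
  expect_equal(res$ratio, 0.9)
})

test_that("optimal matching equals the exhaustive assignment oracle and is symmetric", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(6:15, 1)
    labs <- sprintf("x%02d", 1:n)
    pA <- module_partition(random_membership(labs, sample(2:5, 1)))
    pB <- module_partition(random_membership(labs, sample(2:5, 1)))
    ab <- partition_similarity(pA, pB)
    ba <- partition_similarity(pB, pA)
    expect_equal(ab$ratio, ba$ratio)
    tab <- table(pA$membership[labs], pB$membership[labs])
    expect_equal(ab$n_coclassified, bf_match_total(tab),
                 label = sprintf("case %d", i))
  }
})

test_that("similarity is bounded and responds to moving one element", {
  base <- stats::setNames(rep(1:2, each = 4), letters[1:8])
  pA <- module_partition(base)
  moved <- base
  moved["a"] <- 2
  expect_lt(partition_similarity(pA, module_partition(moved))$ratio, 1)
  expect_equal(partition_similarity(pA, pA)$ratio, 1)
})

test_that("label maps bridge disjoint label sets; empty overlap errors", {
  pUL <- module_partition(stats::setNames(c(1, 1, 2),
                                          c("Humerus", "Radius", "Ulna")))
  pLL <- module_partition(stats::setNames(c(1, 1, 2),
                                          c("Femur", "Tibia", "Fibula")))
  expect_error(partition_similarity(pUL, pLL),
               class = "limbnet_error_empty_common")
  res <- partition_similarity(pUL, pLL, label_map = serial_homology_map())
  expect_equal(res$n_common, 3)
  expect_equal(res$ratio, 1)
})

test_that("NMI is 1 for identical partitions and near 0 for independent ones", {
  p <- module_partition(stats::setNames(rep(1:5, each = 4),
                                        sprintf("n%02d", 1:20)))
  expect_equal(nmi_similarity(p, p)$nmi, 1)
  # invariance to module relabeling
  relab <- module_partition(stats::setNames(rep(c(9, 3, 7, 1, 5), each = 4),
                                            sprintf("n%02d", 1:20)))
  expect_equal(nmi_similarity(p, relab)$nmi, 1)

  set.seed(47)
  labs <- sprintf("e%04d", 1:1000)
  a <- module_partition(random_membership(labs, 5))
  b <- module_partition(random_membership(labs, 5))
  expect_lt(nmi_similarity(a, b)$nmi, 0.05)
})

test_that("NMI of a coarsening matches the independent contingency oracle", {
  set.seed(53)
  labs <- sprintf("e%03d", 1:60)
  fine <- random_membership(labs, 10)
  coarse <- fine
  coarse[coarse == 10] <- 9  # merge two small modules
  got <- nmi_similarity(module_partition(fine), module_partition(coarse))
  expect_gt(got$nmi, 0)
  expect_lt(got$nmi, 1)
  # independent oracle: igraph's information-theoretic comparison
  ref <- igraph::compare(unname(fine), unname(coarse), method = "nmi")
  expect_equal(got$nmi, ref, tolerance = 1e-12)

  # degenerate single-group inputs on both sides count as identical
  one <- module_partition(stats::setNames(rep(1, 4), letters[1:4]))
  expect_equal(nmi_similarity(one, one)$nmi, 1)
})

test_that("proximal/distal comparison scores are symmetric and zero on identical limbs", {
  limb <- limb_like_network(seed = 31)
  pd <- proximal_distal_params(limb, limb)
  expect_equal(pd$proximal_score, 0)
  expect_equal(pd$distal_score, 0)
  expect_equal(nrow(pd$params), 4)

  # identical distal chains, different proximal organization
  ulA <- limb_like_network(girdle_size = 2, n_muscles = 0, seed = 8)
  ulB <- limb_like_network(girdle_size = 6, n_muscles = 0, seed = 8)
  pd <- proximal_distal_params(ulA, ulB)
  expect_lt(pd$distal_score, pd$proximal_score)
  swapped <- proximal_distal_params(ulB, ulA)
  expect_equal(pd$proximal_score, swapped$proximal_score)
  expect_equal(pd$distal_score, swapped$distal_score)
})
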