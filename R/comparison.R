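#' Co-classification similarity between two module partitions
#'
#' The similarity between two networks' modular organizations is the ratio
#' of elements grouped in the same module in both networks at the same time,
#' divided by the number of elements common to both networks. "The same
#' module" requires deciding which modules correspond: here the one-to-one
#' module correspondence maximising the total overlap is used (maximum-weight
#' bipartite matching on the module-overlap contingency table), which is
#' deterministic and symmetric in the two partitions.
#'
#' @param pA,pB [module_partition()] objects (or named membership vectors).
#' @param label_map optional named character vector translating `pA` labels
#'   into `pB` labels (e.g. a [serial_homology_map()] for upper-vs-lower limb
#'   comparisons); labels without an entry keep their own name.
#' @return an object of class `similarity_result`: list with `n_common`,
#'   `n_coclassified`, `ratio` (= n_coclassified / n_common),
#'   `module_matching` (data.frame of matched module pairs and overlaps).
#' @export
partition_similarity <- function(pA, pB, label_map = NULL) {
  mA <- membership_vector(pA)
  mB <- membership_vector(pB)
  if (!is.null(label_map)) {
    nm <- names(mA)
    hit <- nm %in% names(label_map)
    nm[hit] <- unname(label_map[nm[hit]])
    names(mA) <- nm
  }
  common <- intersect(names(mA), names(mB))
  if (!length(common)) {
    stop_limbnet("no elements in common between the two partitions",
                 "limbnet_error_empty_common")
  }
  tab <- table(A = mA[common], B = mB[common])
  match_res <- optimal_module_matching(tab)
  structure(list(n_common = length(common),
                 n_coclassified = match_res$total,
                 ratio = match_res$total / length(common),
                 module_matching = match_res$pairs),
            class = "similarity_result")
}

membership_vector <- function(p) {
  if (inherits(p, "module_partition")) return(p$membership)
  if (is.null(names(p))) {
    stop_limbnet("membership vector must be named by node label",
                 "limbnet_error_uncovered_label")
  }
  stats::setNames(match(p, unique(p)), names(p))
}

# Maximum-weight one-to-one assignment on a contingency table, via a
# bipartite matching on the positive-overlap cells.
optimal_module_matching <- function(tab) {
  nr <- nrow(tab); nc <- ncol(tab)
  cells <- which(tab > 0, arr.ind = TRUE)
  edges <- rbind(cells[, 1], nr + cells[, 2])
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nr), rep(TRUE, nc)),
                                    as.vector(edges))
  w <- tab[cells]
  m <- igraph::max_bipartite_match(g, weights = w)
  pairs <- data.frame(module_a = character(0), module_b = character(0),
                      overlap = integer(0))
  total <- 0
  for (i in seq_len(nr)) {
    j <- m$matching[i]
    if (!is.na(j)) {
      jj <- j - nr
      pairs <- rbind(pairs, data.frame(
        module_a = rownames(tab)[i], module_b = colnames(tab)[jj],
        overlap = as.integer(tab[i, jj])))
      total <- total + tab[i, jj]
    }
  }
  list(total = as.integer(total), pairs = pairs)
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "<similarity_result> %d of %d common elements co-classified: %.1f%%\n",
    x$n_coclassified, x$n_common, 100 * x$ratio))
  invisible(x)
}

#' Normalized mutual information between partitions
#'
#' Standard NMI on the contingency table of two partitions of the same
#' element set, normalised as `2 I(A;B) / (H(A) + H(B))` so that identical
#' partitions (up to module relabeling) score 1 and independent ones score
#' near 0. Used both for partition-vs-partition comparison and for checking
#' a network partition against a priori functional or developmental
#' groupings.
#'
#' @param pA,pB [module_partition()] objects, named membership vectors, or a
#'   grouping hypothesis from [read_grouping_csv()]. If the element sets
#'   differ the comparison is restricted to their intersection, with a
#'   warning.
#' @return an object of class `nmi_comparison`: list with `nmi`,
#'   `similarity_percent` (= 100 * nmi) and `n`.
#' @export
nmi_similarity <- function(pA, pB) {
  mA <- membership_vector(pA)
  mB <- membership_vector(pB)
  common <- intersect(names(mA), names(mB))
  if (!length(common)) {
    stop_limbnet("no elements in common between the two partitions",
                 "limbnet_error_empty_common")
  }
  if (length(common) < length(mA) || length(common) < length(mB)) {
    warning("element sets differ; comparing the ",
            length(common), " elements in common")
  }
  a <- mA[common]; b <- mB[common]
  n <- length(common)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  Ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  Hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (Ha == 0 && Hb == 0) {
    nmi <- 1   # both sides a single group: identical by definition
  } else {
    I <- 0
    for (i in seq_along(pa)) {
      for (j in seq_along(pb)) {
        pij <- tab[i, j]
        if (pij > 0) I <- I + pij * log(pij / (pa[i] * pb[j]))
      }
    }
    nmi <- 2 * I / (Ha + Hb)
    nmi <- min(1, max(0, nmi))  # guard rounding at the boundaries
  }
  structure(list(nmi = unname(nmi), similarity_percent = unname(100 * nmi),
                 n = n),
            class = "nmi_comparison")
}

#' @export
print.nmi_comparison <- function(x, ...) {
  cat(sprintf("<nmi_comparison> NMI = %.3f (similarity %.1f%%) over %d elements\n",
              x$nmi, x$similarity_percent, x$n))
  invisible(x)
}

#' Proximal vs distal parameter comparison of two limbs
#'
#' Splits each network into its proximal and distal subnetworks, computes
#' [network_params()] for each of the four pieces, and scores the
#' dissimilarity between the proximal pair and between the distal pair as
#' the mean absolute relative difference over the scale-free descriptors D,
#' C, L and H (each term `|x - y| / ((|x| + |y|) / 2)`, with 0/0 counted as
#' 0 and descriptors undefined on either side dropped). A smaller score
#' means more similar organization.
#'
#' @param netA,netB two [anatomical_network()] objects (e.g. an upper and a
#'   lower limb).
#' @param regionsA,regionsB optional [region_map()]s; default to the
#'   networks' own region tags.
#' @return an object of class `proximal_distal`: list with `params`
#'   (data.frame of the four parameter rows), `proximal_score`,
#'   `distal_score` (either may be `NA` when a region subgraph is empty).
#' @export
proximal_distal_params <- function(netA, netB, regionsA = NULL,
                                   regionsB = NULL) {
  sA <- split_by_region(netA, regionsA)
  sB <- split_by_region(netB, regionsB)
  nets <- list(A_proximal = sA$proximal, A_distal = sA$distal,
               B_proximal = sB$proximal, B_distal = sB$distal)
  ok <- vapply(nets, function(x) n_nodes(x) > 0, logical(1))
  params <- params_table(nets[ok])
  score <- function(n1, n2) {
    if (!ok[[n1]] || !ok[[n2]]) return(NA_real_)
    p1 <- network_params(nets[[n1]]); p2 <- network_params(nets[[n2]])
    terms <- vapply(c("D", "C", "L", "H"), function(f) {
      x <- p1[[f]]; y <- p2[[f]]
      if (is.na(x) || is.na(y)) return(NA_real_)
      if (x == 0 && y == 0) return(0)
      abs(x - y) / ((abs(x) + abs(y)) / 2)
    }, numeric(1))
    mean(terms, na.rm = TRUE)
  }
  structure(list(params = params,
                 proximal_score = score("A_proximal", "B_proximal"),
                 distal_score = score("A_distal", "B_distal")),
            class = "proximal_distal")
}

#' @export
print.proximal_distal <- function(x, ...) {
  cat("<proximal_distal> parameter dissimilarity (mean |rel. diff.| over D,C,L,H)\n")
  cat(sprintf("  proximal vs proximal: %s\n",
              if (is.na(x$proximal_score)) "not assessable"
              else sprintf("%.3f", x$proximal_score)))
  cat(sprintf("  distal   vs distal  : %s\n",
              if (is.na(x$distal_score)) "not assessable"
              else sprintf("%.3f", x$distal_score)))
  invisible(x)
}
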