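#' Anatomical network analysis of one network
#'
#' Runs the full analysis pipeline on a single anatomical network: global
#' parameters ([network_params()]), degree profiles, small-world assessment
#' against an ensemble of random equivalent networks
#' ([small_world_assess()]), hierarchy assessment by power-law profile fits
#' ([hierarchy_assess()]), and connectivity-module detection by the random
#' walk agglomeration with maximum-modularity cut selection
#' ([walktrap_dendrogram()], [best_partition()]).
#'
#' @param net an [anatomical_network()].
#' @param steps random-walk length for module detection (default 3).
#' @param n_random size of the random null ensemble (default 10,000).
#' @param seed master RNG seed; every stochastic step derives from it.
#' @param r2_min minimum R-squared for the hierarchy fits.
#' @return an object of class `anna`: list with `network`, `params`,
#'   `profiles`, `ensemble` (`NULL` for edgeless networks), `small_world`,
#'   `hierarchy`, `dendrogram`, `partition`, and the call settings.
#' @examples
#' net <- limb_like_network(seed = 7)
#' fit <- anna(net, n_random = 200, seed = 7)
#' fit
#' @export
anna <- function(net, steps = 3, n_random = 10000, seed = 1L, r2_min = 0.7) {
  stopifnot(inherits(net, "anatomical_network"))
  params <- network_params(net)
  profiles <- degree_profiles(net)
  if (params$K >= 1) {
    ensemble <- random_equivalent_ensemble(net, n_random = n_random,
                                           seed = seed)
    sw <- small_world_assess(net, ensemble)
  } else {
    ensemble <- NULL
    sw <- structure(list(swi = NA_real_,
                         threshold = 0.012 * params$N^1.11,
                         is_small_world = NA, assessable = FALSE,
                         C = params$C, L = params$L, C_rand = NA_real_,
                         L_rand = NA_real_, N = params$N),
                    class = "small_world")
  }
  hier <- hierarchy_assess(net, r2_min = r2_min)
  dend <- walktrap_dendrogram(net, steps = steps)
  part <- best_partition(dend, net)
  structure(list(network = net, params = params, profiles = profiles,
                 ensemble = ensemble, small_world = sw, hierarchy = hier,
                 dendrogram = dend, partition = part,
                 settings = list(steps = steps, n_random = n_random,
                                 seed = as.integer(seed), r2_min = r2_min)),
            class = "anna")
}

#' @export
print.anna <- function(x, ...) {
  cat("Anatomical network analysis\n")
  print(x$network)
  print(x$params)
  cat(sprintf("  modules: %d (Q = %.4f)\n", x$partition$n_modules,
              x$partition$Q))
  sw <- x$small_world
  cat(sprintf("  small-world: %s\n",
              if (!sw$assessable) "not assessable"
              else if (sw$is_small_world) {
                sprintf("yes (swi %.2f >= %.2f)", sw$swi, sw$threshold)
              } else sprintf("no (swi %.2f < %.2f)", sw$swi, sw$threshold)))
  h <- x$hierarchy
  cat(sprintf("  hierarchical: %s\n",
              if (!h$assessable) "not assessable"
              else if (h$is_hierarchical) "yes" else "no"))
  invisible(x)
}

#' @export
summary.anna <- function(object, ...) {
  print(object)
  cat("\nModule membership:\n")
  memb <- object$partition$membership
  for (mod in sort(unique(memb))) {
    members <- names(memb)[memb == mod]
    cat(sprintf("  [%d] %s\n", mod, paste(members, collapse = ", ")))
  }
  invisible(object)
}

#' @export
plot.anna <- function(x, ...) {
  g <- as_igraph(x$network)
  memb <- x$partition$membership
  shapes <- ifelse(x$network$node_class == "muscle", "square", "circle")
  igraph::plot.igraph(
    g,
    vertex.color = memb[igraph::V(g)$name],
    vertex.shape = shapes[igraph::V(g)$name],
    vertex.size = 7, vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Analyse a set of networks into a report
#'
#' Runs [anna()] on each network and assembles a report: one parameter row
#' per network (N, K, D, C, L, Diameter, H), the
#' small-world and hierarchy verdicts, and the module partition with its Q.
#' Regenerating the report from the same inputs and seed gives identical
#' results.
#'
#' Any validation failure in an input halts the run with its named
#' condition class.
#'
#' @param nets named list of [anatomical_network()] objects.
#' @param ... passed to [anna()] (`steps`, `n_random`, `seed`, `r2_min`).
#' @return an object of class `anna_report`: list with `fits` (named list of
#'   `anna` objects) and `table` (one row per network).
#' @export
analyze_networks <- function(nets, ...) {
  stopifnot(is.list(nets), length(nets) > 0)
  if (is.null(names(nets))) names(nets) <- paste0("net", seq_along(nets))
  fits <- lapply(nets, anna, ...)
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(network = nm, N = f$params$N, K = f$params$K,
               D = f$params$D, C = f$params$C, L = f$params$L,
               Diameter = f$params$diameter, H = f$params$H,
               n_modules = f$partition$n_modules, Q = f$partition$Q,
               swi = f$small_world$swi,
               small_world = f$small_world$is_small_world,
               hierarchical = f$hierarchy$is_hierarchical,
               stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, table = tab), class = "anna_report")
}

#' @export
print.anna_report <- function(x, ...) {
  cat(sprintf("<anna_report> %d network(s)\n", nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a report to disk
#'
#' Writes the parameter/verdict table (`params.csv`), one module-membership
#' CSV and one Newick dendrogram per network, and a JSON summary including
#' the seeds and settings used (`report.json`). Output is deterministic for
#' a fixed input and seed.
#'
#' @param report an [analyze_networks()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_anna_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "params.csv"),
                   row.names = FALSE)
  for (nm in names(report$fits)) {
    f <- report$fits[[nm]]
    write_partition_csv(f$partition,
                        file.path(dir, paste0(nm, "_modules.csv")))
    export_dendrogram(f$dendrogram,
                      newick_path = file.path(dir, paste0(nm, "_dendrogram.nwk")))
  }
  summary <- list(
    networks = report$table,
    settings = lapply(report$fits, function(f) f$settings))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Compare the partitions of two reports
#'
#' For every network name present in both reports, computes the
#' co-classification similarity ratio ([partition_similarity()]) and the
#' normalized mutual information ([nmi_similarity()]) between the two
#' module partitions; optionally also the NMI of each partition against a
#' priori grouping hypotheses.
#'
#' @param repA,repB [analyze_networks()] reports.
#' @param label_map optional label correspondence applied to `repA` labels
#'   (required when comparing limbs with disjoint label sets, e.g. an upper
#'   against a lower limb: see [serial_homology_map()]).
#' @param groupings optional named list of grouping hypotheses
#'   ([read_grouping_csv()] vectors) to score against both partitions.
#' @param out_dir optional directory; when given, `similarity.csv` (and
#'   `grouping_nmi.csv` if groupings were supplied) are written there.
#' @return list with data.frames `similarity` and (possibly) `grouping_nmi`.
#' @export
compare_reports <- function(repA, repB, label_map = NULL, groupings = NULL,
                            out_dir = NULL) {
  shared <- intersect(names(repA$fits), names(repB$fits))
  if (!length(shared)) {
    stop_limbnet("reports have no network names in common",
                 "limbnet_error_empty_common")
  }
  rows <- lapply(shared, function(nm) {
    pA <- repA$fits[[nm]]$partition
    pB <- repB$fits[[nm]]$partition
    sim <- tryCatch(
      partition_similarity(pA, pB, label_map = label_map),
      limbnet_error_empty_common = function(e) {
        stop_limbnet(paste0(
          "no elements in common for network '", nm, "'; supply a ",
          "label_map giving the serial correspondence between the two ",
          "label sets"), "limbnet_error_empty_common")
      })
    nmi <- suppressWarnings(
      nmi_similarity(apply_label_map(pA, label_map), pB$membership))
    data.frame(network = nm, n_common = sim$n_common,
               ratio = sim$ratio, similarity_percent = 100 * sim$ratio,
               nmi = nmi$nmi, stringsAsFactors = FALSE)
  })
  out <- list(similarity = do.call(rbind, rows))
  if (!is.null(groupings)) {
    grows <- list()
    for (gnm in names(groupings)) {
      for (nm in shared) {
        for (side in c("A", "B")) {
          p <- (if (side == "A") repA else repB)$fits[[nm]]$partition
          cmp <- suppressWarnings(nmi_similarity(p, groupings[[gnm]]))
          grows[[length(grows) + 1]] <- data.frame(
            network = nm, report = side, grouping = gnm,
            nmi = cmp$nmi, similarity_percent = cmp$similarity_percent,
            stringsAsFactors = FALSE)
        }
      }
    }
    out$grouping_nmi <- do.call(rbind, grows)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$similarity, file.path(out_dir, "similarity.csv"),
                     row.names = FALSE)
    if (!is.null(out$grouping_nmi)) {
      utils::write.csv(out$grouping_nmi,
                       file.path(out_dir, "grouping_nmi.csv"),
                       row.names = FALSE)
    }
  }
  out
}

apply_label_map <- function(p, label_map) {
  m <- membership_vector(p)
  if (is.null(label_map)) return(m)
  nm <- names(m)
  hit <- nm %in% names(label_map)
  nm[hit] <- unname(label_map[nm[hit]])
  stats::setNames(unname(m), nm)
}
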