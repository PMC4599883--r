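#' Ensemble of random equivalent networks
#'
#' A random equivalent network has the same number of nodes and edges as the
#' empirical network, re-connected uniformly at random (a uniform simple
#' graph on N nodes and K edges). The ensemble supplies the null expectations
#' `C_rand` and `L_rand` for the small-world test. C and L of each replicate
#' are computed exactly as in [network_params()], with L averaged over
#' reachable pairs only, since sparse replicates are often disconnected.
#'
#' All replicates are drawn from a single RNG stream seeded once with `seed`,
#' so the summary is reproducible bit-for-bit.
#'
#' @param net an [anatomical_network()] with at least one edge.
#' @param n_random ensemble size; the default follows the convention of
#'   10,000 replicates. Smaller values trade precision for speed.
#' @param seed integer RNG seed.
#' @return an object of class `random_ensemble`: list with `n_random`,
#'   `C_rand`, `L_rand`, `C_sd`, `L_sd`, `N`, `K`, `seed`.
#' @export
random_equivalent_ensemble <- function(net, n_random = 10000, seed = 1L) {
  N <- n_nodes(net)
  K <- n_edges(net)
  if (K < 1) stop_limbnet("network has no edges", "limbnet_error_empty")
  if (K > N * (N - 1) / 2) {
    stop_limbnet("edge count exceeds the maximum for a simple graph",
                 "limbnet_error_nonbinary")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  Cs <- numeric(n_random)
  Ls <- numeric(n_random)
  for (r in seq_len(n_random)) {
    g <- igraph::sample_gnm(N, K)
    Cs[r] <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
    Ls[r] <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  }
  structure(list(n_random = n_random, C_rand = mean(Cs), L_rand = mean(Ls),
                 C_sd = stats::sd(Cs), L_sd = stats::sd(Ls),
                 N = N, K = K, seed = as.integer(seed)),
            class = "random_ensemble")
}

#' @export
print.random_ensemble <- function(x, ...) {
  cat(sprintf(
    "<random_ensemble> %d uniform graphs on N=%d, K=%d (seed %d)\n",
    x$n_random, x$N, x$K, x$seed))
  cat(sprintf("  C_rand = %.4f (sd %.4f), L_rand = %.4f (sd %.4f)\n",
              x$C_rand, x$C_sd, x$L_rand, x$L_sd))
  invisible(x)
}

#' Size-corrected small-world assessment
#'
#' A network is judged small-world when its clustering is high and its paths
#' short relative to random equivalent networks, after correcting for size:
#' \deqn{\frac{C/C_{rand}}{L/L_{rand}} \ge 0.012 \times N^{1.11}}
#' The left-hand side is the small-world index `swi`.
#'
#' @param net an [anatomical_network()].
#' @param ensemble a [random_equivalent_ensemble()] for the same N and K; if
#'   missing, one is generated with `n_random` and `seed`.
#' @param n_random,seed used only when `ensemble` is missing.
#' @return an object of class `small_world`: list with `swi`, `threshold`
#'   (`0.012 * N^1.11`), `is_small_world` (logical, `NA` when not
#'   assessable), `assessable`, plus the ingredients `C`, `L`, `C_rand`,
#'   `L_rand`, `N`. A degenerate null (C_rand = 0, or a network with no
#'   paths) yields an explicit not-assessable outcome.
#' @export
small_world_assess <- function(net, ensemble = NULL, n_random = 10000,
                               seed = 1L) {
  p <- network_params(net)
  if (is.null(ensemble)) {
    ensemble <- random_equivalent_ensemble(net, n_random = n_random,
                                           seed = seed)
  }
  if (ensemble$N != p$N || ensemble$K != p$K) {
    stop_limbnet("ensemble was built for a different N or K",
                 "limbnet_error_ensemble_mismatch")
  }
  threshold <- 0.012 * p$N^1.11
  if (is.na(p$L) || ensemble$C_rand <= 0 || ensemble$L_rand <= 0) {
    out <- list(swi = NA_real_, threshold = threshold,
                is_small_world = NA, assessable = FALSE)
  } else {
    swi <- (p$C / ensemble$C_rand) / (p$L / ensemble$L_rand)
    out <- list(swi = swi, threshold = threshold,
                is_small_world = swi >= threshold, assessable = TRUE)
  }
  structure(c(out, list(C = p$C, L = p$L, C_rand = ensemble$C_rand,
                        L_rand = ensemble$L_rand, N = p$N)),
            class = "small_world")
}

#' @export
print.small_world <- function(x, ...) {
  if (!x$assessable) {
    cat("<small_world> not assessable (degenerate network or null)\n")
  } else {
    cat(sprintf(
      "<small_world> swi = %.3f %s threshold 0.012 N^1.11 = %.3f -> %s\n",
      x$swi, if (x$is_small_world) ">=" else "<", x$threshold,
      if (x$is_small_world) "small-world" else "not small-world"))
  }
  invisible(x)
}

#' Least-squares power-law fit on log-log scales
#'
#' Fits `value = c * k^(-alpha)` by regressing `log(value)` on `log(k)` over
#' the strictly positive points of a degree-indexed profile. This is the
#' simple distributional fit used for hierarchy assessment, not a
#' maximum-likelihood tail fit.
#'
#' @param k degrees (or a named numeric `value` vector whose names are the
#'   degrees, in which case `value` may be omitted).
#' @param value profile values at each `k`.
#' @return list with `exponent` (the slope; `-alpha`), `intercept`
#'   (`log c`), `r_squared`, `n_points`, `assessable`. Fewer than 3 usable
#'   points gives `assessable = FALSE` and `NA` estimates.
#' @export
power_law_fit <- function(k, value = NULL) {
  if (is.null(value)) {
    value <- as.numeric(k)
    k <- as.numeric(names(k))
  }
  ok <- is.finite(k) & is.finite(value) & k > 0 & value > 0
  if (sum(ok) < 3) {
    return(list(exponent = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n_points = sum(ok),
                assessable = FALSE))
  }
  fit <- stats::lm(log(value[ok]) ~ log(k[ok]))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(value[ok]) - mean(log(value[ok])))^2)
  # manual R^2: summary.lm warns on numerically perfect fits
  r2 <- if (ss_tot < 1e-12) {
    if (ss_res < 1e-12) 1 else 0
  } else 1 - ss_res / ss_tot
  list(exponent = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n_points = sum(ok), assessable = TRUE)
}

#' Hierarchy assessment by power-law profile fits
#'
#' A hierarchical organization — clustering concentrated in nested groups —
#' shows up as approximately power-law degree and clustering-by-degree
#' profiles: `P(k) ~ k^-alpha` and `C(k) ~ k^-alpha`, the latter with
#' clustering declining as degree grows. The verdict requires both fits to
#' reach `r2_min` and the C(k) slope to be negative; the criterion is
#' recorded in the output rather than hidden.
#'
#' @param net an [anatomical_network()] with at least three distinct degrees.
#' @param r2_min minimum R-squared for a fit to count (default 0.7).
#' @return an object of class `hierarchy`: list with `pk_fit`, `ck_fit`
#'   (each as returned by [power_law_fit()]), `is_hierarchical` (logical,
#'   `NA` when either fit is not assessable), `assessable` and `criterion`.
#' @export
hierarchy_assess <- function(net, r2_min = 0.7) {
  prof <- degree_profiles(net)
  pk <- power_law_fit(prof$P)
  ck <- power_law_fit(prof$Cprof)
  criterion <- sprintf(
    "P(k) and C(k) log-log fits both with R^2 >= %.2f and C(k) slope < 0",
    r2_min)
  if (length(unique(prof$k)) < 3 || !pk$assessable || !ck$assessable) {
    return(structure(list(pk_fit = pk, ck_fit = ck, is_hierarchical = NA,
                          assessable = FALSE, r2_min = r2_min,
                          criterion = criterion),
                     class = "hierarchy"))
  }
  verdict <- pk$r_squared >= r2_min && ck$r_squared >= r2_min &&
    ck$exponent < 0
  structure(list(pk_fit = pk, ck_fit = ck, is_hierarchical = verdict,
                 assessable = TRUE, r2_min = r2_min, criterion = criterion),
            class = "hierarchy")
}

#' @export
print.hierarchy <- function(x, ...) {
  if (!x$assessable) {
    cat("<hierarchy> not assessable (degenerate degree structure)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<hierarchy> P(k): slope %.2f (R2 %.2f); C(k): slope %.2f (R2 %.2f) -> %s\n",
    x$pk_fit$exponent, x$pk_fit$r_squared, x$ck_fit$exponent,
    x$ck_fit$r_squared,
    if (x$is_hierarchical) "hierarchical" else "not hierarchical"))
  cat("  criterion:", x$criterion, "\n")
  invisible(x)
}
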