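#' Single-input scan
#'
#' Evaluates every node as the sole input: its control energy
#' \eqn{\log_{10}\varepsilon(t_f)} (from [node_energies()], one block
#' exponential for all nodes) and its single-input LCC (BFS eccentricity).
#' This is the per-region table behind the LCC--energy relationship: regions
#' with small eccentricity, typically hubs, control the network with the
#' least energy.
#'
#' @param net a [binary_network()].
#' @param t_f control horizon.
#' @return data.frame with one row per node: `node`, `label`, `degree`,
#'   `log10_energy`, `lcc`.
#' @export
single_input_scan <- function(net, t_f = 1) {
  stopifnot(inherits(net, "binary_network"))
  eps <- node_energies(net, t_f)
  ecc <- lcc_range_single_input(net)$per_node
  data.frame(node = seq_len(net$n_nodes), label = node_names(net),
             degree = node_degree(net), log10_energy = log10(eps),
             lcc = ecc)
}

#' Rank-sum tests between adjacent LCC strata
#'
#' Groups the single-input scan by LCC and compares the
#' \eqn{\log_{10}\varepsilon} of adjacent strata (\eqn{\ell} vs
#' \eqn{\ell + 1}) with the two-sided Wilcoxon rank-sum test: exact
#' enumeration when both strata have at most 10 tie-free values, otherwise
#' the normal approximation with midranks and continuity correction. Strata
#' with fewer than 2 members are skipped with a warning; nodes with infinite
#' LCC are excluded.
#'
#' @param scan a [single_input_scan()] data.frame (columns `log10_energy`,
#'   `lcc`).
#' @return data.frame with one row per adjacent pair: `lcc_low`, `lcc_high`,
#'   `n_low`, `n_high`, `statistic`, `p_value`, and the stratum means.
#' @export
lcc_strata_test <- function(scan) {
  stopifnot(all(c("log10_energy", "lcc") %in% names(scan)))
  scan <- scan[is.finite(scan$lcc) & is.finite(scan$log10_energy), ]
  strata <- sort(unique(scan$lcc))
  if (length(strata) < 2) stop("need at least 2 LCC strata to compare")
  rows <- list()
  for (i in seq_len(length(strata) - 1)) {
    l0 <- strata[i]; l1 <- strata[i + 1]
    x <- scan$log10_energy[scan$lcc == l0]
    y <- scan$log10_energy[scan$lcc == l1]
    if (length(x) < 2 || length(y) < 2) {
      warning("stratum LCC = ", if (length(x) < 2) l0 else l1,
              " has fewer than 2 members; pair skipped")
      next
    }
    if (length(unique(c(x, y))) == 1) {
      # fully tied groups: statistic at its null mean, no evidence at all
      stat <- length(x) * length(y) / 2
      pv <- 1
    } else {
      exact <- length(x) <= 10 && length(y) <= 10 && !anyDuplicated(c(x, y))
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = exact, correct = TRUE))
      stat <- unname(wt$statistic)
      pv <- wt$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      lcc_low = l0, lcc_high = l1, n_low = length(x), n_high = length(y),
      statistic = stat, p_value = pv,
      mean_low = mean(x), mean_high = mean(y))
  }
  if (length(rows) == 0) stop("no adjacent strata pair had 2 members on both sides")
  do.call(rbind, rows)
}

#' Study configuration
#'
#' @param t_f control horizon.
#' @param lcc_targets vector of target LCC values for placement search.
#' @param census_sets input sets drawn by [input_set_census()] per network
#'   (0 skips the census).
#' @param census_lcc LCC constraint for the census.
#' @param null_replicates randomized replicates per network (0 skips the
#'   null-model comparison).
#' @param null_lcc LCC at which originals and nulls are compared.
#' @param epsilon rewiring residual probability.
#' @param seed study-level seed; per-network, per-stage seeds are derived as
#'   `seed + 101 * network_index + stage offset`.
#' @return object of class `study_config`.
#' @export
study_config <- function(t_f = 1, lcc_targets = 1:2, census_sets = 0L,
                         census_lcc = 1L, null_replicates = 0L, null_lcc = 1L,
                         epsilon = 1e-6, seed = 1L) {
  structure(list(t_f = t_f, lcc_targets = lcc_targets,
                 census_sets = as.integer(census_sets),
                 census_lcc = as.integer(census_lcc),
                 null_replicates = as.integer(null_replicates),
                 null_lcc = as.integer(null_lcc),
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full controllability study on a set of networks
#'
#' For each network: isolated nodes are removed; structural properties,
#' minimum driver count (maximum matching), the single-input energy/LCC scan,
#' adjacent-strata rank-sum tests, placement results (greedy cover and the
#' two hub baselines) for each target LCC, the motif census, optionally a
#' node-participation census and a degree-preserving null-model comparison.
#' Failures in one network are caught and logged, the run continues.
#'
#' @param networks list of [binary_network()] objects (a single network is
#'   accepted).
#' @param config a [study_config()].
#' @return object of class `study_report`: list with `networks` (per-network
#'   result lists), `config`, `errors`.
#' @export
run_study <- function(networks, config = study_config()) {
  if (inherits(networks, "binary_network")) networks <- list(networks)
  if (length(networks) == 0) {
    warning("empty network list; empty report")
    return(structure(list(networks = list(), config = config,
                          errors = character(0)), class = "study_report"))
  }
  errors <- character(0)
  results <- vector("list", length(networks))
  for (i in seq_along(networks)) {
    res <- tryCatch(
      run_study_one(networks[[i]], config,
                    seed = config$seed + 101L * i),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0("network ", i, ": ", conditionMessage(res)))
      results[[i]] <- NULL
    } else {
      results[[i]] <- res
    }
  }
  structure(list(networks = results, config = config, errors = errors),
            class = "study_report")
}

run_study_one <- function(net, config, seed) {
  ri <- remove_isolated(net)
  cc <- ri$network
  scan <- single_input_scan(cc, config$t_f)
  strata <- tryCatch(lcc_strata_test(scan), error = function(e) NULL,
                     warning = function(w) suppressWarnings(lcc_strata_test(scan)))
  placements <- lapply(config$lcc_targets, function(l) {
    opt <- min_inputs_for_lcc(cc, l, mode = "greedy")
    list(target_lcc = l, optimal = opt,
         hub_greedy = hub_greedy_for_lcc(cc, l),
         hub_matched = matched_size_hub_set(cc, opt))
  })
  census <- if (config$census_sets > 0) {
    input_set_census(cc, config$census_lcc, n_sets = config$census_sets,
                     seed = seed + 1L)
  } else NULL
  nulls <- if (config$null_replicates > 0) {
    cfg <- rewiring_config(epsilon = config$epsilon,
                           n_replicates = config$null_replicates,
                           seed = seed + 2L)
    randomized_ensemble_inputs(cc, config$null_lcc, cfg)
  } else NULL
  list(
    properties = properties(cc),
    removed_isolated = ri$removed,
    matching = maximum_matching(cc),
    scan = scan,
    strata_tests = strata,
    placements = placements,
    census = census,
    null_comparison = nulls,
    motifs = motif_census(cc)
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", length(x$networks), " network(s)\n", sep = "")
  for (i in seq_along(x$networks)) {
    r <- x$networks[[i]]
    if (is.null(r)) next
    cat(sprintf(
      " network %d: N = %d, N_i = %d, LCC range [%s, %s], M = %d\n",
      i, r$properties$n_nodes, r$matching$n_inputs,
      format(min(r$scan$lcc)), format(max(r$scan$lcc)), r$motifs$M))
  }
  if (length(x$errors)) cat(" errors:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

#' Write a study report to CSV files
#'
#' Emits per-network CSV tables (properties, scan, strata tests, placements,
#' census, null comparison, motifs) under `dir`.
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  nets <- report$networks
  if (length(nets)) {
    props <- do.call(rbind, lapply(seq_along(nets), function(i) {
      p <- nets[[i]]$properties
      data.frame(network = i, n_nodes = p$n_nodes, n_links = p$n_links,
                 H = p$heterogeneity, c = p$mean_degree, k_min = p$k_min,
                 k_max = p$k_max, d = p$mean_distance,
                 n_inputs = nets[[i]]$matching$n_inputs,
                 M = nets[[i]]$motifs$M)
    }))
    put(props, "properties.csv")
    for (i in seq_along(nets)) {
      put(nets[[i]]$scan, sprintf("scan_network%02d.csv", i))
      if (!is.null(nets[[i]]$strata_tests)) {
        put(nets[[i]]$strata_tests, sprintf("strata_network%02d.csv", i))
      }
      pl <- do.call(rbind, lapply(nets[[i]]$placements, function(p) {
        data.frame(target_lcc = p$target_lcc,
                   n_optimal = length(p$optimal$inputs),
                   n_hub_greedy = length(p$hub_greedy$inputs),
                   d_i = p$optimal$mean_pairwise_input_distance,
                   d_i_std = p$optimal$d_i_std,
                   d_i_hubs = p$hub_matched$mean_pairwise_input_distance,
                   d_i_hubs_std = p$hub_matched$d_i_std)
      }))
      put(pl, sprintf("placement_network%02d.csv", i))
      if (!is.null(nets[[i]]$census)) {
        put(nets[[i]]$census$counts, sprintf("census_network%02d.csv", i))
      }
    }
  }
  invisible(files)
}
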