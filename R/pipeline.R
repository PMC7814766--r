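#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the standard
#' defaults: age bands 7-11 / 12-17 / 18-29 years, density grid 8-35% in 1%
#' steps, hub grid 5-35% in 5% steps, hub z threshold 1.5, 5000 permutations,
#' 100 random references, consensus Louvain with 150 + 100 runs at agreement
#' threshold 0.5.
#'
#' @param input A cohort CSV path, a `cohort_table`, or a
#'   [synthetic_config()] (generated at run time).
#' @param measure Label of the morphometric measure ("SA" or "CT"); carried
#'   into outputs, not interpreted.
#' @param age_bands Named list of (min, max) age pairs; bands must not
#'   overlap. Subjects are assigned by closed-interval membership.
#' @param densities Density grid for the metric curves.
#' @param hub_grid Density grid averaged over for hub profiles.
#' @param hub_z Hub threshold on the z-scored average centrality.
#' @param n_perm Permutations per test family.
#' @param n_rand Random references for small-worldness.
#' @param tau Consensus agreement threshold.
#' @param consensus_runs Two integers: initial Louvain runs, consensus-matrix
#'   runs.
#' @param perm_metrics Which density-curve statistics enter the permutation
#'   family: any of "clustering", "path_length", "efficiency",
#'   "assortativity", "sigma", "modularity". Small-worldness and modularity
#'   are costly inside permutations (surrogates / Louvain per draw) and are
#'   off by default; their observed curves are always reported.
#' @param efficiency_variant Passed to [global_efficiency()].
#' @param case_group Label of the case (ASD-role) group whose consensus
#'   partition is transferred for the segregation contrasts.
#' @param by_group Passed to [regress_covariates()].
#' @param seed Top-level seed; every stage seed is derived from it.
#' @param out_dir Output directory; NULL skips writing artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, measure = "SA",
                            age_bands = list(child = c(7, 11),
                                             adolescent = c(12, 17),
                                             adult = c(18, 29)),
                            densities = seq(0.08, 0.35, by = 0.01),
                            hub_grid = seq(0.05, 0.35, by = 0.05),
                            hub_z = 1.5, n_perm = 5000L, n_rand = 100L,
                            tau = 0.5, consensus_runs = c(150L, 100L),
                            perm_metrics = c("clustering", "path_length",
                                             "efficiency", "assortativity"),
                            efficiency_variant = "inverse_L",
                            case_group = "B", by_group = FALSE,
                            seed = 1L, out_dir = NULL) {
  if (any(diff(densities) <= 0) || min(densities) <= 0 || max(densities) > 1) {
    stop("densities must be strictly increasing within (0, 1]")
  }
  bands <- do.call(rbind, age_bands)
  if (nrow(bands) > 1L) {
    o <- order(bands[, 1L])
    if (any(bands[o, 1L][-1L] <= bands[o, 2L][-nrow(bands)])) {
      stop("age bands overlap")
    }
  }
  perm_metrics <- match.arg(perm_metrics,
                            c("clustering", "path_length", "efficiency",
                              "assortativity", "sigma", "modularity"),
                            several.ok = TRUE)
  structure(list(input = input, measure = measure, age_bands = age_bands,
                 densities = densities, hub_grid = hub_grid, hub_z = hub_z,
                 n_perm = as.integer(n_perm), n_rand = as.integer(n_rand),
                 tau = tau, consensus_runs = as.integer(consensus_runs),
                 perm_metrics = perm_metrics,
                 efficiency_variant = efficiency_variant,
                 case_group = case_group, by_group = by_group,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `input` may be a cohort
#' CSV path.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$densities) && length(y$densities) == 3L &&
      !is.null(names(y$densities))) {
    y$densities <- seq(y$densities[["min"]], y$densities[["max"]],
                       by = y$densities[["step"]])
  }
  do.call(pipeline_config, y)
}

# ---- density-curve statistic used both for observed curves and permutations

curve_statistic <- function(config) {
  densities <- config$densities
  # fixed evaluation order, restricted to the configured set
  metrics <- intersect(c("clustering", "path_length", "efficiency",
                         "assortativity", "sigma", "modularity"),
                       config$perm_metrics)
  per_group <- function(X) {
    C <- stats::cor(X)
    graphs <- lapply(densities, function(d) threshold_density(C, d))
    one <- function(m) {
      switch(m,
        clustering = vapply(graphs, function(g)
          clustering_coefficient(g)$mean, numeric(1)),
        path_length = vapply(graphs, function(g)
          characteristic_path_length(g)$L, numeric(1)),
        efficiency = vapply(graphs, function(g)
          global_efficiency(g, config$efficiency_variant), numeric(1)),
        assortativity = {
          strength <- rowMeans(vapply(config$hub_grid, function(d) {
            eigenvector_centrality(threshold_density(C, d))$centrality
          }, numeric(nrow(C))))
          vapply(graphs, function(g)
            assortativity_strength(g, strength), numeric(1))
        },
        sigma = vapply(graphs, function(g)
          small_worldness(g, n_rand = config$n_rand, seed = 1L)$sigma,
          numeric(1)),
        modularity = vapply(graphs, function(g)
          modularity_q(g, louvain_once(C, seed = 1L)), numeric(1)))
    }
    unlist(lapply(metrics, one))
  }
  function(xa, xb) {
    d <- per_group(xa) - per_group(xb)
    names(d) <- paste0(rep(metrics, each = length(densities)), "_",
                       formatC(rep(densities, length(metrics)), format = "g"))
    d
  }
}

# observed (non-difference) metric curves for one group, incl. sigma and Q
observed_curves <- function(C, config, partition, sigma_seed) {
  graphs <- lapply(config$densities, function(d) threshold_density(C, d))
  strength <- rowMeans(vapply(config$hub_grid, function(d) {
    eigenvector_centrality(threshold_density(C, d))$centrality
  }, numeric(nrow(C))))
  data.frame(
    density = config$densities,
    clustering = vapply(graphs, function(g)
      clustering_coefficient(g)$mean, numeric(1)),
    path_length = vapply(graphs, function(g)
      characteristic_path_length(g)$L, numeric(1)),
    efficiency = vapply(graphs, function(g)
      global_efficiency(g, config$efficiency_variant), numeric(1)),
    sigma = vapply(graphs, function(g)
      small_worldness(g, n_rand = config$n_rand, seed = sigma_seed)$sigma,
      numeric(1)),
    modularity = vapply(graphs, function(g)
      modularity_q(g, partition), numeric(1)),
    assortativity = vapply(graphs, function(g)
      assortativity_strength(g, strength), numeric(1)),
    connected = vapply(graphs, function(g)
      !characteristic_path_length(g)$disconnected, logical(1))
  )
}

#' Run the full structural covariance network analysis
#'
#' Per age band: MAD rescaling, covariate regression, per-group covariance
#' matrices, metric curves over the density grid with center-paired
#' permutation tests, hub profiles and assortativity, consensus Louvain
#' modules per group, segregation-index contrasts with partition transfer
#' (case partition applied to both groups), regionwise group tests, and
#' structure-centrality correlations. All randomness derives from
#' `config$seed`, so reruns with the same config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with one entry per analyzed age band plus
#'   `manifest`; artifacts are written under `config$out_dir` if set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- config$input
  if (inherits(cohort, "synthetic_config")) cohort <- generate_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!is.data.frame(cohort)) stop("input must be a path, table or config")

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  band_seeds <- derive_seeds(config$seed, names(config$age_bands))
  results <- list()

  for (band in names(config$age_bands)) {
    rng <- config$age_bands[[band]]
    tab <- cohort[cohort$age >= rng[1] & cohort$age <= rng[2], , drop = FALSE]
    # keep only sites usable in this band: >= 2 subjects and both groups
    keep_sites <- names(which(vapply(split(tab$group, tab$site), function(g) {
      length(g) >= 2L && length(unique(g)) == 2L
    }, logical(1))))
    tab <- tab[tab$site %in% keep_sites, , drop = FALSE]
    grp_n <- table(tab$group)
    if (length(grp_n) < 2L || min(grp_n) < 6L) {
      message(sprintf("skipping band '%s': too few subjects", band))
      next
    }
    seeds <- derive_seeds(band_seeds[[band]],
                          c("perm_curves", "perm_si", "perm_region",
                            "consensus_a", "consensus_b", "sigma_a", "sigma_b"))
    rescaled <- mad_rescale(tab)
    res <- regress_covariates(rescaled, by_group = config$by_group)
    groups <- sort(unique(res$group))
    cov_list <- lapply(groups, function(g) build_covariance(res, g))
    names(cov_list) <- groups

    parts <- list(
      consensus_partition(cov_list[[1L]], n_runs = config$consensus_runs[1L],
                          tau = config$tau,
                          n_consensus_runs = config$consensus_runs[2L],
                          seed = seeds[["consensus_a"]]),
      consensus_partition(cov_list[[2L]], n_runs = config$consensus_runs[1L],
                          tau = config$tau,
                          n_consensus_runs = config$consensus_runs[2L],
                          seed = seeds[["consensus_b"]]))
    names(parts) <- groups

    curves <- lapply(groups, function(g) {
      observed_curves(cov_list[[g]], config, parts[[g]],
                      seeds[[if (g == groups[1L]) "sigma_a" else "sigma_b"]])
    })
    names(curves) <- groups

    curve_test <- permutation_test(
      res, statistic = curve_statistic(config), n_perm = config$n_perm,
      seed = seeds[["perm_curves"]], name = "metric curves (group difference)")
    # FDR family: the density grid within each metric
    curve_q <- unlist(lapply(config$perm_metrics, function(m) {
      fdr_correct(curve_test$p[grep(paste0("^", m, "_"),
                                    names(curve_test$observed))])$q
    }))

    hubs <- lapply(groups, function(g) {
      hub_profile(cov_list[[g]], grid = config$hub_grid,
                  z_threshold = config$hub_z)
    })
    names(hubs) <- groups

    # SI contrasts: case-group partition transferred to both groups
    case <- config$case_group
    ctrl <- setdiff(groups, case)[1L]
    case_part <- parts[[case]]
    modules <- sort(unique(as.integer(case_part)))
    testable <- modules[vapply(modules, function(m) {
      n_in <- sum(case_part == m)
      n_in >= 2L && n_in < length(case_part)
    }, logical(1))]
    si_stat <- function(xa, xb) {
      Xs <- list(xa, xb)
      names(Xs) <- groups
      ca <- stats::cor(Xs[[case]])
      cb <- stats::cor(Xs[[ctrl]])
      vapply(testable, function(m) {
        si_case <- segregation_index(ca, case_part, m)$si
        si_ctrl <- segregation_index(cb, case_part, m)$si
        si_case - si_ctrl
      }, numeric(1))
    }
    si_test <- permutation_test(
      res, statistic = si_stat, n_perm = config$n_perm,
      seed = seeds[["perm_si"]],
      name = sprintf("segregation index (group %s - group %s, partition of %s)",
                     case, ctrl, case))
    si_q <- fdr_correct(si_test$p)
    si_table <- data.frame(
      module = testable,
      n_regions = vapply(testable, function(m)
        sum(case_part == m), integer(1)),
      si_difference = unname(si_test$observed),
      ci_lower = unname(si_test$ci_lower), ci_upper = unname(si_test$ci_upper),
      p = si_test$p, q = si_q$q, reject = si_q$reject)

    regionwise <- regionwise_group_test(rescaled, n_perm = config$n_perm,
                                        seed = seeds[["perm_region"]])

    struct_cent <- lapply(groups, function(g) {
      correlate_structure_centrality(res[res$group == g, , drop = FALSE],
                                     hubs[[g]])
    })
    names(struct_cent) <- groups

    band_res <- list(band = band, n_subjects = as.list(grp_n),
                     residuals = res, covariance = cov_list,
                     partitions = parts, curves = curves,
                     curve_test = curve_test, curve_q = curve_q,
                     hubs = hubs, si_table = si_table, si_test = si_test,
                     regionwise = regionwise, struct_cent = struct_cent)
    results[[band]] <- band_res

    if (!is.null(out_dir)) {
      bd <- file.path(out_dir, band)
      dir.create(bd, recursive = TRUE, showWarnings = FALSE)
      write_cohort(res, file.path(bd, "residuals.csv"))
      for (g in groups) {
        write_covariance(cov_list[[g]],
                         file.path(bd, sprintf("covariance_%s.csv", g)))
        write_partition(parts[[g]],
                        file.path(bd, sprintf("partition_%s.csv", g)))
        utils::write.csv(curves[[g]],
                         file.path(bd, sprintf("curves_%s.csv", g)),
                         row.names = FALSE)
        utils::write.csv(hubs[[g]],
                         file.path(bd, sprintf("hubs_%s.csv", g)),
                         row.names = FALSE)
      }
      write_test_result(curve_test, file.path(bd, "curve_test.json"))
      write_test_result(si_test, file.path(bd, "si_test.json"))
      utils::write.csv(si_table, file.path(bd, "si_contrasts.csv"),
                       row.names = FALSE)
      utils::write.csv(regionwise, file.path(bd, "regionwise.csv"),
                       row.names = FALSE)
      jsonlite::write_json(struct_cent,
                           file.path(bd, "structure_centrality.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  manifest <- list(
    seed = config$seed, measure = config$measure,
    densities = config$densities, hub_grid = config$hub_grid,
    hub_z = config$hub_z, n_perm = config$n_perm, n_rand = config$n_rand,
    tau = config$tau, consensus_runs = config$consensus_runs,
    perm_metrics = config$perm_metrics,
    efficiency_variant = config$efficiency_variant,
    case_group = config$case_group, by_group = config$by_group,
    age_bands = config$age_bands,
    bands_analyzed = names(results),
    package_version = as.character(utils::packageVersion("scnet")))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  results$manifest <- manifest
  invisible(results)
}
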