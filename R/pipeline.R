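#' Configuration for the full analysis pipeline
#'
#' Defaults reproduce the study's stated settings: rare-taxon filter at a
#' mean of 2 reads per sample, the three diet-pair comparisons L-H, L-LSO
#' and H-HSO, networks thresholded at partial correlations of 0.05 and
#' 0.25, 999 PERMANOVA permutations, and hub detection at a betweenness
#' z-score of 1.5.  EBIC gamma 0.5 and pseudocount 1 are the package's
#' documented conventions where the procedure leaves a choice open.
#'
#' @param counts a [count_table], a path to a count TSV, or a
#'   [generator_config()] for a synthetic study.
#' @param metadata optional path to a sample-metadata TSV (ignored when
#'   `counts` already carries diet metadata).
#' @param diet_pairs character vector of diet-pair names.
#' @param thresholds ascending non-negative partial-correlation thresholds.
#' @param min_mean_per_sample rare-taxon filter threshold.
#' @param pseudocount offset for the log transform.
#' @param gamma,n_lambda,lambda_min_ratio EBIC-glasso settings.
#' @param n_permutations PERMANOVA permutations.
#' @param hub_z hub threshold on the betweenness z-score.
#' @param nmds_k,nmds_starts NMDS dimension and random starts.
#' @param seed root seed for every stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts,
                            metadata = NULL,
                            diet_pairs = c("L-H", "L-LSO", "H-HSO"),
                            thresholds = c(0.05, 0.25),
                            min_mean_per_sample = 2,
                            pseudocount = 1,
                            gamma = 0.5,
                            n_lambda = 100,
                            lambda_min_ratio = 0.01,
                            n_permutations = 999,
                            hub_z = 1.5,
                            nmds_k = 2,
                            nmds_starts = 10,
                            seed = 1) {
  stopifnot(all(thresholds >= 0), !is.unsorted(thresholds))
  structure(list(counts = counts, metadata = metadata,
                 diet_pairs = diet_pairs, thresholds = thresholds,
                 min_mean_per_sample = min_mean_per_sample,
                 pseudocount = pseudocount, gamma = gamma,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 n_permutations = n_permutations, hub_z = hub_z,
                 nmds_k = nmds_k, nmds_starts = nmds_starts, seed = seed),
            class = "pipeline_config")
}

#' Run the full multi-domain analysis pipeline
#'
#' Executes, deterministically given the seed: rare-taxon filtering of the
#' merged table; per-sample alpha diversity; Bray-Curtis dissimilarities
#' with NMDS ordination and PERMANOVA on diet; and, per diet pair, the
#' network stage — sample subset, natural-log transform, pairwise-complete
#' correlation, nearest-PD repair, EBIC-tuned graphical lasso, partial
#' correlations, and thresholded networks with centrality, hubs,
#' vicariance tests, densities and the betweenness ANOVA.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_report`: `config` echo, `filter` stage
#'   summary, `diversity`, `ordination`, `permanova`, and `pairs` — one
#'   entry per diet pair with the `ebic_glasso` fit and a per-threshold
#'   [network_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  table <- stage("input", {
    x <- config$counts
    if (inherits(x, "generator_config")) {
      generate_study(x)$table
    } else if (is.character(x)) {
      tb <- read_count_table(x)
      if (!is.null(config$metadata)) {
        tb <- attach_metadata(tb, read_sample_metadata(config$metadata))
      }
      tb
    } else if (inherits(x, "count_table")) {
      x
    } else stop("unsupported counts input")
  })
  if (!"diet" %in% names(table$samples)) {
    stop("pipeline requires diet metadata")
  }

  seeds <- derive_seeds(config$seed, 2)

  filtered <- stage("filter_rare_taxa",
                    filter_rare_taxa(table, config$min_mean_per_sample))
  dropped <- attr(filtered, "dropped_taxa")
  if (length(dropped)) {
    note("rare-taxon filter dropped %d of %d taxa", length(dropped),
         nrow(table$counts))
  }

  diversity <- stage("diversity", diversity_table(filtered))
  bc <- stage("bray_curtis", bray_curtis(to_relative_abundance(filtered)))
  ordination <- stage("nmds",
                      nmds(bc, k = config$nmds_k,
                           n_starts = config$nmds_starts, seed = seeds[1]))
  perm <- stage("permanova",
                permanova(bc, filtered$samples$diet,
                          n_permutations = config$n_permutations,
                          seed = seeds[2]))

  pairs <- list()
  for (pname in config$diet_pairs) {
    pair_tab <- stage(paste0("select_diet_pair[", pname, "]"),
                      select_diet_pair(filtered, pname))
    missing_tx <- attr(pair_tab, "all_missing_taxa")
    if (length(missing_tx)) {
      note("%s: %d taxa entirely unobserved in this comparison", pname,
           length(missing_tx))
    }
    fit <- stage(paste0("ebic_glasso[", pname, "]"), {
      lm_ <- transform_log(pair_tab, pseudocount = config$pseudocount)
      suppressWarnings(
        ebic_glasso(lm_, gamma = config$gamma, n_lambda = config$n_lambda,
                    lambda_min_ratio = config$lambda_min_ratio))
    })
    if (nrow(fit$dropped)) {
      note("%s: dropped %d variables before correlation", pname,
           nrow(fit$dropped))
    }
    nets <- lapply(config$thresholds, function(th) {
      net <- build_network(fit, threshold = th)
      network_report(net, hub_z = config$hub_z)
    })
    names(nets) <- paste0("threshold_", config$thresholds)
    pairs[[pname]] <- list(pair = pname, fit = fit, networks = nets,
                           all_missing_taxa = missing_tx)
  }

  structure(list(config = config,
                 filter = list(n_taxa_in = nrow(table$counts),
                               n_taxa_out = nrow(filtered$counts),
                               dropped_taxa = dropped),
                 diversity = diversity,
                 dissimilarity = bc,
                 ordination = ordination,
                 permanova = perm,
                 pairs = pairs,
                 warnings = warnings_log),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("rumennet run report\n")
  cat(sprintf("  taxa: %d -> %d after rare-taxon filter\n",
              x$filter$n_taxa_in, x$filter$n_taxa_out))
  cat(sprintf("  PERMANOVA (diet): pseudo-F = %.3f, p = %.4g\n",
              x$permanova$pseudo_F, x$permanova$p_value))
  cat(sprintf("  NMDS stress-1 = %.4f\n", x$ordination$stress))
  for (pr in x$pairs) {
    edge_counts <- vapply(pr$networks, `[[`, 0, "n_edges")
    cat(sprintf("  %s: lambda = %.4g; edges %s\n", pr$pair, pr$fit$lambda,
                paste(sprintf("%s at >%s", edge_counts,
                              sub("threshold_", "", names(pr$networks))),
                      collapse = ", ")))
  }
  if (length(x$warnings)) {
    cat("  notes:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

report_json <- function(report) {
  pair_summ <- lapply(report$pairs, function(pr) {
    nets <- lapply(pr$networks, function(nr) {
      list(threshold = nr$threshold,
           n_edges = nr$n_edges,
           hubs = nr$hubs,
           vicariance = lapply(Filter(Negate(is.null), nr$vicariance),
                               function(v) v[c("focal_domain", "k_within",
                                               "n_incident", "p0", "p_value",
                                               "sidedness")]),
           density = lapply(Filter(Negate(is.null), nr$density),
                            function(d) d[c("scope", "realized_edges",
                                            "possible_pairs",
                                            "density_percent")]),
           anova = if (is.null(nr$anova)) NULL else
             nr$anova[c("F", "df_between", "df_within", "p_value")])
    })
    list(pair = pr$pair,
         selected_lambda = pr$fit$lambda,
         gamma = pr$fit$gamma,
         n_effective = pr$fit$n_effective,
         n_variables = ncol(pr$fit$Theta),
         dropped_variables = pr$fit$dropped$variable,
         networks = nets)
  })
  cfg <- report$config
  cfg$counts <- if (inherits(cfg$counts, "generator_config")) {
    c(list(type = "synthetic"), unclass(cfg$counts))
  } else if (is.character(cfg$counts)) {
    list(type = "file", path = cfg$counts)
  } else list(type = "in-memory count_table")
  list(config = unclass(cfg),
       filter = report$filter,
       permanova = report$permanova[c("pseudo_F", "p_value",
                                      "n_permutations", "ss_among",
                                      "ss_within", "ss_total", "seed")],
       nmds = list(stress = report$ordination$stress,
                   converged = report$ordination$converged,
                   n_starts_used = report$ordination$n_starts_used),
       pairs = pair_summ,
       warnings = report$warnings)
}

#' Write all pipeline artifacts to a directory
#'
#' Stable layout: per-sample diversity TSV, the Bray-Curtis matrix and
#' NMDS coordinates as TSV, a JSON summary (`report.json`, containing the
#' config echo, PERMANOVA decomposition, per-pair network statistics and
#' warnings), and per diet pair the partial-correlation matrix, the
#' penalty path, and per threshold an edge list TSV plus GraphML.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_reports <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f, rn = FALSE) {
    utils::write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  }
  tsv(report$diversity, "diversity.tsv")
  tsv(as.data.frame(unclass(report$dissimilarity)), "bray_curtis.tsv",
      rn = TRUE)
  tsv(as.data.frame(report$ordination$coordinates), "nmds_coordinates.tsv",
      rn = TRUE)
  for (pr in report$pairs) {
    tag <- gsub("[^A-Za-z0-9]", "_", pr$pair)
    tsv(as.data.frame(pr$fit$pcor), paste0("pcor_", tag, ".tsv"), rn = TRUE)
    tsv(pr$fit$path, paste0("path_", tag, ".tsv"))
    for (nr in pr$networks) {
      net <- build_network(pr$fit, threshold = nr$threshold)
      base <- sprintf("network_%s_t%s", tag, nr$threshold)
      write_edge_list(net, file.path(outdir, paste0(base, ".tsv")))
      write_graphml(net, file.path(outdir, paste0(base, ".graphml")))
      tsv(nr$centrality, sprintf("betweenness_%s_t%s.tsv", tag,
                                 nr$threshold))
    }
  }
  jsonlite::write_json(report_json(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(outdir)
}
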