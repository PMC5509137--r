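#' Build a thresholded taxon co-occurrence network
#'
#' Nodes are all analysed taxa (isolated nodes are kept); an edge joins
#' taxa `i` and `j` when `|pcor_ij|` strictly exceeds the threshold, and
#' carries the signed partial correlation as its weight.  Following the
#' study design, networks are typically built at a permissive (0.05) and a
#' stringent (0.25) threshold.
#'
#' @param x an [ebic_glasso] fit or a symmetric partial-correlation matrix.
#' @param threshold non-negative threshold on `|pcor|` (strict inequality).
#' @param taxa optional data.frame with `taxon_id` and `domain` for the
#'   matrix interface; taken from the fit otherwise.
#' @return an object of class `taxon_network`: `nodes` (data.frame with
#'   `taxon_id`, `domain`), `edges` (data.frame with `taxon_a`, `taxon_b`,
#'   `weight`), and `threshold`.
#' @export
build_network <- function(x, threshold, taxa = NULL) {
  stopifnot(threshold >= 0)
  if (inherits(x, "ebic_glasso")) {
    pcor <- x$pcor
    if (is.null(taxa)) taxa <- x$taxa
  } else {
    pcor <- as.matrix(x)
  }
  p <- ncol(pcor)
  ids <- colnames(pcor)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  if (is.null(taxa)) {
    taxa <- data.frame(taxon_id = ids, domain = NA_character_,
                       stringsAsFactors = FALSE)
  }
  nodes <- data.frame(taxon_id = taxa$taxon_id, domain = taxa$domain,
                      stringsAsFactors = FALSE)
  pr <- upper_pairs(p)
  w <- pcor[pr]
  on <- abs(w) > threshold
  edges <- data.frame(taxon_a = nodes$taxon_id[pr[on, 1]],
                      taxon_b = nodes$taxon_id[pr[on, 2]],
                      weight = w[on], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "taxon_network")
}

#' @export
print.taxon_network <- function(x, ...) {
  cat(sprintf("taxon_network: %d nodes, %d edges (|pcor| > %g; %d+, %d-)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold,
              sum(x$edges$weight > 0), sum(x$edges$weight < 0)))
  invisible(x)
}

#' Convert a taxon network to an igraph object
#'
#' @param net a `taxon_network`.
#' @return an undirected [igraph::igraph] with `weight` edge attributes and
#'   `domain` vertex attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "taxon_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Weighted betweenness centrality of a taxon network
#'
#' Shortest paths use edge lengths `1 / |partial correlation|`, so stronger
#' associations are shorter; betweenness counts shortest paths through each
#' node with the standard equal-split accumulation over pairs.  Z-scores
#' standardise the raw values across nodes (all zero when the raw values
#' have no spread).
#'
#' @param net a `taxon_network`.
#' @return a data.frame of class `centrality_table` with columns
#'   `taxon_id`, `domain`, `betweenness`, `z`.
#' @export
weighted_betweenness <- function(net) {
  stopifnot(inherits(net, "taxon_network"))
  b <- stats::setNames(numeric(nrow(net$nodes)), net$nodes$taxon_id)
  if (nrow(net$edges) > 0) {
    g <- as_igraph(net)
    bw <- igraph::betweenness(g, directed = FALSE,
                              weights = 1 / abs(igraph::E(g)$weight))
    b[names(bw)] <- bw
  }
  s <- stats::sd(b)
  z <- if (is.na(s) || s == 0) rep(0, length(b)) else (b - mean(b)) / s
  out <- data.frame(taxon_id = net$nodes$taxon_id,
                    domain = net$nodes$domain,
                    betweenness = unname(b), z = unname(z),
                    stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", class(out))
  out
}

#' Identify hub taxa from standardized betweenness
#'
#' Hubs are taxa whose betweenness z-score exceeds `z_threshold`
#' (default 1.5): nodes acting as information gateways in the network.
#'
#' @param centrality a `centrality_table` from [weighted_betweenness()].
#' @param z_threshold hub cutoff on the z-score.
#' @return character vector of hub taxon ids (possibly empty).
#' @export
identify_hubs <- function(centrality, z_threshold = 1.5) {
  stopifnot(is.data.frame(centrality))
  if (all(centrality$z == 0) && stats::sd(centrality$betweenness) == 0) {
    warning("betweenness has no spread; no hubs identifiable")
    return(character(0))
  }
  centrality$taxon_id[centrality$z > z_threshold]
}

#' Exact binomial tail p-value
#'
#' One-sided `greater`: `P(X >= k)` under `Binomial(n, p0)`; `less`:
#' `P(X <= k)`; two-sided: the sum of outcome probabilities not exceeding
#' `P(X = k)` (the small-p method of [stats::binom.test()], which performs
#' the computation).
#'
#' @param k observed successes, `0 <= k <= n`.
#' @param n number of trials.
#' @param p0 null success probability in `(0, 1)`.
#' @param sidedness `"greater"` (default), `"less"` or `"two.sided"`.
#' @return the p-value.
#' @export
exact_binomial_pvalue <- function(k, n, p0,
                                  sidedness = c("greater", "less", "two.sided")) {
  sidedness <- match.arg(sidedness)
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  stats::binom.test(k, n, p = p0, alternative = sidedness)$p.value
}

#' Binomial vicariance test for within-domain edge enrichment
#'
#' Tests whether edges incident to a focal microbial domain connect within
#' that domain more often than expected by chance.  Since every edge has
#' exactly two endpoints, the number of within-domain edges among the
#' `n_incident` edges touching the domain has a binomial expectation; the
#' null proportion is `p0 = (n_d - 1) / (N - 1)` — the probability that the
#' second endpoint of an edge touching the domain also lies in it under
#' uniform endpoint choice, with `n_d` domain nodes out of `N` total.
#'
#' @param net a `taxon_network` with domain-labelled nodes.
#' @param focal_domain the domain to test.
#' @param sidedness alternative for the binomial test; the default
#'   `"greater"` asks whether taxa interact more within their own domain.
#' @return an object of class `vicariance_test`: `focal_domain`,
#'   `k_within`, `n_incident`, `p0`, `p_value`, `sidedness`.
#' @export
vicariance_binomial_test <- function(net, focal_domain,
                                     sidedness = c("greater", "less",
                                                   "two.sided")) {
  sidedness <- match.arg(sidedness)
  stopifnot(inherits(net, "taxon_network"))
  dom <- stats::setNames(net$nodes$domain, net$nodes$taxon_id)
  if (!focal_domain %in% dom) stop("no nodes in domain '", focal_domain, "'")
  da <- dom[net$edges$taxon_a]
  db <- dom[net$edges$taxon_b]
  incident <- da == focal_domain | db == focal_domain
  n_incident <- sum(incident)
  if (n_incident == 0) {
    stop("test undefined: no edges incident to domain '", focal_domain, "'")
  }
  k_within <- sum(da == focal_domain & db == focal_domain)
  n_d <- sum(dom == focal_domain)
  N <- length(dom)
  p0 <- (n_d - 1) / (N - 1)
  if (p0 <= 0 || p0 >= 1) stop("degenerate null proportion p0 = ", p0)
  structure(list(focal_domain = focal_domain, k_within = k_within,
                 n_incident = n_incident, p0 = p0,
                 p_value = exact_binomial_pvalue(k_within, n_incident, p0,
                                                 sidedness),
                 sidedness = sidedness),
            class = "vicariance_test")
}

#' @export
print.vicariance_test <- function(x, ...) {
  cat(sprintf(
    "vicariance test (%s): %d/%d incident edges within domain, p0 = %.3f, p = %.4g (%s)\n",
    x$focal_domain, x$k_within, x$n_incident, x$p0, x$p_value, x$sidedness))
  invisible(x)
}

#' Edge density within a domain, a set of domains, or the whole network
#'
#' Density is the percentage of realised edges among all node pairs of the
#' scope: `100 * realized / choose(m, 2)`.
#'
#' @param net a `taxon_network`.
#' @param domains `NULL` for the total network, a single domain name for a
#'   within-domain density, or several names for the density within their
#'   pooled node set.
#' @return an object of class `domain_density`: `scope`, `realized_edges`,
#'   `possible_pairs`, `density_percent`.
#' @export
domain_edge_density <- function(net, domains = NULL) {
  stopifnot(inherits(net, "taxon_network"))
  if (is.null(domains)) {
    in_scope <- rep(TRUE, nrow(net$nodes))
    scope <- "total"
  } else {
    in_scope <- net$nodes$domain %in% domains
    scope <- paste(domains, collapse = "+")
  }
  m <- sum(in_scope)
  if (m < 2) stop("scope '", scope, "' has fewer than 2 nodes")
  ids <- net$nodes$taxon_id[in_scope]
  realized <- sum(net$edges$taxon_a %in% ids & net$edges$taxon_b %in% ids)
  possible <- choose(m, 2)
  structure(list(scope = scope, realized_edges = realized,
                 possible_pairs = possible,
                 density_percent = 100 * realized / possible),
            class = "domain_density")
}

#' @export
print.domain_density <- function(x, ...) {
  cat(sprintf("edge density [%s]: %d/%d pairs = %.2f%%\n",
              x$scope, x$realized_edges, x$possible_pairs,
              x$density_percent))
  invisible(x)
}

#' One-way ANOVA of betweenness across microbial domains
#'
#' Tests whether mean (raw) betweenness differs among the domains with the
#' standard one-way F statistic.  When every value is identical the
#' degenerate convention `F = 0, p = 1` is returned.
#'
#' @param centrality a `centrality_table` from [weighted_betweenness()].
#' @return an object of class `betweenness_anova`: `F`, `df_between`,
#'   `df_within`, `p_value`.
#' @export
betweenness_domain_anova <- function(centrality) {
  stopifnot(is.data.frame(centrality))
  cl <- centrality[!is.na(centrality$domain), , drop = FALSE]
  counts <- table(cl$domain)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need at least 2 domains with at least 2 nodes each")
  }
  a <- length(counts)
  n <- nrow(cl)
  if (stats::sd(cl$betweenness) == 0) {
    res <- list(F = 0, df_between = a - 1L, df_within = n - a, p_value = 1)
  } else {
    fit <- suppressWarnings(
      stats::anova(stats::lm(betweenness ~ domain, data = cl)))
    res <- list(F = fit$`F value`[1], df_between = fit$Df[1],
                df_within = fit$Df[2], p_value = fit$`Pr(>F)`[1])
  }
  class(res) <- "betweenness_anova"
  res
}

#' @export
print.betweenness_anova <- function(x, ...) {
  cat(sprintf("betweenness ~ domain: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

#' Write a network edge list to TSV
#'
#' Columns: `taxon_a`, `taxon_b`, `pcor`, `sign`, `within_domain`.
#'
#' @param net a `taxon_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  dom <- stats::setNames(net$nodes$domain, net$nodes$taxon_id)
  out <- data.frame(taxon_a = net$edges$taxon_a,
                    taxon_b = net$edges$taxon_b,
                    pcor = net$edges$weight,
                    sign = ifelse(net$edges$weight >= 0, "+", "-"),
                    within_domain = dom[net$edges$taxon_a] ==
                      dom[net$edges$taxon_b],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network to GraphML
#'
#' @param net a `taxon_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' All network statistics for one thresholded network
#'
#' Convenience wrapper computing the centrality table, hubs, per-domain
#' vicariance tests, within/total edge densities and the betweenness
#' ANOVA.
#'
#' @param net a `taxon_network`.
#' @param hub_z hub threshold on the betweenness z-score.
#' @return a list with elements `centrality`, `hubs`, `vicariance`,
#'   `density`, `anova`, `n_edges`, `threshold`.
#' @export
network_report <- function(net, hub_z = 1.5) {
  centrality <- weighted_betweenness(net)
  hubs <- withCallingHandlers(
    identify_hubs(centrality, z_threshold = hub_z),
    warning = function(w) invokeRestart("muffleWarning"))
  domains <- unique(net$nodes$domain)
  domains <- domains[!is.na(domains)]
  vic <- lapply(stats::setNames(domains, domains), function(d) {
    tryCatch(vicariance_binomial_test(net, d),
             error = function(e) NULL)
  })
  dens <- lapply(stats::setNames(domains, domains), function(d) {
    tryCatch(domain_edge_density(net, d), error = function(e) NULL)
  })
  dens$total <- domain_edge_density(net)
  anova <- tryCatch(betweenness_domain_anova(centrality),
                    error = function(e) NULL)
  list(threshold = net$threshold, n_edges = nrow(net$edges),
       centrality = centrality, hubs = hubs, vicariance = vic,
       density = dens, anova = anova)
}
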