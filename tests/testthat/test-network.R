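pcor_fixture <- function(entries, ids = NULL) {
  p <- if (is.null(ids)) max(unlist(lapply(entries, `[`, 1:2)))
       else length(ids)
  m <- matrix(0, p, p)
  for (e in entries) {
    m[e[1], e[2]] <- m[e[2], e[1]] <- e[3]
  }
  if (is.null(ids)) ids <- paste0("t", seq_len(p))
  dimnames(m) <- list(ids, ids)
  m
}

test_that("network construction thresholds |pcor| strictly and keeps signs", {
  m <- pcor_fixture(list(c(1, 2, 0.3), c(2, 3, -0.26), c(3, 4, 0.05)))
  net <- build_network(m, 0.25)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(sign(net$edges$weight), c(1, -1))
  # exact boundary excluded
  mb <- pcor_fixture(list(c(1, 2, 0.25)))
  expect_equal(nrow(build_network(mb, 0.25)$edges), 0)
  # zero matrix keeps the full node set
  net0 <- build_network(matrix(0, 4, 4), 0.05)
  expect_equal(nrow(net0$nodes), 4)
  expect_equal(nrow(net0$edges), 0)
  # monotone in the threshold
  set.seed(24)
  mm <- pcor_fixture(lapply(1:10, function(i)
    c(sample(8, 2), runif(1, -0.5, 0.5))))
  e_low <- nrow(build_network(mm, 0.05)$edges)
  e_high <- nrow(build_network(mm, 0.25)$edges)
  expect_gte(e_low, e_high)
})

test_that("weighted betweenness reproduces closed forms", {
  # path a-b-c with equal weights: b carries the single shortest path
  taxa <- data.frame(taxon_id = c("a", "b", "c"), domain = "bacteria")
  m <- pcor_fixture(list(c(1, 2, 0.5), c(2, 3, 0.5)), ids = taxa$taxon_id)
  ct <- weighted_betweenness(build_network(m, 0.1, taxa = taxa))
  expect_equal(ct$betweenness, c(0, 1, 0))
  # star with 5 leaves: center (n-1)(n-2)/2 = 10
  ids <- c("hub", paste0("leaf", 1:5))
  entries <- lapply(2:6, function(j) c(1, j, 0.4))
  st <- pcor_fixture(entries, ids = ids)
  ct2 <- weighted_betweenness(
    build_network(st, 0.1, taxa = data.frame(taxon_id = ids,
                                             domain = "bacteria")))
  expect_equal(ct2$betweenness[1], 10)
  expect_equal(ct2$betweenness[-1], rep(0, 5))
  # weighted triangle: strong two-hop route beats the weak direct edge
  tri <- pcor_fixture(list(c(1, 2, 0.9), c(2, 3, 0.9), c(1, 3, 0.1)),
                      ids = c("a", "b", "c"))
  ct3 <- weighted_betweenness(
    build_network(tri, 0.05, taxa = data.frame(taxon_id = c("a", "b", "c"),
                                               domain = "bacteria")))
  expect_equal(ct3$betweenness, c(0, 1, 0))
})

test_that("betweenness matches a brute-force path-enumeration oracle", {
  set.seed(25)
  for (rep in 1:30) {
    n <- sample(4:7, 1)
    ids <- paste0("n", seq_len(n))
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.5
    w <- runif(nrow(pairs), 0.1, 0.9) * sample(c(-1, 1), nrow(pairs), TRUE)
    entries <- lapply(which(on), function(k) c(pairs[k, 1], pairs[k, 2], w[k]))
    if (!length(entries)) next
    m <- pcor_fixture(c(list(c(1, n, 0)), entries), ids = ids)
    net <- build_network(m, 0.05,
                         taxa = data.frame(taxon_id = ids, domain = "archaea"))
    ours <- weighted_betweenness(net)
    oracle <- brute_force_betweenness(ids, net$edges)
    expect_equal(ours$betweenness, unname(oracle[ours$taxon_id]),
                 tolerance = 1e-9)
  }
})

test_that("betweenness is invariant to rescaling all edge weights", {
  set.seed(26)
  ids <- paste0("n", 1:6)
  entries <- list(c(1, 2, 0.3), c(2, 3, 0.2), c(3, 4, 0.45), c(4, 5, 0.15),
                  c(5, 6, 0.5), c(1, 6, 0.35), c(2, 5, 0.25))
  m <- pcor_fixture(entries, ids = ids)
  taxa <- data.frame(taxon_id = ids, domain = "protozoa")
  b1 <- weighted_betweenness(build_network(m, 0.05, taxa = taxa))$betweenness
  b2 <- weighted_betweenness(build_network(m / 2, 0.05, taxa = taxa))$betweenness
  expect_equal(b1, b2)
})

test_that("hubs are taxa with standardized betweenness above the cutoff", {
  ct <- data.frame(taxon_id = paste0("t", 1:20), domain = "bacteria",
                   betweenness = c(10, rep(0, 19)))
  ct$z <- (ct$betweenness - mean(ct$betweenness)) / sd(ct$betweenness)
  expect_identical(identify_hubs(ct), "t1")
  expect_identical(identify_hubs(ct, z_threshold = Inf), character(0))
  flat <- data.frame(taxon_id = paste0("t", 1:5), domain = "fungi",
                     betweenness = rep(2, 5), z = rep(0, 5))
  expect_warning(h <- identify_hubs(flat), "no spread")
  expect_length(h, 0)
})

test_that("exact binomial p-values match direct tail summation", {
  expect_equal(exact_binomial_pvalue(0, 7, 0.3, "greater"), 1)
  expect_equal(exact_binomial_pvalue(6, 6, 0.5, "greater"), 0.5^6)
  expect_equal(exact_binomial_pvalue(3, 10, 0.3, "greater"),
               binom_tail_oracle(3, 10, 0.3))
  for (n in c(5, 12)) {
    for (p0 in c(0.2, 0.5)) {
      for (k in 0:n) {
        expect_equal(exact_binomial_pvalue(k, n, p0, "greater"),
                     binom_tail_oracle(k, n, p0), tolerance = 1e-12)
      }
    }
  }
})

test_that("vicariance test counts incident and within-domain edges", {
  ids <- c(paste0("b", 1:3), paste0("a", 1:3))
  taxa <- data.frame(taxon_id = ids,
                     domain = rep(c("bacteria", "archaea"), each = 3))
  # four edges, all within bacteria is impossible with 3 nodes; use 3 within +
  # a self-domain configuration: N=6, n_d=3 -> p0 = 2/5 = 0.4
  m <- pcor_fixture(list(c(1, 2, 0.5), c(1, 3, 0.5), c(2, 3, 0.5),
                         c(4, 5, 0.5)), ids = ids)
  net <- build_network(m, 0.1, taxa = taxa)
  v <- vicariance_binomial_test(net, "bacteria")
  expect_equal(v$p0, 0.4)
  expect_equal(v$k_within, 3)
  expect_equal(v$n_incident, 3)
  expect_equal(v$p_value, 0.4^3)
  # all incident edges between domains: k = 0, p = 1 one-sided greater
  m2 <- pcor_fixture(list(c(1, 4, 0.5), c(2, 5, 0.5)), ids = ids)
  v2 <- vicariance_binomial_test(build_network(m2, 0.1, taxa = taxa),
                                 "bacteria")
  expect_equal(v2$k_within, 0)
  expect_equal(v2$p_value, 1)
  # under-representation yields p >= 0.5 under "greater"
  expect_gte(v2$p_value, 0.5)
  # no incident edges -> test undefined
  m3 <- pcor_fixture(list(c(4, 5, 0.5)), ids = ids)
  expect_error(vicariance_binomial_test(build_network(m3, 0.1, taxa = taxa),
                                        "bacteria"), "undefined")
})

test_that("the spec'd vicariance worked example evaluates exactly", {
  # N = 6 nodes, n_d = 3 in the focal domain, 4 incident edges all within:
  # needs 4 within-domain edges among 3 nodes -> use a 4-node domain subset
  ids <- c(paste0("b", 1:3), "a1", "a2", "a3")
  taxa <- data.frame(taxon_id = ids,
                     domain = rep(c("bacteria", "archaea"), each = 3))
  p0 <- (3 - 1) / (6 - 1)
  expect_equal(exact_binomial_pvalue(4, 4, 0.4, "greater"), 0.4^4)
  expect_equal(0.4^4, 0.0256)
  expect_equal(p0, 0.4)
})

test_that("edge densities and the within/between partition add up", {
  ids <- c(paste0("b", 1:3), paste0("f", 1:2))
  taxa <- data.frame(taxon_id = ids,
                     domain = rep(c("bacteria", "fungi"), c(3, 2)))
  m <- pcor_fixture(list(c(1, 2, 0.5), c(1, 4, 0.4), c(4, 5, 0.3)), ids = ids)
  net <- build_network(m, 0.1, taxa = taxa)
  d_b <- domain_edge_density(net, "bacteria")
  expect_equal(d_b$density_percent, 100 * 1 / 3)
  d_f <- domain_edge_density(net, "fungi")
  expect_equal(d_f$density_percent, 100)
  d_all <- domain_edge_density(net)
  expect_equal(d_all$realized_edges, 3)
  # complete and empty subgraphs
  mc <- pcor_fixture(list(c(1, 2, 0.5), c(1, 3, 0.5), c(2, 3, 0.5)), ids = ids)
  expect_equal(domain_edge_density(build_network(mc, 0.1, taxa = taxa),
                                   "bacteria")$density_percent, 100)
  expect_equal(domain_edge_density(build_network(matrix(0, 5, 5), 0.1,
                                     taxa = taxa))$density_percent, 0)
  expect_error(domain_edge_density(net, "archaea"), "fewer than 2")
  # within + between = total edge count
  dom <- setNames(taxa$domain, taxa$taxon_id)
  within_total <- sum(vapply(unique(taxa$domain), function(d)
    domain_edge_density(net, d)$realized_edges, 0))
  between <- sum(dom[net$edges$taxon_a] != dom[net$edges$taxon_b])
  expect_equal(within_total + between, nrow(net$edges))
})

test_that("betweenness ANOVA across domains handles the degenerate case", {
  flat <- data.frame(taxon_id = paste0("t", 1:8),
                     domain = rep(c("bacteria", "archaea"), each = 4),
                     betweenness = rep(3, 8), z = 0)
  res <- betweenness_domain_anova(flat)
  expect_equal(res$F, 0)
  expect_equal(res$p_value, 1)
  sep <- flat
  sep$betweenness <- rep(c(0, 10), each = 4)
  res2 <- betweenness_domain_anova(sep)
  expect_lt(res2$p_value, 0.001)
  expect_equal(res2$df_between, 1)
  expect_equal(res2$df_within, 6)
  one <- flat[flat$domain == "bacteria", ]
  expect_error(betweenness_domain_anova(one), "at least 2 domains")
})

test_that("edge lists and GraphML round-trip through files", {
  ids <- c("b1", "b2", "f1")
  taxa <- data.frame(taxon_id = ids, domain = c("bacteria", "bacteria", "fungi"))
  m <- pcor_fixture(list(c(1, 2, 0.5), c(1, 3, -0.4)), ids = ids)
  net <- build_network(m, 0.1, taxa = taxa)
  tsv <- tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  el <- read.delim(tsv)
  expect_equal(nrow(el), 2)
  expect_setequal(el$sign, c("+", "-"))
  expect_equal(sum(el$within_domain), 1)
  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  # empty network still yields valid GraphML with all nodes
  net0 <- build_network(matrix(0, 3, 3), 0.1, taxa = taxa)
  write_graphml(net0, gml)
  g0 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g0), 3)
  expect_equal(igraph::ecount(g0), 0)
})
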