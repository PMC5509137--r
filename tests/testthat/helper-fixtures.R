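# Shared fixtures and independent oracles for the test suite.

# small study-shaped count table built in code
tiny_table <- function() {
  counts <- rbind(
    b1 = c(10, 20, 30, 40),
    b2 = c(5, 5, 5, 5),
    a1 = c(0, 2, 4, 8),
    f1 = c(3, 0, 7, 1))
  taxa <- data.frame(
    taxon_id = rownames(counts),
    domain = c("bacteria", "bacteria", "archaea", "fungi"),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste0("s", 1:4),
    cow = paste0("cow", c(1, 2, 1, 2)),
    period = c(1L, 1L, 2L, 2L),
    diet = c("H", "L", "H", "L"),
    stringsAsFactors = FALSE)
  count_table(counts, taxa, samples)
}

# write a count-table TSV from a character matrix of cells
write_fixture_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

random_pd_correlation <- function(p) {
  A <- matrix(rnorm(p * p), p)
  stats::cov2cor(crossprod(A) + diag(p))
}

# penalized Gaussian log-likelihood the graphical lasso maximises
glasso_objective <- function(Theta, R, lambda) {
  determinant(Theta, logarithm = TRUE)$modulus[1] - sum(R * Theta) -
    lambda * sum(abs(Theta[row(Theta) != col(Theta)]))
}

# Independent generic optimizer for the penalized likelihood: BFGS over a
# Cholesky parameterisation with a smoothed |x|, polished by repeated
# Nelder-Mead on the exact non-smooth objective.  Knows nothing about
# coordinate descent.
oracle_glasso_optimum <- function(R, lambda) {
  p <- ncol(R)
  par_to_theta <- function(par) {
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- par
    tcrossprod(L)
  }
  f_smooth <- function(par) {
    Th <- par_to_theta(par)
    ld <- determinant(Th, logarithm = TRUE)
    if (ld$sign <= 0) return(1e10)
    -(ld$modulus[1] - sum(R * Th) -
        lambda * sum(sqrt(Th[row(Th) != col(Th)]^2 + 1e-10)))
  }
  f_exact <- function(par) {
    Th <- par_to_theta(par)
    ld <- determinant(Th, logarithm = TRUE)
    if (ld$sign <= 0) return(1e10)
    -glasso_objective(Th, R, lambda)
  }
  best <- Inf
  for (s in 1:2) {
    M <- if (s == 1) diag(p) else solve(R)
    L0 <- t(chol(M))
    par <- L0[lower.tri(L0, diag = TRUE)]
    o <- stats::optim(par, f_smooth, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
    val <- Inf
    par <- o$par
    for (r in 1:25) {
      o2 <- stats::optim(par, f_exact, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-15))
      improved <- val - o2$value
      val <- o2$value
      par <- o2$par
      if (improved < 1e-10) break
    }
    best <- min(best, val)
  }
  -best
}

# Brute-force betweenness by exhaustive simple-path enumeration (DFS),
# independent of any shortest-path library code.  Edge lengths 1/|weight|.
brute_force_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  len <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      i <- edges$taxon_a[e]; j <- edges$taxon_b[e]
      len[i, j] <- len[j, i] <- 1 / abs(edges$weight[e])
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path, total) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1]] <<- list(path = path, length = total)
        return()
      }
      for (nb in nodes[adj[last, ]]) {
        if (!(nb %in% path)) walk(c(path, nb), total + len[last, nb])
      }
    }
    walk(from, 0)
    out
  }
  bet <- stats::setNames(numeric(n), nodes)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      paths <- all_paths(nodes[i], nodes[j])
      if (!length(paths)) next
      lens <- vapply(paths, `[[`, 0, "length")
      short <- paths[abs(lens - min(lens)) < 1e-12]
      for (pp in short) {
        inner <- setdiff(pp$path, c(nodes[i], nodes[j]))
        bet[inner] <- bet[inner] + 1 / length(short)
      }
    }
  }
  bet
}

# direct binomial tail by summation of the mass function
binom_tail_oracle <- function(k, n, p0) {
  sum(vapply(k:n, function(x) choose(n, x) * p0^x * (1 - p0)^(n - x), 0))
}
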