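#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds samples in `k` dimensions so that the rank order of configuration
#' distances matches the rank order of the input dissimilarities.  Each
#' iteration fits disparities by monotone (isotonic, pool-adjacent-
#' violators) regression of the configuration distances on the
#' dissimilarity ranks, then moves the configuration by a Guttman
#' transform towards the disparities; a step that fails to decrease
#' stress terminates the start.  The reported solution is the best of a
#' metric (principal-coordinates) start plus `n_starts` random starts.
#'
#' Ties in the dissimilarities are handled by the primary approach: tied
#' values may receive unequal disparities.
#'
#' @param d a `dissimilarity_matrix`, `dist`, or symmetric matrix.
#' @param k embedding dimension (default 2).
#' @param n_starts number of random starts in addition to the metric start.
#' @param max_iter maximum iterations per start.
#' @param tol convergence: stop when the stress decrease falls below `tol`.
#' @param seed integer seed for the random starts.
#' @return an object of class `nmds`: `coordinates` (samples x k),
#'   `stress` (Kruskal stress-1), `converged`, `n_starts_used`, `seed`,
#'   and `stress_trace` (per-iteration stress of the winning start).
#' @export
nmds <- function(d, k = 2, n_starts = 10, max_iter = 500, tol = 1e-7,
                 seed = NULL) {
  dm <- as.matrix(d)
  stopifnot(isSymmetric(unname(dm), tol = 1e-8), k >= 1)
  n <- nrow(dm)
  if (n < 3) stop("need at least 3 samples")
  dv <- dm[lower.tri(dm)]
  ord <- order(dv)
  denom_pos <- any(dv > 0)
  if (!denom_pos) stop("all dissimilarities are zero")

  run_start <- function(X) {
    X <- scale(X, scale = FALSE)
    trace <- numeric(0)
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Dv <- as.vector(stats::dist(X))
      dhat <- numeric(length(Dv))
      dhat[ord] <- stats::isoreg(seq_along(ord), Dv[ord])$yf
      ss_d <- sum(Dv^2)
      if (ss_d == 0) break
      stress <- sqrt(sum((Dv - dhat)^2) / ss_d)
      if (stress > prev + 1e-12) break  # safeguard: never accept an increase
      trace <- c(trace, stress)
      if (prev - stress < tol) {
        converged <- TRUE
        break
      }
      prev <- stress
      # Guttman transform towards the disparities
      Dm <- matrix(0, n, n)
      Dm[lower.tri(Dm)] <- Dv
      Dm <- Dm + t(Dm)
      Hm <- matrix(0, n, n)
      Hm[lower.tri(Hm)] <- dhat
      Hm <- Hm + t(Hm)
      Bm <- ifelse(Dm > 0, -Hm / Dm, 0)
      diag(Bm) <- 0
      diag(Bm) <- -rowSums(Bm)
      X_new <- Bm %*% X / n
      # evaluate; keep the old configuration if the step increased stress
      Dv_new <- as.vector(stats::dist(X_new))
      dhat_new <- numeric(length(Dv_new))
      dhat_new[ord] <- stats::isoreg(seq_along(ord), Dv_new[ord])$yf
      ss_new <- sum(Dv_new^2)
      stress_new <- if (ss_new > 0) {
        sqrt(sum((Dv_new - dhat_new)^2) / ss_new)
      } else Inf
      if (stress_new > stress + 1e-12) break
      X <- X_new
    }
    list(X = X, stress = if (length(trace)) trace[length(trace)] else Inf,
         trace = trace, converged = converged)
  }

  # metric start: classical scaling, padded with zeros if rank-deficient
  Xm <- suppressWarnings(stats::cmdscale(dm, k = k))
  if (ncol(Xm) < k) Xm <- cbind(Xm, matrix(0, n, k - ncol(Xm)))
  starts <- list(Xm)
  rand <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) matrix(stats::rnorm(n * k), n, k))
  })
  starts <- c(starts, rand)

  best <- NULL
  for (X0 in starts) {
    res <- run_start(X0)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  coords <- best$X
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("NMDS", seq_len(k))
  structure(list(coordinates = coords, stress = best$stress,
                 converged = best$converged,
                 n_starts_used = length(starts), seed = seed,
                 stress_trace = best$trace),
            class = "nmds")
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf("NMDS: %d samples in %d dimensions, stress-1 = %.4g (%s, %d starts)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "converged" else "not converged",
              x$n_starts_used))
  invisible(x)
}

#' @export
plot.nmds <- function(x, ...) {
  graphics::plot(x$coordinates[, 1], x$coordinates[, 2],
                 xlab = "NMDS1", ylab = "NMDS2", ...)
  invisible(x)
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Partitions dissimilarity-based sums of squares among and within groups:
#' `SS_total = sum_(i<j) d_ij^2 / N`, `SS_within = sum_g sum_(i<j in g)
#' d_ij^2 / n_g`, `SS_among = SS_total - SS_within`, and `pseudo-F =
#' (SS_among / (a - 1)) / (SS_within / (N - a))`.  Significance comes from
#' free permutation of the group labels: `p = (1 + #(F_perm >= F_obs)) /
#' (1 + n_permutations)`.
#'
#' @param d a `dissimilarity_matrix`, `dist`, or symmetric matrix.
#' @param groups group labels, length = number of samples.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return an object of class `permanova` with `pseudo_F`, `p_value`,
#'   `n_permutations`, `ss_among`, `ss_within`, `ss_total`, degrees of
#'   freedom and `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL) {
  dm <- as.matrix(d)
  groups <- as.factor(groups)
  n <- nrow(dm)
  stopifnot(length(groups) == n)
  a <- nlevels(droplevels(groups))
  if (a < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  ss_within_for <- function(g) {
    M <- stats::model.matrix(~ g - 1)
    per_group <- colSums((d2 %*% M) * M) / 2
    sum(per_group / colSums(M))
  }
  f_for <- function(g) {
    ssw <- ss_within_for(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  ss_within <- ss_within_for(groups)
  ss_among <- ss_total - ss_within
  f_obs <- (ss_among / (a - 1)) / (ss_within / (n - a))

  f_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) f_for(sample(groups)), 0)
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  structure(list(pseudo_F = f_obs, p_value = p,
                 n_permutations = n_permutations,
                 ss_among = ss_among, ss_within = ss_within,
                 ss_total = ss_total,
                 df_among = a - 1, df_within = n - a, seed = seed),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (free permutation of labels)\n")
  cat(sprintf("  pseudo-F = %.4g on %d and %d df, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df_among, x$df_within, x$p_value,
              x$n_permutations))
  cat(sprintf("  SS among = %.4g, within = %.4g, total = %.4g\n",
              x$ss_among, x$ss_within, x$ss_total))
  invisible(x)
}
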