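#' Pairwise-complete Pearson correlation with missing data
#'
#' Computes the correlation matrix of taxa (rows of an abundance matrix)
#' across samples, using for each pair of taxa only the samples where both
#' are observed.  This is what makes it possible to include a domain that
#' was not assayed under one diet: its taxa are correlated on their
#' observed samples, and cross-domain pairs on the intersection.  The
#' resulting matrix is a pseudo-correlation and need not be positive
#' definite; repair it with [nearest_positive_definite()] before the
#' graphical lasso.
#'
#' @param x an `abundance_matrix` (taxa x samples, `NA` = unobserved) or a
#'   plain numeric matrix in the statistical convention samples x variables.
#' @param min_obs minimum observed samples for a variable to be retained
#'   (default 3); variables below it, or with zero variance on their
#'   observed samples, are dropped and reported.
#' @param n_effective_strategy how to summarise pairwise complete counts
#'   into the single sample size used by EBIC: `"min"` (conservative,
#'   default) or `"mean"`.
#' @return an object of class `correlation_estimate`: `R` (correlation,
#'   unit diagonal), `n_pairs` (complete-observation counts), `n_effective`,
#'   `dropped` (data.frame of dropped variables and reasons), `taxa`
#'   (labels/domains of retained variables, when available).
#' @export
pairwise_complete_correlation <- function(x, min_obs = 3,
                                          n_effective_strategy = c("min", "mean")) {
  n_effective_strategy <- match.arg(n_effective_strategy)
  taxa <- NULL
  if (inherits(x, "abundance_matrix")) {
    taxa <- attr(x, "taxa")
    X <- t(unclass(x))  # samples x variables
  } else {
    X <- as.matrix(x)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n_obs <- colSums(!is.na(X))
  v_obs <- apply(X, 2, function(col) stats::var(col[!is.na(col)]))
  v_obs[is.na(v_obs)] <- 0
  drop_few <- n_obs < min_obs
  drop_flat <- !drop_few & v_obs == 0
  dropped <- data.frame(
    variable = colnames(X)[drop_few | drop_flat],
    reason = c(rep("too_few_observations", sum(drop_few)),
               rep("zero_variance", sum(drop_flat))),
    stringsAsFactors = FALSE)
  keep <- !(drop_few | drop_flat)
  if (sum(keep) < 2) stop("fewer than 2 variables remain after dropping")
  X <- X[, keep, drop = FALSE]
  R <- stats::cor(X, use = "pairwise.complete.obs")
  n_pairs <- crossprod(!is.na(X))
  if (anyNA(R)) {
    warning("variable pairs with < 2 complete observations; their ",
            "correlations set to 0")
    R[is.na(R)] <- 0
  }
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  off <- n_pairs[upper.tri(n_pairs)]
  n_eff <- if (n_effective_strategy == "min") min(off) else mean(off)
  if (!is.null(taxa)) taxa <- taxa[keep, , drop = FALSE]
  structure(list(R = R, n_pairs = n_pairs, n_effective = n_eff,
                 dropped = dropped, taxa = taxa, keep = which(keep)),
            class = "correlation_estimate")
}

#' Nearest positive-definite correlation matrix
#'
#' Repairs an indefinite pseudo-correlation matrix (as arises from
#' pairwise-complete estimation) by Higham's alternating projections with
#' Dykstra correction — eigenvalue clipping alternated with unit-diagonal
#' restoration — via [Matrix::nearPD()].
#'
#' @param R symmetric matrix with unit diagonal.
#' @param eig_floor smallest acceptable eigenvalue relative to the largest.
#' @param tol convergence tolerance on the relative Frobenius change.
#' @param max_iter maximum number of projection iterations; if exceeded the
#'   best iterate is returned with `attr(, "converged") = FALSE` and a
#'   warning.
#' @return a symmetric unit-diagonal matrix whose smallest eigenvalue is
#'   non-negative up to numerical tolerance.
#' @export
nearest_positive_definite <- function(R, eig_floor = 1e-6, tol = 1e-7,
                                      max_iter = 100) {
  R <- as.matrix(R)
  if (!isSymmetric(R, tol = 1e-8)) stop("R must be symmetric")
  res <- Matrix::nearPD(R, corr = TRUE, do2eigen = TRUE,
                        posd.tol = eig_floor, conv.tol = tol,
                        maxit = max_iter, ensureSymmetry = TRUE)
  out <- as.matrix(res$mat)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(R)
  if (!res$converged) {
    warning("nearest-PD projection did not converge in ", max_iter,
            " iterations; returning best iterate")
  }
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  out
}

#' Penalty grid for the graphical lasso path
#'
#' Log-spaced descending grid from the smallest penalty that empties the
#' graph (`max |off-diagonal|` of the correlation matrix) down to
#' `min_ratio` times it.
#'
#' @param R correlation matrix.
#' @param n_lambda grid length (default 100).
#' @param min_ratio ratio of smallest to largest penalty (default 0.01).
#' @return numeric vector, strictly decreasing.
#' @export
lambda_grid <- function(R, n_lambda = 100, min_ratio = 0.01) {
  stopifnot(n_lambda >= 1, min_ratio > 0, min_ratio < 1)
  off <- abs(R[upper.tri(R)])
  lmax <- if (length(off)) max(off) else 0
  if (lmax == 0) return(0)
  if (n_lambda == 1) return(lmax)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Graphical lasso at a single penalty
#'
#' Maximises the penalised Gaussian log-likelihood
#' `log det(Theta) - tr(R Theta) - lambda * sum_(i!=j) |Theta_ij|`
#' (penalty on off-diagonals only) by blockwise coordinate descent: each
#' column of the covariance estimate is updated by solving a lasso
#' subproblem.  `lambda = 0` returns the unpenalised MLE `solve(R)`
#' directly.
#'
#' @param R symmetric positive-definite correlation (or covariance) matrix.
#' @param lambda penalty, `>= 0`.
#' @param tol convergence: mean absolute change of the covariance estimate
#'   below `tol * mean |off-diagonal of R|`.
#' @param max_iter maximum outer sweeps.
#' @param warm optional list with elements `W` and `B` from a previous fit
#'   at a nearby penalty (used for warm starts along a path).
#' @param zero_tol entries of `Theta` below this magnitude are treated as
#'   exact zeros when counting edges.
#' @return an object of class `glasso_fit`: `lambda`, `Theta` (precision),
#'   `W` (covariance), `n_edges` (nonzero upper-triangle off-diagonals),
#'   `loglik` (`log det Theta - tr(R Theta)`), `converged`, `iterations`.
#' @export
glasso_fit <- function(R, lambda, tol = 1e-4, max_iter = 200, warm = NULL,
                       zero_tol = 1e-10) {
  R <- as.matrix(R)
  if (!isSymmetric(R, tol = 1e-8)) stop("R must be symmetric")
  if (lambda < 0) stop("lambda must be non-negative")
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    stop("R is not positive definite; apply nearest_positive_definite() first")
  }
  p <- ncol(R)
  if (lambda == 0) {
    Theta <- solve(R)
    Theta <- (Theta + t(Theta)) / 2
    fit <- list(W = R, Theta = Theta, B = matrix(0, p, p),
                iterations = 0L, converged = TRUE)
  } else {
    fit <- .glasso_cd(R, lambda, tol, max_iter,
                      if (is.null(warm)) NULL else warm$W,
                      if (is.null(warm)) NULL else warm$B)
  }
  Theta <- fit$Theta
  Theta[abs(Theta) < zero_tol & row(Theta) != col(Theta)] <- 0
  dimnames(Theta) <- dimnames(R)
  n_edges <- sum(Theta[upper.tri(Theta)] != 0)
  loglik <- determinant(Theta, logarithm = TRUE)$modulus[1] -
    sum(R * Theta)
  structure(list(lambda = lambda, Theta = Theta, W = fit$W, B = fit$B,
                 n_edges = n_edges, loglik = loglik,
                 converged = fit$converged, iterations = fit$iterations),
            class = "glasso_fit")
}

#' Extended Bayesian Information Criterion for a graphical-lasso fit
#'
#' With `l = (n/2) * (log det Theta - tr(R Theta))` and `E` the number of
#' estimated edges, `EBIC = -2 l + E log(n) + 4 E gamma log(p)`.
#' `gamma = 0` reduces to the ordinary BIC; larger values penalise model
#' size more heavily, which is appropriate when `p` approaches or exceeds
#' `n`.
#'
#' @param fit a [glasso_fit()].
#' @param R the correlation matrix the fit was computed from.
#' @param n effective sample size.
#' @param gamma EBIC hyperparameter in `[0, 1]`.
#' @return the EBIC value (smaller is better).
#' @export
ebic_score <- function(fit, R, n, gamma = 0.5) {
  stopifnot(inherits(fit, "glasso_fit"), n >= 2, gamma >= 0)
  p <- ncol(fit$Theta)
  l <- (n / 2) * fit$loglik
  -2 * l + fit$n_edges * log(n) + 4 * fit$n_edges * gamma * log(p)
}

#' Convert a precision matrix to partial correlations
#'
#' `pcor_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)`, with a zero diagonal
#' by convention.  In a Gaussian graphical model this is the correlation
#' between taxa `i` and `j` after removing the linear effect of all other
#' taxa; it is zero exactly when the precision entry is zero.
#'
#' @param Theta symmetric precision matrix with positive diagonal.
#' @return symmetric matrix of partial correlations, zero diagonal.
#' @export
precision_to_partial_correlation <- function(Theta) {
  Theta <- as.matrix(Theta)
  if (any(diag(Theta) <= 0)) stop("Theta must have a positive diagonal")
  d <- 1 / sqrt(diag(Theta))
  pcor <- -Theta * tcrossprod(d)
  diag(pcor) <- 0
  pcor
}

#' Fit a sparse Gaussian graphical model with EBIC-tuned graphical lasso
#'
#' The central estimator of the package.  From (log-transformed) taxon
#' abundances it computes the pairwise-complete correlation matrix, repairs
#' it to the nearest positive-definite correlation matrix, fits the
#' graphical lasso along a descending penalty path with warm starts, scores
#' every fit with the Extended BIC, and selects the penalty with the
#' smallest EBIC (ties broken toward the larger penalty, i.e. the sparser
#' graph).  The selected precision matrix is converted to partial
#' correlations, which are the edge weights of the co-occurrence network.
#'
#' @param x taxon abundances: an `abundance_matrix` (taxa x samples, from
#'   [transform_log()]), a plain samples x variables matrix, or a
#'   pre-computed `correlation_estimate`.
#' @param gamma EBIC hyperparameter (default 0.5, the common conservative
#'   choice for graph selection).
#' @param n_lambda,lambda_min_ratio penalty-grid parameters, see
#'   [lambda_grid()].
#' @param n effective sample size for EBIC; defaults to the pairwise
#'   estimate reported by [pairwise_complete_correlation()].
#' @param tol,max_iter convergence controls passed to [glasso_fit()].
#' @param keep_fits if `TRUE` all per-penalty fits are stored (memory
#'   permitting); otherwise only the selected fit.
#' @param ... passed to [pairwise_complete_correlation()].
#' @return an object of class `ebic_glasso` with, among others, elements
#'   `Theta` (selected precision), `pcor` (selected partial correlations),
#'   `path` (data.frame of lambda, edges, log-likelihood, EBIC),
#'   `selected` (index into the path), `R` (repaired correlation),
#'   `n_effective`, and `taxa` (labels of retained variables).
#' @examples
#' study <- generate_study(generator_config(seed = 42))
#' lp <- select_diet_pair(study$table, "L-H")
#' fit <- ebic_glasso(transform_log(filter_rare_taxa(lp)))
#' fit
#' @export
ebic_glasso <- function(x, gamma = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01, n = NULL, tol = 1e-4,
                        max_iter = 200, keep_fits = FALSE, ...) {
  est <- if (inherits(x, "correlation_estimate")) x
         else pairwise_complete_correlation(x, ...)
  R_raw <- est$R
  ev <- eigen(R_raw, symmetric = TRUE, only.values = TRUE)$values
  repaired <- FALSE
  R <- R_raw
  if (min(ev) < 1e-8 * max(ev)) {
    R <- nearest_positive_definite(R_raw)
    repaired <- TRUE
  }
  if (is.null(n)) n <- est$n_effective
  lambdas <- lambda_grid(R, n_lambda = n_lambda, min_ratio = lambda_min_ratio)
  fits <- vector("list", length(lambdas))
  ebic <- numeric(length(lambdas))
  warm <- NULL
  for (i in seq_along(lambdas)) {
    fits[[i]] <- glasso_fit(R, lambdas[i], tol = tol, max_iter = max_iter,
                            warm = warm)
    warm <- fits[[i]]
    ebic[i] <- ebic_score(fits[[i]], R, n = n, gamma = gamma)
  }
  # argmin; on ties keep the earliest index = largest lambda = sparser model
  selected <- which.min(ebic)
  sel_fit <- fits[[selected]]
  path <- data.frame(lambda = lambdas,
                     n_edges = vapply(fits, `[[`, 0, "n_edges"),
                     loglik = vapply(fits, `[[`, 0, "loglik"),
                     converged = vapply(fits, `[[`, TRUE, "converged"),
                     ebic = ebic)
  structure(list(Theta = sel_fit$Theta,
                 pcor = precision_to_partial_correlation(sel_fit$Theta),
                 W = sel_fit$W,
                 path = path, selected = selected,
                 lambda = lambdas[selected],
                 gamma = gamma, n_effective = n,
                 R = R, R_raw = R_raw, repaired = repaired,
                 n_pairs = est$n_pairs, dropped = est$dropped,
                 taxa = est$taxa,
                 fits = if (keep_fits) fits else NULL),
            class = "ebic_glasso")
}

#' @export
print.ebic_glasso <- function(x, ...) {
  p <- ncol(x$Theta)
  cat("EBIC graphical lasso fit\n")
  cat(sprintf("  variables: %d, effective n: %g, gamma: %g\n",
              p, x$n_effective, x$gamma))
  cat(sprintf("  path: %d penalties in [%.4g, %.4g]%s\n",
              nrow(x$path), min(x$path$lambda), max(x$path$lambda),
              if (x$repaired) " (correlation repaired to nearest PD)" else ""))
  cat(sprintf("  selected lambda = %.4g with %d edges (EBIC = %.2f)\n",
              x$lambda, x$path$n_edges[x$selected],
              x$path$ebic[x$selected]))
  if (nrow(x$dropped)) {
    cat("  dropped variables:", paste(x$dropped$variable, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.ebic_glasso <- function(object, ...) {
  pc <- object$pcor[upper.tri(object$pcor)]
  nz <- pc[pc != 0]
  out <- list(
    n_variables = ncol(object$Theta),
    n_effective = object$n_effective,
    gamma = object$gamma,
    lambda = object$lambda,
    n_edges = object$path$n_edges[object$selected],
    n_positive = sum(nz > 0), n_negative = sum(nz < 0),
    pcor_range = if (length(nz)) range(abs(nz)) else c(NA_real_, NA_real_),
    path = object$path, dropped = object$dropped)
  class(out) <- "summary.ebic_glasso"
  out
}

#' @export
print.summary.ebic_glasso <- function(x, ...) {
  cat(sprintf("EBIC graphical lasso: %d variables, n = %g, gamma = %g\n",
              x$n_variables, x$n_effective, x$gamma))
  cat(sprintf("  selected lambda %.4g: %d edges (%d positive, %d negative)\n",
              x$lambda, x$n_edges, x$n_positive, x$n_negative))
  if (x$n_edges > 0) {
    cat(sprintf("  |partial correlation| range: %.3f .. %.3f\n",
                x$pcor_range[1], x$pcor_range[2]))
  }
  invisible(x)
}

#' @export
coef.ebic_glasso <- function(object, ...) object$pcor

#' @export
plot.ebic_glasso <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(log(x$path$lambda), x$path$ebic, type = "l",
                 xlab = "log(lambda)", ylab = "EBIC", ...)
  graphics::abline(v = log(x$lambda), lty = 2)
  graphics::plot(log(x$path$lambda), x$path$n_edges, type = "l",
                 xlab = "log(lambda)", ylab = "edges", ...)
  graphics::abline(v = log(x$lambda), lty = 2)
  invisible(x)
}

#' Simulate Gaussian data from a fitted graphical model
#'
#' Draws multivariate-normal samples whose precision matrix is the selected
#' sparse estimate, useful for parametric-bootstrap checks.
#'
#' @param object an `ebic_glasso` fit.
#' @param nsim number of samples.
#' @param seed integer seed.
#' @param ... unused.
#' @return an `nsim x p` matrix.
#' @export
simulate.ebic_glasso <- function(object, nsim = 1, seed = NULL, ...) {
  Sigma <- solve(object$Theta)
  Sigma <- (Sigma + t(Sigma)) / 2
  L <- chol(Sigma)
  with_seed(seed, {
    matrix(stats::rnorm(nsim * ncol(Sigma)), nsim) %*% L
  })
}
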