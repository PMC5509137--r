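test_that("pairwise-complete correlation equals Pearson on complete data", {
  set.seed(10)
  X <- matrix(rnorm(80), 20, 4)
  est <- pairwise_complete_correlation(X)
  expect_equal(unname(est$R), unname(cor(X)))
  expect_true(all(est$n_pairs == 20))
  expect_equal(est$n_effective, 20)
})

test_that("pairwise-complete correlation uses exactly the shared samples", {
  set.seed(11)
  X <- matrix(rnorm(16), 8, 2)
  X[5:8, 1] <- NA
  X[1:2, 2] <- NA
  est <- pairwise_complete_correlation(X)
  shared <- 3:4
  expect_equal(est$R[1, 2], cor(X[shared, 1], X[shared, 2]))
  expect_equal(est$n_pairs[1, 2], length(shared))
  expect_no_warning(pairwise_complete_correlation(cbind(X, rnorm(8))))
})

test_that("a domain missing in half the samples is handled pairwise-complete", {
  # emulate fungi absent from the HSO half of an H-HSO comparison
  set.seed(12)
  n <- 8
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- c(paste0("b", 1:4), paste0("f", 1:2))
  X[5:8, 5:6] <- NA  # fungal taxa unobserved in the second half
  est <- pairwise_complete_correlation(X)
  expect_equal(est$R["f1", "f2"], cor(X[1:4, 5], X[1:4, 6]))
  expect_equal(est$R["b1", "f1"], cor(X[1:4, 1], X[1:4, 5]))
  expect_equal(est$R["b1", "b2"], cor(X[, 1], X[, 2]))
  expect_equal(est$n_pairs["f1", "f2"], 4)
  expect_equal(est$n_effective, 4)
  expect_equal(pairwise_complete_correlation(X,
                 n_effective_strategy = "mean")$n_effective,
               mean(est$n_pairs[upper.tri(est$n_pairs)]))
})

test_that("under-observed and flat variables are dropped with a report", {
  set.seed(13)
  X <- matrix(rnorm(40), 10, 4)
  X[3:10, 2] <- NA          # only 2 observations
  X[, 3] <- 5               # zero variance
  est <- pairwise_complete_correlation(X)
  expect_equal(ncol(est$R), 2)
  expect_setequal(est$dropped$variable, c("V2", "V3"))
  expect_setequal(est$dropped$reason,
                  c("too_few_observations", "zero_variance"))
  expect_error(pairwise_complete_correlation(X[, 2:3]), "fewer than 2")
})

test_that("nearest-PD repair fixes indefinite matrices and fixes points PD ones", {
  R_bad <- matrix(c(1, 0.9, -0.9,
                    0.9, 1, 0.9,
                    -0.9, 0.9, 1), 3)
  expect_lt(min(eigen(R_bad, symmetric = TRUE, only.values = TRUE)$values), 0)
  R_fix <- nearest_positive_definite(R_bad)
  expect_equal(unname(diag(R_fix)), rep(1, 3))
  expect_gte(min(eigen(R_fix, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # idempotence
  R_fix2 <- nearest_positive_definite(R_fix)
  expect_lt(max(abs(R_fix2 - R_fix)), 1e-6)
  # PD input returned unchanged
  set.seed(14)
  R_ok <- random_pd_correlation(5)
  expect_lt(max(abs(nearest_positive_definite(R_ok) - R_ok)), 1e-8)
  expect_error(nearest_positive_definite(matrix(1:4, 2)), "symmetric")
})

test_that("lambda grid is log-spaced from the largest off-diagonal", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.8
  R[1, 3] <- R[3, 1] <- 0.1
  g <- lambda_grid(R, n_lambda = 100, min_ratio = 0.01)
  expect_length(g, 100)
  expect_equal(g[1], 0.8)
  expect_equal(g[100], 0.008)
  expect_true(all(diff(g) < 0))
  expect_equal(lambda_grid(R, n_lambda = 1), 0.8)
  expect_equal(lambda_grid(diag(4)), 0)
})

test_that("graphical lasso solves the 2x2 problem in closed form", {
  for (r in c(0.6, -0.45, 0.2)) {
    R <- matrix(c(1, r, r, 1), 2)
    for (lam in c(0.1, 0.3, abs(r), abs(r) + 0.05)) {
      f <- glasso_fit(R, lam)
      if (abs(r) > lam) {
        expect_equal(f$W[1, 2], sign(r) * (abs(r) - lam), tolerance = 1e-8)
        expect_equal(f$Theta, solve(f$W), tolerance = 1e-7)
        expect_equal(f$n_edges, 1)
      } else {
        expect_equal(f$n_edges, 0)
        expect_equal(unname(f$Theta), diag(2))
      }
    }
  }
})

test_that("unpenalized fit inverts the correlation matrix", {
  set.seed(15)
  R <- random_pd_correlation(6)
  f <- glasso_fit(R, 0)
  expect_lt(max(abs(f$Theta - solve(R))), 1e-6)
  expect_true(f$converged)
})

test_that("a penalty above all off-diagonals empties the graph", {
  set.seed(16)
  R <- random_pd_correlation(5)
  lam <- max(abs(R[upper.tri(R)]))
  f <- glasso_fit(R, lam + 1e-6)
  expect_equal(f$n_edges, 0)
  expect_equal(unname(f$Theta), diag(1 / diag(R)))
})

test_that("glasso rejects non-PD inputs with advice", {
  R_bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(glasso_fit(R_bad, 0.1), "nearest_positive_definite")
})

test_that("glasso objective matches a generic optimizer on small problems", {
  set.seed(17)
  for (i in 1:6) {
    p <- sample(2:4, 1)
    R <- random_pd_correlation(p)
    lam <- runif(1, 0.05, 0.4)
    f <- glasso_fit(R, lam, tol = 1e-7, max_iter = 500)
    ours <- glasso_objective(f$Theta, R, lam)
    oracle <- oracle_glasso_optimum(R, lam)
    expect_lt(abs(ours - oracle), 1e-4)
  }
})

test_that("strong edges never appear as the penalty grows", {
  # glasso solution paths are not exactly support-monotone: edges near
  # their entry penalty can flicker in and out.  The meaningful property
  # is that any edge appearing while lambda increases is weak; edges of
  # material partial correlation only vanish.
  set.seed(18)
  appearing <- numeric(0)
  for (i in 1:5) {
    R <- random_pd_correlation(8)
    g <- lambda_grid(R, n_lambda = 25)
    warm <- NULL
    prev_support <- NULL
    for (lam in rev(g)) {  # ascending lambda
      f <- glasso_fit(R, lam, warm = warm)
      warm <- f
      pc <- precision_to_partial_correlation(f$Theta)
      sup <- abs(pc) > 1e-10 & upper.tri(pc)
      if (!is.null(prev_support) && any(sup & !prev_support)) {
        appearing <- c(appearing, abs(pc)[sup & !prev_support])
      }
      prev_support <- sup
    }
  }
  expect_true(length(appearing) == 0 || max(appearing) <= 0.1)
})

test_that("EBIC reduces to BIC at gamma 0 and to -2l for empty graphs", {
  set.seed(19)
  R <- random_pd_correlation(4)
  f <- glasso_fit(R, 0.15)
  n <- 50
  l <- (n / 2) * f$loglik
  expect_equal(ebic_score(f, R, n, gamma = 0), -2 * l + f$n_edges * log(n))
  f_empty <- glasso_fit(R, 1)
  expect_equal(ebic_score(f_empty, R, n, gamma = 0.5),
               -n * f_empty$loglik)
})

test_that("EBIC on a worked 2x2 fixture matches independent arithmetic", {
  r <- 0.7; lam <- 0.2; n <- 8; gamma <- 0.5
  f <- glasso_fit(matrix(c(1, r, r, 1), 2), lam)
  # independent scalar evaluation from the closed-form solution
  w <- r - lam
  Theta <- matrix(c(1, -w, -w, 1), 2) / (1 - w^2)
  logdet <- log(Theta[1, 1] * Theta[2, 2] - Theta[1, 2]^2)
  trace <- Theta[1, 1] + Theta[2, 2] + 2 * r * Theta[1, 2]
  expected <- -2 * (n / 2) * (logdet - trace) + 1 * log(n) +
    4 * 1 * gamma * log(2)
  expect_equal(ebic_score(f, matrix(c(1, r, r, 1), 2), n, gamma), expected,
               tolerance = 1e-6)
})

test_that("precision converts to partial correlations by the standard formula", {
  expect_equal(precision_to_partial_correlation(diag(c(2, 3, 4))),
               matrix(0, 3, 3))
  Th <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_partial_correlation(Th)[1, 2], 0.5)
  expect_error(precision_to_partial_correlation(matrix(c(-1, 0, 0, 1), 2)),
               "positive diagonal")
  # bivariate identity: partial correlation equals Pearson correlation
  set.seed(20)
  X <- matrix(rnorm(400), 200, 2)
  X[, 2] <- 0.6 * X[, 1] + 0.8 * X[, 2]
  f <- glasso_fit(cor(X), 0)
  expect_equal(precision_to_partial_correlation(f$Theta)[1, 2],
               cor(X)[1, 2], tolerance = 1e-6)
})

test_that("EBIC model selection finds empty and block-structured truths", {
  # a single-point grid selects that fit
  set.seed(21)
  fit1 <- ebic_glasso(matrix(rnorm(200), 50, 4), n_lambda = 1)
  expect_equal(nrow(fit1$path), 1)
  expect_equal(fit1$selected, 1)

  # independent variables: empty model selected in nearly all seeds
  empties <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(200 * 10), 200, 10)
    fit <- ebic_glasso(X, n = 200)
    fit$path$n_edges[fit$selected]
  }, 0)
  expect_gte(mean(empties == 0), 0.95)

  # strong 2-variable blocks: selected support equals the planted support
  Theta <- diag(6)
  for (i in c(1, 3, 5)) Theta[i, i + 1] <- Theta[i + 1, i] <- -0.5
  truth <- structure(list(precision = Theta), class = "ground_truth")
  Z <- simulate_gaussian_latents(truth, 500, seed = 22)
  fit <- ebic_glasso(Z, n = 500)
  sup <- abs(fit$pcor) > 0 & upper.tri(fit$pcor)
  expected <- matrix(FALSE, 6, 6)
  for (i in c(1, 3, 5)) expected[i, i + 1] <- TRUE
  expect_identical(unname(sup), expected)
})

test_that("EBIC ties select the sparser (larger-penalty) model", {
  set.seed(23)
  X <- matrix(rnorm(100 * 6), 100, 6)
  fit <- ebic_glasso(X, n = 100)
  mins <- which(fit$path$ebic == min(fit$path$ebic))
  expect_equal(fit$selected, min(mins))
  expect_equal(fit$lambda, max(fit$path$lambda[mins]))
})

test_that("the fitted model object behaves like a classed fit", {
  study <- generate_study(generator_config(seed = 33))
  lp <- select_diet_pair(study$table, "L-H")
  fit <- suppressWarnings(ebic_glasso(transform_log(lp), n_lambda = 20))
  expect_s3_class(fit, "ebic_glasso")
  expect_output(print(fit), "selected lambda")
  sm <- summary(fit)
  expect_output(print(sm), "EBIC graphical lasso")
  expect_identical(coef(fit), fit$pcor)
  expect_equal(dim(coef(fit)), rep(ncol(fit$Theta), 2))
  sims <- simulate(fit, nsim = 25, seed = 1)
  expect_equal(dim(sims), c(25, ncol(fit$Theta)))
  expect_identical(sims, simulate(fit, nsim = 25, seed = 1))
})
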