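#' Simpson's index of diversity (1 - D)
#'
#' `1 - sum(p_i^2)` for a relative-abundance vector `p`.  Zero for a
#' single-taxon community, approaching 1 as diversity increases.
#'
#' @param p numeric vector of relative abundances summing to 1.
#' @return the index value in `[0, 1)`.
#' @export
simpson_index <- function(p) {
  check_rel_abundance(p)
  1 - sum(p^2)
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i log p_i)` over positive entries.
#'
#' @inheritParams simpson_index
#' @return the index value, `>= 0`.
#' @export
shannon_index <- function(p) {
  check_rel_abundance(p)
  q <- p[p > 0]
  -sum(q * log(q))
}

#' Observed richness
#'
#' Number of taxa with strictly positive counts.
#'
#' @param counts numeric vector of counts or abundances, `>= 0`.
#' @return integer count of present taxa.
#' @export
observed_richness <- function(counts) {
  stopifnot(all(counts >= 0, na.rm = TRUE))
  sum(counts > 0, na.rm = TRUE)
}

#' Pielou's evenness
#'
#' `J = H / log(S)`, the Shannon index relative to its maximum for the
#' observed richness.  Undefined for communities with fewer than two taxa
#' (returned as `NA` with a warning).
#'
#' @inheritParams simpson_index
#' @return the evenness in `[0, 1]`, or `NA` if richness `<= 1`.
#' @export
pielou_evenness <- function(p) {
  check_rel_abundance(p)
  s <- sum(p > 0)
  if (s <= 1) {
    warning("evenness undefined for richness <= 1")
    return(NA_real_)
  }
  shannon_index(p) / log(s)
}

check_rel_abundance <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("p must be a relative-abundance vector (non-negative, summing to 1)")
  }
  invisible(p)
}

#' Per-sample alpha diversity of a count table
#'
#' Computes richness, Shannon (natural log), Simpson (1 - D) and Pielou
#' evenness for each sample, using observed cells only.
#'
#' @param x a [count_table].
#' @return data.frame with one row per sample, alongside available diet
#'   metadata.
#' @export
diversity_table <- function(x) {
  stopifnot(inherits(x, "count_table"))
  out <- lapply(seq_len(ncol(x$counts)), function(j) {
    cts <- x$counts[x$mask[, j], j]
    tot <- sum(cts)
    if (tot <= 0) {
      return(data.frame(richness = 0L, shannon = NA_real_,
                        simpson = NA_real_, pielou = NA_real_))
    }
    p <- cts / tot
    s <- observed_richness(cts)
    data.frame(richness = s, shannon = shannon_index(p),
               simpson = simpson_index(p),
               pielou = if (s > 1) shannon_index(p) / log(s) else NA_real_)
  })
  res <- cbind(x$samples, do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_xy = sum |x_i - y_i| / sum (x_i + y_i)` between sample columns,
#' computed with [vegan::vegdist()].  Unobserved cells are treated as
#' absences.  Bray-Curtis is bounded in `[0, 1]` and is a semi-metric (the
#' triangle inequality may fail).
#'
#' @param x a [count_table], an `abundance_matrix`, or a taxa x samples
#'   numeric matrix with non-negative entries.
#' @return a symmetric `samples x samples` matrix of class
#'   `dissimilarity_matrix` with zero diagonal.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(unclass(x))
  m[is.na(m)] <- 0
  if (any(m < 0)) stop("abundances must be non-negative")
  zero <- colSums(m) <= 0
  if (any(zero)) {
    stop("all-zero sample(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  diag(d) <- 0
  class(d) <- c("dissimilarity_matrix", class(matrix()))
  d
}
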