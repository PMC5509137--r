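#' @keywords internal
abundance_matrix <- function(values, table, transform_tag) {
  dimnames(values) <- dimnames(table$counts)
  structure(values,
            taxa = table$taxa, samples = table$samples,
            transform_tag = transform_tag,
            class = c("abundance_matrix", class(matrix())))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix (", attr(x, "transform_tag"), "): ",
      nrow(x), " taxa x ", ncol(x), " samples, ",
      sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

#' Natural-log transform of absolute counts
#'
#' Returns `ln(count + pseudocount)` on observed cells and `NA` on masked
#' cells.  This is the transform applied to counts before correlation-based
#' network inference.
#'
#' @param x a [count_table].
#' @param pseudocount non-negative offset added before taking logs
#'   (default 1, so zero counts map to 0).
#' @return an `abundance_matrix` with `transform_tag = "log_natural"`.
#' @export
transform_log <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "count_table"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  v <- log(x$counts + pseudocount)
  v[!x$mask] <- NA_real_
  abundance_matrix(v, x, "log_natural")
}

#' Per-taxon standardized log2 abundances
#'
#' Computes `log2(count + pseudocount)` and standardizes each taxon across
#' its observed samples to mean 0 and standard deviation 1 (sample,
#' i.e. divide-by-(n-1), convention).  Zero-variance taxa are returned as
#' rows of zeros with a warning.
#'
#' @inheritParams transform_log
#' @return an `abundance_matrix` with `transform_tag = "log2_zscore"`.
#' @export
transform_log2_zscore <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "count_table"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (any(rowSums(x$mask) < 2)) {
    stop("each taxon needs at least 2 observed samples to standardize")
  }
  v <- log2(x$counts + pseudocount)
  v[!x$mask] <- NA_real_
  flat <- FALSE
  for (i in seq_len(nrow(v))) {
    obs <- !is.na(v[i, ])
    m <- mean(v[i, obs])
    s <- stats::sd(v[i, obs])
    if (s == 0) {
      v[i, obs] <- 0
      flat <- TRUE
    } else {
      v[i, obs] <- (v[i, obs] - m) / s
    }
  }
  if (flat) warning("zero-variance taxa standardized to all-zero rows")
  abundance_matrix(v, x, "log2_zscore")
}

#' Per-sample relative abundances
#'
#' Divides each sample's observed counts by their total, so observed
#' entries of each column sum to 1.
#'
#' @param x a [count_table].
#' @return an `abundance_matrix` with `transform_tag = "relative"`.
#' @export
to_relative_abundance <- function(x) {
  stopifnot(inherits(x, "count_table"))
  v <- x$counts
  v[!x$mask] <- NA_real_
  tot <- colSums(v, na.rm = TRUE)
  zero <- tot <= 0
  if (any(zero)) {
    stop("zero-total sample(s): ",
         paste(x$samples$sample_id[zero], collapse = ", "))
  }
  abundance_matrix(sweep(v, 2, tot, "/"), x, "relative")
}
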