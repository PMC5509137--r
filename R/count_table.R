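#' @keywords internal
DIET_LEVELS <- c("H", "HSO", "L", "LSO")

#' @keywords internal
DOMAIN_LEVELS <- c("bacteria", "archaea", "protozoa", "fungi")

#' Construct a multi-domain count table
#'
#' A `count_table` couples a taxa-by-samples matrix of non-negative counts
#' with per-taxon domain labels, per-sample study metadata (cow, period,
#' diet), and an observedness mask.  Mask cells set to `FALSE` mark
#' taxon/sample combinations that were not assayed (for example a microbial
#' domain not measured under one diet); such cells carry no count
#' information and propagate as missing values through all transforms.
#'
#' @param counts numeric matrix, taxa in rows and samples in columns;
#'   non-negative on observed cells.
#' @param taxa data.frame with columns `taxon_id`, `domain` (one of
#'   `"bacteria"`, `"archaea"`, `"protozoa"`, `"fungi"`) and optionally
#'   `lineage`.
#' @param samples data.frame with column `sample_id` and optionally `cow`,
#'   `period` (integer 1-4) and `diet` (one of `"H"`, `"HSO"`, `"L"`,
#'   `"LSO"`).  Defaults to bare sample ids taken from `colnames(counts)`.
#' @param mask logical matrix of the same shape as `counts`; `TRUE` where
#'   the cell was observed.  Defaults to all observed.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, taxa, samples = NULL, mask = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(counts), ncol(counts))
  }
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(counts))) {
    stop("mask dimensions must match counts")
  }
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "domain") %in% names(taxa))) {
    stop("taxa must have columns 'taxon_id' and 'domain'")
  }
  if (anyDuplicated(taxa$taxon_id)) {
    dup <- unique(taxa$taxon_id[duplicated(taxa$taxon_id)])
    stop("duplicate taxon ids: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(taxa$domain), DOMAIN_LEVELS)
  if (length(bad)) {
    stop("unknown domain label(s): ", paste(bad, collapse = ", "))
  }
  if (nrow(taxa) != nrow(counts)) {
    stop("taxa rows must match count rows")
  }
  if (is.null(samples)) {
    ids <- colnames(counts)
    if (is.null(ids)) ids <- paste0("S", seq_len(ncol(counts)))
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples)) {
    stop("samples must have a 'sample_id' column")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids")
  }
  if (nrow(samples) != ncol(counts)) {
    stop("sample metadata rows must match count columns")
  }
  if ("diet" %in% names(samples)) {
    bad <- setdiff(unique(samples$diet), DIET_LEVELS)
    if (length(bad)) {
      stop("unknown diet level(s): ", paste(bad, collapse = ", "))
    }
  }
  obs <- counts[mask]
  if (any(!is.finite(obs)) || any(obs < 0)) {
    stop("counts must be finite and non-negative on observed cells")
  }
  counts[!mask] <- 0
  dimnames(counts) <- list(taxa$taxon_id, samples$sample_id)
  dimnames(mask) <- dimnames(counts)
  structure(
    list(counts = counts, taxa = taxa, samples = samples, mask = mask),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  dom <- table(factor(x$taxa$domain, levels = DOMAIN_LEVELS))
  cat("count_table: ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  domains:", paste(sprintf("%s=%d", names(dom), dom), collapse = ", "),
      "\n")
  if ("diet" %in% names(x$samples)) {
    dt <- table(x$samples$diet)
    cat("  diets:  ", paste(sprintf("%s=%d", names(dt), dt), collapse = ", "),
        "\n")
  }
  n_masked <- sum(!x$mask)
  if (n_masked > 0) {
    cat("  unobserved cells:", n_masked, "\n")
  }
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read a count table from TSV
#'
#' Expects a tab-separated file with a `taxon_id` column, a domain column
#' (default `domain`), an optional `lineage` column, and one column per
#' sample.  Lines starting with `#` are ignored.  The sentinel `NA` marks
#' unobserved cells (domain not assayed for that sample) and yields
#' `mask = FALSE` there.
#'
#' @param path file path.
#' @param domain_column name of the column holding the domain label.
#' @return a [count_table].
#' @export
read_count_table <- function(path, domain_column = "domain") {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (!"taxon_id" %in% names(df)) stop("missing 'taxon_id' column in ", path)
  if (!domain_column %in% names(df)) {
    stop("missing domain column '", domain_column, "' in ", path)
  }
  meta_cols <- c("taxon_id", domain_column,
                 intersect("lineage", names(df)))
  sample_cols <- setdiff(names(df), meta_cols)
  if (!length(sample_cols)) stop("no sample columns in ", path)
  raw <- as.matrix(df[, sample_cols, drop = FALSE])
  mask <- !(raw == "NA" | raw == "" | is.na(raw))
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(mask & !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric count at taxon '%s', sample '%s'",
                 df$taxon_id[bad[1, 1]], sample_cols[bad[1, 2]]))
  }
  neg <- which(mask & vals < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative count at taxon '%s', sample '%s'",
                 df$taxon_id[neg[1, 1]], sample_cols[neg[1, 2]]))
  }
  vals[!mask] <- 0
  taxa <- data.frame(taxon_id = df$taxon_id, domain = df[[domain_column]],
                     stringsAsFactors = FALSE)
  if ("lineage" %in% names(df)) taxa$lineage <- df$lineage
  count_table(vals, taxa,
              samples = data.frame(sample_id = sample_cols,
                                   stringsAsFactors = FALSE),
              mask = mask)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]: unobserved cells are written as the
#' sentinel `NA`.
#'
#' @param x a [count_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  vals <- matrix(format_count(x$counts), nrow(x$counts))
  vals[!x$mask] <- "NA"
  out <- data.frame(taxon_id = x$taxa$taxon_id, domain = x$taxa$domain,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if ("lineage" %in% names(x$taxa)) out$lineage <- x$taxa$lineage
  out <- cbind(out, as.data.frame(vals, stringsAsFactors = FALSE))
  names(out) <- c(names(out)[seq_len(ncol(out) - ncol(x$counts))],
                  x$samples$sample_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_count <- function(v) {
  ifelse(v == round(v), format(v, scientific = FALSE, trim = TRUE),
         as.character(v))
}

#' Read sample metadata from TSV
#'
#' @param path tab-separated file with columns `sample_id`, `cow`, `period`,
#'   `diet`.
#' @return a validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "cow", "period", "diet")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$diet), DIET_LEVELS)
  if (length(bad)) stop("unknown diet level(s): ", paste(bad, collapse = ", "))
  df$period <- as.integer(df$period)
  df
}

#' Attach sample metadata to a count table
#'
#' @param x a [count_table].
#' @param metadata data.frame with a `sample_id` column covering all samples
#'   of `x`.
#' @return `x` with its `samples` slot replaced by the matched metadata.
#' @export
attach_metadata <- function(x, metadata) {
  stopifnot(inherits(x, "count_table"))
  idx <- match(x$samples$sample_id, metadata$sample_id)
  if (anyNA(idx)) {
    stop("metadata missing sample(s): ",
         paste(x$samples$sample_id[is.na(idx)], collapse = ", "))
  }
  count_table(x$counts, x$taxa,
              samples = metadata[idx, , drop = FALSE], mask = x$mask)
}

#' Merge per-domain count tables over a shared sample set
#'
#' Row-concatenates count tables (typically one per microbial domain) that
#' cover the same samples.  Taxon ids must be disjoint across tables;
#' domain labels and masks are preserved.
#'
#' @param tables list of [count_table] objects.
#' @return a single merged [count_table].
#' @export
merge_domain_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  if (length(tables) == 1) return(tables[[1]])
  ref <- tables[[1]]$samples$sample_id
  for (i in seq_along(tables)[-1]) {
    ids <- tables[[i]]$samples$sample_id
    if (!setequal(ids, ref)) {
      diff <- c(setdiff(ref, ids), setdiff(ids, ref))
      stop("sample sets differ between tables: ", paste(diff, collapse = ", "))
    }
  }
  all_ids <- unlist(lapply(tables, function(t) t$taxa$taxon_id))
  if (anyDuplicated(all_ids)) {
    dup <- unique(all_ids[duplicated(all_ids)])
    stop("taxon id(s) shared between tables: ", paste(dup, collapse = ", "))
  }
  # keep the richest sample metadata available (prefer one carrying diet)
  samples <- tables[[1]]$samples
  for (t in tables) if ("diet" %in% names(t$samples)) samples <- t$samples
  aligned <- lapply(tables, function(t) {
    j <- match(samples$sample_id, t$samples$sample_id)
    list(counts = t$counts[, j, drop = FALSE],
         mask = t$mask[, j, drop = FALSE], taxa = t$taxa)
  })
  taxa_cols <- Reduce(intersect, lapply(aligned, function(a) names(a$taxa)))
  count_table(do.call(rbind, lapply(aligned, `[[`, "counts")),
              do.call(rbind, lapply(aligned, function(a)
                a$taxa[, taxa_cols, drop = FALSE])),
              samples = samples,
              mask = do.call(rbind, lapply(aligned, `[[`, "mask")))
}

#' Filter rare taxa by mean count per observed sample
#'
#' Removes taxa whose mean count over their observed samples falls below
#' `min_mean_per_sample` (default 2 reads per sample, the conventional
#' rare-taxon cut for genus-level amplicon tables).  The boundary value is
#' retained.  Applied to the full study table before any diet-pair split so
#' that all comparisons share one taxon universe.
#'
#' @param x a [count_table].
#' @param min_mean_per_sample minimum mean count per observed sample.
#' @return the filtered [count_table]; dropped taxon ids are available in
#'   `attr(, "dropped_taxa")`.
#' @export
filter_rare_taxa <- function(x, min_mean_per_sample = 2) {
  stopifnot(inherits(x, "count_table"))
  n_obs <- rowSums(x$mask)
  means <- ifelse(n_obs > 0, rowSums(x$counts * x$mask) / n_obs, 0)
  keep <- means >= min_mean_per_sample
  if (!any(keep)) warning("all taxa fall below the rare-taxon threshold")
  out <- count_table(x$counts[keep, , drop = FALSE],
                     x$taxa[keep, , drop = FALSE],
                     samples = x$samples,
                     mask = x$mask[keep, , drop = FALSE])
  attr(out, "dropped_taxa") <- x$taxa$taxon_id[!keep]
  out
}

#' Define a diet-pair comparison
#'
#' The study compares three diet changes: concentrate level (`"L-H"`), oil
#' supplementation on the low-concentrate diet (`"L-LSO"`) and on the
#' high-concentrate diet (`"H-HSO"`).  Arbitrary pairs of distinct diet
#' levels are also accepted.
#'
#' @param x either a pair name such as `"L-H"` or a character vector of two
#'   distinct diet levels.
#' @return an object of class `diet_pair` with fields `name` and `diets`.
#' @export
diet_pair <- function(x) {
  if (length(x) == 1) {
    parts <- strsplit(x, "-", fixed = TRUE)[[1]]
  } else {
    parts <- x
  }
  if (length(parts) != 2 || parts[1] == parts[2]) {
    stop("a diet pair needs exactly two distinct diets")
  }
  bad <- setdiff(parts, DIET_LEVELS)
  if (length(bad)) stop("unknown diet level(s): ", paste(bad, collapse = ", "))
  structure(list(name = paste(parts, collapse = "-"), diets = parts),
            class = "diet_pair")
}

#' Subset a count table to one diet-pair comparison
#'
#' @param x a [count_table] whose sample metadata carries `diet`.
#' @param pair a [diet_pair] or a pair name accepted by [diet_pair()].
#' @return a [count_table] restricted to samples of the two diets.  Taxa
#'   whose cells are entirely unobserved in the subset (e.g. a domain not
#'   assayed under one of the diets) keep `mask = FALSE` rows and are
#'   reported in `attr(, "all_missing_taxa")` for downstream exclusion.
#' @export
select_diet_pair <- function(x, pair) {
  stopifnot(inherits(x, "count_table"))
  if (!inherits(pair, "diet_pair")) pair <- diet_pair(pair)
  if (!"diet" %in% names(x$samples)) stop("table has no diet metadata")
  absent <- setdiff(pair$diets, unique(x$samples$diet))
  if (length(absent)) {
    stop("diet level(s) absent from table: ", paste(absent, collapse = ", "))
  }
  j <- x$samples$diet %in% pair$diets
  out <- count_table(x$counts[, j, drop = FALSE], x$taxa,
                     samples = x$samples[j, , drop = FALSE],
                     mask = x$mask[, j, drop = FALSE])
  attr(out, "pair") <- pair
  attr(out, "all_missing_taxa") <- x$taxa$taxon_id[rowSums(out$mask) == 0]
  out
}
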