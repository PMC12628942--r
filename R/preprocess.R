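#' Rarefy a count table to even depth
#'
#' Seeded subsampling without replacement (hypergeometric draw, via
#' [vegan::rrarefy()]) of every sample to a common depth. Samples whose total
#' is below the depth are dropped with a warning rather than padded, trading
#' a few samples for an even per-sample effort.
#'
#' @param table a [count_table].
#' @param depth target library size (> 0); e.g. 4485 for 16S, 10526 for ITS,
#'   1079 for 18S, 412 for 28S.
#' @param seed integer seed; identical seed gives identical output.
#' @return a [count_table] whose retained columns each sum to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  if (!is.numeric(depth) || length(depth) != 1 || depth <= 0)
    stop("rarefy: depth must be a single positive count")
  depth <- as.integer(depth)
  totals <- colSums(table$counts)
  keep <- totals >= depth
  if (!all(keep))
    warning("rarefy: dropping ", sum(!keep), " sample(s) below depth ", depth,
            ": ", paste(sample_ids(table)[!keep], collapse = ", "))
  if (!any(keep))
    stop("rarefy: no sample reaches depth ", depth)
  sub <- table$counts[, keep, drop = FALSE]
  set.seed(seed)
  sub_t <- t(sub)  # vegan orientation: samples x taxa
  rar <- suppressWarnings(vegan::rrarefy(sub_t, depth))
  # restore shape/dimnames (rrarefy collapses degenerate single-taxon input)
  rar <- matrix(as.integer(rar), nrow = nrow(sub_t), ncol = ncol(sub_t),
                dimnames = dimnames(sub_t))
  count_table(t(rar), table$domain)
}

#' Merge per-domain count tables into one multitrophic table
#'
#' Row-concatenates the tables over a shared sample set, prefixing taxon ids
#' with the domain initial (`B_`, `F_`, `P_`, `N_`) so identical ASV labels
#' from different markers cannot collide.
#'
#' @param tables list of [count_table]s over identical sample-id sets
#'   (order may differ; columns are aligned to the first table).
#' @return a single [count_table].
#' @export
merge_domains <- function(tables) {
  stopifnot(length(tables) >= 1, all(vapply(tables, inherits, TRUE, "count_table")))
  ref <- sample_ids(tables[[1]])
  for (t in tables[-1]) {
    diff <- c(setdiff(ref, sample_ids(t)), setdiff(sample_ids(t), ref))
    if (length(diff) > 0)
      stop("merge_domains: sample-id mismatch; differing sample(s): ",
           paste(unique(diff), collapse = ", "))
  }
  mats <- lapply(tables, function(t) {
    m <- t$counts[, ref, drop = FALSE]
    rownames(m) <- paste(DOMAIN_PREFIX[t$domain], rownames(m), sep = "_")
    m
  })
  domains <- unlist(lapply(tables, function(t) unname(t$domain)))
  count_table(do.call(rbind, mats), domains)
}

#' Prevalence filter
#'
#' Retains taxa detected (count > 0) in strictly more than `min_frac` of the
#' samples; with the default 0.5, presence in 9 of 18 samples is not enough.
#'
#' @param table a [count_table].
#' @param min_frac prevalence threshold in `[0, 1)`.
#' @return the filtered [count_table]; empty (with a warning) if nothing passes.
#' @export
prevalence_filter <- function(table, min_frac = 0.5) {
  stopifnot(inherits(table, "count_table"))
  if (min_frac < 0 || min_frac >= 1)
    stop("prevalence_filter: min_frac must be in [0, 1)")
  prev <- rowSums(table$counts > 0)
  keep <- prev > min_frac * ncol(table$counts)
  if (!any(keep))
    warning("prevalence_filter: no taxon detected in more than ",
            round(100 * min_frac), "% of samples; returning empty table")
  subset_taxa(table, keep)
}

#' Log-transform counts for correlation analysis
#'
#' Zeros are replaced by a small pseudo-abundance and all values are
#' log10-transformed, the standard pre-correlation transform for rarefied
#' ASV counts. Strictly monotone in the input counts.
#'
#' @param table a [count_table].
#' @param pseudo replacement for zero counts (> 0; default 0.01, i.e. -2 on
#'   the log10 scale).
#' @return numeric matrix (taxa x samples) of log10 abundances.
#' @export
transform_abundance <- function(table, pseudo = 0.01) {
  stopifnot(inherits(table, "count_table"))
  if (!is.numeric(pseudo) || length(pseudo) != 1 || pseudo <= 0)
    stop("transform_abundance: pseudo must be a single positive number")
  m <- table$counts
  storage.mode(m) <- "double"
  m[m == 0] <- pseudo
  log10(m)
}
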