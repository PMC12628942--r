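#' Construct a domain-tagged ASV count table
#'
#' The raw currency of the pipeline: a taxa x samples matrix of non-negative
#' integer counts, each taxon tagged with the marker-gene domain it came from
#' (16S bacteria, ITS fungi, 18S protists, 28S nematodes).
#'
#' @param counts integer matrix, taxa in rows, samples in columns; must carry
#'   unique row and column names.
#' @param domain either a single domain tag applied to all taxa or a per-taxon
#'   character vector; values must be one of `"bacteria"`, `"fungi"`,
#'   `"protist"`, `"nematode"`.
#' @return an object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `domain` (named character vector per taxon).
#' @export
count_table <- function(counts, domain) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0)
      stop("count_table: counts must have taxon rownames")
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0)
      stop("count_table: counts must have sample colnames")
    colnames(counts) <- character(0)
  }
  taxa <- rownames(counts)
  samples <- colnames(counts)
  if (anyDuplicated(taxa))
    stop("count_table: duplicate taxon id(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("count_table: duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("count_table: counts must be numeric and non-missing")
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("count_table: negative or non-integer count at taxon '%s', sample '%s'",
                 taxa[bad[1, 1]], samples[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  if (length(domain) == 1) domain <- rep(domain, nrow(counts))
  if (length(domain) != nrow(counts))
    stop("count_table: domain must be length 1 or one tag per taxon")
  if (!all(domain %in% DOMAINS))
    stop("count_table: unknown domain tag(s): ",
         paste(setdiff(unique(domain), DOMAINS), collapse = ", "),
         "; allowed: ", paste(DOMAINS, collapse = ", "))
  structure(list(counts = counts, domain = setNames(as.character(domain), taxa)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$domain))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

taxon_ids <- function(x) rownames(x$counts)
sample_ids <- function(x) colnames(x$counts)

# subset helpers used by preprocess and the pipeline
subset_taxa <- function(x, keep) {
  count_table(x$counts[keep, , drop = FALSE], x$domain[keep])
}

subset_samples <- function(x, keep) {
  count_table(x$counts[, keep, drop = FALSE], x$domain)
}
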