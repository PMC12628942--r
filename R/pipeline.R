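#' Pipeline configuration
#'
#' Collects every tunable of the per-group analysis. Exactly one of `paths`
#' (real data on disk) or `synthetic` (a [synth_spec()]) must be supplied.
#' Defaults mirror the published settings: prevalence > 0.5, |r| >= 0.6,
#' FDR q < 0.001, Zi/Pi thresholds 2.5/0.62, minimum module size 5.
#'
#' @param paths named list with `bacteria`, `fungi`, `protist`, `nematode`
#'   count-table TSVs plus `taxonomy` and `metadata`; or `NULL`.
#' @param synthetic a [synth_spec()]; or `NULL`.
#' @param depths named rarefaction depths per domain.
#' @param min_prevalence prevalence threshold (strict >).
#' @param pseudo zero replacement before log10.
#' @param method `"pearson"` or `"sparcc"`.
#' @param r_min,q_max edge thresholds.
#' @param null_method,null_reps null-model settings.
#' @param z_thresh,p_thresh Zi/Pi role thresholds.
#' @param min_module_size smallest module kept for eigengenes.
#' @param alpha significance level for correlation flags.
#' @param seed integer root seed.
#' @param out_dir optional output directory; when set, all per-group
#'   artifacts are written there.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, synthetic = NULL,
                            depths = c(bacteria = 4485, fungi = 10526,
                                       protist = 1079, nematode = 412),
                            min_prevalence = 0.5, pseudo = 0.01,
                            method = c("pearson", "sparcc"),
                            r_min = 0.6, q_max = 0.001,
                            null_method = c("rewire", "er"), null_reps = 100,
                            z_thresh = 2.5, p_thresh = 0.62,
                            min_module_size = 5, alpha = 0.05,
                            seed = 1L, out_dir = NULL) {
  method <- match.arg(method)
  null_method <- match.arg(null_method)
  if (is.null(paths) == is.null(synthetic))
    stop("pipeline_config: supply exactly one of 'paths' or 'synthetic'")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synth_spec"))
  if (!is.null(paths)) {
    need <- c(DOMAINS, "taxonomy", "metadata")
    missing <- setdiff(need, names(paths))
    if (length(missing) > 0)
      stop("pipeline_config: paths missing ", paste(missing, collapse = ", "))
  }
  stopifnot(min_prevalence >= 0, min_prevalence < 1, pseudo > 0,
            r_min > 0, r_min <= 1, q_max > 0, q_max <= 1,
            null_reps >= 2, min_module_size >= 1,
            alpha > 0, alpha <= 1)
  structure(list(paths = paths, synthetic = synthetic, depths = depths,
                 min_prevalence = min_prevalence, pseudo = pseudo,
                 method = method, r_min = r_min, q_max = q_max,
                 null_method = null_method, null_reps = null_reps,
                 z_thresh = z_thresh, p_thresh = p_thresh,
                 min_module_size = min_module_size, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  printable <- config
  printable$synthetic <- unclass(printable$synthetic)
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(printable), f)
  unname(tools::md5sum(f))
}

#' Run the full per-group network analysis
#'
#' For every climatic group in the metadata: per-domain rarefaction, merge,
#' prevalence filter, log10 transform, association inference with BH-FDR,
#' signed network construction, topology metrics and a null ensemble,
#' fast-greedy modules, Zi-Pi roles, module eigengenes and their
#' environmental correlations, guild annotation, cross-domain edge summary,
#' and keystone-group Spearman correlations. Fully deterministic for a given
#' config + seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `groups` (named list of
#'   per-group stage outputs), `guilds`, `manifest` (config hash, seed, any
#'   files written), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 4)

  if (!is.null(config$synthetic)) {
    bundle <- generate_dataset(config$synthetic)
    merged_raw <- bundle$counts
    frame <- bundle$frame
    taxonomy <- bundle$taxonomy
  } else {
    bundle <- NULL
    tables <- lapply(DOMAINS, function(d) read_count_table(config$paths[[d]], d))
    frame <- read_sample_frame(config$paths$metadata)
    taxonomy <- read_taxonomy_table(config$paths$taxonomy)
    merged_raw <- merge_domains(tables)
  }

  # per-domain rarefaction on the merged table, each block at its own depth
  rarefied <- local({
    blocks <- lapply(DOMAINS, function(d) {
      rows <- merged_raw$domain == d
      if (!any(rows)) return(NULL)
      block <- subset_taxa(merged_raw, rows)
      depth <- min(config$depths[[d]], max(colSums(block$counts)))
      rarefy(block, depth, seed = seeds[1])
    })
    blocks <- Filter(Negate(is.null), blocks)
    common <- Reduce(intersect, lapply(blocks, sample_ids))
    blocks <- lapply(blocks, subset_samples, keep = common)
    mats <- do.call(rbind, lapply(blocks, `[[`, "counts"))
    count_table(mats, unlist(lapply(blocks, function(b) unname(b$domain))))
  })
  frame <- frame[frame$sample_id %in% sample_ids(rarefied), ]

  guilds <- classify_functional_groups(taxonomy)
  files <- character()
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  groups <- if ("group" %in% names(frame)) unique(frame$group) else "all"
  out_groups <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    samp <- if (identical(g, "all")) frame$sample_id
            else frame$sample_id[frame$group == g]
    sub <- subset_samples(rarefied, sample_ids(rarefied) %in% samp)
    filt <- prevalence_filter(sub, config$min_prevalence)
    res <- list(group = g, n_samples = ncol(sub$counts),
                n_taxa_filtered = nrow(filt$counts))
    if (nrow(filt$counts) < 2) {
      warning("run_pipeline [", g, "]: fewer than 2 taxa after filtering; skipping")
      out_groups[[g]] <- res
      next
    }
    X <- transform_abundance(filt, config$pseudo)
    assoc <- switch(config$method,
      pearson = pearson_with_p(X),
      sparcc = sparcc(filt, seed = seeds[2] %% .Machine$integer.max))
    assoc <- bh_fdr(assoc)
    net <- withCallingHandlers(
      build_network(assoc, config$r_min, config$q_max,
                    domain = filt$domain),
      warning = function(w) invokeRestart("muffleWarning"))
    res$abundance <- X
    res$assoc <- assoc
    res$network <- net
    if (igraph::ecount(net) == 0) {
      warning("run_pipeline [", g, "]: empty network at |r| >= ", config$r_min,
              ", q < ", config$q_max)
      out_groups[[g]] <- res
      next
    }
    res$topology <- topology_summary(net)
    res$nulls <- null_ensemble(net, config$null_reps, config$null_method,
                               seed = (seeds[3] + gi) %% .Machine$integer.max)
    res$partition <- fast_greedy_partition(net)
    res$topology$Q <- res$partition$Q
    res$roles <- zi_pi_roles(net, res$partition, config$z_thresh, config$p_thresh)
    res$eigengenes <- module_eigengenes(X, res$partition, config$min_module_size)
    res$module_env <- module_env_correlation(res$eigengenes, frame,
                                             alpha = config$alpha)
    res$crossdomain <- crossdomain_edge_summary(net, guilds)
    res$keystone_env <- tryCatch(
      keystone_env_spearman(filt, res$roles, guilds, frame[frame$sample_id %in% samp, ],
                            alpha = config$alpha),
      warning = function(w) empty_association_table("group"))
    if (!is.null(config$out_dir)) {
      prefix <- file.path(config$out_dir,
                          gsub("[^A-Za-z0-9]+", "_", tolower(g)))
      files <- c(files, export_network(net, res$partition, res$roles, prefix))
      write.table(res$roles, paste0(prefix, "_zipi.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      files <- c(files, paste0(prefix, "_zipi.tsv"))
    }
    out_groups[[g]] <- res
  }

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   groups = names(out_groups), files = unname(files),
                   note = paste("null model:", config$null_method,
                                "(same node and edge counts; rewire additionally",
                                "preserves the degree sequence)"))
  structure(list(groups = out_groups, guilds = guilds, frame = frame,
                 rarefied = rarefied, bundle = bundle,
                 manifest = manifest, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d group(s); config %s, seed %d\n",
              length(x$groups), substr(x$manifest$config_hash, 1, 8),
              x$manifest$seed))
  for (g in names(x$groups)) {
    t <- x$groups[[g]]$topology
    if (is.null(t)) { cat(sprintf("  %s: (no network)\n", g)); next }
    cat(sprintf("  %s: N = %d, E = %d, avgK = %.3f, Q = %.3f\n",
                g, t$N, t$E, t$avgK, t$Q))
  }
  invisible(x)
}
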