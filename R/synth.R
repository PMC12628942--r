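# Seeded generator of multitrophic ASV datasets with planted structure. The
# latent model is a sparse factor model on log abundance: taxon j in module
# k(j) has lambda_j = mu_j + s_j * beta * f_k(j) + eps_j per sample, with one
# standard-normal factor per module per sample, loading sign s_j in {+1, -1},
# and residual sd sigma_noise. Planted connectors ("keystones") load equally
# on three modules (loadings scaled by 1/sqrt(3)); background taxa carry
# independent noise only and calibrate false-positive edge rates. Counts are
# drawn per sample and domain by multinomial sampling of exp(lambda)
# proportions at the domain's sequencing depth, mirroring separate amplicon
# assays; environmental variables are linear maps of designated factors plus
# unit noise.

#' Specification for a synthetic multitrophic dataset
#'
#' @param n_samples samples per climatic group (default 18).
#' @param n_groups number of climatic groups, at most 3 (default 3).
#' @param module_sizes taxa per planted module, each >= 2.
#' @param n_background taxa with independent noise only.
#' @param domain_fractions named proportions for bacteria/fungi/protist/
#'   nematode, summing to 1.
#' @param mu baseline mean log-abundance; per-taxon baselines are
#'   `mu + N(0, 1)` so abundances span a realistic log-normal range.
#' @param beta factor loading magnitude.
#' @param frac_negative probability a loading is negative.
#' @param sigma_noise residual log-abundance sd (>= 0).
#' @param n_keystone planted connectors loading on 3 modules each.
#' @param depth_by_domain named sequencing depths; a single unnamed value is
#'   recycled. Defaults follow common per-marker rarefaction depths
#'   (16S 4485, ITS 10526, 18S 1079, 28S 412).
#' @param env_coupling list mapping module index (as name) to
#'   `list(variable = <env column>, sign = +/-1)`.
#' @param seed integer root seed; all draws derive from it.
#' @return validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 18, n_groups = 3,
                       module_sizes = c(20, 18, 15, 12, 10, 8, 6, 5),
                       n_background = 40,
                       domain_fractions = c(bacteria = 0.60, fungi = 0.28,
                                            protist = 0.09, nematode = 0.03),
                       mu = 0, beta = 1, frac_negative = 0.3,
                       sigma_noise = 0.3, n_keystone = 3,
                       depth_by_domain = c(bacteria = 4485, fungi = 10526,
                                           protist = 1079, nematode = 412),
                       env_coupling = list(
                         "1" = list(variable = "MAP", sign = 1),
                         "2" = list(variable = "pH", sign = -1),
                         "3" = list(variable = "SB", sign = 1)),
                       seed = 1L) {
  if (length(depth_by_domain) == 1 && is.null(names(depth_by_domain)))
    depth_by_domain <- setNames(rep(depth_by_domain, 4), DOMAINS)
  spec <- list(n_samples = n_samples, n_groups = n_groups,
               module_sizes = module_sizes, n_background = n_background,
               domain_fractions = domain_fractions, mu = mu, beta = beta,
               frac_negative = frac_negative, sigma_noise = sigma_noise,
               n_keystone = n_keystone, depth_by_domain = depth_by_domain,
               env_coupling = env_coupling, seed = as.integer(seed))
  validate_synth_spec(spec)
  structure(spec, class = "synth_spec")
}

validate_synth_spec <- function(s) {
  fail <- function(field, why) stop("synth_spec: invalid '", field, "': ", why)
  if (s$n_samples < 2) fail("n_samples", "need >= 2 samples per group")
  if (s$n_groups < 1 || s$n_groups > length(CLIMATE_GROUPS))
    fail("n_groups", paste("must be between 1 and", length(CLIMATE_GROUPS)))
  if (length(s$module_sizes) < 1 || any(s$module_sizes < 2))
    fail("module_sizes", "each module needs >= 2 taxa")
  if (s$n_background < 0) fail("n_background", "must be >= 0")
  if (!setequal(names(s$domain_fractions), DOMAINS))
    fail("domain_fractions", paste("names must be", paste(DOMAINS, collapse = ", ")))
  if (abs(sum(s$domain_fractions) - 1) > 1e-9)
    fail("domain_fractions", "must sum to 1")
  if (s$sigma_noise < 0) fail("sigma_noise", "must be >= 0")
  if (s$frac_negative < 0 || s$frac_negative > 1)
    fail("frac_negative", "must be in [0, 1]")
  if (!setequal(names(s$depth_by_domain), DOMAINS))
    fail("depth_by_domain", paste("names must be", paste(DOMAINS, collapse = ", ")))
  if (any(s$depth_by_domain <= 0)) fail("depth_by_domain", "depths must be > 0")
  if (s$n_keystone > 0 && length(s$module_sizes) < 3)
    fail("n_keystone", "keystones need >= 3 modules to connect")
  for (k in names(s$env_coupling)) {
    cp <- s$env_coupling[[k]]
    if (as.integer(k) > length(s$module_sizes))
      fail("env_coupling", paste("module index", k, "out of range"))
    if (!cp$variable %in% ENV_VARS)
      fail("env_coupling", paste("unknown environmental variable", cp$variable))
    if (!cp$sign %in% c(-1, 1)) fail("env_coupling", "sign must be +1 or -1")
  }
  invisible(s)
}

# location/scale used to place environmental variables on field-realistic
# ranges (Pearson/Spearman results are unaffected by the affine map)
env_location <- c(pH = 7, TotalC = 1.2, TotalN = 0.10, TotalP = 0.04,
                  CN = 12, CP = 30, NP = 2.6, VR = 8, SB = 150, MAP = 340,
                  OYR = 300, TMR = 60, MAT = 20.4, CV = 0.42, AI = 0.22)
env_scale <- c(pH = 0.5, TotalC = 0.35, TotalN = 0.03, TotalP = 0.012,
               CN = 2, CP = 6, NP = 0.6, VR = 2.5, SB = 45, MAP = 60,
               OYR = 75, TMR = 22, MAT = 1.1, CV = 0.10, AI = 0.05)

#' Generate a synthetic multitrophic dataset
#'
#' @param spec a [synth_spec()].
#' @return list of class `synthetic_bundle` with elements `counts`
#'   ([count_table], merged and domain-prefixed), `frame` (sample metadata),
#'   `taxonomy`, `guilds`, `truth_partition` (named character, `"M<k>"` or
#'   `"background"`), `truth_keystones`, `truth_env_links`, `latent`
#'   (taxa x samples log-abundance matrix, for diagnostics), and `spec`.
#'   Identical spec + seed gives a byte-identical bundle.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  seeds <- derive_seeds(spec$seed, 6)

  K <- length(spec$module_sizes)
  n_module_taxa <- sum(spec$module_sizes)
  n_taxa <- n_module_taxa + spec$n_keystone + spec$n_background
  n <- spec$n_samples * spec$n_groups

  module_of <- c(rep(seq_len(K), spec$module_sizes),
                 rep(NA_integer_, spec$n_keystone + spec$n_background))
  is_keystone <- seq_len(n_taxa) > n_module_taxa &
    seq_len(n_taxa) <= n_module_taxa + spec$n_keystone
  is_background <- seq_len(n_taxa) > n_module_taxa + spec$n_keystone

  # --- domains: largest-remainder allocation, shuffled across taxa so every
  # module is multitrophic
  set.seed(seeds[1])
  quota <- spec$domain_fractions * n_taxa
  n_dom <- floor(quota)
  rem <- n_taxa - sum(n_dom)
  if (rem > 0) {
    extra <- order(quota - n_dom, decreasing = TRUE)[seq_len(rem)]
    n_dom[extra] <- n_dom[extra] + 1
  }
  domain <- sample(rep(DOMAINS, times = n_dom[DOMAINS]))
  ids <- paste0(DOMAIN_PREFIX[domain], "_ASV",
                ave(seq_len(n_taxa), domain, FUN = seq_along))

  # --- latent log abundances
  set.seed(seeds[2])
  mu_j <- spec$mu + rnorm(n_taxa)
  s_j <- ifelse(runif(n_taxa) < spec$frac_negative, -1, 1)
  F <- matrix(rnorm(n * K), n, K)   # samples x module factors
  key_modules <- lapply(seq_len(spec$n_keystone), function(i)
    ((i - 1 + 0:2) %% K) + 1)       # 3 modules each, staggered
  lambda <- matrix(0, n_taxa, n)
  for (j in seq_len(n_taxa)) {
    signal <- if (!is.na(module_of[j])) {
      s_j[j] * spec$beta * F[, module_of[j]]
    } else if (is_keystone[j]) {
      ks <- key_modules[[j - n_module_taxa]]
      s_j[j] * spec$beta * rowSums(F[, ks, drop = FALSE]) / sqrt(3)
    } else {
      0
    }
    lambda[j, ] <- mu_j[j] + signal
  }
  if (spec$sigma_noise > 0)
    lambda <- lambda + matrix(rnorm(n_taxa * n, 0, spec$sigma_noise), n_taxa, n)
  rownames(lambda) <- ids

  # --- samples and metadata
  groups <- rep(CLIMATE_GROUPS[seq_len(spec$n_groups)], each = spec$n_samples)
  sample_names <- paste0("S", sprintf("%02d", seq_len(n)))
  colnames(lambda) <- sample_names
  treatment <- rep(rep(TREATMENTS, length.out = spec$n_samples), spec$n_groups)

  set.seed(seeds[3])
  env_signal <- setNames(vector("list", length(ENV_VARS)), ENV_VARS)
  for (v in ENV_VARS) env_signal[[v]] <- rnorm(n)   # uncoupled: pure noise
  for (k in names(spec$env_coupling)) {
    cp <- spec$env_coupling[[k]]
    env_signal[[cp$variable]] <- cp$sign * F[, as.integer(k)] + rnorm(n)
  }
  frame <- data.frame(sample_id = sample_names, group = groups,
                      treatment = treatment, stringsAsFactors = FALSE)
  for (v in ENV_VARS)
    frame[[v]] <- env_location[v] + env_scale[v] * env_signal[[v]]

  # --- compositional count sampling, per domain at the domain depth
  set.seed(seeds[4])
  counts <- matrix(0L, n_taxa, n, dimnames = list(ids, sample_names))
  for (d in DOMAINS) {
    rows <- which(domain == d)
    if (length(rows) == 0) next
    depth <- spec$depth_by_domain[[d]]
    for (i in seq_len(n)) {
      p <- exp(lambda[rows, i] - max(lambda[rows, i]))
      counts[rows, i] <- rmultinom(1, depth, p)[, 1]
    }
  }
  ct <- count_table(counts, domain)

  # --- taxonomy drawn from the packaged guild lookups so downstream
  # annotation is exercised end to end
  set.seed(seeds[5])
  taxonomy <- synth_taxonomy(ids, domain)
  guilds <- classify_functional_groups(taxonomy)

  truth <- rep("background", n_taxa)
  truth[!is.na(module_of)] <- paste0("M", module_of[!is.na(module_of)])
  for (i in seq_len(spec$n_keystone))   # a connector's label: first module it loads on
    truth[n_module_taxa + i] <- paste0("M", key_modules[[i]][1])
  names(truth) <- ids

  structure(list(
    counts = ct, frame = frame, taxonomy = taxonomy, guilds = guilds,
    truth_partition = truth,
    truth_keystones = ids[is_keystone],
    truth_env_links = spec$env_coupling,
    latent = lambda, spec = spec), class = "synthetic_bundle")
}

synth_taxonomy <- function(ids, domain) {
  rrn <- read_lookup(default_lookup_path("rrn_copies.tsv"), c("genus", "mean_rrn"))
  fgl <- read_lookup(default_lookup_path("fungal_guilds.tsv"), c("genus", "guild"))
  prl <- read_lookup(default_lookup_path("protist_groups.tsv"), c("genus", "group"))
  kingdom_of <- c(bacteria = "Bacteria", fungi = "Fungi",
                  protist = "Eukaryota", nematode = "Animalia")
  n <- length(ids)
  genus <- character(n); guild <- character(n)
  for (i in seq_len(n)) {
    pool <- switch(domain[i],
                   bacteria = rrn$genus, fungi = fgl$genus,
                   protist = prl$genus, nematode = c("Acrobeles", "Aphelenchus"))
    # ~10% of taxa get an unlisted genus, exercising the "unknown" path
    genus[i] <- if (runif(1) < 0.1) paste0("Unknown_genus_", i)
                else sample(pool, 1)
    if (domain[i] == "fungi") {
      hit <- match(genus[i], fgl$genus)
      guild[i] <- if (is.na(hit)) "" else fgl$guild[hit]
    }
  }
  data.frame(taxon_id = ids, domain = domain,
             kingdom = unname(kingdom_of[domain]),
             family = paste0(genus, "aceae"), genus = genus, guild = guild,
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d taxa x %d samples; %d modules, %d keystones, %d background\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              length(x$spec$module_sizes), x$spec$n_keystone,
              x$spec$n_background))
  invisible(x)
}

#' Write a synthetic bundle to TSV files
#'
#' Emits the same formats the readers in this package consume: per-domain
#' count tables, sample frame, taxonomy, and the ground-truth partition.
#'
#' @param bundle a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  for (d in DOMAINS) {
    rows <- bundle$counts$domain == d
    if (!any(rows)) next
    sub <- subset_taxa(bundle$counts, rows)
    f <- file.path(dir, paste0("counts_", d, ".tsv"))
    write_count_table(sub, f)
    files[paste0("counts_", d)] <- f
  }
  files["frame"] <- write_sample_frame(bundle$frame, file.path(dir, "samples.tsv"))
  files["taxonomy"] <- write_taxonomy_table(bundle$taxonomy, file.path(dir, "taxonomy.tsv"))
  truth <- data.frame(taxon_id = names(bundle$truth_partition),
                      module = unname(bundle$truth_partition),
                      keystone = names(bundle$truth_partition) %in% bundle$truth_keystones)
  f <- file.path(dir, "truth_partition.tsv")
  write.table(truth, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["truth"] <- f
  invisible(files)
}
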