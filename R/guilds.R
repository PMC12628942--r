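# Functional-guild annotation. The classification rules follow common
# amplicon practice: bacteria are split into copiotrophs (mean rrn operon
# copies >= 5) and oligotrophs (< 5) by genus with a one-level family
# fallback; fungi take the first-listed trophic mode of their (possibly
# multi-mode) guild string; protists are classified by feeding habit at the
# genus level; nematodes are collectively consumers. Anything unmatched is
# "unknown". Packaged lookups under inst/extdata are abridged synthetic
# stand-ins for rrnDB/FUNGuild/feeding-habit tables; users can supply fuller
# ones.

read_lookup <- function(path, required) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("lookup table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

default_lookup_path <- function(file) {
  system.file("extdata", file, package = "mconet", mustWork = TRUE)
}

fungal_mode_map <- c(pathotroph = "pathotroph", saprotroph = "saprotroph",
                     symbiotroph = "symbiotroph")

first_listed_mode <- function(guild_string) {
  if (is.na(guild_string) || guild_string == "") return("unknown")
  first <- tolower(strsplit(guild_string, "-", fixed = TRUE)[[1]][1])
  if (first %in% names(fungal_mode_map)) unname(fungal_mode_map[first]) else "unknown"
}

#' Classify taxa into functional groups
#'
#' @param tax taxonomy data.frame with columns `taxon_id`, `domain`, and any
#'   of `genus`, `family`, `guild` (free-text fungal guild string).
#' @param rrn_lookup data.frame (`genus`/optionally `family`, `mean_rrn`) or
#'   path; default packaged fixture.
#' @param fungal_guild_lookup data.frame (`genus`, `guild`) or path, used for
#'   fungi lacking a guild string in `tax`; default packaged fixture.
#' @param protist_lookup data.frame (`genus`, `group`) or path; default
#'   packaged fixture.
#' @param overrides optional data.frame (`taxon_id`, `group`) of explicit
#'   expert reassignments applied last.
#' @return data.frame (class `guild_map`): `taxon_id`, `domain`, `group`,
#'   `source`, `rrn` (NA outside bacteria). Every taxon gets exactly one
#'   group.
#' @export
classify_functional_groups <- function(tax,
                                       rrn_lookup = NULL,
                                       fungal_guild_lookup = NULL,
                                       protist_lookup = NULL,
                                       overrides = NULL) {
  if (!all(c("taxon_id", "domain") %in% names(tax)))
    stop("classify_functional_groups: tax needs 'taxon_id' and 'domain' columns")
  as_lookup <- function(x, file, required) {
    if (is.null(x)) x <- default_lookup_path(file)
    if (is.character(x)) read_lookup(x, required) else x
  }
  rrn <- as_lookup(rrn_lookup, "rrn_copies.tsv", c("genus", "mean_rrn"))
  fgl <- as_lookup(fungal_guild_lookup, "fungal_guilds.tsv", c("genus", "guild"))
  prl <- as_lookup(protist_lookup, "protist_groups.tsv", c("genus", "group"))

  n <- nrow(tax)
  group <- rep("unknown", n)
  source <- rep("unmatched", n)
  rrn_copies <- rep(NA_real_, n)
  genus <- if ("genus" %in% names(tax)) tax$genus else rep("", n)
  family <- if ("family" %in% names(tax)) tax$family else rep("", n)
  guild_str <- if ("guild" %in% names(tax)) tax$guild else rep("", n)

  for (i in seq_len(n)) {
    d <- tax$domain[i]
    if (d == "bacteria") {
      hit <- match(genus[i], rrn$genus)
      lvl <- "genus"
      if (is.na(hit) && "family" %in% names(rrn) && nzchar(family[i])) {
        hit <- match(family[i], rrn$family)
        lvl <- "family"
      }
      if (!is.na(hit)) {
        rrn_copies[i] <- rrn$mean_rrn[hit]
        group[i] <- if (rrn$mean_rrn[hit] >= 5) "copiotroph" else "oligotroph"
        source[i] <- paste0("rrn:", lvl)
      }
    } else if (d == "fungi") {
      gs <- guild_str[i]
      if (!nzchar(gs)) {
        hit <- match(genus[i], fgl$genus)
        if (!is.na(hit)) gs <- fgl$guild[hit]
      }
      mode <- first_listed_mode(gs)
      if (mode != "unknown") {
        group[i] <- mode
        source[i] <- "guild-string"
      }
    } else if (d == "protist") {
      hit <- match(genus[i], prl$genus)
      if (!is.na(hit)) {
        group[i] <- prl$group[hit]
        source[i] <- "feeding-habit:genus"
      }
    } else if (d == "nematode") {
      group[i] <- "consumer"
      source[i] <- "domain-rule"
    }
  }
  out <- data.frame(taxon_id = tax$taxon_id, domain = tax$domain,
                    group = group, source = source, rrn = rrn_copies,
                    stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    hit <- match(out$taxon_id, overrides$taxon_id)
    ov <- !is.na(hit)
    out$group[ov] <- overrides$group[hit[ov]]
    out$source[ov] <- "override"
  }
  structure(out, class = c("guild_map", "data.frame"))
}

#' Edge composition within and between domains
#'
#' Assigns every edge to one unordered domain pair (BB, BF, BP, BN, FF, FP,
#' FN, PP, PN, NN), split by sign, with percentages of the total edge count,
#' plus node tallies per domain and per functional group.
#'
#' @param net a network from [build_network()].
#' @param guilds a [classify_functional_groups()] result covering the nodes.
#' @return list of class `crossdomain_summary`: `edges` (data.frame pair,
#'   positive, negative, total, percent), `nodes_by_domain`,
#'   `nodes_by_group`.
#' @export
crossdomain_edge_summary <- function(net, guilds) {
  nodes <- igraph::V(net)$name
  dom <- igraph::V(net)$domain
  if (is.null(dom) || anyNA(dom))
    stop("crossdomain_edge_summary: node(s) without a domain attribute")
  names(dom) <- nodes
  gmap <- setNames(guilds$group, guilds$taxon_id)
  ed <- igraph::as_data_frame(net, what = "edges")
  code <- function(d) unname(DOMAIN_PREFIX[d])
  pair <- apply(cbind(code(dom[ed$from]), code(dom[ed$to])), 1, function(x) {
    x <- x[order(match(x, DOMAIN_PREFIX))]
    paste0(x[1], x[2])
  })
  all_pairs <- c("BB", "BF", "BP", "BN", "FF", "FP", "FN", "PP", "PN", "NN")
  pos <- table(factor(pair[ed$sign == "positive"], levels = all_pairs))
  neg <- table(factor(pair[ed$sign == "negative"], levels = all_pairs))
  total <- as.integer(pos + neg)
  edges <- data.frame(pair = all_pairs,
                      positive = as.integer(pos), negative = as.integer(neg),
                      total = total,
                      percent = if (nrow(ed) > 0) 100 * total / nrow(ed) else 0)
  structure(list(
    edges = edges,
    nodes_by_domain = table(factor(dom, levels = DOMAINS)),
    nodes_by_group = table(gmap[nodes], useNA = "ifany")),
    class = "crossdomain_summary")
}

#' Spearman correlations of keystone-group abundances with environment
#'
#' Pools keystone nodes (connectors, module hubs, network hubs) by
#' functional group, computes each group's per-sample relative abundance
#' (group counts / sample total), and correlates it -- plus each individual
#' keystone taxon -- with every environmental variable by Spearman's rho
#' (average ranks for ties, two-sided p). The flag uses the raw p (default
#' alpha 0.05); BH q across the table is reported alongside.
#'
#' @param table the (rarefied, merged) [count_table] for the samples.
#' @param roles a [zi_pi_roles()] result.
#' @param guilds a [classify_functional_groups()] result.
#' @param frame sample metadata frame (`sample_id` + environmental columns).
#' @param env_vars environmental columns; defaults to the standard set
#'   present in `frame`.
#' @param alpha significance level for the flag.
#' @param min_group_size smallest keystone group correlated as a pooled
#'   group (default 2).
#' @return data.frame (class `association_table`): `group`, `variable`,
#'   `rho`, `p`, `q`, `significant`.
#' @export
keystone_env_spearman <- function(table, roles, guilds, frame,
                                  env_vars = NULL, alpha = 0.05,
                                  min_group_size = 2) {
  keys <- keystone_nodes(roles)
  if (length(keys) == 0) {
    warning("keystone_env_spearman: empty keystone set")
    return(empty_association_table("group"))
  }
  keys <- intersect(keys, taxon_ids(table))
  frame <- frame[match(sample_ids(table), frame$sample_id), ]
  if (anyNA(frame$sample_id))
    stop("keystone_env_spearman: sample sets of table and frame differ")
  if (is.null(env_vars)) env_vars <- intersect(ENV_VARS, names(frame))
  totals <- colSums(table$counts)
  gmap <- setNames(guilds$group, guilds$taxon_id)
  groups <- split(keys, gmap[keys])
  groups <- groups[lengths(groups) >= min_group_size]
  abund <- lapply(groups, function(members)
    colSums(table$counts[members, , drop = FALSE]) / totals)
  for (k in keys) abund[[k]] <- table$counts[k, ] / totals
  rows <- expand.grid(group = names(abund), variable = env_vars,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    ct <- suppressWarnings(cor.test(abund[[rows$group[i]]],
                                    frame[[rows$variable[i]]],
                                    method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(rows, rho = res[, "rho"], p = res[, "p"])
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  structure(out, class = c("association_table", "data.frame"))
}
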