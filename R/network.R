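#' Build a signed co-occurrence network
#'
#' Keeps every taxon pair with `|r| >= r_min` (inclusive) and FDR
#' `q < q_max` (strict) as an edge carrying the correlation as weight and its
#' sign as an attribute; taxa left without any edge are excluded from the
#' node set (node counts in co-occurrence studies are edge-bearing taxa).
#'
#' @param assoc an `assoc_matrix` with `q` filled (see [bh_fdr()]).
#' @param r_min minimum absolute correlation (default 0.6).
#' @param q_max FDR ceiling (default 0.001).
#' @param domain optional named character vector taxon -> domain; defaults to
#'   parsing the merged-id prefix (`B_`/`F_`/`P_`/`N_`).
#' @return an igraph graph (class also `signed_network`) with vertex
#'   attributes `name`, `domain` and edge attributes `r`, `sign`, `q`.
#'   An edgeless graph is returned with a warning when nothing passes.
#' @export
build_network <- function(assoc, r_min = 0.6, q_max = 0.001, domain = NULL) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  if (is.null(assoc$q)) stop("build_network: q not filled; run bh_fdr() first")
  ids <- assoc$taxon_ids
  sel <- abs(assoc$r) >= r_min & assoc$q < q_max
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("build_network: no edges pass |r| >= ", r_min, " and q < ", q_max,
            "; returning empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    class(g) <- c("signed_network", class(g))
    return(g)
  }
  edges <- data.frame(
    from = ids[idx[, 1]], to = ids[idx[, 2]],
    r = assoc$r[idx], q = assoc$q[idx],
    sign = ifelse(assoc$r[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  if (is.null(domain)) {
    pref <- sub("_.*$", "", nodes)
    map <- setNames(names(DOMAIN_PREFIX), DOMAIN_PREFIX)
    dom <- unname(map[pref])
    dom[is.na(dom)] <- "bacteria"
  } else {
    dom <- unname(domain[nodes])
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, domain = dom, stringsAsFactors = FALSE))
  class(g) <- c("signed_network", class(g))
  g
}

#' Topology metrics of a signed network
#'
#' Computes the standard co-occurrence metric set on the unsigned skeleton:
#' node and signed edge counts, positive:negative ratio, average degree
#' `avgK = 2E/N`, average clustering coefficient (local, zero for degree < 2),
#' and average path distance GD (mean unweighted shortest path over connected
#' pairs).
#'
#' @param net a network from [build_network()].
#' @return a list of class `topology_summary` with elements `N`, `E`,
#'   `E_pos`, `E_neg`, `ratio`, `avgK`, `avgCC`, `GD` (and `Q = NA`, filled
#'   by the pipeline after partitioning).
#' @export
topology_summary <- function(net) {
  N <- igraph::vcount(net)
  E <- igraph::ecount(net)
  if (N < 1) stop("topology_summary: empty network")
  signs <- igraph::E(net)$sign %||% rep("positive", E)
  E_pos <- sum(signs == "positive")
  E_neg <- sum(signs == "negative")
  ratio <- if (E_neg > 0) E_pos / E_neg else NA_real_
  local_cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  local_cc[is.na(local_cc)] <- 0
  structure(list(
    N = N, E = E, E_pos = E_pos, E_neg = E_neg, ratio = ratio,
    avgK = 2 * E / N,
    avgCC = mean(local_cc),
    GD = if (E >= 1) igraph::mean_distance(net, directed = FALSE) else NA_real_,
    Q = NA_real_), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(
    "<topology_summary> N = %d, E = %d (+%d/-%d, ratio %s)\n  avgK = %.3f, avgCC = %.3f, GD = %s, Q = %s\n",
    x$N, x$E, x$E_pos, x$E_neg,
    if (is.na(x$ratio)) "NA" else sprintf("%.2f", x$ratio),
    x$avgK, x$avgCC,
    if (is.na(x$GD)) "NA" else sprintf("%.3f", x$GD),
    if (is.na(x$Q)) "unset" else sprintf("%.3f", x$Q)))
  invisible(x)
}

#' Null-model ensemble for network metrics
#'
#' Baselines the observed topology against random networks with the same
#' number of nodes and edges. `method = "rewire"` (default) performs
#' degree-preserving double-edge swaps (`10 * E` attempted swaps per
#' replicate) and randomly reassigns the observed sign multiset to edges;
#' `method = "er"` draws a uniform random graph with the same N and E (the
#' weaker "same nodes and edges" null). Per replicate the average clustering
#' coefficient, average path distance and fast-greedy modularity are
#' recorded.
#'
#' @param net a network from [build_network()].
#' @param n_reps replicates (>= 2; default 100).
#' @param method `"rewire"` or `"er"`.
#' @param seed integer seed.
#' @return a list of class `null_summary`: per-metric mean and sd, the
#'   replicate matrix, method and seed.
#' @export
null_ensemble <- function(net, n_reps = 100, method = c("rewire", "er"),
                          seed = 1L) {
  method <- match.arg(method)
  if (n_reps < 2) stop("null_ensemble: n_reps must be >= 2")
  N <- igraph::vcount(net)
  E <- igraph::ecount(net)
  signs <- igraph::E(net)$sign %||% rep("positive", E)
  set.seed(seed)
  reps <- matrix(NA_real_, n_reps, 3,
                 dimnames = list(NULL, c("avgCC", "GD", "Q")))
  for (b in seq_len(n_reps)) {
    g <- if (method == "rewire") {
      igraph::rewire(net, igraph::keeping_degseq(niter = 10 * E))
    } else {
      igraph::sample_gnm(N, E, directed = FALSE)
    }
    igraph::E(g)$sign <- sample(signs)
    cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    cc[is.na(cc)] <- 0
    reps[b, "avgCC"] <- mean(cc)
    reps[b, "GD"] <- igraph::mean_distance(g, directed = FALSE)
    reps[b, "Q"] <- if (igraph::ecount(g) > 0)
      igraph::modularity(igraph::cluster_fast_greedy(
        igraph::simplify(g), weights = NULL)) else NA_real_
  }
  structure(list(
    mean = colMeans(reps), sd = apply(reps, 2, sd),
    replicates = reps, n_replicates = n_reps, method = method, seed = seed,
    N = N, E = E), class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("<null_summary> %s, %d replicates (N = %d, E = %d)\n",
              x$method, x$n_replicates, x$N, x$E))
  for (m in names(x$mean))
    cat(sprintf("  %s = %.3f (sd %.3f)\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}
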