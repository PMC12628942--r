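# Shared fixtures and independent oracles. The "recovery" settings are the
# parameter-recovery study conditions: 3 planted modules of 20 taxa plus 3
# planted connectors, 50 samples, beta = 1, sigma_noise = 0.3, shared
# sequencing depth 5e4, seed 1.

recovery_spec <- function(seed = 1L) {
  synth_spec(n_samples = 50, n_groups = 1,
             module_sizes = c(20, 20, 20), n_background = 0, n_keystone = 3,
             beta = 1, sigma_noise = 0.3, frac_negative = 0.3,
             depth_by_domain = 5e4,
             env_coupling = list("1" = list(variable = "MAP", sign = 1),
                                 "2" = list(variable = "pH", sign = -1),
                                 "3" = list(variable = "SB", sign = 1)),
             seed = seed)
}

.fixture_cache <- new.env(parent = emptyenv())

# run the core pipeline stages once on the recovery bundle; memoized across
# test files (helpers are sourced once per test run)
recovery_fixture <- function() {
  if (is.null(.fixture_cache$recovery)) {
    bundle <- generate_dataset(recovery_spec())
    filt <- prevalence_filter(bundle$counts, 0.5)
    X <- transform_abundance(filt)
    assoc <- bh_fdr(pearson_with_p(X))
    net <- build_network(assoc, 0.6, 0.001, domain = filt$domain)
    part <- fast_greedy_partition(net)
    roles <- zi_pi_roles(net, part)
    .fixture_cache$recovery <- list(bundle = bundle, filt = filt, X = X,
                                    assoc = assoc, net = net,
                                    partition = part, roles = roles)
  }
  .fixture_cache$recovery
}

# small count table for io tests
tiny_count_table <- function() {
  m <- matrix(c(5L, 0L, 2L, 7L,
                1L, 3L, 0L, 4L,
                0L, 0L, 9L, 1L,
                2L, 2L, 2L, 2L,
                8L, 1L, 0L, 0L), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("ASV_", 1:5), paste0("S", 1:4)))
  count_table(m, "bacteria")
}

# --- exhaustive modularity oracle (restricted-growth-string enumeration) ---
all_memberships <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    if (length(prefix) == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in seq_len(maxv + 1)) grow(c(prefix, v), max(maxv, v))
  }
  grow(integer(), 0L)
  out
}

exhaustive_best_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8)
  best <- -Inf
  for (mem in all_memberships(n))
    best <- max(best, igraph::modularity(g, mem))
  best
}

# --- brute-force Zi/Pi oracle: explicit loops over the edge list ---
brute_zipi <- function(edges, membership) {
  nodes <- names(membership)
  mods <- sort(unique(membership))
  kappa <- matrix(0, length(nodes), length(mods),
                  dimnames = list(nodes, as.character(mods)))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    kappa[a, as.character(membership[b])] <- kappa[a, as.character(membership[b])] + 1
    kappa[b, as.character(membership[a])] <- kappa[b, as.character(membership[a])] + 1
  }
  k <- rowSums(kappa)
  own <- vapply(nodes, function(v) kappa[v, as.character(membership[v])], 1)
  Zi <- vapply(nodes, function(v) {
    peers <- own[names(membership)[membership == membership[v]]]
    s <- sd(peers)
    if (is.na(s) || s == 0) 0 else (own[v] - mean(peers)) / s
  }, 1)
  Pi <- 1 - rowSums((kappa / k)^2)
  list(Zi = Zi, Pi = Pi, k = k)
}

# fixed 12-node, two-module graph with a clear hub and a cross-module node
two_module_graph <- function() {
  edges <- rbind(
    c("a1", "a2"), c("a1", "a3"), c("a1", "a4"), c("a1", "a5"), c("a1", "a6"),
    c("a2", "a3"), c("a4", "a5"),
    c("b1", "b2"), c("b1", "b3"), c("b2", "b3"), c("b3", "b4"),
    c("b4", "b5"), c("b5", "b6"), c("b6", "b1"),
    c("a6", "b1"), c("a6", "b4"), c("a2", "b2"))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$domain <- "bacteria"
  membership <- setNames(rep(c(1L, 2L), each = 6),
                         c(paste0("a", 1:6), paste0("b", 1:6)))
  list(graph = g, edges = edges, membership = membership)
}

as_partition <- function(membership, Q = NA_real_) {
  structure(list(membership = membership, Q = Q,
                 sizes = as.integer(table(membership)), communities = NULL),
            class = "network_partition")
}

# random signed network with prescribed node/edge/sign counts
signed_gnm <- function(n, m, n_pos, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m, directed = FALSE)
  igraph::V(g)$name <- paste0("B_ASV", seq_len(n))
  igraph::V(g)$domain <- "bacteria"
  igraph::E(g)$sign <- sample(rep(c("positive", "negative"), c(n_pos, m - n_pos)))
  igraph::E(g)$r <- ifelse(igraph::E(g)$sign == "positive", 0.7, -0.7)
  igraph::E(g)$q <- 1e-4
  class(g) <- c("signed_network", class(g))
  g
}
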