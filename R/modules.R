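#' Fast-greedy module detection
#'
#' Clauset-Newman-Moore agglomerative modularity maximization on the unsigned
#' skeleton: starting from singleton communities, the pair of communities
#' whose merge most increases `Q = sum_c [L_c/L - (d_c/2L)^2]` is merged
#' repeatedly, and the partition with the highest Q along the merge path is
#' returned (via [igraph::cluster_fast_greedy()]).
#'
#' @param net a network from [build_network()] (or any undirected igraph).
#' @return a list of class `network_partition`: `membership` (named integer,
#'   node -> module id), `Q`, `sizes`, and the `igraph` communities object
#'   (merge history) as `communities`.
#' @export
fast_greedy_partition <- function(net) {
  if (igraph::vcount(net) < 2 || igraph::ecount(net) < 1)
    stop("fast_greedy_partition: need at least 2 nodes and 1 edge")
  g <- igraph::simplify(igraph::as_undirected(net, mode = "collapse"))
  cm <- igraph::cluster_fast_greedy(g, weights = NULL)
  # cut the merge path explicitly at its modularity maximum (igraph's own
  # membership can disagree with the path optimum on near-tied Q values)
  best <- which.max(cm$modularity)
  membership <- igraph::cut_at(cm, no = igraph::vcount(g) - (best - 1))
  membership <- setNames(as.integer(membership), igraph::V(g)$name)
  structure(list(
    membership = membership,
    Q = igraph::modularity(g, membership),
    sizes = as.integer(table(membership)),
    communities = cm), class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d modules, Q = %.3f; sizes: %s\n",
              length(x$sizes), x$Q, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Zi-Pi topological roles
#'
#' Within-module degree z-score `Zi = (k_is - mean_s)/sd_s` (sample sd over
#' the module's members; 0 when the sd is 0) and among-module participation
#' coefficient `Pi = 1 - sum_s (k_is/k_i)^2`. Nodes are classified with the
#' conventional thresholds 2.5 / 0.62, boundary values falling in the "low"
#' class: peripheral (low/low), connector (low Zi, high Pi), module hub
#' (high Zi, low Pi), network hub (high/high). Connectors and hubs are the
#' putative keystone taxa.
#'
#' @param net a network from [build_network()].
#' @param partition a [fast_greedy_partition()] covering all nodes.
#' @param z_thresh,p_thresh role thresholds (defaults 2.5 and 0.62).
#' @return data.frame (class `role_table`) with columns `node`, `module`,
#'   `degree`, `Zi`, `Pi`, `role`.
#' @export
zi_pi_roles <- function(net, partition, z_thresh = 2.5, p_thresh = 0.62) {
  nodes <- igraph::V(net)$name
  mem <- partition$membership
  missing <- setdiff(nodes, names(mem))
  if (length(missing) > 0)
    stop("zi_pi_roles: node(s) absent from partition: ",
         paste(missing, collapse = ", "))
  mem <- mem[nodes]
  modules <- sort(unique(mem))
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  adj[adj > 1] <- 1
  # kappa[i, s] = links of node i into module s
  kappa <- sapply(modules, function(s) rowSums(adj[, mem == s, drop = FALSE]))
  if (is.null(dim(kappa))) kappa <- matrix(kappa, nrow = length(nodes))
  colnames(kappa) <- as.character(modules)
  k <- rowSums(kappa)
  own <- kappa[cbind(seq_along(nodes), match(mem, modules))]
  Zi <- numeric(length(nodes))
  for (s in modules) {
    in_s <- mem == s
    mu <- mean(own[in_s]); sdev <- sd(own[in_s])
    Zi[in_s] <- if (is.na(sdev) || sdev == 0) 0 else (own[in_s] - mu) / sdev
  }
  Pi <- 1 - rowSums((kappa / k)^2)
  role <- ifelse(Zi > z_thresh,
                 ifelse(Pi > p_thresh, "network hub", "module hub"),
                 ifelse(Pi > p_thresh, "connector", "peripheral"))
  structure(data.frame(node = nodes, module = unname(mem), degree = unname(k),
                       Zi = Zi, Pi = Pi, role = role,
                       stringsAsFactors = FALSE),
            class = c("role_table", "data.frame"))
}

#' Keystone node set of a role table
#' @param roles a [zi_pi_roles()] result.
#' @return character vector of connector / module hub / network hub nodes.
#' @export
keystone_nodes <- function(roles) {
  roles$node[roles$role %in% c("connector", "module hub", "network hub")]
}

#' Module eigengenes
#'
#' Summarizes each module of `min_size` or more members by the first left
#' singular vector of its samples x members matrix of z-scored profiles
#' (the module "eigengene"), oriented so the summed member correlations are
#' non-negative.
#'
#' @param X abundance matrix (taxa x samples) covering all module members.
#' @param partition a [fast_greedy_partition()].
#' @param min_size smallest module summarized (default 5).
#' @return list of class `eigengene_table`: `eigengenes` (samples x modules
#'   matrix, unit-norm columns named `M<module>`), `var_explained` (named
#'   fraction per module), `modules` (integer ids).
#' @export
module_eigengenes <- function(X, partition, min_size = 5) {
  mem <- partition$membership
  missing <- setdiff(names(mem), rownames(X))
  if (length(missing) > 0)
    stop("module_eigengenes: module member(s) missing from X: ",
         paste(missing, collapse = ", "))
  tab <- table(mem)
  keep_modules <- as.integer(names(tab)[tab >= min_size])
  eig <- list(); ve <- numeric()
  for (s in keep_modules) {
    members <- names(mem)[mem == s]
    M <- t(X[members, , drop = FALSE])          # samples x members
    M <- scale(M)
    M[is.na(M)] <- 0                            # constant members carry no signal
    sv <- svd(M)
    e <- sv$u[, 1]
    cors <- suppressWarnings(cor(e, M))
    if (sum(cors, na.rm = TRUE) < 0) e <- -e
    eig[[paste0("M", s)]] <- e
    ve[paste0("M", s)] <- sv$d[1]^2 / sum(sv$d^2)
  }
  if (length(eig) == 0)
    return(structure(list(eigengenes = matrix(numeric(), ncol = 0,
                                              nrow = ncol(X),
                                              dimnames = list(colnames(X), NULL)),
                          var_explained = ve, modules = integer()),
                     class = "eigengene_table"))
  E <- do.call(cbind, eig)
  rownames(E) <- colnames(X)
  structure(list(eigengenes = E, var_explained = ve, modules = keep_modules),
            class = "eigengene_table")
}

#' Correlate module eigengenes with environmental variables
#'
#' Pearson r and two-sided p for every module x environmental-variable pair,
#' with BH q-values across the whole table. The significance flag uses the
#' raw p (default alpha 0.05); q is reported alongside.
#'
#' @param eig an [module_eigengenes()] result.
#' @param frame sample metadata frame whose rows match the eigengene samples
#'   (by `sample_id`).
#' @param env_vars environmental columns to use; defaults to the numeric
#'   columns among the standard variable set present in `frame`.
#' @param alpha significance level for the flag.
#' @return data.frame (class `association_table`): `module`, `variable`,
#'   `r`, `p`, `q`, `significant`.
#' @export
module_env_correlation <- function(eig, frame, env_vars = NULL, alpha = 0.05) {
  E <- eig$eigengenes
  if (ncol(E) == 0) {
    warning("module_env_correlation: no eigengenes to correlate")
    return(empty_association_table("module"))
  }
  frame <- frame[match(rownames(E), frame$sample_id), ]
  if (anyNA(frame$sample_id))
    stop("module_env_correlation: sample sets of eigengenes and frame differ")
  if (is.null(env_vars))
    env_vars <- intersect(ENV_VARS, names(frame))
  for (v in env_vars)
    if (!is.numeric(frame[[v]]))
      stop("module_env_correlation: non-numeric environmental column '", v, "'")
  rows <- expand.grid(module = colnames(E), variable = env_vars,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    ct <- cor.test(E[, rows$module[i]], frame[[rows$variable[i]]])
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(rows, r = res[, "r"], p = res[, "p"])
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  structure(out, class = c("association_table", "data.frame"))
}

empty_association_table <- function(key) {
  out <- data.frame(key = character(), variable = character(),
                    r = numeric(), p = numeric(), q = numeric(),
                    significant = logical())
  names(out)[1] <- key
  structure(out, class = c("association_table", "data.frame"))
}
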