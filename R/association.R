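new_assoc_matrix <- function(taxon_ids, r, p, q, method, n_samples,
                             constant_taxa = character()) {
  dimnames(r) <- list(taxon_ids, taxon_ids)
  dimnames(p) <- dimnames(r)
  if (!is.null(q)) dimnames(q) <- dimnames(r)
  structure(list(taxon_ids = taxon_ids, r = r, p = p, q = q,
                 method = method, n_samples = n_samples,
                 constant_taxa = constant_taxa),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %s, %d taxa, n = %d samples, q %s\n",
              x$method, length(x$taxon_ids), x$n_samples,
              if (is.null(x$q)) "unset" else "set"))
  invisible(x)
}

#' Pairwise Pearson correlations with parametric p-values
#'
#' Sample Pearson r between every pair of taxon profiles across samples, with
#' two-sided p-values from the t statistic `r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom. Taxa with constant profiles get r = 0, p = 1
#' and are flagged (rather than dropped) so matrix dimensions stay aligned
#' with the filtered table.
#'
#' @param X numeric matrix of (log) abundances, taxa x samples, from
#'   [transform_abundance()].
#' @return an `assoc_matrix` with `r` and `p` filled (`q` unset; see
#'   [bh_fdr()]).
#' @export
pearson_with_p <- function(X) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (n < 3) stop("pearson_with_p: need at least 3 samples")
  sds <- apply(X, 1, sd)
  constant <- rownames(X)[sds == 0]
  Xs <- X
  Xs[sds == 0, ] <- 0   # cor() would yield NA; zero rows give r = 0 below
  r <- suppressWarnings(cor(t(X)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  rc <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- rc * sqrt((n - 2) / (1 - rc^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  const_idx <- which(sds == 0)
  if (length(const_idx) > 0) {
    p[const_idx, ] <- 1
    p[, const_idx] <- 1
    message("pearson_with_p: ", length(const_idx),
            " constant profile(s) flagged (r = 0, p = 1)")
  }
  diag(p) <- 0
  new_assoc_matrix(rownames(X), r, p, NULL, "pearson", n, constant)
}

#' Benjamini-Hochberg FDR over the pair family
#'
#' Applies BH step-up correction to the `m = D(D-1)/2` upper-triangle
#' p-values (each taxon pair counted once) and mirrors the resulting q-values
#' into the lower triangle.
#'
#' @param assoc an `assoc_matrix` with `p` filled.
#' @return the `assoc_matrix` with `q` filled.
#' @export
bh_fdr <- function(assoc) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  D <- length(assoc$taxon_ids)
  q <- matrix(0, D, D)
  if (D >= 2) {
    ut <- upper.tri(q)
    q[ut] <- p.adjust(assoc$p[ut], method = "BH")
    q <- q + t(q)
  }
  diag(q) <- 0
  assoc$q <- q
  dimnames(assoc$q) <- dimnames(assoc$r)
  assoc
}

# log-ratio variance matrix T_ij = Var_s log(x_i / x_j) for fractions (taxa x samples)
logratio_variance <- function(frac) {
  L <- log(frac)
  D <- nrow(L)
  cv <- cov(t(L))      # T_ij = v_i + v_j - 2 cov_ij
  v <- diag(cv)
  Tm <- outer(v, v, "+") - 2 * cv
  Tm[Tm < 0] <- 0
  diag(Tm) <- 0
  Tm
}

# solve basis variances omega from T under the sparsity assumption, honouring
# the pair-exclusion indicator M (symmetric logical, TRUE = pair included)
solve_basis <- function(Tm, M) {
  D <- nrow(Tm)
  deg <- rowSums(M)
  t_i <- rowSums(Tm * M)
  A <- diag(deg) + M
  omega <- tryCatch(solve(A, t_i), error = function(e) rep(mean(t_i) / (2 * D - 2), D))
  if (any(omega <= 0)) {
    warning("sparcc: ", sum(omega <= 0),
            " non-positive basis variance(s) clipped to 1e-6")
    omega[omega <= 0] <- 1e-6
  }
  omega
}

sparcc_rho <- function(Tm, excl_threshold, excl_iters) {
  D <- nrow(Tm)
  M <- matrix(TRUE, D, D)
  diag(M) <- FALSE
  for (it in seq_len(excl_iters + 1)) {
    omega <- solve_basis(Tm, M)
    rho <- (outer(omega, omega, "+") - Tm) / (2 * sqrt(outer(omega, omega)))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (it > excl_iters) break
    cand <- abs(rho) * M
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= excl_threshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1, ]
    M[idx[1], idx[2]] <- M[idx[2], idx[1]] <- FALSE
  }
  rho
}

#' SparCC compositionally aware correlations
#'
#' Estimates basis (absolute-abundance) correlations from compositional
#' counts: taxon fractions are estimated by averaging Dirichlet posterior
#' draws (counts + 1), the log-ratio variance matrix `T_ij = Var log(x_i/x_j)`
#' is inverted for basis variances under a sparsity assumption, and the
#' strongest correlated pairs are iteratively excluded from the estimation.
#' Two-sided p-values come from permuting each taxon's samples independently.
#'
#' @param table a [count_table] with >= 4 taxa and >= 4 samples.
#' @param n_dirichlet posterior draws averaged for the fraction estimate.
#' @param excl_threshold |rho| above which the strongest pair is excluded.
#' @param excl_iters maximum exclusion rounds.
#' @param n_boot permutation replicates for p-values (add-one estimator,
#'   so the smallest attainable p is `1/(n_boot + 1)`).
#' @param seed integer seed.
#' @return an `assoc_matrix` with `method = "sparcc"` (`q` unset).
#' @export
sparcc <- function(table, n_dirichlet = 20, excl_threshold = 0.1,
                   excl_iters = 10, n_boot = 100, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  counts <- table$counts
  D <- nrow(counts); n <- ncol(counts)
  if (D <= 3) stop("sparcc: need more than 3 taxa (basis system under-determined)")
  if (n < 4) stop("sparcc: need at least 4 samples")
  set.seed(seed)

  draw_fractions <- function(cnt) {
    acc <- matrix(0, nrow(cnt), ncol(cnt))
    for (b in seq_len(n_dirichlet)) {
      g <- matrix(rgamma(length(cnt), shape = cnt + 1, rate = 1),
                  nrow(cnt), ncol(cnt))
      acc <- acc + sweep(g, 2, colSums(g), "/")
    }
    acc / n_dirichlet
  }

  frac <- draw_fractions(counts)
  Tm <- logratio_variance(frac)
  rho <- sparcc_rho(Tm, excl_threshold, excl_iters)

  exceed <- matrix(0, D, D)
  for (b in seq_len(n_boot)) {
    perm <- t(apply(frac, 1, sample))
    rho_null <- sparcc_rho(logratio_variance(perm), excl_threshold, 0L)
    exceed <- exceed + (abs(rho_null) >= abs(rho))
  }
  p <- (1 + exceed) / (1 + n_boot)
  diag(p) <- 0
  p <- (p + t(p)) / 2   # symmetrize permutation noise
  new_assoc_matrix(rownames(counts), rho, p, NULL, "sparcc", n)
}
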