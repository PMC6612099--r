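# Independent oracles used by the tests. Deliberately brute-force and
# written without reference to the package implementation paths they
# check.

# Two-sided permutation p-value for the rank-sum U statistic: enumerate
# every split of the pooled values into groups of the observed sizes
# and count splits whose U is at least as far from its mean.
perm_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n_x <- length(x)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  mu <- n_x * length(y) / 2
  u_obs <- u_of(x, y)
  splits <- utils::combn(length(pooled), n_x)
  u_all <- apply(splits, 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# AUC by direct pair counting: concordant pairs plus half the ties.
pair_count_auc <- function(scores, labels, positive_label) {
  pos <- scores[labels == positive_label]
  neg <- scores[labels != positive_label]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Hypergeometric upper-tail by combinatorial enumeration: probability
# that a uniformly drawn candidate set of the same size overlaps the
# gene set at least as much as observed.
enum_hypergeom_p <- function(candidates, universe, gene_set) {
  k <- length(candidates)
  obs <- length(intersect(candidates, gene_set))
  draws <- utils::combn(length(universe), k)
  hits <- apply(draws, 2, function(idx)
    length(intersect(universe[idx], gene_set)))
  mean(hits >= obs)
}

# Kruskal-Wallis H from the textbook rank formula with tie correction,
# computed from scratch.
rank_formula_H <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  splits <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, splits, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Damped Newton-Raphson logistic fit, independent of stats::glm.
newton_logistic <- function(x, y, tol = 1e-12, max_iter = 200) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, y - p))
    W <- p * (1 - p)
    hess <- crossprod(X, X * W)
    step <- solve(hess, grad)
    lambda <- 1
    while (ll(beta + lambda * step) < ll(beta) && lambda > 1e-8)
      lambda <- lambda / 2
    beta_new <- beta + lambda * step
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# Tiny beta matrix straight from numbers, for unit tests.
toy_beta <- function(sens, res, probes = NULL) {
  stopifnot(length(sens) == length(res))
  if (is.null(probes)) probes <- sprintf("cg%08d", seq_along(sens))
  values <- cbind(sens_1 = sens, res_1 = res)
  rownames(values) <- probes
  beta_matrix(values, c(sens_1 = "sensitive", res_1 = "resistant"))
}

# The published 46-CpG panel as a beta matrix (one pseudo-sample per
# condition, from the printed two-decimal values).
panel_beta <- function(panel = hyper_cpg_panel()) {
  toy_beta(panel$beta_sensitive, panel$beta_resistant, panel$TargetID)
}
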