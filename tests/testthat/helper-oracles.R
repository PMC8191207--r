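# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: explicit matrix inversion instead of Cholesky
# whitening, naive path enumeration instead of the vectorized statistic,
# and the textbook step-up definition of the BH adjustment.

# GLS by the explicit-inverse closed form
oracle_gls <- function(y, x, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  n <- length(y)
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - 2)
  se <- sqrt(s2 * solve(XtVi %*% X)[2, 2])
  tt <- beta[2] / se
  list(intercept = beta[1], slope = beta[2], slope_se = se, t_stat = tt,
       p_value = 2 * pt(-abs(tt), n - 2), residuals = as.numeric(r))
}

# root-to-tip omega by naive enumeration with ape::nodepath
oracle_root_to_tip <- function(tree, rates, threshold = 2e-4) {
  labs <- c(tree$tip.label, tree$node.label)
  root <- length(tree$tip.label) + 1L
  out <- list()
  for (g in unique(rates$gene)) {
    sub <- rates[rates$gene == g, ]
    for (i in seq_along(tree$tip.label)) {
      nodes <- ape::nodepath(tree, from = root, to = i)
      ids <- labs[nodes[-1]]
      vals <- c()
      for (b in ids) {
        row <- sub[sub$branch == b, ]
        if (nrow(row) == 1 && !is.na(row$dN) && !is.na(row$dS) &&
            row$dN >= threshold && row$dS >= threshold && !is.na(row$omega)) {
          vals <- c(vals, row$omega)
        }
      }
      out[[length(out) + 1]] <- data.frame(
        gene = g, species = tree$tip.label[i],
        omega_bar = if (length(vals)) mean(vals) else NA_real_,
        n_valid_branches = length(vals))
    }
  }
  do.call(rbind, out)
}

# Benjamini-Hochberg step-up from its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- cummin(p[o] * n / (n:1))
  pmin(adj, 1)[ro]
}

# random symmetric positive-definite matrix
random_spd <- function(n) {
  M <- matrix(rnorm(n * n), n)
  crossprod(M) + diag(n) * 0.5
}

# a small fixture tree shared by several files
fixture_tree <- function() parse_newick("((A:1,B:1):1,C:2);")

# rates rows for one gene from named omega/dN/dS vectors
rates_row <- function(gene, branch, dN, dS, omega = dN / dS) {
  data.frame(gene = gene, branch = branch, dN = dN, dS = dS, omega = omega,
             stringsAsFactors = FALSE)
}
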