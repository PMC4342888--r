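# Independent oracles used to freeze expected values. Each is a brute-force
# or closed-form computation kept deliberately separate from the package's
# own code paths.

# all permutations of 1..n (n small)
perms_all <- function(n) {
  if (n == 1) return(matrix(1))
  p <- perms_all(n - 1)
  do.call(rbind, lapply(1:n, function(k)
    cbind(k, matrix(setdiff(1:n, k)[p], nrow(p)))))
}

# exhaustive optimum of the design criterion (1/block-centered SSX) over all
# feasible triplex designs; blocks are exchangeable so the light-label
# assignment is fixed to the identity without loss of generality
enum_best_design <- function(x, pop) {
  n <- length(x)
  P <- perms_all(n)
  best <- Inf
  for (i in seq_len(nrow(P))) {
    cM <- P[i, ]
    if (any(cM == 1:n) || any(pop[cM] == pop)) next
    okH <- rep(TRUE, nrow(P))
    for (b in 1:n) {
      okH <- okH & P[, b] != b & P[, b] != cM[b] &
        pop[P[, b]] != pop[b] & pop[P[, b]] != pop[cM[b]]
    }
    if (!any(okH)) next
    H <- P[okH, , drop = FALSE]
    S <- matrix(x[H], nrow(H)) + rep(x + x[cM], each = nrow(H))
    ssx <- 3 * sum(x^2) - min(rowSums(S^2)) / 3
    if (ssx > 1e-12) best <- min(best, 1 / ssx)
  }
  best
}

# estimator variance of the covariate slope from the explicit projection
# (hat matrix of the block dummies): 1 / (x' (I - H_block) x)
projection_criterion <- function(blocks_df, colonies, hb_variable) {
  x <- colonies[[hb_variable]][match(blocks_df$colony_id,
                                     colonies$colony_id)]
  B <- model.matrix(~ 0 + factor(blocks_df$block_id))
  Hx <- B %*% solve(crossprod(B), crossprod(B, x))
  1 / sum((x - Hx)^2)
}

# exact minimum set cover size by subset enumeration (<= ~15 sets);
# proteins with identical peptide sets count as one candidate
set_cover_min <- function(pep_sets) {
  sig <- vapply(pep_sets, paste, "", collapse = "\r")
  sets <- pep_sets[!duplicated(sig)]
  universe <- unique(unlist(sets))
  m <- length(sets)
  for (k in 1:m) {
    combos <- utils::combn(m, k, simplify = FALSE)
    for (cc in combos) {
      if (setequal(unlist(sets[cc]), universe)) return(k)
    }
  }
  m
}

# brute-force decoy-FDR threshold: scan all unique scores
fdr_threshold_oracle <- function(score, decoy, fdr) {
  for (t in sort(unique(score))) {
    nt <- sum(!decoy & score >= t)
    nd <- sum(decoy & score >= t)
    if (nt > 0 && nd / nt <= fdr) return(t)
  }
  NA_real_
}

# 1:1 equilibrium bound concentration by grid search on the mass-balance
# residual (independent of the closed-form quadratic)
bound_grid_oracle <- function(P, L, kd, n_grid = 2e6) {
  b <- seq(0, min(P, L), length.out = n_grid)
  resid <- abs((P - b) * (L - b) - kd * b)
  b[which.min(resid)]
}

# Benjamini-Hochberg by the step-up definition, written out
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}
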