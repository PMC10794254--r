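# Independent reference implementations used to validate the package's
# algorithms on small instances. These deliberately take different
# computational routes than the implementations they check.

# Locus partition oracle: greedy index selection by brute force, then
# interval-graph connected components (igraph) over the chosen indices.
oracle_loci <- function(pos, p, alpha = 5e-8, window = 1e6) {
  half <- window / 2
  sig <- which(p < alpha)
  pool <- sig[order(p[sig], pos[sig])]
  idx <- integer()
  while (length(pool) > 0) {
    i <- pool[1]
    idx <- c(idx, i)
    pool <- pool[abs(pos[pool] - pos[i]) > half]
  }
  if (length(idx) == 0)
    return(data.frame(index_pos = numeric(), start = numeric(),
                      end = numeric()))
  # merge indices whose 1-Mb intervals overlap or touch
  adj <- abs(outer(pos[idx], pos[idx], "-")) <= window
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- do.call(rbind, lapply(split(seq_along(idx), comp), function(m) {
    members <- idx[m]
    best <- members[order(p[members], pos[members])][1]
    data.frame(index_pos = pos[best],
               start = min(pos[members]) - half,
               end = max(pos[members]) + half)
  }))
  out[order(out$start), , drop = FALSE]
}

# Stepwise-selection oracle: conditional z of candidate i given set S taken
# from the joint solve on S u {i} (partitioned-inverse route), instead of
# the residualization formula.
oracle_stepwise <- function(z, R, alpha = 5e-8, collinearity = 0.9) {
  joint_z <- function(set) {
    Ri <- solve(R[set, set, drop = FALSE])
    drop(Ri %*% z[set]) / sqrt(diag(Ri))
  }
  p <- 2 * pnorm(-abs(z))
  first <- names(z)[order(p, names(z))][1]
  if (p[first] >= alpha) return(character())
  sel <- first
  repeat {
    cand <- setdiff(names(z), sel)
    cand <- cand[apply(R[cand, sel, drop = FALSE]^2, 1, max) < collinearity]
    if (length(cand) == 0) break
    zc <- vapply(cand, function(i) {
      zz <- joint_z(c(sel, i))
      zz[length(zz)]
    }, 0)
    pc <- 2 * pnorm(-abs(zc))
    best <- cand[order(pc, cand)][1]
    if (pc[best] >= alpha) break
    sel <- c(sel, best)
  }
  sel
}

# Random correlation matrix with positive definiteness guaranteed.
random_corr <- function(n, jitter = 0.3) {
  A <- matrix(rnorm(n * n), n)
  S <- crossprod(A) + diag(n) * jitter
  D <- diag(1 / sqrt(diag(S)))
  R <- D %*% S %*% D
  dimnames(R) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  (R + t(R)) / 2
}

# Draw z ~ N(R lambda, R) given an LD matrix.
draw_z <- function(R, ncp = rep(0, nrow(R))) {
  U <- chol(R)
  setNames(drop(R %*% ncp + crossprod(U, rnorm(nrow(R)))), rownames(R))
}
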