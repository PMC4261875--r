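# Independent oracles used by the tests. These deliberately avoid the
# package's own algorithms: reconciliation by exhaustive enumeration of all
# internal-node placements, OLS by the normal equations, and stop
# probabilities by enumerating codon fates.

fixture_path <- function(name) {
  system.file("extdata", name, package = "paleofv", mustWork = TRUE)
}

# Exhaustive minimum reconciliation cost: every internal virus node is tried
# at every host node; an assignment is scored by the cheapest feasible event
# label at each internal node (cospeciation if the children lie in the two
# child subtrees of the host node; duplication if both lie at-or-below it;
# duplication-and-switch if one lies at-or-below and the other at a
# non-ancestral host node), or discarded if any node has no feasible label.
brute_force_min_cost <- function(vtree, htree, assoc,
                                 cc = -1, cd = 0, cs = 0) {
  ntip_v <- length(vtree$tip.label)
  nv <- ntip_v + vtree$Nnode
  ntip_h <- length(htree$tip.label)
  nh <- ntip_h + htree$Nnode
  hpar <- integer(nh)
  hpar[htree$edge[, 2]] <- htree$edge[, 1]
  hkids <- vector("list", nh)
  for (e in seq_len(nrow(htree$edge)))
    hkids[[htree$edge[e, 1]]] <- c(hkids[[htree$edge[e, 1]]], htree$edge[e, 2])
  # S[h, x]: x lies in subtree(h) (h included)
  S <- matrix(FALSE, nh, nh)
  for (x in seq_len(nh)) {
    nd <- x
    while (nd != 0L) { S[nd, x] <- TRUE; nd <- hpar[nd] }
  }
  # note S[x, h] also reads: x is an ancestor-or-self of h
  vpar <- integer(nv)
  vpar[vtree$edge[, 2]] <- vtree$edge[, 1]
  vkids <- vector("list", nv)
  for (e in seq_len(nrow(vtree$edge)))
    vkids[[vtree$edge[e, 1]]] <- c(vkids[[vtree$edge[e, 1]]], vtree$edge[e, 2])
  internal_v <- (ntip_v + 1L):nv
  tip_pos <- integer(ntip_v)
  m <- match(vtree$tip.label, assoc$virus_tip)
  tip_pos <- match(assoc$host_tip[m], htree$tip.label)

  grid <- as.matrix(expand.grid(rep(list(seq_len(nh)), length(internal_v))))
  ng <- nrow(grid)
  total <- rep(0, ng)
  pos_of <- function(nd) {
    if (nd <= ntip_v) rep(tip_pos[nd], ng) else grid[, match(nd, internal_v)]
  }
  h_internal <- lengths(hkids) == 2L
  hk1 <- vapply(seq_len(nh), function(h) if (h_internal[h]) hkids[[h]][1] else 1L, integer(1))
  hk2 <- vapply(seq_len(nh), function(h) if (h_internal[h]) hkids[[h]][2] else 1L, integer(1))
  for (v in internal_v) {
    H <- grid[, match(v, internal_v)]
    P1 <- pos_of(vkids[[v]][1])
    P2 <- pos_of(vkids[[v]][2])
    cosp_ok <- h_internal[H] &
      ((S[cbind(hk1[H], P1)] & S[cbind(hk2[H], P2)]) |
       (S[cbind(hk2[H], P1)] & S[cbind(hk1[H], P2)]))
    dup_ok <- S[cbind(H, P1)] & S[cbind(H, P2)]
    sw_ok <- (S[cbind(H, P1)] & !S[cbind(P2, H)]) |
             (S[cbind(H, P2)] & !S[cbind(P1, H)])
    cost_v <- rep(Inf, ng)
    cost_v[sw_ok] <- pmin(cost_v[sw_ok], cs)
    cost_v[dup_ok] <- pmin(cost_v[dup_ok], cd)
    cost_v[cosp_ok] <- pmin(cost_v[cosp_ok], cc)
    total <- total + cost_v
  }
  min(total)
}

# Random rooted binary tree pair over n tips with the identity association.
random_tree_pair <- function(n) {
  vt <- ape::rtree(n, rooted = TRUE)
  ht <- ape::rtree(n, rooted = TRUE)
  vt$tip.label <- paste0("V", seq_len(n))
  ht$tip.label <- paste0("H", seq_len(n))
  assoc <- tip_association(paste0("V", seq_len(n)), paste0("H", seq_len(n)))
  list(vtree = vt, htree = ht, assoc = assoc)
}

# Exact stop probability of a single codon after time t: enumerate all 64
# descendant codons of the equal-rates chain and sum the stop ones.
enumerate_codon_stop_prob <- function(codon, rate, t) {
  bases <- c("A", "C", "G", "T")
  ps <- 0.25 + 0.75 * exp(-4 * rate * t / 3)
  pd <- (1 - ps) / 3
  from <- strsplit(codon, "")[[1]]
  total <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    to <- c(b1, b2, b3)
    if (!paste(to, collapse = "") %in% c("TAA", "TAG", "TGA")) next
    p <- prod(ifelse(to == from, ps, pd))
    total <- total + p
  }
  total
}

# Closed-form OLS through the normal equations (no lm()).
normal_equations_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}
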