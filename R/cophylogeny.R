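#' Event costs for cophylogeny reconciliation
#'
#' Vertex-based event costs in the style of event-based reconciliation
#' software (Jane and relatives). The defaults — cospeciation \eqn{-1}, all
#' other events 0 — make minimum total cost equivalent to maximising the
#' number of cospeciation events, the setting used when asking "how much of
#' this virus phylogeny can be explained by codivergence alone?".
#'
#' The exact solver prices the three internal-node events (cospeciation,
#' duplication, duplication-and-host-switch). Losses and failure-to-diverge
#' must be costed 0: with free losses the optimum never depends on them, and
#' with a bijective tip association failure-to-diverge cannot occur.
#'
#' @param cospeciation,duplication,duplication_and_switch,loss,failure_to_diverge
#'   Finite real costs.
#' @return An object of class \code{event_costs}.
#' @export
event_costs <- function(cospeciation = -1, duplication = 0,
                        duplication_and_switch = 0, loss = 0,
                        failure_to_diverge = 0) {
  costs <- c(cospeciation = cospeciation, duplication = duplication,
             duplication_and_switch = duplication_and_switch, loss = loss,
             failure_to_diverge = failure_to_diverge)
  if (!all(is.finite(costs))) stop("event costs must be finite", call. = FALSE)
  if (loss != 0 || failure_to_diverge != 0)
    stop("the exact solver requires loss and failure-to-diverge costs of 0",
         call. = FALSE)
  structure(as.list(costs), class = "event_costs")
}

# ---- tree indexing ----------------------------------------------------------

# Precomputed index structure for the DP: children, parents, postorder,
# ancestor sets (self included), depths, and postorder rank for tie-breaks.
tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nall <- ntip + tree$Nnode
  kids <- children_list(tree)
  par <- parent_vec(tree)
  post <- postorder_nodes(tree)
  depth <- integer(nall)
  for (nd in rev(post)) if (par[nd] > 0L) depth[nd] <- depth[par[nd]] + 1L
  anc_self <- vector("list", nall)
  for (nd in seq_len(nall)) {
    path <- nd
    p <- par[nd]
    while (p > 0L) { path <- c(path, p); p <- par[p] }
    anc_self[[nd]] <- path
  }
  post_rank <- integer(nall)
  post_rank[post] <- seq_along(post)
  list(ntip = ntip, nall = nall, kids = kids, par = par, post = post,
       depth = depth, anc_self = anc_self, post_rank = post_rank,
       root = post[length(post)], labels = tree$tip.label)
}

check_binary_rooted <- function(tree, what) {
  if (!ape::is.rooted(tree)) stop(what, " tree must be rooted", call. = FALSE)
  if (!ape::is.binary(tree)) stop(what, " tree must be fully binary",
                                  call. = FALSE)
  invisible(TRUE)
}

# ---- fast path: maximum cospeciation count ----------------------------------

# Maximum number of cospeciations over all feasible reconciliations, with
# host switches allowed to any non-ancestral host position. vmap: host tip
# index for each virus tip. Used by the permutation test (default costs).
max_cospeciation_count <- function(vi, hi, vmap) {
  nH <- hi$nall
  Bs <- vector("list", vi$nall)
  As <- vector("list", vi$nall)
  for (v in vi$post) {
    if (v <= vi$ntip) {
      B <- rep(-Inf, nH)
      B[vmap[v]] <- 0
    } else {
      ch <- vi$kids[[v]]
      B1 <- Bs[[ch[1L]]]; B2 <- Bs[[ch[2L]]]
      A1 <- As[[ch[1L]]]; A2 <- As[[ch[2L]]]
      # best B over non-ancestral hosts, per host node
      NA1 <- excl_max(B1, hi)
      NA2 <- excl_max(B2, hi)
      B <- pmax(A1 + NA2, A2 + NA1)          # duplication & switch
      B <- pmax(B, A1 + A2)                  # duplication
      for (h in seq_len(nH)) {               # cospeciation
        hk <- hi$kids[[h]]
        if (length(hk) == 2L) {
          cosp <- 1 + max(A1[hk[1L]] + A2[hk[2L]], A1[hk[2L]] + A2[hk[1L]])
          if (cosp > B[h]) B[h] <- cosp
        }
      }
    }
    A <- B
    for (h in hi$post) {
      hk <- hi$kids[[h]]
      for (k in hk) if (A[k] > A[h]) A[h] <- A[k]
    }
    Bs[[v]] <- B
    As[[v]] <- A
  }
  max(Bs[[vi$root]])
}

# For each host node h, max of x over nodes outside (ancestors of h + h).
excl_max <- function(x, hi) {
  ord <- order(x, decreasing = TRUE)
  out <- rep(-Inf, hi$nall)
  for (h in seq_len(hi$nall)) {
    excl <- hi$anc_self[[h]]
    for (j in ord) {
      if (!(j %in% excl)) { out[h] <- x[j]; break }
    }
  }
  out
}

# ---- full solver with general costs, tie-breaking and traceback -------------

# Lexicographic solution score: (total cost, -n_cospeciations, n_switches).
tri_better <- function(a, b) {
  if (a[1L] != b[1L]) return(a[1L] < b[1L])
  if (a[2L] != b[2L]) return(a[2L] < b[2L])
  a[3L] < b[3L]
}

TRI_INF <- c(Inf, Inf, Inf)

#' Reconcile a virus tree onto a host tree
#'
#' Exact event-based reconciliation by dynamic programming over (virus node,
#' host node) states. Internal virus nodes are labelled cospeciation,
#' duplication, or duplication-and-host-switch; losses are free and counted
#' from the embedding; with a bijective association failure-to-diverge never
#' occurs. Host switches may land on any host position that is not an
#' ancestor of the current one (the host tree is treated as untimed).
#' Under the default [event_costs()] the optimum maximises the number of
#' cospeciation events.
#'
#' Among equal-cost solutions the solver prefers more cospeciations, then
#' fewer switches, then the host assignment that is smallest in host-tree
#' postorder, making the reported reconciliation deterministic.
#'
#' @param vtree,htree Rooted, fully binary \code{phylo} trees (virus and
#'   host). Exact search is limited to trees of at most 25 tips.
#' @param assoc A [tip_association()] bijection over the two tip sets.
#' @param costs An [event_costs()] object.
#' @return An object of class \code{fv_reconciliation}: a list with
#'   \code{events} (data frame: virus node, clade, host node, host clade,
#'   event), \code{n_cospeciations}, \code{n_duplications},
#'   \code{n_switches}, \code{n_losses}, \code{n_failure_to_diverge},
#'   \code{total_cost}, and the \code{costs} used.
#' @export
reconcile <- function(vtree, htree, assoc, costs = event_costs()) {
  check_binary_rooted(vtree, "virus")
  check_binary_rooted(htree, "host")
  stopifnot(inherits(costs, "event_costs"))
  validate_tip_consistency(vtree, htree, assoc)
  if (length(vtree$tip.label) > 25L)
    stop("exact reconciliation is limited to <= 25 tips; heuristic search ",
         "for larger instances is out of scope", call. = FALSE)
  vi <- tree_index(vtree)
  hi <- tree_index(htree)
  vmap <- vtip_map(vtree, htree, assoc)

  nH <- hi$nall
  B <- vector("list", vi$nall)      # B[[v]]: list over h of score triple
  A <- vector("list", vi$nall)      # subtree-minimised scores
  Aarg <- vector("list", vi$nall)   # argmin host node for A
  choice <- vector("list", vi$nall) # traceback records

  cc <- costs$cospeciation; cd <- costs$duplication
  cs <- costs$duplication_and_switch

  for (v in vi$post) {
    Bv <- rep(list(TRI_INF), nH)
    Cv <- vector("list", nH)
    if (v <= vi$ntip) {
      Bv[[vmap[v]]] <- c(0, 0, 0)
      Cv[[vmap[v]]] <- list(type = "tip")
    } else {
      ch <- vi$kids[[v]]
      A1 <- A[[ch[1L]]]; A2 <- A[[ch[2L]]]
      B1 <- B[[ch[1L]]]; B2 <- B[[ch[2L]]]
      for (h in seq_len(nH)) {
        best <- TRI_INF; bc <- NULL
        hk <- hi$kids[[h]]
        if (length(hk) == 2L) {
          for (swap in c(FALSE, TRUE)) {
            c1 <- if (swap) hk[2L] else hk[1L]
            c2 <- if (swap) hk[1L] else hk[2L]
            s <- c(cc, -1, 0) + A1[[c1]] + A2[[c2]]
            if (tri_better(s, best)) {
              best <- s
              bc <- list(type = "cospeciation", to1 = c1, to2 = c2)
            }
          }
        }
        s <- c(cd, 0, 0) + A1[[h]] + A2[[h]]
        if (tri_better(s, best)) { best <- s; bc <- list(type = "duplication") }
        allowed <- setdiff(seq_len(nH), hi$anc_self[[h]])
        for (keep in 1:2) {
          Ak <- if (keep == 1L) A1 else A2
          Bo <- if (keep == 1L) B2 else B1
          tgt <- 0L; bsw <- TRI_INF
          for (hh in allowed) {
            s2 <- Bo[[hh]]
            if (tri_better(s2, bsw) ||
                (!tri_better(bsw, s2) && tgt > 0L &&
                 hi$post_rank[hh] < hi$post_rank[tgt])) {
              bsw <- s2; tgt <- hh
            }
          }
          if (tgt > 0L) {
            s <- c(cs, 0, 1) + Ak[[h]] + bsw
            if (tri_better(s, best)) {
              best <- s
              bc <- list(type = "duplication_and_switch", keep = keep,
                         target = tgt)
            }
          }
        }
        Bv[[h]] <- best
        Cv[[h]] <- bc
      }
    }
    # subtree minimisation for A, postorder tie-break
    Av <- Bv
    argv <- seq_len(nH)
    for (h in hi$post) {
      for (k in hi$kids[[h]]) {
        if (tri_better(Av[[k]], Av[[h]]) ||
            (!tri_better(Av[[h]], Av[[k]]) &&
             hi$post_rank[argv[k]] < hi$post_rank[argv[h]])) {
          Av[[h]] <- Av[[k]]
          argv[h] <- argv[k]
        }
      }
    }
    B[[v]] <- Bv; A[[v]] <- Av; Aarg[[v]] <- argv; choice[[v]] <- Cv
  }

  # optimal root placement
  root_scores <- B[[vi$root]]
  best <- TRI_INF; best_h <- 0L
  for (h in hi$post) {            # postorder scan = postorder tie-break
    if (tri_better(root_scores[[h]], best)) { best <- root_scores[[h]]; best_h <- h }
  }
  if (!is.finite(best[1L]))
    stop("no feasible reconciliation found (internal error)", call. = FALSE)

  # traceback
  events <- list()
  n_losses <- 0L
  walk <- function(v, h) {
    ch_rec <- choice[[v]][[h]]
    if (is.null(ch_rec)) stop("traceback error", call. = FALSE)
    events[[length(events) + 1L]] <<- list(virus_node = v, host_node = h,
                                           event = ch_rec$type)
    if (ch_rec$type == "tip") return(invisible())
    vk <- vi$kids[[v]]
    if (ch_rec$type == "cospeciation") {
      for (i in 1:2) {
        tgt <- if (i == 1L) ch_rec$to1 else ch_rec$to2
        g <- Aarg[[vk[i]]][tgt]
        n_losses <<- n_losses + (hi$depth[g] - hi$depth[tgt])
        walk(vk[i], g)
      }
    } else if (ch_rec$type == "duplication") {
      for (i in 1:2) {
        g <- Aarg[[vk[i]]][h]
        n_losses <<- n_losses + (hi$depth[g] - hi$depth[h])
        walk(vk[i], g)
      }
    } else {
      keep <- ch_rec$keep
      kept_child <- vk[keep]
      sw_child <- vk[3L - keep]
      g <- Aarg[[kept_child]][h]
      n_losses <<- n_losses + (hi$depth[g] - hi$depth[h])
      walk(kept_child, g)
      walk(sw_child, ch_rec$target)
    }
  }
  walk(vi$root, best_h)

  ev <- do.call(rbind, lapply(events, function(e)
    data.frame(virus_node = e$virus_node, host_node = e$host_node,
               event = e$event, stringsAsFactors = FALSE)))
  ev$virus_clade <- vapply(ev$virus_node, function(nd)
    paste(sort(vtree$tip.label[descendant_tips(vtree, nd)]), collapse = "+"),
    character(1))
  ev$host_clade <- vapply(ev$host_node, function(nd)
    paste(sort(htree$tip.label[descendant_tips(htree, nd)]), collapse = "+"),
    character(1))
  ev <- ev[, c("virus_node", "virus_clade", "host_node", "host_clade", "event")]
  n_cosp <- sum(ev$event == "cospeciation")
  n_dup <- sum(ev$event == "duplication")
  n_sw <- sum(ev$event == "duplication_and_switch")
  structure(
    list(events = ev,
         n_cospeciations = n_cosp,
         n_duplications = n_dup,
         n_switches = n_sw,
         n_losses = n_losses,
         n_failure_to_diverge = 0L,
         total_cost = unname(best[1L]),
         costs = costs,
         vtree = vtree, htree = htree, assoc = assoc),
    class = "fv_reconciliation"
  )
}

#' @export
print.fv_reconciliation <- function(x, ...) {
  cat(sprintf(paste0("<fv_reconciliation> %d cospeciations, %d duplications, ",
                     "%d switches, %d losses; total cost %g\n"),
              x$n_cospeciations, x$n_duplications, x$n_switches, x$n_losses,
              x$total_cost))
  invisible(x)
}

vtip_map <- function(vtree, htree, assoc) {
  vmap <- integer(length(vtree$tip.label))
  m <- match(vtree$tip.label, assoc$virus_tip)
  vmap <- match(assoc$host_tip[m], htree$tip.label)
  vmap
}

#' Random tip-mapping permutation test
#'
#' Significance test for the observed number of cospeciation events: tip
#' associations are replaced by uniform random bijections, the reconciliation
#' is re-solved for each, and the p-value is computed with the add-one
#' estimator \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}.
#'
#' @inheritParams reconcile
#' @param n_perm Number of random bijections (default 1000).
#' @param seed Optional integer seed.
#' @param observed Observed cospeciation count to test. Defaults to the
#'   count from reconciling \code{assoc} itself; supply a smaller value to
#'   test a conservative re-reading of the reconciliation (for example after
#'   manually discounting an ambiguous event).
#' @return An object of class \code{tipmap_test}: \code{observed},
#'   \code{null_counts}, \code{n_perm}, \code{p_value}.
#' @export
random_tip_mapping_test <- function(vtree, htree, assoc,
                                    costs = event_costs(), n_perm = 1000L,
                                    seed = NULL, observed = NULL) {
  check_binary_rooted(vtree, "virus")
  check_binary_rooted(htree, "host")
  validate_tip_consistency(vtree, htree, assoc)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  default_costs <- identical(unlist(costs), unlist(event_costs()))
  vi <- tree_index(vtree)
  hi <- tree_index(htree)
  if (is.null(observed)) {
    observed <- if (default_costs) {
      max_cospeciation_count(vi, hi, vtip_map(vtree, htree, assoc))
    } else {
      reconcile(vtree, htree, assoc, costs)$n_cospeciations
    }
  }
  ntip <- length(vtree$tip.label)
  null_counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(ntip)
    if (default_costs) {
      null_counts[b] <- max_cospeciation_count(vi, hi, perm)
    } else {
      assoc_b <- tip_association(vtree$tip.label, htree$tip.label[perm])
      null_counts[b] <- reconcile(vtree, htree, assoc_b, costs)$n_cospeciations
    }
  }
  p <- (1 + sum(null_counts >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null_counts = null_counts,
                 n_perm = n_perm, p_value = p),
            class = "tipmap_test")
}

#' @export
print.tipmap_test <- function(x, ...) {
  cat(sprintf("<tipmap_test> observed %d cospeciations; null max %d over %d permutations; p = %.4g\n",
              x$observed, max(x$null_counts), x$n_perm, x$p_value))
  invisible(x)
}
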