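congruent_pair <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ht <- ape::rtree(n)
  ht$tip.label <- paste0("H", seq_len(n))
  vt <- ht
  vt$tip.label <- paste0("V", seq_len(n))
  list(vtree = vt, htree = ht,
       assoc = tip_association(paste0("V", seq_len(n)),
                               paste0("H", seq_len(n))))
}

test_that("fully congruent trees give n_tips - 1 cospeciations at cost -(n-1)", {
  v4 <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  h4 <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1);")
  a4 <- tip_association(c("A", "B", "C", "D"), c("a", "b", "c", "d"))
  r <- reconcile(v4, h4, a4)
  expect_equal(r$n_cospeciations, 3L)
  expect_equal(r$total_cost, -3)
  expect_equal(r$n_switches, 0L)
  expect_equal(r$n_losses, 0L)
  expect_equal(r$n_failure_to_diverge, 0L)

  for (n in c(5, 9)) {
    p <- congruent_pair(n, seed = n)
    expect_equal(reconcile(p$vtree, p$htree, p$assoc)$n_cospeciations, n - 1L)
  }
})

test_that("the 17-tip virus/host fixture reconciles with 14 cospeciations", {
  vt <- read_newick(fixture_path("fv_tree_17_synthetic.nwk"))
  ht <- read_newick(fixture_path("host_tree_17_synthetic.nwk"))
  as <- read_associations(fixture_path("fv_host_assoc_17_synthetic.tsv"))
  r <- reconcile(vt, ht, as)
  expect_equal(r$n_cospeciations, 14L)
  expect_equal(r$total_cost, -14)
  # the mismatching clades are the bat/aye-aye virus pair and the
  # New World monkey virus clade
  off <- r$events[!r$events$event %in% c("tip", "cospeciation"), ]
  expect_true("PSFVaye+RhiFV" %in% off$virus_clade)
  expect_true("SFVmar+SFVspm+SFVsqu" %in% off$virus_clade)
})

test_that("dynamic programming equals exhaustive enumeration on small instances", {
  set.seed(17)
  cases <- c(rep(4, 10), rep(5, 6), rep(6, 2))
  for (n in cases) {
    p <- random_tree_pair(n)
    dp <- reconcile(p$vtree, p$htree, p$assoc)
    bf <- brute_force_min_cost(p$vtree, p$htree, p$assoc)
    expect_equal(dp$total_cost, bf,
                 info = sprintf("n = %d", n))
  }
  # and on congruent pairs, where the optimum is known a priori
  p <- congruent_pair(5, seed = 99)
  expect_equal(brute_force_min_cost(p$vtree, p$htree, p$assoc), -4)
})

test_that("reconciliation cost is invariant to consistent relabelling", {
  p <- random_tree_pair(7)
  r1 <- reconcile(p$vtree, p$htree, p$assoc)
  perm <- sample(7)
  vt2 <- p$vtree
  vt2$tip.label <- paste0("W", perm)[match(vt2$tip.label, paste0("V", 1:7))]
  ht2 <- p$htree
  ht2$tip.label <- paste0("G", perm)[match(ht2$tip.label, paste0("H", 1:7))]
  a2 <- tip_association(paste0("W", 1:7), paste0("G", 1:7))
  r2 <- reconcile(vt2, ht2, a2)
  expect_equal(r2$total_cost, r1$total_cost)
  expect_equal(r2$n_cospeciations, r1$n_cospeciations)
})

test_that("cospeciation count is bounded by internal node counts", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(4:10, 1)
    p <- random_tree_pair(n)
    r <- reconcile(p$vtree, p$htree, p$assoc)
    expect_lte(r$n_cospeciations, n - 1L)
    expect_gte(r$n_cospeciations, 0L)
  }
})

test_that("input validation rejects bad trees, costs and sizes", {
  p <- congruent_pair(4, seed = 1)
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:1);")
  a <- tip_association(c("A", "B", "C", "D"), paste0("H", 1:4))
  expect_error(reconcile(poly, p$htree, a), "binary")
  expect_error(event_costs(loss = 1), "loss")
  big <- congruent_pair(26, seed = 2)
  expect_error(reconcile(big$vtree, big$htree, big$assoc), "25 tips")
})

test_that("two-tip trees give p = 1 under random tip mapping", {
  p <- congruent_pair(2, seed = 5)
  tt <- random_tip_mapping_test(p$vtree, p$htree, p$assoc, n_perm = 50,
                                seed = 1)
  expect_equal(tt$observed, 1L)
  expect_true(all(tt$null_counts == 1L))
  expect_equal(tt$p_value, 1)
})

test_that("permutation p-value matches exact enumeration on 4-tip trees", {
  p <- congruent_pair(4, seed = 31)
  # exact null: reconcile under all 24 bijections
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4L), ]
  obs <- reconcile(p$vtree, p$htree, p$assoc)$n_cospeciations
  null_exact <- apply(perms, 1, function(pr) {
    a <- tip_association(paste0("V", 1:4), paste0("H", pr))
    reconcile(p$vtree, p$htree, a)$n_cospeciations
  })
  p_exact <- mean(null_exact >= obs)
  tt <- random_tip_mapping_test(p$vtree, p$htree, p$assoc, n_perm = 400,
                                seed = 7)
  se <- sqrt(p_exact * (1 - p_exact) / 400)
  expect_lt(abs(tt$p_value - p_exact), 3 * se + 1 / 400)
})

test_that("permutation test is seed-reproducible and supports observed overrides", {
  p <- congruent_pair(6, seed = 41)
  t1 <- random_tip_mapping_test(p$vtree, p$htree, p$assoc, n_perm = 100,
                                seed = 3)
  t2 <- random_tip_mapping_test(p$vtree, p$htree, p$assoc, n_perm = 100,
                                seed = 3)
  expect_identical(t1$null_counts, t2$null_counts)
  # a conservative observed count can only enlarge p
  t3 <- random_tip_mapping_test(p$vtree, p$htree, p$assoc, n_perm = 100,
                                seed = 3, observed = t1$observed - 1L)
  expect_gte(t3$p_value, t1$p_value)
})
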