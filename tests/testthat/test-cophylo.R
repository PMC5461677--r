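test_that("Newick I/O round-trips and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_equal(ape::Ntip(tr), 3L)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_equal(tr2$tip.label, tr$tip.label)
  expect_equal(tr2$edge, tr$edge)
  expect_equal(tr2$edge.length, tr$edge.length)

  writeLines("((A:1,A:1):1,C:2);", f)
  expect_error(read_newick(f), "duplicate")
  writeLines("this is not newick", f)
  expect_error(suppressWarnings(read_newick(f)), "")
})

test_that("patristic distances are path sums, matching the graph oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D <- patristic_distances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  star <- ape::read.tree(text = "(A:1.5,B:1.5,C:1.5,D:1.5);")
  expect_true(all(patristic_distances(star)[upper.tri(diag(4))] == 3))
  for (seed in 1:3) {
    tr <- simulate_host_tree(10, 1, seed = seed)
    D <- patristic_distances(tr)
    O <- oracle_patristic(tr)
    expect_equal(D, O[rownames(D), colnames(D)], tolerance = 1e-9)
    expect_equal(unname(diag(D)), rep(0, 10))
  }
})

test_that("ParaFit statistic matches PCoA oracle and relabeling invariance", {
  h <- simulate_host_tree(6, 1, seed = 11)
  p <- simulate_host_tree(6, 1, seed = 12, tip_prefix = "P")
  Dh <- patristic_distances(h); Dp <- patristic_distances(p)
  set.seed(13)
  A <- association_matrix(paste0("P", 1:6), paste0("H", sample(6)))
  res <- parafit_test(Dh, Dp, A, n_perm = 199, seed = 5)
  expect_equal(res$statistic, oracle_parafit_stat(Dh, Dp, A), tolerance = 1e-8)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)

  # simultaneous relabeling of hosts leaves the statistic unchanged
  perm <- c(3, 1, 2, 6, 5, 4)
  Dh2 <- Dh[perm, perm]
  A2 <- A[, perm]
  res2 <- parafit_test(Dh2, Dp, A2, n_perm = 199, seed = 5)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-8)

  # identical seed and inputs give identical p-values
  expect_equal(parafit_test(Dh, Dp, A, 199, seed = 5)$p_value, res$p_value)
  expect_error(parafit_test(Dh, Dp, A[, 1:3] * 0, 199, 1), "no link")
  expect_error(parafit_test(Dh, Dp, A, 50, 1), "n_perm")
})

test_that("Hommola statistic equals the direct pair-correlation oracle", {
  h <- ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:0.5):2);")
  p <- ape::read.tree(text = "((pA:2,pB:1):1,(pC:1,pD:2):1);")
  Dh <- patristic_distances(h); Dp <- patristic_distances(p)
  links <- data.frame(parasite = c("pA", "pB", "pC", "pD"),
                      host = c("A", "B", "C", "D"))
  res <- hommola_test(Dh, Dp, links, n_perm = 199, seed = 3)
  expect_equal(res$statistic, oracle_hommola_stat(Dh, Dp, links), tolerance = 1e-12)

  # identical trees with 1:1 links give r = 1
  m <- mirror_parasite(h)
  resm <- hommola_test(Dh, patristic_distances(m),
                       expand_links(mirror_links(h)), n_perm = 199, seed = 3)
  expect_equal(resm$statistic, 1)

  # zero-variance distances are flagged, not an error
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  stp <- ape::read.tree(text = "(pA:1,pB:1,pC:1);")
  dg <- hommola_test(patristic_distances(star), patristic_distances(stp),
                     data.frame(parasite = c("pA", "pB", "pC"),
                                host = c("A", "B", "C")), 199, 1)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$statistic))
  expect_error(hommola_test(Dh, Dp, links[1:2, ], 199, 1), "3 links")
})

test_that("null p-values are uniform (Hommola) / tail-calibrated (ParaFit)", {
  # Scaled-down null calibration: 6-tip trees, 199 permutations, 400 sims.
  # Hommola's label-permutation null is exchangeable with the bijective
  # observed links, so its p-values are exactly uniform (KS test).
  # ParaFit's published null permutes each parasite's hosts independently,
  # which matches a one-to-one observed matrix only in the rejection tail;
  # the bulk is non-uniform by construction (see the methods vignette), so
  # the assertion is binomial-tolerance tail calibration, not KS.
  pvals_pf <- pvals_hm <- numeric(400)
  for (i in 1:400) {
    h <- simulate_host_tree(6, 1, seed = 3000 + i)
    p <- simulate_host_tree(6, 1, seed = 4000 + i, tip_prefix = "P")
    set.seed(5000 + i)
    A <- association_matrix(paste0("P", 1:6), paste0("H", sample(6)))
    Dh <- patristic_distances(h); Dp <- patristic_distances(p)
    pvals_pf[i] <- parafit_test(Dh, Dp, A, 199, seed = 6000 + i)$p_value
    pvals_hm[i] <- hommola_test(Dh, Dp, expand_links(A), 199,
                                seed = 7000 + i)$p_value
  }
  expect_gt(suppressWarnings(stats::ks.test(pvals_hm, "punif"))$p.value, 0.01)
  tail_pf <- mean(pvals_pf <= 0.05)   # 3 binomial SDs around 0.05 for n = 400
  expect_gte(tail_pf, 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
  expect_lte(tail_pf, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("reconciliation of mirror trees yields n-1 codivergences only", {
  for (n in c(4, 5, 8)) {
    h <- simulate_host_tree(n, 1, seed = n)
    res <- enumerate_reconciliations(h, mirror_parasite(h), mirror_links(h))
    expect_equal(res$counts$codivergence, n - 1L)
    expect_equal(res$counts$duplication, 0L)
    expect_equal(res$counts$loss, 0L)
    expect_equal(res$counts$host_switch, 0L)
    expect_equal(res$n_optimal, 1L)
  }
})

test_that("reconciliation agrees with the independent exhaustive oracle", {
  # the canonical one-switch case
  h <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  p <- ape::read.tree(text = "((pA:1,pC:1):1,pB:2);")
  A <- association_matrix(c("pA", "pB", "pC"), c("A", "B", "C"))
  got <- enumerate_reconciliations(h, p, A)
  want <- oracle_reconcile(h, p, A)
  expect_equal(got$counts, want$counts, ignore_attr = TRUE)
  expect_equal(got$n_optimal, want$n_optimal)

  # random mismatched 5-tip pairs
  for (seed in 1:4) {
    h <- simulate_host_tree(5, 1, seed = 20 + seed)
    p <- simulate_host_tree(5, 1, seed = 40 + seed, tip_prefix = "p")
    set.seed(60 + seed)
    A <- association_matrix(paste0("p", 1:5), paste0("H", sample(5)))
    got <- enumerate_reconciliations(h, p, A)
    want <- oracle_reconcile(h, p, A)
    expect_equal(got$counts, want$counts, ignore_attr = TRUE)
    expect_equal(got$n_optimal, want$n_optimal)
    expect_lte(got$counts$codivergence, 4L)
  }
  big <- simulate_host_tree(9, 1, seed = 1)
  expect_error(enumerate_reconciliations(big, mirror_parasite(big),
                                         mirror_links(big)), "size error")
})

test_that("polytomies are refused by default and resolvable on request", {
  h <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  poly <- ape::read.tree(text = "(pA:1,pB:1,pC:1);")
  A <- association_matrix(c("pA", "pB", "pC"), c("A", "B", "C"))
  expect_error(enumerate_reconciliations(h, poly, A), "not fully resolved")
  res <- enumerate_reconciliations(h, poly, A, polytomy = "resolve")
  expect_s3_class(res, "reconciliation_result")
})
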