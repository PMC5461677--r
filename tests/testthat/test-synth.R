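test_that("Yule simulator meets its structural contract and is reproducible", {
  tr <- simulate_host_tree(3, 1, seed = 1)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 2L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_identical(ape::write.tree(simulate_host_tree(7, 2, seed = 9)),
                   ape::write.tree(simulate_host_tree(7, 2, seed = 9)))
  expect_error(simulate_host_tree(2), ">= 3")
})

test_that("mean Yule depth matches the closed-form expectation", {
  n <- 6; lambda <- 1
  depths <- vapply(1:1000, function(i) {
    tr <- simulate_host_tree(n, lambda, seed = 100000 + i)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expectation <- sum(1 / ((2:n) * lambda))
  se <- sqrt(sum(1 / ((2:n) * lambda)^2) / 1000)
  expect_lt(abs(mean(depths) - expectation), 3 * se)
})

test_that("pure codivergence reproduces the host topology; total loss empties", {
  for (seed in 1:5) {
    h <- simulate_host_tree(7, 1, seed = seed)
    sim <- simulate_parasite_evolution(h, p_switch = 0, p_loss = 0, seed = seed)
    expect_false(sim$empty)
    expect_equal(sim$true_events[["codivergence"]], 6L)
    expect_equal(sim$true_events[["host_switch"]], 0L)
    rec <- enumerate_reconciliations(h, sim$parasite, sim$A)
    expect_equal(rec$counts$codivergence, 6L)
    expect_equal(rec$counts$duplication + rec$counts$loss +
                   rec$counts$host_switch, 0L)
  }
  lost <- simulate_parasite_evolution(simulate_host_tree(5, 1, seed = 2),
                                      p_switch = 0, p_loss = 1, seed = 3)
  expect_true(lost$empty)
  expect_error(simulate_parasite_evolution(simulate_host_tree(5, 1, seed = 2),
                                           0.7, 0.7), "<= 1")
})

test_that("realised switch counts match the binomial expectation", {
  # with p_loss = 0 every non-root divergence has at least one external
  # contemporary branch, so switches are Bernoulli(p_switch) there
  total_sw <- 0; total_m <- 0
  for (i in 1:300) {
    h <- simulate_host_tree(6, 1, seed = 200000 + i)
    sim <- simulate_parasite_evolution(h, p_switch = 0.5, p_loss = 0,
                                       seed = 300000 + i)
    ev <- sim$true_events
    decisions <- sum(ev[c("codivergence", "loss", "host_switch")])
    total_sw <- total_sw + ev[["host_switch"]]
    total_m <- total_m + (decisions - 1L)      # root cannot switch
  }
  se <- sqrt(total_m * 0.25)
  expect_lt(abs(total_sw - 0.5 * total_m), 3 * se)
})

test_that("JC69 evolution is exact in expectation and deterministic", {
  two <- ape::read.tree(text = "(A:0.15,B:0.15);")
  expect_equal(evolve_sequences(two, 100, subst_rate = 0, seed = 1)$records$seq[1],
               evolve_sequences(two, 100, subst_rate = 0, seed = 1)$records$seq[2])
  s1 <- evolve_sequences(two, 100, 1, seed = 4)
  s2 <- evolve_sequences(two, 100, 1, seed = 4)
  expect_identical(s1$records$seq, s2$records$seq)

  # mean p-distance over replicates vs the closed form 75(1 - exp(-4t/3))
  t_tot <- 0.3; len <- 100; reps <- 1000
  pd <- vapply(seq_len(reps), function(i) {
    s <- evolve_sequences(two, len, 1, seed = 400000 + i)
    p_distance(s$records$seq[1], s$records$seq[2])
  }, numeric(1))
  expectation <- 75 * (1 - exp(-4 * t_tot / 3))
  p <- expectation / 100
  se <- 100 * sqrt(p * (1 - p) / (len * reps))
  expect_lt(abs(mean(pd) - expectation), 3 * se)
  expect_error(evolve_sequences(two, 10, 1, 1), ">= 50")
})

test_that("divergent-population sets separate cleanly at the 5% threshold", {
  ok <- 0L
  for (i in 1:20) {
    s <- simulate_divergent_populations(n_species = 3, pops_per_species = 2,
                                        seqs_per_pop = 2, length = 344,
                                        seed = 500000 + i)
    D <- divergence_matrix(s, "host_population", "max")
    part <- single_linkage_partition(D, 5)
    truth <- lapply(sort(unique(s$records$morphospecies)), function(sp)
      sort(unique(s$records$host_population[s$records$morphospecies == sp])))
    ok <- ok + identical(part$clusters, truth)
  }
  expect_gte(ok, 19L)
})

test_that("simulated mummy tables mirror the detection-success contrast", {
  tab <- simulate_mummy_table(n_per_stratum = 200,
                              detect_prob = c(psyllid = 0.9, P1 = 0.2, P2 = 0.9,
                                              H = 0.9, HH = 0.9),
                              seed = 77)
  det <- detection_success(tab)
  p1 <- det$detection_success[det$emerged_species == "P1"]
  others <- det$detection_success[det$emerged_species != "P1"]
  expect_true(all(p1 >= 10 & p1 <= 35))
  expect_true(all(others >= 60))

  # noiseless world: everything informative, roles recovered exactly
  clean <- simulate_mummy_table(n_per_stratum = 5, detect_prob = c(psyllid = 1),
                                seed = 1)
  expect_true(all(flag_informative(clean)$is_informative))
  roles <- summarize_roles(classify_trophic_roles(clean))
  want <- role_map()
  expect_equal(roles$role[match(want$morphospecies, roles$morphospecies)],
               want$role)
})

test_that("simulated systems are internally consistent and reproducible", {
  sys <- simulate_system(n_hosts = 7, seed = 5)
  expect_false(sys$empty)
  validate_phylogeny(sys$host)
  validate_phylogeny(sys$parasite)
  expect_setequal(colnames(sys$A), sys$host$tip.label)
  expect_setequal(rownames(sys$A), sys$parasite$tip.label)
  expect_true(all(rowSums(sys$A) >= 1))
  expect_equal(sys$host_seqs$records$id, sys$host$tip.label)
  expect_equal(sys$parasite_seqs$records$id, sys$parasite$tip.label)
  expect_s3_class(sys$mummies, "mummy_table")
  # distance matrices and tests accept the simulated system end to end
  res <- hommola_test(patristic_distances(sys$host),
                      patristic_distances(sys$parasite),
                      expand_links(sys$A), 99, seed = 1)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  sys2 <- simulate_system(n_hosts = 7, seed = 5)
  expect_identical(ape::write.tree(sys$parasite), ape::write.tree(sys2$parasite))
  expect_identical(sys$host_seqs$records$seq, sys2$host_seqs$records$seq)
})
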