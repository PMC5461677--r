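test_that("mummy tables load with schema validation and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mummy_id,host_species,emerged_species,emerged_sex,psyllid_dna,det_P1,det_P2",
               "m1,h,P1,female,yes,1,0",
               "m2,h,P2,male,no,0,1",
               "m3,h,P1,female,1,0,0"), f)
  tab <- load_mummy_table(f)
  expect_s3_class(tab, "mummy_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "targets"), c("P1", "P2"))
  expect_type(tab$psyllid_dna, "logical")

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_mummy_table(tab, f2)
  expect_equal(as.data.frame(load_mummy_table(f2)), as.data.frame(tab))

  writeLines(c("mummy_id,host_species,emerged_species,emerged_sex,det_P1",
               "m1,h,P1,female,1"), f)
  expect_error(load_mummy_table(f), "schema error.*psyllid_dna")
  writeLines(c("mummy_id,host_species,emerged_species,emerged_sex,psyllid_dna,det_P1",
               "m1,h,P1,female,1,1", "m1,h,P1,female,1,1"), f)
  expect_error(load_mummy_table(f), "duplicate")
})

test_that("informative flagging partitions exhaustively and disjointly", {
  tab <- toy_mummy_table(list(
    mummy_row(sp = "P1", psyllid = TRUE, det = "P1"),
    mummy_row(sp = "P1", psyllid = TRUE, det = character(0)),
    mummy_row(sp = "P1", psyllid = FALSE, det = "P1")))
  fl <- flag_informative(tab)
  expect_equal(fl$is_informative, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(fl$informative) + nrow(fl$uninformative), nrow(tab))
  expect_length(intersect(fl$informative$mummy_id, fl$uninformative$mummy_id), 0L)
})

test_that("detection success reproduces the published percentages", {
  det <- detection_success(expand_mummy_screen())
  pick <- function(h, sp, sx) det$detection_success[
    det$host_species == h & det$emerged_species == sp & det$emerged_sex == sx]
  expect_equal(pick("albitextura", "H", "female"), 80)   # 20/25
  expect_equal(pick("albitextura", "H", "male"), 88)     # 15/17
  expect_equal(pick("albitextura", "P1", "female"), 33)  # 20/60
  expect_equal(pick("GB", "P1", "female"), 11)           # 20/182
  expect_equal(pick("maniformis", "P1", "female"), 17)   # 2/12
  expect_equal(pick("tenuitela", "H", "male"), 67)       # 4/6
  expect_equal(pick("tenuitela", "HH", "female"), 63)    # 5/8 rounds half-up
  expect_equal(pick("tenuitela", "H", "female"), 100)    # 14/0
  # conservation: informative + uninformative = stratum size
  expect_equal(sum(det$informative) + sum(det$uninformative),
               nrow(expand_mummy_screen()))
})

test_that("trophic classification recovers the canonical detection patterns", {
  tab <- toy_mummy_table(c(
    lapply(1:5, function(i) mummy_row(sp = "P2", det = "P2")),
    lapply(1:5, function(i) mummy_row(sp = "H", det = c("H", "P2"))),
    lapply(1:5, function(i) mummy_row(sp = "HH", sex = "female", det = "HH")),
    lapply(1:5, function(i) mummy_row(sp = "HH", sex = "male", det = c("HH", "P1")))))
  asg <- classify_trophic_roles(tab)
  role_of <- function(sp) asg$role[asg$morphospecies == sp]
  expect_equal(role_of("P2"), "primary")
  expect_equal(role_of("H"), "hyperparasitoid")
  expect_equal(asg$prey_female[asg$morphospecies == "H"], "P2")
  expect_equal(role_of("HH"), "heteronomous_hyperparasitoid")
  expect_equal(asg$prey_female[asg$morphospecies == "HH"], "psyllid")
  expect_equal(asg$prey_male[asg$morphospecies == "HH"], "P1")

  # below min_n, and with contradictory patterns, the call is undetermined
  small <- toy_mummy_table(list(mummy_row(sp = "P1", det = "P1")))
  expect_equal(classify_trophic_roles(small)$role, "undetermined")
  mixed <- toy_mummy_table(c(
    lapply(1:3, function(i) mummy_row(sp = "P1", det = "P1")),
    lapply(1:3, function(i) mummy_row(sp = "P1", det = c("P1", "H")))))
  expect_equal(classify_trophic_roles(mixed)$role, "undetermined")
  expect_error(classify_trophic_roles(small, consistency = 0.4), "consistency")
})

test_that("the full published screen classifies every morphospecies correctly", {
  asg <- classify_trophic_roles(expand_mummy_screen())
  roles <- summarize_roles(asg)
  expect_equal(roles$role[roles$morphospecies == "P1"], "primary")
  expect_equal(roles$role[roles$morphospecies == "P2"], "primary")
  expect_equal(roles$role[roles$morphospecies == "H"], "hyperparasitoid")
  expect_equal(roles$prey_female[roles$morphospecies == "H"], "P2")
  expect_equal(roles$role[roles$morphospecies == "HH"],
               "heteronomous_hyperparasitoid")
  expect_equal(roles$prey_male[roles$morphospecies == "HH"], "P1")
  # hyperparasitoid prey are primaries wherever data exist
  expect_equal(nrow(validate_assignments(asg)), 0L)
})

test_that("co-occurrence counts are exact", {
  tab <- expand_mummy_screen()
  expect_equal(cooccurrence_check(tab, c("P1", "P2")), 0L)
  both <- toy_mummy_table(list(mummy_row(sp = "P1", det = c("P1", "P2"))))
  expect_equal(cooccurrence_check(both, c("P1", "P2")), 1L)
  # equals a brute-force row scan on an arbitrary table
  expect_equal(cooccurrence_check(tab, c("H", "P2")),
               sum(tab$det_H & tab$det_P2))
  expect_error(cooccurrence_check(tab, c("P1", "XX")), "panel targets")
})

test_that("roles are recovered from simulated tables under good detection", {
  ok <- 0L
  for (rep in 1:30) {
    tab <- simulate_mummy_table(n_per_stratum = 10,
                                detect_prob = c(psyllid = 1, P1 = 0.9, P2 = 0.9,
                                                H = 0.9, HH = 0.9),
                                seed = 100 + rep)
    roles <- summarize_roles(classify_trophic_roles(tab))
    want <- role_map()
    got <- roles[match(want$morphospecies, roles$morphospecies), ]
    ok <- ok + all(got$role == want$role)
  }
  expect_gte(ok, 29L)
})
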