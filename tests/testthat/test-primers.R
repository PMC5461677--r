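test_that("diagnostic sites are fixed differences, matching the column oracle", {
  tg <- aligned_seq_set(c("t1", "t2"), c("AAAAAAAAAA", "AAAAAAAAAA"))
  ot <- aligned_seq_set(c("o1", "o2"), c("AAAAAAGAAA", "AAAAAAGAAA"))
  expect_equal(find_diagnostic_sites(tg, ot), 7L)

  # a polymorphic target column is never diagnostic
  tg2 <- aligned_seq_set(c("t1", "t2"), c("AAAAAAAAAA", "AAAAAAGAAA"))
  expect_equal(find_diagnostic_sites(tg2, ot), integer(0))

  # random alignments against the per-column scan oracle
  for (seed in 1:5) {
    seqs <- random_seqs(9, 200, seed)
    tset <- aligned_seq_set(paste0("t", 1:3), seqs[1:3])
    oset <- aligned_seq_set(paste0("o", 1:6), seqs[4:9])
    expect_equal(find_diagnostic_sites(tset, oset),
                 oracle_diagnostic_sites(seqs[1:3], seqs[4:9]))
  }
  expect_error(find_diagnostic_sites(tg, aligned_seq_set("x", "AAAA")),
               "differ in length")
})

test_that("Wallace-rule Tm is exact", {
  expect_equal(melting_temperature("GCGCGCGCGCATATATATAT"), 60)
  expect_equal(melting_temperature("AAAAAAAAAA"), 20)
  expect_equal(melting_temperature("GGGGCCCC"), 32)
  expect_error(melting_temperature("GGGGCCN"), "shorter")
  expect_error(melting_temperature("GGGGCCNN"), "ambiguous")
})

test_that("designed pairs satisfy every constraint per the independent checker", {
  aln <- make_primer_alignment(seed = 1)
  for (tg in paste0("S", 1:4)) {
    pair <- design_species_primer(tg, aln)
    expect_s3_class(pair, "primer_pair")
    tset <- subset_seqs(aln, aln$records$morphospecies == tg)
    oset <- subset_seqs(aln, aln$records$morphospecies != tg)
    expect_equal(check_primer_pair(pair, tset, oset), character(0))
    expect_true(all(pair$diagnostic_sites_3prime >= 2))
    expect_equal(pair$amplicon_length, pair$rev_end - pair$fwd_start)
  }
})

test_that("impossible designs yield a no-solution report, not a bogus pair", {
  # target identical to non-targets everywhere: no diagnostic sites
  s <- random_seqs(1, 200, seed = 3)
  aln <- aligned_seq_set(c("t", "o"), c(s, s), morphospecies = c("T", "O"))
  res <- design_species_primer("T", aln)
  expect_s3_class(res, "no_solution")
  expect_match(res$reason, "no diagnostic sites")

  # diagnostic sites confined to a 50-bp window: amplicon >= 145 impossible
  set.seed(4)
  v <- strsplit(random_seqs(1, 200, seed = 4), "")[[1]]
  t <- v
  for (pos in c(100:104, 140:144)) t[pos] <- setdiff(c("A", "C", "G", "T"), v[pos])[1]
  aln2 <- aligned_seq_set(c("t", "o"), c(paste(t, collapse = ""),
                                         paste(v, collapse = "")),
                          morphospecies = c("T", "O"))
  expect_s3_class(design_species_primer("T", aln2), "no_solution")

  # alignment shorter than the minimum amplicon is an input error
  short <- aligned_seq_set(c("t", "o"), c("ACGTACGTAC", "ACGTACGTAA"),
                           morphospecies = c("T", "O"))
  expect_error(design_species_primer("T", short), "shorter than minimum amplicon")
})

fake_pair <- function(len, tm = 60) {
  len <- as.integer(len)
  structure(list(target = paste0("L", len), forward = "A", reverse = "A",
                 fwd_start = 0L, rev_end = len, amplicon_length = len,
                 tm_forward = tm, tm_reverse = tm,
                 diagnostic_sites_3prime = c(forward = 2L, reverse = 2L)),
            class = "primer_pair")
}

test_that("multiplex assembly is minimal (vs the set-partition oracle)", {
  one <- assemble_multiplex(lapply(c(150, 220, 300, 380), fake_pair),
                            length_separation = 30)
  expect_length(one, 1L)

  two <- assemble_multiplex(lapply(c(150, 160), fake_pair), length_separation = 30)
  expect_length(two, 2L)

  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(2:6, 1)
    lens <- sample(145:400, k)
    tms <- lapply(sample(c(54, 56, 58, 60), k, replace = TRUE), function(t) c(t, t))
    pairs <- mapply(function(l, t) fake_pair(l, t[1]), lens, tms,
                    SIMPLIFY = FALSE)
    got <- length(assemble_multiplex(pairs, length_separation = 30, tm_window = 4))
    want <- oracle_min_stages(lens, tms, sep = 30, window = 4)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("in-silico PCR detects targets, rejects 3'-mismatched templates, and
          matches the sliding-window oracle", {
  aln <- make_primer_alignment(seed = 2)
  pairs <- lapply(paste0("S", 1:4), function(tg) design_species_primer(tg, aln))
  panel <- assemble_multiplex(pairs)

  # each target template yields exactly its own designed product
  for (k in 1:4) {
    tpl <- subset_seqs(aln, aln$records$id == sprintf("S%d_1", k))
    det <- in_silico_pcr(panel, tpl)
    expect_equal(nrow(det), 1L)
    expect_equal(det$target, paste0("S", k))
    expect_equal(det$amplicon_length, pairs[[k]]$amplicon_length)
  }

  # full mixture: one detection per present target, none spurious, and the
  # product set per template equals the exhaustive scan oracle
  tmpl <- subset_seqs(aln, !duplicated(aln$records$morphospecies))
  det <- in_silico_pcr(panel, tmpl)
  expect_equal(nrow(det), 4L)
  expect_equal(sub("_1$", "", det$template), det$target)
  for (k in 1:4) {
    for (j in 1:4) {
      prods <- oracle_pcr_detections(pairs[[k]]$forward, pairs[[k]]$reverse,
                                     tmpl$records$seq[j])
      got <- det$amplicon_length[det$target == paste0("S", k) &
                                   det$template == tmpl$records$id[j]]
      expect_equal(sort(got), prods)
    }
  }
})
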