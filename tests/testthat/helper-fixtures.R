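# Shared in-code fixtures.

# alignment of n_species engineered morphospecies, each carrying two private
# 5-bp diagnostic blocks spaced so that species-specific primers with
# distinct amplicon lengths exist
make_primer_alignment <- function(n_species = 4L, len = 420L, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  base <- sample(bases, len, replace = TRUE)
  ids <- character(0); sp <- character(0); seqs <- character(0)
  for (k in seq_len(n_species)) {
    fk <- 30L + 12L * k
    rk <- fk + 150L + 30L * k
    s <- base
    for (pos in c(fk:(fk + 4L), rk:(rk + 4L))) {
      s[pos] <- sample(setdiff(bases, base[pos]), 1L)
    }
    str <- paste(s, collapse = "")
    for (cpy in 1:2) {
      ids <- c(ids, sprintf("S%d_%d", k, cpy))
      sp <- c(sp, paste0("S", k))
      seqs <- c(seqs, str)
    }
  }
  aligned_seq_set(ids, seqs, locus = "cytb", morphospecies = sp)
}

# small mummy table built row by row
toy_mummy_table <- function(rows) {
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  tab$mummy_id <- sprintf("M%03d", seq_len(nrow(tab)))
  psyllidwebs:::as_mummy_table(tab)
}

mummy_row <- function(host = "h1", sp, sex = "female", psyllid = TRUE,
                      det = character(0), targets = c("P1", "P2", "H", "HH")) {
  flags <- as.list(stats::setNames(targets %in% det, paste0("det_", targets)))
  c(list(mummy_id = NA_character_, host_species = host, emerged_species = sp,
         emerged_sex = sex, psyllid_dna = psyllid), flags)
}

# mirror parasite tree: same topology/lengths as the host, P-prefixed tips
mirror_parasite <- function(host) {
  p <- host
  p$tip.label <- paste0("p", host$tip.label)
  p
}

mirror_links <- function(host) {
  association_matrix(paste0("p", host$tip.label), host$tip.label)
}
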