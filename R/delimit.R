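#' Putative species delimitation by single-linkage divergence clustering
#'
#' Clusters population/genotype labels into putative species: two labels are
#' chained into the same species whenever their divergence is at or below
#' `threshold`. Clusters are the connected components of the graph with an
#' edge wherever `D[g, h] <= threshold`; `NA` entries (unsampled
#' comparisons) contribute no edge. The default 5% cytb threshold sits in
#' the empirical gap between conspecific (<= ~4.7%) and heterospecific
#' (>= ~8.4%) population divergences in this system.
#'
#' @param D a `divergence_matrix` (see [divergence_matrix()]); `NA` entries
#'   allowed.
#' @param threshold percent divergence at or below which two labels are
#'   linked (default 5).
#' @param morphospecies optional label attached to the partition.
#' @return a `species_partition`: list with `morphospecies`, `threshold` and
#'   `clusters` (list of character vectors, sorted by smallest member label,
#'   members sorted within each cluster).
#' @export
single_linkage_partition <- function(D, threshold = 5, morphospecies = NA_character_) {
  validate_divergence_matrix(D)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  labels <- rownames(D)
  n <- length(labels)
  # union-find over labels
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && !is.na(D[i, j]) && D[i, j] <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  clusters <- unname(split(labels, roots))
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, `[`, character(1L), 1L))]
  structure(list(morphospecies = morphospecies, threshold = threshold,
                 clusters = clusters),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat("species_partition", if (!is.na(x$morphospecies)) paste0("(", x$morphospecies, ")"),
      ":", length(x$clusters), "putative species at", x$threshold, "% threshold\n")
  for (i in seq_along(x$clusters)) {
    cat("  ", i, ": ", paste(x$clusters[[i]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Count putative species per morphospecies
#'
#' Summarises a list of per-morphospecies partitions (computed at a common
#' threshold) into species counts, and reports the ratio of the summed
#' species count to the number of morphospecies for a focal genus subset
#' (genetic diversity inflation relative to morphology).
#'
#' @param partitions named list of `species_partition` objects (names =
#'   morphospecies).
#' @param focal character vector of morphospecies to include in the ratio
#'   (default: all).
#' @return list with `counts` (named integer vector), `total` (sum over
#'   `focal`) and `ratio` (`total` / number of focal morphospecies).
#' @export
count_putative_species <- function(partitions, focal = names(partitions)) {
  stopifnot(length(partitions) >= 1L, !is.null(names(partitions)))
  thr <- unique(vapply(partitions, function(p) p$threshold, numeric(1L)))
  if (length(thr) != 1L) {
    stop("partitions were not computed at a common threshold", call. = FALSE)
  }
  counts <- vapply(partitions, function(p) length(p$clusters), integer(1L))
  focal <- intersect(focal, names(counts))
  total <- sum(counts[focal])
  list(counts = counts, total = total, ratio = total / length(focal),
       threshold = thr)
}

#' Group sex-separated morphotypes into morphospecies by genotype matching
#'
#' Female and male morphotypes are merged into one morphospecies when the
#' minimum cross-sex p-distance between their sequences is at or below
#' `max_divergence` (sequencing-noise allowance around "identical
#' genotype"). Morphotypes without a match become single-sex morphospecies;
#' morphotypes without sequence data are reported as unassignable.
#'
#' @param morphotypes data.frame with columns `morphotype`, `sex`
#'   (`"female"`/`"male"`) and `count` (non-negative integer).
#' @param seqs an [aligned_seq_set()] whose `morphospecies` metadata column
#'   carries the morphotype label of each sequence.
#' @param max_divergence percent divergence at or below which a female and a
#'   male morphotype are deemed conspecific (default 2).
#' @return list with `groups` (data.frame: `morphospecies`, `female_morphotype`,
#'   `male_morphotype`, `sexes`) and `unassignable` (character vector).
#' @export
match_morphotypes <- function(morphotypes, seqs, max_divergence = 2) {
  stopifnot(is.data.frame(morphotypes),
            all(c("morphotype", "sex") %in% names(morphotypes)))
  if (!all(morphotypes$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  P <- pairwise_p_matrix(seqs)
  tag <- seqs$records$morphospecies
  have_seq <- morphotypes$morphotype %in% tag
  unassignable <- morphotypes$morphotype[!have_seq]
  mt <- morphotypes[have_seq, , drop = FALSE]
  females <- mt$morphotype[mt$sex == "female"]
  males <- mt$morphotype[mt$sex == "male"]

  min_cross <- function(a, b) {
    ia <- which(tag == a); ib <- which(tag == b)
    min(P[ia, ib, drop = FALSE])
  }
  # greedy nearest-genotype pairing: repeatedly merge the globally closest
  # female/male pair within the allowance
  pairs <- expand.grid(female = females, male = males,
                       stringsAsFactors = FALSE)
  if (nrow(pairs) > 0L) {
    pairs$d <- mapply(min_cross, pairs$female, pairs$male)
    pairs <- pairs[pairs$d <= max_divergence, , drop = FALSE]
    pairs <- pairs[order(pairs$d, pairs$female, pairs$male), , drop = FALSE]
  }
  matched_f <- character(0); matched_m <- character(0)
  groups <- list()
  for (k in seq_len(nrow(pairs))) {
    f <- pairs$female[k]; m <- pairs$male[k]
    if (f %in% matched_f || m %in% matched_m) next
    matched_f <- c(matched_f, f); matched_m <- c(matched_m, m)
    groups[[length(groups) + 1L]] <- data.frame(
      morphospecies = f, female_morphotype = f, male_morphotype = m,
      sexes = "both", stringsAsFactors = FALSE)
  }
  for (f in setdiff(females, matched_f)) {
    groups[[length(groups) + 1L]] <- data.frame(
      morphospecies = f, female_morphotype = f, male_morphotype = NA_character_,
      sexes = "female-only", stringsAsFactors = FALSE)
  }
  for (m in setdiff(males, matched_m)) {
    groups[[length(groups) + 1L]] <- data.frame(
      morphospecies = m, female_morphotype = NA_character_, male_morphotype = m,
      sexes = "male-only", stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, groups)
  g <- g[order(g$morphospecies), , drop = FALSE]
  rownames(g) <- NULL
  list(groups = g, unassignable = unassignable)
}

#' Flag candidate thelytokous (all-female) morphospecies
#'
#' A morphospecies is a thelytoky candidate when no males were collected
#' despite a female sample large enough to make their absence informative.
#'
#' @param counts data.frame with columns `morphospecies`, `females`, `males`
#'   (specimen counts).
#' @param min_females minimum female count required to call absence of males
#'   informative (default 5).
#' @return the input with an added `reproduction` column:
#'   `"thelytokous-candidate"`, `"sexual"` or `"undetermined"`.
#' @export
infer_thelytoky <- function(counts, min_females = 5) {
  stopifnot(all(c("morphospecies", "females", "males") %in% names(counts)))
  flag <- ifelse(counts$males > 0, "sexual",
                 ifelse(counts$females >= min_females,
                        "thelytokous-candidate", "undetermined"))
  counts$reproduction <- flag
  counts
}
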