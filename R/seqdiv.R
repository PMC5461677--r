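#' Aligned sequence sets
#'
#' An `aligned_seq_set` holds aligned nucleotide sequences for one locus,
#' together with the specimen metadata used throughout the package:
#' morphospecies (e.g. P1, P2, H, HH), host population and genotype (GT)
#' number. All sequences in a set must have the same alignment length;
#' residues are restricted to `A`, `C`, `G`, `T`, `-` (gap) and `N`.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of aligned sequences (same length as `ids`).
#' @param locus single label for the locus (e.g. `"cytb"`, `"28S"`, `"COI"`).
#' @param morphospecies,host_population optional character metadata vectors,
#'   recycled to length 1 defaults (`NA`) when absent.
#' @param genotype optional integer genotype (GT) numbers.
#'
#' @return An object of class `aligned_seq_set`: a list with elements
#'   `locus` and `records` (a data.frame with columns `id`, `morphospecies`,
#'   `host_population`, `genotype`, `seq`).
#' @export
aligned_seq_set <- function(ids, seqs, locus = "cytb",
                            morphospecies = NA_character_,
                            host_population = NA_character_,
                            genotype = NA_integer_) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) == 0L) stop("empty sequence set", call. = FALSE)
  if (length(seqs) != length(ids)) stop("ids and seqs differ in length", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  if (any(!nzchar(seqs))) stop("empty sequence", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  }
  if (any(grepl("[^ACGTN-]", seqs))) {
    stop("illegal characters in sequences (allowed: A,C,G,T,N,-)", call. = FALSE)
  }
  records <- data.frame(
    id = ids,
    morphospecies = rep_len(as.character(morphospecies), length(ids)),
    host_population = rep_len(as.character(host_population), length(ids)),
    genotype = rep_len(as.integer(genotype), length(ids)),
    seq = seqs,
    stringsAsFactors = FALSE
  )
  structure(list(locus = as.character(locus)[1L], records = records),
            class = "aligned_seq_set")
}

#' @export
print.aligned_seq_set <- function(x, ...) {
  cat("aligned_seq_set:", nrow(x$records), "sequences, locus", x$locus,
      ", alignment length", nchar(x$records$seq[1L]), "bp\n")
  invisible(x)
}

#' @export
length.aligned_seq_set <- function(x) nrow(x$records)

#' Alignment length of a sequence set
#' @param x an `aligned_seq_set`.
#' @return integer alignment length in bp.
#' @export
alignment_length <- function(x) {
  stopifnot(inherits(x, "aligned_seq_set"))
  nchar(x$records$seq[1L])
}

#' Subset an aligned sequence set by record index or predicate
#' @param x an `aligned_seq_set`.
#' @param i logical or integer index into the records.
#' @return an `aligned_seq_set` with the selected records.
#' @export
subset_seqs <- function(x, i) {
  stopifnot(inherits(x, "aligned_seq_set"))
  r <- x$records[i, , drop = FALSE]
  if (nrow(r) == 0L) stop("subset selects no sequences", call. = FALSE)
  aligned_seq_set(r$id, r$seq, x$locus, r$morphospecies, r$host_population,
                  r$genotype)
}

#' Read an aligned FASTA file
#'
#' Headers may carry metadata as pipe-delimited fields after the id:
#' `>id|morphospecies|host_population|GT`. Fields after the id are optional;
#' missing fields default to `NA`.
#'
#' @param path path to a FASTA file with aligned sequences.
#' @param locus locus label to attach to the set.
#' @return an [aligned_seq_set()].
#' @export
read_alignment <- function(path, locus = "cytb") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(dna)) stop("input error: empty or unreadable FASTA file: ", path,
                         call. = FALSE)
  if (length(dna) == 0L) stop("input error: empty FASTA file: ", path, call. = FALSE)
  headers <- names(dna)
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1L))
  parts <- strsplit(headers, "|", fixed = TRUE)
  field <- function(k, as = identity) {
    vapply(parts, function(p) if (length(p) >= k && nzchar(p[k])) p[k] else NA_character_,
           character(1L))
  }
  gt <- suppressWarnings(as.integer(field(4L)))
  aligned_seq_set(field(1L), seqs, locus = locus,
                  morphospecies = field(2L), host_population = field(3L),
                  genotype = gt)
}

#' Write an aligned sequence set to FASTA
#'
#' Metadata are encoded back into pipe-delimited headers so that
#' [read_alignment()] round-trips losslessly.
#'
#' @param x an `aligned_seq_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "aligned_seq_set"))
  r <- x$records
  has_meta <- !is.na(r$morphospecies) | !is.na(r$host_population) | !is.na(r$genotype)
  enc <- function(v) ifelse(is.na(v), "", as.character(v))
  hdr <- ifelse(has_meta,
                paste(r$id, enc(r$morphospecies), enc(r$host_population),
                      enc(r$genotype), sep = "|"),
                r$id)
  lines <- character(2L * nrow(r))
  lines[c(TRUE, FALSE)] <- paste0(">", hdr)
  lines[c(FALSE, TRUE)] <- r$seq
  writeLines(lines, path)
  invisible(path)
}

#' Uncorrected pairwise distance between two aligned sequences
#'
#' The p-distance is the percentage of differing sites among comparable
#' sites. Columns where either sequence has a gap (`-`) or ambiguity (`N`)
#' are excluded (pairwise deletion).
#'
#' @param a,b aligned sequences of equal length (character strings).
#' @return percent divergence in `[0, 100]`.
#' @export
p_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences differ in alignment length", call. = FALSE)
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  ok <- !(av %in% c("-", "N")) & !(bv %in% c("-", "N"))
  n <- sum(ok)
  if (n == 0L) stop("undefined distance: zero comparable sites", call. = FALSE)
  100 * sum(av[ok] != bv[ok]) / n
}

# All-pairs p-distance matrix over the records of a set (internal workhorse).
pairwise_p_matrix <- function(x) {
  stopifnot(inherits(x, "aligned_seq_set"))
  s <- x$records$seq
  n <- length(s)
  chars <- matrix(unlist(strsplit(s, "", fixed = TRUE)), ncol = n)
  usable <- !(chars == "-" | chars == "N")
  D <- matrix(0, n, n, dimnames = list(x$records$id, x$records$id))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- usable[, i] & usable[, j]
        m <- sum(ok)
        if (m == 0L) stop("undefined distance: zero comparable sites between ",
                          x$records$id[i], " and ", x$records$id[j], call. = FALSE)
        D[i, j] <- D[j, i] <- 100 * sum(chars[ok, i] != chars[ok, j]) / m
      }
    }
  }
  D
}

#' Grouped divergence matrix
#'
#' Summarises all-pairs p-distances into a symmetric percent-divergence
#' matrix over groups (host populations, genotypes, ...), the same shape as
#' a published between-population divergence table. Off-diagonal entries
#' summarise all cross-group sequence pairs; the diagonal summarises
#' within-group pairs and is 0 for singleton groups.
#'
#' @param seqs an [aligned_seq_set()].
#' @param group_by name of the metadata column to group by
#'   (`"host_population"`, `"morphospecies"` or `"genotype"`), or a vector
#'   of group labels of the same length as the set.
#' @param statistic `"max"` or `"mean"` over pairwise distances.
#' @return a `divergence_matrix`: a square numeric matrix with group labels
#'   as dimnames and attributes `statistic` and `locus`.
#' @export
divergence_matrix <- function(seqs, group_by = "host_population",
                              statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(seqs, "aligned_seq_set"))
  if (length(group_by) == 1L && group_by %in% names(seqs$records)) {
    g <- as.character(seqs$records[[group_by]])
  } else {
    g <- as.character(group_by)
    if (length(g) != length(seqs)) {
      stop("group_by must name a metadata column or give one label per sequence",
           call. = FALSE)
    }
  }
  if (anyNA(g)) stop("input error: sequences with missing group label", call. = FALSE)
  labels <- sort(unique(g))
  P <- pairwise_p_matrix(seqs)
  stat_fun <- if (statistic == "max") max else mean
  k <- length(labels)
  D <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ri <- which(g == labels[i]); rj <- which(g == labels[j])
      if (i == j) {
        if (length(ri) > 1L) {
          pairs <- P[ri, ri][upper.tri(matrix(0, length(ri), length(ri)))]
          D[i, i] <- stat_fun(pairs)
        } # singleton group: stays 0
      } else {
        D[i, j] <- D[j, i] <- stat_fun(P[ri, rj, drop = FALSE])
      }
    }
  }
  new_divergence_matrix(D, statistic = statistic, locus = seqs$locus)
}

new_divergence_matrix <- function(D, statistic = "max", locus = NA_character_) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  structure(D, statistic = statistic, locus = locus,
            class = c("divergence_matrix", "matrix", "array"))
}

#' Validate a divergence matrix
#'
#' Checks squareness, symmetry and the percent range. The diagonal holds
#' the within-group divergence, which is 0 only for singleton or monomorphic
#' groups. `NA` entries are permitted (published tables omit unsampled
#' comparisons); they are treated as absent edges by the clustering
#' functions.
#'
#' @param D matrix to validate.
#' @return `D`, invisibly, or an error.
#' @export
validate_divergence_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("divergence matrix must be square", call. = FALSE)
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D))) {
    stop("divergence matrix must carry identical row/column labels", call. = FALSE)
  }
  if (!isTRUE(all.equal(D[!is.na(D)], t(D)[!is.na(t(D))], tolerance = 1e-9)) ||
      !identical(is.na(D), is.na(t(D)))) {
    stop("divergence matrix must be symmetric", call. = FALSE)
  }
  if (any(D < 0 | D > 100, na.rm = TRUE)) stop("divergence entries must lie in [0, 100]", call. = FALSE)
  invisible(D)
}

#' Read / write labelled divergence-matrix CSV
#'
#' The CSV has the group labels in the first row and first column; empty
#' cells denote comparisons without data.
#'
#' @param path CSV file path.
#' @param D a divergence matrix (for writing).
#' @param statistic statistic label to attach on read.
#' @return `read_divergence_csv`: a `divergence_matrix`;
#'   `write_divergence_csv`: `path` invisibly.
#' @export
read_divergence_csv <- function(path, statistic = "max") {
  tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  D <- as.matrix(tab)
  storage.mode(D) <- "double"
  D <- new_divergence_matrix(D, statistic = statistic)
  validate_divergence_matrix(D)
  D
}

#' @rdname read_divergence_csv
#' @export
write_divergence_csv <- function(D, path) {
  validate_divergence_matrix(D)
  utils::write.csv(as.data.frame(unclass(D)), path, na = "")
  invisible(path)
}
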