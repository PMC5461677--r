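#' Diagnostic alignment sites for a target morphospecies
#'
#' A diagnostic site is an alignment column where every target sequence
#' carries one and the same unambiguous base (`A`/`C`/`G`/`T`) and no
#' non-target sequence carries that base. Such fixed differences anchor the
#' 3' ends of species-specific primers.
#'
#' @param target_seqs [aligned_seq_set()] of the target morphospecies.
#' @param other_seqs [aligned_seq_set()] of all non-target sequences at the
#'   same locus/alignment.
#' @return sorted integer vector of 1-based alignment positions.
#' @export
find_diagnostic_sites <- function(target_seqs, other_seqs) {
  stopifnot(inherits(target_seqs, "aligned_seq_set"),
            inherits(other_seqs, "aligned_seq_set"))
  if (length(target_seqs) == 0L || length(other_seqs) == 0L) {
    stop("input error: empty target or non-target set", call. = FALSE)
  }
  L <- alignment_length(target_seqs)
  if (alignment_length(other_seqs) != L) {
    stop("target and non-target alignments differ in length", call. = FALSE)
  }
  tc <- seq_char_matrix(target_seqs)   # L x n_target
  oc <- seq_char_matrix(other_seqs)
  fixed <- apply(tc, 1L, function(col) {
    u <- unique(col)
    if (length(u) == 1L && u %in% c("A", "C", "G", "T")) u else NA_character_
  })
  ok <- !is.na(fixed) &
    vapply(seq_len(L), function(i) !any(oc[i, ] == fixed[i]), logical(1L))
  which(ok)
}

seq_char_matrix <- function(x) {
  matrix(unlist(strsplit(x$records$seq, "", fixed = TRUE)),
         ncol = length(x), dimnames = list(NULL, x$records$id))
}

#' Primer melting temperature (Wallace rule)
#'
#' `Tm = 2 * (#A + #T) + 4 * (#G + #C)` degrees C. Adequate for ranking and
#' matching short diagnostic primers; not a thermodynamic model.
#'
#' @param primer nucleotide string, length >= 8, unambiguous bases only.
#' @return melting temperature in degrees C.
#' @export
melting_temperature <- function(primer) {
  primer <- toupper(primer)
  if (nchar(primer) < 8L) stop("primer shorter than 8 nt", call. = FALSE)
  v <- strsplit(primer, "", fixed = TRUE)[[1L]]
  if (any(!v %in% c("A", "C", "G", "T"))) {
    stop("input error: ambiguous base in primer", call. = FALSE)
  }
  2 * sum(v %in% c("A", "T")) + 4 * sum(v %in% c("G", "C"))
}

#' Default primer-design constraints
#'
#' @param primer_length_range integer length 2; allowed primer lengths in nt.
#' @param amplicon_range integer length 2; allowed amplicon lengths in bp.
#' @param min_diag_3prime minimum diagnostic sites within the 3'-terminal
#'   five positions of each primer.
#' @param tm_pair_tolerance maximum |Tm difference| between the two primers
#'   of a pair, degrees C.
#' @param tm_window maximum Tm spread within one multiplex stage, degrees C.
#' @param length_separation minimum amplicon-length difference between pairs
#'   co-amplified in one stage, bp.
#' @param allowed_mismatches template mismatches tolerated outside the
#'   3'-terminal pentamer during in-silico PCR.
#' @return a named list of constraints.
#' @export
primer_constraints <- function(primer_length_range = c(16L, 30L),
                               amplicon_range = c(145L, 400L),
                               min_diag_3prime = 2L,
                               tm_pair_tolerance = 2,
                               tm_window = 4,
                               length_separation = 30L,
                               allowed_mismatches = 2L) {
  list(primer_length_range = as.integer(primer_length_range),
       amplicon_range = as.integer(amplicon_range),
       min_diag_3prime = as.integer(min_diag_3prime),
       tm_pair_tolerance = tm_pair_tolerance,
       tm_window = tm_window,
       length_separation = as.integer(length_separation),
       allowed_mismatches = as.integer(allowed_mismatches))
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(toupper(s), "", fixed = TRUE),
                function(v) paste(rev(v), collapse = ""), character(1L)))
}

# strict majority consensus of the target alignment; ties broken
# alphabetically so designs are reproducible
target_consensus <- function(target_seqs) {
  cm <- seq_char_matrix(target_seqs)
  apply(cm, 1L, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[order(-tab, names(tab))][1L]
  })
}

#' Design a species-specific primer pair
#'
#' Deterministically scans the alignment for the first primer pair whose
#' primers each carry at least `min_diag_3prime` diagnostic sites among
#' their 3'-terminal five positions, whose amplicon length falls in
#' `amplicon_range`, and whose Tm difference is within `tm_pair_tolerance`.
#' Scan order: leftmost forward start, then shortest amplicon, then shortest
#' primers; the first valid pair is returned, so designs are reproducible.
#' Primer sequences are taken from the majority consensus of the target
#' alignment; windows containing gaps or `N` are skipped.
#'
#' @param target morphospecies label (value of the `morphospecies` metadata
#'   column identifying target records in `seqs`).
#' @param seqs [aligned_seq_set()] containing target and non-target records.
#' @param constraints see [primer_constraints()].
#' @return a `primer_pair` (list with `target`, `forward`, `reverse`,
#'   `fwd_start`, `rev_end` (0-based half-open alignment coordinates),
#'   `amplicon_length`, `tm_forward`, `tm_reverse`,
#'   `diagnostic_sites_3prime`), or a `no_solution` object describing the
#'   first violated constraint per candidate region.
#' @export
design_species_primer <- function(target, seqs, constraints = primer_constraints()) {
  stopifnot(inherits(seqs, "aligned_seq_set"))
  is_target <- seqs$records$morphospecies == target
  if (!any(is_target)) stop("input error: no sequences for target ", target, call. = FALSE)
  if (all(is_target)) stop("input error: no non-target sequences", call. = FALSE)
  tset <- subset_seqs(seqs, is_target)
  oset <- subset_seqs(seqs, !is_target)
  L <- alignment_length(seqs)
  if (L < constraints$amplicon_range[1L]) {
    stop("input error: alignment (", L, " bp) shorter than minimum amplicon",
         call. = FALSE)
  }
  diag_sites <- find_diagnostic_sites(tset, oset)
  if (length(diag_sites) == 0L) {
    return(structure(list(target = target, reason = "no diagnostic sites in alignment"),
                     class = "no_solution"))
  }
  cons <- target_consensus(tset)
  clean <- cons %in% c("A", "C", "G", "T")
  is_diag <- logical(L); is_diag[diag_sites] <- TRUE
  plen <- constraints$primer_length_range
  arange <- constraints$amplicon_range
  need <- constraints$min_diag_3prime

  # candidate forward primers: 3' pentamer = rightmost 5 columns of window
  # candidate reverse primers: 3' pentamer = leftmost 5 columns of window
  fwd_ok <- function(s, l) {           # s = 1-based start, l = length
    e <- s + l - 1L
    all(clean[s:e]) && sum(is_diag[(e - 4L):e]) >= need
  }
  rev_ok <- function(s, l) {
    e <- s + l - 1L
    all(clean[s:e]) && sum(is_diag[s:(s + 4L)]) >= need
  }
  first_reason <- NULL
  for (fs in seq_len(L - arange[1L] + 1L)) {
    f_len <- NULL
    for (l in plen[1L]:plen[2L]) {
      if (fs + l - 1L > L) break
      if (fwd_ok(fs, l)) { f_len <- l; break }
    }
    if (is.null(f_len)) next
    fwd_seq <- paste(cons[fs:(fs + f_len - 1L)], collapse = "")
    tm_f <- melting_temperature(fwd_seq)
    amps <- max(arange[1L], f_len + plen[1L]):min(arange[2L], L - fs + 1L)
    for (amp in amps) {
      re <- fs + amp - 1L             # 1-based inclusive end of amplicon
      for (rl in plen[1L]:plen[2L]) {
        rs <- re - rl + 1L
        if (rs <= fs + f_len - 1L) break  # primers must not overlap
        if (!rev_ok(rs, rl)) next
        rev_seq <- revcomp(paste(cons[rs:re], collapse = ""))
        tm_r <- melting_temperature(rev_seq)
        if (abs(tm_f - tm_r) > constraints$tm_pair_tolerance) {
          if (is.null(first_reason)) first_reason <- "Tm pair tolerance exceeded"
          next
        }
        return(new_primer_pair(target, fwd_seq, rev_seq,
                               fwd_start = fs - 1L, rev_end = re,
                               tm_f = tm_f, tm_r = tm_r,
                               diag_f = sum(is_diag[(fs + f_len - 5L):(fs + f_len - 1L)]),
                               diag_r = sum(is_diag[rs:(rs + 4L)])))
      }
    }
    if (is.null(first_reason)) first_reason <- "no compatible reverse primer in amplicon range"
  }
  structure(list(target = target,
                 reason = if (is.null(first_reason))
                   "no forward primer with enough 3' diagnostic sites"
                 else first_reason),
            class = "no_solution")
}

new_primer_pair <- function(target, fwd, rev, fwd_start, rev_end, tm_f, tm_r,
                            diag_f, diag_r) {
  structure(list(target = target, forward = fwd, reverse = rev,
                 fwd_start = as.integer(fwd_start), rev_end = as.integer(rev_end),
                 amplicon_length = as.integer(rev_end - fwd_start),
                 tm_forward = tm_f, tm_reverse = tm_r,
                 diagnostic_sites_3prime = c(forward = diag_f, reverse = diag_r)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("primer_pair for", x$target, ":", x$amplicon_length, "bp amplicon [",
      x$fwd_start, ",", x$rev_end, ")\n  F:", x$forward, "(Tm", x$tm_forward,
      ")\n  R:", x$reverse, "(Tm", x$tm_reverse, ")\n")
  invisible(x)
}

#' Independent constraint checker for a designed primer pair
#'
#' Re-validates a `primer_pair` against the design alignment from scratch:
#' primer length range, amplicon range, coordinate consistency, Tm pairing,
#' the primer sequences matching the target consensus at their footprints,
#' and at least the required number of diagnostic sites in each 3' pentamer
#' (recomputed independently column-by-column).
#'
#' @param pair a `primer_pair`.
#' @param target_seqs,other_seqs the design alignments.
#' @param constraints see [primer_constraints()].
#' @return character vector of violations (empty if the pair is valid).
#' @export
check_primer_pair <- function(pair, target_seqs, other_seqs,
                              constraints = primer_constraints()) {
  bad <- character(0)
  fl <- nchar(pair$forward); rl <- nchar(pair$reverse)
  pr <- constraints$primer_length_range
  if (fl < pr[1L] || fl > pr[2L] || rl < pr[1L] || rl > pr[2L]) {
    bad <- c(bad, "primer length out of range")
  }
  if (pair$amplicon_length != pair$rev_end - pair$fwd_start) {
    bad <- c(bad, "amplicon length inconsistent with coordinates")
  }
  ar <- constraints$amplicon_range
  if (pair$amplicon_length < ar[1L] || pair$amplicon_length > ar[2L]) {
    bad <- c(bad, "amplicon length out of range")
  }
  if (abs(pair$tm_forward - pair$tm_reverse) > constraints$tm_pair_tolerance) {
    bad <- c(bad, "primer Tm difference exceeds tolerance")
  }
  if (melting_temperature(pair$forward) != pair$tm_forward ||
      melting_temperature(pair$reverse) != pair$tm_reverse) {
    bad <- c(bad, "stored Tm does not match Wallace-rule recomputation")
  }
  # recompute diagnostic sites column-by-column
  sites <- find_diagnostic_sites(target_seqs, other_seqs)
  f_end <- pair$fwd_start + fl            # 1-based inclusive end
  f_pent <- (f_end - 4L):f_end
  r_start <- pair$rev_end - rl + 1L
  r_pent <- r_start:(r_start + 4L)
  if (sum(f_pent %in% sites) < constraints$min_diag_3prime) {
    bad <- c(bad, "forward primer lacks diagnostic sites in 3' pentamer")
  }
  if (sum(r_pent %in% sites) < constraints$min_diag_3prime) {
    bad <- c(bad, "reverse primer lacks diagnostic sites in 3' pentamer")
  }
  cons <- target_consensus(target_seqs)
  fwd_tpl <- paste(cons[(pair$fwd_start + 1L):f_end], collapse = "")
  rev_tpl <- paste(cons[r_start:pair$rev_end], collapse = "")
  if (fwd_tpl != pair$forward) bad <- c(bad, "forward primer does not match target consensus")
  if (revcomp(rev_tpl) != pair$reverse) bad <- c(bad, "reverse primer does not match target consensus")
  bad
}

#' Assemble primer pairs into multiplex stages
#'
#' Greedily partitions pairs into the minimum number of PCR stages such
#' that, within a stage, every two amplicons differ in length by at least
#' `length_separation` (so products are distinguishable on a gel) and the
#' Tm spread over all primers is at most `tm_window`. Pairs are processed in
#' decreasing amplicon length and placed into the first compatible stage
#' (first-fit decreasing).
#'
#' @param pairs list of `primer_pair` objects.
#' @param length_separation minimum pairwise amplicon-length difference, bp.
#' @param tm_window maximum Tm spread within a stage, degrees C.
#' @return a `primer_panel`: list of stages, each a list of `primer_pair`s,
#'   with attributes `length_separation` and `tm_window`.
#' @export
assemble_multiplex <- function(pairs, length_separation = 30L, tm_window = 4) {
  stopifnot(length(pairs) >= 1L)
  lens <- vapply(pairs, function(p) p$amplicon_length, integer(1L))
  ord <- order(-lens, vapply(pairs, function(p) p$target, character(1L)))
  stages <- list()
  compatible <- function(stage, p) {
    slens <- vapply(stage, function(q) q$amplicon_length, integer(1L))
    if (any(abs(slens - p$amplicon_length) < length_separation)) return(FALSE)
    tms <- unlist(lapply(c(stage, list(p)),
                         function(q) c(q$tm_forward, q$tm_reverse)))
    diff(range(tms)) <= tm_window
  }
  for (i in ord) {
    placed <- FALSE
    for (s in seq_along(stages)) {
      if (compatible(stages[[s]], pairs[[i]])) {
        stages[[s]] <- c(stages[[s]], list(pairs[[i]]))
        placed <- TRUE
        break
      }
    }
    if (!placed) stages[[length(stages) + 1L]] <- list(pairs[[i]])
  }
  structure(stages, length_separation = as.integer(length_separation),
            tm_window = tm_window, class = "primer_panel")
}

#' @export
print.primer_panel <- function(x, ...) {
  cat("primer_panel:", length(x), "stage(s)\n")
  for (s in seq_along(x)) {
    cat(" stage", s, ":",
        paste(vapply(x[[s]], function(p)
          paste0(p$target, " (", p$amplicon_length, " bp)"), character(1L)),
          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Panel report table
#'
#' @param panel a `primer_panel`.
#' @return data.frame with one row per primer pair: target, forward,
#'   reverse, amplicon length, Tm of each primer, and stage.
#' @export
panel_report <- function(panel) {
  rows <- list()
  for (s in seq_along(panel)) {
    for (p in panel[[s]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = p$target, forward = p$forward, reverse = p$reverse,
        amplicon_length = p$amplicon_length,
        tm_forward = p$tm_forward, tm_reverse = p$tm_reverse, stage = s,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# all 0-mismatch-pentamer binding sites of a primer on one template strand;
# returns 1-based start positions of windows where the 3'-terminal pentamer
# matches exactly and at most max_mm mismatches occur elsewhere. `pent` is
# "right" for a plus-strand (forward) primer, "left" for the
# reverse-complemented footprint of a reverse primer. Gap/N template
# positions count as mismatches.
primer_hits <- function(primer_on_template, template, pent = c("right", "left"),
                        max_mm = 2L) {
  pent <- match.arg(pent)
  pv <- strsplit(primer_on_template, "", fixed = TRUE)[[1L]]
  tv <- strsplit(toupper(template), "", fixed = TRUE)[[1L]]
  l <- length(pv); L <- length(tv)
  if (L < l) return(integer(0))
  hits <- integer(0)
  pent_idx <- if (pent == "right") (l - 4L):l else 1L:5L
  rest_idx <- setdiff(seq_len(l), pent_idx)
  for (s in seq_len(L - l + 1L)) {
    w <- tv[s:(s + l - 1L)]
    if (any(w[pent_idx] != pv[pent_idx])) next
    if (sum(w[rest_idx] != pv[rest_idx]) <= max_mm) hits <- c(hits, s)
  }
  hits
}

#' In-silico single/multiplex PCR
#'
#' Runs a primer panel against a mixture of template sequences (in the same
#' alignment coordinate system as the design). A primer binds wherever its
#' 3'-terminal five positions match the template exactly and at most
#' `allowed_mismatches` mismatches occur elsewhere; a detection is emitted
#' for every forward/reverse binding combination that yields a product
#' (reverse site downstream of the forward site). Output is sorted by
#' template id, then amplicon length.
#'
#' @param panel a `primer_panel` (all stages are run).
#' @param templates an [aligned_seq_set()] of template sequences.
#' @param allowed_mismatches mismatches tolerated outside the 3' pentamer.
#' @return data.frame with columns `template`, `target`, `amplicon_length`,
#'   `stage` (zero rows if nothing amplifies).
#' @export
in_silico_pcr <- function(panel, templates, allowed_mismatches = 2L) {
  stopifnot(inherits(panel, "primer_panel"), inherits(templates, "aligned_seq_set"))
  out <- list()
  for (s in seq_along(panel)) {
    for (p in panel[[s]]) {
      rev_on_template <- revcomp(p$reverse)
      for (k in seq_len(length(templates))) {
        tpl <- templates$records$seq[k]
        fh <- primer_hits(p$forward, tpl, "right", allowed_mismatches)
        if (length(fh) == 0L) next
        rh <- primer_hits(rev_on_template, tpl, "left", allowed_mismatches)
        for (f in fh) {
          for (r in rh) {
            re <- r + nchar(rev_on_template) - 1L
            if (re > f + nchar(p$forward) - 1L) {
              out[[length(out) + 1L]] <- data.frame(
                template = templates$records$id[k], target = p$target,
                amplicon_length = re - f + 1L, stage = s,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(template = character(0), target = character(0),
                      amplicon_length = integer(0), stage = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$template, res$amplicon_length, res$target), , drop = FALSE]
  rownames(res) <- NULL
  res
}
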