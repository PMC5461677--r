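#' Load a mummy detection table
#'
#' Reads a CSV of per-mummy multiplex-PCR results. Required columns:
#' `mummy_id`, `host_species`, `emerged_species`, `emerged_sex`,
#' `psyllid_dna`, plus one `det_<TARGET>` column per panel target (e.g.
#' `det_P1`). Boolean flags accept 0/1, yes/no, true/false.
#'
#' @param path CSV file path.
#' @return a data.frame of class `mummy_table` with logical detection
#'   columns; attribute `targets` lists the panel target labels.
#' @export
load_mummy_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("mummy_id", "host_species", "emerged_species", "emerged_sex",
                "psyllid_dna")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L) {
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  det_cols <- grep("^det_", names(tab), value = TRUE)
  if (length(det_cols) == 0L) {
    stop("schema error: no det_<TARGET> detection columns", call. = FALSE)
  }
  if (anyDuplicated(tab$mummy_id)) {
    stop("input error: duplicate mummy_id", call. = FALSE)
  }
  parse_bool <- function(v) {
    v <- tolower(as.character(v))
    out <- v %in% c("1", "yes", "true", "y")
    bad <- !v %in% c("1", "yes", "true", "y", "0", "no", "false", "n")
    if (any(bad)) stop("input error: unparseable boolean value: ",
                       v[bad][1L], call. = FALSE)
    out
  }
  tab$psyllid_dna <- parse_bool(tab$psyllid_dna)
  for (cc in det_cols) tab[[cc]] <- parse_bool(tab[[cc]])
  as_mummy_table(tab)
}

as_mummy_table <- function(tab) {
  det_cols <- grep("^det_", names(tab), value = TRUE)
  structure(tab, targets = sub("^det_", "", det_cols),
            class = c("mummy_table", "data.frame"))
}

#' Write a mummy table to CSV
#' @param records a `mummy_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mummy_table <- function(records, path) {
  out <- as.data.frame(records)
  logi <- vapply(out, is.logical, logical(1L))
  out[logi] <- lapply(out[logi], as.integer)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Partition mummies into informative and uninformative
#'
#' A post-emergence mummy is informative when DNA of both the psyllid host
#' and the emerged parasitoid species was detected; only informative mummies
#' carry forensic evidence about additional occupants.
#'
#' @param records a `mummy_table`.
#' @return list with `informative` and `uninformative` (both `mummy_table`s,
#'   possibly with zero rows) and logical vector `is_informative`.
#' @export
flag_informative <- function(records) {
  stopifnot(inherits(records, "mummy_table"))
  targets <- attr(records, "targets")
  det_emerged <- vapply(seq_len(nrow(records)), function(i) {
    sp <- records$emerged_species[i]
    if (!sp %in% targets) return(FALSE)
    isTRUE(records[[paste0("det_", sp)]][i])
  }, logical(1L))
  inf <- records$psyllid_dna & det_emerged
  list(informative = as_mummy_table(records[inf, , drop = FALSE]),
       uninformative = as_mummy_table(records[!inf, , drop = FALSE]),
       is_informative = inf)
}

round_half_up <- function(x) floor(x + 0.5)

#' Detection success per stratum
#'
#' Percentage of informative mummies per (host, emerged species, sex)
#' stratum, rounded half-up to the nearest integer. Strata with zero
#' mummies are omitted.
#'
#' @param records a `mummy_table`.
#' @return data.frame with columns `host_species`, `emerged_species`,
#'   `emerged_sex`, `informative`, `uninformative`, `detection_success`.
#' @export
detection_success <- function(records) {
  stopifnot(inherits(records, "mummy_table"))
  inf <- flag_informative(records)$is_informative
  key <- interaction(records$host_species, records$emerged_species,
                     records$emerged_sex, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    first <- which(sel)[1L]
    ni <- sum(inf[sel]); nu <- sum(!inf[sel])
    data.frame(host_species = records$host_species[first],
               emerged_species = records$emerged_species[first],
               emerged_sex = records$emerged_sex[first],
               informative = ni, uninformative = nu,
               detection_success = round_half_up(100 * ni / (ni + nu)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$host_species, out$emerged_species, out$emerged_sex), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count mummies containing DNA of both members of a species pair
#'
#' A zero count for two primary parasitoids supports the absence of larval
#' competition between them (their DNA never co-occurs in one mummy).
#'
#' @param records a `mummy_table`.
#' @param pair character vector of two panel target labels.
#' @return integer count.
#' @export
cooccurrence_check <- function(records, pair) {
  stopifnot(inherits(records, "mummy_table"), length(pair) == 2L)
  targets <- attr(records, "targets")
  if (!all(pair %in% targets)) {
    stop("input error: pair labels not in panel targets", call. = FALSE)
  }
  sum(records[[paste0("det_", pair[1L])]] & records[[paste0("det_", pair[2L])]])
}

#' Classify trophic roles from mummy detection patterns
#'
#' Works on informative mummies only, per (host, emerged species, sex)
#' stratum:
#' * `primary` - at least a `consistency` fraction of mummies contain no
#'   non-emerged parasitoid DNA (prey = psyllid);
#' * `hyperparasitoid` of X - at least a `consistency` fraction contain
#'   exactly one non-emerged species X and the emerged species never
#'   appears without another parasitoid;
#' * otherwise, or with fewer than `min_n` informative mummies,
#'   `undetermined`.
#'
#' Sexes are classified first, then merged per (host, morphospecies): a
#' morphospecies whose females are primary and whose males are
#' hyperparasitoids of some X is re-labelled `heteronomous_hyperparasitoid`
#' with per-sex prey.
#'
#' @param records a `mummy_table`.
#' @param consistency required agreement fraction in (0.5, 1]; default 1
#'   (the detection pattern must be unanimous).
#' @param min_n minimum informative mummies for a confident call (default 2).
#' @return data.frame of class `trophic_assignment` with columns
#'   `host_species`, `morphospecies`, `sex_scope`, `role`, `prey_female`,
#'   `prey_male`, `n_informative`, `n_conforming`.
#' @export
classify_trophic_roles <- function(records, consistency = 1.0, min_n = 2L) {
  stopifnot(inherits(records, "mummy_table"))
  if (consistency <= 0.5 || consistency > 1) {
    stop("consistency must lie in (0.5, 1]", call. = FALSE)
  }
  targets <- attr(records, "targets")
  inf <- flag_informative(records)$informative

  strata <- unique(records[, c("host_species", "emerged_species", "emerged_sex")])
  per_sex <- lapply(seq_len(nrow(strata)), function(i) {
    h <- strata$host_species[i]; sp <- strata$emerged_species[i]
    sx <- strata$emerged_sex[i]
    sub <- inf[inf$host_species == h & inf$emerged_species == sp &
                 inf$emerged_sex == sx, , drop = FALSE]
    n <- nrow(sub)
    res <- data.frame(host_species = h, morphospecies = sp, sex = sx,
                      role = "undetermined", prey = NA_character_,
                      n_informative = n, n_conforming = 0L,
                      stringsAsFactors = FALSE)
    if (n < min_n) return(res)
    others <- lapply(seq_len(n), function(k) {
      det <- vapply(targets, function(tg) isTRUE(sub[[paste0("det_", tg)]][k]),
                    logical(1L))
      setdiff(targets[det], sp)
    })
    n_other <- lengths(others)
    n_none <- sum(n_other == 0L)
    if (n_none / n >= consistency) {
      res$role <- "primary"; res$prey <- "psyllid"; res$n_conforming <- n_none
      return(res)
    }
    single <- unlist(others[n_other == 1L])
    if (length(single) > 0L) {
      cand <- names(sort(table(single), decreasing = TRUE))[1L]
      n_cand <- sum(vapply(others, function(o) identical(o, cand), logical(1L)))
      if (n_cand / n >= consistency && n_none == 0L) {
        res$role <- "hyperparasitoid"; res$prey <- cand
        res$n_conforming <- n_cand
        return(res)
      }
    }
    res
  })
  per_sex <- do.call(rbind, per_sex)

  # merge sexes per (host, morphospecies)
  keys <- unique(per_sex[, c("host_species", "morphospecies")])
  merged <- lapply(seq_len(nrow(keys)), function(i) {
    h <- keys$host_species[i]; sp <- keys$morphospecies[i]
    sub <- per_sex[per_sex$host_species == h & per_sex$morphospecies == sp, ,
                   drop = FALSE]
    f <- sub[sub$sex == "female", , drop = FALSE]
    m <- sub[sub$sex == "male", , drop = FALSE]
    frole <- if (nrow(f) > 0L) f$role[1L] else NA_character_
    mrole <- if (nrow(m) > 0L) m$role[1L] else NA_character_
    out <- data.frame(host_species = h, morphospecies = sp,
                      sex_scope = "both", role = "undetermined",
                      prey_female = if (nrow(f)) f$prey[1L] else NA_character_,
                      prey_male = if (nrow(m)) m$prey[1L] else NA_character_,
                      n_informative = sum(sub$n_informative),
                      n_conforming = sum(sub$n_conforming),
                      stringsAsFactors = FALSE)
    if (identical(frole, "primary") && identical(mrole, "hyperparasitoid")) {
      out$role <- "heteronomous_hyperparasitoid"
    } else if (!is.na(frole) && is.na(mrole)) {
      out$role <- frole; out$sex_scope <- "female"
    } else if (is.na(frole) && !is.na(mrole)) {
      out$role <- mrole; out$sex_scope <- "male"
    } else if (identical(frole, mrole)) {
      out$role <- frole
    }
    out
  })
  merged <- do.call(rbind, merged)
  merged <- merged[order(merged$host_species, merged$morphospecies), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  class(merged) <- c("trophic_assignment", "data.frame")
  merged
}

#' Aggregate per-host trophic assignments to morphospecies level
#'
#' A morphospecies is heteronomous if it is called heteronomous in any host
#' system, or if its female-only strata classify primary while its male
#' strata classify hyperparasitoid across systems. Otherwise the consensus
#' determinate role across host systems is reported (`undetermined` on
#' conflict or absence of determinate calls).
#'
#' @param assignments a `trophic_assignment` from [classify_trophic_roles()].
#' @return data.frame with `morphospecies`, `role`, `prey_female`, `prey_male`.
#' @export
summarize_roles <- function(assignments) {
  sp <- unique(assignments$morphospecies)
  rows <- lapply(sp, function(s) {
    sub <- assignments[assignments$morphospecies == s, , drop = FALSE]
    det <- sub[sub$role != "undetermined", , drop = FALSE]
    pf <- unique(stats::na.omit(det$prey_female))
    pm <- unique(stats::na.omit(det$prey_male))
    role <- "undetermined"
    if (any(det$role == "heteronomous_hyperparasitoid")) {
      role <- "heteronomous_hyperparasitoid"
    } else {
      fem_primary <- any(det$role == "primary" & det$sex_scope %in% c("female", "both"))
      male_hyper <- any(det$role == "hyperparasitoid" & det$sex_scope == "male")
      if (fem_primary && male_hyper) {
        role <- "heteronomous_hyperparasitoid"
      } else if (nrow(det) > 0L && length(unique(det$role)) == 1L) {
        role <- det$role[1L]
      }
    }
    data.frame(morphospecies = s, role = role,
               prey_female = if (length(pf)) pf[1L] else NA_character_,
               prey_male = if (length(pm)) pm[1L] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$morphospecies), , drop = FALSE]
}

#' Check that hyperparasitoid prey are primaries in the same host system
#'
#' Reports (does not error on) hyperparasitoid calls whose prey species
#' carries a contradictory determinate role in the same host system. Prey
#' strata that are absent or undetermined (e.g. too few informative
#' mummies) are not violations: absence of evidence is not a
#' contradiction.
#'
#' @param assignments a `trophic_assignment`.
#' @return data.frame of violations (zero rows when all calls are coherent).
#' @export
validate_assignments <- function(assignments) {
  bad <- list()
  hyp <- assignments[assignments$role %in%
                       c("hyperparasitoid", "heteronomous_hyperparasitoid"), ,
                     drop = FALSE]
  for (i in seq_len(nrow(hyp))) {
    prey <- stats::na.omit(c(hyp$prey_male[i], hyp$prey_female[i]))
    prey <- setdiff(prey, "psyllid")
    for (p in prey) {
      ref <- assignments[assignments$host_species == hyp$host_species[i] &
                           assignments$morphospecies == p, , drop = FALSE]
      ref <- ref[ref$role != "undetermined", , drop = FALSE]
      if (nrow(ref) > 0L && !any(ref$role %in% c("primary",
                                                 "heteronomous_hyperparasitoid"))) {
        bad[[length(bad) + 1L]] <- data.frame(
          host_species = hyp$host_species[i],
          hyperparasitoid = hyp$morphospecies[i], prey = p,
          prey_role = ref$role[1L], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(bad) == 0L) {
    return(data.frame(host_species = character(0), hyperparasitoid = character(0),
                      prey = character(0), prey_role = character(0)))
  }
  do.call(rbind, bad)
}
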