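#' Bundled field-study tables
#'
#' The package ships the published summary tables of a psyllid-parasitoid
#' field study as plain CSV: specimen emergence counts per host species,
#' morphospecies and sex; maximum cytb percent-divergence matrices between
#' host populations for the four major parasitoid morphospecies (P1, P2, H,
#' HH); and the per-stratum outcome of the morphospecies-specific multiplex
#' PCR screen of post-emergence mummies. `psyllid_` loaders return them as
#' package-native objects.
#'
#' @name psyllid_tables
NULL

pw_extdata <- function(file) {
  path <- system.file("extdata", file, package = "psyllidwebs")
  if (path == "") stop("bundled data file not found: ", file, call. = FALSE)
  path
}

#' @describeIn psyllid_tables emergence counts: data.frame with
#'   `host_species`, `morphospecies`, `sex`, `count`.
#' @export
psyllid_emergence_counts <- function() {
  utils::read.csv(pw_extdata("emergence_counts.csv"), stringsAsFactors = FALSE)
}

#' @describeIn psyllid_tables maximum cytb divergence matrices: named list
#'   of `divergence_matrix` objects for morphospecies P1, P2, H and HH.
#' @export
psyllid_divergence_tables <- function() {
  sp <- c("P1", "P2", "H", "HH")
  out <- lapply(sp, function(s)
    read_divergence_csv(pw_extdata(paste0("divergence_cytb_", s, ".csv")),
                        statistic = "max"))
  names(out) <- sp
  out
}

#' @describeIn psyllid_tables multiplex-PCR mummy screen summary: data.frame
#'   with `host_species`, `emerged_species`, `emerged_sex`, `other_species`
#'   (`"No"` or a morphospecies label), `informative`, `uninformative`.
#' @export
psyllid_mummy_screen <- function() {
  utils::read.csv(pw_extdata("mummy_screen.csv"), stringsAsFactors = FALSE)
}

#' Expand a mummy-screen summary into per-mummy records
#'
#' Reconstitutes one record per mummy from the per-stratum summary:
#' informative mummies carry psyllid DNA, emerged-species DNA and (when the
#' stratum lists one) the non-emerged species' DNA; uninformative mummies
#' carry no detections. This inverts exactly the aggregation performed by
#' [detection_success()] and feeds [classify_trophic_roles()].
#'
#' @param screen a summary data.frame as from [psyllid_mummy_screen()].
#' @param targets panel target labels (columns of the detection map).
#' @return a `mummy_table`.
#' @export
expand_mummy_screen <- function(screen = psyllid_mummy_screen(),
                                targets = c("P1", "P2", "H", "HH")) {
  rows <- list()
  mummy <- 0L
  for (i in seq_len(nrow(screen))) {
    r <- screen[i, ]
    other <- if (!is.na(r$other_species) && r$other_species != "No")
      r$other_species else NA_character_
    for (k in seq_len(r$informative + r$uninformative)) {
      mummy <- mummy + 1L
      informative <- k <= r$informative
      det <- stats::setNames(rep(FALSE, length(targets)), targets)
      if (informative) {
        det[r$emerged_species] <- TRUE
        if (!is.na(other)) det[other] <- TRUE
      }
      rows[[mummy]] <- c(
        list(mummy_id = sprintf("M%05d", mummy),
             host_species = r$host_species,
             emerged_species = r$emerged_species,
             emerged_sex = r$emerged_sex,
             psyllid_dna = informative),
        as.list(stats::setNames(det, paste0("det_", targets))))
    }
  }
  tab <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  as_mummy_table(tab)
}

#' Per-morphospecies sex totals from emergence counts
#'
#' @param counts data.frame as from [psyllid_emergence_counts()].
#' @return data.frame with `morphospecies`, `females`, `males`, ready for
#'   [infer_thelytoky()].
#' @export
emergence_sex_totals <- function(counts = psyllid_emergence_counts()) {
  sp <- sort(unique(counts$morphospecies))
  out <- data.frame(
    morphospecies = sp,
    females = vapply(sp, function(s)
      sum(counts$count[counts$morphospecies == s & counts$sex == "female"]),
      numeric(1L)),
    males = vapply(sp, function(s)
      sum(counts$count[counts$morphospecies == s & counts$sex == "male"]),
      numeric(1L)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
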