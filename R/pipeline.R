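#' Pipeline configuration
#'
#' Builds (and validates) the configuration for [run_pipeline()]. Any subset
#' of analyses can be run: sequence/delimitation analyses need
#' `seqs_fasta`; trophic analyses need `mummy_csv`; cophylogenetic tests
#' need `host_tree`, `parasite_tree` and `association_csv`. Values read
#' from a YAML file override these defaults; arguments override the file.
#'
#' @param config_file optional YAML file with any of the fields below.
#' @param seqs_fasta aligned FASTA of parasitoid sequences (pipe-delimited
#'   metadata headers, see [read_alignment()]).
#' @param locus locus label of `seqs_fasta`.
#' @param group_by grouping column for divergence matrices.
#' @param delimit_threshold percent divergence threshold for species
#'   delimitation.
#' @param mummy_csv mummy detection table CSV (see [load_mummy_table()]).
#' @param consistency,min_n trophic classification knobs
#'   (see [classify_trophic_roles()]).
#' @param host_tree,parasite_tree Newick files.
#' @param association_csv binary association matrix CSV (parasites in rows).
#' @param n_perm permutations for the cophylogenetic tests.
#' @param seed integer seed recorded in every output.
#' @param primer_target optional morphospecies label; when set, a
#'   species-specific primer pair is designed from `seqs_fasta`.
#' @param outdir output directory (created if missing).
#' @param ... further overrides of the same field names.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(config_file = NULL, seqs_fasta = NULL,
                            locus = "cytb", group_by = "host_population",
                            delimit_threshold = 5, mummy_csv = NULL,
                            consistency = 1.0, min_n = 2L, host_tree = NULL,
                            parasite_tree = NULL, association_csv = NULL,
                            n_perm = 10000L, seed = 1L, primer_target = NULL,
                            outdir = "psyllidwebs_out", ...) {
  cfg <- list(seqs_fasta = seqs_fasta, locus = locus, group_by = group_by,
              delimit_threshold = delimit_threshold, mummy_csv = mummy_csv,
              consistency = consistency, min_n = min_n, host_tree = host_tree,
              parasite_tree = parasite_tree, association_csv = association_csv,
              n_perm = n_perm, seed = seed, primer_target = primer_target,
              outdir = outdir)
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop("config error: config file not found: ", config_file, call. = FALSE)
    }
    file_cfg <- yaml::read_yaml(config_file)
    bad <- setdiff(names(file_cfg), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  # explicit arguments win over the file
  supplied <- intersect(names(as.list(match.call()))[-1L], names(cfg))
  for (nm in supplied) cfg[[nm]] <- get(nm)
  for (f in c("seqs_fasta", "mummy_csv", "host_tree", "parasite_tree",
              "association_csv")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config error: ", f, " does not exist: ", cfg[[f]], call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the food-web inference pipeline
#'
#' Executes, in order, the stages enabled by the configuration: sequence
#' divergence and species delimitation, optional primer design, trophic
#' classification, and cophylogenetic congruence tests. All artifacts are
#' written under `config$outdir`; a machine-readable JSON summary records
#' the package version, a hash of the configuration, and the seed, so runs
#' are reproducible and attributable.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly; the JSON is written to
#'   `<outdir>/summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hashed <- unclass(config)
  hashed$outdir <- NULL                # where results land does not alter them
  summary <- list(
    package = "psyllidwebs",
    version = as.character(utils::packageVersion("psyllidwebs")),
    config_hash = digest::digest(hashed),
    seed = config$seed)

  if (!is.null(config$seqs_fasta)) {
    seqs <- stage("seqdiv", read_alignment(config$seqs_fasta, config$locus))
    sp_labels <- unique(stats::na.omit(seqs$records$morphospecies))
    partitions <- list()
    for (sp in sort(sp_labels)) {
      sub <- subset_seqs(seqs, seqs$records$morphospecies == sp)
      D <- stage("seqdiv", divergence_matrix(sub, config$group_by, "max"))
      write_divergence_csv(D, file.path(config$outdir,
                                        paste0("divergence_", sp, ".csv")))
      partitions[[sp]] <- stage("delimit",
                                single_linkage_partition(D, config$delimit_threshold, sp))
    }
    counts <- stage("delimit", count_putative_species(partitions))
    part_rows <- do.call(rbind, lapply(names(partitions), function(sp) {
      p <- partitions[[sp]]
      do.call(rbind, lapply(seq_along(p$clusters), function(k)
        data.frame(morphospecies = sp, cluster_id = k,
                   member = p$clusters[[k]], stringsAsFactors = FALSE)))
    }))
    utils::write.csv(part_rows, file.path(config$outdir, "partitions.csv"),
                     row.names = FALSE)
    summary$delimitation <- list(threshold = config$delimit_threshold,
                                 species_counts = as.list(counts$counts),
                                 total = counts$total, ratio = counts$ratio)
    if (!is.null(config$primer_target)) {
      pair <- stage("primers",
                    design_species_primer(config$primer_target, seqs))
      summary$primer <- if (inherits(pair, "no_solution")) {
        list(target = pair$target, status = "no_solution", reason = pair$reason)
      } else {
        list(target = pair$target, forward = pair$forward,
             reverse = pair$reverse, amplicon_length = pair$amplicon_length)
      }
    }
  }

  if (!is.null(config$mummy_csv)) {
    mummies <- stage("trophic", load_mummy_table(config$mummy_csv))
    det <- stage("trophic", detection_success(mummies))
    utils::write.csv(det, file.path(config$outdir, "detection_success.csv"),
                     row.names = FALSE)
    assign <- stage("trophic",
                    classify_trophic_roles(mummies, config$consistency,
                                           config$min_n))
    utils::write.csv(as.data.frame(assign),
                     file.path(config$outdir, "trophic_assignments.csv"),
                     row.names = FALSE)
    roles <- summarize_roles(assign)
    summary$trophic <- list(
      assignments = lapply(seq_len(nrow(roles)), function(i) as.list(roles[i, ])),
      violations = nrow(validate_assignments(assign)))
  }

  if (!is.null(config$host_tree) && !is.null(config$parasite_tree) &&
      !is.null(config$association_csv)) {
    host <- stage("cophylo", read_newick(config$host_tree))
    parasite <- stage("cophylo", read_newick(config$parasite_tree))
    A <- stage("cophylo", {
      tab <- utils::read.csv(config$association_csv, row.names = 1L,
                             check.names = FALSE)
      as.matrix(tab)
    })
    Dh <- patristic_distances(host)
    Dp <- patristic_distances(parasite)
    pf <- stage("cophylo", parafit_test(Dh, Dp, A, config$n_perm, config$seed))
    hm <- stage("cophylo", hommola_test(Dh, Dp, expand_links(A),
                                        config$n_perm, config$seed))
    summary$cophylo <- list(
      parafit = list(statistic = pf$statistic, p_value = pf$p_value,
                     n_permutations = pf$n_permutations, seed = pf$seed),
      hommola = list(statistic = hm$statistic, p_value = hm$p_value,
                     n_permutations = hm$n_permutations, seed = hm$seed))
  }

  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}

#' Write a simulated system as a file-based fixture
#'
#' Materialises a [simulate_system()] scenario as the standard formats the
#' pipeline consumes (Newick, FASTA, CSV) plus a JSON provenance sidecar
#' recording the seed, parameters and true event counts.
#'
#' @param outdir writable output directory.
#' @param seed integer seed.
#' @param ... passed to [simulate_system()].
#' @return named list of the written file paths, invisibly.
#' @export
make_fixture <- function(outdir, seed = 1L, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sys <- simulate_system(seed = seed, ...)
  if (isTRUE(sys$empty)) stop("simulated system is empty (all parasites lost)",
                              call. = FALSE)
  paths <- list(
    host_tree = file.path(outdir, "host.nwk"),
    parasite_tree = file.path(outdir, "parasite.nwk"),
    association_csv = file.path(outdir, "association.csv"),
    host_seqs = file.path(outdir, "host_seqs.fasta"),
    parasite_seqs = file.path(outdir, "parasite_seqs.fasta"),
    mummy_csv = file.path(outdir, "mummies.csv"),
    provenance = file.path(outdir, "provenance.json"))
  write_newick(sys$host, paths$host_tree)
  write_newick(sys$parasite, paths$parasite_tree)
  utils::write.csv(as.data.frame(sys$A), paths$association_csv)
  write_alignment(sys$host_seqs, paths$host_seqs)
  write_alignment(sys$parasite_seqs, paths$parasite_seqs)
  write_mummy_table(sys$mummies, paths$mummy_csv)
  jsonlite::write_json(
    list(package = "psyllidwebs",
         version = as.character(utils::packageVersion("psyllidwebs")),
         seed = seed, parameters = list(...),
         true_events = as.list(sys$true_events)),
    paths$provenance, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(paths)
}
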