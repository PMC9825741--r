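# Multi-sample scenario driver: a shared genome profile generated at several
# per-sample settings (tumor-content dilution series, longitudinal subclone
# regression/emergence), each tumor sample paired with one matched control.

#' Assemble a multi-sample simulation scenario
#'
#' @param models A [model_bundle()] or path to a bundle saved with
#'   [save_models()].
#' @param reference Indexed FASTA path.
#' @param profile A [genome_profile()] shared by all samples.
#' @param samples A list of per-sample settings; each element is a list with
#'   `name`, `tumor_content`, one of `coverage`/`n_reads`, and optionally
#'   `read_length`, `paired`, `strand_bias`, `seed` and `clonality` (a named
#'   vector of per-clone clonality overrides; a clone set to 0 is dropped for
#'   that sample).
#' @param name Scenario name (prefixes outputs and the shared control).
#' @param control Settings for the matched control (same fields as a sample
#'   entry; defaults mirror the first sample).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(models, reference, profile, samples,
                            name = "scenario", control = list()) {
  if (is.character(models)) models <- load_models(models)
  stopifnot(inherits(models, "model_bundle"),
            inherits(profile, "genome_profile"), length(samples) >= 1L)
  for (s in samples) {
    if (is.null(s$name)) stop_validation("every scenario sample needs a name")
    cl <- s$clonality
    if (!is.null(cl)) {
      known <- unique(c(profile$cnas$clone_id, profile$pms$clone_id))
      bad <- setdiff(names(cl), known)
      if (length(bad)) {
        stop_validation(sprintf("clonality override for undeclared clone(s): %s",
                                paste(bad, collapse = ", ")))
      }
      if (any(cl < 0 | cl > 1)) {
        stop_validation("clonality overrides must lie in [0, 1]")
      }
    }
    tc <- s$tumor_content %||% 0
    if (tc < 0 || tc > 1) stop_validation("tumor_content must lie in [0, 1]")
  }
  structure(list(models = models, reference = reference, profile = profile,
                 samples = samples, name = name, control = control),
            class = "scenario_config")
}

#' Read a scenario configuration from YAML
#'
#' The YAML file carries the file-based equivalents of [scenario_config()]
#' fields: `models` (bundle path), `reference`, `snps`, `cnas`, `pms` (table
#' paths), `name`, optional `control`, and a `samples` list.
#'
#' @param path YAML file path.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  check_file_exists(path, "scenario config")
  y <- yaml::read_yaml(path)
  for (f in c("models", "reference", "samples")) {
    if (is.null(y[[f]])) stop_validation(sprintf("scenario config missing '%s'", f))
  }
  profile <- genome_profile(
    snps = if (!is.null(y$snps)) parse_snps(y$snps, y$reference),
    cnas = if (!is.null(y$cnas)) read_cna_table(y$cnas),
    pms = if (!is.null(y$pms)) read_pm_table(y$pms, y$reference),
    reference = y$reference)
  scenario_config(load_models(y$models), y$reference, profile, y$samples,
                  name = y$name %||% "scenario", control = y$control %||% list())
}

# apply per-clone clonality overrides to a profile; clones at 0 are dropped
override_clonality <- function(profile, overrides) {
  if (is.null(overrides) || !length(overrides)) return(profile)
  adj <- function(tab) {
    if (!nrow(tab)) return(tab)
    hit <- tab$clone_id %in% names(overrides)
    tab$clonality[hit] <- unname(overrides[tab$clone_id[hit]])
    tab[tab$clonality > 0, ]
  }
  genome_profile(profile$snps, adj(profile$cnas), adj(profile$pms))
}

#' Run a simulation scenario
#'
#' Generates one tumor sample per plan plus one matched control sharing the
#' phased SNPs, and tabulates expected versus observed allele fractions and
#' log2 ratios per event per sample. Expected columns come from the
#' closed-form dosage arithmetic ([locus_expectation()]), never recomputed ad
#' hoc.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory for FASTQ/truth files.
#' @param gzip Compress FASTQ outputs.
#' @return A `scenario_result`: `reports` (named list of generation reports,
#'   control first) and `summary` (tibble of per-sample, per-event expected
#'   and observed values).
#' @export
run_scenario <- function(config, out_dir, gzip = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  first <- config$samples[[1]]
  ctrl <- config$control
  ctrl_plan <- sample_plan(
    name = ctrl$name %||% paste0(config$name, "_control"),
    kind = "matched_control",
    coverage = ctrl$coverage %||% first$coverage,
    n_reads = if (is.null(ctrl$coverage %||% first$coverage)) {
      ctrl$n_reads %||% first$n_reads
    } else NULL,
    read_length = ctrl$read_length %||% first$read_length %||% 100L,
    paired = ctrl$paired %||% first$paired %||% TRUE,
    strand_bias = ctrl$strand_bias %||% 0.5,
    seed = ctrl$seed %||% 1000L)
  reports <- list()
  reports[[ctrl_plan$name]] <- generate_sample(
    config$models, config$reference, config$profile, ctrl_plan,
    file.path(out_dir, ctrl_plan$name), gzip = gzip)
  for (s in config$samples) {
    plan <- sample_plan(
      name = s$name, kind = "tumor",
      tumor_content = s$tumor_content %||% 0,
      coverage = s$coverage,
      n_reads = if (is.null(s$coverage)) s$n_reads else NULL,
      read_length = s$read_length %||% 100L,
      paired = s$paired %||% TRUE,
      strand_bias = s$strand_bias %||% 0.5,
      seed = s$seed %||% 1L)
    prof <- override_clonality(config$profile, s$clonality)
    reports[[s$name]] <- generate_sample(
      config$models, config$reference, prof, plan,
      file.path(out_dir, s$name), gzip = gzip)
  }
  summary <- purrr::imap_dfr(reports, function(rep, nm) {
    if (!nrow(rep$events)) return(NULL)
    mutate(rep$events, sample = nm, kind = rep$kind,
           tumor_content = rep$tumor_content, .before = 1)
  })
  structure(list(reports = reports, summary = summary, name = config$name),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s': %d samples, %d event observations\n",
              x$name, length(x$reports), nrow(x$summary)))
  invisible(x)
}

#' Tumor-content dilution series settings
#'
#' Convenience builder for a serial-dilution scenario: the same genome profile
#' generated at decreasing tumor content.
#'
#' @param tumor_contents Numeric vector of tumor contents.
#' @param coverage Mean coverage per sample.
#' @param seed Base seed (sample k uses `seed + k`).
#' @param ... Extra per-sample fields (`read_length`, `paired`, ...).
#' @return A list suitable as `samples` in [scenario_config()].
#' @export
dilution_samples <- function(tumor_contents, coverage, seed = 1L, ...) {
  purrr::imap(tumor_contents, function(tc, k) {
    c(list(name = sprintf("dilution_t%02.0f", tc * 100), tumor_content = tc,
           coverage = coverage, seed = seed + k), list(...))
  })
}

#' Longitudinal subclone regression/emergence settings
#'
#' Convenience builder for a temporal-sampling scenario at fixed tumor
#' content: per time point, per-clone clonality overrides describe regressing
#' and emerging subclones.
#'
#' @param clonality_by_time A list of named clonality vectors, one per time
#'   point.
#' @param tumor_content Fixed tumor content.
#' @param coverage Mean coverage per sample.
#' @param seed Base seed.
#' @param ... Extra per-sample fields.
#' @return A list suitable as `samples` in [scenario_config()].
#' @export
longitudinal_samples <- function(clonality_by_time, tumor_content, coverage,
                                 seed = 1L, ...) {
  purrr::imap(clonality_by_time, function(cl, k) {
    c(list(name = sprintf("timepoint_%d", k), tumor_content = tumor_content,
           coverage = coverage, seed = seed + k, clonality = unlist(cl)),
      list(...))
  })
}
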