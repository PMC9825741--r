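# Serialization of the reference-model bundle.
#
# A bundle is a single JSON document: a header (format version, builder
# parameters) plus flat arrays for each model, written at full numeric
# precision so that load(save(x)) reproduces every field exactly.

BUNDLE_FORMAT_VERSION <- "1.0"

#' Bundle the three reference models
#'
#' @param rdm An `rdm_model` from [build_rdm()].
#' @param qm A `quality_model` from [build_qm()].
#' @param pbe A `pbe_model` from [build_pbe()].
#' @return A `model_bundle` list with elements `rdm`, `qm`, `pbe`.
#' @export
model_bundle <- function(rdm, qm, pbe) {
  stopifnot(inherits(rdm, "rdm_model"), inherits(qm, "quality_model"),
            inherits(pbe, "pbe_model"))
  structure(list(rdm = rdm, qm = qm, pbe = pbe), class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("<model_bundle>\n")
  print(x$rdm); print(x$qm); print(x$pbe)
  invisible(x)
}

#' Save reference models to a bundle file
#'
#' @param models A [model_bundle()], or an `rdm_model` when `qm` and `pbe` are
#'   given separately.
#' @param path Output path for the JSON bundle.
#' @param qm,pbe Optional models when `models` is an `rdm_model`.
#' @return `path`, invisibly.
#' @export
save_models <- function(models, path, qm = NULL, pbe = NULL) {
  if (inherits(models, "rdm_model")) models <- model_bundle(models, qm, pbe)
  stopifnot(inherits(models, "model_bundle"))
  rdm <- models$rdm
  payload <- list(
    format_version = BUNDLE_FORMAT_VERSION,
    tool = "oncoreads",
    rdm = list(
      regions = as.list(rdm$regions),
      weights = lapply(rdm$weights, identity),
      norm = rdm$norm,
      insert_mean = rdm$insert_mean,
      insert_sd = rdm$insert_sd,
      paired = rdm$paired,
      read_length_observed = rdm$read_length_observed,
      n_source_samples = rdm$n_source_samples),
    qm = list(max_read_length = models$qm$max_read_length,
              counts = models$qm$counts),
    pbe = list(sites = as.list(models$pbe$sites),
               hq_base_quality_min = models$pbe$hq_base_quality_min,
               hq_mapping_quality_min = models$pbe$hq_mapping_quality_min,
               min_depth = models$pbe$min_depth,
               min_error_rate = models$pbe$min_error_rate)
  )
  # digits = I(17): significant-digit mode, enough for bit-exact doubles
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' Load reference models from a bundle file
#'
#' @param path Path written by [save_models()].
#' @return A [model_bundle()].
#' @export
load_models <- function(path) {
  check_file_exists(path, "model bundle")
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_bundle(sprintf("corrupt model bundle %s: %s",
                                        path, conditionMessage(e)))
                  })
  fv <- raw$format_version
  if (is.null(fv) || is.null(raw$rdm)) {
    stop_bundle(sprintf("corrupt model bundle %s: missing header fields", path))
  }
  if (!identical(substr(fv, 1, 2), substr(BUNDLE_FORMAT_VERSION, 1, 2))) {
    stop_version(sprintf("unsupported bundle format version '%s' (reader supports %s)",
                         fv, BUNDLE_FORMAT_VERSION))
  }
  r <- raw$rdm
  weights <- r$weights
  if (is.matrix(weights)) weights <- lapply(seq_len(nrow(weights)),
                                            function(i) weights[i, ])
  if (!is.list(weights)) weights <- list(as.numeric(weights))
  rdm <- new_rdm(regions = as_tibble(r$regions),
                 weights = lapply(weights, as.numeric),
                 norm = r$norm,
                 insert_mean = r$insert_mean %||% NA_real_,
                 insert_sd = r$insert_sd %||% NA_real_,
                 paired = r$paired,
                 read_length_observed = as.integer(r$read_length_observed),
                 n_source_samples = as.integer(r$n_source_samples))
  qm <- new_qm(matrix(as.numeric(raw$qm$counts), nrow = 94L))
  s <- raw$pbe$sites
  sites <- if (length(s$chrom)) {
    as_tibble(lapply(s, unlist))
  } else {
    empty_pbe_sites()
  }
  sites$pos <- as.integer(sites$pos)
  pbe <- new_pbe(sites, raw$pbe$hq_base_quality_min,
                 raw$pbe$hq_mapping_quality_min, raw$pbe$min_depth,
                 raw$pbe$min_error_rate)
  model_bundle(rdm, qm, pbe)
}
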