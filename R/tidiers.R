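# broom-style tidiers and ggplot2 autoplot methods for model and result
# objects.

#' Tidy a read-depth model into a per-position tibble
#' @param x An `rdm_model`.
#' @param ... Unused.
#' @return Tibble: `chrom`, `pos` (0-based), `weight`, `prob`.
#' @method tidy rdm_model
#' @export
tidy.rdm_model <- function(x, ...) {
  tab <- tibble(
    chrom = rep(x$regions$chrom, lengths(x$weights)),
    pos = unlist(lapply(seq_len(nrow(x$regions)), function(i) {
      seq(x$regions$start[i], x$regions$end[i] - 1L)
    })),
    weight = unlist(x$weights))
  tab$prob <- tab$weight / x$norm
  tab
}

#' @method glance rdm_model
#' @export
glance.rdm_model <- function(x, ...) {
  tibble(n_regions = nrow(x$regions), n_positions = sum(lengths(x$weights)),
         norm = x$norm, insert_mean = x$insert_mean, insert_sd = x$insert_sd,
         paired = x$paired, read_length_observed = x$read_length_observed,
         n_source_samples = x$n_source_samples)
}

#' Tidy a quality model into a per-cycle/quality tibble
#' @param x A `quality_model`.
#' @param ... Unused.
#' @return Tibble: `cycle` (1-based), `quality`, `count`, `prob`.
#' @method tidy quality_model
#' @export
tidy.quality_model <- function(x, ...) {
  probs <- qm_probs(x)
  idx <- which(x$counts > 0, arr.ind = TRUE)
  tibble(cycle = idx[, 2], quality = idx[, 1] - 1L,
         count = x$counts[idx], prob = probs[idx])
}

#' @method glance quality_model
#' @export
glance.quality_model <- function(x, ...) {
  tot <- sum(x$counts)
  tibble(max_read_length = x$max_read_length, n_bases = tot,
         mean_quality = sum((0:93) * rowSums(x$counts)) / tot)
}

#' Tidy a position-error model into its site table
#' @param x A `pbe_model`.
#' @param ... Unused.
#' @return The site tibble (`chrom`, `pos`, `error_rate`, `p_A`..`p_T`).
#' @method tidy pbe_model
#' @export
tidy.pbe_model <- function(x, ...) x$sites

#' @method glance pbe_model
#' @export
glance.pbe_model <- function(x, ...) {
  tibble(n_sites = nrow(x$sites),
         mean_error_rate = if (nrow(x$sites)) mean(x$sites$error_rate) else NA_real_,
         hq_base_quality_min = x$hq_base_quality_min,
         hq_mapping_quality_min = x$hq_mapping_quality_min,
         min_depth = x$min_depth, min_error_rate = x$min_error_rate)
}

#' Tidy a generation report into its per-event table
#' @param x A `generation_report`.
#' @param ... Unused.
#' @return Tibble of events with expected and observed allele fractions.
#' @method tidy generation_report
#' @export
tidy.generation_report <- function(x, ...) x$events

#' @method glance generation_report
#' @export
glance.generation_report <- function(x, ...) {
  tibble(sample = x$sample, kind = x$kind, tumor_content = x$tumor_content,
         n_fragments = x$n_fragments, n_records = x$n_records,
         requested_coverage = x$requested_coverage %||% NA_real_,
         realized_coverage = x$realized_coverage,
         forward_fraction = x$forward_fraction,
         insert_mean_realized = x$insert_mean_realized,
         insert_sd_realized = x$insert_sd_realized,
         read_length = x$read_length, paired = x$paired, seed = x$seed)
}

#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) x$summary

#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  purrr::map_dfr(x$reports, glance)
}

#' Plot the fragment-start weight track of a read-depth model
#' @param object An `rdm_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rdm_model
#' @export
autoplot.rdm_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$weight)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "genomic position (0-based)",
                  y = "fragment-start weight",
                  title = "Read-depth model") +
    ggplot2::theme_minimal()
}

#' Plot per-cycle base-quality distributions of a quality model
#' @param object A `quality_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quality_model
#' @export
autoplot.quality_model <- function(object, ...) {
  df <- tidy(object) |>
    group_by(.data$cycle) |>
    summarise(mean_q = sum(.data$quality * .data$prob),
              q10 = .data$quality[which.max(cumsum(.data$prob) >= 0.1)],
              q90 = .data$quality[which.max(cumsum(.data$prob) >= 0.9)],
              .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$mean_q)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q10, ymax = .data$q90),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "read cycle", y = "Phred quality",
                  title = "Quality model (mean, 10-90% band)") +
    ggplot2::theme_minimal()
}

#' Plot expected vs observed allele fractions of a generation report
#'
#' One panel per event type (heterozygous-SNP BAF, point-mutation VAF), with
#' the identity line marking perfect recovery of the closed-form expectation.
#'
#' @param object A `generation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot generation_report
#' @export
autoplot.generation_report <- function(object, ...) {
  df <- tidy(object) |> filter(!is.na(.data$observed_af))
  if (!nrow(df)) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No tracked events in report"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected_af,
                                   y = .data$observed_af)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~type) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "expected allele fraction",
                  y = "observed allele fraction",
                  title = sprintf("%s: allele-fraction recovery", object$sample)) +
    ggplot2::theme_minimal()
}

#' Plot per-sample allele-fraction trajectories of a scenario
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  df <- tidy(object) |> filter(!is.na(.data$observed_af))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$observed_af,
                                   group = .data$id, colour = .data$type)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected_af), shape = 4) +
    ggplot2::labs(x = NULL, y = "allele fraction",
                  title = sprintf("Scenario '%s': observed (lines) vs expected (crosses)",
                                  object$name)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
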