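#' Generation plan for one synthetic sample
#'
#' @param name Sample name (used in read names and file prefixes).
#' @param kind `"tumor"` or `"matched_control"`. Matched controls ignore all
#'   somatic events and are generated at tumor content 0 from the same phased
#'   SNPs.
#' @param tumor_content Fraction of tumor cells, in `[0, 1]`.
#' @param coverage Requested mean on-target depth of coverage; exactly one of
#'   `coverage` and `n_reads` must be given.
#' @param n_reads Number of fragments to emit (read pairs when paired).
#' @param read_length Read length in bases.
#' @param paired Logical; paired-end when `TRUE`.
#' @param strand_bias Probability that a fragment is emitted on the forward
#'   strand (default 0.5).
#' @param seed Integer seed; generation output is a pure function of the
#'   inputs and this seed.
#' @param insert_mean,insert_sd Optional overrides of the insert-size
#'   statistics embedded in the read-depth model.
#' @return A `sample_plan` list.
#' @export
sample_plan <- function(name = "sample",
                        kind = c("tumor", "matched_control"),
                        tumor_content = 0,
                        coverage = NULL, n_reads = NULL,
                        read_length = 100L, paired = TRUE,
                        strand_bias = 0.5, seed = 1L,
                        insert_mean = NULL, insert_sd = NULL) {
  kind <- match.arg(kind)
  if (is.null(coverage) == is.null(n_reads)) {
    stop_validation("exactly one of coverage and n_reads must be set")
  }
  if (tumor_content < 0 || tumor_content > 1) {
    stop_validation("tumor_content must lie in [0, 1]")
  }
  if (strand_bias < 0 || strand_bias > 1) {
    stop_validation("strand_bias must lie in [0, 1]")
  }
  if (read_length < 1) stop_validation("read_length must be positive")
  structure(list(name = name, kind = kind, tumor_content = tumor_content,
                 coverage = coverage, n_reads = n_reads,
                 read_length = as.integer(read_length), paired = paired,
                 strand_bias = strand_bias, seed = as.integer(seed),
                 insert_mean = insert_mean, insert_sd = insert_sd),
            class = "sample_plan")
}

#' @export
print.sample_plan <- function(x, ...) {
  cat(sprintf("<sample_plan> %s (%s), t=%.2f, %s, %s, read length %d, strand bias %.2f, seed %d\n",
              x$name, x$kind, x$tumor_content,
              if (!is.null(x$coverage)) sprintf("%gx coverage", x$coverage)
              else sprintf("%d fragments", x$n_reads),
              if (x$paired) "paired-end" else "single-end",
              x$read_length, x$strand_bias, x$seed))
  invisible(x)
}
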