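#' Genetic conservation gap: size-ratio form
#'
#' What fraction of the current collection would suffice, under random
#' sampling of the wild populations, to capture the same percentage of
#' alleles the collection holds today? Computed as the minimum sufficient
#' size of the resampling curve at a target equal to the collection's
#' measured capture, divided by the current collection size. Values well
#' below 1 mean the collection is much larger than an optimally sampled one
#' would need to be.
#'
#' @param current_capture_percent the collection's measured capture (percent).
#' @param current_n number of plants in the current collection (>= 1).
#' @param curve a `resampling_curve` for the same taxon and dataset variant.
#' @param category allele category the capture refers to (default `"all"`).
#' @return the ratio, or `NA` when the curve never attains the collection's
#'   capture level.
#' @export
gap_size_ratio <- function(current_capture_percent, current_n, curve,
                           category = "all") {
  stopifnot(current_n >= 1)
  suff <- minimum_sufficient_size(curve, current_capture_percent, category)
  if (!suff$attainable[1L]) return(NA_real_)
  suff$minimum_size[1L] / current_n
}

#' Genetic conservation gap: diversity-ratio form
#'
#' The proportional increase in capture a collection of the same size could
#' achieve under random wild sampling: the curve's mean capture at the
#' current collection size divided by the measured capture. Undefined (`NA`)
#' when the collection is larger than the genotyped wild sample, since the
#' curve's grid stops at N in situ individuals.
#'
#' @param curve a `resampling_curve`.
#' @param current_n current collection size.
#' @param current_capture_percent measured capture (percent, > 0).
#' @param category allele category (default `"all"`).
#' @return the ratio, or `NA` when `current_n` exceeds the curve grid.
#' @export
gap_diversity_ratio <- function(curve, current_n, current_capture_percent,
                                category = "all") {
  stopifnot(inherits(curve, "resampling_curve"))
  if (current_capture_percent <= 0) {
    stop("current capture must be positive", call. = FALSE)
  }
  sub <- curve[curve$category == category, , drop = FALSE]
  if (current_n > max(sub$n)) return(NA_real_)
  row <- sub[sub$n == current_n, , drop = FALSE]
  if (nrow(row) == 0L || is.na(row$mean[1L])) return(NA_real_)
  row$mean[1L] / current_capture_percent
}

#' Inflate a minimum collection size for expected attrition
#'
#' Collections lose plants: seeds fail to germinate and living plants die.
#' To keep at least `minimum_size` plants alive, collect
#' `ceiling(minimum_size / survival_rate)` propagules. E.g. a minimum size of
#' 82 with 10% seed-to-adult survival calls for 820 seeds.
#'
#' @param minimum_size integer >= 1, the target number of surviving plants.
#' @param survival_rate probability in (0, 1] of surviving to adulthood.
#' @return integer number of propagules to collect.
#' @export
attrition_adjust <- function(minimum_size, survival_rate) {
  stopifnot(minimum_size >= 1)
  if (survival_rate <= 0 || survival_rate > 1) {
    stop("survival_rate must lie in (0, 1]", call. = FALSE)
  }
  as.integer(ceiling(minimum_size / survival_rate))
}

#' Convert an allele copy count to a frequency
#'
#' In a sample of n diploid individuals there are 2n allele copies, so c
#' copies correspond to frequency c / (2n). The reduced-dataset cutoff of two
#' copies in 200 diploids is thus a frequency of 0.005.
#'
#' @param copies non-negative copy count.
#' @param n_diploid_individuals number of diploid individuals (>= 1).
#' @return the frequency, in `[0, 1]`.
#' @export
copies_to_frequency <- function(copies, n_diploid_individuals) {
  stopifnot(copies >= 0, n_diploid_individuals >= 1)
  if (any(copies > 2 * n_diploid_individuals)) {
    stop("copies exceed total allele copies (2n)", call. = FALSE)
  }
  copies / (2 * n_diploid_individuals)
}

#' Gap report for one taxon
#'
#' Bundles both printed forms of the genetic conservation gap for a taxon and
#' dataset variant. Ratios are kept at full precision; use `round(x, 2)` for
#' table-parity display and serialize `NA` as `"NA"`.
#'
#' @param taxon taxon label.
#' @param capture a `capture_summary` for the current collection.
#' @param curve the matching `resampling_curve` (same variant).
#' @param current_n_ex_situ number of genotyped collection plants.
#' @param category allele category the gap refers to (default `"all"`).
#' @return a `gap_report` data.frame (one row).
#' @export
gap_report <- function(taxon, capture, curve, current_n_ex_situ,
                       category = "all") {
  stopifnot(inherits(capture, "capture_summary"))
  pct <- capture$percent[capture$category == category]
  size_ratio <- div_ratio <- NA_real_
  if (length(pct) == 1L && !is.na(pct) && pct > 0 && current_n_ex_situ >= 1) {
    size_ratio <- gap_size_ratio(pct, current_n_ex_situ, curve, category)
    div_ratio <- gap_diversity_ratio(curve, current_n_ex_situ, pct, category)
  }
  structure(
    data.frame(taxon = taxon, variant = attr(curve, "variant"),
               category = category,
               current_n_ex_situ = as.integer(current_n_ex_situ),
               current_capture_percent = if (length(pct) == 1L) pct else NA_real_,
               size_ratio = size_ratio, diversity_ratio = div_ratio,
               stringsAsFactors = FALSE),
    class = c("gap_report", "data.frame")
  )
}
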