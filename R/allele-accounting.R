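#' Allele frequency category thresholds
#'
#' The five categories used throughout the package are defined by strict
#' inequalities on the in situ allele frequency: very common (> 0.10), common
#' (> 0.05), low frequency (< 0.10 and > 0.01), rare (< 0.01), and "all"
#' (every allele). The categories overlap: a very common allele is also
#' common, and every allele is in "all". An allele at exactly 0.10 is common
#' but neither very common nor low frequency; one at exactly 0.01 is in no
#' named band but "all".
#'
#' @param very_common_gt frequency above which an allele is very common.
#' @param common_gt frequency above which an allele is common.
#' @param low_freq_lt,low_freq_gt open interval defining low frequency.
#' @param rare_lt frequency below which an allele is rare.
#' @return a `category_thresholds` list.
#' @export
category_thresholds <- function(very_common_gt = 0.10, common_gt = 0.05,
                                low_freq_lt = 0.10, low_freq_gt = 0.01,
                                rare_lt = 0.01) {
  vals <- c(very_common_gt, common_gt, low_freq_lt, low_freq_gt, rare_lt)
  if (any(vals <= 0) || any(vals >= 1)) {
    stop("all thresholds must lie in (0, 1)", call. = FALSE)
  }
  structure(list(very_common_gt = very_common_gt, common_gt = common_gt,
                 low_freq_lt = low_freq_lt, low_freq_gt = low_freq_gt,
                 rare_lt = rare_lt),
            class = "category_thresholds")
}

#' Category labels in reporting order
#' @keywords internal
CATEGORIES <- c("all", "very_common", "common", "low_frequency", "rare")

#' Classify one allele frequency into its categories
#'
#' @param frequency a frequency in `[0, 1]`.
#' @param thresholds a [category_thresholds()] object.
#' @return character vector of every category the allele belongs to
#'   (`"all"` is always included).
#' @examples
#' classify_allele_frequency(0.15)  # all, very_common, common
#' classify_allele_frequency(0.02)  # all, low_frequency
#' @export
classify_allele_frequency <- function(frequency, thresholds = category_thresholds()) {
  stopifnot(length(frequency) == 1L, frequency >= 0, frequency <= 1)
  m <- category_membership(frequency, thresholds)
  CATEGORIES[as.logical(m[1L, ])]
}

#' Membership matrix of frequencies in the five categories
#'
#' Vectorized workhorse behind [classify_allele_frequency()].
#'
#' @param freqs numeric vector of frequencies.
#' @param thresholds a [category_thresholds()] object.
#' @return logical matrix, `length(freqs)` rows, columns
#'   `all, very_common, common, low_frequency, rare`.
#' @export
category_membership <- function(freqs, thresholds = category_thresholds()) {
  t <- thresholds
  cbind(all = rep(TRUE, length(freqs)),
        very_common = freqs > t$very_common_gt,
        common = freqs > t$common_gt,
        low_frequency = freqs < t$low_freq_lt & freqs > t$low_freq_gt,
        rare = freqs < t$rare_lt)
}

#' Tabulate alleles of a genotype matrix
#'
#' Counts every non-missing allele copy per locus and derives relative
#' frequencies. Missing genotypes are excluded from both numerator and
#' denominator, so each locus has its own denominator (non-missing copies).
#' A locus with zero non-missing copies is dropped with a warning.
#'
#' @param matrix a [genotype_matrix()].
#' @param source_filter which individuals to count: `"in_situ"` (default,
#'   the reference wild gene pool), `"ex_situ"`, or `"both"`.
#' @return an `allele_table`: a data.frame with columns `locus`, `allele`,
#'   `count`, `freq`, plus attributes `n_individuals` (filtered count) and
#'   `denominators` (named per-locus non-missing copy counts).
#' @export
tabulate_alleles <- function(matrix, source_filter = c("in_situ", "ex_situ", "both")) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  source_filter <- match.arg(source_filter)
  keep <- if (source_filter == "both") rep(TRUE, length(matrix$ids))
          else matrix$source == source_filter
  if (!any(keep)) stop("no individuals match source_filter = ", source_filter, call. = FALSE)
  al <- matrix$alleles[keep, , drop = FALSE]

  out <- vector("list", length(matrix$loci))
  denom <- integer(0)
  for (l in seq_along(matrix$loci)) {
    codes <- c(al[, 2L * l - 1L], al[, 2L * l])
    codes <- codes[!is.na(codes)]
    if (length(codes) == 0L) {
      warning("locus ", matrix$loci[l], " has no non-missing copies; dropped",
              call. = FALSE)
      next
    }
    tab <- table(codes)
    out[[l]] <- data.frame(locus = matrix$loci[l],
                           allele = as.integer(names(tab)),
                           count = as.integer(tab),
                           freq = as.integer(tab) / length(codes),
                           stringsAsFactors = FALSE)
    denom[matrix$loci[l]] <- length(codes)
  }
  tbl <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(tbl) <- NULL
  structure(tbl, n_individuals = sum(keep), denominators = denom,
            variant = "full", class = c("allele_table", "data.frame"))
}

#' Remove low-copy alleles (the reduced dataset)
#'
#' Drops alleles whose in situ copy count is at most `max_excluded_copies`.
#' The default of 2 yields the "reduced dataset" (alleles seen once or twice
#' excluded — such alleles have a low chance of persisting and may be
#' genotyping artefacts); 0 is the identity and yields the "full dataset".
#' Frequencies are deliberately not renormalized: they stay relative to the
#' original per-locus denominators, and capture ratios use allele counts, so
#' renormalization would not change any downstream result.
#'
#' @param table an `allele_table` from [tabulate_alleles()].
#' @param max_excluded_copies alleles with `count <=` this are removed.
#' @return the filtered `allele_table`; attribute `variant` becomes
#'   `"reduced"` when `max_excluded_copies` is 2, `"full"` when 0.
#' @export
apply_min_copy_filter <- function(table, max_excluded_copies = 2) {
  stopifnot(inherits(table, "allele_table"), max_excluded_copies >= 0)
  keep <- table$count > max_excluded_copies
  lost <- setdiff(unique(table$locus), unique(table$locus[keep]))
  if (length(lost) > 0L) {
    warning("all alleles removed at locus: ", paste(lost, collapse = ", "),
            call. = FALSE)
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  variant <- if (max_excluded_copies == 0) "full"
             else if (max_excluded_copies == 2) "reduced"
             else paste0("excl_le_", max_excluded_copies)
  structure(out, n_individuals = attr(table, "n_individuals"),
            denominators = attr(table, "denominators"),
            variant = variant, class = c("allele_table", "data.frame"))
}

#' Percent of wild alleles captured by an ex situ set
#'
#' An in situ allele counts as captured when it appears at least once in the
#' ex situ individuals at the same locus. Alleles found ex situ but absent
#' from the wild table are ignored (they are not conservation targets here).
#' Percentages pool alleles across loci — captured total divided by existing
#' total — per frequency category, with categories assigned from the in situ
#' frequencies and never from the collection.
#'
#' @param in_situ_table `allele_table` built from in situ individuals
#'   (optionally reduced via [apply_min_copy_filter()]).
#' @param ex_situ_matrix a [genotype_matrix()] holding the collection; all of
#'   its individuals are used regardless of their `source` flag, and it may
#'   hold zero individuals (0% capture).
#' @param thresholds a [category_thresholds()] object.
#' @return a `capture_summary` data.frame with one row per category:
#'   `category`, `n_existing`, `n_captured`, `percent` (`NA` when the
#'   category holds no alleles).
#' @export
capture_percentages <- function(in_situ_table, ex_situ_matrix,
                                thresholds = category_thresholds()) {
  stopifnot(inherits(in_situ_table, "allele_table"))
  if (nrow(in_situ_table) == 0L) stop("empty in situ allele table", call. = FALSE)
  stopifnot(inherits(ex_situ_matrix, "genotype_matrix"))

  captured <- logical(nrow(in_situ_table))
  if (length(ex_situ_matrix$ids) > 0L) {
    keys <- character(0)
    for (l in seq_along(ex_situ_matrix$loci)) {
      codes <- c(ex_situ_matrix$alleles[, 2L * l - 1L],
                 ex_situ_matrix$alleles[, 2L * l])
      codes <- codes[!is.na(codes)]
      if (length(codes) > 0L) {
        keys <- c(keys, paste(ex_situ_matrix$loci[l], unique(codes), sep = "\r"))
      }
    }
    captured <- paste(in_situ_table$locus, in_situ_table$allele, sep = "\r") %in% keys
  }

  member <- category_membership(in_situ_table$freq, thresholds)
  n_existing <- colSums(member)
  n_captured <- colSums(member & captured)
  percent <- ifelse(n_existing > 0, 100 * n_captured / n_existing, NA_real_)
  structure(
    data.frame(category = CATEGORIES, n_existing = as.integer(n_existing),
               n_captured = as.integer(n_captured), percent = percent,
               row.names = NULL, stringsAsFactors = FALSE),
    variant = attr(in_situ_table, "variant"),
    class = c("capture_summary", "data.frame")
  )
}
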