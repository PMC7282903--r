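#' Draw a random subsample of wild individuals
#'
#' Samples `n` distinct in situ individuals without replacement, pooled
#' across populations (the idealized collector who can visit every wild
#' population). Uses R's global RNG stream; call `set.seed()` for
#' reproducibility.
#'
#' @param matrix a [genotype_matrix()] with at least `n` in situ individuals.
#' @param n subsample size, `2 <= n <= N`.
#' @return character vector of `n` individual ids.
#' @export
subsample_individuals <- function(matrix, n) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  wild <- matrix$ids[matrix$source == "in_situ"]
  N <- length(wild)
  if (n < 2L || n > N) {
    stop("subsample size must satisfy 2 <= n <= ", N, " (got ", n, ")",
         call. = FALSE)
  }
  sample(wild, n)
}

#' Monte-Carlo allele-capture curve over all collection sizes
#'
#' For every potential collection size n from 2 up to the number of genotyped
#' wild individuals N, estimates the mean (and SD) percentage of in situ
#' alleles captured by a random sample of n wild individuals, per frequency
#' category, over many replicates. The in situ allele table and its category
#' assignments are computed once from the full wild dataset and frozen; each
#' replicate only asks which of those alleles the subsample carries.
#'
#' With `variant = "reduced"` the in situ table is first passed through
#' [apply_min_copy_filter()] (default: alleles in 1-2 copies excluded), which
#' changes both the allele set and the denominators.
#'
#' @param matrix a [genotype_matrix()] with at least 2 in situ individuals.
#' @param replicates Monte-Carlo replicates (study-scale default 75000;
#'   a few thousand suffice for tests).
#' @param seed integer seed, recorded in the result; `NULL` leaves the RNG
#'   stream untouched.
#' @param thresholds a [category_thresholds()] object.
#' @param variant `"full"` or `"reduced"`.
#' @param reduced_copies copy-count cutoff for the reduced variant.
#' @return a `resampling_curve`: long data.frame with columns `category`,
#'   `n`, `mean`, `sd`, and attributes `replicates`, `seed`, `variant`,
#'   `n_in_situ`, `n_alleles` (per-category allele totals).
#' @export
resample_capture_curve <- function(matrix, replicates = 75000, seed = NULL,
                                   thresholds = category_thresholds(),
                                   variant = c("full", "reduced"),
                                   reduced_copies = 2) {
  stopifnot(inherits(matrix, "genotype_matrix"), replicates >= 1)
  variant <- match.arg(variant)
  wild_idx <- which(matrix$source == "in_situ")
  N <- length(wild_idx)
  if (N < 2L) stop("need at least 2 in situ individuals", call. = FALSE)

  table <- tabulate_alleles(matrix, "in_situ")
  if (variant == "reduced") table <- apply_min_copy_filter(table, reduced_copies)
  if (nrow(table) == 0L) stop("no alleles left to resample", call. = FALSE)

  carriers <- allele_carriers(matrix, table, wild_idx)
  member <- category_membership(table$freq, thresholds)
  cats <- lapply(seq_len(ncol(member)), function(c) which(member[, c]) - 1L)

  if (!is.null(seed)) set.seed(seed)
  res <- capture_curve_kernel(carriers, cats, N, as.integer(replicates))

  grid <- 2:N
  n_alleles <- colSums(member)
  out <- vector("list", length(CATEGORIES))
  for (c in seq_along(CATEGORIES)) {
    if (n_alleles[c] == 0L) {
      mn <- rep(NA_real_, length(grid)); sdv <- rep(NA_real_, length(grid))
    } else {
      s <- res$sum[grid, c]; s2 <- res$sumsq[grid, c]
      mn <- s / replicates
      varr <- pmax(0, (s2 - s^2 / replicates) / max(1, replicates - 1))
      sdv <- sqrt(varr)
    }
    out[[c]] <- data.frame(category = CATEGORIES[c], n = grid,
                           mean = mn, sd = sdv, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out),
            replicates = as.integer(replicates), seed = seed,
            variant = variant, n_in_situ = N,
            n_alleles = stats::setNames(as.integer(n_alleles), CATEGORIES),
            class = c("resampling_curve", "data.frame"))
}

# carrier index lists (0-based, into the wild individuals) per allele-table row
allele_carriers <- function(matrix, table, wild_idx) {
  al <- matrix$alleles[wild_idx, , drop = FALSE]
  lpos <- match(table$locus, matrix$loci)
  lapply(seq_len(nrow(table)), function(r) {
    c1 <- 2L * lpos[r] - 1L
    code <- table$allele[r]
    hit <- which(al[, c1] == code | al[, c1 + 1L] == code)
    if (length(hit) == 0L) {
      stop("allele ", code, " at locus ", table$locus[r],
           " has no in situ carrier", call. = FALSE)
    }
    hit - 1L
  })
}

#' Exact expected capture under sampling without replacement
#'
#' Closed-form (hypergeometric) oracle for the Monte-Carlo engine: an allele
#' carried by m of N individuals is captured by a random subsample of n
#' individuals with probability 1 - C(N-m, n)/C(N, n); the expected percent
#' captured over a set of alleles is the mean of these probabilities times
#' 100. Kept independent of the resampling path so the two can cross-check
#' each other.
#'
#' @param carrier_counts integer vector, number of carriers per allele
#'   (each in `1..N`).
#' @param n subsample size, `0 <= n <= N`.
#' @param N number of wild individuals.
#' @return expected percent captured, a single number in `[0, 100]`.
#' @examples
#' expected_capture_oracle(1, n = 5, N = 10)  # 50
#' @export
expected_capture_oracle <- function(carrier_counts, n, N) {
  stopifnot(length(n) == 1L, length(N) == 1L, n >= 0, n <= N)
  m <- as.numeric(carrier_counts)
  if (any(m < 1) || any(m > N)) {
    stop("carrier counts must lie in 1..N", call. = FALSE)
  }
  # lchoose(N - m, n) is -Inf when n > N - m, i.e. capture is certain
  p_miss <- exp(lchoose(N - m, n) - lchoose(N, n))
  100 * mean(1 - p_miss)
}

#' Minimum sufficient collection size
#'
#' The sufficiency statistic: the first (smallest) subsample size whose mean
#' capture strictly exceeds the target percentage. When the curve never
#' crosses the target (possible for rare alleles), the size is reported as
#' not attainable (`NA`).
#'
#' @param curve a `resampling_curve` from [resample_capture_curve()].
#' @param threshold_percent target percent of alleles captured, e.g. 70 or 95.
#' @param categories which categories to report (default: all present).
#' @return a `sufficiency_result` data.frame with columns `category`,
#'   `threshold`, `minimum_size` (integer, `NA` if not attainable),
#'   `attainable`, `variant`.
#' @export
minimum_sufficient_size <- function(curve, threshold_percent,
                                    categories = unique(curve$category)) {
  stopifnot(inherits(curve, "resampling_curve"))
  rows <- lapply(categories, function(cat) {
    sub <- curve[curve$category == cat, , drop = FALSE]
    hit <- which(!is.na(sub$mean) & sub$mean > threshold_percent)
    ms <- if (length(hit) == 0L) NA_integer_ else as.integer(sub$n[min(hit)])
    data.frame(category = cat, threshold = threshold_percent,
               minimum_size = ms, attainable = !is.na(ms),
               variant = attr(curve, "variant"), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("sufficiency_result", "data.frame"))
}
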