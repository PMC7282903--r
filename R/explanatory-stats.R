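#' Pairwise Weir-Cockerham FST among populations
#'
#' Estimates multilocus theta (Weir & Cockerham 1984) for every pair of
#' populations, as the ratio of summed among-population variance components
#' (a) to summed total components (a + b + c) over all alleles and loci.
#' Theta behaves correctly with unequal sample sizes and may be slightly
#' negative when differentiation is absent; negative estimates are retained,
#' not clamped. Missing genotypes are excluded per locus, so each locus and
#' population has its own sample size.
#'
#' @param matrix a [genotype_matrix()]; individuals are grouped by their
#'   `population` label.
#' @param source_filter which individuals to use (default `"in_situ"`; the
#'   wild populations are the differentiation of interest).
#' @return an `fst_summary`: list with the symmetric pairwise `matrix`
#'   (diagonal `NA`) and scalars `mean`, `min`, `max`, `sd` over the
#'   off-diagonal pairs.
#' @references Weir BS, Cockerham CC (1984) Estimating F-statistics for the
#'   analysis of population structure. Evolution 38:1358-1370.
#' @export
pairwise_fst_matrix <- function(matrix, source_filter = "in_situ") {
  stopifnot(inherits(matrix, "genotype_matrix"))
  keep <- if (source_filter == "both") rep(TRUE, length(matrix$ids))
          else matrix$source == source_filter
  al <- matrix$alleles[keep, , drop = FALSE]
  pops <- matrix$population[keep]
  tab <- table(pops)
  usable <- names(tab)[tab >= 2L]
  if (length(usable) < length(tab)) {
    warning("dropping populations with < 2 individuals: ",
            paste(setdiff(names(tab), usable), collapse = ", "), call. = FALSE)
  }
  if (length(usable) < 2L) {
    stop("need at least 2 populations with >= 2 individuals", call. = FALSE)
  }
  k <- length(usable)
  M <- matrix(NA_real_, k, k, dimnames = list(usable, usable))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      th <- wc_theta_pair(al[pops == usable[i], , drop = FALSE],
                          al[pops == usable[j], , drop = FALSE],
                          length(matrix$loci))
      M[i, j] <- M[j, i] <- th
    }
  }
  off <- M[upper.tri(M)]
  structure(list(matrix = M, mean = mean(off), min = min(off),
                 max = max(off), sd = if (length(off) > 1L) stats::sd(off) else NA_real_),
            class = "fst_summary")
}

# Weir-Cockerham (1984) theta for two populations, ratio of sums over all
# alleles and loci. al1/al2: allele matrices (2 columns per locus).
wc_theta_pair <- function(al1, al2, n_loci) {
  r <- 2
  A <- B <- C <- 0
  for (l in seq_len(n_loci)) {
    c1 <- 2L * l - 1L; c2 <- 2L * l
    g1 <- al1[!is.na(al1[, c1]), c(c1, c2), drop = FALSE]
    g2 <- al2[!is.na(al2[, c1]), c(c1, c2), drop = FALSE]
    n1 <- nrow(g1); n2 <- nrow(g2)
    if (n1 < 1L || n2 < 1L) next
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    codes <- unique(c(g1, g2))
    for (u in codes) {
      p1 <- sum(g1 == u) / (2 * n1)
      p2 <- sum(g2 == u) / (2 * n2)
      h1 <- sum(xor(g1[, 1L] == u, g1[, 2L] == u)) / n1
      h2 <- sum(xor(g2[, 1L] == u, g2[, 2L] == u)) / n2
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
  }
  denom <- A + B + C
  if (denom == 0) return(NA_real_)
  A / denom
}

#' Lower-tail summaries of the allele frequency spectrum
#'
#' Proportion of alleles strictly below each cutoff frequency; the lower tail
#' of the spectrum reflects demographic history such as bottlenecks and is a
#' candidate predictor of minimum collection size.
#'
#' @param table an `allele_table`.
#' @param cutoffs frequencies to evaluate (default `c(0.001, 0.01, 0.05)`).
#' @return named numeric vector, one proportion in `[0, 1]` per cutoff.
#' @export
spectrum_summaries <- function(table, cutoffs = c(0.001, 0.01, 0.05)) {
  stopifnot(inherits(table, "allele_table"))
  if (nrow(table) == 0L) stop("empty allele table", call. = FALSE)
  stats::setNames(vapply(cutoffs, function(ct) mean(table$freq < ct), 0),
                  paste0("below_", cutoffs))
}

#' Regress percent captured on log collection size
#'
#' Ordinary least squares of percent captured on the natural log of the
#' number of plants — capture grows roughly logarithmically in collection
#' size, so this is the fit drawn through per-taxon (size, capture) points.
#'
#' @param n_plants positive integer vector of collection sizes, or a
#'   two-column data.frame `(n_plants, percent_captured)`.
#' @param percent_captured numeric vector of capture percentages.
#' @return a `log_fit` list: `intercept`, `slope`, `r_squared`,
#'   `adj_r_squared` (`NA` with only 2 points), `n_points`.
#' @export
log_capture_fit <- function(n_plants, percent_captured = NULL) {
  if (is.data.frame(n_plants)) {
    percent_captured <- n_plants[[2L]]
    n_plants <- n_plants[[1L]]
  }
  stopifnot(length(n_plants) == length(percent_captured))
  if (length(n_plants) < 2L) stop("need at least 2 points", call. = FALSE)
  if (any(n_plants < 1)) stop("n_plants must be >= 1", call. = FALSE)
  x <- log(n_plants)
  if (length(unique(x)) == 1L) {
    stop("all collection sizes identical: degenerate design", call. = FALSE)
  }
  fit <- stats::lm(percent_captured ~ x)
  n <- length(x)
  ssr <- sum(stats::resid(fit)^2)
  sst <- sum((percent_captured - mean(percent_captured))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  adj <- if (n > 2L) 1 - (1 - r2) * (n - 1) / (n - 2) else NA_real_
  structure(list(intercept = unname(stats::coef(fit)[1L]),
                 slope = unname(stats::coef(fit)[2L]),
                 r_squared = r2, adj_r_squared = adj, n_points = n),
            class = "log_fit")
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf("percent = %.3f + %.3f * log(n)   (adj R^2 = %s, n = %d)\n",
              x$intercept, x$slope,
              ifelse(is.na(x$adj_r_squared), "NA",
                     sprintf("%.3f", x$adj_r_squared)), x$n_points))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA from group sums of squares: F is the
#' between-group mean square over the within-group mean square, with an
#' upper-tail p-value from the F distribution. Used to test whether a
#' grouping factor (e.g. genus) explains variation in a response such as
#' diversity conserved, sufficiency size, or the conservation gap.
#'
#' @param groups named list, one numeric vector of responses per group.
#' @return list with `f`, `p`, `df_between`, `df_within`. When the
#'   within-group variance is zero but groups differ, `f` is `Inf` and `p`
#'   is 0.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups))
  groups <- groups[lengths(groups) > 0L]
  k <- length(groups)
  if (k < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  n <- length(y)
  if (n - k < 1L) stop("no residual degrees of freedom", call. = FALSE)
  gm <- mean(y)
  means <- vapply(groups, mean, 0)
  ssb <- sum(lengths(groups) * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ssb == 0 && ssw == 0) {
    stop("zero between- and within-group variance", call. = FALSE)
  }
  df1 <- k - 1L; df2 <- n - k
  if (ssw == 0) {
    return(list(f = Inf, p = 0, df_between = df1, df_within = df2))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple testing by the step-up false
#' discovery rate procedure: sort ascending, multiply by m/rank, enforce
#' monotonicity from the largest down, cap at 1, and return in the original
#' order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)          # largest first
  ranks <- m:1                              # rank of each, in that order
  adj <- pmin(1, cummin(p[o] * m / ranks))  # step-up monotone enforcement
  adj[order(o)]
}
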