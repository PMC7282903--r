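#' Construct a diploid multilocus genotype matrix
#'
#' The central container of the package: diploid genotypes for a set of
#' individuals at a common set of loci, together with each individual's
#' population label and provenance (`in_situ` for wild plants, `ex_situ` for
#' collection plants). Alleles are integer codes (e.g. microsatellite fragment
#' sizes); missing genotypes are `NA`. A half-missing genotype (one allele
#' observed, one not) is normalized to fully missing so that per-locus copy
#' counts stay even.
#'
#' @param ids character vector of unique individual identifiers.
#' @param population character vector of population labels, one per individual.
#' @param source character vector, each element `"in_situ"` or `"ex_situ"`.
#' @param alleles integer matrix with one row per individual and `2 * length(loci)`
#'   columns: the two allele slots of locus 1, then locus 2, and so on. `NA`
#'   marks a missing allele.
#' @param loci character vector of locus names.
#' @return An object of class `genotype_matrix`.
#' @examples
#' gm <- genotype_matrix(
#'   ids = c("a", "b"), population = c("p1", "p1"),
#'   source = c("in_situ", "in_situ"),
#'   alleles = matrix(c(100L, 102L, 100L, 100L), nrow = 2, byrow = TRUE),
#'   loci = "L1"
#' )
#' n_individuals(gm)
#' @export
genotype_matrix <- function(ids, population, source, alleles, loci) {
  ids <- as.character(ids)
  population <- as.character(population)
  source <- as.character(source)
  loci <- as.character(loci)
  if (!is.matrix(alleles)) alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"

  n <- length(ids)
  if (length(population) != n || length(source) != n) {
    stop("ids, population and source must have equal length", call. = FALSE)
  }
  if (nrow(alleles) != n) {
    stop("alleles must have one row per individual", call. = FALSE)
  }
  if (ncol(alleles) != 2L * length(loci)) {
    stop("alleles must have exactly two columns per locus (diploid)", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate individual id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  bad <- !source %in% c("in_situ", "ex_situ")
  if (any(bad)) {
    stop("unknown source value '", source[bad][1L],
         "' (expected in_situ or ex_situ)", call. = FALSE)
  }

  # normalize half-missing genotypes to fully missing
  if (length(loci) > 0L && n > 0L) {
    for (l in seq_along(loci)) {
      c1 <- 2L * l - 1L
      c2 <- 2L * l
      half <- xor(is.na(alleles[, c1]), is.na(alleles[, c2]))
      if (any(half)) {
        alleles[half, c(c1, c2)] <- NA_integer_
      }
    }
  }
  dimnames(alleles) <- list(ids, paste(rep(loci, each = 2L), 1:2, sep = "."))

  structure(
    list(ids = ids, population = population, source = source,
         alleles = alleles, loci = loci),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals x", length(x$loci), "loci\n")
  cat("  in situ:", sum(x$source == "in_situ"),
      " ex situ:", sum(x$source == "ex_situ"), "\n")
  cat("  populations:", paste(unique(x$population), collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals in a genotype matrix
#' @param x a `genotype_matrix`.
#' @param source optional filter: `"in_situ"`, `"ex_situ"` or `"both"`.
#' @return integer count.
#' @export
n_individuals <- function(x, source = "both") {
  stopifnot(inherits(x, "genotype_matrix"))
  if (source == "both") length(x$ids) else sum(x$source == source)
}

#' Subset a genotype matrix by individual
#'
#' @param x a `genotype_matrix`.
#' @param i index vector (logical, integer, or character ids).
#' @param ... unused.
#' @return a `genotype_matrix` with the selected individuals, same loci.
#' @export
`[.genotype_matrix` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  if (anyNA(i)) stop("unknown individual id in subset", call. = FALSE)
  genotype_matrix(x$ids[i], x$population[i], x$source[i],
                  x$alleles[i, , drop = FALSE], x$loci)
}

#' Keep only individuals from one provenance
#' @param x a `genotype_matrix`.
#' @param source `"in_situ"` or `"ex_situ"`.
#' @return a `genotype_matrix` (possibly with zero individuals).
#' @export
filter_source <- function(x, source = c("in_situ", "ex_situ")) {
  source <- match.arg(source)
  `[.genotype_matrix`(x, x$source == source)
}

#' Combine two genotype matrices over the same loci
#' @param x,y `genotype_matrix` objects with identical loci.
#' @return a `genotype_matrix` holding the individuals of both.
#' @export
bind_individuals <- function(x, y) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(y, "genotype_matrix"))
  if (!identical(x$loci, y$loci)) stop("loci differ between matrices", call. = FALSE)
  genotype_matrix(c(x$ids, y$ids), c(x$population, y$population),
                  c(x$source, y$source), rbind(x$alleles, y$alleles), x$loci)
}
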