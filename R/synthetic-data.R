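#' Specification for a synthetic microsatellite dataset
#'
#' Describes the world the generator emulates: a threatened plant taxon
#' genotyped at about 10 microsatellite loci across a handful of wild
#' populations, with moderate differentiation (FST roughly 0 to 0.3) and a
#' heavy tail of rare alleles (on the order of a fifth of alleles observed in
#' only one or two copies).
#'
#' @param n_populations number of wild populations (>= 1).
#' @param n_per_pop individuals per population (recycled to `n_populations`).
#' @param n_loci number of microsatellite loci (default 10).
#' @param n_alleles ancestral alleles per locus (default 8; microsatellites
#'   are multi-allelic).
#' @param target_fst expected differentiation among populations, in `[0, 1)`.
#' @param decay geometric-decay parameter of the ancestral frequency profile
#'   in (0, 1]; smaller values give a more uneven spectrum. Frequencies are
#'   proportional to `decay^(0:(n_alleles-1))`.
#' @param rare_tail_target desired proportion of alleles at 1-2 copies, used
#'   by [shape_rare_tail()]; `NA` to skip shaping.
#' @param seed integer RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_populations = 3, n_per_pop = 50, n_loci = 10,
                           n_alleles = 8, target_fst = 0.1, decay = 0.7,
                           rare_tail_target = NA, seed = 1) {
  stopifnot(n_populations >= 1, n_loci >= 1, target_fst >= 0, target_fst < 1,
            decay > 0, decay <= 1)
  if (n_alleles < 1) stop("need at least one allele per locus", call. = FALSE)
  n_per_pop <- rep_len(as.integer(n_per_pop), n_populations)
  if (any(n_per_pop < 1)) stop("all population sizes must be positive", call. = FALSE)
  structure(list(n_populations = as.integer(n_populations),
                 n_per_pop = n_per_pop, n_loci = as.integer(n_loci),
                 n_alleles = as.integer(n_alleles), target_fst = target_fst,
                 decay = decay, rare_tail_target = rare_tail_target,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a structured wild population dataset
#'
#' Balding-Nichols construction: each locus has ancestral frequencies from a
#' geometric profile; each population's frequencies are drawn from a
#' Dirichlet centred on the ancestral vector with concentration
#' `(1 - F) / F`, so the F parameter maps directly onto expected FST (the
#' clean recovery test for the whole pipeline). Individuals are two
#' independent allele draws per locus (Hardy-Weinberg within populations).
#' At `target_fst = 0` populations share the ancestral frequencies exactly.
#' All individuals are `in_situ`; allele codes mimic microsatellite fragment
#' sizes (100, 102, 104, ...).
#'
#' @param spec a [synthetic_spec()].
#' @return a [genotype_matrix()]; applies [shape_rare_tail()] afterwards when
#'   `spec$rare_tail_target` is set.
#' @export
generate_structured_population <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  K <- spec$n_populations
  A <- spec$n_alleles
  N <- sum(spec$n_per_pop)
  anc <- spec$decay^(0:(A - 1)); anc <- anc / sum(anc)
  codes <- 100L + 2L * (0:(A - 1))
  F <- spec$target_fst

  alleles <- matrix(NA_integer_, nrow = N, ncol = 2L * spec$n_loci)
  pop_of <- rep(seq_len(K), spec$n_per_pop)
  for (l in seq_len(spec$n_loci)) {
    for (p in seq_len(K)) {
      if (F == 0) {
        pf <- anc
      } else {
        conc <- (1 - F) / F
        g <- stats::rgamma(A, shape = anc * conc, rate = 1)
        if (sum(g) == 0) g[sample.int(A, 1L)] <- 1  # pathological underflow guard
        pf <- g / sum(g)
      }
      rows <- which(pop_of == p)
      draws <- sample(codes, 2L * length(rows), replace = TRUE, prob = pf)
      alleles[rows, 2L * l - 1L] <- draws[seq_along(rows)]
      alleles[rows, 2L * l] <- draws[length(rows) + seq_along(rows)]
    }
  }
  gm <- genotype_matrix(
    ids = paste0("pop", pop_of, "_ind", unlist(lapply(spec$n_per_pop, seq_len))),
    population = paste0("pop_", pop_of),
    source = rep("in_situ", N),
    alleles = alleles,
    loci = paste0("L", seq_len(spec$n_loci))
  )
  if (!is.na(spec$rare_tail_target)) {
    gm <- shape_rare_tail(gm, spec$rare_tail_target, seed = spec$seed + 1L)
  }
  gm
}

#' Inject a rare-allele tail into a dataset
#'
#' Empirical microsatellite datasets of threatened plants carry many alleles
#' seen only once or twice. This mutates single allele copies of well
#' represented alleles (copy count at least 4, so the donor never drops into
#' the 1-2 copy band itself) into novel private alleles until the proportion
#' of alleles at 1-2 copies is within `tol` of `rare_tail_target`, or no
#' donor remains (best effort, with a warning). Individual and locus counts
#' are never altered.
#'
#' @param matrix a [genotype_matrix()].
#' @param rare_tail_target desired proportion of alleles at 1-2 copies, in
#'   `[0, 1)`.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @param tol acceptable deviation from the target (default 0.05).
#' @return the reshaped `genotype_matrix`.
#' @export
shape_rare_tail <- function(matrix, rare_tail_target, seed = NULL, tol = 0.05) {
  stopifnot(inherits(matrix, "genotype_matrix"),
            rare_tail_target >= 0, rare_tail_target < 1)
  if (!is.null(seed)) set.seed(seed)
  al <- matrix$alleles
  n_loci <- length(matrix$loci)

  rare_prop <- function(a) {
    counts <- unlist(lapply(seq_len(n_loci), function(l) {
      codes <- c(a[, 2L * l - 1L], a[, 2L * l])
      table(codes[!is.na(codes)])
    }), use.names = FALSE)
    if (length(counts) == 0L) return(0)
    mean(counts <= 2L)
  }

  if (rare_prop(al) >= rare_tail_target) {
    # already at or above target (lowering the tail is out of scope)
    return(matrix)
  }

  # aim at the target itself: each mutation moves the proportion by far less
  # than tol, so stopping at the first crossing lands well inside the band
  next_code <- max(al, na.rm = TRUE) + 1L
  repeat {
    prop <- rare_prop(al)
    if (prop >= rare_tail_target) break
    # pick a random donor copy whose allele has >= 4 copies at its locus
    donor <- NULL
    for (l in sample.int(n_loci)) {
      cols <- c(2L * l - 1L, 2L * l)
      codes <- c(al[, cols[1L]], al[, cols[2L]])
      tab <- table(codes[!is.na(codes)])
      rich <- as.integer(names(tab)[tab >= 4L])
      if (length(rich) == 0L) next
      code <- if (length(rich) == 1L) rich else sample(rich, 1L)
      slots <- which(al[, cols[1L]] == code | al[, cols[2L]] == code)
      ind <- if (length(slots) == 1L) slots else sample(slots, 1L)
      slot <- if (al[ind, cols[1L]] == code) cols[1L] else cols[2L]
      donor <- c(ind, slot)
      break
    }
    if (is.null(donor)) {
      warning(sprintf(
        "rare-tail target %.2f not reachable (achieved %.2f): no donor allele left",
        rare_tail_target, prop), call. = FALSE)
      break
    }
    al[donor[1L], donor[2L]] <- next_code
    next_code <- next_code + 1L
  }
  genotype_matrix(matrix$ids, matrix$population, matrix$source, al, matrix$loci)
}

#' Simulate an ex situ collection from a wild dataset
#'
#' Builds a collection matrix (source `ex_situ`) by one of three acquisition
#' strategies: `random` samples n wild individuals without replacement,
#' pooled over populations (the idealized collector); `single_population`
#' samples n individuals from one randomly chosen population (geographically
#' narrow collecting); `maternal_clusters` picks mother plants and simulates
#' `cluster_size` open-pollinated offspring per mother, each offspring
#' drawing one maternal allele and one allele from the mother's population
#' frequencies per locus (many seeds per plant, few plants). The biased
#' strategies exist to demonstrate the capture penalty of non-random
#' sampling, not to model plant reproduction in detail.
#'
#' @param matrix a [genotype_matrix()] with in situ individuals.
#' @param strategy one of `"random"`, `"single_population"`,
#'   `"maternal_clusters"`.
#' @param n collection size (for `maternal_clusters`, the number of
#'   offspring; `ceiling(n / cluster_size)` mothers are drawn).
#' @param cluster_size offspring per mother (>= 1).
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return a `genotype_matrix` of n individuals, source `ex_situ`.
#' @export
simulate_ex_situ_collection <- function(matrix,
                                        strategy = c("random", "single_population",
                                                     "maternal_clusters"),
                                        n, cluster_size = 1, seed = NULL) {
  stopifnot(inherits(matrix, "genotype_matrix"), n >= 1)
  strategy <- match.arg(strategy)
  if (!is.null(seed)) set.seed(seed)
  wild <- filter_source(matrix, "in_situ")
  N <- length(wild$ids)

  as_ex_situ <- function(idx, ids = NULL, alleles = NULL, pops = NULL) {
    if (is.null(alleles)) {
      alleles <- wild$alleles[idx, , drop = FALSE]
      pops <- wild$population[idx]
      ids <- paste0("ex_", wild$ids[idx])
    }
    genotype_matrix(ids, pops, rep("ex_situ", length(ids)), alleles, wild$loci)
  }

  if (strategy == "random") {
    if (n > N) stop("n exceeds the ", N, " available wild individuals", call. = FALSE)
    return(as_ex_situ(sample.int(N, n)))
  }

  if (strategy == "single_population") {
    pop <- sample(unique(wild$population), 1L)
    members <- which(wild$population == pop)
    if (n > length(members)) {
      stop("n exceeds the ", length(members), " individuals of population ",
           pop, call. = FALSE)
    }
    return(as_ex_situ(members[sample.int(length(members), n)]))
  }

  # maternal_clusters
  stopifnot(cluster_size >= 1)
  n_mothers <- as.integer(ceiling(n / cluster_size))
  if (n_mothers > N) stop("n/cluster_size exceeds available mothers", call. = FALSE)
  mothers <- sample.int(N, n_mothers)
  # per-population, per-locus observed allele pools for the paternal draw
  n_loci <- length(wild$loci)
  out <- matrix(NA_integer_, nrow = n, ncol = 2L * n_loci)
  ids <- character(n); pops <- character(n)
  row <- 0L
  for (mi in seq_along(mothers)) {
    m <- mothers[mi]
    pool_rows <- which(wild$population == wild$population[m])
    kids <- min(cluster_size, n - row)
    for (kk in seq_len(kids)) {
      row <- row + 1L
      ids[row] <- paste0("ex_fam", mi, "_off", kk)
      pops[row] <- wild$population[m]
      for (l in seq_len(n_loci)) {
        c1 <- 2L * l - 1L
        mat_pair <- wild$alleles[m, c(c1, c1 + 1L)]
        if (is.na(mat_pair[1L])) next  # mother untyped: offspring missing
        pool <- c(wild$alleles[pool_rows, c1], wild$alleles[pool_rows, c1 + 1L])
        pool <- pool[!is.na(pool)]
        out[row, c1] <- mat_pair[sample.int(2L, 1L)]
        out[row, c1 + 1L] <- pool[sample.int(length(pool), 1L)]
      }
    }
    if (row >= n) break
  }
  as_ex_situ(NULL, ids = ids, alleles = out, pops = pops)
}
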