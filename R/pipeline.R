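#' Build an analysis configuration
#'
#' Collects everything one end-to-end run needs: the taxa (each either a
#' pair of genotype files or a [synthetic_spec()]), the Monte-Carlo effort,
#' the category thresholds, the sufficiency targets (70% after GSPC Target 9
#' and 95% as the customary research goal), which dataset variants to run,
#' and the reduced-filter copy cutoff.
#'
#' @param taxa named list; each element is either
#'   `list(in_situ = path, ex_situ = path, format = "csv"|"genepop")` or
#'   `list(synthetic = synthetic_spec(...), ex_situ_n = int,
#'   ex_situ_strategy = "random")` (`ex_situ_n = 0` for no collection).
#' @param replicates Monte-Carlo replicates per taxon (study-scale 75000).
#' @param seed master integer seed; each taxon gets its own derived stream so
#'   adding a taxon never perturbs another's numbers.
#' @param targets sufficiency targets in percent, default `c(70, 95)`.
#' @param variants dataset variants to run, subset of `c("full", "reduced")`.
#' @param reduced_copies copy cutoff of the reduced filter (default 2).
#' @param thresholds a [category_thresholds()] object.
#' @param missing_code missing cell code for CSV inputs.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(taxa, replicates = 75000, seed = 1,
                            targets = c(70, 95),
                            variants = c("full", "reduced"),
                            reduced_copies = 2,
                            thresholds = category_thresholds(),
                            missing_code = "-9/-9") {
  stopifnot(is.list(taxa), length(taxa) >= 1, !is.null(names(taxa)),
            replicates >= 1, all(targets > 0), all(targets < 100))
  variants <- match.arg(variants, c("full", "reduced"), several.ok = TRUE)
  structure(list(taxa = taxa, replicates = as.integer(replicates),
                 seed = as.integer(seed), targets = targets,
                 variants = variants, reduced_copies = reduced_copies,
                 thresholds = thresholds, missing_code = missing_code),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Mirrors [analysis_config()]: top-level keys `replicates`, `seed`,
#' `targets`, `variants`, `reduced_copies`, `missing_code`, and a `taxa`
#' mapping whose entries carry either `in_situ`/`ex_situ`/`format` paths or a
#' `synthetic` block of [synthetic_spec()] arguments.
#'
#' @param path path to a YAML file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  taxa <- lapply(y$taxa, function(tx) {
    if (!is.null(tx$synthetic)) {
      tx$synthetic <- do.call(synthetic_spec, tx$synthetic)
    }
    tx
  })
  args <- y[setdiff(names(y), "taxa")]
  args <- args[names(args) %in% names(formals(analysis_config))]
  if (!is.null(args$targets)) args$targets <- as.numeric(unlist(args$targets))
  if (!is.null(args$variants)) args$variants <- as.character(unlist(args$variants))
  do.call(analysis_config, c(list(taxa = taxa), args))
}

# derived per-taxon seed; kept below 2^31
taxon_seed <- function(master, i) as.integer((as.numeric(master) + 99991 * i) %% 2147483647)

load_taxon <- function(tx, config, seed) {
  if (!is.null(tx$synthetic)) {
    spec <- tx$synthetic
    spec$seed <- seed
    wild <- generate_structured_population(spec)
    n_ex <- if (is.null(tx$ex_situ_n)) 0L else as.integer(tx$ex_situ_n)
    if (n_ex > 0L) {
      strat <- if (is.null(tx$ex_situ_strategy)) "random" else tx$ex_situ_strategy
      ex <- simulate_ex_situ_collection(wild, strat, n_ex, seed = seed + 7L)
    } else {
      ex <- genotype_matrix(character(0), character(0), character(0),
                            matrix(integer(0), 0, 2L * length(wild$loci)),
                            wild$loci)
    }
    return(list(wild = wild, ex = ex))
  }
  fmt <- if (is.null(tx$format)) "csv" else tx$format
  read1 <- function(p, src) {
    if (fmt == "genepop") read_genepop(p, source = src)
    else read_genotype_table(p, missing_code = config$missing_code)
  }
  wild <- filter_source(read1(tx$in_situ, "in_situ"), "in_situ")
  if (!is.null(tx$ex_situ) && nzchar(tx$ex_situ)) {
    ex <- read1(tx$ex_situ, "ex_situ")
    ex$source <- rep("ex_situ", length(ex$ids))
  } else {
    ex <- genotype_matrix(character(0), character(0), character(0),
                          matrix(integer(0), 0, 2L * length(wild$loci)),
                          wild$loci)
  }
  list(wild = wild, ex = ex)
}

#' Run the full allele-capture analysis
#'
#' For every taxon and dataset variant: tabulates the wild alleles, measures
#' the collection's current capture per category, estimates the resampling
#' curve, extracts minimum sufficient sizes for each target, computes both
#' gap statistics, pairwise FST summaries (when two or more wild populations
#' are present), and spectrum summaries. Writes per-taxon curve CSVs, the
#' capture and gap tables, the sufficiency table, and a JSON manifest
#' (seed, replicates, package version) from which every number can be
#' reproduced. A failing taxon is reported and skipped; the rest still run.
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, the report bundle: per-taxon objects plus `paths` of
#'   the files written.
#' @export
run_full_analysis <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  results <- list()
  for (i in seq_along(config$taxa)) {
    name <- names(config$taxa)[i]
    seed_i <- taxon_seed(config$seed, i)
    res <- tryCatch({
      say("[", name, "] loading (seed ", seed_i, ")")
      d <- load_taxon(config$taxa[[i]], config, seed_i)
      wild_tab <- tabulate_alleles(d$wild, "in_situ")
      taxon_res <- list(n_in_situ = n_individuals(d$wild, "in_situ"),
                        n_ex_situ = length(d$ex$ids), variants = list())
      for (v in config$variants) {
        say("[", name, "] variant ", v)
        tab <- if (v == "reduced") {
          apply_min_copy_filter(wild_tab, config$reduced_copies)
        } else wild_tab
        cap <- capture_percentages(tab, d$ex, config$thresholds)
        curve <- resample_capture_curve(d$wild, config$replicates,
                                        seed = seed_i + 13L,
                                        thresholds = config$thresholds,
                                        variant = v,
                                        reduced_copies = config$reduced_copies)
        suff <- do.call(rbind, lapply(config$targets, function(t)
          minimum_sufficient_size(curve, t)))
        gap <- gap_report(name, cap, curve, length(d$ex$ids))
        taxon_res$variants[[v]] <- list(capture = cap, curve = curve,
                                        sufficiency = suff, gap = gap)
      }
      taxon_res$spectrum <- spectrum_summaries(wild_tab)
      taxon_res$fst <- tryCatch(pairwise_fst_matrix(d$wild),
                                error = function(e) NULL)
      taxon_res
    }, error = function(e) {
      warning("taxon '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    results[[name]] <- res
  }
  results <- results[!vapply(results, is.null, TRUE)]
  if (length(results) == 0L) stop("every taxon failed", call. = FALSE)

  bundle <- list(taxa = results, config = config)
  bundle$paths <- export_tables(bundle, out_dir = out_dir)
  manifest <- list(seed = config$seed, replicates = config$replicates,
                   targets = config$targets, variants = config$variants,
                   reduced_copies = config$reduced_copies,
                   taxa = names(results),
                   package_version = as.character(utils::packageVersion("allelecap")))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  bundle$paths$manifest <- mpath
  invisible(bundle)
}

fmt_na <- function(x, digits) ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))

#' Export report tables from an analysis bundle
#'
#' Writes the current-capture table (one row per taxon: collection sizes and
#' capture percent per category, reduced and full side by side, plus mean and
#' s.d. summary rows), the gap table (size and diversity ratios per variant,
#' 2 d.p., `NA` literal for undefined cells), the sufficiency table, and
#' per-taxon long-form curve files. JSON copies carry full precision.
#'
#' @param bundle the result of [run_full_analysis()].
#' @param out_dir output directory.
#' @param format `"csv"`, `"json"`, or both.
#' @return named list of file paths.
#' @export
export_tables <- function(bundle, out_dir, format = c("csv", "json")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  format <- match.arg(format, several.ok = TRUE)
  taxa <- bundle$taxa
  variants <- bundle$config$variants
  paths <- list()

  # capture table (percent per category, one column block per variant)
  cap_rows <- lapply(names(taxa), function(nm) {
    tx <- taxa[[nm]]
    row <- data.frame(taxon = nm, n_in_situ = tx$n_in_situ,
                      n_ex_situ = tx$n_ex_situ, stringsAsFactors = FALSE)
    for (v in variants) {
      cap <- tx$variants[[v]]$capture
      vals <- stats::setNames(cap$percent, paste0(cap$category, "_", v))
      row <- cbind(row, as.data.frame(as.list(vals)))
    }
    row
  })
  cap_df <- do.call(rbind, cap_rows)
  # printable copy: whole-percent cells plus mean / s.d. summary rows
  cap_out <- cap_df
  cap_out[-1L] <- lapply(cap_df[-1L], fmt_na, digits = 0)
  mean_row <- c(taxon = "mean",
                lapply(cap_df[-1L], function(x) fmt_na(mean(x, na.rm = TRUE), 0)))
  sd_row <- c(taxon = "s.d.",
              lapply(cap_df[-1L], function(x) fmt_na(stats::sd(x, na.rm = TRUE), 0)))
  cap_print <- rbind(cap_out,
                     as.data.frame(mean_row, stringsAsFactors = FALSE),
                     as.data.frame(sd_row, stringsAsFactors = FALSE))

  # gap table
  gap_rows <- lapply(names(taxa), function(nm) {
    tx <- taxa[[nm]]
    row <- data.frame(taxon = nm, stringsAsFactors = FALSE)
    for (v in variants) {
      g <- tx$variants[[v]]$gap
      row[[paste0("size_ratio_", v)]] <- g$size_ratio
      row[[paste0("diversity_ratio_", v)]] <- g$diversity_ratio
    }
    row
  })
  gap_df <- do.call(rbind, gap_rows)
  gap_mean <- data.frame(taxon = "mean", stringsAsFactors = FALSE)
  for (cn in names(gap_df)[-1L]) gap_mean[[cn]] <- mean(gap_df[[cn]], na.rm = TRUE)
  gap_print <- rbind(gap_df, gap_mean)
  gap_print[-1L] <- lapply(gap_print[-1L], fmt_na, digits = 2)

  # sufficiency table
  suff_df <- do.call(rbind, lapply(names(taxa), function(nm) {
    do.call(rbind, lapply(variants, function(v) {
      s <- taxa[[nm]]$variants[[v]]$sufficiency
      cbind(taxon = nm, s)
    }))
  }))

  if ("csv" %in% format) {
    paths$capture_csv <- file.path(out_dir, "capture_table.csv")
    utils::write.csv(cap_print, paths$capture_csv, row.names = FALSE, quote = FALSE)
    paths$gap_csv <- file.path(out_dir, "gap_table.csv")
    utils::write.csv(gap_print, paths$gap_csv, row.names = FALSE, quote = FALSE)
    paths$sufficiency_csv <- file.path(out_dir, "sufficiency_table.csv")
    utils::write.csv(suff_df, paths$sufficiency_csv, row.names = FALSE, quote = FALSE)
    for (nm in names(taxa)) {
      for (v in variants) {
        curve <- taxa[[nm]]$variants[[v]]$curve
        cdf <- cbind(taxon = nm, variant = v, as.data.frame(curve),
                     replicates = attr(curve, "replicates"),
                     seed = attr(curve, "seed"))
        p <- file.path(out_dir, paste0("curve_", nm, "_", v, ".csv"))
        utils::write.csv(cdf, p, row.names = FALSE, quote = FALSE)
        paths[[paste0("curve_", nm, "_", v)]] <- p
      }
    }
  }
  if ("json" %in% format) {
    paths$capture_json <- file.path(out_dir, "capture_table.json")
    jsonlite::write_json(cap_df, paths$capture_json, auto_unbox = TRUE,
                         digits = NA, na = "null")
    paths$gap_json <- file.path(out_dir, "gap_table.json")
    jsonlite::write_json(gap_df, paths$gap_json, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  paths
}
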