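#' Read a genotype table from CSV
#'
#' Reads the package's CSV dialect: a header row `id,population,source`
#' followed by one column per locus, cells holding the two allele codes as
#' `"a/b"` (e.g. `"100/102"`). A cell equal to `missing_code` is a missing
#' genotype.
#'
#' @param path path to a CSV file.
#' @param missing_code cell value marking a missing genotype (default `"-9/-9"`).
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, missing_code = "-9/-9") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("id", "population", "source")
  if (length(names(df)) < 3L || !identical(names(df)[1:3], need)) {
    stop("header must begin with id,population,source", call. = FALSE)
  }
  loci <- names(df)[-(1:3)]
  n <- nrow(df)
  alleles <- matrix(NA_integer_, nrow = n, ncol = 2L * length(loci))
  for (l in seq_along(loci)) {
    cells <- df[[loci[l]]]
    miss <- cells == missing_code
    parts <- strsplit(cells, "/", fixed = TRUE)
    for (i in seq_len(n)) {
      if (miss[i]) next
      p <- suppressWarnings(as.integer(parts[[i]]))
      if (length(p) != 2L || anyNA(p)) {
        stop(sprintf("malformed allele pair '%s' at row %d, column '%s'",
                     cells[i], i, loci[l]), call. = FALSE)
      }
      alleles[i, c(2L * l - 1L, 2L * l)] <- p
    }
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate id '", df$id[duplicated(df$id)][1L], "' at row ",
         which(duplicated(df$id))[1L], call. = FALSE)
  }
  bad <- !df$source %in% c("in_situ", "ex_situ")
  if (any(bad)) {
    stop("unknown source value '", df$source[bad][1L], "' at row ",
         which(bad)[1L], ", column 'source'", call. = FALSE)
  }
  genotype_matrix(df$id, df$population, df$source, alleles, loci)
}

#' Write a genotype matrix as CSV
#'
#' Inverse of [read_genotype_table()]: columns `id,population,source` then one
#' column per locus with `"a/b"` cells and `"-9/-9"` for missing genotypes.
#' Row and column order follow the matrix, so write-then-read is the identity.
#'
#' @param matrix a [genotype_matrix()].
#' @param path output file path.
#' @param missing_code cell value for missing genotypes.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(matrix, path, missing_code = "-9/-9") {
  stopifnot(inherits(matrix, "genotype_matrix"))
  df <- data.frame(id = matrix$ids, population = matrix$population,
                   source = matrix$source, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (l in seq_along(matrix$loci)) {
    a1 <- matrix$alleles[, 2L * l - 1L]
    a2 <- matrix$alleles[, 2L * l]
    cell <- ifelse(is.na(a1), missing_code, paste0(a1, "/", a2))
    df[[matrix$loci[l]]] <- cell
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GenePop file
#'
#' Parses the standard GenePop text format (2- or 3-digit allele coding).
#' Populations are taken from `POP` blocks and labelled `pop_1 .. pop_k` in
#' block order unless `pop_labels` is given. GenePop carries no wild/collection
#' flag, so `source` defaults to `"in_situ"` (the wild dataset is the
#' resampling substrate); override with `source`.
#'
#' @param path path to a GenePop file.
#' @param digits 2 or 3: digits per allele in the concatenated genotype codes.
#' @param pop_labels optional character vector of labels, one per POP block.
#' @param source provenance assigned to all individuals.
#' @return a [genotype_matrix()].
#' @export
read_genepop <- function(path, digits = 3, pop_labels = NULL,
                         source = "in_situ") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("truncated GenePop file", call. = FALSE)
  body <- lines[-1L]  # first line is a free-text title
  pop_rows <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_rows) == 0L) stop("no POP block found", call. = FALSE)

  # locus names: everything before the first POP, one per line or comma-separated
  locus_lines <- body[seq_len(pop_rows[1L] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("no locus names before first POP", call. = FALSE)

  k <- length(pop_rows)
  if (is.null(pop_labels)) pop_labels <- paste0("pop_", seq_len(k))
  if (length(pop_labels) != k) stop("pop_labels must match POP block count", call. = FALSE)

  ids <- character(0); pops <- character(0)
  rows <- list()
  bounds <- c(pop_rows, length(body) + 1L)
  for (b in seq_len(k)) {
    block <- body[seq(bounds[b] + 1L, bounds[b + 1L] - 1L)]
    block <- block[!grepl("^\\s*pop\\s*$", block, ignore.case = TRUE)]
    for (line in block) {
      halves <- strsplit(line, ",", fixed = TRUE)[[1L]]
      if (length(halves) < 2L) stop("GenePop line lacks 'id , genotypes': ", line, call. = FALSE)
      id <- trimws(halves[1L])
      geno <- strsplit(trimws(paste(halves[-1L], collapse = ",")), "\\s+")[[1L]]
      if (length(geno) != length(loci)) {
        stop("individual '", id, "' has ", length(geno), " genotypes for ",
             length(loci), " loci", call. = FALSE)
      }
      row <- integer(2L * length(loci))
      for (l in seq_along(geno)) {
        g <- geno[l]
        if (nchar(g) != 2L * digits) {
          stop("odd-length allele string '", g, "' for individual '", id,
               "' at locus ", loci[l], call. = FALSE)
        }
        a1 <- as.integer(substr(g, 1L, digits))
        a2 <- as.integer(substr(g, digits + 1L, 2L * digits))
        if (a1 == 0L || a2 == 0L) { a1 <- NA_integer_; a2 <- NA_integer_ }
        row[c(2L * l - 1L, 2L * l)] <- c(a1, a2)
      }
      ids <- c(ids, id); pops <- c(pops, pop_labels[b])
      rows[[length(rows) + 1L]] <- row
    }
  }
  alleles <- do.call(rbind, rows)
  # GenePop ids are frequently reused across populations; disambiguate
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  genotype_matrix(ids, pops, rep(source, length(ids)), alleles, loci)
}

#' Write a genotype matrix in GenePop format
#'
#' Individuals are grouped into POP blocks by population label (first
#' appearance order). Missing genotypes become all-zero codes.
#'
#' @param matrix a [genotype_matrix()].
#' @param path output file path.
#' @param digits 2 or 3 digits per allele; codes must fit.
#' @param title first line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(matrix, path, digits = 3, title = "allelecap export") {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3", call. = FALSE)
  maxcode <- suppressWarnings(max(matrix$alleles, na.rm = TRUE))
  if (is.finite(maxcode) && maxcode >= 10^digits) {
    stop("allele codes do not fit in ", digits, " digits", call. = FALSE)
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(title, matrix$loci), con)
  fmt <- function(a) ifelse(is.na(a), strrep("0", digits),
                            formatC(a, width = digits, flag = "0"))
  for (p in unique(matrix$population)) {
    writeLines("POP", con)
    for (i in which(matrix$population == p)) {
      g <- character(length(matrix$loci))
      for (l in seq_along(matrix$loci)) {
        g[l] <- paste0(fmt(matrix$alleles[i, 2L * l - 1L]),
                       fmt(matrix$alleles[i, 2L * l]))
      }
      writeLines(paste0(matrix$ids[i], " ,  ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}
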