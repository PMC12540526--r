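#' Read a FASTA file
#'
#' Minimal strict FASTA reader. Identifiers are preserved verbatim (the full
#' header line after `>`); sequences are uppercased and RNA `U` is mapped to
#' `T`. Malformed input is rejected with the offending line number rather
#' than silently coerced, and duplicate identifiers are an error, because a
#' haplotype library must index uniquely by name.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences; names are the record ids.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) ts_stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) ts_stop("FASTA parse error: empty file: ", path)
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  buf <- character(0)
  flush <- function() {
    if (!is.null(cur)) {
      seqs[[length(seqs) + 1L]] <<- paste0(buf, collapse = "")
      ids[[length(ids) + 1L]] <<- cur
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      id <- sub("^>", "", ln)
      if (!nzchar(trimws(id)))
        ts_stop("FASTA parse error: empty header at line ", i)
      flush()
      cur <- id
      buf <- character(0)
    } else {
      if (is.null(cur))
        ts_stop("FASTA parse error: sequence before any header at line ", i)
      sq <- gsub("\\s", "", ln)
      if (grepl("[^ACGTUNacgtun-]", sq))
        ts_stop("FASTA parse error: invalid sequence character at line ", i)
      buf[[length(buf) + 1L]] <- sq
    }
  }
  flush()
  if (length(ids) == 0L) ts_stop("FASTA parse error: no records in ", path)
  if (anyDuplicated(ids))
    ts_stop("FASTA parse error: duplicate id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("U", "T", toupper(seqs))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    ts_stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    ts_stop("duplicate sequence ids")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nzchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read a haplotype reference library
#'
#' The library is a CSV with columns `name`, `marker`, `accession`,
#' `sequence` (sequence may be empty for mtSTR records, whose identity is
#' the repeat-count string). For extended D-loop records the parent short
#' haplotype name is derived by stripping the `.k` suffix, following the
#' ACCSTR convention in which `CM-A8.1` and `CM-A8.3` are extended variants
#' of the short haplotype `CM-A8`.
#'
#' @param path path to the library CSV.
#' @param short_length length of the short D-loop window (default 486).
#' @return a data frame of class `haplotype_library` with columns
#'   `name`, `marker`, `accession`, `sequence`, `parent_short_name`.
#' @export
read_haplotype_library <- function(path, short_length = 486L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("name", "marker", "accession")
  if (!all(need %in% names(df)))
    ts_stop("library must have columns name, marker, accession")
  if (is.null(df$sequence)) df$sequence <- ""
  df$sequence[is.na(df$sequence)] <- ""
  df$sequence <- toupper(chartr("U", "T", df$sequence))
  ok_marker <- c("short_dloop", "extended_dloop", "mtstr")
  if (any(!df$marker %in% ok_marker))
    ts_stop("unknown marker value(s): ",
            paste(setdiff(unique(df$marker), ok_marker), collapse = ", "))
  if (any(!nzchar(df$name))) ts_stop("library record with empty name")
  key <- paste(df$marker, df$name)
  if (anyDuplicated(key))
    ts_stop("duplicate (marker, name) in library: ",
            paste(unique(key[duplicated(key)]), collapse = "; "))
  bad <- grepl("[^ACGTN-]", df$sequence)
  if (any(bad))
    ts_stop("invalid sequence characters for record(s): ",
            paste(df$name[bad], collapse = ", "))
  ext <- df$marker == "extended_dloop"
  short_seq <- nchar(df$sequence) < short_length
  if (any(ext & short_seq))
    ts_stop("extended record(s) shorter than the short window (",
            short_length, " bp): ",
            paste(df$name[ext & short_seq], collapse = ", "))
  df$parent_short_name <- ifelse(df$marker == "extended_dloop",
                                 derive_short_name(df$name), df$name)
  class(df) <- c("haplotype_library", "data.frame")
  df
}

#' Construct a population-by-haplotype frequency table
#'
#' The central tabular container: an integer count matrix with populations
#' as rows and haplotypes as columns, tagged with the marker system the
#' haplotype ids belong to.
#'
#' @param counts integer matrix, rows = populations, columns = haplotypes,
#'   with dimnames set.
#' @param marker one of `"short"`, `"extended"`, `"mtstr"`, `"combined"`.
#' @param drop_empty drop all-zero haplotype columns (default TRUE).
#' @return an object of class `frequency_table`.
#' @export
frequency_table <- function(counts, marker = c("short", "extended", "mtstr",
                                               "combined"),
                            drop_empty = TRUE) {
  marker <- match.arg(marker)
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    ts_stop("counts must have population rownames and haplotype colnames")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    ts_stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  if (drop_empty && ncol(counts) > 0) {
    keep <- colSums(counts) > 0
    counts <- counts[, keep, drop = FALSE]
  }
  structure(list(counts = counts, marker = marker),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("frequency_table [%s]: %d populations x %d haplotypes, n = %d\n",
              x$marker, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Population sample sizes of a frequency table
#' @param table a `frequency_table`.
#' @return named integer vector of row sums.
#' @export
sample_sizes <- function(table) {
  stopifnot(inherits(table, "frequency_table"))
  stats::setNames(as.integer(rowSums(table$counts)),
                  rownames(table$counts))
}

#' Read a frequency table from CSV
#'
#' Layout: first column holds haplotype ids, remaining columns one
#' population each (so the CSV is the transpose of the internal matrix,
#' matching how published haplotype tables are printed).
#'
#' @param path CSV path.
#' @param marker marker system of the haplotype ids.
#' @return a `frequency_table`.
#' @seealso [write_frequency_table()]
#' @export
read_frequency_table <- function(path, marker = c("short", "extended",
                                                  "mtstr", "combined")) {
  marker <- match.arg(marker)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    ts_stop("frequency table must have >= 1 haplotype row and >= 1 population column")
  haps <- as.character(df[[1]])
  if (anyDuplicated(haps)) ts_stop("duplicate haplotype ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      ts_stop(sprintf(
        "invalid count at haplotype '%s', population '%s' in %s",
        haps[bad[1]], colnames(m)[j], path))
  }
  mm <- matrix(as.integer(m), nrow = nrow(m),
               dimnames = list(haps, colnames(m)))
  frequency_table(t(mm), marker = marker, drop_empty = FALSE)
}

#' Write a frequency table to CSV
#'
#' Inverse of [read_frequency_table()]: haplotypes as rows, populations as
#' columns. Writing then reading returns an identical table.
#'
#' @param table a `frequency_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  stopifnot(inherits(table, "frequency_table"))
  m <- t(table$counts)
  df <- data.frame(haplotype = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse a frequency table's haplotype columns by a grouping
#'
#' Sums columns that share a group label (e.g. extended haplotypes collapsed
#' to their parent short haplotype, or combined haplotypes to their extended
#' component). Total counts are conserved.
#'
#' @param table a `frequency_table`.
#' @param groups character vector, one group label per haplotype column of
#'   `table`; defaults to [derive_short_name()] of the column names.
#' @param marker marker label for the collapsed table.
#' @return a `frequency_table` with one column per group.
#' @export
collapse_haplotypes <- function(table, groups = NULL, marker = "short") {
  stopifnot(inherits(table, "frequency_table"))
  if (is.null(groups)) groups <- derive_short_name(colnames(table$counts))
  if (length(groups) != ncol(table$counts))
    ts_stop("'groups' must have one label per haplotype column")
  g <- factor(groups, levels = unique(groups))
  collapsed <- t(rowsum(t(table$counts), g))
  colnames(collapsed) <- levels(g)
  frequency_table(collapsed, marker = marker, drop_empty = FALSE)
}

#' Read population metadata
#'
#' CSV with columns `abbrev`, `full_name`, `role` (rookery or foraging),
#' `msa_group`, `nester_abundance`, `region`. Abundance (number of nesting
#' females) may be empty for foraging grounds; it is required only when a
#' rookery participates in a size-weighted mixed-stock prior.
#'
#' @param path CSV path.
#' @return data frame of class `population_meta`.
#' @export
read_population_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("abbrev", "full_name", "role", "msa_group")
  if (!all(need %in% names(df)))
    ts_stop("population metadata must have columns: ",
            paste(need, collapse = ", "))
  if (anyDuplicated(df$abbrev))
    ts_stop("duplicate population abbrev(s): ",
            paste(unique(df$abbrev[duplicated(df$abbrev)]), collapse = ", "))
  bad <- !df$role %in% c("rookery", "foraging")
  if (any(bad))
    ts_stop("unknown role label(s): ",
            paste(unique(df$role[bad]), collapse = ", "),
            " (expected 'rookery' or 'foraging')")
  if (is.null(df$nester_abundance)) df$nester_abundance <- NA_real_
  df$nester_abundance <- suppressWarnings(as.numeric(df$nester_abundance))
  if (any(!is.na(df$nester_abundance) & df$nester_abundance < 0))
    ts_stop("nester_abundance must be nonnegative")
  if (is.null(df$region)) df$region <- ""
  class(df) <- c("population_meta", "data.frame")
  df
}
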