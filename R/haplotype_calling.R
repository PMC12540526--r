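#' Derive the short D-loop haplotype name from an extended name
#'
#' Extended (~738 bp) haplotype names carry a `.k` suffix distinguishing
#' variants of one short (~486 bp) haplotype family: `CM-A8.1` and `CM-A8.3`
#' are both variants of `CM-A8`. Names are otherwise opaque strings.
#'
#' @param extended_name character vector of haplotype names.
#' @return character vector of parent short names.
#' @examples
#' derive_short_name(c("CM-A8.3", "CM-A8", "CM-A45.1"))
#' @export
derive_short_name <- function(extended_name) {
  if (any(is.na(extended_name) | !nzchar(extended_name)))
    ts_stop("empty haplotype name")
  sub("\\.[0-9]+$", "", extended_name)
}

#' Default window specification for D-loop truncation
#'
#' The extended D-loop fragment analysed is ~738 bp and contains the legacy
#' ~486 bp short fragment as its leading window.
#'
#' @param short_length short window length in bases.
#' @param extended_length extended window length in bases.
#' @return a list with elements `short_length`, `extended_length`.
#' @export
window_spec <- function(short_length = 486L, extended_length = 738L) {
  short_length <- as.integer(short_length)
  extended_length <- as.integer(extended_length)
  if (short_length >= extended_length)
    ts_stop("short window must be strictly contained in the extended window")
  list(short_length = short_length, extended_length = extended_length)
}

#' Majority-rule consensus of the extended D-loop library records
#'
#' Used as the anchoring reference for sliding-window alignment of queries.
#'
#' @param library a `haplotype_library` with `extended_dloop` records.
#' @param width window width (default: extended window, 738).
#' @return consensus sequence string of length `width`.
#' @export
dloop_consensus <- function(library, width = 738L) {
  ext <- library[library$marker == "extended_dloop", , drop = FALSE]
  if (nrow(ext) == 0L) ts_stop("library contains no extended_dloop records")
  mats <- vapply(ext$sequence,
                 function(s) strsplit(substr(s, 1L, width), "")[[1]],
                 character(width))
  paste0(apply(matrix(mats, nrow = width), 1, function(col) {
    names(which.max(table(col)))
  }), collapse = "")
}

#' Truncate a D-loop read and match it against a haplotype library
#'
#' Positions the query by best ungapped sliding-window alignment to the
#' majority consensus of the extended library records, cuts it to the
#' extended window from the alignment start, and looks for an exact match
#' (case-insensitive). Haplotypes are defined by exact sequence identity, so
#' no mismatch tolerance is applied; a query matching no record is flagged
#' `novel_candidate` and the closest record with its mismatch count is
#' reported.
#'
#' @param sequence query nucleotide string (an assembled read, typically
#'   longer than the extended window).
#' @param library a `haplotype_library` containing `extended_dloop` records.
#' @param spec a [window_spec()].
#' @param consensus optional precomputed library consensus (from
#'   [dloop_consensus()]); avoids recomputation when calling a whole cohort.
#' @return a list with elements `extended_hap`, `short_hap`, `flags`
#'   (character vector), `closest`, `mismatches`, `offset`.
#' @export
truncate_and_match_dloop <- function(sequence, library, spec = window_spec(),
                                     consensus = NULL) {
  stopifnot(inherits(library, "haplotype_library"))
  ext <- library[library$marker == "extended_dloop", , drop = FALSE]
  if (nrow(ext) == 0L) ts_stop("library contains no extended_dloop records")
  q <- toupper(chartr("U", "T", sequence))
  res <- list(extended_hap = NA_character_, short_hap = NA_character_,
              flags = character(0), closest = NA_character_,
              mismatches = NA_integer_, offset = NA_integer_)
  if (nchar(q) < spec$short_length) {
    res$flags <- "dloop_failed"
    return(res)
  }
  W <- min(nchar(q), spec$extended_length)
  cons <- if (is.null(consensus)) dloop_consensus(library, W)
          else substr(consensus, 1L, W)
  qv <- charToRaw(q)
  cv <- charToRaw(cons)
  offsets <- 0:(nchar(q) - W)
  scores <- vapply(offsets, function(o) sum(qv[(o + 1):(o + W)] == cv),
                   integer(1))
  off <- offsets[which.max(scores)]
  window <- substr(q, off + 1L, off + W)
  res$offset <- off + 1L
  lib_win <- substr(ext$sequence, 1L, W)
  hit <- which(lib_win == window)
  if (W == spec$extended_length && length(hit) >= 1L) {
    res$extended_hap <- ext$name[hit[1L]]
    res$short_hap <- ext$parent_short_name[hit[1L]]
    res$mismatches <- 0L
    res$closest <- ext$name[hit[1L]]
    return(res)
  }
  # no exact extended match (or query too short for the full window):
  # report the closest record, and fall back to an exact short-window match
  wv <- charToRaw(window)
  mm <- vapply(lib_win, function(s) sum(charToRaw(s) != wv), integer(1))
  best <- which.min(mm)
  res$closest <- ext$name[best]
  res$mismatches <- as.integer(mm[best])
  res$flags <- "novel_candidate"
  short_win <- substr(window, 1L, spec$short_length)
  lib_short <- substr(ext$sequence, 1L, spec$short_length)
  shit <- which(lib_short == short_win)
  if (length(shit) >= 1L) {
    parents <- unique(ext$parent_short_name[shit])
    if (length(parents) == 1L) res$short_hap <- parents
  }
  res
}

#' Default mtSTR locus anchors
#'
#' The four AT-repeat loci are located by flanking anchor motifs, which are
#' configuration rather than code: the motifs differ between reference
#' systems. These defaults are the motifs used by the package's synthetic
#' sequence builder; for real data supply the motifs of your amplicon.
#'
#' @return character vector of four anchor motifs.
#' @export
default_mtstr_anchors <- function() {
  c("CGGTCCGC", "GGCACGGC", "CCGTTCGG", "GCCGGTCC")
}

#' Count AT repeats at the four mtSTR loci
#'
#' mtSTR haplotypes are designated by the number of `AT` dinucleotide units
#' at four loci, written `r1-r2-r3-r4` (e.g. `7-12-4-4`). Each locus is
#' located by its flanking anchor motif (searched in order) and the maximal
#' run of consecutive `AT` units immediately following the anchor is
#' counted.
#'
#' @param sequence mtSTR region nucleotide string.
#' @param locus_anchors character vector of four anchor motifs.
#' @return an object of class `mtstr_profile`: list with `repeats`
#'   (integer[4] or NA), `haplotype` (`"r1-r2-r3-r4"` or NA), `status`
#'   (`"clear"` or `"unidentified"`), `flags`.
#' @export
call_mtstr <- function(sequence, locus_anchors = default_mtstr_anchors()) {
  if (length(locus_anchors) != 4L) ts_stop("exactly four locus anchors required")
  q <- toupper(chartr("U", "T", sequence))
  repeats <- integer(4)
  pos <- 1L
  for (i in 1:4) {
    hit <- regexpr(locus_anchors[i], substr(q, pos, nchar(q)), fixed = TRUE)
    if (hit == -1L) {
      return(structure(list(repeats = rep(NA_integer_, 4),
                            haplotype = NA_character_,
                            status = "unidentified",
                            flags = "mtstr_unidentified"),
                       class = "mtstr_profile"))
    }
    start <- pos + as.integer(hit) - 1L + nchar(locus_anchors[i])
    r <- 0L
    while (substr(q, start + 2L * r, start + 2L * r + 1L) == "AT") r <- r + 1L
    if (r == 0L)
      ts_stop("zero AT repeats after anchor ", i,
              ": corrupt anchor specification")
    repeats[i] <- r
    pos <- start + 2L * r
  }
  structure(list(repeats = repeats,
                 haplotype = paste(repeats, collapse = "-"),
                 status = "clear", flags = character(0)),
            class = "mtstr_profile")
}

#' @export
print.mtstr_profile <- function(x, ...) {
  cat("mtstr_profile:", if (is.na(x$haplotype)) x$status else x$haplotype, "\n")
  invisible(x)
}

#' Warn about variation at loci expected to be fixed
#'
#' Ascension-type data vary only at the first two repeat loci, with loci 3
#' and 4 fixed at 4 units; a departure usually signals a miscounted locus.
#'
#' @param profile an `mtstr_profile`.
#' @param fixed expected repeat count per locus (NA = unconstrained).
#' @return `profile`, invisibly; warns on departure.
#' @export
validate_mtstr <- function(profile, fixed = c(NA, NA, 4L, 4L)) {
  stopifnot(inherits(profile, "mtstr_profile"))
  if (profile$status == "clear") {
    bad <- which(!is.na(fixed) & profile$repeats != fixed)
    if (length(bad))
      ts_warn("mtSTR locus ", paste(bad, collapse = ","),
              " departs from the expected fixed repeat count")
  }
  invisible(profile)
}

#' Resolve mtSTR heteroplasmy from per-locus variant intensities
#'
#' Heteroplasmic individuals carry two repeat-count variants at one or more
#' loci. The haplotype is taken from the dominant signal: at every locus
#' with multiple candidate calls, the variant with the largest intensity
#' fraction is accepted if that fraction reaches `dominance_threshold`
#' (boundary counts as dominant); otherwise the profile is `unclear` and
#' the sample is excluded from mtSTR-based tables.
#'
#' @param locus_variants list of four data frames (or lists) with elements
#'   `repeat_count` and `fraction`.
#' @param dominance_threshold minimum intensity fraction of the dominant
#'   variant (default 0.6).
#' @return an `mtstr_profile` with `status` `"clear"` or `"unclear"`.
#' @export
resolve_heteroplasmy <- function(locus_variants, dominance_threshold = 0.6) {
  check_prob(dominance_threshold, "dominance_threshold", open = TRUE)
  if (length(locus_variants) != 4L)
    ts_stop("locus_variants must describe four loci")
  repeats <- integer(4)
  unclear <- FALSE
  for (i in 1:4) {
    lv <- as.data.frame(locus_variants[[i]])
    if (nrow(lv) == 0L) ts_stop("empty candidate list at locus ", i)
    if (sum(lv$fraction) > 1 + 1e-6)
      ts_stop("intensity fractions at locus ", i, " sum to more than 1")
    top <- which.max(lv$fraction)
    if (nrow(lv) > 1L && lv$fraction[top] < dominance_threshold)
      unclear <- TRUE
    repeats[i] <- as.integer(lv$repeat_count[top])
  }
  if (unclear) {
    structure(list(repeats = rep(NA_integer_, 4), haplotype = NA_character_,
                   status = "unclear", flags = "heteroplasmy_unclear"),
              class = "mtstr_profile")
  } else {
    structure(list(repeats = repeats,
                   haplotype = paste(repeats, collapse = "-"),
                   status = "clear", flags = character(0)),
              class = "mtstr_profile")
  }
}

#' Combine an extended D-loop haplotype with an mtSTR haplotype
#'
#' The combined haplotype id is `"EXTENDED/r1-r2-r3-r4"`, e.g.
#' `"CM-A8.1/7-12-4-4"`. If either component is missing or unresolved no
#' combined call is made.
#'
#' @param extended_hap extended haplotype name or NA.
#' @param mtstr an `mtstr_profile` or an `"r1-r2-r3-r4"` string or NA.
#' @return combined haplotype string, or `NA_character_`.
#' @export
combine_haplotypes <- function(extended_hap, mtstr) {
  ms <- if (inherits(mtstr, "mtstr_profile")) {
    if (identical(mtstr$status, "clear")) mtstr$haplotype else NA_character_
  } else {
    as.character(mtstr)
  }
  if (is.na(extended_hap) || !nzchar(extended_hap) || is.na(ms) || !nzchar(ms))
    return(NA_character_)
  if (!grepl("^[0-9]+-[0-9]+-[0-9]+-[0-9]+$", ms))
    ts_stop("mtSTR haplotype must match the pattern int-int-int-int")
  paste0(extended_hap, "/", ms)
}

#' Split combined haplotype ids into their components
#'
#' @param combined character vector of `"EXTENDED/r1-r2-r3-r4"` ids.
#' @return data frame with columns `extended`, `mtstr`, `parent_short`.
#' @export
split_combined <- function(combined) {
  parts <- strsplit(combined, "/", fixed = TRUE)
  ext <- vapply(parts, `[`, character(1), 1L)
  ms <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
               character(1))
  data.frame(extended = ext, mtstr = ms,
             parent_short = derive_short_name(ext),
             stringsAsFactors = FALSE)
}

#' Tabulate per-sample haplotype calls into a frequency table
#'
#' Counts calls for the requested marker by a grouping column, reporting
#' excluded (unassigned) samples separately with their reasons so the
#' bookkeeping always reconstructs the input size exactly.
#'
#' @param calls a data frame of per-sample calls with columns `sample_id`,
#'   a grouping column, `short_hap`, `extended_hap`, `mtstr_hap`,
#'   `combined_hap` and `flags` (semicolon-joined strings).
#' @param group_by name of the grouping column (default `"population"`).
#' @param marker which haplotype system to tabulate.
#' @return a list of class `tabulation`: `table` (a `frequency_table`),
#'   `excluded` (data frame reason/n), `n_total`, `n_assigned`.
#' @export
tabulate_calls <- function(calls, group_by = "population",
                           marker = c("short", "extended", "mtstr",
                                      "combined")) {
  marker <- match.arg(marker)
  if (!group_by %in% names(calls))
    ts_stop("unknown group label: ", group_by)
  col <- switch(marker, short = "short_hap", extended = "extended_hap",
                mtstr = "mtstr_hap", combined = "combined_hap")
  if (!col %in% names(calls)) ts_stop("calls lack column ", col)
  hap <- as.character(calls[[col]])
  assigned <- !is.na(hap) & nzchar(hap)
  if (nrow(calls) == 0L || !any(assigned)) {
    tab <- frequency_table(matrix(integer(0), nrow = 0, ncol = 0,
                                  dimnames = list(character(0),
                                                  character(0))),
                           marker = marker, drop_empty = FALSE)
    excluded <- data.frame(reason = character(0), n = integer(0))
    return(structure(list(table = tab, excluded = excluded,
                          n_total = nrow(calls), n_assigned = 0L),
                     class = "tabulation"))
  }
  grp <- as.character(calls[[group_by]])
  counts <- table(factor(grp[assigned], levels = unique(grp)),
                  factor(hap[assigned], levels = unique(hap[assigned])))
  m <- matrix(as.integer(counts), nrow = nrow(counts),
              dimnames = dimnames(counts))
  reasons <- vapply(which(!assigned), function(i) {
    f <- calls$flags[i]
    if (!is.na(f) && nzchar(f)) f else "unassigned"
  }, character(1))
  excluded <- as.data.frame(table(reason = reasons),
                            stringsAsFactors = FALSE)
  names(excluded) <- c("reason", "n")
  structure(list(table = frequency_table(m, marker = marker,
                                         drop_empty = FALSE),
                 excluded = excluded,
                 n_total = nrow(calls), n_assigned = sum(assigned)),
            class = "tabulation")
}

#' @export
print.tabulation <- function(x, ...) {
  cat(sprintf("tabulation: %d of %d samples assigned (%s)\n", x$n_assigned,
              x$n_total, x$table$marker))
  if (nrow(x$excluded)) {
    cat("excluded:\n")
    print(x$excluded, row.names = FALSE)
  }
  invisible(x)
}

#' Percentage frequencies of a tabulation
#'
#' @param x a `tabulation`.
#' @param denominator `"total"` (all input samples, the convention of
#'   published haplotype tables) or `"assigned"`.
#' @return named numeric vector of per-haplotype percentages, rounded
#'   half-up to one decimal.
#' @export
tabulation_percent <- function(x, denominator = c("total", "assigned")) {
  stopifnot(inherits(x, "tabulation"))
  denominator <- match.arg(denominator)
  denom <- if (denominator == "total") x$n_total else x$n_assigned
  percent_round1(100 * colSums(x$table$counts) / denom)
}

#' Read a grouped haplotype-count CSV and expand it to per-sample calls
#'
#' Reads a CSV in the layout of a published haplotype-frequency table
#' (columns `short_hap`, `extended_hap`, `accession`, `mtstr_hap`, `count`;
#' the literal values `NA` for an unidentified D-loop and `Unidentified`
#' for an indiscernible mtSTR) and expands each row into `count` individual
#' sample-call rows with the appropriate status flags.
#'
#' @param path CSV path.
#' @param population population label assigned to all samples.
#' @return data frame of per-sample calls (see [tabulate_calls()]).
#' @export
read_call_counts <- function(path, population = "ASC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("short_hap", "extended_hap", "mtstr_hap", "count")
  if (!all(need %in% names(df)))
    ts_stop("call-count CSV must have columns: ", paste(need, collapse = ", "))
  n <- suppressWarnings(as.integer(df$count))
  if (any(is.na(n) | n < 0)) ts_stop("counts must be nonnegative integers")
  idx <- rep(seq_len(nrow(df)), n)
  short <- df$short_hap[idx]
  ext <- df$extended_hap[idx]
  ms <- df$mtstr_hap[idx]
  short[short %in% c("NA", "")] <- NA_character_
  ext[ext %in% c("NA", "")] <- NA_character_
  ms[ms %in% c("Unidentified", "")] <- NA_character_
  flags <- character(length(idx))
  flags[is.na(ext)] <- "dloop_failed"
  flags[is.na(ms)] <- ifelse(nzchar(flags[is.na(ms)]),
                             paste0(flags[is.na(ms)], ";mtstr_unidentified"),
                             "mtstr_unidentified")
  combined <- ifelse(is.na(ext) | is.na(ms), NA_character_,
                     paste0(ext, "/", ms))
  data.frame(sample_id = sprintf("S%04d", seq_along(idx)),
             population = population, year = NA_integer_,
             short_hap = short, extended_hap = ext, mtstr_hap = ms,
             combined_hap = combined, flags = flags,
             stringsAsFactors = FALSE)
}
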