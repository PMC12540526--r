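#' Nei haplotype (gene) diversity with its standard deviation
#'
#' Computes the unbiased haplotype diversity
#' \deqn{\hat h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' and its sampling variance (Nei 1987, eq. 8.12)
#' \deqn{V(\hat h) = \frac{2}{n(n-1)}\left[2(n-2)\left(\sum p_i^3 -
#'   \left(\sum p_i^2\right)^2\right) + \sum p_i^2 -
#'   \left(\sum p_i^2\right)^2\right]}
#' from a vector of haplotype counts.
#'
#' @param counts nonnegative integer vector of haplotype counts, n >= 2.
#' @return a list of class `diversity_result`: `n`, `n_hap`, `h`, `sd_h`.
#' @examples
#' haplotype_diversity(c(1, 1))   # h = 1
#' haplotype_diversity(c(5))      # h = 0
#' @export
haplotype_diversity <- function(counts) {
  if (any(is.na(counts) | counts < 0 | counts != round(counts)))
    ts_stop("counts must be nonnegative integers")
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) ts_stop("haplotype diversity requires n >= 2")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  h <- n * (1 - s2) / (n - 1)
  V <- (2 / (n * (n - 1))) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  structure(list(n = n, n_hap = length(counts), h = h,
                 sd_h = sqrt(max(V, 0))),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("n = %d, haplotypes = %d, h = %.3f +/- %.3f\n",
              x$n, x$n_hap, x$h, x$sd_h))
  invisible(x)
}

#' Per-population diversity summary of a frequency table
#'
#' @param table a `frequency_table`.
#' @return data frame with columns `population`, `n`, `n_hap`, `h`, `sd_h`.
#' @export
diversity_table <- function(table) {
  stopifnot(inherits(table, "frequency_table"))
  rows <- lapply(rownames(table$counts), function(p) {
    d <- haplotype_diversity(table$counts[p, ])
    data.frame(population = p, n = d$n, n_hap = d$n_hap, h = d$h,
               sd_h = d$sd_h, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Narum-modified false discovery rate threshold
#'
#' For a family of `k` comparisons at nominal level `alpha`, the corrected
#' significance threshold is \eqn{\alpha' = \alpha / \sum_{i=1}^{k} 1/i}.
#'
#' @param alpha nominal significance level in (0, 1).
#' @param k number of comparisons in the family (>= 1).
#' @return list with `threshold` (full precision), `threshold_rounded`
#'   (3 decimals, the value conventionally reported), `alpha`, `k`.
#' @examples
#' narum_fdr(0.05, 210)$threshold_rounded  # 0.008
#' @export
narum_fdr <- function(alpha, k) {
  check_prob(alpha, "alpha", open = TRUE)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    ts_stop("'k' must be a single integer >= 1")
  thr <- alpha / sum(1 / seq_len(k))
  list(threshold = thr, threshold_rounded = round(thr, 3),
       alpha = alpha, k = as.integer(k))
}

# internal: two-level AMOVA fixation index from per-population haplotype
# counts (P x H) and a squared-distance matrix delta (H x H, zero diagonal).
# Returns F_ST computed from the variance components (Excoffier et al.).
fst_from_counts <- function(counts, delta) {
  P <- nrow(counts)
  np <- rowSums(counts)
  N <- sum(np)
  qf <- function(v) as.numeric(crossprod(v, delta %*% v))
  ssd_w <- sum(vapply(seq_len(P),
                      function(p) qf(counts[p, ]) / (2 * np[p]), numeric(1)))
  ssd_t <- qf(colSums(counts)) / (2 * N)
  ssd_a <- ssd_t - ssd_w
  df_a <- P - 1
  df_w <- N - P
  sigma_c <- ssd_w / df_w
  n_eff <- (N - sum(np^2) / N) / df_a
  sigma_a <- (ssd_a / df_a - sigma_c) / n_eff
  tot <- sigma_a + sigma_c
  if (tot == 0) 0 else sigma_a / tot
}

# internal: shared permutation engine for pairwise F_ST / Phi_ST
pairwise_stat_engine <- function(table, delta, stat_name, n_permutations,
                                 seed, alpha) {
  stopifnot(inherits(table, "frequency_table"))
  counts <- table$counts
  P <- nrow(counts)
  H <- ncol(counts)
  if (P < 2) ts_stop("at least two populations required")
  np <- rowSums(counts)
  if (any(np < 2))
    ts_stop("population(s) with n < 2: ",
            paste(rownames(counts)[np < 2], collapse = ", "))
  values <- matrix(0, P, P, dimnames = list(rownames(counts),
                                            rownames(counts)))
  p_values <- matrix(1, P, P, dimnames = dimnames(values))
  set.seed(seed)
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      pair <- counts[c(i, j), , drop = FALSE]
      obs <- fst_from_counts(pair, delta)
      # permute individuals between the two populations
      haps <- rep(seq_len(H), colSums(pair))
      n1 <- np[i]
      Ntot <- length(haps)
      ctot <- colSums(pair)
      b <- 0L
      for (r in seq_len(n_permutations)) {
        sel <- sample.int(Ntot, n1)
        c1 <- tabulate(haps[sel], nbins = H)
        perm <- fst_from_counts(rbind(c1, ctot - c1), delta)
        if (perm >= obs - 1e-12) b <- b + 1L
      }
      values[i, j] <- values[j, i] <- obs
      p_values[i, j] <- p_values[j, i] <- (b + 1) / (n_permutations + 1)
    }
  }
  k <- P * (P - 1) / 2
  fdr <- narum_fdr(alpha, k)
  structure(list(stat_name = stat_name, values = values,
                 p_values = p_values, n_permutations = n_permutations,
                 alpha = alpha, k = k, fdr_threshold = fdr$threshold,
                 significant = p_values <= fdr$threshold &
                   row(values) != col(values)),
            class = "pairwise_stat")
}

#' @export
print.pairwise_stat <- function(x, ...) {
  cat(sprintf("pairwise %s (%d permutations, FDR alpha' = %.4f):\n",
              x$stat_name, x$n_permutations, x$fdr_threshold))
  m <- x$values
  m[upper.tri(m)] <- x$p_values[upper.tri(m)]
  cat("(values below diagonal, permutation p-values above)\n")
  print(round(m, 4))
  invisible(x)
}

#' Pairwise F_ST from haplotype frequencies, with permutation tests
#'
#' For each population pair, F_ST is the two-level AMOVA fixation index with
#' the frequency-based inter-haplotype distance (0 for the same haplotype, 1
#' otherwise). Significance is assessed by permuting individuals between the
#' two populations; p-values use the (b+1)/(m+1) correction. Negative
#' estimates are reported as computed, not truncated. The Narum-modified FDR
#' threshold for the whole matrix family is attached.
#'
#' @param table a `frequency_table` with >= 2 populations, each n >= 2.
#' @param n_permutations permutations per pair (default 10000).
#' @param seed RNG seed.
#' @param alpha nominal significance level (default 0.05).
#' @return an object of class `pairwise_stat` (see [print.pairwise_stat()]).
#' @export
pairwise_fst <- function(table, n_permutations = 10000L, seed = 1L,
                         alpha = 0.05) {
  H <- ncol(table$counts)
  delta <- 1 - diag(H)
  pairwise_stat_engine(table, delta, "F_ST", n_permutations, seed, alpha)
}

#' Number of differing aligned sites between haplotype sequences
#'
#' Pairwise-deletion distance: positions where either sequence has a gap or
#' `N` are ignored for that pair.
#'
#' @param sequences named character vector of aligned sequences of common
#'   length (names = haplotype ids).
#' @return symmetric integer matrix of site differences.
#' @export
site_difference_matrix <- function(sequences) {
  if (length(unique(nchar(sequences))) != 1L)
    ts_stop("sequences must share a common aligned length")
  M <- do.call(rbind, strsplit(toupper(sequences), ""))
  valid <- M %in% c("A", "C", "G", "T")
  dim(valid) <- dim(M)
  H <- nrow(M)
  d <- matrix(0L, H, H, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(H)) {
    for (j in seq_len(H)) {
      if (j > i) {
        use <- valid[i, ] & valid[j, ]
        d[i, j] <- d[j, i] <- sum(M[i, use] != M[j, use])
      }
    }
  }
  d
}

#' Pairwise Phi_ST from haplotype frequencies and sequence divergence
#'
#' Identical to [pairwise_fst()] except that the inter-haplotype distance is
#' the number of differing aligned sites between the haplotype sequences
#' (raw p-distance numerator, no substitution model), so differentiation is
#' weighted by sequence divergence.
#'
#' @inheritParams pairwise_fst
#' @param haplotype_sequences named character vector of aligned sequences
#'   covering every haplotype column of `table`, or a precomputed H x H
#'   distance matrix with matching dimnames.
#' @return an object of class `pairwise_stat`.
#' @export
pairwise_phist <- function(table, haplotype_sequences,
                           n_permutations = 10000L, seed = 1L,
                           alpha = 0.05) {
  haps <- colnames(table$counts)
  if (is.matrix(haplotype_sequences)) {
    delta <- haplotype_sequences
    missing <- setdiff(haps, rownames(delta))
  } else {
    missing <- setdiff(haps, names(haplotype_sequences))
    delta <- NULL
  }
  if (length(missing))
    ts_stop("missing sequence for haplotype(s): ",
            paste(missing, collapse = ", "))
  if (is.null(delta))
    delta <- site_difference_matrix(haplotype_sequences[haps])
  delta <- delta[haps, haps, drop = FALSE]
  pairwise_stat_engine(table, delta, "Phi_ST", n_permutations, seed, alpha)
}

#' Restrict a combined-haplotype table to CM-A8 variants
#'
#' The South Atlantic is dominated by the CM-A8 D-loop haplotype; comparing
#' only the mtSTR variation carried on a CM-A8 background removes noise from
#' rarer D-loop haplotypes. Keeps only combined-haplotype columns whose
#' extended component has parent short name `CM-A8` (or another given stem);
#' populations left with zero samples are dropped with a warning.
#'
#' @param combined_table a `frequency_table` with marker `"combined"`.
#' @param stem parent short name to keep (default `"CM-A8"`).
#' @return a `frequency_table` (possibly empty, with a warning).
#' @export
subset_cma8_mtstr <- function(combined_table, stem = "CM-A8") {
  stopifnot(inherits(combined_table, "frequency_table"))
  if (combined_table$marker != "combined")
    ts_stop("subset_cma8_mtstr expects a combined-marker table")
  comp <- split_combined(colnames(combined_table$counts))
  keep <- comp$parent_short == stem
  if (!any(keep)) {
    ts_warn("no combined haplotypes with parent ", stem)
    m <- combined_table$counts[, keep, drop = FALSE]
    return(frequency_table(m, marker = "combined", drop_empty = FALSE))
  }
  m <- combined_table$counts[, keep, drop = FALSE]
  empty <- rowSums(m) == 0
  if (any(empty)) {
    ts_warn("dropping population(s) with no ", stem, " samples: ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  frequency_table(m, marker = "combined", drop_empty = FALSE)
}
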