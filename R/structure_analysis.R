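#' Principal coordinates analysis of a genetic distance matrix
#'
#' Classical (metric) multidimensional scaling: the squared distances are
#' double-centered (Gower) and eigendecomposed; coordinates are the
#' eigenvectors scaled by the square roots of the positive eigenvalues.
#' Negative off-diagonal entries (negative F_ST estimates) are clamped to
#' zero first, because a distance interpretation requires nonnegativity;
#' the number of clamped cells is reported. Percent variance is relative to
#' the sum of the positive eigenvalues; negative eigenvalues are listed but
#' carry no axes.
#'
#' @param distance_matrix symmetric numeric matrix with zero diagonal.
#' @param tol asymmetry tolerance (default 1e-9).
#' @return a list of class `pcoa_result`: `coordinates` (population x axis),
#'   `eigenvalues` (all, descending), `percent_variance` (per positive
#'   axis), `cumulative_first_two`, `n_clamped`, `reconstruction_error`
#'   (max abs error reproducing the clamped distances from the positive
#'   axes; meaningful when the matrix is Euclidean-embeddable).
#' @export
pcoa_genetic <- function(distance_matrix, tol = 1e-9) {
  D <- as.matrix(distance_matrix)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > tol)
    ts_stop("distance matrix must be symmetric (tolerance ", tol, ")")
  if (max(abs(diag(D))) > tol) ts_stop("distance matrix must have zero diagonal")
  diag(D) <- 0
  n_clamped <- sum(D < 0)
  D[D < 0] <- 0
  n <- nrow(D)
  A <- -0.5 * D^2
  B <- A - rowMeans(A) - rep(colMeans(A), each = n) + mean(A)
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(abs(ev), 1) * 1e-12)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]),
                                                   length(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  pv <- 100 * ev[pos] / sum(ev[pos])
  cum2 <- sum(pv[seq_len(min(2, length(pv)))])
  rec_err <- if (length(pos)) max(abs(as.matrix(stats::dist(coords)) - D))
             else max(abs(D))
  structure(list(coordinates = coords, eigenvalues = ev,
                 percent_variance = pv, cumulative_first_two = cum2,
                 n_clamped = n_clamped, reconstruction_error = rec_err),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d positive axes; axes 1-2 explain %.1f%% of variance\n",
              length(x$percent_variance), x$cumulative_first_two))
  if (x$n_clamped > 0)
    cat(sprintf("(%d negative distance(s) clamped to 0)\n", x$n_clamped))
  invisible(x)
}

# internal: sums of squared deviations for a set of count vectors forming
# one unit, from the quadratic form over the squared-distance matrix
unit_ssd <- function(count_vec, delta) {
  n <- sum(count_vec)
  if (n == 0) return(0)
  as.numeric(crossprod(count_vec, delta %*% count_vec)) / (2 * n)
}

# internal: three-level variance components (among groups / among
# populations within groups / within populations), Excoffier et al. 1992
amova_components <- function(counts, delta, group) {
  P <- nrow(counts)
  np <- rowSums(counts)
  N <- sum(np)
  gl <- unique(group)
  G <- length(gl)
  ssd_wp <- sum(vapply(seq_len(P), function(p) unit_ssd(counts[p, ], delta),
                       numeric(1)))
  ssd_grp <- vapply(gl, function(g) {
    unit_ssd(colSums(counts[group == g, , drop = FALSE]), delta)
  }, numeric(1))
  ssd_ap <- sum(ssd_grp) - ssd_wp
  ssd_t <- unit_ssd(colSums(counts), delta)
  ssd_ag <- ssd_t - ssd_ap - ssd_wp
  Ng <- vapply(gl, function(g) sum(np[group == g]), numeric(1))
  sum_np2_by_g <- vapply(gl, function(g) sum(np[group == g]^2), numeric(1))
  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P
  sigma_c <- ssd_wp / df_wp
  n1 <- (N - sum(sum_np2_by_g / Ng)) / df_ap
  n2 <- (sum(sum_np2_by_g / Ng) - sum(np^2) / N) / df_ag
  n3 <- (N - sum(Ng^2) / N) / df_ag
  sigma_b <- (ssd_ap / df_ap - sigma_c) / n1
  sigma_a <- (ssd_ag / df_ag - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  list(sigma = c(among_groups = sigma_a, among_pops_within = sigma_b,
                 within_pops = sigma_c),
       fct = if (tot == 0) 0 else sigma_a / tot,
       fsc = if (sigma_b + sigma_c == 0) 0 else sigma_b / (sigma_b + sigma_c),
       fst = if (tot == 0) 0 else (sigma_a + sigma_b) / tot,
       ssd = c(among_groups = ssd_ag, among_pops_within = ssd_ap,
               within_pops = ssd_wp, total = ssd_t),
       df = c(df_ag, df_ap, df_wp))
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions molecular variance among a-priori groups of populations,
#' among populations within groups, and within populations, from squared
#' inter-individual distances (identity distance in frequency mode,
#' site-difference distance in sequence mode). The among-group index F_CT
#' is tested by permuting whole populations among groups.
#'
#' @param table a `frequency_table`.
#' @param group_assignment named character vector mapping every population
#'   of `table` to a group label; >= 2 groups required.
#' @param sequences optional named aligned sequences (or an H x H distance
#'   matrix) for sequence-divergence mode; `NULL` uses the identity
#'   (frequency) distance.
#' @param n_permutations permutations for the F_CT test (default 10000).
#' @param seed RNG seed.
#' @return list of class `amova_result`: `variance_components`,
#'   `fixation_indices` (F_CT, F_SC, F_ST), `p_fct`, `ssd`, `df`,
#'   `n_permutations`.
#' @export
amova <- function(table, group_assignment, sequences = NULL,
                  n_permutations = 10000L, seed = 1L) {
  stopifnot(inherits(table, "frequency_table"))
  counts <- table$counts
  pops <- rownames(counts)
  if (!all(pops %in% names(group_assignment)))
    ts_stop("every population must be assigned to exactly one group; missing: ",
            paste(setdiff(pops, names(group_assignment)), collapse = ", "))
  group <- as.character(group_assignment[pops])
  if (length(unique(group)) < 2) ts_stop("at least two groups required")
  H <- ncol(counts)
  haps <- colnames(counts)
  if (is.null(sequences)) {
    delta <- 1 - diag(H)
  } else if (is.matrix(sequences)) {
    delta <- sequences[haps, haps, drop = FALSE]
  } else {
    missing <- setdiff(haps, names(sequences))
    if (length(missing))
      ts_stop("missing sequence for haplotype(s): ",
              paste(missing, collapse = ", "))
    delta <- site_difference_matrix(sequences[haps])
  }
  obs <- amova_components(counts, delta, group)
  if (any(table(group) == 1) && n_permutations > 0)
    ts_warn("group(s) containing a single population: ",
            "the permutation space is degenerate")
  p_fct <- NA_real_
  if (n_permutations > 0) {
    set.seed(seed)
    b <- 0L
    for (r in seq_len(n_permutations)) {
      perm <- amova_components(counts, delta, sample(group))
      if (perm$fct >= obs$fct - 1e-12) b <- b + 1L
    }
    p_fct <- (b + 1) / (n_permutations + 1)
  }
  structure(list(variance_components = obs$sigma,
                 fixation_indices = c(F_CT = obs$fct, F_SC = obs$fsc,
                                      F_ST = obs$fst),
                 p_fct = p_fct, ssd = obs$ssd, df = obs$df,
                 n_permutations = n_permutations),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA variance components:\n")
  print(round(x$variance_components, 5))
  cat(sprintf("F_CT = %.3f (p = %.4g), F_SC = %.3f, F_ST = %.3f\n",
              x$fixation_indices["F_CT"], x$p_fct,
              x$fixation_indices["F_SC"], x$fixation_indices["F_ST"]))
  invisible(x)
}

#' Two-level AMOVA fixation index for a pair or set of populations
#'
#' Convenience wrapper exposing the F_ST used by [pairwise_fst()] /
#' [pairwise_phist()] as a direct computation (no permutations), mainly for
#' cross-checking against the hierarchical decomposition.
#'
#' @param table a `frequency_table`.
#' @param sequences as in [amova()]; `NULL` for the identity distance.
#' @return the fixation index (scalar).
#' @export
amova_fst <- function(table, sequences = NULL) {
  counts <- table$counts
  H <- ncol(counts)
  haps <- colnames(counts)
  if (is.null(sequences)) {
    delta <- 1 - diag(H)
  } else if (is.matrix(sequences)) {
    delta <- sequences[haps, haps, drop = FALSE]
  } else {
    delta <- site_difference_matrix(sequences[haps])
  }
  fst_from_counts(counts, delta)
}
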