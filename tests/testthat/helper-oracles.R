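# Independent brute-force oracles: variance components computed from the
# explicit individual-by-individual distance matrix, not from haplotype
# frequency algebra. Deliberately slow and literal.

# expand a counts matrix into per-individual haplotype / population labels
expand_individuals <- function(counts) {
  P <- nrow(counts)
  H <- ncol(counts)
  hap <- unlist(lapply(seq_len(P), function(p)
    rep(seq_len(H), counts[p, ])))
  pop <- rep(seq_len(P), rowSums(counts))
  list(hap = hap, pop = pop)
}

# two-level fixation index from the explicit squared-distance matrix
oracle_fst <- function(counts, delta) {
  e <- expand_individuals(counts)
  D <- delta[e$hap, e$hap, drop = FALSE]
  N <- length(e$hap)
  P <- nrow(counts)
  np <- rowSums(counts)
  ssd_t <- sum(D) / (2 * N)
  ssd_w <- sum(vapply(seq_len(P), function(p) {
    idx <- which(e$pop == p)
    sum(D[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
  ssd_a <- ssd_t - ssd_w
  sigma_c <- ssd_w / (N - P)
  n_eff <- (N - sum(np^2) / N) / (P - 1)
  sigma_a <- (ssd_a / (P - 1) - sigma_c) / n_eff
  if (sigma_a + sigma_c == 0) 0 else sigma_a / (sigma_a + sigma_c)
}

# three-level AMOVA components from the explicit distance matrix
oracle_amova3 <- function(counts, delta, group) {
  e <- expand_individuals(counts)
  D <- delta[e$hap, e$hap, drop = FALSE]
  N <- length(e$hap)
  P <- nrow(counts)
  np <- rowSums(counts)
  gl <- unique(group)
  G <- length(gl)
  ind_group <- group[e$pop]
  ssd_unit <- function(idx) {
    if (!length(idx)) return(0)
    sum(D[idx, idx]) / (2 * length(idx))
  }
  ssd_t <- ssd_unit(seq_len(N))
  ssd_wp <- sum(vapply(seq_len(P), function(p)
    ssd_unit(which(e$pop == p)), numeric(1)))
  ssd_g <- sum(vapply(gl, function(g)
    ssd_unit(which(ind_group == g)), numeric(1)))
  ssd_ap <- ssd_g - ssd_wp
  ssd_ag <- ssd_t - ssd_ap - ssd_wp
  Ng <- vapply(gl, function(g) sum(np[group == g]), numeric(1))
  sum_np2_g <- vapply(gl, function(g) sum(np[group == g]^2), numeric(1))
  sigma_c <- ssd_wp / (N - P)
  n1 <- (N - sum(sum_np2_g / Ng)) / (P - G)
  n2 <- (sum(sum_np2_g / Ng) - sum(np^2) / N) / (G - 1)
  n3 <- (N - sum(Ng^2) / N) / (G - 1)
  sigma_b <- (ssd_ap / (P - G) - sigma_c) / n1
  sigma_a <- (ssd_ag / (G - 1) - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  list(sigma = c(sigma_a, sigma_b, sigma_c),
       fct = if (tot == 0) 0 else sigma_a / tot)
}

# Monte Carlo standard error of a chain mean by batch means
mcse_batch <- function(x, n_batch = 40) {
  nb <- floor(length(x) / n_batch)
  bm <- colMeans(matrix(x[seq_len(nb * n_batch)], nrow = nb))
  stats::sd(bm) / sqrt(n_batch)
}

# random small frequency_table instances for property tests
random_table <- function(P, H, n_max, seed) {
  set.seed(seed)
  repeat {
    counts <- matrix(rpois(P * H, 1.2), P, H)
    np <- rowSums(counts)
    if (all(np >= 2) && all(np <= n_max) && all(colSums(counts) > 0)) break
  }
  dimnames(counts) <- list(paste0("P", seq_len(P)), paste0("H", seq_len(H)))
  frequency_table(counts, marker = "extended", drop_empty = FALSE)
}

table2_path <- function() {
  system.file("extdata", "ascension_haplotype_counts.csv",
              package = "turtlestock")
}
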