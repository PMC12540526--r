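#' Build an mtSTR sequence from four repeat counts
#'
#' Concatenates the four locus anchors, each followed by its run of `AT`
#' units, plus a closing tail, reproducing the structure of the ~200 bp
#' repeat region. Inverse of [call_mtstr()] for any repeat vector.
#'
#' @param repeats integer vector of four repeat counts (all >= 1).
#' @param anchors four anchor motifs (default [default_mtstr_anchors()]).
#' @param tail closing motif after the fourth locus.
#' @return the mtSTR nucleotide string.
#' @export
build_mtstr_sequence <- function(repeats,
                                 anchors = default_mtstr_anchors(),
                                 tail = "CGGCTTCG") {
  if (length(repeats) != 4L || any(repeats < 1))
    ts_stop("repeats must be four counts >= 1")
  paste0(paste0(anchors, vapply(repeats, function(r)
    strrep("AT", r), character(1)), collapse = ""), tail)
}

#' Generate a synthetic haplotype reference library
#'
#' Emulates the structure of a real control-region library: a root extended
#' D-loop sequence of `extended_length` bases; one dominant haplotype family
#' (`SY-A1`) with two extended variants (`SY-A1.1` = root, `SY-A1.3` =
#' root mutated at one site beyond the short window, so both collapse to
#' the same short haplotype); and further families `SY-Ak.1` mutated at
#' distinct sites inside the short window. mtSTR haplotypes vary only at
#' the first two repeat loci, with loci 3-4 fixed at 4 units.
#'
#' @param n_dloop number of extended D-loop haplotypes (>= 1).
#' @param n_mtstr number of mtSTR haplotypes (<= 24 under the default
#'   repeat ranges).
#' @param seed RNG seed.
#' @param spec a [window_spec()].
#' @return list of class `synthetic_library`: `library` (a
#'   `haplotype_library`), `dloop_seqs` (named sequences), `mtstr`
#'   (data frame name/r1..r4/sequence), `anchors`, `seed`.
#' @export
make_library <- function(n_dloop = 4L, n_mtstr = 4L, seed = 1L,
                         spec = window_spec()) {
  if (n_dloop < 1) ts_stop("n_dloop must be >= 1")
  n_extra <- max(0L, n_dloop - 2L)
  if (n_extra > spec$short_length)
    ts_stop("requested haplotypes exceed available mutation sites")
  set.seed(derive_seed(seed, 1L))
  bases <- c("A", "C", "G", "T")
  root <- paste0(sample(bases, spec$extended_length, replace = TRUE),
                 collapse = "")
  mutate_at <- function(s, pos) {
    old <- substr(s, pos, pos)
    substr(s, pos, pos) <- sample(setdiff(bases, old), 1)
    s
  }
  names_d <- character(n_dloop)
  seqs <- character(n_dloop)
  names_d[1] <- "SY-A1.1"
  seqs[1] <- root
  if (n_dloop >= 2) {
    pos_ext <- sample((spec$short_length + 1L):spec$extended_length, 1)
    names_d[2] <- "SY-A1.3"
    seqs[2] <- mutate_at(root, pos_ext)
  }
  if (n_extra > 0) {
    pos_short <- sample(seq_len(spec$short_length), n_extra)
    for (k in seq_len(n_extra)) {
      names_d[k + 2L] <- sprintf("SY-A%d.1", k + 1L)
      seqs[k + 2L] <- mutate_at(root, pos_short[k])
    }
  }
  names(seqs) <- names_d
  grid <- expand.grid(r1 = 6:8, r2 = 10:17)
  if (n_mtstr > nrow(grid))
    ts_stop("n_mtstr exceeds the available repeat combinations (",
            nrow(grid), ")")
  ord <- order(!(grid$r1 == 7 & grid$r2 == 12))  # 7-12 first: dominant
  pick <- grid[ord[seq_len(n_mtstr)], , drop = FALSE]
  mt <- data.frame(r1 = pick$r1, r2 = pick$r2, r3 = 4L, r4 = 4L)
  mt$name <- apply(mt, 1, paste, collapse = "-")
  mt$sequence <- vapply(seq_len(nrow(mt)), function(i)
    build_mtstr_sequence(unlist(mt[i, c("r1", "r2", "r3", "r4")])),
    character(1))
  lib <- data.frame(
    name = c(names_d, mt$name),
    marker = c(rep("extended_dloop", n_dloop), rep("mtstr", nrow(mt))),
    accession = "",
    sequence = c(unname(seqs), mt$sequence),
    stringsAsFactors = FALSE)
  lib$parent_short_name <- ifelse(lib$marker == "extended_dloop",
                                  derive_short_name(lib$name), lib$name)
  class(lib) <- c("haplotype_library", "data.frame")
  structure(list(library = lib, dloop_seqs = seqs,
                 mtstr = mt[, c("name", "r1", "r2", "r3", "r4", "sequence")],
                 anchors = default_mtstr_anchors(), seed = seed),
            class = "synthetic_library")
}

#' Simulate rookery haplotype-frequency baselines
#'
#' Emulates the regional structure of South Atlantic rookeries: one shared
#' dominant haplotype (mean frequency `dominant_mass` across rookeries,
#' drawn per rookery from a Beta distribution) and the remaining mass
#' spread over rare, partly private haplotypes via a sparse Dirichlet.
#' Counts are drawn multinomially at the requested sample sizes.
#'
#' @param R number of rookeries.
#' @param H number of haplotypes (>= 2); haplotype 1 is the dominant one.
#' @param concentration Dirichlet concentration for the non-dominant mass;
#'   small values give near-private rare haplotypes (default 0.5).
#' @param dominant_mass mean frequency of the dominant haplotype in (0, 1)
#'   (default 0.75, matching the ~74-75% dominance typical of the region).
#' @param sample_sizes per-rookery sample sizes (recycled; default 200).
#' @param seed RNG seed.
#' @param hap_names optional haplotype names (default `H1..HH`).
#' @param dominant_kappa Beta concentration of the per-rookery dominant
#'   frequency around `dominant_mass` (default 50).
#' @return list: `pi` (R x H frequency matrix), `table`
#'   (a `frequency_table` of counts), `seed`.
#' @export
simulate_baselines <- function(R, H, concentration = 0.5,
                               dominant_mass = 0.75, sample_sizes = 200L,
                               seed = 1L, hap_names = NULL,
                               dominant_kappa = 50) {
  if (H < 2) ts_stop("H must be >= 2")
  check_prob(dominant_mass, "dominant_mass", open = TRUE)
  set.seed(derive_seed(seed, 2L))
  if (is.null(hap_names)) hap_names <- paste0("H", seq_len(H))
  sample_sizes <- rep_len(sample_sizes, R)
  pi <- matrix(0, R, H, dimnames = list(paste0("R", seq_len(R)), hap_names))
  for (r in seq_len(R)) {
    d <- stats::rbeta(1, dominant_mass * dominant_kappa,
                      (1 - dominant_mass) * dominant_kappa)
    g <- stats::rgamma(H - 1, shape = concentration)
    if (sum(g) == 0) g <- rep(1, H - 1)
    pi[r, ] <- c(d, (1 - d) * g / sum(g))
  }
  counts <- t(vapply(seq_len(R), function(r)
    as.integer(stats::rmultinom(1, sample_sizes[r], pi[r, ])),
    integer(H)))
  dimnames(counts) <- dimnames(pi)
  list(pi = pi,
       table = frequency_table(counts, marker = "extended",
                               drop_empty = FALSE),
       seed = seed)
}

#' Simulate a finite-mixture foraging sample with known contributions
#'
#' Each individual's source rookery is drawn from `theta_true` and its
#' haplotype from that rookery's frequency vector: the data model assumed
#' by mixed stock analysis.
#'
#' @param pi R x H matrix of rookery haplotype frequencies.
#' @param theta_true contribution vector over rookeries (sums to 1).
#' @param n number of individuals (>= 1).
#' @param seed RNG seed.
#' @return list: `counts` (named haplotype count vector), `sources`
#'   (integer source label per individual), `haplotypes` (per individual).
#' @export
simulate_mixture <- function(pi, theta_true, n, seed = 1L) {
  if (n < 1) ts_stop("n must be >= 1")
  if (length(theta_true) != nrow(pi))
    ts_stop("theta_true must have one entry per rookery")
  if (abs(sum(theta_true) - 1) > 1e-8 || any(theta_true < 0))
    ts_stop("theta_true must lie on the simplex")
  set.seed(derive_seed(seed, 3L))
  R <- nrow(pi)
  H <- ncol(pi)
  sources <- sample.int(R, n, replace = TRUE, prob = theta_true)
  haps <- vapply(sources, function(r)
    sample.int(H, 1, prob = pi[r, ]), integer(1))
  counts <- tabulate(haps, nbins = H)
  names(counts) <- colnames(pi)
  list(counts = counts, sources = sources,
       haplotypes = colnames(pi)[haps])
}

#' Inject heteroplasmy into mtSTR repeat profiles
#'
#' Every profile receives a secondary repeat-count variant at at least one
#' locus (heteroplasmy is ubiquitous in real mtSTR chromatograms); a chosen
#' fraction of profiles receives a dominant-peak fraction below the
#' resolution threshold and is therefore unclear by construction. The true
#' repeat count always remains the dominant variant of clear profiles, so
#' the resolver's exclusions are exactly the injected-unclear set.
#'
#' @param repeats n x 4 matrix (or data frame) of true repeat counts.
#' @param fraction_unclear fraction of profiles made unresolvable, in
#'   `[0, 1]`.
#' @param dominance_range range the dominant fraction of clear profiles is
#'   drawn from (default c(0.7, 0.95); must lie at or above `threshold`).
#' @param seed RNG seed.
#' @param threshold the resolution threshold the unclear profiles are
#'   pushed below (default 0.6).
#' @return list: `locus_variants` (per sample: list of four data frames
#'   with `repeat_count`, `fraction`), `unclear` (logical vector of the
#'   injected-unclear samples).
#' @export
simulate_heteroplasmy <- function(repeats, fraction_unclear = 0.1,
                                  dominance_range = c(0.7, 0.95),
                                  seed = 1L, threshold = 0.6) {
  check_prob(fraction_unclear, "fraction_unclear")
  repeats <- as.matrix(repeats)
  if (ncol(repeats) != 4L) ts_stop("repeats must have four columns")
  if (dominance_range[1] < threshold)
    ts_stop("dominance_range must lie at or above the resolution threshold")
  set.seed(derive_seed(seed, 4L))
  n <- nrow(repeats)
  n_unclear <- round(fraction_unclear * n)
  unclear <- rep(FALSE, n)
  if (n_unclear > 0) unclear[sample.int(n, n_unclear)] <- TRUE
  lv <- lapply(seq_len(n), function(i) {
    locus <- sample.int(4L, 1)
    dom <- if (unclear[i]) stats::runif(1, 0.5, threshold - 1e-6)
           else stats::runif(1, dominance_range[1], dominance_range[2])
    secondary <- repeats[i, locus] + sample(c(-1L, 1L), 1)
    if (secondary < 1L) secondary <- repeats[i, locus] + 1L
    lapply(1:4, function(l) {
      if (l == locus) {
        data.frame(repeat_count = c(repeats[i, l], secondary),
                   fraction = c(dom, 1 - dom))
      } else {
        data.frame(repeat_count = repeats[i, l], fraction = 1)
      }
    })
  })
  list(locus_variants = lv, unclear = unclear)
}

#' Simulate curved carapace lengths for adults and juveniles
#'
#' Normal CCL draws per life stage with truth labels, used to exercise the
#' minimum-adult-size filter. Defaults approximate nesting green turtle
#' females (112 +/- 5 cm CCL) and neritic juveniles (65 +/- 10 cm).
#'
#' @param n_adult,n_juvenile class sizes.
#' @param adult_mean,adult_sd,juvenile_mean,juvenile_sd normal parameters
#'   (cm); SDs must be positive.
#' @param seed RNG seed.
#' @return data frame with columns `ccl`, `stage` (`"adult"`/`"juvenile"`).
#' @export
simulate_ccl <- function(n_adult, n_juvenile, adult_mean = 112,
                         adult_sd = 5, juvenile_mean = 65,
                         juvenile_sd = 10, seed = 1L) {
  if (adult_sd <= 0 || juvenile_sd <= 0) ts_stop("sds must be positive")
  set.seed(derive_seed(seed, 5L))
  data.frame(
    ccl = c(stats::rnorm(n_adult, adult_mean, adult_sd),
            stats::rnorm(n_juvenile, juvenile_mean, juvenile_sd)),
    stage = rep(c("adult", "juvenile"), c(n_adult, n_juvenile)),
    stringsAsFactors = FALSE)
}
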