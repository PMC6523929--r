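# Within-population diversity: heterozygosities, rarefaction allelic
# richness, marker-class correlation, and the heterozygosity-excess
# bottleneck test under the stepwise mutation model.

#' Unbiased expected heterozygosity (gene diversity)
#'
#' Nei's unbiased estimator over gene copies,
#' `H_E = (2N / (2N - 1)) (1 - sum p_i^2)`, where 2N is the number of gene
#' copies and `p_i` the sample allele (or haplotype) frequencies.
#'
#' @param counts non-negative integer vector of allele/haplotype counts.
#' @return `H_E` in \[0, 1\].
#' @examples
#' expected_heterozygosity(c(1, 7, 4, 2, 2))  # 0.7583
#' @export
expected_heterozygosity <- function(counts) {
  stopifnot(length(counts) >= 1L, all(counts >= 0))
  n <- sum(counts)
  if (n < 2) stop("need at least two gene copies")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Observed heterozygosity of phased diplotypes
#'
#' Fraction of individuals whose two haplotypes differ.
#'
#' @param diplotypes two-column matrix/data frame of haplotype ids (one row
#'   per individual), or a phased table from [phase_population()] (columns
#'   `h1`, `h2`).
#' @return `H_O` in \[0, 1\].
#' @export
observed_heterozygosity <- function(diplotypes) {
  d <- if (is.data.frame(diplotypes) && all(c("h1", "h2") %in% names(diplotypes)))
    cbind(diplotypes$h1, diplotypes$h2) else as.matrix(diplotypes)
  stopifnot(ncol(d) == 2L)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0L) stop("no phased individuals")
  mean(d[, 1] != d[, 2])
}

#' Allelic richness by hypergeometric rarefaction
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, `AR(g) = sum_a [1 - C(2N - n_a, g) / C(2N, g)]`, evaluated with
#' log-factorial combinatorics.  Rarefaction to the smallest sample corrects
#' allele counts for unequal sample sizes.
#'
#' @param counts allele/haplotype count vector (2N = `sum(counts)`).
#' @param g rarefaction size in gene copies; must not exceed 2N.
#' @return `AR(g)`, between 1 and the observed allele count for `g >= 1`.
#' @examples
#' allelic_richness(c(49, 55, 55, 2, 11), g = 16)  # 3.84
#' @export
allelic_richness <- function(counts, g) {
  stopifnot(length(counts) >= 1L, all(counts >= 0), g >= 1,
            g == round(g))
  n <- sum(counts)
  if (g > n) stop("rarefaction size g = ", g, " exceeds 2N = ", n)
  sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
}

#' Rarefaction allelic richness for every population of a count table
#'
#' @param counts population-by-class count matrix.
#' @param g rarefaction size; default the smallest row sum, the standard
#'   choice when comparing populations.
#' @return Named vector of AR values.
#' @export
allelic_richness_table <- function(counts, g = min(rowSums(counts))) {
  validate_count_table(counts)
  apply(counts, 1, allelic_richness, g = g)
}

#' Pearson correlation between per-population richness of two marker classes
#'
#' @param ar_marker1,ar_marker2 equal-length numeric vectors (one entry per
#'   population), `n >= 3`.
#' @return List with `r`, `p` (two-tailed, from the t distribution with
#'   `n - 2` df), `n`.
#' @examples
#' ar_correlation(c(5.00, 4.67, 4.59, 4.60, 4.09, 4.61, 3.84),
#'                c(2.27, 2.22, 2.22, 2.14, 2.14, 2.17, 2.13))
#' @export
ar_correlation <- function(ar_marker1, ar_marker2) {
  stopifnot(length(ar_marker1) == length(ar_marker2),
            length(ar_marker1) >= 3L)
  if (stats::sd(ar_marker1) == 0 || stats::sd(ar_marker2) == 0)
    stop("correlation undefined: zero variance in a richness vector")
  ct <- stats::cor.test(ar_marker1, ar_marker2, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ar_marker1))
}

# -- heterozygosity-excess bottleneck test ---------------------------------

# One coalescent sample of n genes under the SMM: build the Kingman tree,
# drop Poisson mutations on branches and propagate +/-1 steps root to tips.
.smm_coalescent <- function(n, theta) {
  # nodes 1..n tips; internal nodes appended
  parent <- integer(2 * n - 1)
  blen <- numeric(2 * n - 1)
  active <- seq_len(n)
  tnow <- 0
  tbirth <- numeric(2 * n - 1)  # time each node starts (towards the past)
  nxt <- n
  k <- n
  while (k > 1L) {
    tnow <- tnow + stats::rexp(1, k * (k - 1) / 2)
    pick <- sample(k, 2L)
    nxt <- nxt + 1L
    for (v in active[pick]) {
      parent[v] <- nxt
      blen[v] <- tnow - tbirth[v]
    }
    tbirth[nxt] <- tnow
    active <- c(active[-pick], nxt)
    k <- k - 1L
  }
  root <- nxt
  # mutations: Poisson(theta/2 * branch length) per branch, each +/-1 step
  state <- integer(2 * n - 1)
  ord <- order(tbirth[seq_len(2 * n - 1)], decreasing = TRUE)  # old -> young
  for (v in ord) {
    if (v == root) next
    nm <- stats::rpois(1, theta / 2 * blen[v])
    d <- if (nm > 0) sum(sample(c(-1L, 1L), nm, replace = TRUE)) else 0L
    state[v] <- state[parent[v]] + d
  }
  state[seq_len(n)]
}

# mean number of distinct alleles in samples of n genes at rate theta
.smm_mean_k <- function(n, theta, reps) {
  mean(vapply(seq_len(reps), function(i)
    length(unique(.smm_coalescent(n, theta))), numeric(1)))
}

# find theta whose mean simulated allele count matches k_obs
.calibrate_theta <- function(n, k_obs, reps = 30L) {
  lo <- 0.01; hi <- 0.1
  while (.smm_mean_k(n, hi, reps) < k_obs && hi < 1e3) hi <- hi * 3
  while (.smm_mean_k(n, lo, reps) > k_obs && lo > 1e-5) lo <- lo / 3
  for (i in 1:9) {
    mid <- sqrt(lo * hi)
    if (.smm_mean_k(n, mid, reps) < k_obs) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Heterozygosity-excess test for a recent bottleneck (SMM)
#'
#' After a recent reduction in effective size, rare alleles are lost faster
#' than gene diversity, so the observed expected heterozygosity `H_E` tends
#' to exceed the equilibrium heterozygosity `H_eq` of a population with the
#' same number of alleles.  For each locus, coalescent samples of the same
#' number of gene copies are simulated under the stepwise mutation model with
#' the mutation parameter tuned so that the mean simulated allele count
#' matches the observed count, keeping only simulations with exactly the
#' observed allele number; the standardized excess
#' `DH = (H_E - mean H_eq) / sd H_eq` is computed per locus, and loci are
#' combined by a one-tailed Wilcoxon signed-rank test for excess.
#'
#' @param locus_counts list of allele count vectors, one per locus (same
#'   sample of individuals; monomorphic loci are dropped with a note).
#' @param model mutation model; only `"SMM"` is implemented.
#' @param n_sim number of retained equilibrium simulations per locus
#'   (default 2000; the published analysis used 2000 replicates).
#' @param seed RNG seed.
#' @param max_attempts cap on total coalescent simulations per locus during
#'   accept-reject conditioning.
#' @return List with `per_locus` (data frame: locus, k, H_E, mean/sd of
#'   `H_eq`, DH, replicates retained), `p` (one-tailed Wilcoxon for excess),
#'   `statistic`, `n_loci`, `dropped`.
#' @export
bottleneck_test <- function(locus_counts, model = "SMM", n_sim = 2000L,
                            seed = 1L, max_attempts = 50L * n_sim) {
  stopifnot(identical(model, "SMM"), is.list(locus_counts))
  set.seed(seed)
  ks <- vapply(locus_counts, function(x) sum(x > 0), integer(1))
  dropped <- names(locus_counts)[ks < 2L]
  usable <- which(ks >= 2L)
  if (length(usable) < 4L)
    stop("bottleneck test refused: fewer than 4 polymorphic loci")
  rows <- lapply(usable, function(li) {
    cnt <- locus_counts[[li]]
    cnt <- cnt[cnt > 0]
    n <- sum(cnt); k <- length(cnt)
    theta <- .calibrate_theta(n, k)
    heq <- numeric(0)
    attempts <- 0L
    while (length(heq) < n_sim && attempts < max_attempts) {
      batch <- min(2L * n_sim, max_attempts - attempts)
      for (b in seq_len(batch)) {
        s <- .smm_coalescent(n, theta)
        if (length(unique(s)) == k)
          heq <- c(heq, expected_heterozygosity(table(s)))
      }
      attempts <- attempts + batch
      if (length(heq) >= n_sim) break
    }
    if (length(heq) < 10L)
      stop("conditioning failed for locus ", li,
           ": too few accepted simulations")
    he <- expected_heterozygosity(cnt)
    m <- mean(heq); s <- stats::sd(heq)
    data.frame(locus = if (!is.null(names(locus_counts)))
                 names(locus_counts)[li] else paste0("L", li),
               k = k, H_E = he, H_eq_mean = m, H_eq_sd = s,
               DH = (he - m) / s, replicates = length(heq),
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  wt <- stats::wilcox.test(per_locus$DH, alternative = "greater",
                           exact = TRUE)
  list(per_locus = per_locus, p = wt$p.value,
       statistic = unname(wt$statistic), n_loci = nrow(per_locus),
       dropped = dropped)
}
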