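# Between-population structure at a haplotype-coded marker: hierarchical
# AMOVA over gene copies with 0/1 haplotype-mismatch distance, pairwise
# F_ST, Hedrick's standardized G'_ST with loci-bootstrap neutral envelopes,
# Mantel tests, chord-distance NJ trees and the among- vs within-group t-test.

# sum of squared deviations for one unit of gene copies under the 0/1
# mismatch distance: SSD = N (1 - sum p^2) / 2
.ssd01 <- function(x) {
  n <- sum(x)
  if (n == 0) return(0)
  n * (1 - sum((x / n)^2)) / 2
}

.amova_components <- function(counts, gidx) {
  Np <- rowSums(counts); N <- sum(Np)
  P <- nrow(counts); G <- length(gidx)
  SSD_T <- .ssd01(colSums(counts))
  SSD_WP <- sum(apply(counts, 1, .ssd01))
  SSD_WG <- sum(vapply(gidx, function(i)
    .ssd01(colSums(counts[i, , drop = FALSE])), numeric(1)))
  SSD_AP <- SSD_WG - SSD_WP
  SSD_AG <- SSD_T - SSD_WG
  df <- c(G - 1L, P - G, N - P)
  Ng <- vapply(gidx, function(i) sum(Np[i]), numeric(1))
  sA <- vapply(gidx, function(i) sum(Np[i]^2), numeric(1))
  sig_c <- SSD_WP / df[3]
  if (G < P) {
    n1 <- (N - sum(sA / Ng)) / df[2]
    sig_b <- (SSD_AP / df[2] - sig_c) / n1
  } else sig_b <- 0
  if (G > 1L) {
    n2 <- (sum(sA / Ng) - sum(Np^2) / N) / df[1]
    n3 <- (N - sum(Ng^2) / N) / df[1]
    sig_a <- (SSD_AG / df[1] - sig_c - n2 * sig_b) / n3
  } else sig_a <- 0
  list(SS = c(SSD_AG, SSD_AP, SSD_WP), df = df,
       sigma = c(sig_a, sig_b, sig_c))
}

.grouping_index <- function(counts, grouping) {
  pops <- rownames(counts)
  if (is.null(grouping)) grouping <- list(pops)
  if (!is.list(grouping))
    grouping <- split(pops, grouping[pops])
  gidx <- lapply(grouping, function(g) {
    i <- match(g, pops)
    if (anyNA(i)) stop("unknown population(s) in grouping: ",
                       paste(g[is.na(i)], collapse = ", "))
    i
  })
  if (any(lengths(gidx) == 0L)) stop("empty group in grouping")
  if (length(unlist(gidx)) != length(pops) || anyDuplicated(unlist(gidx)))
    stop("grouping must partition all populations")
  gidx
}

# redistribute each group's pooled gene copies at random among its
# populations, keeping the per-population sample sizes (F_SC null)
.permute_within_groups <- function(counts, gidx) {
  out <- counts
  for (i in gidx) {
    if (length(i) < 2L) next
    sub <- counts[i, , drop = FALSE]
    copies <- rep(seq_len(ncol(sub)), colSums(sub))
    copies <- sample(copies)
    sizes <- rowSums(sub)
    at <- 0L
    for (r in seq_along(i)) {
      take <- copies[(at + 1L):(at + sizes[r])]
      out[i[r], ] <- tabulate(take, nbins = ncol(sub))
      at <- at + sizes[r]
    }
  }
  out
}

#' Hierarchical AMOVA of gene copies with haplotype identity distance
#'
#' Three-level analysis of molecular variance (among groups / among
#' populations within groups / within populations) over individual gene
#' copies, with the 0/1 mismatch distance between haplotype classes and the
#' classical unequal-sample-size coefficients.  Significance of `F_CT` is
#' assessed by permuting whole populations among groups (preserving the
#' number of populations per group), of `F_SC` by permuting gene copies among
#' populations within groups, and of `F_ST` by permuting gene copies among
#' all populations.  With a single group (or `grouping = NULL`) the analysis
#' reduces to the two-level decomposition and only `F_ST` is reported.
#'
#' @param counts population-by-haplotype integer count matrix (row names are
#'   population labels; row sums are gene copies 2N).
#' @param grouping a list of character vectors partitioning the population
#'   labels into groups (or `NULL` for a two-level analysis).
#' @param n_perm permutations for the significance tests (default 1023).
#' @param seed RNG seed.
#' @return Object of class `"haplopop_amova"`: list with `table` (data frame
#'   of df, SS, variance components, percentages), `sigma`, `F`
#'   (`F_CT`, `F_SC`, `F_ST`), `p` (permutation p-values), `grouping`,
#'   `n_perm`, `seed`.
#' @export
amova <- function(counts, grouping = NULL, n_perm = 1023L, seed = 1L) {
  validate_count_table(counts)
  if (nrow(counts) < 2L) stop("AMOVA needs at least two populations")
  gidx <- .grouping_index(counts, grouping)
  G <- length(gidx)
  cmp <- .amova_components(counts, gidx)
  sig <- cmp$sigma
  tot <- sum(sig)
  FCT <- if (G > 1L) sig[1] / tot else NA_real_
  FSC <- if (G > 1L && G < nrow(counts)) sig[2] / (sig[2] + sig[3])
         else NA_real_
  FST <- (sig[1] + sig[2]) / tot
  p <- c(F_CT = NA_real_, F_SC = NA_real_, F_ST = NA_real_)
  if (n_perm > 0L) {
    set.seed(seed)
    sizes <- lengths(gidx)
    if (G > 1L) {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample(nrow(counts))
        pg <- split(perm, rep(seq_len(G), sizes))
        s <- .amova_components(counts, pg)$sigma
        if (s[1] / sum(s) >= FCT - 1e-12) hits <- hits + 1L
      }
      p["F_CT"] <- (hits + 1) / (n_perm + 1)
    }
    if (!is.na(FSC)) {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        s <- .amova_components(.permute_within_groups(counts, gidx),
                               gidx)$sigma
        if (s[2] / (s[2] + s[3]) >= FSC - 1e-12) hits <- hits + 1L
      }
      p["F_SC"] <- (hits + 1) / (n_perm + 1)
    }
    hits <- 0L
    all_idx <- list(seq_len(nrow(counts)))
    for (b in seq_len(n_perm)) {
      s <- .amova_components(.permute_within_groups(counts, all_idx),
                             gidx)$sigma
      if ((s[1] + s[2]) / sum(s) >= FST - 1e-12) hits <- hits + 1L
    }
    p["F_ST"] <- (hits + 1) / (n_perm + 1)
  }
  lvl <- c("Among groups", "Among populations within groups",
           "Within populations")
  keep <- if (G > 1L) 1:3 else 2:3
  tab <- data.frame(
    source = lvl[keep], df = cmp$df[keep], SS = cmp$SS[keep],
    variance = sig[keep], percentage = 100 * sig[keep] / tot,
    stringsAsFactors = FALSE)
  structure(list(table = tab, sigma = sig,
                 F = c(F_CT = FCT, F_SC = FSC, F_ST = FST), p = p,
                 grouping = lapply(gidx, function(i) rownames(counts)[i]),
                 n_perm = n_perm, seed = seed),
            class = "haplopop_amova")
}

#' @export
print.haplopop_amova <- function(x, ...) {
  cat("Hierarchical AMOVA (0/1 haplotype mismatch distance)\n")
  pcol <- if (nrow(x$table) == 3L) unname(x$p) else c(unname(x$p["F_ST"]), NA)
  print(cbind(x$table, p = pcol))
  cat(sprintf("F_CT = %.5f  F_SC = %.5f  F_ST = %.5f\n",
              x$F["F_CT"], x$F["F_SC"], x$F["F_ST"]))
  invisible(x)
}

#' Pairwise F_ST between all populations
#'
#' Two-population AMOVA-based `F_ST` (identity distance) per population pair;
#' negative estimates are retained.
#'
#' @param counts population-by-haplotype count matrix.
#' @return Symmetric matrix of pairwise `F_ST` (diagonal `NA`).
#' @export
pairwise_fst <- function(counts) {
  validate_count_table(counts)
  P <- nrow(counts)
  if (P < 2L) stop("need at least two populations")
  M <- matrix(NA_real_, P, P, dimnames = list(rownames(counts),
                                              rownames(counts)))
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    sub <- counts[c(i, j), , drop = FALSE]
    cmp <- .amova_components(sub, list(1:2))  # one group of both pops
    # two-level: among-populations component is sigma_b under a single group
    s <- cmp$sigma
    M[i, j] <- M[j, i] <- s[2] / (s[2] + s[3])
  }
  M
}

#' Rank candidate groupings by among-group differentiation
#'
#' Runs the hierarchical [amova()] for every candidate grouping and ranks
#' them by `F_CT`; duplicate groupings (identical partitions up to order) are
#' collapsed with a warning.
#'
#' @param counts count matrix.
#' @param groupings named list of groupings (each a list of character
#'   vectors).
#' @param n_perm permutations per grouping (default 50000, the published
#'   search depth; reduce for exploratory work).
#' @param seed RNG seed.
#' @return Data frame ranked by decreasing `F_CT` with columns `grouping`,
#'   `F_CT`, `pct_among`, `p`.
#' @export
grouping_search <- function(counts, groupings, n_perm = 50000L, seed = 1L) {
  stopifnot(is.list(groupings), length(groupings) >= 2L)
  canon <- vapply(groupings, function(g)
    paste(sort(vapply(g, function(v) paste(sort(v), collapse = ","),
                      character(1))), collapse = " | "), character(1))
  if (anyDuplicated(canon)) {
    warning("duplicate groupings collapsed")
    groupings <- groupings[!duplicated(canon)]
    canon <- canon[!duplicated(canon)]
  }
  rows <- lapply(seq_along(groupings), function(k) {
    a <- amova(counts, groupings[[k]], n_perm = n_perm, seed = seed + k)
    data.frame(grouping = if (!is.null(names(groupings)))
                 names(groupings)[k] else canon[k],
               F_CT = unname(a$F["F_CT"]),
               pct_among = a$table$percentage[1],
               p = unname(a$p["F_CT"]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$F_CT), , drop = FALSE]
}

# -- Hedrick's standardized G'ST -------------------------------------------

.gst_one_locus <- function(counts) {
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  k <- nrow(counts)
  Np <- rowSums(counts)
  ntilde <- k / sum(1 / Np)                       # harmonic mean sample size
  p <- counts / Np
  Hs_obs <- mean(1 - rowSums(p^2))
  Hs <- ntilde / (ntilde - 1) * Hs_obs
  pbar <- colMeans(p)
  Ht <- 1 - sum(pbar^2) + Hs / (ntilde * k)
  c(Hs = Hs, Ht = Ht, k = k)
}

#' Nei's G_ST and Hedrick's standardized G'_ST
#'
#' Sample-size-corrected gene diversities follow Nei & Chesser: the mean
#' within-population diversity `H_S` uses the `n/(n-1)` correction at the
#' harmonic mean sample size, and the total diversity `H_T` is computed from
#' unweighted mean allele frequencies with the `H_S/(n k)` correction.
#' `G_ST = (H_T - H_S)/H_T` and Hedrick's standardization divides by its
#' maximum given `H_S`:
#' `G'_ST = G_ST (k - 1 + H_S) / ((k - 1)(1 - H_S))`.
#' Multilocus panels are combined by averaging `H_S` and `H_T` across loci
#' before taking ratios (`combine = "mean_H"`); averaging per-locus ratios is
#' available as `combine = "mean_ratio"`.
#'
#' @param counts a population-by-allele count matrix, or a list of such
#'   matrices (one per locus, same populations).
#' @param combine multilocus combination rule.
#' @return List with `G_ST`, `G_prime_ST`, `H_S`, `H_T`, `k`, and `per_locus`
#'   (data frame) for multilocus input.
#' @export
gst_hedrick <- function(counts, combine = c("mean_H", "mean_ratio")) {
  combine <- match.arg(combine)
  loci <- if (is.matrix(counts)) list(counts) else counts
  stopifnot(length(loci) >= 1L)
  per <- t(vapply(loci, .gst_one_locus, numeric(3)))
  gst_from <- function(Hs, Ht, k) {
    Hs <- unname(Hs); Ht <- unname(Ht); k <- unname(k)
    if (Ht <= 0) return(c(G_ST = NA_real_, G_prime_ST = NA_real_))
    g <- (Ht - Hs) / Ht
    gp <- if (Hs >= 1) NA_real_ else g * (k - 1 + Hs) / ((k - 1) * (1 - Hs))
    c(G_ST = g, G_prime_ST = gp)
  }
  per_df <- data.frame(locus = if (!is.null(names(loci))) names(loci)
                               else paste0("L", seq_along(loci)),
                       H_S = per[, "Hs"], H_T = per[, "Ht"], k = per[, "k"],
                       stringsAsFactors = FALSE)
  pg <- t(apply(per, 1, function(r) gst_from(r["Hs"], r["Ht"], r["k"])))
  per_df$G_ST <- pg[, 1]; per_df$G_prime_ST <- pg[, 2]
  k <- per[1, "k"]
  if (combine == "mean_H") {
    Hs <- mean(per[, "Hs"]); Ht <- mean(per[, "Ht"])
    g <- gst_from(Hs, Ht, k)
  } else {
    g <- c(G_ST = mean(per_df$G_ST), G_prime_ST = mean(per_df$G_prime_ST))
    Hs <- mean(per[, "Hs"]); Ht <- mean(per[, "Ht"])
  }
  list(G_ST = unname(g["G_ST"]), G_prime_ST = unname(g["G_prime_ST"]),
       H_S = Hs, H_T = Ht, k = k,
       per_locus = if (length(loci) > 1L) per_df else NULL)
}

#' Pairwise multilocus G'_ST matrix
#'
#' @param counts count matrix or list of per-locus count matrices.
#' @param combine multilocus combination rule, see [gst_hedrick()].
#' @return Symmetric matrix of pairwise `G'_ST`.
#' @export
gst_pairwise <- function(counts, combine = "mean_H") {
  loci <- if (is.matrix(counts)) list(counts) else counts
  pops <- rownames(loci[[1]])
  P <- length(pops)
  M <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    sub <- lapply(loci, function(m) m[c(i, j), , drop = FALSE])
    M[i, j] <- M[j, i] <- gst_hedrick(sub, combine = combine)$G_prime_ST
  }
  M
}

#' Bootstrap neutral envelope for pairwise microsatellite G'_ST
#'
#' Resamples loci with replacement and recomputes the pairwise multilocus
#' `G'_ST`, yielding a percentile confidence interval per population pair.
#' The locus is the resampling unit: it is the only unit that captures
#' among-marker variation when a single haplotype locus is compared against
#' a multilocus neutral panel.
#'
#' @param loci list of per-locus population-by-allele count matrices.
#' @param B bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return Data frame with one row per population pair: `pop1`, `pop2`,
#'   `estimate`, `low`, `high`, `degenerate`.
#' @export
gst_bootstrap_envelope <- function(loci, B = 1000L, level = 0.95,
                                   seed = 1L) {
  stopifnot(is.list(loci), length(loci) >= 1L)
  degenerate <- length(loci) < 2L || B < 2L
  if (length(loci) < 2L)
    warning("single locus: bootstrap envelope is degenerate")
  pops <- rownames(loci[[1]])
  P <- length(pops)
  est <- gst_pairwise(loci)
  set.seed(seed)
  reps <- array(NA_real_, c(P, P, B))
  for (b in seq_len(B)) {
    pick <- sample(length(loci), replace = TRUE)
    reps[, , b] <- gst_pairwise(loci[pick])
  }
  alpha <- (1 - level) / 2
  rows <- list()
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    q <- stats::quantile(reps[i, j, ], c(alpha, 1 - alpha), na.rm = TRUE,
                         names = FALSE, type = 7)
    rows[[length(rows) + 1L]] <- data.frame(
      pop1 = pops[i], pop2 = pops[j], estimate = est[i, j],
      low = q[1], high = q[2], degenerate = degenerate,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Compare adaptive-marker G'_ST values against neutral envelopes
#'
#' Classifies each population pair's adaptive-marker `G'_ST` against the
#' neutral confidence interval: strictly above the high bound, strictly
#' below the low bound, or inside (intervals are closed, so a value equal to
#' a bound is `inside`).
#'
#' @param adaptive named numeric vector of adaptive-marker pairwise `G'_ST`,
#'   names `"pop1:pop2"`, or a matrix as from [gst_pairwise()].
#' @param envelope data frame from [gst_bootstrap_envelope()].
#' @return List with `calls` (data frame adding `adaptive` and
#'   `classification`), `n_above`, `n_below`.
#' @export
outlier_compare <- function(adaptive, envelope) {
  key <- paste(envelope$pop1, envelope$pop2, sep = ":")
  if (is.matrix(adaptive)) {
    vals <- adaptive[cbind(envelope$pop1, envelope$pop2)]
  } else {
    if (!all(key %in% names(adaptive)))
      stop("adaptive pair set does not match envelope pairs")
    vals <- unname(adaptive[key])
  }
  if (anyNA(vals)) stop("adaptive pair set does not match envelope pairs")
  cls <- ifelse(vals > envelope$high, "above",
                ifelse(vals < envelope$low, "below", "inside"))
  calls <- cbind(envelope, adaptive = vals, classification = cls)
  list(calls = calls, n_above = sum(cls == "above"),
       n_below = sum(cls == "below"))
}

#' Mantel test between two pairwise distance/differentiation matrices
#'
#' Pearson correlation over off-diagonal entries, with significance from
#' joint row/column permutation of one matrix,
#' `p = (#{permuted r >= observed} + 1)/(n_perm + 1)` (delegated to
#' \code{vegan::mantel}).
#'
#' @param A,B symmetric matrices of equal dimension.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return List with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(A, B, n_perm = 999L, seed = 1L) {
  stopifnot(is.matrix(A), is.matrix(B))
  if (!all(dim(A) == dim(B))) stop("matrix size mismatch")
  if (n_perm < 1L) {
    r <- stats::cor(as.vector(stats::as.dist(A)),
                    as.vector(stats::as.dist(B)))
    return(list(r = r, p = NA_real_, n_perm = 0L, seed = seed))
  }
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(A), stats::as.dist(B),
                       method = "pearson", permutations = n_perm)
  list(r = unname(fit$statistic), p = fit$signif, n_perm = n_perm,
       seed = seed)
}

#' Cavalli-Sforza & Edwards chord distance between populations
#'
#' `D_c = (2 / (pi L)) sum_l sqrt(2 (1 - sum_i sqrt(x_li y_li)))` over loci
#' `l` and allele frequencies `x`, `y`.
#'
#' @param counts count matrix or list of per-locus count matrices.
#' @return Symmetric distance matrix.
#' @export
chord_distance <- function(counts) {
  loci <- if (is.matrix(counts)) list(counts) else counts
  pops <- rownames(loci[[1]])
  P <- length(pops); L <- length(loci)
  freqs <- lapply(loci, function(m) m / rowSums(m))
  D <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P)) for (j in seq_len(P)) {
    if (i >= j) next
    s <- sum(vapply(freqs, function(f)
      sqrt(2 * max(0, 1 - sum(sqrt(f[i, ] * f[j, ])))), numeric(1)))
    D[i, j] <- D[j, i] <- 2 / (pi * L) * s
  }
  D
}

#' Neighbour-joining population tree from chord distances, with bootstrap
#'
#' Builds the NJ tree on the chord distance matrix and, when `n_boot > 0`,
#' evaluates node support by resampling gene copies with replacement within
#' each population and recording the fraction of bootstrap trees containing
#' each bipartition.
#'
#' @param counts count matrix or list of per-locus count matrices.
#' @param n_boot bootstrap replicates (0 for none).
#' @param seed RNG seed.
#' @return List with `tree` (class `phylo`, support values in
#'   `node.label` as fractions), `newick` (string) and `n_boot`.
#' @export
chord_nj_tree <- function(counts, n_boot = 0L, seed = 1L) {
  loci <- if (is.matrix(counts)) list(counts) else counts
  if (nrow(loci[[1]]) < 3L) stop("need at least three populations")
  if (any(vapply(loci, function(m) any(rowSums(m) == 0), logical(1))))
    stop("population with zero gene copies")
  tree <- ape::nj(stats::as.dist(chord_distance(loci)))
  support <- NULL
  if (n_boot > 0L) {
    set.seed(seed)
    resample <- function(m) {
      out <- m
      for (r in seq_len(nrow(m))) {
        n <- sum(m[r, ])
        out[r, ] <- stats::rmultinom(1, n, m[r, ] / n)
      }
      out
    }
    boots <- lapply(seq_len(n_boot), function(b)
      ape::nj(stats::as.dist(chord_distance(lapply(loci, resample)))))
    class(boots) <- "multiPhylo"
    hits <- ape::prop.clades(tree, boots, rooted = FALSE)
    hits[is.na(hits)] <- 0L
    support <- hits / n_boot
    tree$node.label <- round(support, 3)
  }
  list(tree = tree, newick = ape::write.tree(tree), n_boot = n_boot,
       support = support)
}

#' t-test of among-group versus within-group pairwise F_ST
#'
#' Splits the off-diagonal pairwise values by whether the two populations
#' fall in the same group and compares the classes with a pooled-variance
#' two-sample t-test.
#'
#' @param fst matrix of pairwise values.
#' @param grouping list of character vectors partitioning the populations.
#' @return List with `t`, `df`, `p`, `n_among`, `n_within`.
#' @export
fst_group_ttest <- function(fst, grouping) {
  pops <- rownames(fst)
  gl <- stats::setNames(rep(seq_along(grouping), lengths(grouping)),
                        unlist(grouping))
  if (!all(pops %in% names(gl))) stop("grouping must cover all populations")
  among <- c(); within <- c()
  P <- nrow(fst)
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    if (gl[pops[i]] == gl[pops[j]]) within <- c(within, fst[i, j])
    else among <- c(among, fst[i, j])
  }
  if (length(among) < 2L || length(within) < 2L)
    stop("need at least two pairs in each class")
  if (stats::sd(among) == 0 && stats::sd(within) == 0)
    stop("t statistic undefined: zero variance in both classes")
  tt <- stats::t.test(among, within, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       n_among = length(among), n_within = length(within))
}
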