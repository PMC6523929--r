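# Independent oracles, coded from first principles and kept separate from
# the package implementation paths they check.

# Weir & Cockerham theta for haploid allele-count data, two or more
# populations, any allele number (sum over alleles of components).
oracle_wc_theta <- function(counts) {
  r <- nrow(counts)
  n_i <- rowSums(counts)
  N <- sum(n_i)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  msp_tot <- 0
  msg_tot <- 0
  for (a in seq_len(ncol(counts))) {
    p_i <- counts[, a] / n_i
    pbar <- sum(counts[, a]) / N
    MSP <- sum(n_i * (p_i - pbar)^2) / (r - 1)
    MSG <- sum(n_i * p_i * (1 - p_i)) / (N - r)
    msp_tot <- msp_tot + MSP
    msg_tot <- msg_tot + MSG
  }
  sa <- (msp_tot - msg_tot) / nc
  sa / (sa + msg_tot)
}

# Hedrick's G'ST written directly from the textbook formulas (Nei & Chesser
# corrected Hs/Ht, then the standardization), structured differently from
# the package code.
oracle_gst_prime <- function(counts) {
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  k <- nrow(counts)
  sizes <- rowSums(counts)
  harm <- 1 / mean(1 / sizes)
  homo <- vapply(seq_len(k), function(i)
    sum((counts[i, ] / sizes[i])^2), numeric(1))
  Hs <- (harm / (harm - 1)) * (1 - mean(homo))
  pbar <- vapply(seq_len(ncol(counts)), function(a)
    mean(counts[, a] / sizes), numeric(1))
  Ht <- 1 - sum(pbar^2) + Hs / (harm * k)
  Gst <- (Ht - Hs) / Ht
  Gst * (k - 1 + Hs) / ((k - 1) * (1 - Hs))
}

# Monte-Carlo rarefaction: expected allele count in subsamples of g copies
# drawn without replacement.
oracle_rarefaction_mc <- function(counts, g, n_draws = 10000L) {
  pool <- rep(seq_along(counts), counts)
  mean(vapply(seq_len(n_draws), function(i)
    length(unique(sample(pool, g))), numeric(1)))
}

# Brute-force ML haplotype frequencies for a 2x2-allele two-locus sample:
# margins are phase-invariant, so the likelihood is maximized over the
# single free coupling-haplotype frequency on a fine grid.
oracle_em_grid_2x2 <- function(geno, grid_n = 4001L) {
  a <- sort(unique(c(geno[, 1], geno[, 2])))
  b <- sort(unique(c(geno[, 3], geno[, 4])))
  stopifnot(length(a) == 2L, length(b) == 2L)
  n <- nrow(geno)
  pA <- mean(c(geno[, 1], geno[, 2]) == a[1])
  pB <- mean(c(geno[, 3], geno[, 4]) == b[1])
  loglik <- function(f11) {
    f <- c(f11, pA - f11, pB - f11, 1 - pA - pB + f11)
    names(f) <- c(paste(a[1], b[1], sep = "|"), paste(a[1], b[2], sep = "|"),
                  paste(a[2], b[1], sep = "|"), paste(a[2], b[2], sep = "|"))
    if (any(f < -1e-12)) return(-Inf)
    f <- pmax(f, 0)
    ll <- 0
    for (i in seq_len(n)) {
      g1 <- geno[i, 1:2]; g2 <- geno[i, 3:4]
      pr <- function(h1, h2) {
        p <- f[h1] * f[h2]
        if (h1 != h2) 2 * p else p
      }
      h <- function(x, y) paste(x, y, sep = "|")
      p <- pr(h(g1[1], g2[1]), h(g1[2], g2[2]))
      if (g1[1] != g1[2] && g2[1] != g2[2])
        p <- p + pr(h(g1[1], g2[2]), h(g1[2], g2[1]))
      ll <- ll + log(p)
    }
    ll
  }
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = grid_n)
  lls <- vapply(grid, loglik, numeric(1))
  best <- grid[which.max(lls)]
  c(f11 = best, loglik = max(lls), pA = pA, pB = pB)
}

# Brute-force pathway counting between two codons: enumerate substitution
# orders directly on nucleotide strings, skipping stop-codon intermediates.
oracle_codon_paths <- function(c1, c2, code) {
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(d) == 0L) return(c(syn = 0, nonsyn = 0))
  orders <- if (length(d) == 1L) list(d) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    perms(d)
  }
  results <- list()
  for (ord in orders) {
    cur <- c1; s <- 0; n <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code[nxt] == "*") { ok <- FALSE; break }
      if (code[nxt] == code[cur]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) results[[length(results) + 1L]] <- c(s, n)
  }
  if (length(results) == 0L) return(NULL)
  m <- do.call(rbind, results)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

# random population-by-allele count table
random_count_table <- function(n_pops, n_alleles, copies_range = c(20, 80)) {
  t(vapply(seq_len(n_pops), function(i) {
    n <- sample(copies_range[1]:copies_range[2], 1)
    as.integer(stats::rmultinom(1, n, stats::runif(n_alleles, 0.2, 1)))
  }, integer(n_alleles))) |>
    (\(m) { rownames(m) <- paste0("P", seq_len(n_pops)); m })()
}

# simulate unphased genotypes for two loci in linkage equilibrium
sim_le_genotypes <- function(n, pa, pb) {
  a <- names(pa); b <- names(pb)
  g <- matrix("", n, 4)
  for (i in seq_len(n)) {
    g[i, 1:2] <- sample(a, 2, replace = TRUE, prob = pa)
    g[i, 3:4] <- sample(b, 2, replace = TRUE, prob = pb)
  }
  g
}
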