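# Rule-based phasing of two-locus MHC diplotypes.
#
# Phase is resolved in three tiers, in order: (1) individuals with at most one
# heterozygous locus are phase-unambiguous; (2) doubly heterozygous
# individuals with both parents already phased are resolved by Mendelian
# transmission, allowing at most one block-recombination per gamete; (3) the
# remainder are resolved towards the most frequent haplotypes of their own
# population.  An EM estimator over unphased genotypes provides an
# independent frequency cross-check.

.as_genotype <- function(genotype) {
  # accept list(dab=, uaa=) with length-2 vectors or "a/b" strings
  g <- genotype
  for (locus in c("dab", "uaa")) {
    v <- g[[locus]]
    if (is.null(v)) stop("genotype must carry dab and uaa")
    if (length(v) == 1L) v <- strsplit(v, "/", fixed = TRUE)[[1]]
    if (length(v) != 2L || anyNA(v))
      stop("genotype at ", locus, " must be an unordered allele pair")
    g[[locus]] <- sort(v)
  }
  g
}

.phase_result <- function(haplotypes = NULL, method = NA_character_,
                          status = "phased", note = NA_character_,
                          recombination = NULL) {
  structure(list(haplotypes = if (is.null(haplotypes)) NULL
                              else sort(haplotypes),
                 method = method, status = status, note = note,
                 recombination = recombination),
            class = "haplopop_phase")
}

#' @export
print.haplopop_phase <- function(x, ...) {
  if (x$status == "phased")
    cat(sprintf("diplotype %s/%s (%s)%s\n", x$haplotypes[1], x$haplotypes[2],
                x$method, if (is.na(x$note)) "" else paste0(" - ", x$note)))
  else cat(x$status, if (!is.na(x$note)) x$note, "\n")
  invisible(x)
}

#' Tier 1: phase individuals with at most one heterozygous locus
#'
#' With the DAB--UAA block treated as two linked loci, phase is trivially
#' known whenever at most one locus is heterozygous: the two gametes are then
#' fully determined.  Doubly heterozygous genotypes are returned `undecided`
#' for the later tiers.
#'
#' @param genotype list with elements `dab` and `uaa`, each an unordered
#'   allele pair (length-2 vector or `"a1/a2"` string).
#' @param catalog haplotype catalog, see [mhc_haplotype_catalog()].
#' @return A phase result: list with `haplotypes` (sorted pair of haplotype
#'   ids or `NULL`), `method`, `status` (`"phased"` or `"undecided"`).
#' @export
phase_unambiguous <- function(genotype, catalog = mhc_haplotype_catalog()) {
  g <- .as_genotype(genotype)
  het <- (g$dab[1] != g$dab[2]) + (g$uaa[1] != g$uaa[2])
  cand <- compatible_diplotypes(g$dab, g$uaa, catalog)
  if (length(cand) == 0L)
    stop(sprintf("genotype DAB %s/%s, UAA %s/%s matches no haplotype pair in catalog",
                 g$dab[1], g$dab[2], g$uaa[1], g$uaa[2]))
  if (het >= 2L)
    return(.phase_result(status = "undecided", method = NA_character_,
                         note = "heterozygous at both loci"))
  .phase_result(cand[[1]], method = "unambiguous")
}

# gametes a parent diplotype can produce; n_rec = block recombinations needed
.parent_gametes <- function(diplotype, catalog) {
  p <- catalog[match(diplotype, catalog$id), ]
  g <- data.frame(hap = p$id, n_rec = 0L, parental = p$id,
                  stringsAsFactors = FALSE)
  if (nrow(p) == 2L) {
    for (k in 1:2) {
      other <- 3L - k
      h <- haplotype_for_alleles(p$dab[k], p$uaa[other], catalog)
      if (!is.na(h)) # recombinant keeps the DAB block of haplotype k
        g <- rbind(g, data.frame(hap = h, n_rec = 1L, parental = p$id[k],
                                 stringsAsFactors = FALSE))
    }
  }
  g[!duplicated(g[c("hap", "n_rec", "parental")]), ]
}

#' Tier 2: phase a doubly heterozygous child through its phased parents
#'
#' Assumes Mendelian transmission: one haplotype from each parent.  If no
#' recombination-free solution exists, solutions requiring a single block
#' recombination (exchange of the `UAA` allele between the two parental
#' haplotypes during meiosis) are considered and the minimum-recombination
#' solution is returned together with the implied recombination event(s);
#' solutions needing two or more recombinant gametes are rejected.  Multiple
#' equally parsimonious solutions leave the child `undecided`.
#'
#' @param child_id individual label (used in recombination records).
#' @param genotype child genotype, as for [phase_unambiguous()].
#' @param sire,dam phased parental diplotypes (length-2 vectors of haplotype
#'   ids).
#' @param catalog haplotype catalog.
#' @return A phase result; when recombination is implied, element
#'   `recombination` is a data frame with columns `child`, `observed`,
#'   `parental`, `meiosis`.
#' @export
phase_by_pedigree <- function(child_id, genotype, sire, dam,
                              catalog = mhc_haplotype_catalog()) {
  g <- .as_genotype(genotype)
  cand <- compatible_diplotypes(g$dab, g$uaa, catalog)
  if (length(cand) == 0L) stop("child genotype matches no haplotype pair")
  child_alleles_ok <- function() {
    par_hap <- catalog[match(c(sire, dam), catalog$id), ]
    all(g$dab %in% par_hap$dab)  # recombination cannot create new alleles
  }
  gs <- .parent_gametes(sire, catalog)
  gd <- .parent_gametes(dam, catalog)
  sols <- list()
  for (dip in cand) {
    # haplotype 1 from sire + haplotype 2 from dam, and the swap
    for (ord in list(dip, rev(dip))) {
      is <- which(gs$hap == ord[1])
      id <- which(gd$hap == ord[2])
      for (a in is) for (b in id) {
        sols[[length(sols) + 1L]] <- list(
          dip = sort(dip), cost = gs$n_rec[a] + gd$n_rec[b],
          ev = rbind(
            if (gs$n_rec[a] > 0)
              data.frame(child = child_id, observed = gs$hap[a],
                         parental = gs$parental[a], meiosis = "sire",
                         stringsAsFactors = FALSE),
            if (gd$n_rec[b] > 0)
              data.frame(child = child_id, observed = gd$hap[b],
                         parental = gd$parental[b], meiosis = "dam",
                         stringsAsFactors = FALSE)))
      }
    }
  }
  if (length(sols) == 0L) {
    if (!child_alleles_ok())
      stop(sprintf("Mendelian incompatibility: child %s carries an allele absent from both parents",
                   child_id))
    return(.phase_result(status = "undecided",
                         note = "no transmissible solution with <2 recombinations"))
  }
  costs <- vapply(sols, `[[`, 1, "cost")
  best <- sols[costs == min(costs)]
  dips <- unique(lapply(best, `[[`, "dip"))
  if (length(dips) > 1L)
    return(.phase_result(status = "undecided",
                         note = "multiple equally parsimonious solutions"))
  # same diplotype may be reachable by several event attributions; keep one
  sol <- best[[1]]
  .phase_result(sol$dip, method = "pedigree",
                note = if (sol$cost > 0) "recombinant gamete" else NA_character_,
                recombination = sol$ev)
}

#' Tier 3: phase towards the most frequent haplotypes of the population
#'
#' Among the diplotypes compatible with a doubly heterozygous genotype, the
#' one maximizing the product of the population haplotype frequencies is
#' selected.  Exact ties are broken towards the lexicographically first
#' haplotype pair and flagged low-confidence.
#'
#' @param genotype child genotype.
#' @param freqs named numeric vector of haplotype frequencies for the
#'   individual's own population.
#' @param catalog haplotype catalog.
#' @return A phase result; `status` is `"unresolvable"` when every compatible
#'   diplotype has zero frequency support.
#' @export
phase_by_frequency <- function(genotype, freqs,
                               catalog = mhc_haplotype_catalog()) {
  g <- .as_genotype(genotype)
  cand <- compatible_diplotypes(g$dab, g$uaa, catalog)
  if (length(cand) == 0L) stop("genotype matches no haplotype pair")
  f <- function(h) if (h %in% names(freqs)) unname(freqs[h]) else 0
  score <- vapply(cand, function(d) f(d[1]) * f(d[2]), numeric(1))
  if (all(score == 0))
    return(.phase_result(status = "unresolvable",
                         note = "all compatible haplotypes at zero frequency"))
  top <- which(score == max(score))
  if (length(top) > 1L) {
    keys <- vapply(cand[top], paste, character(1), collapse = "/")
    pick <- top[order(keys)][1]
    return(.phase_result(cand[[pick]], method = "frequency",
                         note = "tie broken lexicographically (low confidence)"))
  }
  .phase_result(cand[[top]], method = "frequency")
}

#' Phase a whole sample through the three tiers
#'
#' Applies [phase_unambiguous()] to every individual, then iterates
#' [phase_by_pedigree()] over doubly heterozygous individuals whose parents
#' are phased until no further progress, and finally applies
#' [phase_by_frequency()] using haplotype frequencies pooled from the already
#' phased gametes of each individual's own population.
#'
#' @param genotypes genotype table ([read_genotype_table()] format: columns
#'   `id`, `population`, `dab`, `uaa`).
#' @param pedigree optional pedigree data frame ([read_pedigree()] format).
#' @param catalog haplotype catalog.
#' @param freqs optional named list of per-population haplotype frequency
#'   vectors overriding the pooled tier-3 frequencies.
#' @return Data frame with columns `id`, `population`, `h1`, `h2`, `method`,
#'   `note`; attribute `"recombination"` collects all inferred recombination
#'   events.
#' @export
phase_population <- function(genotypes, pedigree = NULL,
                             catalog = mhc_haplotype_catalog(),
                             freqs = NULL) {
  n <- nrow(genotypes)
  out <- data.frame(id = genotypes$id, population = genotypes$population,
                    h1 = NA_character_, h2 = NA_character_,
                    method = NA_character_, note = NA_character_,
                    stringsAsFactors = FALSE)
  recs <- list()
  geno_of <- function(i) list(dab = genotypes$dab[i], uaa = genotypes$uaa[i])
  store <- function(i, r) {
    out$h1[i] <<- r$haplotypes[1]; out$h2[i] <<- r$haplotypes[2]
    out$method[i] <<- r$method; out$note[i] <<- r$note
    if (!is.null(r$recombination))
      recs[[length(recs) + 1L]] <<- r$recombination
  }
  for (i in seq_len(n)) {
    r <- phase_unambiguous(geno_of(i), catalog)
    if (r$status == "phased") store(i, r)
  }
  if (!is.null(pedigree)) {
    repeat {
      progressed <- FALSE
      for (i in which(is.na(out$h1))) {
        p <- pedigree[match(genotypes$id[i], pedigree$id), ]
        if (nrow(p) == 0L || is.na(p$sire) || is.na(p$dam)) next
        si <- match(p$sire, out$id); di <- match(p$dam, out$id)
        if (is.na(si) || is.na(di) || is.na(out$h1[si]) || is.na(out$h1[di]))
          next
        r <- phase_by_pedigree(genotypes$id[i], geno_of(i),
                               c(out$h1[si], out$h2[si]),
                               c(out$h1[di], out$h2[di]), catalog)
        if (r$status == "phased") { store(i, r); progressed <- TRUE }
      }
      if (!progressed) break
    }
  }
  if (any(is.na(out$h1))) {
    pool <- function(pop) {
      if (!is.null(freqs) && pop %in% names(freqs)) return(freqs[[pop]])
      ph <- out[!is.na(out$h1) & out$population == pop, ]
      if (nrow(ph) == 0L) ph <- out[!is.na(out$h1), ]  # fall back to pooled
      tab <- table(c(ph$h1, ph$h2))
      tab / sum(tab)
    }
    for (i in which(is.na(out$h1))) {
      r <- phase_by_frequency(geno_of(i), pool(genotypes$population[i]),
                              catalog)
      if (r$status == "phased") store(i, r)
      else out$note[i] <- r$note
    }
  }
  attr(out, "recombination") <-
    if (length(recs)) do.call(rbind, recs)
    else data.frame(child = character(0), observed = character(0),
                    parental = character(0), meiosis = character(0))
  out
}

# -- EM haplotype frequency estimation -------------------------------------

#' EM estimation of two-locus haplotype frequencies from unphased genotypes
#'
#' Standard expectation-maximization for gametic phase over a pair of
#' multiallelic loci under Hardy-Weinberg: double heterozygotes are split
#' between their two phase resolutions in proportion to the current haplotype
#' frequency products.  The log-likelihood is non-decreasing across
#' iterations.
#'
#' @param geno matrix or data frame with four columns: the two alleles at
#'   locus A and the two alleles at locus B, one row per individual.
#' @param tol convergence tolerance on the maximum absolute frequency change.
#' @param max_iter iteration cap; exceeding it raises a warning.
#' @return List with `freq` (named vector, names `"a|b"`), `loglik`,
#'   `iterations`, `converged`.
#' @export
em_haplotype_frequencies <- function(geno, tol = 1e-8, max_iter = 1000L) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == 4L, nrow(geno) >= 1L)
  a_all <- sort(unique(c(geno[, 1], geno[, 2])))
  b_all <- sort(unique(c(geno[, 3], geno[, 4])))
  hkey <- function(a, b) paste(a, b, sep = "|")
  haps <- as.vector(outer(a_all, b_all, hkey))
  # per-individual phase resolutions: list of (hap1, hap2) index pairs
  res <- lapply(seq_len(nrow(geno)), function(i) {
    a <- geno[i, 1:2]; b <- geno[i, 3:4]
    r1 <- c(hkey(a[1], b[1]), hkey(a[2], b[2]))
    if (a[1] != a[2] && b[1] != b[2]) {
      r2 <- c(hkey(a[1], b[2]), hkey(a[2], b[1]))
      list(match(r1, haps), match(r2, haps))
    } else list(match(r1, haps))
  })
  f <- rep(1 / length(haps), length(haps))
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    cnt <- numeric(length(haps))
    ll_new <- 0
    for (r in res) {
      w <- vapply(r, function(p) {
        pr <- f[p[1]] * f[p[2]]
        if (p[1] != p[2]) 2 * pr else pr
      }, numeric(1))
      s <- sum(w)
      ll_new <- ll_new + log(s)
      w <- if (s > 0) w / s else rep(1 / length(w), length(w))
      for (k in seq_along(r)) {
        cnt[r[[k]][1]] <- cnt[r[[k]][1]] + w[k]
        cnt[r[[k]][2]] <- cnt[r[[k]][2]] + w[k]
      }
    }
    f_new <- cnt / sum(cnt)
    delta <- max(abs(f_new - f))
    f <- f_new
    ll <- ll_new
    if (delta < tol)
      return(list(freq = stats::setNames(f, haps), loglik = ll,
                  iterations = it, converged = TRUE))
  }
  warning("EM did not converge within ", max_iter, " iterations")
  list(freq = stats::setNames(f, haps), loglik = ll,
       iterations = max_iter, converged = FALSE)
}

# log-likelihood of unphased genotypes under given haplotype frequencies
.two_locus_loglik <- function(geno, freq) {
  hkey <- function(a, b) paste(a, b, sep = "|")
  f <- function(h) if (h %in% names(freq)) unname(freq[h]) else 0
  ll <- 0
  for (i in seq_len(nrow(geno))) {
    a <- geno[i, 1:2]; b <- geno[i, 3:4]
    pr <- function(h1, h2) {
      p <- f(h1) * f(h2)
      if (h1 != h2) 2 * p else p
    }
    p <- pr(hkey(a[1], b[1]), hkey(a[2], b[2]))
    if (a[1] != a[2] && b[1] != b[2])
      p <- p + pr(hkey(a[1], b[2]), hkey(a[2], b[1]))
    ll <- ll + log(p)
  }
  ll
}

#' Likelihood-ratio permutation test of linkage disequilibrium (phase unknown)
#'
#' Compares the EM maximum likelihood under free haplotype frequencies with
#' the likelihood under independence (haplotype frequencies equal to products
#' of allele frequencies).  Significance is assessed by permuting the
#' genotypes of one locus among individuals, which preserves both single-locus
#' genotype distributions while destroying inter-locus association:
#' `p = (#{permuted LR >= observed} + 1) / (n_perm + 1)`.
#'
#' @param geno four-column genotype matrix as in
#'   [em_haplotype_frequencies()].
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed (recorded in the result).
#' @return List with `lr`, `p`, `n_perm`, `seed`, `em` (the observed-data EM
#'   fit).
#' @export
ld_test <- function(geno, n_perm = 10000L, seed = 1L) {
  geno <- as.matrix(geno)
  if (length(unique(c(geno[, 1], geno[, 2]))) < 2L ||
      length(unique(c(geno[, 3], geno[, 4]))) < 2L)
    stop("LD test undefined: monomorphic locus")
  lr_stat <- function(g) {
    em <- em_haplotype_frequencies(g)
    pa <- table(c(g[, 1], g[, 2])) / (2 * nrow(g))
    pb <- table(c(g[, 3], g[, 4])) / (2 * nrow(g))
    f0 <- as.vector(outer(pa, pb))
    names(f0) <- as.vector(outer(names(pa), names(pb), paste, sep = "|"))
    list(lr = 2 * (em$loglik - .two_locus_loglik(g, f0)), em = em)
  }
  obs <- lr_stat(geno)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    g <- geno
    g[, 3:4] <- g[sample(nrow(g)), 3:4]
    lr_stat(g)$lr
  }, numeric(1))
  list(lr = obs$lr, p = (sum(perm >= obs$lr - 1e-12) + 1) / (n_perm + 1),
       n_perm = n_perm, seed = seed, em = obs$em)
}

#' Phase-known LD coefficients D and D' per allele pair
#'
#' From a table of phased two-locus haplotype counts, computes for every
#' allele pair `D = p_AB - p_A p_B` and the normalized `D' = D / D_max`,
#' where `D_max = min(p_A (1-p_B), (1-p_A) p_B)` for positive `D` and
#' `min(p_A p_B, (1-p_A)(1-p_B))` for negative `D`.  Pairs involving an
#' allele at frequency 0 or 1 are skipped with a note.
#'
#' @param hap_counts numeric matrix of haplotype counts, locus-A alleles in
#'   rows, locus-B alleles in columns.
#' @return Data frame with columns `allele_a`, `allele_b`, `D`, `Dprime`,
#'   `note`.
#' @export
ld_coefficients <- function(hap_counts) {
  stopifnot(is.matrix(hap_counts), sum(hap_counts) > 0)
  f <- hap_counts / sum(hap_counts)
  pa <- rowSums(f); pb <- colSums(f)
  out <- expand.grid(allele_a = rownames(f), allele_b = colnames(f),
                     stringsAsFactors = FALSE)
  out$D <- NA_real_; out$Dprime <- NA_real_; out$note <- NA_character_
  for (k in seq_len(nrow(out))) {
    i <- out$allele_a[k]; j <- out$allele_b[k]
    if (pa[i] %in% c(0, 1) || pb[j] %in% c(0, 1)) {
      out$note[k] <- "allele frequency 0 or 1; coefficient undefined"
      next
    }
    D <- f[i, j] - pa[i] * pb[j]
    dmax <- if (D >= 0) min(pa[i] * (1 - pb[j]), (1 - pa[i]) * pb[j])
            else min(pa[i] * pb[j], (1 - pa[i]) * (1 - pb[j]))
    out$D[k] <- D
    out$Dprime[k] <- if (dmax > 0) D / dmax else 0
  }
  out
}

# -- parentage verification -------------------------------------------------

.msat_pair <- function(x) {
  if (is.na(x)) return(NULL)
  as.integer(strsplit(x, "/", fixed = TRUE)[[1]])
}

# loci where child shares no allele with the candidate parent
.single_exclusions <- function(child, cand, loci, geno) {
  ci <- match(child, geno$id); ki <- match(cand, geno$id)
  n <- 0L
  for (l in loci) {
    a <- .msat_pair(geno[[l]][ci]); b <- .msat_pair(geno[[l]][ki])
    if (is.null(a) || is.null(b)) next
    if (length(intersect(a, b)) == 0L) n <- n + 1L
  }
  n
}

# loci where no joint assignment (one allele from each parent) exists
.pair_exclusions <- function(child, sire, dam, loci, geno) {
  ci <- match(child, geno$id)
  si <- match(sire, geno$id); di <- match(dam, geno$id)
  n <- 0L
  for (l in loci) {
    a <- .msat_pair(geno[[l]][ci])
    s <- .msat_pair(geno[[l]][si]); d <- .msat_pair(geno[[l]][di])
    if (is.null(a) || is.null(s) || is.null(d)) next
    ok <- (a[1] %in% s && a[2] %in% d) || (a[2] %in% s && a[1] %in% d)
    if (!ok) n <- n + 1L
  }
  n
}

#' Verify recorded parentage against microsatellite genotypes
#'
#' Captive cages may hold more than one breeding pair, so recorded
#' parentages can be wrong.  Every candidate sire-dam pair is scored by the
#' number of loci at which the child's genotype is Mendelian-impossible
#' (no assignment of one child allele to each parent).  The recorded pair is
#' kept if it has zero exclusions; if it is excluded while exactly one
#' alternative pair is not, a correction is reported.
#'
#' @param child child id.
#' @param recorded_sire,recorded_dam recorded parents (may be `NA`).
#' @param candidate_sires,candidate_dams character vectors of candidate
#'   parents (should include the recorded ones).
#' @param genotypes genotype table with microsatellite columns (`a1/a2`),
#'   attribute `"msat_loci"` or all non-id columns used.
#' @return List with `best` (named pair), `pair_exclusions` (data frame over
#'   all candidate pairs), `per_candidate` (single-parent exclusion counts),
#'   `corrected` (logical), `status` (`"confirmed"`, `"corrected"`,
#'   `"ambiguous"` or `"orphan"`).
#' @export
verify_parentage <- function(child, recorded_sire, recorded_dam,
                             candidate_sires, candidate_dams, genotypes) {
  loci <- attr(genotypes, "msat_loci")
  if (is.null(loci))
    loci <- setdiff(names(genotypes),
                    c("id", "population", "dab", "uaa"))
  candidate_sires <- unique(c(recorded_sire[!is.na(recorded_sire)],
                              candidate_sires))
  candidate_dams <- unique(c(recorded_dam[!is.na(recorded_dam)],
                             candidate_dams))
  if (length(candidate_sires) == 0L || length(candidate_dams) == 0L)
    stop("need at least one candidate on each side")
  pairs <- expand.grid(sire = candidate_sires, dam = candidate_dams,
                       stringsAsFactors = FALSE)
  pairs$exclusions <- vapply(seq_len(nrow(pairs)), function(k)
    .pair_exclusions(child, pairs$sire[k], pairs$dam[k], loci, genotypes),
    integer(1))
  per_cand <- rbind(
    data.frame(candidate = candidate_sires, side = "sire",
               exclusions = vapply(candidate_sires, .single_exclusions,
                                   integer(1), child = child, loci = loci,
                                   geno = genotypes),
               stringsAsFactors = FALSE),
    data.frame(candidate = candidate_dams, side = "dam",
               exclusions = vapply(candidate_dams, .single_exclusions,
                                   integer(1), child = child, loci = loci,
                                   geno = genotypes),
               stringsAsFactors = FALSE))
  zero <- pairs[pairs$exclusions == 0L, , drop = FALSE]
  rec_ok <- !is.na(recorded_sire) && !is.na(recorded_dam) &&
    any(zero$sire == recorded_sire & zero$dam == recorded_dam)
  if (nrow(zero) == 0L)
    return(list(best = NULL, pair_exclusions = pairs,
                per_candidate = per_cand, corrected = FALSE,
                status = "orphan"))
  if (rec_ok)
    return(list(best = c(sire = recorded_sire, dam = recorded_dam),
                pair_exclusions = pairs, per_candidate = per_cand,
                corrected = FALSE, status = "confirmed"))
  if (nrow(zero) == 1L)
    return(list(best = c(sire = zero$sire, dam = zero$dam),
                pair_exclusions = pairs, per_candidate = per_cand,
                corrected = TRUE, status = "corrected"))
  list(best = NULL, pair_exclusions = pairs, per_candidate = per_cand,
       corrected = FALSE, status = "ambiguous")
}
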