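# Forward-in-time founder-effect simulator.  Discrete non-overlapping
# generations, monogamous random pairing, Mendelian transmission of the
# DAB--UAA haplotype block with rare block recombination, and unlinked
# microsatellites mutating under the stepwise mutation model.  Produces a
# genotype table covering every simulated individual, a pedigree with
# cage-mate candidate parents, and a truth set (true diplotypes with
# parental origin, recombination events) so that the phasing and
# differentiation machinery can be validated end to end.

#' Printed-table haplotype count fixture
#'
#' The seven-population haplotype count matrix reconstructed from the
#' published percentage frequencies (one decimal) and sample sizes via
#' [reconstruct_counts()]; row sums are the per-population gene copies
#' (16, 108, 96, 90, 70, 36, 172).
#'
#' @return Integer matrix, populations (Wild, YX, LGT, DQ, BJ, SD, HN) by
#'   haplotypes (HT01--HT07).
#' @export
make_table2_fixture <- function() {
  freq <- rbind(
    Wild = c(6.3, 43.8, 25.0, 12.5, 12.5, 0.0, 0.0),
    YX   = c(7.4, 28.7, 26.9, 19.4, 17.6, 0.0, 0.0),
    LGT  = c(5.2, 44.8, 21.9, 15.6, 11.5, 1.0, 0.0),
    DQ   = c(10.0, 51.1, 18.9, 6.7, 12.2, 1.1, 0.0),
    BJ   = c(0.0, 14.3, 60.0, 2.9, 8.6, 0.0, 14.3),
    SD   = c(0.0, 25.0, 36.1, 22.2, 5.6, 0.0, 11.1),
    HN   = c(0.0, 28.5, 32.0, 32.0, 1.2, 0.0, 6.4))
  copies <- c(Wild = 16L, YX = 108L, LGT = 96L, DQ = 90L, BJ = 70L,
              SD = 36L, HN = 172L)
  out <- t(vapply(rownames(freq), function(p)
    reconstruct_counts(freq[p, ], copies[[p]]), integer(7)))
  colnames(out) <- paste0("HT0", 1:7)
  validate_count_table(out)
  out
}

#' Default simulation configuration
#'
#' Mirrors the documented founding history of the seven study populations:
#' a six-bird wild source and six serially founded captive populations
#' (founder counts per the published establishment summary), compressed to
#' nine discrete generations.  Founders are removed from the source
#' population at the event generation.  Defaults: block recombination
#' probability `r_rec = 0.01` per meiosis, stepwise microsatellite mutation
#' rate `mu = 5e-4` per meiosis, 11 di/tri-allelic microsatellite loci, and
#' monogamous pairing with Poisson(6) offspring per pair truncated to the
#' carrying capacity (roughly threefold growth per generation, consistent
#' with the species' rapid managed recovery).
#'
#' @param founder_freqs named haplotype frequency vector of the wild source.
#' @param events data frame of founding events: columns `pop`, `generation`,
#'   `sources` (comma-separated source populations, `""` for the root),
#'   `n_founders` (comma-separated counts aligned with `sources`).
#' @param capacity named per-population carrying capacities.
#' @param n_generations total simulated generations.
#' @param r_rec,mu recombination and microsatellite mutation probabilities
#'   per meiosis.
#' @param offspring_lambda mean of the per-pair Poisson offspring number.
#' @param n_msat number of microsatellite loci.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(founder_freqs = c(HT01 = 0.06, HT02 = 0.40,
                                         HT03 = 0.22, HT04 = 0.12,
                                         HT05 = 0.12, HT06 = 0.00,
                                         HT07 = 0.08),
                       events = NULL, capacity = NULL,
                       n_generations = 9L, r_rec = 0.01, mu = 5e-4,
                       offspring_lambda = 6, n_msat = 11L) {
  stopifnot(r_rec >= 0, r_rec <= 1, mu >= 0, mu <= 1,
            abs(sum(founder_freqs) - 1) < 1e-8)
  if (is.null(events))
    events <- data.frame(
      pop = c("Wild", "BJ", "YX", "SD", "LGT", "DQ", "HN"),
      generation = c(0L, 1L, 2L, 4L, 5L, 7L, 7L),
      sources = c("", "Wild", "Wild", "YX", "YX", "LGT", "SD,BJ"),
      n_founders = c("6", "4", "10", "5", "60", "10", "11,2"),
      stringsAsFactors = FALSE)
  if (is.null(capacity))
    capacity <- c(Wild = 24, YX = 150, LGT = 185, DQ = 60, BJ = 40,
                  SD = 120, HN = 90)
  stopifnot(all(events$pop %in% names(capacity)))
  structure(list(founder_freqs = founder_freqs, events = events,
                 capacity = capacity,
                 n_generations = as.integer(n_generations),
                 r_rec = r_rec, mu = mu,
                 offspring_lambda = offspring_lambda,
                 n_msat = as.integer(n_msat)),
            class = "sim_config")
}

#' Preset simulation scenarios
#'
#' * `drift_only`: four populations serially founded from one source with
#'   moderate founder numbers; both marker classes evolve neutrally, so any
#'   MHC-analogue vs microsatellite contrast reflects drift alone.
#' * `isolated_pop`: as `drift_only`, but one daughter population is founded
#'   from two pairs early and then completely isolated (an analogue of the
#'   long-isolated BJ population).
#' * `bottleneck_panel`: a single population crashed to two pairs and
#'   regrown, for exercising the heterozygosity-excess bottleneck test.
#'
#' @param name preset name.
#' @return A [sim_config()].
#' @export
scenario_presets <- function(name = c("drift_only", "isolated_pop",
                                      "bottleneck_panel")) {
  name <- match.arg(name)
  if (name == "drift_only") {
    # founder numbers vary strongly among daughters so that the expected
    # differentiation gradient is shared by both marker classes
    sim_config(
      events = data.frame(
        pop = c("P1", "P2", "P3", "P4", "P5"),
        generation = c(0L, 1L, 2L, 4L, 3L),
        sources = c("", "P1", "P1", "P2", "P3"),
        n_founders = c("30", "4", "24", "4", "12"),
        stringsAsFactors = FALSE),
      capacity = c(P1 = 80, P2 = 30, P3 = 80, P4 = 30, P5 = 60),
      n_generations = 9L, r_rec = 0)
  } else if (name == "isolated_pop") {
    sim_config(
      events = data.frame(
        pop = c("P1", "ISO", "P3", "P4"),
        generation = c(0L, 1L, 3L, 4L),
        sources = c("", "P1", "P1", "P3"),
        n_founders = c("30", "4", "24", "12"),
        stringsAsFactors = FALSE),
      capacity = c(P1 = 80, ISO = 40, P3 = 80, P4 = 80),
      n_generations = 8L, r_rec = 0)
  } else {
    # large source, then a two-pair crash into B which regrows for four
    # generations before sampling
    sim_config(
      founder_freqs = c(HT01 = 0.15, HT02 = 0.25, HT03 = 0.25, HT04 = 0.15,
                        HT05 = 0.10, HT06 = 0.05, HT07 = 0.05),
      events = data.frame(pop = c("P1", "B"), generation = c(0L, 4L),
                          sources = c("", "P1"), n_founders = c("40", "4"),
                          stringsAsFactors = FALSE),
      capacity = c(P1 = 120, B = 100), n_generations = 8L, r_rec = 0)
  }
}

# founder microsatellite allele frequencies: 8 di-allelic + 3 tri-allelic
# loci (matching the published panel's polymorphism), repeat numbers near 10
.msat_panel <- function(n_msat) {
  lapply(seq_len(n_msat), function(l) {
    if (l %% 4L == 0L)
      stats::setNames(c(0.5, 0.3, 0.2), c(9, 10, 11))
    else
      stats::setNames(c(0.7, 0.3), c(10, 12))
  })
}

#' Forward-in-time founder-effect simulation
#'
#' Runs the founding-event graph of `config` for `config$n_generations`
#' discrete generations.  Within each population, adults are paired
#' monogamously at random (two pairs per cage); each pair produces a
#' Poisson number of offspring, truncated at the carrying capacity; each
#' gamete carries one of the parent's two MHC block haplotypes, with
#' probability `r_rec` recombined (the `UAA` allele exchanged between the
#' two parental haplotypes; recombinants whose allele combination is
#' undefined in the catalog are not formed), and one allele per
#' microsatellite locus with stepwise +/-1 mutation at rate `mu`.
#' Founding events move the stated number of birds out of the source
#' population at their generation.  All individuals of all generations are
#' reported; `final` marks those alive at the end.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return List with `genotypes` (a [read_genotype_table()]-format data
#'   frame over all individuals), `final_ids` (ids of the last generation),
#'   `pedigree` ([read_pedigree()] format with cage-mate candidate
#'   parents), `truth` (data frame `id`, `hap_from_sire`, `hap_from_dam`),
#'   `recombination` (true recombination events), `config`, `seed`.
#' @export
simulate_populations <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  catalog <- mhc_haplotype_catalog()
  panel <- .msat_panel(config$n_msat)
  ev <- config$events
  pops <- list()
  archive <- list()
  next_id <- 0L
  recombs <- list()
  ped_rows <- list()
  new_ind <- function(pop, h, msat, sire = NA_character_,
                      dam = NA_character_) {
    next_id <<- next_id + 1L
    list(id = sprintf("I%05d", next_id), pop = pop, h = h, msat = msat,
         sire = sire, dam = dam)
  }
  draw_founder <- function(pop) {
    h <- sample(names(config$founder_freqs), 2L, replace = TRUE,
                prob = config$founder_freqs)
    msat <- do.call(cbind, lapply(panel, function(fr)
      as.integer(sample(names(fr), 2L, replace = TRUE, prob = fr))))
    new_ind(pop, h, msat)
  }
  make_gamete <- function(ind, child_id, meiosis) {
    pick <- sample(2L, 1L)
    hap <- ind$h[pick]
    if (config$r_rec > 0 && ind$h[1] != ind$h[2] &&
        stats::runif(1) < config$r_rec) {
      other <- ind$h[3L - pick]
      rec <- haplotype_for_alleles(
        catalog$dab[match(hap, catalog$id)],
        catalog$uaa[match(other, catalog$id)], catalog)
      if (!is.na(rec) && rec != hap) {
        recombs[[length(recombs) + 1L]] <<- data.frame(
          child = child_id, observed = rec, parental = hap,
          meiosis = meiosis, stringsAsFactors = FALSE)
        hap <- rec
      }
    }
    ms <- ind$msat[cbind(sample(2L, config$n_msat, replace = TRUE),
                         seq_len(config$n_msat))]
    mut <- which(stats::runif(config$n_msat) < config$mu)
    if (length(mut))
      ms[mut] <- ms[mut] + sample(c(-1L, 1L), length(mut), replace = TRUE)
    list(hap = hap, msat = ms)
  }
  breed <- function(inds, pop, gen) {
    n <- length(inds)
    if (n < 2L)
      stop(sprintf("population %s extinct at generation %d (no pairs)",
                   pop, gen))
    ord <- sample(n)
    npair <- n %/% 2L
    cage_of_pair <- ceiling(seq_len(npair) / 2)  # two pairs per cage
    kids <- list()
    kid_pair <- integer(0)
    for (k in seq_len(npair)) {
      sire <- inds[[ord[2L * k - 1L]]]
      dam <- inds[[ord[2L * k]]]
      for (o in seq_len(stats::rpois(1, config$offspring_lambda))) {
        child_id <- sprintf("I%05d", next_id + 1L)
        gs <- make_gamete(sire, child_id, "sire")
        gd <- make_gamete(dam, child_id, "dam")
        kid <- new_ind(pop, c(gs$hap, gd$hap), rbind(gs$msat, gd$msat),
                       sire = sire$id, dam = dam$id)
        kids[[length(kids) + 1L]] <- kid
        kid_pair <- c(kid_pair, k)
      }
    }
    if (length(kids) == 0L)
      stop(sprintf("population %s extinct at generation %d (no offspring)",
                   pop, gen))
    cap <- config$capacity[[pop]]
    if (length(kids) > cap) {
      keep <- sort(sample(length(kids), cap))
      drop_ids <- vapply(kids[-keep], `[[`, character(1), "id")
      recombs <<- Filter(function(r) !(r$child %in% drop_ids), recombs)
      kids <- kids[keep]
      kid_pair <- kid_pair[keep]
    }
    for (k in seq_along(kids)) {
      mates <- which(cage_of_pair == cage_of_pair[kid_pair[k]])
      ped_rows[[length(ped_rows) + 1L]] <<- list(
        id = kids[[k]]$id, sire = kids[[k]]$sire, dam = kids[[k]]$dam,
        candidate_sires = unique(vapply(mates, function(m)
          inds[[ord[2L * m - 1L]]]$id, character(1))),
        candidate_dams = unique(vapply(mates, function(m)
          inds[[ord[2L * m]]]$id, character(1))))
    }
    kids
  }
  for (gen in 0:config$n_generations) {
    for (e in which(ev$generation == gen)) {
      pop <- ev$pop[e]
      srcs <- strsplit(ev$sources[e], ",", fixed = TRUE)[[1]]
      ns <- as.integer(strsplit(ev$n_founders[e], ",", fixed = TRUE)[[1]])
      if (length(srcs) == 0L) {
        pops[[pop]] <- replicate(ns[1], draw_founder(pop),
                                 simplify = FALSE)
      } else {
        founders <- list()
        for (s in seq_along(srcs)) {
          src <- srcs[s]
          if (is.null(pops[[src]]) || length(pops[[src]]) < ns[s])
            stop(sprintf(
              "founding of %s at generation %d needs %d birds from %s (has %d)",
              pop, gen, ns[s], src, length(pops[[src]])))
          take <- sample(length(pops[[src]]), ns[s])
          moved <- lapply(pops[[src]][take],
                          function(x) { x$pop <- pop; x })
          founders <- c(founders, moved)
          pops[[src]] <- pops[[src]][-take]
        }
        pops[[pop]] <- founders
      }
    }
    if (gen == config$n_generations) break
    # parents are archived once bred (non-overlapping generations)
    archive <- c(archive, unlist(unname(pops), recursive = FALSE))
    pops <- stats::setNames(
      lapply(names(pops), function(p) breed(pops[[p]], p, gen)),
      names(pops))
  }
  final <- unlist(unname(pops), recursive = FALSE)
  inds <- c(archive, final)
  fmt_pair <- function(x) paste(sort(x), collapse = "/")
  geno <- data.frame(
    id = vapply(inds, `[[`, character(1), "id"),
    population = vapply(inds, `[[`, character(1), "pop"),
    dab = vapply(inds, function(x)
      fmt_pair(catalog$dab[match(x$h, catalog$id)]), character(1)),
    uaa = vapply(inds, function(x)
      fmt_pair(catalog$uaa[match(x$h, catalog$id)]), character(1)),
    stringsAsFactors = FALSE)
  loci <- paste0("Nn", sprintf("%02d", seq_len(config$n_msat)))
  for (l in seq_len(config$n_msat))
    geno[[loci[l]]] <- vapply(inds, function(x) fmt_pair(x$msat[, l]),
                              character(1))
  attr(geno, "msat_loci") <- loci
  class(geno) <- c("haplopop_genotypes", class(geno))
  ped <- data.frame(
    id = vapply(ped_rows, `[[`, character(1), "id"),
    sire = vapply(ped_rows, `[[`, character(1), "sire"),
    dam = vapply(ped_rows, `[[`, character(1), "dam"),
    stringsAsFactors = FALSE)
  ped$candidate_sires <- lapply(ped_rows, `[[`, "candidate_sires")
  ped$candidate_dams <- lapply(ped_rows, `[[`, "candidate_dams")
  truth <- data.frame(
    id = geno$id,
    hap_from_sire = vapply(inds, function(x) x$h[1], character(1)),
    hap_from_dam = vapply(inds, function(x) x$h[2], character(1)),
    stringsAsFactors = FALSE)
  rec <- if (length(recombs)) do.call(rbind, recombs)
         else data.frame(child = character(0), observed = character(0),
                         parental = character(0), meiosis = character(0))
  rec <- rec[rec$child %in% geno$id, , drop = FALSE]
  list(genotypes = geno,
       final_ids = vapply(final, `[[`, character(1), "id"),
       pedigree = ped, truth = truth, recombination = rec,
       config = config, seed = seed)
}

#' Tabulate true haplotype counts per population from a simulation
#'
#' @param sim result of [simulate_populations()].
#' @param final_only count only the last generation (default) or everyone.
#' @return Population-by-haplotype count matrix.
#' @export
sim_haplotype_counts <- function(sim, final_only = TRUE) {
  keep <- if (final_only) sim$genotypes$id %in% sim$final_ids
          else rep(TRUE, nrow(sim$genotypes))
  haps <- paste0("HT0", 1:7)
  pops <- unique(sim$genotypes$population[keep])
  out <- matrix(0L, length(pops), length(haps),
                dimnames = list(pops, haps))
  for (i in which(keep)) {
    p <- sim$genotypes$population[i]
    for (h in c(sim$truth$hap_from_sire[i], sim$truth$hap_from_dam[i]))
      out[p, h] <- out[p, h] + 1L
  }
  out
}

#' Tabulate microsatellite allele counts per population
#'
#' @param genotypes genotype table with microsatellite columns.
#' @param ids optional subset of individual ids to include.
#' @return Named list of population-by-allele count matrices, one per
#'   locus.
#' @export
msat_counts <- function(genotypes, ids = NULL) {
  loci <- attr(genotypes, "msat_loci")
  if (is.null(loci))
    loci <- setdiff(names(genotypes), c("id", "population", "dab", "uaa"))
  keep <- if (is.null(ids)) rep(TRUE, nrow(genotypes))
          else genotypes$id %in% ids
  pops <- unique(genotypes$population[keep])
  stats::setNames(lapply(loci, function(l) {
    gl <- genotypes[[l]][keep]
    pl <- genotypes$population[keep]
    pairs <- strsplit(gl, "/", fixed = TRUE)
    alleles <- sort(unique(as.integer(unlist(pairs[!is.na(gl)]))))
    m <- matrix(0L, length(pops), length(alleles),
                dimnames = list(pops, as.character(alleles)))
    for (i in seq_along(pairs)) {
      if (is.na(gl[i])) next
      for (a in pairs[[i]])
        m[pl[i], a] <- m[pl[i], a] + 1L
    }
    m
  }), loci)
}
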