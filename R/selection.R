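# Historical positive-selection tests on class II beta exon 2:
# Nei-Gojobori proportions of synonymous / nonsynonymous differences with
# equal-pathway counting, Jukes-Cantor correction, frequency weighting of
# alleles, an antigen-binding-site (ABS) codon partition, and a one-tailed
# Z-test with bootstrap variance over codons.

.codon_env <- new.env(parent = emptyenv())

.standard_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  # standard genetic code in TCAG order
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
}

.codon_tables <- function() {
  if (!is.null(.codon_env$aa)) return(.codon_env)
  aa <- .standard_code()
  codons <- names(aa)
  bases <- c("T", "C", "A", "G")
  # per-codon synonymous site count with stop-codon changes excluded
  syn_sites <- stats::setNames(numeric(64), codons)
  for (c0 in codons) {
    if (aa[c0] == "*") { syn_sites[c0] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      alts <- vapply(setdiff(bases, substr(c0, pos, pos)), function(b) {
        c1 <- c0; substr(c1, pos, pos) <- b; c1
      }, character(1))
      alts <- alts[aa[alts] != "*"]
      if (length(alts))
        s <- s + sum(aa[alts] == aa[c0]) / length(alts)
    }
    syn_sites[c0] <- s
  }
  # equal-pathway counts of synonymous / nonsynonymous differences for all
  # ordered codon pairs (symmetric)
  sd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd <- sd
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(64)) for (j in i:64) {
    c1 <- codons[i]; c2 <- codons[j]
    if (aa[c1] == "*" || aa[c2] == "*") next
    diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(diffs) == 0L) { sd[i, j] <- sd[j, i] <- 0; nd[i, j] <- nd[j, i] <- 0; next }
    walk <- function(order, allow_stop) {
      cur <- c1; s <- 0; n <- 0
      for (pos in order) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (aa[nxt] == "*" && !allow_stop) return(NULL)
        if (aa[nxt] == aa[cur] && aa[nxt] != "*") s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    }
    orders <- lapply(perms[[length(diffs)]], function(ix) diffs[ix])
    paths <- Filter(Negate(is.null),
                    lapply(orders, walk, allow_stop = FALSE))
    if (length(paths) == 0L)
      paths <- lapply(orders, walk, allow_stop = TRUE)
    m <- do.call(rbind, paths)
    sd[i, j] <- sd[j, i] <- mean(m[, 1])
    nd[i, j] <- nd[j, i] <- mean(m[, 2])
  }
  .codon_env$aa <- aa
  .codon_env$syn_sites <- syn_sites
  .codon_env$sd <- sd
  .codon_env$nd <- nd
  .codon_env
}

#' Construct a weighted codon alignment
#'
#' @param sequences named character vector of in-frame nucleotide sequences
#'   of equal length divisible by 3, no internal stop codons.
#' @param weights per-sequence non-negative integer multiplicities (allele
#'   frequencies in the sample); default 1 each.
#' @param abs_mask integer vector of 1-based codon indices forming the
#'   antigen-binding-site partition.
#' @return Object of class `"codon_alignment"`: list with `codons` (matrix,
#'   sequences x codons), `weights`, `abs_mask`, `n_codons`.
#' @export
codon_alignment <- function(sequences, weights = NULL, abs_mask = integer(0)) {
  sequences <- toupper(gsub("U", "T", sequences))
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must have equal length")
  if (L %% 3L != 0L) stop("alignment length must be divisible by 3")
  nc <- L %/% 3L
  if (is.null(weights)) weights <- rep(1L, length(sequences))
  stopifnot(length(weights) == length(sequences), all(weights >= 0),
            all(weights == round(weights)))
  if (sum(weights) == 0) stop("all sequence weights are zero")
  abs_mask <- sort(unique(as.integer(abs_mask)))
  if (length(abs_mask) && (min(abs_mask) < 1L || max(abs_mask) > nc))
    stop("ABS mask indices must lie in [1, ", nc, "]")
  tab <- .codon_tables()
  cod <- t(vapply(sequences, function(s)
    substring(s, seq(1, L, 3), seq(3, L, 3)), character(nc)))
  if (nc == 1L) cod <- matrix(cod, ncol = 1L,
                              dimnames = list(names(sequences), NULL))
  ok <- matrix(cod %in% names(tab$aa), nrow = nrow(cod))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)
    stop("non-ACGT codon at sequence ", bad[1, 1], ", codon ", bad[1, 2])
  }
  if (any(tab$aa[cod] == "*"))
    stop("alignment contains stop codon(s)")
  structure(list(codons = cod, weights = as.integer(weights),
                 abs_mask = abs_mask, n_codons = nc,
                 sequences = sequences),
            class = "codon_alignment")
}

#' Read an in-frame FASTA codon alignment
#'
#' @param path FASTA file.
#' @param weights optional named integer vector of sequence weights.
#' @param abs_mask optional mask (indices, or a path readable by
#'   [read_abs_mask()]).
#' @return A [codon_alignment()] object.
#' @export
read_codon_alignment <- function(path, weights = NULL,
                                 abs_mask = integer(0)) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  seqs <- vapply(fa, function(x) as.character(x)[1], character(1))
  if (is.character(abs_mask) && length(abs_mask) == 1L)
    abs_mask <- read_abs_mask(abs_mask)
  if (!is.null(weights)) weights <- weights[names(seqs)]
  codon_alignment(seqs, weights = weights, abs_mask = abs_mask)
}

#' Read an ABS codon mask (one 1-based codon index per line)
#'
#' @param path file path.
#' @return Sorted integer vector.
#' @export
read_abs_mask <- function(path) {
  x <- scan(path, what = integer(), quiet = TRUE, comment.char = "#")
  sort(unique(x))
}

#' Expand sequence weights into a pair list
#'
#' Enumerates all unordered pairs of the weight-expanded sequence set:
#' distinct sequences `u != v` with multiplicity `w_u w_v`, identical pairs
#' with multiplicity `choose(w_u, 2)` (these contribute zero distance).
#'
#' @param aln a [codon_alignment()].
#' @return Data frame with columns `i`, `j`, `mult`.
#' @export
expand_weights <- function(aln) {
  w <- aln$weights
  keep <- which(w > 0)
  rows <- list()
  for (a in seq_along(keep)) for (b in a:length(keep)) {
    i <- keep[a]; j <- keep[b]
    mult <- if (i == j) choose(w[i], 2) else w[i] * w[j]
    if (mult > 0)
      rows[[length(rows) + 1L]] <- data.frame(i = i, j = j, mult = mult)
  }
  do.call(rbind, rows)
}

.partition_idx <- function(aln, partition) {
  all_idx <- seq_len(aln$n_codons)
  switch(partition,
         all = all_idx,
         ABS = aln$abs_mask,
         nonABS = setdiff(all_idx, aln$abs_mask),
         stop("unknown partition: ", partition))
}

# weighted-average proportions and JC distances over a codon index set
.ng_core <- function(aln, idx) {
  if (length(idx) == 0L) stop("empty codon partition")
  tab <- .codon_tables()
  pairs <- expand_weights(aln)
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) stop("proportion of differences >= 3/4; Jukes-Cantor correction undefined")
    -0.75 * log(1 - 4 * p / 3)
  }
  dn_sum <- 0; ds_sum <- 0; wsum <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]; m <- pairs$mult[k]
    wsum <- wsum + m
    if (i == j) next  # identical expansion pairs: zero distance
    ci <- aln$codons[i, idx]; cj <- aln$codons[j, idx]
    S <- (sum(tab$syn_sites[ci]) + sum(tab$syn_sites[cj])) / 2
    N <- 3 * length(idx) - S
    sd <- sum(tab$sd[cbind(ci, cj)])
    nd <- sum(tab$nd[cbind(ci, cj)])
    ps <- if (S > 0) sd / S else 0
    pn <- if (N > 0) nd / N else 0
    ds_sum <- ds_sum + m * jc(ps)
    dn_sum <- dn_sum + m * jc(pn)
  }
  list(dN = dn_sum / wsum, dS = ds_sum / wsum)
}

#' Nei-Gojobori dN and dS with Jukes-Cantor correction
#'
#' For every weighted sequence pair, counts synonymous and nonsynonymous
#' sites (stop-codon changes excluded) and differences (equal-pathway
#' averaging over substitution orders, pathways through stop codons
#' excluded), forms the proportions `pS`, `pN` over the chosen codon
#' partition, applies the Jukes-Cantor correction
#' `d = -(3/4) log(1 - 4p/3)`, and averages over pairs with the sequence
#' multiplicities as weights.
#'
#' @param aln a [codon_alignment()].
#' @param partition `"all"`, `"ABS"` or `"nonABS"`.
#' @return List with `dN`, `dS`, `omega` (`dN/dS`, `NA` when `dS = 0`),
#'   `partition`, `n_codons`.
#' @export
nei_gojobori_dnds <- function(aln, partition = c("all", "ABS", "nonABS")) {
  partition <- match.arg(partition)
  stopifnot(inherits(aln, "codon_alignment"))
  if (sum(aln$weights > 0) < 2L &&
      length(unique(aln$sequences[aln$weights > 0])) < 2L)
    stop("need at least two distinct sequences with positive weight")
  idx <- .partition_idx(aln, partition)
  d <- .ng_core(aln, idx)
  list(dN = d$dN, dS = d$dS,
       omega = if (d$dS > 0) d$dN / d$dS else NA_real_,
       partition = partition, n_codons = length(idx))
}

#' Codon-based Z-test of positive selection (dN > dS)
#'
#' `Z = (dN - dS) / sqrt(Var(dN - dS))` with the variance estimated by
#' bootstrap over codons within the partition; the one-tailed p-value comes
#' from the standard normal.
#'
#' @param aln a [codon_alignment()].
#' @param partition codon partition, see [nei_gojobori_dnds()].
#' @param bootstrap_reps bootstrap replicates for the variance (default
#'   1000).
#' @param seed RNG seed.
#' @return List with `dN`, `dS`, `omega`, `Z`, `p` (one-tailed for
#'   `dN > dS`), `bootstrap_reps`, `zero_variance` flag.
#' @export
z_test_selection <- function(aln, partition = c("all", "ABS", "nonABS"),
                             bootstrap_reps = 1000L, seed = 1L) {
  partition <- match.arg(partition)
  est <- nei_gojobori_dnds(aln, partition)
  idx <- .partition_idx(aln, partition)
  set.seed(seed)
  diffs <- vapply(seq_len(bootstrap_reps), function(b) {
    take <- sample(idx, replace = TRUE)
    d <- tryCatch(.ng_core(aln, take), error = function(e) NULL)
    if (is.null(d)) NA_real_ else d$dN - d$dS
  }, numeric(1))
  v <- stats::var(diffs, na.rm = TRUE)
  obs <- est$dN - est$dS
  if (!is.finite(v) || v == 0) {
    return(c(est, list(Z = NA_real_,
                       p = if (obs > 0) 0 else 1,
                       bootstrap_reps = bootstrap_reps,
                       zero_variance = TRUE)))
  }
  Z <- obs / sqrt(v)
  c(est, list(Z = Z, p = stats::pnorm(Z, lower.tail = FALSE),
              bootstrap_reps = bootstrap_reps, zero_variance = FALSE))
}
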