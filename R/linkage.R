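#' Pairwise D' from unphased genotypes
#'
#' Estimates Lewontin's normalized linkage-disequilibrium coefficient
#' D' = |D| / Dmax between two biallelic loci. Two-locus haplotype
#' frequencies are estimated by expectation-maximization from unphased
#' genotype calls (only the double heterozygote is phase-ambiguous),
#' starting from linkage-equilibrium frequencies, tolerance 1e-8, at most
#' 1000 iterations. The sign of D is discarded. A monomorphic locus or an
#' all-missing overlap yields `NA` (treated as unlinked).
#'
#' @param gA,gB integer vectors of calls (0/1/2 dosage, `NA` missing) at
#'   the two loci over the same individuals.
#' @param tol,max_iter EM convergence controls.
#' @return D' in \code{[0, 1]}, or `NA` if undefined.
#' @export
dprime <- function(gA, gB, tol = 1e-8, max_iter = 1000L) {
  ok <- !is.na(gA) & !is.na(gB)
  if (sum(ok) < 2L) return(NA_real_)
  gA <- gA[ok]; gB <- gB[ok]
  # 3x3 genotype count table, indices = dosage + 1
  tab <- matrix(tabulate(3L * gA + gB + 1L, 9L), 3, 3, byrow = TRUE)
  em_dprime_from_table(tab, tol = tol, max_iter = max_iter)
}

# EM on a 3x3 genotype count table; haplotype 1 = allele "0" at a locus.
em_dprime_from_table <- function(tab, tol = 1e-8, max_iter = 1000L) {
  n <- sum(tab)
  pA <- sum(tab * c(2, 1, 0)[row(tab)]) / (2 * n)   # freq of allele 0 at A
  pB <- sum(tab * c(2, 1, 0)[col(tab)]) / (2 * n)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  # unambiguous haplotype counts; h = c(AB, Ab, aB, ab) with A,B = allele 0
  base <- c(
    AB = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
    Ab = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    aB = 2 * tab[3, 1] + tab[2, 1] + tab[3, 2],
    ab = 2 * tab[3, 3] + tab[2, 3] + tab[3, 2])
  ndh <- tab[2, 2]                       # double heterozygotes
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  for (it in seq_len(max_iter)) {
    # E: split double hets between coupling (AB/ab) and repulsion (Ab/aB)
    cpl <- p[1] * p[4]; rpl <- p[2] * p[3]
    w <- if (cpl + rpl > 0) cpl / (cpl + rpl) else 0.5
    h <- base + ndh * c(w, 1 - w, 1 - w, w)
    p_new <- h / (2 * n)
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  D <- p[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(NA_real_)
  min(1, abs(D) / dmax)
}

#' Pairwise D' matrix for a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @inheritParams dprime
#' @return symmetric matrix of pairwise D' with `NA` diagonal.
#' @export
dprime_matrix <- function(gm, tol = 1e-8, max_iter = 1000L) {
  calls <- gm$calls
  L <- ncol(calls)
  out <- matrix(NA_real_, L, L,
                dimnames = list(gm$alleles$locus, gm$alleles$locus))
  if (L < 2L) return(out)
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      d <- dprime(calls[, i], calls[, j], tol = tol, max_iter = max_iter)
      out[i, j] <- d; out[j, i] <- d
    }
  }
  out
}

#' Build putative linkage groups
#'
#' Loci are connected when pairwise D' exceeds `threshold`; candidate
#' groups are the maximal cliques of that graph. A SNP occurring in more
#' than one maximal clique is excluded; surviving cliques with at least
#' two members become the putative linkage groups; loci with no retained
#' edge are singletons. Every input locus ends up in exactly one of
#' singletons / a group / excluded.
#'
#' @param gm a [genotype_matrix()], or a precomputed [dprime_matrix()].
#' @param threshold D' cutoff in (0, 1]; edges require D' > threshold.
#' @return object of class `linkage_groups`: list with `singletons`
#'   (character), `groups` (list of character vectors), `excluded`
#'   (character), `threshold`.
#' @export
build_linkage_groups <- function(gm, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  D <- if (inherits(gm, "genotype_matrix")) dprime_matrix(gm) else as.matrix(gm)
  loci <- rownames(D)
  adj <- !is.na(D) & D > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::max_cliques(g, min = 2)
  cl <- lapply(cl, function(v) loci[as.integer(v)])
  membership <- table(unlist(cl))
  excluded <- names(membership)[membership > 1]
  groups <- lapply(cl, function(v) setdiff(v, excluded))
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  grouped <- unlist(groups)
  singletons <- setdiff(loci, c(grouped, excluded))
  structure(list(singletons = singletons, groups = groups,
                 excluded = excluded, threshold = threshold),
            class = "linkage_groups")
}

#' @export
print.linkage_groups <- function(x, ...) {
  sz <- vapply(x$groups, length, 1L)
  cat(sprintf(paste0(
    "linkage_groups (D' > %g): %d singletons, %d groups (%d SNPs%s), ",
    "%d excluded\n"),
    x$threshold, length(x$singletons), length(x$groups), sum(sz),
    if (length(sz)) sprintf(", mean size %.1f", mean(sz)) else "",
    length(x$excluded)))
  invisible(x)
}

#' One-SNP-per-group resampling
#'
#' Returns all singleton loci plus one uniformly chosen member of each
#' linkage group: the locus subset over which resampled multilocus
#' heterozygosity and permuted models are computed. The subset size is
#' always `length(singletons) + length(groups)`.
#'
#' @param lg a [build_linkage_groups()] result.
#' @param seed integer seed.
#' @return character vector of locus ids.
#' @export
resample_representatives <- function(lg, seed = NULL) {
  stopifnot(inherits(lg, "linkage_groups"))
  with_seed(seed, {
    reps <- vapply(lg$groups, function(g) sample_exact(g, 1L), character(1))
    c(lg$singletons, reps)
  })
}

#' Linkage-group assignments as a table
#'
#' @param lg a `linkage_groups` object.
#' @return data frame with columns `locus` and `status` (`"singleton"`,
#'   `"group:<k>"`, or `"excluded"`).
#' @export
linkage_group_table <- function(lg) {
  rows <- list(
    data.frame(locus = lg$singletons, status = "singleton",
               stringsAsFactors = FALSE),
    if (length(lg$groups))
      do.call(rbind, lapply(seq_along(lg$groups), function(k)
        data.frame(locus = lg$groups[[k]], status = paste0("group:", k),
                   stringsAsFactors = FALSE))),
    data.frame(locus = lg$excluded, status = "excluded",
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
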