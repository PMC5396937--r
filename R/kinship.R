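#' Pedigree kinship matrix (tabular method)
#'
#' Computes the full matrix of kinship coefficients f(i,j) — the probability
#' that alleles drawn at random from i and j at one autosomal locus are
#' identical by descent — by the recursive tabular method, in pedigree
#' order. Founders are assumed unrelated and non-inbred, so
#' founder–founder off-diagonals are 0 and founder diagonals are 1/2.
#' An individual with one recorded and one unknown parent is treated as if
#' the unknown parent were a unique unrelated founder.
#'
#' @param ped a `pedigree_table` (see [as_pedigree()]).
#' @return symmetric numeric matrix with dimnames = member ids;
#'   `f[i,i] = (1 + F_i) / 2`.
#' @seealso [inbreeding_f()], [mean_kinship()], [gene_drop()]
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (is.na(s)) 0 else K[s, j]) +
                    (if (is.na(d)) 0 else K[d, j]))
      K[i, j] <- row
      K[j, i] <- row
    }
    fsd <- if (is.na(s) || is.na(d)) 0 else K[s, d]
    K[i, i] <- 0.5 * (1 + fsd)
  }
  K
}

#' Pedigree inbreeding coefficient F
#'
#' F(i) is the probability that i's two alleles at a locus are identical by
#' descent; it equals the kinship of i's parents. Founders and individuals
#' with an unknown parent get F = 0.
#'
#' @inheritParams kinship_matrix
#' @param K optional precomputed [kinship_matrix()] (avoids recomputation).
#' @return named numeric vector of F, one entry per pedigree member.
#' @export
inbreeding_f <- function(ped, K = NULL) {
  if (is.null(K)) K <- kinship_matrix(ped)
  f <- 2 * diag(K) - 1
  names(f) <- ped$id
  f
}

#' Mean kinship within a cohort
#'
#' mk(i) is the mean kinship of i to the members of `cohort` — the quantity
#' minimized by genetic management: breeders with low mk carry
#' under-represented founder lineages. By default the self-kinship term is
#' included (the studbook-software convention); set `include_self = FALSE`
#' to average over the cohort excluding i. Rankings are essentially
#' unaffected in realistic cohorts, but the choice is explicit and testable.
#'
#' @param K kinship matrix from [kinship_matrix()].
#' @param cohort character ids (or indices) of the cohort; defaults to all.
#' @param include_self logical; include f(i,i) in the average.
#' @return named numeric vector of mean kinship for each cohort member. A
#'   singleton cohort with `include_self = FALSE` yields `NaN` with a warning.
#' @export
mean_kinship <- function(K, cohort = rownames(K), include_self = TRUE) {
  if (length(cohort) == 0L) stop("cohort is empty")
  Kc <- K[cohort, cohort, drop = FALSE]
  m <- length(cohort)
  if (include_self) {
    mk <- rowMeans(Kc)
  } else {
    if (m == 1L) {
      warning("singleton cohort with include_self = FALSE: mk undefined")
      mk <- NaN
    } else {
      mk <- (rowSums(Kc) - diag(Kc)) / (m - 1)
    }
  }
  names(mk) <- cohort
  mk
}

#' Gene-dropping Monte Carlo estimates of F and kinship
#'
#' Drops uniquely labelled founder alleles through the pedigree `n_drops`
#' times and estimates identity-by-descent probabilities by counting. This
#' is the independent oracle for [kinship_matrix()] / [inbreeding_f()]:
#' the two agree within Monte Carlo error on valid pedigrees.
#'
#' @inheritParams kinship_matrix
#' @param n_drops number of independent transmissions (>= 1).
#' @param seed integer seed.
#' @param pairs optional 2-column matrix/data frame of id pairs at which to
#'   estimate pairwise kinship (the full matrix is quadratic in members and
#'   linear in drops, so only requested pairs are returned).
#' @return list with `F` (named vector of Monte Carlo F estimates), `F_se`
#'   (binomial standard errors), and if `pairs` was given, `f` and `f_se`
#'   vectors aligned with the rows of `pairs`.
#' @export
gene_drop <- function(ped, n_drops = 10000L, seed = NULL, pairs = NULL) {
  stopifnot(inherits(ped, "pedigree_table"), n_drops >= 1)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  with_seed(seed, {
    # A1, A2: n x n_drops integer matrices of allele labels. Each founder
    # contributes two globally unique labels; an unknown parent of a
    # non-founder contributes fresh labels per individual (unique founder
    # convention).
    A1 <- matrix(0L, n, n_drops)
    A2 <- matrix(0L, n, n_drops)
    next_label <- 1L
    for (i in seq_len(n)) {
      s <- si[i]; d <- di[i]
      if (is.na(s)) {
        A1[i, ] <- next_label; next_label <- next_label + 1L
      } else {
        pick <- stats::runif(n_drops) < 0.5
        A1[i, ] <- ifelse(pick, A1[s, ], A2[s, ])
      }
      if (is.na(d)) {
        A2[i, ] <- next_label; next_label <- next_label + 1L
      } else {
        pick <- stats::runif(n_drops) < 0.5
        A2[i, ] <- ifelse(pick, A1[d, ], A2[d, ])
      }
    }
    Fhat <- rowMeans(A1 == A2)
    names(Fhat) <- ped$id
    out <- list(F = Fhat,
                F_se = sqrt(Fhat * (1 - Fhat) / n_drops),
                n_drops = as.integer(n_drops))
    if (!is.null(pairs)) {
      pairs <- as.matrix(pairs)
      fhat <- apply(pairs, 1, function(pr) {
        i <- idx[[pr[1]]]; j <- idx[[pr[2]]]
        # P(random allele from i == random allele from j)
        mean((A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
             (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])) / 4
      })
      out$f <- fhat
      out$f_se <- sqrt(fhat * (1 - fhat) / n_drops)
    }
    out
  })
}
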