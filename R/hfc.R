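#' Spearman rank correlation
#'
#' Tie-aware Spearman r: the Pearson correlation of mid-ranks. Pairs with
#' a missing value in either vector are dropped (pairwise-complete).
#' Undefined (NA, with a warning) when fewer than 3 complete pairs remain
#' or either ranked vector has zero variance.
#'
#' @param x,y paired numeric vectors.
#' @return r in \code{[-1, 1]}, or `NA` if undefined.
#' @export
spearman_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) { warning("fewer than 3 complete pairs"); return(NA_real_) }
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero variance in ranked vector"); return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Permutation p-value for a Spearman correlation
#'
#' Permutes the diversity vector `x` against fixed `y` and reports the
#' proportion of permutations whose correlation is at least as extreme as
#' the observed one. Two-sided (`|r_perm| >= |r_obs|`) by default;
#' `alternative` gives one-sided variants. `exact = TRUE` enumerates all
#' `n!` permutations instead of sampling (requires n <= 8). The observed
#' (identity) permutation is not counted; `mode = "add_one"` reports the
#' conservative `(b + 1) / (m + 1)` version.
#'
#' @param x,y paired numeric vectors (`x` is permuted).
#' @param n_perm number of random permutations (ignored when exact).
#' @param seed integer seed.
#' @param alternative `"two.sided"`, `"greater"` (r_perm >= r_obs) or
#'   `"less"`.
#' @param exact enumerate all permutations.
#' @param mode `"proportion"` or `"add_one"`.
#' @return list with `r` (observed), `p`, `n` (complete pairs), `n_perm`.
#' @export
permutation_pvalue <- function(x, y, n_perm = 1000L, seed = NULL,
                               alternative = c("two.sided", "greater",
                                               "less"),
                               exact = FALSE,
                               mode = c("proportion", "add_one")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  r_obs <- spearman_r(x, y)
  if (is.na(r_obs))
    return(list(r = NA_real_, p = NA_real_, n = n, n_perm = 0L))
  rx <- rank(x); ry <- rank(y)
  score <- function(rxp) stats::cor(rxp, ry)
  if (exact) {
    if (n > 8L) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    rs <- apply(perms, 1, function(i) score(rx[i]))
    m <- nrow(perms)
  } else {
    rs <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      score(rx[sample.int(n)]), numeric(1)))
    m <- n_perm
  }
  b <- switch(alternative,
              two.sided = sum(abs(rs) >= abs(r_obs) - 1e-12),
              greater = sum(rs >= r_obs - 1e-12),
              less = sum(rs <= r_obs + 1e-12))
  p <- if (mode == "add_one") (b + 1) / (m + 1) else b / m
  list(r = r_obs, p = min(1, p), n = n, n_perm = m)
}

# all n! permutations of 1..n as rows (n small)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Heterozygosity-fitness correlation table
#'
#' Crosses every genetic-diversity measure with every trait in every sex
#' stratum (females, males, combined), computing Spearman r and a
#' permutation p-value per cell with pairwise-complete deletion.
#'
#' @param gd data frame (or named list of vectors) of per-individual
#'   diversity measures, first column `id` — typically all-SNP MLH,
#'   neutral MLH, nonneutral MLH, and pedigree F.
#' @param traits trait table (see [read_traits()]): columns `id`, `sex`,
#'   then numeric traits.
#' @param n_perm permutations per cell (study design: 1000).
#' @param seed integer seed.
#' @param alpha significance threshold for the flag column.
#' @inheritParams permutation_pvalue
#' @return data frame: measure, trait, stratum, n, r, p, significant.
#' @export
hfc_table <- function(gd, traits, n_perm = 1000L, seed = NULL,
                      alternative = "two.sided", alpha = 0.05) {
  gd <- as.data.frame(gd, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(gd), all(c("id", "sex") %in% names(traits)))
  ids <- intersect(gd$id, traits$id)
  if (!length(ids)) stop("no overlapping individuals between gd and traits")
  gd <- gd[match(ids, gd$id), , drop = FALSE]
  tr <- traits[match(ids, traits$id), , drop = FALSE]
  measures <- setdiff(names(gd), "id")
  trait_cols <- setdiff(names(tr), c("id", "sex"))
  strata <- list(female = tr$sex == "F", male = tr$sex == "M",
                 combined = rep(TRUE, nrow(tr)))
  rows <- list(); k <- 0L
  for (msr in measures) for (tcol in trait_cols) for (s in names(strata)) {
    sel <- strata[[s]]
    if (!any(sel)) next
    k <- k + 1L
    pp <- suppressWarnings(permutation_pvalue(
      gd[[msr]][sel], tr[[tcol]][sel], n_perm = n_perm,
      seed = if (is.null(seed)) NULL else sub_seed(seed, k),
      alternative = alternative))
    rows[[k]] <- data.frame(measure = msr, trait = tcol, stratum = s,
                            n = pp$n, r = pp$r, p = pp$p,
                            significant = !is.na(pp$p) & pp$p < alpha,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance of SNP and pedigree diversity measures
#'
#' Spearman correlation (with permutation p) between per-individual MLH
#' and pedigree inbreeding F, per stratum (typically protocol). F is
#' inversely related to heterozygosity, so r is expected negative; the
#' correlation weakens as pedigrees deepen and Mendelian sampling noise
#' accumulates.
#'
#' @param mlh_est named per-individual MLH vector.
#' @param F_ped named per-individual pedigree F vector.
#' @param strata optional named factor (e.g. protocol) per individual.
#' @inheritParams hfc_table
#' @return data frame: stratum, n, r, p.
#' @export
gd_concordance <- function(mlh_est, F_ped, strata = NULL, n_perm = 1000L,
                           seed = NULL) {
  ids <- intersect(names(mlh_est), names(F_ped))
  if (length(ids) < 3L) stop("need >= 3 overlapping individuals")
  if (is.null(strata)) strata <- stats::setNames(rep("all", length(ids)), ids)
  st <- strata[ids]
  out <- do.call(rbind, lapply(unique(st), function(s) {
    i <- ids[st == s]
    pp <- suppressWarnings(permutation_pvalue(
      mlh_est[i], F_ped[i], n_perm = n_perm, seed = seed))
    data.frame(stratum = s, n = pp$n, r = pp$r, p = pp$p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
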