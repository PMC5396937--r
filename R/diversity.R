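#' Multilocus heterozygosity
#'
#' MLH for one individual is the fraction of its scorable (non-missing)
#' calls in the chosen locus subset that are heterozygous. Individuals
#' with no scorable locus get `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param loci locus ids or column indices to score (default: all).
#' @return named numeric vector, one MLH per individual.
#' @export
mlh <- function(gm, loci = NULL) {
  calls <- gm$calls
  if (!is.null(loci)) calls <- calls[, loci, drop = FALSE]
  het <- rowSums(calls == 1L, na.rm = TRUE)
  scor <- rowSums(!is.na(calls))
  out <- ifelse(scor > 0, het / scor, NA_real_)
  names(out) <- gm$samples$id
  out
}

#' Resampled multilocus heterozygosity
#'
#' Averages individual MLH over `n_reps` resampling replicates, each
#' computed at all singleton SNPs plus one randomly selected SNP per
#' linkage group (see [resample_representatives()]). Excluded loci never
#' contribute.
#'
#' @param gm a [genotype_matrix()].
#' @param lg a [build_linkage_groups()] partition; `NULL` treats every
#'   locus as a singleton (no resampling variance).
#' @param n_reps resampling replicates (the study design uses 100).
#' @param seed integer seed.
#' @param loci optional restriction: only singletons/groups intersecting
#'   this locus set are used (the neutral / nonneutral partitions).
#' @return named numeric vector of resampled MLH per individual.
#' @export
mlh_resampled <- function(gm, lg = NULL, n_reps = 100L, seed = NULL,
                          loci = NULL) {
  if (is.null(lg)) {
    use <- loci %||% gm$alleles$locus
    return(mlh(gm, use))
  }
  stopifnot(inherits(lg, "linkage_groups"))
  lg_use <- lg
  if (!is.null(loci)) {
    lg_use$singletons <- intersect(lg$singletons, loci)
    lg_use$groups <- lapply(lg$groups, intersect, loci)
    lg_use$groups <- lg_use$groups[vapply(lg_use$groups, length, 1L) > 0]
  }
  if (!length(lg_use$singletons) && !length(lg_use$groups))
    return(stats::setNames(rep(NA_real_, nrow(gm$calls)), gm$samples$id))
  with_seed(seed, {
    acc <- rep(0, nrow(gm$calls)); cnt <- rep(0L, nrow(gm$calls))
    for (r in seq_len(n_reps)) {
      sub <- resample_representatives(lg_use)
      v <- mlh(gm, sub)
      ok <- !is.na(v)
      acc[ok] <- acc[ok] + v[ok]
      cnt <- cnt + ok
    }
    stats::setNames(ifelse(cnt > 0, acc / cnt, NA_real_), gm$samples$id)
  })
}

#' Mean and standard error by group
#'
#' Summarizes per-individual estimates (e.g. MLH) over population x
#' generation cells: mean and SE = sd / sqrt(n). Cells with one
#' individual report `NA` SE.
#'
#' @param values named numeric vector of per-individual estimates.
#' @param groups data frame aligned with `values` whose columns define the
#'   grouping (e.g. population, generation).
#' @return data frame of group keys, `n`, `mean`, `se`.
#' @export
group_summary <- function(values, groups) {
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  stopifnot(nrow(groups) == length(values))
  key <- interaction(groups, drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    i <- which(key == k & !is.na(values))
    cbind(groups[match(k, key), , drop = FALSE],
          data.frame(n = length(i),
                     mean = if (length(i)) mean(values[i]) else NA_real_,
                     se = if (length(i) > 1)
                       stats::sd(values[i]) / sqrt(length(i)) else NA_real_))
  }))
  rownames(out) <- NULL
  out
}

#' Within-individual neutral-minus-nonneutral MLH difference
#'
#' For each individual with both partitions defined,
#' `d = MLH(neutral) - MLH(nonneutral)`; summarized per stratum as mean(d)
#' with a mean +/- 1 SE interval. Selective sweeps depress heterozygosity
#' at nonneutral loci, so d is typically positive and larger where
#' selection bit harder.
#'
#' @param est_neutral,est_nonneutral named per-individual MLH vectors
#'   (e.g. from [mlh_resampled()] on the two partitions).
#' @param strata optional factor (e.g. protocol) aligned with the
#'   individuals; `NULL` summarizes everything as one stratum.
#' @return data frame: stratum, n, mean_diff, se, lower, upper.
#' @export
partition_difference <- function(est_neutral, est_nonneutral, strata = NULL) {
  ids <- intersect(names(est_neutral), names(est_nonneutral))
  d <- est_neutral[ids] - est_nonneutral[ids]
  ok <- !is.na(d)
  d <- d[ok]; ids <- ids[ok]
  if (is.null(strata)) strata <- rep("all", length(d))
  else {
    if (!is.null(names(strata))) strata <- strata[ids]
    else stop("strata must be a named vector when individuals are dropped")
  }
  out <- do.call(rbind, lapply(unique(strata), function(s) {
    di <- d[strata == s]
    se <- if (length(di) > 1) stats::sd(di) / sqrt(length(di)) else NA_real_
    data.frame(stratum = s, n = length(di), mean_diff = mean(di), se = se,
               lower = mean(di) - se, upper = mean(di) + se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Effective population size from heterozygosity loss
#'
#' Inverts the Wright-Fisher heterozygosity decay
#' `H_t = H_0 (1 - 1/(2 Ne))^t`:
#' `Ne = 1 / (2 (1 - (H_t/H_0)^(1/t)))`. `H_0` and `H_t` are mean
#' individual MLH (observed heterozygosity) at the initial and final
#' generations. Undefined (with an explanatory status) when `H_t >= H_0`.
#'
#' @param H0,Ht initial and final heterozygosity, both in (0, 1].
#' @param t elapsed generations (the study spans generation-1 founder
#'   offspring to generation 19, i.e. t = 18).
#' @return list with `Ne`, `H0`, `Ht`, `t`, `status` ("ok" or a reason
#'   why `Ne` is `NA`).
#' @export
ne_from_heterozygosity <- function(H0, Ht, t = 18) {
  stopifnot(t >= 1, H0 > 0, H0 <= 1, Ht >= 0, Ht <= 1)
  if (Ht >= H0)
    return(list(Ne = NA_real_, H0 = H0, Ht = Ht, t = t,
                status = "no heterozygosity loss (Ht >= H0)"))
  if (Ht <= 0)
    return(list(Ne = NA_real_, H0 = H0, Ht = Ht, t = t,
                status = "heterozygosity fully lost (Ht = 0)"))
  ne <- 1 / (2 * (1 - (Ht / H0)^(1 / t)))
  list(Ne = ne, H0 = H0, Ht = Ht, t = t, status = "ok")
}

#' Fit the heterozygosity decay rate of a set of trajectories
#'
#' Least-squares fit of `log H_t = log H_0 + t log(1 - 1/(2 Ne))` to
#' per-generation mean heterozygosities, returning the implied Ne and the
#' R-squared of the fit (drift physics check).
#'
#' @param H numeric vector of mean heterozygosity per generation.
#' @param generations generation indices aligned with `H`.
#' @return list with `Ne`, `r_squared`, `fit` (the `lm` object).
#' @export
fit_heterozygosity_decay <- function(H, generations = seq_along(H) - 1L) {
  ok <- !is.na(H) & H > 0
  fit <- stats::lm(log(H[ok]) ~ generations[ok])
  lam <- exp(stats::coef(fit)[2])
  ne <- if (lam < 1) 1 / (2 * (1 - lam)) else NA_real_
  list(Ne = unname(ne), r_squared = summary(fit)$r.squared, fit = fit)
}
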