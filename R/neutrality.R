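#' Null allele-frequency distributions under neutral breeding
#'
#' Simulates the colony `n_reps` times from the same founder state under
#' the matched protocol with no selection on the genotyped loci, recording
#' for every locus the frequency of the founder-defined minor allele at
#' each requested generation. All loci ride the same pedigree within a
#' replicate (the breeding program is simulated once per replicate). A
#' replicate that goes extinct before the last requested generation is
#' re-drawn with a fresh sub-seed.
#'
#' @param founders founder `colony_state` (see [generate_founders()]).
#' @param config [breeding_config()]; any viability selection in it is
#'   switched off for the null runs.
#' @param generations generation(s) at which to record frequencies.
#' @param n_reps replicate count (the study design uses 100).
#' @param seed integer seed; replicate r runs on sub-stream r.
#' @return object of class `null_distribution`: list with `freq` (a list,
#'   one loci x n_reps matrix per generation), `generations`, `protocol`,
#'   `n_redrawn`.
#' @export
null_frequency_distributions <- function(founders, config, generations = 19L,
                                         n_reps = 100L, seed = NULL) {
  stopifnot(inherits(founders, "colony_state"), n_reps >= 1,
            all(generations > max(founders$ped$generation)),
            all(generations <= config$n_generations))
  config$selection_s <- 0
  config$selection_loci <- integer(0)
  L <- ncol(founders$geno)
  freq <- lapply(generations, function(g) matrix(NA_real_, L, n_reps))
  names(freq) <- as.character(generations)
  n_redrawn <- 0L
  seed <- seed %||% sample.int(2147480000L, 1)
  for (r in seq_len(n_reps)) {
    attempt <- 0L
    repeat {
      rseed <- sub_seed(seed, r + attempt * n_reps)
      st <- simulate_colony(founders, config, seed = rseed)
      if (st$final_gen >= max(generations)) break
      attempt <- attempt + 1L
      n_redrawn <- n_redrawn + 1L
      if (attempt > 50L) stop("null replicate extinct 50 times in a row; ",
                              "offspring distribution too harsh")
    }
    for (gch in names(freq)) freq[[gch]][, r] <- st$traj[, gch]
  }
  structure(list(freq = freq, generations = as.integer(generations),
                 protocol = config$protocol, n_reps = as.integer(n_reps),
                 n_redrawn = n_redrawn,
                 loci = founders$alleles$locus),
            class = "null_distribution")
}

#' Empirical p-value for allele-frequency extremeness
#'
#' Extremeness of a frequency q is its distance to the nearest boundary,
#' E(q) = min(q, 1 - q). The p-value of an observed frequency is the
#' proportion of simulated replicate frequencies strictly more extreme
#' (closer to 0 or 1): `p = #{E(q_sim) < E(q_emp)} / n_reps`, so p = 0 is
#' attainable. `mode = "add_one"` gives the conservative
#' `(b + 1) / (n + 1)` variant.
#'
#' The strict inequality means a locus whose observed frequency sits
#' exactly at a boundary (fixed or lost) always gets p = 0, even when the
#' null fixes at the same rate — in strongly drifting colonies the test
#' therefore auto-flags every fixed locus. `mode = "tie_inclusive"`
#' counts replicates at the same extremeness as well
#' (`#\{E_sim <= E_emp\}/n`), which restores calibration at the boundary
#' atoms at the price of departing from the strict "more extreme" reading.
#'
#' @param q_emp observed minor-allele frequency (scalar or vector).
#' @param q_sim replicate frequencies: a vector (one locus) or a matrix
#'   with one row per locus aligned with `q_emp`.
#' @param mode `"proportion"` (default), `"add_one"`, or
#'   `"tie_inclusive"`.
#' @return raw p-value(s) in \code{[0, 1]}.
#' @export
empirical_pvalue <- function(q_emp, q_sim,
                             mode = c("proportion", "add_one",
                                      "tie_inclusive")) {
  mode <- match.arg(mode)
  if (is.matrix(q_sim)) {
    stopifnot(length(q_emp) == nrow(q_sim))
    return(vapply(seq_along(q_emp), function(i)
      empirical_pvalue(q_emp[i], q_sim[i, ], mode = mode), numeric(1)))
  }
  if (is.na(q_emp) || all(is.na(q_sim))) return(NA_real_)
  stopifnot(q_emp >= 0, q_emp <= 1)
  e_emp <- pmin(q_emp, 1 - q_emp)
  e_sim <- pmin(q_sim, 1 - q_sim)
  n <- sum(!is.na(e_sim))
  if (mode == "tie_inclusive")
    return(sum(e_sim <= e_emp + 1e-12, na.rm = TRUE) / n)
  b <- sum(e_sim < e_emp, na.rm = TRUE)
  if (mode == "add_one") (b + 1) / (n + 1) else b / n
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1 and mapped back
#' to the input order; flags from `adj < alpha` coincide with the classic
#' step-up rejection rule.
#'
#' @param pvals numeric vector of raw p-values in \code{[0, 1]} (`NA`
#'   allowed, returned as `NA`).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  out <- rep(NA_real_, length(pvals))
  ok <- which(!is.na(pvals))
  p <- pvals[ok]
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(out)
  o <- order(p)
  adj <- pmin(1, cummin(rev(m * p[o] / seq_len(m))))
  out[ok[o]] <- rev(adj)
  out
}

#' Neutrality scan of observed frequencies against the null
#'
#' @param q_emp observed minor-allele frequencies (one per locus).
#' @param nd a [null_frequency_distributions()] result.
#' @param generation which recorded generation to test.
#' @param alpha FDR level for the nonneutral flag.
#' @inheritParams empirical_pvalue
#' @return data frame: locus, p_raw, p_adj, nonneutral.
#' @export
neutrality_scan <- function(q_emp, nd, generation = nd$generations[1],
                            alpha = 0.05, mode = "proportion") {
  stopifnot(inherits(nd, "null_distribution"))
  qs <- nd$freq[[as.character(generation)]]
  if (is.null(qs)) stop("generation ", generation, " not recorded in null")
  p <- empirical_pvalue(q_emp, qs, mode = mode)
  adj <- bh_adjust(p)
  data.frame(locus = nd$loci, p_raw = p, p_adj = adj,
             nonneutral = !is.na(adj) & adj < alpha,
             stringsAsFactors = FALSE)
}

#' Aggregate nonneutral flags over linkage units
#'
#' A singleton counts as one unit; a linkage group counts as one unit and
#' is flagged if any member locus is flagged. The reported count is the
#' number of flagged singletons plus flagged groups (excluded loci do not
#' contribute units).
#'
#' @param scan data frame from [neutrality_scan()] (columns `locus`,
#'   `nonneutral`).
#' @param lg a [build_linkage_groups()] partition of the scanned loci.
#' @return list with `units` (data frame: unit, kind, nonneutral) and
#'   `n_nonneutral` (flagged singletons + flagged groups).
#' @export
classify_nonneutral <- function(scan, lg) {
  stopifnot(inherits(lg, "linkage_groups"))
  flag <- scan$nonneutral
  names(flag) <- scan$locus
  s_units <- if (length(lg$singletons)) data.frame(
    unit = lg$singletons, kind = "singleton",
    nonneutral = unname(flag[lg$singletons]) %in% TRUE,
    stringsAsFactors = FALSE) else NULL
  g_units <- if (length(lg$groups)) data.frame(
    unit = paste0("group:", seq_along(lg$groups)), kind = "group",
    nonneutral = vapply(lg$groups, function(g)
      any(flag[g] %in% TRUE), logical(1)),
    stringsAsFactors = FALSE) else NULL
  units <- rbind(s_units, g_units)
  if (is.null(units))
    units <- data.frame(unit = character(0), kind = character(0),
                        nonneutral = logical(0))
  rownames(units) <- NULL
  list(units = units, n_nonneutral = sum(units$nonneutral))
}

#' Two-way ANOVA with Tukey HSD on nonneutral counts
#'
#' Fits `count ~ protocol + generation` (fixed effects, no interaction) on
#' per-population nonneutral-unit counts and runs Tukey's honest
#' significant difference on the generation means. A factor with a single
#' level is dropped with a warning.
#'
#' @param counts data frame with columns `count`, `protocol`, `generation`
#'   (and optionally `population`).
#' @return list with `anova` (data frame of F and p per factor) and
#'   `tukey` (data frame of pairwise generation differences with adjusted
#'   p), plus the fitted `aov` object.
#' @export
count_anova_tukey <- function(counts) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("count", "protocol", "generation") %in% names(counts)))
  counts$protocol <- factor(counts$protocol)
  counts$generation <- factor(counts$generation)
  terms <- c("protocol", "generation")
  for (tname in terms) {
    if (nlevels(counts[[tname]]) < 2L) {
      warning("factor '", tname, "' has a single level; dropped")
      terms <- setdiff(terms, tname)
    }
  }
  if (!length(terms)) stop("no factor with >= 2 levels")
  fit <- stats::aov(stats::reformulate(terms, "count"), data = counts)
  at <- stats::anova(fit)
  an <- data.frame(factor = rownames(at)[seq_along(terms)],
                   df = at$Df[seq_along(terms)],
                   F = at$`F value`[seq_along(terms)],
                   p = at$`Pr(>F)`[seq_along(terms)],
                   stringsAsFactors = FALSE)
  tk <- NULL
  if ("generation" %in% terms) {
    th <- stats::TukeyHSD(fit, which = "generation")$generation
    tk <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                     p_adj = th[, "p adj"], stringsAsFactors = FALSE)
    rownames(tk) <- NULL
  }
  list(anova = an, tukey = tk, fit = fit)
}
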