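#' Breeding configuration
#'
#' Describes one captive-colony breeding protocol:
#' \describe{
#'   \item{MK}{minimize mean kinship: mean kinships are computed over the
#'     living cohort, the single highest-mk individual is removed, kinships
#'     are recalculated, and the procedure repeats until `pairs_per_generation`
#'     males and females remain (a ranked-removal procedure).}
#'   \item{RAN}{random mating: breeders drawn uniformly; pairs more closely
#'     related than the current mean pairwise kinship are avoided.}
#'   \item{DOC}{docility selection: the most sedentary (lowest trait value)
#'     individuals are chosen as breeders; requires a `trait_model`.}
#' }
#' All protocols avoid close-kin pairings when `close_kin_rule` is on.
#'
#' @param protocol `"MK"`, `"RAN"` or `"DOC"`.
#' @param pairs_per_generation breeding pairs formed each generation.
#' @param n_generations last generation bred (founder offspring are
#'   generation 1).
#' @param offspring_dist probability table over litter sizes (number of
#'   offspring weaned per pair): a named numeric vector, names = sizes.
#'   Default: negative binomial (mean 4, dispersion 2) truncated at 12.
#' @param close_kin_rule avoid pairs more related than the cohort average.
#' @param trait_model a [trait_model()] (required for DOC).
#' @param doc_select_on_trait for DOC: select breeders on the simulated
#'   trait (default) or randomly (the alternative null reading).
#' @param mk_batch_removal MK variant removing all tied-top individuals per
#'   iteration instead of one; off by default.
#' @param selection_loci,selection_s optional soft viability selection
#'   against the founder-minor allele: relative pre-weaning fitness
#'   `(1 - s)^g`, `g` the minor-allele copies summed over
#'   `selection_loci`; an offspring survives with probability
#'   `min(1, w / mean(w))` over the conceived cohort, so weaned counts
#'   stay close to the configured distribution even under heavy
#'   multilocus load. Used by the synthetic-study generator; the
#'   neutrality null keeps `s = 0`.
#' @return a `breeding_config` list.
#' @export
breeding_config <- function(protocol = c("RAN", "MK", "DOC"),
                            pairs_per_generation = 20L,
                            n_generations = 20L,
                            offspring_dist = default_offspring_dist(),
                            close_kin_rule = TRUE,
                            trait_model = NULL,
                            doc_select_on_trait = TRUE,
                            mk_batch_removal = FALSE,
                            selection_loci = integer(0),
                            selection_s = 0) {
  protocol <- match.arg(protocol)
  stopifnot(pairs_per_generation >= 1, n_generations >= 1,
            abs(sum(offspring_dist) - 1) < 1e-8,
            !is.null(names(offspring_dist)),
            selection_s >= 0, selection_s < 1)
  if (protocol == "DOC" && is.null(trait_model))
    stop("DOC protocol requires a trait_model")
  structure(list(protocol = protocol,
                 pairs_per_generation = as.integer(pairs_per_generation),
                 n_generations = as.integer(n_generations),
                 offspring_dist = offspring_dist,
                 close_kin_rule = isTRUE(close_kin_rule),
                 trait_model = trait_model,
                 doc_select_on_trait = isTRUE(doc_select_on_trait),
                 mk_batch_removal = isTRUE(mk_batch_removal),
                 selection_loci = as.integer(selection_loci),
                 selection_s = selection_s),
            class = "breeding_config")
}

#' @rdname breeding_config
#' @param mean,dispersion,max_size negative-binomial litter-size parameters.
#' @export
default_offspring_dist <- function(mean = 4, dispersion = 2, max_size = 12L) {
  p <- stats::dnbinom(0:max_size, size = dispersion, mu = mean)
  p <- p / sum(p)
  names(p) <- 0:max_size
  p
}

#' Additive trait architecture
#'
#' A simple additive genetic model with biallelic loci: the trait is the sum
#' over `loci` of `effects` per copy of the locus's second allele plus
#' Gaussian noise. Used for the docility trait under DOC selection.
#'
#' @param loci integer indices into the genotype matrix columns.
#' @param effects per-locus additive effects (trait units per allele copy).
#' @param noise_sd environmental noise standard deviation.
#' @export
trait_model <- function(loci, effects, noise_sd) {
  stopifnot(length(loci) == length(effects), all(is.finite(effects)),
            noise_sd >= 0)
  structure(list(loci = as.integer(loci), effects = as.numeric(effects),
                 noise_sd = noise_sd), class = "trait_model")
}

#' @rdname trait_model
#' @param founder_freq allele-2 frequencies at all loci (used to scale the
#'   noise so narrow-sense heritability is approximately `h2`).
#' @param n_loci,effect number of trait loci and the common effect size.
#' @param h2 target heritability in the founder population.
#' @param seed seed for the random choice of trait loci.
#' @export
default_trait_model <- function(founder_freq, n_loci = 10L, effect = 1,
                                h2 = 0.5, seed = NULL) {
  with_seed(seed, {
    loci <- sample_exact(seq_along(founder_freq), min(n_loci,
                                                      length(founder_freq)))
    p <- founder_freq[loci]
    va <- sum(2 * p * (1 - p) * effect^2)
    if (va <= 0) va <- 1
    trait_model(loci, rep(effect, length(loci)),
                noise_sd = sqrt(va * (1 - h2) / h2))
  })
}

# ---- colony state ----------------------------------------------------------

# A colony_state holds the whole simulated colony: an integer-indexed
# pedigree, the dosage genotype matrix (copies of allele a2), the kinship
# matrix grown generation by generation, the founder-defined minor allele,
# and the minor-allele-frequency trajectory.
new_colony_state <- function(geno, sex, generation, sire, dam, alleles,
                             population = "sim", trait = NULL) {
  n <- nrow(geno)
  stopifnot(length(sex) == n, length(generation) == n,
            length(sire) == n, length(dam) == n)
  ped <- data.frame(id = seq_len(n), sire = as.integer(sire),
                    dam = as.integer(dam), sex = as.integer(sex),
                    generation = as.integer(generation))
  pt <- as_pedigree(data.frame(
    id = as.character(ped$id),
    sire = ifelse(is.na(ped$sire), NA, as.character(ped$sire)),
    dam = ifelse(is.na(ped$dam), NA, as.character(ped$dam)),
    sex = c("M", "F")[ped$sex], generation = ped$generation,
    population = population, stringsAsFactors = FALSE))
  K <- kinship_matrix(pt)
  # kinship_matrix may reorder; map back to integer id order
  K <- K[as.character(ped$id), as.character(ped$id)]
  gen1 <- which(ped$generation == max(ped$generation))
  gm1 <- genotype_matrix(geno[gen1, , drop = FALSE], alleles,
                         data.frame(id = as.character(gen1)))
  minor <- minor_allele(gm1)
  st <- list(ped = ped, geno = geno, K = unname(K), alleles = alleles,
             minor = minor, population = population,
             trait = trait %||% rep(NA_real_, n),
             alive = gen1,
             extinct = FALSE, final_gen = max(ped$generation),
             traj = NULL)
  class(st) <- "colony_state"
  st$traj <- cbind(colony_minor_freq(st, st$alive))
  colnames(st$traj) <- max(ped$generation)
  st
}

#' @export
print.colony_state <- function(x, ...) {
  cat(sprintf(
    "colony_state (%s): %d members, generations %d-%d, %d loci%s\n",
    x$population, nrow(x$ped), min(x$ped$generation), x$final_gen,
    ncol(x$geno), if (x$extinct) " [EXTINCT]" else ""))
  invisible(x)
}

# minor-allele frequency across `rows` of the colony genotype matrix
colony_minor_freq <- function(state, rows) {
  q2 <- colMeans(state$geno[rows, , drop = FALSE], na.rm = TRUE) / 2
  ifelse(state$minor == 2L, q2, 1 - q2)
}

#' Extract standard containers from a simulated colony
#'
#' @param state a `colony_state` from [simulate_colony()] or
#'   [generate_founders()].
#' @param prefix id prefix for member names.
#' @return `colony_pedigree()`: a [as_pedigree()] table;
#'   `colony_genotypes()`: a [genotype_matrix()] (optionally subset by
#'   generation).
#' @export
colony_pedigree <- function(state, prefix = "I") {
  nm <- paste0(prefix, state$ped$id)
  as_pedigree(data.frame(
    id = nm,
    sire = ifelse(is.na(state$ped$sire), NA, paste0(prefix, state$ped$sire)),
    dam = ifelse(is.na(state$ped$dam), NA, paste0(prefix, state$ped$dam)),
    sex = c("M", "F")[state$ped$sex],
    generation = state$ped$generation,
    population = state$population, stringsAsFactors = FALSE))
}

#' @rdname colony_pedigree
#' @param generations optional generations to keep.
#' @export
colony_genotypes <- function(state, generations = NULL, prefix = "I") {
  keep <- if (is.null(generations)) seq_len(nrow(state$ped))
          else which(state$ped$generation %in% generations)
  genotype_matrix(state$geno[keep, , drop = FALSE], state$alleles,
                  data.frame(id = paste0(prefix, state$ped$id[keep]),
                             population = state$population,
                             generation = state$ped$generation[keep],
                             stringsAsFactors = FALSE))
}

# ---- selection / pairing / transmission kernels ----------------------------
# The kernels work on the living cohort only (small matrices), so the
# simulator never has to copy its full kinship/genotype buffers.

# ranked mean-kinship removal; returns list(males, females) of local indices
mk_select_kernel <- function(Ks, sex, n_pairs, batch_removal = FALSE) {
  keep <- rep(TRUE, length(sex))
  rs <- rowSums(Ks)
  repeat {
    n_m <- sum(keep & sex == 1L); n_f <- sum(keep & sex == 2L)
    if (n_m == n_pairs && n_f == n_pairs) break
    # only individuals whose sex still has surplus are removable
    removable <- keep & ((sex == 1L & n_m > n_pairs) |
                         (sex == 2L & n_f > n_pairs))
    mk <- rs[removable] / sum(keep)
    top <- which(removable)[mk >= max(mk) - 1e-12]
    drop_i <- if (batch_removal) top else sample_exact(top, 1L)
    keep[drop_i] <- FALSE
    # removing a column updates every remaining row sum
    rs <- rs - rowSums(Ks[, drop_i, drop = FALSE])
  }
  list(males = which(keep & sex == 1L), females = which(keep & sex == 2L))
}

doc_select_kernel <- function(tv, sex, n_pairs) {
  pick_low <- function(which_sex) {
    i <- which(sex == which_sex)
    # seeded uniform jitter rank breaks exact ties reproducibly
    i[order(tv[i], stats::runif(length(i)))][seq_len(n_pairs)]
  }
  list(males = pick_low(1L), females = pick_low(2L))
}

# close-kin-aware monogamous pairing on cohort kinship Ks; males/females are
# local indices into Ks. Returns local (sire, dam) index matrix + relaxed n.
pair_kernel <- function(Ks, males, females, close_kin_rule = TRUE) {
  n <- length(males)
  if (!close_kin_rule)
    return(list(sire = males, dam = sample_exact(females, n), relaxed = 0L))
  thr <- if (nrow(Ks) > 1L) mean(Ks[upper.tri(Ks)]) else Inf
  Kp <- Ks[males, females, drop = FALSE]
  left_m <- seq_len(n); left_f <- seq_len(n)
  sire <- dam <- integer(n); relaxed <- 0L
  for (step in seq_len(n)) {
    adm <- Kp[left_m, left_f, drop = FALSE] <= thr
    n_adm <- rowSums(adm)
    # most-constrained male first; ties broken uniformly
    mi <- left_m[order(n_adm, stats::runif(length(left_m)))][1]
    ok <- left_f[Kp[mi, left_f] <= thr]
    if (length(ok)) {
      fi <- sample_exact(ok, 1L)
    } else {
      relaxed <- relaxed + 1L
      fi <- left_f[which.min(Kp[mi, left_f])]
    }
    sire[step] <- males[mi]; dam[step] <- females[fi]
    left_m <- setdiff(left_m, mi); left_f <- setdiff(left_f, fi)
  }
  list(sire = sire, dam = dam, relaxed = relaxed)
}

# Mendelian transmission: one uniformly chosen allele per parent per locus.
# P(transmit allele-2) = dosage/2, so a single uniform draw per parent-locus
# suffices (0 -> never, 2 -> always, het -> fair coin).
mendel_kernel <- function(GS, GD) {
  geno <- (stats::runif(length(GS)) < GS / 2) +
          (stats::runif(length(GD)) < GD / 2)
  storage.mode(geno) <- "integer"
  geno
}

# Soft viability selection before weaning. Relative fitness is
# (1-s)^g with g = minor-allele copies at the selected loci; an offspring
# survives with probability min(1, w / wbar), wbar the mean fitness of
# the conceived cohort. Normalizing by the cohort mean keeps weaned
# counts close to the configured (observed) offspring distribution even
# under a heavy multilocus load, while preserving between-family fitness
# variance — the channel through which family-size-equalizing management
# damps the response to selection.
viability_survivors <- function(geno, minor, sel_loci, s) {
  gsel <- geno[, sel_loci, drop = FALSE]
  flip <- minor[sel_loci] == 1L
  gsel[, flip] <- 2L - gsel[, flip, drop = FALSE]
  w <- (1 - s)^rowSums(gsel)
  stats::runif(nrow(geno)) < pmin(1, w / mean(w))
}

# ---- exported per-step operations ------------------------------------------

#' Breeder selection under the three protocols
#'
#' Each returns `list(males, females)` of member indices of length
#' `n_pairs`, or `NULL` when fewer than `n_pairs` candidates of either sex
#' are alive (the colony then goes extinct).
#'
#' `select_breeders_mk()` implements the ranked mean-kinship procedure:
#' mean kinship is computed over the living cohort, the individual with the
#' highest mk whose sex still has surplus candidates is removed, mean
#' kinships are recalculated over the remaining cohort, and this repeats
#' until exactly `n_pairs` of each sex remain. Ties at the top are broken
#' by a seeded uniform draw.
#'
#' @param state a `colony_state`.
#' @param n_pairs pairs to form.
#' @param seed integer seed.
#' @param batch_removal remove all tied-highest individuals per iteration.
#' @export
select_breeders_mk <- function(state, n_pairs, seed = NULL,
                               batch_removal = FALSE) {
  cand <- state$alive
  sex <- state$ped$sex[cand]
  if (sum(sex == 1L) < n_pairs || sum(sex == 2L) < n_pairs) return(NULL)
  with_seed(seed, {
    sel <- mk_select_kernel(state$K[cand, cand, drop = FALSE], sex, n_pairs,
                            batch_removal)
    list(males = cand[sel$males], females = cand[sel$females])
  })
}

#' @rdname select_breeders_mk
#' @export
select_breeders_random <- function(state, n_pairs, seed = NULL) {
  cand <- state$alive
  sex <- state$ped$sex[cand]
  males <- cand[sex == 1L]; females <- cand[sex == 2L]
  if (length(males) < n_pairs || length(females) < n_pairs) return(NULL)
  with_seed(seed, list(males = sample_exact(males, n_pairs),
                       females = sample_exact(females, n_pairs)))
}

#' @rdname select_breeders_mk
#' @param trait_values per-member trait vector (lower = more docile =
#'   preferred); defaults to the colony's stored docility trait.
#' @export
select_breeders_doc <- function(state, n_pairs, trait_values = state$trait,
                                seed = NULL) {
  cand <- state$alive
  sex <- state$ped$sex[cand]
  tv <- trait_values[cand]
  if (any(is.na(tv))) stop("DOC selection requires trait values for all ",
                           "candidates")
  if (sum(sex == 1L) < n_pairs || sum(sex == 2L) < n_pairs) return(NULL)
  with_seed(seed, {
    sel <- doc_select_kernel(tv, sex, n_pairs)
    list(males = cand[sel$males], females = cand[sel$females])
  })
}

#' Pair selected breeders under the close-kin rule
#'
#' Monogamous pairing of `n_pairs` males with `n_pairs` females. With the
#' close-kin rule on, a pair is admissible only if its kinship does not
#' exceed the mean pairwise kinship of the living cohort. Males are
#' matched most-constrained-first (fewest admissible partners), each
#' receiving a uniformly chosen admissible female; when none is admissible
#' the minimum-kinship remaining female is used and a warning is recorded.
#'
#' @param state colony state (supplies kinship and the living cohort).
#' @param males,females equal-length member index vectors.
#' @param close_kin_rule logical.
#' @param seed integer seed.
#' @return data frame with columns `sire`, `dam` (member indices) and
#'   attribute `relaxed` = number of pairs where the rule had to be relaxed.
#' @export
pair_breeders <- function(state, males, females, close_kin_rule = TRUE,
                          seed = NULL) {
  stopifnot(length(males) == length(females))
  with_seed(seed, {
    cohort <- state$alive
    loc <- match(c(males, females), cohort)
    if (anyNA(loc)) stop("breeders must belong to the living cohort")
    n <- length(males)
    pr <- pair_kernel(state$K[cohort, cohort, drop = FALSE],
                      loc[seq_len(n)], loc[n + seq_len(n)],
                      close_kin_rule = close_kin_rule)
    if (pr$relaxed > 0L)
      warning("close-kin rule relaxed for ", pr$relaxed, " pairing(s)")
    structure(data.frame(sire = cohort[pr$sire], dam = cohort[pr$dam]),
              relaxed = pr$relaxed)
  })
}

#' Produce one offspring generation
#'
#' Litter sizes are drawn per pair from the configured offspring-count
#' distribution; each offspring receives one uniformly chosen allele per
#' parent per locus (Mendelian transmission) and is assigned male/female
#' with probability 0.5. Optional soft viability selection thins
#' conceived offspring before weaning with survival
#' `min(1, w / mean(w))`, `w = (1 - s)^g` the relative fitness from the
#' minor-allele copies at the selected loci.
#'
#' @param pairs data frame from [pair_breeders()].
#' @param state colony state.
#' @param config [breeding_config()].
#' @param seed integer seed.
#' @return list with `geno` (offspring dosage matrix), `sex`, `sire`,
#'   `dam` (member indices of parents, one entry per offspring).
#' @export
reproduce_pairs <- function(pairs, state, config, seed = NULL) {
  with_seed(seed, {
    sizes <- as.integer(names(config$offspring_dist))
    litter <- sample_exact(sizes, nrow(pairs), replace = TRUE,
                           prob = config$offspring_dist)
    sire <- rep(pairs$sire, litter)
    dam <- rep(pairs$dam, litter)
    m <- length(sire)
    if (m == 0L)
      return(list(geno = state$geno[0, , drop = FALSE], sex = integer(0),
                  sire = integer(0), dam = integer(0)))
    geno <- mendel_kernel(state$geno[sire, , drop = FALSE],
                          state$geno[dam, , drop = FALSE])
    if (config$selection_s > 0 && length(config$selection_loci)) {
      ok <- viability_survivors(geno, state$minor, config$selection_loci,
                                config$selection_s)
      geno <- geno[ok, , drop = FALSE]
      sire <- sire[ok]; dam <- dam[ok]
      m <- sum(ok)
    }
    sex <- 1L + stats::rbinom(m, 1L, 0.5)
    list(geno = geno, sex = sex, sire = sire, dam = dam)
  })
}

# ---- the simulator ---------------------------------------------------------

#' Simulate a captive colony forward in time
#'
#' Starting from a founder state (wild founders at generation 0 plus their
#' generation-1 offspring, see [generate_founders()]), breeds the colony to
#' `config$n_generations` under the configured protocol: breeder selection,
#' close-kin-aware pairing, litter sizes from the offspring-count
#' distribution, and Mendelian transmission. The minor-allele frequency of
#' every locus — for the allele identified as minor in the generation-1
#' founder-offspring genotypes — is recorded at every generation.
#'
#' @param founders a `colony_state` containing generations 0 and 1.
#' @param config a [breeding_config()].
#' @param seed integer seed (all randomness in the run flows from it).
#' @return a `colony_state` with the full pedigree, genotypes, kinship
#'   matrix and `traj` (loci x generations matrix of minor-allele
#'   frequencies). If the colony dies out before the last generation the
#'   state is flagged `extinct` and the trajectory is truncated.
#' @export
simulate_colony <- function(founders, config, seed = NULL) {
  stopifnot(inherits(founders, "colony_state"),
            inherits(config, "breeding_config"))
  state <- founders
  n_pairs <- config$pairs_per_generation
  first_gen <- max(state$ped$generation) + 1L
  if (first_gen > config$n_generations) return(state)
  # DOC founders bred before a trait model existed: backfill trait values
  if (!is.null(config$trait_model) && anyNA(state$trait[state$alive])) {
    tm <- config$trait_model
    gv <- drop(state$geno[state$alive, tm$loci, drop = FALSE] %*% tm$effects)
    state$trait[state$alive] <- with_seed(
      if (is.null(seed)) NULL else sub_seed(seed, 999L),
      gv + stats::rnorm(length(gv), 0, tm$noise_sd))
  }
  with_seed(seed, {
    gen_seeds <- sample.int(2147483000L, config$n_generations)
    n <- nrow(state$ped)
    L <- ncol(state$geno)
    # size the buffers for the expected colony once, to avoid doubling
    # copies of the kinship matrix mid-run
    mean_litter <- sum(as.integer(names(config$offspring_dist)) *
                         config$offspring_dist)
    exp_total <- (config$n_generations - first_gen + 1L) * n_pairs *
      mean_litter
    cap <- max(256L, n + as.integer(ceiling(1.25 * exp_total)) + 64L)
    Kb <- matrix(0, cap, cap); Kb[1:n, 1:n] <- state$K
    Gb <- matrix(NA_integer_, cap, L); Gb[1:n, ] <- state$geno
    sire_v <- c(state$ped$sire, rep(NA_integer_, cap - n))
    dam_v <- c(state$ped$dam, rep(NA_integer_, cap - n))
    sex_v <- c(state$ped$sex, rep(NA_integer_, cap - n))
    gen_v <- c(state$ped$generation, rep(NA_integer_, cap - n))
    trait_v <- c(state$trait, rep(NA_real_, cap - n))
    traj <- matrix(NA_real_, L, config$n_generations,
                   dimnames = list(NULL, seq_len(config$n_generations)))
    traj[, colnames(state$traj)] <- state$traj
    alive <- state$alive
    for (g in seq(first_gen, config$n_generations)) {
      gseed <- gen_seeds[g]
      sex_a <- sex_v[alive]
      if (sum(sex_a == 1L) < n_pairs || sum(sex_a == 2L) < n_pairs) {
        state$extinct <- TRUE; break
      }
      Ks <- Kb[alive, alive, drop = FALSE]    # cohort-size working copy
      off <- with_seed(gseed, {
        sel <- switch(config$protocol,
          MK = mk_select_kernel(Ks, sex_a, n_pairs,
                                config$mk_batch_removal),
          RAN = list(males = sample_exact(which(sex_a == 1L), n_pairs),
                     females = sample_exact(which(sex_a == 2L), n_pairs)),
          DOC = if (config$doc_select_on_trait)
                  doc_select_kernel(trait_v[alive], sex_a, n_pairs)
                else
                  list(males = sample_exact(which(sex_a == 1L), n_pairs),
                       females = sample_exact(which(sex_a == 2L), n_pairs)))
        pr <- pair_kernel(Ks, sel$males, sel$females,
                          close_kin_rule = config$close_kin_rule)
        sire_g <- alive[pr$sire]; dam_g <- alive[pr$dam]
        litter <- sample_exact(as.integer(names(config$offspring_dist)),
                               n_pairs, replace = TRUE,
                               prob = config$offspring_dist)
        sire_o <- rep(sire_g, litter); dam_o <- rep(dam_g, litter)
        if (!length(sire_o))
          list(geno = matrix(NA_integer_, 0, L), sex = integer(0),
               sire = integer(0), dam = integer(0))
        else {
          geno <- mendel_kernel(Gb[sire_o, , drop = FALSE],
                                Gb[dam_o, , drop = FALSE])
          if (config$selection_s > 0 && length(config$selection_loci)) {
            ok <- viability_survivors(geno, state$minor,
                                      config$selection_loci,
                                      config$selection_s)
            geno <- geno[ok, , drop = FALSE]
            sire_o <- sire_o[ok]; dam_o <- dam_o[ok]
          }
          list(geno = geno,
               sex = 1L + stats::rbinom(length(sire_o), 1L, 0.5),
               sire = sire_o, dam = dam_o)
        }
      })
      m <- length(off$sex)
      if (m == 0L) { state$extinct <- TRUE; break }
      if (n + m > cap) {
        cap2 <- max(2L * cap, n + m)
        K2 <- matrix(0, cap2, cap2); K2[1:n, 1:n] <- Kb[1:n, 1:n]
        Kb <- K2
        G2 <- matrix(NA_integer_, cap2, L); G2[1:n, ] <- Gb[1:n, ]
        Gb <- G2
        pad <- rep(NA_integer_, cap2 - cap)
        sire_v <- c(sire_v, pad); dam_v <- c(dam_v, pad)
        sex_v <- c(sex_v, pad); gen_v <- c(gen_v, pad)
        trait_v <- c(trait_v, as.numeric(pad))
        cap <- cap2
      }
      new <- n + seq_len(m)
      # tabular kinship extension, in place (parents are all in 1:n)
      K_on <- 0.5 * (Kb[1:n, off$sire, drop = FALSE] +
                     Kb[1:n, off$dam, drop = FALSE])
      Kb[1:n, new] <- K_on
      Kb[new, 1:n] <- t(K_on)
      C <- 0.5 * (K_on[off$sire, , drop = FALSE] +
                  K_on[off$dam, , drop = FALSE])
      diag(C) <- 0.5 * (1 + Kb[cbind(off$sire, off$dam)])
      Kb[new, new] <- C
      Gb[new, ] <- off$geno
      sire_v[new] <- off$sire; dam_v[new] <- off$dam
      sex_v[new] <- off$sex; gen_v[new] <- g
      if (!is.null(config$trait_model)) {
        tm <- config$trait_model
        trait_v[new] <- with_seed(gseed + 3L,
          drop(off$geno[, tm$loci, drop = FALSE] %*% tm$effects) +
            stats::rnorm(m, 0, tm$noise_sd))
      }
      n <- n + m
      alive <- new
      state$final_gen <- g
      q2 <- colMeans(off$geno, na.rm = TRUE) / 2
      traj[, g] <- ifelse(state$minor == 2L, q2, 1 - q2)
    }
    state$K <- Kb[1:n, 1:n]
    state$geno <- Gb[1:n, , drop = FALSE]
    state$ped <- data.frame(id = 1:n, sire = sire_v[1:n], dam = dam_v[1:n],
                            sex = sex_v[1:n], generation = gen_v[1:n])
    state$trait <- trait_v[1:n]
    state$alive <- alive
    keep_gen <- colSums(!is.na(traj)) > 0
    state$traj <- traj[, keep_gen, drop = FALSE]
    state
  })
}
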