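#' Synthetic study configuration
#'
#' The generator emulates the captive-colony study design: 20 wild founders
#' kept as 10 breeding pairs, whose offspring (generation 1) seed replicate
#' colonies bred at 20 pairs per generation for 20 generations under the
#' MK / RAN / DOC protocols. Genotypes carry block linkage structure
#' (each block descends from a small number of ancestral haplotypes, so
#' within-block D' is high by construction), a 10-locus additive docility
#' trait, litter sizes from a truncated negative-binomial distribution,
#' optional viability selection on designated loci, and fitness traits with
#' inbreeding depression so heterozygosity-fitness correlations exist by
#' construction.
#'
#' @param n_founders number of wild founders (paired as `n_founders/2`
#'   pairs; must be even).
#' @param n_snps total SNP loci.
#' @param n_linkage_blocks number of linked blocks (block loci are carved
#'   from the front of the locus list; the rest are independent).
#' @param block_size_probs probability table over block sizes (names =
#'   sizes, all >= 2).
#' @param block_haplotypes ancestral haplotypes per block (default 4).
#' @param founder_maf_range minor-allele-frequency range for founder loci
#'   (frequencies drawn uniformly within it).
#' @param n_selection_loci,selection_s loci under viability selection in
#'   the generating colonies and the selection coefficient (0 = neutral).
#' @param docility_loci,docility_h2 architecture of the additive docility
#'   trait used by DOC selection.
#' @param depression_slopes named vector of inbreeding-depression slopes,
#'   in trait units per unit F, for the five recorded traits.
#' @param trait_noise_sd named vector of environmental noise scales.
#' @param trait_baseline named vector of trait baselines (grams for weaning
#'   weight; millimetres for tail, ear and hind foot; expected counts for
#'   offspring weaned).
#' @param offspring_dist litter-size table (see [default_offspring_dist()]).
#' @param pairs_per_generation,n_generations colony design.
#' @param founder_offspring_per_pair generation-1 offspring contributed by
#'   each founding pair to each colony.
#' @param protocols protocols to generate; `n_replicates` colonies each.
#' @param sample_generations,sample_size genotyped generations and
#'   individuals sampled per colony-generation.
#' @param genotype_missing_rate,trait_missing_rate uniform missingness
#'   injected into emitted tables.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_founders = 20L,
                         n_snps = 500L,
                         n_linkage_blocks = 40L,
                         block_size_probs = c("2" = 0.6, "3" = 0.25,
                                              "4" = 0.1, "5" = 0.05),
                         block_haplotypes = 4L,
                         founder_maf_range = c(0.05, 0.5),
                         n_selection_loci = 0L,
                         selection_s = 0,
                         docility_loci = 10L,
                         docility_h2 = 0.5,
                         depression_slopes = c(offspring_weaned = 5,
                                               weight_weaning = 4,
                                               tail_length = 10,
                                               ear_size = 3,
                                               hind_foot_length = 2),
                         trait_noise_sd = c(offspring_weaned = NA,
                                            weight_weaning = 0.8,
                                            tail_length = 2.5,
                                            ear_size = 0.8,
                                            hind_foot_length = 0.7),
                         trait_baseline = c(offspring_weaned = 4,
                                            weight_weaning = 8,
                                            tail_length = 65,
                                            ear_size = 16,
                                            hind_foot_length = 20),
                         offspring_dist = default_offspring_dist(),
                         pairs_per_generation = 20L,
                         n_generations = 20L,
                         founder_offspring_per_pair = 6L,
                         protocols = c("MK", "RAN", "DOC"),
                         n_replicates = 2L,
                         sample_generations = c(1L, 6L, 12L, 19L),
                         sample_size = 15L,
                         genotype_missing_rate = 0.02,
                         trait_missing_rate = 0.02) {
  stopifnot(n_founders %% 2 == 0, n_snps >= 1,
            all(as.integer(names(block_size_probs)) >= 2),
            abs(sum(block_size_probs) - 1) < 1e-8,
            block_haplotypes >= 2,
            founder_maf_range[1] > 0, founder_maf_range[2] <= 0.5,
            n_selection_loci >= 0, selection_s >= 0, selection_s < 1)
  structure(as.list(environment()), class = "synth_config")
}

# founder locus architecture + 20 wild founder genotypes.
# Blocks descend from `block_haplotypes` ancestral haplotypes with random
# weights; singleton loci are Hardy-Weinberg draws at a frequency from
# founder_maf_range. Returns dosage genotypes of allele a2.
generate_founder_genotypes <- function(cfg, seed = NULL) {
  with_seed(seed, {
    L <- cfg$n_snps
    sizes <- as.integer(names(cfg$block_size_probs))
    bs <- integer(0)
    if (cfg$n_linkage_blocks > 0)
      bs <- sample_exact(sizes, cfg$n_linkage_blocks, replace = TRUE,
                         prob = cfg$block_size_probs)
    while (sum(bs) > L - 1L && length(bs)) bs <- bs[-length(bs)]
    block_of <- rep(NA_integer_, L)
    if (length(bs)) block_of[seq_len(sum(bs))] <- rep(seq_along(bs), bs)
    target <- stats::runif(L, cfg$founder_maf_range[1],
                           cfg$founder_maf_range[2])
    nf <- cfg$n_founders
    # two gametes per founder
    H1 <- matrix(0L, nf, L); H2 <- matrix(0L, nf, L)
    single <- which(is.na(block_of))
    for (Hn in c("H1", "H2")) {
      H <- get(Hn)
      H[, single] <- matrix(
        stats::rbinom(nf * length(single), 1L,
                      rep(target[single], each = nf)), nf)
      assign(Hn, H)
    }
    for (b in seq_along(bs)) {
      loci <- which(block_of == b)
      nh <- cfg$block_haplotypes
      # symmetric Dirichlet(5): enough spread to vary blocks, but weights
      # stay far from 0/1 so block-locus frequencies can track their
      # configured targets
      w <- stats::rgamma(nh, shape = 5); w <- w / sum(w)
      # each locus's a2 allele rides a random subset of the haplotypes,
      # chosen so the pooled frequency approximates the locus target
      hap <- matrix(0L, nh, length(loci))
      for (k in seq_along(loci)) {
        ord <- sample.int(nh)
        cum <- cumsum(w[ord])
        take <- max(1L, which.min(abs(cum - target[loci[k]])))
        hap[ord[seq_len(take)], k] <- 1L
      }
      i1 <- sample_exact(seq_len(nh), nf, replace = TRUE, prob = w)
      i2 <- sample_exact(seq_len(nh), nf, replace = TRUE, prob = w)
      H1[, loci] <- hap[i1, , drop = FALSE]
      H2[, loci] <- hap[i2, , drop = FALSE]
    }
    geno <- H1 + H2
    storage.mode(geno) <- "integer"
    base_pairs <- t(vapply(seq_len(L), function(i)
      sort(sample_exact(c("A", "C", "G", "T"), 2L)), character(2)))
    alleles <- data.frame(locus = sprintf("TP%05d", seq_len(L)),
                          a1 = base_pairs[, 1], a2 = base_pairs[, 2],
                          stringsAsFactors = FALSE)
    list(geno = geno, alleles = alleles, target_freq = target,
         block_of = block_of)
  })
}

#' Generate a founder colony state
#'
#' Wild founders (generation 0, `n_founders/2` male-female pairs) plus one
#' colony's generation-1 founder offspring produced by Mendelian
#' transmission (`founder_offspring_per_pair` per pair, sex assigned with
#' probability 0.5). The returned state is the starting point for
#' [simulate_colony()]; the minor allele of every locus is defined from
#' the generation-1 genotypes of this state.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @param population population label.
#' @param founder_pool optional shared founder genotypes (internal use: the
#'   replicate colonies of one study descend from the same wild founders).
#' @return a `colony_state`; attribute `target_freq` records the
#'   configured founder allele frequencies.
#' @export
generate_founders <- function(cfg, seed = NULL, population = "sim",
                              founder_pool = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(founder_pool))
    founder_pool <- generate_founder_genotypes(cfg, seed = seed)
  with_seed(if (is.null(seed)) NULL else sub_seed(seed, 1L), {
    nf <- cfg$n_founders
    np <- nf %/% 2L
    fsex <- rep(c(1L, 2L), np)            # founders stored pairwise M,F
    sire0 <- seq(1L, nf, by = 2L)
    dam0 <- seq(2L, nf, by = 2L)
    k <- cfg$founder_offspring_per_pair
    sire <- rep(sire0, each = k)
    dam <- rep(dam0, each = k)
    m <- length(sire)
    G0 <- founder_pool$geno
    rb <- function(G) (G == 2L) +
      (G == 1L) * matrix(stats::rbinom(length(G), 1L, 0.5), nrow(G))
    off <- rb(G0[sire, , drop = FALSE]) + rb(G0[dam, , drop = FALSE])
    storage.mode(off) <- "integer"
    st <- new_colony_state(
      geno = rbind(G0, off),
      sex = c(fsex, 1L + stats::rbinom(m, 1L, 0.5)),
      generation = c(rep(0L, nf), rep(1L, m)),
      sire = c(rep(NA_integer_, nf), sire),
      dam = c(rep(NA_integer_, nf), dam),
      alleles = founder_pool$alleles, population = population)
    attr(st, "target_freq") <- founder_pool$target_freq
    attr(st, "block_of") <- founder_pool$block_of
    st
  })
}

#' Generate a complete synthetic study
#'
#' Runs the breeding simulator for every protocol and replicate from a
#' common founder pool, samples individuals at the configured generations,
#' and assembles the emitted study tables: a genotype matrix, the full
#' multi-colony pedigree, a per-individual trait table, and a truth
#' manifest recording what was built in (selection loci, depression
#' slopes, seeds) for downstream assertions.
#'
#' Trait construction: each trait is
#' `baseline + additive genetic value - depression_slope * F + noise`,
#' with F the pedigree inbreeding coefficient, so trait-F correlations are
#' negative by construction when the slope is positive. The offspring
#' count is Poisson with mean `max(0.1, baseline - slope * F)`.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed for the whole study.
#' @param keep_states keep the simulated `colony_state`s (kinship matrices
#'   dropped) in the result for inspection.
#' @return list with elements `genotypes` ([genotype_matrix()] of sampled
#'   individuals), `pedigree` (full pedigree), `traits` (data frame),
#'   `truth` (manifest list), and optionally `states`.
#' @export
generate_study <- function(cfg, seed = 1L, keep_states = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  pool <- generate_founder_genotypes(cfg, seed = seed)
  sel_loci <- integer(0)
  if (cfg$n_selection_loci > 0)
    sel_loci <- with_seed(sub_seed(seed, 2L),
                          sample_exact(seq_len(cfg$n_snps),
                                       cfg$n_selection_loci))
  tm <- default_trait_model(colMeans(pool$geno) / 2,
                            n_loci = cfg$docility_loci,
                            h2 = cfg$docility_h2, seed = sub_seed(seed, 3L))
  runs <- expand.grid(protocol = cfg$protocols,
                      rep = seq_len(cfg$n_replicates),
                      stringsAsFactors = FALSE)
  states <- list(); peds <- list(); gms <- list(); trs <- list()
  for (r in seq_len(nrow(runs))) {
    pop <- paste0(runs$protocol[r], runs$rep[r])
    rs <- sub_seed(seed, 10L + r)
    founders <- generate_founders(cfg, seed = rs, population = pop,
                                  founder_pool = pool)
    bc <- breeding_config(protocol = runs$protocol[r],
                          pairs_per_generation = cfg$pairs_per_generation,
                          n_generations = cfg$n_generations,
                          offspring_dist = cfg$offspring_dist,
                          trait_model = tm,
                          selection_loci = sel_loci,
                          selection_s = cfg$selection_s)
    st <- simulate_colony(founders, bc, seed = sub_seed(rs, 7L))
    Fped <- 2 * diag(st$K) - 1
    samp <- sample_study_individuals(st, cfg, seed = sub_seed(rs, 8L))
    prefix <- paste0(pop, "_")
    gms[[r]] <- colony_genotypes(st, prefix = prefix)
    gms[[r]]$samples$sampled <- gms[[r]]$samples$id %in%
      paste0(prefix, samp)
    peds[[r]] <- colony_pedigree(st, prefix = prefix)
    trs[[r]] <- synth_traits(st, samp, Fped, cfg, prefix = prefix,
                             seed = sub_seed(rs, 9L))
    if (keep_states) { st$K <- NULL; states[[pop]] <- st }
  }
  traits <- do.call(rbind, trs)
  ped_all <- do.call(rbind, lapply(peds, as.data.frame))
  # one emitted genotype matrix over the sampled individuals of all colonies
  sampled <- do.call(rbind, lapply(gms, function(g)
    cbind(as.data.frame(g$samples), as.data.frame(g$calls))))
  keep <- sampled$sampled
  calls <- as.matrix(sampled[keep, -(1:4), drop = FALSE])
  gm <- genotype_matrix(calls, pool$alleles,
                        sampled[keep, c("id", "population", "generation")])
  gm <- inject_missing(gm, cfg$genotype_missing_rate,
                       seed = sub_seed(seed, 4L))
  truth <- list(seed = as.integer(seed),
                selection_loci = pool$alleles$locus[sel_loci],
                selection_s = cfg$selection_s,
                depression_slopes = as.list(cfg$depression_slopes),
                docility_loci = pool$alleles$locus[tm$loci],
                block_of = pool$block_of,
                extinct = vapply(seq_len(nrow(runs)), function(r)
                  isTRUE(attr(trs[[r]], "extinct")), logical(1)))
  names(truth$extinct) <- paste0(runs$protocol, runs$rep)
  out <- list(genotypes = gm, pedigree = as_pedigree(ped_all),
              traits = traits, truth = truth)
  if (keep_states) out$states <- states
  out
}

# sample ~sample_size individuals per configured generation of one colony
sample_study_individuals <- function(st, cfg, seed = NULL) {
  with_seed(seed, {
    unlist(lapply(cfg$sample_generations, function(g) {
      ids <- st$ped$id[st$ped$generation == g]
      if (!length(ids)) return(integer(0))
      sample_exact(ids, min(cfg$sample_size, length(ids)))
    }))
  })
}

# per-individual trait table with built-in inbreeding depression
synth_traits <- function(st, members, Fped, cfg, prefix, seed = NULL) {
  with_seed(seed, {
    n <- length(members)
    f <- Fped[members]
    tmv <- st$trait[members]            # docility genetic+env value
    addv <- if (all(is.na(tmv))) rep(0, n) else scale(tmv)[, 1] * 0.2
    bl <- cfg$trait_baseline; sl <- cfg$depression_slopes
    ns <- cfg$trait_noise_sd
    out <- data.frame(
      id = paste0(prefix, members),
      sex = c("M", "F")[st$ped$sex[members]],
      offspring_weaned = stats::rpois(
        n, pmax(0.1, bl["offspring_weaned"] - sl["offspring_weaned"] * f)),
      weight_weaning = bl["weight_weaning"] + addv -
        sl["weight_weaning"] * f + stats::rnorm(n, 0, ns["weight_weaning"]),
      tail_length = bl["tail_length"] + addv -
        sl["tail_length"] * f + stats::rnorm(n, 0, ns["tail_length"]),
      ear_size = bl["ear_size"] + addv -
        sl["ear_size"] * f + stats::rnorm(n, 0, ns["ear_size"]),
      hind_foot_length = bl["hind_foot_length"] + addv -
        sl["hind_foot_length"] * f +
        stats::rnorm(n, 0, ns["hind_foot_length"]),
      stringsAsFactors = FALSE)
    if (cfg$trait_missing_rate > 0) {
      for (cl in setdiff(names(out), c("id", "sex"))) {
        out[[cl]][stats::runif(n) < cfg$trait_missing_rate] <- NA
      }
    }
    attr(out, "extinct") <- st$extinct
    out
  })
}

# uniform missing-call injection into a genotype matrix
inject_missing <- function(gm, rate, seed = NULL) {
  if (rate <= 0) return(gm)
  with_seed(seed, {
    hit <- matrix(stats::runif(length(gm$calls)) < rate, nrow(gm$calls))
    gm$calls[hit] <- NA_integer_
    gm
  })
}

#' Write the emitted study files
#'
#' Writes `genotypes.tsv` (IUPAC dialect), `pedigree.csv`, `traits.csv`
#' and `truth.json` under `dir`.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_matrix(study$genotypes, file.path(dir, "genotypes.tsv"))
  write_pedigree(study$pedigree, file.path(dir, "pedigree.csv"))
  write_traits(study$traits, file.path(dir, "traits.csv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}
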