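# Shared fixtures, all generated in code.

# classic nuclear-family pedigrees
ped_trio <- function() {
  as_pedigree(data.frame(
    id = c("s", "d", "o"), sire = c(NA, NA, "s"), dam = c(NA, NA, "d"),
    sex = c("M", "F", "F"), generation = c(0, 0, 1), population = "p"))
}

ped_full_sibs <- function() {
  as_pedigree(data.frame(
    id = c("s", "d", "b1", "b2", "o"),
    sire = c(NA, NA, "s", "s", "b1"), dam = c(NA, NA, "d", "d", "b2"),
    sex = c("M", "F", "M", "F", "M"),
    generation = c(0, 0, 1, 1, 2), population = "p"))
}

ped_half_sibs <- function() {
  as_pedigree(data.frame(
    id = c("s", "d1", "d2", "h1", "h2", "o"),
    sire = c(NA, NA, NA, "s", "s", "h1"),
    dam = c(NA, NA, NA, "d1", "d2", "h2"),
    sex = c("M", "F", "F", "M", "F", "F"),
    generation = c(0, 0, 0, 1, 1, 2), population = "p"))
}

# random closed-population pedigree: n0 founders then g generations of
# random matings, m offspring per generation
random_pedigree <- function(n0 = 10, g = 4, m = 12, seed = 1) {
  set.seed(seed)
  id <- paste0("F", seq_len(n0))
  sire <- dam <- rep(NA_character_, n0)
  sex <- rep(c("M", "F"), length.out = n0)
  gen <- rep(0L, n0)
  for (gg in seq_len(g)) {
    prev <- which(gen == gg - 1L)
    males <- id[prev][sex[prev] == "M"]
    females <- id[prev][sex[prev] == "F"]
    if (!length(males) || !length(females)) break
    for (k in seq_len(m)) {
      id <- c(id, paste0("G", gg, "_", k))
      sire <- c(sire, sample(males, 1))
      dam <- c(dam, sample(females, 1))
      sex <- c(sex, sample(c("M", "F"), 1))
      gen <- c(gen, gg)
    }
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                         generation = gen, population = "p",
                         stringsAsFactors = FALSE))
}

# small, fast synthetic-colony configuration for unit tests
small_cfg <- function(...) {
  synth_config(n_snps = 80L, n_linkage_blocks = 6L, n_generations = 8L,
               pairs_per_generation = 10L, founder_offspring_per_pair = 4L,
               sample_generations = c(1L, 4L, 7L), sample_size = 10L,
               ...)
}

# simulate until a non-extinct colony results (fresh sub-seeds), so tests
# that need a full trajectory are not at the mercy of demographic luck
simulate_surviving <- function(founders, config, seed, max_tries = 60L) {
  for (k in seq_len(max_tries)) {
    st <- simulate_colony(founders, config,
                          seed = captivepop:::sub_seed(seed, k - 1L))
    if (!st$extinct) return(st)
  }
  stop("no surviving colony in ", max_tries, " tries")
}

# small colony state straight from vectors (1-locus genotypes by default)
toy_state <- function(sex, generation, sire = NA, dam = NA, geno = NULL) {
  n <- length(sex)
  if (is.null(geno)) geno <- matrix(1L, n, 1)
  captivepop:::new_colony_state(
    geno = geno, sex = sex, generation = generation,
    sire = rep_len(sire, n), dam = rep_len(dam, n),
    alleles = data.frame(locus = paste0("L", seq_len(ncol(geno))),
                         a1 = "A", a2 = "C", stringsAsFactors = FALSE))
}

# genotype matrix from a plain dosage matrix
gm_from_calls <- function(calls, prefix = "L") {
  L <- ncol(calls)
  genotype_matrix(calls,
                  data.frame(locus = paste0(prefix, seq_len(L)),
                             a1 = "A", a2 = "C", stringsAsFactors = FALSE),
                  data.frame(id = paste0("i", seq_len(nrow(calls))),
                             stringsAsFactors = FALSE))
}
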