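test_that("D' is exact on unambiguous tables and matches the phased oracle", {
  # perfect coupling: AABB and aabb homozygotes only
  g <- c(rep(0L, 6), rep(2L, 6))
  expect_equal(dprime(g, g), 1)
  # phased counts (AB, Ab, aB, ab) = (40, 10, 10, 40): closed form
  # D = 0.4 - 0.5 * 0.5 = 0.15, Dmax = 0.25, D' = 0.6
  pAB <- 40 / 100; pA <- 0.5; pB <- 0.5
  D <- pAB - pA * pB
  d_oracle <- abs(D) / min(pA * (1 - pB), (1 - pA) * pB)
  expect_equal(D, 0.15)
  expect_equal(d_oracle, 0.6)
  # build unambiguous genotypes: each individual carries two copies of one
  # haplotype, so no double heterozygotes exist and EM has nothing to guess
  hapA <- c(0L, 0L, 1L, 1L); hapB <- c(0L, 1L, 0L, 1L)
  h <- rep(1:4, c(40, 10, 10, 40))
  expect_equal(dprime(2L * hapA[h], 2L * hapB[h]), d_oracle,
               tolerance = 1e-6)
  # symmetry
  set.seed(1)
  a <- rbinom(60, 2, 0.4); b <- rbinom(60, 2, 0.3)
  expect_equal(dprime(a, b), dprime(b, a))
  # monomorphic locus and all-missing overlap are undefined
  expect_true(is.na(dprime(rep(0L, 10), rbinom(10, 2, 0.5))))
  expect_true(is.na(dprime(c(NA, NA, 1L), c(1L, 1L, NA))))
})

test_that("EM recovers the phase of double heterozygotes in strong LD", {
  # two-haplotype system AB / ab: genotype dosages equal at both loci,
  # including double hets, which the EM must resolve into coupling
  set.seed(2)
  hap <- rbinom(400, 1, 0.4)
  g <- hap[1:200] + hap[201:400]
  expect_equal(dprime(g, g), 1, tolerance = 1e-6)
})

test_that("independently simulated loci rarely exceed the threshold", {
  set.seed(33)
  hits <- replicate(40, {
    a <- rbinom(2000, 2, 0.5); b <- rbinom(2000, 2, 0.5)
    dprime(a, b)
  })
  expect_gt(mean(hits < 0.2), 0.95)
})

test_that("linkage grouping follows clique semantics with exclusions", {
  mk_D <- function(edges, loci) {
    D <- matrix(0, length(loci), length(loci),
                dimnames = list(loci, loci))
    for (e in edges) { D[e[1], e[2]] <- D[e[2], e[1]] <- 0.95 }
    D
  }
  # no pair above threshold: all singletons
  lg0 <- build_linkage_groups(mk_D(list(), c("A", "B", "C")), 0.8)
  expect_equal(sort(lg0$singletons), c("A", "B", "C"))
  expect_length(lg0$groups, 0)
  expect_length(lg0$excluded, 0)
  # triangle: one group of three
  lg1 <- build_linkage_groups(
    mk_D(list(c("A", "B"), c("B", "C"), c("A", "C")), c("A", "B", "C")),
    0.8)
  expect_length(lg1$groups, 1)
  expect_equal(sort(lg1$groups[[1]]), c("A", "B", "C"))
  expect_length(lg1$excluded, 0)
  # path A-B-C: B sits in two maximal cliques -> excluded; A, C singletons
  lg2 <- build_linkage_groups(
    mk_D(list(c("A", "B"), c("B", "C")), c("A", "B", "C")), 0.8)
  expect_equal(lg2$excluded, "B")
  expect_equal(sort(lg2$singletons), c("A", "C"))
  expect_length(lg2$groups, 0)
})

test_that("grouping always partitions the loci", {
  set.seed(7)
  for (rep in 1:5) {
    L <- 30
    D <- matrix(runif(L * L), L, L); D <- (D + t(D)) / 2
    diag(D) <- NA
    dimnames(D) <- list(paste0("L", 1:L), paste0("L", 1:L))
    lg <- build_linkage_groups(D, 0.9)
    got <- c(lg$singletons, unlist(lg$groups), lg$excluded)
    expect_setequal(got, paste0("L", 1:L))
    expect_equal(anyDuplicated(got), 0L)
    expect_true(all(lengths(lg$groups) >= 2))
  }
})

test_that("raising the threshold does not increase grouped loci on block data", {
  # two-haplotype blocks give clean, non-overlapping cliques, where the
  # monotonicity claim is meaningful (with overlapping cliques, exclusion
  # can release loci back into groups as the threshold rises)
  cfg <- synth_config(n_snps = 30, n_linkage_blocks = 4,
                      block_size_probs = c("3" = 1), block_haplotypes = 2L,
                      n_founders = 300L, founder_offspring_per_pair = 1L,
                      founder_maf_range = c(0.3, 0.5))
  f <- generate_founders(cfg, seed = 15)
  gm <- colony_genotypes(f, generations = 0)
  D <- dprime_matrix(gm)
  grouped <- sapply(c(0.5, 0.7, 0.9, 0.99), function(th)
    length(unlist(build_linkage_groups(D, th)$groups)))
  expect_true(all(diff(grouped) <= 0))
})

test_that("resampling keeps all singletons and one member per group", {
  lg <- structure(list(singletons = paste0("S", 1:5),
                       groups = list(c("g1a", "g1b"),
                                     c("g2a", "g2b", "g2c")),
                       excluded = "X", threshold = 0.8),
                  class = "linkage_groups")
  sub <- resample_representatives(lg, seed = 1)
  expect_length(sub, 5 + 2)
  expect_true(all(paste0("S", 1:5) %in% sub))
  expect_identical(sub, resample_representatives(lg, seed = 1))
  # members of a 2-SNP group are drawn uniformly
  picks <- replicate(4000, resample_representatives(lg)[6])
  phat <- mean(picks == "g1a")
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 4000))
  # no groups: subset equals the singletons
  lg0 <- structure(list(singletons = c("a", "b"), groups = list(),
                        excluded = character(0), threshold = 0.8),
                   class = "linkage_groups")
  expect_equal(resample_representatives(lg0, seed = 1), c("a", "b"))
})

test_that("group assignment tables round-trip the partition", {
  lg <- structure(list(singletons = c("s1", "s2"),
                       groups = list(c("a", "b"), c("c", "d")),
                       excluded = "x", threshold = 0.8),
                  class = "linkage_groups")
  tab <- linkage_group_table(lg)
  expect_equal(nrow(tab), 7)
  expect_equal(sum(tab$status == "singleton"), 2)
  expect_equal(sum(startsWith(tab$status, "group:")), 4)
  expect_equal(sum(tab$status == "excluded"), 1)
})
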