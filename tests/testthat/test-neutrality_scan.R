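test_that("empirical p-values follow the extremeness definition", {
  # 7 of 100 replicates more extreme -> p = 0.07
  sims <- c(rep(0.02, 7), rep(0.3, 93))
  expect_equal(empirical_pvalue(0.1, sims), 0.07)
  # fixed observation beats any non-fixed replicate
  expect_equal(empirical_pvalue(0, rep(0.4, 50)), 0)
  expect_equal(empirical_pvalue(0.99, c(1, rep(0.5, 9))), 0.1)
  # q = 0.5 is maximally entropic: everything not exactly 0.5 is more extreme
  sims2 <- c(0.5, 0.1, 0.9, 0.4)
  expect_equal(empirical_pvalue(0.5, sims2), 0.75)
  # extremeness is symmetric around 0.5
  expect_equal(empirical_pvalue(0.2, sims), empirical_pvalue(0.8, sims))
  # add-one mode is conservative
  expect_equal(empirical_pvalue(0, rep(0.4, 50), mode = "add_one"), 1 / 51)
  # tie-inclusive mode counts same-extremeness replicates
  expect_equal(empirical_pvalue(0, c(0, 0, 0.4, 0.4),
                                mode = "tie_inclusive"), 0.5)
  # matrix form maps rows to loci
  m <- rbind(c(0.02, 0.3, 0.3, 0.3), c(0.5, 0.5, 0.5, 0.5))
  expect_equal(empirical_pvalue(c(0.1, 0.5), m), c(0.25, 0))
})

test_that("BH adjustment matches the step-up formula and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(4)
  for (rep in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  # adjusted >= raw, NA passthrough, order preserved
  p <- c(0.001, NA, 0.2, 0.04)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p, na.rm = TRUE))
  expect_true(is.na(adj[2]))
  # flags at alpha equal the classic step-up rejection set
  set.seed(9)
  p <- runif(40)^3
  alpha <- 0.05
  m <- length(p)
  k <- max(c(0, which(sort(p) <= alpha * seq_len(m) / m)))
  stepup <- p <= (if (k > 0) sort(p)[k] else -1)
  expect_equal(bh_adjust(p) < alpha, stepup)
})

test_that("nonneutral units count flagged singletons plus flagged groups", {
  lg <- structure(list(singletons = c("s1", "s2", "s3"),
                       groups = list(paste0("ga", 1:5), c("gb1", "gb2")),
                       excluded = "x", threshold = 0.8),
                  class = "linkage_groups")
  scan <- data.frame(locus = c("s1", "s2", "s3", paste0("ga", 1:5),
                               "gb1", "gb2"),
                     nonneutral = FALSE)
  expect_equal(classify_nonneutral(scan, lg)$n_nonneutral, 0)
  # one flagged locus inside a 5-SNP group counts once
  scan$nonneutral[scan$locus == "ga3"] <- TRUE
  expect_equal(classify_nonneutral(scan, lg)$n_nonneutral, 1)
  # two flagged singletons + one flagged group -> 3
  scan$nonneutral[scan$locus %in% c("s1", "s3")] <- TRUE
  res <- classify_nonneutral(scan, lg)
  expect_equal(res$n_nonneutral, 3)
  expect_equal(sum(res$units$kind == "group" & res$units$nonneutral), 1)
})

test_that("null distributions honour fixation and the replicate contract", {
  cfg <- small_cfg()
  f <- generate_founders(cfg, seed = 12)
  bc <- breeding_config("RAN", pairs_per_generation = 10L,
                        n_generations = 5L)
  nd <- null_frequency_distributions(f, bc, generations = c(3L, 5L),
                                     n_reps = 12L, seed = 2)
  expect_equal(dim(nd$freq[["5"]]), c(80L, 12L))
  expect_equal(nd$n_reps, 12L)
  # founder-fixed loci are identical across replicates (absorbing)
  q0 <- colony_minor_freq(f, f$alive)
  fixed <- which(q0 == 0)
  if (length(fixed))
    expect_true(all(nd$freq[["5"]][fixed, ] == 0))
  expect_true(all(nd$freq[["5"]] >= 0 & nd$freq[["5"]] <= 1))
  # neutral replicate-mean frequency stays near the founder value
  dev <- rowMeans(nd$freq[["3"]]) - q0
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(length(dev)))
  # scan output contract
  scan <- neutrality_scan(q0, nd, generation = 3L)
  expect_equal(names(scan), c("locus", "p_raw", "p_adj", "nonneutral"))
  expect_true(all(scan$p_adj >= scan$p_raw, na.rm = TRUE))
})

test_that("ANOVA and Tukey agree with hand values and a matrix oracle", {
  # identical counts everywhere: all Tukey diffs are zero
  counts <- expand.grid(protocol = c("MK", "RAN", "DOC"),
                        generation = c(6, 12, 19))
  counts$count <- 5
  res <- suppressWarnings(count_anova_tukey(counts))
  expect_true(all(abs(res$tukey$diff) < 1e-12))
  # balanced two-group toy data: Tukey diff = difference of means = 5
  toy <- data.frame(count = c(4, 6, 5, 5, 9, 11, 10, 10),
                    generation = rep(c(6, 19), each = 4),
                    protocol = rep(c("A", "B"), 4))
  res2 <- count_anova_tukey(toy)
  expect_equal(res2$tukey$diff, 5.0)
  # F statistics match a normal-equations least-squares oracle
  set.seed(21)
  tab <- expand.grid(protocol = c("MK", "RAN", "DOC"),
                     generation = factor(c(6, 12, 19)),
                     rep = 1:2)
  tab$count <- rpois(nrow(tab), 30)
  res3 <- count_anova_tukey(tab)
  X_full <- model.matrix(~ protocol + generation, tab)
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% tab$count)
    sum((tab$count - X %*% b)^2)
  }
  rss_f <- rss(X_full)
  df_res <- nrow(tab) - ncol(X_full)
  # sequential (type I) F for generation given protocol, as anova() reports
  rss_prot <- rss(model.matrix(~ protocol, tab))
  F_gen <- ((rss_prot - rss_f) / 2) / (rss_f / df_res)
  expect_equal(res3$anova$F[res3$anova$factor == "generation"], F_gen,
               tolerance = 1e-8)
  # single-level factor is dropped with a warning
  one <- data.frame(count = c(1, 2, 3, 4),
                    protocol = "MK", generation = c(6, 6, 19, 19))
  expect_warning(res4 <- count_anova_tukey(one), "single level")
  expect_equal(res4$anova$factor, "generation")
})

test_that("scan_genotype_table flags a locus pushed to extremeness", {
  cfg <- small_cfg()
  f <- generate_founders(cfg, seed = 31)
  bc <- breeding_config("RAN", pairs_per_generation = 10L,
                        n_generations = 7L)
  st <- simulate_surviving(f, bc, seed = 77)
  gm <- colony_genotypes(st, generations = c(1L, 7L))
  # push one well-segregating locus to fixation by hand in the sampled data
  q1 <- colony_minor_freq(f, f$alive)
  loc <- which.min(abs(q1 - 0.5))
  rows <- gm$samples$generation == 7L
  gm$calls[rows, loc] <- ifelse(f$minor[loc] == 2L, 2L, 0L)
  res <- scan_genotype_table(gm, protocol = "RAN", generation = 7L,
                             n_reps = 30L, seed = 5)
  expect_equal(res$p_raw[loc], 0)
  expect_true(res$nonneutral[loc])
})
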