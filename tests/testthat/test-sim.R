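test_that("invalid simulation inputs are rejected", {
  expect_error(simulate_bivalent(0, nu = 1), "positive")
  expect_error(simulate_bivalent(-5, nu = 1), "positive")
  expect_error(simulate_bivalent(100, nu = 0), "positive")
  expect_error(simulate_bivalent(100, nu = 1, p = 1.2), "fraction")
  expect_error(simulate_gametes(10, 100, nu = -1), "invalid")
})

test_that("bivalent CO counts match the Poisson limit at nu = 1 and are
           sub-Poisson at large nu", {
  set.seed(101)
  n <- 10000
  counts <- vapply(seq_len(n), function(i)
    length(simulate_bivalent(100, nu = 1, p = 0)), numeric(1))
  # Poisson limit: mean 2 COs per bivalent on a 100 cM (gamete) chromosome
  se <- sd(counts) / sqrt(n)
  expect_lt(abs(mean(counts) - 2), 3 * se)

  g <- simulate_gametes(n, 100, nu = 50, p = 0)
  # strong interference regularises spacing: variance below the mean
  expect_lt(var(2 * g$counts) / 2, mean(2 * g$counts))
  # same property on the bivalent scale via the vectorised path
  set.seed(102)
  biv_counts <- vapply(seq_len(2000), function(i)
    length(simulate_bivalent(100, nu = 50, p = 0)), numeric(1))
  expect_lt(var(biv_counts), mean(biv_counts))
})

test_that("vanishing interval yields an empty bivalent with high probability", {
  set.seed(103)
  n_co <- vapply(seq_len(200), function(i)
    length(simulate_bivalent(1e-4, nu = 2, p = 0.1)), numeric(1))
  expect_gt(mean(n_co == 0), 0.99)
})

test_that("chromatid thinning is Binomial(k, 1/2)", {
  set.seed(104)
  biv <- c(10, 30, 50, 80)
  kept <- vapply(seq_len(100000), function(i)
    length(thin_to_gamete(biv)), numeric(1))
  # exact enumeration of Binomial(4, 0.5): P(2) = 6/16 = 0.375
  probs <- choose(4, 0:4) / 16
  obs <- tabulate(kept + 1L, nbins = 5L) / length(kept)
  se <- sqrt(probs * (1 - probs) / length(kept))
  expect_true(all(abs(obs - probs) < 4 * se + 1e-12))
  expect_lt(abs(mean(kept) - 2), 3 * sd(kept) / sqrt(length(kept)))
  expect_identical(thin_to_gamete(numeric(0)), numeric(0))
})

test_that("gamete genotypes flip parity at crossovers", {
  markers <- c(10, 20, 30, 40)
  set.seed(105)
  expect_length(unique(genotypes_from_gamete(numeric(0), markers, 50)), 1L)
  g1 <- genotypes_from_gamete(25, markers, 50)
  expect_identical(which(g1[-1] != g1[-4]), 2L)   # one transition at (2,3)
  g2 <- genotypes_from_gamete(c(24, 26), markers, 50)
  expect_length(unique(g2), 1L)                   # double CO cancels
  expect_error(genotypes_from_gamete(5, c(10, 60), 50), "within")
})

test_that("genome-wide viability selection matches the exact Poisson tail", {
  set.seed(106)
  # nu = 1, p = 0 genome of 700 cM: genome-wide counts are Poisson(7)
  sc <- scenario_preset("diploid", n_progeny = 2, seed = 1, nu = 1, p = 0)
  counts <- rowSums(vapply(names(sc$chrom_len_cM), function(ch)
    simulate_gametes(1e5, sc$chrom_len_cM[[ch]], nu = 1, p = 0)$counts,
    numeric(1e5)))
  res <- apply_gamete_selection(counts, X = 20)
  p_exact <- sum(dpois(20:200, 7))    # brute-force pmf tail oracle
  mc_se <- sqrt(p_exact * (1 - p_exact) / length(counts))
  expect_lt(abs(res$fraction - p_exact), 3 * mc_se + 1e-12)
  expect_gte(mean(counts[res$keep]), mean(counts))
  expect_equal(apply_gamete_selection(counts, 0)$fraction, 1)
  expect_warning(apply_gamete_selection(c(1, 2), 10), "threshold")
  expect_error(apply_gamete_selection(counts, -1), "integer")
})

test_that("per-gamete CO counts at nu = 1 pass a Poisson goodness-of-fit test", {
  set.seed(107)
  g <- simulate_gametes(10000, 100, nu = 1, p = 0)
  lam <- 1
  kmax <- max(g$counts)
  obs <- tabulate(g$counts + 1L, nbins = kmax + 1L)
  expp <- dpois(0:kmax, lam)
  expp[kmax + 1L] <- expp[kmax + 1L] + ppois(kmax, lam, lower.tail = FALSE)
  keep <- expp * length(g$counts) >= 5
  obs2 <- c(obs[keep], if (any(!keep)) sum(obs[!keep]))
  expp2 <- c(expp[keep], if (any(!keep)) sum(expp[!keep]))
  gof <- suppressWarnings(chisq.test(obs2, p = expp2 / sum(expp2)))
  expect_gt(gof$p.value, 0.01)
})

test_that("map-length identity holds for any (nu, p)", {
  set.seed(108)
  for (par in list(c(1, 0), c(5, 0.05), c(1.3, 0.10), c(20, 0.25))) {
    g <- simulate_gametes(10000, 120, nu = par[1], p = par[2])
    se <- sd(g$counts) / sqrt(length(g$counts))
    expect_lt(abs(mean(g$counts) - 1.2), 3 * se)
  }
})

test_that("ICD spacing is exponential-like at nu = 1 and regular at nu = 20", {
  set.seed(109)
  g1 <- simulate_gametes(40000, 200, nu = 1, p = 0)
  cv1 <- sd(g1$icds) / mean(g1$icds)
  expect_gt(cv1, 0.8)    # coefficient of variation near 1 for exponential
  g20 <- simulate_gametes(40000, 200, nu = 20, p = 0)
  cv20 <- sd(g20$icds) / mean(g20$icds)
  expect_lt(cv20, 0.6)
})

test_that("simulate_population is deterministic and dimensioned correctly", {
  sc <- scenario_preset("diploid", n_progeny = 30, seed = 42)
  a <- simulate_population(sc)
  b <- simulate_population(sc)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$truth$co_positions, b$truth$co_positions)
  expect_identical(dim(a$genotypes$geno),
                   c(nrow(sc$marker_map), sc$n_progeny))
})

test_that("diploid preset reaches its nominal genome map length", {
  fx <- cached_pop("dip400", "diploid", 400, 7)
  # 700 cM gamete map <=> 7 COs per gamete
  m <- mean(fx$sim$truth$counts)
  se <- sd(fx$sim$truth$counts) / sqrt(length(fx$sim$truth$counts))
  expect_lt(abs(m - 7), 3 * se)
})

test_that("an unreachable selection threshold fails explicitly", {
  sc <- scenario_preset("diploid", n_progeny = 5, seed = 3,
                        selection_threshold = 60)
  sc$max_attempts <- 50L
  expect_error(simulate_population(sc), "budget")
})

test_that("selection thresholds are honoured and enrich CO counts", {
  sc0 <- scenario_preset("diploid", n_progeny = 60, seed = 13)
  sc1 <- scenario_preset("diploid", n_progeny = 60, seed = 13,
                         selection_threshold = 9)
  p0 <- simulate_population(sc0)
  p1 <- simulate_population(sc1)
  expect_true(all(p1$truth$counts >= 9))
  expect_gt(mean(p1$truth$counts), mean(p0$truth$counts))
  expect_lt(p1$truth$survival_fraction, 1)
})
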