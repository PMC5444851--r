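test_that("Kosambi map function matches its closed form", {
  expect_equal(kosambi_distance(0), 0)
  expect_equal(kosambi_distance(0.1), 25 * log(1.5))
  expect_equal(kosambi_distance(0.1), 10.13663, tolerance = 1e-6)
  expect_lt(abs(kosambi_distance(0.01) - 1) / 1, 0.01)  # small-r limit
  expect_error(kosambi_distance(0.5), "0.5")
  expect_error(kosambi_distance(-0.1), "0.5")
})

test_that("genetic map construction recovers interval distances", {
  # single interval with 10 recombinants of 100 progeny: r = 0.1
  rows <- c(paste(rep("A", 100), collapse = ""),
            paste(rep(c("B", "A"), c(10, 90)), collapse = ""))
  gm <- toy_genotypes(rows)
  gmap <- build_genetic_map(gm)
  iv <- attr(gmap, "intervals")
  expect_equal(iv$r, 0.1)
  expect_equal(iv$cM, 25 * log(1.5))

  # zero crossovers: all distances zero
  gm0 <- toy_genotypes(c("AB", "AB", "AB"))
  gmap0 <- build_genetic_map(gm0)
  expect_equal(max(gmap0$pos_cM), 0)
})

test_that("r >= 0.5 intervals are capped with a warning", {
  rows <- c(paste(rep("A", 10), collapse = ""),
            paste(rep(c("B", "A"), c(6, 4)), collapse = ""))
  gm <- toy_genotypes(rows)
  expect_warning(gmap <- build_genetic_map(gm), "capped")
  expect_equal(attr(gmap, "intervals")$r, 0.49)
  expect_true(attr(gmap, "intervals")$capped)
})

test_that("simulated diploid preset recovers its 700 cM genome length", {
  fx <- cached_pop("dip400", "diploid", 400, 7)
  genome_len <- sum(fx$pop$chrom_len_cM)
  expect_lt(abs(genome_len - 700) / 700, 0.05)
})

test_that("dense-marker chromosome length matches 100 x mean CO count", {
  fx <- cached_pop("dip400", "diploid", 400, 7)
  m <- mean(fx$pop$counts[, "A03"])
  expect_lt(abs(fx$pop$chrom_len_cM[["A03"]] / (100 * m) - 1), 0.02)
})

test_that("landscape rates normalise to 100 percent per chromosome", {
  fx <- cached_pop("dip120", "diploid", 120, 31)
  ls <- landscape_rates(fx$pop)
  sums <- tapply(ls$normalized_pct, ls$chrom, sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
  expect_true(all(ls$cM_per_Mbp >= 0))
  # uniform synthetic case: equal counts give equal rates
  rows <- c("AABB", "AABB", "ABAB", "ABBA")
  gm <- toy_genotypes(rows, pos_bp = c(1e6, 2e6, 3e6, 4e6),
                      pos_cM = c(0, 10, 20, 30))
  lsu <- landscape_rates(call_crossovers(gm))
  expect_equal(length(unique(lsu$cM_per_Mbp)), 1L)
})

test_that("scaling a population leaves normalised rates unchanged", {
  fx <- cached_pop("dip120", "diploid", 120, 31)
  pop2 <- fx$pop
  pop2$calls <- rbind(pop2$calls, pop2$calls)   # double every count
  ls1 <- landscape_rates(fx$pop)
  ls2 <- landscape_rates(pop2)
  expect_equal(ls1$normalized_pct, ls2$normalized_pct)
})

test_that("heterogeneity test matches the closed-form 2x2 chi-squared", {
  fx <- cached_pop("dip120", "diploid", 120, 31)
  het_self <- interval_heterogeneity_test(fx$pop, fx$pop, scope = "genome")
  expect_equal(het_self$statistic, 0)
  expect_equal(het_self$p_value, 1)

  # one interval, 10 COs of 100 gametes vs 30 of 100:
  # closed form N(ad-bc)^2/(r1 r2 c1 c2) = 12.5
  popA <- call_crossovers(toy_genotypes(
    c(paste(rep("A", 100), collapse = ""),
      paste(rep(c("B", "A"), c(10, 90)), collapse = "")),
    pos_cM = c(0, 11)))
  popB <- call_crossovers(toy_genotypes(
    c(paste(rep("A", 100), collapse = ""),
      paste(rep(c("B", "A"), c(30, 70)), collapse = "")),
    pos_cM = c(0, 19)))
  het1 <- interval_heterogeneity_test(popA, popB, scope = "interval")
  expect_equal(het1$statistic, 12.5)
  expect_equal(het1$p_value, pchisq(12.5, 1, lower.tail = FALSE))
  expect_equal(het1$p_value, 4.07e-4, tolerance = 2e-3)

  # Bonferroni threshold for 194 intervals
  expect_equal(0.05 / 194, 2.577320e-4, tolerance = 1e-6)
  het <- interval_heterogeneity_test(fx$pop, fx$pop, scope = "interval")
  expect_equal(unique(het$bonferroni_threshold), 0.05 / nrow(het))
})

test_that("heterogeneity test detects the diploid-allotriploid contrast", {
  dip <- cached_pop("dip120", "diploid", 120, 31)$pop
  tri <- cached_pop("tri120", "allotriploid", 120, 32)$pop
  g <- interval_heterogeneity_test(dip, tri, scope = "genome")
  expect_true(g$significant_bonferroni)
  ch <- interval_heterogeneity_test(dip, tri, scope = "chromosome")
  expect_true(all(ch$significant_bonferroni))
  expect_equal(nrow(ch), 10L)
})

test_that("shape test: pooled per-bin counts are equal by construction", {
  dip <- cached_pop("dip120", "diploid", 120, 31)$pop
  tri <- cached_pop("tri120", "allotriploid", 120, 32)$pop
  set.seed(61)
  st <- landscape_shape_test(dip, tri, chrom = "A02")
  expect_lte(diff(range(st$pooled_counts)), 1)
  expect_equal(sum(st$counts), sum(st$pooled_counts))
})

test_that("shape test is calibrated on random halves and detects a shift", {
  dip <- cached_pop("dip300", "diploid", 300, 21)$pop
  set.seed(62)
  ps <- replicate(60, {
    idx <- sample(rownames(dip$counts), 150)
    a <- dip; a$calls <- dip$calls[dip$calls$progeny %in% idx, ]
    a$n_progeny <- 150L
    b <- dip; b$calls <- dip$calls[!dip$calls$progeny %in% idx, ]
    b$n_progeny <- 150L
    landscape_shape_test(a, b, chrom = "A01")$p_value
  })
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)

  shifted <- dip
  half <- tapply(shifted$calls$bp_mid, shifted$calls$chrom, median)
  shifted$calls$bp_mid <- pmin(shifted$calls$bp_mid,
                               half[shifted$calls$chrom])
  st <- landscape_shape_test(dip, shifted, chrom = "A01")
  expect_lt(st$p_value, 1e-3)
})

test_that("shape test compares shapes, not totals", {
  dip <- cached_pop("dip300", "diploid", 300, 21)$pop
  tripled <- dip
  tripled$calls <- rbind(dip$calls, dip$calls, dip$calls)
  set.seed(63)
  st <- landscape_shape_test(dip, tripled, chrom = "A05")
  expect_gt(st$p_value, 0.05)
})

test_that("shape test warns and reduces bins on sparse chromosomes", {
  gm <- toy_genotypes(c("AABB", "AABB", "ABAB", "ABBA"),
                      pos_cM = c(0, 10, 20, 30))
  small <- call_crossovers(gm)
  set.seed(64)
  expect_warning(st <- landscape_shape_test(small, small, chrom = "A01"),
                 "bins")
  expect_lt(st$df, 9)
})

# co_pop in which chromosome c carries exactly k_c COs per progeny over a
# physical span of s_c Mbp, so the count-vs-size regression is exact
exact_count_pop <- function(k_per_chrom, span_mbp) {
  maps <- list(); genos <- list()
  for (i in seq_along(k_per_chrom)) {
    k <- k_per_chrom[i]
    nm <- k + 1L
    pos <- round(seq(1, span_mbp[i] * 1e6, length.out = nm))
    maps[[i]] <- data.frame(
      marker_id = sprintf("C%02d_M%02d", i, seq_len(nm)),
      chrom = sprintf("C%02d", i), pos_bp = pos,
      pos_cM = seq(0, k, length.out = nm),
      stringsAsFactors = FALSE)
    genos[[i]] <- matrix(rep(rep(c("A", "B"), length.out = nm), 3),
                         nrow = nm)   # 3 progeny, k transitions each
  }
  map <- marker_map(do.call(rbind, maps))
  geno <- do.call(rbind, genos)
  rownames(geno) <- map$marker_id
  call_crossovers(genotype_matrix(geno, map))
}

test_that("regressions recover exact fits and the centromere trend", {
  # mean COs/meiosis = 2 k_c; spans chosen so y = 2x exactly
  pop_lin <- exact_count_pop(k_per_chrom = c(1, 2, 3, 4),
                             span_mbp = c(1, 2, 3, 4))
  # summary.lm warns on an exact fit; the warning is the point here
  r_lin <- suppressWarnings(
    regress_landscape(pop_lin, mode = "count-vs-size", kind = "linear"))
  expect_equal(r_lin$a, 2, tolerance = 1e-8)
  expect_equal(r_lin$r_squared, 1, tolerance = 1e-8)

  # y = 2x^2 exactly under the quadratic kind
  pop_quad <- exact_count_pop(k_per_chrom = c(1, 4, 9, 16),
                              span_mbp = c(1, 2, 3, 4))
  r_quad <- suppressWarnings(
    regress_landscape(pop_quad, mode = "count-vs-size", kind = "quadratic"))
  expect_equal(r_quad$a, 2, tolerance = 1e-6)
  expect_equal(r_quad$r_squared, 1, tolerance = 1e-8)

  # pericentromere suppression: rate rises with distance from centromere
  fx <- cached_pop("dip300", "diploid", 300, 21)
  r3 <- regress_landscape(fx$pop,
                          mode = "normrate-vs-centromere-distance",
                          kind = "linear")
  expect_gt(r3$a, 0)
  expect_lt(r3$p_value_a, 0.05)

  r2 <- regress_landscape(fx$pop, mode = "rate-vs-position",
                          kind = "quadratic", chrom = "A01")
  expect_true(is.finite(r2$p_value_a))
  expect_error(regress_landscape(pop_lin, mode = "rate-vs-position",
                                 chrom = "C01"),
               "fewer than 3")
})
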