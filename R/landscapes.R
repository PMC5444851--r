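#' Kosambi map function
#'
#' Converts a recombination fraction to genetic distance,
#' d = 25 ln((1 + 2r) / (1 - 2r)) cM. Approximately 100 r for small r.
#'
#' @param r Recombination fraction(s) in \[0, 0.5).
#' @return Genetic distance(s) in cM.
#' @export
kosambi_distance <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Build a Kosambi genetic map from backcross genotypes
#'
#' For each adjacent-marker interval (marker order fixed by physical
#' position), the recombination fraction r is the fraction of progeny with
#' discordant calls at the two flanking markers (computed over progeny
#' non-missing at both); the Kosambi function converts r to cM and cumulative
#' genetic positions are assembled per chromosome (0 at the first marker).
#' Intervals with r at or above 0.5 - possible in tiny samples - are capped
#' at \code{cap} with a warning rather than failing.
#'
#' @param gm A \code{\link{genotype_matrix}} (or a
#'   \code{\link{simulate_population}} result, whose genotypes are used).
#' @param cap Cap applied to r >= 0.5.
#' @return The input map with a \code{pos_cM} column filled, plus an
#'   \code{"intervals"} attribute: data frame with \code{chrom},
#'   \code{left_marker}, \code{right_marker}, \code{bp_left}, \code{bp_right},
#'   \code{n_informative}, \code{r}, \code{cM} and a \code{capped} flag.
#' @export
build_genetic_map <- function(gm, cap = 0.49) {
  if (inherits(gm, "sim_population")) gm <- gm$genotypes
  stopifnot(inherits(gm, "genotype_matrix"))
  map <- gm$map
  chroms <- unique(map$chrom)
  pos_cM <- numeric(nrow(map))
  iv <- list()
  for (ch in chroms) {
    sel <- which(map$chrom == ch)
    n_iv <- length(sel) - 1L
    if (n_iv < 1L) { pos_cM[sel] <- 0; next }
    r <- numeric(n_iv); n_inf <- integer(n_iv)
    for (k in seq_len(n_iv)) {
      a <- gm$geno[sel[k], ]; b <- gm$geno[sel[k + 1L], ]
      ok <- !is.na(a) & !is.na(b)
      n_inf[k] <- sum(ok)
      r[k] <- if (n_inf[k] > 0) mean(a[ok] != b[ok]) else 0
    }
    capped <- r >= 0.5
    if (any(capped)) {
      warning(sum(capped), " interval(s) on ", ch,
              " with r >= 0.5 capped at ", cap)
      r[capped] <- cap
    }
    d <- kosambi_distance(r)
    pos_cM[sel] <- c(0, cumsum(d))
    iv[[ch]] <- data.frame(
      chrom = ch,
      left_marker = map$marker_id[sel[-length(sel)]],
      right_marker = map$marker_id[sel[-1L]],
      bp_left = map$pos_bp[sel[-length(sel)]],
      bp_right = map$pos_bp[sel[-1L]],
      n_informative = n_inf, r = r, cM = d, capped = capped,
      stringsAsFactors = FALSE)
  }
  out <- map
  out$pos_cM <- pos_cM
  attr(out, "intervals") <- do.call(rbind, c(iv, list(make.row.names = FALSE)))
  attr(out, "centromeres") <- attr(map, "centromeres")
  class(out) <- unique(c("marker_map", class(out)))
  out
}

# per-interval CO counts for a co_pop, aligned with the map's interval table
.interval_counts <- function(pop) {
  iv <- attr(pop$map, "intervals")
  if (is.null(iv)) {
    # derive intervals from the map itself (genetic positions preset)
    map <- pop$map
    iv <- do.call(rbind, lapply(unique(map$chrom), function(ch) {
      sel <- which(map$chrom == ch)
      data.frame(chrom = ch,
                 left_marker = map$marker_id[sel[-length(sel)]],
                 right_marker = map$marker_id[sel[-1L]],
                 bp_left = map$pos_bp[sel[-length(sel)]],
                 bp_right = map$pos_bp[sel[-1L]],
                 cM = diff(map$pos_cM[sel]),
                 stringsAsFactors = FALSE)
    }))
    rownames(iv) <- NULL
  }
  key <- paste(iv$chrom, iv$left_marker)
  hits <- table(paste(pop$calls$chrom, pop$calls$left_marker))
  iv$count <- as.integer(hits[key])
  iv$count[is.na(iv$count)] <- 0L
  iv
}

#' Recombination landscape along the chromosomes
#'
#' Per adjacent-marker interval: CO count, recombination rate in cM per Mbp
#' (interval cM over interval Mbp) and the rate normalised by the chromosome
#' total (percent of the chromosome's genetic length), which compares
#' landscape shapes independently of overall map length.
#'
#' @param pop A \code{\link{call_crossovers}} result whose map carries a
#'   genetic map (interval cM).
#' @return Data frame with one row per interval: \code{chrom},
#'   \code{left_marker}, \code{right_marker}, \code{bp_mid}, \code{count},
#'   \code{cM}, \code{cM_per_Mbp}, \code{normalized_pct}.
#' @export
landscape_rates <- function(pop) {
  stopifnot(inherits(pop, "co_pop"))
  iv <- .interval_counts(pop)
  mbp <- (iv$bp_right - iv$bp_left) / 1e6
  if (any(mbp <= 0)) stop("zero-length physical interval")
  chrom_cM <- tapply(iv$cM, iv$chrom, sum)
  data.frame(chrom = iv$chrom, left_marker = iv$left_marker,
             right_marker = iv$right_marker,
             bp_mid = (iv$bp_left + iv$bp_right) / 2,
             count = iv$count, cM = iv$cM,
             cM_per_Mbp = iv$cM / mbp,
             normalized_pct = 100 * iv$cM / as.numeric(chrom_cM[iv$chrom]),
             stringsAsFactors = FALSE)
}

.chisq22 <- function(a1, a2, b1, b2) {
  # 2x2 chi-squared without continuity correction
  tab <- matrix(c(a1, a2, b1, b2), 2, 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(c(statistic = 0, p_value = 1))
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  c(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Heterogeneity of crossover rates between two populations
#'
#' 2-by-2 chi-squared comparisons of CO counts between two populations
#' sharing a marker map, at interval, chromosome or genome scope. At interval
#' scope the table for each interval is (COs, gametes without a CO there) by
#' population; at chromosome and genome scope it is total COs against total
#' scored gamete-intervals minus COs. Significance is reported both at the
#' raw threshold \code{alpha} and at the conservative Bonferroni-corrected
#' threshold, whose divisor is the number of intervals on the chromosome
#' (chromosome scope) or genome-wide (interval and genome scope).
#'
#' @param popA,popB \code{\link{call_crossovers}} results on the same map.
#' @param scope \code{"interval"}, \code{"chromosome"} or \code{"genome"}.
#' @param alpha Significance threshold before correction.
#' @return Data frame with counts, \code{statistic}, \code{p_value},
#'   \code{significant} (at \code{alpha}) and \code{significant_bonferroni}.
#' @export
interval_heterogeneity_test <- function(popA, popB,
                                        scope = c("interval", "chromosome",
                                                  "genome"),
                                        alpha = 0.05) {
  scope <- match.arg(scope)
  stopifnot(inherits(popA, "co_pop"), inherits(popB, "co_pop"))
  if (popA$n_progeny == 0 || popB$n_progeny == 0) stop("empty population")
  ivA <- .interval_counts(popA)
  ivB <- .interval_counts(popB)
  if (!identical(paste(ivA$chrom, ivA$left_marker),
                 paste(ivB$chrom, ivB$left_marker)))
    stop("populations do not share the marker map")
  nA <- popA$n_progeny; nB <- popB$n_progeny
  n_iv_total <- nrow(ivA)
  if (scope == "interval") {
    res <- t(mapply(function(a, b) .chisq22(a, nA - a, b, nB - b),
                    ivA$count, ivB$count))
    out <- data.frame(chrom = ivA$chrom, left_marker = ivA$left_marker,
                      right_marker = ivA$right_marker,
                      count_A = ivA$count, count_B = ivB$count,
                      statistic = res[, 1], p_value = res[, 2],
                      stringsAsFactors = FALSE)
    divisor <- n_iv_total
  } else if (scope == "chromosome") {
    chroms <- unique(ivA$chrom)
    out <- do.call(rbind, lapply(chroms, function(ch) {
      sA <- sum(ivA$count[ivA$chrom == ch])
      sB <- sum(ivB$count[ivB$chrom == ch])
      k <- sum(ivA$chrom == ch)
      r <- .chisq22(sA, nA * k - sA, sB, nB * k - sB)
      data.frame(chrom = ch, count_A = sA, count_B = sB,
                 n_intervals = k, statistic = r[1], p_value = r[2],
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    divisor <- out$n_intervals
  } else {
    sA <- sum(ivA$count); sB <- sum(ivB$count)
    r <- .chisq22(sA, nA * n_iv_total - sA, sB, nB * n_iv_total - sB)
    out <- data.frame(chrom = "ALL", count_A = sA, count_B = sB,
                      n_intervals = n_iv_total,
                      statistic = r[1], p_value = r[2],
                      stringsAsFactors = FALSE)
    divisor <- n_iv_total
  }
  out$significant <- out$p_value < alpha
  out$bonferroni_threshold <- alpha / divisor
  out$significant_bonferroni <- out$p_value < out$bonferroni_threshold
  out
}

#' Compare the shapes of two recombination landscapes
#'
#' Equal-count binning comparison: CO physical positions of both populations
#' are pooled on a chromosome and the chromosome is divided into 10
#' consecutive bins each containing the same pooled number of COs (ties in
#' position, frequent because COs are placed at interval midpoints, are
#' broken by occurrence order so pooled per-bin counts are equal up to
#' integer rounding). The per-population bin counts are compared with a
#' 2-by-10 chi-squared test; because each population's counts are normalised
#' by its own total, the test compares shapes, not totals. \code{"ALL"} pools
#' the per-chromosome analyses by summing their chi-squared statistics and
#' degrees of freedom.
#'
#' @param popA,popB \code{\link{call_crossovers}} results on the same map.
#' @param chrom A chromosome id, or \code{"ALL"}.
#' @param bins Number of equal-count bins (reduced with a warning when the
#'   pooled count is smaller).
#' @param conf_level Level of the per-bin Clopper-Pearson binomial
#'   confidence intervals on each population's bin proportion.
#' @return For one chromosome: list with \code{chrom}, \code{edges_bp},
#'   \code{counts} (2 x bins), \code{statistic}, \code{df}, \code{p_value}
#'   and \code{ci} (per-bin CIs per population). For \code{"ALL"}: list with
#'   \code{per_chrom} (data frame) and pooled \code{statistic}, \code{df},
#'   \code{p_value}.
#' @export
landscape_shape_test <- function(popA, popB, chrom = "ALL", bins = 10,
                                 conf_level = 0.95) {
  stopifnot(inherits(popA, "co_pop"), inherits(popB, "co_pop"))
  one <- function(ch) {
    xA <- popA$calls$bp_mid[popA$calls$chrom == ch]
    xB <- popB$calls$bp_mid[popB$calls$chrom == ch]
    N <- length(xA) + length(xB)
    b <- bins
    if (N < bins) {
      b <- max(2L, N)
      warning("only ", N, " pooled COs on ", ch, ": using ", b, " bins")
    }
    pos <- c(xA, xB)
    lab <- rep(c("A", "B"), c(length(xA), length(xB)))
    # ties in position are massive (COs sit at interval midpoints); break
    # them at random so neither population is pushed into earlier bins
    o <- order(pos, sample.int(N))
    bin <- ceiling(seq_len(N) * b / N)     # equal-count by rank
    labo <- lab[o]
    cA <- tabulate(bin[labo == "A"], nbins = b)
    cB <- tabulate(bin[labo == "B"], nbins = b)
    tab <- rbind(A = cA, B = cB)
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    edge_idx <- round(seq_len(b - 1) * N / b)
    ci <- function(counts) t(vapply(seq_len(b), function(j) {
      n <- sum(counts)
      if (n == 0) return(c(NA_real_, NA_real_))
      stats::binom.test(counts[j], n, conf.level = conf_level)$conf.int
    }, numeric(2)))
    list(chrom = ch,
         edges_bp = sort(pos)[edge_idx],
         counts = tab,
         pooled_counts = cA + cB,
         statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value),
         ci = list(A = ci(cA), B = ci(cB)))
  }
  if (!identical(chrom, "ALL")) return(one(chrom))
  chroms <- intersect(unique(popA$map$chrom), unique(popB$map$chrom))
  per <- lapply(chroms, one)
  stat <- sum(vapply(per, `[[`, numeric(1), "statistic"))
  df <- sum(vapply(per, `[[`, numeric(1), "df"))
  list(per_chrom = data.frame(
         chrom = chroms,
         statistic = vapply(per, `[[`, numeric(1), "statistic"),
         df = vapply(per, `[[`, numeric(1), "df"),
         p_value = vapply(per, `[[`, numeric(1), "p_value"),
         stringsAsFactors = FALSE),
       statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Regression analyses of crossover patterns
#'
#' Ordinary least squares fits of the three relationships used to
#' characterise a landscape: (i) \code{"count-vs-size"} - mean COs per
#' chromosome per meiosis against physical length covered by markers (Mbp);
#' (ii) \code{"rate-vs-position"} - interval recombination rate (cM/Mbp)
#' against interval physical midpoint (Mbp), per chromosome; (iii)
#' \code{"normrate-vs-centromere-distance"} - normalised interval rate (%)
#' against relative distance from the centromere (%), genome-wide. Linear
#' fits report y = a x + b; quadratic fits y = a x^2 + b x + c. Only the
#' p-value of the leading coefficient 'a' is reported.
#'
#' @param pop A \code{\link{call_crossovers}} result.
#' @param mode One of the three relationship modes above.
#' @param kind \code{"linear"} or \code{"quadratic"}.
#' @param chrom Chromosome id for mode (ii); ignored otherwise.
#' @param centromeres Optional centromere table (\code{chrom},
#'   \code{start_bp}, \code{end_bp}) for mode (iii); defaults to the map's
#'   \code{centromeres} attribute.
#' @return List of class \code{landscape_regression} with \code{kind},
#'   coefficients \code{a}, \code{b} (and \code{c}), \code{r_squared},
#'   \code{p_value_a} and \code{n}.
#' @export
regress_landscape <- function(pop,
                              mode = c("count-vs-size", "rate-vs-position",
                                       "normrate-vs-centromere-distance"),
                              kind = c("linear", "quadratic"),
                              chrom = NULL, centromeres = NULL) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  stopifnot(inherits(pop, "co_pop"))
  if (mode == "count-vs-size") {
    s <- summarize_counts(pop)
    s <- s[s$chrom != "GENOME", ]
    span <- tapply(pop$map$pos_bp, pop$map$chrom, function(p) diff(range(p)))
    x <- as.numeric(span[s$chrom]) / 1e6
    y <- s$mean_meiosis
  } else if (mode == "rate-vs-position") {
    ls <- landscape_rates(pop)
    if (!is.null(chrom)) ls <- ls[ls$chrom == chrom, ]
    x <- ls$bp_mid / 1e6
    y <- ls$cM_per_Mbp
  } else {
    cen <- if (!is.null(centromeres)) centromeres
           else attr(pop$map, "centromeres")
    if (is.null(cen)) stop("mode (iii) needs a centromere table")
    ls <- landscape_rates(pop)
    x <- numeric(nrow(ls)); y <- ls$normalized_pct
    for (ch in unique(ls$chrom)) {
      sel <- ls$chrom == ch
      ce <- cen[cen$chrom == ch, ]
      if (nrow(ce) != 1) stop("missing centromere for ", ch)
      mid <- ls$bp_mid[sel]
      d <- pmax(0, pmax(ce$start_bp - mid, mid - ce$end_bp))
      # normalise per arm: distance relative to that arm's furthest interval
      arm <- ifelse(mid < ce$start_bp, "L", "R")
      rel <- d
      for (a in c("L", "R")) {
        ai <- arm == a
        if (any(ai) && max(d[ai]) > 0) rel[ai] <- d[ai] / max(d[ai])
      }
      x[sel] <- 100 * rel
    }
  }
  if (length(x) < 3L) stop("fewer than 3 points for regression")
  fit <- if (kind == "linear") stats::lm(y ~ x)
         else stats::lm(y ~ I(x^2) + x)
  sm <- summary(fit)
  co <- stats::coef(sm)
  out <- if (kind == "linear") {
    list(kind = kind, a = co["x", "Estimate"],
         b = co["(Intercept)", "Estimate"], c = NA_real_,
         r_squared = sm$r.squared, p_value_a = co["x", "Pr(>|t|)"],
         n = length(x))
  } else {
    list(kind = kind, a = co["I(x^2)", "Estimate"],
         b = co["x", "Estimate"], c = co["(Intercept)", "Estimate"],
         r_squared = sm$r.squared, p_value_a = co["I(x^2)", "Pr(>|t|)"],
         n = length(x))
  }
  class(out) <- "landscape_regression"
  out
}

#' @export
print.landscape_regression <- function(x, ...) {
  cat("landscape regression (", x$kind, "): a = ", signif(x$a, 4),
      ", R^2 = ", signif(x$r_squared, 3),
      ", p(a) = ", signif(x$p_value_a, 3), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}
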