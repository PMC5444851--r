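#' Inter-crossover distances (ICDs)
#'
#' Genetic distances between adjacent COs on one progeny chromosome,
#' computed for every plant-chromosome carrying at least two COs; plants with
#' fewer contribute nothing. The pooled scope concatenates per-chromosome
#' ICDs - distances are never measured across chromosome boundaries.
#'
#' @param pop A \code{\link{call_crossovers}} result.
#' @param scope A chromosome id, or \code{"pooled"} for all chromosomes.
#' @return Object of class \code{icd_sample}: list with \code{label},
#'   \code{scope}, \code{icds} (numeric vector, cM) and \code{n}.
#' @export
compute_icds <- function(pop, scope = "pooled") {
  stopifnot(inherits(pop, "co_pop"))
  calls <- pop$calls
  if (!identical(scope, "pooled")) calls <- calls[calls$chrom == scope, ]
  icds <- numeric(0)
  if (nrow(calls) > 0) {
    o <- order(calls$progeny, calls$chrom, calls$cM_mid)
    pos <- calls$cM_mid[o]
    grp <- paste(calls$progeny, calls$chrom)[o]
    d <- diff(pos)
    icds <- d[grp[-length(grp)] == grp[-1L]]
  }
  structure(list(label = pop$label, scope = scope, icds = icds,
                 n = length(icds)),
            class = "icd_sample")
}

#' Kolmogorov-Smirnov comparison of two ICD samples
#'
#' Two-sample two-sided KS test on the raw (unbinned) ICD values.
#'
#' @param a,b \code{\link{compute_icds}} results (or numeric vectors).
#' @return List with \code{D} and \code{p_value}.
#' @export
ks_compare <- function(a, b) {
  xa <- if (inherits(a, "icd_sample")) a$icds else a
  xb <- if (inherits(b, "icd_sample")) b$icds else b
  if (length(xa) == 0 || length(xb) == 0) stop("empty ICD sample")
  res <- suppressWarnings(stats::ks.test(xa, xb))
  list(D = unname(res$statistic), p_value = unname(res$p.value))
}

# draw, for each of n_rows rows, k positions from 'pool' with replacement,
# redrawing any row containing two identical values (max 1000 attempts)
.draw_rows_distinct <- function(n_rows, k, pool, max_redraw = 1000L) {
  if (sum(!duplicated(pool)) < k)
    stop("a plant's CO count exceeds the number of distinct pooled positions")
  m <- matrix(sample(pool, n_rows * k, replace = TRUE), n_rows, k)
  bad <- which(apply(m, 1L, anyDuplicated) > 0)
  tries <- 0L
  while (length(bad) > 0) {
    tries <- tries + 1L
    if (tries > max_redraw) stop("unsatisfiable redraw while shuffling")
    m[bad, ] <- sample(pool, length(bad) * k, replace = TRUE)
    bad <- bad[apply(m[bad, , drop = FALSE], 1L, anyDuplicated) > 0]
  }
  m
}

#' Shuffle-derived no-interference null for ICDs
#'
#' Builds the ICD distribution expected in the absence of interference by
#' randomly re-drawing CO positions: per replicate and per plant with at
#' least two COs on a chromosome, the plant's CO count of positions is drawn
#' (with replacement) from the pooled list of all CO positions of all plants
#' on that chromosome; a draw containing two identical positions is discarded
#' and repeated. ICDs are computed on the shuffled positions and cumulated
#' over all replicates. Per-plant CO counts are preserved exactly.
#'
#' @param pop A \code{\link{call_crossovers}} result.
#' @param reps Number of shuffle replicates (default 1000).
#' @param chrom Chromosome ids to shuffle; default all in the population.
#' @return Object of class \code{shuffle_null}: list with \code{icds}
#'   (cumulated null ICDs, all replicates), \code{per_chrom} (list of
#'   per-chromosome null ICD vectors), \code{reps}, \code{n_per_rep}
#'   (experimental ICD count, reproduced by each replicate). Uses the R
#'   random number generator; seed with \code{set.seed}.
#' @export
shuffle_no_interference <- function(pop, reps = 1000L, chrom = NULL) {
  stopifnot(inherits(pop, "co_pop"))
  calls <- pop$calls
  chroms <- if (is.null(chrom)) unique(calls$chrom) else chrom
  per_chrom <- list()
  n_per_rep <- 0L
  for (ch in chroms) {
    sub <- calls[calls$chrom == ch, ]
    if (nrow(sub) == 0) { per_chrom[[ch]] <- numeric(0); next }
    pool <- sub$cM_mid
    kcounts <- table(sub$progeny)
    kcounts <- kcounts[kcounts >= 2]
    if (length(kcounts) == 0) { per_chrom[[ch]] <- numeric(0); next }
    n_per_rep <- n_per_rep + sum(kcounts - 1L)
    acc <- vector("list", length(unique(kcounts)))
    ki <- 0L
    for (k in sort(unique(as.integer(kcounts)))) {
      nk <- sum(kcounts == k)
      m <- .draw_rows_distinct(reps * nk, k, pool)
      # row-wise sorted differences via one global ordering
      rid <- rep(seq_len(nrow(m)), each = k)
      v <- as.vector(t(m))
      o <- order(rid, v)
      d <- diff(v[o])
      ki <- ki + 1L
      acc[[ki]] <- d[diff(rid[o]) == 0L]
    }
    per_chrom[[ch]] <- unlist(acc, use.names = FALSE)
  }
  structure(list(icds = unlist(per_chrom, use.names = FALSE),
                 per_chrom = per_chrom, reps = as.integer(reps),
                 n_per_rep = n_per_rep, label = pop$label),
            class = "shuffle_null")
}

# shared fixed-width binning for the KL plug-in estimator
.icd_edges <- function(max_val, bin_cm = 5) {
  seq(0, bin_cm * max(1, ceiling(max_val / bin_cm + 1e-9)), by = bin_cm)
}

# KL(P||Q) on bin counts with the merge-right guard: any bin with q = 0 and
# p > 0 is merged into its right neighbour (leftward for the last bin) until
# all p-supporting bins have q > 0. Returns the divergence in nats.
.kl_binned <- function(cp, cq) {
  p <- cp / sum(cp)
  q <- cq / sum(cq)
  merged <- 0L
  repeat {
    i <- which(q == 0 & p > 0)
    if (length(i) == 0) break
    i <- i[1]
    j <- if (i < length(p)) i + 1L else i - 1L
    p[j] <- p[j] + p[i]; q[j] <- q[j] + q[i]
    p <- p[-i]; q <- q[-i]
    merged <- merged + 1L
    if (length(p) < 2L) stop("degenerate binning after merging")
  }
  nz <- p > 0
  structure(sum(p[nz] * log(p[nz] / q[nz])), merged = merged)
}

#' Kullback-Leibler interference index
#'
#' Plug-in KL divergence (nats) from the experimental ICD distribution P to
#' the no-interference (shuffle) distribution Q, on shared fixed-width bins:
#' KL(P||Q) = sum p_i log(p_i / q_i). Bins where P is empty contribute 0;
#' bins where Q is empty but P is not are merged rightward until Q is
#' positive, keeping the index finite without pseudocounts. The index is 0
#' for a non-interfering population and grows with interference strength.
#'
#' @param exp An \code{\link{compute_icds}} result (or numeric ICD vector).
#' @param null A \code{\link{shuffle_no_interference}} result (or numeric
#'   vector of null ICDs).
#' @param bin_cm Bin width in cM (shared by P and Q; edges run from 0 to the
#'   common maximum).
#' @return Object of class \code{kl_index}: list with \code{value} (nats),
#'   \code{bin_cm}, \code{edges}, \code{n_exp}, \code{n_null},
#'   \code{n_merged} (bins merged by the zero-null guard), \code{label}.
#' @export
kl_interference_index <- function(exp, null, bin_cm = 5) {
  xe <- if (inherits(exp, "icd_sample")) exp$icds else exp
  xq <- if (inherits(null, "shuffle_null")) null$icds else null
  if (length(xe) == 0 || length(xq) == 0) stop("empty distribution")
  edges <- .icd_edges(max(xe, xq), bin_cm)
  if (length(edges) < 3L) stop("degenerate binning: a single bin")
  cp <- tabulate(findInterval(xe, edges, left.open = TRUE,
                              rightmost.closed = TRUE),
                 nbins = length(edges) - 1L)
  cq <- tabulate(findInterval(xq, edges, left.open = TRUE,
                              rightmost.closed = TRUE),
                 nbins = length(edges) - 1L)
  kl <- .kl_binned(cp, cq)
  structure(list(value = as.numeric(kl), bin_cm = bin_cm, edges = edges,
                 n_exp = length(xe), n_null = length(xq),
                 n_merged = attr(kl, "merged"),
                 label = if (inherits(exp, "icd_sample")) exp$label else ""),
            class = "kl_index")
}

#' @export
print.kl_index <- function(x, ...) {
  cat("KL interference index (", x$label, "): ", signif(x$value, 4),
      " nats [", x$bin_cm, " cM bins, n = ", x$n_exp, "]\n", sep = "")
  invisible(x)
}

#' Permutation test on the difference of KL interference indices
#'
#' Tests whether two populations have the same interference strength, using
#' the difference of their KL indices as the score (population A minus
#' population B). The null distribution is obtained by re-partitioning the
#' pooled list of ICD values into two groups of the original sizes n1 and n2
#' (a true re-partition, without replacement); each group is scored against
#' the weighted average of the two populations' no-interference
#' distributions, the weights being the proportions of the group's ICDs that
#' were actually drawn from each population. The one-sided p-value is the
#' proportion of replicates whose score is at least the observed score, the
#' two-sided p-value uses absolute scores; both include the observed score in
#' the null set, so p >= 1/(reps+1) and is never exactly 0.
#'
#' @param popA,popB \code{\link{call_crossovers}} results.
#' @param reps Number of random re-partitions (default 1e6 as in practice for
#'   final inference; at least 100).
#' @param null_reps Shuffle replicates for each population's no-interference
#'   distribution.
#' @param bin_cm KL bin width (cM).
#' @param scope \code{"pooled"} or a chromosome id.
#' @return Object of class \code{kl_permutation}: list with \code{score}
#'   (KL_A - KL_B), \code{kl_A}, \code{kl_B}, \code{n_1}, \code{n_2},
#'   \code{reps}, \code{p_one_sided}, \code{p_two_sided}. Uses the R random
#'   number generator; seed with \code{set.seed}.
#' @export
kl_difference_permutation_test <- function(popA, popB, reps = 1e6,
                                           null_reps = 1000L, bin_cm = 5,
                                           scope = "pooled") {
  if (reps < 100) stop("'reps' must be at least 100")
  icdA <- compute_icds(popA, scope)
  icdB <- compute_icds(popB, scope)
  chrom <- if (identical(scope, "pooled")) NULL else scope
  # both nulls start from the same RNG state so that identical populations
  # get identical no-interference distributions (score exactly 0)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  rng_state <- get(".Random.seed", envir = globalenv())
  nullA <- shuffle_no_interference(popA, reps = null_reps, chrom = chrom)
  assign(".Random.seed", rng_state, envir = globalenv())
  nullB <- shuffle_no_interference(popB, reps = null_reps, chrom = chrom)
  if (icdA$n == 0 || icdB$n == 0) stop("empty ICD sample")
  edges <- .icd_edges(max(icdA$icds, icdB$icds, nullA$icds, nullB$icds),
                      bin_cm)
  nb <- length(edges) - 1L
  bin_of <- function(x) findInterval(x, edges, left.open = TRUE,
                                     rightmost.closed = TRUE)
  tabq <- function(x) tabulate(bin_of(x), nbins = nb)
  qA <- tabq(nullA$icds); qA <- qA / sum(qA)
  qB <- tabq(nullB$icds); qB <- qB / sum(qB)
  pA <- tabq(icdA$icds); pB <- tabq(icdB$icds)
  klA <- as.numeric(.kl_binned(pA, qA))
  klB <- as.numeric(.kl_binned(pB, qB))
  obs <- klA - klB

  pool <- c(icdA$icds, icdB$icds)
  from_A <- rep(c(TRUE, FALSE), c(icdA$n, icdB$n))
  ib <- bin_of(pool)
  N <- length(pool); n1 <- icdA$n; n2 <- icdB$n
  tot <- tabulate(ib, nbins = nb)
  totA <- sum(from_A)
  null_scores <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(N, n1)
    c1 <- tabulate(ib[idx], nbins = nb)
    a1 <- sum(from_A[idx])
    w1 <- a1 / n1
    w2 <- (totA - a1) / n2
    kl1 <- as.numeric(.kl_binned(c1, w1 * qA + (1 - w1) * qB))
    kl2 <- as.numeric(.kl_binned(tot - c1, w2 * qA + (1 - w2) * qB))
    null_scores[r] <- kl1 - kl2
  }
  eps <- 1e-12
  structure(list(score = obs, kl_A = klA, kl_B = klB,
                 n_1 = n1, n_2 = n2, reps = as.integer(reps),
                 p_one_sided = (1 + sum(null_scores >= obs - eps)) /
                   (reps + 1),
                 p_two_sided = (1 + sum(abs(null_scores) >= abs(obs) - eps)) /
                   (reps + 1)),
            class = "kl_permutation")
}

#' @export
print.kl_permutation <- function(x, ...) {
  cat("KL difference permutation test: score = ", signif(x$score, 4),
      " (KL_A = ", signif(x$kl_A, 4), ", KL_B = ", signif(x$kl_B, 4),
      ")\n  n1 = ", x$n_1, ", n2 = ", x$n_2, ", reps = ", x$reps,
      "\n  one-sided p = ", signif(x$p_one_sided, 4),
      ", two-sided p = ", signif(x$p_two_sided, 4), "\n", sep = "")
  invisible(x)
}
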