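#' Control settings for gamma-sprinkling fitting
#'
#' @param n_sim Simulated gametes per objective evaluation (the simulated
#'   composite likelihood compares binned data summaries to summaries of this
#'   sample; common random numbers across evaluations smooth the objective).
#' @param bin_cm ICD bin width (cM) used in the composite likelihood.
#' @param grid_nu,grid_p Starting grid for the optimiser.
#' @param nu_bounds Admissible range for nu.
#' @param p_max Upper bound for the Class II proportion.
#' @param n_starts Number of best grid points used as Nelder-Mead starts.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param sim_seed Seed of the common-random-number stream; drawn from the
#'   current RNG when \code{NULL}.
#' @return List of control settings.
#' @export
fit_control <- function(n_sim = 20000L, bin_cm = 5,
                        grid_nu = c(0.8, 2, 5, 12),
                        grid_p = c(0.01, 0.1, 0.25),
                        nu_bounds = c(0.2, 50), p_max = 0.5,
                        n_starts = 2L, maxit = 150L, sim_seed = NULL) {
  list(n_sim = as.integer(n_sim), bin_cm = bin_cm, grid_nu = grid_nu,
       grid_p = grid_p, nu_bounds = nu_bounds, p_max = p_max,
       n_starts = as.integer(n_starts), maxit = as.integer(maxit),
       sim_seed = sim_seed)
}

# multinomial log-likelihood of observed bin counts under simulated bin
# frequencies (0.5 pseudocount per category keeps the objective finite)
.multinom_ll <- function(obs_counts, sim_counts, n_sim) {
  pr <- (sim_counts + 0.5) / (n_sim + 0.5 * length(sim_counts))
  sum(obs_counts * log(pr))
}

#' Fit the two-pathway gamma-sprinkling interference model
#'
#' Estimates the Class I interference strength nu and the Class II
#' (non-interfering) proportion p for one chromosome of one population, by
#' maximising a simulated composite likelihood: for each candidate (nu, p)
#' the two-pathway simulator generates a large gamete sample at the
#' chromosome's observed map length, and the data's per-gamete CO-count
#' distribution and binned ICD distribution are scored against the simulated
#' ones by multinomial log-likelihood. Optimisation is Nelder-Mead over
#' (log nu, logit p) from multiple grid-seeded starts, with common random
#' numbers across evaluations. The chromosome map length is held fixed at
#' the observed value (100 x mean gamete CO count).
#'
#' @param pop A \code{\link{call_crossovers}} result, or \code{NULL} when
#'   \code{counts}/\code{icds}/\code{length_cM} are given directly.
#' @param chrom Chromosome id (when \code{pop} is given).
#' @param control A \code{\link{fit_control}} list.
#' @param counts,icds,length_cM Raw inputs for refitting simulated data:
#'   per-gamete CO counts, pooled ICDs, and the map length to fix.
#' @return Object of class \code{twopathway_fit}: list with \code{nu},
#'   \code{p}, \code{logLik}, \code{converged}, \code{chrom},
#'   \code{length_cM}, \code{n_gametes}, \code{n_informative} (gametes with
#'   >= 1 CO), \code{control} and the data summaries used.
#' @export
fit_gamma_sprinkling <- function(pop = NULL, chrom = NULL,
                                 control = fit_control(),
                                 counts = NULL, icds = NULL,
                                 length_cM = NULL) {
  if (!is.null(pop)) {
    stopifnot(inherits(pop, "co_pop"))
    if (is.null(chrom) || !chrom %in% colnames(pop$counts))
      stop("'chrom' must name a chromosome of the population")
    counts <- pop$counts[, chrom]
    icds <- compute_icds(pop, scope = chrom)$icds
  }
  if (is.null(counts)) stop("no data supplied")
  n_inf <- sum(counts >= 1)
  if (n_inf < 50)
    warning("fewer than 50 gametes with >= 1 CO: estimates will be ",
            "imprecise; widen confidence intervals accordingly")
  L <- if (!is.null(length_cM)) length_cM else 100 * mean(counts)
  if (L <= 0) stop("chromosome has no crossovers: map length is zero")

  kmax <- max(counts) + 2L
  ctab <- tabulate(counts + 1L, nbins = kmax + 1L)   # categories 0..kmax
  edges <- .icd_edges(max(c(icds, L / 2)), control$bin_cm)
  nb <- length(edges) - 1L
  itab <- tabulate(findInterval(icds, edges, left.open = TRUE,
                                rightmost.closed = TRUE), nbins = nb)
  sim_seed <- if (is.null(control$sim_seed))
    sample.int(.Machine$integer.max - 1L, 1L) else control$sim_seed

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))

  objective <- function(par) {
    nu <- exp(par[1]); pfrac <- control$p_max * stats::plogis(par[2])
    if (nu < control$nu_bounds[1] || nu > control$nu_bounds[2])
      return(1e8 + abs(log(nu))^2)
    set.seed(sim_seed)                        # common random numbers
    sim <- simulate_gametes(control$n_sim, L, nu, pfrac)
    sc <- tabulate(pmin(sim$counts, kmax) + 1L, nbins = kmax + 1L)
    si <- tabulate(findInterval(sim$icds, edges, left.open = TRUE,
                                rightmost.closed = TRUE), nbins = nb)
    -(.multinom_ll(ctab, sc, control$n_sim) +
        .multinom_ll(itab, si, length(sim$icds) + 1L))
  }

  grid <- expand.grid(nu = control$grid_nu, p = control$grid_p)
  grid_val <- vapply(seq_len(nrow(grid)), function(i)
    objective(c(log(grid$nu[i]),
                stats::qlogis(grid$p[i] / control$p_max))),
    numeric(1))
  starts <- order(grid_val)[seq_len(min(control$n_starts, nrow(grid)))]
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    par0 <- c(log(grid$nu[s]), stats::qlogis(grid$p[s] / control$p_max))
    opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                        control = list(maxit = control$maxit))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) converged <- TRUE
  }
  structure(list(nu = exp(best$par[1]),
                 p = control$p_max * stats::plogis(best$par[2]),
                 logLik = -best$value, converged = converged,
                 chrom = chrom %||% "", length_cM = L,
                 n_gametes = length(counts), n_informative = n_inf,
                 control = utils::modifyList(control,
                                             list(sim_seed = sim_seed)),
                 data = list(counts = counts, icds = icds)),
            class = "twopathway_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.twopathway_fit <- function(x, ...) {
  cat("two-pathway gamma-sprinkling fit",
      if (nzchar(x$chrom)) paste0(" (", x$chrom, ")"), "\n",
      "  nu = ", signif(x$nu, 4),
      if (!is.null(x$nu_Inf)) paste0(" [", signif(x$nu_Inf, 4), ", ",
                                     signif(x$nu_Sup, 4), "]"),
      "\n  p  = ", signif(x$p, 4),
      if (!is.null(x$p_Inf)) paste0(" [", signif(x$p_Inf, 4), ", ",
                                    signif(x$p_Sup, 4), "]"),
      "\n  logLik = ", signif(x$logLik, 6),
      ", converged: ", x$converged,
      ", n = ", x$n_gametes, " gametes (", x$n_informative,
      " with >= 1 CO)\n", sep = "")
  invisible(x)
}

#' Resimulation (parametric bootstrap) confidence intervals
#'
#' Simulates \code{replicates} datasets of the original size at the fitted
#' (nu, p), refits each, and takes the 2.5 and 97.5 percentiles of the
#' refitted parameters as 95 percent bounds (widened, if necessary, to
#' bracket the point estimate). Bounds are flagged unreliable when more than
#' 20 percent of refits fail to converge.
#'
#' @param fit A \code{\link{fit_gamma_sprinkling}} result.
#' @param replicates Number of bootstrap datasets.
#' @param control Optional lighter \code{\link{fit_control}} for the refits
#'   (defaults to the original fit's control).
#' @param conf_level Confidence level.
#' @return The fit with added \code{nu_Inf}, \code{nu_Sup}, \code{p_Inf},
#'   \code{p_Sup}, \code{ci_replicates}, \code{ci_failures} and
#'   \code{ci_unreliable}. Uses the R random number generator.
#' @export
ci_by_resimulation <- function(fit, replicates = 100L, control = NULL,
                               conf_level = 0.95) {
  stopifnot(inherits(fit, "twopathway_fit"))
  if (!fit$converged) stop("cannot bootstrap a non-converged fit")
  ctl <- control %||% fit$control
  n <- fit$n_gametes
  nus <- ps <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    sim <- simulate_gametes(n, fit$length_cM, fit$nu, fit$p)
    rf <- tryCatch(
      suppressWarnings(
        fit_gamma_sprinkling(counts = sim$counts, icds = sim$icds,
                             length_cM = fit$length_cM,
                             control = utils::modifyList(
                               ctl, list(sim_seed = NULL)))),
      error = function(e) NULL)
    if (!is.null(rf) && rf$converged) { nus[r] <- rf$nu; ps[r] <- rf$p }
  }
  ok <- !is.na(nus)
  if (!any(ok)) stop("all bootstrap refits failed")
  a <- (1 - conf_level) / 2
  qn <- stats::quantile(nus[ok], c(a, 1 - a), names = FALSE)
  qp <- stats::quantile(ps[ok], c(a, 1 - a), names = FALSE)
  fit$nu_Inf <- min(qn[1], fit$nu); fit$nu_Sup <- max(qn[2], fit$nu)
  fit$p_Inf <- min(qp[1], fit$p);   fit$p_Sup <- max(qp[2], fit$p)
  fit$ci_replicates <- sum(ok)
  fit$ci_failures <- replicates - sum(ok)
  fit$ci_unreliable <- fit$ci_failures > 0.2 * replicates
  if (fit$ci_unreliable)
    warning("more than 20% of bootstrap refits failed: bounds unreliable")
  fit
}

#' Permutation test on mean interference strength
#'
#' Tests whether two crosses share the same mean per-chromosome interference
#' strength. With per-chromosome strengths paired by chromosome, the score
#' is mean(B) - mean(A); under the null the two members of each pair are
#' exchangeable, so the null distribution enumerates all 2^n independent
#' within-pair swaps (the exact distribution; 1024 permutations for 10
#' chromosomes) when n <= 20, and samples \code{reps} random swap patterns
#' otherwise (e.g. the 30-chromosome pooled variant). The one-sided p-value
#' is the proportion of null scores at least the observed score; the
#' identity assignment is part of the enumeration, so p >= 1/2^n.
#'
#' @param fitsA,fitsB Numeric vectors of per-chromosome interference
#'   strengths (e.g. fitted nu), paired by position; or lists of
#'   \code{twopathway_fit} objects.
#' @param reps \code{"exact"} to enumerate (required n <= 20), or a number
#'   of random permutations.
#' @return Object of class \code{interference_mean_test}: list with
#'   \code{V_1}, \code{V_2}, \code{score}, \code{n_permutations},
#'   \code{exact}, \code{p_one_sided}.
#' @export
mean_interference_test <- function(fitsA, fitsB, reps = "exact") {
  get_nu <- function(x) if (is.list(x) && !is.numeric(x))
    vapply(x, function(f) f$nu, numeric(1)) else as.numeric(x)
  a <- get_nu(fitsA); b <- get_nu(fitsB)
  if (length(a) != length(b)) stop("paired vectors of unequal length")
  n <- length(a)
  d <- b - a
  obs <- mean(d)
  eps <- 1e-12
  if (identical(reps, "exact")) {
    if (n > 20) stop("exact enumeration limited to n <= 20")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_scores <- as.numeric(signs %*% d) / n
    n_perm <- 2^n
    p <- sum(null_scores >= obs - eps) / n_perm
    exact <- TRUE
  } else {
    n_perm <- as.integer(reps)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    null_scores <- as.numeric(signs %*% d) / n
    p <- (1 + sum(null_scores >= obs - eps)) / (n_perm + 1)
    exact <- FALSE
  }
  structure(list(V_1 = mean(a), V_2 = mean(b), score = obs,
                 n_permutations = n_perm, exact = exact,
                 p_one_sided = p),
            class = "interference_mean_test")
}

#' @export
print.interference_mean_test <- function(x, ...) {
  cat("mean interference strength test\n",
      "  V_1 = ", signif(x$V_1, 4), ", V_2 = ", signif(x$V_2, 4),
      ", score (V_2 - V_1) = ", signif(x$score, 4),
      "\n  ", if (x$exact) "exact, " else "sampled, ",
      x$n_permutations, " permutations, one-sided p = ",
      signif(x$p_one_sided, 4), "\n", sep = "")
  invisible(x)
}
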