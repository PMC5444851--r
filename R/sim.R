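#' Simulate crossovers on a meiotic bivalent under the two-pathway model
#'
#' Draws crossover (CO) positions on the four-chromatid bundle of one
#' chromosome. Interfering (Class I) COs follow a stationary gamma renewal
#' process with shape \code{nu}; non-interfering (Class II) COs are an
#' independent Poisson process "sprinkled" on top. Densities are calibrated so
#' that the expected total bivalent CO density is 2 per 100 cM of gamete map,
#' i.e. after chromatid thinning (\code{\link{thin_to_gamete}}) the gamete map
#' length identity holds: mean gamete CO count = \code{length_cM} / 100.
#'
#' The first Class I event is placed at the equilibrium forward-recurrence
#' distance from the chromosome start (a uniform fraction of a length-biased
#' inter-event interval, which for a gamma law is again gamma with shape
#' \code{nu + 1}), so the process is stationary and free of edge artifacts.
#' There is no obligate-CO constraint: zero-CO bivalents are allowed.
#'
#' @param length_cM Genetic length of the chromosome in centimorgans (gamete
#'   scale). Must be positive.
#' @param nu Interference strength (gamma shape). \code{nu = 1} is a Poisson
#'   process (no interference); larger values give more regular spacing.
#' @param p Proportion of COs formed through the non-interfering Class II
#'   pathway, in \[0, 1\].
#' @return Sorted numeric vector of CO positions (cM) on the bivalent.
#'   Uses the R random number generator; seed with \code{set.seed} for
#'   reproducibility.
#' @examples
#' set.seed(1)
#' simulate_bivalent(100, nu = 5, p = 0.05)
#' @export
simulate_bivalent <- function(length_cM, nu, p = 0) {
  if (!is.numeric(length_cM) || length(length_cM) != 1L || length_cM <= 0)
    stop("'length_cM' must be a positive number")
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0)
    stop("'nu' must be a positive number")
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("'p' must be a fraction in [0, 1]")

  pos1 <- numeric(0)
  if (p < 1) {
    m <- 50 / (1 - p)             # mean Class I inter-event distance (cM)
    theta <- m / nu
    # stationary start: U * length-biased interval, length-biased Gamma(nu)
    # is Gamma(nu + 1) with the same scale
    x <- stats::runif(1) * stats::rgamma(1, shape = nu + 1, scale = theta)
    while (x < length_cM) {
      pos1 <- c(pos1, x)
      x <- x + stats::rgamma(1, shape = nu, scale = theta)
    }
  }
  n2 <- stats::rpois(1, 2 * p * length_cM / 100)
  pos2 <- stats::runif(n2, 0, length_cM)
  sort(c(pos1, pos2))
}

#' Thin bivalent crossovers to one gamete chromatid
#'
#' Each CO on the bivalent involves two of the four chromatids, so a given
#' chromatid carries it with probability 1/2. Assuming no chromatid
#' interference, each CO is retained independently.
#'
#' @param bivalent Sorted numeric vector of bivalent CO positions (cM).
#' @return Sorted numeric vector, the subset transmitted to the gamete.
#' @export
thin_to_gamete <- function(bivalent) {
  if (length(bivalent) == 0L) return(numeric(0))
  bivalent[stats::runif(length(bivalent)) < 0.5]
}

#' Genotype a gamete at a set of markers
#'
#' Translates gamete CO positions into backcross allele calls: the allele
#' alternates at every CO, so a marker reports the parity of the number of COs
#' to its left. Two COs falling between the same adjacent markers therefore
#' produce no observable transition.
#'
#' @param gamete Sorted numeric vector of gamete CO positions (cM).
#' @param marker_cM Numeric vector of marker genetic positions (cM), within
#'   \code{[0, length_cM]}.
#' @param length_cM Chromosome genetic length (cM).
#' @param codes Two allele codes; the starting allele is drawn uniformly.
#' @return Character vector of allele codes, one per marker.
#' @export
genotypes_from_gamete <- function(gamete, marker_cM, length_cM,
                                  codes = c("A", "B")) {
  if (any(marker_cM < 0 | marker_cM > length_cM))
    stop("marker genetic positions must lie within [0, length_cM]")
  if (length(codes) != 2L) stop("'codes' must have exactly two values")
  start <- sample.int(2L, 1L) - 1L
  nco <- findInterval(marker_cM, sort(gamete))
  codes[1L + (start + nco) %% 2L]
}

#' Apply genome-wide viability selection to gametes
#'
#' Models post-meiotic selection in which a meiotic product is viable only if
#' its genome-wide CO count reaches a threshold \code{X}.
#'
#' @param counts Integer vector of genome-wide CO counts, one per gamete.
#' @param X Minimum CO count for viability (integer >= 0).
#' @return List with \code{keep} (logical vector), \code{n_total},
#'   \code{n_survivors} and \code{fraction} (surviving fraction). A warning is
#'   issued when no gamete survives.
#' @export
apply_gamete_selection <- function(counts, X) {
  if (!is.numeric(X) || length(X) != 1L || X < 0 || X != round(X))
    stop("'X' must be a non-negative integer")
  keep <- counts >= X
  if (!any(keep)) warning("no gamete reaches the selection threshold X = ", X)
  list(keep = keep,
       n_total = length(counts),
       n_survivors = sum(keep),
       fraction = mean(keep))
}

#' Simulate a large gamete sample on one chromosome (vectorised)
#'
#' Fast path used by the model-fitting objective and by calibration tests:
#' simulates \code{n} independent meioses of a single chromosome under the
#' two-pathway model, thins to gametes, and returns per-gamete CO counts and
#' the pooled inter-crossover distances (ICDs).
#'
#' @inheritParams simulate_bivalent
#' @param n Number of gametes (one per meiosis).
#' @return List with \code{counts} (integer vector of length \code{n}) and
#'   \code{icds} (numeric vector of all within-gamete adjacent-CO distances).
#' @export
simulate_gametes <- function(n, length_cM, nu, p = 0) {
  if (n < 1) stop("'n' must be >= 1")
  if (length_cM <= 0 || nu <= 0 || p < 0 || p > 1)
    stop("invalid scenario parameters")
  rowb <- integer(0); posb <- numeric(0)
  if (p < 1) {
    m <- 50 / (1 - p)
    theta <- m / nu
    mu_n <- length_cM / m
    K <- max(4L, ceiling(mu_n + 6 * sqrt((mu_n + 1) / min(nu, 1)) + 6))
    pos <- matrix(0, n, K)
    pos[, 1L] <- stats::runif(n) * stats::rgamma(n, nu + 1, scale = theta)
    if (K > 1L) {
      arr <- matrix(stats::rgamma(n * (K - 1L), nu, scale = theta), n, K - 1L)
      for (j in 2:K) pos[, j] <- pos[, j - 1L] + arr[, j - 1L]
    }
    while (any(pos[, ncol(pos)] < length_cM)) {
      pos <- cbind(pos, pos[, ncol(pos)] +
                     stats::rgamma(n, nu, scale = theta))
    }
    keep <- pos < length_cM
    rowb <- row(pos)[keep]
    posb <- pos[keep]
  }
  n2 <- stats::rpois(n, 2 * p * length_cM / 100)
  if (sum(n2) > 0) {
    rowb <- c(rowb, rep.int(seq_len(n), n2))
    posb <- c(posb, stats::runif(sum(n2), 0, length_cM))
  }
  thin <- stats::runif(length(posb)) < 0.5
  rowg <- rowb[thin]; posg <- posb[thin]
  o <- order(rowg, posg)
  rowg <- rowg[o]; posg <- posg[o]
  d <- diff(posg)
  same <- diff(rowg) == 0L
  list(counts = tabulate(rowg, nbins = n), icds = d[same])
}

# Synthetic physical frame: 10 chromosomes at the scale of the Brassica rapa
# A genome (sizes in Mbp are synthetic approximations), centromere location
# as a fraction of chromosome length.
.synthetic_genome <- function() {
  data.frame(
    chrom = sprintf("A%02d", 1:10),
    size_bp = round(1e6 * c(28.6, 27.8, 31.6, 18.6, 23.9,
                            26.3, 22.6, 21.6, 37.1, 17.1)),
    cen_frac = c(0.45, 0.40, 0.52, 0.35, 0.48,
                 0.38, 0.55, 0.42, 0.50, 0.44),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic marker map
#'
#' Generates an ordered SNP map emulating a backcross genotyping design:
#' 10 chromosomes, markers at ~1.25 Mbp mean spacing (~20 per chromosome,
#' 204 genome-wide with the default frame), physical positions lightly
#' jittered around an even grid. Genetic positions (\code{pos_cM}) are filled
#' by \code{\link{meiosis_scenario}} / \code{\link{scenario_preset}} through a
#' Marey function.
#'
#' @param genome Data frame with columns \code{chrom}, \code{size_bp},
#'   \code{cen_frac}; defaults to the built-in synthetic 10-chromosome frame.
#' @param spacing_bp Target mean marker spacing in bp.
#' @param jitter Fraction of the spacing used as uniform positional jitter.
#' @return A \code{marker_map} data frame (columns \code{marker_id},
#'   \code{chrom}, \code{pos_bp}) with a \code{centromeres} attribute
#'   (\code{chrom}, \code{start_bp}, \code{end_bp}) and a \code{chrom_size_bp}
#'   attribute. Uses the R random number generator.
#' @export
make_marker_map <- function(genome = .synthetic_genome(),
                            spacing_bp = 1.25e6, jitter = 0.2) {
  maps <- lapply(seq_len(nrow(genome)), function(i) {
    size <- genome$size_bp[i]
    nm <- max(2L, round(size / spacing_bp))
    # terminal markers anchored at the chromosome ends so the map covers the
    # full physical (and hence genetic) span; interior markers jittered
    grid <- 1 + (size - 1) * (seq_len(nm) - 1) / (nm - 1)
    pos <- grid
    if (nm > 2L)
      pos[2:(nm - 1L)] <- grid[2:(nm - 1L)] +
        stats::runif(nm - 2L, -jitter, jitter) * spacing_bp
    pos <- sort(pmin(pmax(round(pos), 1), size))
    pos <- pos + cumsum(c(0, diff(pos) <= 0))   # enforce strict increase
    data.frame(marker_id = sprintf("%s_M%02d", genome$chrom[i], seq_len(nm)),
               chrom = genome$chrom[i], pos_bp = pos,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  cen_mid <- genome$size_bp * genome$cen_frac
  attr(map, "centromeres") <- data.frame(
    chrom = genome$chrom,
    start_bp = round(cen_mid - 0.01 * genome$size_bp),
    end_bp = round(cen_mid + 0.01 * genome$size_bp),
    stringsAsFactors = FALSE)
  attr(map, "chrom_size_bp") <- stats::setNames(genome$size_bp, genome$chrom)
  class(map) <- c("marker_map", "data.frame")
  map
}

# Marey function: cumulative genetic position (cM) as a function of physical
# position. "flat" gives a uniform recombination rate; "suppressed" gives a
# pericentromere-suppressed profile with local rate proportional to
# eps + ((x - cen)/size)^2 (near-zero at the centromere, highest distally).
.marey_cM <- function(pos_bp, size_bp, cen_bp, length_cM,
                      shape = c("suppressed", "flat"), eps = 0.01) {
  shape <- match.arg(shape)
  if (shape == "flat") return(length_cM * pos_bp / size_bp)
  W <- function(b) eps * b + ((b - cen_bp)^3 + cen_bp^3) / (3 * size_bp^2)
  length_cM * W(pos_bp) / W(size_bp)
}

#' Define a meiosis simulation scenario
#'
#' Bundles everything \code{\link{simulate_population}} needs: per-chromosome
#' genetic lengths, interference parameters, a marker map with genetic
#' positions, population size, optional viability truncation and a seed.
#'
#' @param chrom_len_cM Named numeric vector of chromosome genetic lengths
#'   (cM, gamete scale).
#' @param nu Interference strength (> 0).
#' @param p Class II (non-interfering) CO proportion in \[0, 1\].
#' @param n_progeny Number of progeny (post-selection if a threshold is set).
#' @param marker_map A \code{marker_map} with a \code{pos_cM} column whose
#'   per-chromosome genetic positions lie within \code{[0, chrom_len_cM]}.
#' @param selection_threshold Optional minimum genome-wide CO count for a
#'   gamete to be viable (integer >= 0), or \code{NULL} for no selection.
#' @param seed Integer seed; the population is fully reproducible given it.
#' @param max_attempts Simulation budget when selection is active.
#' @return An object of class \code{meiosis_scenario}.
#' @export
meiosis_scenario <- function(chrom_len_cM, nu, p, n_progeny, marker_map,
                             selection_threshold = NULL, seed = 1L,
                             max_attempts = 200L * n_progeny) {
  if (any(chrom_len_cM <= 0)) stop("all chromosome lengths must be > 0")
  if (nu <= 0) stop("'nu' must be > 0")
  if (p < 0 || p > 1) stop("'p' must be in [0, 1]")
  if (is.null(names(chrom_len_cM)))
    stop("'chrom_len_cM' must be named by chromosome")
  if (is.null(marker_map$pos_cM))
    stop("'marker_map' must carry genetic positions in a 'pos_cM' column")
  for (ch in names(chrom_len_cM)) {
    g <- marker_map$pos_cM[marker_map$chrom == ch]
    if (any(g < 0 | g > chrom_len_cM[[ch]]))
      stop("marker genetic positions on ", ch, " fall outside [0, length]")
  }
  if (!is.null(selection_threshold) &&
      (selection_threshold < 0 || selection_threshold != round(selection_threshold)))
    stop("'selection_threshold' must be a non-negative integer")
  structure(list(chrom_len_cM = chrom_len_cM, nu = nu, p = p,
                 n_progeny = as.integer(n_progeny), marker_map = marker_map,
                 selection_threshold = selection_threshold,
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "meiosis_scenario")
}

#' Preset diploid-like and allotriploid-like scenarios
#'
#' Two fixed parameter sets emulating the contrasted backcross populations the
#' package targets. The diploid-like preset has a short map (700 cM gamete
#' scale, i.e. 14 COs per meiosis genome-wide), strong interference
#' (\code{nu = 5}), a small Class II fraction (\code{p = 0.05}) and a
#' pericentromere-suppressed Marey map. The allotriploid-like preset has a
#' 2.8-fold longer map (1970 cM; 39.4 COs per meiosis), weak interference
#' (\code{nu = 1.3}), \code{p = 0.10} and a flat Marey map, so crossovers
#' occur at the centromeres as well.
#'
#' @param type \code{"diploid"} or \code{"allotriploid"}.
#' @param n_progeny Number of progeny.
#' @param seed Integer seed.
#' @param selection_threshold Optional viability threshold, see
#'   \code{\link{meiosis_scenario}}.
#' @param nu,p,genome_cM Optional overrides of the preset parameters (the
#'   Marey shape and physical frame stay those of \code{type}); used for
#'   sensitivity sweeps.
#' @return A \code{meiosis_scenario}.
#' @export
scenario_preset <- function(type = c("diploid", "allotriploid"),
                            n_progeny = 200L, seed = 1L,
                            selection_threshold = NULL,
                            nu = NULL, p = NULL, genome_cM = NULL) {
  type <- match.arg(type)
  genome <- .synthetic_genome()
  set.seed(seed)
  map <- make_marker_map(genome)
  genome_cM <- genome_cM %||% (if (type == "diploid") 700 else 1970)
  len <- genome_cM * genome$size_bp / sum(genome$size_bp)
  names(len) <- genome$chrom
  shape <- if (type == "diploid") "suppressed" else "flat"
  pos_cM <- numeric(nrow(map))
  for (i in seq_len(nrow(genome))) {
    sel <- map$chrom == genome$chrom[i]
    pos_cM[sel] <- pmin(len[i], pmax(0, .marey_cM(
      map$pos_bp[sel], genome$size_bp[i],
      genome$size_bp[i] * genome$cen_frac[i], len[i], shape = shape)))
  }
  map$pos_cM <- pos_cM
  nu <- nu %||% (if (type == "diploid") 5 else 1.3)
  p <- p %||% (if (type == "diploid") 0.05 else 0.10)
  meiosis_scenario(len, nu = nu, p = p, n_progeny = n_progeny,
                   marker_map = map, selection_threshold = selection_threshold,
                   seed = seed)
}

#' Simulate a backcross population under a scenario
#'
#' For each progeny, simulates one meiosis per chromosome (bivalent COs,
#' chromatid thinning), applies the optional genome-wide viability threshold,
#' and genotypes the transmitted chromatid at the scenario's markers. The
#' result is deterministic given the scenario seed: a master stream draws one
#' sub-seed per attempted gamete, so accepted progeny are reproducible whether
#' or not selection discards earlier attempts.
#'
#' @param scenario A \code{\link{meiosis_scenario}}.
#' @return List of class \code{sim_population} with elements
#'   \code{genotypes} (a \code{\link{genotype_matrix}}), \code{truth}
#'   (true gamete CO positions per progeny and chromosome, true \code{nu},
#'   \code{p}, seed, attempts and pre-selection survival fraction).
#' @export
simulate_population <- function(scenario) {
  stopifnot(inherits(scenario, "meiosis_scenario"))
  map <- scenario$marker_map
  chroms <- names(scenario$chrom_len_cM)
  set.seed(scenario$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, scenario$max_attempts)
  X <- scenario$selection_threshold
  n_target <- scenario$n_progeny

  geno <- matrix(NA_character_, nrow = nrow(map), ncol = n_target)
  truth_pos <- vector("list", n_target)
  kept <- 0L; attempt <- 0L
  while (kept < n_target) {
    attempt <- attempt + 1L
    if (attempt > scenario$max_attempts)
      stop("simulation budget exhausted: selection threshold too high for ",
           "the requested population size")
    set.seed(sub_seeds[attempt])
    gam <- lapply(chroms, function(ch)
      thin_to_gamete(simulate_bivalent(scenario$chrom_len_cM[[ch]],
                                       scenario$nu, scenario$p)))
    names(gam) <- chroms
    total <- sum(lengths(gam))
    if (!is.null(X) && total < X) next
    kept <- kept + 1L
    truth_pos[[kept]] <- gam
    for (ch in chroms) {
      sel <- map$chrom == ch
      geno[sel, kept] <- genotypes_from_gamete(
        gam[[ch]], map$pos_cM[sel], scenario$chrom_len_cM[[ch]])
    }
  }
  progeny <- sprintf("P%04d", seq_len(n_target))
  colnames(geno) <- progeny
  rownames(geno) <- map$marker_id
  names(truth_pos) <- progeny
  gm <- genotype_matrix(geno, map)
  structure(list(
    genotypes = gm,
    truth = list(co_positions = truth_pos,
                 counts = vapply(truth_pos, function(g) sum(lengths(g)),
                                 integer(1)),
                 nu = scenario$nu, p = scenario$p, seed = scenario$seed,
                 n_attempts = attempt,
                 survival_fraction = n_target / attempt)),
    class = "sim_population")
}
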