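#' Poisson upper-tail probability P(k >= X)
#'
#' Exact tail via stable summation of log-space probability masses, with an
#' upper cutoff far beyond double-precision relevance
#' (lambda + 40 sqrt(lambda) + 100). Terms are summed in increasing order of
#' magnitude.
#'
#' @param lambda Poisson mean (> 0).
#' @param X Integer threshold (>= 0).
#' @return P(k >= X) under Poisson(lambda).
#' @export
poisson_tail <- function(lambda, X) {
  if (lambda <= 0) stop("'lambda' must be > 0")
  if (X < 0 || X != round(X)) stop("'X' must be a non-negative integer")
  if (X == 0) return(1)
  upper <- ceiling(lambda + 40 * sqrt(lambda) + 100)
  k <- X:max(X, upper)
  terms <- exp(k * log(lambda) - lambda - lgamma(k + 1))
  sum(sort(terms))
}

#' Mean of a lower-truncated Poisson distribution
#'
#' E\[k | k >= X\] under Poisson(lambda): the expected CO count among gametes
#' surviving a viability threshold X. Non-decreasing in X; at least
#' max(lambda, X).
#'
#' @inheritParams poisson_tail
#' @return The conditional mean.
#' @export
truncated_poisson_mean <- function(lambda, X) {
  if (lambda <= 0) stop("'lambda' must be > 0")
  if (X < 0 || X != round(X)) stop("'X' must be a non-negative integer")
  tail <- poisson_tail(lambda, X)
  if (tail < 1e-300)
    stop("tail probability numerically zero for lambda = ", lambda,
         ", X = ", X)
  upper <- ceiling(lambda + 40 * sqrt(lambda) + 100)
  k <- X:max(X, upper)
  terms <- k * exp(k * log(lambda) - lambda - lgamma(k + 1))
  sum(sort(terms)) / tail
}

#' Selection strength required to explain an elevated crossover rate
#'
#' Tests whether post-meiotic viability selection alone could raise an
#' observed genome-wide map length from L_G to L_G'. Assume no selection in
#' the reference (shorter-map) population, so gametes carry on average
#' lambda = L_G/100 COs; without interference the pre-selection count k is
#' Poisson(lambda). If only gametes with k >= X are viable, X must be large
#' enough that the truncated mean reaches the target L_G'/100. The function
#' finds the smallest such integer X numerically and reports the implied
#' viable fraction P(k >= X). With interference the count distribution is
#' narrower than Poisson, so the required selection would be even more
#' severe: the Poisson assumption is conservative and the returned fraction
#' is an upper bound.
#'
#' @param L_G Genome-wide genetic length (cM) of the reference population.
#' @param L_G_prime Genome-wide genetic length (cM) of the elevated
#'   population; must exceed \code{L_G}.
#' @param per_meiosis If \code{TRUE}, the inputs are per-meiosis lengths
#'   (twice the gamete scale) and are halved first.
#' @return Object of class \code{selection_test}: list with \code{lambda},
#'   \code{target_mean}, \code{X}, \code{truncated_mean},
#'   \code{viable_fraction}.
#' @export
required_selection <- function(L_G, L_G_prime, per_meiosis = FALSE) {
  if (per_meiosis) { L_G <- L_G / 2; L_G_prime <- L_G_prime / 2 }
  if (!(L_G_prime > L_G) || L_G <= 0)
    stop("need L_G_prime > L_G > 0")
  lambda <- L_G / 100
  target <- L_G_prime / 100
  X <- 0L
  while (truncated_poisson_mean(lambda, X) < target) X <- X + 1L
  structure(list(lambda = lambda, target_mean = target, X = X,
                 truncated_mean = truncated_poisson_mean(lambda, X),
                 viable_fraction = poisson_tail(lambda, X)),
            class = "selection_test")
}

#' Predicted Class II crossover proportion from a Class I count
#'
#' When the total CO count per meiosis is known from genotyping and the
#' Class I count from MLH1 focus counts, the excess is attributed to the
#' non-interfering Class II pathway:
#' 100 (total - class1) / total percent.
#'
#' @param total_mean Mean total COs per meiosis (genotyping).
#' @param class1_mean Mean Class I COs per meiosis (MLH1 foci).
#' @return Predicted Class II proportion, in percent.
#' @export
class2_proportion <- function(total_mean, class1_mean) {
  if (total_mean <= 0) stop("'total_mean' must be > 0")
  if (class1_mean > total_mean)
    stop("Class I count exceeds the total CO count")
  100 * (total_mean - class1_mean) / total_mean
}

#' @export
print.selection_test <- function(x, ...) {
  cat("post-meiotic selection test (truncated Poisson)\n",
      "  pre-selection mean COs/gamete (lambda): ", signif(x$lambda, 4),
      "\n  target post-selection mean:             ", signif(x$target_mean, 4),
      "\n  required threshold X:                   ", x$X,
      "\n  truncated mean at X:                    ",
      signif(x$truncated_mean, 4),
      "\n  implied viable fraction P(k >= X):      ",
      signif(x$viable_fraction, 3),
      "\n  (interference-free assumption is conservative: an upper bound)\n",
      sep = "")
  invisible(x)
}
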