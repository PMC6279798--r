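# Beta-binomial nucleotide count model: wild-type, heterozygous (with the
# allelic drop-out mixture) and homozygous-alternative states.

#' Bounds on the model parameters
#'
#' Proposals outside these bounds are rejected during MCMC; they keep the
#' beta-binomial well defined (alpha, beta > 0).
#'
#' @return named list of length-2 numeric vectors `c(lower, upper)`.
#' @export
param_bounds <- function() {
  list(
    f_wt     = c(1e-6, 0.49),
    omega_wt = c(1, 1e9),
    omega_a  = c(0.1, 1e4),
    mu       = c(0, 0.99),
    nu       = c(0, 0.99)
  )
}

#' Model parameters for the nucleotide count model
#'
#' @param f_wt expected frequency of the alternative nucleotide in the absence
#'   of a mutation (sequencing error rate), in (1e-6, 0.49).
#' @param omega_wt beta-binomial overdispersion of the wild-type state; large
#'   values approach an independent-errors binomial.
#' @param omega_a overdispersion of the mutated (heterozygous) state; small
#'   values reflect the few initial genomic fragments amplified by MDA.
#' @param mu allelic drop-out probability in `[0, 0.99]`.
#' @param nu homozygosity (loss-of-heterozygosity) coefficient in `[0, 0.99]`.
#' @return object of class `model_params`.
#' @export
model_params <- function(f_wt = 0.001, omega_wt = 100, omega_a = 2,
                         mu = 0.1, nu = 0.1) {
  p <- list(f_wt = f_wt, omega_wt = omega_wt, omega_a = omega_a,
            mu = mu, nu = nu)
  b <- param_bounds()
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite scalar")
    if (v < b[[nm]][1] || v > b[[nm]][2])
      stop("parameter '", nm, "' = ", v, " outside bounds [",
           b[[nm]][1], ", ", b[[nm]][2], "]")
  }
  structure(p, class = "model_params")
}

#' Check whether a parameter set is within bounds
#' @param params named list of parameter values.
#' @return logical scalar.
#' @export
params_in_bounds <- function(params) {
  b <- param_bounds()
  all(vapply(names(b), function(nm) {
    v <- params[[nm]]
    is.finite(v) && v >= b[[nm]][1] && v <= b[[nm]][2]
  }, logical(1)))
}

#' Beta-binomial log probability mass
#'
#' Log pmf of the beta-binomial in the mean/overdispersion parametrization
#' `alpha = f * omega`, `beta = (1 - f) * omega`, computed via log-gamma so
#' large coverages do not overflow.
#'
#' @param s observed count of the nucleotide, `0 <= s <= c`.
#' @param c total coverage.
#' @param f mean nucleotide frequency in (0, 1).
#' @param omega overdispersion (> 0); `omega -> Inf` approaches
#'   `dbinom(s, c, f)`.
#' @return log probability (vectorized over `s`, `c`).
#' @export
log_beta_binomial <- function(s, c, f, omega) {
  if (any(s < 0 | s > c)) stop("require 0 <= s <= c")
  if (any(f <= 0 | f >= 1)) stop("require 0 < f < 1")
  if (any(omega <= 0)) stop("require omega > 0")
  alpha <- f * omega
  beta <- (1 - f) * omega
  lchoose(c, s) + lbeta(s + alpha, c - s + beta) - lbeta(alpha, beta)
}

#' Wild-type state log likelihood
#'
#' Probability of `s` alternative reads out of `c` when no mutation is
#' present: errors only.
#'
#' @inheritParams log_beta_binomial
#' @param params a [model_params()] object.
#' @return log probability.
#' @export
log_p_wt <- function(s, c, params) {
  log_beta_binomial(s, c, params$f_wt, params$omega_wt)
}

#' Homozygous-alternative state log likelihood
#'
#' Only alternative alleles present: the reference count `c - s` plays the
#' role of the error count, mirroring the wild-type state.
#'
#' @inheritParams log_p_wt
#' @return log probability.
#' @export
log_p_hom <- function(s, c, params) {
  log_beta_binomial(c - s, c, params$f_wt, params$omega_wt)
}

#' Heterozygous state log likelihood with allelic drop-out mixture
#'
#' Three-component mixture: loss of the mutant allele (weight mu/2, wild-type
#' counts), loss of the wild-type allele (weight mu/2, reflected counts) and
#' a proper heterozygous signal (weight 1 - mu) with mean allele frequency
#' `1/2 - (2/3) f_wt` (errors move reads to the two other bases). At `mu = 0`
#' this is exactly the pure heterozygous beta-binomial.
#'
#' @inheritParams log_p_wt
#' @return log probability.
#' @export
log_p_het <- function(s, c, params) {
  f_het <- 0.5 - (2 / 3) * params$f_wt
  t3 <- log_beta_binomial(s, c, f_het, params$omega_a)
  mu <- params$mu
  if (mu == 0) return(t3)
  t1 <- log_beta_binomial(s, c, params$f_wt, params$omega_wt)
  t2 <- log_beta_binomial(c - s, c, params$f_wt, params$omega_wt)
  w <- log(c(mu / 2, mu / 2, 1 - mu))
  if (mu == 1) {
    return(logaddexp(w[1] + t1, w[2] + t2))
  }
  logaddexp(logaddexp(w[1] + t1, w[2] + t2), w[3] + t3)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters:\n")
  cat(sprintf("  f_wt = %g, omega_wt = %g, omega_a = %g, mu = %g, nu = %g\n",
              x$f_wt, x$omega_wt, x$omega_a, x$mu, x$nu))
  invisible(x)
}
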