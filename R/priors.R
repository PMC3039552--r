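#' Hyperprior specifications for the spatial models
#'
#' Both the BYM incidence model and the excess-mortality survival model place
#' hyperpriors on the precisions of the spatial (`u`, intrinsic CAR) and
#' unstructured (`v`, exchangeable normal) random effects, either directly as
#' a Gamma on the precision tau, or reparameterised as a Uniform on
#' sigma = 1/sqrt(tau). Fixed-effect coefficients get vague mean-zero normal
#' priors whose variance differs between the two models.
#'
#' @param shape,rate Gamma shape and rate, both > 0.
#' @return A prior-component object (`tau_prior`).
#' @export
gamma_prior <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  structure(list(family = "gamma", shape = shape, rate = rate),
            class = "tau_prior")
}

#' @param lower,upper Bounds of the uniform prior on sigma, `lower < upper`.
#' @rdname gamma_prior
#' @export
sigma_uniform_prior <- function(lower, upper) {
  stopifnot(lower >= 0, upper > lower)
  structure(list(family = "uniform_sigma", lower = lower, upper = upper),
            class = "tau_prior")
}

#' @export
print.tau_prior <- function(x, ...) {
  if (x$family == "gamma") {
    cat("tau ~ Gamma(", x$shape, ", ", x$rate, ")\n", sep = "")
  } else {
    cat("sigma ~ Uniform(", x$lower, ", ", x$upper, ")\n", sep = "")
  }
  invisible(x)
}

#' @param tau_u,tau_v Hyperpriors for the spatial and unstructured precision,
#'   from [gamma_prior()] or [sigma_uniform_prior()].
#' @param coef_variance Variance of the mean-zero normal prior on the fixed
#'   effects: the intercept alpha in the incidence model (default 1e10), or
#'   the follow-up-year intercepts alpha_j and age coefficients beta_k in the
#'   survival model (1e6).
#' @rdname gamma_prior
#' @export
prior_spec <- function(tau_u, tau_v, coef_variance) {
  stopifnot(inherits(tau_u, "tau_prior"), inherits(tau_v, "tau_prior"),
            coef_variance > 0)
  structure(list(tau_u = tau_u, tau_v = tau_v, coef_variance = coef_variance),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> coef variance ", format(x$coef_variance), "\n  u: ", sep = "")
  print(x$tau_u)
  cat("  v: ")
  print(x$tau_v)
  invisible(x)
}

#' Named prior presets for the sensitivity analysis
#'
#' Six candidate hyperprior pairs per model were compared; preset `"prior3"`
#' is the production default for both models (incidence:
#' tau_u ~ Gamma(0.1, 0.1), tau_v ~ Gamma(0.001, 0.001); survival:
#' tau_u ~ Gamma(0.1, 0.01), tau_v ~ Gamma(0.1, 0.01)).
#'
#' @param name Preset name, `"prior1"` ... `"prior6"`.
#' @return A [prior_spec()].
#' @export
incidence_prior <- function(name = "prior3") {
  presets <- list(
    prior1 = list(gamma_prior(0.5, 0.0005), gamma_prior(0.5, 0.0005)),
    prior2 = list(gamma_prior(1, 1), gamma_prior(7.801, 2.793)),
    prior3 = list(gamma_prior(0.1, 0.1), gamma_prior(0.001, 0.001)),
    prior4 = list(gamma_prior(0.1, 0.01), gamma_prior(0.1, 0.01)),
    prior5 = list(sigma_uniform_prior(0, 1), sigma_uniform_prior(0, 1)),
    prior6 = list(sigma_uniform_prior(0, 1000), sigma_uniform_prior(0, 1000))
  )
  p <- presets[[match.arg(name, names(presets))]]
  prior_spec(tau_u = p[[1]], tau_v = p[[2]], coef_variance = 1e10)
}

#' @rdname incidence_prior
#' @export
survival_prior <- function(name = "prior3") {
  presets <- list(
    prior1 = list(gamma_prior(0.5, 0.001), gamma_prior(0.5, 0.001)),
    prior2 = list(gamma_prior(0.1, 0.1), gamma_prior(0.001, 0.001)),
    prior3 = list(gamma_prior(0.1, 0.01), gamma_prior(0.1, 0.01)),
    prior4 = list(gamma_prior(0.5, 0.0005), gamma_prior(0.5, 0.0005)),
    prior5 = list(sigma_uniform_prior(0, 1), sigma_uniform_prior(0, 1)),
    prior6 = list(sigma_uniform_prior(0, 1000), sigma_uniform_prior(0, 1000))
  )
  p <- presets[[match.arg(name, names(presets))]]
  prior_spec(tau_u = p[[1]], tau_v = p[[2]], coef_variance = 1e6)
}

#' MCMC run configuration
#'
#' A single chain of `burn_in` warm-up sweeps followed by `kept` sweeps of
#' which every `thin`-th state is stored, so `kept / thin` draws are
#' retained. Proposal scales adapt only during burn-in.
#'
#' @param burn_in,kept,thin Positive integers; `thin` must divide `kept`.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return An `mcmc_control` object.
#' @export
mcmc_control <- function(burn_in, kept, thin, seed = 1L) {
  stopifnot(burn_in > 0, kept > 0, thin > 0, kept %% thin == 0)
  structure(list(burn_in = as.integer(burn_in), kept = as.integer(kept),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Production-scale and desk-scale MCMC settings
#'
#' Production scale uses a 100,000-sweep burn-in for incidence models and
#' 250,000 for survival models, then 100,000 further sweeps thinned by 10
#' (10,000 stored draws). Desk scale (5,000 / 5,000 / 5) is for tests and
#' exploration.
#'
#' @param model `"incidence"` or `"survival"` (they differ only in burn-in).
#' @param seed Integer seed.
#' @rdname mcmc_control
#' @export
mcmc_production_scale <- function(model = c("incidence", "survival"), seed = 1L) {
  model <- match.arg(model)
  burn <- if (model == "incidence") 100000L else 250000L
  mcmc_control(burn_in = burn, kept = 100000L, thin = 10L, seed = seed)
}

#' @rdname mcmc_control
#' @export
mcmc_desk_scale <- function(seed = 1L) {
  mcmc_control(burn_in = 5000L, kept = 5000L, thin = 5L, seed = seed)
}

#' Five-class map cut-offs
#'
#' Smoothed ratios are classified relative to the regional average as more
#' than 30% below, 10-30% below, within 10%, 10-30% above, or more than 30%
#' above: cut points 1/1.3, 1/1.1, 1.1, 1.3 with the central class closed on
#' both sides.
#'
#' @return Numeric vector of the four interior cut points.
#' @export
map_cutoffs <- function() c(1 / 1.3, 1 / 1.1, 1.1, 1.3)

#' Evidence bands for the global clustering test
#'
#' Adjusted p-values from Tango's MEET classify as: below 0.01 strong
#' evidence of spatial variation; 0.01 to below 0.05 moderate; 0.05 to below
#' 0.10 weak; 0.10 and above none.
#'
#' @return Named numeric vector of the three band boundaries.
#' @export
meet_evidence_bands <- function() c(strong = 0.01, moderate = 0.05, weak = 0.10)

#' Default number of runs for the stability rule
#'
#' The clustering test is Monte-Carlo based, so classification is repeated
#' (one initial run plus five more) and disagreements resolve to the less
#' significant category.
#' @return Integer, 6.
#' @export
meet_stability_runs <- function() 6L
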