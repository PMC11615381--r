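#' Roles in a family quad
#'
#' A quad is one couple plus one randomly drawn full sibling of each partner:
#' \code{index} (the female partner), \code{partner} (the male partner),
#' \code{sib_index}, and \code{sib_partner}. \code{sib_partner} is the index
#' person's sibling-in-law; \code{sib_index} and \code{sib_partner} are
#' co-siblings-in-law.
#'
#' @return character vector of the four role names.
#' @export
quad_roles <- function() c("index", "partner", "sib_index", "sib_partner")

#' Mechanism parameters for partner-similarity simulations
#'
#' Parameters of the four generating mechanisms, on standardized (unit
#' variance) liabilities:
#' \describe{
#'   \item{direct}{assortment on the phenotype itself: copath \code{m}
#'     between partners' phenotypes, sibling correlation \code{r_s}.}
#'   \item{indirect}{assortment on a latent mating factor M: phenotype
#'     loading \code{a} (or its square \code{a2}), copath \code{mu} between
#'     partners' M, sibling correlation \code{r_m} in M, and residual sibling
#'     correlation \code{r_e} (contributing \code{E = (1 - a^2) * r_e} to the
#'     phenotypic sibling correlation).}
#'   \item{stratification}{a stratum factor shared by all four members with
#'     loading \code{q}.}
#' }
#' \code{n2} (couple-shared environmental variance) and \code{x} (mutual
#' influence coefficient) describe post-formation convergence and are applied
#' by [overlay_convergence()]. \code{skew_gamma} sets the sinh-arcsinh
#' skewness of the liability innovations (0 = Gaussian), used by
#' [skewed_liability()].
#'
#' The implied 4x4 quad correlation matrix is validated to be positive
#' definite at construction.
#'
#' @param mechanism one of "direct", "indirect", "stratification".
#' @param m,r_s direct-assortment copath and sibling correlation.
#' @param a,a2,mu,r_m,r_e indirect-assortment parameters (supply \code{a} or
#'   \code{a2}).
#' @param q stratification loading.
#' @param n2,x convergence overlay parameters.
#' @param skew_gamma liability skewness (sign = direction of skew).
#' @return an object of class \code{mechanism_params}.
#' @export
mechanism_params <- function(mechanism = c("direct", "indirect", "stratification"),
                             m = NULL, r_s = NULL, a = NULL, a2 = NULL,
                             mu = NULL, r_m = NULL, r_e = 0, q = NULL,
                             n2 = 0, x = 0, skew_gamma = 0) {
  mechanism <- match.arg(mechanism)
  in_open <- function(v, lo = -1, hi = 1) !is.null(v) && v > lo && v < hi
  if (mechanism == "direct") {
    if (!in_open(m) || !in_open(r_s))
      stop("direct assortment needs m and r_s inside (-1, 1)")
  } else if (mechanism == "indirect") {
    if (is.null(a) && !is.null(a2)) {
      if (a2 <= 0 || a2 >= 1) stop("a2 must be inside (0, 1)")
      a <- sqrt(a2)
    }
    if (!in_open(a) || !in_open(mu) || !in_open(r_m) || !in_open(r_e, -1, 1))
      stop("indirect assortment needs a (or a2), mu, r_m inside (-1, 1)")
  } else {
    if (!in_open(q)) stop("stratification needs q inside (-1, 1)")
  }
  if (n2 < 0) stop("n2 must be nonnegative")
  p <- structure(list(mechanism = mechanism, m = m, r_s = r_s, a = a,
                      mu = mu, r_m = r_m, r_e = r_e, q = q, n2 = n2, x = x,
                      skew_gamma = skew_gamma),
                 class = "mechanism_params")
  R <- implied_quad_matrix(p)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10)
    stop("parameters imply a non-positive-definite quad correlation matrix")
  p
}

# Implied 4x4 correlation matrix over (index, partner, sib_index, sib_partner).
implied_quad_matrix <- function(params) {
  e <- expected_relative_correlations(params)
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- e$r_partner
  R[1, 3] <- R[3, 1] <- e$r_sibling
  R[2, 4] <- R[4, 2] <- e$r_sibling
  R[1, 4] <- R[4, 1] <- e$r_inlaw
  R[2, 3] <- R[3, 2] <- e$r_inlaw
  R[3, 4] <- R[4, 3] <- e$r_cosib
  R
}

#' Simulation design for quad populations
#'
#' Defaults mirror the registry-style study conditions the package is built
#' around: 93,963 couples, a random full sibling observed for about 83.2\% of
#' members on each side (independent thinning), and no additional
#' missingness.
#'
#' @param n_families number of quads (couples) to generate.
#' @param traits list of [trait_spec()] objects; each trait is generated
#'   independently under the same mechanism.
#' @param sibling_availability probability that a member's sibling is
#'   observed, per side.
#' @param missingness per-role missingness rates; scalar or named vector over
#'   [quad_roles()].
#' @param seed integer seed; set before any draws for reproducibility.
#' @return an object of class \code{simulation_design}.
#' @export
simulation_design <- function(n_families = 93963,
                              traits = list(trait_spec("trait", "continuous")),
                              sibling_availability = 156335 / 187926,
                              missingness = 0, seed = NULL) {
  if (n_families < 1) stop("n_families must be at least 1")
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  if (sibling_availability < 0 || sibling_availability > 1)
    stop("sibling_availability must be in [0, 1]")
  miss <- rep(0, 4); names(miss) <- quad_roles()
  if (is.null(names(missingness))) miss[] <- missingness
  else miss[names(missingness)] <- missingness
  if (any(miss < 0 | miss > 1)) stop("missingness rates must be in [0, 1]")
  structure(list(n_families = as.integer(n_families), traits = traits,
                 sibling_availability = sibling_availability,
                 missingness = miss, seed = seed),
            class = "simulation_design")
}

# One trait's standardized quad liabilities under a mechanism.
# `noise(n)` supplies iid mean-0 variance-1 innovations; rnorm gives the
# Gaussian case, skewed innovations give non-Gaussian marginals while linear
# mixing preserves all pairwise Pearson correlations.
sim_chain <- function(params, n, noise = rnorm) {
  mix <- function(base, r) r * base + sqrt(1 - r^2) * noise(n)
  switch(params$mechanism,
    direct = {
      zi <- noise(n)
      zsi <- mix(zi, params$r_s)
      zp <- mix(zi, params$m)
      zsp <- mix(zp, params$r_s)
      cbind(index = zi, partner = zp, sib_index = zsi, sib_partner = zsp)
    },
    indirect = {
      a <- params$a
      Mi <- noise(n); Msi <- mix(Mi, params$r_m)
      Mp <- mix(Mi, params$mu); Msp <- mix(Mp, params$r_m)
      Ei <- noise(n); Esi <- mix(Ei, params$r_e)
      Ep <- noise(n); Esp <- mix(Ep, params$r_e)
      b <- sqrt(1 - a^2)
      cbind(index = a * Mi + b * Ei, partner = a * Mp + b * Ep,
            sib_index = a * Msi + b * Esi, sib_partner = a * Msp + b * Esp)
    },
    stratification = {
      S <- noise(n); q <- params$q; b <- sqrt(1 - q^2)
      cbind(index = q * S + b * noise(n), partner = q * S + b * noise(n),
            sib_index = q * S + b * noise(n), sib_partner = q * S + b * noise(n))
    })
}

# standardized sinh-arcsinh skewed innovations; gamma > 0 stretches the right
# tail (right skew), gamma < 0 the left
sas_noise <- function(gamma) {
  function(n) {
    v <- sinh(asinh(rnorm(n)) + gamma)
    (v - mean(v)) / sd(v)
  }
}

assemble_population <- function(liab, design, params, quantile_method) {
  n <- design$n_families
  roles <- quad_roles()
  pop <- data.frame(family_id = seq_len(n))
  pop$sex_index <- 0L
  pop$sex_partner <- 1L
  pop$sex_sib_index <- rbinom(n, 1, 0.5)
  pop$sex_sib_partner <- rbinom(n, 1, 0.5)
  pop$birth_year_index <- round(rnorm(n, 1988, 3))
  pop$birth_year_partner <- round(rnorm(n, 1986, 3))
  pop$birth_year_sib_index <- round(rnorm(n, 1987, 3))
  pop$birth_year_sib_partner <- round(rnorm(n, 1987, 3))
  # sibling availability + per-role missingness, by independent thinning
  obs <- matrix(TRUE, n, 4, dimnames = list(NULL, roles))
  obs[, "sib_index"] <- runif(n) < design$sibling_availability
  obs[, "sib_partner"] <- runif(n) < design$sibling_availability
  for (role in roles) {
    mr <- design$missingness[[role]]
    if (mr > 0) obs[, role] <- obs[, role] & (runif(n) >= mr)
  }
  for (tr in design$traits) {
    z <- liab[[tr$name]]
    for (role in roles) {
      v <- z[, role]
      v[!obs[, role]] <- NA
      pop[[paste0(tr$name, "_liab_", role)]] <- v
      if (tr$kind == "binary") {
        pop[[paste0(tr$name, "_", role)]] <-
          dichotomize(v, tr$prevalence, method = quantile_method)
      } else {
        pop[[paste0(tr$name, "_", role)]] <- tr$mean + tr$sd * v
      }
    }
  }
  attr(pop, "params") <- params
  attr(pop, "design") <- design
  class(pop) <- c("quad_population", "data.frame")
  pop
}

#' Simulate a quad population under a partner-similarity mechanism
#'
#' Generates standardized Gaussian liabilities for the four quad members by
#' conditional sampling along the family chain (index and sibling first, then
#' the partner through the mechanism's copath, then the partner's sibling),
#' which reproduces the path-traced expected correlations exactly: under
#' direct assortment \eqn{E[r_{inlaw}] = m r_s}; under indirect assortment
#' \eqn{E[r_{partner}] = a^2\mu}, \eqn{E[r_{sibling}] = a^2 r_m + (1-a^2)
#' r_e}, \eqn{E[r_{inlaw}] = a^2 \mu r_m}; under stratification all pairwise
#' correlations equal \eqn{q^2}. Binary traits are dichotomized at the
#' threshold implied by their prevalence; their liabilities are kept in
#' \code{<trait>_liab_<role>} columns.
#'
#' @param params a [mechanism_params()] object.
#' @param design a [simulation_design()] object.
#' @return a \code{quad_population} data frame (wide, role-suffixed columns)
#'   with the generating \code{params} and \code{design} as attributes.
#' @export
simulate_quads <- function(params, design) {
  stopifnot(inherits(params, "mechanism_params"),
            inherits(design, "simulation_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  n <- design$n_families
  liab <- lapply(design$traits, function(tr) sim_chain(params, n))
  names(liab) <- vapply(design$traits, `[[`, "", "name")
  assemble_population(liab, design, params, quantile_method = "population")
}

#' Dichotomize liabilities at a prevalence
#'
#' Returns 1 where the liability exceeds the upper-tail quantile at the
#' stated prevalence, so the expected affected fraction equals
#' \code{prevalence}. The population method uses the standard-normal
#' quantile (appropriate for Gaussian liabilities); the empirical method uses
#' the sample quantile (appropriate for skewed liabilities).
#'
#' @param liabilities numeric vector; missing values propagate.
#' @param prevalence affected proportion, strictly inside (0, 1).
#' @param method "population" or "empirical".
#' @return integer 0/1 vector.
#' @export
dichotomize <- function(liabilities, prevalence,
                        method = c("population", "empirical")) {
  method <- match.arg(method)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be strictly inside (0, 1)")
  thr <- if (method == "population") qnorm(1 - prevalence)
         else quantile(liabilities, 1 - prevalence, na.rm = TRUE, names = FALSE)
  as.integer(liabilities > thr)
}

#' Apply post-formation convergence to a simulated population
#'
#' Adds a couple-shared Gaussian environment with variance \code{n2} to both
#' partners' liabilities and then applies symmetric mutual influence with
#' coefficient \code{x} between the partners, re-standardizing so all
#' liabilities stay on the unit-variance scale. Siblings are untouched, so
#' convergence inflates the partner correlation much more than the in-law
#' correlation and drives the in-law inflation factor below its base value.
#' Binary phenotypes are re-dichotomized from the updated liabilities.
#'
#' @param pop a \code{quad_population}.
#' @param n2 couple-shared environmental variance, \code{>= 0}.
#' @param x mutual-influence coefficient.
#' @return the modified \code{quad_population}.
#' @export
overlay_convergence <- function(pop, n2 = 0, x = 0) {
  stopifnot(inherits(pop, "quad_population"))
  if (n2 < 0) stop("n2 must be nonnegative")
  if (n2 == 0 && x == 0) return(pop)
  design <- attr(pop, "design")
  params <- attr(pop, "params")
  n <- nrow(pop)
  quantile_method <- if (!is.null(params$skew_gamma) && params$skew_gamma != 0)
    "empirical" else "population"
  for (tr in design$traits) {
    zi <- pop[[paste0(tr$name, "_liab_index")]]
    zp <- pop[[paste0(tr$name, "_liab_partner")]]
    C <- sqrt(n2) * rnorm(n)
    zi1 <- zi + C; zp1 <- zp + C
    zi2 <- zi1 + x * zp1
    zp2 <- zp1 + x * zi1
    # exact variance bookkeeping on the unit-variance base scale
    rp <- stats::cov(cbind(zi, zp), use = "complete.obs")[1, 2]
    v <- (1 + n2) * (1 + x^2) + 2 * x * (rp + n2)
    zi2 <- zi2 / sqrt(v); zp2 <- zp2 / sqrt(v)
    pop[[paste0(tr$name, "_liab_index")]] <- zi2
    pop[[paste0(tr$name, "_liab_partner")]] <- zp2
    if (tr$kind == "binary") {
      pop[[paste0(tr$name, "_index")]] <-
        dichotomize(zi2, tr$prevalence, quantile_method)
      pop[[paste0(tr$name, "_partner")]] <-
        dichotomize(zp2, tr$prevalence, quantile_method)
    } else {
      pop[[paste0(tr$name, "_index")]] <- tr$mean + tr$sd * zi2
      pop[[paste0(tr$name, "_partner")]] <- tr$mean + tr$sd * zp2
    }
  }
  params$n2 <- n2; params$x <- x
  attr(pop, "params") <- params
  pop
}

#' Simulate quads with skewed (non-Gaussian) liabilities
#'
#' Generates quad liabilities whose marginal distributions are skewed, for
#' the robustness experiment on the product identity
#' \eqn{r_{ab} r_{bc} = r_{ac}} that underpins the test of direct
#' assortment. Two constructions are offered:
#' \describe{
#'   \item{marginal transform (default)}{a monotone sinh-arcsinh transform
#'   is applied to each member's Gaussian chain liability. The observed
#'   liabilities are skewed and their Pearson correlations are attenuated
#'   relative to the generating chain, so the tetrachoric correlations of
#'   the dichotomized traits overestimate them — yet the product identity
#'   holds, because dichotomizing a monotone transform at a fixed quantile
#'   is dichotomizing the underlying chain.}
#'   \item{innovation skewing (\code{skew_innovations = TRUE})}{the chain's
#'   independent innovations are themselves skewed before linear mixing.
#'   Pearson correlations of the liabilities then satisfy the product
#'   identity exactly while the joint distribution is non-Gaussian; the
#'   tetrachorics acquire pair-specific biases, and the identity holds only
#'   approximately, degrading with the strength of the skew.}
#' }
#' Binary traits are dichotomized at empirical quantiles so prevalences are
#' preserved under skew.
#'
#' @inheritParams simulate_quads
#' @param skew_gamma skewness parameter; negative values give left skew,
#'   0 recovers the Gaussian generator.
#' @param skew_innovations skew the chain innovations instead of the
#'   marginals (see Details).
#' @return a \code{quad_population}.
#' @export
skewed_liability <- function(params, design, skew_gamma = 0,
                             skew_innovations = FALSE) {
  stopifnot(inherits(params, "mechanism_params"),
            inherits(design, "simulation_design"))
  if (!is.finite(skew_gamma)) stop("skew_gamma must be finite")
  if (!is.null(design$seed)) set.seed(design$seed)
  n <- design$n_families
  if (skew_innovations) {
    noise <- if (skew_gamma == 0) rnorm else sas_noise(skew_gamma)
    liab <- lapply(design$traits, function(tr) sim_chain(params, n, noise))
  } else {
    liab <- lapply(design$traits, function(tr) {
      z <- sim_chain(params, n)
      if (skew_gamma != 0)
        z <- apply(z, 2, function(v) {
          w <- sinh(asinh(v) + skew_gamma)
          (w - mean(w)) / sd(w)
        })
      z
    })
  }
  names(liab) <- vapply(design$traits, `[[`, "", "name")
  params$skew_gamma <- skew_gamma
  assemble_population(liab, design, params,
                      quantile_method = if (skew_gamma == 0) "population"
                                        else "empirical")
}

#' Simulate a multitrait quad population with a single latent mating factor
#'
#' Every member carries a latent mating factor M (sibling correlation
#' \code{params$r_m}, partner copath \code{params$mu}); each trait loads on M
#' with its own loading and has a trait-specific residual with its own
#' sibling correlation. Expected partner correlations follow
#' \eqn{a_i \mu a_j} for traits i (female) and j (male), so cross-trait and
#' within-trait partner correlations share one structure. An education-like
#' continuous trait with loading 1 makes partner health similarity flow
#' entirely through the measured education trait.
#'
#' @param traits a data frame with columns \code{name}, \code{kind}
#'   ("binary"/"continuous"), \code{prevalence} (binary), \code{loading}
#'   (on M, in [-1, 1]), and \code{r_sib_resid} (residual sibling
#'   correlation).
#' @param params a [mechanism_params()] of mechanism "indirect" supplying
#'   \code{mu} and \code{r_m} (its \code{a} is ignored; loadings come from
#'   \code{traits}).
#' @param design a [simulation_design()]; its \code{traits} field is ignored
#'   in favour of \code{traits}.
#' @return a \code{quad_population} with one set of role-suffixed columns per
#'   trait.
#' @export
simulate_multitrait <- function(traits, params, design) {
  stopifnot(inherits(params, "mechanism_params"),
            params$mechanism == "indirect",
            inherits(design, "simulation_design"))
  traits <- as.data.frame(traits)
  need <- c("name", "kind", "loading")
  if (!all(need %in% names(traits)))
    stop("traits needs columns name, kind, loading")
  if (is.null(traits$r_sib_resid)) traits$r_sib_resid <- 0
  if (any(abs(traits$loading) > 1)) stop("loadings must be in [-1, 1]")
  if (!is.null(design$seed)) set.seed(design$seed)
  n <- design$n_families
  mix <- function(base, r) r * base + sqrt(1 - r^2) * rnorm(n)
  Mi <- rnorm(n); Msi <- mix(Mi, params$r_m)
  Mp <- mix(Mi, params$mu); Msp <- mix(Mp, params$r_m)
  M <- cbind(index = Mi, partner = Mp, sib_index = Msi, sib_partner = Msp)
  spec_list <- list(); liab <- list()
  for (i in seq_len(nrow(traits))) {
    a <- traits$loading[i]; re <- traits$r_sib_resid[i]; b <- sqrt(1 - a^2)
    Ui <- rnorm(n); Usi <- mix(Ui, re)
    Up <- rnorm(n); Usp <- mix(Up, re)
    z <- a * M + b * cbind(Ui, Up, Usi, Usp)
    colnames(z) <- quad_roles()
    spec_list[[i]] <- if (traits$kind[i] == "binary")
      trait_spec(traits$name[i], "binary", prevalence = traits$prevalence[i])
    else trait_spec(traits$name[i], "continuous")
    liab[[traits$name[i]]] <- z
  }
  design$traits <- spec_list
  attr_params <- params; attr_params$loadings <- traits
  assemble_population(liab, design, attr_params, quantile_method = "population")
}

#' Health-condition prevalences used as simulation defaults
#'
#' Reads the bundled table of 20 primary-care conditions (10 mental, 10
#' somatic) with their sample prevalences, used to calibrate dichotomization
#' thresholds in synthetic populations.
#'
#' @return data frame with columns \code{trait}, \code{category},
#'   \code{prevalence} (proportion).
#' @export
condition_prevalences <- function() {
  path <- system.file("extdata", "condition_prevalences.csv",
                      package = "quadassort", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
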