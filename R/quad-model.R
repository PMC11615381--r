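#' In-law inflation factor
#'
#' The ratio of the observed sibling-in-law correlation to its expectation
#' under direct phenotypic assortment, \eqn{IIF = r_{inlaw} / (r_{sibling}
#' \cdot r_{partner})}. Equals 1 when partner similarity is produced by
#' assortment on the phenotype itself; exceeds 1 under indirect assortment on
#' a correlated latent trait or under social stratification; is pushed below
#' its base value by post-formation convergence.
#'
#' @param r_partner,r_sibling,r_inlaw correlations; vectorized.
#' @return the ratio; \code{NA} where the denominator is zero.
#' @examples
#' iif(0.42, 0.52, 0.29)  # 1.33 to two decimals
#' @export
iif <- function(r_partner, r_sibling, r_inlaw) {
  den <- r_sibling * r_partner
  out <- r_inlaw / den
  out[den == 0] <- NA_real_
  out
}

#' Expected quad correlations under each mechanism
#'
#' Closed-form path-traced expectations for the partner, sibling,
#' sibling-in-law, and co-sibling-in-law correlations, and the implied
#' in-law inflation factor:
#' direct assortment gives \eqn{(m, r_s, m r_s)} and IIF = 1; indirect
#' assortment gives \eqn{(a^2\mu, a^2 r_m + E, a^2\mu r_m)} with
#' \eqn{E = (1-a^2) r_e} and \eqn{IIF = 1/(a^2 + E/r_m)} (so \eqn{1/a^2}
#' when \eqn{r_e = 0}, and exactly 1 when \eqn{r_e = r_m}); social
#' stratification gives \eqn{q^2} for every pair and \eqn{IIF = 1/q^2}.
#'
#' When the params carry nonzero convergence terms and
#' \code{include_convergence} is TRUE, the first-order path contributions are
#' added: \eqn{n^2 + 2xa} to the partner correlation and \eqn{x r_m a} to the
#' in-law correlation (phenotype loading taken as 1 under direct assortment).
#' These sums ignore the re-standardization that [overlay_convergence()]
#' performs, so they are upper-bound approximations for large \code{x}.
#'
#' @param params a [mechanism_params()] object.
#' @param include_convergence add the convergence path contributions?
#' @return list with \code{r_partner}, \code{r_sibling}, \code{r_inlaw},
#'   \code{r_cosib}, \code{iif}.
#' @export
expected_relative_correlations <- function(params, include_convergence = TRUE) {
  stopifnot(inherits(params, "mechanism_params"))
  out <- switch(params$mechanism,
    direct = {
      m <- params$m; rs <- params$r_s
      list(r_partner = m, r_sibling = rs, r_inlaw = m * rs,
           r_cosib = rs * m * rs, a_eff = 1, rm_eff = rs)
    },
    indirect = {
      a <- params$a; mu <- params$mu; rm <- params$r_m
      E <- (1 - a^2) * params$r_e
      list(r_partner = a^2 * mu, r_sibling = a^2 * rm + E,
           r_inlaw = a^2 * mu * rm, r_cosib = a^2 * rm * mu * rm,
           a_eff = a, rm_eff = rm)
    },
    stratification = {
      q2 <- params$q^2
      list(r_partner = q2, r_sibling = q2, r_inlaw = q2, r_cosib = q2,
           a_eff = params$q, rm_eff = q2)
    })
  if (include_convergence && (params$n2 != 0 || params$x != 0)) {
    out$r_partner <- out$r_partner + params$n2 + 2 * params$x * out$a_eff
    out$r_inlaw <- out$r_inlaw + params$x * out$rm_eff * out$a_eff
  }
  out$a_eff <- out$rm_eff <- NULL
  out$iif <- iif(out$r_partner, out$r_sibling, out$r_inlaw)
  out
}

# ---- quad FIML ---------------------------------------------------------------

quad_corr_matrix <- function(rp, rs, ril, rcs) {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- rp
  R[1, 3] <- R[3, 1] <- rs
  R[2, 4] <- R[4, 2] <- rs
  R[1, 4] <- R[4, 1] <- ril
  R[2, 3] <- R[3, 2] <- ril
  R[3, 4] <- R[4, 3] <- rcs
  R
}

# covariate design per role; constant columns dropped (collinear with the
# role intercept: e.g. sex_index never varies)
quad_covariates <- function(quads, adjust, n) {
  if (is.null(adjust)) return(NULL)
  roles <- quad_roles()
  out <- lapply(roles, function(role) {
    cols <- paste0(adjust, "_", role)
    cols <- cols[cols %in% names(quads)]
    if (!length(cols)) return(NULL)
    as_covmat(quads[, cols, drop = FALSE], n, paste0("covariates for ", role))
  })
  names(out) <- roles
  if (all(vapply(out, is.null, TRUE))) NULL else out
}

#' Fit the four-person quad correlation structure
#'
#' Full-information maximum likelihood over the joint distribution of one
#' trait in the four quad members, with the relationship structure
#' (one partner correlation; one sibling correlation shared by the two sides;
#' one sibling-in-law correlation shared by the two sides; a free
#' co-sibling-in-law correlation). Quads with missing members contribute the
#' marginal sub-model of their observed members, so couples without siblings
#' still inform the partner correlation. For continuous traits the likelihood
#' is the multivariate normal density; for binary traits the liability
#' threshold model is used with cell probabilities computed as
#' multivariate-normal rectangle probabilities (deterministic Miwa
#' quadrature). Covariates enter means (continuous) or thresholds (binary)
#' linearly per role; the constrained fit substitutes
#' \eqn{r_{inlaw} = r_{partner} r_{sibling}} by reparameterization, which
#' guarantees exact nesting for the likelihood-ratio test.
#'
#' @param quads wide quad table with columns \code{<trait>_<role>} for the
#'   roles in [quad_roles()].
#' @param trait trait (column prefix) to fit.
#' @param kind "auto" (detect 0/1 coding), "continuous", or "binary".
#' @param constrained impose the direct-assortment product constraint?
#' @param adjust character vector of covariate prefixes (e.g. "sex"), read
#'   from \code{<cov>_<role>} columns.
#' @param se compute observed-information standard errors (free fit only)?
#'   Skipping them speeds up replicate loops.
#' @return a \code{quad_model_fit} with the correlation structure, per-
#'   correlation SEs (free fit), log-likelihood, and convergence flag.
#' @export
fit_quad_model <- function(quads, trait, kind = c("auto", "continuous", "binary"),
                           constrained = FALSE, adjust = NULL, se = TRUE) {
  kind <- match.arg(kind)
  roles <- quad_roles()
  cols <- paste0(trait, "_", roles)
  if (!all(cols %in% names(quads)))
    stop("quad table lacks columns ", paste(setdiff(cols, names(quads)), collapse = ", "))
  Y <- as.matrix(quads[, cols]); colnames(Y) <- roles
  keep <- rowSums(!is.na(Y)) >= 1
  Y <- Y[keep, , drop = FALSE]
  quads <- quads[keep, , drop = FALSE]
  n <- nrow(Y)
  if (n < 10) stop("too few quads with observed members")
  vals <- Y[!is.na(Y)]
  if (kind == "auto")
    kind <- if (all(vals %in% c(0, 1))) "binary" else "continuous"
  if (length(unique(vals)) < 2)
    stop("degenerate data: trait takes a single value (boundary)")
  X <- quad_covariates(quads, adjust, n)

  if (kind == "continuous")
    fit_quad_continuous(Y, X, constrained, trait, se)
  else
    fit_quad_binary(Y, X, constrained, trait, se)
}

# pairwise-complete starting correlations for the four structure parameters
quad_start_corrs <- function(Y) {
  pc <- function(i, j) {
    v <- suppressWarnings(cor(Y[, i], Y[, j], use = "pairwise.complete.obs"))
    if (is.finite(v)) v else 0
  }
  rp <- pc(1, 2)
  rs <- mean(c(pc(1, 3), pc(2, 4)), na.rm = TRUE)
  ril <- mean(c(pc(1, 4), pc(2, 3)), na.rm = TRUE)
  rcs <- pc(3, 4)
  pmin(pmax(c(rp, rs, ril, rcs), -0.95), 0.95)
}

fit_quad_continuous <- function(Y, X, constrained, trait, want_se = TRUE) {
  n <- nrow(Y)
  obs <- !is.na(Y)
  pat <- drop(obs %*% c(1L, 2L, 4L, 8L))
  has_cov <- !is.null(X)
  groups <- split(seq_len(n), pat)
  # sufficient statistics per missingness pattern (covariate-free case)
  stats_list <- NULL
  if (!has_cov) {
    stats_list <- lapply(groups, function(idx) {
      o <- which(obs[idx[1], ])
      Yo <- Y[idx, o, drop = FALSE]
      m <- colMeans(Yo)
      Sc <- crossprod(sweep(Yo, 2, m))
      list(o = o, n = length(idx), m = m, Sc = Sc)
    })
  }
  k_betas <- if (has_cov) vapply(X, function(m) if (is.null(m)) 0L else ncol(m), 0L)
             else integer(4)
  nb <- sum(k_betas)
  nz <- if (constrained) 3L else 4L
  # par: mu(4), betas(nb), log sd(4), z(nz)
  unpack <- function(par) {
    mu <- par[1:4]
    betas <- if (nb) par[5:(4 + nb)] else numeric(0)
    lsd <- par[(5 + nb):(8 + nb)]
    z <- par[(9 + nb):(8 + nb + nz)]
    r <- tanh(z)
    if (constrained) r <- c(r[1], r[2], r[1] * r[2], r[3])
    list(mu = mu, betas = betas, sd = exp(lsd), r = r)
  }
  negll <- function(par) {
    p <- unpack(par)
    R <- quad_corr_matrix(p$r[1], p$r[2], p$r[3], p$r[4])
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) return(1e10)  # PSD barrier: reject the proposal
    M <- matrix(rep(p$mu, each = n), n, 4)
    if (has_cov) {
      off <- 0L
      for (j in 1:4) {
        if (k_betas[j] > 0) {
          M[, j] <- M[, j] + drop(X[[j]] %*% p$betas[(off + 1):(off + k_betas[j])])
          off <- off + k_betas[j]
        }
      }
    }
    total <- 0
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      o <- which(obs[idx[1], ])
      k <- length(o)
      So <- diag(p$sd[o], k) %*% R[o, o, drop = FALSE] %*% diag(p$sd[o], k)
      cho <- tryCatch(chol(So), error = function(e) NULL)
      if (is.null(cho)) return(1e10)
      logdet <- 2 * sum(log(diag(cho)))
      inv <- chol2inv(cho)
      if (!has_cov) {
        st <- stats_list[[g]]
        d <- st$m - p$mu[o]
        total <- total - 0.5 * (st$n * (k * log(2 * pi) + logdet) +
                                  sum(inv * st$Sc) +
                                  st$n * drop(t(d) %*% inv %*% d))
      } else {
        Rm <- Y[idx, o, drop = FALSE] - M[idx, o, drop = FALSE]
        Q <- rowSums((Rm %*% inv) * Rm)
        total <- total - 0.5 * (length(idx) * (k * log(2 * pi) + logdet) + sum(Q))
      }
    }
    finite_or_big(-total)
  }
  mu0 <- colMeans(Y, na.rm = TRUE)
  sd0 <- apply(Y, 2, sd, na.rm = TRUE)
  r0 <- quad_start_corrs(Y)
  z0 <- atanh(if (constrained) r0[c(1, 2, 4)] else r0)
  start <- c(mu0, rep(0, nb), log(sd0), z0)
  fit <- run_nlminb(negll, start)
  p <- unpack(fit$par)
  finish_quad_fit(fit, negll, p, n, trait, "continuous", constrained, nb, want_se)
}

fit_quad_binary <- function(Y, X, constrained, trait, want_se = TRUE) {
  n <- nrow(Y)
  obs <- !is.na(Y)
  # covariate combos must be categorical and few: thresholds are shared
  # within a (pattern, response, combo) cell
  combo <- rep("", n)
  Xc <- NULL
  if (!is.null(X)) {
    Xc <- do.call(cbind, X[!vapply(X, is.null, TRUE)])
    combo <- apply(Xc, 1, paste, collapse = "|")
    if (length(unique(combo)) > 64)
      stop("binary quad FIML supports only low-cardinality (categorical) covariates")
  }
  resp <- apply(Y, 1, function(v) paste(ifelse(is.na(v), ".", v), collapse = ""))
  key <- paste(resp, combo, sep = "@")
  groups <- split(seq_len(n), key)
  ginfo <- lapply(groups, function(idx) {
    i <- idx[1]
    list(n = length(idx), y = Y[i, ], o = which(obs[i, ]),
         x = if (is.null(Xc)) NULL else Xc[i, ])
  })
  k_betas <- if (!is.null(X)) vapply(X, function(m) if (is.null(m)) 0L else ncol(m), 0L)
             else integer(4)
  nb <- sum(k_betas)
  nz <- if (constrained) 3L else 4L
  unpack <- function(par) {
    tau <- par[1:4]
    betas <- if (nb) par[5:(4 + nb)] else numeric(0)
    z <- par[(5 + nb):(4 + nb + nz)]
    r <- tanh(z)
    if (constrained) r <- c(r[1], r[2], r[1] * r[2], r[3])
    list(tau = tau, betas = betas, r = r)
  }
  role_tau <- function(p, g) {
    tau <- p$tau
    if (nb) {
      off <- 0L
      for (j in 1:4) {
        if (k_betas[j] > 0) {
          xj <- g$x[(off + 1):(off + k_betas[j])]
          tau[j] <- tau[j] + sum(xj * p$betas[(off + 1):(off + k_betas[j])])
          off <- off + k_betas[j]
        }
      }
    }
    tau
  }
  negll <- function(par) {
    p <- unpack(par)
    R <- quad_corr_matrix(p$r[1], p$r[2], p$r[3], p$r[4])
    if (inherits(tryCatch(chol(R), error = function(e) e), "error")) return(1e10)
    total <- 0
    for (g in ginfo) {
      tau <- role_tau(p, g)
      o <- g$o; k <- length(o)
      y <- g$y[o]; t_o <- tau[o]
      if (k == 1) {
        pr <- if (y == 1) pnorm(t_o, lower.tail = FALSE) else pnorm(t_o)
      } else if (k == 2) {
        P11 <- bivariate_upper_orthant(t_o[1], t_o[2], R[o[1], o[2]])
        q1 <- pnorm(t_o[1], lower.tail = FALSE)
        q2 <- pnorm(t_o[2], lower.tail = FALSE)
        pr <- if (y[1] == 1 && y[2] == 1) P11
              else if (y[1] == 1) q1 - P11
              else if (y[2] == 1) q2 - P11
              else 1 - q1 - q2 + P11
      } else {
        lower <- ifelse(y == 1, t_o, -Inf)
        upper <- ifelse(y == 1, Inf, t_o)
        pr <- mvtnorm::pmvnorm(lower = lower, upper = upper,
                               corr = R[o, o, drop = FALSE],
                               algorithm = mvtnorm::Miwa(steps = 128))[1]
      }
      total <- total + g$n * log(clamp_prob(pr))
    }
    finite_or_big(-total)
  }
  p_role <- colMeans(Y, na.rm = TRUE)
  tau0 <- qnorm(1 - pmin(pmax(p_role, 1e-4), 1 - 1e-4))
  r0 <- quad_start_corrs(Y) * 1.3
  r0 <- pmin(pmax(r0, -0.9), 0.9)
  z0 <- atanh(if (constrained) r0[c(1, 2, 4)] else r0)
  start <- c(tau0, rep(0, nb), z0)
  fit <- run_nlminb(negll, start)
  p <- unpack(fit$par)
  finish_quad_fit(fit, negll, p, n, trait, "binary", constrained, nb, want_se)
}

finish_quad_fit <- function(fit, negll, p, n, trait, kind, constrained, nb, want_se = TRUE) {
  r <- p$r
  names(r) <- c("r_partner", "r_sibling", "r_inlaw", "r_cosib")
  boundary <- any(abs(r) > 0.999)
  ok <- nlminb_converged(fit)
  se <- rep(NA_real_, 4); names(se) <- names(r)
  if (!constrained && want_se) {
    H <- tryCatch(numDeriv::hessian(negll, fit$par,
                                    method.args = list(r = 2)),
                  error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        nz_idx <- (length(fit$par) - 3):length(fit$par)
        vz <- diag(V)[nz_idx]
        se <- ifelse(vz > 0, (1 - r^2) * sqrt(vz), NA_real_)
        names(se) <- names(r)
      }
    }
  }
  structure(list(
    trait = trait, kind = kind,
    structure = c(as.list(r), list(constrained = constrained)),
    se = se, loglik = -fit$objective, n_quads = n,
    converged = ok && !boundary, boundary = boundary,
    par = fit$par
  ), class = "quad_model_fit")
}

#' @export
print.quad_model_fit <- function(x, ...) {
  s <- x$structure
  cat(sprintf("<quad_model_fit> %s (%s%s)\n", x$trait, x$kind,
              if (s$constrained) ", constrained r_inlaw = r_partner*r_sibling" else ""))
  cat(sprintf("  r_partner = %.4f  r_sibling = %.4f  r_inlaw = %.4f  r_cosib = %.4f\n",
              s$r_partner, s$r_sibling, s$r_inlaw, s$r_cosib))
  cat(sprintf("  loglik = %.2f on %d quads, converged = %s\n",
              x$loglik, x$n_quads, x$converged))
  invisible(x)
}

#' Likelihood-ratio test of direct assortment
#'
#' Compares the free quad fit to the fit constrained to
#' \eqn{r_{inlaw} = r_{partner} r_{sibling}} (the direct-assortment
#' prediction) with a 1-degree-of-freedom chi-square test, and attaches the
#' in-law inflation factor computed from the free fit. A small p-value means
#' direct assortment fits poorly.
#'
#' @param free,constrained \code{quad_model_fit}s of the same trait on the
#'   same data, free and constrained respectively.
#' @return a \code{direct_assortment_test} with \code{iif},
#'   \code{lrt_stat}, \code{df = 1}, \code{p_raw} (and a \code{p_bh} slot
#'   filled when tests are collected across traits).
#' @export
lrt_direct_assortment <- function(free, constrained) {
  stopifnot(inherits(free, "quad_model_fit"),
            inherits(constrained, "quad_model_fit"))
  if (free$structure$constrained || !constrained$structure$constrained)
    stop("arguments must be (free fit, constrained fit)")
  if (free$trait != constrained$trait || free$n_quads != constrained$n_quads)
    stop("fits must share trait and data")
  stat <- 2 * (free$loglik - constrained$loglik)
  if (stat < -0.05)
    stop("constrained log-likelihood exceeds the free fit: refit needed")
  stat <- max(0, stat)
  s <- free$structure
  structure(list(
    trait = free$trait,
    iif = iif(s$r_partner, s$r_sibling, s$r_inlaw),
    lrt_stat = stat, df = 1L,
    p_raw = pchisq(stat, df = 1, lower.tail = FALSE),
    p_bh = NA_real_
  ), class = "direct_assortment_test")
}

#' @export
print.direct_assortment_test <- function(x, ...) {
  cat(sprintf("<direct_assortment_test> %s: IIF = %.2f, LRT(1) = %.3f, p = %.3g\n",
              x$trait, x$iif, x$lrt_stat, x$p_raw))
  invisible(x)
}

#' Joint likelihood-ratio test of equal correlations across two sets
#'
#' Tests whether each trait's correlation is equal across two independently
#' estimated sets (e.g. prospective vs cross-sectional observation windows).
#' For each trait the constrained fit maximizes the summed profile
#' log-likelihoods over a common correlation; the statistic sums over traits
#' with one degree of freedom per equality constraint.
#'
#' @param fits_a,fits_b named lists of \code{cor_estimate}s over the same
#'   traits (single estimates are accepted).
#' @return list with \code{stat}, \code{df}, \code{p}, and a per-trait table.
#' @export
lrt_equal_correlations <- function(fits_a, fits_b) {
  if (inherits(fits_a, "cor_estimate")) fits_a <- list(fits_a)
  if (inherits(fits_b, "cor_estimate")) fits_b <- list(fits_b)
  if (length(fits_a) != length(fits_b))
    stop("the two sets must cover the same traits")
  if (!is.null(names(fits_a)) && !is.null(names(fits_b))) {
    if (!setequal(names(fits_a), names(fits_b)))
      stop("the two sets must cover the same traits")
    fits_b <- fits_b[names(fits_a)]
  }
  per <- lapply(seq_along(fits_a), function(i) {
    ea <- fits_a[[i]]; eb <- fits_b[[i]]
    ll_free <- ea$loglik + eb$loglik
    obj <- function(z) {
      r <- tanh(z)
      -(profile_loglik(ea, r) + profile_loglik(eb, r))
    }
    z0 <- atanh(mean(c(ea$r, eb$r)) * 0.999)
    opt <- optim(z0, obj, method = "Brent", lower = -4, upper = 4)
    stat <- max(0, 2 * (ll_free + opt$value))  # opt$value = -ll_constrained
    c(stat = stat, r_common = tanh(opt$par))
  })
  stats <- vapply(per, `[[`, 0, "stat")
  df <- length(stats)
  total <- sum(stats)
  list(stat = total, df = df,
       p = pchisq(total, df = df, lower.tail = FALSE),
       per_trait = data.frame(
         trait = if (is.null(names(fits_a))) seq_along(fits_a) else names(fits_a),
         stat = stats,
         r_common = vapply(per, `[[`, 0, "r_common")))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, delegated to
#' \code{stats::p.adjust(method = "BH")} after input validation.
#'
#' @param pvalues numeric vector of p-values in \eqn{[0, 1]} (NA allowed).
#' @return adjusted p-values, element-wise \code{>=} the input.
#' @export
bh_adjust <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
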