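#' Trait specification
#'
#' Describes a phenotype used by the estimators and simulators. Binary traits
#' are modelled as dichotomized latent liabilities: affected (coded 1) means
#' the standard-normal liability exceeded the upper-tail threshold implied by
#' \code{prevalence}. Continuous traits carry a mean and standard deviation.
#'
#' @param name trait identifier.
#' @param kind "binary" or "continuous".
#' @param prevalence affected proportion, strictly inside (0, 1); binary only.
#' @param mean,sd marginal moments; continuous only, \code{sd > 0}.
#' @return an object of class \code{trait_spec}.
#' @export
trait_spec <- function(name, kind = c("binary", "continuous"),
                       prevalence = NULL, mean = 0, sd = 1) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1)
      stop("binary traits need a prevalence strictly inside (0, 1)")
  } else {
    if (!is.null(sd) && sd <= 0) stop("sd must be positive")
  }
  structure(list(name = name, kind = kind, prevalence = prevalence,
                 mean = mean, sd = sd),
            class = "trait_spec")
}

#' @export
print.trait_spec <- function(x, ...) {
  if (x$kind == "binary")
    cat(sprintf("<trait_spec> %s: binary, prevalence %.4g (threshold %.3f)\n",
                x$name, x$prevalence, qnorm(1 - x$prevalence)))
  else
    cat(sprintf("<trait_spec> %s: continuous, mean %.3g, sd %.3g\n",
                x$name, x$mean, x$sd))
  invisible(x)
}

# ---- shared FIML machinery ---------------------------------------------------

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1)

# nlminb warns on NA/NaN objective evaluations; return a finite penalty
finite_or_big <- function(v) if (is.finite(v)) v else 1e10

as_covmat <- function(cov, n, what) {
  if (is.null(cov)) return(NULL)
  cov <- as.matrix(cov)
  if (nrow(cov) != n) stop(what, " must have one row per observation")
  storage.mode(cov) <- "double"
  # constant columns are collinear with the intercept/baseline threshold
  keep <- apply(cov, 2, function(v) length(unique(v[is.finite(v)])) > 1)
  if (!any(keep)) return(NULL)
  cov[, keep, drop = FALSE]
}

check_binary <- function(v, what) {
  bad <- !is.na(v) & !(v %in% c(0, 1))
  if (any(bad)) stop(what, " must be coded 0/1 (1 = affected) or missing")
  v
}

# Maximize a negative log-likelihood; observed-information SEs; CI by the
# delta method on the atanh scale (the correlation is parameterized as
# z = atanh(r) internally, which keeps the optimizer off the +/-1 boundary).
fiml_finish <- function(negll, par, z_index, n_pairs, method, fit,
                        boundary_tol = 0.999) {
  z <- par[z_index]
  r <- tanh(z)
  H <- tryCatch(numDeriv::hessian(negll, par), error = function(e) NULL)
  se_z <- NA_real_
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && is.finite(V[z_index, z_index]) && V[z_index, z_index] > 0)
      se_z <- sqrt(V[z_index, z_index])
  }
  se <- (1 - r^2) * se_z
  ci <- tanh(z + c(-1, 1) * 1.96 * se_z)
  p <- if (is.finite(se_z)) 2 * pnorm(-abs(z / se_z)) else NA_real_
  boundary <- abs(r) > boundary_tol
  ok <- nlminb_converged(fit)
  est <- list(
    r = r, se = se, ci95 = ci, method = method, n_pairs = n_pairs,
    loglik = -fit$objective, p = p,
    converged = ok && !boundary,
    boundary = boundary,
    par = par, z_index = z_index, negll = negll
  )
  class(est) <- "cor_estimate"
  est
}

run_nlminb <- function(negll, start) {
  ctrl <- list(rel.tol = 1e-10, abs.tol = 1e-12,
               iter.max = 500, eval.max = 2000)
  fit <- nlminb(start, negll, control = ctrl)
  # restart from the solution: finite-difference gradients can trigger
  # premature or mislabelled "false convergence" on large-n objectives.
  # A restart that cannot improve the objective certifies stationarity.
  fit$restart_stable <- FALSE
  for (pass in 1:2) {
    refit <- nlminb(fit$par, negll, control = ctrl)
    tol <- 1e-9 * max(1, abs(fit$objective))
    if (refit$objective < fit$objective - tol) {
      refit$restart_stable <- FALSE
      fit <- refit
    } else {
      fit$restart_stable <- TRUE
      break
    }
  }
  fit
}

nlminb_converged <- function(fit) {
  msg <- if (is.null(fit$message)) "" else fit$message
  fit$convergence == 0 || isTRUE(fit$restart_stable) ||
    grepl("relative convergence|X-convergence|absolute function convergence",
          msg)
}

#' @export
print.cor_estimate <- function(x, ...) {
  cat(sprintf("<cor_estimate> %s r = %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$method, x$r, x$se, x$ci95[1], x$ci95[2]))
  cat(sprintf("  n_pairs = %d, loglik = %.2f, converged = %s%s\n",
              x$n_pairs, x$loglik, x$converged,
              if (isTRUE(x$boundary)) " (boundary)" else ""))
  invisible(x)
}

#' Profile log-likelihood of a fitted correlation at a fixed value
#'
#' Re-maximizes the estimator's likelihood over the nuisance parameters
#' (thresholds, means, variances, covariate slopes) with the correlation held
#' fixed. Used by [lrt_equal_correlations()] to fit equality-constrained
#' models without refitting from raw data.
#'
#' @param est a \code{cor_estimate}.
#' @param r correlation at which to profile, inside (-1, 1).
#' @return the profiled log-likelihood (a scalar).
#' @export
profile_loglik <- function(est, r) {
  stopifnot(inherits(est, "cor_estimate"), abs(r) < 1)
  z <- atanh(r)
  zi <- est$z_index
  if (length(est$par) == 1L) return(-est$negll(z))
  start <- est$par[-zi]
  wrap <- function(q) {
    full <- numeric(length(est$par))
    full[-zi] <- q
    full[zi] <- z
    est$negll(full)
  }
  -run_nlminb(wrap, start)$objective
}

# ---- tetrachoric -------------------------------------------------------------

#' Tetrachoric correlation by full-information maximum likelihood
#'
#' Estimates the latent liability correlation between two binary phenotypes
#' under the liability-threshold model. Each complete pair contributes its
#' 2x2 cell probability, built from [bivariate_upper_orthant()]; pairs where
#' one member is missing contribute that member's marginal probit likelihood,
#' so all available data are used. Covariates ("definition variables") enter
#' the thresholds linearly with estimated slopes; the correlation itself is
#' covariate-free.
#'
#' @param x,y binary vectors coded 0/1 (1 = affected), missing allowed.
#' @param covariates_x,covariates_y optional numeric covariate matrices
#'   shifting each member's threshold, one row per observation.
#' @param two_stage if TRUE, thresholds are fixed by probit inversion of the
#'   margins and only the correlation is profiled (fast mode; only available
#'   without covariates). Default is joint FIML.
#' @return a \code{cor_estimate} with \code{method = "tetrachoric"}.
#' @export
estimate_tetrachoric <- function(x, y, covariates_x = NULL, covariates_y = NULL,
                                 two_stage = FALSE) {
  x <- check_binary(x, "x"); y <- check_binary(y, "y")
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !(is.na(x) & is.na(y))
  n <- length(x)
  cx <- as_covmat(covariates_x, n, "covariates_x")
  cy <- as_covmat(covariates_y, n, "covariates_y")
  x <- x[keep]; y <- y[keep]
  if (!is.null(cx)) cx <- cx[keep, , drop = FALSE]
  if (!is.null(cy)) cy <- cy[keep, , drop = FALSE]
  n_pairs <- sum(!is.na(x) & !is.na(y))

  both <- !is.na(x) & !is.na(y)
  if (sum(both) < 2) stop("degenerate table: too few complete pairs")
  tab <- table(factor(x[both], 0:1), factor(y[both], 0:1))
  if (sum(tab > 0) < 2 || all(rowSums(tab) == 0) ||
      length(unique(x[both])) < 2 || length(unique(y[both])) < 2)
    stop("degenerate table: a margin has a single observed level")

  p1 <- mean(x, na.rm = TRUE); p2 <- mean(y, na.rm = TRUE)
  t1_start <- qnorm(1 - min(max(p1, 1e-4), 1 - 1e-4))
  t2_start <- qnorm(1 - min(max(p2, 1e-4), 1 - 1e-4))
  r_start <- min(max(cor(x[both], y[both]) * 1.2, -0.9), 0.9)
  if (!is.finite(r_start)) r_start <- 0

  if (is.null(cx) && is.null(cy)) {
    # aggregated-counts path
    n11 <- tab["1", "1"]; n10 <- tab["1", "0"]
    n01 <- tab["0", "1"]; n00 <- tab["0", "0"]
    xo <- !is.na(x) & is.na(y); yo <- is.na(x) & !is.na(y)
    kx1 <- sum(x[xo] == 1); kx0 <- sum(x[xo] == 0)
    ky1 <- sum(y[yo] == 1); ky0 <- sum(y[yo] == 0)
    cell_negll <- function(t1, t2, r) {
      P11 <- bivariate_upper_orthant(t1, t2, r)
      q1 <- pnorm(t1, lower.tail = FALSE)
      q2 <- pnorm(t2, lower.tail = FALSE)
      P10 <- clamp_prob(q1 - P11); P01 <- clamp_prob(q2 - P11)
      P00 <- clamp_prob(1 - q1 - q2 + P11); P11 <- clamp_prob(P11)
      finite_or_big(
        -(n11 * log(P11) + n10 * log(P10) + n01 * log(P01) + n00 * log(P00) +
            kx1 * log(clamp_prob(q1)) + kx0 * log(clamp_prob(1 - q1)) +
            ky1 * log(clamp_prob(q2)) + ky0 * log(clamp_prob(1 - q2))))
    }
    if (two_stage) {
      t1 <- qnorm(1 - p1); t2 <- qnorm(1 - p2)
      negll <- function(par) cell_negll(t1, t2, tanh(par[1]))
      fit <- run_nlminb(negll, atanh(r_start))
      return(fiml_finish(negll, fit$par, 1L, n_pairs, "tetrachoric", fit))
    }
    negll <- function(par) cell_negll(par[1], par[2], tanh(par[3]))
    fit <- run_nlminb(negll, c(t1_start, t2_start, atanh(r_start)))
    return(fiml_finish(negll, fit$par, 3L, n_pairs, "tetrachoric", fit))
  }

  if (two_stage) stop("two-stage mode requires no covariates")
  k1 <- if (is.null(cx)) 0L else ncol(cx)
  k2 <- if (is.null(cy)) 0L else ncol(cy)
  xobs <- !is.na(x); yobs <- !is.na(y)
  negll <- function(par) {
    t1 <- par[1] + if (k1) drop(cx %*% par[2:(1 + k1)]) else 0
    t2 <- par[2 + k1] + if (k2) drop(cy %*% par[(3 + k1):(2 + k1 + k2)]) else 0
    r <- tanh(par[3 + k1 + k2])
    ll <- numeric(length(x))
    b <- xobs & yobs
    if (any(b)) {
      P11 <- bivariate_upper_orthant(t1[b], t2[b], r)
      q1 <- pnorm(t1[b], lower.tail = FALSE)
      q2 <- pnorm(t2[b], lower.tail = FALSE)
      pv <- ifelse(x[b] == 1 & y[b] == 1, P11,
            ifelse(x[b] == 1, q1 - P11,
            ifelse(y[b] == 1, q2 - P11, 1 - q1 - q2 + P11)))
      ll[b] <- log(clamp_prob(pv))
    }
    mx <- xobs & !yobs
    if (any(mx)) {
      q <- pnorm(t1[mx], lower.tail = FALSE)
      ll[mx] <- log(clamp_prob(ifelse(x[mx] == 1, q, 1 - q)))
    }
    my <- !xobs & yobs
    if (any(my)) {
      q <- pnorm(t2[my], lower.tail = FALSE)
      ll[my] <- log(clamp_prob(ifelse(y[my] == 1, q, 1 - q)))
    }
    finite_or_big(-sum(ll))
  }
  start <- c(t1_start, rep(0, k1), t2_start, rep(0, k2), atanh(r_start))
  fit <- run_nlminb(negll, start)
  fiml_finish(negll, fit$par, 3L + k1 + k2, n_pairs, "tetrachoric", fit)
}

# ---- polyserial --------------------------------------------------------------

#' Polyserial correlation by full-information maximum likelihood
#'
#' Latent correlation between a continuous phenotype and the liability
#' underlying a binary phenotype. Per complete pair the likelihood is the
#' normal density of the continuous member times the conditional probit
#' probability of the binary member given the continuous score; incomplete
#' pairs contribute their observed member's marginal. Covariates enter the
#' continuous mean and the binary threshold linearly.
#'
#' @param x continuous vector (missing allowed).
#' @param y binary vector coded 0/1 (missing allowed).
#' @param covariates_x,covariates_y optional covariate matrices for the mean
#'   of \code{x} and the threshold of \code{y}.
#' @return a \code{cor_estimate} with \code{method = "polyserial"}.
#' @export
estimate_polyserial <- function(x, y, covariates_x = NULL, covariates_y = NULL) {
  y <- check_binary(y, "y")
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !(is.na(x) & is.na(y))
  n <- length(x)
  cx <- as_covmat(covariates_x, n, "covariates_x")
  cy <- as_covmat(covariates_y, n, "covariates_y")
  x <- x[keep]; y <- y[keep]
  if (!is.null(cx)) cx <- cx[keep, , drop = FALSE]
  if (!is.null(cy)) cy <- cy[keep, , drop = FALSE]
  if (sd(x, na.rm = TRUE) == 0 || !is.finite(sd(x, na.rm = TRUE)))
    stop("continuous trait has zero variance")
  xobs <- !is.na(x); yobs <- !is.na(y)
  n_pairs <- sum(xobs & yobs)
  k1 <- if (is.null(cx)) 0L else ncol(cx)
  k2 <- if (is.null(cy)) 0L else ncol(cy)
  py <- mean(y, na.rm = TRUE)
  b0 <- xobs & yobs
  r_start <- suppressWarnings(cor(x[b0], y[b0]))
  if (!is.finite(r_start)) r_start <- 0
  # point-biserial start, de-attenuated toward the latent scale
  tau0 <- qnorm(1 - min(max(py, 1e-4), 1 - 1e-4))
  r_start <- min(max(r_start * sqrt(py * (1 - py)) / dnorm(tau0), -0.95), 0.95)

  negll <- function(par) {
    mu <- par[1] + if (k1) drop(cx %*% par[2:(1 + k1)]) else 0
    sig <- exp(par[2 + k1])
    tau <- par[3 + k1] + if (k2) drop(cy %*% par[(4 + k1):(3 + k1 + k2)]) else 0
    r <- tanh(par[4 + k1 + k2])
    ll <- numeric(length(x))
    b <- xobs & yobs
    mu_v <- rep_len(mu, length(x)); tau_v <- rep_len(tau, length(x))
    if (any(b)) {
      z <- (x[b] - mu_v[b]) / sig
      q <- (r * z - tau_v[b]) / sqrt(1 - r^2)
      ll[b] <- dnorm(x[b], mu_v[b], sig, log = TRUE) +
        ifelse(y[b] == 1, pnorm(q, log.p = TRUE),
               pnorm(q, lower.tail = FALSE, log.p = TRUE))
    }
    mx <- xobs & !yobs
    if (any(mx)) ll[mx] <- dnorm(x[mx], mu_v[mx], sig, log = TRUE)
    my <- !xobs & yobs
    if (any(my)) {
      q <- pnorm(tau_v[my], lower.tail = FALSE)
      ll[my] <- log(clamp_prob(ifelse(y[my] == 1, q, 1 - q)))
    }
    finite_or_big(-sum(ll))
  }
  start <- c(mean(x, na.rm = TRUE), rep(0, k1), log(sd(x, na.rm = TRUE)),
             tau0, rep(0, k2), atanh(r_start))
  fit <- run_nlminb(negll, start)
  fiml_finish(negll, fit$par, 4L + k1 + k2, n_pairs, "polyserial", fit)
}

# ---- Pearson (bivariate-normal FIML) ----------------------------------------

#' Pearson correlation by bivariate-normal full-information maximum likelihood
#'
#' With complete data and no covariates the maximum-likelihood estimate is the
#' textbook sample correlation, computed in closed form. With missing values
#' or covariate-adjusted means the bivariate-normal likelihood is maximized
#' numerically; singleton members contribute their marginal density.
#'
#' @param x,y continuous vectors, missing allowed.
#' @param covariates_x,covariates_y optional covariate matrices for the means.
#' @return a \code{cor_estimate} with \code{method = "pearson"}.
#' @export
estimate_pearson <- function(x, y, covariates_x = NULL, covariates_y = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !(is.na(x) & is.na(y))
  n <- length(x)
  cx <- as_covmat(covariates_x, n, "covariates_x")
  cy <- as_covmat(covariates_y, n, "covariates_y")
  x <- x[keep]; y <- y[keep]
  if (!is.null(cx)) cx <- cx[keep, , drop = FALSE]
  if (!is.null(cy)) cy <- cy[keep, , drop = FALSE]
  xobs <- !is.na(x); yobs <- !is.na(y)
  n_pairs <- sum(xobs & yobs)
  if (n_pairs < 3) stop("fewer than 3 complete pairs")
  k1 <- if (is.null(cx)) 0L else ncol(cx)
  k2 <- if (is.null(cy)) 0L else ncol(cy)

  complete <- all(xobs & yobs)
  if (complete && k1 == 0 && k2 == 0) {
    # closed-form MLE: sample moments (n denominators), r = sample correlation
    r <- cor(x, y)
    if (abs(r) > 0.999) {
      warning("correlation at the +/-1 boundary; estimate flagged")
      r <- sign(r) * 0.999
    }
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    negll <- function(par) {
      mu1 <- par[1]; mu2 <- par[2]; s1 <- exp(par[3]); s2 <- exp(par[4])
      rr <- tanh(par[5])
      S11 <- vx + (mx - mu1)^2; S22 <- vy + (my - mu2)^2
      S12 <- mean((x - mx) * (y - my)) + (mx - mu1) * (my - mu2)
      det <- s1^2 * s2^2 * (1 - rr^2)
      quad <- (S11 / s1^2 - 2 * rr * S12 / (s1 * s2) + S22 / s2^2) / (1 - rr^2)
      n_pairs * (log(2 * pi) + 0.5 * log(det) + 0.5 * quad)
    }
    par <- c(mx, my, 0.5 * log(vx), 0.5 * log(vy), atanh(r))
    fit <- list(objective = negll(par), convergence = 0L, par = par,
                message = "closed form")
    est <- fiml_finish(negll, par, 5L, n_pairs, "pearson", fit)
    est$r <- cor(x, y)  # exact, not round-tripped through tanh(atanh())
    if (abs(est$r) > 0.999) { est$converged <- FALSE; est$boundary <- TRUE }
    return(est)
  }

  negll <- function(par) {
    mu1 <- par[1] + if (k1) drop(cx %*% par[2:(1 + k1)]) else 0
    mu2 <- par[2 + k1] + if (k2) drop(cy %*% par[(3 + k1):(2 + k1 + k2)]) else 0
    s1 <- exp(par[3 + k1 + k2]); s2 <- exp(par[4 + k1 + k2])
    r <- tanh(par[5 + k1 + k2])
    mu1 <- rep_len(mu1, length(x)); mu2 <- rep_len(mu2, length(x))
    ll <- numeric(length(x))
    b <- xobs & yobs
    if (any(b)) {
      z1 <- (x[b] - mu1[b]) / s1; z2 <- (y[b] - mu2[b]) / s2
      ll[b] <- -log(2 * pi) - log(s1) - log(s2) - 0.5 * log(1 - r^2) -
        (z1^2 - 2 * r * z1 * z2 + z2^2) / (2 * (1 - r^2))
    }
    mx_ <- xobs & !yobs
    if (any(mx_)) ll[mx_] <- dnorm(x[mx_], mu1[mx_], s1, log = TRUE)
    my_ <- !xobs & yobs
    if (any(my_)) ll[my_] <- dnorm(y[my_], mu2[my_], s2, log = TRUE)
    finite_or_big(-sum(ll))
  }
  b0 <- xobs & yobs
  r0 <- suppressWarnings(cor(x[b0], y[b0])); if (!is.finite(r0)) r0 <- 0
  r0 <- min(max(r0, -0.99), 0.99)
  start <- c(mean(x, na.rm = TRUE), rep(0, k1), mean(y, na.rm = TRUE), rep(0, k2),
             log(sd(x, na.rm = TRUE)), log(sd(y, na.rm = TRUE)), atanh(r0))
  fit <- run_nlminb(negll, start)
  fiml_finish(negll, fit$par, 5L + k1 + k2, n_pairs, "pearson", fit)
}

#' Dispatch a pairwise correlation estimate on trait kinds
#'
#' Chooses tetrachoric (binary-binary), polyserial (continuous-binary, either
#' order), or Pearson (continuous-continuous), mirroring the convention of
#' using the liability scale wherever a binary outcome is involved.
#'
#' @param x,y phenotype vectors.
#' @param kind_x,kind_y "binary" or "continuous".
#' @inheritParams estimate_tetrachoric
#' @return a \code{cor_estimate}.
#' @export
estimate_pair_correlation <- function(x, y, kind_x, kind_y,
                                      covariates_x = NULL, covariates_y = NULL) {
  kinds <- c(kind_x, kind_y)
  if (all(kinds == "binary"))
    estimate_tetrachoric(x, y, covariates_x, covariates_y)
  else if (all(kinds == "continuous"))
    estimate_pearson(x, y, covariates_x, covariates_y)
  else if (kind_x == "continuous")
    estimate_polyserial(x, y, covariates_x, covariates_y)
  else {
    est <- estimate_polyserial(y, x, covariates_y, covariates_x)
    est
  }
}

#' Percent reduction of a correlation after covariate adjustment
#'
#' \code{100 * (1 - r_adjusted / r_unadjusted)}. Note that applying this to
#' correlations already rounded for display can differ from a reduction
#' computed on unrounded estimates: e.g. rounded inputs (0.14, 0.10) give
#' 28.6\% where unrounded medians may give a nearby but different figure.
#'
#' @param r_unadjusted,r_adjusted correlations; \code{r_unadjusted} nonzero.
#' @return percentage; \code{NA} when \code{r_unadjusted} is zero.
#' @export
percent_reduction <- function(r_unadjusted, r_adjusted) {
  out <- 100 * (1 - r_adjusted / r_unadjusted)
  out[r_unadjusted == 0] <- NA_real_
  out
}
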