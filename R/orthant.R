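# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch. Cached per order.
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- seq_len(n - 1)
    b <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- b
    J[cbind(k + 1, k)] <- b
    e <- eigen(J, symmetric = TRUE)
    out <- list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
    cache[[key]] <<- out
    out
  }
})

# Vectorized standard bivariate normal CDF P(Z1 <= h, Z2 <= k; r), scalar r.
# Drezner-Wesolowsky correlation integral with the arcsine substitution that
# removes the 1/sqrt(1-t^2) singularity:
#   Phi2(h, k; r) = Phi(h)Phi(k) +
#     (2*pi)^-1 * int_0^{asin r} exp(-(h^2 - 2 h k sin t + k^2) / (2 cos^2 t)) dt
pbvnorm <- function(h, k, r, nodes = 48L) {
  stopifnot(length(r) == 1L, is.finite(r) || abs(r) <= 1)
  if (abs(r) >= 1) stop("|r| must be strictly less than 1")
  n <- max(length(h), length(k))
  h <- rep_len(h, n)
  k <- rep_len(k, n)
  out <- pnorm(h) * pnorm(k)
  if (r != 0) {
    gl <- gauss_legendre(nodes)
    a <- asin(r)
    theta <- a * (gl$nodes + 1) / 2
    w <- gl$weights * a / 2
    fin <- is.finite(h) & is.finite(k)
    if (any(fin)) {
      hf <- h[fin]; kf <- k[fin]
      acc <- 0
      for (j in seq_along(theta)) {
        ct2 <- cos(theta[j])^2
        acc <- acc + w[j] *
          exp(-(hf^2 - 2 * hf * kf * sin(theta[j]) + kf^2) / (2 * ct2))
      }
      out[fin] <- out[fin] + acc / (2 * pi)
    }
    # +/-Inf margins: Phi2 collapses to the finite margin (or 0)
    inf <- !fin
    if (any(inf)) {
      hi <- h[inf]; ki <- k[inf]
      v <- ifelse(hi == -Inf | ki == -Inf, 0,
                  ifelse(hi == Inf & ki == Inf, 1,
                         ifelse(hi == Inf, pnorm(ki), pnorm(hi))))
      out[inf] <- v
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Upper-orthant probability of the standard bivariate normal
#'
#' Computes \eqn{P(Z_1 > \tau_1, Z_2 > \tau_2)} for a standard bivariate
#' normal vector with correlation \code{r}. This is the cell-probability
#' kernel of the liability-threshold model: under that model a binary
#' diagnosis is the exceedance of a threshold \eqn{\tau} by a latent
#' standard-normal liability, and the probability that two relatives are
#' both affected is exactly this orthant probability evaluated at their
#' thresholds and latent (tetrachoric) correlation.
#'
#' Vectorized over \code{tau1} and \code{tau2}; \code{r} must be scalar.
#' Infinite thresholds are allowed and saturate the corresponding margin.
#'
#' @param tau1,tau2 thresholds on the probit scale; finite or +/-Inf.
#' @param r latent correlation, strictly inside (-1, 1).
#' @return probabilities in \eqn{[0, 1]}, symmetric in argument exchange.
#' @examples
#' bivariate_upper_orthant(0, 0, 0)      # 0.25
#' bivariate_upper_orthant(0, 0, 0.5)    # 1/4 + asin(0.5)/(2*pi)
#' @export
bivariate_upper_orthant <- function(tau1, tau2, r) {
  if (length(r) != 1L || !is.finite(r) || abs(r) >= 1)
    stop("correlation must be a single value strictly inside (-1, 1)")
  pbvnorm(-tau1, -tau2, r)
}
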