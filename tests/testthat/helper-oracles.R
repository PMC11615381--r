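# Independent oracles and small generators used across the suite. These stay
# deliberately separate from the package's own code paths: the orthant oracle
# is mvtnorm's rectangle integration, the pair generator is a direct
# Cholesky-free bivariate construction, and the partial-correlation oracle
# inverts the generating covariance matrix.

# oracle: P(Z1 > t1, Z2 > t2) by mvtnorm rectangle integration
orthant_oracle <- function(t1, t2, r) {
  mvtnorm::pmvnorm(lower = c(t1, t2), upper = c(Inf, Inf),
                   corr = matrix(c(1, r, r, 1), 2),
                   algorithm = mvtnorm::Miwa(steps = 512))[1]
}

# bivariate standard normal pairs with correlation r
rbvn <- function(n, r) {
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  cbind(z1, z2)
}

# binary/binary liability pair at given prevalences
rbinpair <- function(n, r, prev1, prev2 = prev1) {
  z <- rbvn(n, r)
  cbind(as.integer(z[, 1] > qnorm(1 - prev1)),
        as.integer(z[, 2] > qnorm(1 - prev2)))
}

# exact-count binary vectors realizing given 2x2 cell counts
cells_to_pair <- function(n11, n10, n01, n00) {
  x <- rep(c(1, 1, 0, 0), c(n11, n10, n01, n00))
  y <- rep(c(1, 0, 1, 0), c(n11, n10, n01, n00))
  list(x = x, y = y)
}

# partial correlation of variables i and j given the rest, from a covariance
partial_cor_oracle <- function(S, i, j, given) {
  idx <- c(i, j, given)
  P <- solve(S[idx, idx])
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# generating covariance of (health_f, health_m, edu_f, edu_m) in the
# multitrait factor model: trait = loading * M + sqrt(1-loading^2) * U,
# partners' M correlated mu
multitrait_partner_cov <- function(a_health, a_edu, mu) {
  S <- diag(4)
  S[1, 2] <- S[2, 1] <- a_health * mu * a_health
  S[1, 3] <- S[3, 1] <- a_health * a_edu
  S[1, 4] <- S[4, 1] <- a_health * mu * a_edu
  S[2, 3] <- S[3, 2] <- a_health * mu * a_edu
  S[2, 4] <- S[4, 2] <- a_health * a_edu
  S[3, 4] <- S[4, 3] <- a_edu * mu * a_edu
  S
}

# Monte-Carlo SE of a sample correlation
mc_se_cor <- function(r, n) (1 - r^2) / sqrt(n)

# minimal hand-built quad_model_fit for LRT bookkeeping tests
fake_quad_fit <- function(loglik, constrained, trait = "t", n = 100,
                          r = c(0.3, 0.3, 0.09, 0.05)) {
  structure(list(trait = trait, kind = "continuous",
                 structure = list(r_partner = r[1], r_sibling = r[2],
                                  r_inlaw = r[3], r_cosib = r[4],
                                  constrained = constrained),
                 se = rep(NA_real_, 4), loglik = loglik, n_quads = n,
                 converged = TRUE, boundary = FALSE),
            class = "quad_model_fit")
}
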