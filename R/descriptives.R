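# stacked (focal, relative) phenotype pairs for a relation, both directions
relation_pairs_stacked <- function(pop, trait, relation) {
  prs <- switch(relation,
    partner = list(c("index", "partner"), c("partner", "index")),
    sibling = list(c("index", "sib_index"), c("partner", "sib_partner")),
    inlaw = list(c("index", "sib_partner"), c("partner", "sib_index")))
  focal <- unlist(lapply(prs, function(p) pop[[paste0(trait, "_", p[1])]]))
  rel <- unlist(lapply(prs, function(p) pop[[paste0(trait, "_", p[2])]]))
  cbind(focal = focal, relative = rel)
}

#' Prevalence and conditional-prevalence descriptives
#'
#' For each binary trait: the overall prevalence among the focal individuals
#' (both members of each couple) and, among relatives of affected
#' individuals, the count and percentage affected, for partners, siblings,
#' and siblings-in-law. Small conditional cells are suppressed (reported as
#' missing) below a configurable disclosure threshold, mirroring
#' registry-style small-cell rules.
#'
#' @param pop a quad table.
#' @param traits character vector of binary trait names.
#' @param suppress_below suppress conditional counts smaller than this
#'   (default 10); set to 0 to disable.
#' @return data frame with one row per trait: \code{n_affected},
#'   \code{prevalence} (percent), and \code{<relation>_n} /
#'   \code{<relation>_pct} for partner, sibling, inlaw.
#' @export
prevalence_table <- function(pop, traits, suppress_below = 10) {
  rows <- lapply(traits, function(tr) {
    focal <- c(pop[[paste0(tr, "_index")]], pop[[paste0(tr, "_partner")]])
    bad <- !is.na(focal) & !(focal %in% c(0, 1))
    if (any(bad)) stop("trait ", tr, " is not coded 0/1")
    n_aff <- sum(focal == 1, na.rm = TRUE)
    prev <- 100 * n_aff / sum(!is.na(focal))
    row <- data.frame(trait = tr, n_affected = n_aff, prevalence = prev)
    for (relation in c("partner", "sibling", "inlaw")) {
      m <- relation_pairs_stacked(pop, tr, relation)
      sel <- m[, "focal"] == 1 & !is.na(m[, "focal"]) & !is.na(m[, "relative"])
      n_rel <- sum(m[sel, "relative"] == 1)
      pct <- if (any(sel)) 100 * n_rel / sum(sel) else NA_real_
      if (n_aff == 0 || (suppress_below > 0 && n_rel < suppress_below)) {
        n_rel <- NA_integer_; pct <- NA_real_
      }
      row[[paste0(relation, "_n")]] <- n_rel
      row[[paste0(relation, "_pct")]] <- pct
    }
    row
  })
  do.call(rbind, rows)
}

#' Prevalence by sex and partner affection status
#'
#' Prevalence of each condition among female and male partners, split by
#' whether their partner is affected, with Wilson 95\% confidence intervals.
#'
#' @param pop a quad table.
#' @param traits character vector of binary trait names.
#' @return tidy data frame: trait, sex ("female"/"male"), partner_affected,
#'   n, prevalence (percent), ci_low, ci_high.
#' @export
prevalence_by_partner_status <- function(pop, traits) {
  rows <- list()
  for (tr in traits) {
    for (side in c("female", "male")) {
      own <- pop[[paste0(tr, if (side == "female") "_index" else "_partner")]]
      oth <- pop[[paste0(tr, if (side == "female") "_partner" else "_index")]]
      for (status in c(0, 1)) {
        sel <- !is.na(own) & !is.na(oth) & oth == status
        n <- sum(sel); k <- sum(own[sel] == 1)
        ci <- if (n > 0)
          suppressWarnings(prop.test(k, n, correct = FALSE)$conf.int)
        else c(NA_real_, NA_real_)
        rows[[length(rows) + 1]] <- data.frame(
          trait = tr, sex = side, partner_affected = status, n = n,
          prevalence = if (n > 0) 100 * k / n else NA_real_,
          ci_low = 100 * ci[1], ci_high = 100 * ci[2])
      }
    }
  }
  do.call(rbind, rows)
}

#' Adjusted odds ratios for partner and sibling-in-law phenotypes
#'
#' Multiple logistic regression of the index person's binary outcome on the
#' partner's and the sibling-in-law's phenotypes (jointly), optionally with
#' covariates. Under direct assortment the sibling-in-law coefficient is null
#' once the partner's phenotype is in the model; a positive sibling-in-law
#' association indicates indirect assortment or stratification. Fitted by
#' \code{stats::glm} (iteratively reweighted least squares); Wald confidence
#' intervals; separation is flagged, never silently returned.
#'
#' @param pop a quad table.
#' @param outcome binary trait name (outcome read from the index person).
#' @param predictors which relatives' phenotypes enter the model; any of
#'   "partner", "sib_partner", "sib_index".
#' @param covariates covariate prefixes read as \code{<cov>_index} columns.
#' @return data frame: predictor, or, ci_low, ci_high, p, separation.
#' @export
logistic_adjusted_or <- function(pop, outcome,
                                 predictors = c("partner", "sib_partner"),
                                 covariates = NULL) {
  y <- pop[[paste0(outcome, "_index")]]
  if (is.null(y)) stop("unknown outcome trait: ", outcome)
  df <- data.frame(y = y)
  for (p in predictors) df[[p]] <- pop[[paste0(outcome, "_", p)]]
  if (!is.null(covariates))
    for (v in covariates) df[[v]] <- pop[[paste0(v, "_index")]]
  df <- df[complete.cases(df), , drop = FALSE]
  fit <- suppressWarnings(
    glm(y ~ ., data = df, family = binomial(),
        control = glm.control(epsilon = 1e-10, maxit = 50)))
  separation <- !fit$converged || any(abs(coef(fit)[-1]) > 15)
  cf <- summary(fit)$coefficients
  keep <- rownames(cf) %in% predictors
  data.frame(
    predictor = rownames(cf)[keep],
    or = exp(cf[keep, "Estimate"]),
    ci_low = exp(cf[keep, "Estimate"] - 1.96 * cf[keep, "Std. Error"]),
    ci_high = exp(cf[keep, "Estimate"] + 1.96 * cf[keep, "Std. Error"]),
    p = cf[keep, "Pr(>|z|)"],
    separation = separation)
}

#' Within-person association matrix
#'
#' Correlations between different traits measured on the same person,
#' delegated to the pairwise estimators (tetrachoric, polyserial, or Pearson
#' by trait kind), with Benjamini-Hochberg adjustment across the matrix.
#' Self-correlations are reported as 1 and excluded from the FDR family.
#'
#' @inheritParams correlation_matrix
#' @return as [correlation_matrix()].
#' @export
within_person_matrix <- function(pop, traits, adjust = NULL) {
  correlation_matrix(pop, traits, relationship = "within_person",
                     adjust = adjust)
}
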