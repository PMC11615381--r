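trait_kind_auto <- function(pop, trait) {
  v <- unlist(pop[paste0(trait, "_", quad_roles())], use.names = FALSE)
  v <- v[!is.na(v)]
  if (length(v) && all(v %in% c(0, 1))) "binary" else "continuous"
}

resolve_traits <- function(pop, traits) {
  if (is.null(traits)) stop("traits must be supplied")
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  if (is.list(traits) && all(vapply(traits, inherits, TRUE, "trait_spec"))) {
    data.frame(name = vapply(traits, `[[`, "", "name"),
               kind = vapply(traits, `[[`, "", "kind"))
  } else {
    data.frame(name = as.character(traits),
               kind = vapply(as.character(traits), function(tr)
                 trait_kind_auto(pop, tr), ""))
  }
}

# member pairs supplying (x, y) for each relationship; pooled pairs are
# stacked so both sides of the family inform the shared correlation
relationship_pairs <- function(relationship) {
  switch(relationship,
    partner = list(c("index", "partner")),
    sibling = list(c("index", "sib_index"), c("partner", "sib_partner")),
    inlaw = list(c("index", "sib_partner"), c("partner", "sib_index")),
    cross_trait_partner = list(c("index", "partner")),
    within_person = list(c("index", "index"), c("partner", "partner")),
    stop("unknown relationship: ", relationship))
}

pair_vectors <- function(pop, trait_a, trait_b, relationship,
                         adjust = NULL, adjust_pair = NULL) {
  pairs <- relationship_pairs(relationship)
  xs <- list(); ys <- list(); cxs <- list(); cys <- list()
  for (pr in pairs) {
    ca <- paste0(trait_a, "_", pr[1]); cb <- paste0(trait_b, "_", pr[2])
    if (!ca %in% names(pop)) stop("unknown trait column: ", ca)
    if (!cb %in% names(pop)) stop("unknown trait column: ", cb)
    xs[[length(xs) + 1]] <- pop[[ca]]
    ys[[length(ys) + 1]] <- pop[[cb]]
    covs_for <- function(role) {
      own <- if (is.null(adjust)) NULL else {
        cols <- paste0(adjust, "_", role)
        cols <- cols[cols %in% names(pop)]
        if (length(cols)) as.matrix(pop[, cols, drop = FALSE]) else NULL
      }
      ap <- setdiff(adjust_pair, c(trait_a, trait_b))  # never adjust a trait for itself
      shared <- if (!length(ap)) NULL else {
        cols <- c(paste0(ap, "_", pr[1]), paste0(ap, "_", pr[2]))
        cols <- cols[cols %in% names(pop)]
        if (length(cols)) as.matrix(pop[, cols, drop = FALSE]) else NULL
      }
      if (is.null(own) && is.null(shared)) NULL else cbind(own, shared)
    }
    cxs[[length(cxs) + 1]] <- covs_for(pr[1])
    cys[[length(cys) + 1]] <- covs_for(pr[2])
  }
  bindm <- function(lst) if (all(vapply(lst, is.null, TRUE))) NULL
                         else do.call(rbind, lst)
  list(x = unlist(xs), y = unlist(ys), cx = bindm(cxs), cy = bindm(cys))
}

#' Pairwise correlation matrix for a quad population
#'
#' Estimates every requested trait-pair correlation for one relationship,
#' choosing tetrachoric, polyserial, or Pearson estimation from the trait
#' kinds, with optional definition-variable adjustment. The sibling and
#' in-law relationships pool both sides of the family (the two sibling pairs
#' and the two in-law pairs share one correlation each). The cross-trait
#' partner matrix pairs trait A in the female partner with trait B in the
#' male partner for every ordered pair; \code{partner}, \code{sibling}, and
#' \code{inlaw} estimate within-trait cells only. Two-sided z-tests on the
#' atanh scale give per-cell p-values; Benjamini-Hochberg adjustment is
#' applied across the matrix (self-correlation cells excluded from the FDR
#' family).
#'
#' @param pop a quad table (wide, role-suffixed columns).
#' @param traits character vector of trait names, or list of [trait_spec()]s.
#' @param relationship one of "partner", "sibling", "inlaw", "within_person",
#'   "cross_trait_partner".
#' @param adjust covariate prefixes applied as each member's own covariate
#'   (e.g. \code{c("sex", "birth_year")}).
#' @param adjust_pair covariate prefixes applied as both members' values on
#'   both sides (e.g. \code{"gpa"} to adjust for both partners' GPA).
#' @return data frame with columns \code{trait_a}, \code{trait_b},
#'   \code{relationship}, \code{r}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{p_bh}, \code{n_pairs}, \code{method}, \code{converged};
#'   the underlying \code{cor_estimate} objects are in
#'   \code{attr(, "estimates")}.
#' @export
correlation_matrix <- function(pop, traits,
                               relationship = c("partner", "sibling", "inlaw",
                                                "within_person",
                                                "cross_trait_partner"),
                               adjust = NULL, adjust_pair = NULL) {
  relationship <- match.arg(relationship)
  info <- resolve_traits(pop, traits)
  cells <- if (relationship %in% c("cross_trait_partner", "within_person")) {
    expand.grid(a = seq_len(nrow(info)), b = seq_len(nrow(info)))
  } else {
    data.frame(a = seq_len(nrow(info)), b = seq_len(nrow(info)))
  }
  rows <- vector("list", nrow(cells))
  ests <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ta <- info$name[cells$a[i]]; tb <- info$name[cells$b[i]]
    ka <- info$kind[cells$a[i]]; kb <- info$kind[cells$b[i]]
    if (relationship == "within_person" && ta == tb) {
      rows[[i]] <- data.frame(trait_a = ta, trait_b = tb,
                              relationship = relationship, r = 1, se = 0,
                              ci_low = 1, ci_high = 1, p = NA_real_,
                              p_bh = NA_real_, n_pairs = NA_integer_,
                              method = NA_character_, converged = TRUE)
      next
    }
    pv <- pair_vectors(pop, ta, tb, relationship, adjust, adjust_pair)
    est <- tryCatch(
      estimate_pair_correlation(pv$x, pv$y, ka, kb, pv$cx, pv$cy),
      error = function(e) e)
    if (inherits(est, "error")) {
      rows[[i]] <- data.frame(trait_a = ta, trait_b = tb,
                              relationship = relationship, r = NA_real_,
                              se = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, p = NA_real_,
                              p_bh = NA_real_, n_pairs = NA_integer_,
                              method = NA_character_, converged = FALSE)
      next
    }
    ests[[i]] <- est
    rows[[i]] <- data.frame(trait_a = ta, trait_b = tb,
                            relationship = relationship, r = est$r,
                            se = est$se, ci_low = est$ci95[1],
                            ci_high = est$ci95[2], p = est$p, p_bh = NA_real_,
                            n_pairs = est$n_pairs, method = est$method,
                            converged = est$converged)
  }
  out <- do.call(rbind, rows)
  fdr_family <- !(out$trait_a == out$trait_b & relationship == "within_person")
  out$p_bh[fdr_family] <- bh_adjust(out$p[fdr_family])
  names(ests) <- paste(out$trait_a, out$trait_b, sep = ":")
  attr(out, "estimates") <- ests
  out
}
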