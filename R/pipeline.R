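#' Pipeline configuration
#'
#' Bundles everything one analysis run needs: exactly one input source
#' (a quad CSV path or a simulation block), the traits and relationships to
#' estimate, the covariate-adjustment arms, the FDR level, and the seed.
#'
#' @param input path to a quad CSV, or NULL when simulating.
#' @param simulate list with \code{params} (a [mechanism_params()] or plain
#'   list of its arguments), \code{design} (a [simulation_design()] or plain
#'   list), optional \code{multitrait} (trait loading table for
#'   [simulate_multitrait()]), and optional \code{convergence}
#'   (\code{list(n2 =, x =)}) producing a second, post-formation observation
#'   window.
#' @param traits trait names to analyse (NULL = all traits found).
#' @param categories optional named vector mapping traits to categories
#'   (e.g. education/mental/somatic) for the median summary.
#' @param relationships relationships to estimate per arm.
#' @param adjust_arms named list of arms; each arm is a list with optional
#'   \code{adjust} and \code{adjust_pair} covariate prefixes. The first arm
#'   is the baseline for percent-reduction summaries.
#' @param quad_adjust covariates for the quad model fits (default "sex").
#' @param fdr_alpha FDR significance level, in (0, 1).
#' @param out_dir optional directory for CSV outputs.
#' @param seed integer seed governing every stochastic stage.
#' @return a validated \code{run_config}.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL, traits = NULL,
                            categories = NULL,
                            relationships = c("partner", "sibling", "inlaw"),
                            adjust_arms = list(none = list()),
                            quad_adjust = "sex",
                            fdr_alpha = 0.05, out_dir = NULL, seed = 1) {
  if (is.null(input) == is.null(simulate))
    stop("config error at 'input'/'simulate': supply exactly one input source")
  if (fdr_alpha <= 0 || fdr_alpha >= 1)
    stop("config error at 'fdr_alpha': must be inside (0, 1)")
  if (is.null(names(adjust_arms)) || any(names(adjust_arms) == ""))
    stop("config error at 'adjust_arms': arms must be named")
  structure(list(input = input, simulate = simulate, traits = traits,
                 categories = categories, relationships = relationships,
                 adjust_arms = adjust_arms, quad_adjust = quad_adjust,
                 fdr_alpha = fdr_alpha, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

as_params <- function(x) {
  if (inherits(x, "mechanism_params")) x else do.call(mechanism_params, x)
}

as_design <- function(x) {
  if (inherits(x, "simulation_design")) return(x)
  if (length(x$traits) == 0) x$traits <- NULL
  if (!is.null(x$traits) && is.list(x$traits) &&
      !inherits(x$traits[[1]], "trait_spec"))
    x$traits <- lapply(x$traits, function(t) do.call(trait_spec, t))
  do.call(simulation_design, x)
}

pipeline_population <- function(config) {
  if (!is.null(config$input)) return(read_quads(config$input))
  sim <- config$simulate
  params <- as_params(sim$params)
  design <- as_design(sim$design)
  if (is.null(design$seed)) design$seed <- config$seed
  if (!is.null(sim$multitrait))
    simulate_multitrait(as.data.frame(sim$multitrait), params, design)
  else
    simulate_quads(params, design)
}

population_traits <- function(pop) {
  cand <- sub("_index$", "", names(pop)[endsWith(names(pop), "_index")])
  has_all <- vapply(cand, function(tr)
    all(paste0(tr, "_", quad_roles()) %in% names(pop)), TRUE)
  cand <- cand[has_all & !grepl("_liab$", cand)]
  setdiff(cand, c("sex", "birth_year", "family_id"))
}

#' Run the end-to-end assortative-mating analysis
#'
#' Sequences the full analysis on a quad table (read or simulated):
#' correlation matrices per relationship for every adjustment arm; per-trait
#' free and constrained quad fits with the in-law inflation factor, the
#' direct-assortment likelihood-ratio test, and Benjamini-Hochberg
#' adjustment across traits; optional second observation window under a
#' convergence overlay with an equality LRT between the windows; median
#' correlations by trait category; and percent-reduction summaries of each
#' adjusted arm against the baseline arm. Deterministic given the config and
#' seed; per-trait estimation failures are recorded, not fatal.
#'
#' @param config a [pipeline_config()].
#' @return an \code{analysis_report}: list with \code{matrices} (per arm and
#'   relationship), \code{direct_assortment} (Table-3-style data frame),
#'   \code{windows} (when a convergence overlay is configured),
#'   \code{medians}, \code{reductions}, and \code{provenance}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  log <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- force(expr)
    log[[name]] <<- sprintf("%.2fs", as.numeric(Sys.time() - t0, units = "secs"))
    val
  }
  pop <- stage("population", pipeline_population(config))
  traits <- config$traits
  if (is.null(traits)) traits <- population_traits(pop)

  matrices <- list()
  for (arm in names(config$adjust_arms)) {
    spec <- config$adjust_arms[[arm]]
    matrices[[arm]] <- stage(paste0("matrices_", arm), lapply(
      stats::setNames(config$relationships, config$relationships),
      function(rel) correlation_matrix(pop, traits, relationship = rel,
                                       adjust = spec$adjust,
                                       adjust_pair = spec$adjust_pair)))
  }

  da <- stage("direct_assortment", {
    rows <- lapply(traits, function(tr) {
      res <- tryCatch({
        free <- fit_quad_model(pop, tr, constrained = FALSE,
                               adjust = config$quad_adjust)
        con <- fit_quad_model(pop, tr, constrained = TRUE,
                              adjust = config$quad_adjust, se = FALSE)
        tst <- lrt_direct_assortment(free, con)
        s <- free$structure
        data.frame(trait = tr, r_partner = s$r_partner,
                   r_sibling = s$r_sibling, r_inlaw = s$r_inlaw,
                   r_cosib = s$r_cosib,
                   se_partner = free$se[["r_partner"]],
                   se_sibling = free$se[["r_sibling"]],
                   se_inlaw = free$se[["r_inlaw"]],
                   iif = tst$iif, lrt_stat = tst$lrt_stat,
                   p_raw = tst$p_raw, p_bh = NA_real_,
                   n_quads = free$n_quads, converged = free$converged)
      }, error = function(e)
        data.frame(trait = tr, r_partner = NA_real_, r_sibling = NA_real_,
                   r_inlaw = NA_real_, r_cosib = NA_real_,
                   se_partner = NA_real_, se_sibling = NA_real_,
                   se_inlaw = NA_real_, iif = NA_real_, lrt_stat = NA_real_,
                   p_raw = NA_real_, p_bh = NA_real_, n_quads = NA_integer_,
                   converged = FALSE))
      res
    })
    tab <- do.call(rbind, rows)
    # IIFs with undefined (zero-product) denominators stay out of the family
    ok <- !is.na(tab$p_raw) & !is.na(tab$iif)
    tab$p_bh[ok] <- bh_adjust(tab$p_raw[ok])
    tab
  })

  windows <- NULL
  conv <- config$simulate$convergence
  if (!is.null(conv)) {
    windows <- stage("windows", {
      pop2 <- overlay_convergence(pop, n2 = conv$n2 %||% 0, x = conv$x %||% 0)
      m1 <- matrices[[1]][["partner"]]
      m2 <- correlation_matrix(pop2, traits, relationship = "partner",
                               adjust = config$adjust_arms[[1]]$adjust,
                               adjust_pair = config$adjust_arms[[1]]$adjust_pair)
      eq <- lrt_equal_correlations(attr(m1, "estimates"), attr(m2, "estimates"))
      list(prospective = m1, cross_sectional = m2, equality_test = eq,
           median_prospective = median(m1$r, na.rm = TRUE),
           median_cross_sectional = median(m2$r, na.rm = TRUE))
    })
  }

  medians <- NULL
  if (!is.null(config$categories) &&
      "cross_trait_partner" %in% config$relationships) {
    medians <- lapply(matrices, function(m)
      median_by_category(m[["cross_trait_partner"]], config$categories))
  }

  reductions <- NULL
  if (length(matrices) > 1 && "partner" %in% config$relationships) {
    base <- matrices[[1]][["partner"]]
    base <- base[base$trait_a == base$trait_b, ]
    reductions <- lapply(matrices[-1], function(m) {
      adj <- m[["partner"]]; adj <- adj[adj$trait_a == adj$trait_b, ]
      idx <- match(base$trait_a, adj$trait_a)
      out <- data.frame(trait = base$trait_a, r_unadjusted = base$r,
                        r_adjusted = adj$r[idx],
                        pct_reduction = percent_reduction(base$r, adj$r[idx]))
      attr(out, "median_pct_reduction") <-
        median(out$pct_reduction, na.rm = TRUE)
      out
    })
  }

  report <- structure(list(
    matrices = matrices, direct_assortment = da, windows = windows,
    medians = medians, reductions = reductions,
    provenance = list(seed = config$seed, config = config,
                      config_hash = config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("quadassort"))),
    log = log
  ), class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (arm in names(report$matrices))
    for (rel in names(report$matrices[[arm]]))
      utils::write.csv(report$matrices[[arm]][[rel]],
                       file.path(out_dir, sprintf("correlations_%s_%s.csv", arm, rel)),
                       row.names = FALSE)
  utils::write.csv(report$direct_assortment,
                   file.path(out_dir, "direct_assortment.csv"),
                   row.names = FALSE)
  if (!is.null(report$reductions))
    for (arm in names(report$reductions))
      utils::write.csv(report$reductions[[arm]],
                       file.path(out_dir, sprintf("reductions_%s.csv", arm)),
                       row.names = FALSE)
  if (!is.null(report$medians))
    for (arm in names(report$medians))
      utils::write.csv(report$medians[[arm]],
                       file.path(out_dir, sprintf("medians_%s.csv", arm)),
                       row.names = FALSE)
  yaml::write_yaml(list(seed = report$provenance$seed,
                        config_hash = report$provenance$config_hash,
                        package_version = report$provenance$package_version),
                   file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  arms:", paste(names(x$matrices), collapse = ", "), "\n")
  da <- x$direct_assortment
  cat(sprintf("  direct assortment: %d traits, median IIF %.2f, %d FDR-significant\n",
              nrow(da), median(da$iif, na.rm = TRUE),
              sum(da$p_bh < 0.05, na.rm = TRUE)))
  if (!is.null(x$windows))
    cat(sprintf("  windows: median partner r %.3f (prospective) vs %.3f (cross-sectional)\n",
                x$windows$median_prospective, x$windows$median_cross_sectional))
  cat("  seed:", x$provenance$seed, " hash:", x$provenance$config_hash, "\n")
  invisible(x)
}

#' Median correlations by trait category
#'
#' Summarizes a cross-trait partner correlation matrix as median correlations
#' and median standard errors per ordered category pair (female-partner
#' category by male-partner category), separating within-trait from
#' cross-trait cells.
#'
#' @param matrix_df output of [correlation_matrix()] with
#'   \code{relationship = "cross_trait_partner"}.
#' @param categories named character vector mapping every trait to a
#'   category.
#' @return data frame: category_female, category_male, within_or_across,
#'   median_r, median_se, n_cells.
#' @export
median_by_category <- function(matrix_df, categories) {
  miss <- setdiff(unique(c(matrix_df$trait_a, matrix_df$trait_b)),
                  names(categories))
  if (length(miss))
    stop("uncategorized traits: ", paste(miss, collapse = ", "))
  df <- matrix_df
  df$cat_a <- unname(categories[df$trait_a])
  df$cat_b <- unname(categories[df$trait_b])
  df$within <- ifelse(df$trait_a == df$trait_b, "within", "across")
  agg <- aggregate(cbind(r, se) ~ cat_a + cat_b + within, data = df,
                   FUN = median, na.action = na.omit)
  n <- aggregate(r ~ cat_a + cat_b + within, data = df,
                 FUN = function(v) sum(!is.na(v)))
  out <- merge(agg, n, by = c("cat_a", "cat_b", "within"),
               suffixes = c("", "_n"))
  names(out) <- c("category_female", "category_male", "within_or_across",
                  "median_r", "median_se", "n_cells")
  out[order(out$category_female, out$category_male, out$within_or_across), ]
}
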