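#' Write a quad table to CSV with a metadata sidecar
#'
#' Missing values become empty fields. When the table carries generating
#' parameters and a design (simulated populations do), they are written to a
#' YAML sidecar \code{<path>.meta.yaml} so that params, design, and seed
#' round-trip through file I/O.
#'
#' @param pop quad table.
#' @param path CSV path.
#' @param sidecar write the metadata sidecar?
#' @return \code{path}, invisibly.
#' @export
write_quads <- function(pop, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE, na = "")
  params <- attr(pop, "params"); design <- attr(pop, "design")
  if (sidecar && (!is.null(params) || !is.null(design))) {
    meta <- list()
    if (!is.null(params)) meta$params <- unclass(params)
    if (!is.null(design)) {
      d <- unclass(design)
      d$traits <- lapply(d$traits, unclass)
      d$missingness <- as.list(d$missingness)
      meta$design <- d
    }
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' Read a quad table from CSV
#'
#' Accepts the wide dialect (role-suffixed columns, as written by
#' [write_quads()]) or a long dialect with columns \code{family_id},
#' \code{role}, trait and covariate columns, which is pivoted to wide. Empty
#' fields are read as missing. A metadata sidecar, if present, is restored
#' into the table's attributes.
#'
#' @param path CSV path; header row mandatory.
#' @param format "wide" or "long".
#' @return a \code{quad_population} data frame.
#' @export
read_quads <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  pop <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  if (format == "long") {
    if (!all(c("family_id", "role") %in% names(pop)))
      stop("long format needs family_id and role columns")
    bad <- setdiff(unique(pop$role), quad_roles())
    if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
    value_cols <- setdiff(names(pop), c("family_id", "role"))
    fams <- sort(unique(pop$family_id))
    wide <- data.frame(family_id = fams)
    for (role in quad_roles()) {
      sub <- pop[pop$role == role, , drop = FALSE]
      idx <- match(fams, sub$family_id)
      for (v in value_cols)
        wide[[paste0(v, "_", role)]] <- sub[[v]][idx]
    }
    pop <- wide
  }
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (!is.null(meta$params))
      attr(pop, "params") <- structure(meta$params, class = "mechanism_params")
    if (!is.null(meta$design)) {
      d <- meta$design
      d$traits <- lapply(d$traits, function(t) structure(t, class = "trait_spec"))
      d$missingness <- unlist(d$missingness)
      attr(pop, "design") <- structure(d, class = "simulation_design")
    }
  }
  class(pop) <- c("quad_population", "data.frame")
  pop
}
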