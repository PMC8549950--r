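#' Read a crossbridge parameter document
#'
#' Parameter documents are flat JSON key/value maps with unit-suffixed
#' keys: \code{mu_f0_per_s}, \code{mu_f1_per_s}, \code{r0_per_s},
#' \code{alpha}, \code{growth}, \code{a_XB_MPa}, and the optional
#' \code{permissivity} (default 1), \code{SL0_nm} (default 2200) and
#' \code{D_M_nm} (default 43). Unknown keys are rejected; applied
#' defaults are reported via \code{message()}. The usual model
#' invariants are validated on load (a linear-growth document with
#' \code{alpha >= mu_f0/mu_f1} loads with a warning that v_max is
#' undefined).
#'
#' @param path file path.
#' @return an [xb_model()].
#' @seealso [write_xb_params()]
#' @export
read_xb_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("mu_f0_per_s", "mu_f1_per_s", "r0_per_s", "alpha",
                "growth", "a_XB_MPa")
  optional <- c(permissivity = 1, SL0_nm = 2200, D_M_nm = 43)
  allowed <- c(required, names(optional))
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  missing_keys <- setdiff(required, names(doc))
  if (length(missing_keys))
    stop("missing required parameter key(s): ",
         paste(missing_keys, collapse = ", "))
  for (k in names(optional)) {
    if (is.null(doc[[k]])) {
      doc[[k]] <- optional[[k]]
      message("applying default ", k, " = ", optional[[k]])
    }
  }
  num <- function(x) as.numeric(x)  # JSON integers parse as integer
  xb_model(mu_f0 = num(doc$mu_f0_per_s), mu_f1 = num(doc$mu_f1_per_s),
           r0 = num(doc$r0_per_s), alpha = num(doc$alpha),
           growth = doc$growth, a_XB = num(doc$a_XB_MPa) * 1e6,
           P = num(doc$permissivity), SL0 = num(doc$SL0_nm),
           D_M = num(doc$D_M_nm))
}

#' Write a crossbridge parameter document
#'
#' Serializes a model to the flat JSON document read by
#' [read_xb_params()]; round-trips losslessly (full double precision).
#'
#' @param m an [xb_model()].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_xb_params <- function(m, path) {
  stopifnot(inherits(m, "xb_model"))
  doc <- list(mu_f0_per_s = m$mu_f0, mu_f1_per_s = m$mu_f1,
              r0_per_s = m$r0, alpha = m$alpha, growth = m$growth,
              a_XB_MPa = m$a_XB / 1e6, permissivity = m$P,
              SL0_nm = m$SL0, D_M_nm = m$D_M)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Write a curve to CSV
#'
#' Deterministic CSV export: columns are reordered to the supplied
#' schema regardless of insertion order, full float precision, header
#' row, no row names. An empty curve produces a header-only file.
#'
#' @param curve a data.frame.
#' @param path file path.
#' @param columns character vector naming (and ordering) the columns to
#'   write; defaults to the curve's own columns in sorted order.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(curve, path, columns = sort(names(curve))) {
  stopifnot(is.data.frame(curve), all(columns %in% names(curve)))
  utils::write.csv(curve[, columns, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
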