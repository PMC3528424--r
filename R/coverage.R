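# Field-strength units and their factor to V/m.
.nf_unit_to_Vm <- c("V/cm" = 100, "V/mm" = 1000, "V/in" = 1 / 0.0254)

#' Convert a field strength between supported units
#'
#' Supported units are `V/cm`, `V/mm` and `V/in`; conversions are exact
#' (1 V/mm = 10 V/cm, 1 V/in = (1/2.54) V/cm). `V/m` is also accepted as
#' the internal SI unit.
#'
#' @param value Numeric field strength(s).
#' @param from,to Unit names.
#' @return Converted value(s).
#' @examples
#' convert_field_unit(300, "V/cm", "V/in")  # 762
#' @export
convert_field_unit <- function(value, from, to) {
  tab <- c(.nf_unit_to_Vm, "V/m" = 1)
  if (!from %in% names(tab)) stop("unknown field unit: '", from, "'", call. = FALSE)
  if (!to %in% names(tab)) stop("unknown field unit: '", to, "'", call. = FALSE)
  value * tab[[from]] / tab[[to]]
}

#' Electroporation field-strength thresholds
#'
#' Local field magnitudes above which reversible (E_rev) and irreversible
#' (E_irrev) electroporation are assumed to occur. The defaults, 300 and
#' 800 V/cm, are typical textbook values; both thresholds are strongly
#' tissue- and pulse-protocol-dependent and should be adjusted to the
#' modelled case.
#'
#' @param e_rev Reversible threshold (in `unit`), > 0.
#' @param e_irrev Irreversible threshold (in `unit`), >= `e_rev`.
#' @param unit One of `"V/cm"`, `"V/mm"`, `"V/in"`.
#' @return An object of class `nf_thresholds`.
#' @export
thresholds <- function(e_rev = 300, e_irrev = 800, unit = c("V/cm", "V/mm", "V/in")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(e_rev), is.numeric(e_irrev))
  if (!(e_rev > 0 && e_rev <= e_irrev))
    stop("thresholds must satisfy 0 < e_rev <= e_irrev; got ",
         e_rev, " and ", e_irrev, " ", unit, call. = FALSE)
  structure(list(e_rev = as.numeric(e_rev), e_irrev = as.numeric(e_irrev),
                 unit = unit),
            class = "nf_thresholds")
}

#' Label mesh pixels as tumor or surrounding tissue
#'
#' A pixel centre belongs to the tumor iff its distance from the origin is
#' strictly less than half the tumor diameter; every other pixel is
#' surrounding tissue. The tumor circle is always centred at the origin of
#' the tissue square.
#'
#' @param layout An `nf_layout` (supplies the tumor diameter).
#' @param spec An `nf_mesh_spec`.
#' @return A character matrix (n_y x n_x) with entries `"tumor"` /
#'   `"surrounding"`, oriented like [evaluate_mesh()] values.
#' @export
region_masks <- function(layout, spec) {
  stopifnot(inherits(layout, "nf_layout"), inherits(spec, "nf_mesh_spec"))
  ax <- mesh_axes(spec)
  X <- matrix(ax$x, nrow = spec$n_y, ncol = spec$n_x, byrow = TRUE)
  Y <- matrix(ax$y, nrow = spec$n_y, ncol = spec$n_x)
  r2 <- (layout$tumor_diameter / 2)^2
  ifelse(X^2 + Y^2 < r2, "tumor", "surrounding")
}

#' Threshold coverage statistics of a field map
#'
#' The planning summary: field extrema over unmasked points and, for the
#' tumor and the surrounding tissue separately, the percentage of unmasked
#' pixels whose field magnitude meets or exceeds (`>=`) the reversible and
#' irreversible thresholds. Pixels inside electrodes are excluded from both
#' numerator and denominator; a region with no unmasked pixels reports `NA`
#' percentages rather than 0. Extrema are reported in the threshold unit.
#'
#' @param map An `nf_field_map`.
#' @param regions Region label matrix from [region_masks()] on the same mesh.
#' @param thr An `nf_thresholds`.
#' @return An object of class `nf_coverage_report`: `e_max`, `e_min` (in
#'   `thr$unit`), `tumor_pct_rev`, `tumor_pct_irrev`, `surround_pct_rev`,
#'   `surround_pct_irrev` (percent, `NA` if undefined), `n_tumor_px`,
#'   `n_surround_px`, `n_masked_px`, `unit`.
#' @export
coverage_report <- function(map, regions, thr) {
  stopifnot(inherits(map, "nf_field_map"), inherits(thr, "nf_thresholds"))
  if (!identical(dim(map$values), dim(regions)))
    stop("field map and region labels use different meshes", call. = FALSE)
  ok <- !map$mask
  v <- map$values
  rev_Vm <- convert_field_unit(thr$e_rev, thr$unit, "V/m")
  irr_Vm <- convert_field_unit(thr$e_irrev, thr$unit, "V/m")

  pct <- function(region, theta) {
    sel <- ok & regions == region
    n <- sum(sel)
    if (n == 0L) return(NA_real_)
    100 * sum(v[sel] >= theta) / n
  }
  any_ok <- any(ok)
  structure(list(
    e_max = if (any_ok) convert_field_unit(max(v[ok]), "V/m", thr$unit) else NA_real_,
    e_min = if (any_ok) convert_field_unit(min(v[ok]), "V/m", thr$unit) else NA_real_,
    tumor_pct_rev = pct("tumor", rev_Vm),
    tumor_pct_irrev = pct("tumor", irr_Vm),
    surround_pct_rev = pct("surrounding", rev_Vm),
    surround_pct_irrev = pct("surrounding", irr_Vm),
    n_tumor_px = sum(ok & regions == "tumor"),
    n_surround_px = sum(ok & regions == "surrounding"),
    n_masked_px = sum(map$mask),
    unit = thr$unit
  ), class = "nf_coverage_report")
}

#' @export
print.nf_coverage_report <- function(x, ...) {
  cat("<nf_coverage_report> (", x$unit, ")\n",
      "  E range: [", signif(x$e_min, 5), ", ", signif(x$e_max, 5), "]\n",
      "  tumor:       ", signif(x$tumor_pct_rev, 4), "% >= E_rev, ",
      signif(x$tumor_pct_irrev, 4), "% >= E_irrev (", x$n_tumor_px, " px)\n",
      "  surrounding: ", signif(x$surround_pct_rev, 4), "% >= E_rev, ",
      signif(x$surround_pct_irrev, 4), "% >= E_irrev (", x$n_surround_px, " px)\n",
      sep = "")
  invisible(x)
}

#' Serialize a coverage report to JSON
#'
#' @param report An `nf_coverage_report`.
#' @param path Output path; when `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
write_coverage_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "nf_coverage_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Append a coverage record to a JSON-lines log
#'
#' The analysis log keeps one record per invocation: a timestamp, the
#' layout snapshot hash, and the full coverage report. Records are
#' append-only, one JSON object per line.
#'
#' @param report An `nf_coverage_report`.
#' @param layout The `nf_layout` the report was computed from.
#' @param log_path Path of the JSON-lines log (created if absent).
#' @return `log_path`, invisibly.
#' @export
append_record_log <- function(report, layout, log_path) {
  rec <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              layout_hash = layout_hash(layout),
              report = unclass(report))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  con <- file(log_path, open = "a")
  on.exit(close(con))
  writeLines(line, con)
  invisible(log_path)
}
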