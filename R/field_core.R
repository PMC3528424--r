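#' Mesh specification for field evaluation
#'
#' Sample points are pixel centres of an `n_x` by `n_y` grid over the square
#' tissue region: `x_i = (i - 0.5)/n_x * L - L/2` for `i` in 1..n_x (and the
#' same along y). The default 400 x 400 mesh evaluates 160,000 points.
#'
#' @param n_x,n_y Number of samples along x and y (>= 2); default 400.
#' @param extent Side length L of the sampled square region (m).
#' @return An object of class `nf_mesh_spec`.
#' @export
mesh_spec <- function(extent, n_x = 400L, n_y = 400L) {
  stopifnot(is.numeric(extent), extent > 0, n_x >= 2, n_y >= 2)
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 extent = as.numeric(extent)),
            class = "nf_mesh_spec")
}

#' Pixel-centre coordinates of a mesh
#' @param spec An `nf_mesh_spec`.
#' @return List with vectors `x` (length n_x) and `y` (length n_y), metres.
#' @export
mesh_axes <- function(spec) {
  L <- spec$extent
  list(x = (seq_len(spec$n_x) - 0.5) / spec$n_x * L - L / 2,
       y = (seq_len(spec$n_y) - 0.5) / spec$n_y * L - L / 2)
}

#' Potential scale constant of an anode--cathode pair
#'
#' The image-charge solution fixes the potential scale from the applied
#' voltage:
#' \deqn{C = \frac{V_{AB}}{2\,\ln\!\big[(d_{AB} + \sqrt{d_{AB}^2 - 4\rho_0^2})/(2\rho_0)\big]}.}
#' The logarithm is natural: the derivation carries a \eqn{q/2\pi\epsilon_0}
#' factor that only cancels in base e.
#'
#' @param V_AB Applied pair voltage (V), > 0.
#' @param d_AB Centre distance (m), > 2 rho0.
#' @param rho0 Conductor radius (m).
#' @return The constant C (V), positive and finite.
#' @examples
#' pair_constant(1300, 0.016, 0.001)  # 234.77 V
#' @export
pair_constant <- function(V_AB, d_AB, rho0) {
  stopifnot(V_AB > 0)
  if (d_AB <= 2 * rho0)
    stop("d_AB must exceed 2*rho0 (electrodes touching or overlapping)", call. = FALSE)
  V_AB / (2 * log((d_AB + sqrt(d_AB^2 - 4 * rho0^2)) / (2 * rho0)))
}

#' Scalar potential of a pair at arbitrary points
#'
#' \deqn{V(x,y) = C \,\ln(\rho_B/\rho_A)} with \eqn{\rho_A,\rho_B} the
#' distances from the point to the two electrical axes. The potential is
#' antisymmetric under swapping the electrodes, equals +/- V_AB/2 on the two
#' conductor surfaces, and vanishes on the perpendicular bisector of the
#' electrical axes. It diverges on the axes themselves; evaluation exactly
#' on an axis is an error.
#'
#' @param x,y Coordinates (m); vectors of equal length (recycled).
#' @param pair An `nf_pair_geometry` with voltage set.
#' @return Potential (V), same length as the inputs.
#' @export
pair_potential <- function(x, y, pair) {
  stopifnot(inherits(pair, "nf_pair_geometry"), is.finite(pair$C))
  rA2 <- (pair$xpA - x)^2 + (pair$ypA - y)^2
  rB2 <- (pair$xpB - x)^2 + (pair$ypB - y)^2
  if (any(rA2 == 0 | rB2 == 0))
    stop("potential is singular on an electrical axis", call. = FALSE)
  pair$C * 0.5 * log(rB2 / rA2)
}

#' Electric field magnitude of a pair at arbitrary points
#'
#' The closed-form magnitude of the negative potential gradient:
#' \deqn{E(x,y) = C\sqrt{\Big[\tfrac{x'_A-x}{\rho_A^2}-\tfrac{x'_B-x}{\rho_B^2}\Big]^2
#'  + \Big[\tfrac{y'_A-y}{\rho_A^2}-\tfrac{y'_B-y}{\rho_B^2}\Big]^2}.}
#' At the midpoint of a symmetric pair this reduces to `2 C / s`.
#'
#' @inheritParams pair_potential
#' @return Field magnitude (V/m), non-negative, same length as inputs.
#' @examples
#' pg <- electrical_axes(electrode(-0.008, 0, "anode"),
#'                       electrode(0.008, 0, "cathode"),
#'                       rho0 = 0.001, voltage = 1300)
#' pair_field(0, 0, pg) / 100  # ~591.6 V/cm, not the naive 1300/1.6 = 812.5
#' @export
pair_field <- function(x, y, pair) {
  stopifnot(inherits(pair, "nf_pair_geometry"), is.finite(pair$C))
  dxA <- pair$xpA - x; dyA <- pair$ypA - y
  dxB <- pair$xpB - x; dyB <- pair$ypB - y
  rA2 <- dxA^2 + dyA^2
  rB2 <- dxB^2 + dyB^2
  if (any(rA2 == 0 | rB2 == 0))
    stop("field is singular on an electrical axis", call. = FALSE)
  pair$C * sqrt((dxA / rA2 - dxB / rB2)^2 + (dyA / rA2 - dyB / rB2)^2)
}

#' Evaluate the composed field of a layout on a mesh
#'
#' Computes, at every pixel centre, the maximum over all anode--cathode
#' pairs of the pair field magnitude -- the relevant quantity when a
#' generator pulses one pair at a time and electroporation is governed by
#' the largest local field any pulse establishes. Points lying within one
#' electrode radius of any electrode centre are masked `inside_electrode`
#' (the analytic expression diverges at the electrical axes and the field
#' inside a conductor is not meaningful in this model); masked points carry
#' `NA` values and are excluded from statistics and colour scaling.
#'
#' @param layout An `nf_layout`.
#' @param spec An `nf_mesh_spec`; defaults to a 400 x 400 mesh spanning the
#'   layout's tissue square.
#' @return An object of class `nf_field_map`: list with `spec`, `values`
#'   (n_y x n_x matrix, V/m, row i at y index i ascending), `mask` (logical
#'   matrix, `TRUE` inside an electrode) and the `layout`.
#' @export
evaluate_mesh <- function(layout, spec = NULL) {
  stopifnot(inherits(layout, "nf_layout"))
  if (is.null(spec)) spec <- mesh_spec(layout$tissue_side)
  stopifnot(inherits(spec, "nf_mesh_spec"))
  ax <- mesh_axes(spec)
  # column-per-x, row-per-y matrices of coordinates
  X <- matrix(ax$x, nrow = spec$n_y, ncol = spec$n_x, byrow = TRUE)
  Y <- matrix(ax$y, nrow = spec$n_y, ncol = spec$n_x)

  rho0 <- layout$electrode_radius
  mask <- matrix(FALSE, spec$n_y, spec$n_x)
  for (el in all_electrodes(layout))
    mask <- mask | ((X - el$x)^2 + (Y - el$y)^2 <= rho0^2)

  vals <- matrix(0, spec$n_y, spec$n_x)
  for (pg in enumerate_pairs(layout)) {
    dxA <- pg$xpA - X; dyA <- pg$ypA - Y
    dxB <- pg$xpB - X; dyB <- pg$ypB - Y
    rA2 <- dxA^2 + dyA^2
    rB2 <- dxB^2 + dyB^2
    E <- pg$C * sqrt((dxA / rA2 - dxB / rB2)^2 + (dyA / rA2 - dyB / rB2)^2)
    vals <- pmax(vals, E)
  }
  vals[mask] <- NA_real_
  structure(list(spec = spec, values = vals, mask = mask, layout = layout),
            class = "nf_field_map")
}

#' @export
print.nf_field_map <- function(x, ...) {
  v <- x$values[!x$mask]
  cat("<nf_field_map> ", x$spec$n_x, " x ", x$spec$n_y, " points over ",
      signif(x$spec$extent * 1e3, 6), " mm; E in [",
      signif(min(v), 4), ", ", signif(max(v), 4), "] V/m; ",
      sum(x$mask), " masked\n", sep = "")
  invisible(x)
}

#' Write a field map as a TSV matrix with a JSON sidecar header
#'
#' The TSV holds `n_y` rows by `n_x` columns with row 1 at the TOP of the
#' display (maximum y); masked cells are written as `NA`. Values use 6
#' significant digits with a `.` decimal separator regardless of locale.
#' A `<path>.json` sidecar records the extent, units, mesh size and a hash
#' of the generating layout.
#'
#' @param map An `nf_field_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_field_map <- function(map, path) {
  stopifnot(inherits(map, "nf_field_map"))
  vals <- map$values[rev(seq_len(map$spec$n_y)), , drop = FALSE]  # top row = max y
  txt <- apply(vals, 1L, function(r)
    paste(ifelse(is.na(r), "NA", formatC(r, format = "g", digits = 6)),
          collapse = "\t"))
  writeLines(txt, path)
  header <- list(
    n_x = map$spec$n_x, n_y = map$spec$n_y,
    extent_m = map$spec$extent, units = "V/m",
    orientation = "row 1 = top (max y)",
    layout_hash = layout_hash(map$layout)
  )
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stable hash of a layout's defining numbers
#' @param layout An `nf_layout`.
#' @return A character checksum.
#' @keywords internal
layout_hash <- function(layout) {
  flat <- unlist(lapply(layout$groups, function(g) c(
    g$voltage,
    unlist(lapply(g$electrodes, function(e) c(e$x, e$y, e$polarity == "anode")))
  )))
  flat <- c(flat, layout$electrode_radius, layout$tissue_side,
            layout$tumor_diameter, layout$conductivity_ratio)
  s <- paste(formatC(flat, format = "g", digits = 15), collapse = ",")
  # polynomial rolling hash (exact in double arithmetic); fingerprints a config
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
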