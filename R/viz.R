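# Palette ramps: key colours interpolated linearly in RGB. "hot" is the
# classic black-red-yellow-white ramp; "jet" and "coolwarm" are the usual
# rainbow and diverging maps.
.nf_palettes <- list(
  hot      = c("#000000", "#FF0000", "#FFFF00", "#FFFFFF"),
  gray     = c("#000000", "#FFFFFF"),
  jet      = c("#00007F", "#0000FF", "#00FFFF", "#7FFF7F", "#FFFF00",
               "#FF0000", "#7F0000"),
  coolwarm = c("#3B4CC0", "#F7F7F7", "#B40426")
)

#' Names of the available colour palettes
#' @return Character vector of palette names.
#' @export
palette_names <- function() names(.nf_palettes)

#' Look up palette colours for normalized values
#'
#' Monotone map from \[0, 1\] to the palette ramp; values outside the range
#' clamp to the endpoints.
#'
#' @param t Numeric vector of normalized values.
#' @param palette Palette name; see [palette_names()].
#' @return Matrix with one row per value and columns r, g, b in \[0, 1\].
#' @export
palette_lookup <- function(t, palette = "hot") {
  if (!palette %in% names(.nf_palettes))
    stop("unknown palette '", palette, "'; available: ",
         paste(palette_names(), collapse = ", "), call. = FALSE)
  ramp <- grDevices::colorRamp(.nf_palettes[[palette]], space = "rgb")
  ramp(pmin(pmax(t, 0), 1)) / 255
}

#' Rendering specification for field maps
#'
#' @param palette Palette name; see [palette_names()].
#' @param scale_min,scale_max Colour scale limits in `unit`; `NULL` for
#'   auto-scaling (`scale_min` 0, `scale_max` the 99.5th percentile of
#'   unmasked values, which keeps the unbounded near-electrode field from
#'   washing out the map).
#' @param unit Display unit for the scale; one of `"V/cm"`, `"V/mm"`,
#'   `"V/in"`.
#' @param annotate_thresholds Draw labelled threshold lines on the colour
#'   bar when they fall inside the scale.
#' @param show_tumor_circle Overlay the tumor boundary circle.
#' @param show_electrodes Draw masked electrode pixels in polarity-distinct
#'   colours (anode dark red, cathode dark blue).
#' @param output_size Output image side in pixels (nearest-neighbour
#'   upscale when larger than the mesh); default 400.
#' @param log_scale Map colours to log10 of the field instead of the field
#'   itself (requires positive scale limits); off by default.
#' @return An object of class `nf_render_spec`.
#' @export
render_spec <- function(palette = "hot", scale_min = NULL, scale_max = NULL,
                        unit = c("V/cm", "V/mm", "V/in"),
                        annotate_thresholds = TRUE, show_tumor_circle = TRUE,
                        show_electrodes = TRUE, output_size = 400L,
                        log_scale = FALSE) {
  unit <- match.arg(unit)
  if (!palette %in% names(.nf_palettes))
    stop("unknown palette '", palette, "'", call. = FALSE)
  if (!is.null(scale_min) && !is.null(scale_max) && scale_min >= scale_max)
    stop("scale_min must be < scale_max", call. = FALSE)
  structure(list(palette = palette, scale_min = scale_min,
                 scale_max = scale_max, unit = unit,
                 annotate_thresholds = isTRUE(annotate_thresholds),
                 show_tumor_circle = isTRUE(show_tumor_circle),
                 show_electrodes = isTRUE(show_electrodes),
                 output_size = as.integer(output_size),
                 log_scale = isTRUE(log_scale)),
            class = "nf_render_spec")
}

#' Resolve auto colour-scale limits against a field map
#' @param map An `nf_field_map`.
#' @param spec An `nf_render_spec`.
#' @return The spec with explicit `scale_min` / `scale_max` (in `spec$unit`).
#' @export
resolve_scale <- function(map, spec) {
  v <- convert_field_unit(map$values[!map$mask], "V/m", spec$unit)
  if (is.null(spec$scale_min))
    spec$scale_min <- if (spec$log_scale) max(min(v), 1e-6) else 0
  if (is.null(spec$scale_max))
    spec$scale_max <- as.numeric(stats::quantile(v, 0.995, names = FALSE))
  if (spec$scale_min >= spec$scale_max)
    stop("degenerate colour scale: scale_min (", spec$scale_min,
         ") >= scale_max (", spec$scale_max, ") ", spec$unit, call. = FALSE)
  spec
}

.nf_marker_cols <- list(anode = c(0.70, 0.13, 0.13), cathode = c(0.00, 0.00, 0.50),
                        tumor = c(1, 1, 1))

#' Render a field map as an RGB raster
#'
#' One coloured pixel per mesh point (nearest-neighbour upscaled when
#' `output_size` exceeds the mesh), with row 1 at the top of the display
#' (maximum y). Masked inside-electrode points are drawn in
#' polarity-distinct marker colours and the tumor boundary circle is
#' overlaid when enabled. Rendering is pure: identical inputs give
#' bit-identical output.
#'
#' @param map An `nf_field_map`.
#' @param spec An `nf_render_spec`.
#' @return An `output_size` x `output_size` x 3 numeric array in \[0, 1\]
#'   (class `nf_raster`), suitable for [write_png()].
#' @export
colorize <- function(map, spec = render_spec()) {
  stopifnot(inherits(map, "nf_field_map"), inherits(spec, "nf_render_spec"))
  spec <- resolve_scale(map, spec)
  v <- convert_field_unit(map$values, "V/m", spec$unit)
  if (spec$log_scale) {
    if (spec$scale_min <= 0) stop("log scale requires scale_min > 0", call. = FALSE)
    t <- (log10(pmax(v, spec$scale_min)) - log10(spec$scale_min)) /
         (log10(spec$scale_max) - log10(spec$scale_min))
  } else {
    t <- (v - spec$scale_min) / (spec$scale_max - spec$scale_min)
  }
  t[is.na(t)] <- 0
  rgb <- palette_lookup(as.vector(t), spec$palette)
  ny <- map$spec$n_y; nx <- map$spec$n_x
  img <- array(rgb, dim = c(ny, nx, 3))

  if (spec$show_electrodes) {
    ax <- mesh_axes(map$spec)
    X <- matrix(ax$x, ny, nx, byrow = TRUE)
    Y <- matrix(ax$y, ny, nx)
    r0 <- map$layout$electrode_radius
    for (el in all_electrodes(map$layout)) {
      hit <- (X - el$x)^2 + (Y - el$y)^2 <= r0^2
      col <- .nf_marker_cols[[el$polarity]]
      for (k in 1:3) { ch <- img[, , k]; ch[hit] <- col[k]; img[, , k] <- ch }
    }
  }
  if (spec$show_tumor_circle && map$layout$tumor_diameter > 0) {
    ax <- mesh_axes(map$spec)
    X <- matrix(ax$x, ny, nx, byrow = TRUE)
    Y <- matrix(ax$y, ny, nx)
    R <- map$layout$tumor_diameter / 2
    px <- map$spec$extent / max(nx, ny)
    ring <- abs(sqrt(X^2 + Y^2) - R) <= px / 2
    for (k in 1:3) { ch <- img[, , k]; ch[ring] <- .nf_marker_cols$tumor[k]; img[, , k] <- ch }
  }

  img <- img[rev(seq_len(ny)), , , drop = FALSE]   # row 1 = top (max y)
  out <- spec$output_size
  if (out != nx || out != ny) {
    ri <- ceiling(seq_len(out) / out * ny)
    ci <- ceiling(seq_len(out) / out * nx)
    img <- img[ri, ci, , drop = FALSE]
  }
  structure(img, class = "nf_raster")
}

# --- minimal 3x5 bitmap glyphs for deterministic numeric labels ----------
.nf_glyphs <- list(
  "0" = c("111","101","101","101","111"), "1" = c("010","110","010","010","111"),
  "2" = c("111","001","111","100","111"), "3" = c("111","001","111","001","111"),
  "4" = c("101","101","111","001","001"), "5" = c("111","100","111","001","111"),
  "6" = c("111","100","111","101","111"), "7" = c("111","001","010","010","010"),
  "8" = c("111","101","111","101","111"), "9" = c("111","101","111","001","111"),
  "." = c("000","000","000","000","010"), "-" = c("000","000","111","000","000"),
  "/" = c("001","001","010","100","100"), " " = c("000","000","000","000","000")
)

# stamp `text` onto img (H x W x 3) with glyph top-left at (row, col)
.nf_stamp_text <- function(img, text, row, col, colour = c(0, 0, 0), zoom = 2L) {
  chars <- strsplit(text, "")[[1]]
  H <- dim(img)[1]; W <- dim(img)[2]
  for (ch in chars) {
    g <- .nf_glyphs[[ch]]
    if (!is.null(g)) {
      for (r in 1:5) for (c in 1:3) {
        if (substr(g[r], c, c) == "1") {
          rr <- row + (r - 1L) * zoom + seq_len(zoom) - 1L
          cc <- col + (c - 1L) * zoom + seq_len(zoom) - 1L
          rr <- rr[rr >= 1 & rr <= H]; cc <- cc[cc >= 1 & cc <= W]
          for (k in 1:3) img[rr, cc, k] <- colour[k]
        }
      }
    }
    col <- col + 4L * zoom
  }
  img
}

#' Render an annotated colour bar
#'
#' A vertical palette ramp with numeric tick labels at the scale limits,
#' and -- when `annotate_thresholds` is on and the values fall inside the
#' scale -- labelled marker lines at the reversible and irreversible
#' thresholds. Tick geometry is identical across palettes.
#'
#' @param spec An `nf_render_spec` with explicit scale limits (in
#'   `spec$unit`).
#' @param thr An `nf_thresholds` (converted to `spec$unit` for placement).
#' @return A raster array (class `nf_raster`): height `spec$output_size`,
#'   width 100, RGB in \[0, 1\].
#' @export
render_colorbar <- function(spec, thr) {
  stopifnot(inherits(spec, "nf_render_spec"), inherits(thr, "nf_thresholds"))
  if (is.null(spec$scale_min) || is.null(spec$scale_max))
    stop("render_colorbar needs explicit scale limits; see resolve_scale()",
         call. = FALSE)
  H <- spec$output_size; W <- 100L
  img <- array(1, dim = c(H, W, 3))          # white background
  r0 <- 11L; r1 <- H - 10L                   # ramp rows (r0 top = scale_max)
  c0 <- 11L; c1 <- 40L
  rgb <- palette_lookup((r1 - seq(r0, r1)) / (r1 - r0), spec$palette)
  for (k in 1:3) img[r0:r1, c0:c1, k] <- rgb[, k]

  fmt <- function(v) formatC(v, format = "g", digits = 6)
  row_of <- function(value) {
    f <- (value - spec$scale_min) / (spec$scale_max - spec$scale_min)
    as.integer(round(r1 - f * (r1 - r0)))
  }
  tick <- function(img, value, colour, label) {
    r <- row_of(value)
    for (k in 1:3) img[r, c0:(c1 + 6L), k] <- colour[k]
    .nf_stamp_text(img, label, row = max(1L, r - 5L), col = c1 + 10L,
                   colour = colour)
  }
  img <- tick(img, spec$scale_min, c(0, 0, 0), fmt(spec$scale_min))
  img <- tick(img, spec$scale_max, c(0, 0, 0), fmt(spec$scale_max))
  if (spec$annotate_thresholds) {
    for (v in c(rev_ = convert_field_unit(thr$e_rev, thr$unit, spec$unit),
                irr_ = convert_field_unit(thr$e_irrev, thr$unit, spec$unit))) {
      if (v >= spec$scale_min && v <= spec$scale_max)
        img <- tick(img, v, c(0, 0.45, 0), fmt(v))
    }
  }
  structure(img, class = "nf_raster")
}

#' Write a raster to a PNG file
#' @param raster An `nf_raster` (H x W x 3 array in \[0, 1\]).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_png <- function(raster, path) {
  png::writePNG(unclass(raster), target = path)
  invisible(path)
}
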