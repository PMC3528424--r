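#' Create a needle electrode
#'
#' An electrode is a long cylindrical conductor inserted perpendicular to
#' the modelled tissue slice, reduced here to its cross-section: a centre
#' point and a polarity. Coordinates are in metres with the origin at the
#' centre of the tissue square, x rightward and y upward.
#'
#' @param x,y Coordinates of the geometric centre (m).
#' @param polarity `"anode"` or `"cathode"`.
#' @param id Optional label; defaults to an auto-generated one.
#' @return An object of class `nf_electrode`.
#' @examples
#' electrode(-0.008, 0, "anode")
#' @export
electrode <- function(x, y, polarity = c("anode", "cathode"), id = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x),
            is.numeric(y), length(y) == 1L, is.finite(y))
  structure(
    list(x = as.numeric(x), y = as.numeric(y), polarity = polarity,
         id = if (is.null(id)) paste0(substr(polarity, 1, 1), "?") else as.character(id)),
    class = "nf_electrode"
  )
}

#' Create an electrode group
#'
#' A group is the unit of activation: one electrode of one polarity and
#' one or more of the other, all driven at a single applied voltage.
#' Pulse generators energise one anode--cathode pair at a time, so a
#' group of n electrodes decomposes into n - 1 pairs sharing the
#' singleton electrode.
#'
#' @param electrodes List of [electrode()] objects (at least 2).
#' @param voltage Applied voltage across each pair of the group (V), > 0.
#' @return An object of class `nf_group`.
#' @export
electrode_group <- function(electrodes, voltage) {
  if (!is.list(electrodes) || length(electrodes) < 2L ||
      !all(vapply(electrodes, inherits, logical(1), "nf_electrode")))
    stop("`electrodes` must be a list of >= 2 electrode objects", call. = FALSE)
  if (!is.numeric(voltage) || length(voltage) != 1L || !is.finite(voltage) || voltage <= 0)
    stop("group `voltage` must be a single positive number (V)", call. = FALSE)
  pol <- vapply(electrodes, `[[`, character(1), "polarity")
  n_an <- sum(pol == "anode"); n_ca <- sum(pol == "cathode")
  if (n_an == 0L || n_ca == 0L)
    stop("a group must contain both polarities (one cathode and one or more anodes, or vice versa)",
         call. = FALSE)
  if (n_an != 1L && n_ca != 1L)
    stop("a group must have exactly one electrode of one polarity ",
         "(one cathode and one or more anodes, or vice versa); got ",
         n_an, " anodes and ", n_ca, " cathodes", call. = FALSE)
  structure(list(electrodes = electrodes, voltage = as.numeric(voltage)),
            class = "nf_group")
}

# Minimum admissible clearance between conductor surfaces (m); pairs closer
# than 2*rho0 + this are rejected at validation time, not at computation time.
.nf_min_clearance <- 1e-9

#' Create and validate a full electrode layout
#'
#' The layout holds every quantity that defines a model run geometry: the
#' electrode groups, the common electrode radius, the square tissue region
#' and the centred circular tumor. Validation enforces the tool's bounds
#' (2--12 electrodes, 1--6 groups, non-overlapping conductors) at
#' construction so downstream computation can assume an admissible
#' configuration.
#'
#' @param groups List of [electrode_group()] objects (1 to 6).
#' @param electrode_radius Common conductor radius rho0 (m), > 0.
#' @param tissue_side Side length of the square tissue region (m).
#' @param tumor_diameter Diameter of the centred tumor circle (m),
#'   between 0 and `tissue_side`.
#' @param conductivity_ratio Tumor-to-tissue conductivity ratio. Stored and
#'   round-tripped for completeness, but the field model treats the whole
#'   area as homogeneous in conductivity, so this value does not enter any
#'   computation.
#' @return An object of class `nf_layout`.
#' @seealso [enumerate_pairs()], [evaluate_mesh()]
#' @export
layout <- function(groups, electrode_radius, tissue_side, tumor_diameter,
                   conductivity_ratio = 1) {
  if (inherits(groups, "nf_group")) groups <- list(groups)
  if (!is.list(groups) || length(groups) < 1L ||
      !all(vapply(groups, inherits, logical(1), "nf_group")))
    stop("`groups` must be a list of electrode_group objects", call. = FALSE)
  if (length(groups) > 6L)
    stop("at most 6 electrode groups are supported; got ", length(groups), call. = FALSE)
  stopifnot(is.numeric(electrode_radius), electrode_radius > 0,
            is.numeric(tissue_side), tissue_side > 0,
            is.numeric(tumor_diameter), tumor_diameter >= 0)
  if (tumor_diameter > tissue_side)
    stop("tumor_diameter (", tumor_diameter, " m) exceeds tissue_side (",
         tissue_side, " m)", call. = FALSE)

  els <- unlist(lapply(groups, `[[`, "electrodes"), recursive = FALSE)
  n <- length(els)
  if (n < 2L || n > 12L)
    stop("total electrode count must be in [2, 12]; got ", n, call. = FALSE)

  half <- tissue_side / 2
  for (el in els)
    if (abs(el$x) > half || abs(el$y) > half)
      stop("electrode '", el$id, "' at (", el$x, ", ", el$y,
           ") m lies outside the tissue square of side ", tissue_side, " m",
           call. = FALSE)

  # no overlapping/touching conductors within a group (these form pairs)
  for (g in groups) {
    ge <- g$electrodes
    for (i in seq_len(length(ge) - 1L)) for (j in seq.int(i + 1L, length(ge))) {
      d <- sqrt((ge[[i]]$x - ge[[j]]$x)^2 + (ge[[i]]$y - ge[[j]]$y)^2)
      if (d <= 2 * electrode_radius + .nf_min_clearance)
        stop("electrodes '", ge[[i]]$id, "' and '", ge[[j]]$id,
             "' are closer (", signif(d, 6), " m) than the conductor diameter ",
             2 * electrode_radius, " m: overlapping electrodes", call. = FALSE)
    }
  }

  structure(
    list(groups = groups, electrode_radius = as.numeric(electrode_radius),
         tissue_side = as.numeric(tissue_side),
         tumor_diameter = as.numeric(tumor_diameter),
         conductivity_ratio = as.numeric(conductivity_ratio)),
    class = "nf_layout"
  )
}

#' @export
print.nf_layout <- function(x, ...) {
  n <- length(all_electrodes(x))
  cat("<nf_layout> ", n, " electrodes in ", length(x$groups), " group(s); ",
      "tissue side ", signif(x$tissue_side * 1e3, 6), " mm; tumor diameter ",
      signif(x$tumor_diameter * 1e3, 6), " mm; electrode radius ",
      signif(x$electrode_radius * 1e3, 6), " mm\n", sep = "")
  invisible(x)
}

#' All electrodes of a layout, flattened over groups
#' @param layout An `nf_layout`.
#' @return A list of `nf_electrode` objects.
#' @export
all_electrodes <- function(layout) {
  unlist(lapply(layout$groups, `[[`, "electrodes"), recursive = FALSE)
}

#' Eccentricity of the electrical axes of a two-conductor pair
#'
#' In the image-charge solution for two parallel cylindrical conductors the
#' equivalent line charges do not sit on the geometric axes: each is
#' displaced toward the other conductor by the eccentricity
#' \deqn{e = d_{AB}/2 - \sqrt{(d_{AB}/2)^2 - \rho_0^2},}
#' which satisfies the exact identity \eqn{e (d_{AB} - e) = \rho_0^2}.
#'
#' @param d_AB Centre-to-centre distance between the conductors (m).
#' @param rho0 Conductor radius (m).
#' @return Eccentricity e (m), with 0 < e < rho0.
#' @examples
#' eccentricity(0.016, 0.001)  # 6.27461e-05 m for a 1.6 cm / 1 mm-radius pair
#' @export
eccentricity <- function(d_AB, rho0) {
  if (!is.numeric(d_AB) || !is.numeric(rho0) || any(d_AB <= 0) || any(rho0 <= 0))
    stop("d_AB and rho0 must be positive", call. = FALSE)
  if (any(d_AB <= 2 * rho0))
    stop("d_AB must exceed 2*rho0 (electrodes touching or overlapping)", call. = FALSE)
  half <- d_AB / 2
  half - sqrt(half^2 - rho0^2)
}

#' Electrical-axis geometry of an anode--cathode pair
#'
#' Builds every derived quantity the closed-form field expression needs for
#' one pair: the centre distance, the half-distance s between the electrical
#' axes, the eccentricity e, the direction angles, the electrical-axis
#' coordinates obtained by displacing each geometric centre by e toward the
#' other electrode (a rotational transformation using the quadrant-aware
#' two-argument arctangent), and optionally the pair potential scale C.
#'
#' @param A,B `nf_electrode` objects (A is taken as the positive conductor).
#' @param rho0 Conductor radius (m).
#' @param voltage Optional pair voltage (V); when given, the constant C is
#'   attached via [pair_constant()].
#' @return An object of class `nf_pair_geometry` with fields `d_AB`, `rho0`,
#'   `e`, `s`, `theta1`, `theta2`, `xpA`, `ypA`, `xpB`, `ypB`, `xA`, `yA`,
#'   `xB`, `yB`, `voltage`, `C`.
#' @export
electrical_axes <- function(A, B, rho0, voltage = NULL) {
  stopifnot(inherits(A, "nf_electrode"), inherits(B, "nf_electrode"))
  dx <- B$x - A$x; dy <- B$y - A$y
  d_AB <- sqrt(dx^2 + dy^2)
  if (d_AB == 0)
    stop("electrodes '", A$id, "' and '", B$id, "' have coincident centres",
         call. = FALSE)
  e <- eccentricity(d_AB, rho0)   # also validates d_AB > 2*rho0
  s <- sqrt((d_AB / 2)^2 - rho0^2)
  theta1 <- atan2(dy, dx)         # direction A -> B
  theta2 <- atan2(-dy, -dx)       # direction B -> A
  pg <- list(
    d_AB = d_AB, rho0 = rho0, e = e, s = s,
    theta1 = theta1, theta2 = theta2,
    xpA = A$x + e * cos(theta1), ypA = A$y + e * sin(theta1),
    xpB = B$x + e * cos(theta2), ypB = B$y + e * sin(theta2),
    xA = A$x, yA = A$y, xB = B$x, yB = B$y,
    voltage = if (is.null(voltage)) NA_real_ else as.numeric(voltage),
    C = NA_real_
  )
  if (!is.null(voltage)) pg$C <- pair_constant(voltage, d_AB, rho0)
  structure(pg, class = "nf_pair_geometry")
}

#' Enumerate the anode--cathode pairs of a layout
#'
#' Each group decomposes into pairs of the singleton-polarity electrode with
#' every electrode of the majority polarity, at the group voltage. Pairs are
#' never formed across groups: only one pair is pulsed at a time, and the
#' multi-electrode field is composed as a pointwise maximum over pairs.
#'
#' @param layout An `nf_layout`.
#' @return A list of `nf_pair_geometry` objects (with voltages and C set),
#'   one per anode--cathode pair, ordered by group then by majority
#'   electrode. Each element also carries `anode` and `cathode` fields.
#' @export
enumerate_pairs <- function(layout) {
  stopifnot(inherits(layout, "nf_layout"))
  rho0 <- layout$electrode_radius
  out <- list()
  for (g in layout$groups) {
    pol <- vapply(g$electrodes, `[[`, character(1), "polarity")
    singleton_pol <- if (sum(pol == "anode") == 1L) "anode" else "cathode"
    hub <- g$electrodes[[which(pol == singleton_pol)]]
    for (other in g$electrodes[pol != singleton_pol]) {
      an <- if (singleton_pol == "anode") hub else other
      ca <- if (singleton_pol == "anode") other else hub
      pg <- electrical_axes(an, ca, rho0, voltage = g$voltage)
      pg$anode <- an; pg$cathode <- ca
      out[[length(out) + 1L]] <- pg
    }
  }
  out
}

#' Construct a standard fixture layout
#'
#' Three canonical arrangements used throughout examples and tests:
#' `"pair"` is a single opposed anode--cathode pair spaced `spacing` apart;
#' `"two_rows"` is three anodes facing three cathodes (three groups, each
#' pairing opposite electrodes across the rows, rows `spacing` apart and
#' electrodes `spacing/2` apart within a row); `"hex6"` places six
#' electrodes of alternating polarity on a circle of circumradius `spacing`
#' (three groups of adjacent pairs).
#'
#' @param kind One of `"pair"`, `"two_rows"`, `"hex6"`.
#' @param spacing Characteristic spacing (m); see Details per kind.
#' @param voltage Applied group voltage (V).
#' @param electrode_radius Conductor radius (m); default 0.5 mm.
#' @param tissue_side Side of the tissue square (m); default 4x spacing.
#' @param tumor_diameter Tumor circle diameter (m); default 1.25x spacing.
#' @return A valid `nf_layout`.
#' @examples
#' make_fixture_layout("pair", spacing = 0.016, voltage = 1300)
#' @export
make_fixture_layout <- function(kind = c("pair", "two_rows", "hex6"),
                                spacing, voltage,
                                electrode_radius = 5e-4,
                                tissue_side = 4 * spacing,
                                tumor_diameter = 1.25 * spacing) {
  kind <- match.arg(kind)
  stopifnot(spacing > 2 * electrode_radius, voltage > 0)
  h <- spacing / 2
  groups <- switch(kind,
    pair = list(electrode_group(list(
      electrode(-h, 0, "anode", "a1"),
      electrode(+h, 0, "cathode", "c1")), voltage)),
    two_rows = {
      xs <- c(-h, 0, h)
      lapply(seq_along(xs), function(i) electrode_group(list(
        electrode(xs[i], +h, "anode", paste0("a", i)),
        electrode(xs[i], -h, "cathode", paste0("c", i))), voltage))
    },
    hex6 = {
      ang <- (0:5) * pi / 3
      els <- lapply(0:5, function(k) electrode(
        spacing * cos(ang[k + 1]), spacing * sin(ang[k + 1]),
        if (k %% 2 == 0) "anode" else "cathode", paste0("e", k + 1)))
      lapply(c(1, 3, 5), function(k) electrode_group(els[k:(k + 1)], voltage))
    })
  layout(groups, electrode_radius, tissue_side, tumor_diameter)
}
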