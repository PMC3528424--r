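# User-facing configuration bounds (display units: mm, mm^2).
.nf_bounds <- list(
  tissue_area_mm2 = c(1.61, 16129.00),
  electrode_diameter_mm = c(0.10, 2.00),
  n_electrodes = c(2L, 12L),
  n_groups = c(1L, 6L)
)
.nf_schema_version <- 1L

#' Default application configuration (user-facing units)
#'
#' Supplies every optional field of a configuration document: default
#' thresholds 300 / 800 V/cm, a 400 x 400 mesh, the `"hot"` palette and a
#' tumor-to-tissue diameter ratio of 0.5. The tissue region is a square of
#' side `sqrt(tissue_area)`; the tumor is a centred circle of diameter
#' `tumor_tissue_ratio * tissue_side`.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    schema_version = .nf_schema_version,
    tissue_area_mm2 = 1600,
    tumor_tissue_ratio = 0.5,
    conductivity_ratio = 1.0,
    electrode_diameter_mm = 1.0,
    groups = list(),
    thresholds = list(e_rev = 300, e_irrev = 800, unit = "V/cm"),
    mesh = list(n_x = 400L, n_y = 400L),
    render = list(palette = "hot", output_size = 400L),
    seed = 1L
  )
}

.nf_known_keys <- c("schema_version", "tissue_area_mm2", "tumor_tissue_ratio",
                    "conductivity_ratio", "electrode_diameter_mm", "groups",
                    "thresholds", "mesh", "render", "seed")

#' Validate a raw configuration document
#'
#' Checks a parsed configuration (a list, e.g. from [jsonlite::fromJSON()]
#' or [yaml::read_yaml()]) against the tool's bounds: tissue area
#' 1.61--16129.00 mm^2, electrode diameter 0.10--2.00 mm, 2--12 electrodes
#' in 1--6 groups, each group one singleton polarity facing one or more of
#' the other, positive group voltages, electrodes inside the tissue square
#' and not overlapping. ALL violations are collected and reported together,
#' each naming the field, the offending value and the admissible range. A
#' warning notes that `conductivity_ratio` is stored but not used in the
#' field computation when it differs from 1.
#'
#' @param raw A named list (parsed JSON/YAML document). Missing optional
#'   fields take the [default_config()] values.
#' @return On success, an object of class `nf_app_config`: the canonical
#'   user-facing fields plus a derived `$layout` (`nf_layout`),
#'   `$thresholds` (`nf_thresholds`), `$mesh` (`nf_mesh_spec`) and
#'   `$render` (`nf_render_spec`). On failure, an object of class
#'   `nf_config_errors` (character vector of violations).
#' @export
validate_config <- function(raw) {
  if (!is.list(raw)) return(structure("configuration is not a key-value document",
                                      class = "nf_config_errors"))
  # modifyList merges named lists recursively but drops unnamed ones
  # (electrode groups), so splice those in verbatim
  cfg <- utils::modifyList(default_config(), raw[names(raw) != "groups"])
  if (!is.null(raw$groups)) cfg$groups <- raw$groups
  errs <- character()
  add <- function(...) errs <<- c(errs, paste0(...))

  num_in <- function(name, value, lo, hi, unit = "") {
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
      add(name, ": not a finite number (got '", paste(value, collapse = ","), "')")
      FALSE
    } else if (value < lo || value > hi) {
      add(name, " = ", value, unit, " outside admissible range [", lo, ", ",
          hi, "]", unit)
      FALSE
    } else TRUE
  }

  b <- .nf_bounds
  ok_area <- num_in("tissue_area_mm2", cfg$tissue_area_mm2,
                    b$tissue_area_mm2[1], b$tissue_area_mm2[2], " mm^2")
  ok_diam <- num_in("electrode_diameter_mm", cfg$electrode_diameter_mm,
                    b$electrode_diameter_mm[1], b$electrode_diameter_mm[2], " mm")
  ok_ratio <- num_in("tumor_tissue_ratio", cfg$tumor_tissue_ratio, 0, 1)

  thr <- NULL
  tl <- cfg$thresholds
  if (!is.list(tl) || !all(c("e_rev", "e_irrev") %in% names(tl))) {
    add("thresholds: must provide e_rev and e_irrev")
  } else {
    unit <- if (is.null(tl$unit)) "V/cm" else tl$unit
    thr <- tryCatch(thresholds(tl$e_rev, tl$e_irrev, unit),
                    error = function(e) { add("thresholds: ", conditionMessage(e)); NULL })
  }

  if (!is.list(cfg$groups)) {
    add("groups: must be a list of electrode groups")
    cfg$groups <- list()
  }
  ng <- length(cfg$groups)
  if (ng < b$n_groups[1] || ng > b$n_groups[2])
    add("groups: count ", ng, " outside admissible range [",
        b$n_groups[1], ", ", b$n_groups[2], "]")

  # electrodes: structural checks first, then assemble
  groups <- list(); n_el <- 0L
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    gname <- paste0("groups[", gi, "]")
    if (!is.list(g) || is.null(g$electrodes) || !is.list(g$electrodes)) {
      add(gname, ": missing electrode list"); next
    }
    if (is.null(g$voltage_V) || !is.numeric(g$voltage_V) || g$voltage_V <= 0) {
      add(gname, ".voltage_V = ", paste(g$voltage_V, collapse = ","),
          " must be a positive voltage (V)")
    }
    els <- list(); bad <- FALSE
    for (ei in seq_along(g$electrodes)) {
      e <- g$electrodes[[ei]]
      ename <- paste0(gname, ".electrodes[", ei, "]")
      if (!is.list(e) || is.null(e$x_mm) || is.null(e$y_mm) || is.null(e$polarity)) {
        add(ename, ": needs x_mm, y_mm and polarity"); bad <- TRUE; next
      }
      if (!e$polarity %in% c("anode", "cathode")) {
        add(ename, ".polarity = '", e$polarity, "' must be 'anode' or 'cathode'")
        bad <- TRUE; next
      }
      els[[length(els) + 1L]] <- electrode(e$x_mm * 1e-3, e$y_mm * 1e-3, e$polarity,
                                           if (is.null(e$id)) paste0("g", gi, "e", ei) else e$id)
    }
    n_el <- n_el + length(g$electrodes)
    if (bad) next
    grp <- tryCatch(electrode_group(els, g$voltage_V),
                    error = function(err) { add(gname, ": ", conditionMessage(err)); NULL })
    if (!is.null(grp)) groups[[length(groups) + 1L]] <- grp
  }
  if (n_el < b$n_electrodes[1] || n_el > b$n_electrodes[2])
    add("electrodes: total count ", n_el, " outside admissible range [",
        b$n_electrodes[1], ", ", b$n_electrodes[2], "]")

  lay <- NULL
  if (ok_area && ok_diam && ok_ratio && length(groups) == ng && ng >= 1 &&
      n_el >= b$n_electrodes[1] && n_el <= b$n_electrodes[2] &&
      ng <= b$n_groups[2]) {
    side_m <- sqrt(cfg$tissue_area_mm2) * 1e-3
    lay <- tryCatch(
      layout(groups,
             electrode_radius = cfg$electrode_diameter_mm / 2 * 1e-3,
             tissue_side = side_m,
             tumor_diameter = cfg$tumor_tissue_ratio * side_m,
             conductivity_ratio = cfg$conductivity_ratio),
      error = function(e) { add("layout: ", conditionMessage(e)); NULL })
  }

  if (length(errs) > 0L)
    return(structure(errs, class = "nf_config_errors"))

  if (!isTRUE(all.equal(cfg$conductivity_ratio, 1)))
    warning("conductivity_ratio is stored but not used in the field ",
            "computation (homogeneous-conductivity model)", call. = FALSE)

  mesh <- mesh_spec(lay$tissue_side, cfg$mesh$n_x, cfg$mesh$n_y)
  rnd <- do.call(render_spec, cfg$render)
  structure(list(
    schema_version = cfg$schema_version,
    tissue_area_mm2 = cfg$tissue_area_mm2,
    tumor_tissue_ratio = cfg$tumor_tissue_ratio,
    conductivity_ratio = cfg$conductivity_ratio,
    electrode_diameter_mm = cfg$electrode_diameter_mm,
    groups = cfg$groups,
    thresholds_raw = cfg$thresholds,
    mesh_raw = cfg$mesh,
    render_raw = cfg$render,
    seed = cfg$seed,
    layout = lay, thresholds = thr, mesh = mesh, render = rnd
  ), class = "nf_app_config")
}

#' @export
print.nf_config_errors <- function(x, ...) {
  cat("configuration invalid (", length(x), " violation",
      if (length(x) > 1) "s", "):\n", sep = "")
  for (m in x) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

#' Save a configuration to canonical JSON
#'
#' @param config An `nf_app_config` (or a raw list already in user-facing
#'   form).
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  doc <- config_document(config)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Canonical user-facing document of a configuration
#' @param config An `nf_app_config` or raw list.
#' @return A named list ready for serialization.
#' @export
config_document <- function(config) {
  if (inherits(config, "nf_app_config"))
    list(schema_version = config$schema_version,
         tissue_area_mm2 = config$tissue_area_mm2,
         tumor_tissue_ratio = config$tumor_tissue_ratio,
         conductivity_ratio = config$conductivity_ratio,
         electrode_diameter_mm = config$electrode_diameter_mm,
         groups = config$groups,
         thresholds = config$thresholds_raw,
         mesh = config$mesh_raw,
         render = config$render_raw,
         seed = config$seed)
  else config
}

#' Load and validate a configuration file
#'
#' JSON is the canonical format; YAML is accepted as a convenience dialect
#' (by `.yaml` / `.yml` extension). Unknown top-level keys produce a
#' warning and are ignored (forward tolerance); a schema_version other than
#' the supported one is a migration error; a malformed file is a parse
#' error with no partial configuration.
#'
#' @param path Configuration file path.
#' @return An `nf_app_config`, or an error.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw)) stop("configuration file is not a key-value document: ",
                          path, call. = FALSE)
  unknown <- setdiff(names(raw), .nf_known_keys)
  if (length(unknown) > 0L)
    warning("ignoring unknown configuration key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  raw <- raw[intersect(names(raw), .nf_known_keys)]
  sv <- raw$schema_version
  if (!is.null(sv) && !identical(as.integer(sv), .nf_schema_version))
    stop("configuration schema_version ", sv, " not supported (expected ",
         .nf_schema_version, "); migrate the file", call. = FALSE)
  res <- validate_config(raw)
  if (inherits(res, "nf_config_errors"))
    stop("invalid configuration '", path, "':\n  - ",
         paste(res, collapse = "\n  - "), call. = FALSE)
  res
}

#' Configuration document for a fixture layout
#'
#' Builds the canonical user-facing document corresponding to
#' [make_fixture_layout()], ready to save or validate.
#'
#' @inheritParams make_fixture_layout
#' @return A named list (raw configuration document).
#' @export
fixture_config <- function(kind = c("pair", "two_rows", "hex6"),
                           spacing = 0.016, voltage = 1300,
                           electrode_radius = 5e-4) {
  kind <- match.arg(kind)
  lay <- make_fixture_layout(kind, spacing, voltage,
                             electrode_radius = electrode_radius)
  doc <- default_config()
  doc$tissue_area_mm2 <- (lay$tissue_side * 1e3)^2
  doc$tumor_tissue_ratio <- lay$tumor_diameter / lay$tissue_side
  doc$electrode_diameter_mm <- 2 * electrode_radius * 1e3
  doc$groups <- lapply(lay$groups, function(g) list(
    voltage_V = g$voltage,
    electrodes = lapply(g$electrodes, function(e) list(
      id = e$id, x_mm = e$x * 1e3, y_mm = e$y * 1e3, polarity = e$polarity))
  ))
  doc
}
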