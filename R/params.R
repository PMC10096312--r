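#' Built-in element parameter table
#'
#' Per-element perception parameters: covalent radius (Cordero 2008 values,
#' Angstrom), the maximum number of covalent bonds the element may form, and
#' flags marking metals (candidates for organometallic contacts) and ion
#' candidates (candidates for electrostatic contacts).
#'
#' @return A tibble with columns `symbol`, `covalent_radius`,
#'   `max_covalent_bonds`, `is_metal`, `is_ion_candidate`.
#' @export
#' @examples
#' default_elements()
default_elements <- function() {
  tibble::tribble(
    ~symbol, ~covalent_radius, ~max_covalent_bonds, ~is_metal, ~is_ion_candidate,
    "H",  0.31, 1L, FALSE, FALSE,
    "He", 0.28, 0L, FALSE, FALSE,
    "Li", 1.28, 0L, FALSE, TRUE,
    "B",  0.84, 3L, FALSE, FALSE,
    "C",  0.76, 4L, FALSE, FALSE,
    "N",  0.71, 4L, FALSE, FALSE,  # cap 4 admits NH4+/NH3+ termini
    "O",  0.66, 2L, FALSE, FALSE,
    "F",  0.57, 1L, FALSE, FALSE,
    "Na", 1.66, 0L, FALSE, TRUE,
    "Mg", 1.41, 0L, FALSE, TRUE,
    "P",  1.07, 5L, FALSE, FALSE,
    "S",  1.05, 6L, FALSE, FALSE,
    "Cl", 1.02, 1L, FALSE, FALSE,
    "K",  2.03, 0L, FALSE, TRUE,
    "Ca", 1.76, 0L, FALSE, TRUE,
    "Mn", 1.39, 8L, TRUE,  FALSE,
    "Fe", 1.32, 8L, TRUE,  FALSE,
    "Cu", 1.32, 8L, TRUE,  FALSE,
    "Zn", 1.22, 8L, TRUE,  FALSE,
    "Br", 1.20, 1L, FALSE, FALSE,
    "Ru", 1.46, 8L, TRUE,  FALSE,
    "I",  1.39, 1L, FALSE, FALSE,
    "Au", 1.36, 8L, TRUE,  FALSE
  )
}

#' Default interaction-perception thresholds
#'
#' Distance/angle cutoffs used when perceiving the typed edges of a molecular
#' graph. All distances in Angstrom, angles in degrees.
#'
#' @return A named list of class `mt_thresholds` with entries
#'   `covalent_tolerance`, `hbond_heavy_max`, `hbond_angle_min`,
#'   `electrostatic_max`, `organometallic_max`, `acceptor_elements`,
#'   `metal_elements`.
#' @export
default_thresholds <- function() {
  structure(
    list(
      covalent_tolerance = 0.40,
      hbond_heavy_max    = 3.5,
      hbond_angle_min    = 140,
      electrostatic_max  = 3.0,
      organometallic_max = 2.8,
      acceptor_elements  = c("N", "O", "F", "S", "Cl"),
      metal_elements     = c("Mn", "Fe", "Cu", "Zn", "Ru", "Au")
    ),
    class = "mt_thresholds"
  )
}

.threshold_distance_names <- c(
  "covalent_tolerance", "hbond_heavy_max", "electrostatic_max",
  "organometallic_max"
)

validate_thresholds <- function(th) {
  for (nm in .threshold_distance_names) {
    if (!is.numeric(th[[nm]]) || length(th[[nm]]) != 1 || th[[nm]] <= 0) {
      stop("threshold '", nm, "' must be a single positive distance", call. = FALSE)
    }
  }
  a <- th$hbond_angle_min
  if (!is.numeric(a) || length(a) != 1 || a < 0 || a > 180) {
    stop("hbond_angle_min must lie in [0, 180] degrees", call. = FALSE)
  }
  invisible(th)
}

validate_elements <- function(el) {
  stopifnot(is.data.frame(el))
  if (any(el$covalent_radius <= 0)) {
    stop("covalent radii must be positive", call. = FALSE)
  }
  if (any(el$max_covalent_bonds < 0 | el$max_covalent_bonds > 8)) {
    stop("max_covalent_bonds must lie in 0..8", call. = FALSE)
  }
  if (anyDuplicated(el$symbol)) stop("duplicated element symbol", call. = FALSE)
  invisible(el)
}

#' Load perception parameters, optionally overlaid with a user config
#'
#' Returns the built-in element table and thresholds, with any overrides from a
#' YAML config applied on top. The config may contain two top-level maps:
#' `thresholds` (scalar or list values keyed by threshold name) and `elements`
#' (per-symbol maps of element fields, which may introduce new symbols).
#' Unknown keys are rejected so that typos fail loudly.
#'
#' @param config Path to a YAML config file, or `NULL` for pure defaults.
#' @return A list with components `elements` (tibble) and `thresholds`
#'   (`mt_thresholds` list).
#' @seealso [write_params()] for emitting the effective configuration.
#' @export
#' @examples
#' p <- load_params()
#' p$thresholds$hbond_heavy_max
load_params <- function(config = NULL) {
  elements <- default_elements()
  thresholds <- default_thresholds()
  if (!is.null(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    cfg <- yaml::read_yaml(config)
    if (is.null(cfg)) cfg <- list()
    bad <- setdiff(names(cfg), c("thresholds", "elements"))
    if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(cfg$thresholds)) {
      if (!nm %in% names(thresholds)) stop("unknown threshold key: ", nm, call. = FALSE)
      val <- cfg$thresholds[[nm]]
      if (nm %in% c("acceptor_elements", "metal_elements")) val <- as.character(unlist(val))
      thresholds[[nm]] <- val
    }
    el_fields <- c("covalent_radius", "max_covalent_bonds", "is_metal", "is_ion_candidate")
    for (sym in names(cfg$elements)) {
      entry <- cfg$elements[[sym]]
      bad <- setdiff(names(entry), el_fields)
      if (length(bad)) stop("unknown element field(s) for ", sym, ": ", paste(bad, collapse = ", "), call. = FALSE)
      sym_norm <- normalize_symbol(sym)
      if (!sym_norm %in% elements$symbol) {
        elements <- dplyr::bind_rows(elements, tibble::tibble(
          symbol = sym_norm, covalent_radius = NA_real_, max_covalent_bonds = NA_integer_,
          is_metal = FALSE, is_ion_candidate = FALSE
        ))
      }
      i <- match(sym_norm, elements$symbol)
      for (f in names(entry)) elements[[f]][i] <- entry[[f]]
      if (is.na(elements$covalent_radius[i])) {
        stop("new element ", sym_norm, " needs a covalent_radius", call. = FALSE)
      }
      if (is.na(elements$max_covalent_bonds[i])) elements$max_covalent_bonds[i] <- 4L
    }
  }
  validate_thresholds(thresholds)
  validate_elements(elements)
  list(elements = elements, thresholds = thresholds)
}

#' Write the effective parameter configuration to YAML
#'
#' Emits every element row and threshold so that [load_params()] on the emitted
#' file reproduces identical parameters (load/emit is idempotent).
#'
#' @param params A parameter list as returned by [load_params()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  el <- params$elements
  el_list <- stats::setNames(lapply(seq_len(nrow(el)), function(i) {
    list(
      covalent_radius = el$covalent_radius[i],
      max_covalent_bonds = el$max_covalent_bonds[i],
      is_metal = el$is_metal[i],
      is_ion_candidate = el$is_ion_candidate[i]
    )
  }), el$symbol)
  th <- unclass(params$thresholds)
  yaml::write_yaml(list(thresholds = th, elements = el_list), path)
  invisible(path)
}

normalize_symbol <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

# Largest distance cutoff any perception rule can use under `params`.
max_interaction_cutoff <- function(params) {
  max(
    2 * max(params$elements$covalent_radius) + params$thresholds$covalent_tolerance,
    params$thresholds$hbond_heavy_max,
    params$thresholds$electrostatic_max,
    params$thresholds$organometallic_max
  )
}
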