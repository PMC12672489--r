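#' Indicator specifications
#'
#' An indicator specification declares, for each soil indicator, its short
#' name, measurement unit, and scoring orientation: `"more_is_better"` for
#' indicators whose larger values indicate better soil function, or
#' `"less_is_better"` for indicators (such as bulk density) whose smaller
#' values do.
#'
#' @param name Character vector of unique indicator names.
#' @param unit Character vector of units (free text), recycled.
#' @param orientation Character vector, each `"more_is_better"` or
#'   `"less_is_better"`, recycled.
#' @return A data frame with columns `name`, `unit`, `orientation`.
#' @seealso [default_indicator_specs()]
#' @export
indicator_specs <- function(name, unit = "", orientation = "more_is_better") {
  stopifnot(is.character(name), length(name) >= 1L)
  if (anyDuplicated(name)) {
    stop("duplicate indicator names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  orientation <- rep_len(orientation, length(name))
  ok <- orientation %in% c("more_is_better", "less_is_better")
  if (!all(ok)) {
    stop("invalid orientation for: ", paste(name[!ok], collapse = ", "))
  }
  data.frame(name = name, unit = rep_len(unit, length(name)),
             orientation = orientation, stringsAsFactors = FALSE)
}

#' Default 20-indicator total data set
#'
#' The standard total data set (TDS) used for mixed-plantation soil quality
#' assessment: one physical indicator (soil moisture, SM), bulk density (BD),
#' six chemical indicators (TN, TP, SOC, NH4, NO3, AP), three microbial
#' biomass pools (MBC, MBN, MBP), and nine enzymes of C, N and P cycling
#' (POD, LAP, BX, ALP, URE, CBH, NAG, ACP, BG). All indicators are scored
#' "more is better" except bulk density.
#'
#' @return A 20-row indicator specification data frame.
#' @export
default_indicator_specs <- function() {
  units <- c(
    SM = "%", BD = "g.cm-3", TN = "g.kg-1", TP = "g.kg-1", SOC = "g.kg-1",
    MBC = "mg.kg-1", NH4 = "ug.g-1", NO3 = "ug.g-1", MBN = "mg.kg-1",
    MBP = "ug.g-1", AP = "ug.g-1", POD = "umol.d-1.g-1", LAP = "umol.d-1.g-1",
    BX = "umol.d-1.g-1", ALP = "umol.d-1.g-1", URE = "umol.d-1.g-1",
    CBH = "umol.d-1.g-1", NAG = "umol.d-1.g-1", ACP = "umol.d-1.g-1",
    BG = "umol.d-1.g-1")
  specs <- indicator_specs(names(units), unname(units))
  specs$orientation[specs$name == "BD"] <- "less_is_better"
  specs
}

id_columns <- c("sample_id", "pattern_id", "plot_id")

#' Read a plot-level soil indicator table
#'
#' Reads a CSV with columns `sample_id`, `pattern_id`, `plot_id` and one
#' numeric column per declared indicator. Validation is strict: every
#' declared indicator must be present, cells must be numeric, finite and
#' non-negative, and sample ids unique. Missing values are rejected rather
#' than imputed; the assessment pipeline assumes complete cases.
#'
#' @param path Path to a CSV file (comma separated, `.` decimal, header row).
#' @param specs Indicator specification data frame; defaults to the
#'   20-indicator set of [default_indicator_specs()].
#' @return An `indicator_table`: a data frame with the three id columns
#'   followed by the indicators in declared spec order, with the specs
#'   attached as attribute `"specs"`.
#' @export
read_indicator_table <- function(path, specs = default_indicator_specs()) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_indicator_table(raw, specs)
}

#' Validate a data frame as an indicator table
#'
#' @param x Data frame with id columns and indicator columns.
#' @param specs Indicator specification data frame.
#' @return A validated `indicator_table` (columns reordered to spec order).
#' @export
as_indicator_table <- function(x, specs = default_indicator_specs()) {
  missing_id <- setdiff(id_columns, names(x))
  if (length(missing_id)) {
    stop("missing required column(s): ", paste(missing_id, collapse = ", "))
  }
  missing_ind <- setdiff(specs$name, names(x))
  if (length(missing_ind)) {
    stop("missing declared indicator column(s): ",
         paste(missing_ind, collapse = ", "))
  }
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  }
  for (ind in specs$name) {
    v <- x[[ind]]
    if (!is.numeric(v)) {
      stop("non-numeric values in indicator column '", ind, "'")
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("non-finite/missing value in column '", ind, "', row ", bad[1L])
    }
    neg <- which(v < 0)
    if (length(neg)) {
      stop("negative value in column '", ind, "', row ", neg[1L])
    }
  }
  out <- x[, c(id_columns, specs$name)]
  out$sample_id <- as.character(out$sample_id)
  out$pattern_id <- as.character(out$pattern_id)
  out$plot_id <- as.character(out$plot_id)
  attr(out, "specs") <- specs
  class(out) <- c("indicator_table", "data.frame")
  out
}

#' Write an indicator table to CSV
#'
#' @param x An `indicator_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the numeric samples-by-indicators matrix
#'
#' @param x An `indicator_table`.
#' @return Numeric matrix, rownames = sample ids, columns in spec order.
#' @export
indicator_matrix <- function(x) {
  specs <- attr(x, "specs")
  m <- as.matrix(as.data.frame(x)[, specs$name, drop = FALSE])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

#' Read a tree inventory table
#'
#' Expects columns `plot_id`, `species`, `is_broadleaf` (logical or 0/1),
#' `dbh` (stem diameter at breast height, cm) and `height` (m). DBH and
#' height must be strictly positive; the inventory records living stems.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame of tree records.
#' @export
read_tree_inventory <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tree_inventory(x)
}

#' Validate a data frame as a tree inventory
#' @param x Data frame with plot_id, species, is_broadleaf, dbh, height.
#' @return The validated inventory.
#' @export
as_tree_inventory <- function(x) {
  need <- c("plot_id", "species", "is_broadleaf", "dbh", "height")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("missing inventory column(s): ", paste(missing, collapse = ", "))
  }
  x$is_broadleaf <- as.logical(x$is_broadleaf)
  if (anyNA(x$is_broadleaf)) stop("is_broadleaf must be logical or 0/1")
  bad <- which(!is.finite(x$dbh) | x$dbh <= 0)
  if (length(bad)) stop("non-positive or missing dbh in row ", bad[1L])
  bad <- which(!is.finite(x$height) | x$height <= 0)
  if (length(bad)) stop("non-positive or missing height in row ", bad[1L])
  x$plot_id <- as.character(x$plot_id)
  x$species <- as.character(x$species)
  x
}

#' Read species-specific allometric coefficients
#'
#' Aboveground biomass is modelled as W = a (D^2 H)^b with species-specific
#' coefficients a and b. Expects CSV columns `species`, `a`, `b`.
#'
#' @param path Path to a CSV file.
#' @return Data frame with columns species, a, b; `a` strictly positive.
#' @export
read_allometric_coefs <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "a", "b")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("missing coefficient column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(x$species)) {
    stop("duplicate species in coefficient table: ",
         paste(unique(x$species[duplicated(x$species)]), collapse = ", "))
  }
  bad <- which(!is.finite(x$a) | x$a <= 0)
  if (length(bad)) stop("non-positive coefficient a in row ", bad[1L])
  if (anyNA(x$b) || any(!is.finite(x$b))) stop("missing exponent b")
  x$species <- as.character(x$species)
  x
}

#' Read plot metadata
#'
#' Expects columns `plot_id`, `pattern_id`, `area` (m^2) and `stand_age`
#' (years); the survey default is 600 m^2 plots aged 20 years.
#'
#' @param path Path to a CSV file.
#' @return Validated data frame.
#' @export
read_plot_meta <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "pattern_id", "area", "stand_age")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("missing plot metadata column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(x$area) | x$area <= 0)) stop("plot area must be > 0")
  if (any(!is.finite(x$stand_age) | x$stand_age <= 0)) {
    stop("stand_age must be > 0")
  }
  x$plot_id <- as.character(x$plot_id)
  x$pattern_id <- as.character(x$pattern_id)
  x
}

#' Load the packaged reference PCA solution
#'
#' The package ships, as plain-text fixtures, the published principal
#' component solution of a 20-indicator soil survey of fir-broadleaf mixed
#' plantations: the 20 x 6 loading matrix, component eigenvalues and
#' contribution rates, the printed norm values, communalities and group
#' labels, and the in-text Pearson correlation statements used for
#' minimum-data-set pruning (stored as an edge list; pairs reported only as
#' "not significant" carry `r = NA`).
#'
#' @return A list of class `reference_pca` with elements `indicators`,
#'   `loadings` (20 x 6 matrix), `eigenvalues`, `contribution_rate`,
#'   `cumulative_rate`, `norm`, `communality`, `group` (all named by
#'   indicator where applicable), and `correlations` (data frame `a`, `b`,
#'   `r`, `significant`).
#' @export
load_reference_pca <- function() {
  ext <- function(f) system.file("extdata", f, package = "soilqualkit",
                                 mustWork = TRUE)
  load_tab <- utils::read.csv(ext("reference_pca_loadings.csv"),
                              stringsAsFactors = FALSE)
  eig_tab <- utils::read.csv(ext("reference_pca_eigenvalues.csv"),
                             stringsAsFactors = FALSE)
  cor_tab <- utils::read.csv(ext("reference_pca_correlations.csv"),
                             stringsAsFactors = FALSE)
  pcs <- paste0("PC", seq_len(nrow(eig_tab)))
  if (!all(pcs %in% names(load_tab)) || nrow(load_tab) != 20L) {
    stop("reference PCA fixture is corrupted")
  }
  loadings <- as.matrix(load_tab[, pcs])
  rownames(loadings) <- load_tab$indicator
  if (any(abs(loadings) > 1)) stop("reference loadings outside [-1, 1]")
  if (any(eig_tab$eigenvalue < 1)) stop("reference eigenvalues below 1")
  if (is.unsorted(rev(eig_tab$eigenvalue))) {
    stop("reference eigenvalues not non-increasing")
  }
  structure(list(
    indicators = load_tab$indicator,
    loadings = loadings,
    eigenvalues = stats::setNames(eig_tab$eigenvalue, pcs),
    contribution_rate = stats::setNames(eig_tab$contribution_rate, pcs),
    cumulative_rate = stats::setNames(eig_tab$cumulative_rate, pcs),
    norm = stats::setNames(load_tab$norm, load_tab$indicator),
    communality = stats::setNames(load_tab$communality, load_tab$indicator),
    group = stats::setNames(load_tab$group, load_tab$indicator),
    correlations = cor_tab
  ), class = "reference_pca")
}

#' Read a JSON run configuration
#'
#' Optional structured-text configuration for an assessment run. Recognised
#' keys: `indicators` (list of name/unit/orientation), `stand_age`,
#' `plot_area`, `seed`. Unknown keys are kept and echoed in reports.
#'
#' @param path Path to a JSON file.
#' @return A named list; missing keys filled with defaults (stand_age 20,
#'   plot_area 600).
#' @export
read_run_config <- function(path) {
  conf <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(conf$stand_age)) conf$stand_age <- 20
  if (is.null(conf$plot_area)) conf$plot_area <- 600
  if (!is.null(conf$indicators)) {
    conf$indicators <- indicator_specs(
      name = conf$indicators$name,
      unit = if (is.null(conf$indicators$unit)) "" else conf$indicators$unit,
      orientation = conf$indicators$orientation)
  }
  conf
}
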