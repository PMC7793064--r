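#' Multi-tube staining panel design
#'
#' Describes how a cohort's marker panel is split across tubes
#' (aliquots): every tube carries the backbone markers (used later for
#' nearest-neighbour merging) plus a tube-specific subset.
#'
#' @param markers Character vector of all marker names in the panel.
#' @param tubes Named list; each element is the character vector of
#'   markers stained in that tube. Names are tube ids.
#' @param backbone Character vector of markers present in every tube.
#' @param channels Optional named character vector mapping marker name to
#'   detector channel name; defaults to `"FL<k>-A"` in panel order.
#'
#' @return An object of class `panel_design`.
#' @export
#' @examples
#' design <- default_panel()
#' design$backbone
panel_design <- function(markers, tubes, backbone, channels = NULL) {
  markers <- as.character(markers)
  stopifnot(length(markers) >= 1, !anyDuplicated(markers),
            is.list(tubes), length(tubes) >= 1, !is.null(names(tubes)))
  for (tb in tubes) {
    if (!all(tb %in% markers)) {
      stop("tube contains markers outside the panel: ",
           paste(setdiff(tb, markers), collapse = ", "))
    }
    if (anyDuplicated(tb)) stop("duplicated marker within a tube")
  }
  if (length(backbone) < 2) {
    stop("backbone must contain at least 2 markers (needed for ",
         "nearest-neighbour merging)")
  }
  for (id in names(tubes)) {
    if (!all(backbone %in% tubes[[id]])) {
      stop("backbone markers missing from tube ", id, ": ",
           paste(setdiff(backbone, tubes[[id]]), collapse = ", "))
    }
  }
  if (!setequal(unlist(tubes), markers)) {
    stop("union of tube subsets must equal the full marker panel; ",
         "unassigned: ",
         paste(setdiff(markers, unlist(tubes)), collapse = ", "))
  }
  if (is.null(channels)) {
    channels <- stats::setNames(sprintf("FL%d-A", seq_along(markers)), markers)
  }
  stopifnot(all(markers %in% names(channels)))
  structure(list(markers = markers, tubes = tubes,
                 backbone = as.character(backbone),
                 channels = channels[markers]),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat("<panel_design> ", length(x$markers), " markers, ",
      length(x$tubes), " tubes, backbone: ",
      paste(x$backbone, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default 20-marker, 3-tube B-ALL diagnostic panel
#'
#' A realistic childhood B-ALL immunophenotyping panel: B-cell markers
#' (CD19, CD10, CD20, CD22, CD24, IgM, CD66c, CD79a), T/myeloid-related
#' markers (CD7, cyCD3, CD9, CD13, CD33, CD123) and general markers
#' (CD15, CD34, CD38, CD45, CD58, HLA-DR), split over three 8-colour
#' tubes that share a 4-marker backbone (CD19, CD45, CD10, CD34).
#'
#' @return A [panel_design()].
#' @export
default_panel <- function() {
  backbone <- c("CD19", "CD45", "CD10", "CD34")
  tubes <- list(
    T1 = c(backbone, "CD20", "CD22", "CD24", "CD38"),
    T2 = c(backbone, "IgM", "CD66c", "CD79a", "CD58"),
    T3 = c(backbone, "CD7", "cyCD3", "CD9", "CD13", "CD33", "CD123",
           "CD15", "HLA-DR")
  )
  panel_design(markers = unique(unlist(tubes)), tubes = tubes,
               backbone = backbone)
}

# Baseline two-component mixture parameters per marker, on the logicle
# display scale (decades). mu_neg/mu_pos are the negative/positive
# population locations, sd_* their spreads, pi_pos the positive fraction
# in the leukaemic B-cell compartment.
.marker_baseline <- function(markers) {
  base <- tibble::tibble(
    marker = markers,
    mu_neg = 0.7, mu_pos = 2.6, sd_neg = 0.30, sd_pos = 0.35,
    pi_pos = 0.60
  )
  override <- function(b, m, ...) {
    vals <- list(...)
    i <- b$marker %in% m
    for (nm in names(vals)) b[[nm]][i] <- vals[[nm]]
    b
  }
  base <- override(base, "CD19", mu_neg = 0.5, mu_pos = 3.0, sd_neg = 0.25,
                   sd_pos = 0.28, pi_pos = 0.85)
  base <- override(base, "CD45", mu_neg = 1.2, mu_pos = 2.4, pi_pos = 0.90)
  base <- override(base, "CD10", mu_pos = 3.1, pi_pos = 0.80)
  base <- override(base, "CD34", mu_pos = 2.8, pi_pos = 0.70)
  base <- override(base, "CD38", mu_neg = 0.8, mu_pos = 2.8, pi_pos = 0.70)
  base <- override(base, c("CD20", "IgM"), pi_pos = 0.30)
  base <- override(base, c("CD7", "cyCD3", "CD15"), pi_pos = 0.05)
  base <- override(base, c("CD13", "CD33", "CD123", "CD66c", "CD9"),
                   pi_pos = 0.25)
  base <- override(base, c("CD22", "CD24", "CD58", "CD79a", "HLA-DR"),
                   pi_pos = 0.75)
  base
}

#' Ground-truth effect specification for the cohort simulator
#'
#' Defines (i) class-dependent marker shifts -- for relapse-class
#' patients, the positive population of `marker` is shifted by `delta`
#' display decades for a fraction `fraction` of cells -- and (ii) links
#' between clinical covariates and per-patient marker levels, induced by
#' thresholding latent Gaussians shared with the marker location
#' (Pearson structure controlled by `rho`).
#'
#' @param shifts Tibble/data frame with columns `marker`, `delta`
#'   (decades, finite), `fraction` (in `[0,1]`).
#' @param links Tibble/data frame with columns `covariate`, `marker`,
#'   `rho` (in `(-1,1)`) and `region` (`"high"` reads the positive
#'   population location, `"low"` the negative one).
#'
#' @return An object of class `effect_spec`.
#' @export
#' @examples
#' effect_spec(shifts = data.frame(marker = "CD38", delta = -1, fraction = 1))
effect_spec <- function(shifts = NULL, links = NULL) {
  if (is.null(shifts)) {
    shifts <- tibble::tibble(marker = character(), delta = numeric(),
                             fraction = numeric())
  }
  shifts <- tibble::as_tibble(shifts)
  stopifnot(all(c("marker", "delta") %in% names(shifts)))
  if (!"fraction" %in% names(shifts)) shifts$fraction <- 1
  if (!all(is.finite(shifts$delta))) stop("delta must be finite")
  if (!all(shifts$fraction >= 0 & shifts$fraction <= 1)) {
    stop("fraction must lie in [0, 1]")
  }
  if (is.null(links)) {
    links <- tibble::tibble(covariate = character(), marker = character(),
                            rho = numeric(), region = character())
  }
  links <- tibble::as_tibble(links)
  stopifnot(all(c("covariate", "marker", "rho") %in% names(links)))
  if (!"region" %in% names(links)) links$region <- "high"
  if (!all(abs(links$rho) < 1)) stop("rho must lie in (-1, 1)")
  structure(list(shifts = shifts, links = links), class = "effect_spec")
}

#' Default planted effects: CD38 underexpression in relapse
#'
#' Relapse-class patients have the CD38 positive population shifted down
#' by one display decade for all cells; hyperdiploid karyotype is
#' inversely linked, and female sex directly linked, to the per-patient
#' CD38 level.
#'
#' @param delta Class shift on CD38 in decades (negative = down in
#'   relapse). Default -1.
#' @param fraction Fraction of cells affected. Default 1.
#' @return An [effect_spec()].
#' @export
default_effects <- function(delta = -1, fraction = 1) {
  effect_spec(
    shifts = tibble::tibble(marker = "CD38", delta = delta,
                            fraction = fraction),
    links = tibble::tibble(
      covariate = c("hyperdiploid", "male", "t_12_21"),
      marker = "CD38",
      rho = c(-0.5, -0.4, 0.4),
      region = "high"
    )
  )
}

#' Null effect specification (no planted differences)
#' @return An [effect_spec()] with no shifts and no covariate links.
#' @export
null_effects <- function() effect_spec()

#' Spectral-neighbour spillover matrix
#'
#' A simple banded spillover model: each fluorophore spills a fixed
#' fraction into adjacent detectors and a smaller fraction two detectors
#' away, mimicking emission-spectrum overlap on a conventional analyser.
#'
#' @param channels Character vector of detector names (defines order and
#'   size).
#' @param near Spill fraction into adjacent detectors. Default 0.06.
#' @param far Spill fraction two detectors away. Default 0.015.
#' @return Square matrix with unit diagonal, dimnames = channels.
#' @export
default_spillover <- function(channels, near = 0.06, far = 0.015) {
  n <- length(channels)
  s <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) == 1) s[i, j] <- near
    if (abs(i - j) == 2) s[i, j] <- far
  }
  dimnames(s) <- list(channels, channels)
  s
}
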