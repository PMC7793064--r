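# Preprocessing: compensation, logicle transform, nearest-neighbour tube
# merging, quantile normalisation, density-based CD19 gating, seeded
# event subsampling.

#' Compensate a tube with its spillover matrix
#'
#' Inverts spectral spillover: `true = observed %*% solve(S)` where
#' `S[f, d]` is the fraction of fluorophore f recorded by detector d.
#'
#' @param tube A [tube_frame()] on raw scale.
#' @return The tube with compensated events (`compensated = TRUE`).
#' @export
compensate <- function(tube) {
  stopifnot(inherits(tube, "tube_frame"))
  if (tube$compensated) return(tube)
  .check_spillover(tube$spillover)
  tube$events <- tube$events %*% solve(tube$spillover)
  colnames(tube$events) <- tube$markers
  tube$compensated <- TRUE
  tube
}

#' Apply the logicle transformation to a tube
#'
#' @param tube A [tube_frame()] (normally compensated raw data).
#' @param params [logicle_params()].
#' @return The tube with events on logicle display scale.
#' @export
transform_logicle <- function(tube, params = logicle_params()) {
  stopifnot(inherits(tube, "tube_frame"))
  ev <- logicle_transform(as.vector(tube$events), params)
  tube$events <- matrix(ev, nrow = nrow(tube$events),
                        dimnames = dimnames(tube$events))
  tube$scale <- "logicle"
  tube
}

# chunked brute-force 1-NN: index in `donor` of the nearest row to each
# row of `ref` (Euclidean; ties broken by lowest donor index)
.nn1_index <- function(ref, donor, chunk = 256L) {
  ref <- as.matrix(ref); donor <- as.matrix(donor)
  nd <- nrow(donor)
  d_sq <- rowSums(donor^2)
  out <- integer(nrow(ref))
  for (start in seq(1L, nrow(ref), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(ref))
    cross <- ref[idx, , drop = FALSE] %*% t(donor)
    # ||r - d||^2 = ||r||^2 - 2 r.d + ||d||^2 ; ||r||^2 constant per row
    dist2 <- sweep(-2 * cross, 2L, d_sq, "+")
    out[idx] <- max.col(-dist2, ties.method = "first")
  }
  out
}

#' Merge a patient's tubes by backbone nearest-neighbour imputation
#'
#' Retains the cells of a reference tube (the tube with the most
#' markers; ties broken by tube order) and, for every other tube,
#' copies onto each reference cell the tube-specific marker values of
#' its nearest neighbour in backbone-marker space (k = 1, Euclidean on
#' the transformed scale; distance ties go to the lowest donor index).
#' All non-reference tubes are imputed independently onto the reference
#' (star topology), so the result does not depend on tube order beyond
#' the documented tie-breaks.
#'
#' @param tubes List of [tube_frame()]s for one patient, on logicle
#'   scale.
#' @param backbone Character vector of backbone markers, present in
#'   every tube.
#' @return A single merged [tube_frame()] carrying the union of all
#'   markers for every retained cell.
#' @export
merge_tubes <- function(tubes, backbone) {
  stopifnot(is.list(tubes), length(tubes) >= 2)
  if (length(backbone) == 0) stop("backbone marker set is empty")
  for (tb in tubes) {
    stopifnot(inherits(tb, "tube_frame"))
    if (!all(backbone %in% tb$markers)) {
      stop("tube ", tb$tube_id, " lacks backbone markers: ",
           paste(setdiff(backbone, tb$markers), collapse = ", "))
    }
    if (nrow(tb$events) < 1) {
      stop("tube ", tb$tube_id, " has no events to act as neighbours")
    }
  }
  n_mark <- vapply(tubes, function(tb) length(tb$markers), integer(1))
  ref_i <- which.max(n_mark)
  ref <- tubes[[ref_i]]
  merged <- ref$events
  for (i in seq_along(tubes)) {
    if (i == ref_i) next
    tb <- tubes[[i]]
    new_mk <- setdiff(tb$markers, colnames(merged))
    if (length(new_mk) == 0) next
    nn <- .nn1_index(ref$events[, backbone, drop = FALSE],
                     tb$events[, backbone, drop = FALSE])
    merged <- cbind(merged, tb$events[nn, new_mk, drop = FALSE])
  }
  tube_frame(merged,
             channels = paste0("M_", colnames(merged)),
             markers = colnames(merged),
             tube_id = "merged", patient_id = ref$patient_id,
             scale = ref$scale, compensated = TRUE)
}

#' Quantile (5th--95th percentile) normalisation of an event matrix
#'
#' Per marker, maps the 5th percentile to 0 and the 95th to 1:
#' `x' = (x - q05) / (q95 - q05)`, then clips to `[0, 1]` so that
#' percentile curves live on a fixed domain. Applying the normalisation
#' twice is refused (the quantiles would be recomputed on already
#' normalised data).
#'
#' @param events Numeric matrix, cells x markers (named columns).
#' @param clip Clip to `[0, 1]` after scaling. Default `TRUE`.
#' @return Normalised matrix with attribute `normalised = TRUE`.
#' @export
normalise_events <- function(events, clip = TRUE) {
  events <- as.matrix(events)
  if (isTRUE(attr(events, "normalised"))) {
    stop("events are already normalised; re-application would rescale ",
         "with recomputed quantiles")
  }
  q <- apply(events, 2L, stats::quantile, probs = c(0.05, 0.95),
             names = FALSE)
  span <- q[2, ] - q[1, ]
  if (any(span <= 0)) {
    stop("degenerate marker(s) with equal 5th and 95th percentiles: ",
         paste(colnames(events)[span <= 0], collapse = ", "))
  }
  out <- sweep(sweep(events, 2L, q[1, ]), 2L, span, "/")
  if (clip) out <- pmin(pmax(out, 0), 1)
  attr(out, "normalised") <- TRUE
  out
}

#' Density-based CD19 gate
#'
#' Estimates a 1-D kernel density (Gaussian kernel, Silverman
#' bandwidth) on the gating marker, locates the two largest modes and
#' thresholds at the deepest minimum between them; cells above the
#' threshold are retained. Deterministic: no randomness enters the KDE.
#'
#' @param events Normalised event matrix with named columns.
#' @param marker Gating marker. Default `"CD19"`.
#' @param fallback Optional numeric threshold used when the density has
#'   fewer than two (separated) modes; `NULL` (default) raises an error
#'   in that case, prompting a manual threshold.
#' @param min_sep Minimum separation between the two population modes,
#'   as a fraction of the marker's range; closer maxima are treated as
#'   ripples of a single population. Default 0.15.
#' @return The retained rows, with attribute `threshold`.
#' @export
gate_cd19 <- function(events, marker = "CD19", fallback = NULL,
                      min_sep = 0.15) {
  events <- as.matrix(events)
  if (!marker %in% colnames(events)) {
    stop("gating marker ", marker, " not present")
  }
  x <- events[, marker]
  # clipped values pile up exactly on the domain boundaries and would
  # appear as spurious density spikes; the mode search uses interior
  # values only (the threshold is still applied to every cell)
  interior <- x > min(x) & x < max(x)
  xd <- if (sum(interior) >= 10) x[interior] else x
  dens <- stats::density(xd, bw = "nrd0", n = 512)
  y <- dens$y
  maxima <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) maxima <- c(1L, maxima)
  if (y[512] > y[511]) maxima <- c(maxima, 512L)
  sep <- min_sep * diff(range(xd))
  main <- maxima[which.max(y[maxima])]
  rivals <- maxima[abs(dens$x[maxima] - dens$x[main]) >= sep]
  if (length(rivals) == 0) {
    if (is.null(fallback)) {
      stop("density of ", marker, " is unimodal; supply a manual ",
           "fallback threshold")
    }
    thr <- fallback
  } else {
    second <- rivals[which.max(y[rivals])]
    top2 <- sort(c(main, second))
    between <- top2[1]:top2[2]
    thr <- dens$x[between[which.min(y[between])]]
  }
  keep <- x > thr
  out <- events[keep, , drop = FALSE]
  attr(out, "normalised") <- attr(events, "normalised")
  attr(out, "threshold") <- thr
  out
}

#' Seeded uniform event subsampling
#'
#' @param events Event matrix.
#' @param n Number of events to retain; must not exceed the available
#'   cells (sampling with replacement is never done).
#' @param seed Integer seed.
#' @param patient_id Used in the error message when too few cells
#'   remain.
#' @return Matrix of `n` rows drawn uniformly without replacement.
#' @export
subsample_events <- function(events, n, seed, patient_id = "?") {
  events <- as.matrix(events)
  if (n > nrow(events)) {
    stop("patient ", patient_id, " has only ", nrow(events),
         " gated cells, fewer than the requested subsample of ", n)
  }
  norm_attr <- attr(events, "normalised")
  out <- .with_seed(
    seed, events[sample.int(nrow(events), n), , drop = FALSE])
  attr(out, "normalised") <- norm_attr
  out
}

#' Preprocess a cohort of raw tubes into per-patient samples
#'
#' Runs the full chain per patient: compensation, logicle transform,
#' backbone nearest-neighbour merging, 5th--95th quantile
#' normalisation, density-based CD19 gating and seeded subsampling to a
#' fixed cell count. Markers not shared by every patient are dropped to
#' the common panel; a common panel smaller than `min_markers` is an
#' error (cohort inclusion criterion).
#'
#' @param x A `flow_cohort` on raw scale, or a directory of FCS files
#'   written by [write_cohort()].
#' @param backbone Backbone markers for merging; defaults to the cohort
#'   design's backbone (required when reading from a directory).
#' @param n_events Events retained per patient after gating. Default
#'   2000.
#' @param seed Master seed for the per-patient subsampling streams.
#' @param params [logicle_params()].
#' @param gate_marker,gate_fallback Passed to [gate_cd19()].
#' @param min_markers Minimum size of the common marker panel. Default
#'   15.
#' @param clip Passed to [normalise_events()].
#' @return A `sample_set`: named list of `patient_sample` objects
#'   (fields `events`, `patient_id`, `label`), with the clinical table
#'   as attribute `clinical`.
#' @export
preprocess_cohort <- function(x, backbone = NULL, n_events = 2000,
                              seed = 1L, params = logicle_params(),
                              gate_marker = "CD19",
                              gate_fallback = NULL, min_markers = 15L,
                              clip = TRUE) {
  if (inherits(x, "flow_cohort")) {
    tubes_by_patient <- lapply(x$patients, function(p) p$tubes)
    clinical <- x$clinical
    if (is.null(backbone)) backbone <- x$design$backbone
  } else if (is.character(x) && dir.exists(x)) {
    files <- list.files(x, pattern = "\\.fcs$", full.names = TRUE)
    if (length(files) == 0) stop("no FCS files in ", x)
    tubes <- lapply(sort(files), read_fcs)
    ids <- vapply(tubes, function(tb) tb$patient_id, character(1))
    tubes_by_patient <- split(tubes, ids)
    clinical <- read_clinical(x)
    if (is.null(backbone)) {
      stop("backbone must be given when reading from a directory")
    }
  } else {
    stop("x must be a flow_cohort or a directory path")
  }

  samples <- vector("list", length(tubes_by_patient))
  names(samples) <- names(tubes_by_patient)
  for (pid in names(tubes_by_patient)) {
    tubes <- tubes_by_patient[[pid]]
    tubes <- lapply(tubes, function(tb) {
      if (tb$scale == "raw") {
        tb <- transform_logicle(compensate(tb), params)
      }
      tb
    })
    merged <- if (length(tubes) >= 2) {
      merge_tubes(tubes, backbone)
    } else {
      tubes[[1]]
    }
    ev <- normalise_events(merged$events, clip = clip)
    ev <- gate_cd19(ev, marker = gate_marker, fallback = gate_fallback)
    ev <- subsample_events(ev, n_events,
                           seed = seed + match(pid,
                                               names(tubes_by_patient)),
                           patient_id = pid)
    samples[[pid]] <- structure(
      list(events = ev, patient_id = pid,
           label = clinical$label[match(pid, clinical$patient_id)]),
      class = "patient_sample")
  }

  panels <- lapply(samples, function(s) colnames(s$events))
  common <- Reduce(intersect, panels)
  if (length(common) < min_markers) {
    stop("common marker panel has ", length(common),
         " markers, fewer than the required minimum of ", min_markers)
  }
  samples <- lapply(samples, function(s) {
    s$events <- s$events[, common, drop = FALSE]
    s
  })
  structure(samples, class = "sample_set", clinical = clinical)
}

#' Ground-truth samples straight from the simulator
#'
#' Bypasses the raw-scale/FCS path: takes each patient's directly
#' generated complete event matrix and applies only normalisation,
#' CD19 gating and subsampling. Used for calibration studies where the
#' preprocessing chain itself is not under test.
#'
#' @inheritParams preprocess_cohort
#' @param cohort A `flow_cohort` with `direct` matrices.
#' @return A `sample_set` (see [preprocess_cohort()]).
#' @export
direct_samples <- function(cohort, n_events = 2000, seed = 1L,
                           gate_marker = "CD19", gate_fallback = NULL,
                           clip = TRUE) {
  stopifnot(inherits(cohort, "flow_cohort"))
  samples <- vector("list", length(cohort$patients))
  names(samples) <- names(cohort$patients)
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    if (is.null(p$direct)) stop("cohort lacks direct event matrices")
    ev <- normalise_events(p$direct, clip = clip)
    ev <- gate_cd19(ev, marker = gate_marker, fallback = gate_fallback)
    ev <- subsample_events(ev, n_events, seed = seed + i,
                           patient_id = p$patient_id)
    samples[[i]] <- structure(
      list(events = ev, patient_id = p$patient_id, label = p$label),
      class = "patient_sample")
  }
  structure(samples, class = "sample_set",
            clinical = cohort$clinical)
}

#' @export
print.sample_set <- function(x, ...) {
  m <- ncol(x[[1]]$events)
  cat("<sample_set> ", length(x), " patients, ",
      nrow(x[[1]]$events), " events x ", m, " markers each\n", sep = "")
  invisible(x)
}
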