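# Fisher's-Ratio feature ranking and the control-point distance
# classifier.

# percentile_tbl -> wide patient-by-feature matrix (+ labels); feature
# columns are "<marker>@<level>"
.feature_wide <- function(features) {
  key <- paste0(features$marker, "@", features$level)
  pid <- unique(features$patient_id)
  feat <- unique(key)
  x <- matrix(NA_real_, length(pid), length(feat),
              dimnames = list(pid, feat))
  x[cbind(match(features$patient_id, pid), match(key, feat))] <-
    features$value
  lab <- features$label[match(pid, features$patient_id)]
  info <- do.call(rbind, strsplit(feat, "@", fixed = TRUE))
  list(x = x, label = lab,
       marker = info[, 1], level = as.numeric(info[, 2]))
}

#' Fit a Fisher's-Ratio model on a labelled percentile cohort
#'
#' For every (marker, percentile) feature, computes the Fisher's Ratio
#' `FR = (mu_R - mu_N)^2 / (sigma_R^2 + sigma_N^2)` where `mu` is the
#' class location (median across patients by default) and `sigma` the
#' within-class sample standard deviation across patients. Features
#' with `FR > threshold` are selected; if none passes, the single
#' highest-FR feature is used so that a classifier is always
#' constructible inside cross-validation folds.
#'
#' @param features A `percentile_tbl` with labels `"R"`/`"N"`.
#' @param threshold Selection threshold on FR. Default 0.5.
#' @param location `"median"` (default) or `"mean"` class location.
#' @param convention Probability convention used at prediction time:
#'   `"proximity"` (default; membership probability decreases with the
#'   distance to that class's control point) or `"as_printed"` (the
#'   inverted orientation; see vignette).
#' @param distance How patient-to-class separation is measured (see
#'   Details): `"feature"` (default) -- per-feature absolute distance
#'   between the patient's value and each class location;
#'   `"marker_curve"` -- Euclidean distance between the patient's
#'   percentile curve and each class median curve over that marker's
#'   selected percentiles, one probability per marker;
#'   `"control_point"` -- absolute distance between the
#'   scale-normalised patient point ([patient_point()]) and the class
#'   control points ([control_points()]). The control-point variant
#'   normalises the patient by the mean of the class dispersions but
#'   each class reference by its own, so when the two class dispersions
#'   differ the comparison is dominated by their ratio rather than by
#'   the patient's value; it is kept for literal reproduction, while
#'   the default measures the same distances on a common scale (the
#'   shared scaling cancels from the probability ratio).
#' @return An object of class `fisher_model`; `$features` is a tibble
#'   with columns `marker`, `level`, `mu_r`, `mu_n`, `sigma_r`,
#'   `sigma_n`, `fr`, `selected`.
#' @export
fisher_fit <- function(features, threshold = 0.5,
                       location = c("median", "mean"),
                       convention = c("proximity", "as_printed"),
                       distance = c("feature", "zscore", "marker_curve",
                                    "control_point")) {
  location <- match.arg(location)
  convention <- match.arg(convention)
  distance <- match.arg(distance)
  w <- .feature_wide(features)
  if (anyNA(w$x)) stop("incomplete percentile matrix (missing features)")
  is_r <- w$label == "R"
  if (sum(is_r) < 2 || sum(!is_r) < 2) {
    stop("need at least 2 patients per class to estimate within-class ",
         "standard deviations (have ", sum(is_r), " R, ",
         sum(!is_r), " N)")
  }
  xr <- w$x[is_r, , drop = FALSE]
  xn <- w$x[!is_r, , drop = FALSE]
  loc <- function(m) {
    if (location == "median") apply(m, 2L, stats::median) else colMeans(m)
  }
  mu_r <- loc(xr); mu_n <- loc(xn)
  sigma_r <- apply(xr, 2L, stats::sd)
  sigma_n <- apply(xn, 2L, stats::sd)
  denom <- sigma_r^2 + sigma_n^2
  keep <- denom > 0
  if (!any(keep)) stop("all features have zero within-class variance")
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped")
  }
  fr <- rep(NA_real_, length(denom))
  fr[keep] <- (mu_r[keep] - mu_n[keep])^2 / denom[keep]
  selected <- keep & !is.na(fr) & fr > threshold
  if (!any(selected)) selected[which.max(fr)] <- TRUE
  tbl <- tibble::tibble(
    marker = w$marker, level = w$level,
    mu_r = unname(mu_r), mu_n = unname(mu_n),
    sigma_r = unname(sigma_r), sigma_n = unname(sigma_n),
    fr = unname(fr), selected = unname(selected))[keep, ]
  structure(list(features = tbl, threshold = threshold,
                 location = location, convention = convention,
                 distance = distance,
                 n_r = sum(is_r), n_n = sum(!is_r)),
            class = "fisher_model")
}

#' @export
print.fisher_model <- function(x, ...) {
  sel <- x$features[x$features$selected, ]
  cat("<fisher_model> ", nrow(x$features), " features, ",
      nrow(sel), " selected (FR > ", x$threshold, "), markers: ",
      paste(unique(sel$marker), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Class control points of a Fisher model
#'
#' Each selected feature's class reference values, scale-normalised
#' within class: `R_bar = mu_R / sigma_R` and `N_bar = mu_N / sigma_N`.
#'
#' @param model A [fisher_fit()] model.
#' @return Tibble: `marker`, `level`, `r_bar`, `n_bar`.
#' @export
control_points <- function(model) {
  stopifnot(inherits(model, "fisher_model"))
  sel <- model$features[model$features$selected, ]
  tibble::tibble(marker = sel$marker, level = sel$level,
                 r_bar = sel$mu_r / sel$sigma_r,
                 n_bar = sel$mu_n / sel$sigma_n)
}

#' Normalised control point of an unassigned patient
#'
#' Scales a patient's feature value by the mean of the two class
#' dispersions: `P_bar = v / ((sigma_R + sigma_N) / 2)`.
#'
#' @param value Feature value(s) `v`.
#' @param sigma_r,sigma_n Class standard deviations of the feature.
#' @return Normalised value(s).
#' @export
patient_point <- function(value, sigma_r, sigma_n) {
  value / ((sigma_r + sigma_n) / 2)
}

#' Classify patients with a fitted Fisher model
#'
#' For every selected feature, the patient's normalised control point
#' is compared with the two class control points through a distance
#' function, and converted into class probabilities that share a common
#' denominator (so they sum to one exactly). Under the default
#' proximity convention `P(R) = d(P_bar, N_bar) / (d(P_bar, R_bar) +
#' d(P_bar, N_bar))`: membership probability increases as the patient
#' approaches that class's control point. Probabilities are averaged
#' over selected features (or over markers under the `marker_curve`
#' distance) and thresholded at 0.5, ties going to N.
#'
#' @param object A `fisher_model`.
#' @param features A `percentile_tbl` for the patients to classify.
#' @param type `"response"` (default; one row per patient) or
#'   `"features"` (per-feature probabilities).
#' @param ... Unused.
#' @return Tibble with `patient_id`, `prob_relapse`, `pred` (and for
#'   `type = "features"` one row per feature with `p_r`, `p_n`).
#' @export
predict.fisher_model <- function(object, features,
                                 type = c("response", "features"),
                                 ...) {
  type <- match.arg(type)
  sel <- object$features[object$features$selected, , drop = FALSE]
  w <- .feature_wide(features)
  key <- paste0(sel$marker, "@", sel$level)
  have <- paste0(w$marker, "@", w$level)
  idx <- match(key, have)
  if (anyNA(idx)) {
    stop("patients lack selected feature(s): ",
         paste(key[is.na(idx)], collapse = ", "))
  }
  v <- w$x[, idx, drop = FALSE]
  if (object$distance == "control_point") {
    p_bar <- sweep(v, 2L, (sel$sigma_r + sel$sigma_n) / 2, "/")
    d_r <- abs(sweep(p_bar, 2L, sel$mu_r / sel$sigma_r))
    d_n <- abs(sweep(p_bar, 2L, sel$mu_n / sel$sigma_n))
  } else if (object$distance == "zscore") {
    d_r <- abs(sweep(sweep(v, 2L, sel$mu_r), 2L, sel$sigma_r, "/"))
    d_n <- abs(sweep(sweep(v, 2L, sel$mu_n), 2L, sel$sigma_n, "/"))
  } else {
    d_r <- abs(sweep(v, 2L, sel$mu_r))
    d_n <- abs(sweep(v, 2L, sel$mu_n))
  }
  if (object$distance == "marker_curve") {
    # one curve-to-curve Euclidean distance per marker
    groups <- split(seq_along(key), sel$marker)
    d_r <- vapply(groups, function(g)
      sqrt(rowSums(d_r[, g, drop = FALSE]^2)), numeric(nrow(d_r)))
    d_n <- vapply(groups, function(g)
      sqrt(rowSums(d_n[, g, drop = FALSE]^2)), numeric(nrow(d_n)))
    d_r <- matrix(d_r, nrow = nrow(v))
    d_n <- matrix(d_n, nrow = nrow(v))
  }
  tot <- d_r + d_n
  p_r <- ifelse(tot == 0, 0.5,
                if (object$convention == "proximity") d_n / tot
                else d_r / tot)
  p_r <- matrix(p_r, nrow = nrow(v))
  prob <- rowMeans(p_r)
  pred <- ifelse(prob > 0.5, "R", "N")
  if (type == "features") {
    nm <- if (object$distance == "marker_curve") {
      names(split(seq_along(key), sel$marker))
    } else key
    return(tibble::tibble(
      patient_id = rep(rownames(w$x), times = length(nm)),
      feature = rep(nm, each = nrow(w$x)),
      p_r = as.vector(p_r), p_n = as.vector(1 - p_r)))
  }
  tibble::tibble(patient_id = rownames(w$x),
                 label = w$label,
                 prob_relapse = prob, pred = pred)
}

#' @method tidy fisher_model
#' @export
tidy.fisher_model <- function(x, ...) x$features

#' @method glance fisher_model
#' @export
glance.fisher_model <- function(x, ...) {
  sel <- x$features[x$features$selected, ]
  tibble::tibble(n_features = nrow(x$features),
                 n_selected = nrow(sel),
                 n_markers_selected = length(unique(sel$marker)),
                 max_fr = max(x$features$fr, na.rm = TRUE),
                 threshold = x$threshold,
                 n_r = x$n_r, n_n = x$n_n)
}

#' Marker-level Fisher's Ratio summary
#'
#' Aggregates the FR matrix over percentiles per marker (mean and max),
#' the marker-level view used to rank discriminant markers.
#'
#' @param model A `fisher_model`.
#' @return Tibble: `marker`, `mean_fr`, `max_fr`, `n_selected`, sorted
#'   by decreasing `mean_fr`.
#' @export
marker_fr <- function(model) {
  stopifnot(inherits(model, "fisher_model"))
  model$features |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(mean_fr = mean(.data$fr, na.rm = TRUE),
                     max_fr = max(.data$fr, na.rm = TRUE),
                     n_selected = sum(.data$selected),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_fr))
}
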