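#' Construct a tube frame
#'
#' A tube frame holds one tube's event-by-channel matrix together with
#' its channel/marker names, spillover matrix and acquisition metadata.
#' This is the unit the preprocessing stage operates on.
#'
#' @param events Numeric matrix, cells x channels.
#' @param channels Character vector of detector channel names.
#' @param markers Character vector of marker names (same length).
#' @param spillover Square spillover matrix with unit diagonal.
#' @param tube_id,patient_id Identifiers.
#' @param scale `"raw"` or `"logicle"`.
#' @param compensated Logical flag.
#' @return An object of class `tube_frame`.
#' @export
tube_frame <- function(events, channels, markers, spillover = NULL,
                       tube_id = "T1", patient_id = "P1",
                       scale = "raw", compensated = FALSE) {
  events <- as.matrix(events)
  stopifnot(ncol(events) == length(channels),
            length(channels) == length(markers),
            !anyDuplicated(markers))
  if (is.null(spillover)) {
    spillover <- diag(length(channels))
    dimnames(spillover) <- list(channels, channels)
  }
  stopifnot(nrow(spillover) == ncol(spillover),
            nrow(spillover) == length(channels))
  if (any(abs(diag(spillover) - 1) > 1e-9)) {
    stop("spillover matrix must have unit diagonal")
  }
  colnames(events) <- markers
  structure(list(events = events, channels = as.character(channels),
                 markers = as.character(markers), spillover = spillover,
                 tube_id = tube_id, patient_id = patient_id,
                 scale = scale, compensated = compensated),
            class = "tube_frame")
}

#' @export
print.tube_frame <- function(x, ...) {
  cat("<tube_frame> ", x$patient_id, "/", x$tube_id, ": ",
      nrow(x$events), " events x ", length(x$markers), " markers (",
      x$scale, if (x$compensated) ", compensated" else "", ")\n", sep = "")
  invisible(x)
}

# per-patient generative parameters: baseline mixture + patient-level
# random effects + class effect on the positive population.
# Patient-level variation acts on component locations only: mixture
# quantiles are discontinuous in the mixing weight at plateau-crossing
# levels, so weight jitter would add an across-patient variance
# component the percentile-curve representation does not model (the
# curves are meant to vary smoothly patient to patient).
.draw_patient_params <- function(design, effects, label, sd_common = 0.15,
                                 sd_pos = 0.15, sd_logit_pi = 0) {
  par <- .marker_baseline(design$markers)
  m <- nrow(par)
  shift_common <- stats::rnorm(m, 0, sd_common)
  shift_pos <- stats::rnorm(m, 0, sd_pos)
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  if (sd_logit_pi > 0) {
    par$pi_pos <- inv_logit(logit(par$pi_pos) +
                              stats::rnorm(m, 0, sd_logit_pi))
  }
  par$mu_neg <- par$mu_neg + shift_common
  par$mu_pos <- par$mu_pos + shift_common + shift_pos
  par$delta <- 0
  par$fraction <- 0
  if (label == "R" && nrow(effects$shifts) > 0) {
    idx <- match(effects$shifts$marker, par$marker)
    par$delta[idx] <- effects$shifts$delta
    par$fraction[idx] <- effects$shifts$fraction
  }
  par
}

# one independent draw of n events for the given marker subset
.draw_events <- function(n, par, markers) {
  par <- par[match(markers, par$marker), , drop = FALSE]
  x <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  for (j in seq_along(markers)) {
    p <- par[j, ]
    pos <- stats::runif(n) < p$pi_pos
    mu <- ifelse(pos, p$mu_pos, p$mu_neg)
    if (p$fraction > 0 && p$delta != 0) {
      hit <- pos & (stats::runif(n) < p$fraction)
      mu <- mu + ifelse(hit, p$delta, 0)
    }
    x[, j] <- stats::rnorm(n, mu, ifelse(pos, p$sd_pos, p$sd_neg))
  }
  x
}

#' Simulate a multi-tube flow-cytometry cohort
#'
#' Generates a synthetic B-ALL diagnostic cohort with the statistical
#' structure the downstream analysis assumes: per-cell marker expression
#' from a two-component (negative/positive) location--scale mixture on
#' the logicle display scale; multi-tube acquisition sharing backbone
#' markers (each tube an independent draw from the same patient-level
#' model, so merging is statistically consistent); an imbalanced relapse
#' outcome; plantable class-dependent marker shifts; and clinical
#' covariates correlated with per-patient marker levels through shared
#' latent Gaussians.
#'
#' @param n_patients Number of patients (>= 4). Default 56.
#' @param prevalence Relapse fraction in `(0, 1)`. Default 13/56.
#' @param events_per_tube Events per tube (>= 100). Default 5000.
#' @param design A [panel_design()]. Default [default_panel()].
#' @param effects An [effect_spec()]. Default [default_effects()].
#' @param seed Integer master seed; all randomness flows from it, split
#'   per patient by counter.
#' @param include Which event sets to materialise: `"tubes"` (per-tube
#'   frames for the preprocessing path) and/or `"direct"` (one complete
#'   event-by-marker draw per patient, the ground-truth shortcut used by
#'   calibration studies). Either subset yields identical draws for the
#'   retained component.
#'
#' @return An object of class `flow_cohort`: fields `patients` (list
#'   with per-patient `tubes`, `direct`, `params`, `label`), `clinical`
#'   (tibble, one row per patient), `design`, `effects`, `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(n_patients = 8, events_per_tube = 300, seed = 1)
#' coh$clinical
simulate_cohort <- function(n_patients = 56, prevalence = 13 / 56,
                            events_per_tube = 5000,
                            design = default_panel(),
                            effects = default_effects(),
                            seed = 1L,
                            include = c("tubes", "direct")) {
  stopifnot(inherits(design, "panel_design"),
            inherits(effects, "effect_spec"))
  if (n_patients < 4) stop("n_patients must be >= 4")
  if (events_per_tube < 100) stop("events_per_tube must be >= 100")
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly between 0 and 1")
  }
  if (prevalence * n_patients < 1) {
    stop("prevalence * n_patients < 1: no relapse patient possible")
  }
  include <- match.arg(include, several.ok = TRUE)
  bad <- setdiff(c(effects$shifts$marker, effects$links$marker),
                 design$markers)
  if (length(bad) > 0) {
    stop("effect spec names markers outside the panel: ",
         paste(unique(bad), collapse = ", "))
  }

  old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_rng))
    assign(".Random.seed", old_rng, globalenv()))
  set.seed(seed)
  n_r <- round(prevalence * n_patients)
  labels <- sample(c(rep("R", n_r), rep("N", n_patients - n_r)))
  pseed <- sample.int(.Machine$integer.max - 4000000L, n_patients)
  cov_eps <- matrix(stats::rnorm(n_patients * 16), n_patients, 16)
  cov_u <- matrix(stats::runif(n_patients * 8), n_patients, 8)

  ids <- sprintf("P%02d", seq_len(n_patients))
  patients <- vector("list", n_patients)
  names(patients) <- ids
  for (i in seq_len(n_patients)) {
    set.seed(pseed[i])
    par <- .draw_patient_params(design, effects, labels[i])
    tubes <- NULL
    if ("tubes" %in% include) {
      tubes <- lapply(names(design$tubes), function(tid) {
        set.seed(pseed[i] + 1000000L + match(tid, names(design$tubes)))
        mk <- design$tubes[[tid]]
        tube_frame(.draw_events(events_per_tube, par, mk),
                   channels = unname(design$channels[mk]), markers = mk,
                   tube_id = tid, patient_id = ids[i], scale = "logicle",
                   compensated = TRUE)
      })
      names(tubes) <- names(design$tubes)
    }
    direct <- NULL
    if ("direct" %in% include) {
      set.seed(pseed[i] + 2000000L)
      direct <- .draw_events(events_per_tube, par, design$markers)
    }
    patients[[i]] <- list(patient_id = ids[i], label = labels[i],
                          params = par, tubes = tubes, direct = direct)
  }

  clinical <- .draw_clinical(ids, labels, patients, effects,
                             cov_eps, cov_u)
  structure(list(patients = patients, clinical = clinical,
                 design = design, effects = effects, seed = seed,
                 n_patients = n_patients, prevalence = prevalence,
                 events_per_tube = events_per_tube, scale = "logicle"),
            class = "flow_cohort")
}

# clinical/genetic covariates; linked covariates share latent Gaussians
# with the per-patient marker location (thresholded for binaries)
.draw_clinical <- function(ids, labels, patients, effects, eps, u) {
  n <- length(ids)
  read_level <- function(marker, region) {
    v <- vapply(patients, function(p) {
      i <- match(marker, p$params$marker)
      if (region == "low") p$params$mu_neg[i]
      else p$params$mu_pos[i] + p$params$delta[i] * p$params$fraction[i]
    }, numeric(1))
    as.numeric(scale(v))
  }
  latent <- function(covariate, col) {
    ln <- effects$links[effects$links$covariate == covariate, ]
    if (nrow(ln) == 0) return(eps[, col])
    z <- read_level(ln$marker[1], ln$region[1])
    ln$rho[1] * z + sqrt(1 - ln$rho[1]^2) * eps[, col]
  }
  hyper <- latent("hyperdiploid", 1) > stats::qnorm(1 - 0.30)
  hypo <- !hyper & (u[, 1] < 0.05 / 0.70)
  karyotype <- ifelse(hyper, "hyperdiploid",
                      ifelse(hypo, "hypodiploid", "normal"))
  karyotype[u[, 2] < 0.07] <- NA  # karyotyping occasionally unavailable
  male <- latent("male", 2) > 0
  tibble::tibble(
    patient_id = ids,
    label = labels,
    age = round(pmin(pmax(stats::qlnorm(u[, 3], log(4.5), 0.6), 0.6),
                     18.5), 1),
    sex = ifelse(male, "male", "female"),
    blast_pct = round(100 * stats::qbeta(u[, 4], 8, 2), 1),
    karyotype = karyotype,
    t_12_21 = as.integer(latent("t_12_21", 3) > stats::qnorm(1 - 0.25)),
    t_1_19 = as.integer(latent("t_1_19", 4) > stats::qnorm(1 - 0.06)),
    t_4_11 = as.integer(latent("t_4_11", 5) > stats::qnorm(1 - 0.04)),
    mll = as.integer(latent("mll", 6) > stats::qnorm(1 - 0.04)),
    t_9_22 = as.integer(latent("t_9_22", 7) > stats::qnorm(1 - 0.03)),
    time_to_relapse = ifelse(labels == "R",
                             round(stats::qlnorm(u[, 5], log(24), 0.5), 1),
                             NA_real_)
  )
}

#' @export
print.flow_cohort <- function(x, ...) {
  cat("<flow_cohort> ", x$n_patients, " patients (",
      sum(x$clinical$label == "R"), " relapse), ",
      length(x$design$tubes), " tubes x ", x$events_per_tube,
      " events, scale: ", x$scale, "\n", sep = "")
  invisible(x)
}

#' Map a simulated cohort to raw acquisition scale with spillover
#'
#' Sends each tube's logicle-scale values through the inverse logicle to
#' raw fluorescence and then mixes channels by the spillover matrix,
#' producing files as an instrument would record them. The preprocessing
#' chain (compensation followed by the logicle transform) recovers the
#' original values up to numerical tolerance.
#'
#' @param cohort A `flow_cohort` on logicle scale.
#' @param spillover Spillover matrix over all panel detector channels
#'   (per-tube submatrices are taken), or `NULL` for
#'   [default_spillover()]. Must be invertible, unit-diagonal,
#'   non-negative off-diagonal.
#' @param params [logicle_params()] used for the inverse transform.
#' @return The cohort with tube events on raw scale (spillover applied)
#'   and per-tube spillover matrices attached. The `direct` ground-truth
#'   matrices are left on logicle scale.
#' @export
cohort_raw <- function(cohort, spillover = NULL,
                       params = logicle_params()) {
  stopifnot(inherits(cohort, "flow_cohort"))
  if (cohort$scale != "logicle") stop("cohort is not on logicle scale")
  channels <- unname(cohort$design$channels)
  if (is.null(spillover)) spillover <- default_spillover(channels)
  stopifnot(nrow(spillover) == ncol(spillover))
  if (is.null(rownames(spillover))) {
    dimnames(spillover) <- list(channels, channels)
  }
  .check_spillover(spillover)
  cohort$patients <- lapply(cohort$patients, function(p) {
    p$tubes <- lapply(p$tubes, function(tb) {
      s <- spillover[tb$channels, tb$channels, drop = FALSE]
      raw <- logicle_inverse(tb$events, params)
      tb$events <- raw %*% s  # observed_d = sum_f true_f * S[f, d]
      colnames(tb$events) <- tb$markers
      tb$spillover <- s
      tb$scale <- "raw"
      tb$compensated <- FALSE
      tb
    })
    p
  })
  cohort$scale <- "raw"
  cohort$logicle_params <- params
  cohort
}

.check_spillover <- function(s) {
  if (any(abs(diag(s) - 1) > 1e-9)) stop("spillover diagonal must be 1")
  if (any(s < 0)) stop("spillover entries must be non-negative")
  det_s <- det(s)
  if (!is.finite(det_s) || abs(det_s) < 1e-12) {
    stop("spillover matrix is singular")
  }
  invisible(s)
}
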