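# Association of marker percentile expression with clinical and
# cytogenetic covariates: pairwise Pearson correlation with t-test
# significance, and group comparisons.

# clinical table -> numeric covariate frame (binary 0/1 codings;
# point-biserial correlation is Pearson on these codes)
.encode_clinical <- function(clinical) {
  num <- tibble::tibble(
    relapse = as.numeric(clinical$label == "R"),
    age = clinical$age,
    male = as.numeric(clinical$sex == "male"),
    blast_pct = clinical$blast_pct,
    hyperdiploid = as.numeric(clinical$karyotype == "hyperdiploid"),
    hypodiploid = as.numeric(clinical$karyotype == "hypodiploid"),
    t_12_21 = as.numeric(clinical$t_12_21),
    t_1_19 = as.numeric(clinical$t_1_19),
    t_4_11 = as.numeric(clinical$t_4_11),
    mll = as.numeric(clinical$mll),
    t_9_22 = as.numeric(clinical$t_9_22),
    time_to_relapse = clinical$time_to_relapse)
  num[, vapply(num, function(v) !all(is.na(v)), TRUE), drop = FALSE]
}

#' Correlate marker percentiles with clinical covariates
#'
#' Builds a variable table from selected percentile levels of one
#' marker (e.g. P15/P50/P85 of CD38, representing low, normal and high
#' expression) together with the encoded clinical covariates, and
#' computes all pairwise Pearson correlations over complete cases, with
#' p-values from the t-transform of r. Missing fields (e.g. karyotype)
#' are handled by pairwise complete-case deletion -- never imputed;
#' time to relapse is missing for non-relapsing patients.
#'
#' @param clinical Clinical tibble (as produced by the simulator or
#'   [read_clinical()]).
#' @param features A `percentile_tbl` for the same patients.
#' @param marker Marker whose percentiles enter the table. Default
#'   `"CD38"`.
#' @param levels Percentile levels. Default `c(15, 50, 85)`.
#' @param min_pairs Minimum complete pairs per correlation; pairs below
#'   it (or constant variables) yield `NA` cells. Default 4.
#' @return An object of class `correlation_report`: `$pairs` (tibble
#'   `var1`, `var2`, `r`, `p`, `n`, `significant`), `$r`, `$p`, `$n`
#'   (matrices; in the printed matrix form r occupies the lower and p
#'   the upper triangle).
#' @export
correlate_markers <- function(clinical, features, marker = "CD38",
                              levels = c(15, 50, 85), min_pairs = 4) {
  sub <- features[features$marker == marker &
                    features$level %in% levels, ]
  if (nrow(sub) == 0) stop("no percentile rows for marker ", marker)
  wide <- tidyr::pivot_wider(
    sub[, c("patient_id", "level", "value")],
    names_from = "level", values_from = "value",
    names_prefix = paste0(marker, "_P"))
  wide <- wide[match(clinical$patient_id, wide$patient_id), ]
  tab <- dplyr::bind_cols(wide[, -1], .encode_clinical(clinical))
  vars <- names(tab)
  k <- length(vars)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- tab[[i]]; y <- tab[[j]]
    ok <- stats::complete.cases(x, y)
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < min_pairs || stats::sd(x[ok]) == 0 ||
        stats::sd(y[ok]) == 0) {
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        var1 = vars[i], var2 = vars[j], r = NA_real_, p = NA_real_,
        n = sum(ok), significant = NA)
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
    pairs[[length(pairs) + 1]] <- tibble::tibble(
      var1 = vars[i], var2 = vars[j], r = unname(ct$estimate),
      p = ct$p.value, n = sum(ok), significant = ct$p.value < 0.05)
  }
  diag(n) <- vapply(tab, function(v) sum(!is.na(v)), 0)
  structure(list(pairs = dplyr::bind_rows(pairs), r = r, p = p, n = n,
                 marker = marker, levels = levels),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 3, ...) {
  cat("<correlation_report> ", x$marker, " P",
      paste(x$levels, collapse = "/P"),
      " vs clinical covariates (r lower triangle, p upper)\n", sep = "")
  m <- x$r
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  print(round(m, digits))
  invisible(x)
}

#' Matrix form of a correlation report (r lower, p upper triangle)
#' @param x A `correlation_report`.
#' @return Square matrix.
#' @export
report_matrix <- function(x) {
  stopifnot(inherits(x, "correlation_report"))
  m <- x$r
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  m
}

#' @method tidy correlation_report
#' @export
tidy.correlation_report <- function(x, ...) x$pairs

#' Compare a marker percentile between covariate groups
#'
#' Two-sample t-test on one percentile level of one marker between the
#' two groups of a binary covariate (e.g. CD38 P50 between female and
#' male patients).
#'
#' @param features A `percentile_tbl`.
#' @param clinical Clinical tibble.
#' @param covariate Name of a clinical column with exactly two
#'   non-missing groups (e.g. `"sex"`).
#' @param marker,level Percentile feature to compare.
#' @param var_equal Pooled t-test instead of Welch. A group of size 1
#'   errors under the pooled test and falls back to nothing -- Welch
#'   (default) requires 2 per group as well.
#' @return One-row tibble: `marker`, `level`, `group1`, `group2`,
#'   `mean1`, `mean2`, `t`, `p`.
#' @export
group_difference <- function(features, clinical, covariate,
                             marker = "CD38", level = 50,
                             var_equal = FALSE) {
  sub <- features[features$marker == marker &
                    features$level == level, ]
  if (nrow(sub) == 0) stop("no rows for ", marker, " P", level)
  g <- clinical[[covariate]][match(sub$patient_id,
                                   clinical$patient_id)]
  ok <- !is.na(g)
  sub <- sub[ok, ]; g <- g[ok]
  gl <- sort(unique(g))
  if (length(gl) < 2) stop("covariate ", covariate,
                           " has a single group")
  if (length(gl) > 2) stop("covariate ", covariate,
                           " has more than two groups")
  v1 <- sub$value[g == gl[1]]; v2 <- sub$value[g == gl[2]]
  if (min(length(v1), length(v2)) < 2) {
    stop("group of size < 2 for covariate ", covariate,
         "; a t-test is not defined")
  }
  tt <- stats::t.test(v1, v2, var.equal = var_equal)
  tibble::tibble(marker = marker, level = level,
                 group1 = as.character(gl[1]),
                 group2 = as.character(gl[2]),
                 mean1 = mean(v1), mean2 = mean(v2),
                 t = unname(tt$statistic), p = tt$p.value)
}
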