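# Small in-code fixtures.

# percentile_tbl built directly from a patients x features value matrix;
# feature columns follow the "<marker>@<level>" convention
make_features <- function(x, labels, markers = NULL, levels = NULL) {
  n <- nrow(x)
  if (is.null(markers)) {
    markers <- rep(paste0("M", seq_len(ncol(x))), each = 1)
    levels <- rep(50, ncol(x))
  }
  pid <- sprintf("P%02d", seq_len(n))
  out <- tibble::tibble(
    patient_id = rep(pid, times = ncol(x)),
    label = rep(labels, times = ncol(x)),
    marker = rep(markers, each = n),
    level = rep(levels, each = n),
    value = as.vector(x))
  class(out) <- c("percentile_tbl", class(out))
  out
}

# random labelled feature matrix for oracle checks
random_instance <- function(n_r = 3, n_n = 4, n_marker = 3, n_level = 4) {
  n <- n_r + n_n
  x <- matrix(stats::rnorm(n * n_marker * n_level), nrow = n)
  markers <- rep(paste0("M", seq_len(n_marker)), each = n_level)
  levels <- rep(seq_len(n_level) * 10, times = n_marker)
  labels <- sample(c(rep("R", n_r), rep("N", n_n)))
  list(x = x, labels = labels, markers = markers, levels = levels,
       features = make_features(x, labels, markers, levels))
}

# a tiny two-class cohort with a cleanly separated feature
separable_features <- function(n_r = 5, n_n = 9, n_noise = 3, seed = 1) {
  set.seed(seed)
  n <- n_r + n_n
  labels <- c(rep("R", n_r), rep("N", n_n))
  sig <- ifelse(labels == "R", 0.2, 0.8) + stats::rnorm(n, 0, 0.01)
  noise <- matrix(stats::rnorm(n * n_noise, 0.5, 0.05), n)
  make_features(cbind(sig, noise), labels,
                markers = c("CD38", paste0("M", seq_len(n_noise))),
                levels = rep(50, n_noise + 1))
}

toy_clinical <- function(n = 8, seed = 31) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("P%02d", 1:n),
    label = rep(c("R", "N"), length.out = n),
    age = runif(n, 2, 15),
    sex = sample(c("male", "female"), n, replace = TRUE),
    blast_pct = runif(n, 60, 95),
    karyotype = sample(c("hyperdiploid", "normal", "hypodiploid"),
                       n, replace = TRUE),
    t_12_21 = rbinom(n, 1, 0.3), t_1_19 = rbinom(n, 1, 0.1),
    t_4_11 = 0L, mll = 0L, t_9_22 = 0L,
    time_to_relapse = ifelse(rep(c(TRUE, FALSE), length.out = n),
                             runif(n, 6, 40), NA))
}

toy_features <- function(clinical, seed = 32) {
  set.seed(seed)
  n <- nrow(clinical)
  x <- cbind(runif(n), runif(n), runif(n))
  make_features(x, clinical$label,
                markers = rep("CD38", 3), levels = c(15, 50, 85))
}

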