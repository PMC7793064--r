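test_that("compensation inverts a known 2x2 spillover exactly", {
  s <- matrix(c(1, 0.1, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("FL1", "FL2"), c("FL1", "FL2")))
  true <- matrix(c(1.0, 1.0), 1, 2)
  observed <- true %*% s  # c(1.0, 1.1)
  tube <- tube_frame(observed, channels = c("FL1", "FL2"),
                     markers = c("A", "B"), spillover = s)
  comp <- compensate(tube)
  # closed-form 2x2 inverse: [[1, -0.1], [0, 1]]
  expect_equal(unname(comp$events), true, tolerance = 1e-12)
  expect_true(comp$compensated)
})

test_that("identity spillover leaves events unchanged", {
  ev <- matrix(rnorm(20), 10, 2)
  tube <- tube_frame(ev, channels = c("c1", "c2"),
                     markers = c("A", "B"))
  expect_equal(unname(compensate(tube)$events), ev)
})

test_that("compensating twice is a no-op", {
  s <- matrix(c(1, 0.2, 0.1, 1), 2, 2)
  tube <- tube_frame(matrix(runif(10), 5, 2), c("c1", "c2"),
                     c("A", "B"), spillover = s)
  once <- compensate(tube)
  expect_identical(compensate(once)$events, once$events)
})

test_that("merging identical cells recovers held-out values exactly", {
  set.seed(4)
  backbone <- c("B1", "B2")
  common <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, backbone))
  extra1 <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "X1"))
  extra2 <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "X2"))
  t1 <- tube_frame(cbind(common, extra1, matrix(0, 20, 1)),
                   channels = paste0("c", 1:4),
                   markers = c(backbone, "X1", "X1b"),
                   tube_id = "T1", scale = "logicle")
  t2 <- tube_frame(cbind(common, extra2),
                   channels = paste0("d", 1:3),
                   markers = c(backbone, "X2"),
                   tube_id = "T2", scale = "logicle")
  merged <- merge_tubes(list(t1, t2), backbone)
  # reference is T1 (more markers); T2 cells match backbone exactly
  expect_equal(merged$events[, "X2"], extra2[, 1], ignore_attr = TRUE)
  expect_setequal(colnames(merged$events),
                  c(backbone, "X1", "X1b", "X2"))
})

test_that("distance ties pick the lowest donor index", {
  backbone <- "B1"
  # dyadic values make the two squared distances exactly equal in
  # floating point: ref 0.5 vs donors 0.25 and 0.75
  donor <- tube_frame(cbind(B1 = c(0.25, 0.75, 9), Y = c(10, 20, 30)),
                      c("d1", "d2"), c("B1", "Y"),
                      tube_id = "T2", scale = "logicle")
  ref <- tube_frame(cbind(B1 = c(0.5, 9), Z = c(1, 2), W = c(3, 4)),
                    paste0("c", 1:3), c("B1", "Z", "W"),
                    tube_id = "T1", scale = "logicle")
  merged <- merge_tubes(list(ref, donor), backbone)
  # lowest donor index (0.25 -> Y = 10) must win the tie
  expect_equal(merged$events[1, "Y"], 10, ignore_attr = TRUE)
  expect_equal(merged$events[2, "Y"], 30, ignore_attr = TRUE)
})

test_that("merge errors on empty backbone or empty tubes", {
  t1 <- tube_frame(matrix(1, 3, 1, dimnames = list(NULL, "B1")),
                   "c1", "B1", scale = "logicle")
  expect_error(merge_tubes(list(t1, t1), character(0)), "empty")
  t0 <- tube_frame(matrix(numeric(0), 0, 1,
                          dimnames = list(NULL, "B1")),
                   "c1", "B1", scale = "logicle")
  expect_error(merge_tubes(list(t1, t0), "B1"), "no events")
  expect_error(merge_tubes(list(t1), "B1"))
})

test_that("normalisation maps the 5th and 95th percentiles to 0 and 1", {
  set.seed(5)
  x <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("A", "B")))
  norm <- normalise_events(x, clip = FALSE)
  # quantiles are equivariant under the per-marker affine map, so the
  # transformed 5th/95th percentiles must land exactly on 0 and 1
  qn <- apply(norm, 2, quantile, c(0.05, 0.95), names = FALSE)
  expect_equal(unname(qn[1, ]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(qn[2, ]), c(1, 1), tolerance = 1e-12)
  # and the linear map itself is applied: slope/offset recoverable
  q <- apply(x, 2, quantile, c(0.05, 0.95), names = FALSE)
  expect_equal(norm[, 1], (x[, 1] - q[1, 1]) / (q[2, 1] - q[1, 1]),
               ignore_attr = TRUE)
})

test_that("normalised median of a uniform sample is about one half", {
  set.seed(6)
  x <- matrix(runif(10000), ncol = 1, dimnames = list(NULL, "U"))
  norm <- normalise_events(x)
  expect_equal(unname(median(norm)), 0.5, tolerance = 0.02)
})

test_that("degenerate markers and double application are refused", {
  x <- cbind(A = rnorm(100), B = rep(1, 100))
  expect_error(normalise_events(x), "B")
  y <- normalise_events(cbind(A = rnorm(100)))
  expect_error(normalise_events(y), "already normalised")
})

test_that("clipping keeps all values inside the unit interval", {
  set.seed(7)
  norm <- normalise_events(cbind(A = rt(500, df = 2)))
  expect_gte(min(norm), 0)
  expect_lte(max(norm), 1)
})

test_that("the density gate separates two clean populations", {
  set.seed(8)
  x <- cbind(CD19 = c(rnorm(400, 0.2, 0.05), rnorm(600, 0.8, 0.05)),
             other = rnorm(1000))
  gated <- gate_cd19(x)
  thr <- attr(gated, "threshold")
  expect_lt(abs(thr - 0.5), 0.1)
  # recall of the positive component
  pos <- x[, "CD19"] > 0.5
  expect_gt(mean(x[pos, "CD19"] > thr), 0.99)
  # determinism: same input, same threshold
  expect_identical(thr, attr(gate_cd19(x), "threshold"))
})

test_that("unimodal input uses the fallback or errors", {
  x <- cbind(CD19 = rnorm(500, 0.6, 0.05))
  expect_error(gate_cd19(x), "unimodal")
  gated <- gate_cd19(x, fallback = 0)
  expect_equal(nrow(gated), 500)
})

test_that("raising the gate threshold never increases retained cells", {
  set.seed(9)
  x <- cbind(CD19 = c(rnorm(300, 0.2, 0.05), rnorm(700, 0.8, 0.08)))
  counts <- vapply(seq(0, 0.9, by = 0.1),
                   function(thr) sum(x[, "CD19"] > thr), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("subsampling is seeded, uniform and bounded", {
  set.seed(10)
  x <- matrix(rnorm(60), 20, 3)
  a <- subsample_events(x, 5, seed = 42)
  b <- subsample_events(x, 5, seed = 42)
  expect_identical(a, b)
  # n = all rows gives a permutation
  perm <- subsample_events(x, 20, seed = 1)
  expect_equal(dim(perm), dim(x))
  expect_setequal(perm[, 1], x[, 1])
  expect_error(subsample_events(x, 21, seed = 1, patient_id = "P07"),
               "P07")
  # uniformity: inclusion frequency of each row ~ n/N over many draws
  counts <- numeric(20)
  for (s in 1:4000) {
    idx <- subsample_events(cbind(seq_len(20)), 5, seed = s)[, 1]
    counts[idx] <- counts[idx] + 1
  }
  p_hat <- counts / 4000
  se <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(p_hat - 0.25) < 3.5 * se))
})

test_that("full preprocessing agrees with ground-truth generation", {
  coh <- simulate_cohort(n_patients = 4, prevalence = 0.5,
                         events_per_tube = 2000, seed = 31)
  raw <- cohort_raw(coh)
  pre <- preprocess_cohort(raw, n_events = 1200, seed = 2)
  dir <- direct_samples(coh, n_events = 1200, seed = 2)
  fp <- percentile_features(pre)
  fd <- percentile_features(dir)
  j <- dplyr::inner_join(fp, fd, by = c("patient_id", "marker", "level"))
  expect_equal(nrow(j), 4 * 20 * 19)
  expect_lt(mean(abs(j$value.x - j$value.y)), 0.04)
  expect_identical(sort(unique(fp$label)), c("N", "R"))
})

test_that("preprocessing from a written directory matches in-memory", {
  coh <- simulate_cohort(n_patients = 4, prevalence = 0.3,
                         events_per_tube = 800, seed = 32)
  raw <- cohort_raw(coh)
  dir <- withr::local_tempdir()
  write_cohort(raw, dir)
  a <- preprocess_cohort(raw, n_events = 400, seed = 5)
  b <- preprocess_cohort(dir, backbone = coh$design$backbone,
                         n_events = 400, seed = 5)
  for (pid in names(a)) {
    expect_equal(a[[pid]]$events, b[[pid]]$events, tolerance = 1e-4)
    expect_identical(a[[pid]]$label, b[[pid]]$label)
  }
})

test_that("a too-small common panel is rejected", {
  coh <- simulate_cohort(n_patients = 4, prevalence = 0.3,
                         events_per_tube = 300, seed = 33)
  raw <- cohort_raw(coh)
  expect_error(preprocess_cohort(raw, n_events = 100, seed = 1,
                                 min_markers = 50),
               "fewer than the required minimum")
})
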