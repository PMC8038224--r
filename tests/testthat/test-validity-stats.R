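test_that("curve agreement handles identity, offsets and flat channels", {
  set.seed(17)
  M <- matrix(rnorm(300, sd = 10), 100, 3)
  a <- series_of(M)
  r1 <- compare_curves(a, a)
  expect_equal(r1$per_axis$rmse, rep(0, 3))
  expect_equal(r1$per_axis$r, rep(1, 3))
  expect_true(all(r1$per_axis$band == "very_good"))
  b <- series_of(M + 5)
  r2 <- compare_curves(b, a)
  expect_equal(r2$per_axis$rmse, rep(5, 3))
  expect_equal(r2$per_axis$r, rep(1, 3))
  flat <- series_of(cbind(M[, 1:2], 0))
  r3 <- compare_curves(flat, a)
  expect_true(is.na(r3$per_axis$r[3]))
})

test_that("curve agreement matches a brute-force computation", {
  set.seed(18)
  for (i in 1:5) {
    A <- matrix(rnorm(60), 20, 3); B <- matrix(rnorm(60), 20, 3)
    res <- compare_curves(series_of(A), series_of(B))
    for (j in 1:3) {
      expect_equal(res$per_axis$rmse[j],
                   sqrt(sum((A[, j] - B[, j])^2) / 20), tolerance = 1e-12)
      ma <- mean(A[, j]); mb <- mean(B[, j])
      r_bf <- sum((A[, j] - ma) * (B[, j] - mb)) /
        sqrt(sum((A[, j] - ma)^2) * sum((B[, j] - mb)^2))
      expect_equal(res$per_axis$r[j], r_bf, tolerance = 1e-12)
      expect_equal(res$per_axis$r2[j], r_bf^2, tolerance = 1e-12)
    }
  }
})

test_that("correlation bands follow the stated cutpoints", {
  expect_identical(lumbarload:::r_band(c(0.95, 0.85, 0.6, 0.3, 0.05)),
                   c("very_good", "good", "moderate", "weak", "none"))
})

test_that("task descriptives use mean, max and sample SD of the norm", {
  tr <- list(id = "t", borg = 5, checklist_rank = 3L)
  class(tr) <- "trial"
  m <- series_of(cbind(c(10, 20, 30), 0, 0))
  td <- task_descriptives(tr, m)
  expect_equal(td$mean, 20)
  expect_equal(td$peak, 30)
  expect_equal(td$variance, 10)
  m2 <- series_of(cbind(rep(20, 5), 0, 0))
  td2 <- task_descriptives(tr, m2)
  expect_equal(c(td2$mean, td2$peak, td2$variance), c(20, 20, 0))
})

test_that("direction splits partition by sign and mirror under negation", {
  set.seed(19)
  M <- matrix(rnorm(600), 200, 3)
  m <- series_of(M)
  for (ax in c("x", "y", "z")) {
    ds <- direction_split(m, ax)
    v <- M[, match(ax, c("x", "y", "z"))]
    expect_identical(ds$positive$n + ds$negative$n,
                     length(v[v != 0]))
    expect_equal(ds$positive$mean, mean(v[v > 0]))
    expect_equal(ds$negative$mean, mean(abs(v[v < 0])))
    neg <- direction_split(series_of(-M), ax)
    expect_equal(neg$positive, ds$negative)
    expect_equal(neg$negative, ds$positive)
  }
})

test_that("one-sided series leave the opposite segment absent", {
  m <- series_of(cbind(0, abs(rnorm(50)) + 0.1, 0))
  ds <- direction_split(m, "y")
  expect_identical(ds$negative$n, 0L)
  expect_true(is.na(ds$negative$mean))
})

test_that("a sine splits into half-cycle segments with mean 2A/pi", {
  A <- 7
  t <- (0:9999) * 0.02
  M <- cbind(0, A * sin(2 * pi * t / 10), 0)  # whole 10 s periods
  ds <- direction_split(net_moment_series(t, M), "y")
  expect_equal(ds$positive$mean, 2 * A / pi, tolerance = 0.01)
  expect_equal(ds$negative$mean, 2 * A / pi, tolerance = 0.01)
})

test_that("norm splits follow the sign of the dominant component", {
  M <- rbind(c(1, -5, 2), c(0.5, 0.2, -0.1), c(-3, 1, 1))
  ds <- direction_split(series_of(M), "norm")
  # dominant components: -5, +0.5, -3
  expect_identical(ds$positive$n, 1L)
  expect_identical(ds$negative$n, 2L)
  expect_equal(ds$positive$mean, sqrt(sum(M[2, ]^2)))
})

test_that("paired comparisons reproduce the closed-form t statistics", {
  expect_error(paired_comparison(1:2, 2:3), "n >= 3")
  same <- paired_comparison(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$MD, 0)
  expect_equal(same$p, 1)
  a <- c(5, 7, 9); b <- c(4, 5, 6)   # differences 1, 2, 3
  pc <- paired_comparison(a, b)
  expect_equal(pc$MD, 2)
  expect_equal(pc$SDD, 1)
  expect_identical(pc$test_used, "paired_t")
  t_stat <- pc$MD / (pc$SDD / sqrt(3))
  expect_equal(t_stat, 3.464, tolerance = 1e-3)
  expect_equal(pc$p, 2 * (1 - pt(t_stat, df = 2)), tolerance = 1e-6)
  expect_equal(pc$p, 0.074, tolerance = 0.01)
  expect_equal(pc$CI95, 2 + c(-1, 1) * qt(0.975, 2) / sqrt(3),
               tolerance = 1e-9)
  expect_true(pc$CI95[1] <= pc$MD && pc$MD <= pc$CI95[2])
  # relative differences both ways
  expect_equal(pc$rel_md, mean(100 * (a - b) / b))
  expect_equal(pc$rel_md_group, 100 * 2 / 5)
})

test_that("clearly non-normal differences switch to the signed-rank test", {
  set.seed(20)
  b <- rnorm(20)
  a <- b + c(rep(0.01, 19), 50)   # one massive outlier difference
  pc <- paired_comparison(a, b)
  expect_lt(pc$normality_p, 0.05)
  expect_identical(pc$test_used, "wilcoxon")
})

test_that("task selection follows ranks, Borg tie-breaks and posture flags", {
  ses <- sim_session_cached(seed = 1, phases = 1:3)
  work <- lumbarload:::session_trials(ses, kind = "work_task")
  sel <- select_tasks(work)
  expect_identical(sel$light, "task_light")
  expect_identical(sel$heavy, "task_dynamic")
  expect_identical(sel$static, "task_static")
  expect_identical(sel$dynamic, "task_dynamic")
  # Borg breaks rank ties: duplicate the heavy trial with a higher Borg
  dup <- work[[which(vapply(work, function(tr) tr$id, "") ==
                       "task_dynamic")]]
  dup$id <- "task_dynamic2"
  dup$borg <- min(dup$borg + 1, 10)
  sel2 <- select_tasks(c(work, list(dup)))
  expect_identical(sel2$heavy, "task_dynamic2")
  # without any held posture there is no static task
  nonstatic <- work[vapply(work, function(tr) tr$id, "") != "task_static"]
  expect_error(select_tasks(nonstatic), "no static task")
  expect_error(select_tasks(list()), "no work tasks")
})

test_that("report mean columns equal the mean of their subject cells", {
  ref <- reference_cohort_tables()
  ag <- append_row_stats(ref$agreement, paste0("s", 1:9))
  for (i in seq_len(nrow(ag))) {
    cells <- as.numeric(ag[i, paste0("s", 1:9)])
    expect_equal(ag$mean[i], mean(cells, na.rm = TRUE))
  }
})
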