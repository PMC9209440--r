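pred_df <- function(est, act, id = seq_along(est)) {
  data.frame(individual_id = id, scan_id = seq_along(est),
             side = rep("left", length(est)),
             estimated_age = est, actual_age = act,
             stringsAsFactors = FALSE)
}

test_that("metrics match hand arithmetic and vanish on perfect estimates", {
  m <- compute_metrics(pred_df(c(30, 50), c(40, 40)))
  expect_equal(unname(m), c(10, 0, 10))
  expect_equal(unname(compute_metrics(pred_df(c(25, 70), c(25, 70)))),
               c(0, 0, 0))
  expect_error(compute_metrics(pred_df(numeric(0), numeric(0))), "empty")
})

test_that("metrics equal an independent brute-force loop", {
  set.seed(12)
  n <- 1000
  est <- stats::runif(n, 10, 100)
  act <- stats::runif(n, 18, 92)
  m <- compute_metrics(pred_df(est, act))
  sa <- 0; sb <- 0; sq <- 0
  for (i in seq_len(n)) {
    d <- est[i] - act[i]
    sa <- sa + abs(d); sb <- sb + d; sq <- sq + d^2
  }
  expect_equal(unname(m["mae"]), sa / n, tolerance = 1e-12)
  expect_equal(unname(m["mbe"]), sb / n, tolerance = 1e-12)
  expect_equal(unname(m["rmse"]), sqrt(sq / n), tolerance = 1e-12)
})

test_that("RMSE >= MAE >= |MBE| on random prediction sets", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(2:200, 1)
    m <- compute_metrics(pred_df(stats::rnorm(n, 50, 20),
                                 stats::runif(n, 18, 92)))
    expect_gte(m[["mae"]], abs(m[["mbe"]]))
    expect_gte(m[["rmse"]], m[["mae"]] - 1e-12)
  }
})

test_that("bilateral estimates average per individual", {
  p <- pred_df(c(40, 50, 61.2), c(55, 55, 61.2), id = c("a", "a", "b"))
  agg <- aggregate_individuals(p)
  expect_equal(nrow(agg), 2L)
  expect_equal(agg$estimated_age[agg$individual_id == "a"], 45)
  expect_equal(agg$estimated_age[agg$individual_id == "b"], 61.2)
  bad <- pred_df(c(1, 2), c(30, 31), id = c("a", "a"))
  expect_error(aggregate_individuals(bad), "conflicting")
})

test_that("a 374-individual cohort with 104 bilateral aggregates to 374 rows", {
  set.seed(1)
  ages <- sample(18:92, 374, replace = TRUE)
  two <- seq_len(374) %in% sample(374, 104)
  id <- rep(seq_len(374), times = 1 + two)
  p <- pred_df(stats::rnorm(length(id), 50, 15), ages[id], id = id)
  expect_equal(nrow(p), 478L)
  expect_equal(nrow(aggregate_individuals(p)), 374L)
})

test_that("cross-validation predicts every unit exactly once and is seeded", {
  tab <- simulate_feature_table(120, slopes = c(x3 = 2, x6 = 1),
                                offset = 18, noise_sd = 8, seed = 4)
  r1 <- crossval(tab, k = 5, seed = 10)
  expect_equal(sort(as.character(r1$predictions$individual_id)),
               sort(unique(tab$individual_id)))
  expect_true(all(table(r1$predictions$fold) >= floor(120 / 5)))
  r2 <- crossval(tab, k = 5, seed = 10)
  expect_identical(r1$predictions, r2$predictions)
  expect_equal(r1$mae, r2$mae)
  r3 <- crossval(tab, k = 5, seed = 11)
  expect_false(identical(r1$predictions$fold, r3$predictions$fold))
})

test_that("cross-validated MAE matches the Gaussian closed form", {
  tab <- simulate_feature_table(500, slopes = c(x2 = 120, x3 = 1.2,
                                                x6 = 0.9),
                                offset = 22, noise_sd = 8, seed = 20)
  rep <- crossval(tab, k = 5, seed = 2)
  expect_equal(rep$mae, 8 * sqrt(2 / pi), tolerance = 0.15)
  expect_lt(abs(rep$mbe), 0.5)
})

test_that("fold metrics are invariant to row shuffling under one seed", {
  tab <- simulate_feature_table(100, slopes = c(x3 = 2), noise_sd = 5,
                                seed = 9)
  r1 <- crossval(tab, k = 4, seed = 3)
  shuf <- tab[sample(nrow(tab)), ]
  r2 <- crossval(shuf, k = 4, seed = 3)
  expect_equal(r1$mae, r2$mae, tolerance = 1e-12)
  expect_equal(r1$rmse, r2$rmse, tolerance = 1e-12)
})

test_that("bilateral scans stay in one fold under individual partitioning", {
  coh_tab <- simulate_feature_table(60, slopes = c(x3 = 2), noise_sd = 5,
                                    seed = 14)
  coh_tab$individual_id <- rep(sprintf("ind%02d", 1:30), each = 2)
  coh_tab$age <- rep(coh_tab$age[seq(1, 60, 2)], each = 2)
  r <- crossval(coh_tab, k = 5, seed = 8, unit = "individual")
  expect_equal(r$n, 30L)
})

test_that("the constant-mean predictor has exactly zero bias", {
  set.seed(55)
  for (i in 1:20) {
    ages <- stats::runif(sample(5:300, 1), 18, 92)
    p <- pred_df(rep(mean(ages), length(ages)), ages)
    expect_equal(compute_metrics(p)[["mbe"]], 0, tolerance = 1e-12)
  }
})

test_that("the per-age dispersion table gives five-number summaries", {
  p <- pred_df(30, 25)
  tab <- age_dispersion_table(p)
  expect_equal(unlist(tab[1, c("min", "q1", "median", "q3", "max")]),
               c(min = 30, q1 = 30, median = 30, q3 = 30, max = 30))

  p4 <- pred_df(c(10, 20, 30, 40), rep(60, 4))
  expect_equal(age_dispersion_table(p4)$median, 25)

  set.seed(2)
  est <- stats::rnorm(500, 50, 15)
  act <- sample(40:49, 500, replace = TRUE)
  tab <- age_dispersion_table(pred_df(est, act))
  for (a in tab$age) {
    e <- sort(est[act == a])
    expect_equal(tab$min[tab$age == a], e[1])
    expect_equal(tab$max[tab$age == a], e[length(e)])
    expect_equal(tab$median[tab$age == a],
                 unname(stats::quantile(e, 0.5, type = 7)))
    expect_equal(tab$q1[tab$age == a],
                 unname(stats::quantile(e, 0.25, type = 7)))
  }
  nr <- age_dispersion_table(pred_df(est, act), quartiles = "nearest")
  expect_equal(nr$q3[1],
               unname(stats::quantile(sort(est[act == nr$age[1]]), 0.75,
                                      type = 1)))
})

test_that("evaluation reports write out as readable delimited text", {
  tab <- simulate_feature_table(80, slopes = c(x3 = 2), noise_sd = 6,
                                seed = 5)
  rep <- crossval(tab, k = 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(rep, path)
  lines <- readLines(path)
  expect_true("# pooled" %in% lines)
  expect_true("# per_age" %in% lines)
  pooled <- utils::read.table(text = lines[2:3], header = TRUE)
  expect_equal(pooled$mae, rep$mae, tolerance = 1e-6)
})
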