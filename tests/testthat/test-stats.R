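test_that("one-way ANOVA matches hand-computed F", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  av <- anova_oneway(g)
  expect_equal(av$F, 3.0, tolerance = 1e-12)
  expect_equal(av$df, c(2, 6))
  expect_equal(av$p, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(anova_oneway(same)$F, 0)

  shifted <- lapply(g, `+`, 100)
  expect_equal(anova_oneway(shifted)$F, av$F, tolerance = 1e-10)

  expect_error(anova_oneway(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("F equals t squared for two groups", {
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(5, mean = 0.5)
    g <- list(a = a, b = b)
    expect_equal(anova_oneway(g)$F, bonferroni_pairwise(g)$t^2,
                 tolerance = 1e-10)
  }
})

test_that("Bonferroni correction multiplies by the number of pairs and caps", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  pw <- bonferroni_pairwise(g)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adj, pmin(1, pw$p_raw * 3))
  expect_true(all(pw$p_adj >= pw$p_raw))

  same <- list(a = c(1, 2), b = c(1, 2), c = c(1, 2))
  expect_true(all(bonferroni_pairwise(same)$p_adj == 1))
})

test_that("Cohen's d matches hand computation and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(abs(cohens_d(c(1, 2, 3), c(3, 4, 5))), 2)
  expect_equal(cohens_d(c(1, 2), c(1, 2)), 0)
  a <- c(1, 5, 2); b <- c(4, 4, 7)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
})

fake_metrics <- function(n_heads = 5, montages = c("LUL", "BL", "TWO_BY_ONE"),
                         rois = c("STG_L", "STG_R"), amps = seq(1, 4, 0.5),
                         seed = 3, scramble = FALSE) {
  set.seed(seed)
  rows <- expand.grid(head = paste0("S", seq_len(n_heads)),
                      montage = montages, amplitude = amps,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    base <- match(r$montage, montages)
    k <- length(rois) + 2
    data.frame(
      head = rep(r$head, k), montage = rep(r$montage, k),
      amplitude = rep(r$amplitude, k),
      measure = rep(c("peak_field", "modulated_volume"),
                    c(length(rois), 2)),
      target = c(rois, "left", "right"),
      value = c(base * r$amplitude + rnorm(length(rois), sd = 0.1),
                pmin(100, 10 * base * r$amplitude + rnorm(2, sd = 0.5))),
      stringsAsFactors = FALSE)
  }))
  if (scramble) out <- out[sample(nrow(out)), ]
  out
}

test_that("stats report has one row per ROI and per side x amplitude", {
  met <- fake_metrics()
  rep <- build_report(met, peak_amplitude = 2)
  expect_s3_class(rep, "stats_report")
  expect_equal(sort(rep$peak_field$roi), c("STG_L", "STG_R"))
  expect_equal(nrow(rep$modulated_volume), 2 * 7)
  expect_equal(sum(rep$modulated_volume$side == "left"), 7)
  # three pairwise columns per row
  expect_length(grep("^p_adj_", names(rep$peak_field)), 3)
  expect_length(grep("^d_", names(rep$peak_field)), 3)
  expect_true(all(rep$peak_field$F >= 0))
  d_cols <- grep("^d_", names(rep$peak_field))
  expect_true(all(as.matrix(rep$peak_field[, d_cols]) >= 0))
  expect_error(build_report(met, montages = c("LUL", "BL", "HD")), "HD")
})

test_that("the report is a pure, order-independent function of the metrics", {
  r1 <- build_report(fake_metrics())
  r2 <- build_report(fake_metrics(scramble = TRUE))
  expect_equal(r1$peak_field, r2$peak_field, tolerance = 1e-12)
  expect_equal(r1$modulated_volume, r2$modulated_volume, tolerance = 1e-12)
})

test_that("indistinguishable montages yield no significant pairs", {
  met <- fake_metrics()
  # montage-independent values: the three groups per outcome are identical
  met$value <- as.integer(factor(met$head)) + met$amplitude
  rep <- build_report(met)
  sig_cols <- grep("^sig_", names(rep$peak_field))
  expect_true(all(as.matrix(rep$peak_field[, sig_cols]) == "NS"))
})
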