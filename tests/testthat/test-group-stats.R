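# Statistical layer: Welch t, Yates chi-square, ANCOVA, partial correlation,
# Fisher r-to-z, BH FDR, and the composed analysis plan.

test_that("Welch t: summary and raw forms agree and match stats::t.test", {
  set.seed(1)
  x <- rnorm(40, 1, 2); y <- rnorm(55, 0.4, 1.5)
  raw <- welch_t(x = x, y = y)
  summ <- welch_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  expect_equal(raw, summ, tolerance = 1e-12)
  tt <- t.test(x, y)
  expect_equal(raw$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(raw$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(raw$p, tt$p.value, tolerance = 1e-10)
  expect_equal(welch_t(5, 1, 10, 5, 1, 10)$t, 0)
  expect_error(welch_t(1, 0, 10, 1, 0, 12), "zero variance")
})

test_that("Yates chi-square matches its definition and clamps at zero", {
  set.seed(2)
  for (i in 1:5) {
    tab <- matrix(rpois(4, 30) + 1, 2, 2)
    expect_equal(chi2_yates(tab)$chi2, bf_yates_chi2(tab), tolerance = 1e-10)
  }
  prop <- matrix(c(10, 20, 20, 40), 2, byrow = TRUE)
  expect_equal(chi2_yates(prop)$chi2, 0)
  expect_error(chi2_yates(matrix(c(0, 0, 5, 5), 2)), "zero margin")
  expect_error(chi2_yates(matrix(1:6, 2)), "2x2")
})

test_that("ANCOVA group F equals the squared group-coefficient t", {
  set.seed(3)
  n <- 80
  grp <- rep(c("patient", "control"), each = n / 2)
  cov <- data.frame(gmv = rnorm(n, 600, 50))
  y <- 2 + 0.01 * cov$gmv + 0.5 * (grp == "control") + rnorm(n, 0, 0.4)
  a <- ancova_group_effect(y, grp, cov)
  expect_equal(a$F, a$t_group^2, tolerance = 1e-8)
  fit <- lm(y ~ g + gmv, data = data.frame(y = y, g = factor(grp,
            c("patient", "control")), gmv = cov$gmv))
  expect_equal(a$F, summary(fit)$coefficients[2, "t value"]^2,
               tolerance = 1e-8)
  expect_equal(a$df[2], n - 3)

  # response equal to the covariate with balanced groups: F ~ 0
  a0 <- suppressWarnings(ancova_group_effect(cov$gmv, grp, cov))
  expect_lt(a0$F, 1e-20)
  expect_error(ancova_group_effect(y, grp,
                                   data.frame(ind = as.numeric(grp == "patient"))),
               "collinear")
})

test_that("ANCOVA holds its nominal type-I rate on null Gaussian data", {
  set.seed(4)
  rej <- mean(replicate(100, {
    grp <- rep(c("a", "b"), each = 100)
    covar <- rnorm(200)
    y <- 0.3 * covar + rnorm(200)
    ancova_group_effect(y, grp, data.frame(covar))$p < 0.05
  }))
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.11)
})

test_that("partial correlation: no-covariate case, exact construction, oracle", {
  set.seed(5)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)

  covs <- matrix(rnorm(100), 50)
  y2 <- x + covs %*% c(2, -1)
  expect_equal(partial_correlation(x, as.vector(y2), covs)$r, 1,
               tolerance = 1e-8)

  for (i in 1:5) {
    x <- rnorm(60); y <- rnorm(60); covs <- matrix(rnorm(120), 60)
    pc <- partial_correlation(x, y, covs)
    expect_equal(pc$r, bf_partial_cor(x, y, covs), tolerance = 1e-10)
    expect_equal(pc$k, 2L)
    expect_equal(pc$n, 60L)
  }
  # listwise deletion
  x[1:10] <- NA
  expect_equal(partial_correlation(x, y, covs)$n, 50L)
  expect_error(partial_correlation(rnorm(5), rnorm(5), matrix(rnorm(10), 5)),
               "n > k \\+ 3")
})

test_that("Fisher r-to-z comparison: closed form, symmetry, degenerate input", {
  eq <- compare_correlations_fisher(0.4, 50, 0, 0.4, 80, 1)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  fz <- compare_correlations_fisher(0.5, 50, 0, 0.0, 50, 0)
  expect_equal(fz$z, atanh(0.5) / sqrt(2 / 47), tolerance = 1e-12)
  expect_equal(fz$z, 2.663, tolerance = 1e-3)
  sw <- compare_correlations_fisher(0.0, 50, 0, 0.5, 50, 0)
  expect_equal(sw$z, -fz$z)
  expect_equal(sw$p, fz$p)
  expect_error(compare_correlations_fisher(1, 50, 0, 0, 50, 0), "r1")
  expect_error(compare_correlations_fisher(0.2, 5, 3, 0.1, 50, 0), "n - 3 - k")
})

test_that("BH FDR matches the step-up definition", {
  expect_equal(fdr_bh(0.03)$p_adj, 0.03)
  four <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(four$rejected))
  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    got <- fdr_bh(p, q = 0.05)
    expect_identical(got$rejected, bf_bh_reject(p, 0.05))
    expect_equal(got$p_adj, p.adjust(p, "BH"))
    expect_true(all(got$p_adj >= p))
  }
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.2, 1.4)), "\\[0, 1\\]")
})

# ---- composed analysis plan -------------------------------------------------

fake_subjects <- function(n_pat = 40, n_ctl = 50, seed = 1) {
  set.seed(seed)
  n <- n_pat + n_ctl
  grp <- c(rep("patient", n_pat), rep("control", n_ctl))
  data.frame(
    subject_id = sprintf("S%03d", 1:n), group = grp,
    age = rnorm(n, 34, 8),
    sex = sample(c("female", "male"), n, replace = TRUE),
    education = rnorm(n, 15, 2.5),
    gm_volume = rnorm(n, 600, 55),
    pas = round(pmin(pmax(rnorm(n, ifelse(grp == "patient", 21, 12), 8),
                          0), 61)),
    sas = round(pmin(pmax(rnorm(n, ifelse(grp == "patient", 16, 9), 5),
                          0), 40)),
    duration_illness = ifelse(grp == "patient", abs(rnorm(n, 9, 7)), NA),
    cpz_dose = ifelse(grp == "patient", abs(rnorm(n, 420, 300)), NA),
    sigma = rnorm(n, 2.5 + 0.3 * (grp == "control"), 0.4),
    stringsAsFactors = FALSE)
}

fake_regional <- function(subjects, scopes, seed = 2) {
  set.seed(seed)
  do.call(rbind, lapply(scopes, function(s)
    data.frame(subject_id = subjects$subject_id, scope = s,
               sigma = rnorm(nrow(subjects), 2, 0.3),
               n_nodes = rpois(nrow(subjects), 60),
               stringsAsFactors = FALSE)))
}

test_that("the composed analysis plan reproduces the study's table structure", {
  subj <- fake_subjects()
  reg <- fake_regional(subj, c(paste0("icn:", c("DMN", "CCN", "SVN", "DAN",
                                                "LN", "SMN", "VN")),
                               paste0("region:", 1:5)))
  res <- run_full_statistics(subj, regional = reg)
  expect_setequal(res$demographics$variable,
                  c("age", "education", "gm_volume", "pas", "sas", "sex"))
  # one global row, 7 ICN rows, 5 regional rows; FDR within family
  expect_equal(sum(res$ancova$family == "global"), 1L)
  expect_equal(sum(res$ancova$family == "icn"), 7L)
  expect_equal(sum(res$ancova$family == "region"), 5L)
  expect_true(all(res$ancova$p_fdr >= res$ancova$p_unc - 1e-12))
  expect_true(all(res$correlations$p_fdr >= res$correlations$p_unc - 1e-12))
  # per-group covariate bookkeeping: k = 3 in patients, 1 in controls
  gl <- res$correlations[res$correlations$family == "global", ]
  expect_true(all(gl$k_patient == 3L))
  expect_true(all(gl$k_control == 1L))
  # SAS rows use complete cases only
  expect_equal(unique(gl$n_control[gl$scale == "SAS"]),
               sum(!is.na(subj$sas[subj$group == "control"])))
})

test_that("regional scopes below the average-node filter are excluded", {
  subj <- fake_subjects(20, 20)
  reg <- fake_regional(subj, c("region:1", "region:2"))
  reg$n_nodes[reg$scope == "region:2"] <- 10        # mean 10 < 30
  res <- run_full_statistics(subj, regional = reg)
  expect_true("region:1" %in% res$retained_scopes)
  expect_false("region:2" %in% res$retained_scopes)
  expect_false("region:2" %in% res$ancova$scope)
})

test_that("education never enters the adjustment set and row order is irrelevant", {
  subj <- fake_subjects(seed = 9)
  res1 <- run_full_statistics(subj)
  shuffled <- subj
  set.seed(10); shuffled$education <- sample(shuffled$education)
  res2 <- run_full_statistics(shuffled)
  expect_equal(res1$ancova$F, res2$ancova$F)
  expect_equal(res1$correlations$z, res2$correlations$z)

  set.seed(11)
  perm <- subj[sample(nrow(subj)), ]
  res3 <- run_full_statistics(perm)
  expect_equal(res1$ancova$F, res3$ancova$F, tolerance = 1e-10)
  expect_equal(res1$correlations$z, res3$correlations$z, tolerance = 1e-10)
  expect_equal(res1$demographics$statistic, res3$demographics$statistic,
               tolerance = 1e-10)
})

test_that("a strong planted correlation difference surfaces as significant", {
  subj <- fake_subjects(60, 60, seed = 12)
  # plant sigma-SAS coupling in controls only
  ctl <- subj$group == "control"
  subj$sas[ctl] <- round(pmin(pmax(9 + 4 * scale(subj$sigma[ctl]), 0), 40))
  res <- run_full_statistics(subj)
  row <- res$correlations[res$correlations$scale == "SAS", ]
  expect_gt(abs(row$z), 1.96)
  expect_gt(row$r_control, row$r_patient)
  # post-hoc table reports the surviving scope
  if (!is.null(res$posthoc))
    expect_true("SAS" %in% res$posthoc$scale)
})
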