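## Group-comparison and anhedonia-correlation statistics.
##
## Demographics: Welch unequal-variance t (the fractional dfs printed in the
## study's demographics table identify Welch's test) and a Yates-corrected
## chi-square for sex. Network metric: ANCOVA on sigma controlling total GM
## volume. Scale coupling: partial correlations of sigma with the anhedonia
## scales (GM volume controlled in both groups; illness duration and
## antipsychotic dose additionally controlled in patients), group difference
## assessed by a z-test on Fisher-transformed coefficients, all families
## corrected by Benjamini-Hochberg FDR.

#' Welch's unequal-variance t-test
#'
#' Callable on summary statistics (mean, sd, n per group) or on raw vectors
#' via `x` and `y`; both forms agree. Two-sided p with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 summary statistics per group.
#' @param x,y alternatively, raw vectors (missing values dropped).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2, x = NULL, y = NULL) {
  if (!is.null(x) || !is.null(y)) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  n1 <- stop_if_not_count(n1, "n1", 2L); n2 <- stop_if_not_count(n2, "n2", 2L)
  if (sd1 <= 0 && sd2 <= 0)
    stop("both groups have zero variance; t is undefined", call. = FALSE)
  se1 <- sd1^2 / n1; se2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Chi-square test of independence for a 2x2 table
#'
#' With the Yates continuity correction by default (the convention matching
#' the study's printed sex statistic); set `correct = FALSE` for the plain
#' Pearson statistic.
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @param correct apply the continuity correction (default TRUE).
#' @return list with `chi2`, `df`, `p`.
#' @export
chi2_yates <- function(counts, correct = TRUE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0))
    stop("`counts` must be a 2x2 table of non-negative counts", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin: chi-square test undefined", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' ANCOVA group effect on a network metric
#'
#' Ordinary least-squares fit of `y` on intercept + group indicator +
#' covariates; the group effect is the F statistic of the group term with
#' (1, n - p) degrees of freedom (identical to the squared t of the group
#' coefficient).
#'
#' @param y numeric response (e.g. per-subject sigma), no missing values.
#' @param group two-level factor or character vector.
#' @param covariates data frame / matrix of numeric covariates (may be
#'   empty).
#' @return list with `F`, `df` (length 2), `p`, `t_group`, `n`.
#' @export
ancova_group_effect <- function(y, group, covariates = NULL) {
  if (anyNA(y)) stop("`y` must not contain missing values", call. = FALSE)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("`group` must have exactly 2 levels",
                                 call. = FALSE)
  dat <- data.frame(y = y, group = group)
  form <- y ~ group
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- make.names(names(covariates), unique = TRUE)
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(c("group", names(covariates)), response = "y")
  }
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design: dropped terms ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  tg <- sm$coefficients[2L, "t value"]
  df2 <- fit$df.residual
  Fg <- tg^2
  list(F = Fg, df = c(1, df2), p = stats::pf(Fg, 1, df2, lower.tail = FALSE),
       t_group = tg, n = length(fit$residuals))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after each is
#' regressed on intercept + covariates; rows with any missing value are
#' dropped listwise first. The p-value uses the t distribution with
#' n - k - 2 degrees of freedom (k = number of covariates).
#'
#' @param x,y numeric vectors.
#' @param covariates data frame / matrix of numeric covariates or NULL.
#' @return list with `r`, `n`, `k`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)
  k <- if (is.null(cv)) 0L else ncol(cv)
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(cv)) keep <- keep & !apply(cv, 1, anyNA)
  x <- x[keep]; y <- y[keep]
  if (!is.null(cv)) cv <- cv[keep, , drop = FALSE]
  n <- length(x)
  if (n <= k + 3L) stop("need n > k + 3 complete observations", call. = FALSE)
  if (k > 0L) {
    X <- cbind(1, cv)
    x <- stats::lm.fit(X, x)$residuals
    y <- stats::lm.fit(X, y)$residuals
  }
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("degenerate residual variance: partial correlation undefined",
         call. = FALSE)
  r <- stats::cor(x, y)
  df <- n - k - 2L
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, n = n, k = k, p = 2 * stats::pt(-abs(t), df))
}

#' Compare two independent (partial) correlations via Fisher's r-to-z
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1 - 3 - k1) + 1/(n2 - 3 - k2))`,
#' two-sided p from the standard normal. The k-adjustment in the variance is
#' the standard extension of the Fisher variance to partial correlations.
#'
#' @param r1,n1,k1 coefficient, sample size and number of controlled
#'   covariates in group 1.
#' @param r2,n2,k2 same for group 2.
#' @return list with `z`, `p`.
#' @export
compare_correlations_fisher <- function(r1, n1, k1, r2, n2, k2) {
  stop_if_not_scalar(r1, "r1", -1 + 1e-12, 1 - 1e-12)
  stop_if_not_scalar(r2, "r2", -1 + 1e-12, 1 - 1e-12)
  v1 <- n1 - 3 - k1; v2 <- n2 - 3 - k2
  if (v1 <= 0 || v2 <= 0) stop("need n - 3 - k > 0 in each group", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / v1 + 1 / v2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values for one family of tests; rejection iff adjusted
#' p <= q.
#'
#' @param p_values numeric vector of uncorrected p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return list with `p_adj` and logical `rejected`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value family", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p_adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adj = p_adj, rejected = p_adj <= q)
}

# full analysis plan ----------------------------------------------------

# per-group partial correlation of sigma with one scale, with the group's
# covariate set; returns NULL on failed preconditions
group_scale_cor <- function(dat, scale_col, grp) {
  d <- dat[dat$group == grp, ]
  covs <- d[, "gm_volume", drop = FALSE]
  if (grp == "patient")
    covs <- cbind(covs, duration_illness = d$duration_illness,
                  cpz_dose = d$cpz_dose)
  tryCatch(partial_correlation(d$sigma, d[[scale_col]], covs),
           error = function(e) NULL)
}

#' Run the full statistical analysis plan on a cohort table
#'
#' Reproduces the study's analysis structure: (a) demographics tests (Welch
#' t for age, education, GM volume, PAS, SAS; Yates chi-square for sex —
#' education is deliberately never entered as a covariate); (b) ANCOVA on
#' sigma controlling GM volume at the global scope and, when regional rows
#' are supplied, per 7-ICN scope (one FDR family) and per retained region
#' (another family); (c) per group, partial correlation of sigma with PAS
#' and SAS controlling GM volume (plus illness duration and antipsychotic
#' dose in patients), SAS restricted to subjects with SAS present; (d)
#' Fisher r-to-z group comparison per scope and scale, FDR-corrected per
#' family; (e) post-hoc per-group coefficients reported for scopes whose
#' z-test survives FDR. Results with FDR-corrected p in (0.05, 0.1] are
#' tagged `"trend"` and never counted as significant.
#'
#' @param subjects data frame with columns `subject_id`, `group`
#'   (patient/control), `age`, `sex`, `education`, `gm_volume`, `pas`,
#'   `sas` (may be NA), `duration_illness`, `cpz_dose` (patients), and
#'   `sigma` (global-scale small-worldness).
#' @param regional optional long data frame of local-scale metrics:
#'   `subject_id`, `scope` (e.g. `"icn:DMN"`, `"region:12"`), `sigma`,
#'   `n_nodes`. Scopes are filtered with [filter_regions_min_nodes()] before
#'   analysis.
#' @param q FDR level (default 0.05).
#' @param min_avg_nodes cohort-average node-count filter for regional scopes
#'   (default 30).
#' @return list of data frames: `demographics`, `ancova`, `correlations`,
#'   `posthoc`, plus `retained_scopes`.
#' @export
run_full_statistics <- function(subjects, regional = NULL, q = 0.05,
                                min_avg_nodes = 30) {
  stopifnot(is.data.frame(subjects))
  need <- c("subject_id", "group", "age", "sex", "education", "gm_volume",
            "pas", "sas", "sigma")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("missing cohort columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  subjects$group <- factor(subjects$group, levels = c("patient", "control"))
  pat <- subjects[subjects$group == "patient", ]
  ctl <- subjects[subjects$group == "control", ]

  # (a) demographics
  demo_rows <- lapply(c("age", "education", "gm_volume", "pas", "sas"),
    function(v) {
      w <- tryCatch(welch_t(x = pat[[v]], y = ctl[[v]]),
                    error = function(e) list(t = NA_real_, df = NA_real_,
                                             p = NA_real_))
      data.frame(variable = v, test = "welch_t", statistic = w$t, df = w$df,
                 p_unc = w$p, stringsAsFactors = FALSE)
    })
  sex_tab <- rbind(table(factor(pat$sex, c("female", "male"))),
                   table(factor(ctl$sex, c("female", "male"))))
  cs <- chi2_yates(sex_tab)
  demographics <- rbind(do.call(rbind, demo_rows),
                        data.frame(variable = "sex", test = "chi2_yates",
                                   statistic = cs$chi2, df = cs$df,
                                   p_unc = cs$p, stringsAsFactors = FALSE))

  # regional scope bookkeeping: the cohort-level node-count filter applies to
  # the individual-region family; the 7 ICN scopes are analysed as-is
  retained <- character(0)
  if (!is.null(regional) && nrow(regional)) {
    cnt <- tapply(regional$n_nodes,
                  list(regional$subject_id, regional$scope), mean)
    cnt[is.na(cnt)] <- 0
    retained <- filter_regions_min_nodes(cnt, min_avg = min_avg_nodes)
    keep <- !startsWith(regional$scope, "region:") |
      regional$scope %in% retained
    regional <- regional[keep & !is.na(regional$sigma), ]
  }

  # (b) ANCOVA on sigma controlling GM volume, per scope family
  anc_row <- function(dat, scope) {
    a <- ancova_group_effect(dat$sigma, dat$group,
                             dat[, "gm_volume", drop = FALSE])
    data.frame(scope = scope, F = a$F, df1 = a$df[1], df2 = a$df[2],
               p_unc = a$p, stringsAsFactors = FALSE)
  }
  ancova <- anc_row(subjects[!is.na(subjects$sigma), ], "global")
  ancova$family <- "global"
  if (!is.null(regional) && nrow(regional)) {
    merged <- merge(regional,
                    subjects[, c("subject_id", "group", "gm_volume")],
                    by = "subject_id")
    for (fam in c("icn", "region")) {
      scopes <- sort(unique(merged$scope[startsWith(merged$scope,
                                                    paste0(fam, ":"))]))
      if (!length(scopes)) next
      rows <- do.call(rbind, lapply(scopes, function(s)
        anc_row(merged[merged$scope == s, ], s)))
      rows$family <- fam
      ancova <- rbind(ancova, rows)
    }
  }
  ancova$p_fdr <- NA_real_
  for (fam in unique(ancova$family)) {
    i <- ancova$family == fam
    ancova$p_fdr[i] <- fdr_bh(ancova$p_unc[i], q)$p_adj
  }
  ancova$label <- ifelse(ancova$p_fdr <= q, "significant",
                         ifelse(ancova$p_fdr <= 0.1, "trend", "ns"))

  # (c)+(d) correlation comparison per scope x scale
  cor_rows <- function(dat, scope) {
    out <- list()
    for (scale_col in c("pas", "sas")) {
      cp <- group_scale_cor(dat, scale_col, "patient")
      cc <- group_scale_cor(dat, scale_col, "control")
      if (is.null(cp) || is.null(cc)) next
      fz <- compare_correlations_fisher(cp$r, cp$n, cp$k, cc$r, cc$n, cc$k)
      out[[scale_col]] <- data.frame(
        scope = scope, scale = toupper(scale_col),
        r_patient = cp$r, n_patient = cp$n, k_patient = cp$k,
        r_control = cc$r, n_control = cc$n, k_control = cc$k,
        z = fz$z, p_unc = fz$p, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  correlations <- cor_rows(subjects[!is.na(subjects$sigma), ], "global")
  if (!is.null(correlations)) correlations$family <- "global"
  if (!is.null(regional) && nrow(regional)) {
    merged <- merge(regional[, c("subject_id", "scope", "sigma")],
                    subjects[, setdiff(names(subjects), "sigma")],
                    by = "subject_id")
    for (fam in c("icn", "region")) {
      scopes <- sort(unique(merged$scope[startsWith(merged$scope,
                                                    paste0(fam, ":"))]))
      if (!length(scopes)) next
      rows <- do.call(rbind, lapply(scopes, function(s)
        cor_rows(merged[merged$scope == s, ], s)))
      if (is.null(rows)) next
      rows$family <- fam
      correlations <- rbind(correlations, rows)
    }
  }
  posthoc <- NULL
  if (!is.null(correlations) && nrow(correlations)) {
    correlations$p_fdr <- NA_real_
    # one family per (scope family, scale), mirroring "based on the number of
    # statistical tests performed"
    for (fam in unique(correlations$family)) for (sc in c("PAS", "SAS")) {
      i <- correlations$family == fam & correlations$scale == sc
      if (any(i)) correlations$p_fdr[i] <- fdr_bh(correlations$p_unc[i], q)$p_adj
    }
    correlations$label <- ifelse(correlations$p_fdr <= q, "significant",
                                 ifelse(correlations$p_fdr <= 0.1, "trend", "ns"))
    sig <- correlations[correlations$label == "significant", ]
    if (nrow(sig)) {
      posthoc <- sig[, c("scope", "scale", "r_patient", "n_patient",
                         "r_control", "n_control")]
      # per-group post-hoc p-values for the surviving scopes
      ph_p <- function(r, n, k) {
        df <- n - k - 2
        t <- r * sqrt(df / (1 - r^2))
        2 * stats::pt(-abs(t), df)
      }
      posthoc$p_patient <- ph_p(sig$r_patient, sig$n_patient, sig$k_patient)
      posthoc$p_control <- ph_p(sig$r_control, sig$n_control, sig$k_control)
    }
  }
  list(demographics = demographics, ancova = ancova,
       correlations = correlations, posthoc = posthoc,
       retained_scopes = retained)
}
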