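#' Percent change between two timepoints
#'
#' The study convention is `(initial - followup) / initial * 100`, which is
#' negative when a quantity increases. Because increases are usually
#' reported as positive percentages, the signed-increase form
#' `(followup - initial) / initial * 100` is exposed as
#' [percent_increase()]; take `abs()` of either for a magnitude. Vectorised.
#'
#' @param initial,followup numeric vectors; `initial` must be nonzero.
#' @return Percent change (numeric).
#' @export
percent_change <- function(initial, followup) {
  if (any(initial == 0, na.rm = TRUE))
    stop("percent change undefined for initial value 0")
  (initial - followup) / initial * 100
}

#' @rdname percent_change
#' @export
percent_increase <- function(initial, followup) {
  -percent_change(initial, followup)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (the classic Wilcoxon convention; Pratt's alternative changes p
#' and is not used), ties among |differences| are mid-ranked. For n <= 25
#' pairs the exact null distribution is computed by convolution over the
#' (doubled, hence integer) mid-ranks, so the exact p is available even
#' under ties; beyond that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param before,after equal-length numeric vectors; NA pairs are dropped.
#' @param exact_max largest n for which the exact distribution is used.
#' @return A list of class `cv_stat`: `statistic` (V, rank sum of positive
#'   differences), `p.value` (two-sided), `n` (pairs used after dropping
#'   zeros), `method`.
#' @export
paired_wilcoxon <- function(before, after, exact_max = 25) {
  if (length(before) != length(after)) stop("before/after must have equal length")
  ok <- !(is.na(before) | is.na(after))
  d <- after[ok] - before[ok]
  if (length(d) < 5) stop("fewer than 5 complete pairs: small-sample error")
  if (all(d == 0)) stop("all differences zero: test undefined")
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) stop(sprintf("only %d nonzero differences after zero-dropping: small-sample error", n))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- wilcoxon_exact_p(r, V)
    method <- "exact signed-rank (convolution over mid-ranks)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(V - mu) * 0.5
    z <- (V - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with continuity and tie correction"
  }
  structure(list(statistic = c(V = V), p.value = p, n = n, method = method),
            class = "cv_stat")
}

# Exact two-sided p for the signed-rank statistic given the mid-ranks of
# |d| and observed V. Works on doubled ranks (integers); null assigns each
# rank a sign +/- with probability 1/2.
wilcoxon_exact_p <- function(ranks, V) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # probability vector over 2V = 0..total
  prob <- numeric(total + 1)
  prob[1] <- 1
  for (rk in r2) {
    shifted <- c(rep(0, rk), prob[seq_len(total + 1 - rk)])
    prob <- (prob + shifted) / 2
  }
  v2 <- as.integer(round(2 * V))
  lo <- sum(prob[seq_len(v2 + 1)])           # P(V <= v)
  hi <- sum(prob[(v2 + 1):(total + 1)])      # P(V >= v)
  min(1, 2 * min(lo, hi))
}

#' @export
print.cv_stat <- function(x, ...) {
  cat(sprintf("V = %g, p = %.4g (n = %d; %s)\n",
              x$statistic, x$p.value, x$n, x$method))
  invisible(x)
}

#' Ordinary least squares with per-covariate confidence intervals
#'
#' OLS with intercept; 95% CIs from the t distribution. `mode =
#' "multivariable"` fits all covariates jointly (one model);
#' `"univariable"` fits one single-covariate model per column. Complete-case
#' analysis per model, with the n used reported.
#'
#' @param response numeric vector (e.g. per-subject percent change).
#' @param covariates data.frame or matrix with named columns.
#' @param mode `"multivariable"` or `"univariable"`.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame: `term`, `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `n`, `model`.
#' @export
ols_regression <- function(response, covariates,
                           mode = c("multivariable", "univariable"),
                           conf_level = 0.95) {
  mode <- match.arg(mode)
  covariates <- as.data.frame(covariates)
  if (is.null(names(covariates)) || any(!nzchar(names(covariates))))
    stop("covariates must have named columns")
  if (any(vapply(covariates, function(x) length(unique(x[!is.na(x)])) <= 1, TRUE)))
    stop("constant covariate column(s): ",
         paste(names(covariates)[vapply(covariates, function(x)
           length(unique(x[!is.na(x)])) <= 1, TRUE)], collapse = ", "))
  fit_one <- function(dat, label) {
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    n <- nrow(dat)
    if (n <= ncol(dat)) stop("too few complete cases for the design: n = ", n)
    X <- cbind(`(Intercept)` = 1, as.matrix(dat[, -1, drop = FALSE]))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("rank-deficient design; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
    fit <- lm(.response ~ ., data = dat)
    ci <- confint(fit, level = conf_level)
    sm <- summary(fit)$coefficients
    terms <- setdiff(rownames(sm), "(Intercept)")
    data.frame(term = terms,
               estimate = sm[terms, 1],
               ci_low = ci[terms, 1], ci_high = ci[terms, 2],
               p_value = sm[terms, 4],
               n = n, model = label, row.names = NULL)
  }
  if (mode == "multivariable") {
    dat <- data.frame(.response = response, covariates, check.names = FALSE)
    fit_one(dat, "multivariable")
  } else {
    out <- lapply(names(covariates), function(nm)
      fit_one(data.frame(.response = response,
                         covariates[, nm, drop = FALSE], check.names = FALSE),
              "univariable"))
    do.call(rbind, out)
  }
}

#' Longitudinal change table over chunks and features
#'
#' For every (chunk, feature) cell, computes the mean per-subject percent
#' change between baseline and follow-up (in both sign conventions), a
#' paired Wilcoxon signed-rank p-value, and a Benjamini-Hochberg adjusted
#' p-value column (informational only; significance calls in the study used
#' raw p < 0.05). When covariates are supplied, a multivariable OLS of the
#' per-subject percent increase on the covariates is fitted per cell and the
#' per-covariate coefficients with 95% CIs are returned alongside — the
#' "interference" heatmap table.
#'
#' @param cohort long data.frame with columns `subject_id`, `timepoint`
#'   (`"baseline"` / `"followup"`), `chunk_id`, and one column per feature.
#'   Subjects missing a timepoint are excluded with a warning.
#' @param covariates optional data.frame with `subject_id` plus numeric or
#'   binary covariate columns (age, sex, SBP, LDL change, ...).
#' @param features feature columns to analyse; defaults to the nine
#'   morphometric features present in `cohort`.
#' @return A list of class `cv_change_table`: `changes` (long data.frame:
#'   `chunk_id`, `feature`, `n`, `mean_baseline`, `mean_followup`,
#'   `pct_decrease`, `pct_increase`, `p_value`, `p_adj_bh`) and
#'   `covariate_effects` (NULL, or long data.frame with per-cell covariate
#'   coefficients and CIs).
#' @export
build_change_table <- function(cohort, covariates = NULL, features = NULL) {
  req <- c("subject_id", "timepoint", "chunk_id")
  if (!all(req %in% names(cohort)))
    stop("cohort needs columns: ", paste(req, collapse = ", "))
  allfeat <- c("area_mm2", "misr_mm", "min_diameter_mm", "max_diameter_mm",
               "min_max_ratio", "curvature_per_mm", "torsion_per_mm",
               "perimeter_mm", "circularity")
  if (is.null(features)) features <- intersect(allfeat, names(cohort))
  if (!length(features)) stop("no feature columns found in cohort")
  bl <- cohort[cohort$timepoint == "baseline", , drop = FALSE]
  fu <- cohort[cohort$timepoint == "followup", , drop = FALSE]
  both <- intersect(unique(bl$subject_id), unique(fu$subject_id))
  dropped <- setdiff(unique(cohort$subject_id), both)
  if (length(dropped))
    warning("subject(s) missing a timepoint, excluded: ",
            paste(dropped, collapse = ", "))
  if (length(both) < 5)
    stop("fewer than 5 subjects with both timepoints: ", length(both))
  chunks <- sort(unique(cohort$chunk_id))
  rows <- list(); covrows <- list()
  for (ck in chunks) {
    bls <- bl[bl$chunk_id == ck, , drop = FALSE]
    fus <- fu[fu$chunk_id == ck, , drop = FALSE]
    for (ft in features) {
      b <- setNames(bls[[ft]], bls$subject_id)[as.character(both)]
      a <- setNames(fus[[ft]], fus$subject_id)[as.character(both)]
      ok <- !(is.na(b) | is.na(a)) & b != 0
      pv <- tryCatch(paired_wilcoxon(b[ok], a[ok])$p.value,
                     error = function(e) NA_real_)
      pc <- percent_change(b[ok], a[ok])
      rows[[length(rows) + 1]] <- data.frame(
        chunk_id = ck, feature = ft, n = sum(ok),
        mean_baseline = mean(b[ok]), mean_followup = mean(a[ok]),
        pct_decrease = mean(pc), pct_increase = mean(-pc),
        p_value = pv)
      if (!is.null(covariates) && sum(ok) >= 5) {
        covs <- covariates[match(both[ok], covariates$subject_id), , drop = FALSE]
        covs <- covs[, setdiff(names(covs), "subject_id"), drop = FALSE]
        eff <- tryCatch(ols_regression(-pc, covs, mode = "multivariable"),
                        error = function(e) NULL)
        if (!is.null(eff)) {
          eff$chunk_id <- ck; eff$feature <- ft
          covrows[[length(covrows) + 1]] <- eff
        }
      }
    }
  }
  changes <- do.call(rbind, rows)
  changes$p_adj_bh <- p.adjust(changes$p_value, method = "BH")
  rownames(changes) <- NULL
  covariate_effects <- if (length(covrows)) {
    ce <- do.call(rbind, covrows)
    rownames(ce) <- NULL
    ce[, c("chunk_id", "feature", "term", "estimate", "ci_low", "ci_high",
           "p_value", "n", "model")]
  } else NULL
  structure(list(changes = changes, covariate_effects = covariate_effects),
            class = "cv_change_table")
}

#' @export
print.cv_change_table <- function(x, ...) {
  cat(sprintf("<cv_change_table> %d chunk x feature cells, %d with p < 0.05\n",
              nrow(x$changes), sum(x$changes$p_value < 0.05, na.rm = TRUE)))
  invisible(x)
}
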