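# Cohort simulation and the study-level statistics: end-to-end Monte-Carlo
# cohorts, planning/validation summaries, paired comparisons with a normality
# screen, multiple regression on absolute angle differences, and the a-priori
# paired-t sample-size calculation.

#' Simulate a validation cohort end-to-end
#'
#' Samples anatomy and covariates from `dists`, generates a femur and tibia per
#' case, runs both plans, executes them under `error_model`, re-measures the
#' postoperative angles and assembles one record per case. Cases whose
#' construction fails are logged and excluded (count in
#' `attr(x, "n_failed")`).
#'
#' @param n Number of cases.
#' @param dists A [cohort_distributions()].
#' @param policy A [psa_policy()]; the default adds 0.5 deg of PSA per degree
#'   of native slope above 10 deg, capped at the observed range.
#' @param error_model An [execution_error_model()].
#' @param seed Optional integer seed (drives anatomy sampling and execution
#'   error).
#' @return A data.frame of class `tka_cohort`: anatomy parameters, covariates,
#'   plan scalars (`fed`, `psa`, `offset_diff`), pre/post angles, corrected
#'   differences, target flags, notching flag and measured morphometry.
#' @export
#' @examples
#' coh <- run_cohort(5, seed = 1, error_model = zero_error_model())
#' summary(coh)
run_cohort <- function(n, dists = cohort_distributions(),
                       policy = psa_policy("slope_adaptive"),
                       error_model = execution_error_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- sample_cohort(n, dists)
  rows <- vector("list", n)
  failures <- character(0)
  for (i in seq_len(n)) {
    rec <- tryCatch({
      femur <- generate_femur(femur_params(dfb = params$dfb[i]))
      tibia <- generate_tibia(tibia_params(ptb = params$ptb[i],
                                           native_tps = params$tps[i],
                                           tst = params$tst[i]))
      fp <- plan_femur(femur, params$implant[i])
      tp <- plan_tibia(tibia, params$implant[i], policy = policy)
      ex <- execute_plan(fp, tp, error_model)
      cr <- case_result(femur, tibia, fp, tp, ex)
      data.frame(
        case = params$case[i], implant = params$implant[i],
        sex_men = params$sex_men[i], age = params$age[i], bmi = params$bmi[i],
        dxa = params$dxa[i], hka = params$hka[i],
        dfb = measure_dfb(femur), ptb = measure_ptb(tibia),
        tps = measure_tps(tibia), tst = measure_tst(tibia),
        fed = fp$fed, psa = tp$psa, offset_diff = tp$offset_diff,
        preop_gamma = cr$preop_gamma, postop_gamma = cr$postop_gamma,
        gamma_diff = cr$gamma_diff,
        preop_delta = cr$preop_delta, postop_delta = cr$postop_delta,
        delta_diff = cr$delta_diff,
        gamma_within = cr$gamma_within, delta_within = cr$delta_within,
        notching = cr$notching, stringsAsFactors = FALSE)
    }, error = function(e) {
      failures <<- c(failures, sprintf("case %d: %s", params$case[i],
                                       conditionMessage(e)))
      NULL
    })
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all cases failed: ", paste(failures, collapse = "; "))
  attr(out, "n_failed") <- length(failures)
  attr(out, "failures") <- failures
  attr(out, "seed") <- seed
  attr(out, "error_model") <- error_model
  class(out) <- c("tka_cohort", "data.frame")
  out
}

#' Summarise a cohort's planning and validation measurements
#'
#' Sample statistics in the layout of the study's planning/validation table:
#' FED and PSA as mean (range), gamma and delta pre/post as mean +/- SD, and
#' the percentage of cases within the +/-2 degree target (to 0.1%).
#'
#' @param object A `tka_cohort` table.
#' @param ... Unused.
#' @return An object of class `tka_cohort_summary`.
#' @export
summary.tka_cohort <- function(object, ...) {
  x <- object
  stopifnot(nrow(x) >= 1)
  msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
  structure(list(
    n = nrow(x),
    n_failed = attr(x, "n_failed") %||% 0L,
    fed = c(mean = mean(x$fed), min = min(x$fed), max = max(x$fed)),
    psa = c(mean = mean(x$psa), min = min(x$psa), max = max(x$psa)),
    gamma_pre = msd(x$preop_gamma), gamma_post = msd(x$postop_gamma),
    delta_pre = msd(x$preop_delta), delta_post = msd(x$postop_delta),
    gamma_within_n = sum(x$gamma_within),
    delta_within_n = sum(x$delta_within),
    gamma_accuracy = round(100 * mean(x$gamma_within), 1),
    delta_accuracy = round(100 * mean(x$delta_within), 1),
    notching_n = sum(x$notching)
  ), class = "tka_cohort_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tka_cohort_summary <- function(x, ...) {
  cat(sprintf("TKA sagittal planning cohort: n = %d (%d failed/excluded)\n",
              x$n, x$n_failed))
  cat(sprintf("  FED (mm): %.1f (%.1f to %.1f)\n", x$fed["mean"], x$fed["min"],
              x$fed["max"]))
  cat(sprintf("  PSA (deg): %.1f (%.1f to %.1f)\n", x$psa["mean"], x$psa["min"],
              x$psa["max"]))
  cat(sprintf("  gamma (deg): %.1f +/- %.1f planned, %.1f +/- %.1f achieved\n",
              x$gamma_pre["mean"], x$gamma_pre["sd"],
              x$gamma_post["mean"], x$gamma_post["sd"]))
  cat(sprintf("  delta (deg): %.1f +/- %.1f planned, %.1f +/- %.1f achieved\n",
              x$delta_pre["mean"], x$delta_pre["sd"],
              x$delta_post["mean"], x$delta_post["sd"]))
  cat(sprintf("  within +/-2 deg: femur %d/%d (%.1f%%), tibia %d/%d (%.1f%%)\n",
              x$gamma_within_n, x$n, x$gamma_accuracy,
              x$delta_within_n, x$n, x$delta_accuracy))
  cat(sprintf("  anterior notching: %d case(s)\n", x$notching_n))
  invisible(x)
}

#' Paired comparison with a normality screen
#'
#' Screens the paired differences for normality with a Kolmogorov-Smirnov test
#' (standardised differences against the standard normal) at `alpha`; if not
#' rejected, runs a paired t test, otherwise the paired rank-based analogue
#' (Wilcoxon signed-rank). If all differences are identical the comparison is
#' degenerate and `p` is `NA` with `test = "degenerate"`.
#'
#' @param pre,post Equal-length numeric vectors (n >= 3).
#' @param alpha Normality-screen level.
#' @return A list of class `paired_comparison` with `test`, `p`,
#'   `p_normality`, `statistic` and `mean_difference`.
#' @export
#' @examples
#' paired_compare(rnorm(20), rnorm(20, 1))
paired_compare <- function(pre, post, alpha = 0.05) {
  stopifnot(length(pre) == length(post), length(pre) >= 3,
            all(is.finite(pre)), all(is.finite(post)))
  d <- post - pre
  if (stats::sd(d) < 1e-12) {
    return(structure(list(test = "degenerate", p = NA_real_,
                          p_normality = NA_real_, statistic = NA_real_,
                          mean_difference = mean(d)),
                     class = "paired_comparison"))
  }
  z <- (d - mean(d)) / stats::sd(d)
  pn <- suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
  if (pn >= alpha) {
    tt <- stats::t.test(post, pre, paired = TRUE)
    res <- list(test = "paired t", p = tt$p.value, p_normality = pn,
                statistic = unname(tt$statistic), mean_difference = mean(d))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE))
    res <- list(test = "wilcoxon signed-rank", p = wt$p.value,
                p_normality = pn, statistic = unname(wt$statistic),
                mean_difference = mean(d))
  }
  structure(res, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: p = %s (normality screen p = %s)\n",
              x$test, format.pval(x$p, digits = 3),
              format.pval(x$p_normality, digits = 3)))
  cat(sprintf("  mean difference %.3f\n", x$mean_difference))
  invisible(x)
}

#' Multiple regression on absolute angle differences
#'
#' Ordinary least squares of the absolute pre/post angle difference on the
#' stated predictors, reporting per predictor the unstandardised coefficient B
#' with SE, the standardised coefficient Beta, t, p and the 95% CI. Default
#' predictor sets follow the study design: sex, age, BMI, DXA and HKA for both
#' bones, plus DFB for the femur, and TPS, TST, PTB for the tibia.
#'
#' @param table A `tka_cohort` (or any data.frame with the needed columns).
#' @param response `"gamma"` or `"delta"` (uses `abs(<response>_diff)`), or the
#'   name of any numeric column to use directly.
#' @param predictors Character vector of predictor column names; `NULL` for
#'   the bone's default set.
#' @param conf_level Confidence level for the intervals.
#' @return A data.frame of class `regression_table` with one row per term; the
#'   model-matrix condition number is in `attr(x, "condition_number")` (a
#'   warning is raised above 1e8).
#' @export
regress_abs_differences <- function(table, response = c("gamma", "delta"),
                                    predictors = NULL, conf_level = 0.95) {
  df <- as.data.frame(table)
  if (is.character(response) && length(response) == 1L &&
      response %in% c("gamma", "delta")) {
    y <- abs(df[[paste0(response, "_diff")]])
    if (is.null(predictors)) {
      predictors <- if (response == "gamma")
        c("sex_men", "age", "bmi", "dxa", "hka", "dfb")
      else c("sex_men", "age", "bmi", "dxa", "hka", "tps", "tst", "ptb")
    }
    yname <- sprintf("|%s difference|", response)
  } else {
    y <- df[[response]]
    if (is.null(predictors)) stop("predictors must be given for a custom response")
    yname <- response
  }
  missing_cols <- setdiff(predictors, names(df))
  if (length(missing_cols))
    stop("missing predictor columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(df) <= length(predictors) + 1L)
    stop("need n > number of predictors + 1")
  fit <- if (length(predictors) == 0L) {
    stats::lm(y ~ 1, data = data.frame(y = y))
  } else {
    stats::lm(y ~ ., data = cbind(y = y, df[predictors]))
  }
  kap <- kappa(stats::model.matrix(fit), exact = TRUE)
  if (kap > 1e8)
    warning(sprintf("ill-conditioned design (condition number %.3g); coefficients unstable", kap))
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  ci <- ci[rownames(sm), , drop = FALSE]  # aliased terms carry no estimate
  sy <- stats::sd(y)
  beta <- vapply(rownames(sm), function(term) {
    if (term == "(Intercept)") return(NA_real_)
    unname(sm[term, "Estimate"]) * stats::sd(df[[term]]) / sy
  }, numeric(1))
  out <- data.frame(
    term = rownames(sm),
    B = sm[, "Estimate"], SE = sm[, "Std. Error"], Beta = beta,
    t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
    ci_lower = ci[, 1], ci_upper = ci[, 2],
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "response") <- yname
  attr(out, "condition_number") <- kap
  attr(out, "fit") <- fit
  class(out) <- c("regression_table", "data.frame")
  out
}

#' @export
print.regression_table <- function(x, digits = 3, ...) {
  cat("Multiple regression on", attr(x, "response"), "\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) signif(v, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Sample size for a two-tailed paired t test
#'
#' Smallest number of pairs for which the two-tailed paired t test at level
#' `alpha` has at least the target power against a standardised effect
#' `effect_size`, computed from the noncentral t distribution. The design
#' values of the validation study (effect 0.4, alpha 0.05, power 0.95) give 84
#' pairs.
#'
#' @param effect_size Standardised mean paired difference (Cohen's d_z), > 0.
#' @param alpha Two-sided type-I error level.
#' @param power Target power.
#' @param n_max Search bound.
#' @return Integer sample size.
#' @export
#' @examples
#' sample_size_paired_t(0.4, 0.05, 0.95)  # 84
sample_size_paired_t <- function(effect_size, alpha = 0.05, power = 0.95,
                                 n_max = 1e6) {
  stopifnot(effect_size > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:n_max) {
    df <- n - 1
    tcrit <- stats::qt(1 - alpha / 2, df)
    ncp <- effect_size * sqrt(n)
    pw <- 1 - stats::pt(tcrit, df, ncp = ncp) + stats::pt(-tcrit, df, ncp = ncp)
    if (pw >= power) return(as.integer(n))
  }
  stop("target power unattainable within the search bound")
}

#' Inflate a sample size for anticipated dropout
#'
#' `ceiling(n / (1 - rate))`: with the study's 84 calculated pairs and a 25%
#' dropout rate, 112 cases.
#'
#' @param n Required analysable sample size.
#' @param rate Anticipated dropout fraction in `[0, 1)`.
#' @return Integer design sample size.
#' @export
#' @examples
#' dropout_inflation(84, 0.25)  # 112
dropout_inflation <- function(n, rate) {
  stopifnot(n >= 0, is.finite(rate))
  if (rate < 0 || rate >= 1) stop("dropout rate must be in [0, 1)")
  as.integer(ceiling(n / (1 - rate)))
}
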