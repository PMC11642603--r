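#' Congruency effect and its directional context comparison
#'
#' For every subject and social context, the congruency effect is the mean
#' distortion in incongruent trials minus the mean distortion in congruent
#' trials.  The directional hypothesis -- interference is larger when acting
#' in parallel than jointly -- is tested with a one-tailed paired t-test of
#' the Joint minus Parallel effects against zero (alternative: negative,
#' i.e. Parallel larger).
#'
#' @param records Pooled distortion table with columns `subject`, `context`,
#'   `congruency`, and the value column.
#' @param value Name of the distortion column (default the Box-Cox scale).
#' @return A list with `effects` (subject x context effect table, wide) and
#'   `test` (a `stat_result` from [one_sample_t()] on the paired
#'   differences).
#' @export
congruency_effect <- function(records, value = "area_boxcox") {
  stopifnot(all(c("subject", "context", "congruency", value) %in%
                  names(records)))
  agg <- aggregate(records[[value]],
                   by = list(subject = records$subject,
                             context = records$context,
                             congruency = records$congruency), FUN = mean)
  wide <- merge(agg[agg$congruency == "incongruent", c("subject", "context",
                                                       "x")],
                agg[agg$congruency == "congruent", c("subject", "context",
                                                     "x")],
                by = c("subject", "context"),
                suffixes = c("_incongruent", "_congruent"))
  if (nrow(wide) < nrow(unique(agg[, c("subject", "context")]))) {
    warning("subjects with a missing congruency cell were dropped")
  }
  wide$effect <- wide$x_incongruent - wide$x_congruent
  eff <- merge(wide[wide$context == "joint", c("subject", "effect")],
               wide[wide$context == "parallel", c("subject", "effect")],
               by = "subject", suffixes = c("_joint", "_parallel"))
  if (nrow(eff) < 2)
    stop("need at least two subjects with both contexts for the paired test")
  test <- one_sample_t(eff$effect_joint - eff$effect_parallel, 0,
                       alternative = "less")
  list(effects = eff, test = test)
}

#' Linear mixed model for trajectory distortion
#'
#' Fits, by REML, `value ~ context * congruency + (1 | subject)` with sum
#' contrast coding (-1, 1) for both factors, and reports per-coefficient
#' estimates, Wald 95% confidence intervals, t statistics, Satterthwaite
#' degrees of freedom and p-values.  Extra fixed effects (for example a
#' centred drawing-time covariate or a task-order factor) can be added via
#' `extra`.
#'
#' @param records Distortion table with `subject`, `context`, `congruency`
#'   and the value column.
#' @param value Response column name.
#' @param extra Optional character vector of additional fixed-effect terms;
#'   each interacts with the context-by-congruency design
#'   (`context * congruency * extra`).
#' @return A list with `coefficients` (data.frame: `term`, `beta`,
#'   `ci_lower`, `ci_upper`, `t`, `df`, `p`), `converged` flag, and the
#'   fitted `model`.
#' @export
fit_vmi_lmm <- function(records, value = "area_boxcox", extra = NULL) {
  df <- as.data.frame(records)
  df$context <- factor(df$context)
  df$congruency <- factor(df$congruency)
  df$subject <- factor(df$subject)
  contrasts(df$context) <- contr.sum(2)
  contrasts(df$congruency) <- contr.sum(2)
  fixed <- paste(c("context * congruency", extra), collapse = " * ")
  form <- as.formula(paste(value, "~", fixed, "+ (1 | subject)"))
  fit <- lmerTest::lmer(form, data = df, REML = TRUE)
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || !any(grepl("failed to converge", msgs,
                                           ignore.case = TRUE))
  if (!converged)
    return(list(coefficients = NULL, converged = FALSE, model = fit,
                messages = msgs))
  cf <- summary(fit)$coefficients
  if (!"df" %in% colnames(cf) && ncol(cf) < 5)
    stop("Satterthwaite degrees of freedom unavailable; refusing to ",
         "substitute residual df")
  se <- cf[, "Std. Error"]
  out <- data.frame(term = rownames(cf), beta = cf[, "Estimate"],
                    ci_lower = cf[, "Estimate"] - 1.96 * se,
                    ci_upper = cf[, "Estimate"] + 1.96 * se,
                    t = cf[, "t value"], df = cf[, "df"],
                    p = cf[, "Pr(>|t|)"], row.names = NULL)
  list(coefficients = out, converged = TRUE, model = fit)
}

#' Poisson GLM on per-cell error counts
#'
#' Tests whether screening removed more trials in any design cell: fits
#' `count ~ context * congruency` with a Poisson family and sum contrast
#' coding and reports Wald z statistics and p-values.  A diagnostic flag
#' marks unstable fits (separation-like patterns with huge standard
#' errors).
#'
#' @param counts Data frame with columns `subject`, `context`, `congruency`,
#'   `count` (nonnegative integers).
#' @return A list with `coefficients` (`term`, `beta`, `se`, `z`, `p`) and
#'   `unstable` flag.
#' @export
fit_count_glm <- function(counts) {
  stopifnot(all(c("context", "congruency", "count") %in% names(counts)))
  if (any(counts$count < 0) || any(counts$count %% 1 != 0))
    stop("counts must be nonnegative integers")
  if (all(counts$count == 0))
    stop("all counts are zero; the Poisson model is degenerate")
  df <- as.data.frame(counts)
  df$context <- factor(df$context)
  df$congruency <- factor(df$congruency)
  contrasts(df$context) <- contr.sum(2)
  contrasts(df$congruency) <- contr.sum(2)
  fit <- glm(count ~ context * congruency, data = df, family = poisson())
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf), beta = cf[, 1], se = cf[, 2],
                    z = cf[, 3], p = cf[, 4], row.names = NULL)
  list(coefficients = out, unstable = any(cf[, 2] > 10) || !fit$converged)
}
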