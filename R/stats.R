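#' Assemble a per-second sample table for condition-level inference
#'
#' Joins 1-Hz metric series to the labelled timeline, keeping only retained
#' low/high-arousal seconds.
#'
#' @param timeline labelled timeline from [label_timeline()]
#' @param metrics named list of data.frames, each with `time_s` and a value
#'   column (`value`, `log_power`, or the only non-time column)
#' @return long data.frame (`participant`, `movement`, `arousal`, `time_s`,
#'   `metric`, `value`)
#' @export
collect_samples <- function(timeline, metrics) {
  keep <- !timeline$excluded & timeline$label %in% c("low", "high")
  tl <- timeline[keep, , drop = FALSE]
  out <- lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    vcol <- setdiff(names(m), "time_s")[1]
    i <- match(tl$time_s, m$time_s)
    data.frame(participant = tl$participant, movement = tl$movement,
               arousal = as.character(tl$label), time_s = tl$time_s,
               metric = nm, value = m[[vcol]][i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[!is.na(out$value), , drop = FALSE]
}

#' Linear mixed model for a condition-level metric
#'
#' Fits `value ~ arousal * movement` with the same full structure as random
#' slopes within participants, by REML. Type-3 F tests use Satterthwaite
#' denominator degrees of freedom; estimated marginal means with 95% CIs and
#' Tukey-corrected pairwise arousal contrasts within each movement level are
#' computed from the fitted model. If the full random structure fails to
#' converge or is singular, the random part is simplified progressively
#' (interaction slope, movement slope, arousal slope, intercept-only) and the
#' fallback path recorded.
#'
#' @param table long data.frame with columns `participant`, `movement`,
#'   `arousal`, `value` (e.g. one metric from [collect_samples()])
#' @param log_transform natural-log the response first (values must be
#'   positive)
#' @param allow_singular accept a singular fit rather than simplifying; the
#'   flag is still reported
#' @return object of class `arousal_lmm`: `model`, `anova` (type-3 F table),
#'   `emmeans`, `contrasts`, `random_formula`, `fallback`, `singular`,
#'   `log_transform`
#' @export
fit_arousal_lmm <- function(table, log_transform = FALSE,
                            allow_singular = TRUE) {
  d <- table
  stopifnot(all(c("participant", "movement", "arousal", "value") %in%
                  names(d)))
  if (log_transform) {
    if (any(d$value <= 0)) stop("log transform requires positive values")
    d$value <- log(d$value)
  }
  d$arousal <- factor(d$arousal, levels = c("low", "high"))
  d$movement <- factor(d$movement)
  d$participant <- factor(d$participant)
  if (length(unique(d$arousal)) < 2) stop("need both arousal levels")
  two_mov <- nlevels(d$movement) >= 2
  if (stats::sd(d$value) == 0) {
    # degenerate response: every effect is exactly zero, a mixed fit would
    # divide 0 by 0 — report the trivial result instead
    ctr <- unique(d[, "movement", drop = FALSE])
    ctr <- data.frame(contrast = "low - high",
                      movement = if (two_mov) ctr$movement else NULL,
                      estimate = 0, SE = 0, df = NA_real_, t.ratio = 0,
                      p.value = 1)
    an <- data.frame(NumDF = 1, DenDF = NA_real_, `F value` = 0,
                     `Pr(>F)` = 1,
                     term = if (two_mov)
                       c("arousal", "movement", "arousal:movement")
                     else "arousal", check.names = FALSE)
    return(structure(list(model = NULL, anova = an, emmeans = NULL,
                          contrasts = ctr,
      random_formula = NA_character_, fallback = character(0),
      singular = TRUE, degenerate = TRUE, log_transform = log_transform),
      class = "arousal_lmm"))
  }
  fixed <- if (two_mov) "value ~ arousal * movement" else "value ~ arousal"
  rand_terms <- if (two_mov) {
    c("(1 + arousal * movement | participant)",
      "(1 + arousal + movement | participant)",
      "(1 + arousal | participant)",
      "(1 | participant)")
  } else {
    c("(1 + arousal | participant)", "(1 | participant)")
  }
  fallback <- character(0)
  fit <- NULL
  for (rt in rand_terms) {
    f <- stats::as.formula(paste(fixed, "+", rt))
    m <- suppressMessages(suppressWarnings(
      try(lmerTest::lmer(f, data = d, REML = TRUE,
                         control = lme4::lmerControl(
                           check.conv.singular = "ignore",
                           calc.derivs = FALSE)),
          silent = TRUE)))
    if (inherits(m, "try-error")) {
      fallback <- c(fallback, paste("error with", rt))
      next
    }
    sing <- lme4::isSingular(m)
    if (sing && !allow_singular && rt != rand_terms[length(rand_terms)]) {
      fallback <- c(fallback, paste("singular with", rt))
      next
    }
    fit <- m
    singular <- sing
    random_formula <- rt
    break
  }
  if (is.null(fit)) stop("no mixed model converged; fallback path: ",
                         paste(fallback, collapse = "; "))
  an <- as.data.frame(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  an$term <- rownames(an)
  spec <- if (two_mov) ~ arousal | movement else ~ arousal
  # emmeans falls back to asymptotic df above its lmerTest.limit; the note it
  # prints about that is not actionable here
  emm <- suppressMessages(emmeans::emmeans(fit, spec,
                                           lmer.df = "satterthwaite"))
  emm_df <- as.data.frame(emm)
  ctr <- as.data.frame(suppressMessages(
    emmeans::contrast(emm, method = "pairwise", adjust = "tukey")))
  structure(list(model = fit, anova = an, emmeans = emm_df, contrasts = ctr,
                 random_formula = random_formula, fallback = fallback,
                 singular = singular, log_transform = log_transform),
            class = "arousal_lmm")
}

#' @export
print.arousal_lmm <- function(x, ...) {
  cat("Arousal x movement linear mixed model",
      if (x$log_transform) "(log response)", "\n")
  cat("  random structure:", x$random_formula,
      if (x$singular) "[singular fit]", "\n")
  if (length(x$fallback)) cat("  fallback path:",
                              paste(x$fallback, collapse = "; "), "\n")
  cat("  Type-3 F tests (Satterthwaite):\n")
  for (i in seq_len(nrow(x$anova)))
    cat(sprintf("    %s: F(%.0f, %.1f) = %.2f, p = %.4g\n",
                x$anova$term[i], x$anova$NumDF[i], x$anova$DenDF[i],
                x$anova$`F value`[i], x$anova$`Pr(>F)`[i]))
  cat("  Pairwise arousal contrasts (Tukey):\n")
  print(x$contrasts, digits = 3)
  invisible(x)
}

#' @export
summary.arousal_lmm <- function(object, ...) {
  list(anova = object$anova, emmeans = object$emmeans,
       contrasts = object$contrasts, random_formula = object$random_formula,
       singular = object$singular)
}

#' Electrode-wise paired t tests, movement conditions pooled
#'
#' Per participant and electrode the metric is first averaged over the
#' movement conditions; a two-tailed paired t test (high vs low arousal) is
#' then run per electrode, with Benjamini-Yekutieli FDR correction across
#' electrodes.
#'
#' @param table long data.frame with columns `participant`, `electrode`,
#'   `movement`, `arousal`, `value` (per-cell means or per-second samples;
#'   they are averaged per cell first)
#' @return data.frame (`electrode`, `mean_diff`, `t`, `df`, `p`, `p_fdr`) in
#'   the electrode order of the input
#' @export
electrode_wise_paired_t <- function(table) {
  electrodes <- unique(table$electrode)
  cell <- stats::aggregate(value ~ participant + electrode + arousal,
                           data = stats::aggregate(
                             value ~ participant + electrode + movement +
                               arousal, data = table, FUN = mean),
                           FUN = mean)  # average over movement second
  res <- lapply(electrodes, function(el) {
    w <- cell[cell$electrode == el, ]
    hi <- w[w$arousal == "high", ]
    lo <- w[w$arousal == "low", ]
    common <- intersect(hi$participant, lo$participant)
    if (length(common) < 3) stop("fewer than 3 participants with both ",
                                 "conditions at electrode ", el)
    d <- hi$value[match(common, hi$participant)] -
      lo$value[match(common, lo$participant)]
    n <- length(d)
    s <- stats::sd(d)
    tv <- if (s == 0) 0 else mean(d) / (s / sqrt(n))
    p <- if (s == 0) 1 else 2 * stats::pt(-abs(tv), df = n - 1)
    data.frame(electrode = el, mean_diff = mean(d), t = tv, df = n - 1,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BY")
  out
}

#' Classical two-tailed paired t test
#'
#' @param x,y paired condition vectors of equal length
#' @return list with `t`, `df`, `p`, `mean_diff`, `degenerate` (TRUE when the
#'   differences have zero variance; then `p = 1` and `t = 0` only if the
#'   mean difference is also zero)
#' @export
descriptive_paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = if (mean(d) == 0) 0 else NA_real_, df = n - 1, p = 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tv <- mean(d) / (s / sqrt(n))
  list(t = tv, df = n - 1, p = 2 * stats::pt(-abs(tv), df = n - 1),
       mean_diff = mean(d), degenerate = FALSE)
}
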