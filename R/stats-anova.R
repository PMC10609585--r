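#' Balanced two-way factorial ANOVA with generalized omega-squared
#'
#' Sums of squares are computed by the balanced cell-mean decomposition
#' (for a balanced design Type I/II/III coincide); F ratios use the
#' within-cell mean square, and effect sizes are generalized partial
#' omega-squared for the both-factors-manipulated case,
#' `(SS_eff - df_eff * MS_err) / (SS_total + MS_err)`,
#' with plain partial omega-squared and eta-squared reported alongside.
#' Residual normality (Shapiro-Wilk) and variance homogeneity (Levene) are
#' checked and annotated; failures warn but never abort the ANOVA.
#'
#' @name factorial_stats
NULL

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] that reports a constant
#' (zero-variance) vector as inapplicable instead of erroring.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return List with `W`, `p`, and `degenerate` (TRUE when the statistic
#'   is undefined).
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0)
    return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, degenerate = FALSE)
}

#' Levene's test for homogeneity of variances
#'
#' Classic form: one-way ANOVA on absolute deviations from the group mean
#' (median-centering available via `center`), computed directly from the
#' between/within decomposition of the deviations.
#'
#' @param values numeric response vector.
#' @param groups grouping vector (>= 2 groups, each n >= 2).
#' @param center `"mean"` (classic) or `"median"` (Brown-Forsythe).
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("Levene's test needs >= 2 groups with >= 2 values each")
  cfun <- if (center == "mean") mean else stats::median
  centers <- tapply(values, groups, cfun)
  z <- abs(values - centers[groups])
  zbar_g <- tapply(z, groups, mean)
  zbar <- mean(z)
  k <- length(sizes)
  n_tot <- length(z)
  ssb <- sum(as.numeric(sizes) * (zbar_g - zbar)^2)
  ssw <- sum((z - zbar_g[groups])^2)
  df1 <- k - 1
  df2 <- n_tot - k
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Assemble a balanced 2x2 factorial dataset
#'
#' @param y numeric response values.
#' @param a,b factors (two levels each), same length as `y`.
#' @param response_name label used in report tables.
#' @return A `factorial_dataset` data frame.
#' @export
factorial_dataset <- function(y, a, b, response_name = "response") {
  a <- as.factor(a); b <- as.factor(b)
  if (nlevels(a) != 2 || nlevels(b) != 2)
    stop("both factors must have exactly two levels")
  if (any(!is.finite(y)))
    stop("all response values must be finite")
  counts <- table(a, b)
  if (length(unique(as.vector(counts))) != 1 || any(counts < 2))
    stop("design must be balanced with >= 2 replicates per cell")
  structure(data.frame(y = y, a = a, b = b),
            response_name = response_name,
            class = c("factorial_dataset", "data.frame"))
}

#' Two-way ANOVA on a balanced 2x2 dataset
#'
#' @param data a [factorial_dataset()].
#' @param alpha significance level for the `significant` flag.
#' @param omega_threshold generalized omega-squared above which an effect
#'   is flagged as large.
#' @return An `anova_report`: `$effects` data frame (one row per effect
#'   with SS, df, MS, F, p, effect sizes and flags), `$error` list,
#'   `$ss_total`, and `$assumptions` (Shapiro-Wilk on residuals, Levene
#'   across the four cells).
#' @export
two_way_anova <- function(data, alpha = 0.05, omega_threshold = 0.70) {
  stopifnot(inherits(data, "factorial_dataset"))
  y <- data$y; a <- data$a; b <- data$b
  n <- length(y)
  r <- n / 4
  gm <- mean(y)
  cell <- tapply(y, list(a, b), mean)
  am <- rowMeans(cell); bm <- colMeans(cell)
  ss_a <- 2 * r * sum((am - gm)^2)
  ss_b <- 2 * r * sum((bm - gm)^2)
  ss_ab <- r * sum((sweep(sweep(cell, 1, am), 2, bm) + gm)^2)
  fitted <- cell[cbind(a, b)]
  resid <- y - fitted
  ss_err <- sum(resid^2)
  ss_tot <- sum((y - gm)^2)
  df_err <- n - 4
  ms_err <- ss_err / df_err

  eff <- data.frame(
    effect = c("A", "B", "A:B"),
    term = c(levels(a)[2], levels(b)[2], "interaction"),
    ss = c(ss_a, ss_b, ss_ab), df = 1,
    stringsAsFactors = FALSE
  )
  eff$ms <- eff$ss / eff$df
  if (ms_err > 0) {
    eff$F <- eff$ms / ms_err
    eff$p <- stats::pf(eff$F, eff$df, df_err, lower.tail = FALSE)
    eff$omega_g <- (eff$ss - eff$df * ms_err) / (ss_tot + ms_err)
    eff$omega_partial <- (eff$ss - eff$df * ms_err) /
      (eff$ss + (n - eff$df) * ms_err)
  } else {
    # zero within-cell variance: F degenerates; nonzero effects are exact
    eff$F <- ifelse(eff$ss > 0, Inf, 0)
    eff$p <- ifelse(eff$ss > 0, 0, 1)
    eff$omega_g <- NA_real_
    eff$omega_partial <- NA_real_
  }
  eff$eta_sq <- eff$ss / ss_tot
  eff$omega_g_display <- pmax(eff$omega_g, 0)
  eff$significant <- eff$p < alpha
  eff$large_effect <- !is.na(eff$omega_g) & eff$omega_g > omega_threshold

  assumptions <- list(
    shapiro = if (stats::sd(resid) > 0) shapiro_wilk(resid)
              else list(W = NA_real_, p = NA_real_, degenerate = TRUE),
    levene = if (ms_err > 0)
      levene_test(y, interaction(a, b, drop = TRUE))
    else list(F = NA_real_, p = NA_real_, df1 = NA, df2 = NA)
  )
  for (nm in c("shapiro", "levene")) {
    p <- assumptions[[nm]]$p
    if (!is.na(p) && p < alpha)
      warning(sprintf("%s assumption check p = %.3g (< %.2g); report annotated",
                      nm, p, alpha), call. = FALSE)
  }
  structure(
    list(effects = eff,
         error = list(ss = ss_err, df = df_err, ms = ms_err),
         ss_total = ss_tot,
         alpha = alpha, omega_threshold = omega_threshold,
         response_name = attr(data, "response_name"),
         assumptions = assumptions),
    class = "anova_report"
  )
}

#' Effects table across responses
#'
#' One row per response, with p and generalized omega-squared per effect
#' (factor A, factor B, interaction). Effect sizes are suppressed (NA)
#' where the effect is not significant, mirroring the convention of
#' reporting omega-squared only for significant terms.
#'
#' @param reports named list of `anova_report` objects (names are response
#'   labels; unnamed lists fall back to each report's `response_name`).
#' @param factor_names length-2 character, labels for the two factors.
#' @return Data frame with p, effect-size and flag columns per effect.
#' @export
build_effects_table <- function(reports, factor_names = c("A", "B")) {
  if (length(reports) == 0)
    return(data.frame(response = character(0)))
  nms <- names(reports)
  if (is.null(nms))
    nms <- vapply(reports, function(r) r$response_name, character(1))
  rows <- Map(function(rep, nm) {
    e <- rep$effects
    shown <- ifelse(e$significant, e$omega_g_display, NA_real_)
    out <- data.frame(response = nm, stringsAsFactors = FALSE)
    labs <- c(factor_names[1], factor_names[2],
              paste0(factor_names[1], "x", factor_names[2]))
    for (j in 1:3) {
      out[[paste0("p_", labs[j])]] <- e$p[j]
      out[[paste0("omega_", labs[j])]] <- shown[j]
      out[[paste0("sig_", labs[j])]] <- e$significant[j]
      out[[paste0("large_", labs[j])]] <- e$large_effect[j]
    }
    out
  }, reports, nms)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
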