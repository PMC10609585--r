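# Shared helpers for building small synthetic inputs in code.

# Noise model with every stochastic term switched off (exact expectations).
noiseless_model <- function(...) {
  observation_noise_model(dpm_blank_mean = 0, dpm_noise_cv = 0,
                          counting_noise = FALSE, ...)
}

# Truths with zero biovolume spread (needed for exact round trips).
zero_cv_truths <- function(truths) {
  lapply(truths, function(p) { p$cv_cell_volume <- 0; p })
}

# A random balanced 2x2 factorial dataset with r replicates per cell.
random_factorial <- function(r = 3, effect_a = 0, effect_b = 0,
                             effect_ab = 0, sd = 1) {
  a <- factor(rep(rep(c("lo", "hi"), each = r), 2), c("lo", "hi"))
  b <- factor(rep(c("lo", "hi"), each = 2 * r), c("lo", "hi"))
  y <- stats::rnorm(4 * r, sd = sd) +
    effect_a * (a == "hi") + effect_b * (b == "hi") +
    effect_ab * (a == "hi") * (b == "hi")
  factorial_dataset(y, a, b)
}

# Independent projection oracle: SS/F/p for a balanced 2x2 via stats::lm
# with sum contrasts and sequential ANOVA (orthogonal when balanced).
lm_anova_oracle <- function(data) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(y ~ a * b, data = data)
  tab <- stats::anova(fit)
  list(ss = tab$`Sum Sq`[1:3], f = tab$`F value`[1:3],
       p = tab$`Pr(>F)`[1:3], ss_err = tab$`Sum Sq`[4])
}
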