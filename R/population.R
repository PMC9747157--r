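#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' Standard one-way factorial ANOVA across groups of condition magnitudes
#' (e.g. per-condition sums of facilitation area over the eight targets,
#' grouped by current-intensity band or stimulus site), followed by
#' Tukey-Kramer honest significant differences, which handle unequal group
#' sizes.
#'
#' @param values Numeric vector of magnitudes.
#' @param groups Factor (or coercible) of group labels, `>= 2` levels with
#'   `n >= 2` each.
#' @return List `F`, `df`, `p_value`, `pairwise` (data frame `comparison`,
#'   `diff`, `lwr`, `upr`, `p_adj`).
#' @export
one_way_anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], row.names = NULL)
  list(F = an$`F value`[1], df = unname(an$Df),
       p_value = an$`Pr(>F)`[1], pairwise = pairwise)
}

#' Two-sided unpaired t-test
#'
#' Pooled-variance Student t by default; `welch = TRUE` drops the
#' equal-variance assumption.
#'
#' @param a,b Numeric samples, each `n >= 2`.
#' @param welch Use the Welch correction (default `FALSE`).
#' @return List `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
unpaired_t_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per sample")
  ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Sum of effect areas over the eight peripheral targets
#'
#' The population-level magnitude of one muscular condition: the sum of
#' the given effect type's first-PStE areas across the eight target
#' locations.
#'
#' @param per_target Data frame with columns `effect_type` and
#'   `area_uv_ms`, one row per target (as from [classify_output_type()]).
#' @param effect_type `"Facilitation"` or `"Suppression"`.
#' @return Scalar sum (uV·ms).
#' @export
condition_magnitude <- function(per_target, effect_type) {
  sum(per_target$area_uv_ms[per_target$effect_type == effect_type])
}
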