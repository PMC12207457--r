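#' Welch's unequal-variance t test
#'
#' The two-sample t test without the equal-variance assumption, the
#' appropriate comparison given the strong heteroskedasticity between
#' treatment conditions: the statistic uses per-sample variances and the
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param sample_a,sample_b Numeric vectors (each of length >= 2; at least
#'   one with nonzero variance).
#' @param alternative `"two.sided"`, `"greater"` (mean of `sample_a`
#'   exceeds mean of `sample_b`) or `"less"`.
#' @return A one-row tibble: test_name, contrast, statistic, df, p_value,
#'   alternative.
#' @examples
#' welch_t(rnorm(20, 1), rnorm(20, 0), alternative = "greater")
#' @export
welch_t <- function(sample_a, sample_b,
                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    abort("each sample needs at least 2 observations.")
  }
  if (var(sample_a) == 0 && var(sample_b) == 0) {
    abort("both samples are constant; the Welch statistic is undefined.")
  }
  fit <- t.test(sample_a, sample_b, alternative = alternative,
                var.equal = FALSE)
  tibble(
    test_name = "welch_t",
    contrast = "sample_a - sample_b",
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    alternative = alternative
  )
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact inference by hypergeometric enumeration, used for the success-rate
#' and profile-share comparisons between treatment cells. Two-sided by
#' default (the sum of probabilities of all tables with the observed
#' margins no more probable than the observed one); one-sided alternatives
#' are available.
#'
#' @param contingency A 2x2 matrix of non-negative integer counts with
#'   positive margins.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A one-row tibble: test_name, contrast, statistic (the
#'   conditional-MLE odds ratio), df (NA), p_value, alternative.
#' @export
fisher_exact <- function(contingency,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- as.matrix(contingency)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m))) {
    abort("`contingency` must be a 2x2 table of non-negative integer counts.")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("every row and column margin must be positive.")
  }
  fit <- fisher.test(m, alternative = alternative)
  tibble(
    test_name = "fisher_exact",
    contrast = "2x2 table",
    statistic = unname(fit$estimate),
    df = NA_real_,
    p_value = fit$p.value,
    alternative = alternative
  )
}

#' Two-way factorial ANOVA with interaction
#'
#' The 2x2 factorial comparison (delegation x number of choices) on a group
#' or individual metric, with the interaction term. Cells may be unbalanced;
#' sums of squares are Type II by default (each main effect adjusted for
#' the other, the interaction adjusted for both), with Type III available
#' via `ss_type`.
#'
#' @param data A data frame holding the response and the two factors.
#' @param response,factor_a,factor_b Column names (strings) of the numeric
#'   response and the two crossed factors.
#' @param ss_type 2 (default) or 3.
#' @return A tibble with one row per term (factor_a, factor_b, interaction):
#'   test_name, contrast, statistic (F), df, df_residual, p_value.
#' @examples
#' gm <- group_metrics(generate_study(study_design(n_groups = 5)))
#' anova_two_way(gm, "final_public_account",
#'               "treatment_delegation", "treatment_choices")
#' @export
anova_two_way <- function(data, response, factor_a, factor_b, ss_type = 2) {
  stopifnot(ss_type %in% c(2, 3))
  for (col in c(response, factor_a, factor_b)) {
    if (!col %in% names(data)) abort(sprintf("column `%s` not found.", col))
  }
  df <- data.frame(
    y = as.numeric(data[[response]]),
    a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]])
  )
  if (any(table(df$a, df$b) == 0)) {
    abort("every cell of the 2-factor design must be nonempty.")
  }
  contr <- if (ss_type == 3) {
    list(a = "contr.sum", b = "contr.sum")
  } else {
    list(a = "contr.treatment", b = "contr.treatment")
  }
  fit <- lm(y ~ a * b, data = df, contrasts = contr)
  tab <- car::Anova(fit, type = ss_type)
  terms <- rownames(tab)
  keep <- terms %in% c("a", "b", "a:b")
  pretty <- c(a = factor_a, b = factor_b,
              `a:b` = paste0(factor_a, ":", factor_b))
  tibble(
    test_name = "anova_two_way",
    contrast = unname(pretty[terms[keep]]),
    sum_sq = tab[keep, "Sum Sq"],
    df = tab[keep, "Df"],
    df_residual = tab["Residuals", "Df"],
    statistic = tab[keep, "F value"],
    p_value = tab[keep, "Pr(>F)"]
  )
}

#' Treatment-comparison battery for a study
#'
#' Runs the analysis layer's standard tests per game: the two-way ANOVA
#' (delegation x choices, with interaction) on final public accounts and on
#' private-account variances, the one-sided Welch t for
#' delegation > no-delegation public accounts within each choice condition,
#' and Fisher's exact test on success rates between delegation conditions
#' within each choice condition.
#'
#' @inheritParams group_metrics
#' @param ss_type Passed to [anova_two_way()].
#' @return A tibble of test results (one row per test and contrast), with
#'   columns game, test_name, contrast, statistic, df, p_value, alternative.
#' @export
study_tests <- function(study, ss_type = 2) {
  gm <- group_metrics(study)
  per_game <- lapply(c(1, 2), function(g) {
    d <- dplyr::filter(gm, .data$game == g)
    out <- list()
    out$anova_pa <- anova_two_way(
      d, "final_public_account", "treatment_delegation", "treatment_choices",
      ss_type = ss_type
    ) |> dplyr::mutate(response = "final_public_account")
    out$anova_var <- anova_two_way(
      d, "private_account_variance", "treatment_delegation",
      "treatment_choices", ss_type = ss_type
    ) |> dplyr::mutate(response = "private_account_variance")
    welch <- lapply(unique(d$treatment_choices), function(ch) {
      dd <- dplyr::filter(d, .data$treatment_choices == ch)
      welch_t(
        dd$final_public_account[dd$treatment_delegation],
        dd$final_public_account[!dd$treatment_delegation],
        alternative = "greater"
      ) |> dplyr::mutate(
        contrast = sprintf("delegation - no-delegation | %d choices", ch),
        response = "final_public_account"
      )
    })
    fisher <- lapply(unique(d$treatment_choices), function(ch) {
      dd <- dplyr::filter(d, .data$treatment_choices == ch)
      tab <- table(factor(dd$treatment_delegation, c(TRUE, FALSE)),
                   factor(dd$success, c(TRUE, FALSE)))
      fisher_exact(tab) |> dplyr::mutate(
        contrast = sprintf("success x delegation | %d choices", ch),
        response = "success"
      )
    })
    dplyr::bind_rows(c(out, welch, fisher)) |>
      dplyr::mutate(game = g, .before = 1)
  })
  dplyr::bind_rows(per_game)
}
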