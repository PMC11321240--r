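OUTCOME_COLUMNS <- c(agonist = "peak_agonist_norm",
                     antagonist = "peak_antagonist_norm",
                     velocity = "peak_angular_velocity",
                     reaction_time = "reaction_time_ms")

#' Build the analysis table for one outcome
#'
#' Restricts the tidy metrics table to pulled-phase trials of the five
#' non-passive conditions with a usable value of the requested outcome, and
#' returns the modeling columns: participant, condition (factor with control
#' as reference), numeric order position, and the outcome value.
#'
#' @param metrics tidy metrics data frame (see [compute_metrics()]).
#' @param outcome one of `"agonist"`, `"antagonist"`, `"velocity"`,
#'   `"reaction_time"`, or a column name in `metrics`.
#' @return data frame with columns `participant`, `condition`,
#'   `order_position`, `value`.
#' @export
outcome_table <- function(metrics, outcome) {
  col <- if (outcome %in% names(OUTCOME_COLUMNS)) {
    OUTCOME_COLUMNS[[outcome]]
  } else outcome
  if (!col %in% names(metrics)) {
    stop("metrics table has no column '", col, "'", call. = FALSE)
  }
  keep <- metrics$phase == "pulled" & metrics$condition != "passive" &
    is.finite(metrics[[col]])
  tab <- data.frame(
    participant = factor(metrics$participant[keep]),
    condition = factor(metrics$condition[keep],
                       levels = CONDITION_NAMES[1:5]),
    order_position = as.numeric(metrics$order_position[keep]),
    value = metrics[[col]][keep],
    stringsAsFactors = FALSE
  )
  if (any(is.na(tab$condition))) {
    stop("metrics table contains unknown condition labels", call. = FALSE)
  }
  if (nlevels(droplevels(tab$participant)) < 2L) {
    stop("need at least two participants to fit the mixed model",
         call. = FALSE)
  }
  tab
}

#' Fit the mixed model for one outcome
#'
#' Linear mixed model on trial-level data with fixed effects for condition
#' (categorical, control reference) and order (numeric 1-5 covariate) and a
#' participant random intercept, fit by maximum likelihood. The condition
#' main effect is tested with a likelihood-ratio test against the model
#' without condition (4 df). Singular fits (zero between-participant
#' variance) are kept at the boundary with a warning.
#'
#' @param table outcome table from [outcome_table()].
#' @return list of class `emd_fit` with elements `fit`, `null_fit`,
#'   `lrt_chi2`, `lrt_df`, `lrt_p`, `n_participants`, `singular`.
#' @export
fit_outcome_model <- function(table) {
  if (stats::var(table$value) == 0) {
    stop("outcome has zero variance; nothing to model", call. = FALSE)
  }
  drop_conds <- levels(table$condition)[!levels(table$condition) %in%
                                          unique(table$condition)]
  if (length(drop_conds) > 0L) {
    stop("conditions missing from the outcome table: ",
         paste(drop_conds, collapse = ", "), call. = FALSE)
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- lme4::lmer(value ~ condition + order_position + (1 | participant),
                    data = table, REML = FALSE, control = ctrl)
  null_fit <- lme4::lmer(value ~ order_position + (1 | participant),
                         data = table, REML = FALSE, control = ctrl)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular fit: between-participant variance estimated at zero",
            call. = FALSE)
  }
  lrt <- stats::anova(null_fit, fit)
  structure(list(
    fit = fit, null_fit = null_fit,
    lrt_chi2 = lrt$Chisq[2], lrt_df = lrt$Df[2],
    lrt_p = lrt$`Pr(>Chisq)`[2],
    n_participants = nlevels(droplevels(table$participant)),
    singular = singular
  ), class = "emd_fit")
}

#' All-pairwise condition contrasts with Holm adjustment
#'
#' Model-based contrasts between all 10 condition pairs, from the estimated
#' marginal means of the fitted mixed model. P-values use the asymptotic
#' z reference and are Holm-adjusted across the 10-test family. Percent
#' differences are `(EMM_A - EMM_B) / EMM_B * 100`.
#'
#' @param model `emd_fit` from [fit_outcome_model()].
#' @return data frame with one row per pair: `A`, `B`, `estimate` (EMM_A -
#'   EMM_B on the outcome scale), `SE`, `z`, `raw_p`, `holm_p`,
#'   `percent_difference`, plus attribute `"emmeans"` carrying the condition
#'   EMM table.
#' @export
pairwise_contrasts <- function(model) {
  em <- emmeans::emmeans(model$fit, "condition", lmer.df = "asymptotic")
  emdf <- as.data.frame(em)
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "none"))
  parts <- strsplit(as.character(ct$contrast), " - ", fixed = TRUE)
  A <- vapply(parts, `[`, "", 1L)
  B <- vapply(parts, `[`, "", 2L)
  emm <- stats::setNames(emdf$emmean, emdf$condition)
  out <- data.frame(
    A = A, B = B,
    estimate = ct$estimate, SE = ct$SE, z = ct$z.ratio,
    raw_p = ct$p.value,
    holm_p = stats::p.adjust(ct$p.value, method = "holm"),
    percent_difference = percent_difference(emm[A], emm[B]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "emmeans") <- emdf
  out
}

#' Percent difference between two estimated marginal means
#'
#' @param emm_a,emm_b estimated marginal means; `emm_b` (the reference) must
#'   be positive.
#' @return `(emm_a - emm_b) / emm_b * 100`.
#' @export
percent_difference <- function(emm_a, emm_b) {
  if (any(!is.finite(emm_b)) || any(emm_b <= 0)) {
    stop("reference marginal mean must be positive", call. = FALSE)
  }
  unname((emm_a - emm_b) / emm_b * 100)
}

#' Fit and contrast every outcome
#'
#' Runs [outcome_table()], [fit_outcome_model()] and [pairwise_contrasts()]
#' for each requested outcome.
#'
#' @param metrics tidy metrics data frame.
#' @param outcomes outcomes to analyse (default: all four).
#' @param alpha significance level recorded in the result (default 0.05).
#' @return named list of class `emd_results`; each element is a list with
#'   `outcome`, `lrt_chi2`, `lrt_df`, `lrt_p`, `n_participants`, `singular`,
#'   `emmeans`, `contrasts`.
#' @export
analyze_outcomes <- function(metrics, outcomes = names(OUTCOME_COLUMNS),
                             alpha = 0.05) {
  res <- lapply(outcomes, function(oc) {
    tab <- outcome_table(metrics, oc)
    model <- suppressWarnings(fit_outcome_model(tab))
    ct <- pairwise_contrasts(model)
    list(outcome = oc,
         lrt_chi2 = model$lrt_chi2, lrt_df = model$lrt_df,
         lrt_p = model$lrt_p, n_participants = model$n_participants,
         singular = model$singular,
         emmeans = attr(ct, "emmeans"),
         contrasts = ct,
         alpha = alpha)
  })
  names(res) <- outcomes
  class(res) <- "emd_results"
  res
}

#' Extract one pairwise comparison from a results object
#'
#' @param results `emd_results` from [analyze_outcomes()].
#' @param outcome outcome name.
#' @param a,b condition names; the comparison is a versus b (b is the
#'   reference for the percent difference).
#' @return one-row data frame with `estimate`, `SE`, `raw_p`, `holm_p`,
#'   `percent_difference`, oriented as a minus b.
#' @export
get_contrast <- function(results, outcome, a, b) {
  ct <- results[[outcome]]$contrasts
  i <- which(ct$A == a & ct$B == b)
  if (length(i) == 1L) return(ct[i, , drop = FALSE])
  i <- which(ct$A == b & ct$B == a)
  if (length(i) != 1L) {
    stop("no contrast between '", a, "' and '", b, "'", call. = FALSE)
  }
  emm <- attr(ct, "emmeans")
  flipped <- ct[i, , drop = FALSE]
  flipped$A <- a; flipped$B <- b
  flipped$estimate <- -flipped$estimate
  flipped$z <- -flipped$z
  flipped$percent_difference <- percent_difference(
    emm$emmean[emm$condition == a], emm$emmean[emm$condition == b])
  rownames(flipped) <- NULL
  flipped
}

#' @export
print.emd_results <- function(x, ...) {
  for (r in x) {
    cat(sprintf("Outcome: %s\n", r$outcome))
    cat(sprintf("  condition LRT: chi2(%d) = %.2f, p = %.4g (n = %d participants)%s\n",
                r$lrt_df, r$lrt_chi2, r$lrt_p, r$n_participants,
                if (r$singular) " [singular fit]" else ""))
    sig <- r$contrasts[r$contrasts$holm_p < r$alpha, , drop = FALSE]
    if (nrow(sig) > 0L) {
      for (j in seq_len(nrow(sig))) {
        cat(sprintf("  %s vs %s: %+.1f%% (Holm p = %.4g)\n",
                    sig$A[j], sig$B[j], sig$percent_difference[j],
                    sig$holm_p[j]))
      }
    } else {
      cat("  no Holm-significant pairwise contrasts\n")
    }
  }
  invisible(x)
}
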