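#' Split samples into high and low score groups
#'
#' Median split: samples strictly above the median score are `"high"`,
#' samples at or below it (including exactly at the median) are
#' `"low"`.
#'
#' @param scores Named numeric vector (at least 4 values).
#' @return Named character vector of `"high"`/`"low"` labels.
#' @export
dichotomize <- function(scores) {
  if (length(scores) < 4) abort("dichotomize needs at least 4 samples")
  if (length(unique(scores)) == 1) {
    abort("all scores identical; no high/low split possible")
  }
  med <- median(scores)
  setNames(ifelse(scores > med, "high", "low"), names(scores))
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator of the survival function within each group.
#'
#' @param times Nonnegative event/censoring times.
#' @param events 0/1 (or logical) event indicators.
#' @param group Group label per subject.
#' @return Tibble with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_estimate <- function(times, events, group = rep("all", length(times))) {
  events <- as.integer(events)
  if (any(table(group) == 0)) abort("empty group in km_estimate")
  fit <- survival::survfit(survival::Surv(times, events) ~ grp,
                           data = data.frame(grp = group))
  smry <- summary(fit, censored = TRUE)
  grp <- if (is.null(smry$strata)) rep(unique(group)[1], length(smry$time)) else
    sub("^grp=", "", as.character(smry$strata))
  tibble(group = grp, time = smry$time, n_risk = smry$n.risk,
         n_event = smry$n.event, survival = smry$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (hypergeometric expectation and variance
#' at each distinct event time), compared to chi-square with 1 df. With
#' no events P is 1 with a warning.
#'
#' @param times,events Survival data as in [km_estimate()].
#' @param group Two-level group label per subject.
#' @return List with `chi_square` and `p`.
#' @export
logrank_test <- function(times, events, group) {
  events <- as.integer(events)
  if (length(unique(group)) != 2) abort("log-rank test needs exactly 2 groups")
  if (sum(events) == 0) {
    warn("no events observed; log-rank P reported as 1")
    return(list(chi_square = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp,
                           data = data.frame(grp = group))
  chisq <- unname(sd$chisq)
  list(chi_square = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards estimate for a binary covariate
#'
#' Maximum partial-likelihood hazard ratio with Breslow tie handling
#' (Efron available) and a Wald 95 percent confidence interval. Under
#' complete separation the likelihood is monotone; the estimate is
#' reported capped with a warning.
#'
#' @param times,events Survival data.
#' @param covariate Two-level covariate (hazard ratio between groups),
#'   or a numeric vector with more than two distinct values, in which
#'   case the model is fit on the continuous covariate and `hr` is the
#'   hazard ratio per unit.
#' @param numerator Covariate level whose hazard goes in the numerator;
#'   defaults to the alphabetically first level, so `"high"`/`"low"`
#'   labels give the high-versus-low hazard ratio.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param cap Bound on |log HR| beyond which the fit is flagged as
#'   separated (default `log(1e6)`).
#' @return List with `hr`, `ci_low`, `ci_high`, `log_hr`, `se`, `p`
#'   (Wald), `separated`.
#' @export
cox_hr <- function(times, events, covariate, numerator = NULL,
                   ties = c("breslow", "efron"), cap = log(1e6)) {
  ties <- match.arg(ties)
  events <- as.integer(events)
  if (is.numeric(covariate) && length(unique(covariate)) > 2) {
    x <- covariate
  } else {
    lv <- sort(unique(as.character(covariate)))
    if (length(lv) != 2) abort("cox_hr needs a two-level covariate")
    numerator <- numerator %||% lv[1]
    if (!numerator %in% lv) abort("numerator must be a covariate level")
    x <- as.integer(as.character(covariate) == numerator)
  }
  if (sum(events) == 0) abort("cox_hr needs at least one event")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ x, ties = ties)
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  separated <- !is.finite(beta) || abs(beta) > cap
  if (separated) {
    warn("monotone partial likelihood (complete separation); HR capped")
    beta <- sign(beta) * cap
  }
  list(hr = exp(beta), ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se), log_hr = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)), separated = separated)
}

#' Survival association of every module
#'
#' For each module and endpoint (overall survival and progression-free
#' interval), tumor samples are split at the median score, compared by
#' log-rank test, and the hazard ratio of high versus low scores is
#' estimated by a Cox model on the binary indicator.
#'
#' @param scores A `module_scores` object (tumor samples).
#' @param clinical Clinical table as returned by [read_clinical()].
#' @param endpoints Subset of `c("OS", "PFI")`.
#' @param ties Cox tie handling.
#' @return A `survival_association` tibble: one row per module and
#'   endpoint with `hr`, `ci_low`, `ci_high`, `logrank_chisq`,
#'   `logrank_p`, `n_high`, `n_low`.
#' @export
module_survival <- function(scores, clinical, endpoints = c("OS", "PFI"),
                            ties = "breslow") {
  clinical <- validate_clinical(clinical)
  shared <- intersect(colnames(scores$scores), clinical$sample_id)
  if (length(shared) < 4) abort("fewer than 4 samples with both scores and clinical data")
  cl <- clinical[match(shared, clinical$sample_id), ]
  rows <- list()
  for (mod in rownames(scores$scores)) {
    sc <- scores$scores[mod, shared]
    grp <- tryCatch(dichotomize(sc), error = function(e) NULL)
    for (ep in endpoints) {
      tm <- if (ep == "OS") cl$os_time else cl$pfi_time
      ev <- if (ep == "OS") cl$os_event else cl$pfi_event
      if (is.null(grp) || sum(ev) == 0) {
        rows[[length(rows) + 1]] <- tibble(
          module = mod, endpoint = ep, hr = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, logrank_chisq = NA_real_, logrank_p = 1,
          n_high = NA_integer_, n_low = NA_integer_)
        next
      }
      lr <- logrank_test(tm, ev, grp)
      cx <- cox_hr(tm, ev, grp, ties = ties)
      rows[[length(rows) + 1]] <- tibble(
        module = mod, endpoint = ep, hr = cx$hr, ci_low = cx$ci_low,
        ci_high = cx$ci_high, logrank_chisq = lr$chi_square,
        logrank_p = lr$p,
        n_high = sum(grp == "high"), n_low = sum(grp == "low"))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("survival_association", class(out))
  out
}

#' Retain prognosis-related modules
#'
#' A module is retained when its log-rank P is at or below `alpha` for
#' overall survival or for progression-free interval; optionally,
#' modules with OS P strictly between `alpha` and `near_alpha` are also
#' kept as near-significant candidates. Reason codes: `both`, `OS`,
#' `PFI`, `near_OS`.
#'
#' @param assoc A `survival_association` with both endpoints per module,
#'   or any data frame with columns `module`, `endpoint`, `logrank_p`.
#' @param alpha Significance level (default 0.05, inclusive `<=`).
#' @param near_alpha Upper bound of the near-significant OS window
#'   (default 0.1, exclusive).
#' @param include_near Whether to keep near-significant OS modules
#'   (default TRUE).
#' @return Tibble `module`, `os_p`, `pfi_p`, `reason`, `retained`,
#'   one row per module.
#' @export
retain_prognostic <- function(assoc, alpha = 0.05, near_alpha = 0.1,
                              include_near = TRUE) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(assoc), "module", "endpoint", "logrank_p"),
    names_from = "endpoint", values_from = "logrank_p")
  os <- wide$OS %||% rep(NA_real_, nrow(wide))
  pfi <- wide$PFI %||% rep(NA_real_, nrow(wide))
  sig_os <- !is.na(os) & os <= alpha
  sig_pfi <- !is.na(pfi) & pfi <= alpha
  near_os <- include_near & !is.na(os) & os > alpha & os < near_alpha
  reason <- dplyr::case_when(
    sig_os & sig_pfi ~ "both",
    sig_os ~ "OS",
    sig_pfi ~ "PFI",
    near_os ~ "near_OS",
    TRUE ~ NA_character_
  )
  tibble(module = wide$module, os_p = os, pfi_p = pfi,
         reason = reason, retained = !is.na(reason))
}

#' @export
glance.survival_association <- function(x, ...) {
  ret <- retain_prognostic(x)
  tibble(n_modules = length(unique(x$module)),
         n_os_significant = sum(ret$reason %in% c("OS", "both")),
         n_pfi_significant = sum(ret$reason %in% c("PFI", "both")),
         n_both = sum(ret$reason == "both", na.rm = TRUE),
         n_retained = sum(ret$retained))
}

#' Kaplan-Meier plot for one module's high/low groups
#'
#' @param scores A `module_scores`.
#' @param clinical Clinical table.
#' @param module Module name.
#' @param endpoint `"OS"` or `"PFI"`.
#' @return A ggplot object with one step curve per score group.
#' @export
plot_km <- function(scores, clinical, module, endpoint = c("OS", "PFI")) {
  endpoint <- match.arg(endpoint)
  clinical <- validate_clinical(clinical)
  shared <- intersect(colnames(scores$scores), clinical$sample_id)
  cl <- clinical[match(shared, clinical$sample_id), ]
  grp <- dichotomize(scores$scores[module, shared])
  tm <- if (endpoint == "OS") cl$os_time else cl$pfi_time
  ev <- if (endpoint == "OS") cl$os_event else cl$pfi_event
  km <- km_estimate(tm, ev, grp)
  km0 <- dplyr::bind_rows(
    tibble(group = unique(km$group), time = 0,
           n_risk = NA_integer_, n_event = NA_integer_, survival = 1), km)
  ggplot2::ggplot(km0, ggplot2::aes(.data$time, .data$survival,
                                    color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_color_manual(values = c(high = "red", low = "blue")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = paste0(module, " (", endpoint, ")"),
                  x = "days", y = "survival fraction") +
    ggplot2::theme_minimal()
}
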