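#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}
#' over distinct event times, with events preceding censorings at tied
#' times (the standard convention). The median is the smallest time at
#' which `S(t) <= 0.5`, and `NA` when the curve never reaches 0.5.
#' Estimation is delegated to [survival::survfit()].
#'
#' @param times non-negative follow-up times (days).
#' @param events event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return list with `time` (distinct event times), `nRisk`, `nEvent`,
#'   `surv` (S at each event time) and `median`.
#' @export
kmEstimate <- function(times, events) {
    if (length(times) == 0)
        stop("empty survival input")
    stopifnot(length(times) == length(events), all(times >= 0))
    events <- coerceBinary(events)
    fit <- survival::survfit(
        survival::Surv(times, events) ~ 1, conf.type = "none")
    keep <- fit$n.event > 0
    surv <- fit$surv[keep]
    time <- fit$time[keep]
    med <- if (any(surv <= 0.5 + 1e-12)) min(time[surv <= 0.5 + 1e-12])
           else NA_real_
    list(time = time, nRisk = fit$n.risk[keep], nEvent = fit$n.event[keep],
         surv = surv, median = med)
}

#' Two-group log-rank test
#'
#' Standard (rho = 0) log-rank chi-square comparing the survival
#' distributions of two groups, with the hypergeometric variance at each
#' distinct event time; p-value from the upper tail of the chi-square
#' distribution with 1 degree of freedom. Delegated to
#' [survival::survdiff()].
#'
#' @param times,events as in [kmEstimate()].
#' @param group two-level grouping (factor, character or logical), one per
#'   sample.
#' @return list with `chi_square`, `p_value`, `groups` (the two labels
#'   compared).
#' @export
logrankTest <- function(times, events, group) {
    events <- coerceBinary(events)
    group <- as.factor(as.character(group))
    if (nlevels(group) != 2)
        stop("exactly two non-empty groups are required")
    if (sum(events) == 0)
        stop("no events in either group; log-rank test undefined")
    sd <- survival::survdiff(survival::Surv(times, events) ~ group)
    chi <- unname(sd$chisq)
    list(chi_square = chi,
         p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
         groups = levels(group))
}

#' Pairwise log-rank comparisons and per-group median survival
#'
#' Runs [logrankTest()] for every pair of groups present (groups with zero
#' samples are skipped with a message) and reports each group's
#' Kaplan-Meier median. P-values are reported raw, without
#' multiple-testing adjustment.
#'
#' @param ann `data.frame` with columns `os_days`, `os_event` and `group`
#'   (e.g. from [assignmentTable()] merged with clinical data).
#' @return list with `medians` (`data.frame`: group, n, median) and
#'   `tests` (`data.frame`: group1, group2, chi_square, p_value).
#' @export
pairwiseSurvival <- function(ann) {
    stopifnot(all(c("os_days", "os_event", "group") %in% colnames(ann)))
    grp <- as.character(ann$group)
    lev <- unique(grp)
    present <- lev[vapply(lev, function(g) sum(grp == g) > 0, logical(1))]
    if (length(present) < 2)
        stop("at least two non-empty groups are required")
    med <- do.call(rbind, lapply(present, function(g) {
        sel <- grp == g
        km <- kmEstimate(ann$os_days[sel], ann$os_event[sel])
        data.frame(group = g, n = sum(sel), median = km$median,
                   stringsAsFactors = FALSE)
    }))
    pairs <- utils::combn(present, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        g1 <- pairs[1, j]; g2 <- pairs[2, j]
        sel <- grp %in% c(g1, g2)
        lr <- logrankTest(ann$os_days[sel], ann$os_event[sel], grp[sel])
        data.frame(group1 = g1, group2 = g2, chi_square = lr$chi_square,
                   p_value = lr$p_value, stringsAsFactors = FALSE)
    }))
    list(medians = med, tests = tests)
}
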