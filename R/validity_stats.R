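# Construct-validity statistics: pairwise linear associations (with and
# without covariate adjustment) and Bland-Altman agreement of device vs
# stopwatch durations.

#' Linear association between two measures
#'
#' Ordinary least-squares fit of `outcome ~ predictor` (optionally plus
#' covariates), on complete cases only, returning the predictor's slope and
#' two-sided p-value. Collinear covariates make the design rank-deficient
#' and raise an error rather than silently dropping terms.
#'
#' @param outcome,predictor numeric vectors.
#' @param covariates optional data frame of covariates (same length).
#' @param min_n minimum number of complete cases.
#' @return list with `beta`, `p`, `n`.
#' @export
linear_assoc <- function(outcome, predictor, covariates = NULL, min_n = 10) {
  d <- data.frame(.y = outcome, .x = predictor)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < min_n)
    stop(sprintf("too few complete cases: %d < %d", nrow(d), min_n),
         call. = FALSE)
  fit <- stats::lm(.y ~ ., data = d)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient fit: collinear covariates", call. = FALSE)
  cf <- summary(fit)$coefficients
  list(beta = unname(cf[".x", "Estimate"]),
       p = unname(cf[".x", "Pr(>|t|)"]),
       n = nrow(d))
}

#' All pairwise association families of the construct-validity analysis
#'
#' Computes the three families of linear associations: (i) between domains
#' of the conceptual model, (ii) between domains and health-related
#' measures, and (iii) between health-related measures; each either
#' unadjusted or adjusted for the standard covariate set (Age, Gender,
#' Height, Weight, MMSE, number of medications). Significance is flagged at
#' p <= 0.05 with no multiplicity correction, replicating the reporting
#' convention of the source analyses (a known limitation).
#'
#' @param domains data frame or matrix of factor scores (subjects x
#'   domains).
#' @param cohort a [generate_cohort_table()]-style data frame aligned with
#'   `domains` by row.
#' @param adjusted adjust for the covariates?
#' @param covariate_names columns of `cohort` used as covariates.
#' @param health_names health-related measure columns; defaults to all
#'   non-covariate, non-id numeric columns.
#' @return data frame of class `association_table`: `predictor`, `outcome`,
#'   `family`, `beta`, `p`, `n`, `adjusted`, `significant`.
#' @export
association_matrix <- function(domains, cohort, adjusted = FALSE,
                               covariate_names = c("Age", "Gender", "Height",
                                                   "Weight", "MMSE", "NM"),
                               health_names = NULL) {
  domains <- as.data.frame(domains)
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0 || nrow(domains) == 0)
    stop("empty cohort or domain table", call. = FALSE)
  if (nrow(cohort) != nrow(domains))
    stop("domains and cohort must describe the same subjects", call. = FALSE)
  if (adjusted && !all(covariate_names %in% names(cohort)))
    stop("cohort is missing covariates: ",
         paste(setdiff(covariate_names, names(cohort)), collapse = ", "),
         call. = FALSE)
  if (is.null(health_names)) {
    num <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    health_names <- setdiff(num, c(covariate_names, "subject"))
  }
  covs <- if (adjusted) cohort[, covariate_names, drop = FALSE] else NULL
  rows <- list()
  add <- function(pred_name, pred, out_name, out, family) {
    res <- linear_assoc(out, pred, covs)
    rows[[length(rows) + 1]] <<- data.frame(
      predictor = pred_name, outcome = out_name, family = family,
      beta = res$beta, p = res$p, n = res$n, adjusted = adjusted,
      significant = res$p <= 0.05)
  }
  dn <- names(domains)
  if (length(dn) > 1)
    for (i in seq_len(length(dn) - 1)) for (j in (i + 1):length(dn))
      add(dn[i], domains[[i]], dn[j], domains[[j]], "domain-domain")
  for (d in dn) for (h in health_names)
    add(d, domains[[d]], h, cohort[[h]], "domain-health")
  if (length(health_names) > 1)
    for (i in seq_len(length(health_names) - 1))
      for (j in (i + 1):length(health_names))
        add(health_names[i], cohort[[health_names[i]]],
            health_names[j], cohort[[health_names[j]]], "health-health")
  out <- do.call(rbind, rows)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Bland-Altman agreement between two duration measurements
#'
#' Differences `d = device - reference`; bias is their mean and the limits
#' of agreement are `bias +/- 1.96 SD(d)`.
#'
#' @param device,reference paired duration measurements in seconds.
#' @return list of class `bland_altman`: `bias`, `sd`, `lower`, `upper`,
#'   `n`.
#' @examples
#' ba <- bland_altman(c(7.1, 7.4, 6.9), c(7.0, 7.2, 7.0))
#' c(ba$lower, ba$upper)
#' @export
bland_altman <- function(device, reference) {
  if (length(device) != length(reference))
    stop("paired series must have equal length", call. = FALSE)
  keep <- stats::complete.cases(device, reference)
  d <- device[keep] - reference[keep]
  if (length(d) < 2) stop("need at least 2 pairs", call. = FALSE)
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 lower = bias - 1.96 * s, upper = bias + 1.96 * s,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f s, limits [%.3f, %.3f] s (n = %d)\n",
              x$bias, x$lower, x$upper, x$n))
  invisible(x)
}
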