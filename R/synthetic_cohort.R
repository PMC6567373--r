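# Synthetic cohort of health-related measures with marginals matching the
# published demographic/functional profile of the total study population.

cohort_defaults <- function() {
  list(
    # continuous: mean, sd
    Age = c(80.90, 6.37), Weight = c(69.60, 13.30), Height = c(159.72, 9.53),
    HAND = c(26.98, 9.26), PWR = c(88.69, 51.28), TMTA = c(78.37, 43.94),
    GaitSpeed = c(1.11, 0.26),
    # bounded integer scales: mean, sd, min, max
    MMSE = c(27.25, 1.77, 0, 30), PA = c(2.91, 1.01, 1, 7),
    SPPB = c(8.72, 3.18, 0, 12),
    # CES-D matched to P(>= 16) = 35%
    CESD = c(12.5, 9, 0, 60),
    # counts: Poisson rates matched to printed exceedance fractions
    NM = 4.0,            # P(NM >= 4) ~ 56%
    IADL = 0.478,        # P(IADL >= 1) = 38%
    FALL = 0.355,        # P(FALL >= 2) = 5%
    FALL_history = 0.394, # P(>= 2) = 6%
    p_female = 0.54
  )
}

#' Simulate a cohort table of health-related measures
#'
#' Generates subjects x health-related measures with marginal distributions
#' matching the published total-population profile: continuous measures are
#' Gaussian with the printed mean/SD; bounded integer scales (MMSE, PA,
#' SPPB, CES-D) are Gaussian draws rounded and clamped to their printed
#' ranges; count variables (number of medications, IADL dependencies, falls)
#' are Poisson with rates matched to the printed exceedance percentages;
#' Gender is Bernoulli (1 = female). Columns are independent unless a
#' linear dependence is planted.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param overrides named list replacing entries of the default parameter
#'   set (same shapes as the defaults).
#' @param planted optional named list of planted linear dependencies, each
#'   `list(on = <column or columns>, beta = <coefficients>, sd = <noise SD>)`;
#'   the named column is regenerated as the linear combination plus Gaussian
#'   noise (used to verify that the association stage recovers a known
#'   coefficient).
#' @return A data frame of class `cohort_table` with columns `subject`,
#'   `Age`, `Gender`, `Weight`, `Height`, `MMSE`, `NM`, `IADL`, `FALL`,
#'   `FALL_history`, `CESD`, `PA`, `SPPB`, `HAND`, `PWR`, `TMTA`,
#'   `GaitSpeed`.
#' @examples
#' ch <- generate_cohort_table(50, seed = 1)
#' summary(ch$SPPB)
#' @export
generate_cohort_table <- function(n, seed = NULL, overrides = list(),
                                  planted = NULL) {
  if (n < 1) stop("cohort must have at least one subject", call. = FALSE)
  par <- utils::modifyList(cohort_defaults(), overrides)
  with_seed(seed, {
    gauss <- function(p) stats::rnorm(n, p[1], p[2])
    scale_col <- function(p)
      pmin(pmax(round(stats::rnorm(n, p[1], p[2])), p[3]), p[4])
    d <- data.frame(
      subject = sprintf("S%04d", seq_len(n)),
      Age = gauss(par$Age),
      Gender = stats::rbinom(n, 1, par$p_female),
      Weight = gauss(par$Weight),
      Height = gauss(par$Height),
      MMSE = scale_col(par$MMSE),
      NM = stats::rpois(n, par$NM),
      IADL = stats::rpois(n, par$IADL),
      FALL = stats::rpois(n, par$FALL),
      FALL_history = stats::rpois(n, par$FALL_history),
      CESD = scale_col(par$CESD),
      PA = scale_col(par$PA),
      SPPB = scale_col(par$SPPB),
      HAND = gauss(par$HAND),
      PWR = gauss(par$PWR),
      TMTA = gauss(par$TMTA),
      GaitSpeed = gauss(par$GaitSpeed)
    )
    if (!is.null(planted)) {
      for (col in names(planted)) {
        pl <- planted[[col]]
        Z <- as.matrix(d[, pl$on, drop = FALSE])
        sd <- if (is.null(pl$sd)) 1 else pl$sd
        d[[col]] <- drop(Z %*% pl$beta) + stats::rnorm(n, sd = sd)
      }
    }
    class(d) <- c("cohort_table", "data.frame")
    d
  })
}
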