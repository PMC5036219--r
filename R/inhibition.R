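# Serpin inhibition arithmetic: stoichiometry of inhibition (SI) from
# a linear titration, and correction of the apparent association rate
# constant. Serpins are suicide substrates: a fraction of encounters
# partitions to the cleaved-substrate pathway, so more than one mole
# of serpin may be needed per mole of protease (SI > 1), and the true
# association rate is k_ass = SI * k_ass_app.

#' Construct an SI titration
#'
#' @param ratio Serpin:protease molar ratios (>= 0); must include 0.
#' @param residual_activity Fraction of uninhibited protease activity,
#'   expected in \[0, 1.1\].
#' @return An `si_titration` object.
#' @export
si_titration <- function(ratio, residual_activity) {
  if (length(ratio) != length(residual_activity))
    .stop2("ratio/activity length mismatch")
  if (length(ratio) < 4L) .stop2("titrations need >= 4 points")
  if (any(ratio < 0)) .stop2("ratios must be >= 0")
  if (min(ratio) > 0) .stop2("titration must include ratio 0")
  if (any(residual_activity < -0.05 | residual_activity > 1.15))
    .stop2("residual activity outside [0, 1.1]")
  o <- order(ratio)
  structure(list(ratio = ratio[o], residual_activity = residual_activity[o]),
            class = "si_titration")
}

#' Read an SI titration from CSV (columns ratio, residual_activity)
#'
#' @param path CSV path.
#' @return An `si_titration`.
#' @export
read_titration_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ratio", "residual_activity") %in% names(d)))
    .stop2("CSV must have columns ratio, residual_activity")
  si_titration(d$ratio, d$residual_activity)
}

#' Stoichiometry of inhibition from a titration
#'
#' Ordinary least squares on the linear descending region (points with
#' residual activity above `plateau_cutoff`, which excludes the
#' post-equivalence plateau); the SI is the extrapolated x-intercept,
#' with a delta-method standard error.
#'
#' @param titration An `si_titration`.
#' @param plateau_cutoff Activity below which points are excluded from
#'   the regression (default 0.1).
#' @return A list: `SI`, `se`, `slope`, `intercept`, `n_points_used`.
#' @export
stoichiometry <- function(titration, plateau_cutoff = 0.1) {
  r <- titration$ratio
  a <- titration$residual_activity
  use <- a > plateau_cutoff
  if (sum(use) < 3L) .stop2("fewer than 3 points in the linear region")
  if (min(a) >= 0.5)
    .stop2("titration never reaches < 0.5 residual activity; ",
           "cannot locate the equivalence point")
  fit <- stats::lm(a[use] ~ r[use])
  b <- unname(stats::coef(fit))
  if (b[2L] >= 0)
    .stop2("activity does not decrease with serpin:protease ratio")
  SI <- -b[1L] / b[2L]
  V <- suppressWarnings(stats::vcov(fit))   # noiseless data fits exactly
  g <- c(-1 / b[2L], b[1L] / b[2L]^2)
  se <- sqrt(drop(t(g) %*% V %*% g))
  list(SI = SI, se = se, slope = b[2L], intercept = b[1L],
       n_points_used = sum(use))
}

#' Correct an apparent association rate constant for the SI
#'
#' The suicide-substrate partitioning means only 1/SI of association
#' events register as inhibition, so the true association rate is
#' `k_ass = SI * k_ass_app`.
#'
#' @param k_ass_app Apparent association rate constant (M^-1 s^-1),
#'   > 0.
#' @param SI Stoichiometry of inhibition; values below 1 are
#'   sub-stoichiometric and draw a warning.
#' @return `SI * k_ass_app` (M^-1 s^-1).
#' @examples
#' correct_rate(7.5e6, 1.8)  # 1.35e7, i.e. 1.4e7 to 2 s.f.
#' @export
correct_rate <- function(k_ass_app, SI) {
  if (k_ass_app <= 0) .stop2("k_ass_app must be > 0")
  if (SI < 1)
    warning("SI < 1 is sub-stoichiometric (unphysical for a suicide ",
            "substrate); returning SI * k_ass_app regardless",
            call. = FALSE)
  SI * k_ass_app
}
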