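#' Percent displacement of radioligand binding
#'
#' Fraction of specific radioligand binding displaced by a competitor:
#' `100 * (total - compound) / (total - nonspecific)`. Values are never
#' clipped; a competitor that (by noise) binds above the total control
#' yields a negative percentage.
#'
#' @param bound_compound counts bound in the presence of the competitor.
#' @param bound_total counts bound with radioligand alone.
#' @param bound_nonspecific counts bound at saturating cold ligand.
#' @return percent displacement (vectorized over `bound_compound`).
#' @export
percent_displacement <- function(bound_compound, bound_total,
                                 bound_nonspecific) {
  if (bound_total <= bound_nonspecific) {
    stop("total binding must exceed nonspecific binding")
  }
  100 * (bound_total - bound_compound) / (bound_total - bound_nonspecific)
}

#' Four-parameter logistic fit of a displacement curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (c / ic50)^hill)` by
#' Levenberg-Marquardt, parameterizing the IC50 on the log10 scale and
#' multi-starting the IC50 across the sampled concentration range. The Hill
#' slope is bounded (default `[0.3, 5]`) to stabilize sparse curves.
#'
#' @param concentrations positive competitor concentrations (>= 5 values
#'   spanning the transition).
#' @param response measured responses (percent of specific binding).
#' @param hill_bounds (lower, upper) bounds on the Hill slope.
#' @param n_starts number of IC50 starting values (log-spaced across the
#'   concentration range).
#' @return list with `top`, `bottom`, `ic50`, `hill`, `rss`, `converged`,
#'   `fitted`, `n_starts_tried`.
#' @export
fit_4pl <- function(concentrations, response, hill_bounds = c(0.3, 5),
                    n_starts = 8L) {
  stopifnot(length(concentrations) == length(response),
            all(concentrations > 0), all(is.finite(response)))
  if (length(concentrations) < 5) {
    stop("need at least 5 concentrations spanning the transition")
  }
  if (diff(range(response)) < 1e-8 * max(1, abs(mean(response)))) {
    stop("flat response: degenerate curve, no IC50")
  }
  lc <- log10(concentrations)
  df <- data.frame(lc = lc, y = response)
  starts <- seq(min(lc), max(lc), length.out = n_starts)
  top0 <- max(response)
  bot0 <- min(response)
  best <- NULL
  tried <- 0L
  for (p0 in starts) {
    tried <- tried + 1L
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - lic50))),
        data = df,
        start = list(top = top0, bottom = bot0, lic50 = p0, hill = 1),
        lower = c(top = -Inf, bottom = -Inf, lic50 = min(lc) - 3,
                  hill = hill_bounds[1]),
        upper = c(top = Inf, bottom = Inf, lic50 = max(lc) + 3,
                  hill = hill_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                   ic50 = unname(10^cf["lic50"]), hill = unname(cf["hill"]),
                   rss = rss, converged = fit$convInfo$isConv,
                   fitted = unname(stats::fitted(fit)))
    }
  }
  if (is.null(best)) stop("4PL fit failed to converge from any start")
  if (best$top <= best$bottom) {
    # relabel plateaus so top > bottom always holds in the report
    tmp <- best$top; best$top <- best$bottom; best$bottom <- tmp
    best$hill <- -best$hill
  }
  best$n_starts_tried <- tried
  best
}

#' Cheng-Prusoff inhibition constant
#'
#' Converts a competition IC50 to the inhibition constant
#' `Ki = IC50 / (1 + L / Kd)`, where `L` is the radioligand concentration
#' and `Kd` its dissociation constant. Defaults match the assay conditions
#' of the competition experiments: 1.5 nM radiolabelled dexamethasone, with
#' its Kd taken equal to 1.5 nM (an overridable assumption, the only value
#' consistent with every printed IC50/Ki pair).
#'
#' @param ic50 fitted IC50 (any concentration unit; Ki is returned in the
#'   same unit).
#' @param radioligand_conc radioligand concentration L, same unit.
#' @param radioligand_kd radioligand dissociation constant Kd, same unit.
#' @return Ki in the unit of `ic50` (vectorized over `ic50`).
#' @export
cheng_prusoff_ki <- function(ic50, radioligand_conc = 1.5,
                             radioligand_kd = 1.5) {
  stopifnot(all(ic50 > 0), radioligand_conc > 0, radioligand_kd > 0)
  ic50 / (1 + radioligand_conc / radioligand_kd)
}

#' Round to significant figures, halves away from zero
#'
#' Reporting convention for binding constants: `signif()` rounds halves to
#' even (3.65 -> 3.6), whereas assay tables round halves up (3.65 -> 3.7).
#'
#' @param x numeric vector.
#' @param digits significant figures.
#' @return rounded vector.
#' @export
signif_half_up <- function(x, digits = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  m <- floor(log10(abs(x[nz])))
  f <- 10^(digits - 1 - m)
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) * f + 0.5 + 1e-9) / f
  out
}
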