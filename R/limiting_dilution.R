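#' Limiting-dilution assay table
#'
#' One dose-response table of a limiting-dilution transplantation: cell
#' dose per mouse, number of mice tested, number of tumor-positive mice.
#'
#' @param dose Cells injected per mouse (one value per row, > 0).
#' @param tested Number of mice tested at each dose.
#' @param positive Number of tumor-positive mice at each dose.
#' @param group Optional group label (e.g. culture condition).
#' @return Data frame of class \code{"lda_table"}.
#' @export
lda_table <- function(dose, tested, positive, group = NA_character_) {
  stopifnot(length(dose) == length(tested), length(tested) == length(positive),
            length(dose) >= 1, all(dose > 0), all(tested >= 1),
            all(positive >= 0), all(positive <= tested))
  structure(data.frame(dose = as.numeric(dose), tested = as.integer(tested),
                       positive = as.integer(positive),
                       group = as.character(group), stringsAsFactors = FALSE),
            class = c("lda_table", "data.frame"))
}

single_hit_loglik <- function(log_theta, table) {
  theta <- exp(log_theta)
  p <- -expm1(-theta * table$dose)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  sum(table$positive * log(p) + (table$tested - table$positive) * log1p(-p))
}

#' Single-hit Poisson maximum-likelihood fit of TIC frequency
#'
#' Fits the single-hit Poisson dose-response model
#' \eqn{P(\mathrm{tumor} \mid d) = 1 - e^{-\theta d}} by maximum
#' likelihood, where \eqn{\theta} is the per-cell tumor-initiating-cell
#' rate; the TIC frequency is reported as "1 in \eqn{1/\theta}" cells
#' (rounded half away from zero, matching the conventional printed form).
#' Optimization is on \eqn{\log\theta}; the 95% confidence interval comes
#' from the observed information on \eqn{\log\theta} (the complementary
#' log-log scale used by standard limiting-dilution tools).
#'
#' @param table An [lda_table()].
#' @return Object of class \code{"lda_fit"} with elements \code{theta},
#'   \code{log_theta}, \code{frequency_denominator}, \code{ci95}
#'   (denominator scale), \code{se_log_theta}, \code{loglik},
#'   \code{boundary} and \code{table}.
#' @examples
#' fit <- fit_single_hit(lda_table(c(1e4, 1e3, 1e2, 10, 1),
#'                                 rep(4, 5), c(4, 4, 3, 2, 0)))
#' fit$frequency_denominator  # 47
#' @export
fit_single_hit <- function(table) {
  stopifnot(inherits(table, "lda_table"))
  if (all(table$positive == 0)) {
    warning("no positive mouse at any dose: TIC frequency unbounded (infinite denominator)")
    return(structure(list(theta = 0, log_theta = -Inf,
                          frequency_denominator = Inf,
                          ci95 = c(NA_real_, Inf), se_log_theta = NA_real_,
                          loglik = 0, boundary = "all-negative",
                          table = table), class = "lda_fit"))
  }
  boundary <- "none"
  if (all(table$positive == table$tested)) {
    warning("every mouse positive at every dose: estimate at the optimization boundary")
    boundary <- "all-positive"
  }
  # bracket generous enough for doses spanning 1 to 1e7 cells
  opt <- stats::optimize(single_hit_loglik, interval = c(-30, 10),
                         table = table, maximum = TRUE, tol = 1e-10)
  lt <- opt$maximum
  theta <- exp(lt)
  h <- 1e-4                             # numerical observed information
  d2 <- (single_hit_loglik(lt + h, table) - 2 * opt$objective +
           single_hit_loglik(lt - h, table)) / h^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  ci_den <- if (is.na(se)) c(NA_real_, NA_real_) else
    sort(exp(-(lt + c(1, -1) * stats::qnorm(0.975) * se)))
  structure(list(theta = theta, log_theta = lt,
                 frequency_denominator = round_half_up(1 / theta),
                 ci95 = ci_den, se_log_theta = se,
                 loglik = opt$objective, boundary = boundary, table = table),
            class = "lda_fit")
}

#' @export
print.lda_fit <- function(x, ...) {
  if (is.infinite(x$frequency_denominator)) {
    cat("TIC frequency: below detection (no positive mice)\n")
    return(invisible(x))
  }
  cat(sprintf("TIC frequency: 1 in %s cells (95%% CI 1 in %s - 1 in %s)\n",
              format(x$frequency_denominator, big.mark = ","),
              format(round_half_up(x$ci95[1]), big.mark = ","),
              format(round_half_up(x$ci95[2]), big.mark = ",")))
  if (x$boundary != "none") cat("boundary fit:", x$boundary, "\n")
  invisible(x)
}

#' @export
summary.lda_fit <- function(object, ...) {
  print(object)
  cat(sprintf("theta = %.4g per cell, log-likelihood = %.4f\n",
              object$theta, object$loglik))
  pred <- predict(object)
  tab <- cbind(object$table[, c("dose", "tested", "positive")],
               expected = round(pred * object$table$tested, 2))
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @export
coef.lda_fit <- function(object, ...) {
  c(theta = object$theta, log_theta = object$log_theta)
}

#' @export
logLik.lda_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, class = "logLik")
}

#' @export
confint.lda_fit <- function(object, parm = "denominator", level = 0.95, ...) {
  if (is.na(object$se_log_theta)) return(c(NA_real_, NA_real_))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci_lt <- object$log_theta + c(-1, 1) * zq * object$se_log_theta
  switch(match.arg(parm, c("denominator", "theta", "log_theta")),
         denominator = sort(exp(-ci_lt)),
         theta = exp(ci_lt),
         log_theta = ci_lt)
}

#' @export
predict.lda_fit <- function(object, newdose = NULL, ...) {
  d <- if (is.null(newdose)) object$table$dose else newdose
  -expm1(-object$theta * d)
}

#' Likelihood-ratio comparison of two limiting-dilution groups
#'
#' Tests equality of the per-cell TIC rate between two dose-response
#' tables: twice the log-likelihood gain of separate rates over a common
#' rate, referred to a 1-df chi-square.
#'
#' @param a,b Two [lda_table()] objects.
#' @return Object of class \code{"lda_comparison"} with \code{statistic},
#'   \code{p_value}, and the three fits.
#' @export
compare_groups <- function(a, b) {
  stopifnot(inherits(a, "lda_table"), inherits(b, "lda_table"))
  fit_a <- fit_single_hit(a)
  fit_b <- fit_single_hit(b)
  pooled <- lda_table(c(a$dose, b$dose), c(a$tested, b$tested),
                      c(a$positive, b$positive), group = "pooled")
  fit_common <- fit_single_hit(pooled)
  boundary <- fit_a$boundary != "none" || fit_b$boundary != "none"
  stat <- max(0, 2 * (fit_a$loglik + fit_b$loglik - fit_common$loglik))
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
                 fit_a = fit_a, fit_b = fit_b, fit_common = fit_common,
                 boundary = boundary),
            class = "lda_comparison")
}

#' @export
print.lda_comparison <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test of equal TIC frequency: chi2(1) = %.4g, p = %.4g\n",
              x$statistic, x$p_value))
  if (x$boundary) cat("note: at least one group fit is at a boundary; p computed on the profile\n")
  invisible(x)
}
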