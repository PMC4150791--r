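# Downstream quantifications: XXC substrate-panel sequence-preference
# profiles, fluctuation (rifampin) mutation frequencies, and steady-state
# Michaelis-Menten kinetics.

XXC_SYMBOLS <- c("A", "mC", "G", "T")

#' Construct / validate an XXC substrate panel
#'
#' The panel assays a single target cytosine in each of the 16 `XXC`
#' sequence contexts, where the -2 and -1 neighbors `X` are A,
#' 5-methylcytosine (`mC`, a less reactive surrogate for C), G or T.
#'
#' @param panel data.frame with columns `x2`, `x1` (symbols in
#'   `A, mC, G, T`) and `product_fraction` (in `[0, 1]`); all 16 `(x2, x1)`
#'   pairs exactly once.
#' @return The validated data.frame, class `substrate_panel`.
#' @export
substrate_panel <- function(panel) {
  need <- c("x2", "x1", "product_fraction")
  if (!all(need %in% names(panel)))
    stop("panel needs columns ", paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(c(panel$x2, panel$x1), XXC_SYMBOLS)
  if (length(bad))
    stop("unknown context symbol(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  expected <- expand.grid(x2 = XXC_SYMBOLS, x1 = XXC_SYMBOLS,
                          stringsAsFactors = FALSE)
  have <- paste(panel$x2, panel$x1)
  missing <- setdiff(paste(expected$x2, expected$x1), have)
  if (length(missing))
    stop("missing context(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(have))
    stop("duplicated context(s): ",
         paste(unique(have[duplicated(have)]), collapse = ", "),
         call. = FALSE)
  if (any(panel$product_fraction < 0 | panel$product_fraction > 1))
    stop("product_fraction must lie in [0, 1]", call. = FALSE)
  structure(panel, class = c("substrate_panel", "data.frame"))
}

#' Sequence-preference profile from an XXC substrate panel
#'
#' Product formation is averaged across the four substrates sharing the
#' same nucleotide at the -1 (or -2) position; the averages are then
#' normalized to relative reactivities summing to 1 per position.
#'
#' @param panel A [substrate_panel] (or a data.frame accepted by it).
#' @return Object of class `preference_profile`: list with `minus1` and
#'   `minus2`, each a named numeric vector over `A, mC, G, T` summing
#'   to 1.
#' @export
preference_profile <- function(panel) {
  panel <- substrate_panel(panel)
  prof <- function(by) {
    m <- tapply(panel$product_fraction, factor(by, levels = XXC_SYMBOLS),
                mean)
    if (sum(m) == 0)
      stop("no product formation anywhere in the panel", call. = FALSE)
    stats::setNames(as.numeric(m / sum(m)), XXC_SYMBOLS)
  }
  structure(list(minus1 = prof(panel$x1), minus2 = prof(panel$x2)),
            class = "preference_profile")
}

#' @export
print.preference_profile <- function(x, ...) {
  cat("Sequence preference (relative reactivity):\n")
  cat("  -2:", paste(sprintf("%s %.3f", names(x$minus2), x$minus2),
                     collapse = "  "), "\n")
  cat("  -1:", paste(sprintf("%s %.3f", names(x$minus1), x$minus1),
                     collapse = "  "), "\n")
  invisible(x)
}

#' Fluctuation-assay mutation frequencies
#'
#' Per-culture mutation frequency = rifampin-resistant colonies / viable
#' cells, with mean and sample standard deviation across independent
#' cultures.
#'
#' @param resistant Integer vector of resistant colony counts (>= 0).
#' @param viable Integer vector of viable cell counts (> 0), recycled.
#' @param label Optional experiment label.
#' @return Object of class `fluctuation_result`: list with `frequency`
#'   (per culture), `mean`, `sd`, `n`, `label`.
#' @export
mutation_frequency <- function(resistant, viable, label = NULL) {
  if (!length(resistant)) stop("need >= 1 culture", call. = FALSE)
  if (any(resistant < 0)) stop("resistant counts must be >= 0", call. = FALSE)
  if (any(viable <= 0)) stop("viable cells must be > 0", call. = FALSE)
  freq <- resistant / viable
  structure(list(frequency = freq, mean = mean(freq),
                 sd = if (length(freq) > 1L) stats::sd(freq) else NA_real_,
                 n = length(freq), label = label),
            class = "fluctuation_result")
}

#' @export
print.fluctuation_result <- function(x, ...) {
  cat(sprintf("Mutation frequency%s: mean %.3g +/- %.3g (n = %d)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Compare two mutator strains
#'
#' Fold change of mean mutation frequencies plus a two-sided Welch t-test
#' on `log10(frequency + floor)` (mutation frequencies are approximately
#' log-normal across cultures).  When either group is all-zero the test
#' falls back to a Wilcoxon rank-sum test on the raw frequencies, with a
#' warning.
#'
#' @param a,b `fluctuation_result` objects (>= 3 cultures each).
#' @param floor Additive floor before taking logs (default 1e-9).
#' @return List with `fold_change` (`mean(a) / mean(b)`), `p_value`,
#'   `test`.
#' @export
compare_mutators <- function(a, b, floor = 1e-9) {
  stopifnot(inherits(a, "fluctuation_result"),
            inherits(b, "fluctuation_result"))
  if (a$n < 3L || b$n < 3L)
    stop("need >= 3 cultures per group", call. = FALSE)
  fold <- a$mean / b$mean
  if (all(a$frequency == 0) || all(b$frequency == 0)) {
    warning("all-zero group: falling back to rank test", call. = FALSE)
    p <- stats::wilcox.test(a$frequency, b$frequency, exact = FALSE)$p.value
    test <- "wilcoxon"
  } else if (stats::var(a$frequency) == 0 && stats::var(b$frequency) == 0) {
    # degenerate: no within-group variance, the test reduces to equality
    p <- if (a$mean == b$mean) 1 else 0
    test <- "degenerate"
  } else {
    p <- stats::t.test(log10(a$frequency + floor),
                       log10(b$frequency + floor))$p.value
    test <- "welch_log10"
  }
  list(fold_change = fold, p_value = p, test = test)
}

#' Fit the Michaelis-Menten equation
#'
#' Least-squares fit of `v = Vmax * S / (Km + S)` by Levenberg-Marquardt
#' damping, with starting values `Vmax0 = max(rate)` and `Km0 =` the
#' concentration nearest half-maximal rate.  Standard errors come from the
#' Jacobian at the optimum.
#'
#' @param conc Substrate concentrations (>= 3 distinct values).
#' @param rate Observed rates, same length.
#' @return Object of class `mm_fit`: list with `Vmax`, `Km`, `se`
#'   (named), `rss`, `fitted`, `residuals`, `data`, and the underlying
#'   `nls` object in `fit`.
#' @export
fit_michaelis_menten <- function(conc, rate) {
  if (length(conc) != length(rate))
    stop("conc and rate must have equal length", call. = FALSE)
  if (length(unique(conc)) < 3L)
    stop("need >= 3 distinct substrate concentrations", call. = FALSE)
  if (any(conc < 0) || any(rate < 0))
    stop("concentrations and rates must be non-negative", call. = FALSE)
  if (diff(range(rate)) == 0)
    stop("rates are all equal; kinetics unidentifiable", call. = FALSE)
  vmax0 <- max(rate)
  km0 <- conc[which.min(abs(rate - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(conc[conc > 0])
  df <- data.frame(S = conc, v = rate)
  fit <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df,
                           start = list(Vmax = vmax0, Km = km0),
                           lower = c(Vmax = 1e-12, Km = 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(c(NA, NA),
                                                     c("Vmax", "Km")))
  structure(list(Vmax = unname(est["Vmax"]), Km = unname(est["Km"]),
                 se = se, rss = sum(stats::resid(fit)^2),
                 fitted = stats::fitted(fit),
                 residuals = stats::resid(fit),
                 data = df, fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Vmax = %.4g (SE %.2g), Km = %.4g (SE %.2g), RSS = %.3g\n",
              x$Vmax, x$se["Vmax"], x$Km, x$se["Km"], x$rss))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(Vmax = object$Vmax, Km = object$Km)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S else
    if (is.data.frame(newdata)) newdata$S else newdata
  object$Vmax * S / (object$Km + S)
}

#' @export
residuals.mm_fit <- function(object, ...) object$residuals

#' @export
plot.mm_fit <- function(x, ...) {
  S_grid <- seq(0, max(x$data$S) * 1.1, length.out = 200)
  plot(x$data$S, x$data$v, xlab = "[S]", ylab = "rate",
       main = "Michaelis-Menten fit", ...)
  graphics::lines(S_grid, predict(x, S_grid))
  graphics::abline(h = x$Vmax, lty = 2)
  invisible(x)
}
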