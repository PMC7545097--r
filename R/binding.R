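#' Dose-response binding curve
#'
#' Container for an ELISA-style saturation series: one signal per
#' (dose, replicate), optionally with a matched control series (the GST
#' background in the assays this package models).
#'
#' @param dose concentrations in nM (>= 0).
#' @param signal measured signals (same length).
#' @param replicate replicate labels (same length; default single
#'   replicate).
#' @param control optional control signals matched element-wise.
#' @return data.frame of class `binding_curve` with columns `dose`,
#'   `replicate`, `signal` and optionally `control`.
#' @export
binding_curve <- function(dose, signal, replicate = NULL, control = NULL) {
  dose <- as.numeric(dose); signal <- as.numeric(signal)
  if (length(dose) != length(signal)) stop("dose/signal length mismatch")
  if (any(dose < 0)) stop("doses must be >= 0")
  if (is.null(replicate)) replicate <- rep("R1", length(dose))
  if (length(replicate) != length(dose)) stop("replicate length mismatch")
  df <- data.frame(dose = dose, replicate = as.character(replicate),
                   signal = signal, stringsAsFactors = FALSE)
  if (!is.null(control)) {
    if (length(control) != length(dose)) stop("control length mismatch")
    df$control <- as.numeric(control)
  }
  df <- df[order(df$replicate, df$dose), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("binding_curve", "data.frame")
  df
}

#' Subtract the matched control series
#'
#' Signal minus control per (dose, replicate); the reported signal of the
#' assays this models is the specific minus the GST-control signal.
#' Negative differences are kept (with a warning) unless `clip = TRUE`.
#'
#' @param curve a [binding_curve()] with a `control` column.
#' @param clip clip negative corrected signals at 0.
#' @return the corrected `binding_curve` (control column dropped).
#' @export
subtract_control <- function(curve, clip = FALSE) {
  stopifnot(inherits(curve, "binding_curve"))
  if (!"control" %in% names(curve)) {
    stop("no control series present in this curve")
  }
  curve$signal <- curve$signal - curve$control
  if (any(curve$signal < 0)) {
    if (clip) curve$signal <- pmax(curve$signal, 0)
    else warning("negative control-subtracted signals kept (clip = FALSE)")
  }
  curve$control <- NULL
  curve
}

one_site <- function(x, kd, bmax, baseline) baseline + bmax * x / (kd + x)

#' Fit a one-site saturation binding model
#'
#' Least-squares fit of `y = baseline + Bmax * x / (Kd + x)` by
#' Levenberg-Marquardt with a multistart over a log-spaced Kd grid
#' spanning the dose range two decades either side; the best converged
#' solution by residual sum of squares is returned. The baseline is fixed
#' at 0 unless `fit_baseline = TRUE`.
#'
#' @param curve a [binding_curve()] (control already subtracted).
#' @param fit_baseline estimate the baseline instead of fixing it at 0.
#' @param n_starts number of Kd grid starts.
#' @return object of class `one_site_fit`: list with `kd`, `bmax`,
#'   `baseline`, `rss`, `se_kd` (from the fit curvature), `converged`,
#'   and `extrapolated` (`TRUE` when Kd falls outside
#'   `[min dose / 100, max dose * 100]`).
#' @export
fit_one_site <- function(curve, fit_baseline = FALSE, n_starts = 12L) {
  stopifnot(inherits(curve, "binding_curve"))
  x <- curve$dose; y <- curve$signal
  pos <- x > 0
  if (length(unique(x)) < 4L) {
    stop("at least 4 distinct doses are required for a one-site fit")
  }
  span <- range(x[pos])
  kd_grid <- exp(seq(log(span[1] / 100), log(span[2] * 100),
                     length.out = n_starts))
  best <- NULL
  for (kd0 in kd_grid) {
    b0 <- max(y) * (kd0 + max(x)) / max(x)
    fit <- tryCatch({
      if (fit_baseline) {
        minpack.lm::nlsLM(y ~ baseline + bmax * x / (kd + x),
                          start = list(kd = kd0, bmax = b0,
                                       baseline = min(y)),
                          lower = c(kd = 1e-12, bmax = 0, baseline = 0),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ bmax * x / (kd + x),
                          start = list(kd = kd0, bmax = b0),
                          lower = c(kd = 1e-12, bmax = 0),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(kd = NA_real_, bmax = NA_real_, baseline = 0,
                          rss = NA_real_, se_kd = NA_real_,
                          converged = FALSE, extrapolated = NA),
                     class = "one_site_fit"))
  }
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  kd <- unname(cf[["kd"]])
  structure(list(kd = kd, bmax = unname(cf[["bmax"]]),
                 baseline = if (fit_baseline) unname(cf[["baseline"]]) else 0,
                 rss = best$rss, se_kd = se, converged = TRUE,
                 extrapolated = kd < span[1] / 100 || kd > span[2] * 100),
            class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf("<one_site_fit> Kd = %.3g nM (se %.2g), Bmax = %.3g, rss = %.3g%s\n",
              x$kd, x$se_kd, x$bmax, x$rss,
              if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  invisible(x)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' One-tailed homoscedastic two-sample t-test
#'
#' Pooled-variance two-sample t statistic with `n_x + n_y - 2` degrees of
#' freedom; the one-tailed p-value is for the alternative that `y` lies
#' below `x` (the loss-of-binding direction in which mutants are compared
#' with wild type). With zero pooled variance the test is degenerate and
#' the p-value is 0.5 for equal means, or 0/1 by the sign of the observed
#' difference (documented convention).
#'
#' @param x reference sample (wild type), `n >= 2`.
#' @param y comparison sample (mutant), `n >= 2`.
#' @param alternative `"less"` (`y < x`, default) or `"greater"`.
#' @return one-tailed p-value.
#' @export
ttest_homoscedastic_onetail <- function(x, y, alternative = c("less",
                                                              "greater")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  pooled <- ((length(x) - 1) * stats::var(x) +
             (length(y) - 1) * stats::var(y)) / (length(x) + length(y) - 2)
  if (pooled == 0) {
    d <- mean(y) - mean(x)
    if (d == 0) return(0.5)
    p_less <- if (d < 0) 0 else 1
    return(if (alternative == "less") p_less else 1 - p_less)
  }
  # test y < x  <=>  x - y > 0, i.e. t.test(x, y, alternative = "greater")
  tt <- stats::t.test(x, y, var.equal = TRUE,
                      alternative = if (alternative == "less") "greater"
                                    else "less")
  unname(tt$p.value)
}

#' Significance stars for one-tailed p-values
#'
#' Thresholds 0.05, 0.025, 0.01, 0.005 and 0.001 (strict `<`) map to
#' `*` .. `*****`; anything else is `"ns"`.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of star strings.
#' @export
assign_stars <- function(p) {
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  cuts <- c(0.001, 0.005, 0.01, 0.025, 0.05)
  vapply(p, function(pi) {
    k <- sum(pi < cuts)       # how many thresholds it beats
    if (k == 0L) "ns" else strrep("*", k)
  }, "")
}

#' Normalise TR-FIA plate signals to wild type
#'
#' Per experiment, every construct's signal is divided by that
#' experiment's wild-type signal (wild type is 1 by construction).
#' Across experiments the mean and *population* standard deviation are
#' reported, and each mutant is compared against the wild-type normalised
#' values with the one-tailed homoscedastic t-test in the
#' mutant-below-wild-type direction.
#'
#' @param data data.frame with columns `construct`, `experiment`,
#'   `signal` (one row per construct per experiment; replicate wells
#'   should be averaged per experiment beforehand).
#' @param wildtype label of the wild-type construct.
#' @return data.frame of class `trfia_result`: `construct`,
#'   `mean_normalized`, `sd`, `n`, `p_value` (NA for wild type), `stars`.
#' @export
normalize_trfia <- function(data, wildtype = "WT") {
  need <- c("construct", "experiment", "signal")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  data$construct <- as.character(data$construct)
  data$experiment <- as.character(data$experiment)
  exps <- unique(data$experiment)
  norm <- vector("list", length(exps))
  for (i in seq_along(exps)) {
    sub <- data[data$experiment == exps[i], , drop = FALSE]
    wt <- sub$signal[sub$construct == wildtype]
    if (!length(wt)) stop("experiment '", exps[i], "' lacks wild type '",
                          wildtype, "'")
    wt <- mean(wt)
    if (wt == 0) stop("zero wild-type signal in experiment '", exps[i], "'")
    sub$normalized <- sub$signal / wt
    norm[[i]] <- sub
  }
  norm <- do.call(rbind, norm)
  constructs <- unique(norm$construct)
  wt_vals <- norm$normalized[norm$construct == wildtype]
  rows <- lapply(constructs, function(cn) {
    v <- norm$normalized[norm$construct == cn]
    p <- if (cn == wildtype || length(v) < 2L || length(wt_vals) < 2L) {
      NA_real_
    } else {
      ttest_homoscedastic_onetail(wt_vals, v, alternative = "less")
    }
    data.frame(construct = cn, mean_normalized = mean(v), sd = pop_sd(v),
               n = length(v), p_value = p,
               stars = if (is.na(p)) "" else assign_stars(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trfia_result", "data.frame")
  out
}
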