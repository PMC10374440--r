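#' Sigmoid melting model
#'
#' The melting curve model
#' \deqn{f(T) = \frac{1-p}{1 + \exp(b - a/T)} + p}
#' where `T` is temperature in degrees Celsius, `p` the high-temperature
#' plateau, and `a`, `b` jointly set slope and inflection point. For `a > 0`
#' the curve decreases from ~1 at low temperature towards `p`.
#'
#' @param t Temperature(s), strictly positive.
#' @param a,b Slope/inflection parameters.
#' @param p Plateau in `[0, 1)` (p = 1 gives the degenerate flat curve).
#' @return Fold change(s) in `[p, 1]` for `a > 0`.
#' @export
melt_sigmoid <- function(t, a, b, p) {
  if (any(t <= 0)) abort("temperatures must be strictly positive")
  (1 - p) / (1 + exp(b - a / t)) + p
}

#' Fit the sigmoid melting model to one melting curve
#'
#' Nonlinear least squares with a grid of starting values (midpoint grid
#' T0, a = b * T0, plateau from the last observed value), refined with
#' Levenberg-Marquardt; the plateau is constrained to `[0, 1)`. The residual
#' standard deviation is `S_res = sqrt(rss / (n - 3))`.
#'
#' @param temperature,fold_change Numeric vectors (pairs with NA dropped);
#'   at least 4 complete observations are required for a converged fit.
#' @param s_res_max Fits with `S_res` at or above this are flagged
#'   not `accepted` (default 0.1) but retained in outputs.
#' @param t_range Integration window for the melting AUC; defaults to the
#'   observed temperature range.
#' @return An object of class `melt_fit`: list with `a`, `b`, `p`, `rss`,
#'   `s_res`, `n`, `converged`, `accepted`, `tm`, `auc` and the data used.
#' @export
fit_melt_curve <- function(temperature, fold_change, s_res_max = 0.1,
                           t_range = NULL) {
  ok <- !is.na(temperature) & !is.na(fold_change)
  t <- temperature[ok]
  y <- fold_change[ok]
  out <- structure(
    list(a = NA_real_, b = NA_real_, p = NA_real_, rss = NA_real_,
         s_res = NA_real_, n = length(t), converged = FALSE,
         accepted = FALSE, tm = NA_real_, auc = NA_real_,
         data = tibble(temperature = t, fold_change = y)),
    class = "melt_fit")
  if (length(t) < 4) return(out)
  if (is.null(t_range)) t_range <- range(t)

  p0 <- min(max(y[which.max(t)], 0), 0.3)
  starts <- expand.grid(t0 = seq(44, 60, by = 2), b = c(25, 50, 100))
  # rank the start grid by residual sum of squares with the plateau profiled
  # out (the model is linear in p given a and b), and refine only the most
  # promising starts; the objective is non-convex and multi-start
  profile_p <- function(a, b) {
    g <- 1 / (1 + exp(b - a / t))
    denom <- sum((1 - g)^2)
    p <- if (denom > 0) {
      min(max(sum((y - g) * (1 - g)) / denom, 0), 1 - 1e-9)
    } else p0
    list(p = p, rss = sum((y - ((1 - p) * g + p))^2))
  }
  start_fit <- lapply(seq_len(nrow(starts)), function(s) {
    profile_p(starts$b[s] * starts$t0[s], starts$b[s])
  })
  start_rss <- vapply(start_fit, `[[`, numeric(1), "rss")
  ord <- order(start_rss)
  # a numerically perfect grid start is already the least-squares solution
  # (and makes the Levenberg-Marquardt gradient singular)
  if (start_rss[ord[1]] < 1e-20) {
    best <- list(a = starts$b[ord[1]] * starts$t0[ord[1]],
                 b = starts$b[ord[1]], p = start_fit[[ord[1]]]$p,
                 rss = start_rss[ord[1]])
  } else {
    starts <- starts[ord[seq_len(min(4, nrow(starts)))], , drop = FALSE]
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      st <- list(a = starts$b[s] * starts$t0[s], b = starts$b[s], p = p0)
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nlsLM(
          y ~ (1 - p) / (1 + exp(b - a / t)) + p,
          start = st,
          lower = c(a = 0, b = 0, p = 0),
          upper = c(a = Inf, b = Inf, p = 1 - 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 150, ftol = 1e-15,
                                             ptol = 1e-12)
        )),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- c(as.list(coef(fit)), list(rss = rss))
      }
    }
    if (is.null(best)) {
      # fall back to bounded quasi-Newton from the best grid start
      st <- c(starts$b[1] * starts$t0[1], starts$b[1], p0)
      opt <- tryCatch(
        optim(st, function(par) {
          sum((y - melt_sigmoid(t, par[1], par[2], par[3]))^2)
        }, method = "L-BFGS-B",
        lower = c(0, 0, 0), upper = c(Inf, Inf, 1 - 1e-9)),
        error = function(e) NULL
      )
      if (!is.null(opt)) {
        best <- list(a = opt$par[1], b = opt$par[2], p = opt$par[3],
                     rss = opt$value)
      }
    }
  }
  if (is.null(best)) return(out)
  # the model is linear in p given (a, b): polish the plateau exactly
  g <- 1 / (1 + exp(best$b - best$a / t))
  denom <- sum((1 - g)^2)
  if (denom > 0) {
    p_opt <- min(max(sum((y - g) * (1 - g)) / denom, 0), 1 - 1e-9)
    rss_opt <- sum((y - ((1 - p_opt) * g + p_opt))^2)
    if (rss_opt < best$rss) {
      best$p <- p_opt
      best$rss <- rss_opt
    }
  }
  out$a <- best$a
  out$b <- best$b
  out$p <- best$p
  out$rss <- best$rss
  out$s_res <- sqrt(best$rss / (length(t) - 3))
  out$converged <- TRUE
  out$accepted <- out$s_res < s_res_max
  out$tm <- melting_point(out)
  out$auc <- melting_auc(out, t_min = t_range[1], t_max = t_range[2])
  out
}

#' Melting point of a fitted curve
#'
#' The temperature at which the fitted curve crosses 0.5:
#' `Tm = a / (b - log(0.5 / (0.5 - p)))`, defined only for `p < 0.5` and a
#' positive finite solution; otherwise `NA` (the curve never reaches 0.5).
#'
#' @param fit A `melt_fit`, or a list with elements `a`, `b`, `p`.
#' @return Melting point in degrees Celsius, or `NA`.
#' @export
melting_point <- function(fit) {
  if (is.na(fit$a) || is.na(fit$p)) return(NA_real_)
  if (fit$p >= 0.5) return(NA_real_)
  denom <- fit$b - log(0.5 / (0.5 - fit$p))
  tm <- fit$a / denom
  if (!is.finite(tm) || tm <= 0) NA_real_ else tm
}

#' Area under a fitted melting curve
#'
#' Numerical integral of the fitted sigmoid over a fixed temperature window,
#' so that values are comparable across cell lines.
#'
#' @param fit A `melt_fit` (converged).
#' @param t_min,t_max Integration bounds in degrees Celsius.
#' @return Area in degrees Celsius x fold change.
#' @export
melting_auc <- function(fit, t_min = 41, t_max = 63) {
  if (t_min >= t_max) abort("t_min must be below t_max")
  if (is.na(fit$a)) return(NA_real_)
  integrate(function(tt) melt_sigmoid(tt, fit$a, fit$b, fit$p),
            lower = t_min, upper = t_max, abs.tol = 1e-8)$value
}

#' Fit melting curves for every (profile, cell line)
#'
#' @param fc_tbl Fold-change tibble (`id`, `cell_line`, `temperature`,
#'   `fold_change`).
#' @param s_res_max Acceptance threshold on the residual standard deviation.
#' @return A tibble with one row per (id, cell_line): fit parameters,
#'   `s_res`, `converged`, `accepted`, `tm`, `auc`.
#' @export
fit_melt_curves <- function(fc_tbl, s_res_max = 0.1) {
  t_range <- range(fc_tbl$temperature)
  fc_tbl |>
    group_by(.data$id, .data$cell_line) |>
    group_modify(function(d, key) {
      f <- fit_melt_curve(d$temperature, d$fold_change,
                          s_res_max = s_res_max, t_range = t_range)
      glance(f)
    }) |>
    ungroup()
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Sigmoid melting-curve fit\n")
  if (!x$converged) {
    cat(sprintf("  not converged (n = %d points)\n", x$n))
  } else {
    cat(sprintf("  a = %.4g, b = %.4g, p = %.4g\n", x$a, x$b, x$p))
    cat(sprintf("  S_res = %.4g (%s), Tm = %s, AUC = %.4g\n",
                x$s_res, if (x$accepted) "accepted" else "rejected",
                if (is.na(x$tm)) "undefined" else sprintf("%.2f degC", x$tm),
                x$auc))
  }
  invisible(x)
}

#' Tidy a melting-curve fit
#'
#' @param x A `melt_fit`.
#' @param ... Unused.
#' @return One row per model parameter with its estimate.
#' @export
tidy.melt_fit <- function(x, ...) {
  tibble(term = c("a", "b", "p"), estimate = c(x$a, x$b, x$p))
}

#' One-row summary of a melting-curve fit
#'
#' @param x A `melt_fit`.
#' @param ... Unused.
#' @return A one-row tibble: parameters, `rss`, `s_res`, `n`, `converged`,
#'   `accepted`, `tm`, `auc`.
#' @export
glance.melt_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, p = x$p, rss = x$rss, s_res = x$s_res,
         n = x$n, converged = x$converged, accepted = x$accepted,
         tm = x$tm, auc = x$auc)
}

#' Plot a fitted melting curve
#'
#' @param object A `melt_fit`.
#' @param ... Unused.
#' @return A ggplot: observed fold changes and the fitted sigmoid.
#' @export
autoplot.melt_fit <- function(object, ...) {
  stopifnot(inherits(object, "melt_fit"))
  pl <- ggplot2::ggplot(object$data,
                        ggplot2::aes(x = .data$temperature,
                                     y = .data$fold_change)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Temperature (°C)", y = "Fold change (soluble)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(temperature = seq(min(object$data$temperature),
                                     max(object$data$temperature),
                                     length.out = 200))
    grid$fold_change <- melt_sigmoid(grid$temperature, object$a, object$b,
                                     object$p)
    pl <- pl + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  pl
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
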