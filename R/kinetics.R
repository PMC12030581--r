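# Semi-empirical release kinetics: Korsmeyer-Peppas power law and Weibull
# stretched exponential, fitted per sample on the percent scale.

#' Korsmeyer-Peppas release model
#'
#' Power-law release kinetics `Mt/Minf = k * t^n`. The exponent `n`
#' diagnoses the transport mechanism (see [classify_mechanism()]). The model
#' is evaluated without any cap, so the returned fraction may exceed 1 at
#' late times; the power law is only meant to describe the rising portion
#' of a release curve.
#'
#' @param t time in hours, `>= 0` (vectorized).
#' @param k release rate constant (units h^-n), `> 0`.
#' @param n release exponent (dimensionless), `> 0`.
#' @return Released fraction of the total dose, `k * t^n` (0 at `t = 0`).
#' @export
#' @examples
#' kp_release(4, k = 0.1, n = 0.5)   # 0.2
kp_release <- function(t, k, n) {
  check_kinetic_args(t, k, n, c("k", "n"))
  k * t^n
}

#' Weibull release model
#'
#' Stretched-exponential release kinetics `Mt/Minf = 1 - exp(-(t/tau)^beta)`
#' with scale `tau` (the time by which a fraction 1 - 1/e has been released)
#' and shape `beta`. `beta = 1` is first-order release; `beta < 1`
#' diffusion-controlled; `beta > 1` indicates additional influences such as
#' swelling or polymer degradation. Output is always in `[0, 1)`.
#'
#' @param t time in hours, `>= 0` (vectorized).
#' @param tau scale parameter in hours, `> 0`.
#' @param beta shape parameter (dimensionless), `> 0`.
#' @return Released fraction of the total dose.
#' @export
#' @examples
#' weibull_release(24, tau = 24, beta = 1)   # 1 - exp(-1)
weibull_release <- function(t, tau, beta) {
  check_kinetic_args(t, tau, beta, c("tau", "beta"))
  -expm1(-(t / tau)^beta)
}

check_kinetic_args <- function(t, p1, p2, names) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("time must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(p1) || p1 <= 0 || !is.finite(p2) || p2 <= 0) {
    stop(names[1], " and ", names[2], " must be finite and > 0",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify the release mechanism from a fitted kinetic parameter
#'
#' For the Korsmeyer-Peppas exponent `n`: `n <= 0.5` Fickian diffusion;
#' `0.5 < n < 1` anomalous transport (diffusion plus polymer swelling);
#' `n = 1` (within `tol`) Case II transport; `n > 1` super-Case-II. For the
#' Weibull shape `beta`: `beta < 1` diffusion-controlled; `beta = 1`
#' (within `tol`) first-order release; `beta > 1` complex release
#' influenced by swelling or degradation.
#'
#' @param model `"kp"` or `"weibull"`.
#' @param value fitted exponent `n` (K-P) or shape `beta` (Weibull), `> 0`.
#' @param tol half-width of the band around 1 treated as exactly 1
#'   (default 0.01); the rule table itself states exact equalities.
#' @return A mechanism label (character scalar).
#' @export
#' @examples
#' classify_mechanism("kp", 0.3)       # "fickian"
#' classify_mechanism("weibull", 1.4)  # "complex"
classify_mechanism <- function(model = c("kp", "weibull"), value,
                               tol = 0.01) {
  model <- match.arg(model)
  if (!is.finite(value) || value <= 0) {
    stop("mechanism classification needs a positive finite value",
         call. = FALSE)
  }
  if (model == "kp") {
    if (abs(value - 1) <= tol) return("case_II")
    if (value <= 0.5) return("fickian")
    if (value < 1) return("anomalous")
    return("super_case_II")
  }
  if (abs(value - 1) <= tol) return("first_order")
  if (value < 1) return("diffusion_controlled")
  "complex"
}

#' Fit a kinetic release model to one release curve
#'
#' Nonlinear least squares of the model (times 100, i.e. on the percent
#' scale) against the observed cumulative release, over all points of the
#' sample. Fitting uses bounded Levenberg-Marquardt with multi-start:
#' shape/exponent starts at 0.3, 0.6, 1.0 and 1.5 crossed with rate/scale
#' starts from a log-log linearization of the data plus a log-spaced grid.
#' The best optimum is kept (ties broken by smaller parameter norm).
#'
#' For K-P the initializer regresses `log(release)` on `log(t)` over the
#' strictly positive points; its slope estimates `n`. Points with
#' `t = 0` or zero release are excluded from the initializer but kept in
#' the least-squares objective.
#'
#' @param curve data.frame with columns `time_h` and `release_pct`
#'   (at least 3 points, strictly increasing times), e.g. from
#'   [release_curve()].
#' @param sample_id optional id stored in the result.
#' @param n_starts number of multi-start attempts (default 8).
#' @return An object of class `release_fit`: a list with `sample_id`,
#'   `model`, `params` (named vector: `k`, `n` or `tau`, `beta`), `mse`
#'   (squared-percent), `r2`, `n_points`, `converged` and `mechanism`.
#' @seealso [classify_mechanism()], [metric_mse()], [metric_r2()]
#' @export
fit_kp <- function(curve, sample_id = NA_integer_, n_starts = 8L) {
  fit_kinetic(curve, "kp", sample_id, n_starts)
}

#' @rdname fit_kp
#' @export
fit_weibull <- function(curve, sample_id = NA_integer_, n_starts = 8L) {
  fit_kinetic(curve, "weibull", sample_id, n_starts)
}

fit_kinetic <- function(curve, model, sample_id, n_starts) {
  stopifnot(is.data.frame(curve),
            all(c("time_h", "release_pct") %in% names(curve)))
  t <- curve$time_h
  y <- curve$release_pct
  if (length(t) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(t < 0)) stop("negative times", call. = FALSE)
  if (all(y == 0)) stop("degenerate all-zero release curve", call. = FALSE)

  starts <- kinetic_starts(t, y, model, n_starts)
  predfun <- if (model == "kp") {
    function(p, t) 100 * kp_release(t, p[1], p[2])
  } else {
    function(p, t) 100 * weibull_release(t, p[1], p[2])
  }

  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    res <- try(suppressWarnings(minpack.lm::nls.lm(
      par = p0,
      lower = c(1e-12, 1e-6), upper = c(Inf, 20),
      fn = function(p) predfun(p, t) - y,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )), silent = TRUE)
    if (inherits(res, "try-error")) next
    p <- res$par
    obj <- mean((predfun(p, t) - y)^2)
    conv <- res$info %in% 1:4
    any_converged <- any_converged || conv
    if (is.null(best) || obj < best$obj - 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 && sum(p^2) < sum(best$p^2))) {
      best <- list(p = p, obj = obj, conv = conv)
    }
  }
  if (is.null(best)) stop("all fit attempts failed", call. = FALSE)

  yhat <- predfun(best$p, t)
  params <- setNames(best$p,
                     if (model == "kp") c("k", "n") else c("tau", "beta"))
  r2 <- if (stats::var(y) > 0) metric_r2(y, yhat) else NA_real_
  structure(list(
    sample_id = sample_id,
    model = model,
    params = params,
    mse = metric_mse(y, yhat),
    r2 = r2,
    n_points = length(t),
    converged = any_converged,
    mechanism = classify_mechanism(model, params[[2]])
  ), class = "release_fit")
}

# Multi-start grid: exponent/shape values crossed with rate/scale guesses.
# The first start comes from a log-log (K-P) or log(-log) (Weibull)
# linearization over the strictly positive points.
kinetic_starts <- function(t, y, model, n_starts) {
  shapes <- c(0.3, 0.6, 1.0, 1.5)
  init <- loglog_init(t, y, model)
  t_ref <- max(t[t > 0])
  if (model == "kp") {
    frac_end <- max(max(y) / 100, 1e-3)
    rates <- frac_end / t_ref^shapes
    grid <- data.frame(p1 = rates, p2 = shapes)
  } else {
    taus <- exp(seq(log(max(min(t[t > 0]), t_ref / 50)), log(2 * t_ref),
                    length.out = 4))
    grid <- data.frame(p1 = taus, p2 = shapes)
  }
  out <- rbind(init, grid)
  out[!duplicated(out), , drop = FALSE][seq_len(min(n_starts, nrow(out) + 0)), ,
                                        drop = FALSE]
}

loglog_init <- function(t, y, model) {
  ok <- t > 0 & y > 0 & y < 100
  if (sum(ok) >= 2) {
    if (model == "kp") {
      f <- stats::lm(log(y[ok] / 100) ~ log(t[ok]))
      n0 <- max(min(coef(f)[[2]], 19), 1e-3)
      k0 <- max(exp(coef(f)[[1]]), 1e-10)
      return(data.frame(p1 = k0, p2 = n0))
    }
    # Weibull linearization: log(-log(1 - y/100)) = beta*log(t) - beta*log(tau)
    f <- stats::lm(log(-log(1 - y[ok] / 100)) ~ log(t[ok]))
    b0 <- max(min(coef(f)[[2]], 19), 1e-3)
    tau0 <- exp(-coef(f)[[1]] / b0)
    if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t)
    return(data.frame(p1 = tau0, p2 = b0))
  }
  NULL
}

#' @export
print.release_fit <- function(x, ...) {
  pn <- names(x$params)
  cat(sprintf(
    "release_fit [%s] sample %s: %s=%.5g, %s=%.5g | MSE %.3f, R2 %.3f, %s%s\n",
    x$model, as.character(x$sample_id),
    pn[1], x$params[[1]], pn[2], x$params[[2]],
    x$mse, x$r2, x$mechanism,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fit kinetic models to every sample of a dataset
#'
#' @param dataset a `release_dataset`.
#' @param model `"kp"`, `"weibull"` or `"both"`.
#' @param n_starts multi-start attempts per fit.
#' @return data.frame with one row per sample and model: `sample_id`,
#'   `model`, the two parameters (`p1` = k or tau, `p2` = n or beta),
#'   `mse`, `r2`, `n_points`, `converged`, `mechanism`.
#' @export
fit_dataset <- function(dataset, model = c("both", "kp", "weibull"),
                        n_starts = 8L) {
  stopifnot(inherits(dataset, "release_dataset"))
  model <- match.arg(model)
  models <- if (model == "both") c("kp", "weibull") else model
  out <- list()
  for (m in models) {
    for (id in dataset$samples$sample_id) {
      f <- fit_kinetic(release_curve(dataset, id), m, id, n_starts)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = id, model = m,
        p1 = f$params[[1]], p2 = f$params[[2]],
        mse = f$mse, r2 = f$r2, n_points = f$n_points,
        converged = f$converged, mechanism = f$mechanism,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
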