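#' Parameter specification for nonlinear fits
#'
#' Describes one free parameter of a model curve: its name, starting value,
#' box bounds, and whether the optimizer should work in log10 space.
#' Log-scale fitting is the default route for equilibrium and rate
#' constants, which are positive by nature; standard errors are mapped
#' back to the natural scale by the delta method.
#'
#' @param name Parameter name (character scalar).
#' @param init Initial value, on the natural scale.
#' @param lower,upper Box bounds on the natural scale. For `log_scale`
#'   parameters `lower` must be > 0.
#' @param log_scale Fit this parameter as log10(value)?
#' @return An object of class `param_spec`.
#' @examples
#' param_spec("kd", 1e-6, lower = 1e-12, upper = 1e-2, log_scale = TRUE)
#' @export
param_spec <- function(name, init, lower = -Inf, upper = Inf, log_scale = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(init), length(init) == 1L, is.finite(init))
  if (!(lower < upper)) stop("param_spec: lower bound must be < upper bound")
  if (init < lower || init > upper)
    stop("param_spec '", name, "': initial value must lie within bounds")
  if (log_scale && lower <= 0)
    stop("param_spec '", name, "': log_scale requires a positive lower bound")
  structure(list(name = name, init = init, lower = lower, upper = upper,
                 log_scale = isTRUE(log_scale)),
            class = "param_spec")
}

#' Fit control settings
#'
#' @param rel_tol Relative convergence tolerance on the objective and the
#'   parameters.
#' @param max_iter Iteration cap for the optimizer.
#' @param n_starts Number of multi-start initial points tried automatically
#'   when the first fit fails to converge or ends on a bound.
#' @return A list of control settings.
#' @export
fit_control <- function(rel_tol = 1e-8, max_iter = 10000, n_starts = 5) {
  list(rel_tol = rel_tol, max_iter = max_iter, n_starts = n_starts)
}

## internal: natural <-> optimizer scale
.to_internal <- function(theta, specs) {
  lg <- vapply(specs, `[[`, TRUE, "log_scale")
  theta[lg] <- log10(theta[lg])
  theta
}
.from_internal <- function(u, specs) {
  lg <- vapply(specs, `[[`, TRUE, "log_scale")
  u[lg] <- 10^u[lg]
  u
}

## internal: central-difference Jacobian of model predictions wrt internal pars
.pred_jacobian <- function(model, x, u, specs) {
  p <- length(u)
  f0 <- model(.named_pars(.from_internal(u, specs), specs), x)
  J <- matrix(NA_real_, length(f0), p)
  for (j in seq_len(p)) {
    h <- max(1e-6, abs(u[j]) * 1e-6)
    up <- u; up[j] <- u[j] + h
    dn <- u; dn[j] <- u[j] - h
    fp <- model(.named_pars(.from_internal(up, specs), specs), x)
    fm <- model(.named_pars(.from_internal(dn, specs), specs), x)
    J[, j] <- (fp - fm) / (2 * h)
  }
  J
}

.named_pars <- function(theta, specs) {
  setNames(theta, vapply(specs, `[[`, "", "name"))
}

#' Nonlinear least-squares fit with bounds and log-scale parameters
#'
#' Minimizes the (optionally weighted) residual sum of squares of a model
#' curve against observations, using a quasi-Newton bounded optimizer.
#' When the first attempt fails to converge or finishes on a box bound, a
#' log-spaced multi-start over the parameter boxes is tried automatically
#' and the best optimum kept. Standard errors come from the Gauss-Newton
#' approximation of the covariance at the optimum,
#' `sigma^2 * (J' W J)^-1`, mapped to the natural parameter scale by the
#' delta method for log-scale parameters.
#'
#' Non-convergence is reported through `converged = FALSE` in the result,
#' never as an error.
#'
#' @param model Function `(pars, x)` returning predicted signal; `pars` is
#'   a named numeric vector on the natural scale.
#' @param x Abscissa values.
#' @param y Observed values (same length as `x`).
#' @param specs List of [param_spec()] objects, one per free parameter.
#' @param weights Optional positive weights (length of `y`).
#' @param control See [fit_control()].
#' @return A `fit_result` object: list with `estimates`,
#'   `standard_errors`, `covariance`, `rss`, `n_points`, `n_params`,
#'   `converged`, `n_iterations`.
#' @examples
#' line <- function(p, x) p[["m"]] * x + p[["b"]]
#' fit <- nls_fit(line, 0:5, 2 * (0:5) + 1,
#'                list(param_spec("m", 1), param_spec("b", 0)))
#' fit$estimates
#' @export
nls_fit <- function(model, x, y, specs, weights = NULL,
                    control = fit_control()) {
  if (length(x) != length(y))
    stop("nls_fit: abscissa and observations must have the same length")
  if (!all(is.finite(y)))
    stop("nls_fit: observations must be finite")
  if (inherits(specs, "param_spec")) specs <- list(specs)
  p <- length(specs)
  n <- length(y)
  if (n < p)
    stop("nls_fit: need at least as many points as parameters")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0))
    stop("nls_fit: weights must be positive, finite and match the data length")

  nm <- vapply(specs, `[[`, "", "name")
  lower <- .to_internal(vapply(specs, `[[`, 0, "lower"), specs)
  upper <- .to_internal(vapply(specs, `[[`, 0, "upper"), specs)

  obj <- function(u) {
    pred <- model(.named_pars(.from_internal(u, specs), specs), x)
    if (length(pred) != n || any(!is.finite(pred))) return(1e300)
    sum(w * (y - pred)^2)
  }

  run1 <- function(u0) {
    nlminb(u0, obj, lower = lower, upper = upper,
           control = list(iter.max = control$max_iter,
                          eval.max = 10L * control$max_iter,
                          rel.tol = min(control$rel_tol, 1e-10)))
  }

  u0 <- .to_internal(vapply(specs, `[[`, 0, "init"), specs)
  fit <- run1(u0)
  at_bound <- function(f) {
    fin <- is.finite(lower) | is.finite(upper)
    any(fin & (abs(f$par - lower) < 1e-8 | abs(f$par - upper) < 1e-8))
  }
  if ((fit$convergence != 0 || at_bound(fit)) && control$n_starts > 1) {
    for (k in seq_len(control$n_starts)) {
      ## log-spaced (internal-scale) spread across each parameter's box,
      ## falling back to a spread around the initial value when unbounded
      frac <- k / (control$n_starts + 1)
      uk <- ifelse(is.finite(lower) & is.finite(upper),
                   lower + frac * (upper - lower),
                   u0 + (frac - 0.5) * 4)
      cand <- run1(uk)
      if (cand$objective < fit$objective ||
          (fit$convergence != 0 && cand$convergence == 0))
        fit <- cand
    }
  }

  ## Gauss-Newton polish: nlminb stops within its relative tolerance of
  ## the optimum; a few damped GN steps push linear and near-linear
  ## problems to machine precision (required for closed-form agreement)
  u <- fit$par
  rss <- fit$objective
  for (it in seq_len(10)) {
    J <- try(.pred_jacobian(model, x, u, specs), silent = TRUE)
    if (inherits(J, "try-error") || !all(is.finite(J))) break
    r <- y - model(.named_pars(.from_internal(u, specs), specs), x)
    step <- try(solve(crossprod(J * sqrt(w)), crossprod(J, w * r)),
                silent = TRUE)
    if (inherits(step, "try-error") || !all(is.finite(step))) break
    u_new <- pmin(pmax(u + drop(step), lower), upper)
    rss_new <- obj(u_new)
    if (rss_new > rss) break
    moved <- max(abs(u_new - u))
    u <- u_new
    rss <- rss_new
    if (moved < 1e-13 * (1 + max(abs(u)))) break
  }
  theta <- .from_internal(u, specs)
  converged <- fit$convergence == 0

  ## Gauss-Newton covariance at the optimum
  se <- rep(NA_real_, p)
  covm <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  if (n > p) {
    J <- try(.pred_jacobian(model, x, u, specs), silent = TRUE)
    if (!inherits(J, "try-error") && all(is.finite(J))) {
      A <- crossprod(J * sqrt(w))
      sigma2 <- rss / (n - p)
      cov_u <- try(solve(A) * sigma2, silent = TRUE)
      if (inherits(cov_u, "try-error")) {
        sv <- svd(A)
        pos <- sv$d > max(sv$d) * 1e-12
        Ainv <- sv$v[, pos, drop = FALSE] %*%
          (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
        cov_u <- Ainv * sigma2
      }
      D <- ifelse(vapply(specs, `[[`, TRUE, "log_scale"), theta * log(10), 1)
      covm[] <- diag(D, p) %*% cov_u %*% diag(D, p)
      se <- sqrt(pmax(diag(covm), 0))
    }
  } else {
    se <- rep(0, p)
    covm[] <- 0
  }

  structure(list(estimates = .named_pars(theta, specs),
                 standard_errors = setNames(se, nm),
                 covariance = covm,
                 rss = rss,
                 n_points = n,
                 n_params = p,
                 converged = converged,
                 n_iterations = fit$iterations,
                 seed_used = NULL),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Nonlinear least-squares fit (", x$n_points, " points, ",
      x$n_params, " parameters)\n", sep = "")
  cat("  converged: ", x$converged, "   RSS: ",
      format(x$rss, digits = 6), "\n", sep = "")
  tab <- data.frame(estimate = x$estimates, se = x$standard_errors)
  print(format(tab, digits = 4))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Optional file path; when given, JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
fit_result_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(estimates = as.list(fit$estimates),
              standard_errors = as.list(fit$standard_errors),
              converged = fit$converged,
              rss = fit$rss,
              n_points = fit$n_points)
  if (!is.null(fit$seed_used)) obj$seed_used <- fit$seed_used
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Residual-resampling bootstrap confidence intervals
#'
#' Refits the model to `fitted + resampled residuals` and reports
#' percentile intervals per parameter. Reproducible for a fixed seed.
#'
#' @inheritParams nls_fit
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed for the resampling RNG.
#' @param level Interval coverage level (default 0.95).
#' @return A data.frame with one row per parameter: `estimate`, `lower`,
#'   `upper`, plus attributes `n_boot` and `seed`.
#' @export
bootstrap_ci <- function(model, x, y, specs, n_boot = 500, seed,
                         level = 0.95, weights = NULL,
                         control = fit_control()) {
  if (n_boot < 100) stop("bootstrap_ci: n_boot must be at least 100")
  fit0 <- nls_fit(model, x, y, specs, weights = weights, control = control)
  pred0 <- model(fit0$estimates, x)
  res <- y - pred0
  ## restart each refit from the original optimum
  specs1 <- lapply(seq_along(specs), function(j) {
    s <- specs[[j]]
    s$init <- unname(fit0$estimates[j])
    s
  })
  p <- length(specs)
  draws <- matrix(NA_real_, n_boot, p)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      yb <- pred0 + sample(res, replace = TRUE)
      fb <- nls_fit(model, x, yb, specs1, weights = weights,
                    control = control)
      draws[b, ] <- fb$estimates
    }
  })
  a <- (1 - level) / 2
  lo <- apply(draws, 2, quantile, probs = a, na.rm = TRUE)
  hi <- apply(draws, 2, quantile, probs = 1 - a, na.rm = TRUE)
  out <- data.frame(parameter = names(fit0$estimates),
                    estimate = unname(fit0$estimates),
                    lower = unname(lo), upper = unname(hi),
                    row.names = NULL)
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  out
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed locally and restores the previous global RNG state on
#' exit, so that seeded generators never perturb user code.
#'
#' @param seed Integer seed, or NULL for no seeding.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
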