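#' Global fit problem for a SAXS concentration series
#'
#' Bundles several [saxs_dataset()] curves with the refinement layout used
#' for concentration series: the structural parameters `L_t`, `L_h` and `R`
#' are shared across all curves, while the protein fraction `x`, the scales
#' `C1`, `C2` and the background `B` are refined per dataset. Component SLDs
#' stay fixed.
#'
#' Parameters are addressed by name: `"L_t"`, `"L_h"`, `"R"` and, for
#' dataset `j`, `"x_j"`, `"C1_j"`, `"C2_j"`, `"B_j"`.
#'
#' @param datasets list of [saxs_dataset()] objects (at least one, nonempty)
#' @param slds fixed [sld_set()]
#' @param init named list/vector of initial values; omitted entries use
#'   defaults (`L_t` 15, `L_h` 7, `R` 3, `x` 0.02); scale and background
#'   initials default to a data-driven weighted linear estimate
#' @param lower,upper named bounds; defaults are physically plausible
#'   (`L_t` in \[8, 25\], `L_h` in \[3, 12\], `R` in \[0, 15\], `x` in
#'   \[0, 0.5\], scales and background non-negative)
#' @param fixed character vector of parameter names to hold at their
#'   initial values
#' @param q_window length-2 numeric; restrict fitting to this q range.
#'   The model is known to be incomplete at very low q (no explicit vesicle
#'   form factor), so restricting to `q >= 0.02` is a documented option.
#' @return Object of class `global_fit_problem`.
#' @export
global_fit_problem <- function(datasets, slds = sld_set(), init = list(),
                               lower = list(), upper = list(),
                               fixed = character(), q_window = NULL) {
  if (!is.list(datasets) || length(datasets) == 0L)
    stop("need at least one dataset", call. = FALSE)
  if (!all(vapply(datasets, inherits, logical(1), "saxs_dataset")))
    stop("datasets must be saxs_dataset objects", call. = FALSE)
  if (any(vapply(datasets, function(d) length(d$q), integer(1)) == 0L))
    stop("every dataset must be nonempty", call. = FALSE)
  n <- length(datasets)
  nm <- .par_names(n)

  def_init <- c(L_t = 15, L_h = 7, R = 3,
                stats::setNames(rep(0.02, n), sprintf("x_%d", seq_len(n))),
                stats::setNames(rep(NA_real_, 3 * n),
                                c(sprintf("C1_%d", seq_len(n)),
                                  sprintf("C2_%d", seq_len(n)),
                                  sprintf("B_%d", seq_len(n)))))
  def_lower <- c(L_t = 8, L_h = 3, R = 0,
                 stats::setNames(rep(0, n), sprintf("x_%d", seq_len(n))),
                 stats::setNames(rep(0, 3 * n),
                                 c(sprintf("C1_%d", seq_len(n)),
                                   sprintf("C2_%d", seq_len(n)),
                                   sprintf("B_%d", seq_len(n)))))
  def_upper <- c(L_t = 25, L_h = 12, R = 15,
                 stats::setNames(rep(0.5, n), sprintf("x_%d", seq_len(n))),
                 stats::setNames(rep(Inf, 3 * n),
                                 c(sprintf("C1_%d", seq_len(n)),
                                   sprintf("C2_%d", seq_len(n)),
                                   sprintf("B_%d", seq_len(n)))))
  ini <- .merge_named(def_init, init, nm)
  lo <- .merge_named(def_lower, lower, nm)
  up <- .merge_named(def_upper, upper, nm)
  bad <- !is.na(ini) & (ini < lo | ini > up)
  if (any(bad))
    stop("initial values outside bounds: ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  if (!all(fixed %in% nm))
    stop("unknown parameter in 'fixed': ",
         paste(setdiff(fixed, nm), collapse = ", "), call. = FALSE)
  structure(list(datasets = datasets, slds = slds, init = ini,
                 lower = lo, upper = up, fixed = fixed,
                 q_window = q_window, par_names = nm),
            class = "global_fit_problem")
}

.par_names <- function(n) {
  c("L_t", "L_h", "R",
    as.vector(t(outer(c("x", "C1", "C2", "B"), seq_len(n), paste, sep = "_"))))
}

.merge_named <- function(defaults, user, nm) {
  out <- defaults[nm]
  user <- unlist(user)
  if (length(user)) {
    unknown <- setdiff(names(user), nm)
    if (length(unknown))
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    out[names(user)] <- user
  }
  out
}

# fitting view of the data: q/I/sigma restricted to the q window
.fit_data <- function(problem) {
  lapply(problem$datasets, function(d) {
    keep <- rep(TRUE, length(d$q))
    if (!is.null(problem$q_window))
      keep <- d$q >= problem$q_window[1] & d$q <= problem$q_window[2]
    list(q = d$q[keep], I = d$I[keep], sigma = d$sigma[keep])
  })
}

# basis curves for dataset j at given shape parameters: damped lamellar,
# damped micelle, constant
.basis_curves <- function(q, L_t, L_h, R, x, slds) {
  m <- bilayer_model(L_t = L_t, L_h = L_h, x = x, R = 0, C1 = 1, C2 = 0,
                     B = 0, slds = slds)
  damp <- exp(-R^2 * q^2)
  cbind(lam = lamellar_intensity(q, m) * damp,
        mic = micelle_intensity(q, L_t, L_h, slds$rho_t, slds$rho_h,
                                slds$rho_s) * damp,
        bg = rep(1, length(q)))
}

# weighted linear least squares for (C1, C2, B) >= 0 by exhaustive
# active-set over the 3 columns (model is linear in the scales)
.estimate_scales <- function(q, I, sigma, L_t, L_h, R, x, slds) {
  X <- .basis_curves(q, L_t, L_h, R, x, slds) / sigma
  y <- I / sigma
  best <- NULL
  best_ssr <- Inf
  for (mask in 1:7) {
    cols <- which(bitwAnd(mask, c(1L, 2L, 4L)) > 0L)
    cf <- tryCatch(stats::lsfit(X[, cols, drop = FALSE], y,
                                intercept = FALSE)$coefficients,
                   error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf)) || any(cf < 0)) next
    full <- numeric(3)
    full[cols] <- cf
    ssr <- sum((y - X %*% full)^2)
    if (ssr < best_ssr) {
      best_ssr <- ssr
      best <- full
    }
  }
  if (is.null(best)) best <- c(max(mean(I), 0) / max(mean(.basis_curves(
    q, L_t, L_h, R, x, slds)[, 1]), .Machine$double.eps), 0, 0)
  stats::setNames(pmax(best, 0), c("C1", "C2", "B"))
}

# fill NA scale initials with data-driven estimates
.complete_init <- function(problem, par) {
  dat <- .fit_data(problem)
  for (j in seq_along(dat)) {
    keys <- sprintf(c("C1_%d", "C2_%d", "B_%d"), j)
    if (any(is.na(par[keys]))) {
      est <- .estimate_scales(dat[[j]]$q, dat[[j]]$I, dat[[j]]$sigma,
                              par[["L_t"]], par[["L_h"]], par[["R"]],
                              par[[sprintf("x_%d", j)]], problem$slds)
      par[keys][is.na(par[keys])] <- est[is.na(par[keys])]
    }
  }
  par
}

# weighted residual vector over all datasets for a full named parameter set
.global_residuals <- function(par, problem, dat) {
  out <- vector("list", length(dat))
  for (j in seq_along(dat)) {
    X <- .basis_curves(dat[[j]]$q, par[["L_t"]], par[["L_h"]], par[["R"]],
                       par[[sprintf("x_%d", j)]], problem$slds)
    model <- X %*% c(par[[sprintf("C1_%d", j)]], par[[sprintf("C2_%d", j)]],
                     par[[sprintf("B_%d", j)]])
    out[[j]] <- (dat[[j]]$I - model) / dat[[j]]$sigma
  }
  unlist(out, use.names = FALSE)
}

# single bounded Levenberg-Marquardt minimization from one start
.fit_once <- function(problem, start, fixed, maxiter = 200) {
  dat <- .fit_data(problem)
  nm <- problem$par_names
  free <- setdiff(nm, fixed)
  par_full <- start[nm]
  fn <- function(p) {
    par_full[free] <- p
    r <- .global_residuals(par_full, problem, dat)
    r[!is.finite(r)] <- 1e10
    r
  }
  fit <- minpack.lm::nls.lm(
    par = start[free], lower = problem$lower[free],
    upper = pmin(problem$upper[free], 1e300), fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         ftol = 1e-12, ptol = 1e-12))
  par_full[free] <- fit$par
  list(par = par_full, ssr = fit$deviance, free = free,
       niter = fit$niter, info = fit$info, message = fit$message,
       converged = fit$info %in% 1:4)
}

# forward-difference jacobian of the weighted residuals wrt free parameters
.free_jacobian <- function(problem, par, free) {
  dat <- .fit_data(problem)
  r0 <- .global_residuals(par, problem, dat)
  J <- matrix(0, length(r0), length(free), dimnames = list(NULL, free))
  for (k in seq_along(free)) {
    p <- par
    h <- max(abs(p[[free[k]]]), 1e-8) * 1e-6
    p[[free[k]]] <- p[[free[k]]] + h
    J[, k] <- (.global_residuals(p, problem, dat) - r0) / h
  }
  J
}

#' Global refinement of a SAXS concentration series
#'
#' Minimizes the summed weighted squared residuals
#' \eqn{\sum_j \sum_i ((I_{obs} - I_{model})/\sigma)^2} over all datasets
#' simultaneously, with `L_t`, `L_h`, `R` shared and `x`, `C1`, `C2`, `B`
#' per dataset. Uses bounded Levenberg-Marquardt least squares with a
#' multistart strategy: the first start is the problem's initial values and
#' the remainder are drawn from a seeded Latin-hypercube design over the
#' bounds of the shape parameters (scales and background are re-estimated
#' from the data by a weighted linear solve at every start). The best
#' minimum wins; exact ties go to the lowest start index.
#'
#' @param problem a [global_fit_problem()]
#' @param n_starts number of multistart initializations (default 10)
#' @param seed integer seed for the multistart design
#' @param level confidence level for the quick (curvature-based) parameter
#'   intervals reported in the result; default 0.638
#' @return Object of class `saxs_global_fit` with elements `par` (refined
#'   full parameter vector), `se` (curvature standard errors),
#'   `intervals` (matrix of quick intervals at `level`), `chi2_red`
#'   (reduced chi-square), `ssr`, `n_points`, `n_free`, `residuals`
#'   (per-dataset standardized residual vectors), `converged`, `niter`,
#'   `message`, `starts` (multistart summary) and the `problem`.
#'   Non-convergence is flagged via `converged`, never silently dropped.
#' @seealso [profile_confidence_interval()] for profile-likelihood
#'   intervals.
#' @export
fit_global <- function(problem, n_starts = 10, seed = 1, level = 0.638) {
  stopifnot(inherits(problem, "global_fit_problem"))
  n <- length(problem$datasets)
  dat <- .fit_data(problem)
  shape <- c("L_t", "L_h", "R", sprintf("x_%d", seq_len(n)))
  shape <- setdiff(shape, problem$fixed)

  starts <- list(.complete_init(problem, problem$init))
  geom <- intersect(c("L_t", "L_h", "R"), shape)
  if (n_starts > 1 && length(geom) > 0) {
    # coarse stage: seeded Latin-hypercube design over the shared geometry,
    # with the protein fraction profiled over a small grid and the scales
    # and background solved by weighted linear least squares per dataset;
    # the best-scoring candidates are polished by Levenberg-Marquardt
    set.seed(seed)
    n_cand <- 25L * (n_starts - 1L)
    design <- lhs::randomLHS(n_cand, length(geom))
    colnames(design) <- geom
    x_names <- intersect(sprintf("x_%d", seq_len(n)), shape)
    cand_score <- numeric(n_cand)
    cand_par <- vector("list", n_cand)
    for (s in seq_len(n_cand)) {
      p <- problem$init
      for (k in geom) {
        lo <- problem$lower[[k]]
        up <- min(problem$upper[[k]], 1e6)
        p[[k]] <- lo + design[s, k] * (up - lo)
      }
      total <- 0
      for (j in seq_len(n)) {
        xk <- sprintf("x_%d", j)
        x_grid <- if (xk %in% x_names) {
          g <- c(0, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2)
          unique(pmin(pmax(g, problem$lower[[xk]]), problem$upper[[xk]]))
        } else p[[xk]]
        best_ssr <- Inf
        for (xv in x_grid) {
          sc <- .estimate_scales(dat[[j]]$q, dat[[j]]$I, dat[[j]]$sigma,
                                 p[["L_t"]], p[["L_h"]], p[["R"]], xv,
                                 problem$slds)
          X <- .basis_curves(dat[[j]]$q, p[["L_t"]], p[["L_h"]], p[["R"]],
                             xv, problem$slds)
          ssr_j <- sum(((dat[[j]]$I - X %*% sc) / dat[[j]]$sigma)^2)
          if (ssr_j < best_ssr) {
            best_ssr <- ssr_j
            p[[xk]] <- xv
            p[sprintf(c("C1_%d", "C2_%d", "B_%d"), j)] <- sc
          }
        }
        total <- total + best_ssr
      }
      cand_par[[s]] <- p
      cand_score[s] <- total
    }
    top <- order(cand_score)[seq_len(n_starts - 1L)]
    starts <- c(starts, cand_par[top])
  }

  fits <- lapply(starts, function(s) .fit_once(problem, s, problem$fixed))
  ssrs <- vapply(fits, `[[`, numeric(1), "ssr")
  best_i <- which.min(ssrs)  # which.min takes the first (lowest index) tie
  best <- fits[[best_i]]

  n_points <- sum(lengths(lapply(dat, `[[`, "q")))
  n_free <- length(best$free)
  chi2_red <- best$ssr / max(n_points - n_free, 1L)

  J <- .free_jacobian(problem, best$par, best$free)
  # column equilibration keeps the normal equations invertible even though
  # the scale parameters differ by many orders of magnitude
  cn <- sqrt(colSums(J^2))
  cn[cn == 0] <- 1
  cov <- tryCatch({
    Ji <- sweep(J, 2, cn, "/")
    base <- chol2inv(qr.R(qr(Ji)))
    base / tcrossprod(cn)
  }, error = function(e) {
    matrix(NA_real_, n_free, n_free, dimnames = list(best$free, best$free))
  })
  se <- stats::setNames(rep(NA_real_, length(problem$par_names)),
                        problem$par_names)
  se[best$free] <- sqrt(pmax(diag(cov), 0))
  half <- sqrt(stats::qchisq(level, df = 1)) * se
  intervals <- cbind(lower = best$par - half, upper = best$par + half)

  resid <- vector("list", length(dat))
  r_all <- .global_residuals(best$par, problem, dat)
  pos <- 0L
  for (j in seq_along(dat)) {
    nj <- length(dat[[j]]$q)
    resid[[j]] <- r_all[pos + seq_len(nj)]
    pos <- pos + nj
  }

  structure(list(par = best$par, se = se, intervals = intervals,
                 level = level, chi2_red = chi2_red, ssr = best$ssr,
                 n_points = n_points, n_free = n_free, residuals = resid,
                 converged = best$converged, niter = best$niter,
                 message = best$message,
                 starts = data.frame(start = seq_along(ssrs), ssr = ssrs,
                                     converged = vapply(fits, `[[`,
                                                        logical(1),
                                                        "converged")),
                 problem = problem),
            class = "saxs_global_fit")
}

#' @export
print.saxs_global_fit <- function(x, ...) {
  cat(sprintf("Global SAXS fit: %d datasets, %d points, %d free parameters\n",
              length(x$problem$datasets), x$n_points, x$n_free))
  cat(sprintf("  reduced chi-square: %.4g  (converged: %s)\n",
              x$chi2_red, x$converged))
  shown <- x$par[!is.na(x$se)]
  for (nm in names(shown))
    cat(sprintf("  %-6s %.5g +/- %.3g\n", nm, shown[[nm]], x$se[[nm]]))
  invisible(x)
}

#' Profile-likelihood confidence interval for one fit parameter
#'
#' Scans the named parameter away from its refined value, re-minimizing all
#' other free parameters at each trial value, and returns the interval on
#' which \eqn{\chi^2(\theta) \le \chi^2_{min} + \Delta}, where
#' \eqn{\Delta} is the chi-square quantile with one degree of freedom at
#' the requested level (0.874 at the 63.8% level used for scattering
#' refinements). Endpoints are located by bracketing and bisection.
#' If the crossing lies outside the parameter bounds the bound itself is
#' returned and flagged as censored.
#'
#' @param problem the [global_fit_problem()] that was fitted
#' @param result the [fit_global()] result
#' @param parameter parameter name, e.g. `"L_t"` or `"x_2"`
#' @param level confidence level (default 0.638)
#' @param rel_tol relative bisection tolerance on the endpoint (default
#'   1e-3)
#' @return Length-2 numeric `c(lower, upper)` with attributes `censored`
#'   (logical pair), `level` and `parameter`.
#' @export
profile_confidence_interval <- function(problem, result, parameter,
                                        level = 0.638, rel_tol = 1e-3) {
  stopifnot(inherits(problem, "global_fit_problem"),
            inherits(result, "saxs_global_fit"))
  if (!result$converged)
    stop("fit did not converge; profile interval undefined", call. = FALSE)
  free <- setdiff(problem$par_names, problem$fixed)
  if (!(parameter %in% free))
    stop("'", parameter, "' is not a refinable parameter", call. = FALSE)
  est <- result$par[[parameter]]
  if (level <= 0) {
    out <- c(lower = est, upper = est)
    attr(out, "censored") <- c(FALSE, FALSE)
    attr(out, "level") <- level
    attr(out, "parameter") <- parameter
    return(out)
  }
  delta <- stats::qchisq(level, df = 1)
  target <- result$ssr + delta
  warm <- result$par

  prof <- function(theta) {
    start <- warm
    start[[parameter]] <- theta
    f <- .fit_once(problem, start, fixed = c(problem$fixed, parameter))
    if (f$ssr < result$ssr + delta * 2) warm <<- f$par
    f$ssr
  }

  se <- result$se[[parameter]]
  step0 <- if (is.finite(se) && se > 0) se * sqrt(delta) else
    max(abs(est) * 0.1, 1e-4)

  one_side <- function(dir) {
    bound <- if (dir < 0) problem$lower[[parameter]] else
      problem$upper[[parameter]]
    warm <<- result$par
    step <- step0
    inside <- est
    repeat {
      cand <- est + dir * step
      hit_bound <- (dir < 0 && cand <= bound) || (dir > 0 && cand >= bound)
      if (hit_bound) cand <- bound
      s <- prof(cand)
      if (s >= target) {
        outside <- cand
        break
      }
      inside <- cand
      if (hit_bound) return(list(value = bound, censored = TRUE))
      step <- step * 2
    }
    # endpoint located to rel_tol relative to its distance from the
    # estimate (the profile half-width)
    while (abs(outside - inside) >
           rel_tol * abs(outside - est) + 1e-15) {
      mid <- (inside + outside) / 2
      if (prof(mid) >= target) outside <- mid else inside <- mid
    }
    list(value = (inside + outside) / 2, censored = FALSE)
  }

  lo <- one_side(-1)
  hi <- one_side(+1)
  out <- c(lower = lo$value, upper = hi$value)
  attr(out, "censored") <- c(lo$censored, hi$censored)
  attr(out, "level") <- level
  attr(out, "parameter") <- parameter
  out
}
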