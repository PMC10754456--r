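# Segmented (piecewise-linear, continuous) regression of M on u = 1/f:
# phase detection on the accumulation curve.
#
# Breakpoints are estimated by Muggeo-style iterative linearization
# (augmenting the design with hinge terms U = (x - psi)+ and working
# indicator terms V = -1(x > psi), then updating psi by the ratio of the V
# and U coefficients), with deterministic grid restarts against local
# optima. Model size is chosen as the smallest number of breakpoints whose
# adjusted R^2 reaches a target, capped at 20.

segmented_design <- function(x, psi, with_v = TRUE) {
  U <- outer(x, psi, function(xx, p) pmax(xx - p, 0))
  if (!with_v) return(cbind(1, x, U))
  V <- outer(x, psi, function(xx, p) -as.numeric(xx > p))
  cbind(1, x, U, V)
}

# One Muggeo run from a starting breakpoint vector; returns NULL on
# degeneracy (collapsed or escaped breakpoints, singular designs).
muggeo_iterate <- function(x, y, psi, max_iter = 30, tol = 1e-9) {
  k <- length(psi)
  if (k == 0) return(NULL)
  rng <- range(x)
  eps <- diff(rng) * 1e-4
  for (iter in seq_len(max_iter)) {
    X <- segmented_design(x, psi)
    fit <- tryCatch(.lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) return(NULL)
    b <- fit$coefficients
    delta <- b[3:(2 + k)]
    gam <- b[(3 + k):(2 + 2 * k)]
    if (any(abs(delta) < 1e-12)) return(NULL)
    step <- gam / delta
    psi_new <- psi + step
    if (any(psi_new <= rng[1] + eps) || any(psi_new >= rng[2] - eps)) {
      psi_new <- pmin(pmax(psi_new, rng[1] + eps), rng[2] - eps)
    }
    psi_new <- sort(psi_new)
    if (k > 1 && any(diff(psi_new) < eps)) return(NULL)
    done <- max(abs(psi_new - psi)) < tol * diff(rng)
    psi <- psi_new
    if (done) break
  }
  # identifiability: every segment must hold a minimum number of points;
  # a "k-breakpoint" fit whose breakpoints collapse onto the boundary (or
  # onto each other) is not a supported k-breakpoint model
  support <- max(3L, ceiling(0.002 * length(x)))
  seg_counts <- tabulate(findInterval(x, psi) + 1L, nbins = k + 1L)
  if (any(seg_counts < support)) return(NULL)
  X <- segmented_design(x, psi, with_v = FALSE)
  fit <- tryCatch(.lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) return(NULL)
  rss <- sum(fit$residuals^2)
  list(psi = psi, coef = fit$coefficients, rss = rss)
}

# Deterministic restart grid: quantile-based breakpoint starts spread over
# the interior of x, plus optional user-supplied warm starts.
restart_starts <- function(x, k, n_restarts, warm = NULL) {
  qs <- function(p) unname(quantile(x, p, type = 7))
  base <- (seq_len(k)) / (k + 1)
  shifts <- seq(-0.6, 0.6, length.out = max(1, n_restarts - 1))
  starts <- list(qs(base))
  for (s in shifts) {
    p <- pmin(0.98, pmax(0.02, base + s * 0.5 / (k + 1)))
    starts[[length(starts) + 1L]] <- qs(p)
  }
  # a compressed and a stretched layout widen the search
  starts[[length(starts) + 1L]] <- qs(pmin(0.98, base * 0.6 + 0.02))
  starts[[length(starts) + 1L]] <- qs(pmin(0.98, base * 0.6 + 0.38))
  if (!is.null(warm)) starts <- c(warm, starts)
  starts <- unique(lapply(starts, function(p) unname(sort(p))))
  n_take <- min(n_restarts + length(warm %||% list()) + 2, length(starts))
  starts[seq_len(n_take)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a continuous piecewise-linear model with a fixed breakpoint count
#'
#' Lower-level companion of [fit_segmented()]: estimates the best k-break
#' model by iterative linearization with deterministic grid restarts.
#'
#' @param x,y Numeric vectors.
#' @param k Number of breakpoints (0 = simple regression).
#' @param n_restarts Restarts over the deterministic start grid.
#' @param warm Optional list of user-supplied starting breakpoint vectors.
#' @return List with `psi`, `coef` (intercept, base slope, slope changes)
#'   and `rss`, or NULL if every start degenerated.
#' @export
fit_segments_k <- function(x, y, k, n_restarts = 5, warm = NULL) {
  n <- length(x)
  if (k == 0) {
    X <- cbind(1, x)
    fit <- .lm.fit(X, y)
    return(list(psi = numeric(0), coef = fit$coefficients,
                rss = sum(fit$residuals^2)))
  }
  best <- NULL
  for (st in restart_starts(x, k, n_restarts, warm)) {
    res <- muggeo_iterate(x, y, st)
    if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
  }
  best
}

adj_r2 <- function(rss, tss, n, k) {
  1 - (rss / max(1, n - 2 * (k + 1))) / (tss / (n - 1))
}

#' Fit a segmented regression to an accumulation curve
#'
#' Tries k = 0, 1, 2, ... breakpoints and returns the smallest k whose
#' adjusted R^2 (denominator n - 2(k+1): k breakpoints, k+1 slopes, one
#' intercept, continuity constrained) reaches `target_adj_r2`. If the
#' target is unreachable at `max_breakpoints` the largest model is
#' returned flagged `objective_met = FALSE`.
#'
#' @param curve A [build_maf_curve()] result, or a list/data frame with
#'   numeric `u` (or `x`) and `m` (or `y`).
#' @param target_adj_r2 Adjusted-R^2 objective (0.995 is a typical
#'   genome-scale choice; 0.9995 for very dense curves).
#' @param max_breakpoints Cap on the number of breakpoints.
#' @param n_restarts Deterministic grid restarts per k.
#' @return Object of class `segmentation_fit`: breakpoints `psi`,
#'   per-segment `slopes` and `intercepts`, `adj_r2`, `rss`,
#'   `objective_met`, and the data used.
#' @export
fit_segmented <- function(curve, target_adj_r2 = 0.995,
                          max_breakpoints = 20, n_restarts = 5) {
  x <- curve$u %||% curve$x
  y <- curve$m %||% curve$y
  stopifnot(length(x) == length(y), length(x) >= 4)
  n <- length(x)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("constant response: nothing to segment")
  prev_psi <- NULL
  best <- NULL
  for (k in 0:max_breakpoints) {
    if (n < 2 * (k + 1) + k) break
    warm <- if (!is.null(prev_psi) && k >= 1) {
      cand <- quantile(x, c(0.25, 0.5, 0.75), type = 7)
      lapply(cand, function(p) sort(c(prev_psi, p))[seq_len(k)])
    } else NULL
    fit <- fit_segments_k(x, y, k, n_restarts, warm = warm)
    if (is.null(fit)) next
    r2 <- adj_r2(fit$rss, tss, n, k)
    cur <- list(k = k, psi = fit$psi, coef = fit$coef, rss = fit$rss,
                adj_r2 = r2)
    if (is.null(best) || fit$rss < best$rss || k == 0) best <- cur
    prev_psi <- fit$psi
    if (r2 >= target_adj_r2) {
      return(new_segmentation_fit(cur, x, y, target_adj_r2, TRUE))
    }
  }
  new_segmentation_fit(best, x, y, target_adj_r2, FALSE)
}

new_segmentation_fit <- function(fit, x, y, target, met) {
  k <- fit$k
  b <- fit$coef
  slopes <- cumsum(c(b[2], if (k > 0) b[3:(2 + k)] else numeric(0)))
  structure(list(
    k = k, psi = unname(fit$psi), coef = unname(b), slopes = unname(slopes),
    adj_r2 = fit$adj_r2, rss = fit$rss, n = length(x),
    target_adj_r2 = target, objective_met = met, x = x, y = y
  ), class = "segmentation_fit")
}

#' Predict from a segmented fit
#'
#' @param object A `segmentation_fit`.
#' @param newdata Numeric vector of u values (defaults to the fit data).
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.segmentation_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$x
  X <- segmented_design(x, object$psi, with_v = FALSE)
  drop(X %*% object$coef)
}

#' @export
print.segmentation_fit <- function(x, ...) {
  cat("Segmented fit:", x$k, "breakpoint(s)",
      if (x$k) paste0("at ", paste(signif(x$psi, 5), collapse = ", ")),
      "\n  adjusted R^2 =", signif(x$adj_r2, 6),
      if (!x$objective_met) "(objective not met)", "\n")
  invisible(x)
}

#' Davies' test for a change in slope with unknown breakpoint
#'
#' Scans a grid of candidate breakpoints, computes the t statistic of the
#' hinge term at each, and applies Davies' (1987) upper bound for the
#' maximum of the score process:
#' p = 2 * (Phi(-M) + V * exp(-M^2/2) / sqrt(8*pi)), with M the largest
#' absolute statistic and V the total variation of the statistic over the
#' grid. Two-sided by construction.
#'
#' @param curve A `maf_curve` or list with `u`/`x` and `m`/`y`.
#' @param n_grid Number of interior grid points.
#' @return p-value (1 for a constant response).
#' @export
davies_test <- function(curve, n_grid = 10) {
  x <- curve$u %||% curve$x
  y <- curve$m %||% curve$y
  n <- length(x)
  if (var(y) == 0) return(1)
  grid <- unname(quantile(x, seq(0.1, 0.9, length.out = n_grid), type = 7))
  grid <- unique(grid)
  tstat <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    X <- cbind(1, x, pmax(x - grid[i], 0))
    fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit) || fit$rank < 3) next
    res <- fit$residuals
    sigma2 <- sum(res^2) / (n - 3)
    XtX_inv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
    if (is.null(XtX_inv)) next
    se <- sqrt(sigma2 * XtX_inv[3, 3])
    tstat[i] <- fit$coefficients[3] / se
  }
  tstat <- tstat[!is.na(tstat)]
  if (length(tstat) < 2) return(1)
  M <- max(abs(tstat))
  V <- sum(abs(diff(tstat)))
  p <- 2 * (pnorm(-M) + V * exp(-M^2 / 2) / sqrt(8 * pi))
  min(1, max(0, p))
}

#' k-fold cross-validation of the segmentation model size
#'
#' Points are assigned to folds at random (seeded); for each candidate
#' breakpoint count the model is fitted on the training folds (warm-started
#' from the full-data fit) and scored on the held-out fold. `test_mse` is
#' the held-out error, `validation_mse` the training error, and their
#' difference the overfitting indicator: a non-increasing difference when
#' adding one more phase indicates the absence of overfitting.
#'
#' @param curve A `maf_curve` or `u`/`m` list.
#' @param k_folds Number of folds (default 10).
#' @param candidate_ks Breakpoint counts to compare.
#' @param seed Integer seed for the fold assignment.
#' @return Data frame with one row per candidate k.
#' @export
kfold_cv_segmentation <- function(curve, k_folds = 10, candidate_ks = 0:5,
                                  seed = 1) {
  x <- curve$u %||% curve$x
  y <- curve$m %||% curve$y
  n <- length(x)
  max_par <- 2 * (max(candidate_ks) + 1)
  if (n < 10 * max_par) {
    stop("too few points (", n, ") for ", max_par, "-parameter candidates")
  }
  set.seed(seed)
  folds <- sample(rep(seq_len(k_folds), length.out = n))
  out <- lapply(candidate_ks, function(k) {
    full <- fit_segments_k(x, y, k, n_restarts = 4)
    test_mse <- val_mse <- numeric(k_folds)
    for (j in seq_len(k_folds)) {
      tr <- folds != j
      fit <- fit_segments_k(x[tr], y[tr], k, n_restarts = 2,
                            warm = if (k > 0 && !is.null(full)) list(full$psi))
      if (is.null(fit)) { test_mse[j] <- NA; val_mse[j] <- NA; next }
      pred <- function(xx) {
        drop(segmented_design(xx, fit$psi, with_v = FALSE) %*% fit$coef)
      }
      val_mse[j] <- mean((y[tr] - pred(x[tr]))^2)
      test_mse[j] <- mean((y[!tr] - pred(x[!tr]))^2)
    }
    n_ok <- sum(!is.na(test_mse))
    # a candidate whose model is unsupported in half the folds (collapsed
    # or boundary breakpoints) is not a viable phase count
    if (n_ok < k_folds / 2) {
      return(data.frame(k = k, test_mse = NA_real_,
                        validation_mse = NA_real_, se_test = NA_real_))
    }
    data.frame(k = k, test_mse = mean(test_mse, na.rm = TRUE),
               validation_mse = mean(val_mse, na.rm = TRUE),
               se_test = sd(test_mse, na.rm = TRUE) / sqrt(n_ok))
  })
  out <- do.call(rbind, out)
  out$difference <- out$test_mse - out$validation_mse
  out
}

#' Select the segmentation size from a cross-validation table
#'
#' Nested segmented models differ by held-out errors far smaller than the
#' fold noise once the true phase count is reached, so the raw argmin of
#' the test MSE flips between near-tied candidates. The standard
#' one-standard-error rule resolves this: choose the smallest candidate
#' whose test MSE lies within one fold-level standard error of the
#' minimum.
#'
#' @param cv_table Output of [kfold_cv_segmentation()].
#' @return The selected breakpoint count.
#' @export
cv_select_k <- function(cv_table) {
  ok <- !is.na(cv_table$test_mse) & !is.na(cv_table$se_test)
  tab <- cv_table[ok, , drop = FALSE]
  if (nrow(tab) == 0) stop("no supported candidates in the CV table")
  i_min <- which.min(tab$test_mse)
  thresh <- tab$test_mse[i_min] + tab$se_test[i_min]
  min(tab$k[tab$test_mse <= thresh])
}

#' Accepted u-range between the outermost breakpoints
#'
#' Mutations below the first breakpoint (clonal or normal-tissue
#' contamination) and above the last one (near the SNV detection limit)
#' are excluded from downstream stages.
#'
#' @param fit A `segmentation_fit`.
#' @return Numeric length-2 vector `c(lo, hi)` on u. With fewer than two
#'   breakpoints the full data range is returned with a warning.
#' @export
trim_outer_phases <- function(fit) {
  stopifnot(inherits(fit, "segmentation_fit"))
  if (fit$k < 2) {
    warning("fewer than 2 breakpoints: returning the full u range")
    return(range(fit$x))
  }
  c(min(fit$psi), max(fit$psi))
}
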