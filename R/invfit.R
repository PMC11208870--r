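.design_table <- function() {
  tau <- c(0.25, 0.5, 1, 1.5, 3, 5, 7.5)
  list(
    fresh    = list(thickness = c(7.1, 7.4, 7.55, 7.8), tau1 = tau,
                    f = seq(1.0, 3.0, by = 0.25),
                    n = seq(0.65, 1.05, by = 0.05)),
    "de-cap" = list(thickness = c(5.7, 6.3, 6.8, 7.3), tau1 = tau,
                    # generated from the start by increment while <= end:
                    # 1.0 to 4.0 by 0.4 stops at 3.8
                    f = seq(1.0, 4.0, by = 0.4),
                    n = seq(0.85, 1.03, by = 0.03)),
    MEM8     = list(thickness = c(8.1, 8.4, 8.8), tau1 = tau,
                    f = seq(1.0, 3.0, by = 0.25),
                    n = seq(0.65, 1.05, by = 0.05)),
    frozen   = list(thickness = c(8.3, 8.8, 9.2), tau1 = tau,
                    f = seq(2.0, 6.0, by = 0.25),
                    n = seq(0.85, 1.15, by = 0.05))
  )
}

.condition_key <- function(condition) {
  switch(condition,
         fresh = , fridge8 = "fresh",
         frozen20 = , frozen80 = "frozen",
         "de-cap" = "de-cap",
         MEM8 = "MEM8",
         condition)
}

#' Full-factorial design for one preserving condition
#'
#' Returns the level lists (compressed-test thickness of the undeformed
#' lens, nucleus relaxation time tau1, form factor F, nucleus factor N)
#' and their Cartesian product. Group names map onto the four design
#' rows: fresh and fridge8 share one design, frozen20 and frozen80
#' another.
#'
#' Two range sets are available. `"table"` reproduces the published
#' grids used with the axisymmetric FE study. `"screening"` follows the
#' same screening principle (cover the behaviour of each condition's
#' samples) re-applied to this package's quasi-1D forward model: in a
#' series composite the cortical:nuclear strain ratio is tied directly
#' to the layer stiffness profile, so the frozen conditions' observed
#' ratios (roughly 1.5-2.6) are reached for F between 1 and 2 rather
#' than 2 and 6; only the frozen F/N rows differ.
#'
#' @param condition Condition or design name (`fresh`, `fridge8`,
#'   `de-cap`, `MEM8`, `frozen20`, `frozen80`, `frozen`).
#' @param ranges `"table"` (default) or `"screening"`.
#' @return An object of class `factorial_design`: list with `condition`,
#'   `levels` (named list of numeric vectors) and `combos` (data frame
#'   with one row per combination, columns `thickness_mm`, `tau1_s`,
#'   `form_factor_f`, `n_stiffness`).
#' @export
build_factorial <- function(condition, ranges = c("table", "screening")) {
  ranges <- match.arg(ranges)
  key <- .condition_key(condition)
  tbl <- .design_table()
  if (ranges == "screening") {
    tbl$frozen$f <- seq(1.0, 2.0, by = 0.1)
    tbl$frozen$n <- seq(0.85, 1.15, by = 0.05)
  }
  if (!key %in% names(tbl))
    stop("unknown condition '", condition, "'; valid: ",
         paste(unique(c(names(tbl), "fridge8", "frozen20", "frozen80")),
               collapse = ", "))
  lv <- tbl[[key]]
  combos <- expand.grid(thickness_mm = lv$thickness, tau1_s = lv$tau1,
                        form_factor_f = lv$f, n_stiffness = lv$n,
                        KEEP.OUT.ATTRS = FALSE)
  structure(list(condition = condition, design_key = key, levels = lv,
                 combos = combos, ranges = ranges),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf(
    "Factorial design '%s': %d thickness x %d tau x %d F x %d N = %d combinations\n",
    x$condition, length(x$levels$thickness), length(x$levels$tau1),
    length(x$levels$f), length(x$levels$n), nrow(x$combos)))
  invisible(x)
}

#' Coarsen a factorial design
#'
#' Keeps at most `max_levels` evenly spaced levels per factor (always
#' retaining the endpoints), for reduced-grid runs.
#'
#' @param design A [build_factorial()] result.
#' @param max_levels Integer vector of length 4 (thickness, tau1, F, N)
#'   or a single integer recycled.
#' @return A `factorial_design` with the reduced levels.
#' @export
coarsen_design <- function(design, max_levels) {
  max_levels <- rep_len(as.integer(max_levels), 4L)
  lv <- design$levels
  pick <- function(v, k) {
    if (length(v) <= k) v
    else v[unique(round(seq(1, length(v), length.out = k)))]
  }
  lv2 <- list(thickness = pick(lv$thickness, max_levels[1]),
              tau1 = pick(lv$tau1, max_levels[2]),
              f = pick(lv$f, max_levels[3]),
              n = pick(lv$n, max_levels[4]))
  combos <- expand.grid(thickness_mm = lv2$thickness, tau1_s = lv2$tau1,
                        form_factor_f = lv2$f, n_stiffness = lv2$n,
                        KEEP.OUT.ATTRS = FALSE)
  structure(list(condition = design$condition, design_key = design$design_key,
                 levels = lv2, combos = combos, ranges = design$ranges),
            class = "factorial_design")
}

.quad_formula <- function(rows) {
  # tau enters on the log scale: the viscoelastic response is governed by
  # the ratio of tau to the drive period, and the design grid is
  # log-spaced in spirit (0.25 ... 7.5). Squared terms need >= 3 levels;
  # single-level factors drop out entirely (keeps coarse grids full rank).
  raw <- c(thickness_mm = "thickness_mm", tau1_s = "log(tau1_s)",
           form_factor_f = "form_factor_f", n_stiffness = "n_stiffness")
  nlev <- vapply(names(raw), function(v) length(unique(rows[[v]])), 0L)
  v <- raw[nlev >= 2]
  if (length(v) == 0) return(stats::as.formula(".y ~ 1"))
  sq <- paste0("I(", raw[nlev >= 3], "^2)")
  rhs <- if (length(v) > 1) paste0("(", paste(v, collapse = " + "), ")^2")
         else v
  if (length(sq)) rhs <- paste(rhs, "+", paste(sq, collapse = " + "))
  stats::as.formula(paste(".y ~", rhs))
}

#' Run a factorial design through the forward model
#'
#' Evaluates [simulate_test()] at every design combination, records the
#' oscillation outputs (anterior/posterior/nuclear amplitude and nucleus
#' delay) plus the post-relaxation force, and fits a quadratic
#' response-surface surrogate (full pairwise interactions; amplitudes on
#' the log scale, delay raw) per output. Because the test is
#' strain-controlled, the strain outputs are independent of the absolute
#' modulus scale `c10_ref`; forces scale linearly with it.
#'
#' @param design A [build_factorial()] (possibly [coarsen_design()]ed).
#' @param protocol A [compression_protocol()].
#' @param geom_template A [lens_geometry()]; its `lt0_mm` is replaced by
#'   each combination's thickness.
#' @param c10_ref Reference long-term nucleus modulus in kPa.
#' @param g1 Prony factor, fixed at 0.25 across conditions.
#' @param progress Print a dot every 50 rows.
#' @return An object of class `response_surface`: list with `rows` (data
#'   frame: parameters, `amp_ant`, `amp_post`, `amp_nuc` in permille,
#'   `delay_ms`, `min_force_gf`, `max_force_gf`, `ok`), `surrogate`
#'   (fitted predictors), `surrogate_r2`, and the design/protocol
#'   context needed to re-simulate.
#' @export
run_design <- function(design, protocol, geom_template, c10_ref = 1,
                       g1 = 0.25, progress = FALSE) {
  stopifnot(inherits(design, "factorial_design"))
  cmb <- design$combos
  n <- nrow(cmb)
  out <- data.frame(cmb, amp_ant = NA_real_, amp_post = NA_real_,
                    amp_nuc = NA_real_, delay_ms = NA_real_,
                    min_force_gf = NA_real_, max_force_gf = NA_real_,
                    ok = FALSE)
  for (i in seq_len(n)) {
    res <- tryCatch({
      geom <- geom_template
      geom$lt0_mm <- cmb$thickness_mm[i]
      mat <- material_model(c10_nuc_inf_kpa = c10_ref, g1 = g1,
                            tau1_s = cmb$tau1_s[i],
                            form_factor_f = cmb$form_factor_f[i],
                            n_stiffness = cmb$n_stiffness[i])
      sim <- simulate_test(geom, mat, protocol)
      s <- sim$summary
      c(s$amp_ant_permille, s$amp_post_permille, s$amp_nuc_permille,
        if (isTRUE(s$delay_defined)) s$delay_nuc_ms else NA_real_,
        sim$min_force_gf, sim$max_force_gf)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      out[i, c("amp_ant", "amp_post", "amp_nuc", "delay_ms",
               "min_force_gf", "max_force_gf")] <- res
      out$ok[i] <- TRUE
    }
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  if (!any(out$ok)) stop("all design rows failed")

  fit_rows <- out[out$ok, ]
  surrogate <- list(); r2 <- c()
  for (y in c("amp_ant", "amp_post", "amp_nuc", "delay_ms")) {
    dat <- fit_rows
    dat$.y <- if (startsWith(y, "amp")) log(fit_rows[[y]]) else fit_rows[[y]]
    keep <- is.finite(dat$.y)
    m <- stats::lm(.quad_formula(fit_rows), data = dat[keep, ])
    surrogate[[y]] <- m
    r2[y] <- summary(m)$r.squared
  }
  structure(list(rows = out, surrogate = surrogate, surrogate_r2 = r2,
                 design = design, protocol = protocol,
                 geom_template = geom_template, c10_ref = c10_ref, g1 = g1),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf(
    "Response surface '%s': %d rows (%d ok), surrogate R2 %s\n",
    x$design$condition, nrow(x$rows), sum(x$rows$ok),
    paste(sprintf("%s %.3f", names(x$surrogate_r2), x$surrogate_r2),
          collapse = ", ")))
  invisible(x)
}

# surrogate prediction at arbitrary parameter values
.predict_surface <- function(surface, par) {
  nd <- as.data.frame(as.list(par))
  names(nd) <- c("thickness_mm", "tau1_s", "form_factor_f", "n_stiffness")
  p <- vapply(c("amp_ant", "amp_post", "amp_nuc", "delay_ms"),
              function(y) unname(stats::predict(surface$surrogate[[y]], nd)), 0)
  p[1:3] <- exp(p[1:3])
  p
}

#' Observed oscillation summary for inverse fitting
#'
#' Packages measured strain amplitudes (anterior, posterior, nucleus, in
#' permille), the nucleus delay (ms) and the condition-mean relaxed
#' force into the structure consumed by [optimize_fit()].
#'
#' @param amp_ant,amp_post,amp_nuc Measured amplitudes, permille, >= 0.
#' @param delay_ms Nucleus delay (negative = lag); `NA` if undefined.
#' @param min_force_gf Condition-mean post-relaxation force, gf.
#' @return An object of class `observed_summary`.
#' @export
observed_summary <- function(amp_ant, amp_post, amp_nuc, delay_ms = NA,
                             min_force_gf = NA) {
  stopifnot(amp_ant >= 0, amp_post >= 0, amp_nuc >= 0)
  structure(list(amp_ant = amp_ant, amp_post = amp_post, amp_nuc = amp_nuc,
                 delay_ms = delay_ms, min_force_gf = min_force_gf),
            class = "observed_summary")
}

#' Convert an OCE oscillation summary to an observed summary
#'
#' @param summary An `oscillation_summary` from [amplitude_and_delay()].
#' @param min_force_gf Condition-mean relaxed force, gf.
#' @return An [observed_summary()].
#' @export
as_observed <- function(summary, min_force_gf = NA) {
  observed_summary(summary$amp_ant_permille, summary$amp_post_permille,
                   summary$amp_nuc_permille,
                   if (isTRUE(summary$delay_defined)) summary$delay_nuc_ms
                   else NA,
                   min_force_gf)
}

#' Sum-of-squared-errors objective
#'
#' `SSE = ((alpha - kappa)/s1)^2 + ((beta - lambda)/s2)^2 +
#' ((gamma - mu)/s3)^2 + ((delta - nu)/s4)^2`: each component
#' (anterior, posterior, nuclear amplitude, delay) is standardized by
#' `scale` so that equal weighting is meaningful across permille and
#' millisecond units. Components whose observed value is `NA` are
#' dropped.
#'
#' @param observed An [observed_summary()].
#' @param predicted Numeric vector `(kappa, lambda, mu, nu)`: predicted
#'   anterior, posterior, nuclear amplitude (permille) and delay (ms).
#' @param scale Positive length-4 standardization vector (default unit
#'   weights).
#' @return Non-negative scalar; zero iff predicted matches observed in
#'   all non-missing components.
#' @export
fit_sse <- function(observed, predicted, scale = c(1, 1, 1, 1)) {
  stopifnot(length(predicted) >= 4, all(scale > 0))
  obs <- c(observed$amp_ant, observed$amp_post, observed$amp_nuc,
           observed$delay_ms)
  d <- (obs - predicted[1:4]) / scale
  sum(d[!is.na(d)]^2)
}

#' Inverse parameter identification on a response surface
#'
#' Minimizes [fit_sse()] over the design hull: an exact scan over the
#' stored design rows seeds a box-constrained quasi-Newton refinement on
#' the quadratic surrogate; the refined candidate is re-scored with one
#' true forward simulation and only kept if it beats the best design
#' row. Parameters are clipped to the design ranges and flagged when
#' they land on a boundary.
#'
#' @param surface A [run_design()] result.
#' @param observed An [observed_summary()].
#' @param scale Standardization for [fit_sse()]; default: the spread
#'   (SD) of each output across the design rows, the available proxy
#'   for the condition spread when a single lens is fitted.
#' @param refine Run the continuous refinement (default `TRUE`).
#' @param polish Follow the surrogate refinement with a derivative-free
#'   (Nelder-Mead) polish whose objective is the true forward simulator
#'   (default `TRUE`). The surrogate seeds, the simulator decides.
#' @param polish_maxit Simulator-objective iteration budget per start.
#' @param n_starts Number of distinct design rows used to seed the
#'   polish (the SSE landscape carries a shallow F-N ridge; restarting
#'   from diverse seeds escapes the wrong end of it). Starts stop early
#'   once the SSE is numerically zero.
#' @return An object of class `fit_result`: fitted `thickness_mm`,
#'   `tau1_s`, `form_factor_f`, `n_stiffness`, stiffness ratios
#'   (`ratio_ant` = C10_inf/C10bar_ant, `ratio_post`, `ratio_pooled` =
#'   nucleus:cortex ratio, equal for E by Eqs mu = 2 C10, E = 3 mu),
#'   `sse`, predicted outputs, surrogate R2, `at_boundary`,
#'   `c10_ref_kpa` and (until [calibrate_scale()]) `c10_nuc_inf_abs_kpa
#'   = NA`.
#' @export
optimize_fit <- function(surface, observed, scale = NULL, refine = TRUE,
                         polish = TRUE, polish_maxit = 80, n_starts = 1L) {
  stopifnot(inherits(surface, "response_surface"),
            inherits(observed, "observed_summary"))
  rows <- surface$rows[surface$rows$ok, ]
  if (is.null(scale)) {
    scale <- c(stats::sd(rows$amp_ant), stats::sd(rows$amp_post),
               stats::sd(rows$amp_nuc),
               stats::sd(rows$delay_ms, na.rm = TRUE))
    scale[!is.finite(scale) | scale <= 0] <- 1
  }
  pred_mat <- as.matrix(rows[, c("amp_ant", "amp_post", "amp_nuc", "delay_ms")])
  sse_rows <- apply(pred_mat, 1, function(p) fit_sse(observed, p, scale))
  best <- which.min(sse_rows)
  par_names <- c("thickness_mm", "tau1_s", "form_factor_f", "n_stiffness")
  par0 <- as.numeric(rows[best, par_names])
  best_sse <- sse_rows[best]
  best_par <- par0
  best_pred <- pred_mat[best, ]

  lv <- surface$design$levels
  lower <- c(min(lv$thickness), min(lv$tau1), min(lv$f), min(lv$n))
  upper <- c(max(lv$thickness), max(lv$tau1), max(lv$f), max(lv$n))

  if (refine && all(upper > lower)) {
    obj <- function(p) fit_sse(observed, .predict_surface(surface, p), scale)
    opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 200))
    # re-score the refined candidate with the true forward model
    true_pred <- tryCatch({
      geom <- surface$geom_template
      geom$lt0_mm <- opt$par[1]
      mat <- material_model(c10_nuc_inf_kpa = surface$c10_ref,
                            g1 = surface$g1, tau1_s = opt$par[2],
                            form_factor_f = opt$par[3],
                            n_stiffness = opt$par[4])
      s <- simulate_test(geom, mat, surface$protocol)$summary
      c(s$amp_ant_permille, s$amp_post_permille, s$amp_nuc_permille,
        s$delay_nuc_ms)
    }, error = function(e) NULL)
    if (!is.null(true_pred)) {
      true_sse <- fit_sse(observed, true_pred, scale)
      if (true_sse < best_sse) {
        best_sse <- true_sse
        best_par <- opt$par
        best_pred <- true_pred
      }
    }
  }

  if (polish && all(upper > lower)) {
    simulate_at <- function(p) {
      geom <- surface$geom_template
      geom$lt0_mm <- p[1]
      mat <- material_model(c10_nuc_inf_kpa = surface$c10_ref,
                            g1 = surface$g1, tau1_s = p[2],
                            form_factor_f = p[3], n_stiffness = p[4])
      s <- simulate_test(geom, mat, surface$protocol)$summary
      c(s$amp_ant_permille, s$amp_post_permille, s$amp_nuc_permille,
        s$delay_nuc_ms)
    }
    span <- upper - lower
    obj_true <- function(u) {
      pen <- sum(pmax(0, u - 1)^2 + pmax(0, -u)^2)
      p <- lower + pmin(pmax(u, 0), 1) * span
      sse <- tryCatch(fit_sse(observed, simulate_at(p), scale),
                      error = function(e) Inf)
      sse + 1e3 * pen
    }
    # seed points: the refined candidate, then further design rows that
    # differ appreciably from seeds already taken
    seeds <- list(best_par)
    if (n_starts > 1L) {
      for (idx in order(sse_rows)) {
        if (length(seeds) >= n_starts) break
        cand <- as.numeric(rows[idx, par_names])
        far <- all(vapply(seeds, function(s)
          max(abs(cand - s) / span) >= 0.1, TRUE))
        if (far) seeds <- c(seeds, list(cand))
      }
    }
    for (sd0 in seeds) {
      if (best_sse < 1e-8) break
      u0 <- (sd0 - lower) / span
      po <- stats::optim(u0, obj_true, method = "Nelder-Mead",
                         control = list(maxit = polish_maxit,
                                        reltol = 1e-8, abstol = 1e-9))
      p_po <- lower + pmin(pmax(po$par, 0), 1) * span
      pred_po <- tryCatch(simulate_at(p_po), error = function(e) NULL)
      if (!is.null(pred_po)) {
        sse_po <- fit_sse(observed, pred_po, scale)
        if (sse_po < best_sse) {
          best_sse <- sse_po
          best_par <- p_po
          best_pred <- pred_po
        }
      }
    }
  }

  geom <- surface$geom_template
  geom$lt0_mm <- best_par[1]
  mat <- material_model(c10_nuc_inf_kpa = surface$c10_ref, g1 = surface$g1,
                        tau1_s = best_par[2], form_factor_f = best_par[3],
                        n_stiffness = best_par[4])
  mod <- cortical_layer_moduli(mat, geom)
  tol <- 1e-6 * pmax(upper - lower, 1e-12)
  structure(list(
    thickness_mm = best_par[1], tau1_s = best_par[2],
    form_factor_f = best_par[3], n_stiffness = best_par[4],
    ratio_ant = mod$ratio_ant, ratio_post = mod$ratio_post,
    ratio_pooled = mod$ratio_pooled,
    e_ratio_nuc_cortex = mod$ratio_pooled,
    sse = best_sse,
    predicted = stats::setNames(best_pred,
                                c("kappa", "lambda", "mu", "nu")),
    scale = scale,
    surrogate_r2 = surface$surrogate_r2,
    at_boundary = any(best_par <= lower + tol | best_par >= upper - tol),
    c10_ref_kpa = surface$c10_ref,
    c10_nuc_inf_abs_kpa = NA_real_,
    condition = surface$design$condition
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Fit '%s': thickness %.2f mm, tau1 %.3g s, F %.3g, N %.3g | nucleus:cortex E-ratio %.3g, SSE %.4g%s\n",
    x$condition, x$thickness_mm, x$tau1_s, x$form_factor_f, x$n_stiffness,
    x$e_ratio_nuc_cortex, x$sse,
    if (isTRUE(x$at_boundary)) " [at design boundary]" else ""))
  if (is.finite(x$c10_nuc_inf_abs_kpa))
    cat(sprintf("  absolute C10_nuc_inf = %.3g kPa\n", x$c10_nuc_inf_abs_kpa))
  invisible(x)
}

#' Absolute modulus calibration from the relaxed force
#'
#' The oscillation observables fix only stiffness ratios (the test is
#' strain-controlled). The absolute scale is set in a second round by
#' matching the simulated post-relaxation force to the observed
#' condition-mean minimum force: force is proportional to the modulus
#' scale at fixed kinematics, so a single multiplicative factor
#' suffices.
#'
#' @param fit A [optimize_fit()] result.
#' @param observed_min_force_gf Condition-mean relaxed force, gf, > 0.
#' @param geom A [lens_geometry()] template (thickness taken from the
#'   fit).
#' @param protocol A [compression_protocol()].
#' @return The `fit_result` with `c10_nuc_inf_abs_kpa`,
#'   `force_scale_factor` and `simulated_min_force_gf` filled in.
#' @export
calibrate_scale <- function(fit, observed_min_force_gf, geom, protocol) {
  if (!is.finite(observed_min_force_gf) || observed_min_force_gf <= 0)
    stop("observed minimum force must be positive")
  geom$lt0_mm <- fit$thickness_mm
  mat <- material_model(c10_nuc_inf_kpa = fit$c10_ref_kpa,
                        tau1_s = fit$tau1_s,
                        form_factor_f = fit$form_factor_f,
                        n_stiffness = fit$n_stiffness)
  sim <- simulate_test(geom, mat, protocol, summary_fit = FALSE)
  fac <- observed_min_force_gf / sim$min_force_gf
  fit$force_scale_factor <- fac
  fit$simulated_min_force_gf <- sim$min_force_gf
  fit$c10_nuc_inf_abs_kpa <- fit$c10_ref_kpa * fac
  fit
}

#' Goodness of fit between observed and predicted region series
#'
#' `R^2 = 1 - SS_res / SS_tot` over the concatenated anterior, nuclear
#' and posterior series, reported as percent. The predicted series is
#' linearly interpolated onto the observed time base. Incremental
#' (OCE) observations are cumulated first when `observed_incremental`.
#'
#' @param observed_series,predicted_series `region_strain_series` data
#'   frames.
#' @param observed_incremental Cumulate the observed series (default
#'   `TRUE`: OCE series are per-frame-pair increments).
#' @param predicted_incremental Likewise for the predicted series
#'   (default `FALSE`: model series are referenced to one
#'   configuration).
#' @return R-squared in percent; `NA` (with a warning) when the observed
#'   series has zero variance.
#' @export
goodness_r2 <- function(observed_series, predicted_series,
                        observed_incremental = TRUE,
                        predicted_incremental = FALSE) {
  prep <- function(df, inc) {
    out <- df
    for (cn in c("eps_ant", "eps_nuc", "eps_post"))
      if (inc) out[[cn]] <- cumsum(df[[cn]])
    out
  }
  obs <- prep(observed_series, observed_incremental)
  pre <- prep(predicted_series, predicted_incremental)
  res <- tot <- 0
  for (cn in c("eps_ant", "eps_nuc", "eps_post")) {
    y <- obs[[cn]] - mean(obs[[cn]])
    p <- stats::approx(pre$time_s, pre[[cn]], xout = obs$time_s,
                       rule = 2)$y
    p <- p - mean(p)
    res <- res + sum((y - p)^2)
    tot <- tot + sum(y^2)
  }
  if (tot <= 0) {
    warning("observed series has zero variance: R2 undefined")
    return(NA_real_)
  }
  100 * (1 - res / tot)
}
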