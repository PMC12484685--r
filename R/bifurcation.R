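# Sweep-based fixed-point, stability and limit-cycle analysis of the
# mean-field model.  Numerical continuation is deliberately replaced by dense
# parameter sweeps with bisection refinement of fold locations.

active_vars <- function(mode) {
  switch(mode,
         full      = c("r_e", "r_i", "p_ee", "p_ie"),
         fixed_pee = c("r_e", "r_i", "p_ie"),
         fixed_pie = c("r_e", "r_i", "p_ee"))
}

# residual function in the active coordinates; frozen components taken
# from `base` state
reduced_fn <- function(mp, pp_ee, pp_ie, mode, base) {
  av <- active_vars(mode)
  function(x) {
    s <- base
    s[av] <- x
    meanfield_rhs(s, mp, pp_ee, pp_ie, mode)[av]
  }
}

num_jacobian <- function(fn, x, h = 1e-7) {
  k <- length(x)
  J <- matrix(0, k, k)
  for (j in seq_len(k)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

classify_eigs <- function(ev, tol = 1e-8) {
  re <- Re(ev)
  if (all(re < tol)) "stable"
  else if (all(re > -tol)) "unstable"
  else "saddle"
}

#' Locate fixed points of the mean-field model
#'
#' Exploits the model structure: at any equilibrium the efficacies sit at
#' their closed-form fixed points \eqn{\hat p(r_E)} and the inhibitory
#' activation solves a scalar monotone equation, so every equilibrium is a
#' root of a single function of `r_e`.  Roots are bracketed on a dense grid
#' of `r_e` and polished with Brent's method; duplicates are merged
#' (distance below `merge_tol`) and each root is classified by the
#' eigenvalues of the finite-difference Jacobian in the active coordinates
#' of the chosen mode.
#'
#' @inheritParams meanfield_rhs
#' @param p_frozen Value of the frozen efficacy in the reduced modes
#'   (`p_ee = 1` for `fixed_pee`, `p_ie = 0.11` for `fixed_pie` by default).
#' @param grid_n Number of `r_e` bracketing points.
#' @param merge_tol Distance below which roots are considered identical.
#' @return A data frame of class `"fp_set"` with one row per fixed point:
#'   state columns, `stability`, `max_re` (leading eigenvalue real part),
#'   `im_lead` (its imaginary part); eigenvalue vectors in
#'   `attr(, "eigenvalues")`.
#' @examples
#' mp <- mf_params()
#' fps <- find_fixed_points(mp, stp_params(theta = 0.5),
#'                          stp_params(theta = 0.5), mode = "fixed_pee")
#' @export
find_fixed_points <- function(mp, pp_ee, pp_ie, mode = "full",
                              p_frozen = NULL, grid_n = 400,
                              merge_tol = 1e-6) {
  mode <- match.arg(mode, mode_choices)
  if (is.null(p_frozen))
    p_frozen <- switch(mode, full = NA, fixed_pee = 1, fixed_pie = 0.11)
  sN <- sqrt(mp$N)

  pee_of <- function(r_e) if (mode == "fixed_pee") p_frozen
                          else plasticity_fixed_point(r_e, pp_ee)
  pie_of <- function(r_e) if (mode == "fixed_pie") p_frozen
                          else plasticity_fixed_point(r_e, pp_ie)
  # inhibitory equilibrium at given r_e: r_i - f(...) is strictly increasing
  ri_of <- function(r_e) {
    h <- function(r_i)
      r_i - transfer(sN * (mp$j_ie * pie_of(r_e) * r_e -
                           mp$j_ii * r_i + mp$i_i))
    uniroot(h, c(0, 1), tol = 1e-13)$root
  }
  g <- function(r_e)
    -r_e + transfer(sN * (mp$j_ee * pee_of(r_e) * r_e -
                          mp$j_ei * ri_of(r_e) + mp$i_e))

  grid <- seq(0, 1, length.out = grid_n)
  gv <- vapply(grid, g, numeric(1))
  roots <- numeric(0)
  for (i in which(gv[-length(gv)] * gv[-1] <= 0)) {
    if (gv[i] == 0 && i > 1) next   # counted at the left bracket
    r <- uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-13)$root
    if (!length(roots) || min(abs(roots - r)) > merge_tol)
      roots <- c(roots, r)
  }
  if (!length(roots))
    stop("no fixed point found; the system always has at least one",
         call. = FALSE)

  base <- c(r_e = 0, r_i = 0, p_ee = 1, p_ie = 1)
  if (mode == "fixed_pee") base[["p_ee"]] <- p_frozen
  if (mode == "fixed_pie") base[["p_ie"]] <- p_frozen
  av <- active_vars(mode)
  fn <- reduced_fn(mp, pp_ee, pp_ie, mode, base)
  states <- lapply(roots, function(r) {
    s <- base
    s[["r_e"]] <- r
    s[["r_i"]] <- ri_of(r)
    if (mode != "fixed_pee") s[["p_ee"]] <- pee_of(r)
    if (mode != "fixed_pie") s[["p_ie"]] <- pie_of(r)
    s
  })
  eigs <- lapply(states, function(s) {
    eigen(num_jacobian(fn, s[av]), only.values = TRUE)$values
  })
  df <- as.data.frame(do.call(rbind, states))
  df$stability <- vapply(eigs, classify_eigs, character(1))
  df$max_re <- vapply(eigs, function(e) max(Re(e)), numeric(1))
  df$im_lead <- vapply(eigs, function(e) {
    abs(Im(e))[which.max(Re(e))]
  }, numeric(1))
  df <- df[order(df$r_e), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("fp_set", "data.frame"),
            eigenvalues = eigs, mode = mode)
}

#' @export
print.fp_set <- function(x, ...) {
  cat(sprintf("%d fixed point(s), mode %s\n", nrow(x), attr(x, "mode")))
  print.data.frame(round(as.data.frame(x), 5))
  invisible(x)
}

count_fps <- function(theta, vary, mp, pp_ee, pp_ie, mode, p_frozen, grid_n) {
  if (vary == "theta_ee") pp_ee$theta <- theta else pp_ie$theta <- theta
  nrow(find_fixed_points(mp, pp_ee, pp_ie, mode, p_frozen, grid_n = grid_n))
}

#' Locate saddle-node (fold) bifurcations by sweep and bisection
#'
#' Counts fixed points along a monotone grid of one depression threshold and
#' refines every interval where the count changes by two (a stable/saddle
#' pair created or destroyed) by bisection down to `refine_tol`.
#'
#' @inheritParams find_fixed_points
#' @param vary Which threshold is swept: `"theta_ie"` or `"theta_ee"`.
#' @param theta_grid Monotone grid in \[0, 1\].
#' @param refine_tol Final bracket width.
#' @return Numeric vector of fold locations (possibly empty).
#' @export
sweep_saddle_node <- function(mp, pp_ee, pp_ie, mode = "full",
                              vary = c("theta_ie", "theta_ee"),
                              theta_grid = seq(0, 1, by = 0.05),
                              p_frozen = NULL, refine_tol = 1e-4,
                              grid_n = 400) {
  mode <- match.arg(mode, mode_choices)
  vary <- match.arg(vary)
  stopifnot(!is.unsorted(theta_grid))
  counts <- vapply(theta_grid, count_fps, integer(1), vary = vary,
                   mp = mp, pp_ee = pp_ee, pp_ie = pp_ie, mode = mode,
                   p_frozen = p_frozen, grid_n = grid_n)
  folds <- numeric(0)
  for (i in seq_len(length(theta_grid) - 1L)) {
    if (abs(counts[i + 1L] - counts[i]) < 2L) next
    lo <- theta_grid[i]; hi <- theta_grid[i + 1L]
    c_lo <- counts[i]
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      c_mid <- count_fps(mid, vary, mp, pp_ee, pp_ie, mode, p_frozen, grid_n)
      if (c_mid == c_lo) lo <- mid else hi <- mid
    }
    folds <- c(folds, (lo + hi) / 2)
  }
  folds
}

#' Detect a stable limit cycle by long integration
#'
#' Integrates the model, discards the first half of the run as transient, and
#' analyses the peaks of `r_e`.  A cycle is reported when sustained peaks of
#' non-vanishing amplitude persist; peak amplitudes are clustered (tolerance
#' `peak_cluster_tol`) to recognise period-doubled orbits, whose full period
#' is the mean inter-peak interval times the number of distinct peak levels.
#'
#' @inheritParams find_fixed_points
#' @param init Initial state; defaults to a mid-range state off any symmetry.
#' @param T Integration horizon (model units).
#' @param dt Output sampling of the integration.
#' @param amp_tol Peak-to-trough amplitude below which the trajectory is
#'   declared converged to a fixed point.
#' @param peak_cluster_tol Amplitude tolerance for clustering distinct peaks.
#' @return `NULL` if the trajectory converges to a fixed point, otherwise a
#'   list of class `"limit_cycle"` with `period` (model units),
#'   `frequency_hz` (full-cycle frequency, using `time_unit_ms`),
#'   `peak_rate_hz` (rate of individual peaks), `n_distinct_peaks`,
#'   `extrema` (per-variable min/max), `amplitude` and `trough` of `r_e`.
#' @export
find_limit_cycle <- function(mp, pp_ee, pp_ie, mode = "full",
                             p_frozen = NULL, init = NULL,
                             T = 1500, dt = 0.02, amp_tol = 1e-5,
                             peak_cluster_tol = 1e-3) {
  mode <- match.arg(mode, mode_choices)
  if (is.null(p_frozen))
    p_frozen <- switch(mode, full = NA, fixed_pee = 1, fixed_pie = 0.11)
  if (is.null(init)) {
    init <- c(r_e = 0.8, r_i = 0.5, p_ee = 0.5, p_ie = 0.5)
    if (mode == "fixed_pee") init[["p_ee"]] <- p_frozen
    if (mode == "fixed_pie") init[["p_ie"]] <- p_frozen
  }
  sim <- simulate_meanfield(init, mp, pp_ee, pp_ie, mode, T = T, dt_out = dt)
  keep <- sim$t >= T / 2
  x <- sim$r_e[keep]
  tt <- sim$t[keep]
  if (diff(range(x)) < amp_tol) return(NULL)
  dx <- diff(x)
  pk <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L
  if (length(pk) < 4L) return(NULL)
  peak_vals <- x[pk]
  if (diff(range(peak_vals)) > 0.5 * diff(range(x)))
    return(NULL)  # peaks not settled: treat as non-periodic at this horizon
  # cluster peak levels to count period multiplicity
  ord <- sort(peak_vals)
  breaks <- which(diff(ord) > peak_cluster_tol)
  n_distinct <- length(breaks) + 1L
  ipi <- mean(diff(tt[pk]))
  period <- ipi * n_distinct
  tu <- mp$time_unit_ms
  vars <- c("r_e", "r_i", "p_ee", "p_ie")
  extrema <- vapply(vars, function(v) {
    range(sim[[v]][keep])
  }, numeric(2))
  rownames(extrema) <- c("min", "max")
  structure(list(period = period,
                 frequency_hz = 1000 / (period * tu),
                 peak_rate_hz = 1000 / (ipi * tu),
                 n_distinct_peaks = n_distinct,
                 extrema = extrema,
                 amplitude = diff(range(x)),
                 trough = min(x)),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf(
    "Limit cycle: period %.3f units (%.2f Hz), %d distinct peak level(s)\n",
    x$period, x$frequency_hz, x$n_distinct_peaks))
  cat(sprintf("  r_e in [%.3f, %.3f]\n", x$extrema["min", "r_e"],
              x$extrema["max", "r_e"]))
  invisible(x)
}

#' Frequency band of population-event oscillations
#'
#' Sweeps the E-to-E depression threshold in the within-event reduced model
#' (`p_ie` frozen in the depressed state) and records, for every stable limit
#' cycle, its frequency and amplitude.  A cycle qualifies as a population
#' event rhythm when its trough returns to the low-activity state
#' (`trough <= trough_max`); near the Hopf boundary small cycles ring around
#' the high state without quiescent interludes and are reported but flagged
#' as non-qualifying.
#'
#' @inheritParams find_fixed_points
#' @param theta_grid Grid of `theta_ee` values.
#' @param p_ie Frozen E-to-I efficacy (depressed state).
#' @param trough_max Maximum cycle trough of `r_e` for an event-scale cycle.
#' @param ... Passed to [find_limit_cycle()].
#' @return Data frame with columns `theta_ee`, `frequency_hz`, `amplitude`,
#'   `trough`, `n_distinct_peaks`, `event_scale`.
#' @export
oscillation_band <- function(mp, pp_ee, pp_ie,
                             theta_grid = seq(0.1, 0.7, by = 0.05),
                             p_ie = 0.11, trough_max = 0.1, ...) {
  rows <- lapply(theta_grid, function(th) {
    pe <- pp_ee; pe$theta <- th
    lc <- find_limit_cycle(mp, pe, pp_ie, mode = "fixed_pie",
                           p_frozen = p_ie, ...)
    if (is.null(lc))
      return(data.frame(theta_ee = th, frequency_hz = NA_real_,
                        amplitude = NA_real_, trough = NA_real_,
                        n_distinct_peaks = NA_integer_, event_scale = FALSE))
    data.frame(theta_ee = th, frequency_hz = lc$frequency_hz,
               amplitude = lc$amplitude, trough = lc$trough,
               n_distinct_peaks = lc$n_distinct_peaks,
               event_scale = lc$trough <= trough_max)
  })
  do.call(rbind, rows)
}

# excitation threshold: smallest instantaneous bump in r_e from the stable
# low state that triggers a large excursion (r_e crossing 0.5); Inf if even
# a 0.5 bump stays low
excitation_threshold <- function(st, mp, pp_ee, pp_ie, probe_T = 300) {
  trig <- function(d) {
    s0 <- c(r_e = min(st$r_e[1] + d, 0.99), r_i = st$r_i[1],
            p_ee = st$p_ee[1], p_ie = st$p_ie[1])
    sim <- simulate_meanfield(s0, mp, pp_ee, pp_ie, "full", T = probe_T,
                              dt_out = 0.1)
    c(max(sim$r_e) > 0.5,
      sum(diff(sign(diff(sim$r_e))) == -2 & sim$r_e[-c(1, 2)] > 0.5))
  }
  if (!trig(0.5)[1]) return(list(threshold = Inf, n_peaks = 0L))
  lo <- 0; hi <- 0.5
  for (i in 1:9) {
    mid <- (lo + hi) / 2
    if (trig(mid)[1]) hi <- mid else lo <- mid
  }
  # count excursion peaks just above threshold
  res <- trig(min(hi + 0.05, 0.5))
  list(threshold = (lo + hi) / 2, n_peaks = res[2])
}

label_region <- function(fps, lc, mp, pp_ee, pp_ie, probe_T = 300,
                         excitable_max_kick = 0.075) {
  n_stable <- sum(fps$stability == "stable")
  n_unstable <- nrow(fps) - n_stable
  n_cycles <- if (is.null(lc)) 0L else 1L
  st <- fps[fps$stability == "stable", , drop = FALSE]
  label <- if (!is.null(lc)) {
    "oscillatory_limit_cycle"   # a coexisting cycle dominates the label
  } else if (n_stable >= 2L) {
    "bistable"
  } else if (!nrow(st)) {
    NA_character_
  } else if (st$r_e[1] >= 0.5) {
    "saturated"
  } else {
    # excitability probe: can a kick of the scale of rare finite-size
    # fluctuations trigger a full excursion?
    ex <- excitation_threshold(st, mp, pp_ee, pp_ie, probe_T)
    if (ex$threshold > excitable_max_kick) "monostable_low"
    else if (ex$n_peaks >= 2L) "excitable_rhythmic"
    else "excitable_arrhythmic"
  }
  list(label = label,
       counts = c(n_stable_fp = n_stable, n_unstable_fp = n_unstable,
                  n_stable_cycles = n_cycles))
}

#' Two-parameter map of dynamical regimes
#'
#' Classifies the full model on a grid of the two depression thresholds by
#' combining [find_fixed_points()] and [find_limit_cycle()] into a region
#' label: `monostable_low`, `bistable`, `oscillatory_limit_cycle`,
#' `excitable_rhythmic`, `excitable_arrhythmic` or `saturated`.  Individual
#' grid-point failures are recorded as `NA` labels, not fatal.
#'
#' @inheritParams find_fixed_points
#' @param theta_ee_grid,theta_ie_grid Grids in \[0, 1\].
#' @param T Integration horizon used for cycle detection.
#' @return Data frame with `theta_ee`, `theta_ie`, `label`, `n_stable_fp`,
#'   `n_unstable_fp`, `n_stable_cycles`.
#' @export
two_parameter_map <- function(mp, pp_ee, pp_ie,
                              theta_ee_grid = seq(0.1, 0.9, by = 0.1),
                              theta_ie_grid = seq(0.05, 0.9, by = 0.1),
                              T = 1200, grid_n = 400) {
  rows <- list()
  for (te in theta_ee_grid) for (ti in theta_ie_grid) {
    pe <- pp_ee; pe$theta <- te
    pi_ <- pp_ie; pi_$theta <- ti
    row <- tryCatch({
      fps <- find_fixed_points(mp, pe, pi_, "full", grid_n = grid_n)
      lc <- find_limit_cycle(mp, pe, pi_, "full", T = T)
      lab <- label_region(fps, lc, mp, pe, pi_)
      data.frame(theta_ee = te, theta_ie = ti, label = lab$label,
                 n_stable_fp = lab$counts[["n_stable_fp"]],
                 n_unstable_fp = lab$counts[["n_unstable_fp"]],
                 n_stable_cycles = lab$counts[["n_stable_cycles"]])
    }, error = function(e) {
      data.frame(theta_ee = te, theta_ie = ti, label = NA_character_,
                 n_stable_fp = NA_integer_, n_unstable_fp = NA_integer_,
                 n_stable_cycles = NA_integer_)
    })
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
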