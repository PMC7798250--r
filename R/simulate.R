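#' Deterministic time-course integration
#'
#' Integrates the amount-based ODE system with [deSolve::lsoda()] (a
#' stiff/non-stiff switching solver) on a dense uniform time grid.
#'
#' @param model a validated `kin_model`.
#' @param t_end end time (s), positive.
#' @param n_points number of output points (>= 2); >= 1000 recommended when
#'   peak-based metrics are taken from the trajectory.
#' @param rtol,atol relative / absolute integration tolerances (absolute
#'   tolerance in amount units, uM*um^3).
#' @return A `kin_trajectory`: list with `time`, `amounts` and `conc`
#'   (matrices, one column per species), `model`, and `diagnostics`
#'   (tolerances, solver success flag).
#' @export
integrate_model <- function(model, t_end, n_points = 1000,
                            rtol = 1e-8, atol = 1e-12) {
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0",
                                             call. = FALSE)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0", call. = FALSE)
  rhs <- assemble_rhs(model)
  y0 <- initial_amounts(model)
  times <- seq(0, t_end, length.out = max(2L, as.integer(n_points)))
  sol <- deSolve::lsoda(
    y = y0, times = times,
    func = function(t, y, parms) list(rhs(t, y)),
    rtol = rtol, atol = atol)
  istate <- attr(sol, "istate")[1]
  if (istate < 0 || nrow(sol) < length(times))
    stop("integration failed (istate = ", istate, ", reached t = ",
         sol[nrow(sol), 1], " of ", t_end, "); see deSolve diagnostics",
         call. = FALSE)
  amounts <- sol[, names(y0), drop = FALSE]
  spV <- species_volumes(model)
  conc <- sweep(amounts, 2, spV[colnames(amounts)], "/")
  structure(
    list(time = sol[, 1], amounts = amounts, conc = conc, model = model,
         diagnostics = list(rtol = rtol, atol = atol, istate = istate,
                            success = TRUE,
                            n_steps = attr(sol, "istate")[3])),
    class = "kin_trajectory")
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat("<kin_trajectory> ", length(x$time), " points, t in [0, ",
      max(x$time), "] s, species: ",
      paste(colnames(x$conc), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Turn a trajectory into a tidy data frame
#'
#' @param x a `kin_trajectory`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return Data frame with columns `time`, `species`, `amount`, `conc`.
#' @export
as.data.frame.kin_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  sp <- colnames(x$conc)
  data.frame(
    time = rep(x$time, times = length(sp)),
    species = rep(sp, each = length(x$time)),
    amount = as.vector(x$amounts),
    conc = as.vector(x$conc),
    stringsAsFactors = FALSE)
}

#' Equilibrium and transient metrics of a trajectory
#'
#' Requires the trajectory to actually be equilibrated: over the final 5%
#' of points, every species' concentration must vary by less than 0.1%
#' relative (of its dynamic range, or absolutely when the range is ~0);
#' otherwise an error advises a longer `t_end`. The equilibrium value is
#' the final point. `time_to_fraction` is the first time at which
#' `|C(t) - C_eq| <= (1 - f) * |C(0) - C_eq|`, i.e. the species has closed
#' fraction `f` of its gap to equilibrium.
#'
#' @param traj a `kin_trajectory`.
#' @param fraction the gap fraction `f`, in (0, 1); default 0.95.
#' @return Data frame, one row per species: `species`, `c0`, `c_eq`,
#'   `time_to_fraction`, `peak_conc`, `peak_time`, plus the `fraction`
#'   used.
#' @export
equilibrium_metrics <- function(traj, fraction = 0.95) {
  stopifnot(inherits(traj, "kin_trajectory"))
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be in (0, 1)", call. = FALSE)
  n <- length(traj$time)
  tail_idx <- seq.int(max(1L, ceiling(0.95 * n)), n)
  sp <- colnames(traj$conc)
  for (s in sp) {
    col <- traj$conc[, s]
    tail_span <- diff(range(col[tail_idx]))
    scale <- max(diff(range(col)), abs(col[n]), .Machine$double.eps)
    if (tail_span > 1e-3 * scale)
      stop("trajectory not equilibrated for species '", s,
           "' (tail still varies by ", signif(tail_span / scale, 3),
           " relative); increase t_end", call. = FALSE)
  }
  out <- lapply(sp, function(s) {
    col <- traj$conc[, s]
    c0 <- col[1]; c_eq <- col[n]
    gap0 <- abs(c0 - c_eq)
    hit <- which(abs(col - c_eq) <= (1 - fraction) * gap0)[1]
    peak_i <- which.max(col)[1]  # earliest global max
    data.frame(species = s, c0 = c0, c_eq = c_eq,
               time_to_fraction = traj$time[hit],
               peak_conc = col[peak_i], peak_time = traj$time[peak_i],
               fraction = fraction, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Steady state by long integration plus Newton polishing
#'
#' Integrates until the right-hand side is small, extending `t_end`
#' geometrically if needed, then polishes with damped Newton iterations on
#' a finite-difference Jacobian (rank-deficient Jacobians from conservation
#' relations are handled by a least-squares step, which moves only within
#' the reachable stoichiometric subspace).
#'
#' @param model a `kin_model`.
#' @param t_end initial integration horizon (s); extended up to
#'   `max_extensions` times by factors of 10.
#' @param atol steady-state criterion: `max |d(amount)/dt| < atol`.
#' @param rtol integration relative tolerance.
#' @param max_extensions how often to extend the horizon before giving up.
#' @return Named concentration vector (uM) at steady state, with the
#'   amounts in `attr(, "amounts")` and the residual norm in
#'   `attr(, "residual")`.
#' @export
steady_state <- function(model, t_end = 1000, atol = 1e-9, rtol = 1e-10,
                         max_extensions = 6) {
  rhs <- assemble_rhs(model)
  y <- initial_amounts(model)
  resid <- function(y) max(abs(rhs(0, y)))
  if (resid(y) >= atol) {
    t_cur <- t_end
    for (i in seq_len(max_extensions + 1L)) {
      traj <- integrate_model(model, t_cur, n_points = 200,
                              rtol = rtol, atol = atol * 1e-3)
      y <- traj$amounts[nrow(traj$amounts), ]
      if (resid(y) < atol * 100) break
      if (i > max_extensions)
        stop("no steady state found within integration budget (residual ",
             signif(resid(y), 3), " after t = ", t_cur, " s)", call. = FALSE)
      t_cur <- t_cur * 10
    }
  }
  # Newton polish
  n <- length(y)
  for (iter in 1:20) {
    f <- rhs(0, y)
    if (max(abs(f)) < atol) break
    J <- numeric_jacobian(function(z) rhs(0, z), y)
    step <- tryCatch(qr.solve(J, -f, tol = 1e-13),
                     error = function(e) qr.coef(qr(J, LAPACK = TRUE), -f))
    step[is.na(step)] <- 0
    cand <- y + step
    if (max(abs(rhs(0, cand))) < max(abs(f))) y <- cand else break
  }
  f <- rhs(0, y)
  if (max(abs(f)) >= atol)
    stop("steady state residual ", signif(max(abs(f)), 3),
         " did not reach atol = ", atol, call. = FALSE)
  conc <- to_concentrations(model, y)
  attr(conc, "amounts") <- y
  attr(conc, "residual") <- max(abs(f))
  conc
}

numeric_jacobian <- function(f, x, eps = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Exponential relaxation rate of a species
#'
#' Fits `log |C(t) - C_eq|` against time by least squares over the part of
#' the trajectory where the gap is still resolvable, returning the decay
#' rate lambda (1/s). For the linear two-compartment exchange this equals
#' `A*(kaf/V1 + kar/V2)` under area scaling and `kf + kr` under volume
#' scaling.
#'
#' @param traj a `kin_trajectory`.
#' @param species species id.
#' @param gap_window keep points whose remaining gap is within this
#'   relative band of the initial gap (default: between 90% and 1%).
#' @return The fitted rate (1/s).
#' @export
relaxation_rate <- function(traj, species, gap_window = c(0.9, 0.01)) {
  col <- traj$conc[, species]
  c_eq <- col[length(col)]
  gap <- abs(col - c_eq)
  g0 <- abs(col[1] - c_eq)
  if (g0 == 0) stop("species '", species, "' starts at equilibrium",
                    call. = FALSE)
  keep <- gap <= gap_window[1] * g0 & gap >= gap_window[2] * g0
  if (sum(keep) < 5)
    stop("too few points in the relaxation window; increase n_points",
         call. = FALSE)
  fit <- stats::lm(log(gap[keep]) ~ traj$time[keep])
  -unname(stats::coef(fit)[2])
}
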