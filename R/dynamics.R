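# Numerical dynamics: positivity-preserving integration, Poincare return
# maps, limit-cycle witnesses.

field_parts <- function(field) {
  f <- as_field(field)
  list(cx = f$dx$coeff, ax = f$dx$a, bx = f$dx$b,
       cy = f$dy$coeff, ay = f$dy$a, by = f$dy$b)
}

#' Integrate a planar power-law system
#'
#' Integration is performed in \eqn{(\log x, \log y)} with an adaptive
#' Dormand-Prince 5(4) scheme, so trajectories stay in the open positive
#' quadrant by construction.  Leaving the box
#' \eqn{[10^{-30}, 10^{30}]^2} is flagged as blow-up; `stop_y_below`
#' (default 0) stops the run when y drops below a threshold
#' (boundary convergence).
#'
#' @param field `crn_field`, `crn_system` or `crn_scaled`
#' @param start positive length-2 start point
#' @param t_end integration time
#' @param rtol,atol tolerances
#' @param store keep the full trajectory (default TRUE)
#' @param stop_y_below stop when y falls below this value
#' @param max_steps step budget
#' @return list with `times`, `x`, `y`, final state and a `status` string
#'   (`"completed"`, `"blowup"`, `"axis"`, ...)
#' @export
integrate_orbit <- function(field, start, t_end, rtol = 1e-10, atol = 1e-12,
                            store = TRUE, stop_y_below = 0,
                            max_steps = 5e6) {
  stopifnot(length(start) == 2, all(start > 0), t_end > 0)
  p <- field_parts(field)
  out <- cpp_integrate(p$cx, p$ax, p$bx, p$cy, p$ay, p$by,
                       start[1], start[2], t_end, rtol, atol,
                       as.integer(max_steps), log(1e30), store,
                       stop_y_below)
  out
}

#' Poincare return map on the section \{y = 1, x > 1\}
#'
#' Follows the orbit from (x0, 1) until it crosses the section again with
#' the same crossing orientation (sign of \eqn{\dot y}); crossing times are
#' localised by bisection inside the accepted integrator step.
#'
#' @param scaled a `crn_scaled` (or any field with equilibrium (1,1))
#' @param x0 start abscissa, > 1
#' @param n number of returns to compute
#' @param t_max give up after this much time (reported, not an error)
#' @param rtol,atol tolerances
#' @return list with `x` (return abscissae), `t` (crossing times),
#'   `period` (time of first return) and `status`
#' @export
poincare_return <- function(scaled, x0, n = 1, t_max = 1e4, rtol = 1e-12,
                            atol = 1e-13) {
  stopifnot(x0 > 1)
  p <- field_parts(scaled)
  out <- cpp_return_map(p$cx, p$ax, p$bx, p$cy, p$ay, p$by,
                        x0, as.integer(n), t_max, rtol, atol, log(1e6))
  out$period <- if (length(out$t) >= 1) out$t[1] else NA_real_
  out
}

#' Displacement of the return map at radius r0
#'
#' Numeric oracle for focal-value signs: returns
#' \eqn{P(1 + r_0) - (1 + r_0)} on the section \{y = 1, x > 1\}.  A center
#' gives (numerically) zero displacement at every radius.
#'
#' @param scaled a `crn_scaled` with a fine focus / center at (1,1)
#' @param r0 small positive radius, in (0, 0.1]
#' @param rtol,atol integrator tolerances
#' @return signed displacement (numeric scalar)
#' @export
return_map_displacement <- function(scaled, r0, rtol = 1e-12, atol = 1e-13) {
  stopifnot(r0 > 0, r0 <= 0.5)
  out <- poincare_return(scaled, 1 + r0, n = 1, rtol = rtol, atol = atol)
  if (!identical(out$status, "ok"))
    stop("no return found (status ", out$status,
         "): not a fine focus, or r0 too large")
  out$x[1] - (1 + r0)
}

#' Locate and classify limit cycles through the return map
#'
#' Scans the displacement \eqn{P(x) - x} on a grid of section abscissae,
#' refines each sign change by bisection, and classifies stability by the
#' numeric derivative of the return map at the fixed point.
#'
#' @param scaled a `crn_scaled` with equilibrium (1,1)
#' @param x_range section interval to scan (default c(1.02, 3))
#' @param n_grid grid size
#' @param rtol,atol tolerances
#' @return list of cycle witnesses (fixed point, period, stability,
#'   Floquet-like return-map slope)
#' @export
count_limit_cycles <- function(scaled, x_range = c(1.02, 3), n_grid = 60,
                               rtol = 1e-10, atol = 1e-12) {
  xs <- seq(x_range[1], x_range[2], length.out = n_grid)
  disp <- rep(NA_real_, n_grid)
  for (i in seq_along(xs)) {
    out <- poincare_return(scaled, xs[i], rtol = rtol, atol = atol)
    if (identical(out$status, "ok")) disp[i] <- out$x[1] - xs[i]
  }
  ok <- which(!is.na(disp))
  witnesses <- list()
  if (length(ok) >= 2) {
    for (j in seq_len(length(ok) - 1)) {
      i1 <- ok[j]; i2 <- ok[j + 1]
      if (i2 != i1 + 1) next
      if (disp[i1] == 0 || sign(disp[i1]) == sign(disp[i2])) next
      if (abs(disp[i1]) < 1e-9 && abs(disp[i2]) < 1e-9) next  # center noise
      g <- function(x) {
        out <- poincare_return(scaled, x, rtol = rtol, atol = atol)
        if (!identical(out$status, "ok")) return(NA_real_)
        out$x[1] - x
      }
      root <- tryCatch(uniroot(g, c(xs[i1], xs[i2]), tol = 1e-10),
                       error = function(e) NULL)
      if (is.null(root)) next
      xstar <- root$root
      hh <- max(1e-4, 1e-4 * xstar)
      dp <- g(xstar + hh); dm <- g(xstar - hh)
      slope <- 1 + (dp - dm) / (2 * hh)      # return-map derivative
      per <- poincare_return(scaled, xstar, rtol = rtol, atol = atol)$period
      witnesses[[length(witnesses) + 1]] <-
        list(fixed_point = xstar, period = per,
             stability = if (abs(slope) < 1) "stable" else "unstable",
             floquet_ratio = slope)
    }
  }
  witnesses
}

#' Homoclinic-region probe for the reversible chain family
#'
#' For p > 0 > q with p + q > 0 the closed-orbit region of the reversible
#' center family is bounded: all closed orbits lie inside the square
#' \eqn{[0, L]^2} with \eqn{L = (1 - p/q)^{1/(p+q)}}, verified here by
#' sampling \eqn{\dot x < 0} on the segment \{x = L, 0 < y < L\}.  For
#' p + q < 0 the region is unbounded.
#'
#' @param p,q exponents with p > 0 > q
#' @param n_samples sample count on the segment
#' @return list with `bounded_region`, `box_bound` (L or NA) and the
#'   sampled maximum of \eqn{\dot x} on the segment
#' @export
homoclinic_probe <- function(p, q, n_samples = 100) {
  stopifnot(p > 0, q < 0)
  if (p + q < 0)
    return(list(bounded_region = FALSE, box_bound = NA_real_,
                max_dx_on_segment = NA_real_))
  L <- (1 - p / q)^(1 / (p + q))
  fld <- fixture_reversible_42_scaled(p, q)$field
  ys <- seq(L / (n_samples + 1), L * n_samples / (n_samples + 1),
            length.out = n_samples)
  dx <- eval_field(fld, rep(L, n_samples), ys)$dx
  list(bounded_region = all(dx < 0), box_bound = L,
       max_dx_on_segment = max(dx))
}
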