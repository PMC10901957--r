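# Center and global-stability certificates: monomial Bendixson-Dulac test,
# reversible-symmetry centers, Lienard centers and the center-realizing
# rate-constant construction.

#' Feasible Dulac exponent interval for a cyclic exponent sequence
#'
#' For the quadrangle cycle with Dulac function \eqn{h = x^{-\alpha}
#' y^{-\beta}}, the x-part of the divergence is one-signed iff
#' \eqn{(\alpha - a_i)(a_i - a_{i+1}) \le 0} for all i (cyclically).  The
#' feasible set is the interval
#' \eqn{[\max\{a_i : a_i < a_{i+1}\}, \min\{a_i : a_i > a_{i+1}\}]},
#' empty when the lower end exceeds the upper.
#'
#' @param a numeric length-4 cyclic sequence
#' @return list with `lower`, `upper`, `empty`, `chosen` (midpoint, or the
#'   single feasible point) and `strict` (whether some constraint is strict
#'   at `chosen`)
#' @export
dulac_exponent_interval <- function(a) {
  stopifnot(length(a) == 4)
  nxt <- c(a[-1], a[1])
  lo <- suppressWarnings(max(a[a < nxt]))
  hi <- suppressWarnings(min(a[a > nxt]))
  if (!is.finite(lo)) lo <- -Inf
  if (!is.finite(hi)) hi <- Inf
  empty <- lo > hi
  chosen <- NA_real_
  strict <- FALSE
  if (!empty) {
    chosen <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
              else if (is.finite(lo)) lo else if (is.finite(hi)) hi else 0
    strict <- any((chosen - a) * (a - nxt) < 0)
  }
  list(lower = lo, upper = hi, empty = empty, chosen = chosen,
       strict = strict)
}

#' Bendixson-Dulac certificate for a quadrangle cycle
#'
#' Searches for a monomial Dulac function \eqn{h = x^{-\alpha} y^{-\beta}}
#' making the divergence of (hf, hg) non-positive with at least one strict
#' term, which precludes periodic orbits for every choice of rate constants
#' and hence certifies global asymptotic stability of the unique positive
#' equilibrium.  Also reports, for each coordinate, whether the obstruction
#' pattern \eqn{a_i < a_{i+3} < a_{i+1} < a_{i+2}} (with \eqn{a_i}
#' minimal) holds, and at which cyclic index.
#'
#' @param net quadrangle-cycle `crn_network` or `crn_system`
#' @return list with `verdict` (`"globally_stable_all_kappa"` or
#'   `"inconclusive"`), `alpha_interval`, `beta_interval`, `chosen`,
#'   `bad_pattern_a`, `bad_pattern_b` (cyclic index of the pattern or NA)
#' @export
dulac_test_quadrangle <- function(net) {
  if (inherits(net, "crn_system")) net <- net$network
  if (classify_network(net) != "quadrangle_cycle")
    stop("dulac_test_quadrangle needs a quadrangle cycle")
  v <- vertex_matrix(net)
  ia <- dulac_exponent_interval(v[, 1])
  ib <- dulac_exponent_interval(v[, 2])
  feasible <- !ia$empty && !ib$empty
  strict <- feasible && (ia$strict || ib$strict)
  bad <- function(s) {
    nxt <- function(i) (i - 1) %% 4 + 1
    for (j in 1:4) {
      idx <- nxt(j + c(0, 3, 1, 2))
      if (s[idx[1]] < s[idx[2]] && s[idx[2]] < s[idx[3]] &&
          s[idx[3]] < s[idx[4]]) return(j)
    }
    NA_integer_
  }
  list(verdict = if (strict) "globally_stable_all_kappa" else "inconclusive",
       alpha_interval = ia, beta_interval = ib,
       chosen = if (strict) c(alpha = ia$chosen, beta = ib$chosen) else NULL,
       bad_pattern_a = bad(v[, 1]), bad_pattern_b = bad(v[, 2]))
}

#' Divergence of the Dulac-multiplied quadrangle field, divided by h
#'
#' Evaluates \eqn{\mathrm{div}(hf, hg)/h} at positive points for
#' \eqn{h = x^{-\alpha} y^{-\beta}}:
#' \eqn{\sum_i (\alpha - a_i)(a_i - a_{i+1}) \kappa_i x^{a_i - 1} y^{b_i} +
#' \sum_i (\beta - b_i)(b_i - b_{i+1}) \kappa_i x^{a_i} y^{b_i - 1}}.
#'
#' @param sys quadrangle-cycle `crn_system`
#' @param alpha,beta Dulac exponents
#' @param x,y positive evaluation points (vectorised)
#' @return numeric vector
#' @export
dulac_divergence <- function(sys, alpha, beta, x, y) {
  stopifnot(inherits(sys, "crn_system"))
  v <- vertex_matrix(sys$network)
  k <- sys$kappa
  out <- 0
  for (i in 1:4) {
    ip <- i %% 4 + 1
    out <- out +
      (alpha - v[i, 1]) * (v[i, 1] - v[ip, 1]) * k[i] *
        x^(v[i, 1] - 1) * y^v[i, 2] +
      (beta - v[i, 2]) * (v[i, 2] - v[ip, 2]) * k[i] *
        x^v[i, 1] * y^(v[i, 2] - 1)
  }
  out
}

#' Time-reversal symmetry check across the diagonal
#'
#' Returns TRUE iff the field has the form \eqn{\dot x = f(x, y)},
#' \eqn{\dot y = -f(y, x)}: the dy term set must equal the negated,
#' coordinate-swapped dx term set exactly.
#'
#' @param field `crn_field`, `crn_scaled` or `crn_system`
#' @return logical
#' @export
reversibility_check <- function(field) {
  f <- as_field(field)
  want <- collect_terms(data.frame(coeff = -f$dx$coeff,
                                   a = f$dx$b, b = f$dx$a))
  have <- f$dy
  if (nrow(want) != nrow(have)) return(FALSE)
  o1 <- order(want$a, want$b); o2 <- order(have$a, have$b)
  all(abs(want$a[o1] - have$a[o2]) < 1e-12) &&
    all(abs(want$b[o1] - have$b[o2]) < 1e-12) &&
    all(abs(want$coeff[o1] - have$coeff[o2]) <=
          1e-12 * pmax(1, abs(want$coeff[o1])))
}

#' Reversible-center certificate for three independent reactions
#'
#' Checks the sufficient conditions under which the scaled three-reaction
#' system with sources (0,0), (p,q), (q,p) is reversible across the
#' diagonal and (1,1) is a center: (i) \eqn{p^2 > q^2}; (ii) the sign chain
#' \eqn{\mathrm{sgn}\,c_1 = -\mathrm{sgn}\,d_1 = \mathrm{sgn}\,d_2 =
#' -\mathrm{sgn}\,c_3 \ne 0}; (iii) \eqn{\mathrm{sgn}\,c_2 =
#' -\mathrm{sgn}\,d_3}; (iv) \eqn{K = -c_1/d_1}; and, when
#' \eqn{c_2 \ne 0}, the ratio ordering
#' \eqn{|d_3/c_3| < |d_1/c_1| < |d_2/c_2|} together with the
#' geometric-mean condition \eqn{|d_1/c_1| = \sqrt{|d_2/c_2|\,|d_3/c_3|}}.
#' On success the assembled scaled field passes [reversibility_check()].
#'
#' @param p,q source exponents with `|p| != |q|`
#' @param c,d length-3 reaction-vector components
#' @return on success a certificate list (`ok = TRUE`, kind
#'   `"reversible"`, `K`, `lam`, `kbar`, `scaled`); on failure `ok = FALSE`
#'   with `failed_condition` naming the first violated condition
#' @export
reversible_center_three_reactions <- function(p, q, c, d) {
  fail <- function(cond) list(ok = FALSE, failed_condition = cond)
  if (!(p^2 > q^2)) return(fail("condition (i): p^2 > q^2"))
  s1 <- sign(c[1])
  if (s1 == 0 || sign(d[1]) != -s1 || sign(d[2]) != s1 ||
      sign(c[3]) != -s1)
    return(fail("condition (ii): sign chain"))
  if (sign(c[2]) != -sign(d[3]))
    return(fail("condition (iii): sgn c2 = -sgn d3"))
  K <- -c[1] / d[1]
  if (K <= 0) return(fail("condition (iv): K = -c1/d1 positive"))
  if (c[2] != 0) {
    r1 <- abs(d[1] / c[1]); r2 <- abs(d[2] / c[2]); r3 <- abs(d[3] / c[3])
    if (!(r3 < r1 && r1 < r2))
      return(fail("ratio ordering |d3/c3| < |d1/c1| < |d2/c2|"))
    if (abs(r1 - sqrt(r2 * r3)) > 1e-9 * r1)
      return(fail("geometric-mean condition"))
  }
  cr <- cross_products(c, d)
  if (!all(cr > 0) && !all(cr < 0))
    return(fail("cross products do not share a sign"))
  lam <- if (all(cr > 0)) 1 else -1
  kbar <- lam * cr
  if ((1 / lam) * K * (p^2 - q^2) <= 0)
    return(fail("K (p^2 - q^2) / lambda positive"))
  # the three reversibility identities tying the scaled coefficients
  res <- c(c[1] + K * d[1],
           c[2] * kbar[2] + K * d[3] * kbar[3],
           c[3] * kbar[3] + K * d[2] * kbar[2])
  if (max(abs(res)) > 1e-9 * max(1, max(abs(kbar))))
    return(fail("scaled-coefficient identities"))
  scaled <- fixture_reversible_52_scaled(p, q, c, d, K = K)
  if (!reversibility_check(scaled))
    return(fail("assembled field is not reversible"))
  list(ok = TRUE, kind = "reversible", K = K, lam = lam, kbar = kbar,
       residuals = res, scaled = scaled)
}

#' Rate constants realizing a reversible center in the unscaled system
#'
#' Given data satisfying the reversible-center conditions, any
#' \eqn{\kappa_1} works and the center is realized exactly when
#' \eqn{\kappa_3/\kappa_2 = -\frac{c_2}{d_3}(-c_1/d_1)^{p-q-1}}.  The
#' construction is verified by computing the equilibrium of the unscaled
#' system, scaling it to (1,1), and re-running the reversibility check.
#'
#' @param p,q,c,d as in [reversible_center_three_reactions()]
#' @param kappa1 free rate constant of the first reaction
#' @param kappa2 free scale of the second rate constant
#' @param verify run the verification pipeline (default TRUE)
#' @return list with `kappa` (length 3) and, when verified, the scaled
#'   system
#' @export
center_rate_constants <- function(p, q, c, d, kappa1 = 1, kappa2 = 1,
                                  verify = TRUE) {
  cert <- reversible_center_three_reactions(p, q, c, d)
  if (!isTRUE(cert$ok))
    stop("preconditions fail: ", cert$failed_condition)
  ratio <- -(c[2] / d[3]) * (-c[1] / d[1])^(p - q - 1)
  kappa <- c(kappa1, kappa2, kappa2 * ratio)
  if (any(kappa <= 0)) stop("derived rate constants are not positive")
  out <- list(kappa = kappa)
  if (verify) {
    sys <- reaction_system(rbind(c(0, 0), c(p, q), c(q, p)),
                           cbind(c, d), kappa)
    eqr <- three_reaction_equilibrium(sys)
    if (!eqr$exists) stop("verification failed: no positive equilibrium")
    scaled <- scale_to_unit(sys, eqr$point)
    if (!reversibility_check(scaled))
      stop("verification failed: scaled system is not reversible")
    out$scaled <- scaled
    out$equilibrium <- eqr$point
  }
  out
}

lienard_pattern_ok <- function(scaled) {
  # terms with zero coefficient may be absent; every present exponent pair
  # must belong to the required source pattern
  want <- rbind(c(1, 0), c(0, -1 / 2), c(0, -2))
  ok <- function(tt) {
    nrow(tt) >= 2 && all(apply(tt, 1, function(r)
      any(abs(want[, 1] - r["a"]) < 1e-12 & abs(want[, 2] - r["b"]) < 1e-12)))
  }
  ok(scaled$field$dx[c("a", "b")]) && ok(scaled$field$dy[c("a", "b")])
}

lienard_coeffs <- function(scaled) {
  if (!lienard_pattern_ok(scaled))
    stop("wrong exponent pattern: need sources (1,0), (0,-1/2), (0,-2)")
  f <- scaled$field
  pick <- function(tt, a, b) {
    i <- which(abs(tt$a - a) < 1e-12 & abs(tt$b - b) < 1e-12)
    if (length(i) == 0) return(0)
    tt$coeff[i]
  }
  list(A1 = pick(f$dx, 1, 0),          # c1 kbar1
       A2 = pick(f$dx, 0, -1 / 2),     # c2 kbar2
       A3 = pick(f$dx, 0, -2),         # c3 kbar3
       B1 = pick(f$dy, 1, 0),          # K d1 kbar1
       B2 = pick(f$dy, 0, -1 / 2),     # K d2 kbar2
       B3 = pick(f$dy, 0, -2))         # K d3 kbar3
}

#' Lienard form of the scaled three-reaction system with sources
#' (1,0), (0,-1/2), (0,-2)
#'
#' Differentiating the y-equation once turns the shifted system into
#' \eqn{\ddot y + f(y)\dot y + g(y) = 0}; returns f, g and their
#' antiderivatives F, G (normalized to F(0) = G(0) = 0) as R functions
#' together with their coefficients.
#'
#' @param scaled a `crn_scaled` with the required exponent pattern,
#'   carrying `kbar`, `K` and `lam`
#' @return list of functions `f`, `g`, `F`, `G` and coefficient list
#' @export
lienard_transform <- function(scaled) {
  co <- lienard_coeffs(scaled)
  if (is.null(scaled$kbar) || !is.finite(scaled$lam))
    stop("scaled system must carry kbar and lam")
  gc <- scaled$K * prod(scaled$kbar[1:3]) / scaled$lam
  f <- function(y) -co$A1 + (1 / 2) * co$B2 * (y + 1)^(-3 / 2) +
    2 * co$B3 * (y + 1)^(-3)
  g <- function(y) gc * ((y + 1)^(-1 / 2) - (y + 1)^(-2))
  Fb <- function(x) -co$A1 * x - co$B2 * ((x + 1)^(-1 / 2) - 1) -
    co$B3 * ((x + 1)^(-2) - 1)
  Gb <- function(x) gc * (2 * (x + 1)^(1 / 2) + (x + 1)^(-1) - 3)
  list(f = f, g = g, F = Fb, G = Gb,
       coefficients = c(co, list(g_scale = gc)))
}

#' Lienard center certificate
#'
#' Checks \eqn{K/\lambda > 0} and the balance
#' \eqn{c_1\bar\kappa_1 = K d_2 \bar\kappa_2 = 4 K d_3 \bar\kappa_3 \ne 0};
#' under it, \eqn{F = \Phi \circ G} with \eqn{\Phi(z) = \alpha_\Phi z^2 +
#' \beta_\Phi z}, which by the composition criterion certifies a center.
#' The \eqn{\Phi} coefficients are computed from the closed forms and
#' independently re-fitted by least squares on sampled (G, F) pairs; both
#' must agree.
#'
#' @param scaled a `crn_scaled` with the required exponent pattern
#' @param n_samples sample points for the composition residual
#' @return certificate list (`ok`, kind `"lienard"`, `alpha_phi`,
#'   `beta_phi`, `max_residual`) or failure naming the broken equality
#' @export
lienard_center_check <- function(scaled, n_samples = 50) {
  fail <- function(cond) list(ok = FALSE, failed_condition = cond)
  co <- lienard_coeffs(scaled)
  if (!(scaled$K / scaled$lam > 0)) return(fail("K/lambda > 0"))
  sc <- max(abs(co$A1), 1e-12)
  if (abs(co$A1) < 1e-12) return(fail("c1 kbar1 nonzero"))
  if (abs(co$A1 - co$B2) > 1e-9 * sc)
    return(fail("c1 kbar1 = K d2 kbar2"))
  if (abs(co$A1 - 4 * co$B3) > 1e-9 * sc)
    return(fail("c1 kbar1 = 4 K d3 kbar3"))
  lt <- lienard_transform(scaled)
  denom <- scaled$K * prod(scaled$kbar[1:3])
  alpha_phi <- -(scaled$lam^2 / 4) * co$A1 / denom^2
  beta_phi <- -(3 * scaled$lam / 2) * co$A1 / denom
  xs <- seq(-0.6, 1.5, length.out = n_samples)
  Gv <- lt$G(xs); Fv <- lt$F(xs)
  resid <- Fv - (alpha_phi * Gv^2 + beta_phi * Gv)
  scF <- max(abs(Fv), 1)
  if (max(abs(resid)) > 1e-10 * scF)
    return(fail("F = Phi o G composition residual"))
  fit <- qr.solve(cbind(Gv^2, Gv), Fv)
  if (abs(fit[1] - alpha_phi) > 1e-8 * max(1, abs(alpha_phi)) ||
      abs(fit[2] - beta_phi) > 1e-8 * max(1, abs(beta_phi)))
    return(fail("least-squares Phi refit disagrees with closed form"))
  list(ok = TRUE, kind = "lienard", alpha_phi = alpha_phi,
       beta_phi = beta_phi, max_residual = max(abs(resid)))
}
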