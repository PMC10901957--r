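# Hopf loci (trace = 0) and degenerate Hopf points (L1 = L2 = L3 = 0) of
# the parametric families, plus the perturbation schedules that bifurcate
# one to three small limit cycles.

#' Trace-zero (Hopf) locus of a named family
#'
#' Closed forms: the quadrangle family has
#' \eqn{\gamma = b_4^2 - 3 b_4 + 6 + 1/K}; the chain family has
#' \eqn{K = 2/(r - q(2q+1))} (valid for \eqn{r > q(2q+1)}); the
#' three-reaction family has \eqn{K = a/(1 + bd)}; the zigzag network has
#' trace \eqn{5\kappa - 9}, so \eqn{\kappa = 9/5}.
#'
#' @param family `"quadrangle_32"`, `"chain_41"`, `"three_51"` or
#'   `"zigzag"`
#' @param ... free parameters of the family (e.g. `K =` and `b4 =` for the
#'   quadrangle; `q =, r =` for the chain; `a =, b =, d =` for three_51)
#' @return list with `constraint` (text), `solved` (named parameter value)
#'   and `trace` at the solved point (numerically zero)
#' @export
hopf_locus <- function(family, ...) {
  p <- list(...)
  out <- switch(family,
    quadrangle_32 = {
      b4 <- if (is.null(p$b4)) 5 else p$b4
      if (is.null(p$K)) stop("quadrangle_32 locus needs K")
      g <- (b4^2 - 3 * b4 + 6) + 1 / p$K
      sc <- fixture_quadrangle_32_scaled(p$K, b4, gamma = g)
      list(constraint = "gamma = b4^2 - 3 b4 + 6 + 1/K",
           solved = c(gamma = g), scaled = sc)
    },
    chain_41 = {
      if (is.null(p$q) || is.null(p$r)) stop("chain_41 locus needs q and r")
      if (p$r <= p$q * (2 * p$q + 1))
        stop("no positive trace-zero K in the stated domain (needs r > q(2q+1))")
      K <- 2 / (p$r - p$q * (2 * p$q + 1))
      list(constraint = "K = 2/(r - q(2q+1))", solved = c(K = K),
           scaled = fixture_chain_41_scaled(p$q, p$r, K))
    },
    three_51 = {
      if (is.null(p$a) || is.null(p$b) || is.null(p$d))
        stop("three_51 locus needs a, b, d")
      K <- p$a / (1 + p$b * p$d)
      list(constraint = "K = a/(1 + b d)", solved = c(K = K),
           scaled = fixture_three_51_scaled(p$a, p$d, b = p$b, K = K))
    },
    zigzag = {
      list(constraint = "trace = 5 kappa - 9", solved = c(kappa = 9 / 5),
           scaled = NULL)
    },
    stop("unsupported family: ", family))
  tr <- if (!is.null(out$scaled)) {
    J <- field_jacobian(out$scaled, 1, 1); J[1, 1] + J[2, 2]
  } else {
    sys <- fixture_zigzag(out$solved[["kappa"]])
    s <- 2 - out$solved[["kappa"]]
    J <- field_jacobian(mass_action_field(sys), 1 / sqrt(s), sqrt(s))
    J[1, 1] + J[2, 2]
  }
  out$trace <- tr
  if (abs(tr) > 1e-10) stop("trace does not vanish at the solved point")
  out
}

#' Damped Newton iteration with finite differences (2-D)
#' @keywords internal
newton2 <- function(F, x0, tol = 1e-12, h = 1e-7, max_iter = 60) {
  x <- x0
  fv <- F(x); nf <- sqrt(sum(fv^2))
  for (it in seq_len(max_iter)) {
    if (nf < tol) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      dx <- numeric(2); dx[j] <- h * max(1, abs(x[j]))
      J[, j] <- (F(x + dx) - F(x - dx)) / (2 * dx[j])
    }
    step <- solve(J, -fv)
    lam <- 1
    repeat {
      x2 <- x + lam * step
      f2 <- F(x2); n2 <- sqrt(sum(f2^2))
      if (n2 < nf || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- x2; fv <- f2; nf <- n2
  }
  list(root = x, residual = nf, converged = nf < tol * 100)
}

#' Degenerate-Hopf parameter searches
#'
#' Root-finding on focal values along the trace-zero loci of the families:
#' \describe{
#' \item{`quadrangle_32`, kill `"L1"`}{root of L1(K) in a bracket (default
#'   (0.01, 0.5)); returns K0.}
#' \item{`quadrangle_32`, kill `"L2"`}{joint root of (L1, L2) over
#'   (K, b4) with gamma eliminated by trace zero; seeded near
#'   (0.09, 4.76).}
#' \item{`chain_41`, kill `"L1"`}{root of L1 in r for given q (bracket
#'   above q(2q+1)); matches the closed form
#'   \eqn{r = q(4q^2+16q+7)/(3(1-2q))}.}
#' \item{`chain_41`, kill `"L2"`}{root of L2(q) on the L1 = 0 curve over
#'   (0, 1/2); returns q = 1/4.}
#' \item{`three_51`, kill `"L2"`}{root of L2 along the L1 = 0 curve
#'   (b eliminated), in `d` for fixed `a` or in `a` for fixed `d`.}
#' \item{`three_51`, kill `"L3"`}{joint root of (L2, L3) over (a, d) with b
#'   and K eliminated; seeded near (1.01, 3.29).}
#' }
#'
#' @param family family name
#' @param target which focal value to kill (`"L1"`, `"L2"`, `"L3"`)
#' @param bracket interval for 1-D searches
#' @param seed_point start for 2-D searches
#' @param ... fixed family parameters (e.g. `q =` for chain_41; `a =` or
#'   `d =` for three_51)
#' @return list with `root` (named), `residual`, and the focal values at
#'   the root
#' @export
degenerate_hopf_search <- function(family, target = "L1", bracket = NULL,
                                   seed_point = NULL, ...) {
  p <- list(...)
  if (family == "quadrangle_32" && target == "L1") {
    if (is.null(bracket)) bracket <- c(0.01, 0.5)
    b4 <- if (is.null(p$b4)) 5 else p$b4
    f <- function(K) focal_values(fixture_quadrangle_32_scaled(K, b4),
                                  k_max = 1)$L[1]
    r <- uniroot(f, bracket, tol = 1e-13)
    fv <- focal_values(fixture_quadrangle_32_scaled(r$root, b4), k_max = 2)
    return(list(root = c(K = r$root), residual = abs(fv$L[1]), L = fv$L))
  }
  if (family == "quadrangle_32" && target == "L2") {
    if (is.null(seed_point)) seed_point <- c(0.09, 4.76)
    F <- function(v) focal_values(
      fixture_quadrangle_32_scaled(v[1], v[2]), k_max = 2)$L
    out <- newton2(F, seed_point)
    if (!out$converged) stop("no convergence in (K, b4) search")
    fv <- focal_values(fixture_quadrangle_32_scaled(out$root[1], out$root[2]),
                       k_max = 3)
    return(list(root = c(K = out$root[1], b4 = out$root[2]),
                residual = out$residual, L = fv$L))
  }
  if (family == "chain_41" && target == "L1") {
    q <- p$q
    if (is.null(q)) stop("chain_41 L1 search needs q")
    if (is.null(bracket)) bracket <- q * (2 * q + 1) + c(1e-3, 20)
    f <- function(r) focal_values(fixture_chain_41_scaled(q, r),
                                  k_max = 1)$L[1]
    r <- uniroot(f, bracket, tol = 1e-13)
    return(list(root = c(r = r$root), residual = abs(f(r$root)),
                closed_form = q * (4 * q^2 + 16 * q + 7) / (3 * (1 - 2 * q))))
  }
  if (family == "chain_41" && target == "L2") {
    if (is.null(bracket)) bracket <- c(0.05, 0.45)
    f <- function(q) {
      r <- q * (4 * q^2 + 16 * q + 7) / (3 * (1 - 2 * q))
      focal_values(fixture_chain_41_scaled(q, r), k_max = 2)$L[2]
    }
    r <- uniroot(f, bracket, tol = 1e-13)
    q <- r$root
    rr <- q * (4 * q^2 + 16 * q + 7) / (3 * (1 - 2 * q))
    fv <- focal_values(fixture_chain_41_scaled(q, rr), k_max = 3)
    return(list(root = c(q = q, r = rr,
                         K = 2 / (rr - q * (2 * q + 1))),
                residual = abs(fv$L[2]), L = fv$L))
  }
  if (family == "three_51" && target == "L2") {
    if (!is.null(p$a)) {
      a <- p$a
      if (is.null(bracket)) bracket <- c(2, 6)
      f <- function(d) focal_values(fixture_three_51_scaled(a, d),
                                    k_max = 2)$L[2]
      r <- uniroot(f, bracket, tol = 1e-13)
      return(list(root = c(d = r$root), residual = abs(f(r$root))))
    }
    if (!is.null(p$d)) {
      d <- p$d
      if (is.null(bracket)) bracket <- c(0.5, 2)
      f <- function(a) focal_values(fixture_three_51_scaled(a, d),
                                    k_max = 2)$L[2]
      r <- uniroot(f, bracket, tol = 1e-13)
      return(list(root = c(a = r$root), residual = abs(f(r$root))))
    }
    stop("three_51 L2 search needs a fixed a or d")
  }
  if (family == "three_51" && target == "L3") {
    if (is.null(seed_point)) seed_point <- c(1.01, 3.29)
    F <- function(v) focal_values(fixture_three_51_scaled(v[1], v[2]),
                                  k_max = 3)$L[2:3]
    out <- newton2(F, seed_point)
    if (!out$converged) stop("no convergence in (a, d) search")
    a <- out$root[1]; d <- out$root[2]
    b <- (-2 + a * (1 + sqrt(1 + 8 * d))) / (2 * d)
    fv <- focal_values(fixture_three_51_scaled(a, d), k_max = 4)
    return(list(root = c(a = a, b = b, d = d), residual = out$residual,
                L = fv$L))
  }
  stop("unsupported family/target combination: ", family, "/", target)
}

#' Perturbation schedules bifurcating small limit cycles
#'
#' Emits the step order and directions that unfold a degenerate Hopf point
#' into nested limit cycles, with the cycle count and stability expected
#' after each step (cycles listed from the innermost, in creation order).
#'
#' @param family `"chain_41"`, `"quadrangle_32"` or `"zigzag"`
#' @param degenerate_point named parameter vector (defaults to the family's
#'   degenerate point)
#' @return list with `steps` (list of parameter, direction,
#'   maintained relations, expected cycles after the step) and `notes`
#' @export
perturbation_schedule <- function(family, degenerate_point = NULL) {
  if (family == "chain_41") {
    if (is.null(degenerate_point))
      degenerate_point <- c(q = 1 / 4, r = 15 / 8, K = 4 / 3)
    return(list(
      family = family, point = degenerate_point,
      signature = "trace = L1 = L2 = 0, L3 < 0 (stable equilibrium)",
      steps = list(
        list(parameter = "q", direction = "increase",
             maintain = c("r = q(4q^2+16q+7)/(3(1-2q))",
                          "K = 2/(r - q(2q+1))"),
             effect = "L2 > 0: equilibrium unstable",
             cycles_after = list(count = 1, stability = "stable (Gamma2)")),
        list(parameter = "r", direction = "decrease",
             maintain = c("K = 2/(r - q(2q+1))"),
             effect = "L1 < 0: equilibrium stable again",
             cycles_after = list(count = 2,
                                 stability = "unstable (Gamma1) inside stable (Gamma2)")),
        list(parameter = "K", direction = "increase",
             maintain = character(0),
             effect = "trace > 0: equilibrium unstable again",
             cycles_after = list(count = 3,
                                 stability = "stable (Gamma0), unstable (Gamma1), stable (Gamma2), inside out"))),
      notes = "3 limit cycles (2 stable, 1 unstable) around the unstable equilibrium"))
  }
  if (family == "quadrangle_32") {
    if (is.null(degenerate_point)) {
      K0 <- degenerate_hopf_search("quadrangle_32", "L1")$root[["K"]]
      degenerate_point <- c(K = K0, gamma = 16 + 1 / K0)
    }
    return(list(
      family = family, point = degenerate_point,
      signature = "trace = L1 = 0, L2 > 0 (repelling equilibrium)",
      steps = list(
        list(parameter = "K", direction = "decrease",
             maintain = c("gamma = 16 + 1/K"),
             effect = "L1 < 0: equilibrium stable",
             cycles_after = list(count = 1, stability = "unstable (Gamma1)")),
        list(parameter = "gamma", direction = "increase",
             maintain = character(0),
             effect = "trace > 0: equilibrium unstable",
             cycles_after = list(count = 2,
                                 stability = "stable (Gamma0) inside unstable (Gamma1)"))),
      notes = paste("a third, stable cycle surrounding Gamma1 exists by",
                    "permanence and Poincare-Bendixson")))
  }
  if (family == "zigzag") {
    if (is.null(degenerate_point)) degenerate_point <- c(kappa = 9 / 5)
    return(list(
      family = family, point = degenerate_point,
      signature = "trace = 0, L1 = 5 pi / 13 > 0 (subcritical)",
      steps = list(
        list(parameter = "kappa", direction = "decrease",
             maintain = character(0),
             effect = "trace < 0: equilibrium stable",
             cycles_after = list(count = 1, stability = "unstable"))),
      notes = "subcritical Andronov-Hopf bifurcation at kappa = 9/5"))
  }
  stop("unsupported family: ", family)
}
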