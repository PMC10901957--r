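# Equilibrium analysis for the three studied classes: quadrangle cycles,
# chains of three reactions, and three independent reactions.

#' Classify a network into one of the studied classes
#' @param net `crn_network` or `crn_system`
#' @return `"quadrangle_cycle"`, `"chain3"`, `"three_reactions"` or `"other"`
#' @export
classify_network <- function(net) {
  if (inherits(net, "crn_system")) net <- net$network
  e <- net$edges
  m <- n_vertices(net)
  if (m == 4 && nrow(e) == 4 &&
      all(e[, 2] == c(e[2:4, 1], e[1, 1])) &&
      !anyDuplicated(e[, 1]))
    return("quadrangle_cycle")
  if (m == 4 && nrow(e) == 3 && all(e[1:2, 2] == e[2:3, 1]) &&
      !anyDuplicated(e[, 1]))
    return("chain3")
  if (nrow(e) == 3 && !anyDuplicated(e[, 1]))
    return("three_reactions")
  "other"
}

#' Signed-area geometry of a chain of three reactions
#'
#' For a chain with vertices \eqn{P_1 \to P_2 \to P_3 \to P_4} computes the
#' exact h-vector \eqn{h_1 = \Delta(243)}, \eqn{h_2 = \Delta(134)},
#' \eqn{h_3 = \Delta(142)}, \eqn{h_4 = \Delta(123)}, where
#' \eqn{\Delta(ijk) = \det(P_j - P_i, P_k - P_i)} is twice the signed area
#' of the triangle.  Always \eqn{h_1 + h_2 + h_3 + h_4 = 0}, exactly.
#'
#' @param net a `crn_network`/`crn_system` of class chain3 (vertex order =
#'   chain order)
#' @return list with `h` (numeric 4-vector, exact rationals evaluated),
#'   `h_exact` (num/den pairs) and `delta(i, j, k)` (exact signed area)
#' @export
chain_geometry <- function(net) {
  if (inherits(net, "crn_system")) net <- net$network
  if (n_vertices(net) != 4) stop("chain geometry needs 4 vertices")
  va <- net$va; vb <- net$vb
  delta_exact <- function(i, j, k) {
    dx1 <- rat_sub(rat_at(va, j), rat_at(va, i))
    dy1 <- rat_sub(rat_at(vb, j), rat_at(vb, i))
    dx2 <- rat_sub(rat_at(va, k), rat_at(va, i))
    dy2 <- rat_sub(rat_at(vb, k), rat_at(vb, i))
    rat_sub(rat_mul(dx1, dy2), rat_mul(dy1, dx2))
  }
  idx <- rbind(c(2, 4, 3), c(1, 3, 4), c(1, 4, 2), c(1, 2, 3))
  hx <- lapply(1:4, function(r) delta_exact(idx[r, 1], idx[r, 2], idx[r, 3]))
  h <- vapply(hx, rat_num, numeric(1))
  if (h[4] == 0)
    stop("degenerate chain geometry: P1, P2, P3 lie on a line")
  list(h = h, h_exact = hx,
       delta = function(i, j, k) rat_num(delta_exact(i, j, k)))
}

#' Prop 2 geometric existence test for chains (same-side + angle-sum form)
#' @param net chain network
#' @return logical
#' @export
chain_prop2_geometric <- function(net) {
  v <- vertex_matrix(net)
  d2 <- function(i, j, k) {
    u <- v[j, ] - v[i, ]; w <- v[k, ] - v[i, ]
    u[1] * w[2] - u[2] * w[1]
  }
  s1 <- d2(2, 3, 1); s4 <- d2(2, 3, 4)
  if (s1 == 0 || s4 == 0 || sign(s1) != sign(s4)) return(FALSE)
  ang <- function(at, p1, p2) {
    u <- v[p1, ] - v[at, ]; w <- v[p2, ] - v[at, ]
    acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2)))))
  }
  ang(2, 1, 3) + ang(3, 2, 4) < pi
}

solve_binomial_log <- function(A, rhs) {
  # A %*% c(log x, log y) = log(rhs), rhs > 0 componentwise
  if (any(rhs <= 0)) return(NULL)
  lx <- unname(solve(A, log(rhs)))
  c(x = exp(lx[1]), y = exp(lx[2]))
}

equilibrium_report <- function(exists, point = NULL, certificate = NULL,
                               kappa_independent = NA) {
  structure(list(exists = exists, point = point, certificate = certificate,
                 kappa_independent = kappa_independent),
            class = "crn_equilibrium")
}

#' @export
print.crn_equilibrium <- function(x, ...) {
  if (x$exists)
    cat(sprintf("unique positive equilibrium at (%.10g, %.10g)\n",
                x$point[1], x$point[2]))
  else cat("no positive equilibrium\n")
  invisible(x)
}

#' Positive equilibrium of a chain of three reactions
#'
#' A positive equilibrium exists iff \eqn{h_1}, \eqn{h_1+h_2},
#' \eqn{h_1+h_2+h_3} share a (nonzero) sign; existence is independent of the
#' rate constants.  When it exists it is unique and solves the binomial
#' system \eqn{(h_1+h_2+h_3)\kappa_1 x^{a_1} y^{b_1} = h_1 \kappa_3 x^{a_3}
#' y^{b_3}}, \eqn{(h_1+h_2)\kappa_1 x^{a_1} y^{b_1} = h_1 \kappa_2 x^{a_2}
#' y^{b_2}}, solved exactly in \eqn{(\log x, \log y)}.
#'
#' @param sys a chain3 `crn_system`
#' @return a `crn_equilibrium` report
#' @export
chain_equilibrium <- function(sys) {
  stopifnot(inherits(sys, "crn_system"))
  geo <- chain_geometry(sys$network)
  h <- geo$h
  cums <- c(h[1], h[1] + h[2], h[1] + h[2] + h[3])
  sgn <- sign(cums)
  exists <- sgn[1] != 0 && all(sgn == sgn[1])
  cert <- list(h = h, partial_sums = cums)
  if (!exists)
    return(equilibrium_report(FALSE, certificate = cert,
                              kappa_independent = TRUE))
  v <- vertex_matrix(sys$network)
  k <- sys$kappa
  A <- rbind(v[3, ] - v[1, ], v[2, ] - v[1, ])
  rhs <- c(cums[3] * k[1] / (h[1] * k[3]),
           cums[2] * k[1] / (h[1] * k[2]))
  pt <- solve_binomial_log(A, rhs)
  f <- eval_field(sys, pt[1], pt[2])
  res <- max(abs(c(f$dx, f$dy))) / max(1, max(abs(pt)))
  if (res > 1e-10) stop("equilibrium residual too large: ", res)
  equilibrium_report(TRUE, pt, cert, kappa_independent = TRUE)
}

#' Positive equilibrium of three independent reactions
#'
#' Existence is equivalent to the three cross products
#' \eqn{c_2 d_3 - c_3 d_2}, \eqn{c_3 d_1 - c_1 d_3}, \eqn{c_1 d_2 - c_2 d_1}
#' sharing a nonzero sign, independently of the rate constants; the unique
#' equilibrium solves a binomial system in \eqn{(\log x, \log y)}.
#'
#' @param sys a three-reaction `crn_system` (edge i from source i)
#' @return a `crn_equilibrium` report
#' @export
three_reaction_equilibrium <- function(sys) {
  stopifnot(inherits(sys, "crn_system"))
  v <- vertex_matrix(sys$network)
  e <- sys$network$edges
  if (nrow(e) != 3) stop("three_reaction_equilibrium needs exactly 3 reactions")
  src <- v[e[, 1], , drop = FALSE]
  rv <- v[e[, 2], , drop = FALSE] - src
  cc <- rv[, 1]; dd <- rv[, 2]
  if (abs(det(rbind(src[2, ] - src[1, ], src[3, ] - src[1, ]))) < 1e-12)
    stop("degenerate: the three sources lie on a line")
  if (qr(rv)$rank < 2)
    stop("degenerate: reaction vectors do not span the plane")
  cr <- cross_products(cc, dd)
  exists <- all(cr > 0) || all(cr < 0)
  cert <- list(cross_products = cr)
  if (!exists)
    return(equilibrium_report(FALSE, certificate = cert,
                              kappa_independent = TRUE))
  k <- sys$kappa
  A <- rbind(src[3, ] - src[1, ], src[2, ] - src[1, ])
  rhs <- c(cr[3] * k[1] / (cr[1] * k[3]),
           cr[2] * k[1] / (cr[1] * k[2]))
  pt <- solve_binomial_log(A, rhs)
  f <- eval_field(sys, pt[1], pt[2])
  if (max(abs(c(f$dx, f$dy))) > 1e-9 * max(1, max(abs(pt))))
    stop("equilibrium residual too large")
  equilibrium_report(TRUE, pt, cert, kappa_independent = TRUE)
}

#' Positive equilibrium of a quadrangle cycle
#'
#' Existence and uniqueness are guaranteed for every choice of rate
#' constants (weakly reversible, deficiency one); the point is computed by
#' damped Newton iteration in \eqn{(\log x, \log y)} starting from (0,0).
#'
#' @param sys a quadrangle-cycle `crn_system`
#' @return a `crn_equilibrium` report
#' @export
quadrangle_equilibrium <- function(sys) {
  stopifnot(inherits(sys, "crn_system"))
  fld <- mass_action_field(sys)
  v <- vertex_matrix(sys$network)
  e <- sys$network$edges
  src <- v[e[, 1], , drop = FALSE]
  kap <- sys$kappa
  # residual normalised by the total monomial mass, so the boundary (where
  # every monomial vanishes) cannot fake convergence
  Ft <- function(l) {
    x <- exp(l[1]); y <- exp(l[2])
    sc <- sum(kap * x^src[, 1] * y^src[, 2])
    unlist(eval_field(fld, x, y), use.names = FALSE) / sc
  }
  solve_from <- function(l) {
    fv <- Ft(l); nf <- sqrt(sum(fv^2)); lambda <- 1e-3
    for (it in 1:200) {
      if (nf < 1e-13) break
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        dl <- c(0, 0); dl[j] <- 1e-7
        J[, j] <- (Ft(l + dl) - Ft(l - dl)) / 2e-7
      }
      A <- crossprod(J) + lambda * diag(2)
      step <- tryCatch(solve(A, -crossprod(J, fv)),
                       error = function(err) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      l2 <- l + as.numeric(step)
      f2 <- Ft(l2); n2 <- sqrt(sum(f2^2))
      if (n2 < nf) {
        l <- l2; fv <- f2; nf <- n2; lambda <- max(lambda * 0.3, 1e-12)
      } else lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    list(l = l, nf = nf)
  }
  starts <- as.matrix(expand.grid(c(0, -2, 2), c(0, -2, 2)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    out <- solve_from(starts[i, ])
    if (is.null(best) || out$nf < best$nf) best <- out
    if (best$nf < 1e-13) break
  }
  if (best$nf > 1e-11)
    stop("equilibrium iteration failed to converge (residual ", best$nf, ")")
  equilibrium_report(TRUE, c(x = exp(best$l[1]), y = exp(best$l[2])),
                     kappa_independent = TRUE)
}

#' Scale a mass-action system so its equilibrium sits at (1,1)
#'
#' Linear scaling by the equilibrium followed by multiplication by
#' \eqn{\bar x} gives the scaled field with per-reaction constants
#' \eqn{\bar\kappa_i = \kappa_i \bar x^{a_i} \bar y^{b_i}} and
#' \eqn{K = \bar x / \bar y}; the y-equation carries the factor K.  For
#' chains \eqn{\bar\kappa_i = \lambda \cdot} (partial h-sums); for
#' three-reaction systems \eqn{\bar\kappa_i = \lambda \cdot} (cross
#' products); the recovered \eqn{\lambda} is checked for consistency across
#' all three relations.
#'
#' @param sys a `crn_system`
#' @param eq positive equilibrium (length-2), e.g. from the class solvers
#' @return a `crn_scaled` object whose field vanishes at (1,1)
#' @export
scale_to_unit <- function(sys, eq) {
  stopifnot(inherits(sys, "crn_system"), length(eq) == 2, all(eq > 0))
  eq <- unname(eq)
  f <- eval_field(sys, eq[1], eq[2])
  scale_ref <- max(abs(unlist(eval_field(sys, 1.5 * eq[1], eq[2]))), 1e-8)
  if (max(abs(c(f$dx, f$dy))) > 1e-8 * scale_ref)
    stop("eq is not an equilibrium of the system")
  v <- vertex_matrix(sys$network)
  e <- sys$network$edges
  src <- v[e[, 1], , drop = FALSE]
  rv <- v[e[, 2], , drop = FALSE] - src
  kbar <- sys$kappa * eq[1]^src[, 1] * eq[2]^src[, 2]
  K <- eq[1] / eq[2]
  fld <- crn_field(
    data.frame(coeff = rv[, 1] * kbar, a = src[, 1], b = src[, 2]),
    data.frame(coeff = K * rv[, 2] * kbar, a = src[, 1], b = src[, 2]))
  cls <- classify_network(sys$network)
  lam <- NA_real_
  if (cls == "chain3") {
    h <- chain_geometry(sys$network)$h
    cums <- cumsum(h)[1:3]
    lams <- kbar / cums
    if (max(abs(lams - lams[1])) > 1e-10 * abs(lams[1]))
      stop("lambda-consistency violated; wrong equilibrium?")
    lam <- lams[1]
  } else if (cls == "three_reactions") {
    cr <- cross_products(rv[, 1], rv[, 2])
    lams <- kbar / cr
    if (max(abs(lams - lams[1])) > 1e-10 * abs(lams[1]))
      stop("lambda-consistency violated; wrong equilibrium?")
    lam <- lams[1]
  }
  new_scaled(fld, kbar = unname(kbar), K = K, lam = lam, family = cls,
             params = list(eq = eq, class = cls, sources = unname(src)))
}

#' Jacobian report of a scaled system at (1,1)
#'
#' The matrix is obtained by differentiating the scaled field; for chains
#' the determinant is cross-checked against
#' \eqn{\det J = \frac{h_1+h_2+h_3}{\lambda} K \bar\kappa_1 \bar\kappa_2
#' \bar\kappa_3} and for three-reaction systems against
#' \eqn{\det J = \frac{1}{\lambda} K \bar\kappa_1\bar\kappa_2\bar\kappa_3
#' [a_1(b_2-b_3) + a_2(b_3-b_1) + a_3(b_1-b_2)]}.
#'
#' @param scaled a `crn_scaled`
#' @param geometry optional `chain_geometry` output for the chain check
#' @return list with `J`, `trace`, `det`, and `det_closed_form` when a
#'   closed form applies
#' @export
jacobian_report <- function(scaled, geometry = NULL) {
  stopifnot(inherits(scaled, "crn_scaled"))
  J <- field_jacobian(scaled$field, 1, 1)
  out <- list(J = J, trace = J[1, 1] + J[2, 2],
              det = J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1],
              det_closed_form = NA_real_)
  fam <- scaled$family
  kb <- scaled$kbar; K <- scaled$K; lam <- scaled$lam
  if (!is.null(fam) && !is.null(kb) && is.finite(lam)) {
    if (fam == "chain3" && !is.null(geometry)) {
      h <- geometry$h
      out$det_closed_form <- (h[1] + h[2] + h[3]) / lam * K * prod(kb[1:3])
    } else if (fam %in% c("three_reactions", "three_51", "reversible_52",
                          "lienard_53")) {
      ex <- scaled$params$sources
      if (!is.null(ex) && nrow(ex) == 3) {
        br <- ex[1, 1] * (ex[2, 2] - ex[3, 2]) +
          ex[2, 1] * (ex[3, 2] - ex[1, 2]) +
          ex[3, 1] * (ex[1, 2] - ex[2, 2])
        out$det_closed_form <- K / lam * prod(kb[1:3]) * br
      }
    }
    if (is.finite(out$det_closed_form) &&
        abs(out$det_closed_form - out$det) >
          1e-10 * max(1, abs(out$det)))
      stop("determinant closed form disagrees with the Jacobian")
  }
  out
}

#' Printed trace-sign condition for the first quadrangle example
#'
#' For the cycle on (0,1),(1,0),(1,2),(0,3) the trace of the Jacobian at the
#' equilibrium is positive iff
#' \eqn{\sqrt{\kappa_1/\kappa_2} > \sqrt{\kappa_3/\kappa_4} +
#' 6\sqrt{\kappa_4/\kappa_3}}.
#'
#' @param kappa positive 4-vector of rate constants
#' @return logical
#' @export
trace_sign_condition_quadrangle_31 <- function(kappa) {
  stopifnot(length(kappa) == 4, all(kappa > 0))
  sqrt(kappa[1] / kappa[2]) > sqrt(kappa[3] / kappa[4]) +
    6 * sqrt(kappa[4] / kappa[3])
}
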