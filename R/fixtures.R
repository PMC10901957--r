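# Built-in example systems: every worked example ships as a constructor, so
# no external data are needed.  Unscaled fixtures are full mass-action
# systems; *_scaled fixtures are the corresponding families with the
# positive equilibrium moved to (1,1).

new_scaled <- function(field, kbar = NULL, K = NA_real_, lam = NA_real_,
                       family = NULL, params = list()) {
  structure(list(field = field, kbar = kbar, K = K, lam = lam,
                 family = family, params = params), class = "crn_scaled")
}

#' @export
print.crn_scaled <- function(x, ...) {
  cat("scaled planar system (equilibrium at (1,1))\n")
  if (!is.null(x$family)) cat("  family:", x$family, "\n")
  if (is.finite(x$K)) cat("  K =", x$K, "\n")
  print(x$field)
  invisible(x)
}

#' Built-in example systems and families
#'
#' Constructors for every worked example: the two quadrangle cycles, the
#' two chains of three reactions, the three triples of independent
#' reactions, and the zigzag network whose positive equilibrium exists only
#' for some rate constants.
#'
#' Available names (aliases with extra underscores, e.g. `"chain_4_1"`,
#' are accepted):
#' \describe{
#' \item{`quadrangle_31`}{cycle on (0,1),(1,0),(1,2),(0,3); args `kappa`
#'   (4 rates).}
#' \item{`quadrangle_32`}{cycle on (0,1),(0,0),(1,2),(1,b4); args `kappa`,
#'   `b4` (default 5).}
#' \item{`quadrangle_32_scaled`}{scaled family
#'   \eqn{\dot x = 1 - x y^{b_4}},
#'   \eqn{\dot y = K(-\gamma y + 2 + (\gamma + b_4 - 3) x y^2 +
#'   (1-b_4) x y^{b_4})}; args `K`, `b4 = 5`, `gamma` (default the
#'   trace-zero value \eqn{b_4^2 - 3 b_4 + 6 + 1/K}).}
#' \item{`chain_41`}{chain on (0,0),(0,-q),(1,1/2),(0,1/2+r); args `q`, `r`
#'   (both positive), `kappa` (3 rates).}
#' \item{`chain_41_scaled`}{scaled family
#'   \eqn{\dot x = y^{-q} - x y^{1/2}},
#'   \eqn{\dot y = K(-(q+r+1/2) + (q+1/2) y^{-q} + r x y^{1/2})}; args `q`,
#'   `r`, `K` (default the trace-zero value \eqn{2/(r - q(2q+1))}).}
#' \item{`reversible_chain_42`}{chain on (0,0),(p,q),(q,p),
#'   (q-p, p+q^2/p) with the center-making rates; args `p`, `q`
#'   (`p*q < 0`, `p + q != 0`), `xbar` (free equilibrium scale, default
#'   `-p/q`).}
#' \item{`reversible_chain_42_scaled`}{the reversible center family
#'   \eqn{\dot x = (p-q) + q x^p y^q - p x^q y^p},
#'   \eqn{\dot y = (q-p) + p x^p y^q - q x^q y^p}; args `p`, `q`.}
#' \item{`three_51`}{three independent reactions with sources (0,0),(0,-1),
#'   (a,b) and reaction vectors (0,-1),(1,-1),(-1,d); args `a`, `b`, `d`
#'   (`a > 0`, `b > -1`, `d > 0`, `1 + b*d > 0`), `kappa` (3 rates).}
#' \item{`three_51_scaled`}{scaled family
#'   \eqn{\dot x = y^{-1} - x^a y^b},
#'   \eqn{\dot y = K(-(d-1) - y^{-1} + d x^a y^b)}; args `a`, `b`, `d`,
#'   `K` (default the trace-zero value \eqn{a/(1+bd)}).}
#' \item{`reversible_52_scaled`}{three reactions with sources (0,0),(p,q),
#'   (q,p); args `p`, `q`, `c` (3-vector), `d` (3-vector), optional `K`
#'   (default `-c[1]/d[1]`).}
#' \item{`lienard_53_scaled`}{three reactions with sources (1,0),(0,-1/2),
#'   (0,-2); args `c`, `d` (3-vectors), optional `K` (default the
#'   center value `-(4/5)*c[1]/d[1]`).}
#' \item{`zigzag`}{the deficiency-one network on complexes X, Y, X+2Y, 3Y
#'   with \eqn{\dot x = (1+\kappa) y - 3 x y^2 + y^3},
#'   \eqn{\dot y = (1-\kappa) y + x y^2 - y^3}; arg `kappa`.  A positive
#'   equilibrium exists iff \eqn{\kappa < 2}.}
#' }
#'
#' @param name fixture name (see Details)
#' @param ... family parameters
#' @return a `crn_system` or `crn_scaled` object
#' @export
paper_fixture <- function(name, ...) {
  key <- gsub("_([0-9])_([0-9])", "_\\1\\2", tolower(name))
  key <- sub("^reversible_chain", "reversible_chain", key)
  switch(key,
    quadrangle_31 = fixture_quadrangle_31(...),
    quadrangle_32 = fixture_quadrangle_32(...),
    quadrangle_32_scaled = fixture_quadrangle_32_scaled(...),
    chain_41 = fixture_chain_41(...),
    chain_41_scaled = fixture_chain_41_scaled(...),
    reversible_chain_42 = fixture_reversible_42(...),
    reversible_chain_42_scaled = ,
    reversible_42_scaled = fixture_reversible_42_scaled(...),
    three_51 = fixture_three_51(...),
    three_51_scaled = fixture_three_51_scaled(...),
    reversible_52_scaled = fixture_reversible_52_scaled(...),
    lienard_53_scaled = fixture_lienard_53_scaled(...),
    zigzag = fixture_zigzag(...),
    stop("unknown fixture: ", name)
  )
}

fixture_quadrangle_31 <- function(kappa = c(1, 1, 1, 1)) {
  net <- crn_network(rbind(c("0", "1"), c("1", "0"), c("1", "2"), c("0", "3")),
                     cbind(1:4, c(2, 3, 4, 1)))
  crn_system(net, kappa)
}

fixture_quadrangle_32 <- function(kappa = c(1, 1, 1, 1), b4 = 5) {
  if (b4 <= 2) stop("b4 must exceed 2")
  net <- crn_network(rbind(c("0", "1"), c("0", "0"), c("1", "2"),
                           c("1", as.character(b4))),
                     cbind(1:4, c(2, 3, 4, 1)))
  crn_system(net, kappa)
}

fixture_quadrangle_32_scaled <- function(K, b4 = 5, gamma = NULL) {
  stopifnot(K > 0, b4 > 2)
  if (is.null(gamma)) gamma <- (b4^2 - 3 * b4 + 6) + 1 / K
  if (gamma <= 0) stop("gamma must be positive")
  fld <- crn_field(
    data.frame(coeff = c(1, -1), a = c(0, 1), b = c(0, b4)),
    data.frame(coeff = K * c(-gamma, 2, gamma + b4 - 3, 1 - b4),
               a = c(0, 0, 1, 1), b = c(1, 0, 2, b4)))
  new_scaled(fld, kbar = c(gamma, 1, (gamma + b4 - 3) / (b4 - 2), 1), K = K,
             family = "quadrangle_32",
             params = list(K = K, b4 = b4, gamma = gamma))
}

fixture_chain_41 <- function(q, r, kappa = c(1, 1, 1)) {
  if (q <= 0 || r <= 0) stop("chain_41 needs q > 0 and r > 0")
  net <- crn_network(rbind(c("0", "0"), c("0", as.character(-q)),
                           c("1", "1/2"), c("0", as.character(1 / 2 + r))),
                     cbind(1:3, 2:4))
  crn_system(net, kappa)
}

fixture_chain_41_scaled <- function(q, r, K = NULL) {
  if (q <= 0 || r <= 0) stop("chain_41 needs q > 0 and r > 0")
  if (is.null(K)) {
    if (r <= q * (2 * q + 1)) stop("trace-zero K needs r > q(2q+1)")
    K <- 2 / (r - q * (2 * q + 1))
  }
  fld <- crn_field(
    data.frame(coeff = c(1, -1), a = c(0, 1), b = c(-q, 1 / 2)),
    data.frame(coeff = K * c(-(q + r + 1 / 2), q + 1 / 2, r),
               a = c(0, 0, 1), b = c(0, -q, 1 / 2)))
  new_scaled(fld, K = K, lam = -1 / q, family = "chain_41",
             params = list(q = q, r = r, K = K))
}

fixture_reversible_42 <- function(p, q, xbar = NULL) {
  if (p * q >= 0 || p + q == 0) stop("reversible_chain_42 needs pq<0, p+q!=0")
  # center-making rates: kbar = ((p-q)/p, -q/(p-q), 1), K = -p/q, and the
  # equilibrium scale xbar is free (kappa_i = kbar_i / (xbar^a_i ybar^b_i))
  if (is.null(xbar)) xbar <- -p / q
  ybar <- xbar / (-p / q)
  v <- rbind(c(0, 0), c(p, q), c(q, p), c(q - p, p + q^2 / p))
  kbar <- c((p - q) / p, -q / (p - q), 1)
  kap <- kbar / (xbar^v[1:3, 1] * ybar^v[1:3, 2])
  net <- crn_network(matrix(as.character(v), ncol = 2), cbind(1:3, 2:4))
  crn_system(net, kap)
}

fixture_reversible_42_scaled <- function(p, q) {
  if (p * q >= 0 || p + q == 0) stop("reversible_chain_42 needs pq<0, p+q!=0")
  fld <- crn_field(
    data.frame(coeff = c(p - q, q, -p), a = c(0, p, q), b = c(0, q, p)),
    data.frame(coeff = c(q - p, p, -q), a = c(0, p, q), b = c(0, q, p)))
  new_scaled(fld, kbar = c((p - q) / p, -q / (p - q), 1), K = -p / q,
             lam = -1 / (p^2 - q^2), family = "reversible_chain_42",
             params = list(p = p, q = q))
}

check_51 <- function(a, b, d) {
  if (a <= 0 || b <= -1 || d <= 0 || 1 + b * d <= 0)
    stop("three_51 needs a > 0, b > -1, d > 0, 1 + b*d > 0")
}

# build a mass-action system from per-reaction (source, vector) rows,
# sharing coincident vertices
reaction_system <- function(sources, vectors, kappa) {
  pts <- rbind(sources, sources + vectors)
  key <- paste(pts[, 1], pts[, 2])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  n <- nrow(sources)
  net <- crn_network(matrix(as.character(pts[uk, , drop = FALSE]), ncol = 2),
                     cbind(idx[1:n], idx[n + (1:n)]))
  crn_system(net, kappa)
}

fixture_three_51 <- function(a, b, d, kappa = c(1, 1, 1)) {
  check_51(a, b, d)
  reaction_system(rbind(c(0, 0), c(0, -1), c(a, b)),
                  rbind(c(0, -1), c(1, -1), c(-1, d)), kappa)
}

fixture_three_51_scaled <- function(a, d, b = NULL, K = NULL) {
  if (is.null(b)) b <- (-2 + a * (1 + sqrt(1 + 8 * d))) / (2 * d)
  check_51(a, b, d)
  if (is.null(K)) K <- a / (1 + b * d)
  fld <- crn_field(
    data.frame(coeff = c(1, -1), a = c(0, a), b = c(-1, b)),
    data.frame(coeff = K * c(-(d - 1), -1, d),
               a = c(0, 0, a), b = c(0, -1, b)))
  new_scaled(fld, kbar = c(d - 1, 1, 1), K = K, lam = 1, family = "three_51",
             params = list(a = a, b = b, d = d, K = K,
                           sources = rbind(c(0, 0), c(0, -1), c(a, b))))
}

fixture_reversible_52_scaled <- function(p, q, c, d, K = NULL) {
  if (abs(p) == abs(q)) stop("reversible_52 needs |p| != |q|")
  stopifnot(length(c) == 3, length(d) == 3)
  cr <- cross_products(c, d)
  if (!all(cr > 0) && !all(cr < 0))
    stop("no positive equilibrium: cross products do not share a sign")
  lam <- if (all(cr > 0)) 1 else -1
  kbar <- lam * cr
  if (is.null(K)) K <- -c[1] / d[1]
  if (K <= 0) stop("K must be positive")
  fld <- crn_field(
    data.frame(coeff = c * kbar, a = c(0, p, q), b = c(0, q, p)),
    data.frame(coeff = K * d * kbar, a = c(0, p, q), b = c(0, q, p)))
  new_scaled(fld, kbar = kbar, K = K, lam = lam, family = "reversible_52",
             params = list(p = p, q = q, c = c, d = d, K = K,
                           sources = rbind(c(0, 0), c(p, q), c(q, p))))
}

fixture_lienard_53_scaled <- function(c, d, K = NULL) {
  stopifnot(length(c) == 3, length(d) == 3)
  cr <- cross_products(c, d)
  if (!all(cr > 0) && !all(cr < 0))
    stop("no positive equilibrium: cross products do not share a sign")
  lam <- if (all(cr > 0)) 1 else -1
  kbar <- lam * cr
  if (is.null(K)) K <- -(5 / 4) * c[1] / d[1]
  if (K <= 0) stop("K must be positive")
  fld <- crn_field(
    data.frame(coeff = c * kbar, a = c(1, 0, 0), b = c(0, -1 / 2, -2)),
    data.frame(coeff = K * d * kbar, a = c(1, 0, 0), b = c(0, -1 / 2, -2)))
  new_scaled(fld, kbar = kbar, K = K, lam = lam, family = "lienard_53",
             params = list(c = c, d = d, K = K,
                           sources = rbind(c(1, 0), c(0, -1 / 2), c(0, -2))))
}

cross_products <- function(c, d) {
  c(c[2] * d[3] - c[3] * d[2],
    c[3] * d[1] - c[1] * d[3],
    c[1] * d[2] - c[2] * d[1])
}

fixture_zigzag <- function(kappa = 9 / 5) {
  if (kappa <= 0) stop("kappa must be positive")
  # complexes X, Y, X+2Y, 3Y; five reactions, deficiency one, l = t = 1
  net <- crn_network(rbind(c("1", "0"), c("0", "1"), c("1", "2"), c("0", "3")),
                     rbind(c(2, 3),   # Y -> X+2Y
                           c(2, 1),   # Y -> X          (rate kappa)
                           c(3, 4),   # X+2Y -> 3Y      (rate 3)
                           c(3, 1),   # X+2Y -> X
                           c(4, 3)))  # 3Y -> X+2Y
  crn_system(net, c(1, kappa, 3, 1, 1))
}
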