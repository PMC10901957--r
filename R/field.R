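#' Construct a power-law vector field
#'
#' @param dx,dy data.frames with columns `coeff`, `a`, `b`: each row is the
#'   term `coeff * x^a * y^b`.  Terms with equal exponent pairs are merged
#'   and zero terms dropped.
#' @return object of class `crn_field`; evaluation is defined on the open
#'   positive quadrant only
#' @export
crn_field <- function(dx, dy) {
  structure(list(dx = collect_terms(dx), dy = collect_terms(dy)),
            class = "crn_field")
}

collect_terms <- function(tt) {
  tt <- as.data.frame(tt)
  stopifnot(all(c("coeff", "a", "b") %in% names(tt)))
  key <- paste(tt$a, tt$b)
  co <- tapply(tt$coeff, key, sum)
  first <- !duplicated(key)
  out <- data.frame(coeff = as.numeric(co[paste(tt$a, tt$b)[first]]),
                    a = tt$a[first], b = tt$b[first])
  out <- out[abs(out$coeff) > 1e-300, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$a, out$b), , drop = FALSE]
}

#' @export
print.crn_field <- function(x, ...) {
  fmt <- function(tt) paste(sprintf("%+g x^%g y^%g", tt$coeff, tt$a, tt$b),
                            collapse = " ")
  cat("power-law field on the positive quadrant\n")
  cat("  dx/dt =", fmt(x$dx), "\n")
  cat("  dy/dt =", fmt(x$dy), "\n")
  invisible(x)
}

#' The mass-action differential equation of a system
#'
#' Builds the power-law field whose components are
#' \eqn{\dot x = \sum_{(i,j) \in E} (a_j - a_i) \kappa_{ij} x^{a_i} y^{b_i}}
#' and likewise for \eqn{\dot y}, with terms collected.
#'
#' @param sys a `crn_system`
#' @return a `crn_field`
#' @export
mass_action_field <- function(sys) {
  stopifnot(inherits(sys, "crn_system"))
  v <- vertex_matrix(sys$network)
  e <- sys$network$edges
  src <- v[e[, 1], , drop = FALSE]
  rv <- v[e[, 2], , drop = FALSE] - src
  crn_field(data.frame(coeff = rv[, 1] * sys$kappa, a = src[, 1], b = src[, 2]),
            data.frame(coeff = rv[, 2] * sys$kappa, a = src[, 1], b = src[, 2]))
}

as_field <- function(x) {
  if (inherits(x, "crn_field")) return(x)
  if (inherits(x, "crn_scaled")) return(x$field)
  if (inherits(x, "crn_system")) return(mass_action_field(x))
  stop("cannot interpret object as a power-law field")
}

#' Evaluate a power-law field
#' @param field `crn_field` (or system/scaled object)
#' @param x,y positive coordinates (vectorised)
#' @return list with numeric vectors `dx`, `dy`
#' @export
eval_field <- function(field, x, y) {
  f <- as_field(field)
  stopifnot(all(x > 0), all(y > 0))
  ev <- function(tt) {
    out <- numeric(length(x))
    for (i in seq_len(nrow(tt)))
      out <- out + tt$coeff[i] * x^tt$a[i] * y^tt$b[i]
    out
  }
  list(dx = ev(f$dx), dy = ev(f$dy))
}

#' Jacobian matrix of a power-law field at a point
#' @param field `crn_field` (or system/scaled object)
#' @param x,y positive coordinates
#' @return 2 x 2 numeric matrix
#' @export
field_jacobian <- function(field, x = 1, y = 1) {
  f <- as_field(field)
  d <- function(tt, wrt) {
    s <- 0
    for (i in seq_len(nrow(tt))) {
      if (wrt == "x") s <- s + tt$coeff[i] * tt$a[i] * x^(tt$a[i] - 1) * y^tt$b[i]
      else            s <- s + tt$coeff[i] * tt$b[i] * x^tt$a[i] * y^(tt$b[i] - 1)
    }
    s
  }
  matrix(c(d(f$dx, "x"), d(f$dy, "x"), d(f$dx, "y"), d(f$dy, "y")), 2, 2)
}
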