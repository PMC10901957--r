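#' Construct a planar reaction network
#'
#' A planar reaction network (planar Euclidean embedded graph) is a directed
#' graph whose vertices are points \eqn{(a_i, b_i)} in the plane; a vertex
#' stands for the complex \eqn{a_i X + b_i Y}.  The reaction vectors
#' \eqn{(a_j - a_i, b_j - b_i)} over all edges must span the plane.
#'
#' @param vertices an m x 2 matrix (or something coercible) of exponent
#'   points, or a list of two `rat_parse`-style rational lists.  Character
#'   matrices may contain exact rationals such as `"-1/4"`.
#' @param edges two-column matrix/data.frame of 1-based vertex indices
#'   (from, to)
#' @return object of class `crn_network`
#' @export
crn_network <- function(vertices, edges) {
  if (is.list(vertices) && !is.data.frame(vertices) && length(vertices) == 2 &&
      is.list(vertices[[1]]) && !is.null(vertices[[1]]$num)) {
    va <- vertices[[1]]; vb <- vertices[[2]]
  } else {
    vm <- as.matrix(vertices)
    va <- rat_parse(vm[, 1]); vb <- rat_parse(vm[, 2])
  }
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("from", "to")
  net <- structure(list(va = va, vb = vb, edges = edges), class = "crn_network")
  validate_network(net)
  net
}

#' @export
print.crn_network <- function(x, ...) {
  m <- n_vertices(x)
  cat(sprintf("planar reaction network: %d complexes, %d reactions\n",
              m, nrow(x$edges)))
  lab <- vertex_labels(x)
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %s -> %s\n", lab[x$edges[i, 1]], lab[x$edges[i, 2]]))
  invisible(x)
}

n_vertices <- function(net) length(net$va$num)

#' Numeric vertex coordinates of a network
#' @param net a `crn_network` or `crn_system`
#' @return m x 2 numeric matrix of exponent points
#' @export
vertex_matrix <- function(net) {
  if (inherits(net, "crn_system")) net <- net$network
  cbind(a = rat_num(net$va), b = rat_num(net$vb))
}

vertex_labels <- function(net) {
  paste0("(", rat_format(net$va$num, net$va$den), ",",
         rat_format(net$vb$num, net$vb$den), ")")
}

validate_network <- function(net) {
  m <- n_vertices(net)
  if (m < 2) stop("network needs at least two vertices")
  key <- paste(rat_format(net$va$num, net$va$den),
               rat_format(net$vb$num, net$vb$den))
  if (anyDuplicated(key)) stop("duplicate vertices")
  e <- net$edges
  if (nrow(e) == 0) stop("network has no edges")
  if (any(e < 1 | e > m)) stop("edge index out of range")
  if (any(e[, 1] == e[, 2])) stop("self-loop edges are not allowed")
  v <- vertex_matrix(net)
  rv <- v[e[, 2], , drop = FALSE] - v[e[, 1], , drop = FALSE]
  if (qr(rv)$rank < 2) stop("reaction vectors do not span the plane")
  invisible(net)
}

#' Construct a mass-action system
#'
#' @param network a `crn_network`
#' @param kappa positive rate constants, one per edge (recycled if scalar)
#' @return object of class `crn_system`
#' @export
crn_system <- function(network, kappa) {
  stopifnot(inherits(network, "crn_network"))
  kappa <- rep_len(as.numeric(kappa), nrow(network$edges))
  if (any(!is.finite(kappa)) || any(kappa <= 0))
    stop("rate constant must be positive")
  structure(list(network = network, kappa = kappa), class = "crn_system")
}

#' @export
print.crn_system <- function(x, ...) {
  lab <- vertex_labels(x$network)
  cat(sprintf("planar mass-action system: %d complexes, %d reactions\n",
              n_vertices(x$network), nrow(x$network$edges)))
  for (i in seq_len(nrow(x$network$edges)))
    cat(sprintf("  %s -> %s   @ %g\n",
                lab[x$network$edges[i, 1]], lab[x$network$edges[i, 2]],
                x$kappa[i]))
  invisible(x)
}

#' Deficiency of a planar reaction network
#'
#' The deficiency is \eqn{\delta = m - \ell - 2}, with m the number of
#' complexes (vertices) and \eqn{\ell} the number of connected components of
#' the underlying graph.  For networks whose reaction vectors span the plane
#' this is a non-negative integer.
#'
#' @param net a `crn_network` or `crn_system`
#' @return integer deficiency
#' @export
deficiency <- function(net) {
  if (inherits(net, "crn_system")) net <- net$network
  g <- as_igraph(net)
  ell <- igraph::components(g, mode = "weak")$no
  as.integer(n_vertices(net) - ell - 2L)
}

as_igraph <- function(net) {
  igraph::graph_from_edgelist(net$edges, directed = TRUE)
}

#' Structural report for a planar reaction network
#'
#' Reports weak reversibility (every edge lies on a directed cycle,
#' equivalently every strong component of the condensation is isolated),
#' the number of weakly connected components \eqn{\ell}, the number of
#' terminal (absorbing) strong components t, the deficiency, and whether
#' the hypotheses of the Deficiency-One Theorem (\eqn{\delta = 1},
#' \eqn{\ell = t = 1}) hold.
#'
#' @param net a `crn_network` or `crn_system`
#' @return list with entries `weakly_reversible`, `l`, `t`, `deficiency`,
#'   `deficiency_one_applicable`
#' @export
structure_report <- function(net) {
  if (inherits(net, "crn_system")) net <- net$network
  g <- as_igraph(net)
  ell <- igraph::components(g, mode = "weak")$no
  sc <- igraph::components(g, mode = "strong")
  memb <- sc$membership
  e <- net$edges
  # edge is in a cycle iff both endpoints share a strong component
  wr <- all(memb[e[, 1]] == memb[e[, 2]])
  # terminal strong components: no edge leaves them
  leaves <- unique(memb[e[, 1]][memb[e[, 1]] != memb[e[, 2]]])
  t_term <- sc$no - length(leaves)
  delta <- as.integer(n_vertices(net) - ell - 2L)
  list(weakly_reversible = wr, l = as.integer(ell), t = as.integer(t_term),
       deficiency = delta,
       deficiency_one_applicable = (delta == 1L && ell == 1L && t_term == 1L))
}

#' Translate a network in exponent space
#'
#' Shifting every vertex by \eqn{(\alpha, \beta)} multiplies the associated
#' differential equation by the monomial \eqn{x^\alpha y^\beta}, which does
#' not change the orbits in the open positive quadrant.
#'
#' @param net `crn_network` or `crn_system`
#' @param shift length-2 vector (numeric or character rationals)
#' @return translated object of the same class
#' @export
translate_network <- function(net, shift) {
  sys <- NULL
  if (inherits(net, "crn_system")) { sys <- net; net <- net$network }
  sh <- rat_parse(as.character(shift))
  va <- rat_add(net$va, list(num = rep(sh$num[1], n_vertices(net)),
                             den = rep(sh$den[1], n_vertices(net))))
  vb <- rat_add(net$vb, list(num = rep(sh$num[2], n_vertices(net)),
                             den = rep(sh$den[2], n_vertices(net))))
  out <- structure(list(va = va, vb = vb, edges = net$edges),
                   class = "crn_network")
  if (!is.null(sys)) crn_system(out, sys$kappa) else out
}

#' Read a mass-action system from its JSON file format
#'
#' The dialect is
#' `{"species": ["X","Y"], "vertices": [["0","1"], ...],`
#' `"edges": [{"from":0, "to":1, "kappa":"1"}, ...]}` with 0-based vertex
#' indices and rationals given as `"p/q"` strings or decimals.  Exact
#' rationals survive the round-trip.
#'
#' @param path file path
#' @return a `crn_system`
#' @seealso [write_network()]
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$vertices) || is.null(js$edges))
    stop("malformed network file: needs 'vertices' and 'edges'")
  vm <- do.call(rbind, lapply(js$vertices, function(v) {
    if (length(v) != 2) stop("vertex must have two coordinates")
    c(as.character(v[[1]]), as.character(v[[2]]))
  }))
  ed <- do.call(rbind, lapply(js$edges, function(e) {
    c(as.integer(e$from) + 1L, as.integer(e$to) + 1L)
  }))
  kap <- vapply(js$edges, function(e) {
    k <- rat_parse(as.character(e$kappa)); rat_num(k)
  }, numeric(1))
  if (any(kap <= 0)) stop("rate constant must be positive")
  net <- crn_network(vm, ed)
  crn_system(net, kap)
}

#' Write a mass-action system to the JSON file format
#' @param sys a `crn_system`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_network <- function(sys, path) {
  stopifnot(inherits(sys, "crn_system"))
  net <- sys$network
  verts <- lapply(seq_len(n_vertices(net)), function(i)
    list(rat_format(net$va$num[i], net$va$den[i]),
         rat_format(net$vb$num[i], net$vb$den[i])))
  edges <- lapply(seq_len(nrow(net$edges)), function(i)
    list(from = net$edges[i, 1] - 1L, to = net$edges[i, 2] - 1L,
         kappa = format_kappa(sys$kappa[i])))
  jsonlite::write_json(list(species = c("X", "Y"), vertices = verts,
                            edges = edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

format_kappa <- function(k) {
  # keep simple rationals exact in files
  for (d in c(1, 2, 3, 4, 5, 8, 10, 16)) {
    if (abs(k * d - round(k * d)) < 1e-15)
      return(rat_format(round(k * d), d))
  }
  format(k, digits = 17)
}

#' Parse reaction strings such as "X + 2Y -> 3Y @ 1/2"
#'
#' Each line is one reaction; complexes are sums of `cX`/`cY` terms with
#' rational coefficients (e.g. `1/2 X`, `2Y`, `0`); the rate constant
#' follows `@` (default 1).  Vertices are created implicitly.
#'
#' @param lines character vector of reaction strings
#' @return a `crn_system`
#' @export
parse_reactions <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  parse_side <- function(s) {
    s <- trimws(s)
    if (s == "0") return(c("0", "0"))
    a <- "0"; b <- "0"
    for (term in strsplit(s, "+", fixed = TRUE)[[1]]) {
      term <- gsub("[[:space:]]", "", term)
      mm <- regmatches(term, regexec("^(-?[0-9/\\.]*)([XY])$", term))[[1]]
      if (length(mm) != 3) stop("cannot parse complex term: ", term)
      coef <- if (mm[2] == "") "1" else mm[2]
      if (mm[3] == "X") a <- coef else b <- coef
    }
    c(a, b)
  }
  vkeys <- character(0); vrows <- list()
  edges <- NULL; kap <- numeric(0)
  for (ln in lines) {
    parts <- strsplit(ln, "@", fixed = TRUE)[[1]]
    k <- if (length(parts) > 1) rat_num(rat_parse(trimws(parts[2]))) else 1
    sides <- strsplit(parts[1], "->", fixed = TRUE)[[1]]
    if (length(sides) != 2) stop("reaction needs '->': ", ln)
    src <- parse_side(sides[1]); tgt <- parse_side(sides[2])
    idx <- integer(2)
    for (j in 1:2) {
      v <- if (j == 1) src else tgt
      key <- paste(rat_format(rat_parse(v[1])$num, rat_parse(v[1])$den),
                   rat_format(rat_parse(v[2])$num, rat_parse(v[2])$den))
      pos <- match(key, vkeys)
      if (is.na(pos)) { vkeys <- c(vkeys, key); vrows <- c(vrows, list(v));
                        pos <- length(vkeys) }
      idx[j] <- pos
    }
    edges <- rbind(edges, idx)
    kap <- c(kap, k)
  }
  net <- crn_network(do.call(rbind, vrows), edges)
  crn_system(net, kap)
}

#' Seeded random networks of the three studied classes
#'
#' Generates reproducible systems with small-rational exponents satisfying
#' the class non-degeneracy assumptions: quadrangle cycles have four
#' non-collinear distinct vertices (deficiency one by construction), chains
#' have their first three sources non-collinear, and three-reaction systems
#' have non-collinear sources and reaction vectors spanning the plane.
#'
#' @param class one of `"quadrangle_cycle"`, `"chain3"`, `"three_reactions"`
#' @param seed integer seed
#' @return a `crn_system`
#' @export
random_network <- function(class = c("quadrangle_cycle", "chain3",
                                     "three_reactions"), seed) {
  class <- match.arg(class)
  set.seed(as.integer(seed))
  rhalf <- function(n) sample(seq(-4, 8), n, replace = TRUE) / 2
  repeat {
    if (class == "quadrangle_cycle") {
      v <- cbind(rhalf(4), rhalf(4))
      if (anyDuplicated(paste(v[, 1], v[, 2]))) next
      if (abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ]))) < 1e-12 &&
          abs(det(rbind(v[2, ] - v[1, ], v[4, ] - v[1, ]))) < 1e-12) next
      e <- cbind(1:4, c(2, 3, 4, 1))
    } else if (class == "chain3") {
      v <- cbind(rhalf(4), rhalf(4))
      if (anyDuplicated(paste(v[, 1], v[, 2]))) next
      # Eq-8-type non-degeneracy: first three sources not on a line
      if (abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ]))) < 1e-12) next
      e <- cbind(1:3, 2:4)
    } else {
      v <- cbind(rhalf(6), rhalf(6))
      if (anyDuplicated(paste(v[, 1], v[, 2]))) next
      s <- v[c(1, 3, 5), ]
      if (abs(det(rbind(s[2, ] - s[1, ], s[3, ] - s[1, ]))) < 1e-12) next
      e <- cbind(c(1, 3, 5), c(2, 4, 6))
    }
    rv <- v[e[, 2], , drop = FALSE] - v[e[, 1], , drop = FALSE]
    if (qr(rv)$rank < 2) next
    vm <- matrix(as.character(c(v[, 1] * 2, v[, 2] * 2)), ncol = 2)
    vm[, 1] <- paste0(vm[, 1], "/2"); vm[, 2] <- paste0(vm[, 2], "/2")
    net <- tryCatch(crn_network(vm, e), error = function(e) NULL)
    if (is.null(net)) next
    kap <- round(exp(runif(nrow(e), -1, 1)), 3)
    return(crn_system(net, kap))
  }
}
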