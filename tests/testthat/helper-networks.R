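# helpers shared across the test files

# brute-force: every edge lies on a directed cycle (DFS reachability)
brute_weakly_reversible <- function(net) {
  if (inherits(net, "crn_system")) net <- net$network
  m <- length(net$va$num)
  adj <- lapply(seq_len(m), function(i)
    net$edges[net$edges[, 1] == i, 2])
  reach <- function(from, to) {
    seen <- logical(m); stack <- from
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v == to) return(TRUE)
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, adj[[v]])
    }
    FALSE
  }
  all(apply(net$edges, 1, function(e) reach(e[2], e[1])))
}

# random chain of three reactions with integer-ish vertices, seeded
random_chain <- function(seed) {
  set.seed(seed)
  repeat {
    v <- matrix(sample(seq(-4, 8), 8, replace = TRUE) / 2, 4, 2)
    if (anyDuplicated(paste(v[, 1], v[, 2]))) next
    if (abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ]))) < 1e-9) next
    if (qr(v[2:4, ] - v[1:3, ])$rank < 2) next
    net <- tryCatch(
      crn_network(matrix(as.character(c(v[, 1] * 2, v[, 2] * 2)), ncol = 2) |>
                    (\(m) {m[] <- paste0(m, "/2"); m})(),
                  cbind(1:3, 2:4)),
      error = function(e) NULL)
    if (!is.null(net)) return(net)
  }
}

cor2_instance <- function() {
  # satisfies every reversible-center condition with p = 2, q = -1;
  # -c1/d1 = 2 != 1 so the rate-constant exponent is actually exercised
  list(p = 2, q = -1, c = c(2, 1, -1), d = c(-1, 2, -1 / 8))
}

cor3_instance <- function() {
  # satisfies every Lienard-center condition with K = 1
  list(c = c(4 / 5, 0, -4), d = c(-1, 1, 1))
}
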