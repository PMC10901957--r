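test_that("Dulac exponent intervals match brute force on many orderings", {
  brute_interval <- function(a, grid) {
    nxt <- c(a[-1], a[1])
    ok <- vapply(grid, function(al) all((al - a) * (a - nxt) <= 0),
                 logical(1))
    grid[ok]
  }
  # worked examples
  ia <- dulac_exponent_interval(c(0, 1, 1, 0))
  expect_equal(c(ia$lower, ia$upper), c(0, 1)); expect_false(ia$empty)
  ib <- dulac_exponent_interval(c(1, 0, 2, 3))
  expect_true(ib$empty)
  expect_equal(c(ib$lower, ib$upper), c(2, 1))
  ic <- dulac_exponent_interval(c(2, 2, 2, 2))
  expect_false(ic$empty)
  expect_identical(c(ic$lower, ic$upper), c(-Inf, Inf))
  expect_false(ic$strict)

  grid <- seq(-1, 5, by = 0.25)
  combos <- list()
  for (p in list(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4), c(1, 3, 4, 2),
                 c(1, 4, 3, 2), c(1, 4, 2, 3), c(2, 1, 3, 4), c(4, 3, 2, 1),
                 c(3, 1, 4, 2), c(2, 4, 1, 3)))
    combos <- c(combos, list(p))
  # tie patterns from the enumerated case list
  combos <- c(combos, list(c(1, 1, 2, 3), c(1, 2, 2, 3), c(1, 3, 3, 1),
                           c(2, 1, 1, 2), c(0, 0, 1, 1)))
  for (a in combos) {
    iv <- dulac_exponent_interval(a)
    feas <- brute_interval(a, grid)
    inside <- grid >= iv$lower & grid <= iv$upper & !iv$empty
    expect_identical(inside, grid %in% feas, info = paste(a, collapse = ","))
  }
})

test_that("Dulac certificate: unit square certified, both examples not", {
  sq <- crn_system(crn_network(rbind(c("0", "0"), c("1", "0"), c("1", "1"),
                                     c("0", "1")), cbind(1:4, c(2, 3, 4, 1))),
                   rep(1, 4))
  d <- dulac_test_quadrangle(sq)
  expect_identical(d$verdict, "globally_stable_all_kappa")
  expect_equal(unname(d$chosen), c(1 / 2, 1 / 2))

  d31 <- dulac_test_quadrangle(paper_fixture("quadrangle_31"))
  expect_identical(d31$verdict, "inconclusive")
  expect_identical(d31$bad_pattern_b, 2L)

  d32 <- dulac_test_quadrangle(paper_fixture("quadrangle_32"))
  expect_identical(d32$verdict, "inconclusive")
  expect_identical(d32$bad_pattern_b, 2L)
})

test_that("Dulac soundness: certified divergence is negative everywhere", {
  sq_net <- crn_network(rbind(c("0", "0"), c("1", "0"), c("1", "1"),
                              c("0", "1")), cbind(1:4, c(2, 3, 4, 1)))
  d <- dulac_test_quadrangle(sq_net)
  set.seed(11)
  for (i in 1:10) {
    sys <- crn_system(sq_net, exp(runif(4, -2, 2)))
    x <- exp(runif(1000, -3, 3)); y <- exp(runif(1000, -3, 3))
    div <- dulac_divergence(sys, d$chosen["alpha"], d$chosen["beta"], x, y)
    expect_true(all(div < 0))
  }
})

test_that("reversibility check recognises the diagonal symmetry", {
  expect_true(reversibility_check(
    paper_fixture("reversible_chain_42_scaled", p = 2, q = -1)))
  expect_false(reversibility_check(
    paper_fixture("quadrangle_32_scaled", K = 0.1)))
  # xdot = 1 - y, ydot = -(1 - x)
  fld <- crn_field(data.frame(coeff = c(1, -1), a = c(0, 0), b = c(0, 1)),
                   data.frame(coeff = c(-1, 1), a = c(0, 1), b = c(0, 0)))
  expect_true(reversibility_check(fld))
})

test_that("reversible-center certificate accepts Cor-2 data, rejects others", {
  inst <- cor2_instance()
  cert <- reversible_center_three_reactions(inst$p, inst$q, inst$c, inst$d)
  expect_true(cert$ok)
  expect_identical(cert$kind, "reversible")
  expect_true(reversibility_check(cert$scaled))
  jr <- jacobian_report(cert$scaled)
  expect_lt(abs(jr$trace), 1e-12)
  expect_gt(jr$det, 0)

  # breaking the geometric mean is caught by name
  d2 <- inst$d; d2[3] <- d2[3] * 1.05
  bad <- reversible_center_three_reactions(inst$p, inst$q, inst$c, d2)
  expect_false(bad$ok)
  expect_match(bad$failed_condition, "geometric-mean")

  bad <- reversible_center_three_reactions(1, -2, inst$c, inst$d)
  expect_false(bad$ok)
  expect_match(bad$failed_condition, "condition \\(i\\)")

  c2 <- inst$c; c2[3] <- 1    # sign chain broken
  bad <- reversible_center_three_reactions(inst$p, inst$q, c2, inst$d)
  expect_false(bad$ok)
  expect_match(bad$failed_condition, "condition \\(ii\\)")
})

test_that("center-realizing rate constants survive the full pipeline", {
  inst <- cor2_instance()
  for (k1 in c(1, 2.5)) {
    out <- center_rate_constants(inst$p, inst$q, inst$c, inst$d, kappa1 = k1)
    expect_length(out$kappa, 3)
    expect_true(all(out$kappa > 0))
    expect_true(reversibility_check(out$scaled))
  }
  # wrong exponent (p - q instead of p - q - 1) fails verification
  ratio_wrong <- -(inst$c[2] / inst$d[3]) *
    (-inst$c[1] / inst$d[1])^(inst$p - inst$q)
  sys <- planarcrn:::reaction_system(
    rbind(c(0, 0), c(inst$p, inst$q), c(inst$q, inst$p)),
    cbind(inst$c, inst$d), c(1, 1, ratio_wrong))
  eqr <- three_reaction_equilibrium(sys)
  expect_true(eqr$exists)
  expect_false(reversibility_check(scale_to_unit(sys, eqr$point)))
})

test_that("Lienard transform matches the printed antiderivatives", {
  inst <- cor3_instance()
  sc <- paper_fixture("lienard_53_scaled", c = inst$c, d = inst$d)
  lt <- lienard_transform(sc)
  expect_equal(lt$F(0), 0); expect_equal(lt$G(0), 0)
  # F' = f and G' = g numerically
  h <- 1e-6
  for (x in c(-0.3, 0.2, 0.9)) {
    expect_equal((lt$F(x + h) - lt$F(x - h)) / (2 * h), lt$f(x),
                 tolerance = 1e-6)
    expect_equal((lt$G(x + h) - lt$G(x - h)) / (2 * h), lt$g(x),
                 tolerance = 1e-6)
  }
  # closed form of F from the scaled coefficients
  co <- lt$coefficients
  for (x in c(-0.4, 0.5, 1.2))
    expect_equal(lt$F(x),
                 -co$A1 * x - co$B2 * ((x + 1)^(-1 / 2) - 1) -
                   co$B3 * ((x + 1)^(-2) - 1), tolerance = 1e-12)
  # g(y) y > 0 near 0 (restoring force for positive g-scale)
  if (co$g_scale > 0)
    for (y in c(-0.05, 0.05)) expect_gt(lt$g(y) * y, 0)
  expect_error(lienard_transform(
    paper_fixture("reversible_chain_42_scaled", p = 2, q = -1)),
    "exponent pattern")
})

test_that("Lienard center certificate: composition holds, controls fail", {
  inst <- cor3_instance()
  sc <- paper_fixture("lienard_53_scaled", c = inst$c, d = inst$d)
  cert <- lienard_center_check(sc)
  expect_true(cert$ok)
  jr <- jacobian_report(sc)
  expect_lt(abs(jr$trace), 1e-12)
  expect_equal(jr$det, 3 / (2 * sc$lam) * sc$K * prod(sc$kbar),
               tolerance = 1e-10)
  # negative control: wrong K breaks the balance, named equality reported
  sc_bad <- paper_fixture("lienard_53_scaled", c = inst$c, d = inst$d,
                          K = 1.3)
  bad <- lienard_center_check(sc_bad)
  expect_false(bad$ok)
  expect_match(bad$failed_condition, "kbar")
})

test_that("center certificates imply vanishing displacement and L values", {
  inst2 <- cor2_instance(); inst3 <- cor3_instance()
  centers <- list(
    paper_fixture("reversible_chain_42_scaled", p = 2, q = -1),
    reversible_center_three_reactions(inst2$p, inst2$q, inst2$c,
                                      inst2$d)$scaled,
    paper_fixture("lienard_53_scaled", c = inst3$c, d = inst3$d))
  for (sc in centers) {
    expect_lt(abs(return_map_displacement(sc, 0.05)), 1e-8)
    expect_lt(max(abs(focal_values(sc, k_max = 3)$L)), 1e-8)
  }
})

test_that("reversibility implies mirror-symmetric trajectories", {
  sc <- paper_fixture("reversible_chain_42_scaled", p = 2, q = -1)
  neg <- crn_field(transform(sc$field$dx, coeff = -coeff),
                   transform(sc$field$dy, coeff = -coeff))
  start <- c(1.05, 0.97); tt <- 0.8
  fwd <- integrate_orbit(sc, start, tt, rtol = 1e-12, atol = 1e-13,
                         store = FALSE)
  bwd <- integrate_orbit(neg, rev(start), tt, rtol = 1e-12, atol = 1e-13,
                         store = FALSE)
  expect_equal(c(fwd$x_end, fwd$y_end), c(bwd$y_end, bwd$x_end),
               tolerance = 1e-8)
})
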