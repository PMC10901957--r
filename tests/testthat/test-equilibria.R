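test_that("chain geometry gives the known h-vectors, exactly", {
  # h1 = -(q + r + 1/2), h2 = r + 1/2, h3 = 0 for the first chain family
  q <- 1 / 4; r <- 15 / 8
  geo <- chain_geometry(paper_fixture("chain_41", q = q, r = r))
  expect_equal(geo$h[1], -(q + r + 1 / 2))
  expect_equal(geo$h[2], r + 1 / 2)
  expect_identical(geo$h[3], 0)

  # h4 = p^2 - q^2 for the reversible chain family
  for (pq in list(c(2, -1), c(3, -2), c(-2, 1))) {
    sys <- paper_fixture("reversible_chain_42", p = pq[1], q = pq[2])
    expect_equal(chain_geometry(sys)$h[4], pq[1]^2 - pq[2]^2)
  }

  # conservation and antisymmetry on random chains
  for (s in 1:10) {
    geo <- chain_geometry(random_chain(s))
    expect_identical(sum(geo$h), 0)          # exact rational cancellation
    for (tr in list(c(1, 2, 3), c(2, 4, 3), c(1, 3, 4)))
      expect_equal(geo$delta(tr[1], tr[2], tr[3]),
                   -geo$delta(tr[2], tr[1], tr[3]))
  }
  expect_error(
    chain_geometry(crn_network(rbind(c("0", "0"), c("1", "0"), c("2", "0"),
                                     c("0", "1")), cbind(1:3, 2:4))),
    "lie on a line")
})

test_that("chain equilibrium: sign test, exact point, kappa independence", {
  sys <- paper_fixture("chain_41", q = 1 / 4, r = 15 / 8)
  eq <- chain_equilibrium(sys)
  expect_true(eq$exists)
  expect_true(eq$kappa_independent)
  expect_equal(unname(eq$point["y"]), 10.5^4, tolerance = 1e-12)
  expect_equal(unname(eq$point["x"]), 1 / (10.5 * 10.5^2), tolerance = 1e-12)
  f <- eval_field(sys, eq$point[1], eq$point[2])
  expect_lt(max(abs(c(f$dx, f$dy))), 1e-12)

  # family always has an equilibrium (all partial h-sums negative)
  for (qr in list(c(0.1, 0.5), c(0.4, 3), c(1, 1)))
    expect_true(chain_equilibrium(
      paper_fixture("chain_41", q = qr[1], r = qr[2]))$exists)

  # existence is constant across 100 random kappa draws
  set.seed(7)
  net <- sys$network
  ex <- vapply(1:100, function(i)
    chain_equilibrium(crn_system(net, exp(runif(3, -2, 2))))$exists,
    logical(1))
  expect_true(all(ex))

  # mixed partial-sum signs: no equilibrium
  bad <- crn_network(rbind(c("0", "0"), c("1", "0"), c("0", "1"), c("2", "3")),
                     cbind(1:3, 2:4))
  h <- chain_geometry(bad)$h
  cums <- cumsum(h)[1:3]
  expect_false(all(sign(cums) == sign(cums[1])) && sign(cums[1]) != 0)
  expect_false(chain_equilibrium(crn_system(bad, c(1, 1, 1)))$exists)
})

test_that("Prop-2 sign test is equivalent to the geometric test", {
  n_agree <- 0
  for (s in 1:300) {
    net <- random_chain(1000 + s)
    geo <- chain_geometry(net)
    cums <- cumsum(geo$h)[1:3]
    sgn_test <- sign(cums[1]) != 0 && all(sign(cums) == sign(cums[1]))
    expect_identical(sgn_test, chain_prop2_geometric(net), info = s)
    n_agree <- n_agree + sgn_test
  }
  expect_gt(n_agree, 10)   # both outcomes exercised
})

test_that("quadrangle equilibrium: closed form, residual oracle, det > 0", {
  eq <- quadrangle_equilibrium(paper_fixture("quadrangle_31"))
  expect_equal(unname(eq$point), c(1, 1), tolerance = 1e-10)

  # printed closed form ((k1^3 k4 / (k3^3 k2))^{1/4}, (k1 k2/(k3 k4))^{1/4})
  k <- c(16, 1, 1, 1)
  eq <- quadrangle_equilibrium(paper_fixture("quadrangle_31", kappa = k))
  expect_equal(unname(eq$point), c(8, 2), tolerance = 1e-10)
  k <- c(3, 5, 2, 7)
  eq <- quadrangle_equilibrium(paper_fixture("quadrangle_31", kappa = k))
  expect_equal(unname(eq$point),
               c((k[1]^3 * k[4] / (k[3]^3 * k[2]))^(1 / 4),
                 (k[1] * k[2] / (k[3] * k[4]))^(1 / 4)), tolerance = 1e-10)

  for (s in 1:6) {
    sys <- random_network("quadrangle_cycle", 300 + s)
    eq <- quadrangle_equilibrium(sys)
    f <- eval_field(sys, eq$point[1], eq$point[2])
    sc <- sum(sys$kappa * eq$point[1]^vertex_matrix(sys)[sys$network$edges[, 1], 1] *
                eq$point[2]^vertex_matrix(sys)[sys$network$edges[, 1], 2])
    expect_lt(max(abs(c(f$dx, f$dy))) / sc, 1e-12)
    jr <- jacobian_report(scale_to_unit(sys, eq$point))
    expect_gt(jr$det, 0)     # index argument: det J positive
  }
})

test_that("binomial and damped-Newton solvers agree on chains", {
  for (s in c(2, 5, 9)) {
    net <- random_chain(500 + s)
    sys <- crn_system(net, c(1.3, 0.7, 2))
    eq <- chain_equilibrium(sys)
    if (!eq$exists) next
    eq2 <- quadrangle_equilibrium(sys)   # generic solver, same field
    expect_equal(unname(eq$point), unname(eq2$point), tolerance = 1e-10)
  }
  sys <- paper_fixture("chain_41", q = 1 / 4, r = 15 / 8)
  expect_equal(unname(chain_equilibrium(sys)$point),
               unname(quadrangle_equilibrium(sys)$point), tolerance = 1e-10)
})

test_that("scale_to_unit reproduces the printed scaled constants", {
  # reversible chain: kbar = ((p-q)/p, -q/(p-q), 1), lambda = -1/(p^2-q^2)
  for (pq in list(c(2, -1), c(3, -1))) {
    p <- pq[1]; q <- pq[2]
    sys <- paper_fixture("reversible_chain_42", p = p, q = q)
    eq <- chain_equilibrium(sys)
    sc <- scale_to_unit(sys, eq$point)
    expect_equal(unname(sc$kbar), c((p - q) / p, -q / (p - q), 1),
                 tolerance = 1e-10)
    expect_equal(sc$K, -p / q, tolerance = 1e-10)
    expect_equal(sc$lam, -1 / (p^2 - q^2), tolerance = 1e-10)
    ev <- eval_field(sc, 1, 1)
    expect_lt(max(abs(c(ev$dx, ev$dy))), 1e-12)
  }

  # second quadrangle: kbar1 = kbar4 gamma, kbar2 = kbar4,
  # kbar3 = kbar4 (gamma + 2) / 3
  sys <- paper_fixture("quadrangle_32", kappa = c(2, 1, 1.5, 0.8))
  eq <- quadrangle_equilibrium(sys)
  sc <- scale_to_unit(sys, eq$point)
  gam <- sc$kbar[1] / sc$kbar[4]
  expect_equal(sc$kbar[2], sc$kbar[4], tolerance = 1e-10)
  expect_equal(sc$kbar[3], sc$kbar[4] * (gam + 2) / 3, tolerance = 1e-10)

  # identity scaling
  sys <- paper_fixture("quadrangle_31")
  sc <- scale_to_unit(sys, c(1, 1))
  expect_equal(sc$kbar, sys$kappa)
  expect_equal(sc$K, 1)

  expect_error(scale_to_unit(sys, c(2, 3)), "not an equilibrium")
})

test_that("jacobian_report matches the printed trace/det closed forms", {
  # chain family: tr J = -1 + (r - q(2q+1)) K / 2
  for (par in list(c(0.25, 1.875, 1), c(0.2, 1.5, 0.7))) {
    q <- par[1]; r <- par[2]; K <- par[3]
    jr <- jacobian_report(paper_fixture("chain_41_scaled",
                                        q = q, r = r, K = K))
    expect_equal(jr$trace, -1 + (r - q * (2 * q + 1)) / 2 * K,
                 tolerance = 1e-12)
  }
  # three-reaction family: det J = K (d - 1) a
  for (par in list(c(1, 0.5, 3, 0.8), c(1.2, 0.3, 2, 1.1))) {
    sc <- paper_fixture("three_51_scaled", a = par[1], b = par[2],
                        d = par[3], K = par[4])
    jr <- jacobian_report(sc)
    expect_equal(jr$det, par[4] * (par[3] - 1) * par[1], tolerance = 1e-10)
    expect_equal(jr$det_closed_form, jr$det, tolerance = 1e-10)
  }
  # reversible chain at the center: J = (p^2 - q^2) [[0,-1],[1,0]]
  sc <- paper_fixture("reversible_chain_42_scaled", p = 2, q = -1)
  jr <- jacobian_report(sc)
  expect_equal(jr$J, (2^2 - 1) * rbind(c(0, -1), c(1, 0)), tolerance = 1e-12)

  # chain det closed form (h1+h2+h3)/lambda * K * prod(kbar)
  sys <- paper_fixture("chain_41", q = 0.3, r = 2)
  eq <- chain_equilibrium(sys)
  sc <- scale_to_unit(sys, eq$point)
  geo <- chain_geometry(sys)
  jr <- jacobian_report(sc, geometry = geo)
  expect_equal(jr$det, jr$det_closed_form, tolerance = 1e-9)
  expect_gt(jr$det, 0)
})

test_that("printed trace-sign inequality matches the numeric trace sign", {
  expect_true(trace_sign_condition_quadrangle_31(c(64, 1, 1, 1)))
  expect_false(trace_sign_condition_quadrangle_31(c(1, 1, 1, 1)))
  # boundary at kappa1 = 49 (since 7^2 = 49)
  for (k1 in c(48.9, 49.1)) {
    k <- c(k1, 1, 1, 1)
    sys <- paper_fixture("quadrangle_31", kappa = k)
    eq <- quadrangle_equilibrium(sys)
    tr <- sum(diag(field_jacobian(sys, eq$point[1], eq$point[2])))
    expect_identical(trace_sign_condition_quadrangle_31(k), tr > 0,
                     info = k1)
  }
})

test_that("three-reaction equilibrium: cross-product sign test", {
  # family: equilibrium exists iff d > 1
  for (d in c(0.5, 1.5, 3)) {
    sys <- paper_fixture("three_51", a = 1, b = 1 / 2, d = d)
    expect_identical(three_reaction_equilibrium(sys)$exists, d > 1, info = d)
  }
  # Cor-2-type sign pattern with c2 = d3 = 0: all cross products positive
  cc <- c(1, 0, -2); dd <- c(-1, 1, 0)
  expect_true(all(cross_products <- c(cc[2] * dd[3] - cc[3] * dd[2],
                                      cc[3] * dd[1] - cc[1] * dd[3],
                                      cc[1] * dd[2] - cc[2] * dd[1]) > 0))
  v <- rbind(c(0, 0), c(2, -1), c(-1, 2))
  net <- crn_network(matrix(as.character(rbind(v, v + cbind(cc, dd))),
                            ncol = 2), cbind(1:3, 4:6))
  eq <- three_reaction_equilibrium(crn_system(net, c(1, 2, 3)))
  expect_true(eq$exists)
  expect_true(eq$kappa_independent)

  # a vanishing cross product kills existence
  cc <- c(1, 2, -1); dd <- c(-1, -2, 2)       # first two rows proportional
  net2 <- crn_network(matrix(as.character(rbind(v, v + cbind(cc, dd))),
                             ncol = 2), cbind(1:3, 4:6))
  expect_false(three_reaction_equilibrium(crn_system(net2, c(1, 1, 1)))$exists)
})
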