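test_that("sweep-based tangent position matches the analytic tangent", {
  m <- tb_machine()
  lf <- hdmlc_leaf()
  step <- 1e-4
  for (tr in c(-20, -2, 0, 5, 18)) {
    pl <- leaf_placement(lf, tr)
    expect_equal(sweep_vr(pl, m, step), find_vr(pl, m), tolerance = 2 * step)
  }
  # with the apex on the CAX the central ray itself is tangent (VR = 0
  # exactly); off-axis the tangent point moves away from the apex and
  # VR != TR
  expect_equal(find_vr(leaf_placement(lf, 0), m), 0)
  expect_false(isTRUE(all.equal(find_vr(leaf_placement(lf, -10), m), -10)))
})

test_that("near-parallel beam: the tangent offset VR - TR is constant in TR", {
  m <- machine_geometry(sad_cm = 1e6, scd_cm = 51)
  lf <- hdmlc_leaf()
  off <- vapply(c(-20, -5, 0, 5, 20), function(tr) {
    find_vr(leaf_placement(lf, tr), m) - tr
  }, numeric(1))
  expect_lt(diff(range(off)), 2e-4)
})

test_that("the 50% crossing is where the path equals one half-value thickness", {
  m <- tb_machine()
  lf <- hdmlc_leaf()
  for (tr in c(-15, 0, 8)) {
    pl <- leaf_placement(lf, tr)
    cv <- sweep_curve(pl, m, step = 1e-4)
    xr <- find_xr(cv)
    pathlen <- with(leaf_path_lengths(xr, pl, m), len_tip + len_body)
    expect_equal(transmit(pathlen, lf$mu), 0.5, tolerance = 1e-3)
    # independent closed-form + root-finding solver agrees
    expect_equal(xr, analytic_crossings(pl, m, 0.5), tolerance = 2e-4)
    # the oracle root satisfies L(x) = ln 2 / mu essentially exactly
    xo <- analytic_crossings(pl, m, 0.5)
    Lo <- with(leaf_path_lengths(xo, pl, m), len_tip + len_body)
    expect_equal(Lo, log(2) / lf$mu, tolerance = 1e-8)
  }
})

test_that("oracle crossings equal a brute-force fine sweep near the root", {
  m <- tb_machine()
  lf <- hdmlc_leaf()
  for (tr in c(-18, -6, 0, 6, 18)) {
    pl <- leaf_placement(lf, tr)
    xo <- analytic_crossings(pl, m, 0.5)
    xs <- seq(xo - 2e-4, xo + 2e-4, by = 1e-7)
    ts <- transmit(with(leaf_path_lengths(xs, pl, m), len_tip + len_body),
                   lf$mu)
    i <- which.min(abs(ts - 0.5))
    expect_equal(xo, xs[i], tolerance = 1e-6)
  }
})

test_that("increasing attenuation pulls the beam edge toward the light-field edge", {
  m <- tb_machine()
  mu <- attenuation_coefficient(0.0122, 6.60)
  lf1 <- leaf_spec(6.60, 16.00, mu_per_cm = mu)
  lf2 <- leaf_spec(6.60, 16.00, mu_per_cm = 2 * mu)
  p1 <- leaf_placement(lf1, -4); p2 <- leaf_placement(lf2, -4)
  m1 <- edge_metrics(p1, m, step = 1e-4)
  m2 <- edge_metrics(p2, m, step = 1e-4)
  expect_lt(m2$xvo, m1$xvo)            # 50% edge closer to the tangent
  expect_lt(m2$beb, m1$beb)            # thinner partial-transmission band
  expect_equal(m2$tzw, m1$tzw)         # tip zone width is geometry only
})

test_that("edge rays stay ordered from body to open field at every clinical position", {
  m <- tb_machine()
  sc <- scan_positions(hdmlc_leaf(), m, trs = -20:20, step = 1e-4)
  # right bank: open field toward -x, so vr <= x80 <= xr <= x20 <= br
  ok <- with(sc, vr <= x80 & x80 <= xr & xr <= x20 & x20 <= br)
  expect_true(all(ok))
  expect_true(all(sc$xvo >= 0 & sc$beb > 0 & sc$tzw > 0))
})

test_that("metrics are invariant under mirroring the bank", {
  m <- tb_machine()
  lf <- hdmlc_leaf()
  for (tr in c(-13, -2, 0, 7, 19)) {
    a <- edge_metrics(leaf_placement(lf, tr, "right"), m, step = 1e-4)
    b <- edge_metrics(leaf_placement(lf, -tr, "left"), m, step = 1e-4)
    expect_equal(a$xvo, b$xvo, tolerance = 1e-9)
    expect_equal(a$beb, b$beb, tolerance = 1e-9)
    expect_equal(a$tzw, b$tzw, tolerance = 1e-9)
    expect_equal(a$vr, -b$vr, tolerance = 1e-9)
    expect_equal(a$xr, -b$xr, tolerance = 1e-9)
  }
})

test_that("in the near-parallel limit all edge metrics are constant in TR", {
  m <- machine_geometry(sad_cm = 1e6, scd_cm = 51)
  lf <- hdmlc_leaf()
  rows <- lapply(c(-20, 0, 20), function(tr) {
    edge_metrics(leaf_placement(lf, tr), m, method = "analytic")
  })
  rows <- do.call(rbind, rows)
  # compare at the collimator plane: the huge SAD otherwise magnifies
  # physically identical offsets
  k <- m$scd / m$sad
  expect_lt(diff(range(rows$xvo)) * k, 1e-5)
  expect_lt(diff(range(rows$beb)) * k, 1e-5)
  expect_lt(diff(range(rows$tzw)) * k, 2e-4)
})

test_that("sweep and closed-form edge offsets agree on the validation geometry", {
  m <- tb_machine()
  lf <- boyer_leaf()
  rel <- vapply(seq(-20, 20, by = 4), function(tr) {
    pl <- leaf_placement(lf, tr)
    sw <- edge_metrics(pl, m, step = 1e-4, method = "sweep")
    an <- edge_metrics(pl, m, method = "analytic")
    abs(sw$xvo - an$xvo) / an$xvo
  }, numeric(1))
  expect_lt(max(rel), 1e-3)
})
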