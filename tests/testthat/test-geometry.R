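test_that("eccentricity reproduces the closed form and its defining identity", {
  # frozen reference: d = 1.6 cm, rho0 = 0.1 cm (verified independently by
  # high-precision arithmetic and by bisection on e*(d-e) = rho0^2)
  e <- eccentricity(0.016, 0.001)
  expect_equal(e, 6.2746066806228228e-05, tolerance = 1e-12)

  # independent root-finding oracle on the identity
  e_root <- uniroot(function(ee) ee * (0.016 - ee) - 0.001^2,
                    c(1e-12, 0.001), tol = 1e-15)$root
  expect_equal(e, e_root, tolerance = 1e-9)

  # identity holds to machine precision over a random admissible sweep
  set.seed(42)
  p <- random_pair_params(200)
  e <- eccentricity(p$d, p$rho0)
  expect_true(all(e > 0 & e < p$rho0))
  expect_equal(e * (p$d - e), p$rho0^2, tolerance = 1e-13)
})

test_that("eccentricity limits and degenerate inputs behave", {
  # thin-wire limit: e -> rho0^2 / d with relative error O((rho0/d)^2)
  d <- 1; rho0 <- 1e-3   # rho0/d = 1e-3
  expect_equal(eccentricity(d, rho0), rho0^2 / d, tolerance = 1e-5)
  expect_error(eccentricity(0.002, 0.001), "touching|overlapping")
  expect_error(eccentricity(0.0015, 0.001), "touching|overlapping")
  expect_error(eccentricity(-1, 0.001), "positive")
  expect_error(eccentricity(0.016, 0), "positive")
})

test_that("electrical axes sit between the centres, displaced by e", {
  A <- electrode(-0.008, 0, "anode"); B <- electrode(0.008, 0, "cathode")
  pg <- electrical_axes(A, B, 0.001)
  s <- sqrt(0.008^2 - 0.001^2)
  expect_equal(pg$xpA, -s, tolerance = 1e-12)   # -0.7937254 cm
  expect_equal(pg$xpB, +s, tolerance = 1e-12)
  expect_equal(pg$ypA, 0, tolerance = 1e-15)
  expect_equal(pg$ypB, 0, tolerance = 1e-15)
  expect_equal(pg$s, s, tolerance = 1e-15)
  # distance between electrical axes equals 2 s = d - 2 e
  expect_equal(sqrt((pg$xpA - pg$xpB)^2 + (pg$ypA - pg$ypB)^2),
               pg$d_AB - 2 * pg$e, tolerance = 1e-15)

  # vertical pair: displacement purely along y
  pgv <- electrical_axes(electrode(0, -0.008, "anode"),
                         electrode(0, 0.008, "cathode"), 0.001)
  expect_equal(pgv$xpA, 0, tolerance = 1e-15)
  expect_equal(pgv$xpB, 0, tolerance = 1e-15)
  expect_equal(pgv$ypA, -s, tolerance = 1e-12)
  expect_equal(pgv$ypB, +s, tolerance = 1e-12)

  expect_error(electrical_axes(A, electrode(-0.008, 0, "cathode"), 0.001),
               "coincident")
})

test_that("electrical_axes is equivariant under rotation and translation", {
  set.seed(7)
  for (k in 1:20) {
    ax <- runif(2, -0.02, 0.02); bx <- runif(2, -0.02, 0.02)
    if (sqrt(sum((ax - bx)^2)) < 0.005) next
    rho0 <- 5e-4
    pg <- electrical_axes(electrode(ax[1], ax[2], "anode"),
                          electrode(bx[1], bx[2], "cathode"), rho0)
    phi <- runif(1, 0, 2 * pi); tr <- runif(2, -0.01, 0.01)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    a2 <- R %*% ax + tr; b2 <- R %*% bx + tr
    pg2 <- electrical_axes(electrode(a2[1], a2[2], "anode"),
                           electrode(b2[1], b2[2], "cathode"), rho0)
    expect_equal(c(pg2$xpA, pg2$ypA), as.vector(R %*% c(pg$xpA, pg$ypA) + tr),
                 tolerance = 1e-12)
    expect_equal(c(pg2$xpB, pg2$ypB), as.vector(R %*% c(pg$xpB, pg$ypB) + tr),
                 tolerance = 1e-12)
    expect_equal(pg2$e, pg$e, tolerance = 1e-12)
  }
})

test_that("group construction enforces the singleton-polarity rule", {
  a1 <- electrode(-0.01, 0, "anode"); a2 <- electrode(0, 0.01, "anode")
  c1 <- electrode(0.01, 0, "cathode"); c2 <- electrode(0, -0.01, "cathode")
  expect_s3_class(electrode_group(list(a1, c1), 1000), "nf_group")
  expect_s3_class(electrode_group(list(c1, a1, a2), 1000), "nf_group")
  expect_error(electrode_group(list(a1, a2), 1000), "both polarities")
  expect_error(electrode_group(list(a1, a2, c1, c2), 1000),
               "exactly one electrode of one polarity")
  expect_error(electrode_group(list(a1, c1), 0), "positive")
  expect_error(electrode_group(list(a1), 1000), ">= 2")
})

test_that("pair enumeration splits groups into hub pairs at group voltage", {
  c1 <- electrode(0, 0, "cathode", "c1")
  a1 <- electrode(-0.01, 0, "anode", "a1")
  a2 <- electrode(0.01, 0, "anode", "a2")
  lay <- layout(list(electrode_group(list(c1, a1, a2), 1000)),
                electrode_radius = 5e-4, tissue_side = 0.05,
                tumor_diameter = 0.01)
  pairs <- enumerate_pairs(lay)
  expect_length(pairs, 2L)
  expect_equal(vapply(pairs, function(p) p$cathode$id, character(1)),
               c("c1", "c1"))
  expect_setequal(vapply(pairs, function(p) p$anode$id, character(1)),
                  c("a1", "a2"))
  expect_equal(vapply(pairs, `[[`, numeric(1), "voltage"), c(1000, 1000))

  # two single-pair groups: exactly 2 pairs, none cross-group
  g1 <- electrode_group(list(electrode(-0.01, 0.01, "anode", "g1a"),
                             electrode(0.01, 0.01, "cathode", "g1c")), 800)
  g2 <- electrode_group(list(electrode(-0.01, -0.01, "anode", "g2a"),
                             electrode(0.01, -0.01, "cathode", "g2c")), 1200)
  lay2 <- layout(list(g1, g2), 5e-4, 0.05, 0.01)
  pairs2 <- enumerate_pairs(lay2)
  expect_length(pairs2, 2L)
  ids <- lapply(pairs2, function(p) c(p$anode$id, p$cathode$id))
  expect_equal(ids[[1]], c("g1a", "g1c"))
  expect_equal(ids[[2]], c("g2a", "g2c"))
  expect_equal(vapply(pairs2, `[[`, numeric(1), "voltage"), c(800, 1200))

  # single two-electrode group: one pair
  expect_length(enumerate_pairs(std_layout()), 1L)
})

test_that("pair count is n-1 per group and additive over groups", {
  set.seed(11)
  for (rep in 1:10) {
    sizes <- sample(2:4, sample(1:3, 1), replace = TRUE)
    groups <- list(); offset <- 0
    for (n in sizes) {
      els <- list(electrode(offset, 0, "cathode"))
      for (i in seq_len(n - 1L))
        els[[i + 1L]] <- electrode(offset + 0.004 * i, 0.004, "anode")
      groups[[length(groups) + 1L]] <- electrode_group(els, 1000)
      offset <- offset + 0.02
    }
    if (sum(sizes) > 12) next
    lay <- layout(groups, 2e-4, 0.4, 0.05)
    expect_length(enumerate_pairs(lay), sum(sizes - 1L))
  }
})

test_that("layout validation rejects inadmissible configurations", {
  a <- electrode(-0.008, 0, "anode"); c <- electrode(0.008, 0, "cathode")
  g <- electrode_group(list(a, c), 1000)
  expect_error(layout(list(g), 5e-4, 0.05, 0.06), "tumor_diameter")
  expect_error(layout(list(g), 5e-4, 0.01, 0.005), "outside the tissue square")
  # overlapping conductors within a group
  g2 <- electrode_group(list(electrode(0, 0, "anode"),
                             electrode(0.0009, 0, "cathode")), 1000)
  expect_error(layout(list(g2), 5e-4, 0.05, 0.01), "overlapping")
  # too many groups
  many <- lapply(1:7, function(i) electrode_group(
    list(electrode(-0.02 + 0.005 * i, 0.01, "anode"),
         electrode(-0.02 + 0.005 * i, -0.01, "cathode")), 1000))
  expect_error(layout(many, 5e-4, 0.06, 0.01), "at most 6")
})

test_that("fixture layouts have the documented shape", {
  lp <- make_fixture_layout("pair", 0.016, 1300)
  els <- all_electrodes(lp)
  expect_length(els, 2L)
  expect_equal(sort(vapply(els, `[[`, numeric(1), "x")), c(-0.008, 0.008))
  expect_equal(vapply(els, `[[`, numeric(1), "y"), c(0, 0))

  lr <- make_fixture_layout("two_rows", 0.016, 1000)
  expect_length(lr$groups, 3L)
  expect_length(all_electrodes(lr), 6L)
  expect_true(all(vapply(lr$groups, function(g) length(g$electrodes), integer(1)) == 2L))

  lh <- make_fixture_layout("hex6", 0.016, 1000)
  elh <- all_electrodes(lh)
  expect_length(elh, 6L)
  r <- vapply(elh, function(e) sqrt(e$x^2 + e$y^2), numeric(1))
  expect_equal(r, rep(0.016, 6), tolerance = 1e-12)
  pol <- vapply(elh, `[[`, character(1), "polarity")
  expect_equal(sum(pol == "anode"), 3L)

  expect_error(make_fixture_layout("octo", 0.016, 1000))
})
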