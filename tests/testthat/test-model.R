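test_that("symmetric network has the expected structure and volumes", {
  m <- sym_model()
  aus <- m$aus
  expect_identical(nrow(aus), 251L)
  expect_identical(sum(aus$unit == "TU"), 10L)
  # 2^a elements per area, m_AU AUs each
  counts <- table(aus$a[aus$unit == "SU"])
  expect_equal(as.integer(counts), 2^(0:5) * c(1L, 10L, 1L, 1L, 1L, 6L))
  vol <- lung_volumes(m)
  expect_equal(vol$V_total, 3000, tolerance = 0.01)
  expect_equal(vol$V_dead, 144.6, tolerance = 0.01)
  # wiring: chain AUs have 1 child, element-final AUs 2, terminal AUs 0
  kids <- tabulate(aus$parent[aus$parent > 0], nbins = 251)
  last_of_el <- aus$unit == "SU" & aus$zp ==
    c(1L, 10L, 1L, 1L, 1L, 6L)[aus$a + 1L] - 1L
  expect_true(all(kids[which(last_of_el & aus$a < 5L)] == 2L))
  expect_true(all(kids[which(last_of_el & aus$a == 5L)] == 0L))
  expect_true(all(kids[which(!last_of_el)] == 1L))
  expect_error(build_symmetric(weibel_table()[-5, ], 0.0222),
               "generations 0-23")
})

test_that("per-element geometry, flows, Pe and R_D reproduce the reference table", {
  rep <- reproduce_table1(sym_model())
  expect_true(attr(rep, "pass"))
  # named anchors at 1 %
  z15 <- rep[rep$row == "z=15", ]
  expect_equal(z15$Pe, 0.880, tolerance = 0.01)
  expect_equal(z15$R_D, 1.41e-2, tolerance = 0.01)
  expect_equal(rep[rep$row == "z=4", "Pe"], 309.074, tolerance = 0.01)
  expect_equal(rep[rep$row == "TU", "R_D"], 1.33, tolerance = 0.01)
  # Pe = 1 crossing sits between generations 14 and 15
  expect_gt(rep[rep$row == "z=14", "Pe"], 1)
  expect_lt(z15$Pe, 1)
  expect_identical(transition_generation(sym_model()), 15L)
  # inlet link is blocked
  expect_gte(sym_model()$aus$R_D[1], 1e99)
})

test_that("peak flows cascade by subtree alveolar content", {
  m <- sym_model()
  aus <- m$aus
  expect_equal(aus$Q_in[aus$id == "SU-(0,0,0)"], 250)
  # per-element flow halves at each conducting-zone area boundary
  first_pe <- function(a) aus$Q_in[aus$unit == "SU" & aus$a == a &
                                     aus$e == 0 & aus$zp == 0]
  expect_equal(vapply(0:4, first_pe, numeric(1)),
               c(250, 125, 62.5, 31.25, 15.625))
  # flow continuity at every AU (brute-force subtree re-summation)
  for (i in seq_len(nrow(aus))) {
    kids <- which(aus$parent == i)
    expect_equal(aus$Q_in[i], aus$Q_alv[i] + sum(aus$Q_in[kids]),
                 tolerance = 1e-12)
  }
  # total alveolar flow equals the tracheal flow
  expect_equal(sum(aus$Q_alv), 250)
})

test_that("Pe and R_D satisfy the flow-resistance identity on every AU", {
  aus <- sym_model()$aus
  expect_equal(aus$Pe[-1], aus$Q_in[-1] * aus$R_D[-1], tolerance = 1e-12)
})

test_that("asymmetry factorization conserves volume and scales fields", {
  m <- sym_model()
  expect_equal(apply_asymmetry(m, asymmetry_spec(3, 1))$aus, m$aus,
               tolerance = 1e-12)
  for (case in list(c(1, 1.25), c(2, 1.5), c(4, 1.75), c(5, 0.3))) {
    ma <- lung_model(asymmetry = asymmetry_spec(case[1], case[2]))
    expect_equal(sum(ma$aus$V), sum(m$aus$V), tolerance = 1e-12)
    # sibling factor sum within the asymmetry area
    aa <- ma$aus[ma$aus$unit == "SU" & ma$aus$a == case[1] & ma$aus$zp == 0, ]
    aa <- aa[order(aa$e), ]
    expect_equal(aa$f_tot[c(TRUE, FALSE)] + aa$f_tot[c(FALSE, TRUE)],
                 rep(2, nrow(aa) / 2))
    # geometry scalings: l ~ f^(1/3), A ~ f^(2/3), V and flows ~ f
    f <- ma$aus$f_tot
    expect_equal(ma$aus$l, m$aus$l * f^(1 / 3))
    expect_equal(ma$aus$A, m$aus$A * f^(2 / 3))
    expect_equal(ma$aus$Q_in, m$aus$Q_in * f, tolerance = 1e-12)
    # brute-force flow re-summation on the transformed tree
    for (i in seq(1L, nrow(ma$aus), by = 6L)) {
      kids <- which(ma$aus$parent == i)
      expect_equal(ma$aus$Q_in[i],
                   ma$aus$Q_alv[i] + sum(ma$aus$Q_in[kids]),
                   tolerance = 1e-12)
    }
  }
  expect_error(asymmetry_spec(3, 2), "between 0 and 2")
  expect_error(asymmetry_spec(0, 1.5), "1..5")
  # volume ratio of the parallel units for the strongest case
  ma <- asym_model(4, 1.75)
  part <- partition_lung_units(ma)
  expect_equal(sum(ma$aus$V[part$label == "LU1"]) /
                 sum(ma$aus$V[part$label == "LU2"]), 7, tolerance = 1e-9)
})

test_that("time constants factorize as the RC analogy predicts", {
  m <- time_constants(sym_model())
  expect_equal(m$aus$tau_D[-1], m$aus$R_D[-1] * m$aus$V[-1])
  expect_equal(m$aus$tau_c, m$aus$V / m$aus$Q_in)
  ma <- time_constants(asym_model(4, 1.75))
  # convective time constants are invariant under the factorization
  expect_equal(ma$aus$tau_c, m$aus$tau_c, tolerance = 1e-12)
  # deep inside a uniform-factor subtree tau_D scales by f_tot^(2/3)
  deep <- which(ma$aus$unit == "SU" & ma$aus$a == 5 & ma$aus$zp > 0)
  f <- ma$aus$f_tot[deep]
  expect_equal(ma$aus$tau_D[deep], m$aus$tau_D[deep] * f^(2 / 3),
               tolerance = 1e-12)
})

test_that("transition generation follows the flow and diffusion regime", {
  # vanishing diffusion: convection dominates everywhere
  m0 <- lung_model(gas = gas("slow", 1e-9))
  expect_identical(transition_generation(m0), NA_integer_)
  # tenfold flows push the transition at least one generation deeper,
  # verified by re-evaluating Pe from the definition
  mf <- lung_model(pattern = breathing_pattern(4, 2500, 200))
  expect_gte(transition_generation(mf), 16L)
  expect_equal(mf$aus$Pe, mf$aus$Q_in * mf$aus$delta / (0.6 * mf$aus$A))
})

test_that("lung-unit partition labels cover the tree symmetrically", {
  m <- sym_model()
  for (a in 1:5) {
    part <- partition_lung_units(m, a)
    expect_identical(length(part$label), 251L)
    expect_identical(sum(part$label == "LU1"), sum(part$label == "LU2"))
    expect_true(all(part$label %in% c("LU0", "LU1", "LU2")))
    # LU0 holds the TU and every area above a
    expect_identical(which(part$label == "LU0"),
                     which(m$aus$unit == "TU" | m$aus$a < a))
  }
  # at area 4 the shared region is exactly the dead space
  p4 <- partition_lung_units(m, 4)
  expect_equal(p4$V_LU0, lung_volumes(m)$V_dead)
  expect_equal(round(p4$dt_LU0, 1), 0.6)
  # at area 1 it is the TU plus the single area-0 AU
  p1 <- partition_lung_units(m, 1)
  expect_identical(sum(p1$label == "LU0"), 11L)
  expect_error(partition_lung_units(m), "area")
})

test_that("axial positions reproduce the reference coordinate", {
  rep <- reproduce_table1(sym_model())
  su <- rep[rep$row != "TU", ]
  expect_true(all(abs(su$x - su$x_ref) < 0.05))
})

test_that("model JSON export is complete and reimportable", {
  path <- withr::local_tempfile(fileext = ".json")
  export_model_json(sym_model(), path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(nrow(obj$aus), 251L)
  expect_equal(obj$scaling_factor, sym_model()$s)
  expect_equal(sum(obj$aus$V), 3000, tolerance = 0.01)
})
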