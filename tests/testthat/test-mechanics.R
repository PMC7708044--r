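test_that("element labelling follows the block convention", {
  sys <- assemble(design_preset("C170L"), material_params())
  counts <- nanobeam:::spring_counts(sys)
  # per helix: 170 junctions x 5 bp blocks = 850 HJ elements, 2750 intact
  expect_identical(counts$n_elements[counts$label == "HJ"], 2L * 850L)
  expect_identical(counts$n_elements[counts$label == "DS"], 2L * 2750L)
  expect_identical(counts$n_elements[counts$label == "NICK"], 0L)

  sysn <- assemble(design_preset("C170N"), material_params())
  countsn <- nanobeam:::spring_counts(sysn)
  expect_identical(countsn$n_elements[countsn$label == "NICK"], 340L)
})

test_that("identity degradation gives uniform spring stiffness EA / rise", {
  sys <- assemble(design_preset("C170N"), material_params(alpha = 1, beta = 1))
  expect_equal(unique(as.vector(sys$stiffness)), 1100 / 0.34)
})

test_that("overlapping degraded blocks are rejected with positions named", {
  d <- nanobeam_design(2, 100,
                       junctions = data.frame(helix_a = 1, helix_b = 2, pos = 50),
                       nicks = data.frame(helix = 1, pos = 51))
  expect_error(assemble(d, material_params()), "51",
               class = "nanobeam_validation_error")
  # junction blocks closer than their span on the same helix
  d2 <- nanobeam_design(2, 100,
                        junctions = data.frame(helix_a = c(1, 1), helix_b = c(2, 2),
                                               pos = c(50, 53)))
  expect_error(assemble(d2, material_params()), class = "nanobeam_validation_error")
})

test_that("tension solve matches series and parallel closed forms", {
  m <- material_params()
  single <- nanobeam_design(1, 3600, name = "single")
  expect_equal(solve_tension(assemble(single, m), 10), 10 * 1224 / 1100,
               tolerance = 1e-9)
  # two intact helices tied only at the end plates: parallel doubling
  pair <- nanobeam_design(2, 3600, name = "pair")
  expect_equal(solve_tension(assemble(pair, m), 10), 10 * 1224 / 2200,
               tolerance = 1e-9)
})

test_that("response is linear in force", {
  sys <- assemble(design_preset("C85N"), material_params(alpha = 0.02, beta = 0.006))
  d1 <- solve_tension(sys, 7)
  d2 <- solve_tension(sys, 14)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  expect_equal(solve_tension(sys, 0), 0)
})

test_that("apparent stiffness of intact assemblies equals N x EA at machine precision", {
  m <- material_params()
  for (bp in c(500, 3600)) {
    k1 <- apparent_stiffness(nanobeam_design(1, bp), m)$stiffness_pN
    expect_equal(k1, 1100, tolerance = 1e-10)
  }
  for (n in c(2, 5)) {
    kn <- apparent_stiffness(nanobeam_design(n, 1000), m)$stiffness_pN
    expect_equal(kn, n * 1100, tolerance = 1e-10)
  }
  # alpha = beta = 1 on a full design also recovers N x EA exactly
  k <- apparent_stiffness(design_preset("C170N"), material_params(alpha = 1, beta = 1))
  expect_equal(k$stiffness_pN, 2 * 1100, tolerance = 1e-10)
})

test_that("homogenized stiffness evaluates its closed form", {
  expect_equal(homogenized_stiffness(3, 0, 0, material_params()), 3 * 1100)
  m1 <- material_params(alpha = 0.0209)
  expect_equal(homogenized_stiffness(2, 1, 0, m1),
               2 * 1100 * 21 / (16 + 5 / 0.0209), tolerance = 1e-12)
  expect_equal(homogenized_stiffness(2, 1, 0, m1), 181.0, tolerance = 1e-3)
  m2 <- material_params(alpha = 0.0209, beta = 0.00576)
  expect_equal(homogenized_stiffness(2, 0.5, 0.5, m2), 205.9, tolerance = 1e-3)
  expect_error(homogenized_stiffness(2, 4, 2, material_params()),
               class = "nanobeam_validation_error")
})

test_that("network solve agrees with the independent series-parallel oracle", {
  for (s in c(21, 42)) {
    for (lig in c(TRUE, FALSE)) {
      for (a in c(0.02, 0.3)) {
        d <- build_two_helix(3600, s, ligated = lig)
        m <- material_params(alpha = a, beta = 0.006)
        k_net <- apparent_stiffness(d, m)$stiffness_pN
        expect_equal(k_net, oracle_series_stiffness(d, m), tolerance = 1e-9,
                     info = sprintf("s=%d ligated=%s alpha=%g", s, lig, a))
      }
    }
  }
})

test_that("homogenized oracle matches the network within the periodicity error", {
  m <- material_params(alpha = 0.0207, beta = 0.0057)
  # nominal densities, end effects included: < 2 %
  cases <- list(list(design_preset("C170L"), 1, 0),
                list(design_preset("C170N"), 1, 1),
                list(design_preset("C85N"), 0.5, 0.5),
                list(design_preset("6HB"), 2, 0.5),
                list(design_preset("10HB"), 2, 0.5))
  for (cs in cases) {
    k_net <- apparent_stiffness(cs[[1]], m)$stiffness_pN
    k_hom <- homogenized_stiffness(cs[[1]]$n_helices, cs[[2]], cs[[3]], m)
    expect_lt(abs(k_net - k_hom) / k_hom, 0.02)
  }
  # densities measured on the realized design: < 0.5 % (length an exact
  # multiple of the repeat)
  d <- build_two_helix(2100, 21, ligated = TRUE)
  s <- design_summary(d)
  k_net <- apparent_stiffness(d, m)$stiffness_pN
  k_hom <- homogenized_stiffness(2, s$junctions_per_helix_per_21bp, 0, m)
  expect_lt(abs(k_net - k_hom) / k_hom, 0.005)
})

test_that("stiffness is monotone in the material and density parameters", {
  d <- design_preset("C170N")
  k <- function(a, b, EA = 1100) {
    apparent_stiffness(d, material_params(EA = EA, alpha = a, beta = b))$stiffness_pN
  }
  expect_lt(k(0.01, 0.006), k(0.05, 0.006))
  expect_lt(k(0.02, 0.003), k(0.02, 0.01))
  expect_lt(k(0.02, 0.006), k(0.02, 0.006, EA = 1500))
  m <- material_params(alpha = 0.02, beta = 0.006)
  expect_gt(homogenized_stiffness(2, 0.5, 0.5, m), homogenized_stiffness(2, 1, 0.5, m))
  expect_gt(homogenized_stiffness(2, 1, 0.25, m), homogenized_stiffness(2, 1, 1, m))
})

test_that("construct ordering and the ligated >= nicked rule hold", {
  m <- material_params(alpha = 0.0207, beta = 0.0057)
  k <- vapply(c("C85L", "C85N", "C170L", "C170N"),
              function(nm) apparent_stiffness(design_preset(nm), m)$stiffness_pN,
              numeric(1))
  expect_true(all(diff(k) < 0))  # C85L > C85N > C170L > C170N
  expect_gte(k[["C85L"]], k[["C85N"]])
  expect_gte(k[["C170L"]], k[["C170N"]])
})

test_that("force-extension curves pass through the origin and increase", {
  fe <- force_extension(design_preset("C85L"), material_params(alpha = 0.02),
                        forces = seq(0, 65, by = 5))
  expect_equal(fe$extension_nm[1], 0)
  expect_true(all(diff(fe$extension_nm) > 0))
})

test_that("bundle sweep scales stiffness with helix count", {
  m <- material_params(alpha = 0.02, beta = 0.006)
  sw <- bundle_sweep(n_helices = c(2, 4), packing = "honeycomb", material = m,
                     length_nm = 214, junctions_per_21bp = 2, nicks_per_21bp = 0.5)
  expect_identical(nrow(sw), 2L)
  expect_lt(sw$stiffness_pN[1], sw$stiffness_pN[2])
  # identical per-helix densities: stiffness ratio equals the helix-count ratio
  expect_equal(homogenized_stiffness(6, 2, 0.5, m) / homogenized_stiffness(10, 2, 0.5, m),
               0.6, tolerance = 1e-12)
  # no degradation: normalized stiffness is the helix count
  sw1 <- bundle_sweep(n_helices = 1, packing = "pair", material = material_params(),
                      length_nm = 100, junctions_per_21bp = 0, nicks_per_21bp = 0)
  expect_equal(sw1$normalized_stiffness, 1, tolerance = 1e-10)
})
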