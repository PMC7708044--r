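test_that("two-helix builder reproduces the printed junction and nick counts", {
  cases <- list(
    # bp, spacing, ligated, junctions, nicks
    list(3600, 21, FALSE, 170L, 340L),
    list(3600, 42, FALSE, 85L, 170L),
    list(3600, 21, TRUE, 170L, 0L),
    list(3600, 42, TRUE, 85L, 0L),
    list(20, 21, TRUE, 0L, 0L)   # spacing exceeds the helix: no junctions
  )
  for (cs in cases) {
    d <- build_two_helix(cs[[1]], cs[[2]], ligated = cs[[3]])
    expect_identical(nrow(d$junctions), cs[[4]])
    expect_identical(nrow(d$nicks), cs[[5]])
  }
  expect_equal(build_two_helix(3600, 21)$length_nm, 1224, tolerance = 1e-9)
})

test_that("junction placement matches brute-force enumeration of the half-repeat rule", {
  for (bp in c(50, 100, 1050, 2100, 3600)) {
    for (s in c(2, 7, 21, 42, 100)) {
      d <- build_two_helix(bp, s, ligated = TRUE)
      expect_identical(d$junctions$pos, brute_force_junctions(bp, s),
                       info = sprintf("bp=%d spacing=%d", bp, s))
    }
  }
})

test_that("nick count is twice the junction count when nicked, zero when ligated", {
  for (s in c(21, 42, 63)) {
    nicked <- build_two_helix(2100, s, ligated = FALSE)
    ligated <- build_two_helix(2100, s, ligated = TRUE)
    expect_identical(nrow(nicked$nicks), 2L * nrow(nicked$junctions))
    expect_identical(nrow(ligated$nicks), 0L)
    # nicks sit midway between consecutive junctions, same position in both helices
    expect_identical(sort(unique(nicked$nicks$pos)),
                     sort(nicked$nicks$pos[nicked$nicks$helix == 1L]))
  }
})

test_that("design invariants hold: interior, sorted, no duplicates", {
  d <- build_two_helix(3600, 21, ligated = FALSE)
  expect_true(all(d$junctions$pos > 0 & d$junctions$pos < d$bp_per_helix))
  expect_true(all(diff(d$junctions$pos) > 0))
  expect_true(all(d$nicks$pos > 0 & d$nicks$pos < d$bp_per_helix))
  expect_false(any(d$nicks$pos %in% d$junctions$pos))
})

test_that("constructor rejects invalid designs", {
  expect_error(build_two_helix(0, 21), class = "nanobeam_validation_error")
  expect_error(build_two_helix(100, 1), class = "nanobeam_validation_error")
  expect_error(
    nanobeam_design(2, 100, junctions = data.frame(helix_a = 1, helix_b = 2, pos = 100)),
    class = "nanobeam_validation_error")
  expect_error(
    nanobeam_design(2, 100, junctions = data.frame(helix_a = 1, helix_b = 1, pos = 50)),
    class = "nanobeam_validation_error")
  expect_error(
    nanobeam_design(2, 100,
                    junctions = data.frame(helix_a = c(1, 1), helix_b = c(2, 2), pos = c(50, 50))),
    class = "nanobeam_validation_error")
  expect_error(
    nanobeam_design(2, 100,
                    junctions = data.frame(helix_a = 1, helix_b = 2, pos = 50),
                    nicks = data.frame(helix = 1, pos = 50)),
    class = "nanobeam_validation_error")
})

test_that("bundle builder hits the target junction totals of the reference bundles", {
  hb6 <- build_bundle(6, "honeycomb", 428, 2, 0.5)
  expect_identical(hb6$bp_per_helix, 1259L)
  expect_lt(abs(nrow(hb6$junctions) - 336) / 336, 0.10)

  hb10 <- build_bundle(10, "honeycomb", 257, 2, 0.5)
  expect_lt(abs(nrow(hb10$junctions) - 360) / 360, 0.10)

  single <- build_bundle(1, "pair", 100, 0, 0)
  expect_identical(single$n_helices, 1L)
  expect_identical(nrow(single$junctions), 0L)
  expect_identical(nrow(single$nicks), 0L)
})

test_that("bundles keep per-helix participation near the requested density", {
  hb6 <- build_bundle(6, "honeycomb", 428, 2, 0.5)
  target <- round(1259 * 2 / 21)
  for (h in seq_len(6)) {
    got <- sum(hb6$junctions$helix_a == h | hb6$junctions$helix_b == h)
    expect_lte(abs(got - target), 1)
  }
})

test_that("a 2-helix bundle at one participation per 21 bp reproduces the C170 topology", {
  b2 <- build_bundle(2, "pair", 1224, 1, 0)
  ref <- design_preset("C170L")
  expect_lte(abs(nrow(b2$junctions) - nrow(ref$junctions)), 1)
  m <- material_params(alpha = 0.02)
  k_b <- apparent_stiffness(b2, m)$stiffness_pN
  k_r <- apparent_stiffness(ref, m)$stiffness_pN
  expect_lt(abs(k_b - k_r) / k_r, 0.01)
})

test_that("bundle builder rejects impossible requests", {
  expect_error(build_bundle(1, "honeycomb", 100, 2, 0),
               class = "nanobeam_validation_error")
  expect_error(build_bundle(6, "honeycomb", 428, 8, 2),
               class = "nanobeam_validation_error")
})

test_that("design JSON round trip is exact", {
  for (nm in c("C170N", "6HB")) {
    d <- design_preset(nm)
    path <- withr::local_tempfile(fileext = ".json")
    write_design(d, path)
    d2 <- read_design(path)
    expect_identical(d2$junctions, d$junctions)
    expect_identical(d2$nicks, d$nicks)
    expect_identical(d2$bp_per_helix, d$bp_per_helix)
    expect_identical(d2$packing, d$packing)
    expect_equal(d2$rise_per_bp, d$rise_per_bp)
    expect_identical(d2$name, d$name)
  }
})

test_that("presets carry the expected geometry", {
  s <- purrr::map_dfr(c("C85L", "C85N", "C170L", "C170N"), ~design_summary(design_preset(.x)))
  expect_equal(s$length_nm, rep(1224, 4))
  expect_identical(s$n_junctions, c(85L, 85L, 170L, 170L))
  expect_identical(s$n_nicks, c(0L, 170L, 0L, 340L))
})
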