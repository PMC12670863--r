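test_that("chamber volume is a Simpson slice summation", {
  case <- radii_case(rep(20, 5))  # 5 disks r = 20 mm, D = 10 mm
  expect_equal(chamber_volume(case, "lv_endo", "ED"),
               5 * pi * 400 * 10 / 1000, tolerance = 0.1)
  expect_equal(chamber_volume(case, "rv_endo", "ED"), 0)
  expect_error(chamber_volume(case, "lv_endo", "ES"), "missing-phase")
  # linearity in inter-slice distance: doubling D doubles volume
  case2 <- radii_case(rep(20, 5), geom = geom_unit(thickness = 8, gap = 12))
  expect_equal(chamber_volume(case2, "lv_endo", "ED"),
               2 * chamber_volume(case, "lv_endo", "ED"))
  # quadratic in in-plane spacing
  case3 <- radii_case(rep(20, 5), geom = geom_unit(sr = 2, sc = 2))
  expect_equal(chamber_volume(case3, "lv_endo", "ED"),
               4 * chamber_volume(case, "lv_endo", "ED"))
})

ring_case <- function(r_endo, r_epi, n_slices = 5, phase = "ED",
                      geom = geom_unit(), sequence = "sax_cine") {
  slices <- lapply(seq_len(n_slices), function(i)
    cmr_slice(i - 1L, phase, list(
      lv_endo = list(circle_poly(60, 60, r_endo)),
      lv_epi = list(circle_poly(60, 60, r_epi)))))
  cmr_case("ring", "R1", sequence, geom, slices)
}

test_that("myocardial mass is the annulus volume times 1.05 g/ml", {
  case <- ring_case(20, 30)
  expect_equal(myocardial_mass(case, "ED"),
               5 * pi * (900 - 400) * 10 / 1000 * 1.05, tolerance = 0.2)
  expect_equal(myocardial_mass(ring_case(25, 25), "ED"), 0, tolerance = 1e-6)
  # epi accidentally smaller than endo: clamped to zero with a warning
  expect_warning(m <- myocardial_mass(ring_case(30, 20, n_slices = 1), "ED"),
                 "clamped")
  expect_equal(m, 0)
})

test_that("papillary mass follows the same summation", {
  slices <- lapply(1:2, function(i)
    cmr_slice(i - 1L, "ED", list(papmu = list(square_poly(0, 0, 10)))))
  case <- cmr_case("p", "R1", "sax_cine", geom_unit(), slices)
  expect_equal(papillary_mass(case, "ED"), 2 * 100 * 10 / 1000 * 1.05)
})

test_that("stroke volume and ejection fraction identities", {
  expect_equal(sv_ef(160, 80), list(sv = 80, ef = 50))
  expect_equal(sv_ef(120, 48), list(sv = 72, ef = 60))
  expect_equal(sv_ef(100, 100), list(sv = 0, ef = 0))
  expect_warning(r <- sv_ef(80, 100), "negative")
  expect_equal(r$sv, -20)
  expect_true(is.na(sv_ef(0, 0)$ef))
})

test_that("scar mass and fraction, with scar clipped to the myocardial ring", {
  geom <- geom_unit()
  mk_scar <- function(scar_polys) {
    slices <- lapply(1:3, function(i)
      cmr_slice(i - 1L, "single", list(
        lv_endo = list(circle_poly(60, 60, 20)),
        lv_epi = list(circle_poly(60, 60, 30)),
        scar = scar_polys)))
    cmr_case("s", "R1", "sax_lge", geom, slices)
  }
  # a 10x10 patch fully inside the ring (between radii 20 and 30)
  inside <- list(square_poly(60 + 21, 60 - 5, 8))
  res <- scar_mass_fraction(mk_scar(inside))
  expect_equal(res$scarm, 3 * 64 * 10 / 1000 * 1.05, tolerance = 0.01)
  lvm <- myocardial_mass(mk_scar(inside), "single")
  expect_equal(res$scarf, 100 * res$scarm / lvm)
  # scar reaching into the cavity only counts its ring intersection
  crossing <- list(square_poly(60 + 15, 60 - 5, 10))  # spans r=15..25
  res2 <- scar_mass_fraction(mk_scar(crossing))
  full_area <- 3 * 100 * 10 / 1000 * 1.05
  expect_lt(res2$scarm, full_area)
  expect_gt(res2$scarm, 0)
  # no scar contours -> (0, 0)
  no_scar <- scar_mass_fraction(mk_scar(NULL))
  expect_equal(no_scar, list(scarm = 0, scarf = 0))
})

test_that("SCARF is invariant under global scaling of all areas", {
  mk <- function(geom) {
    slices <- lapply(1:3, function(i)
      cmr_slice(i - 1L, "single", list(
        lv_endo = list(circle_poly(60, 60, 20)),
        lv_epi = list(circle_poly(60, 60, 30)),
        scar = list(square_poly(82, 55, 6)))))
    cmr_case("s", "R1", "sax_lge", geom, slices)
  }
  f1 <- scar_mass_fraction(mk(geom_unit()))$scarf
  f2 <- scar_mass_fraction(mk(geom_unit(sr = 2, sc = 2)))$scarf
  expect_equal(f1, f2)
})

test_that("atrial area, length and the area-length ellipsoid volume", {
  geom <- geom_unit()
  rect <- matrix(c(0, 0, 20, 0, 20, 10, 0, 10), ncol = 2, byrow = TRUE)
  case <- cmr_case("a", "R1", "lax_4cv", geom,
                   list(cmr_slice(0, "ES", list(la = list(rect)))))
  expect_equal(atrial_area(case, "la", "ES"), 2)
  expect_true(is.na(atrial_area(case, "ra", "ES")))
  frag <- cmr_case("a", "R1", "lax_4cv", geom,
                   list(cmr_slice(0, "ES", list(la = list(
                     square_poly(0, 0, 10), square_poly(30, 0, sqrt(50)))))))
  expect_equal(atrial_area(frag, "la", "ES"), 1.5)

  expect_equal(atrial_volume(20, 5), 8 * 400 / (3 * pi * 5))
  expect_equal(atrial_volume(20, 5), 67.906, tolerance = 1e-3)
  expect_equal(atrial_volume(0, 5), 0)
  expect_error(atrial_volume(10, 0), "length")
  # sphere consistency: circle of radius r gives (4/3) pi r^3
  r <- 3  # cm
  expect_equal(atrial_volume(pi * r^2, 2 * r), 4 / 3 * pi * r^3)
  expect_equal(atrial_volume(pi * 9, 6), 113.097, tolerance = 1e-3)
  # max-caliper length of a circular contour is its diameter
  circ <- cmr_case("a", "R1", "lax_4cv", geom,
                   list(cmr_slice(0, "ES", list(la = list(circle_poly(60, 60, 30))))))
  expect_equal(atrial_length(circ, "la", "ES"), 6, tolerance = 0.01)
})

map_slice <- function(vm, r_endo = 10, r_epi = 20, center = 32,
                      with_refpoint = TRUE) {
  cont <- list(lv_endo = list(circle_poly(center, center, r_endo)),
               lv_epi = list(circle_poly(center, center, r_epi)))
  if (with_refpoint)
    cont$refpoint <- list(matrix(c(center - r_epi, center), ncol = 2))
  cmr_slice(0, "single", cont, value_map = vm)
}

test_that("global mapping value averages ring voxels", {
  vm <- matrix(1000, 64, 64)
  expect_equal(global_mapping_value(map_slice(vm)), 1000)
  # two half-plane values, ring centered on the split line: exact midpoint
  vm2 <- matrix(900, 64, 64); vm2[, 33:64] <- 1100
  s <- map_slice(vm2, center = 31.5)
  expect_equal(global_mapping_value(s), 1000, tolerance = 0.01)
  # brute-force membership oracle: voxel center radius in [r_endo, r_epi]
  vm3 <- matrix(stats::rnorm(64 * 64, 1000, 50), 64, 64)
  s3 <- map_slice(vm3)
  ii <- rep(0:63, times = 64); jj <- rep(0:63, each = 64)
  rad <- sqrt((jj - 32)^2 + (ii - 32)^2)
  kgon_r <- function(r) r * cos(pi / 180)  # inradius bound of the 180-gon
  sel <- rad <= kgon_r(20) & rad >= 10.001
  expect_equal(global_mapping_value(s3),
               mean(vm3[cbind(ii[sel] + 1, jj[sel] + 1)]), tolerance = 0.5)
})

test_that("angular segments partition the ring and recover sector fields", {
  vm <- matrix(1000, 64, 64)
  s <- map_slice(vm)
  seg <- aha_segments(s, geom_unit(), n_segments = 6)
  expect_equal(nrow(seg), 6)
  expect_true(all(seg$mean == 1000))
  # partition identity: counts sum to ring count, weighted mean = global
  vm2 <- matrix(stats::rnorm(64 * 64, 1000, 100), 64, 64)
  s2 <- map_slice(vm2)
  seg2 <- aha_segments(s2, geom_unit())
  g <- global_mapping_value(s2)
  expect_equal(sum(seg2$voxel_count * seg2$mean) / sum(seg2$voxel_count), g)
  # field valued by angular sector is recovered per sector; sector 1
  # starts at the refpoint ray (pointing at angle pi from the centroid)
  ii <- rep(0:63, times = 64); jj <- rep(0:63, each = 64)
  ang <- (atan2(ii - 32, jj - 32) - pi) %% (2 * pi)
  sec <- pmin(floor(ang / (pi / 3)) + 1, 6)
  vm3 <- matrix(0, 64, 64)
  vm3[cbind(ii + 1, jj + 1)] <- 100 * sec
  s3 <- map_slice(vm3)
  seg3 <- aha_segments(s3, geom_unit())
  expect_equal(seg3$mean, 100 * (1:6), tolerance = 1e-9)
  expect_error(aha_segments(map_slice(vm, with_refpoint = FALSE), geom_unit()),
               "reference-point")
})

test_that("refpoint distance uses anisotropic spacing", {
  mk <- function(p) cmr_slice(0, "single",
                              list(refpoint = list(matrix(p, ncol = 2))))
  expect_equal(refpoint_distance(mk(c(0, 0)), mk(c(3, 4)), geom_unit()), 5)
  expect_equal(refpoint_distance(mk(c(1, 1)), mk(c(1, 1)), geom_unit()), 0)
  expect_equal(refpoint_distance(mk(c(0, 0)), mk(c(3, 4)),
                                 geom_unit(sr = 2, sc = 2)), 10)
  expect_true(is.na(refpoint_distance(mk(c(0, 0)),
                                      cmr_slice(0, "single"), geom_unit())))
})

test_that("clinical_parameters satisfies the SV/EF identities", {
  g <- generate_case(small_params(), seed = 2)
  cp <- clinical_parameters(g$case)
  v <- function(p) cp$value[cp$parameter == p]
  expect_equal(v("LVSV"), v("LVEDV") - v("LVESV"))
  expect_equal(v("LVEF") * v("LVEDV"), 100 * v("LVSV"))
  expect_equal(v("RVSV"), v("RVEDV") - v("RVESV"))
  expect_true(all(c("LVM", "PAPMU_ES", "PAPMU_ED") %in% cp$parameter))
})
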