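two_reader_pair <- function(radii1, radii2, phase = "ED", geom = geom_unit()) {
  pair_cases(radii_case(radii1, phase = phase, geom = geom),
             radii_case(radii2, phase = phase, geom = geom, reader = "R2"))
}

test_that("volume traces conserve the parameter difference exactly", {
  # readers differ only on one slice
  r1 <- rep(20, 5); r2 <- r1; r2[3] <- sqrt(20^2 + 200 / pi)  # +200 mm^2
  pr <- two_reader_pair(r1, r2)
  tr <- trace_parameter(pr, "LVEDV")
  expect_equal(sum(tr$contribution), attr(tr, "total_diff"))
  expect_equal(attr(tr, "total_diff"),
               chamber_volume(radii_case(r1), "lv_endo", "ED") -
               chamber_volume(radii_case(r2, reader = "R2"), "lv_endo", "ED"))
  expect_equal(tr$slice_index[1], 2L)  # the discrepant slice dominates
  expect_equal(tr$contribution[1], -200 * 10 / 1000, tolerance = 0.005)
  expect_true(all(abs(tr$contribution[-1]) < 1e-9))
  # identical readers trace to zero everywhere
  tr0 <- trace_parameter(two_reader_pair(r1, r1), "LVEDV")
  expect_true(all(tr0$contribution == 0))
  expect_true(all(tr0$dice > 1 - 1e-8))
})

test_that("dilation trace matches the first-order ring expansion", {
  radii <- c(30, 27, 24, 21, 18)
  delta <- 1
  pr <- two_reader_pair(radii, radii + delta)
  tr <- trace_parameter(pr, "LVEDV", metrics = FALSE)
  tr <- tr[order(tr$slice_index), ]
  kfac <- 180 / (2 * pi) * sin(2 * pi / 180)
  expected <- -kfac * pi * ((radii + delta)^2 - radii^2) * 10 / 1000
  expect_equal(tr$contribution, expected, tolerance = 1e-9)
  first_order <- -(2 * pi * radii * delta + pi * delta^2) * 10 / 1000
  expect_equal(tr$contribution, first_order, tolerance = 0.001)
  expect_equal(sum(tr$contribution),
               chamber_volume(radii_case(radii), "lv_endo", "ED") -
               chamber_volume(radii_case(radii + delta, reader = "R2"),
                              "lv_endo", "ED"))
})

test_that("stroke volume and ejection fraction traces decompose by phase", {
  mk <- function(r_es, r_ed, reader) {
    slices <- c(
      lapply(seq_along(r_es), function(i)
        cmr_slice(i - 1L, "ES", list(lv_endo = list(circle_poly(60, 60, r_es[i]))))),
      lapply(seq_along(r_ed), function(i)
        cmr_slice(i - 1L, "ED", list(lv_endo = list(circle_poly(60, 60, r_ed[i]))))))
    cmr_case("sv", reader, "sax_cine", geom_unit(), slices)
  }
  c1 <- mk(c(15, 14), c(22, 21), "R1")
  c2 <- mk(c(16, 14), c(21, 21), "R2")
  pr <- pair_cases(c1, c2)
  tr <- trace_parameter(pr, "LVSV")
  sv1 <- sv_ef(chamber_volume(c1, "lv_endo", "ED"), chamber_volume(c1, "lv_endo", "ES"))
  sv2 <- sv_ef(chamber_volume(c2, "lv_endo", "ED"), chamber_volume(c2, "lv_endo", "ES"))
  expect_equal(sum(tr$contribution), sv1$sv - sv2$sv)
  expect_setequal(unique(tr$phase), c("ES", "ED"))
  # EF trace: slice terms plus one nonlinearity residual, conserving total
  trf <- trace_parameter(pr, "LVEF")
  expect_equal(sum(trf$contribution), sv1$ef - sv2$ef)
  expect_equal(sum(trf$ctype == "nonlinearity"), 1)
  # sorted by absolute contribution
  expect_equal(order(-abs(trf$contribution)), seq_len(nrow(trf)))
})

test_that("conservation holds over randomly perturbed phantom pairs", {
  params <- tiny_params()
  for (k in 1:6) {
    g <- generate_case(params, seed = 200 + k)
    r2 <- perturb_reader(g$case,
                         perturbation(radial_sigma = 1,
                                      dilation_mm = c(lv_endo = 0.5),
                                      p_miss_basal = 0.5, p_fragment = 0.5),
                         params, seed = 300 + k)
    pr <- pair_cases(g$case, r2)
    for (p in c("LVESV", "LVEDV", "RVEDV", "LVM", "PAPMU_ED", "LVSV")) {
      tr <- trace_parameter(pr, p, metrics = FALSE)
      cp1 <- clinical_parameters(g$case); cp2 <- clinical_parameters(r2)
      d <- cp1$value[cp1$parameter == p] - cp2$value[cp2$parameter == p]
      expect_equal(sum(tr$contribution), d, tolerance = 1e-9,
                   info = paste(p, k))
    }
  }
})

test_that("mapping traces decompose the pooled ring mean", {
  g <- generate_case(small_params(), seed = 9, sequence = "sax_t1")
  r2 <- perturb_reader(g$case, perturbation(dilation_mm = c(lv_epi = 2)),
                       small_params(), seed = 10)
  pr <- pair_cases(g$case, r2)
  tr <- trace_parameter(pr, "GLOBAL_T1")
  cp1 <- clinical_parameters(g$case); cp2 <- clinical_parameters(r2)
  expect_equal(sum(tr$contribution),
               cp1$value[cp1$parameter == "GLOBAL_T1"] -
               cp2$value[cp2$parameter == "GLOBAL_T1"], tolerance = 1e-9)
})

test_that("the case table matches hand computation on a 2-slice fixture", {
  r1 <- radii_case(c(20, 10))
  r2c <- radii_case(c(22, 10), reader = "R2")
  pr <- pair_cases(r1, r2c)
  tab <- case_table(pr)
  expect_equal(nrow(tab), 2)  # one ctype, two paired slices
  s0 <- tab[tab$slice_index == 0, ]
  expect_equal(s0$dice, 2 * 20^2 / (20^2 + 22^2), tolerance = 1e-3)
  expect_equal(s0$hd_mm, 2, tolerance = 0.01)
  expect_equal(s0$abs_ml_diff, pi * (22^2 - 20^2) * 10 / 1000, tolerance = 0.01)
  expect_equal(tab$dice[tab$slice_index == 1], 1)
  expect_equal(as.character(s0$position), "basal")
  expect_equal(as.character(tab$position[tab$slice_index == 1]), "apical")
  # identical readers: every row dice 1, hd 0
  tab0 <- case_table(pair_cases(r1, radii_case(c(20, 10), reader = "R2")))
  expect_true(all(tab0$dice > 1 - 1e-8))
  expect_true(all(tab0$hd_mm < 1e-9))
})
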