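test_that("generation is deterministic given the seed", {
  g1 <- generate_case(small_params(), seed = 42)
  g2 <- generate_case(small_params(), seed = 42)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$case$slices, g2$case$slices)
  g3 <- generate_case(small_params(), seed = 43)
  expect_false(identical(g1$case$slices, g3$case$slices))
  p1 <- perturb_reader(g1$case, perturbation(radial_sigma = 1), small_params(),
                       seed = 7)
  p2 <- perturb_reader(g1$case, perturbation(radial_sigma = 1), small_params(),
                       seed = 7)
  expect_identical(p1$slices, p2$slices)
})

test_that("exact polygon truth agrees with the analytic closed forms", {
  g <- generate_case(phantom_params(), seed = 1)
  tr <- g$truth
  for (p in c("LVESV", "LVEDV", "LVSV", "LVEF", "LVM")) {
    row <- tr[tr$parameter == p, ]
    expect_equal(row$exact, row$analytic, tolerance = 0.002, info = p)
  }
  # truth is internally consistent with the SV/EF identities
  v <- function(p) tr$exact[tr$parameter == p]
  expect_equal(v("LVSV"), v("LVEDV") - v("LVESV"))
  expect_equal(sv_ef(v("LVEDV"), v("LVESV"))$ef, v("LVEF"))
  # the analytic EF equals 100 (1 - s^2) for the case's drawn ES scale
  expect_equal(tr$analytic[tr$parameter == "LVEF"],
               100 * (1 - (v("LVESV") / v("LVEDV"))), tolerance = 1e-3)
})

test_that("the pipeline reproduces the emitted truth for every sequence", {
  for (sq in c("sax_cine", "sax_lge", "lax_4cv")) {
    g <- generate_case(small_params(), seed = 5, sequence = sq)
    cp <- clinical_parameters(g$case)
    m <- merge(cp[, c("parameter", "value")],
               g$truth[, c("parameter", "exact")])
    expect_true(all(abs(m$value - m$exact) <=
                      1e-6 + 1e-6 * abs(m$exact)), info = sq)
  }
  g <- generate_case(small_params(map_noise_sd = 0), seed = 5, sequence = "sax_t1")
  cp <- clinical_parameters(g$case)
  expect_equal(cp$value[cp$parameter == "GLOBAL_T1"], 1000, tolerance = 1e-9)
})

test_that("zero perturbation is the identity and scores perfectly", {
  g <- generate_case(small_params(), seed = 8)
  r2 <- perturb_reader(g$case, perturbation(), small_params(), seed = 1)
  pr <- pair_cases(g$case, r2)
  m <- slice_metrics(pr, ctypes = c("lv_endo", "myo"))
  expect_true(all(m$dice > 1 - 1e-8))
  expect_true(all(m$hd_mm < 1e-9))
  d1 <- clinical_parameters(g$case)$value
  d2 <- clinical_parameters(r2)$value
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("pure dilation reproduces concentric-disk closed forms", {
  params <- small_params()
  g <- generate_case(params, seed = 3)
  delta <- 1
  r2 <- perturb_reader(g$case, perturbation(dilation_mm = c(lv_endo = delta)),
                       params, seed = 2)
  pr <- pair_cases(g$case, r2)
  ed <- which(pr$phase == "ED")
  for (i in ed) {
    # the slice's actual endocardial radius, read off the emitted polygon
    p1 <- pr$slice_r1[[i]]$contours$lv_endo[[1]]
    r <- sqrt(sum((p1[1, ] - colMeans(p1))^2)) * params$spacing_col
    d <- dice(slice_region(pr$slice_r1[[i]], "lv_endo"),
              slice_region(pr$slice_r2[[i]], "lv_endo"))
    expect_equal(d, 2 * r^2 / (r^2 + (r + delta)^2), tolerance = 1e-3)
    hd <- hausdorff(slice_region(pr$slice_r1[[i]], "lv_endo"),
                    slice_region(pr$slice_r2[[i]], "lv_endo"), g$case$geometry)
    expect_equal(hd, delta, tolerance = 0.01)
  }
})

test_that("forced basal omission zeroes dice_all but not dice_both", {
  params <- small_params()
  g <- generate_case(params, seed = 6)
  r2 <- perturb_reader(g$case, perturbation(p_miss_basal = 1), params, seed = 4)
  pr <- pair_cases(g$case, r2)
  tab <- position_table(pr, ctypes = "lv_endo")
  basal <- tab[tab$position == "basal", ]
  expect_equal(basal$dice_all, 0)
  expect_equal(basal$n_both, 0)
  mid <- tab[tab$position == "mid", ]
  expect_equal(mid$dice_all, mid$dice_both)
  expect_true(all(mid$dice_all > 99.9))
})

test_that("extra-basal and fragmentation produce representable cases", {
  params <- small_params()
  g <- generate_case(params, seed = 12)
  r2 <- perturb_reader(g$case,
                       perturbation(radial_sigma = 0.5, p_extra_basal = 1,
                                    p_fragment = 1),
                       params, seed = 11)
  idx2 <- vapply(r2$slices, `[[`, integer(1), "slice_index")
  expect_true(0L %in% idx2)  # the unannotated basal image gained contours
  expect_false(0L %in% vapply(g$case$slices, `[[`, integer(1), "slice_index"))
  frag <- any(vapply(r2$slices, function(s)
    length(s$contours[["rv_endo"]]) > 1, logical(1)))
  expect_true(frag)
  # the pair is still processable end to end
  pr <- pair_cases(g$case, r2)
  expect_silent(m <- slice_metrics(pr, ctypes = "rv_endo"))
  expect_true(all(is.finite(m$dice)))
})

test_that("cohorts are reproducible and record per-case seeds", {
  c1 <- generate_cohort(3, tiny_params(), perturbation(radial_sigma = 1),
                        seed = 77)
  c2 <- generate_cohort(3, tiny_params(), perturbation(radial_sigma = 1),
                        seed = 77)
  expect_identical(c1$seed, 77 + 1:3)
  expect_identical(lapply(c1$case_r2, `[[`, "slices"),
                   lapply(c2$case_r2, `[[`, "slices"))
  d <- withr::local_tempdir()
  c3 <- generate_cohort(2, tiny_params(), perturbation(), seed = 5, dir = d)
  expect_setequal(list.files(d),
                  c("phantom-001_R1.json", "phantom-001_R2.json",
                    "phantom-002_R1.json", "phantom-002_R2.json", "truth.csv"))
  truth <- readr::read_csv(file.path(d, "truth.csv"), show_col_types = FALSE)
  expect_true(all(c("case_id", "seed", "parameter", "exact") %in% names(truth)))
})
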