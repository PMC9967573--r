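test_that("on-resonance singlet gives a constant-modulus FID peaking at 0 ppm", {
  g <- acq_grid("3T")
  b <- simulate_fid(spin_system("PCr", 0), g, seed_linewidth_hz = 0)
  expect_equal(length(b$fid), g$n_points)
  expect_equal(Mod(b$fid), rep(1, g$n_points), tolerance = 1e-12)
  sp <- process_fid(b$fid, g, proc_params(k_zero = 0, lb_hz = 2))
  expect_lt(abs(sp$ppm[which.max(Re(sp$values))]), 0.02)
})

test_that("simulated multiplets reach the first-order limit under weak coupling", {
  # deeply weak-coupled pair (delta-nu/J ~ 500): positions within 0.01 Hz
  # and amplitude ratios within 1% of the analytic first-order pattern
  tab <- p31corr:::.transition_table(c(-1250, 1250), j_matrix(2, "1-2" = 5))
  got <- cluster_lines(tab$freq_hz, Re(tab$amplitude), 0.001)
  expected <- rbind(weak_coupling_lines(-1250, 5), weak_coupling_lines(1250, 5))
  expected <- expected[order(expected$freq), ]
  expect_equal(nrow(got), 4)
  expect_equal(got$freq, expected$freq, tolerance = 1e-5)
  expect_equal(got$weight / sum(got$weight),
               expected$weight / sum(expected$weight), tolerance = 0.01)
})

test_that("ATP multiplet matches the weak-coupling analytic oracle", {
  # delta-nu >> J at both fields; second-order effects shift lines by
  # ~J^2/(4 delta-nu) < 0.3 Hz and tilt intensities slightly (roofing)
  for (field in c("3T", "7T")) {
    g <- acq_grid(field)
    tab <- p31corr:::.transition_table(
      c(-2.53, -7.56, -16.18) * g$larmor_mhz,
      j_matrix(3, "1-3" = 16.3, "2-3" = 16.3))
    got <- cluster_lines(tab$freq_hz, Re(tab$amplitude), 0.5)
    expected <- rbind(
      weak_coupling_lines(-2.53 * g$larmor_mhz, 16.3),    # gamma doublet
      weak_coupling_lines(-7.56 * g$larmor_mhz, 16.3),    # alpha doublet
      weak_coupling_lines(-16.18 * g$larmor_mhz, c(16.3, 16.3)))  # beta triplet
    expected <- aggregate(weight ~ freq, expected, sum)
    expected <- expected[order(expected$freq), ]
    expect_equal(nrow(got), nrow(expected))  # 2 + 2 + 3 resolved lines
    expect_equal(got$freq, expected$freq, tolerance = 0.3)
    # individual fractions within 0.01 absolute (roofing tilts intensities
    # by ~J/delta-nu ~ 4%); each nucleus still contributes exactly 1/3
    expect_lt(max(abs(got$weight / sum(got$weight) -
                        expected$weight / sum(expected$weight))), 0.01)
    beta <- got$freq < -700 * (acq_grid(field)$larmor_mhz / 51.705)
    expect_equal(sum(got$weight[beta]) / sum(got$weight), 1 / 3,
                 tolerance = 0.005)
  }
  # beta-ATP multiplet is centered at -16.18 ppm
  g <- acq_grid("3T")
  b <- simulate_fid(default_spin_systems("3T")[["ATP"]], g, 4)
  sp <- process_fid(b$fid, g, proc_params(k_zero = 0))
  up <- sp$ppm < -14 & sp$ppm > -18
  expect_equal(sp$ppm[up][which.max(Re(sp$values[up]))], -16.18,
               tolerance = 0.02)
})

test_that("equivalent coupled spins collapse to a single line", {
  tab <- p31corr:::.transition_table(c(120, 120), j_matrix(2, "1-2" = 20))
  expect_equal(unique(round(tab$freq_hz, 6)), 120)
  expect_equal(sum(Re(tab$amplitude)), 2, tolerance = 1e-9)
})

test_that("spectrum integral scales with the number of 31P nuclei", {
  g <- acq_grid("3T")
  proc <- proc_params(k_zero = 0, lb_hz = 0, zf_factor = 1)
  integral <- function(spec) {
    sp <- process_fid(simulate_fid(spec, g, 0)$fid, g, proc)
    sum(Re(sp$values))
  }
  i1 <- integral(spin_system("one", -5))
  i3 <- integral(spin_system("three", c(-2.53, -7.56, -16.18),
                             j_hz = j_matrix(3, "1-3" = 16.3, "2-3" = 16.3)))
  expect_equal(i3 / i1, 3, tolerance = 1e-6)
})

test_that("line positions in Hz scale linearly with the Larmor frequency", {
  g3 <- acq_grid("3T"); g7 <- acq_grid("7T")
  ratio <- g7$larmor_mhz / g3$larmor_mhz
  expect_equal(ratio, 120.645 / 51.705, tolerance = 1e-12)
  # two singlets: Hz separation at 7 T is ~2.33x that at 3 T
  sep <- function(g) diff(c(-16.18, -2.53)) * g$larmor_mhz
  expect_equal(sep(g7) / sep(g3), ratio, tolerance = 1e-12)
  # coupled system: the intensity-weighted multiplet center obeys the exact
  # sum rule (mean chemical shift x Larmor), so centers scale with field
  # even when the J structure (field independent in Hz) does not
  J <- j_matrix(2, "1-2" = 20)
  shifts <- c(-9.8, -11.6)
  center <- function(g) {
    tab <- p31corr:::.transition_table(shifts * g$larmor_mhz, J)
    w <- Re(tab$amplitude)
    sum(w * tab$freq_hz) / sum(w)
  }
  expect_equal(center(g3), mean(shifts) * g3$larmor_mhz, tolerance = 1e-6)
  expect_equal(center(g7) / center(g3), ratio, tolerance = 1e-9)
})

test_that("basis sets have 11 signals at 3 T and 12 at 7 T", {
  b3 <- cached_basis("3T")
  b7 <- cached_basis("7T")
  expect_length(b3, 11)
  expect_length(b7, 12)
  expect_false("UDPG" %in% names(b3))
  expect_true("UDPG" %in% names(b7))
  expect_equal(11 * 10 / 2, 55)
  expect_equal(choose(length(b7), 2), 66)
  # per-phosphorus normalization: fid[1] = n_phosphorus
  expect_equal(Mod(b3[["ATP"]]$fid[1]), 3, tolerance = 1e-9)
  expect_equal(Mod(b7[["NAD+"]]$fid[1]), 2, tolerance = 1e-9)
})

test_that("invalid spin systems are rejected", {
  expect_error(spin_system("bad", c(0, 1), j_hz = matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
  expect_error(spin_system("big", rep(0, 7)), "more than 6")
  expect_error(spin_system("mp", c(0, 1), broad = TRUE), "one nucleus")
  expect_error(spin_system("pm", c(0, 1), proton_multiplet = c(3, 7)),
               "single-31P")
  sys <- default_spin_systems("3T")
  expect_error(build_basis_set("3T", systems = sys[names(sys) != "PCr"]),
               "PCr")
})

test_that("proton multiplets split singlets into first-order patterns", {
  g <- acq_grid("3T")
  b <- simulate_fid(spin_system("PE", 6.78, proton_multiplet = c(3, 7.3)), g, 2)
  sp <- process_fid(b$fid, g, proc_params(k_zero = 0))
  win <- sp$ppm > 6.5 & sp$ppm < 7.1
  re <- Re(sp$values[win]); ppm <- sp$ppm[win]
  center <- ppm[which.max(re)]
  expect_equal(center, 6.78, tolerance = 0.02)
  # satellite lines at +- 7.3 Hz with ~half the central height (1:2:1)
  sat <- re[abs((ppm - 6.78) * g$larmor_mhz - 7.3) < 1.5]
  expect_gt(max(sat), 0.35 * max(re))
  expect_lt(max(sat), 0.65 * max(re))
})

test_that("basis signals round-trip through CSV export", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  b <- cached_basis("3T")[["PCr"]]
  write_basis_signal(b, tmp)
  b2 <- read_basis_signal(tmp)
  expect_equal(b2$fid, b$fid, tolerance = 1e-12)
  expect_equal(b2$grid$larmor_mhz, b$grid$larmor_mhz)
  expect_equal(b2$n_phosphorus, 1)
})
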