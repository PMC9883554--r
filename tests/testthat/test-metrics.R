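# Dose and thermogenesis metrics, each checked against brute-force
# enumeration on explicit voxel lists.

test_that("Joule heating matches closed forms and the sigma-identity", {
  v <- validate_slab("scalp", 100, spacing = 10, frequency = 0)
  q_cons <- joule_heating(v$sol)
  q_pt <- joule_heating(v$sol, "pointwise")
  expect_equal(q_cons$Q, rep(80000, length(q_cons$Q)), tolerance = 1e-12)
  expect_equal(q_pt$Q, rep(80000, length(q_pt$Q)), tolerance = 1e-12)
  # pointwise identity Q = 1/2 sigma |E|^2, voxel by voxel (real and complex)
  ms <- mini_solution()
  qm <- joule_heating(ms$sol, "pointwise")
  sigma <- Re(ms$sys$kappa)
  expect_equal(qm$Q, 0.5 * sigma * ms$sol$emag^2, tolerance = 1e-12)
  # Q = 0 wherever sigma = 0 (electrode body), both estimators
  elec <- ms$sys$labels_dom == ttfieldsim:::label_code("electrode")
  expect_true(any(elec))
  expect_equal(max(qm$Q[elec]), 0)
  expect_equal(max(joule_heating(ms$sol)$Q[elec]), 0)
  # both estimators are nonnegative
  expect_gte(min(joule_heating(ms$sol)$Q), 0)
  expect_gte(min(qm$Q), 0)
})

test_that("conservative heating balances electrode input power exactly", {
  ms <- mini_solution()
  expect_lt(power_balance_error(ms$sol), 1e-8)
})

test_that("gel power stats match brute-force enumeration", {
  ms <- mini_solution()
  qmap <- joule_heating(ms$sol)
  tab <- gel_power_stats(qmap, ms$phantom)
  expect_identical(nrow(tab), 18L)
  gel_code <- ttfieldsim:::label_code("hydrogel")
  vv <- ms$sys$h^3
  for (g in c(1L, 5L, 9L, 10L, 14L, 18L)) {
    sel <- which(ms$sys$labels_dom == gel_code & ms$sys$tid_dom == g)
    expect_identical(tab$n_vox[tab$gel == g], length(sel))
    expect_equal(tab$max_Q_W_m3[tab$gel == g], max(qmap$Q[sel]))
    expect_equal(tab$mean_Q_W_m3[tab$gel == g], mean(qmap$Q[sel]))
    expect_equal(tab$power_W[tab$gel == g], sum(qmap$Q[sel]) * vv)
  }
  expect_equal(attr(tab, "W_max"), max(tab$max_Q_W_m3))
  expect_true(all(tab$mean_Q_W_m3 <= tab$max_Q_W_m3))
  # deterministic tie-break: equal maxima resolve to the lowest gel id
  fake <- qmap
  fake$Q[] <- 1
  tab2 <- gel_power_stats(fake, ms$phantom)
  expect_identical(attr(tab2, "W_max_gel"), 1L)
  expect_equal(tab2$max_Q_W_m3, tab2$mean_Q_W_m3)   # uniform: max == mean
  # no gels -> error
  ph0 <- slab_phantom("scalp", 50, spacing = 5)
  sys0 <- assemble_system(ph0, cfg = solver_config(mode = "direct"),
                          excitation = list(type = "plate", axis = 1L, v = 1))
  sol0 <- solve_potential(sys0, solver_config(mode = "direct"))
  expect_error(gel_power_stats(joule_heating(sol0), ph0), "hydrogel")
})

test_that("tissue field stats match direct enumeration and the union identity", {
  ms <- mini_solution()
  st <- tissue_field_stats(ms$sol)
  lab <- ms$sys$labels_dom
  e <- ms$sol$emag / 100
  shell <- lab == ttfieldsim:::label_code("tumor_shell")
  expect_equal(st$mean_vcm[st$tissue == "tumor_shell"], mean(e[shell]))
  expect_equal(st$max_vcm[st$tissue == "tumor_shell"], max(e[shell]))
  # brain = GM u WM u CSF; volume-weighted mean of parts reproduces union
  parts <- tissue_field_stats(ms$sol, c("gray_matter", "white_matter", "csf"))
  w <- parts$n_vox / sum(parts$n_vox)
  expect_equal(sum(w * parts$mean_vcm), st$mean_vcm[st$tissue == "brain"])
  expect_equal(max(parts$max_vcm), st$max_vcm[st$tissue == "brain"])
  expect_true(all(st$mean_vcm <= st$max_vcm))
  expect_error(tissue_field_stats(ms$sol, "air"), "air")
})

test_that("atv counts inclusively and is monotone and scale-equivariant", {
  e <- c(0.2, 0.5, 1.0, 1.0, 1.3, 2.0, 2.5, 3.1, 0.9, 1.7)  # V/cm
  expect_equal(atv(e, threshold = 1.0), 100 * 7 / 10)  # >= is inclusive
  expect_equal(atv(e, threshold = 0), 100)
  expect_equal(atv(e, threshold = 10), 0)
  ths <- seq(0, 4, by = 0.25)
  vals <- vapply(ths, function(t) atv(e, threshold = t), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 100))
  # doubling the field equals halving the threshold
  expect_equal(atv(2 * e, threshold = 1.0), atv(e, threshold = 0.5))
  # solution interface: brute force over the shell voxel list
  ms <- mini_solution()
  shell <- ms$sys$labels_dom == ttfieldsim:::label_code("tumor_shell")
  ev <- ms$sol$emag[shell] / 100
  expect_equal(atv(ms$sol, threshold = 1.0),
               100 * sum(ev >= 1.0) / length(ev))
  expect_error(atv(ms$sol, mask = rep(FALSE, ms$sys$n)), "empty")
})

test_that("normalized field strength reproduces the published worked examples", {
  # frontal-lobe row: E2 = 1.491 relative, W1 = 7.26e5, W2 = 9.25e5 -> 132.1%
  expect_equal(round(100 * normalized_field_strength(1.491, 7.26e5, 9.25e5), 1),
               132.1)
  # brainstem row: E2 = 1.107, W1 = 6.55e5, W2 = 1.02e6 -> 88.7%
  expect_equal(round(100 * normalized_field_strength(1.107, 6.55e5, 1.02e6), 1),
               88.7)
  # identity when powers match
  expect_equal(normalized_field_strength(1.23, 5e5, 5e5), 1.23)
  # homogeneous of degree 1 in E2; invariant to common power rescaling
  expect_equal(normalized_field_strength(2 * 1.3, 7e5, 9e5),
               2 * normalized_field_strength(1.3, 7e5, 9e5))
  expect_equal(normalized_field_strength(1.3, 3 * 7e5, 3 * 9e5),
               normalized_field_strength(1.3, 7e5, 9e5))
  expect_error(normalized_field_strength(1.2, 0, 1e5), "positive")
  expect_error(normalized_field_strength(1.2, 1e5, -1), "positive")
})

test_that("case_summary carries the full per-case schema", {
  ms <- mini_solution()
  cs <- case_summary(ms$sol, ms$phantom, case = "intact",
                     thresholds = c(1, 2.5))
  expect_s3_class(cs, "case_summary")
  expect_setequal(cs$tissue_stats$tissue,
                  c("tumor_core", "tumor_shell", "brain"))
  expect_named(cs$atv, c("atv_1", "atv_2.5"))
  expect_true(all(cs$atv >= 0 & cs$atv <= 100))
  expect_true(cs$atv[1] >= cs$atv[2])        # nonincreasing in threshold
  expect_identical(nrow(cs$gel), 18L)
  expect_equal(cs$W_max, max(cs$gel$max_Q_W_m3))
  expect_equal(cs$mean_shell_vcm,
               cs$tissue_stats$mean_vcm[cs$tissue_stats$tissue == "tumor_shell"])
})
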