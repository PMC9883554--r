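# Closed-form oracles: layered slab and concentric sphere.

test_that("slab closed form reproduces the single-layer and series cases", {
  # 80 V across 0.1 m of scalp-conductivity material
  s1 <- slab_solution(slab_stack(0.1, 0.25 + 0i, voltage = 80))
  expect_equal(s1$layers$E_V_m, 800)
  expect_equal(s1$layers$Q_W_m3, 80000)
  expect_equal(Re(s1$power_W), 0.5 * 80 * 200)  # 1/2 V J A, J = 2000 A/m^2... per area
  # scalp + skull DC series: frozen from d1/k1 + d2/k2 = 0.2 + 2.36967
  s2 <- slab_solution(slab_stack(c(0.05, 0.05), c(0.25, 0.0211), voltage = 80))
  expect_equal(Mod(s2$J), 31.13242, tolerance = 1e-6)
  expect_equal(s2$layers$E_V_m[2], 1475.4703, tolerance = 1e-6)
  expect_equal(s2$layers$E_V_m[1], 124.5297, tolerance = 1e-6)
  # two identical layers behave as one of double thickness
  s3a <- slab_solution(slab_stack(c(0.03, 0.03), c(0.2, 0.2), voltage = 50))
  s3b <- slab_solution(slab_stack(0.06, 0.2 + 0i, voltage = 50))
  expect_equal(s3a$J, s3b$J)
  expect_equal(s3a$layers$E_V_m, rep(s3b$layers$E_V_m, 2))
  # a zero-admittivity layer blocks the stack
  s4 <- slab_solution(slab_stack(c(0.05, 0.05), c(0.25, 0), voltage = 80))
  expect_equal(Mod(s4$J), 0)
  expect_true(is.infinite(s4$z_specific))
})

test_that("homogeneous sphere reduces to the single-sphere closed form", {
  kap <- 0.3 + 0i
  R <- 70
  sph <- layered_sphere(c(R, 50, 30), rep(kap, 3), cap_half_angle_deg = 15,
                        current_A = 2e-3, L = 40)
  pts <- rbind(c(0, 0, 40), c(20, 10, 30), c(5, -25, -40), c(0, 0, -40))
  got <- layered_sphere_solution(sph, pts)$phi
  # independent evaluation: phi = sum_l f_l R /(kappa l) (r/R)^l P_l(cos)
  c0 <- cos(15 * pi / 180)
  j0 <- 2e-3 / (2 * pi * (R * 1e-3)^2 * (1 - c0))
  r <- sqrt(rowSums(pts^2)) * 1e-3
  ct <- pts[, 3] * 1e-3 / r
  want <- rep(0 + 0i, nrow(pts))
  P_prev <- rep(1, nrow(pts)); P_cur <- ct
  Pc_prev <- 1; Pc_cur <- c0
  for (l in 1:40) {
    P_next <- ((2 * l + 1) * ct * P_cur - l * P_prev) / (l + 1)
    Pc_next <- ((2 * l + 1) * c0 * Pc_cur - l * Pc_prev) / (l + 1)
    if (l %% 2 == 1) {
      f_l <- j0 * (Pc_prev - Pc_next)
      want <- want + f_l * (R * 1e-3) / (kap * l) * (r / (R * 1e-3))^l * P_cur
    }
    P_prev <- P_cur; P_cur <- P_next
    Pc_prev <- Pc_cur; Pc_cur <- Pc_next
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("sphere series obeys reciprocity and shell-admittivity monotonicity", {
  kap <- c(0.25, 0.0211, 0.141)
  pts <- rbind(c(0, 0, 70), c(0, 0, -70), c(10, 0, 40))
  s_pos <- layered_sphere_solution(
    layered_sphere(c(80, 70, 60), kap, current_A = 1e-3, L = 50), pts)
  s_neg <- layered_sphere_solution(
    layered_sphere(c(80, 70, 60), kap, current_A = -1e-3, L = 50), pts)
  expect_equal(s_pos$phi, -s_neg$phi)   # swapping source caps negates phi
  # raising the middle-shell admittivity lowers the pole-to-pole drop
  drops <- vapply(c(0.0211, 0.05, 0.1, 0.25), function(sk) {
    s <- layered_sphere_solution(
      layered_sphere(c(80, 70, 60), c(0.25, sk, 0.141), current_A = 1e-3,
                     L = 50),
      rbind(c(0, 0, 79.9), c(0, 0, -79.9)))
    Re(s$phi[1] - s$phi[2])
  }, numeric(1))
  expect_true(all(diff(drops) < 0))
})

test_that("series truncation error decreases with L", {
  kap <- c(0.25, 0.0211, 0.141)
  pts <- rbind(c(0, 0, 75), c(30, 30, 40))
  tr <- vapply(c(10, 20, 40, 80), function(L) {
    layered_sphere_solution(
      layered_sphere(c(80, 70, 60), kap, current_A = 1e-3, L = L),
      pts)$truncation
  }, numeric(1))
  expect_true(all(diff(tr) < 0))
  # and the evaluated potential stabilizes away from the source surface
  deep <- rbind(c(0, 0, 60), c(20, 20, 20))
  p40 <- layered_sphere_solution(
    layered_sphere(c(80, 70, 60), kap, current_A = 1e-3, L = 40), deep)$phi
  p80 <- layered_sphere_solution(
    layered_sphere(c(80, 70, 60), kap, current_A = 1e-3, L = 80), deep)$phi
  expect_equal(p40, p80, tolerance = 1e-6)
})

test_that("legendre recurrence matches explicit low-order polynomials", {
  x <- seq(-1, 1, by = 0.25)
  P <- ttfieldsim:::legendre_table(3, x)
  expect_equal(P[, 1], rep(1, length(x)))
  expect_equal(P[, 2], x)
  expect_equal(P[, 3], (3 * x^2 - 1) / 2)
  expect_equal(P[, 4], (5 * x^3 - 3 * x) / 2)
})
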