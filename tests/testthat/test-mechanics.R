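test_that("pairwise force magnitude honours all regime boundaries", {
  F0 <- 0.45
  Ri <- 10; Rj <- 10; al <- 0.75
  rsum <- Ri + Rj
  # deep overlap: constant F0, repulsive
  expect_equal(pairwise_force_magnitude(3, Ri, Rj, al, F0), F0)
  expect_equal(pairwise_force_magnitude(min(Ri, Rj), Ri, Rj, al, F0), F0)
  # exact zero crossing at alpha * (Ri + Rj)
  expect_equal(pairwise_force_magnitude(al * rsum, Ri, Rj, al, F0), 0)
  # zero at and beyond contact loss
  expect_equal(pairwise_force_magnitude(rsum, Ri, Rj, al, F0), 0)
  expect_equal(pairwise_force_magnitude(rsum + 5, Ri, Rj, al, F0), 0)
  # attractive mid-branch boundary d = 0.5 (1 + alpha) (Ri + Rj) = 17.5
  mid <- 0.5 * (1 + al) * rsum
  f_mid <- pairwise_force_magnitude(mid, Ri, Rj, al, F0)
  expect_lt(f_mid, 0)
  expect_equal(f_mid, -0.5 * F0)         # linear branch through (15, 0), (10, F0)
})

test_that("signed magnitude is continuous with exactly one sign change", {
  F0 <- 0.3
  cases <- list(c(10, 10, 0.75), c(12, 9, 0.75), c(10, 10, 0.9),
                c(11, 8, 0.9), c(10, 10, 1.0))
  for (cs in cases) {
    Ri <- cs[1]; Rj <- cs[2]; al <- cs[3]
    rsum <- Ri + Rj
    f <- function(d) pairwise_force_magnitude(d, Ri, Rj, al, F0)
    # continuity at every regime boundary
    for (b in c(min(Ri, Rj), al * rsum, 0.5 * (1 + al) * rsum, rsum)) {
      eps <- 1e-9 * rsum
      expect_equal(f(b - eps), f(b + eps), tolerance = 1e-6)
    }
    # sign pattern on a fine grid
    d <- seq(0.2, rsum * 1.2, length.out = 2000)
    v <- vapply(d, f, numeric(1))
    expect_true(all(v[d < al * rsum - 1e-9] > 0))
    if (al < 1) {
      expect_true(all(v[d > al * rsum + 1e-9 & d < rsum - 1e-9] < 0))
      expect_equal(sum(abs(diff(sign(v[d < rsum - 1e-9]))) > 0), 1)
    } else {
      # alpha = 1: repulsion-only, no attraction interval anywhere
      expect_true(all(v >= 0))
    }
  }
})

test_that("pairwise force vector is central and antisymmetric", {
  set.seed(11)
  for (k in 1:20) {
    pi_ <- rnorm(3, 0, 5); pj <- rnorm(3, 0, 5)
    Ri <- runif(1, 8, 12); Rj <- runif(1, 8, 12)
    d <- sqrt(sum((pj - pi_)^2))
    if (d < 1e-3) next
    fi <- pairwise_force(pi_, Ri, pj, Rj, 0.75, 0.3)
    fj <- pairwise_force(pj, Rj, pi_, Ri, 0.75, 0.3)
    expect_equal(fi, -fj, tolerance = 1e-12)
    # parallel to the line of centres
    cr <- c(fi[2] * (pj - pi_)[3] - fi[3] * (pj - pi_)[2],
            fi[3] * (pj - pi_)[1] - fi[1] * (pj - pi_)[3],
            fi[1] * (pj - pi_)[2] - fi[2] * (pj - pi_)[1])
    expect_equal(cr, c(0, 0, 0), tolerance = 1e-10)
  }
  expect_error(pairwise_force(c(1, 2, 3), 5, c(1, 2, 3), 5, 0.75, 0.3),
               "coincident")
})

test_that("alpha lookup is symmetric with default fallback", {
  p <- aa_params()
  expect_equal(alpha_for_pair(p, "EMS", "P2"), 0.90)
  expect_equal(alpha_for_pair(p, "P2", "EMS"), 0.90)
  expect_equal(alpha_for_pair(p, "ABa", "P2"), 0.75)
  r <- ro_params()
  expect_equal(alpha_for_pair(r, "EMS", "P2"), 1)
})

test_that("shell force is zero without touch and inward when touching", {
  prm <- force_params(shell_gain = 0.8)
  big <- eggshell(20, 20)
  expect_equal(shell_force(big, c(0, 0, 0), 5, prm), c(0, 0, 0))
  sph <- eggshell(10, 10)
  f <- shell_force(sph, c(6, 0, 0), 5, prm)   # a = 4 < R = 5
  expect_true(f[1] < 0 && abs(f[2]) < 1e-12 && abs(f[3]) < 1e-12)
  expect_equal(f[1], -0.8 * (5 - 4) / 5)
  # exact contact onset a = R: zero
  expect_equal(shell_force(sph, c(5, 0, 0), 5, prm), c(0, 0, 0))
  # deeper overlap pushes harder
  f2 <- shell_force(sph, c(8, 0, 0), 5, prm)
  expect_gt(abs(f2[1]), abs(f[1]))
  expect_error(shell_force(sph, c(11, 0, 0), 5, prm), "outside")
})

test_that("net forces: equilibria and Newton's third law", {
  prm <- force_params()
  # single cell at shell centre, no touch
  st <- embryo_state(0, data.frame(label = "AB", x = 0, y = 0, z = 0,
                                   radius = 5), eggshell(20, 20))
  expect_equal(unname(net_forces(st, prm)), matrix(0, 1, 3))

  # two equal free cells at the stable separation: zero force on both
  al <- prm$alpha_default
  d0 <- al * 20
  st2 <- embryo_state(0, data.frame(label = c("AB", "P1"),
                                    x = c(-d0 / 2, d0 / 2), y = 0, z = 0,
                                    radius = 10), eggshell(500, 500))
  expect_equal(unname(net_forces(st2, prm)), matrix(0, 2, 3),
               tolerance = 1e-12)

  # symmetric three-cell chain: middle cell balanced
  st3 <- embryo_state(0, data.frame(label = c("AB", "P1", "EMS"),
                                    x = c(-12, 0, 12), y = 0, z = 0,
                                    radius = 8), eggshell(500, 500))
  f3 <- net_forces(st3, prm)
  expect_equal(unname(f3["P1", ]), c(0, 0, 0), tolerance = 1e-12)

  # pairwise contributions sum to zero on random states (forces away from
  # the shell are purely pairwise)
  set.seed(21)
  for (k in 1:25) {
    st4 <- random_four_cell_state(eggshell(500, 500))
    expect_equal(colSums(net_forces(st4, prm)), c(x = 0, y = 0, z = 0),
                 tolerance = 1e-10)
  }
})

test_that("alpha = 1 collapses the AA law onto the RO law", {
  F0 <- 0.45
  set.seed(31)
  for (k in 1:200) {
    Ri <- runif(1, 6, 14); Rj <- runif(1, 6, 14)
    d <- runif(1, 0.5, (Ri + Rj) * 1.2)
    v <- pairwise_force_magnitude(d, Ri, Rj, 1, F0)
    expect_gte(v, 0)
    if (d >= Ri + Rj) expect_equal(v, 0)
  }
})
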