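test_that("initial two-cell state matches the standard configuration", {
  shell <- axes_from_ar(1.6, (4 / 3) * pi * 25 * 15^2)
  st <- initial_two_cell_state(shell, total_volume = 20000,
                               ab_fraction = 0.6)
  expect_equal(st$cells$label, c("AB", "P1"))
  expect_equal(st$cells$x, c(-1, 1))             # AB anterior
  expect_equal(st$cells$y, c(0, 0))
  expect_equal(st$cells$z, c(0, 0))
  expect_equal(sqrt(sum((st$cells[1, c("x", "y", "z")] -
                         st$cells[2, c("x", "y", "z")])^2)), 2)
  expect_equal(sum(st$cells$volume), 20000, tolerance = 1e-12)
  expect_gt(st$cells$radius[1], st$cells$radius[2])

  eq <- initial_two_cell_state(shell, 20000, ab_fraction = 0.5)
  expect_equal(eq$cells$radius[1], eq$cells$radius[2])

  expect_error(initial_two_cell_state(eggshell(0.9, 0.9), 10), "too small")
})

test_that("noise-free fixed points stay fixed", {
  prm <- force_params(noise_variance = 0)
  # lone cell at centre of a large shell
  st <- embryo_state(0, data.frame(label = "AB", x = 0, y = 0, z = 0,
                                   radius = 5), eggshell(30, 30))
  st1 <- sim_step(st, prm)
  expect_equal(st1$cells[, c("x", "y", "z")], st$cells[, c("x", "y", "z")])
  expect_equal(st1$time, st$time + prm$dt)

  # two equal free cells at the stable separation
  d0 <- 0.75 * 20
  st2 <- embryo_state(0, data.frame(label = c("AB", "P1"),
                                    x = c(-d0 / 2, d0 / 2), y = 0, z = 0,
                                    radius = 10), eggshell(500, 500))
  st3 <- sim_step(st2, prm)
  expect_equal(st3$cells[, c("x", "y", "z")], st2$cells[, c("x", "y", "z")],
               tolerance = 1e-14)
})

test_that("noise displacement variance matches the configuration", {
  # forces effectively off: lone cell far from a huge shell
  prm <- force_params(noise_variance = 0.027)
  st <- embryo_state(0, data.frame(label = "AB", x = 0, y = 0, z = 0,
                                   radius = 1), eggshell(5000, 5000))
  set.seed(7)
  n <- 10000
  disp <- matrix(0, n, 3)
  cur <- st
  for (k in seq_len(n)) {
    nxt <- sim_step(cur, prm)
    disp[k, ] <- as.numeric(nxt$cells[1, c("x", "y", "z")]) -
                 as.numeric(cur$cells[1, c("x", "y", "z")])
    cur <- nxt
  }
  v <- apply(disp, 2, var)
  expect_equal(mean(v), 0.027, tolerance = 0.05)   # 5% sampling error
  expect_equal(colMeans(disp), c(0, 0, 0), tolerance = 0.01)
})

test_that("two free cells relax to the stable separation", {
  # AA mode: separation -> alpha * (R1 + R2) within 1e-3 um
  r <- two_cell_relaxation(force_params(F0 = 0.45), R1 = 12, R2 = 11,
                           d0 = 2, alpha = 0.75, duration = 600)
  expect_equal(r$separation, 0.75 * 23, tolerance = 1e-3)
  expect_lt(r$t_converged, 420)          # well within one division interval
  # RO mode: -> R1 + R2 (one-sided approach, slower near the boundary)
  r2 <- two_cell_relaxation(force_params(F0 = 0.45), R1 = 12, R2 = 11,
                            d0 = 2, alpha = 1, duration = 3000)
  expect_equal(r2$separation, 23, tolerance = 1e-3)
})

test_that("runs are reproducible and confined", {
  cfg <- quick_config()
  shell <- axes_from_ar(2.0, cfg$shell_volume)
  prog <- program_from_config(cfg)
  prm <- params_from_config(cfg, "AA")
  tv <- cfg$cell_volume_fraction * cfg$shell_volume
  a <- sim_run(shell, prog, prm, tv, seed = 5, record_stride = 10)
  b <- sim_run(shell, prog, prm, tv, seed = 5, record_stride = 10)
  expect_identical(a$trajectory, b$trajectory)   # bit-identical repeat
  c_ <- sim_run(shell, prog, prm, tv, seed = 6)
  expect_false(identical(a$state$cells, c_$state$cells))

  # every recorded centre stays strictly inside the shell
  for (i in seq_len(nrow(a$trajectory))) {
    p <- as.numeric(a$trajectory[i, c("x_um", "y_um", "z_um")])
    expect_true(shell_contains(shell, p))
  }
})

test_that("compiled and reference engines produce the same trajectories", {
  cfg <- quick_config()
  cfg$settle <- 100                      # keep the R engine affordable
  shell <- axes_from_ar(1.8, cfg$shell_volume)
  prog <- program_from_config(cfg)
  prm <- params_from_config(cfg, "AA")
  tv <- cfg$cell_volume_fraction * cfg$shell_volume
  rc <- sim_run(shell, prog, prm, tv, seed = 3, engine = "cpp")
  rr <- sim_run(shell, prog, prm, tv, seed = 3, engine = "r")
  expect_equal(rc$state$cells, rr$state$cells, tolerance = 1e-9)
  # and in RO mode (shared seeds, different force law)
  prm_ro <- params_from_config(cfg, "RO")
  rc2 <- sim_run(shell, prog, prm_ro, tv, seed = 3, engine = "cpp")
  rr2 <- sim_run(shell, prog, prm_ro, tv, seed = 3, engine = "r")
  expect_equal(rc2$state$cells, rr2$state$cells, tolerance = 1e-9)
})

test_that("trajectory CSV writer round-trips", {
  cfg <- quick_config()
  cfg$settle <- 50
  res <- sim_run(axes_from_ar(1.6, cfg$shell_volume),
                 program_from_config(cfg), params_from_config(cfg, "AA"),
                 cfg$cell_volume_fraction * cfg$shell_volume, seed = 1,
                 record_stride = 20)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(res$trajectory, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(res$trajectory))
  expect_equal(back$x_um, res$trajectory$x_um, tolerance = 1e-12)
  expect_true(all(diff(back$time_s[back$label == "P2"]) > 0))
  unlink(path)
})
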