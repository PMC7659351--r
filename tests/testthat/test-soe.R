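test_that("acceptance probability reproduces the hand-computed cases", {
  # c_i = 1 (the event alone), empty proposal: 1*1 / (2^2 * 0^0) = 1/4
  expect_equal(acceptance_probability(1, 0), 0.25)
  # c_i = 1, c_iprime = 1: (1 * 4) / (4 * 1) = 1
  expect_equal(acceptance_probability(1, 1), 1)
  # moves toward much denser voxels are always accepted
  expect_equal(acceptance_probability(3, 500), 1)
  # monotone in the proposed-voxel count
  a <- acceptance_probability(rep(5, 20), 0:19)
  expect_true(all(diff(a) >= -1e-12))
  expect_error(acceptance_probability(0, 1), "c_i")
})

test_that("initialization is uniform over candidates and conserves events", {
  grid <- image_grid(8, 8, 10)
  # 10^4 events sharing one 10-voxel candidate set
  n <- 1e4
  vox <- 0:9
  cand <- list(voxels = rep(vox, n), offsets = as.integer(seq(0, 10 * n, by = 10)),
               keep = rep(TRUE, n), n_dropped = 0)
  ens <- soe_initialize(cand, grid, seed = 1)
  expect_equal(sum(ens$density), n)
  occ <- ens$density[1:10]
  expect_true(all(abs(occ - n / 10) < 3 * sqrt(n / 10)))
  # single-candidate event: deterministic placement
  cand1 <- list(voxels = 7L, offsets = c(0L, 1L), keep = TRUE, n_dropped = 0)
  ens1 <- soe_initialize(cand1, grid, seed = 2)
  expect_equal(ens1$origins, 7L)
  expect_equal(sum(ens1$density), 1)
  # reproducible under the seed
  ens_a <- soe_initialize(cand, grid, seed = 3)
  ens_b <- soe_initialize(cand, grid, seed = 3)
  expect_identical(ens_a$origins, ens_b$origins)
})

test_that("sweeps conserve the event count and fix single-candidate systems", {
  grid <- image_grid(8, 8, 10)
  set.seed(4)
  # all candidate sets of size 1: the sweep is a no-op with full acceptance
  cand1 <- list(voxels = c(3L, 12L, 3L), offsets = 0:3, keep = rep(TRUE, 3),
                n_dropped = 0)
  ens <- soe_initialize(cand1, grid, seed = 5)
  d0 <- ens$density
  ens <- soe_sweep(ens, 10)
  expect_identical(ens$density, d0)
  expect_equal(ens$last_accept_rate, 1)
  # random system: density always sums to N, occupied where events sit
  n <- 50
  cand <- list(voxels = unlist(lapply(1:n, function(i) sample(0:63, 5))),
               offsets = as.integer(seq(0, 5 * n, by = 5)),
               keep = rep(TRUE, n), n_dropped = 0)
  ens <- soe_initialize(cand, grid, seed = 6)
  for (i in 1:20) {
    ens <- soe_sweep(ens, 1)
    expect_equal(sum(ens$density), n)
    expect_true(all(ens$density[ens$origins + 1L] >= 1))
  }
})

test_that("the chain's stationary distribution matches exact enumeration", {
  # two events, both with candidate set {v1, v2}: 4 labeled states.
  # Build the exact per-step transition matrix with the same acceptance
  # rule, independently of the compiled chain.
  grid <- image_grid(2, 1, 10, fov_radius = 20)
  states <- expand.grid(e1 = 0:1, e2 = 0:1)
  dens_of <- function(s) tabulate(c(s$e1, s$e2) + 1L, nbins = 2)
  P <- matrix(0, 4, 4)
  for (s in 1:4) {
    st <- states[s, ]
    d <- dens_of(st)
    for (k in 1:2) for (prop in 0:1) {
      cur <- st[[k]]
      ns <- st
      ns[[k]] <- prop
      target <- which(states$e1 == ns$e1 & states$e2 == ns$e2)
      if (prop == cur) {
        P[s, target] <- P[s, target] + 1 / 4      # self-proposal accepted
      } else {
        A <- acceptance_probability(d[cur + 1], d[prop + 1])
        P[s, target] <- P[s, target] + A / 4
        P[s, s] <- P[s, s] + (1 - A) / 4
      }
    }
  }
  expect_equal(rowSums(P), rep(1, 4))
  ev <- eigen(t(P))
  pi_exact <- Re(ev$vectors[, which.max(Re(ev$values))])
  pi_exact <- pi_exact / sum(pi_exact)

  cand <- list(voxels = c(0L, 1L, 0L, 1L), offsets = c(0L, 2L, 4L),
               keep = c(TRUE, TRUE), n_dropped = 0)
  ens <- soe_initialize(cand, grid, seed = 8)
  visits <- integer(4)
  n_samp <- 2e4
  for (i in seq_len(n_samp)) {
    ens <- soe_sweep(ens, 1)
    s <- which(states$e1 == ens$origins[1] & states$e2 == ens$origins[2])
    visits[s] <- visits[s] + 1L
  }
  tv <- 0.5 * sum(abs(visits / n_samp - pi_exact))
  expect_lt(tv, 0.02)
})

test_that("reconstruction recovers a central point source", {
  lm <- quick_point_lm()
  ev <- lm$events[lm$events$primary, ]
  grid <- image_grid(64, 64, 4.5)
  rec <- reconstruct(ev, grid, n_sweeps = 150, n_average = 50, seed = 9)
  expect_equal(sum(rec$oe_average), rec$n_events, tolerance = 1e-9)
  img <- rec$oe_average
  cx <- (row(img) - 0.5) * 4.5 - 144
  cy <- (col(img) - 0.5) * 4.5 - 144
  centroid <- c(sum(cx * img), sum(cy * img)) / sum(img)
  expect_lt(sqrt(sum(centroid^2)), 2 * 4.5)
  expect_error(reconstruct(ev, grid, n_sweeps = 10, n_average = 20), "n_average")
})

test_that("two chains from different seeds agree on the reconstruction", {
  lm <- quick_point_lm()
  ev <- lm$events[lm$events$primary, ]
  grid <- image_grid(64, 64, 4.5)
  r1 <- reconstruct(ev, grid, n_sweeps = 200, n_average = 100, seed = 10,
                    smooth_sd = 0.75)
  r2 <- reconstruct(ev, grid, n_sweeps = 200, n_average = 100, seed = 11,
                    smooth_sd = 0.75)
  expect_gt(cor(as.vector(r1$image), as.vector(r2$image)), 0.9)
})

test_that("gaussian post-smoothing preserves counts and reduces roughness", {
  img <- matrix(0, 32, 32)
  img[16, 16] <- 100
  sm <- post_smooth(img, 0.75)
  expect_equal(sum(sm), 100, tolerance = 1e-9)
  expect_lt(max(sm), 100)
  # identity at sd = 0
  expect_identical(post_smooth(img, 0), img)
  # total preserved even for mass at the boundary
  img2 <- matrix(0, 16, 16); img2[1, 1] <- 7
  expect_equal(sum(post_smooth(img2, 2)), 7, tolerance = 1e-9)
  # smoothing can only reduce the coefficient of variation
  set.seed(12)
  noisy <- matrix(rexp(900), 30, 30)
  cv <- function(m) sd(m) / mean(m)
  expect_lt(cv(post_smooth(noisy, 1)), cv(noisy))
})
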