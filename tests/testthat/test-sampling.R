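test_that("integrator: equipartition on a harmonic bond", {
  core <- list(
    n = 2L, bonds = matrix(c(1L, 2L), 1, 2), bond_r0 = 0.38, bond_k = 100,
    angles = matrix(0L, 0, 3), theta0 = numeric(0), angle_k = numeric(0),
    dihedrals = matrix(0L, 0, 4), phi0 = numeric(0), dih_k1 = numeric(0),
    dih_k3 = numeric(0), pair_code = matrix(-1L, 2, 2),
    pair_eps = matrix(0, 2, 2), pair_r0 = matrix(0, 2, 2),
    sigma = rep(0.4, 2), rep_eps = 0
  )
  x0 <- rbind(c(0, 0, 0), c(0.38, 0, 0))
  opts <- swapfold:::run_opts(
    langevin_params(300, 1e6, friction = 5, seed = 5),
    save_every = 20, check_every = 1e6
  )
  res <- swapfold:::cg_run_cpp(x0, core, opts)
  d <- sqrt(colSums((res$frames[1, , ] - res$frames[2, , ])^2))
  # bond-length variance: kT / (2k) for V = k (d - r0)^2
  expect_equal(var(d), kB * 300 / (2 * 100), tolerance = 0.05)
})

test_that("integrator: seed determinism and the T = 0 dissipative limit", {
  m <- toy_small_model()
  p <- langevin_params(350, 20000, seed = 17)
  t1 <- langevin_run(m, p, check_every = 5000)
  t2 <- langevin_run(m, p, check_every = 5000)
  expect_identical(t1$final, t2$final)
  expect_identical(t1$checks, t2$checks)

  # T = 0 with strong friction: damped descent into a local minimum
  x0 <- m$structure$coords +
    with_seed(3, matrix(rnorm(3 * length(m$structure), sd = 0.03), ncol = 3))
  e0 <- potential_energy(m, x0)$total
  tz <- langevin_run(m, langevin_params(0, 20000, friction = 20, seed = 1),
                     initial = x0, check_every = 1000)
  e <- tz$checks$energy
  expect_true(all(e < e0))
  expect_lt(max(diff(e)), 2)        # damped descent; tiny numerical upticks
  expect_lt(e[length(e)], e0 - 50)
})

test_that("classification: native, extended, constructed misfold frames", {
  tm <- toy_small_tandem()
  m <- tm$domain_model
  L <- tm$L
  sets_list <- swapfold:::classification_sets(tm, enumerate_cut_sites(m))

  native <- classify_state(tm$structure$coords, sets_list)
  expect_equal(native$label, "native")
  ext <- classify_state(extended_coords(2 * L), sets_list)
  expect_equal(ext$label, "incomplete")

  # geometric construction: central and terminal domains both native-shaped
  K <- enumerate_cut_sites(m)$K[2]
  nat <- m$structure$coords
  x <- matrix(0, 2 * L, 3)
  for (t in (K + 1):(K + L)) x[t, ] <- nat[((t - 1) %% L) + 1, ]
  shift <- c(4, 0, 0)
  for (t in seq_len(K)) x[t, ] <- nat[t, ] + shift
  for (t in (K + L + 1):(2 * L)) x[t, ] <- nat[t - L, ] + shift
  mis <- classify_state(x, sets_list)
  expect_equal(mis$label, as.character(K))
})

test_that("campaign bookkeeping: fractions sum to one, label set complete", {
  tm <- toy_small_tandem()
  camp <- first_passage_campaign(
    tm, 4, langevin_params(400, 20000, seed = 2), check_every = 5000
  )
  expect_equal(sum(camp$summary$fraction), 1)
  expect_equal(nrow(camp$outcomes), 4)
  expect_true(all(c("native", "incomplete") %in% camp$summary$label))
  expect_equal(sum(camp$summary$count), 4)
})

test_that("umbrella machinery: zero bias at the centre, k controls spread", {
  m <- toy_small_model()
  # the bias energy vanishes when Q sits at the window centre
  core <- swapfold:::model_core(m)
  x <- m$structure$coords
  set <- m$contacts
  q_here <- swapfold:::q_logistic_cpp(x, swapfold:::contact_set_matrix(set),
                                      50, 1.2)
  e_plain <- swapfold:::cg_energy_cpp(x, core)$total
  tr <- langevin_run(m, langevin_params(300, 1, seed = 1), initial = x,
                     check_every = 1, qsets = list(q = set),
                     bias = list(set = set, k = 500, q0 = q_here))
  # one step of dynamics with a centred bias stays near the plain energy
  expect_equal(tr$checks$energy[1], e_plain, tolerance = 1)

  # stiffer windows confine Q more tightly
  run_spread <- function(k) {
    us <- umbrella_sampling(
      m, windows = tibble::tibble(center = 0.5, k = k),
      params = langevin_params(400, 1, seed = 4),
      n_equil = 4000, n_sample = 40000, sample_every = 20
    )
    stats::var(us$q)
  }
  v1 <- run_spread(300)
  v2 <- run_spread(600)
  # harmonic-limit prediction is 2; the landscape contribution and finite
  # sampling move it, but stiffer windows must confine substantially more
  expect_gt(v1 / v2, 1.3)
  expect_lt(v1 / v2, 5)
})

test_that("umbrella sampling errors on non-overlapping windows", {
  samples <- tibble::tibble(
    window = rep(1:2, each = 50),
    center = rep(c(0.1, 0.9), each = 50),
    k = 200,
    q = c(runif(50, 0.05, 0.15), runif(50, 0.85, 0.95))
  )
  expect_error(swapfold:::check_window_overlap(samples), "overlap")
})

test_that("WHAM recovers a known double well from synthetic biased samples", {
  kT <- kB * 300
  Fa <- function(q) 8 * ((q - 0.5)^2 / 0.09 - 1)^2
  centers <- seq(0.05, 0.95, length.out = 21)
  kbias <- 200
  grid <- seq(0.001, 0.999, by = 0.002)
  samples <- purrr::map_dfr(seq_along(centers), function(w) {
    p <- exp(-(Fa(grid) + 0.5 * kbias * (grid - centers[w])^2) / kT)
    draws <- with_seed(100 + w, sample(grid, 6000, replace = TRUE,
                                       prob = p / sum(p)))
    tibble::tibble(window = w, center = centers[w], k = kbias, q = draws)
  })
  prof <- wham(samples, temperature = 300, bin_width = 0.01)
  # evaluate recovery where the sampling gives real support
  counts <- graphics::hist(samples$q,
                           breaks = c(prof$Q - 0.005, max(prof$Q) + 0.005),
                           plot = FALSE)$counts
  keep <- counts >= 100
  want <- Fa(prof$Q)
  resid <- (prof$F - want)[keep]
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.1)

  # order independence
  prof2 <- wham(samples[with_seed(1, sample(nrow(samples))), ],
                temperature = 300, bin_width = 0.01)
  expect_equal(prof$F, prof2$F, tolerance = 1e-8)

  # degenerate case: one unbiased window is just -kT log(histogram)
  unb <- tibble::tibble(window = 1, center = 0.5, k = 0,
                        q = with_seed(2, sample(grid, 4000, replace = TRUE,
                                                prob = exp(-Fa(grid) / kT))))
  p1 <- wham(unb, temperature = 300, bin_width = 0.02)
  lo <- floor(min(unb$q) / 0.02) * 0.02
  hi <- ceiling(max(unb$q) / 0.02) * 0.02
  h <- graphics::hist(unb$q, breaks = seq(lo, hi + 0.01, by = 0.02),
                      plot = FALSE)
  manual <- -kT * log(h$counts[h$counts > 0])
  expect_equal(p1$F, manual - min(manual), tolerance = 1e-6)
})

test_that("profile thermodynamics reproduce closed forms", {
  Q <- seq(0, 1, by = 0.005)
  d <- 3
  Fsym <- d * ((Q - 0.5)^2 / 0.09 - 1)^2
  prof <- free_energy_profile(Q, Fsym, temperature = 300)
  s <- stability_from_profile(prof)
  expect_equal(s$dG_s, 0, tolerance = 1e-9)
  expect_equal(s$Q_barrier, 0.5)
  b <- barrier_from_profile(prof)
  expect_equal(b$dG_f, d)

  # two-Gaussian wells with imposed stability difference of 2 kcal/mol
  kT <- kB * 300
  w2_over_w1 <- exp(2 / kT)
  dens <- stats::dnorm(Q, 0.2, 0.04) + w2_over_w1 * stats::dnorm(Q, 0.8, 0.04)
  prof2 <- free_energy_profile(Q, -kT * log(dens), temperature = 300)
  s2 <- stability_from_profile(prof2)
  expect_equal(s2$dG_s, 2, tolerance = 0.05)

  # adding a constant changes nothing (profiles are re-shifted on entry)
  prof3 <- free_energy_profile(Q, Fsym + 7.3, temperature = 300)
  expect_equal(stability_from_profile(prof3)$dG_s, s$dG_s)
  expect_equal(barrier_from_profile(prof3)$dG_f, b$dG_f)

  # a barrier of 2.5 kT is recovered within grid resolution
  d25 <- 2.5 * kT
  prof4 <- free_energy_profile(Q, d25 * ((Q - 0.5)^2 / 0.09 - 1)^2,
                               temperature = 300)
  expect_equal(barrier_from_profile(prof4)$dG_f, d25, tolerance = 0.01)

  # monotone profile: no two-state structure
  expect_error(stability_from_profile(
    free_energy_profile(Q, 5 * Q, temperature = 300)), "single basin")
})

test_that("nucleus-location distribution is a normalised histogram", {
  tm <- toy_small_tandem()
  # synthesise frames: native tandem plus dilated (partially formed) copies
  nat <- tm$structure$coords
  frames <- array(0, c(nrow(nat), 3, 8))
  for (f in 1:8) frames[, , f] <- nat * (1 + 0.02 * (f - 1))
  expect_error(nucleus_location_distribution(frames, tm, q_value = 0.25),
               "no frames")
  d <- nucleus_location_distribution(frames, tm, q_value = 1, band = 0.2)
  expect_equal(sum(d$density), 1, tolerance = 1e-9)
  expect_gt(attr(d, "n_frames"), 0)
})
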