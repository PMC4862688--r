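# a small duplicated map over 2L with the four-copy structure, built from a
# hand native map
wsme_toy_config <- function(L = 12, Ep = 0, eps = -1.2, ds = -0.004,
                            temperature = 525) {
  nat <- tibble::tibble(i = c(1L, 2L, 4L, 6L), j = c(5L, 7L, 9L, 10L))
  dup <- dplyr::bind_rows(
    nat,
    tibble::tibble(i = nat$i + L, j = nat$j + L),
    tibble::tibble(i = nat$j, j = nat$i + L),
    tibble::tibble(i = nat$i, j = nat$j + L)
  )
  dup$eps <- eps
  wsme_config(dup, L = L, ds = ds, Ep = Ep, temperature = temperature)
}

test_that("state energies follow the segment bookkeeping", {
  cfg <- wsme_toy_config()
  # empty state
  expect_equal(state_energy(0L, 0L, cfg), 0)
  # one residue, no contacts possible
  expect_equal(state_energy(3L, 1L, cfg), -cfg$temperature * cfg$ds)
  # segment spanning the midpoint pays Ep
  cfg_p <- wsme_toy_config(Ep = 3)
  span <- state_energy(10L, 5L, cfg_p)   # covers residues 10..14, L = 12
  no_span <- state_energy(10L, 5L, wsme_toy_config(Ep = 0))
  expect_equal(span - no_span, 3)
  # contact counting agrees with a direct filter
  cm <- cfg$contacts
  for (st in list(c(1, 8), c(3, 9), c(13, 12))) {
    inside <- cm$i >= st[1] & cm$j <= st[1] + st[2] - 1
    expect_equal(state_energy(st[1], st[2], cfg),
                 sum(cm$eps[inside]) - st[2] * cfg$temperature * cfg$ds)
  }
})

test_that("exact enumeration: uniform limit, Ep suppression, mirror symmetry", {
  # all energies zero -> uniform over states
  cfg0 <- wsme_toy_config(eps = 0, ds = 0, Ep = 0)
  ex0 <- exact_partition(cfg0)
  expect_equal(max(ex0$prob) / min(ex0$prob), 1, tolerance = 1e-12)
  expect_equal(sum(ex0$prob), 1)

  # huge Ep kills every midpoint-crossing state
  ex_inf <- exact_partition(wsme_toy_config(Ep = 1e6))
  expect_equal(sum(ex_inf$prob[ex_inf$theta == 1]), 0)

  # mirror symmetry of the duplicated map for non-crossing segments
  ex <- exact_partition(wsme_toy_config())
  L <- 12
  for (st in list(c(2, 4), c(5, 6), c(1, 9))) {
    p1 <- ex$prob[ex$start == st[1] & ex$length == st[2]]
    p2 <- ex$prob[ex$start == st[1] + L & ex$length == st[2]]
    expect_equal(p1, p2, tolerance = 1e-10)
  }
})

test_that("pure entropy chain: occupancy of length l follows the closed form", {
  cfg <- wsme_toy_config(eps = 0, ds = -0.003, temperature = 400)
  ex <- exact_partition(cfg)
  by_len <- ex %>%
    dplyr::filter(length > 0) %>%
    dplyr::group_by(length) %>%
    dplyr::summarise(p = sum(prob), n_states = dplyr::n())
  # P(length = l) proportional to n_states(l) * exp(l * T * ds / kT)
  expected <- by_len$n_states *
    exp(by_len$length * cfg$temperature * cfg$ds / (kB * cfg$temperature))
  expect_equal(by_len$p / sum(expected) * sum(expected[1]) / by_len$p[1] * 0 +
                 by_len$p / by_len$p[1],
               expected / expected[1], tolerance = 1e-10)
})

test_that("Monte Carlo matches exact enumeration (oracle equivalence)", {
  cfg <- wsme_toy_config(Ep = 2)
  ex <- exact_partition(cfg)
  mc <- mc_sample(cfg, n_steps = 4e5, seed = 42)
  tv <- total_variation(wsme_state_probs(mc),
                        dplyr::select(ex, start, length, prob))
  expect_lt(tv, 0.02)
  expect_identical(mc_sample(cfg, 1000, seed = 9)$states,
                   mc_sample(cfg, 1000, seed = 9)$states)
})

test_that("midpoint-crossing occupancy is non-increasing in Ep", {
  occ_exact <- vapply(c(0, 2, 4, 6), function(ep) {
    theta_occupancy(exact_partition(wsme_toy_config(Ep = ep)))
  }, 0)
  expect_true(all(diff(occ_exact) < 0))
  occ_mc <- vapply(c(0, 2, 4, 6), function(ep) {
    theta_occupancy(mc_sample(wsme_toy_config(Ep = ep), 2e5, seed = 7))
  }, 0)
  expect_true(all(diff(occ_mc) <= 0.005))
})

test_that("detailed balance: flux ratios match Boltzmann ratios", {
  cfg <- wsme_toy_config(Ep = 1.5)
  mc <- mc_sample(cfg, 4e5, seed = 3)
  st <- mc$states
  key <- paste(st$start, st$length)
  from <- key[-nrow(st)]
  to <- key[-1]
  moved <- from != to
  flux <- table(paste(from[moved], "->", to[moved]))
  ex <- exact_partition(cfg)
  pk <- setNames(ex$prob, paste(ex$start, ex$length))
  # stationarity: forward and backward fluxes across a move balance, while
  # the occupancies of the two states stand in their Boltzmann ratio
  pair <- names(sort(flux, decreasing = TRUE))[1]
  ab <- strsplit(pair, " -> ")[[1]]
  fwd <- as.numeric(flux[pair])
  rev <- as.numeric(flux[paste(ab[2], "->", ab[1])])
  expect_equal(fwd / rev, 1, tolerance = 0.1)
  occ <- table(key) / length(key)
  expect_equal(as.numeric(occ[ab[1]] / occ[ab[2]]),
               as.numeric(pk[ab[1]] / pk[ab[2]]), tolerance = 0.15)
})

test_that("fold spectrum: permutant minima degenerate with native at Ep = 0", {
  m <- toy_small_model()
  tmod <- build_tandem_model(m, "")
  cfg <- wsme_config(tmod$duplicated_contacts, L = tmod$L, ds = -0.004,
                     Ep = 0, temperature = 525)
  ex <- exact_partition(cfg)
  spec <- wsme_fold_spectrum(ex)
  expect_lt(max(abs(spec$F_rel)), 0.1)

  # with Ep > 0 the midpoint-crossing full-length folds are destabilised
  cfg4 <- wsme_config(tmod$duplicated_contacts, L = tmod$L, ds = -0.004,
                      Ep = 4, temperature = 525)
  spec4 <- wsme_fold_spectrum(exact_partition(cfg4))
  crossing <- spec4$start > 1 & spec4$start < tmod$L + 1
  expect_true(all(spec4$F_rel[crossing] > 3.9))
  expect_lt(abs(spec4$F_rel[spec4$start == tmod$L + 1]), 0.1)
})

test_that("surfaces: exact vs MC agreement, minimum zero, NA for unreachable", {
  cfg <- wsme_toy_config(Ep = 1)
  ex <- exact_partition(cfg)
  surf_ex <- wsme_surface(ex)
  expect_equal(min(surf_ex$F, na.rm = TRUE), 0)
  expect_true(any(is.na(surf_ex$F)))
  mc <- mc_sample(cfg, 6e5, seed = 11)
  surf_mc <- wsme_surface(mc)
  j <- dplyr::inner_join(
    dplyr::filter(surf_ex, is.finite(F)),
    dplyr::filter(surf_mc, is.finite(F)),
    by = c("Q_res", "ij_bar")
  )
  # occupied-cell agreement on well-populated cells
  well <- j[j$F.x < 3, ]
  expect_lt(max(abs(well$F.x - well$F.y)), 0.15)
})
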