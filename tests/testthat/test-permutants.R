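test_that("Heaviside mapping: K = 0 and hand-evaluated K > 0 cases", {
  nat <- hand_map(i = c(2, 1, 3), j = c(7, 6, 8), eps = -1)
  L <- 10

  s0 <- permuted_contact_sets(nat, 0, L)
  expect_setequal(paste(s0$S_in$i, s0$S_in$j), c("2 7", "1 6", "3 8"))
  # S_out at K = 0 is the whole map shifted into the second repeat
  expect_setequal(s0$S_out$i, c(12, 11, 13))
  expect_setequal(s0$S_out$j, c(17, 16, 18))

  s5 <- permuted_contact_sets(hand_map(2, 7, -1), 5, L)
  expect_equal(unlist(s5$S_in[1, c("i", "j")], use.names = FALSE), c(7, 12))
  expect_equal(unlist(s5$S_out[1, c("i", "j")], use.names = FALSE), c(2, 17))

  expect_error(permuted_contact_sets(nat, 10, L), "K must")
})

test_that("contact-set sizes are preserved for every K (property)", {
  for (seed in 1:3) {
    nat <- with_seed(seed, {
      n <- 12
      pairs <- t(combn(n, 2))
      pairs <- pairs[pairs[, 2] - pairs[, 1] >= 3, ]
      pick <- sample(nrow(pairs), 8)
      hand_map(pairs[pick, 1], pairs[pick, 2], eps = -runif(8),
               n_residues = n)
    })
    for (K in 0:11) {
      ps <- permuted_contact_sets(nat, K, 12)
      expect_equal(nrow(ps$S_in), 8)
      expect_equal(nrow(ps$S_out), 8)
      expect_true(all(c(ps$S_in$i, ps$S_in$j, ps$S_out$i, ps$S_out$j) >= 1))
      expect_true(all(c(ps$S_in$i, ps$S_in$j, ps$S_out$i, ps$S_out$j) <= 24))
      # central-domain copies all fall inside the window K+1 .. K+L
      expect_true(all(ps$S_in$i > K & ps$S_in$j <= K + 12))
    }
  }
})

test_that("S_in matches an independent sequence-rotation oracle", {
  # oracle: rotate the chain so the permutant is renumbered 1..L, build its
  # contact pairs directly, then map back into the window frame
  m <- toy_small_model()
  nat <- m$contacts
  L <- length(m$structure)
  for (K in c(4, 13, 21)) {
    ps <- permuted_contact_sets(nat, K, L)
    # renumber the central domain window K+1..K+L to 1..L
    got <- sort(paste(ps$S_in$i - K, ps$S_in$j - K))
    # oracle: position of residue r (1..L) in the rotated chain is
    # r - K if r > K else r - K + L
    rot <- ifelse(seq_len(L) > K, seq_len(L) - K, seq_len(L) - K + L)
    want <- sort(paste(pmin(rot[nat$i], rot[nat$j]),
                       pmax(rot[nat$i], rot[nat$j])))
    expect_identical(got, want)
  }
})

test_that("q_k: logistic midpoint, native frame, extended frame", {
  one <- hand_map(2, 7, -1, r0 = 0.6, n_residues = 10)
  ps <- permuted_contact_sets(one, 0, 10)
  coords <- matrix(0, 20, 3)
  coords[2, ] <- c(0, 0, 0)
  coords[7, ] <- c(1.2 * 0.6, 0, 0)   # exactly lambda * r0
  expect_equal(q_k(coords, ps, "in"), 0.5)

  tm <- toy_small_tandem()
  sets0 <- permuted_contact_sets(tm$domain_model$contacts, 0, tm$L)
  expect_gte(q_k(tm$structure$coords, sets0, "both"), 0.99)
  expect_lt(q_k(extended_coords(2 * tm$L), sets0, "both"), 0.01)
})

test_that("Q is non-increasing under uniform dilation (property)", {
  tm <- toy_small_tandem()
  sets0 <- permuted_contact_sets(tm$domain_model$contacts, 0, tm$L)
  x <- tm$structure$coords
  qs <- vapply(c(1, 1.1, 1.3, 1.8, 3), function(s) q_k(x * s, sets0, "both"),
               0)
  expect_true(all(diff(qs) <= 1e-12))
})

test_that("permutant Q_in is depressed on exact native tandem coordinates", {
  # on the native dimer only the unshifted share of S_in is formed: well
  # below the classification threshold for every cut, and below 1/2 for the
  # central cut (off-centre cuts retain a larger unshifted share)
  tm <- toy_small_tandem()
  m <- tm$domain_model
  Ks <- enumerate_cut_sites(m)$K
  q_in <- vapply(Ks, function(K) {
    q_k(tm$structure$coords, permuted_contact_sets(m$contacts, K, tm$L), "in")
  }, 0)
  expect_true(all(q_in < 0.8))
  central <- which.min(abs(Ks - tm$L / 2))
  expect_lt(q_in[central], 0.5)
})

test_that("rco: hand arithmetic, single contact, frame-shift invariance", {
  set <- tibble::tibble(i = c(1, 2, 3), j = c(5, 9, 8))
  expect_equal(rco(set, 10), (4 + 7 + 5) / 30)
  expect_equal(rco(tibble::tibble(i = 1, j = 10), 10), 0.9)
  expect_equal(rco(dplyr::mutate(set, i = i + 10, j = j + 10), 10),
               rco(set, 10))
  expect_error(rco(set[0, ], 10), "empty")
})

test_that("ij_bar: direct evaluation and frame-shift difference", {
  expect_equal(ij_bar(tibble::tibble(i = c(2, 4), j = c(6, 10))), 5.5)
  expect_equal(ij_bar(tibble::tibble(i = 3, j = 9)), 6)
  expect_true(is.na(ij_bar(tibble::tibble(i = integer(), j = integer()))))

  # formed contacts only in domain 1 vs only in domain 2 differ by exactly L
  tm <- toy_small_tandem()
  L <- tm$L
  dup <- tm$duplicated_contacts
  d1 <- formed_contacts(tm$structure$coords, dup[dup$j <= L, ])
  d2 <- formed_contacts(tm$structure$coords, dup[dup$i > L, ])
  expect_equal(ij_bar(d2) - ij_bar(d1), L)
})

test_that("cut sites: auto-detection, explicit validation, no-loop fixture", {
  m <- toy_small_model()
  sites <- enumerate_cut_sites(m)
  spans <- toy_loop_spans(attr(m$structure, "toy_spec"))
  expect_equal(nrow(sites), nrow(spans))
  expect_true(all(sites$K >= spans$start & sites$K <= spans$end))

  got <- enumerate_cut_sites(m, explicit = sites$K)
  expect_equal(got$K, sites$K)
  expect_error(enumerate_cut_sites(m, explicit = 2), "not inside")

  # a loop-free fixture: a tight helix where every residue has a far contact
  theta <- seq(0, 8 * pi, length.out = 24)
  comp <- calpha_structure(
    cbind(0.3 * cos(theta), 0.3 * sin(theta), seq(0, 2.3, length.out = 24)),
    strrep("A", 24)
  )
  mc <- build_go_model(comp)
  expect_equal(nrow(enumerate_cut_sites(mc)), 0)
})

test_that("permutant model oracle: isolated CP contact map matches S_in", {
  m <- toy_small_model()
  L <- length(m$structure)
  K <- enumerate_cut_sites(m)$K[2]
  cp <- build_permutant_model(m, K)
  ps <- permuted_contact_sets(m$contacts, K, L)
  got <- sort(paste(cp$contacts$i, cp$contacts$j))
  want <- sort(paste(ps$S_in$i - K, ps$S_in$j - K))
  expect_identical(got, want)
})
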