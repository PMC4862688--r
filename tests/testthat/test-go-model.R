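test_that("contact definition: cutoff, minimum separation, hand geometry", {
  # 3-residue chain: min_seq_sep excludes every pair
  short <- calpha_structure(rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.76, 0, 0)),
                            "AAA")
  expect_warning(cm0 <- build_contact_map(short), "empty")
  expect_equal(nrow(cm0), 0)

  # toy meander: every contact satisfies the definition
  cm <- toy_small_model()$contacts
  expect_true(all(cm$j - cm$i >= 3))
  expect_true(all(cm$r0 < 0.8))

  # hand-placed 6-bead chain with exactly one sub-cutoff far pair (1, 5)
  hand <- calpha_structure(rbind(
    c(0.0, 0, 0), c(0.38, 0, 0), c(0.76, 0.1, 0),
    c(0.76, 0.48, 0), c(0.38, 0.55, 0), c(1.5, 1.5, 0)
  ), "AAAAAA")
  cmh <- build_contact_map(hand, cutoff = 0.7)
  got <- cmh[, c("i", "j")]
  expect_true(any(got$i == 1 & got$j == 5))
  expect_true(all(pair_dist <- cmh$r0 < 0.7))
})

test_that("MJ-style well depths scale as requested", {
  toy <- toy_small()
  cm1 <- build_contact_map(toy, energy_unit = 1)
  cm2 <- build_contact_map(toy, energy_unit = 1.5)
  expect_equal(mean(abs(cm1$eps)), 1)
  expect_equal(mean(abs(cm2$eps)), 1.5)
  expect_equal(cm2$eps, 1.5 * cm1$eps)
  cmt <- build_contact_map(toy, total_energy = 42)
  expect_equal(sum(abs(cmt$eps)), 42)
  expect_true(all(cm1$eps < 0))
  # relative depths follow the embedded pair table
  etab <- mj_pair_energies()
  expect_equal(dim(etab), c(20, 20))
  expect_true(all(etab < 0))
  expect_equal(etab, t(etab))
})

test_that("tandem duplication: four equal copies of every native contact", {
  m <- toy_small_model()
  tm <- build_tandem_model(m, "GS")
  L <- length(m$structure) + 2
  expect_equal(tm$L, L)
  expect_equal(length(tm$structure), 2 * L)
  dup <- tm$duplicated_contacts
  expect_equal(nrow(dup), 4 * nrow(m$contacts))
  for (r in sample(nrow(m$contacts), 5)) {
    i <- m$contacts$i[r]; j <- m$contacts$j[r]; e <- m$contacts$eps[r]
    copies <- dup[(dup$i == i & dup$j == j) |
                  (dup$i == i + L & dup$j == j + L) |
                  (dup$i == i & dup$j == j + L) |
                  (dup$i == j & dup$j == i + L), ]
    expect_equal(nrow(copies), 4)
    expect_true(all(copies$eps == e))
    expect_equal(length(unique(copies$r0)), 1)
  }
  expect_equal(sum(dup$eps), 4 * sum(m$contacts$eps))
})

test_that("potential energy: native minimum, extended chain, breakdown", {
  m <- toy_small_model()
  pe <- potential_energy(m, m$structure$coords)
  native_term <- pe$terms$energy[pe$terms$term == "native"]
  expect_equal(native_term, m$total_contact_energy, tolerance = 0.01)
  expect_equal(pe$terms$energy[pe$terms$term == "bond"], 0, tolerance = 1e-6)

  ext <- extended_coords(length(m$structure))
  pe_ext <- potential_energy(m, ext)
  expect_lt(abs(pe_ext$terms$energy[pe_ext$terms$term == "native"]),
            0.05 * abs(m$total_contact_energy))
  expect_error(potential_energy(m, ext * NA), "finite")
})

test_that("forces are the analytic gradient of the energy", {
  m <- toy_small_model()
  core <- swapfold:::model_core(m)
  x <- m$structure$coords +
    with_seed(7, matrix(rnorm(3 * length(m$structure), sd = 0.02), ncol = 3))
  F <- swapfold:::cg_forces_cpp(x, core)
  h <- 1e-6
  idx <- with_seed(8, sample(length(m$structure), 6))
  for (i in idx) {
    for (k in 1:3) {
      xp <- x; xm <- x
      xp[i, k] <- xp[i, k] + h
      xm[i, k] <- xm[i, k] - h
      num <- -(swapfold:::cg_energy_cpp(xp, core)$total -
                 swapfold:::cg_energy_cpp(xm, core)$total) / (2 * h)
      expect_equal(F[i, k], num, tolerance = 1e-4)
    }
  }
})

test_that("energy is invariant under rigid rotation and translation", {
  m <- toy_small_model()
  x <- m$structure$coords
  e0 <- potential_energy(m, x)$total
  for (s in 1:3) {
    th <- with_seed(s, runif(3, 0, 2 * pi))
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0), c(sin(th[1]), cos(th[1]), 0),
                c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])),
                c(0, sin(th[2]), cos(th[2])))
    xr <- x %*% (Rz %*% Rx) + matrix(th, nrow(x), 3, byrow = TRUE)
    expect_equal(potential_energy(m, xr)$total, e0, tolerance = 1e-8)
  }
})

test_that("contact-energy translational symmetry of the tandem", {
  # a conformation with domain 2 folded and domain 1 extended has the same
  # energy as its mirror (domain 1 folded, domain 2 extended)
  tm <- toy_small_tandem()
  L <- tm$L
  nat <- tm$domain_model$structure$coords
  ctr <- colMeans(nat)
  tail_from <- function(anchor, n, reverse = FALSE) {
    u <- unit_vec(anchor - ctr)
    steps <- if (reverse) rev(seq_len(n)) else seq_len(n)
    matrix(anchor, n, 3, byrow = TRUE) + (steps * 0.36) %o% u
  }
  # domain 1 folded, domain 2 extended outward
  conf_a <- rbind(nat, tail_from(nat[L, ], L))
  # mirror: domain 2 folded at the same geometry, domain 1 extended outward
  conf_b <- rbind(tail_from(nat[1, ], L, reverse = TRUE), nat)
  ea <- potential_energy(tm, conf_a)$terms
  eb <- potential_energy(tm, conf_b)$terms
  expect_equal(ea$energy[ea$term == "native"],
               eb$energy[eb$term == "native"], tolerance = 0.2)
})

test_that("linker extension follows the Gly-Ser pattern and the arithmetic", {
  m <- toy_small_model()
  tm0 <- build_tandem_model(m, "")
  expect_identical(apply_linker_extension(tm0, 0), tm0)
  t5 <- apply_linker_extension(tm0, 5)
  expect_equal(t5$linker_sequence, "GSGSS")
  expect_equal(t5$L, tm0$L + 5)
  t20 <- apply_linker_extension(tm0, 20)
  expect_equal(t20$L, tm0$L + 20)
  expect_equal(nrow(t20$duplicated_contacts), nrow(tm0$duplicated_contacts))
  # added residues carry no contacts
  link_idx <- which(t20$is_linker)
  expect_false(any(t20$duplicated_contacts$i %in% link_idx |
                     t20$duplicated_contacts$j %in% link_idx))
})

test_that("model JSON serialization round-trips the energy substrate", {
  m <- toy_small_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$structure$coords, m$structure$coords, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(back$structure$sequence, m$structure$sequence)
  expect_equal(as.data.frame(back$contacts), as.data.frame(m$contacts),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$total_contact_energy, m$total_contact_energy)
  expect_error(read_model_json(withr::local_tempfile(lines = "{}",
                                                     fileext = ".json")),
               "not a swapfold model")
})
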