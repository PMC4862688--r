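# Umbrella sampling along Q, WHAM unbiasing, and free-energy-profile
# thermodynamics.

#' Umbrella windows along Q
#'
#' @param n number of windows.
#' @param k harmonic force constant, kcal/mol per unit Q^2.
#' @param from,to range of window centres.
#' @return tibble with columns `center` and `k`.
#' @export
umbrella_windows <- function(n = 24, k = 200, from = 0.02, to = 0.98) {
  tibble(center = seq(from, to, length.out = n), k = k)
}

#' Umbrella sampling along a contact coordinate
#'
#' Adds a harmonic bias `0.5 k (Q - center)^2` per window and records Q.
#' Windows run from high to low Q, each seeded from the final frame of the
#' previous one (the first starts from the native structure), which keeps
#' low-Q windows equilibrated without long unfolding waits.
#'
#' @param model `go_model` or `tandem_model`.
#' @param set contact tibble defining Q (defaults to the model's native
#'   contacts).
#' @param windows tibble from [umbrella_windows()].
#' @param params [langevin_params()]; `n_steps` is ignored in favour of
#'   `n_equil`/`n_sample`.
#' @param n_equil,n_sample equilibration and production steps per window.
#' @param sample_every record Q every this many steps.
#' @param qp [q_params()].
#' @return An object of class `umbrella_samples`: tibble with columns
#'   `window`, `center`, `k`, `q`; attributes `temperature` and `n_per_window`.
#' @export
umbrella_sampling <- function(model, windows = umbrella_windows(),
                              params, set = NULL,
                              n_equil = 4000, n_sample = 20000,
                              sample_every = 20, qp = q_params()) {
  set <- set %||% model_contact_table(model)
  windows <- arrange(windows, desc(.data$center))
  start <- model$structure$coords
  out <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    p <- params
    p$n_steps <- n_equil + n_sample
    p$seed <- params$seed * 7919 + w
    traj <- langevin_run(
      model, p, initial = start, check_every = sample_every,
      qsets = list(q = set),
      bias = list(set = set, k = windows$k[w], q0 = windows$center[w]),
      qp = qp
    )
    start <- traj$final
    keep <- traj$checks$step > n_equil
    out[[w]] <- tibble(window = w, center = windows$center[w],
                       k = windows$k[w], q = traj$checks$q[keep])
  }
  samples <- bind_rows(out) %>% arrange(.data$center)
  check_window_overlap(samples)
  structure(samples,
            class = c("umbrella_samples", class(tibble())),
            temperature = params$temperature,
            n_per_window = floor(n_sample / sample_every))
}

check_window_overlap <- function(samples) {
  by_w <- samples %>%
    group_by(.data$center) %>%
    summarise(lo = min(.data$q), hi = max(.data$q), .groups = "drop") %>%
    arrange(.data$lo)
  if (nrow(by_w) < 2) return(invisible(TRUE))
  for (w in seq_len(nrow(by_w) - 1)) {
    if (by_w$hi[w] < by_w$lo[w + 1]) {
      abort(sprintf(
        "umbrella histograms do not overlap between Q = %.3f and Q = %.3f; add windows or lower k",
        by_w$hi[w], by_w$lo[w + 1]))
    }
  }
  invisible(TRUE)
}

#' WHAM unbiasing of umbrella samples
#'
#' Standard binned weighted-histogram self-consistency iteration.  Converges
#' the per-window free energies to `tol` and returns the unbiased free-energy
#' profile, shifted so its minimum is zero.  Bins never visited are dropped.
#'
#' @param samples an `umbrella_samples` object, or any tibble with columns
#'   `center`, `k`, `q` (one row per sample).
#' @param temperature K (defaults to the attribute recorded on `samples`).
#' @param bin_width Q bin width.
#' @param tol convergence tolerance on the window free energies (kcal/mol).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return A `free_energy_profile`: tibble with columns `Q`, `F` (kcal/mol).
#' @export
wham <- function(samples, temperature = NULL, bin_width = 0.01, tol = 1e-7,
                 max_iter = 50000) {
  temperature <- temperature %||% attr(samples, "temperature")
  if (is.null(temperature)) abort("temperature not given")
  kT <- kB * temperature
  wins <- samples %>%
    group_by(.data$center, .data$k) %>%
    summarise(n = n(), .groups = "drop")
  lo <- floor(min(samples$q) / bin_width) * bin_width
  hi <- ceiling(max(samples$q) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  mids <- edges[-length(edges)] + bin_width / 2
  counts <- matrix(0, nrow(wins), length(mids))
  for (w in seq_len(nrow(wins))) {
    qs <- samples$q[samples$center == wins$center[w] & samples$k == wins$k[w]]
    counts[w, ] <- tabulate(
      pmin(pmax(findInterval(qs, edges, all.inside = TRUE), 1), length(mids)),
      nbins = length(mids))
  }
  M <- colSums(counts)
  Nw <- wins$n
  bias <- outer(seq_len(nrow(wins)), seq_along(mids), function(w, b) {
    0.5 * wins$k[w] * (mids[b] - wins$center[w])^2
  })
  cwb <- exp(-bias / kT)
  f <- rep(1, nrow(wins))          # exp(f_w / kT), iterated
  for (it in seq_len(max_iter)) {
    denom <- colSums(Nw * f * cwb)
    P <- ifelse(denom > 0, M / denom, 0)
    f_new <- 1 / pmax(cwb %*% P, 1e-300)[, 1]
    f_new <- f_new / f_new[1]
    delta <- max(abs(log(f_new) - log(f)))
    f <- f_new
    if (delta < tol / kT) break
  }
  if (delta >= tol / kT) {
    abort(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                  max_iter, delta * kT))
  }
  keep <- M > 0
  F <- -kT * log(P[keep] / sum(P[keep]))
  new_free_energy_profile(tibble(Q = mids[keep], F = F - min(F)),
                          temperature = temperature)
}

new_free_energy_profile <- function(tbl, temperature, coordinate_id = NA) {
  structure(tbl, class = c("free_energy_profile", class(tibble())),
            temperature = temperature, coordinate_id = coordinate_id)
}

#' Construct a free-energy profile from explicit values
#'
#' @param Q grid (strictly increasing, in `[0, 1]`).
#' @param F free energies, kcal/mol; shifted so the minimum is 0.
#' @param temperature K.
#' @param coordinate_id optional label (e.g. the cut position K).
#' @export
free_energy_profile <- function(Q, F, temperature, coordinate_id = NA) {
  stopifnot(all(diff(Q) > 0), length(Q) == length(F))
  new_free_energy_profile(tibble(Q = Q, F = F - min(F)), temperature,
                          coordinate_id)
}

# Two-basin decomposition.  Local minima are found on a lightly smoothed
# profile (robust against bin noise); the partner of the global minimum is
# the local minimum with the largest barrier prominence between them, and
# the barrier top is the highest intervening point.  Reported indices are
# refined on the raw profile so exact constructed profiles stay exact.
profile_basins <- function(profile, smooth = 3) {
  Q <- profile$Q
  F <- profile$F
  n <- length(F)
  if (n < 5) abort("profile grid too short")
  Fs <- as.numeric(stats::filter(F, rep(1 / smooth, smooth), sides = 2))
  Fs[is.na(Fs)] <- F[is.na(Fs)]
  pad <- c(Inf, Fs, Inf)
  is_min <- vapply(seq_len(n), function(i) {
    pad[i + 1] < pad[i] && pad[i + 1] <= pad[i + 2]
  }, TRUE)
  minima <- which(is_min)
  if (length(minima) < 2) {
    abort("no two-state structure: profile has a single basin")
  }
  i1 <- minima[which.min(Fs[minima])]
  best <- NULL
  for (m in setdiff(minima, i1)) {
    lo <- min(i1, m); hi <- max(i1, m)
    if (hi - lo < 2) next
    ib <- lo + which.max(Fs[(lo + 1):(hi - 1)])
    prom <- Fs[ib] - Fs[m]
    if (is.null(best) || prom > best$prom) best <- list(m = m, ib = ib, prom = prom)
  }
  if (is.null(best) || best$prom <= 0) {
    abort("no two-state structure: no interior barrier between basins")
  }
  refine <- function(i, fun) {
    win <- max(1, i - smooth):min(n, i + smooth)
    win[fun(F[win])]
  }
  i1r <- refine(i1, which.min)
  i2r <- refine(best$m, which.min)
  ibr <- refine(best$ib, which.max)
  list(
    i_unfolded = if (Q[i1r] < Q[i2r]) i1r else i2r,
    i_folded = if (Q[i1r] < Q[i2r]) i2r else i1r,
    i_barrier = ibr
  )
}

#' Folded-state stability from a free-energy profile
#'
#' Integrates the Boltzmann weight on either side of the barrier top and
#' reports `dG_s = kT ln(Z_folded / Z_unfolded)`: positive when the folded
#' (high-Q) basin is more stable, matching the usual sign convention for
#' reported stabilities.
#'
#' @param profile a `free_energy_profile`.
#' @param smooth running-mean window (grid points) used when locating basins.
#' @param Q_split optional fixed dividing point.  By default the barrier top
#'   between the two basins is located automatically; passing `Q_split`
#'   integrates on either side of that point instead, which stays defined
#'   even for one-sided profiles (e.g. a permutant with no folded basin).
#' @return One-row tibble: `dG_s`, `Q_barrier`, `Q_unfolded`, `Q_folded`,
#'   `temperature`.
#' @export
stability_from_profile <- function(profile, smooth = 3, Q_split = NULL) {
  kT <- kB * attr(profile, "temperature")
  Q <- profile$Q
  F <- profile$F
  wts <- exp(-F / kT)
  trap <- function(idx) {
    if (length(idx) < 2) return(wts[idx] * 0.01)
    sum(diff(Q[idx]) * (wts[idx][-1] + wts[idx][-length(idx)]) / 2)
  }
  if (is.null(Q_split)) {
    b <- profile_basins(profile, smooth)
    qb <- Q[b$i_barrier]
    i_unf <- b$i_unfolded
    i_fold <- b$i_folded
  } else {
    qb <- Q_split
    i_unf <- which.min(F[Q < qb])
    i_fold <- which(Q >= qb)[which.min(F[Q >= qb])]
  }
  z_unf <- trap(which(Q <= qb))
  z_fold <- trap(which(Q >= qb))
  tibble(
    dG_s = kT * log(z_fold / z_unf),
    Q_barrier = qb,
    Q_unfolded = Q[i_unf],
    Q_folded = Q[i_fold],
    temperature = attr(profile, "temperature")
  )
}

#' Folding barrier from a free-energy profile
#'
#' `dG_f = F(Q_barrier) - F(Q_unfolded)`, the barrier seen from the unfolded
#' basin.
#'
#' @inheritParams stability_from_profile
#' @return One-row tibble: `dG_f`, `Q_barrier`, `Q_unfolded`, `temperature`.
#' @export
barrier_from_profile <- function(profile, smooth = 3) {
  b <- profile_basins(profile, smooth)
  tibble(
    dG_f = profile$F[b$i_barrier] - profile$F[b$i_unfolded],
    Q_barrier = profile$Q[b$i_barrier],
    Q_unfolded = profile$Q[b$i_unfolded],
    temperature = attr(profile, "temperature")
  )
}

#' @export
glance.free_energy_profile <- function(x, ...) {
  s <- tryCatch(stability_from_profile(x), error = function(e) NULL)
  f <- tryCatch(barrier_from_profile(x), error = function(e) NULL)
  tibble(
    temperature = attr(x, "temperature"),
    dG_s = if (is.null(s)) NA_real_ else s$dG_s,
    dG_f = if (is.null(f)) NA_real_ else f$dG_f,
    Q_barrier = if (is.null(s)) NA_real_ else s$Q_barrier,
    two_state = !is.null(s)
  )
}

# umbrella + WHAM at one temperature; shared by the scans below
profile_at_temperature <- function(model, temperature, seed, set = NULL,
                                   windows = umbrella_windows(),
                                   n_equil = 4000, n_sample = 16000,
                                   sample_every = 20) {
  us <- umbrella_sampling(
    model, windows,
    langevin_params(temperature = temperature, n_steps = 1, seed = seed),
    set = set, n_equil = n_equil, n_sample = n_sample,
    sample_every = sample_every
  )
  wham(us)
}

#' Choose a simulation temperature from the folding barrier
#'
#' Bisects the temperature until the single-domain folding barrier reaches
#' `target` (in units of kT), the regime in which first-passage campaigns
#' resolve both folding and misfolding on accessible time scales.  The
#' melting temperature (where dG_s crosses zero) is reported alongside.
#'
#' @param model a single-domain `go_model`.
#' @param t_range temperature bracket, K.
#' @param target barrier target in kT units.
#' @param tol tolerance on the barrier, kT units.
#' @param seed seed for the umbrella runs.
#' @param max_iter bisection iterations.
#' @param ... passed to the internal umbrella/WHAM evaluation
#'   (`windows`, `n_equil`, `n_sample`, `sample_every`).
#' @return list with `temperature`, `dG_f` (kcal/mol), `Tm`, `scan` tibble,
#'   and the `profile` at the chosen temperature.
#' @export
select_temperature <- function(model, t_range, target = 2.5, tol = 0.1,
                               seed = 1, max_iter = 10, ...) {
  eval_T <- function(temp) {
    pr <- profile_at_temperature(model, temp, seed, ...)
    g <- glance(pr)
    list(profile = pr, dG_f = g$dG_f, dG_s = g$dG_s)
  }
  scan <- tibble(temperature = double(), dG_f = double(), dG_s = double())
  note <- function(temp, ev) {
    scan <<- bind_rows(scan, tibble(temperature = temp, dG_f = ev$dG_f,
                                    dG_s = ev$dG_s))
  }
  g_of <- function(ev, temp) ev$dG_f / (kB * temp) - target
  lo <- t_range[1]; hi <- t_range[2]
  ev_lo <- eval_T(lo); note(lo, ev_lo)
  ev_hi <- eval_T(hi); note(hi, ev_hi)
  if (is.na(ev_lo$dG_f) || is.na(ev_hi$dG_f) ||
      g_of(ev_lo, lo) * g_of(ev_hi, hi) > 0) {
    msg <- paste(utils::capture.output(print(scan)), collapse = "\n")
    abort(paste0("no temperature in range gives the target barrier; scan:\n", msg))
  }
  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    ev <- eval_T(mid); note(mid, ev)
    best <- list(temperature = mid, ev = ev)
    if (is.na(ev$dG_f)) break
    if (abs(g_of(ev, mid)) < tol) break
    if (g_of(ev, mid) * g_of(ev_lo, lo) < 0) {
      hi <- mid; ev_hi <- ev
    } else {
      lo <- mid; ev_lo <- ev
    }
  }
  tm <- tryCatch(
    melting_temperature(model, t_range = range(scan$temperature) + c(-50, 150),
                        seed = seed, ...),
    error = function(e) NA_real_)
  list(temperature = best$temperature, dG_f = best$ev$dG_f,
       Tm = tm, scan = arrange(scan, .data$temperature),
       profile = best$ev$profile)
}

#' Melting temperature (dG_s = 0) of a model
#'
#' @inheritParams select_temperature
#' @export
melting_temperature <- function(model, t_range, seed = 1, tol = 2, ...) {
  g <- function(temp) {
    pr <- profile_at_temperature(model, temp, seed, ...)
    stability_from_profile(pr)$dG_s
  }
  lo <- t_range[1]; hi <- t_range[2]
  glo <- g(lo); ghi <- g(hi)
  if (glo * ghi > 0) abort("melting temperature not bracketed by t_range")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm * glo <= 0) hi <- mid else { lo <- mid; glo <- gm }
  }
  (lo + hi) / 2
}

#' Distribution of the folding-nucleus location at fixed global Q
#'
#' For frames of a tandem trajectory whose global contact fraction falls in
#' `q_value` +/- `band`, computes the nucleus-position order parameter
#' (mean sequence midpoint of all formed native or native-like contacts) and
#' returns its normalised histogram.  Global Q counts formed contacts among
#' all duplicated (native-like) pairs divided by the number of contacts in
#' the native dimer (twice the single-domain count), so Q = 0.5 is one
#' complete domain.
#'
#' @param frames coordinate array (n x 3 x nframe).
#' @param model a `tandem_model`.
#' @param q_value centre of the global-Q slice.
#' @param band half-width of the slice.
#' @param breaks histogram breaks over sequence position (default: 2-residue
#'   bins over the full chain).
#' @param qp [q_params()] (the sharp criterion `dist < lam * r0` is used).
#' @return tibble with `ij_mid` (bin centre) and `density`; attribute
#'   `n_frames` records the slice occupancy.
#' @export
nucleus_location_distribution <- function(frames, model, q_value, band = 0.02,
                                          breaks = NULL, qp = q_params()) {
  dup <- as_tibble(model$duplicated_contacts)
  n_native_dimer <- 2 * nrow(model$domain_model$contacts)
  nf <- dim(frames)[3]
  vals <- purrr::map_dfr(seq_len(nf), function(f) {
    fc <- formed_contacts(frames[, , f], dup, qp)
    tibble(Q = nrow(fc) / n_native_dimer, ij = ij_bar(fc))
  })
  sel <- vals[abs(vals$Q - q_value) <= band & !is.na(vals$ij), , drop = FALSE]
  if (nrow(sel) == 0) {
    abort(sprintf("no frames with global Q within %.3f of %.3f", band, q_value))
  }
  breaks <- breaks %||% seq(0, 2 * model$L + 2, by = 2)
  h <- graphics::hist(sel$ij, breaks = breaks, plot = FALSE)
  structure(
    tibble(ij_mid = h$mids, density = h$density * diff(breaks)[1]),
    n_frames = nrow(sel), q_value = q_value
  )
}
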