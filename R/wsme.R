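# Single-sequence Wako-Saito-Munoz-Eaton model of first-domain formation in
# a tandem dimer, with a midpoint strain penalty Ep.

#' Configuration of the WSME midpoint-penalty model
#'
#' Each residue of the 2L tandem chain is folded or unfolded; native
#' structure grows as one contiguous segment (single-sequence approximation)
#' whose length may not exceed the single-repeat length L (only the first
#' domain's formation is modelled).  A state with segment residues
#' `start ... start+length-1` has free energy
#' `G = sum(eps of contacts inside the segment) - length * T * ds + Ep * theta`,
#' where `theta = 1` when the segment contains both residue L and residue
#' L+1, i.e. it crosses the midpoint and must be a circular-permutant
#' (strained) fold.
#'
#' @param contact_map contact tibble over the 2L chain (typically the
#'   duplicated tandem map), columns `i`, `j`, `eps`.
#' @param L single-repeat length.
#' @param eps optional uniform contact energy (kcal/mol, negative); when
#'   given it overrides the per-contact energies of the map.
#' @param ds per-residue entropy change on folding, kcal/mol/K (negative:
#'   folding costs entropy).
#' @param Ep midpoint strain penalty, kcal/mol (>= 0).
#' @param temperature K.
#' @return A list of class `wsme_config`.
#' @export
wsme_config <- function(contact_map, L, ds, eps = NULL, Ep = 0,
                        temperature = 525) {
  cm <- as_tibble(contact_map)[, c("i", "j")]
  cm$eps <- if (is.null(eps)) as_tibble(contact_map)$eps else eps
  seq_length <- 2L * as.integer(L)
  # note: duplicated tandem maps may hold short-separation swap copies near
  # the junction (sep L - |i - j|); they are kept so window contact counts
  # stay exactly symmetric between native and permutant segments
  stopifnot(Ep >= 0, all(cm$i >= 1), all(cm$j <= seq_length),
            all(cm$j > cm$i))
  structure(
    list(contacts = cm, L = as.integer(L), seq_length = seq_length,
         ds = ds, Ep = Ep, temperature = temperature),
    class = "wsme_config"
  )
}

#' @export
print.wsme_config <- function(x, ...) {
  cat(sprintf(
    "<wsme_config> 2L = %d, %d contacts, ds = %.4g kcal/mol/K, Ep = %.2f, T = %g K\n",
    x$seq_length, nrow(x$contacts), x$ds, x$Ep, x$temperature))
  invisible(x)
}

wsme_theta <- function(start, length, L) {
  as.integer(start <= L & start + length - 1 >= L + 1 & length > 0)
}

#' Free energy of a WSME state
#'
#' @param start first residue of the native segment (0 for the fully
#'   unfolded state).
#' @param length segment length (0 for the unfolded state).
#' @param config a [wsme_config()].
#' @return G in kcal/mol (vectorised over `start`/`length`).
#' @export
state_energy <- function(start, length, config) {
  end <- start + length - 1
  vapply(seq_along(start), function(s) {
    if (length[s] == 0) return(0)
    cm <- config$contacts
    inside <- cm$i >= start[s] & cm$j <= end[s]
    sum(cm$eps[inside]) - length[s] * config$temperature * config$ds +
      config$Ep * wsme_theta(start[s], length[s], config$L)
  }, 0)
}

# 2D suffix/prefix-sum tables: for any segment [s, e], the sum of contact
# energies, the contact count and the sum of contact midpoints fully inside
# the segment, in O(1) per lookup.
wsme_tables <- function(config) {
  n <- config$seq_length
  put <- function(vals) {
    A <- matrix(0, n, n)
    A[cbind(config$contacts$i, config$contacts$j)] <- vals
    A <- t(apply(A, 1, cumsum))           # prefix over j
    apply(A[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]  # suffix over i
  }
  list(
    e_sum = put(config$contacts$eps),
    cnt = put(rep(1, nrow(config$contacts))),
    mid_sum = put((config$contacts$i + config$contacts$j) / 2)
  )
}

#' Exact enumeration of the WSME model
#'
#' Enumerates the fully unfolded state and every contiguous segment of
#' length 1..L, computes Boltzmann probabilities and the per-state order
#' parameters Q_res (segment length over L) and the nucleus position (mean
#' midpoint of contacts inside the segment; for contact-free segments the
#' segment midpoint is used as a documented fallback, and the unfolded state
#' has no position).
#'
#' @param config a [wsme_config()].
#' @param max_states refuse enumerations beyond this (use [mc_sample()]).
#' @return A tibble of class `wsme_exact`: `start`, `length`, `energy`,
#'   `theta`, `prob`, `Q_res`, `ij_bar`; attribute `logZ`.
#' @export
exact_partition <- function(config, max_states = 2e6) {
  n <- config$seq_length
  L <- config$L
  n_states <- sum(pmin(rep(L, n), n - seq_len(n) + 1)) + 1
  if (n_states > max_states) {
    abort(sprintf("state space too large (%d states); use mc_sample()", n_states))
  }
  tabs <- wsme_tables(config)
  grid <- tidyr::expand_grid(start = seq_len(n), length = seq_len(L)) %>%
    filter(.data$start + .data$length - 1 <= n)
  e <- grid$start + grid$length - 1
  idx <- cbind(grid$start, e)
  theta <- wsme_theta(grid$start, grid$length, L)
  energy <- tabs$e_sum[idx] - grid$length * config$temperature * config$ds +
    config$Ep * theta
  cnt <- tabs$cnt[idx]
  ij <- ifelse(cnt > 0, tabs$mid_sum[idx] / cnt, (grid$start + e) / 2)
  states <- bind_rows(
    tibble(start = 0L, length = 0L, energy = 0, theta = 0L,
           Q_res = 0, ij_bar = NA_real_),
    tibble(start = grid$start, length = grid$length, energy = energy,
           theta = theta, Q_res = grid$length / L, ij_bar = ij)
  )
  kT <- kB * config$temperature
  w <- exp(-(states$energy - min(states$energy)) / kT)
  states$prob <- w / sum(w)
  logZ <- log(sum(w)) - min(states$energy) / kT
  structure(states, class = c("wsme_exact", class(tibble())),
            logZ = logZ, config = config)
}

#' Metropolis Monte Carlo sampling of the WSME model
#'
#' Single-residue flips at the segment ends: the candidate positions are the
#' two end residues of the native segment and their outer neighbours; from
#' the unfolded state any residue may nucleate a segment.  Proposals that
#' would break contiguity or grow the segment beyond L are rejected and
#' counted.  Because the proposal distribution is asymmetric between the
#' unfolded state and one-residue segments, the acceptance includes the
#' proposal-ratio (Metropolis-Hastings) correction, which keeps the chain in
#' detailed balance with the exact Boltzmann distribution.
#'
#' @param config a [wsme_config()].
#' @param n_steps Monte Carlo steps.
#' @param seed integer seed.
#' @param init optional `c(start, length)` initial state (default unfolded).
#' @param thin record every `thin`-th state.
#' @return A list of class `wsme_mc`: `states` tibble (`start`, `length`,
#'   `theta`), `acceptance`, `n_invalid`, `config`, `seed`.
#' @export
mc_sample <- function(config, n_steps, seed = 1, init = c(0L, 0L), thin = 1) {
  stopifnot(n_steps >= 1)
  n <- config$seq_length
  L <- config$L
  kT <- kB * config$temperature
  Tds <- config$temperature * config$ds
  Ep <- config$Ep
  # adjacency: contacts of each residue
  adj_p <- vector("list", n)
  adj_e <- vector("list", n)
  for (r in seq_len(nrow(config$contacts))) {
    i <- config$contacts$i[r]; j <- config$contacts$j[r]
    e <- config$contacts$eps[r]
    adj_p[[i]] <- c(adj_p[[i]], j); adj_e[[i]] <- c(adj_e[[i]], e)
    adj_p[[j]] <- c(adj_p[[j]], i); adj_e[[j]] <- c(adj_e[[j]], e)
  }
  contact_sum <- function(r, s, e) {
    p <- adj_p[[r]]
    if (is.null(p)) return(0)
    sum(adj_e[[r]][p >= s & p <= e])
  }
  s_cur <- init[1]; len_cur <- init[2]
  th_cur <- wsme_theta(s_cur, len_cur, L)
  n_rec <- floor(n_steps / thin)
  rec_s <- integer(n_rec); rec_l <- integer(n_rec)
  acc <- 0L; invalid <- 0L; irec <- 0L
  with_seed(seed, {
    u_pick <- runif(n_steps)
    u_acc <- runif(n_steps)
    for (step in seq_len(n_steps)) {
      if (len_cur == 0) {
        pos <- 1L + floor(u_pick[step] * n)
        s_new <- pos; len_new <- 1L
        g_fwd <- 1 / n
        g_rev <- 0.5          # from [p,p]: 2 of 4 candidates collapse it
      } else {
        e_cur <- s_cur + len_cur - 1L
        cand <- c(s_cur - 1L, s_cur, e_cur, e_cur + 1L)
        pick <- cand[1L + floor(u_pick[step] * 4)]
        if (pick < 1L || pick > n) { invalid <- invalid + 1L; s_new <- -1L }
        else if (pick == s_cur - 1L) {         # grow left
          if (len_cur + 1L > L) { invalid <- invalid + 1L; s_new <- -1L }
          else { s_new <- pick; len_new <- len_cur + 1L }
        } else if (pick == e_cur + 1L) {       # grow right
          if (len_cur + 1L > L) { invalid <- invalid + 1L; s_new <- -1L }
          else { s_new <- s_cur; len_new <- len_cur + 1L }
        } else if (pick == s_cur) {            # shrink left
          s_new <- s_cur + 1L; len_new <- len_cur - 1L
          if (len_new == 0L) s_new <- 0L
        } else {                               # shrink right (pick == e_cur)
          s_new <- s_cur; len_new <- len_cur - 1L
          if (len_new == 0L) s_new <- 0L
        }
        if (s_new >= 0L) {
          g_fwd <- sum(cand == pick) / 4
          g_rev <- if (len_new == 0L) 1 / n else if (len_cur == 0L) 0.5 else {
            # reverse move re-flips the same residue from the new state
            e_new <- s_new + len_new - 1L
            cand_r <- c(s_new - 1L, s_new, e_new, e_new + 1L)
            sum(cand_r == pick) / 4
          }
        }
      }
      if (len_cur == 0 || s_new >= 0L) {
        # energy difference via the flipped residue's contacts
        if (len_cur == 0L) {
          dG <- -Tds + Ep * (wsme_theta(s_new, len_new, L))
          th_new <- wsme_theta(s_new, len_new, L)
        } else if (len_new > len_cur) {        # grew by residue `pick`
          th_new <- wsme_theta(s_new, len_new, L)
          dG <- contact_sum(pick, s_new, s_new + len_new - 1L) - Tds +
            Ep * (th_new - th_cur)
        } else {                               # shrank by residue `pick`
          th_new <- wsme_theta(s_new, len_new, L)
          lost <- if (len_new == 0L) 0 else
            contact_sum(pick, s_new, s_new + len_new - 1L)
          dG <- -lost + Tds + Ep * (th_new - th_cur)
        }
        p_acc <- min(1, (g_rev / g_fwd) * exp(-dG / kT))
        if (u_acc[step] < p_acc) {
          s_cur <- s_new; len_cur <- len_new; th_cur <- th_new
          acc <- acc + 1L
        }
      }
      if (step %% thin == 0L) {
        irec <- irec + 1L
        rec_s[irec] <- s_cur; rec_l[irec] <- len_cur
      }
    }
  })
  structure(
    list(states = tibble(start = rec_s[seq_len(irec)],
                         length = rec_l[seq_len(irec)],
                         theta = wsme_theta(rec_s[seq_len(irec)],
                                            rec_l[seq_len(irec)], L)),
         acceptance = acc / n_steps, n_invalid = invalid,
         config = config, seed = seed),
    class = "wsme_mc"
  )
}

#' @export
print.wsme_mc <- function(x, ...) {
  cat(sprintf("<wsme_mc> %d recorded states, acceptance %.2f, invalid %d\n",
              nrow(x$states), x$acceptance, x$n_invalid))
  invisible(x)
}

#' Empirical state probabilities of a Monte Carlo run
#'
#' @param mc a `wsme_mc` object.
#' @param burn_in fraction of initial samples to drop.
#' @return tibble `start`, `length`, `prob`.
#' @export
wsme_state_probs <- function(mc, burn_in = 0.1) {
  st <- mc$states[-seq_len(floor(nrow(mc$states) * burn_in)), , drop = FALSE]
  st %>%
    count(.data$start, .data$length) %>%
    mutate(prob = .data$n / sum(.data$n)) %>%
    select("start", "length", "prob")
}

#' Occupancy of midpoint-crossing (circular-permutant) states
#'
#' @param x a `wsme_exact` tibble or `wsme_mc` object.
#' @param burn_in for MC input, fraction dropped.
#' @return Probability that the native segment crosses the midpoint.
#' @export
theta_occupancy <- function(x, burn_in = 0.1) {
  if (inherits(x, "wsme_exact")) {
    sum(x$prob[x$theta == 1])
  } else {
    st <- x$states[-seq_len(floor(nrow(x$states) * burn_in)), , drop = FALSE]
    mean(st$theta)
  }
}

#' Free-energy surface F(Q_res, nucleus position)
#'
#' Bins state probabilities on the (Q_res, ij_bar) plane and reports
#' `F = -kT log P`, min-shifted to zero.  Never-visited cells are returned
#' as `NA` (unreachable), not zero.
#'
#' @param x a `wsme_exact` tibble, or a `wsme_mc` run (probabilities are then
#'   empirical).
#' @param config the model configuration (taken from `x` when available).
#' @param q_bin,ij_bin bin widths on Q_res and sequence position.
#' @param burn_in for MC input.
#' @return tibble of class `wsme_surface`: `Q_res`, `ij_bar`, `F`.
#' @export
wsme_surface <- function(x, config = NULL, q_bin = 0.1, ij_bin = 2,
                         burn_in = 0.1) {
  if (inherits(x, "wsme_exact")) {
    config <- config %||% attr(x, "config")
    states <- x
  } else {
    config <- config %||% x$config
    probs <- wsme_state_probs(x, burn_in)
    ex_geom <- exact_geometry(config)
    states <- left_join(probs, ex_geom, by = c("start", "length"))
  }
  kT <- kB * config$temperature
  occupied <- states %>%
    filter(!is.na(.data$ij_bar), .data$prob > 0) %>%
    mutate(
      qb = round(.data$Q_res / q_bin) * q_bin,
      ib = round(.data$ij_bar / ij_bin) * ij_bin
    ) %>%
    group_by(.data$qb, .data$ib) %>%
    summarise(P = sum(.data$prob), .groups = "drop")
  grid <- tidyr::expand_grid(
    qb = seq(0, 1, by = q_bin),
    ib = seq(0, config$seq_length, by = ij_bin)
  )
  out <- left_join(grid, occupied, by = c("qb", "ib")) %>%
    mutate(F = -kT * log(.data$P)) %>%
    mutate(F = .data$F - min(.data$F, na.rm = TRUE)) %>%
    select(Q_res = "qb", ij_bar = "ib", "F")
  structure(out, class = c("wsme_surface", class(tibble())),
            temperature = config$temperature, Ep = config$Ep)
}

# geometry columns (Q_res, ij_bar) for every state, without probabilities
exact_geometry <- function(config) {
  tabs <- wsme_tables(config)
  n <- config$seq_length
  grid <- tidyr::expand_grid(start = seq_len(n),
                             length = seq_len(config$L)) %>%
    filter(.data$start + .data$length - 1 <= n)
  e <- grid$start + grid$length - 1
  idx <- cbind(grid$start, e)
  cnt <- tabs$cnt[idx]
  bind_rows(
    tibble(start = 0L, length = 0L, Q_res = 0, ij_bar = NA_real_),
    tibble(start = grid$start, length = grid$length,
           Q_res = grid$length / config$L,
           ij_bar = ifelse(cnt > 0, tabs$mid_sum[idx] / cnt,
                           (grid$start + e) / 2))
  )
}

#' Free energies of the full-length folds by start position
#'
#' For complete first domains (segment length L), the free energy
#' `-kT log P(start)` relative to the native starts (start = 1 or L+1).
#' With Ep = 0 and the duplicated contact map every start position holds the
#' same contact set, so permutant and native minima are degenerate.
#'
#' @param exact a `wsme_exact` tibble.
#' @return tibble `start`, `F_rel` (kcal/mol relative to the native start).
#' @export
wsme_fold_spectrum <- function(exact) {
  config <- attr(exact, "config")
  kT <- kB * config$temperature
  full <- exact %>% filter(.data$length == config$L)
  F <- -kT * log(full$prob)
  tibble(start = full$start, F_rel = F - F[full$start == 1][1])
}
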