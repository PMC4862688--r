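# Langevin dynamics and first-passage misfolding campaigns.

#' Langevin dynamics parameters
#'
#' Defaults follow the standard coarse-grained setup: friction 0.1 ps^-1 and
#' a 10 fs time step.
#'
#' @param temperature K.
#' @param n_steps number of integration steps.
#' @param friction ps^-1.
#' @param dt time step in ps (0.01 ps = 10 fs).
#' @param seed integer seed; recorded in all outputs.
#' @export
langevin_params <- function(temperature, n_steps, friction = 0.1, dt = 0.01,
                            seed = 1) {
  stopifnot(dt > 0, friction > 0, n_steps >= 1, temperature >= 0)
  list(temperature = temperature, n_steps = n_steps, friction = friction,
       dt = dt, seed = seed)
}

#' Fully extended starting configuration
#'
#' A slight zigzag (rather than a straight line) keeps angle and dihedral
#' terms well-defined at the first step.
#'
#' @param n number of beads.
#' @param spacing CA-CA spacing, nm.
#' @return n x 3 coordinate matrix.
#' @export
extended_coords <- function(n, spacing = 0.36) {
  theta <- 2.2  # backbone zigzag angle, rad
  step_x <- spacing * sin(theta / 2)
  step_y <- spacing * cos(theta / 2)
  cbind(cumsum(rep(step_x, n)) - step_x,
        rep(c(0, step_y), length.out = n),
        0)
}

run_opts <- function(params, save_every = 0, check_every = 1000,
                     qsets = list(), stop_groups = NULL, stop_threshold = 0,
                     bias = NULL, qp = q_params()) {
  list(
    n_steps = as.double(params$n_steps), dt = params$dt,
    friction = params$friction, temperature = params$temperature,
    mass = FF_DEFAULTS$mass, seed = as.double(params$seed),
    save_every = as.integer(save_every), check_every = as.integer(check_every),
    beta = qp$beta, lam = qp$lam,
    qsets = lapply(qsets, contact_set_matrix),
    stop_groups = stop_groups %||% matrix(0L, 0, 2),
    stop_threshold = stop_threshold,
    bias = bias
  )
}

#' Run Langevin dynamics
#'
#' Underdamped BAOAB Langevin integration of a Go / tandem model.  The
#' trajectory is bit-reproducible for a fixed seed.  An optional harmonic
#' bias `0.5 k (Q - q0)^2` on a logistic contact coordinate supports umbrella
#' sampling.
#'
#' @param model a `go_model` or `tandem_model`.
#' @param params a [langevin_params()] list.
#' @param initial starting coordinates (n x 3); defaults to the model's
#'   native structure.
#' @param save_every save a frame every this many steps (0 = none).
#' @param check_every evaluate monitors/energy every this many steps.
#' @param qsets named list of contact tibbles; the logistic Q of each is
#'   recorded at every check.
#' @param bias optional list `list(set =, k =, q0 =)` for umbrella bias.
#' @param qp [q_params()] for Q evaluation.
#' @return A `cg_trajectory`: list with `final`, `frames` (or NULL),
#'   `checks` tibble (step, energy, one column per monitored set), `params`.
#' @export
langevin_run <- function(model, params, initial = NULL, save_every = 0,
                         check_every = 1000, qsets = list(), bias = NULL,
                         qp = q_params()) {
  initial <- initial %||% model$structure$coords
  initial <- as.matrix(initial)
  if (nrow(initial) != model_size(model)) {
    abort("initial coordinates do not match the model size")
  }
  if (!is.null(bias)) bias$set <- contact_set_matrix(bias$set)
  res <- cg_run_cpp(initial, model_core(model),
                    run_opts(params, save_every, check_every, qsets,
                             bias = bias, qp = qp))
  if (res$blown) {
    abort(sprintf("dynamics blew up near step %d (energy overflow); reduce dt or temperature",
                  res$steps_done))
  }
  nck <- res$n_checks
  checks <- tibble(step = res$check_step[seq_len(nck)],
                   energy = res$energy[seq_len(nck)])
  if (length(qsets)) {
    qh <- res$qhist[seq_len(nck), , drop = FALSE]
    colnames(qh) <- names(qsets) %||% paste0("set", seq_along(qsets))
    checks <- bind_cols(checks, as_tibble(qh))
  }
  structure(
    list(final = res$coords,
         frames = res$frames %||% NULL,
         checks = checks,
         steps_done = res$steps_done,
         params = params),
    class = "cg_trajectory"
  )
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %g steps at T = %g K (seed %g)\n",
              x$steps_done, x$params$temperature, x$params$seed))
  invisible(x)
}

# contact-set list for state classification: K = 0 plus each cut site
classification_sets <- function(model, cut_sites = NULL) {
  native <- as_tibble(model$domain_model$contacts)
  L <- model$L
  Ks <- c(0L, if (!is.null(cut_sites)) as.integer(cut_sites$K) else {
    as.integer(enumerate_cut_sites(model$domain_model)$K)
  })
  stats::setNames(lapply(Ks, function(k) permuted_contact_sets(native, k, L)),
                  paste0("K", Ks))
}

#' Classify a tandem configuration
#'
#' A configuration is assigned to fold K when both its central-domain and
#' terminal-domain contact fractions reach `threshold`; K = 0 is the native
#' fold.  If several K qualify the one with the highest min(Q_in, Q_out)
#' wins; if none does the label is "incomplete".
#'
#' @param coords configuration (2L x 3).
#' @param sets_list named list of [permuted_contact_sets()] (include K = 0).
#' @param threshold classification threshold in (0.5, 1).
#' @param qp [q_params()].
#' @return A list with `label` ("native", "incomplete" or the K value as a
#'   string) and `q` (tibble of Q_in/Q_out per K).
#' @export
classify_state <- function(coords, sets_list, threshold = 0.8,
                           qp = q_params()) {
  stopifnot(threshold > 0.5, threshold < 1)
  q <- purrr::map_dfr(sets_list, function(ps) {
    tibble(K = ps$K,
           q_in = q_k(coords, ps, "in", qp),
           q_out = q_k(coords, ps, "out", qp))
  })
  q <- mutate(q, q_min = pmin(.data$q_in, .data$q_out))
  hit <- q[q$q_min >= threshold, , drop = FALSE]
  label <- if (nrow(hit) == 0) {
    "incomplete"
  } else {
    kbest <- hit$K[which.max(hit$q_min)]
    if (kbest == 0) "native" else as.character(kbest)
  }
  list(label = label, q = q)
}

#' First-passage folding/misfolding campaign
#'
#' Runs `n_traj` independent Langevin trajectories of the tandem model, each
#' started from a fully extended chain with its own seed, and classifies the
#' final configuration as native, one of the circular-permutant misfolds, or
#' incomplete.  Trajectories stop early once a fold is complete (folded
#' states are effectively absorbing on these time scales).
#'
#' @param model a `tandem_model`.
#' @param n_traj number of trajectories.
#' @param params [langevin_params()]; `n_steps` is the time cap per
#'   trajectory and `seed` the campaign master seed.
#' @param threshold classification threshold on Q_in and Q_out.
#' @param cut_sites optional tibble from [enumerate_cut_sites()] run on the
#'   domain model; auto-detected otherwise.
#' @param check_every classification interval, steps.
#' @param qp [q_params()].
#' @return A list of class `fp_campaign`: `outcomes` tibble (one row per
#'   trajectory: `trajectory_id`, `final_label`, `steps`, final Q columns)
#'   and `summary` tibble (label, count, fraction, se).
#' @export
first_passage_campaign <- function(model, n_traj, params, threshold = 0.8,
                                   cut_sites = NULL, check_every = 2000,
                                   qp = q_params()) {
  stopifnot(n_traj >= 1)
  sets_list <- classification_sets(model, cut_sites)
  qsets <- purrr::flatten(purrr::imap(sets_list, function(ps, nm) {
    stats::setNames(list(ps$S_in, ps$S_out), paste0(nm, c("_in", "_out")))
  }))
  stop_groups <- cbind(seq_along(sets_list) * 2L - 1L,
                       seq_along(sets_list) * 2L)
  x0 <- extended_coords(model_size(model))
  labels_k <- vapply(sets_list, function(ps) ps$K, 0L)

  outcomes <- purrr::map_dfr(seq_len(n_traj), function(t) {
    p <- params
    p$seed <- params$seed * 1000003 + t
    res <- cg_run_cpp(x0, model_core(model),
                      run_opts(p, save_every = 0, check_every = check_every,
                               qsets = qsets, stop_groups = stop_groups,
                               stop_threshold = threshold, qp = qp))
    if (res$blown) {
      return(tibble(trajectory_id = t, final_label = "incomplete",
                    steps = res$steps_done, seed = p$seed, q_best = NA_real_))
    }
    cls <- classify_state(res$coords, sets_list, threshold, qp)
    tibble(trajectory_id = t, final_label = cls$label,
           steps = res$steps_done, seed = p$seed,
           q_best = max(cls$q$q_min))
  })
  structure(
    list(outcomes = outcomes,
         summary = population_summary(outcomes, n = n_traj,
                                      all_labels = c("native",
                                                     as.character(labels_k[labels_k > 0]),
                                                     "incomplete")),
         threshold = threshold,
         params = params),
    class = "fp_campaign"
  )
}

#' @export
print.fp_campaign <- function(x, ...) {
  cat(sprintf("<fp_campaign> %d trajectories at T = %g K\n",
              nrow(x$outcomes), x$params$temperature))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.fp_campaign <- function(x, ...) x$outcomes

#' @export
glance.fp_campaign <- function(x, ...) {
  mis <- x$summary[!x$summary$label %in% c("native", "incomplete"), ]
  tibble(
    n_traj = nrow(x$outcomes),
    fraction_native = x$summary$fraction[x$summary$label == "native"],
    fraction_misfolded = sum(mis$fraction),
    fraction_incomplete = x$summary$fraction[x$summary$label == "incomplete"],
    temperature = x$params$temperature
  )
}
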