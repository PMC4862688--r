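# Circular-permutant cut sites, frame-shifted contact sets and reaction
# coordinates for the tandem dimer.

#' Logistic contact-coordinate parameters
#'
#' `beta` (nm^-1) sets the sharpness of the logistic switching function and
#' `lam` the tolerance factor on the native distance that counts a contact as
#' formed despite thermal fluctuations.
#'
#' @param beta switching steepness, nm^-1.
#' @param lam native-distance tolerance factor (>= 1).
#' @export
q_params <- function(beta = 50, lam = 1.2) {
  stopifnot(beta > 0, lam >= 1)
  list(beta = beta, lam = lam)
}

#' Frame-shifted contact sets of a circular-permutant misfold
#'
#' For a cut position K (K = 0 is the native fold), maps every native contact
#' (i, j) of the single domain into the tandem frame of the misfold with a
#' central domain starting after K: the central-domain ("in") copy shifts any
#' index <= K by the repeat length L, and the terminal-domain ("out") copy
#' shifts any index >= K by L.  The step function treats x = 0 as 1, so
#' residue K itself belongs to the terminal side and the central domain spans
#' K+1 ... K+L.
#'
#' @param native a `contact_map` (or tibble with `i`, `j`, `r0`, `eps`) of
#'   the single domain, indices in 1..L.
#' @param K cut position, `0 <= K < L`.
#' @param L repeat length (domain plus linker).
#' @return An object of class `permutant_sets`: list with `K`, `L`, `S_in`
#'   and `S_out` tibbles (columns `i`, `j`, `r0`, `eps`; `i < j`).
#' @export
permuted_contact_sets <- function(native, K, L) {
  native <- as_tibble(native)
  if (K < 0 || K >= L) abort("K must satisfy 0 <= K < L")
  if (any(native$i < 1 | native$j > L)) {
    abort("native contact indices must lie in [1, L]")
  }
  theta <- function(x) as.integer(x >= 0)
  shift_pair <- function(si, sj) {
    tibble(
      i = pmin(si, sj), j = pmax(si, sj),
      r0 = native$r0, eps = native$eps
    )
  }
  s_in <- shift_pair(native$i + theta(K - native$i) * L,
                     native$j + theta(K - native$j) * L)
  s_out <- shift_pair(native$i + theta(native$i - K) * L,
                      native$j + theta(native$j - K) * L)
  structure(list(K = K, L = L, S_in = s_in, S_out = s_out),
            class = "permutant_sets")
}

#' @export
print.permutant_sets <- function(x, ...) {
  cat(sprintf("<permutant_sets> K = %d (L = %d), |S_in| = |S_out| = %d\n",
              x$K, x$L, nrow(x$S_in)))
  invisible(x)
}

#' @export
tidy.permutant_sets <- function(x, ...) {
  bind_rows(
    mutate(x$S_in, set = "in"),
    mutate(x$S_out, set = "out")
  ) %>% mutate(K = x$K)
}

contact_set_matrix <- function(set) {
  cbind(set$i, set$j, set$r0)
}

#' Fraction of native-like contacts Q_K
#'
#' The logistic fraction of formed contacts over the central-domain set
#' (`which = "in"`), the terminal-domain set (`"out"`), or their union
#' (`"both"`, normalised by the union size), evaluated on one configuration
#' of the tandem chain.  A contact at exactly `lam * r0` counts 1/2.
#'
#' @param coords configuration, matrix (2L x 3) nm.
#' @param sets a [permuted_contact_sets()] object.
#' @param which which contact set to average over.
#' @param params a [q_params()] list.
#' @return A fraction in `[0, 1]`.
#' @export
q_k <- function(coords, sets, which = c("in", "out", "both"),
                params = q_params()) {
  which <- match.arg(which)
  set <- switch(which,
    "in" = sets$S_in,
    "out" = sets$S_out,
    "both" = bind_rows(sets$S_in, sets$S_out)
  )
  if (nrow(set) == 0) abort("empty contact set")
  r <- pair_distances(as.matrix(coords), set$i, set$j)
  mean(stats::plogis(-params$beta * (r - params$lam * set$r0)))
}

#' Contacts currently formed in a configuration
#'
#' The sharp criterion `dist < lam * r0` used for state bookkeeping and for the
#' nucleus-position order parameter.
#'
#' @inheritParams q_k
#' @param set a contact tibble (`i`, `j`, `r0`).
#' @return The subset of `set` whose contacts are formed.
#' @export
formed_contacts <- function(coords, set, params = q_params()) {
  set <- as_tibble(set)
  if (nrow(set) == 0) return(set)
  r <- pair_distances(as.matrix(coords), set$i, set$j)
  set[r < params$lam * set$r0, , drop = FALSE]
}

#' Mean sequence position of formed contacts
#'
#' The nucleus-location order parameter: the average of (i + j)/2 over all
#' currently formed contacts.  With no formed contacts the value is
#' undefined and `NA` is returned.
#'
#' @param formed a contact tibble, e.g. from [formed_contacts()].
#' @return Mean contact midpoint (residue units), or `NA_real_`.
#' @export
ij_bar <- function(formed) {
  if (is.null(formed) || nrow(formed) == 0) return(NA_real_)
  mean((formed$i + formed$j) / 2)
}

#' Relative contact order of a permutant contact set
#'
#' `RCO = sum |i - j| / (L * N)` over the central-domain contact set; a
#' topology descriptor of the permutant fold.  Frame shifts (adding L to both
#' members of every pair) leave it unchanged.
#'
#' @param set contact tibble (columns `i`, `j`).
#' @param L single-repeat length.
#' @return Dimensionless fraction in (0, 1).
#' @export
rco <- function(set, L) {
  set <- as_tibble(set)
  if (nrow(set) == 0) abort("empty contact set")
  sum(abs(set$i - set$j)) / (L * nrow(set))
}

#' Enumerate circular-permutant cut sites
#'
#' Domain swapping requires the cut to fall in a loop.  Loops are detected as
#' maximal runs of at least `min_run` consecutive residues that take part in
#' no contact with sequence separation above 4; each detected loop
#' contributes its central residue as a cut site K.  An explicit K list
#' (e.g. positions read off a structure) is validated against the detected
#' loops instead.
#'
#' @param model a `go_model`.
#' @param explicit optional integer vector of K values to validate and
#'   return.
#' @param min_run minimum loop length for auto-detection.
#' @return A tibble with columns `K`, `loop_start`, `loop_end`.
#' @export
enumerate_cut_sites <- function(model, explicit = NULL, min_run = 3) {
  cm <- as_tibble(model$contacts)
  L <- length(model$structure)
  far <- cm[cm$j - cm$i > 4, , drop = FALSE]
  busy <- rep(FALSE, L)
  busy[unique(c(far$i, far$j))] <- TRUE
  free <- !busy
  runs <- rle(free)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_run &
    starts > 1 & ends < L    # chain termini are not loops
  loops <- tibble(loop_start = starts[keep], loop_end = ends[keep])
  if (!is.null(explicit)) {
    hit <- vapply(explicit, function(k) {
      any(k >= loops$loop_start & k <= loops$loop_end)
    }, TRUE)
    if (any(!hit)) {
      abort(sprintf("K = %s not inside a contact-free loop",
                    paste(explicit[!hit], collapse = ", ")))
    }
    idx <- vapply(explicit, function(k) {
      which(k >= loops$loop_start & k <= loops$loop_end)[1]
    }, 1L)
    return(tibble(K = as.integer(explicit),
                  loop_start = loops$loop_start[idx],
                  loop_end = loops$loop_end[idx]))
  }
  loops %>%
    mutate(K = as.integer(floor((.data$loop_start + .data$loop_end) / 2))) %>%
    select("K", "loop_start", "loop_end")
}

#' Permutant report for a model
#'
#' One row per cut site with the size, relative contact order and loop span
#' of the central-domain contact set.
#'
#' @param model a `go_model`.
#' @param L repeat length used for the frame shift (defaults to the domain
#'   length; pass the tandem `L` when a linker is present).
#' @inheritParams enumerate_cut_sites
#' @return tibble: `K`, `loop_start`, `loop_end`, `n_in`, `rco`.
#' @export
permutant_report <- function(model, explicit = NULL, L = NULL) {
  L <- L %||% length(model$structure)
  sites <- enumerate_cut_sites(model, explicit = explicit)
  rows <- purrr::map_dfr(seq_len(nrow(sites)), function(r) {
    ps <- permuted_contact_sets(model$contacts, sites$K[r], L)
    tibble(n_in = nrow(ps$S_in), rco = rco(ps$S_in, L))
  })
  bind_cols(sites, rows)
}
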