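#' Gaussian random-walk proposal
#'
#' Draws a candidate `x_c ~ N(x_k, sigma^2 I)` from the current state: the
#' state plus `scale` times a pair of independent standard-normal draws. With
#' `scale = 1` the proposal covariance is the two-dimensional identity.
#'
#' @param state Length-2 numeric current state.
#' @param scale Proposal standard deviation: a single value for both
#'   coordinates, or a length-2 vector for per-axis scales.
#' @return Length-2 numeric candidate. Consumes two draws from R's RNG.
#' @export
mh_propose <- function(state, scale = 1) {
  stopifnot(length(state) == 2L, length(scale) %in% c(1L, 2L),
            all(scale >= 0))
  state + scale * stats::rnorm(2L)
}

#' One Metropolis-Hastings accept/reject decision
#'
#' Accepts the candidate with probability `min(1, J(candidate)/J(current))`;
#' otherwise the chain repeats the current state. The proposal is symmetric,
#' so only the density ratio enters: the target needs to be known only up to
#' a multiplicative constant.
#'
#' @param current Length-2 numeric state with positive target density.
#' @param candidate Length-2 numeric proposed state.
#' @param target Function mapping a length-2 state to an unnormalized
#'   density value.
#' @return List with `state` (the next chain state) and `accepted` (logical).
#'   Consumes one uniform draw from R's RNG.
#' @export
mh_step <- function(current, candidate, target) {
  j_cur <- target(current)
  if (!is.finite(j_cur) || j_cur <= 0) {
    stop("chain is in a zero-density state; choose a different start")
  }
  j_cand <- target(candidate)
  accepted <- stats::runif(1L) < j_cand / j_cur
  list(state = if (accepted) candidate else current, accepted = accepted)
}

#' Run a Metropolis-Hastings chain against a target density
#'
#' Repeats propose/accept for `iterations` steps from a positive-density
#' initial state, producing the chain `x_0 ... x_N`. The first `burnin`
#' post-initial states are marked for discarding (they reflect the starting
#' point rather than the target); estimation uses the retained suffix (see
#' [discard_burnin()]).
#'
#' @param target Either a function mapping a length-2 state to an
#'   unnormalized density, or a `score_kde` model (its [kde_density()] is
#'   used).
#' @param iterations Number of MH iterations `N` (default 20000).
#' @param burnin Number of initial states `M < N` to discard (default
#'   `floor(N/10)`).
#' @param proposal_scale Proposal standard deviation: scalar or length-2
#'   (per-axis). Default 1, the identity-covariance proposal of the
#'   underlying method; for targets on wide score scales a larger,
#'   scale-matched value mixes better (see [risk_model()]).
#' @param init Initial state: a length-2 numeric, or a two-column matrix /
#'   data frame of score pairs from which one row (a random individual) is
#'   drawn uniformly.
#' @param seed Optional integer; when given, the chain is fully reproducible.
#' @return An object of class `mh_chain` with fields `states`
#'   (`(N+1) x 2` matrix), `accepted` (logical length `N`), `burnin`, `seed`
#'   and `proposal_scale`.
#' @export
run_chain <- function(target, iterations = 20000L,
                      burnin = iterations %/% 10L,
                      proposal_scale = 1, init, seed = NULL) {
  if (inherits(target, "score_kde")) {
    model <- target
    target <- function(x) kde_density(model, x)
  }
  stopifnot(is.function(target), iterations >= 0L,
            burnin >= 0L, burnin <= max(iterations, 0L),
            length(proposal_scale) %in% c(1L, 2L), all(proposal_scale > 0))
  if (iterations > 0L && burnin >= iterations + 1L) {
    stop("'burnin' must be smaller than the chain length")
  }
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(dim(init))) {
    init <- as.matrix(init)
    init <- init[stats::complete.cases(init), , drop = FALSE]
    if (nrow(init) == 0L) stop("no complete score pairs to initialize from")
    row <- sample.int(nrow(init), 1L)
    init <- as.numeric(init[row, 1:2])
  }
  stopifnot(length(init) == 2L, is.numeric(init))
  j_cur <- target(init)
  if (!is.finite(j_cur) || j_cur <= 0) {
    stop(sprintf("initial state (%g, %g) has zero target density",
                 init[1L], init[2L]))
  }
  states <- matrix(NA_real_, nrow = iterations + 1L, ncol = 2L)
  accepted <- logical(iterations)
  states[1L, ] <- init
  cur <- init
  for (k in seq_len(iterations)) {
    cand <- cur + proposal_scale * stats::rnorm(2L)
    j_cand <- target(cand)
    if (stats::runif(1L) < j_cand / j_cur) {
      cur <- cand
      j_cur <- j_cand
      accepted[k] <- TRUE
    }
    states[k + 1L, ] <- cur
  }
  structure(list(states = states, accepted = accepted, burnin = burnin,
                 seed = seed, proposal_scale = proposal_scale),
            class = "mh_chain")
}

#' @export
print.mh_chain <- function(x, ...) {
  n <- nrow(x$states) - 1L
  cat(sprintf("Metropolis-Hastings chain: %d iterations (+ initial state)\n",
              n))
  cat(sprintf("  burn-in M = %d, proposal sd = %s%s\n", x$burnin,
              paste(signif(x$proposal_scale, 4L), collapse = ", "),
              if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  if (n > 0L) {
    cat(sprintf("  acceptance rate = %.3f\n", acceptance_rate(x)))
  }
  invisible(x)
}

#' Retained (post-burn-in) states of a chain
#'
#' Drops the first `M` states of the chain (the burn-in, whose states still
#' reflect the start rather than the target) and returns the remaining
#' `N + 1 - M` states.
#'
#' @param chain An `mh_chain`.
#' @param burnin Burn-in length `M`; defaults to the chain's own.
#' @return Numeric matrix of retained states, a suffix of `chain$states`.
#' @export
discard_burnin <- function(chain, burnin = chain$burnin) {
  stopifnot(inherits(chain, "mh_chain"))
  len <- nrow(chain$states)
  if (burnin >= len) stop("burn-in is at least the chain length")
  chain$states[(burnin + 1L):len, , drop = FALSE]
}

#' Acceptance rate of a chain
#'
#' @param chain An `mh_chain` with at least one iteration.
#' @return Fraction of proposals accepted, in `[0, 1]`.
#' @export
acceptance_rate <- function(chain) {
  stopifnot(inherits(chain, "mh_chain"))
  if (length(chain$accepted) == 0L) stop("chain has no iterations")
  mean(chain$accepted)
}

#' @export
as.data.frame.mh_chain <- function(x, ...) {
  n <- nrow(x$states) - 1L
  data.frame(iter = 0:n, x1 = x$states[, 1L], x2 = x$states[, 2L],
             accepted = c(NA, x$accepted), is_burnin = 0:n < x$burnin)
}

#' Write a chain to CSV
#'
#' Columns: `iter`, `x1`, `x2`, `accepted`, `is_burnin`.
#'
#' @param chain An `mh_chain`.
#' @param path Output CSV path.
#' @export
write_chain <- function(chain, path) {
  utils::write.csv(as.data.frame(chain), path, row.names = FALSE)
}
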