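#' Metropolis temperature swaps, walker labels, round-trip accounting
#'
#' Neighboring replica clients periodically attempt to swap temperatures with
#' the standard parallel-tempering Metropolis probability
#' \code{min(1, exp[(beta_a - beta_b)(E_a - E_b)])}. Configurations stay in
#' place; a swap exchanges the two replicas' temperature-window assignments,
#' so walker labels (cold/hot, by last temperature extreme visited) travel
#' with the replicas and round trips T_min -> T_max -> T_min are well defined.
#'
#' @name exchange
NULL

#' Boltzmann constant in kcal/(mol K)
#'
#' Physical-unit runs use \code{KB_KCAL}; toy models default to reduced units
#' with \code{k_B = 1}.
#' @export
KB_KCAL <- 0.0019872041

#' Metropolis swap probability for a neighboring pair
#'
#' @param beta_a,beta_b inverse temperatures \code{1/(k_B T)}, positive.
#' @param e_a,e_b instantaneous potential energies of clients a and b.
#' @return \code{min(1, exp[(beta_a - beta_b)(e_a - e_b)])}. Symmetric under
#'   simultaneous relabeling of (a, b).
#' @examples
#' swap_probability(1, 0.5, 1, 2)  # exp(-0.5)
#' @export
swap_probability <- function(beta_a, beta_b, e_a, e_b) {
  if (any(beta_a <= 0) || any(beta_b <= 0)) stop("betas must be positive")
  pmin(1, exp((beta_a - beta_b) * (e_a - e_b)))
}

#' Replica set: window assignment, labels, swap statistics
#'
#' Tracks the bijection between replicas and temperature windows, each
#' replica's walker label, and per-pair attempt/accept counts plus per-replica
#' round-trip counts.
#'
#' @param ladder a \code{temperature_ladder}.
#' @param kB Boltzmann constant (1 for reduced units, \code{KB_KCAL} for
#'   kelvin/kcal runs).
#' @return an object of class \code{replica_set} with fields:
#'   \code{window_of} (window index of each replica, 1-based),
#'   \code{replica_in} (inverse permutation: replica occupying each window),
#'   \code{label} (character: "cold", "hot" or "unlabeled"),
#'   \code{attempts}/\code{accepts} (per neighbor pair, length n-1),
#'   \code{round_trips} (per replica), \code{ladder}, \code{kB}.
#' @export
replica_set <- function(ladder, kB = 1) {
  stopifnot(inherits(ladder, "temperature_ladder"))
  n <- ladder$n
  structure(
    list(window_of = seq_len(n), replica_in = seq_len(n),
         label = rep("unlabeled", n),
         attempts = numeric(n - 1L), accepts = numeric(n - 1L),
         round_trips = numeric(n), ladder = ladder, kB = kB),
    class = "replica_set")
}

#' @export
print.replica_set <- function(x, ...) {
  cat(sprintf("<replica_set> n = %d, round trips = %s\n",
              x$ladder$n, paste(x$round_trips, collapse = " ")))
  invisible(x)
}

.check_bijection <- function(rep) {
  n <- rep$ladder$n
  if (!identical(sort(rep$window_of), seq_len(n)) ||
      !identical(rep$window_of[rep$replica_in], seq_len(n)))
    stop("replica/window permutation is not a bijection")
  invisible(TRUE)
}

#' Attempt Metropolis swaps on alternating neighbor pairs
#'
#' Even parity attempts window pairs (1,2), (3,4), ...; odd parity attempts
#' (2,3), (4,5), ... (1-based windows). Alternating the parity over successive
#' rounds attempts every neighbor pair once per two rounds. An accepted swap
#' exchanges the two occupying replicas' window assignments.
#'
#' @param rep a \code{replica_set}.
#' @param energies per-window instantaneous potential energies of the
#'   configurations currently occupying each window.
#' @param parity \code{"even"} or \code{"odd"}.
#' @return the updated \code{replica_set}; attempt/accept counters are
#'   incremented in place. Uses the R RNG (seed for reproducibility).
#' @export
attempt_swaps <- function(rep, energies, parity = c("even", "odd")) {
  stopifnot(inherits(rep, "replica_set"))
  parity <- match.arg(parity)
  n <- rep$ladder$n
  if (length(energies) != n) stop("need one energy per window")
  lo <- if (parity == "even") seq.int(1L, n - 1L, by = 2L) else
    if (n >= 3L) seq.int(2L, n - 1L, by = 2L) else integer(0)
  if (length(lo) == 0L) return(rep)
  beta <- 1 / (rep$kB * rep$ladder$temps)
  pr <- pmin(1, exp((beta[lo] - beta[lo + 1L]) *
                    (energies[lo] - energies[lo + 1L])))
  u <- stats::runif(length(lo))
  acc <- u < pr
  rep$attempts[lo] <- rep$attempts[lo] + 1
  rep$accepts[lo] <- rep$accepts[lo] + as.numeric(acc)
  for (k in which(acc)) {
    w <- lo[k]
    ra <- rep$replica_in[w]; rb <- rep$replica_in[w + 1L]
    rep$replica_in[w] <- rb; rep$replica_in[w + 1L] <- ra
    rep$window_of[ra] <- w + 1L; rep$window_of[rb] <- w
  }
  rep
}

#' Update walker labels and round-trip counts
#'
#' The replica occupying window 1 becomes (or stays) cold; the replica in
#' window n becomes hot. A replica labeled hot that reaches window 1 has
#' completed a full round trip T_min -> T_max -> T_min and its round-trip
#' count increments by one. Labels never revert to unlabeled.
#'
#' @param rep a \code{replica_set}, called after each swap round.
#' @return the updated \code{replica_set}.
#' @export
update_walker_labels <- function(rep) {
  stopifnot(inherits(rep, "replica_set"))
  n <- rep$ladder$n
  r_cold <- rep$replica_in[1L]
  r_hot <- rep$replica_in[n]
  if (rep$label[r_cold] == "hot")
    rep$round_trips[r_cold] <- rep$round_trips[r_cold] + 1
  rep$label[r_cold] <- "cold"
  rep$label[r_hot] <- "hot"
  rep
}

#' Record labeled visits into a cold/hot histogram
#'
#' Each labeled replica increments the cold or hot counter of its current
#' window; unlabeled replicas contribute nothing.
#'
#' @param rep a \code{replica_set} with labels updated for the current round.
#' @param hist a \code{visit_histogram} over the ladder's windows.
#' @return the updated \code{visit_histogram}.
#' @export
record_visits <- function(rep, hist) {
  stopifnot(inherits(rep, "replica_set"), inherits(hist, "visit_histogram"))
  cold_w <- rep$window_of[rep$label == "cold"]
  hot_w <- rep$window_of[rep$label == "hot"]
  if (length(cold_w))
    hist$n_cold[cold_w] <- hist$n_cold[cold_w] + 1  # windows are distinct
  if (length(hot_w))
    hist$n_hot[hot_w] <- hist$n_hot[hot_w] + 1
  hist
}

#' Per-pair exchange acceptance rates
#'
#' @param rep a \code{replica_set} (or any list with \code{attempts} and
#'   \code{accepts} vectors).
#' @return acceptance fraction per neighbor pair, in \code{[0,1]}; \code{NA}
#'   for pairs never attempted.
#' @export
exchange_rate_profile <- function(rep) {
  ifelse(rep$attempts > 0, rep$accepts / rep$attempts, NA_real_)
}
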