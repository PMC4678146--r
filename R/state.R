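# Pure-R reference implementation of the repertoire state and one Gillespie
# step. This is the readable specification of the dynamics and the oracle the
# compiled engine is tested against; production runs use run_simulation().

#' Construct a repertoire state
#'
#' Builds the live per-clonotype cell counts together with the cached
#' per-pMHC recogniser totals \code{c_q}, per-clonotype division rates
#' \code{Lambda_i}, and current time.
#'
#' @param network a \code{recognition_network}.
#' @param counts either a single count applied to every clonotype in the
#'   network, or a named integer vector (names = clonotype ids, all >= 1).
#' @return an object of class \code{repertoire_state}: list with \code{t},
#'   \code{counts}, \code{c}, \code{Lambda} and the \code{network}.
#' @export
repertoire_state <- function(network, counts) {
  stopifnot(inherits(network, "recognition_network"))
  ids <- names(network$patterns)
  if (length(counts) == 1L && is.null(names(counts)))
    counts <- setNames(rep(as.integer(counts), length(ids)), ids)
  counts <- counts[ids]
  if (any(is.na(counts)) || any(counts < 1))
    stop("'counts' must provide an integer >= 1 for every clonotype")
  state <- list(t = 0, counts = as.integer(counts), network = network)
  names(state$counts) <- ids
  state$c <- compute_c(state$counts, network)
  state$Lambda <- division_rates_scratch(state$counts, state$c, network)
  class(state) <- "repertoire_state"
  state
}

compute_c <- function(counts, network) {
  cq <- numeric(network$M)
  for (id in names(counts)) {
    q <- network$patterns[[id]]
    cq[q] <- cq[q] + counts[[id]]
  }
  cq
}

division_rates_scratch <- function(counts, cq, network) {
  gam <- network$stimulus_rates
  vapply(names(counts), function(id) {
    q <- network$patterns[[id]]
    q <- q[cq[q] > 0]
    counts[[id]] * sum(gam[q] / cq[q])
  }, numeric(1))
}

#' Per-clonotype division rates
#'
#' Computes \code{Lambda_i = n_i * sum_{q in Q_i, c_q > 0} gamma_q / c_q}
#' from scratch (each pMHC subset's stimulus is shared equally among all
#' cells recognising it; an unrecognised subset contributes nothing). This
#' recomputation is the oracle against which incrementally maintained caches
#' are checked.
#'
#' @param state a \code{repertoire_state}.
#' @param network the recognition network (defaults to the one carried in
#'   the state).
#' @return named numeric vector of division rates for the live clonotypes.
#' @export
division_rates <- function(state, network = state$network) {
  cq <- compute_c(state$counts, network)
  division_rates_scratch(state$counts, cq, network)
}

#' Recompute all cached state quantities from scratch
#'
#' @param state a \code{repertoire_state}.
#' @return the state with \code{c} and \code{Lambda} rebuilt from
#'   \code{counts} and the network (oracle for incremental updates).
#' @export
recompute_state <- function(state) {
  state$c <- compute_c(state$counts, state$network)
  state$Lambda <- division_rates_scratch(state$counts, state$c, state$network)
  state
}

#' Total event rate of the Gillespie process
#'
#' \code{S = sum_i (mu * n_i + Lambda_i) + theta}: the total rate of the
#' \code{2 N + 1} possible events (a death or a division in each surviving
#' clonotype, or a thymic arrival).
#'
#' @param state a \code{repertoire_state}.
#' @param params a \code{model_params}.
#' @return the scalar total rate.
#' @export
total_event_rate <- function(state, params) {
  params$mu * sum(state$counts) + sum(state$Lambda) + params$theta
}

#' Select the next event
#'
#' Draws one event with probability exactly proportional to its rate:
#' death of a cell of clonotype \code{i} with probability \code{mu n_i / S},
#' division with \code{Lambda_i / S}, thymic arrival with \code{theta / S}.
#'
#' @param state a \code{repertoire_state}.
#' @param params a \code{model_params}.
#' @return list with \code{type} (\code{"death"}, \code{"division"} or
#'   \code{"thymic"}) and \code{id} (clonotype id, NA for thymic arrivals).
#' @export
select_event <- function(state, params) {
  rates_death <- params$mu * state$counts
  rates_div <- state$Lambda
  S <- sum(rates_death) + sum(rates_div) + params$theta
  if (S <= 0) stop("total event rate is zero; the state is absorbing")
  u <- runif(1) * S
  if (u < params$theta) return(list(type = "thymic", id = NA_integer_))
  u <- u - params$theta
  per_event <- as.vector(rbind(rates_death, rates_div))
  cum <- cumsum(per_event)
  k <- which(u < cum)[1]
  if (is.na(k)) k <- length(per_event)  # guard against roundoff at the edge
  idx <- (k + 1L) %/% 2L
  list(type = if (k %% 2L == 1L) "death" else "division",
       id = as.integer(names(state$counts)[idx]))
}

# Incremental application of one event: c_q changes only for q in the
# affected clonotype's pattern; only clonotypes sharing those q get Lambda
# refreshed.
apply_event <- function(state, type, id, params) {
  net <- state$network
  if (type == "thymic") {
    drawn <- draw_emigrant_pattern(net)
    net <- drawn$network
    key <- as.character(drawn$id)
    state$counts[key] <- params$n_theta
    pattern <- drawn$pattern
    state$c[pattern] <- state$c[pattern] + params$n_theta
    state$network <- net
    state$Lambda[key] <- 0
  } else {
    key <- as.character(id)
    pattern <- net$patterns[[key]]
    delta <- if (type == "death") -1L else 1L
    state$counts[key] <- state$counts[key] + delta
    state$c[pattern] <- state$c[pattern] + delta
    if (state$counts[key] == 0L) {
      state$counts <- state$counts[names(state$counts) != key]
      state$Lambda <- state$Lambda[names(state$Lambda) != key]
      state$network <- remove_clonotype(net, id)
      net <- state$network
    }
  }
  affected <- unique(unlist(net$reverse_index[pattern], use.names = FALSE))
  if (length(affected)) {
    akeys <- as.character(affected)
    gam <- net$stimulus_rates
    for (ak in akeys) {
      q <- net$patterns[[ak]]
      q <- q[state$c[q] > 0]
      state$Lambda[ak] <- state$counts[[ak]] * sum(gam[q] / state$c[q])
    }
  }
  state
}

#' Advance the repertoire by one Gillespie event
#'
#' Selects exactly one event (death, division or thymic arrival) with
#' probability proportional to its rate, applies it with incremental cache
#' updates, and advances time by an Exponential(mean 1/S) increment. If the
#' total rate is zero (no cells and no thymic input) the state is absorbing
#' and is returned unchanged with an event of type \code{"absorbed"}.
#'
#' @param state a \code{repertoire_state}.
#' @param params a \code{model_params}.
#' @return list with the new \code{state} and the \code{event} record
#'   (\code{type}, \code{id}, event time \code{t}).
#' @export
gillespie_step <- function(state, params) {
  S <- total_event_rate(state, params)
  if (S <= 0)
    return(list(state = state,
                event = list(type = "absorbed", id = NA_integer_, t = state$t)))
  dt <- rexp(1, S)
  ev <- select_event(state, params)
  state <- apply_event(state, ev$type, ev$id, params)
  state$t <- state$t + dt
  list(state = state, event = list(type = ev$type, id = ev$id, t = state$t))
}
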