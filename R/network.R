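# Random bipartite recognition structure between T cell clonotypes and
# self-pMHC subsets. Storage is sparse: per-clonotype index sets plus a
# reverse index, never a dense N x M matrix.

new_recognition_network <- function(M, p, patterns, stimulus_rates, next_id,
                                    seed = NULL) {
  structure(
    list(M = M, p = p, patterns = patterns,
         reverse_index = build_reverse_index(patterns, M),
         stimulus_rates = stimulus_rates, next_id = next_id, seed = seed),
    class = "recognition_network")
}

build_reverse_index <- function(patterns, M) {
  if (!length(patterns)) return(vector("list", M))
  ids <- as.integer(names(patterns))
  q <- unlist(patterns, use.names = FALSE)
  cl <- rep(ids, lengths(patterns))
  unname(lapply(split(cl, factor(q, levels = seq_len(M))), as.integer))
}

#' Generate a random clonotype-pMHC recognition network
#'
#' Each of the \code{N0 * M} possible connections is present independently
#' with probability \code{p}; clonotypes that would draw an empty pattern are
#' redrawn, emulating thymic selection (every clonotype recognises at least
#' one self pMHC). Cross-reactivities \code{phi_i} are therefore samples from
#' Binomial(\code{M}, \code{p}) conditioned on \code{phi_i >= 1}.
#'
#' @param N0 number of clonotypes.
#' @param M number of self-pMHC subsets.
#' @param p connection probability, in (0, 1].
#' @param seed optional integer; if given, \code{set.seed(seed)} is called.
#' @param stimulus_rates per-pMHC stimulus rates \code{gamma_q} (length
#'   \code{M}, all positive). Defaults to rate 1 for every subset; see
#'   \code{\link{assign_stimulus_rates}}.
#' @return an object of class \code{recognition_network}: a list with fields
#'   \code{M}, \code{p}, \code{patterns} (named list, clonotype id ->
#'   sorted integer vector of recognised pMHC indices), \code{reverse_index}
#'   (list of length \code{M}, pMHC index -> integer vector of recognising
#'   clonotype ids), \code{stimulus_rates}, \code{next_id}.
#' @examples
#' net <- generate_network(30, 40, 0.1, seed = 1)
#' degree_summaries(net)
#' @export
generate_network <- function(N0, M, p, seed = NULL, stimulus_rates = NULL) {
  if (!is.numeric(N0) || length(N0) != 1L || N0 < 0 || N0 != round(N0))
    stop("'N0' must be a non-negative integer")
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M))
    stop("'M' must be a positive integer")
  check_probability(p)
  if (p * M < 1)
    warning("p * M < 1: conditioning on non-empty patterns dominates the degree distribution")
  if (is.null(stimulus_rates)) stimulus_rates <- rep(1, M)
  if (length(stimulus_rates) != M || any(stimulus_rates <= 0))
    stop("'stimulus_rates' must have length M with all entries > 0")
  if (!is.null(seed)) set.seed(seed)
  patterns <- vector("list", N0)
  if (N0 > 0) {
    ks <- rbinom(N0, M, p)
    while (any(z <- ks == 0L)) ks[z] <- rbinom(sum(z), M, p)
    patterns <- lapply(ks, function(k) sort(sample.int(M, k)))
    names(patterns) <- as.character(seq_len(N0))
  } else names(patterns) <- character(0)
  new_recognition_network(M, p, patterns, stimulus_rates,
                          next_id = as.integer(N0 + 1), seed = seed)
}

check_probability <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    stop("'p' must be a probability in (0, 1]")
  invisible(p)
}

#' Draw the recognition pattern of a new thymic emigrant
#'
#' Adds a fresh clonotype (identifier taken from the network's monotone
#' counter, never reused) whose pattern includes each pMHC independently with
#' probability \code{p}, redrawn if empty. Uses the current R random number
#' stream.
#'
#' @param network a \code{recognition_network}.
#' @return a list with the updated \code{network}, the new clonotype
#'   \code{id}, and its \code{pattern}.
#' @export
draw_emigrant_pattern <- function(network) {
  stopifnot(inherits(network, "recognition_network"))
  M <- network$M
  repeat {
    k <- rbinom(1L, M, network$p)
    if (k > 0L) break
  }
  pattern <- sort(sample.int(M, k))
  id <- network$next_id
  network$patterns[[as.character(id)]] <- pattern
  for (q in pattern)
    network$reverse_index[[q]] <- c(network$reverse_index[[q]], id)
  network$next_id <- id + 1L
  list(network = network, id = id, pattern = pattern)
}

#' Remove clonotypes from a recognition network
#'
#' Used on extinction: the clonotype's pattern is dropped and the reverse
#' index updated, so the network always describes the live repertoire.
#'
#' @param network a \code{recognition_network}.
#' @param ids integer vector of clonotype identifiers to remove.
#' @return the updated network.
#' @export
remove_clonotype <- function(network, ids) {
  stopifnot(inherits(network, "recognition_network"))
  for (id in ids) {
    key <- as.character(id)
    pattern <- network$patterns[[key]]
    if (is.null(pattern)) stop("clonotype ", id, " is not in the network")
    for (q in pattern) {
      m <- network$reverse_index[[q]]
      network$reverse_index[[q]] <- m[m != id]
    }
    network$patterns[[key]] <- NULL
  }
  network
}

#' Assign per-pMHC stimulus rates
#'
#' With \code{sigma = 0} every subset delivers stimulus at the common rate
#' \code{gamma_mean}. With \code{sigma > 0} the rates are i.i.d. log-normal
#' with mean \code{gamma_mean} and standard deviation
#' \code{sigma * gamma_mean} (\code{sigma} is the coefficient of variation).
#' Moment matching gives log-space variance \code{log(1 + sigma^2)} and
#' log-space mean \code{log(gamma_mean) - log(1 + sigma^2) / 2}.
#'
#' @param M number of self-pMHC subsets.
#' @param gamma_mean mean stimulus rate (cell divisions per unit time).
#' @param sigma dimensionless dispersion (sd / mean), \code{>= 0}.
#' @param seed optional integer seed.
#' @return numeric vector of length \code{M}, all entries positive.
#' @export
assign_stimulus_rates <- function(M, gamma_mean, sigma = 0, seed = NULL) {
  if (!is.numeric(gamma_mean) || gamma_mean <= 0)
    stop("'gamma_mean' must be > 0")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(rep(gamma_mean, M))
  sdlog <- sqrt(log(1 + sigma^2))
  rlnorm(M, meanlog = log(gamma_mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Degree bookkeeping of the bipartite recognition graph
#'
#' Computes the mean cross-reactivity \code{phi_bar} over surviving
#' clonotypes, the mean number \code{C_bar} of surviving clonotypes
#' recognising a pMHC subset, and the two degree distributions. Both means
#' derive from the same integer count of connections, so the identity
#' \code{M * C_bar == N * phi_bar} holds exactly.
#'
#' @param network a \code{recognition_network}.
#' @param live optional integer vector of surviving clonotype ids (defaults
#'   to every clonotype in the network).
#' @return an object of class \code{degree_summary}: list with \code{N},
#'   \code{M}, \code{phi_bar} (NA when the repertoire is empty),
#'   \code{C_bar}, \code{total_connections}, \code{phi} (named vector) and
#'   \code{Cq_counts} (length \code{M}).
#' @export
degree_summaries <- function(network, live = NULL) {
  stopifnot(inherits(network, "recognition_network"))
  ids <- as.integer(names(network$patterns))
  if (is.null(live)) live <- ids else {
    if (!all(live %in% ids)) stop("'live' contains ids not present in the network")
  }
  keep <- network$patterns[as.character(live)]
  phi <- lengths(keep)
  total <- sum(phi)
  N <- length(keep)
  q_all <- unlist(keep, use.names = FALSE)
  Cq <- tabulate(if (is.null(q_all)) integer(0) else q_all,
                 nbins = network$M)
  structure(
    list(N = N, M = network$M,
         phi_bar = if (N > 0) total / N else NA_real_,
         C_bar = total / network$M,
         total_connections = total,
         phi = phi, Cq_counts = Cq),
    class = "degree_summary")
}

#' @export
print.degree_summary <- function(x, ...) {
  cat("Degree summary of recognition network\n")
  cat(sprintf("  surviving clonotypes N: %d, pMHC subsets M: %d\n", x$N, x$M))
  cat(sprintf("  phi_bar (mean cross-reactivity): %s\n",
              if (is.na(x$phi_bar)) "undefined (empty repertoire)"
              else format(x$phi_bar)))
  cat(sprintf("  C_bar (mean recognisers per pMHC): %s\n", format(x$C_bar)))
  cat(sprintf("  total connections: %d (M*C_bar = N*phi_bar identity)\n",
              x$total_connections))
  invisible(x)
}

#' @export
print.recognition_network <- function(x, ...) {
  cat("Bipartite clonotype-pMHC recognition network\n")
  cat(sprintf("  clonotypes: %d, pMHC subsets M: %d, connection probability p: %g\n",
              length(x$patterns), x$M, x$p))
  cat(sprintf("  connections: %d (expected N*M*p = %g)\n",
              sum(lengths(x$patterns)), length(x$patterns) * x$M * x$p))
  gam <- x$stimulus_rates
  if (length(unique(gam)) == 1L)
    cat(sprintf("  stimulus rates: constant gamma = %g\n", gam[1]))
  else
    cat(sprintf("  stimulus rates: mean %.4g, cv %.3g\n",
                mean(gam), sd(gam) / mean(gam)))
  invisible(x)
}

#' Probability that two clonotypes share an identical recognition pattern
#'
#' Two independently drawn rows of the biadjacency matrix agree at one column
#' with probability \code{(1-p)^2 + p^2}; over \code{M} independent columns
#' the collision probability is \code{((1-p)^2 + p^2)^M}, evaluated in log
#' space to avoid underflow. At \code{p = 0.1}, \code{M = 1000} this is below
#' \code{1e-85}, so every clonotype's pattern can be taken as unique.
#'
#' @param p connection probability, in [0, 1].
#' @param M number of self-pMHC subsets.
#' @return list with \code{probability} and \code{log10} of the probability.
#' @export
pattern_collision_probability <- function(p, M) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a probability in [0, 1]")
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M))
    stop("'M' must be a positive integer")
  lt <- M * log((1 - p)^2 + p^2)
  list(probability = exp(lt), log10 = lt / log(10))
}

#' Write / read a recognition network
#'
#' The network is serialised as an edge-list CSV with header
#' \code{clonotype_id,pmhc_index}, plus a JSON sidecar holding \code{M},
#' \code{p}, the generation seed, the monotone id counter and the full
#' \code{gamma_q} vector (written at full precision). The round trip is
#' loss-free.
#'
#' @param network a \code{recognition_network}.
#' @param edges_path path of the edge-list CSV.
#' @param meta_path path of the JSON sidecar.
#' @return \code{write_network} returns the two paths invisibly;
#'   \code{read_network} returns the reconstructed network.
#' @export
write_network <- function(network, edges_path, meta_path) {
  stopifnot(inherits(network, "recognition_network"))
  ids <- as.integer(names(network$patterns))
  edges <- data.frame(
    clonotype_id = rep(ids, lengths(network$patterns)),
    pmhc_index = unlist(network$patterns, use.names = FALSE))
  write.csv(edges, edges_path, row.names = FALSE, quote = FALSE)
  meta <- list(M = network$M, p = network$p,
               seed = if (is.null(network$seed)) NA else network$seed,
               next_id = network$next_id,
               stimulus_rates = network$stimulus_rates)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(edges = edges_path, meta = meta_path))
}

#' @rdname write_network
#' @export
read_network <- function(edges_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  edges <- read.csv(edges_path,
                    colClasses = c(clonotype_id = "integer",
                                   pmhc_index = "integer"))
  ids <- sort(unique(edges$clonotype_id))
  patterns <- lapply(split(edges$pmhc_index,
                           factor(edges$clonotype_id, levels = ids)), sort)
  names(patterns) <- as.character(ids)
  new_recognition_network(as.numeric(meta$M), meta$p, patterns,
                          as.numeric(meta$stimulus_rates),
                          next_id = as.integer(meta$next_id),
                          seed = if (is.na(meta$seed)) NULL else meta$seed)
}
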