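#' Kinetic scheme for a population of ion channels
#'
#' A kinetic scheme is a voltage-dependent continuous-time Markov chain over
#' channel configurations, with one or more designated conducting states.
#' Transition rates may reference the built-in Hodgkin-Huxley rate functions
#' by name (`"alpha_m"`, `"beta_m"`, `"alpha_h"`, `"beta_h"`, `"alpha_n"`,
#' `"beta_n"`), be voltage-independent constants, or be arbitrary R
#' functions of voltage (such schemes are usable wherever rates can be
#' evaluated in R, e.g. [build_generator()] and clamped simulation, but not
#' by the compiled hybrid neuron kernels).
#'
#' @param states character vector of state labels.
#' @param open_states labels (or indices) of the conducting state(s).
#' @param edges data frame with columns `from`, `to` (state labels),
#'   `rate` (rate id string, numeric constant, or function of V, as a list
#'   column when mixed) and optional `mult` (combinatorial multiplicity,
#'   default 1).
#' @param factorization `"na"` for the classical 8-state Na scheme
#'   (binomial in m times Bernoulli in h), `"k"` for the classical 5-state K
#'   scheme (binomial in n), or `NULL` for schemes with no subunit
#'   factorization.
#' @return An object of class `kinetic_scheme`.
#' @seealso [hh_na_scheme()], [hh_k_scheme()], [two_state_scheme()]
#' @export
kinetic_scheme <- function(states, open_states, edges, factorization = NULL) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicate state labels")
  if (is.character(open_states)) {
    open_idx <- match(open_states, states)
  } else open_idx <- as.integer(open_states)
  if (any(is.na(open_idx)) || any(open_idx < 1 | open_idx > length(states)))
    stop("open_states not found among states")
  from <- match(as.character(edges$from), states)
  to <- match(as.character(edges$to), states)
  if (any(is.na(from)) || any(is.na(to))) stop("edge endpoints must be states")
  if (any(from == to)) stop("self-transitions are not allowed")
  mult <- if (is.null(edges$mult)) rep(1, length(from)) else as.numeric(edges$mult)
  if (any(!is.finite(mult) | mult <= 0)) stop("edge multiplicities must be > 0")
  rate <- edges$rate
  if (!is.list(rate)) rate <- as.list(rate)
  # connectivity of the undirected transition graph
  adj <- unique(rbind(cbind(from, to), cbind(to, from)))
  seen <- rep(FALSE, length(states)); seen[1] <- TRUE
  repeat {
    new <- unique(adj[seen[adj[, 1]], 2])
    if (all(seen[new])) break
    seen[new] <- TRUE
  }
  if (!all(seen)) stop("transition graph must be connected")
  if (!is.null(factorization))
    factorization <- match.arg(factorization, c("na", "k"))
  structure(list(states = states, open_states = open_idx,
                 from = from, to = to, rate = rate, mult = mult,
                 factorization = factorization),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("kinetic_scheme: %d states, %d directed edges, conducting: %s\n",
              length(x$states), length(x$from),
              paste(x$states[x$open_states], collapse = ", ")))
  if (!is.null(x$factorization))
    cat(sprintf("  subunit factorization: %s\n", x$factorization))
  invisible(x)
}

rate_id_table <- c(alpha_m = 1L, beta_m = 2L, alpha_h = 3L, beta_h = 4L,
                   alpha_n = 5L, beta_n = 6L)

# evaluate one edge rate at voltage V (1/ms, before multiplicity)
eval_edge_rate <- function(rate, V) {
  if (is.character(rate)) {
    id <- rate_id_table[[rate]]
    if (is.null(id)) stop("unknown rate id: ", rate)
    cpp_hh_rates(V)[1, id]
  } else if (is.function(rate)) {
    rate(V)
  } else as.numeric(rate)
}

# compiled encoding: rate_id 0 carries the constant in mult; R-function
# rates are not encodable
scheme_for_cpp <- function(scheme, V = NULL) {
  rid <- integer(length(scheme$rate))
  mult <- scheme$mult
  for (e in seq_along(scheme$rate)) {
    r <- scheme$rate[[e]]
    if (is.character(r)) {
      rid[e] <- rate_id_table[[r]]
    } else if (is.numeric(r)) {
      rid[e] <- 0L
      mult[e] <- mult[e] * as.numeric(r)
    } else if (is.function(r)) {
      if (is.null(V))
        stop("schemes with R-function rates require a fixed voltage here; ",
             "use a built-in or constant-rate scheme")
      rid[e] <- 0L
      mult[e] <- mult[e] * r(V)
    } else stop("unsupported rate entry")
  }
  list(n_states = length(scheme$states),
       edge_from = scheme$from, edge_to = scheme$to,
       edge_rate_id = rid, edge_mult = mult,
       open_states = scheme$open_states)
}

#' Classical Hodgkin-Huxley Na-channel scheme (8 states)
#'
#' States are indexed `m<i>h<j>` with i = 0..3 open m-subunits and
#' j = 0,1 open h-subunits; the conducting state is `m3h1`.
#'
#' @return A `kinetic_scheme`.
#' @export
hh_na_scheme <- function() {
  states <- as.vector(outer(0:3, 0:1, function(i, j) sprintf("m%dh%d", i, j)))
  e <- list()
  for (j in 0:1) for (i in 0:2) {
    e[[length(e) + 1]] <- data.frame(from = sprintf("m%dh%d", i, j),
                                     to = sprintf("m%dh%d", i + 1, j),
                                     rate = "alpha_m", mult = 3 - i)
    e[[length(e) + 1]] <- data.frame(from = sprintf("m%dh%d", i + 1, j),
                                     to = sprintf("m%dh%d", i, j),
                                     rate = "beta_m", mult = i + 1)
  }
  for (i in 0:3) {
    e[[length(e) + 1]] <- data.frame(from = sprintf("m%dh0", i),
                                     to = sprintf("m%dh1", i),
                                     rate = "alpha_h", mult = 1)
    e[[length(e) + 1]] <- data.frame(from = sprintf("m%dh1", i),
                                     to = sprintf("m%dh0", i),
                                     rate = "beta_h", mult = 1)
  }
  kinetic_scheme(states, "m3h1", do.call(rbind, e), factorization = "na")
}

#' Classical Hodgkin-Huxley K-channel scheme (5 states)
#'
#' States `n0` .. `n4` count open n-subunits; `n4` conducts.  Opening
#' rates are `(4-k) alpha_n`, closing rates `k beta_n`.
#'
#' @return A `kinetic_scheme`.
#' @export
hh_k_scheme <- function() {
  states <- sprintf("n%d", 0:4)
  e <- list()
  for (k in 0:3) {
    e[[length(e) + 1]] <- data.frame(from = sprintf("n%d", k),
                                     to = sprintf("n%d", k + 1),
                                     rate = "alpha_n", mult = 4 - k)
    e[[length(e) + 1]] <- data.frame(from = sprintf("n%d", k + 1),
                                     to = sprintf("n%d", k),
                                     rate = "beta_n", mult = k + 1)
  }
  kinetic_scheme(states, "n4", do.call(rbind, e), factorization = "k")
}

#' Two-state open/closed toy scheme
#'
#' @param alpha,beta opening and closing rates: a rate id string, a
#'   constant (1/ms), or a function of voltage.
#' @return A `kinetic_scheme` with states `closed`, `open`.
#' @export
two_state_scheme <- function(alpha, beta) {
  edges <- data.frame(from = c("closed", "open"), to = c("open", "closed"))
  edges$rate <- list(alpha, beta)
  edges$mult <- 1
  kinetic_scheme(c("closed", "open"), "open", edges)
}

#' Infinitesimal generator of a kinetic scheme
#'
#' Builds the transition-rate matrix A at a fixed voltage, with
#' `A[l, k]` the rate from state k to state l and diagonal entries chosen
#' so that every column sums to zero: the state-fraction vector then obeys
#' `dx/dt = A x` with probability conserved.
#'
#' @param scheme a [kinetic_scheme()].
#' @param V voltage (mV), finite scalar.
#' @return Square numeric matrix (1/ms) with state labels as dimnames.
#' @export
build_generator <- function(scheme, V) {
  if (!inherits(scheme, "kinetic_scheme")) stop("scheme must be a kinetic_scheme")
  if (!is.numeric(V) || length(V) != 1 || !is.finite(V))
    stop("V must be a finite scalar")
  ns <- length(scheme$states)
  A <- matrix(0, ns, ns, dimnames = list(scheme$states, scheme$states))
  for (e in seq_along(scheme$from)) {
    r <- tryCatch(scheme$mult[e] * eval_edge_rate(scheme$rate[[e]], V),
                  error = function(err)
                    stop(sprintf("rate evaluation failed on edge %s -> %s: %s",
                                 scheme$states[scheme$from[e]],
                                 scheme$states[scheme$to[e]],
                                 conditionMessage(err)), call. = FALSE))
    if (!is.finite(r) || r < 0)
      stop(sprintf("non-finite or negative rate on edge %s -> %s",
                   scheme$states[scheme$from[e]], scheme$states[scheme$to[e]]))
    k <- scheme$from[e]; l <- scheme$to[e]
    A[l, k] <- A[l, k] + r
    A[k, k] <- A[k, k] - r
  }
  A
}

#' Map the gating triple to channel-state fractions
#'
#' For subunit-factorizable schemes the deterministic state-fraction vector
#' is the multinomial combination of the gating variables: the Na entry for
#' (i open m-gates, j open h-gates) is
#' \eqn{\binom{3}{i} m^i (1-m)^{3-i} [j h + (1-j)(1-h)]} and the K entry for
#' k open n-gates is \eqn{\binom{4}{k} n^k (1-n)^{4-k}}.  The conducting
#' entries equal \eqn{m^3 h} and \eqn{n^4}.
#'
#' @param gating list with elements `m`, `h`, `n` (each in `[0, 1]`); only
#'   the components required by the scheme are used.
#' @param scheme a factorizable [kinetic_scheme()].
#' @return Named probability vector over the scheme's states.
#' @export
gating_to_statevec <- function(gating, scheme) {
  if (is.null(scheme$factorization))
    stop("scheme has no subunit factorization descriptor")
  if (scheme$factorization == "na") {
    m <- gating$m; h <- gating$h
    if (any(c(m, h) < 0 | c(m, h) > 1)) stop("gating values must be in [0,1]")
    mi <- choose(3, 0:3) * m^(0:3) * (1 - m)^(3:0)
    x <- c(mi * (1 - h), mi * h)
  } else {
    n <- gating$n
    if (n < 0 || n > 1) stop("gating values must be in [0,1]")
    x <- choose(4, 0:4) * n^(0:4) * (1 - n)^(4:0)
  }
  setNames(x, scheme$states)
}

#' Serialize / deserialize a kinetic scheme as JSON
#'
#' Only schemes whose rates are rate-id strings or numeric constants can be
#' serialized; R-function rates have no portable representation.
#'
#' @param scheme a [kinetic_scheme()].
#' @param path file path; for [scheme_from_json()] the file to read.
#' @return `scheme_to_json` invisibly returns `path`; `scheme_from_json`
#'   returns the reconstructed `kinetic_scheme`.
#' @export
scheme_to_json <- function(scheme, path) {
  rates <- lapply(scheme$rate, function(r) {
    if (is.function(r)) stop("function rates cannot be serialized")
    r
  })
  obj <- list(states = scheme$states,
              open_states = scheme$states[scheme$open_states],
              edges = data.frame(from = scheme$states[scheme$from],
                                 to = scheme$states[scheme$to],
                                 rate = vapply(rates, as.character, ""),
                                 mult = scheme$mult),
              factorization = scheme$factorization)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname scheme_to_json
#' @export
scheme_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- obj$edges
  raw <- as.character(edges$rate)
  num <- suppressWarnings(as.numeric(raw))
  edges$rate <- lapply(seq_along(raw), function(i)
    if (is.na(num[i])) raw[i] else num[i])
  kinetic_scheme(obj$states, obj$open_states, edges,
                 factorization = obj$factorization)
}
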