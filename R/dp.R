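#' Configure a dynamic state variable model run
#'
#' Bundles everything that defines one backward-iteration experiment: the
#' state grid, the foraging horizon, the candidate unpredictability levels,
#' the effect of unpredictability on the expected foraging outcome, drift,
#' the mortality model, and the terminal-fitness function.
#'
#' @param y_min,y_max integer state bounds (defaults 0 and 50).
#' @param T_steps integer number of foraging time steps \eqn{T} (default 50);
#'   reproduction occurs at \eqn{t = T + 1}.
#' @param q_levels candidate unpredictability levels, a non-empty subset of
#'   \code{0:3} sorted ascending (default \code{0:3}).
#' @param u effect of unpredictability on the expected one-step outcome
#'   (default 0; the analyses also use -0.1).
#' @param drift integer baseline expected state change per step (default 0).
#' @param mortality a [mortality_model()]; default is the combined
#'   starvation/predation curve via [mortality_preset()].
#' @param frozen_dynamics if \code{TRUE}, restrict the model to the identity
#'   kernel (\code{q_levels = 0}, \code{drift = 0}): no state dynamics. This
#'   is the regime in which the fitness surface has the closed form
#'   \eqn{\Phi_\tau(y) = (1 - d(y))^\tau \Phi_0(y)} (see
#'   [closed_form_phi()]).
#' @param terminal terminal-fitness choice; \code{"linear"}
#'   (\eqn{\Phi_0(y) = y / y_{max}}) or a function of \code{(y, y_max)}
#'   returning values in \eqn{[0, 1]}.
#' @param tie_tol tolerance used when comparing expected fitness across
#'   \code{q} levels for the argmax; the default 0 compares exactly, with
#'   ties broken toward the smallest \code{q}.
#' @return an object of class \code{"dsv_config"}.
#' @export
dsv_config <- function(y_min = 0L, y_max = 50L, T_steps = 50L,
                       q_levels = 0:3, u = 0, drift = 0L,
                       mortality = mortality_preset("combined",
                                                    y_min = y_min,
                                                    y_max = y_max),
                       frozen_dynamics = FALSE,
                       terminal = "linear", tie_tol = 0) {
  y_min <- check_integerish(y_min, "y_min")
  y_max <- check_integerish(y_max, "y_max")
  T_steps <- check_integerish(T_steps, "T_steps")
  if (T_steps < 1L) stop("'T_steps' must be >= 1")
  if (y_min >= y_max) stop("'y_min' must be strictly less than 'y_max'")
  q_levels <- as.integer(q_levels)
  if (length(q_levels) == 0L || anyNA(q_levels) ||
      !all(q_levels %in% 0:3) || is.unsorted(q_levels, strictly = TRUE))
    stop("'q_levels' must be a non-empty strictly ascending subset of 0:3")
  stopifnot(inherits(mortality, "mortality_model"))
  if (mortality$y_min != y_min || mortality$y_max != y_max)
    stop("mortality model bounds do not match the configured state grid")
  if (isTRUE(frozen_dynamics)) {
    q_levels <- 0L
    drift <- 0L
  }
  if (!is.function(terminal) && !identical(terminal, "linear"))
    stop("'terminal' must be \"linear\" or a function(y, y_max)")
  if (!is.numeric(tie_tol) || length(tie_tol) != 1L || tie_tol < 0)
    stop("'tie_tol' must be a single non-negative number")
  structure(list(y_min = y_min, y_max = y_max, T_steps = T_steps,
                 q_levels = q_levels, u = u,
                 drift = check_integerish(drift, "drift"),
                 mortality = mortality,
                 frozen_dynamics = isTRUE(frozen_dynamics),
                 terminal = terminal, tie_tol = tie_tol),
            class = "dsv_config")
}

#' Terminal fitness
#'
#' Expected reproductive success as a function of state at the time of
#' reproduction (\eqn{t = T + 1}). The linear choice
#' \eqn{\Phi_0(y) = y / y_{max}} isolates the effect of state-dependent
#' mortality on the curvature of the fitness surface: any curvature that
#' appears at \eqn{\tau > 0} was not put in at the boundary condition.
#'
#' @param y integer state(s), in \eqn{[0, y_{max}]}.
#' @param y_max upper state bound.
#' @return fitness value(s) \eqn{y / y_{max}} in \eqn{[0, 1]}.
#' @export
terminal_fitness <- function(y, y_max = 50L) {
  if (any(y < 0 | y > y_max)) stop("state 'y' outside [0, y_max]")
  y / y_max
}

#' Backward iteration over the foraging horizon
#'
#' Computes the expected-fitness table \eqn{F(y, t)} and the optimal
#' unpredictability policy \eqn{q^*(y, t)} by dynamic programming. The
#' recursion starts from the known terminal fitness
#' \eqn{F(y, T + 1) = \Phi_0(y)} and steps backward: for each candidate
#' level \eqn{q},
#' \deqn{F_q(y, t) = (1 - d(y)) \sum_z P_q(z | y) F(z, t + 1),}
#' and \eqn{F(y, t) = \max_q F_q(y, t)}, with \eqn{q^*(y, t)} the smallest
#' level attaining the maximum. The one-step kernels are time-homogeneous,
#' so each \eqn{P_q} is built once and reused across all time steps.
#'
#' @param config a [dsv_config()].
#' @return an object of class \code{"fitness_policy"}: a list with
#'   \describe{
#'     \item{\code{F}}{numeric matrix of expected fitness, rows = states
#'       \code{y_min:y_max}, columns = times \code{1:(T + 1)}; column
#'       \eqn{T + 1} is the terminal fitness.}
#'     \item{\code{q_star}}{integer matrix of optimal levels for times
#'       \code{1:T} (no decision is taken at \eqn{t = T + 1}).}
#'     \item{\code{config}}{the configuration that produced the tables.}
#'   }
#'   The run is deterministic: identical configurations give bit-identical
#'   tables.
#' @examples
#' pol <- backward_iterate(dsv_config())
#' ps <- phi_surface(pol)
#' ps$phi[ps$tau == 50 & ps$y == 25, ]
#' @export
backward_iterate <- function(config) {
  stopifnot(inherits(config, "dsv_config"))
  states <- config$y_min:config$y_max
  n <- length(states)
  Tn <- config$T_steps
  d <- mortality(config$mortality, states)

  kernels <- lapply(config$q_levels, function(q)
    unpred_kernel(q, u = config$u, drift = config$drift,
                  y_min = config$y_min, y_max = config$y_max)$matrix)

  phi0 <- if (is.function(config$terminal)) {
    v <- config$terminal(states, config$y_max)
    if (length(v) != n || any(!is.finite(v)) || any(v < 0 | v > 1))
      stop("terminal function must return values in [0, 1] for every state")
    v
  } else {
    terminal_fitness(states, config$y_max)
  }

  F <- matrix(NA_real_, n, Tn + 1L,
              dimnames = list(states, seq_len(Tn + 1L)))
  q_star <- matrix(NA_integer_, n, Tn,
                   dimnames = list(states, seq_len(Tn)))
  F[, Tn + 1L] <- phi0
  survive <- 1 - d
  for (t in Tn:1) {
    Fq <- vapply(kernels, function(P) survive * drop(P %*% F[, t + 1L]),
                 numeric(n))                     # n x length(q_levels)
    best <- Fq[, 1L]
    arg <- rep.int(1L, n)
    if (ncol(Fq) > 1L) {
      for (k in 2:ncol(Fq)) {
        better <- Fq[, k] > best + config$tie_tol
        best[better] <- Fq[better, k]
        arg[better] <- k
      }
    }
    F[, t] <- best
    q_star[, t] <- config$q_levels[arg]
  }
  structure(list(F = F, q_star = q_star, config = config),
            class = "fitness_policy")
}

#' Expected-fitness surface indexed by time to reproduction
#'
#' Re-indexes the dynamic-programming output by
#' \eqn{\tau = T + 1 - t}, the number of foraging steps remaining before
#' reproduction, so that \eqn{\Phi_0} is the terminal fitness and
#' \eqn{\Phi_T} the fitness expectation at the start of the foraging period.
#'
#' @param result a [backward_iterate()] result.
#' @return a list with \code{phi}, a long-format data frame (columns
#'   \code{tau}, \code{t}, \code{y}, \code{phi}), and \code{matrix}, the
#'   same surface as a states-by-tau matrix (columns named by \eqn{\tau}).
#' @export
phi_surface <- function(result) {
  stopifnot(inherits(result, "fitness_policy"))
  cfg <- result$config
  Tn <- cfg$T_steps
  taus <- 0:Tn
  M <- result$F[, Tn + 1L - taus, drop = FALSE]
  colnames(M) <- taus
  states <- cfg$y_min:cfg$y_max
  long <- data.frame(
    tau = rep(taus, each = length(states)),
    t = rep(Tn + 1L - taus, each = length(states)),
    y = rep(states, times = length(taus)),
    phi = as.vector(M))
  list(phi = long, matrix = M)
}

#' Optimal-policy table indexed by time to reproduction
#'
#' @param result a [backward_iterate()] result.
#' @return long-format data frame (columns \code{tau}, \code{t}, \code{y},
#'   \code{q_star}) for \eqn{\tau = 1, \ldots, T}. No decision exists at
#'   \eqn{\tau = 0} (reproduction), and under the combined mortality curve
#'   \eqn{y = 0} is deterministic death, so its policy entries are reported
#'   as \code{NA}.
#' @export
policy_table <- function(result) {
  stopifnot(inherits(result, "fitness_policy"))
  cfg <- result$config
  Tn <- cfg$T_steps
  taus <- 1:Tn
  states <- cfg$y_min:cfg$y_max
  Q <- result$q_star[, Tn + 1L - taus, drop = FALSE]
  out <- data.frame(
    tau = rep(taus, each = length(states)),
    t = rep(Tn + 1L - taus, each = length(states)),
    y = rep(states, times = length(taus)),
    q_star = as.integer(Q))
  dead <- mortality(cfg$mortality, states) >= 1
  out$q_star[out$y %in% states[dead]] <- NA_integer_
  out
}

#' Classify the curvature of a fitness row
#'
#' Under the expected-utility hypothesis the local curvature of
#' \eqn{\Phi_\tau(y)} decides the sign of selection on outcome variance:
#' convex regions favor variability, concave regions penalize it, linear
#' regions are neutral. Interior states are classified by the sign of the
#' central second difference
#' \eqn{\Phi(y + 1) - 2 \Phi(y) + \Phi(y - 1)}.
#'
#' @param phi_row numeric vector of fitness values over consecutive states
#'   (length \eqn{\ge 3}).
#' @param tol absolute second differences at or below \code{tol} are
#'   classified \code{"linear"} (default \code{1e-9}).
#' @return character vector of length \code{length(phi_row) - 2} with values
#'   \code{"convex"}, \code{"concave"} or \code{"linear"}, one per interior
#'   state.
#' @export
curvature_profile <- function(phi_row, tol = 1e-9) {
  if (length(phi_row) < 3L) stop("'phi_row' must have length >= 3")
  d2 <- diff(phi_row, differences = 2L)
  ifelse(abs(d2) <= tol, "linear", ifelse(d2 > 0, "convex", "concave"))
}

#' @export
print.fitness_policy <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Fitness/policy tables: states %d..%d, T = %d, q levels {%s}, u = %g%s\n",
    cfg$y_min, cfg$y_max, cfg$T_steps,
    paste(cfg$q_levels, collapse = ","), cfg$u,
    if (cfg$frozen_dynamics) " (frozen dynamics)" else ""))
  invisible(x)
}

#' @export
print.dsv_config <- function(x, ...) {
  cat(sprintf(
    "DSV model config: states %d..%d, T = %d, q levels {%s}, u = %g, drift = %+d%s\n",
    x$y_min, x$y_max, x$T_steps, paste(x$q_levels, collapse = ","),
    x$u, x$drift, if (x$frozen_dynamics) ", frozen dynamics" else ""))
  print(x$mortality)
  invisible(x)
}
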