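#' Closed-form expected fitness under frozen dynamics
#'
#' When there are no state dynamics (only the identity kernel, \eqn{q = 0},
#' no drift), the backward recursion collapses to repeated multiplication by
#' the one-step survival probability, and the fitness surface has the closed
#' form
#' \deqn{\Phi_\tau(y) = s_\tau(y)\, \Phi_0(y), \qquad
#'       s_\tau(y) = (1 - d(y))^\tau,}
#' with linear terminal fitness \eqn{\Phi_0(y) = y / y_{max}}. This is the
#' independent oracle against which the dynamic-programming engine is
#' validated: any curvature in \eqn{\Phi_\tau} here comes purely from the
#' multiplicative survival process acting on a state-dependent \eqn{d(y)}.
#'
#' @param model a [mortality_model()].
#' @param y integer state(s).
#' @param tau non-negative number of foraging steps before reproduction;
#'   scalar.
#' @param y_max upper state bound used by the terminal fitness (defaults to
#'   the model's).
#' @return fitness value(s) \eqn{(1 - d(y))^\tau \cdot y / y_{max}}.
#' @export
closed_form_phi <- function(model, y, tau, y_max = model$y_max) {
  survival(model, y, tau) * terminal_fitness(y, y_max)
}

#' Full closed-form fitness surface (isolated mortality effects)
#'
#' Evaluates [closed_form_phi()] on the whole grid for
#' \eqn{\tau = 0, \ldots, T}, producing the same surface as a
#' frozen-dynamics [backward_iterate()] run without any iteration. The two
#' routes agree to within floating-point accumulation error
#' (\eqn{\le 10^{-12}} absolute); the agreement is asserted in the package
#' test suite for all shipped mortality presets.
#'
#' @param model a [mortality_model()].
#' @param T_steps horizon \eqn{T} (default 50).
#' @return a list with \code{phi}, a long-format data frame (columns
#'   \code{tau}, \code{t}, \code{y}, \code{phi}), and \code{matrix}, the
#'   states-by-tau surface — the same shapes as [phi_surface()].
#' @export
isolated_effects_surface <- function(model, T_steps = 50L) {
  stopifnot(inherits(model, "mortality_model"))
  T_steps <- check_integerish(T_steps, "T_steps")
  if (T_steps < 1L) stop("'T_steps' must be >= 1")
  states <- model$y_min:model$y_max
  taus <- 0:T_steps
  M <- vapply(taus, function(tau) closed_form_phi(model, states, tau),
              numeric(length(states)))
  dimnames(M) <- list(states, taus)
  long <- data.frame(
    tau = rep(taus, each = length(states)),
    t = rep(T_steps + 1L - taus, each = length(states)),
    y = rep(states, times = length(taus)),
    phi = as.vector(M))
  list(phi = long, matrix = M)
}
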