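#' One-step state transition kernel with behavioral unpredictability
#'
#' Builds the row-stochastic matrix \eqn{P_q(z | y)} giving the probability
#' that a forager of state \eqn{y} ends the time step in state \eqn{z}, for a
#' given level of behavioral unpredictability \eqn{q \in \{0, 1, 2, 3\}}.
#'
#' For \eqn{q \ge 1} the distribution over the \eqn{2q + 1} candidate states
#' \eqn{\{c - q, \ldots, c + q\}}, where \eqn{c = y + drift}, is a binomial
#' with size \eqn{N = 2q} whose outcome 0 is mapped onto the lowest candidate
#' state. The success probability is chosen so that the (unclamped) row mean
#' equals \eqn{E(Y_{t+1}) = y + drift + u q}:
#' \deqn{p = \frac{E(Y_{t+1}) - (c - q)}{N} = \frac{1 + u}{2}.}
#' With \eqn{u = 0} this gives the symmetric kernel (e.g. for \eqn{q = 1}:
#' 0.25 / 0.5 / 0.25); with \eqn{u = -0.1} and \eqn{q = 1} it gives
#' 0.3025 / 0.4950 / 0.2025, a binomial with \eqn{Np = 0.9}, \eqn{N = 2}.
#' For \eqn{q = 0} the row is a point mass at \eqn{c} (no environmental
#' stochasticity is modeled at zero unpredictability).
#'
#' State dynamics are constrained by the grid: any probability mass falling
#' below \code{y_min} is accumulated onto \code{y_min}, and mass above
#' \code{y_max} onto \code{y_max}, so every row still sums to one. Clamped
#' boundary rows therefore have a mean pulled toward the interior; interior
#' rows have mean exactly \eqn{y + drift + u q} and, for \eqn{u = 0},
#' variance \eqn{N p (1 - p) = q / 2}.
#'
#' @param q integer unpredictability level, one of 0, 1, 2, 3. Higher
#'   \code{q} widens the distribution of one-step outcomes.
#' @param u dimensionless effect of unpredictability on the expected outcome;
#'   the expected state change per step is \eqn{drift + u q}. Must satisfy
#'   \eqn{|u| \le 1} so the binomial success probability lies in \eqn{[0,1]}.
#' @param drift integer baseline expected state change per step (0, +1 or -1
#'   in the analyses shipped with the package). Non-integer drift is rejected
#'   rather than silently rounded.
#' @param y_min,y_max integer state bounds.
#' @return an object of class \code{"unpred_kernel"}: a list with the
#'   parameters and \code{matrix}, a \code{(y_max - y_min + 1)} square
#'   row-stochastic matrix with dimnames giving the states.
#' @examples
#' k <- unpred_kernel(q = 1, u = -0.1)
#' transition_row(k, 25)[c("24", "25", "26")]  # 0.3025 0.4950 0.2025
#' @export
unpred_kernel <- function(q, u = 0, drift = 0L, y_min = 0L, y_max = 50L) {
  q <- check_integerish(q, "q")
  if (!q %in% 0:3) stop("'q' must be one of 0, 1, 2, 3")
  drift <- check_integerish(drift, "drift")
  y_min <- check_integerish(y_min, "y_min")
  y_max <- check_integerish(y_max, "y_max")
  if (y_min >= y_max) stop("'y_min' must be strictly less than 'y_max'")
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u))
    stop("'u' must be a single finite number")
  p <- (1 + u) / 2
  if (q > 0 && (p < 0 || p > 1))
    stop("success probability (1 + u)/2 outside [0, 1]; require |u| <= 1")

  states <- y_min:y_max
  n <- length(states)
  P <- matrix(0, n, n, dimnames = list(states, states))
  for (i in seq_len(n)) {
    y <- states[i]
    c0 <- y + drift
    if (q == 0L) {
      targets <- c0
      probs <- 1
    } else {
      targets <- (c0 - q):(c0 + q)
      # binomial pmf written out so that dyadic p (u = 0) stays exact
      ks <- 0:(2L * q)
      probs <- choose(2L * q, ks) * p^ks * (1 - p)^(2L * q - ks)
    }
    targets <- pmin(pmax(targets, y_min), y_max)  # clamp, accumulating mass
    for (j in seq_along(targets))
      P[i, targets[j] - y_min + 1L] <- P[i, targets[j] - y_min + 1L] + probs[j]
  }
  structure(list(q = q, u = u, drift = drift,
                 y_min = y_min, y_max = y_max, matrix = P),
            class = "unpred_kernel")
}

#' Extract one row of a transition kernel
#'
#' @param kernel an [unpred_kernel()].
#' @param y integer state within bounds.
#' @return named numeric vector of transition probabilities over all states.
#' @export
transition_row <- function(kernel, y) {
  stopifnot(inherits(kernel, "unpred_kernel"))
  y <- check_integerish(y, "y")
  if (y < kernel$y_min || y > kernel$y_max)
    stop("state 'y' outside [y_min, y_max]")
  kernel$matrix[y - kernel$y_min + 1L, ]
}

#' Sample a one-step transition
#'
#' Draws next states from row \eqn{y} of the kernel. Reproducible under
#' \code{set.seed()}; intended for forward simulation of individual state
#' trajectories under a fixed unpredictability level.
#'
#' @param kernel an [unpred_kernel()].
#' @param y integer current state.
#' @param n number of independent draws.
#' @return integer vector of \code{n} next states.
#' @export
sample_transition <- function(kernel, y, n = 1L) {
  row <- transition_row(kernel, y)
  states <- kernel$y_min:kernel$y_max
  sup <- row > 0
  if (sum(sup) == 1L) return(rep.int(states[sup], n))
  sample(states[sup], size = n, replace = TRUE, prob = row[sup])
}

#' @export
print.unpred_kernel <- function(x, ...) {
  cat(sprintf(
    "Behavioral-unpredictability kernel: q = %d, u = %g, drift = %+d, states %d..%d\n",
    x$q, x$u, x$drift, x$y_min, x$y_max))
  cat(sprintf("Interior row mean y %+g; interior row variance %g\n",
              x$drift + x$u * x$q, if (x$q > 0) x$q / 2 * (1 - x$u^2) else 0))
  invisible(x)
}

#' Tabulate a transition kernel in long format
#'
#' @param x an [unpred_kernel()].
#' @param drop_zero drop zero-probability cells (default \code{TRUE}).
#' @param ... unused.
#' @return data frame with columns \code{y} (current state), \code{z} (next
#'   state), \code{probability}.
#' @export
as.data.frame.unpred_kernel <- function(x, drop_zero = TRUE, ...) {
  states <- x$y_min:x$y_max
  out <- expand.grid(z = states, y = states)[, c("y", "z")]
  out$probability <- as.vector(t(x$matrix))
  if (drop_zero) out <- out[out$probability > 0, ]
  rownames(out) <- NULL
  out
}
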