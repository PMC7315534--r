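#' State-dependent per-step mortality models
#'
#' Constructs a per-time-step probability-of-death function \eqn{d(y)} on the
#' discrete state grid \code{y_min:y_max}. Three kinds are supported:
#' \describe{
#'   \item{\code{"combined"}}{Starvation plus mass-dependent predation acting
#'     independently: \eqn{d(y) = 1 - (1 - e^{-\alpha y})(1 - \beta y^2)}.
#'     Starvation mortality \eqn{e^{-\alpha y}} decreases with state; predation
#'     mortality \eqn{\beta y^2} increases with state. At \eqn{y = 0} the
#'     starvation term forces \eqn{d(0) = 1}: zero state is deterministic
#'     death.}
#'   \item{\code{"linear"}}{\eqn{d(y) = intercept + slope \cdot y}.}
#'   \item{\code{"constant"}}{\eqn{d(y) = intercept}, independent of state.}
#' }
#'
#' Validity (\eqn{d(y) \in [0, 1]} for every grid state) is enforced here, at
#' construction, so downstream dynamic-programming runs can never encounter an
#' invalid probability.
#'
#' @param kind one of \code{"combined"}, \code{"linear"}, \code{"constant"}.
#' @param alpha starvation steepness (\code{combined} kind), \eqn{\ge 0}.
#'   Default 0.5.
#' @param beta predation coefficient per squared state unit (\code{combined}
#'   kind), \eqn{\ge 0}. Default \code{0.2 / y_max^2}, so that the maximum
#'   mass-dependent mortality on the grid is 0.2.
#' @param slope per-state-unit change in death probability (\code{linear}).
#' @param intercept baseline death probability (\code{linear},
#'   \code{constant}).
#' @param y_min,y_max integer state bounds (defaults 0 and 50).
#' @return an object of class \code{"mortality_model"}.
#' @seealso [mortality_preset()] for the named parameterizations used in the
#'   accompanying analyses, [mortality()], [survival()].
#' @examples
#' m <- mortality_model("combined")
#' mortality(m, 0)   # 1: deterministic death at zero state
#' mortality(m, 50)  # 0.2: predation ceiling dominates at the top state
#' @export
mortality_model <- function(kind = c("combined", "linear", "constant"),
                            alpha = 0.5, beta = 0.2 / y_max^2,
                            slope = NULL, intercept = NULL,
                            y_min = 0L, y_max = 50L) {
  kind <- match.arg(kind)
  y_min <- check_integerish(y_min, "y_min")
  y_max <- check_integerish(y_max, "y_max")
  if (y_min >= y_max) stop("'y_min' must be strictly less than 'y_max'")
  beta <- force(beta)

  model <- switch(kind,
    combined = {
      if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
        stop("'alpha' must be a single non-negative number")
      if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
        stop("'beta' must be a single non-negative number")
      list(kind = kind, alpha = alpha, beta = beta)
    },
    linear = {
      if (is.null(slope) || is.null(intercept))
        stop("linear mortality requires both 'slope' and 'intercept'")
      list(kind = kind, slope = slope, intercept = intercept)
    },
    constant = {
      if (is.null(intercept))
        stop("constant mortality requires 'intercept'")
      list(kind = kind, intercept = intercept)
    })
  model$y_min <- y_min
  model$y_max <- y_max
  class(model) <- "mortality_model"

  d <- mortality(model, y_min:y_max)
  bad <- d < 0 | d > 1 | !is.finite(d)
  if (any(bad))
    stop(sprintf(
      "invalid mortality parameterization: d(y) outside [0, 1] at states %s",
      paste(utils::head((y_min:y_max)[bad], 5L), collapse = ", ")))
  model
}

#' Named mortality parameterizations
#'
#' Shorthand constructors for the four curves examined in the accompanying
#' analyses: the combined starvation/predation curve with its default
#' parameters, and the three illustrative cases of state-independent,
#' decreasing-linear, and increasing-linear mortality.
#'
#' @param name one of \code{"combined"} (\eqn{d(y) = 1 - (1 - e^{-0.5 y})
#'   (1 - 0.2 y^2 / y_{max}^2)}), \code{"state_independent"}
#'   (\eqn{d(y) = 0.05}), \code{"decreasing"} (\eqn{d(y) = 0.1 - 0.002 y}),
#'   \code{"increasing"} (\eqn{d(y) = 0.002 y}).
#' @param y_min,y_max integer state bounds.
#' @return a \code{"mortality_model"}.
#' @export
mortality_preset <- function(name = c("combined", "state_independent",
                                      "decreasing", "increasing"),
                             y_min = 0L, y_max = 50L) {
  name <- match.arg(name)
  switch(name,
    combined = mortality_model("combined", alpha = 0.5,
                               beta = 0.2 / y_max^2,
                               y_min = y_min, y_max = y_max),
    state_independent = mortality_model("constant", intercept = 0.05,
                                        y_min = y_min, y_max = y_max),
    decreasing = mortality_model("linear", slope = -0.002, intercept = 0.1,
                                 y_min = y_min, y_max = y_max),
    increasing = mortality_model("linear", slope = 0.002, intercept = 0,
                                 y_min = y_min, y_max = y_max))
}

#' Evaluate per-step death probability
#'
#' @param model a [mortality_model()].
#' @param y integer state(s) within the model's bounds; vectorized.
#' @return death probability \eqn{d(y)} per step, in \eqn{[0, 1]}.
#' @export
mortality <- function(model, y) {
  stopifnot(inherits(model, "mortality_model"))
  if (any(y < model$y_min | y > model$y_max))
    stop("state 'y' outside [y_min, y_max]")
  switch(model$kind,
    combined = 1 - (1 - exp(-model$alpha * y)) * (1 - model$beta * y^2),
    linear   = model$intercept + model$slope * y,
    constant = rep_len(model$intercept, length(y)))
}

#' Multi-step survival probability
#'
#' Probability that an individual of state \eqn{y} survives \eqn{\tau}
#' consecutive time steps at fixed state:
#' \eqn{s_\tau(y) = (1 - d(y))^\tau}, with \eqn{s_0(y) = 1}.
#'
#' @param model a [mortality_model()].
#' @param y integer state(s).
#' @param tau non-negative integer number of steps.
#' @return survival probability.
#' @export
survival <- function(model, y, tau) {
  if (any(tau < 0)) stop("'tau' must be non-negative")
  (1 - mortality(model, y))^tau
}

#' @export
print.mortality_model <- function(x, ...) {
  params <- switch(x$kind,
    combined = sprintf("alpha = %g, beta = %g", x$alpha, x$beta),
    linear   = sprintf("slope = %g, intercept = %g", x$slope, x$intercept),
    constant = sprintf("intercept = %g", x$intercept))
  cat(sprintf("Per-step mortality model (%s): %s; states %d..%d\n",
              x$kind, params, x$y_min, x$y_max))
  invisible(x)
}

#' Tabulate a mortality curve
#'
#' @param x a [mortality_model()].
#' @param ... unused.
#' @return a data frame with columns \code{y} and \code{d}, one row per grid
#'   state, suitable for plotting or CSV export.
#' @export
as.data.frame.mortality_model <- function(x, ...) {
  y <- x$y_min:x$y_max
  data.frame(y = y, d = mortality(x, y))
}

# single integer-valued scalar, returned as integer
check_integerish <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop(sprintf("'%s' must be a single integer", name))
  as.integer(x)
}
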