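# Norm populations: the conformity-weighted distance penalty and the
# per-step mean update.

#' Construct a norm state
#'
#' A norm is defined over a population (here, one per gender) by its
#' protocol: the behaviour components it tracks and their population means.
#' The household model tracks `alpha`, `gamma` and `theta`; the individual
#' and unitary comparison models track only `alpha` and `gamma` (no transfer
#' exists there).
#'
#' @param population_id identifier; `"female"` or `"male"` enables
#'   population/gender consistency checks, other identifiers are allowed.
#' @param means named numeric vector with names among `alpha`, `gamma`,
#'   `theta`, each in `[0, 1]`.
#' @param membership optional vector of agent identifiers.
#' @return An object of class `hh_norm`.
#' @export
norm_state <- function(population_id, means, membership = NULL) {
  if (!is.numeric(means) || is.null(names(means)) ||
      !all(names(means) %in% .COMPONENTS) || anyDuplicated(names(means)))
    stop("`means` must be named with distinct names among ",
         paste(.COMPONENTS, collapse = ", "), call. = FALSE)
  if (any(!is.finite(means)) || any(means < 0) || any(means > 1))
    stop("norm means must lie in [0, 1]", call. = FALSE)
  structure(list(population_id = population_id, means = means,
                 membership = membership),
            class = "hh_norm")
}

#' Squared distance from the norm mean
#'
#' The distance protocol used throughout: `(x - mu)^2`.
#'
#' @param x behaviour value(s).
#' @param mu norm mean(s).
#' @return Non-negative squared distances.
#' @export
norm_distance <- function(x, mu) {
  if (!is.numeric(x) || !is.numeric(mu) || any(!is.finite(x)) || any(!is.finite(mu)))
    stop("`x` and `mu` must be finite numerics", call. = FALSE)
  (x - mu)^2
}

#' Norm penalty for a set of behaviours
#'
#' Computes `N = sum_i c_i * (x_i - mu_i)^2` over the behaviour components
#' and the multiplicative utility factor `exp(-N)`. The factor is 1 exactly
#' when `N` is 0 (behaviours at the means, or all weights zero).
#'
#' @param behaviors named numeric vector of behaviour values; names must be
#'   a subset of the norm's components.
#' @param norm a [norm_state()].
#' @param conformity named non-negative weights (missing components count 0).
#' @return A list with elements `n` (the penalty) and `factor` (`exp(-n)`).
#' @examples
#' nrm <- norm_state("female", c(alpha = 0.2, gamma = 0.8, theta = 0))
#' norm_penalty(c(alpha = 0.8, gamma = 0.8, theta = 0), nrm,
#'              c(alpha = 0.5))   # n = 0.5 * 0.36 = 0.18
#' @export
norm_penalty <- function(behaviors, norm, conformity) {
  stopifnot(inherits(norm, "hh_norm"))
  if (!is.numeric(behaviors) || is.null(names(behaviors)))
    stop("`behaviors` must be a named numeric vector", call. = FALSE)
  miss <- setdiff(names(behaviors), names(norm$means))
  if (length(miss))
    stop("behaviour component(s) not tracked by this norm: ",
         paste(miss, collapse = ", "), call. = FALSE)
  conf <- .conformity_vec(conformity)
  comp <- names(behaviors)
  n <- sum(conf[comp] * (behaviors - norm$means[comp])^2)
  list(n = n, factor = exp(-n))
}

#' Update norm means from population behaviour
#'
#' Each component mean becomes the arithmetic mean of the population's
#' behaviour values from the just-completed time step. The focal agent's own
#' behaviour is included in its population mean.
#'
#' @param population_behaviors a list of named numeric vectors (one per
#'   member, identical component names) or a data.frame with one column per
#'   component.
#' @return Named vector of component means.
#' @export
update_norms <- function(population_behaviors) {
  if (is.data.frame(population_behaviors)) {
    if (nrow(population_behaviors) == 0L)
      stop("empty population", call. = FALSE)
    m <- colMeans(population_behaviors[intersect(names(population_behaviors),
                                                 .COMPONENTS)])
  } else {
    if (!is.list(population_behaviors) || length(population_behaviors) == 0L)
      stop("empty population", call. = FALSE)
    nm <- names(population_behaviors[[1L]])
    mat <- do.call(rbind, lapply(population_behaviors, function(x) x[nm]))
    m <- colMeans(mat)
    names(m) <- nm
  }
  m
}
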