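# Domain types and the goods-plus-norm utility of the household model.

.COMPONENTS <- c("alpha", "gamma", "theta")

.check_scalar <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a single finite number", call. = FALSE)
  if (x < lo || x > hi || (strict_lo && x <= lo))
    stop("`", name, "` out of range [", lo, ", ", hi, "]", call. = FALSE)
  invisible(x)
}

.conformity_vec <- function(conformity) {
  if (is.null(conformity)) conformity <- c(alpha = 0, gamma = 0, theta = 0)
  if (!is.numeric(conformity) || is.null(names(conformity)) ||
      !all(names(conformity) %in% .COMPONENTS))
    stop("`conformity` must be a named numeric vector with names among ",
         paste(.COMPONENTS, collapse = ", "), call. = FALSE)
  if (any(conformity < 0)) stop("conformity weights must be >= 0", call. = FALSE)
  out <- c(alpha = 0, gamma = 0, theta = 0)
  out[names(conformity)] <- conformity
  out
}

#' Construct an agent's fixed parameters
#'
#' An agent has a gender (which determines its norm population and wage
#' schedule), preference weights for the private and public good (summing to
#' one), conformity weights attaching utility cost to deviating from the norm
#' means for time allocation and transfer behaviour, and a wage: the private
#' good produced per unit time on the private activity.
#'
#' @param agent_id identifier (any scalar).
#' @param gender `"female"` or `"male"`.
#' @param p_alpha preference weight for the private good, in `[0, 1]`;
#'   the public-good weight is `1 - p_alpha`.
#' @param conformity named non-negative weights for components `alpha`,
#'   `gamma`, `theta`; missing components default to 0.
#' @param wage private-good output per unit time, `> 0`.
#' @return An object of class `hh_agent`.
#' @examples
#' agent_params(1, "female", p_alpha = 0.5,
#'              conformity = c(alpha = 0.4, gamma = 0.4, theta = 0.4),
#'              wage = 0.1)
#' @export
agent_params <- function(agent_id, gender = c("female", "male"), p_alpha,
                         conformity = NULL, wage) {
  gender <- match.arg(gender)
  .check_scalar(p_alpha, "p_alpha", 0, 1)
  .check_scalar(wage, "wage", 0, Inf, strict_lo = TRUE)
  structure(
    list(agent_id = agent_id, gender = gender,
         p_alpha = p_alpha, p_gamma = 1 - p_alpha,
         conformity = .conformity_vec(conformity), wage = wage),
    class = "hh_agent")
}

#' Pair two agents into a household
#'
#' Member `a` is conventionally the female spouse and `b` the male spouse,
#' but any two agents may be paired; the labels only fix which member the
#' transfer direction `A_to_B` refers to.
#'
#' @param params_a,params_b [agent_params()] objects.
#' @return An object of class `hh_household`.
#' @export
household <- function(params_a, params_b) {
  stopifnot(inherits(params_a, "hh_agent"), inherits(params_b, "hh_agent"))
  structure(list(a = params_a, b = params_b), class = "hh_household")
}

#' Construct a time allocation
#'
#' @param alpha proportion of time on the private activity, in `[0, 1]`;
#'   the public-activity share is `gamma = 1 - alpha` (full time budget).
#' @return An object of class `hh_allocation` with fields `alpha`, `gamma`.
#' @export
allocation <- function(alpha) {
  .check_scalar(alpha, "alpha", 0, 1)
  structure(list(alpha = alpha, gamma = 1 - alpha), class = "hh_allocation")
}

#' Construct a household bargain
#'
#' A bargain is a pair of time allocations plus a transfer: `theta` is the
#' fraction of the transferor's private output given to the other member.
#' `direction` must be `"none"` exactly when `theta` is zero.
#'
#' @param alpha_a,alpha_b private-activity time shares of members A and B.
#' @param theta transfer fraction in `[0, 1]`.
#' @param direction `"none"`, `"A_to_B"` or `"B_to_A"`.
#' @return An object of class `hh_bargain`.
#' @export
bargain <- function(alpha_a, alpha_b, theta = 0,
                    direction = c("none", "A_to_B", "B_to_A")) {
  direction <- match.arg(direction)
  .check_scalar(alpha_a, "alpha_a", 0, 1)
  .check_scalar(alpha_b, "alpha_b", 0, 1)
  .check_scalar(theta, "theta", 0, 1)
  if ((theta == 0) != (direction == "none"))
    stop("`direction` must be \"none\" iff `theta` is 0", call. = FALSE)
  structure(
    list(alpha_a = alpha_a, gamma_a = 1 - alpha_a,
         alpha_b = alpha_b, gamma_b = 1 - alpha_b,
         theta = theta, direction = direction),
    class = "hh_bargain")
}

#' Private-activity output
#'
#' Linear production: time `alpha` at wage `wage` yields `wage * alpha`
#' units of private good.
#'
#' @param alpha time share in `[0, 1]` (vectorised).
#' @param wage wage `> 0`.
#' @return Goods units, `wage * alpha`.
#' @examples
#' private_output(1, 0.6)    # a full day at the male wage: 0.6
#' private_output(0.5, 0.6)  # 0.3
#' @export
private_output <- function(alpha, wage) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha < 0) || any(alpha > 1))
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  .check_scalar(wage, "wage", 0, Inf, strict_lo = TRUE)
  wage * alpha
}

#' Public-activity output
#'
#' Additive production shared by both members: pooled public time
#' `gamma_a + gamma_b` yields that same amount of public good, consumed in
#' full by each member.
#'
#' @param gamma_a,gamma_b public-activity time shares in `[0, 1]` (vectorised).
#' @return Goods units, `gamma_a + gamma_b`.
#' @export
public_output <- function(gamma_a, gamma_b) {
  ok <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (!ok(gamma_a) || !ok(gamma_b))
    stop("time shares must lie in [0, 1]", call. = FALSE)
  gamma_a + gamma_b
}

# Private good consumed by one member under a bargain (post-transfer).
.private_consumed <- function(role, b, params_a, params_b) {
  out_a <- params_a$wage * b$alpha_a
  out_b <- params_b$wage * b$alpha_b
  th <- b$theta
  if (role == "A") {
    switch(b$direction,
           none   = out_a,
           A_to_B = out_a * (1 - th),
           B_to_A = out_a + th * out_b)
  } else {
    switch(b$direction,
           none   = out_b,
           A_to_B = out_b + th * out_a,
           B_to_A = out_b * (1 - th))
  }
}

#' Utility of one household member under a bargain
#'
#' Member utility is a goods term tempered by the norm penalty:
#' `[p_alpha * sqrt(private consumed) + p_gamma * sqrt(public output)] * exp(-N)`,
#' where the private good consumed reflects the bargain's transfer (the
#' transferor loses the fraction `theta` of its own private output, the
#' transferee gains that amount inside its square root) and `N` is the
#' conformity-weighted squared distance between the member's behaviours
#' (own `alpha`, own `gamma`, household `theta`) and its norm-population
#' means (see [norm_penalty()]). The square roots impose diminishing returns
#' so agents do not oscillate to corners under small payoff changes.
#'
#' @param role `"A"` or `"B"`: which member's utility to evaluate.
#' @param bargain an [bargain()] object.
#' @param params_a,params_b the members' [agent_params()].
#' @param norm the [norm_state()] of the evaluated member's own gender
#'   population; must carry means for `alpha`, `gamma` and `theta`.
#' @return A non-negative utility value.
#' @examples
#' nrm <- norm_state("female", c(alpha = 0.5, gamma = 0.5, theta = 0))
#' a <- agent_params(1, "female", 0.5, wage = 0.6)
#' b <- agent_params(2, "male", 0.5, wage = 0.6)
#' utility_member("A", bargain(0.5, 0.5), a, b, nrm)  # 0.5*sqrt(0.3) + 0.5
#' @export
utility_member <- function(role = c("A", "B"), bargain, params_a, params_b,
                           norm) {
  role <- match.arg(role)
  stopifnot(inherits(bargain, "hh_bargain"),
            inherits(params_a, "hh_agent"), inherits(params_b, "hh_agent"),
            inherits(norm, "hh_norm"))
  params <- if (role == "A") params_a else params_b
  if (norm$population_id %in% c("female", "male") &&
      norm$population_id != params$gender)
    stop("`norm` belongs to population \"", norm$population_id,
         "\" but member ", role, " is ", params$gender, call. = FALSE)
  priv <- .private_consumed(role, bargain, params_a, params_b)
  pub <- public_output(bargain$gamma_a, bargain$gamma_b)
  behav <- c(alpha = if (role == "A") bargain$alpha_a else bargain$alpha_b,
             gamma = if (role == "A") bargain$gamma_a else bargain$gamma_b,
             theta = bargain$theta)
  pen <- norm_penalty(behav, norm, params$conformity)
  (params$p_alpha * sqrt(priv) + params$p_gamma * sqrt(pub)) * pen$factor
}
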