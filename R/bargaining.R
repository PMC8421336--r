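# The household bargain: best responses, fixed-theta equilibria,
# separate-spheres threat points, Nash-product selection, and an
# equilibrium-free brute-force oracle.

#' Solver settings
#'
#' Resolutions and tolerances for the grid solver. The allocation grid is
#' `0, step, 2*step, ..., 1`; likewise the transfer grid. Best-response
#' iteration stops on exact repetition of both grid indices or after
#' `max_iterations` rounds (non-convergence is flagged, not fatal).
#'
#' @param alpha_grid_step allocation grid resolution, in `(0, 1]` (default 0.01).
#' @param theta_grid_step transfer grid resolution (default 0.025; coarser
#'   transfer grids can freeze slow norm-driven transfer dynamics whose
#'   per-step increments fall below the grid step).
#' @param max_iterations cap on best-response rounds (default 100).
#' @param convergence_tol allocation-change tolerance for continuous
#'   refinements; the grid path uses exact repetition (default 1e-6).
#' @param constraint_tol slack allowed on the participation constraints
#'   (default 1e-9).
#' @return An object of class `hh_settings`.
#' @export
solver_settings <- function(alpha_grid_step = 0.01, theta_grid_step = 0.025,
                            max_iterations = 100L, convergence_tol = 1e-6,
                            constraint_tol = 1e-9) {
  .check_scalar(alpha_grid_step, "alpha_grid_step", 0, 1, strict_lo = TRUE)
  .check_scalar(theta_grid_step, "theta_grid_step", 0, 1, strict_lo = TRUE)
  if (max_iterations < 1) stop("`max_iterations` must be >= 1", call. = FALSE)
  if (convergence_tol < 0 || constraint_tol < 0)
    stop("tolerances must be >= 0", call. = FALSE)
  structure(list(alpha_grid_step = alpha_grid_step,
                 theta_grid_step = theta_grid_step,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 constraint_tol = constraint_tol),
            class = "hh_settings")
}

# Grid 0, step, ..., 1 with the last point pinned to exactly 1.
.grid <- function(step) {
  n <- round(1 / step) + 1L
  g <- (seq_len(n) - 1L) * step
  g[n] <- 1
  g
}

.snap <- function(x, g) {
  i <- round(x / (g[2L] - g[1L])) + 1L
  min(max(i, 1L), length(g))
}

# Utility of one member over its whole alpha grid, partner fixed.
# `gives` says whether this member is the transferor at |theta|.
.util_grid <- function(p, w, conf, mu, alpha_partner, w_partner, th, gives, g) {
  priv <- if (th == 0) w * g
          else if (gives) w * g * (1 - th)
          else w * g + th * w_partner * alpha_partner
  pub <- (1 - g) + (1 - alpha_partner)
  pen <- conf[["alpha"]] * (g - mu[["alpha"]])^2 +
         conf[["gamma"]] * ((1 - g) - mu[["gamma"]])^2 +
         conf[["theta"]] * (th - mu[["theta"]])^2
  (p * sqrt(priv) + (1 - p) * sqrt(pub)) * exp(-pen)
}

# Argmax with ties broken toward the previous allocation, then smaller alpha.
.argmax_tie <- function(u, g, prev_alpha) {
  m <- max(u)
  cand <- which(u >= m - 1e-12 * max(1, m))
  if (length(cand) > 1L && !is.null(prev_alpha)) {
    d <- abs(g[cand] - prev_alpha)
    cand <- cand[d <= min(d) + 1e-15]
  }
  cand[1L]
}

.full_means <- function(norm) {
  mu <- c(alpha = 0, gamma = 0, theta = 0)
  mu[names(norm$means)] <- norm$means
  for (comp in setdiff(.COMPONENTS, names(norm$means))) mu[comp] <- 0
  mu
}

.norm_for <- function(norms, params) {
  if (inherits(norms, "hh_norm")) return(norms)
  nrm <- norms[[params$gender]]
  if (is.null(nrm))
    stop("`norms` has no entry for gender \"", params$gender, "\"", call. = FALSE)
  nrm
}

#' Best response of one member at a fixed transfer
#'
#' Maximises the member's utility over its own time-allocation grid, holding
#' the partner's public-time contribution and the signed transfer fixed.
#' Ties are broken toward the allocation closest to `prev_alpha`, then
#' toward smaller `alpha`.
#'
#' @param role `"A"` or `"B"` (which member is optimising).
#' @param partner_gamma the partner's public-activity time share.
#' @param theta_signed signed transfer: positive means A transfers to B,
#'   negative means B transfers to A; magnitude in `[0, 1]`.
#' @param params,partner_params the optimiser's and partner's
#'   [agent_params()].
#' @param norm the optimiser's gender-population [norm_state()].
#' @param settings [solver_settings()].
#' @param prev_alpha previous allocation for tie-breaking, or `NULL`.
#' @return An [allocation()].
#' @export
best_response <- function(role = c("A", "B"), partner_gamma, theta_signed,
                          params, partner_params, norm,
                          settings = solver_settings(), prev_alpha = NULL) {
  role <- match.arg(role)
  .check_scalar(partner_gamma, "partner_gamma", 0, 1)
  .check_scalar(theta_signed, "theta_signed", -1, 1)
  g <- .grid(settings$alpha_grid_step)
  th <- abs(theta_signed)
  gives <- th > 0 && ((role == "A") == (theta_signed > 0))
  u <- .util_grid(params$p_alpha, params$wage, params$conformity,
                  .full_means(norm), 1 - partner_gamma, partner_params$wage,
                  th, gives, g)
  allocation(g[.argmax_tie(u, g, prev_alpha)])
}

#' Household equilibrium at a fixed transfer
#'
#' Alternates best responses (member A first) until neither allocation
#' changes on the grid, or `max_iterations` is reached (flagged as
#' non-converged; the last iterate is returned).
#'
#' @param household a [household()].
#' @param theta_signed signed transfer (see [best_response()]).
#' @param norms a list of [norm_state()] keyed by gender (`female`, `male`),
#'   or a single norm applied to both members.
#' @param settings [solver_settings()].
#' @param start optional numeric `c(alpha_a, alpha_b)` starting allocations
#'   (default `c(0.5, 0.5)`), snapped to the grid.
#' @return A list with `bargain`, `utility_a`, `utility_b`, `converged`,
#'   `iterations`.
#' @export
equilibrium_at_theta <- function(household, theta_signed, norms,
                                 settings = solver_settings(), start = NULL) {
  stopifnot(inherits(household, "hh_household"))
  .check_scalar(theta_signed, "theta_signed", -1, 1)
  pa <- household$a; pb <- household$b
  na <- .norm_for(norms, pa); nb <- .norm_for(norms, pb)
  mua <- .full_means(na); mub <- .full_means(nb)
  g <- .grid(settings$alpha_grid_step)
  if (is.null(start)) start <- c(0.5, 0.5)
  ia <- .snap(start[1L], g); ib <- .snap(start[2L], g)
  th <- abs(theta_signed)
  a_gives <- th > 0 && theta_signed > 0
  b_gives <- th > 0 && theta_signed < 0
  converged <- FALSE
  it <- 0L
  while (it < settings$max_iterations) {
    it <- it + 1L
    old <- c(ia, ib)
    ua <- .util_grid(pa$p_alpha, pa$wage, pa$conformity, mua,
                     g[ib], pb$wage, th, a_gives, g)
    ia <- .argmax_tie(ua, g, g[old[1L]])
    ub <- .util_grid(pb$p_alpha, pb$wage, pb$conformity, mub,
                     g[ia], pa$wage, th, b_gives, g)
    ib <- .argmax_tie(ub, g, g[old[2L]])
    if (ia == old[1L] && ib == old[2L]) { converged <- TRUE; break }
  }
  dir <- if (th == 0) "none" else if (theta_signed > 0) "A_to_B" else "B_to_A"
  brg <- bargain(g[ia], g[ib], th, dir)
  list(bargain = brg,
       utility_a = utility_member("A", brg, pa, pb, na),
       utility_b = utility_member("B", brg, pa, pb, nb),
       converged = converged, iterations = it)
}

#' Separate-spheres threat point
#'
#' Each member's bargaining power: its utility at the zero-transfer
#' equilibrium (norm penalties included, as in every utility evaluation).
#'
#' @inheritParams equilibrium_at_theta
#' @return A list with `utility_a`, `utility_b`, `bargain`, `converged`.
#' @export
threat_point <- function(household, norms, settings = solver_settings(),
                         start = NULL) {
  eq <- equilibrium_at_theta(household, 0, norms, settings, start)
  list(utility_a = eq$utility_a, utility_b = eq$utility_b,
       bargain = eq$bargain, converged = eq$converged)
}

#' Select the household bargain
#'
#' Evaluates the fixed-transfer equilibrium over the whole transfer grid in
#' both directions, then maximises the Nash product
#' `(U_A - U_A^s)(U_B - U_B^s)` over the bargains satisfying both
#' participation constraints `U >= U^s - constraint_tol`, where `U^s` are
#' the separate-spheres threat utilities. If no non-zero transfer strictly
#' improves the Nash product, the zero-transfer bargain is returned. Ties
#' break toward smaller transfer magnitude, then toward `prev$direction`.
#'
#' @inheritParams equilibrium_at_theta
#' @param prev optional list with `alpha_a`, `alpha_b`, `direction` from the
#'   previous step: starting point for every equilibrium iteration and
#'   tie-break preferences.
#' @return The selected [bargain()], with attributes `utilities` (members'
#'   utilities), `threat` (threat utilities), `nash_product`, and
#'   `converged` (whether all equilibrium iterations converged).
#' @export
select_bargain <- function(household, norms, settings = solver_settings(),
                           prev = NULL) {
  stopifnot(inherits(household, "hh_household"))
  if (is.null(prev)) prev <- list(alpha_a = 0.5, alpha_b = 0.5, direction = "none")
  start <- c(prev$alpha_a, prev$alpha_b)
  eq0 <- equilibrium_at_theta(household, 0, norms, settings, start)
  u_as <- eq0$utility_a; u_bs <- eq0$utility_b
  best <- eq0$bargain
  best_u <- c(eq0$utility_a, eq0$utility_b)
  np_best <- 0
  all_conv <- eq0$converged
  tg <- .grid(settings$theta_grid_step)
  tg <- tg[tg > 0]
  signs <- if (identical(prev$direction, "B_to_A")) c(-1, 1) else c(1, -1)
  for (th in tg) {
    for (s in signs) {
      eq <- equilibrium_at_theta(household, s * th, norms, settings, start)
      all_conv <- all_conv && eq$converged
      if (eq$utility_a >= u_as - settings$constraint_tol &&
          eq$utility_b >= u_bs - settings$constraint_tol) {
        np <- (eq$utility_a - u_as) * (eq$utility_b - u_bs)
        if (np > np_best) {
          np_best <- np
          best <- eq$bargain
          best_u <- c(eq$utility_a, eq$utility_b)
        }
      }
    }
  }
  attr(best, "utilities") <- c(a = best_u[1L], b = best_u[2L])
  attr(best, "threat") <- c(a = u_as, b = u_bs)
  attr(best, "nash_product") <- np_best
  attr(best, "converged") <- all_conv
  best
}

#' Brute-force bargain oracle
#'
#' Exhaustively evaluates the Nash objective over the joint
#' `(alpha_a, alpha_b, theta, direction)` grid, computing both members'
#' utilities directly at each candidate point (no best-response iteration
#' for the candidates; the zero-transfer threat point is still found by an
#' internal alternating maximisation). Intended for testing: it bounds the
#' main solver's optimality gap on coarse grids and refuses large ones.
#'
#' @inheritParams equilibrium_at_theta
#' @return The argmax [bargain()] with attributes `utilities`, `threat`,
#'   `nash_product`.
#' @export
brute_force_bargain <- function(household, norms,
                                settings = solver_settings(
                                  alpha_grid_step = 0.02,
                                  theta_grid_step = 0.05)) {
  stopifnot(inherits(household, "hh_household"))
  g <- .grid(settings$alpha_grid_step)
  tg <- .grid(settings$theta_grid_step)
  if (length(g) > 51L || length(tg) > 21L)
    stop("grid too large for brute force (max 51 allocation x 21 transfer points)",
         call. = FALSE)
  pa <- household$a; pb <- household$b
  na <- .norm_for(norms, pa); nb <- .norm_for(norms, pb)
  mua <- .full_means(na); mub <- .full_means(nb)

  # joint utility matrices (rows: alpha_a, cols: alpha_b) at (th, dir)
  umat <- function(th, dir) {
    priv_a_own <- pa$wage * g
    priv_b_own <- pb$wage * g
    pub <- sqrt(outer(1 - g, 1 - g, "+"))
    pen_a <- pa$conformity[["alpha"]] * (g - mua[["alpha"]])^2 +
             pa$conformity[["gamma"]] * ((1 - g) - mua[["gamma"]])^2 +
             pa$conformity[["theta"]] * (th - mua[["theta"]])^2
    pen_b <- pb$conformity[["alpha"]] * (g - mub[["alpha"]])^2 +
             pb$conformity[["gamma"]] * ((1 - g) - mub[["gamma"]])^2 +
             pb$conformity[["theta"]] * (th - mub[["theta"]])^2
    if (dir == "A_to_B") {
      priv_a <- matrix(priv_a_own * (1 - th), length(g), length(g))
      priv_b <- outer(th * priv_a_own, priv_b_own, "+")
    } else if (dir == "B_to_A") {
      priv_a <- outer(priv_a_own, th * priv_b_own, "+")
      priv_b <- matrix(priv_b_own * (1 - th), length(g), length(g), byrow = TRUE)
    } else {
      priv_a <- matrix(priv_a_own, length(g), length(g))
      priv_b <- matrix(priv_b_own, length(g), length(g), byrow = TRUE)
    }
    ua <- (pa$p_alpha * sqrt(priv_a) + pa$p_gamma * pub) * exp(-pen_a)
    ub <- (pb$p_alpha * sqrt(priv_b) + pb$p_gamma * pub) *
          matrix(exp(-pen_b), length(g), length(g), byrow = TRUE)
    list(ua = ua, ub = ub)
  }

  # threat point: independent alternating argmax at theta = 0
  u0 <- umat(0, "none")
  ia <- .snap(0.5, g); ib <- .snap(0.5, g)
  for (it in seq_len(settings$max_iterations)) {
    old <- c(ia, ib)
    ia <- .argmax_tie(u0$ua[, ib], g, g[old[1L]])
    ib <- .argmax_tie(u0$ub[ia, ], g, g[old[2L]])
    if (all(c(ia, ib) == old)) break
  }
  u_as <- u0$ua[ia, ib]; u_bs <- u0$ub[ia, ib]

  best <- bargain(g[ia], g[ib], 0, "none")
  best_u <- c(u_as, u_bs)
  np_best <- 0
  for (th in tg[tg > 0]) {
    for (dir in c("A_to_B", "B_to_A")) {
      m <- umat(th, dir)
      feas <- m$ua >= u_as - settings$constraint_tol &
              m$ub >= u_bs - settings$constraint_tol
      np <- (m$ua - u_as) * (m$ub - u_bs)
      np[!feas] <- -Inf
      mx <- max(np)
      if (mx > np_best) {
        idx <- which(np == mx, arr.ind = TRUE)[1L, ]
        np_best <- mx
        best <- bargain(g[idx[1L]], g[idx[2L]], th, dir)
        best_u <- c(m$ua[idx[1L], idx[2L]], m$ub[idx[1L], idx[2L]])
      }
    }
  }
  attr(best, "utilities") <- c(a = best_u[1L], b = best_u[2L])
  attr(best, "threat") <- c(a = u_as, b = u_bs)
  attr(best, "nash_product") <- np_best
  best
}
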