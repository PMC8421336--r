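# Population construction, seeded sampling, the time loop and the
# wage/conformity change event.

#' Experiment configuration
#'
#' Full specification of one simulation run. The default scenario: 100
#' two-agent households (200 agents), female wage 0.1 raised to `w_f_post`
#' after step `t_change`, male wage fixed at 0.6, run to step `t_end`.
#'
#' @param model `"ihm"` (household bargain), `"im"` (individuals) or
#'   `"um"` (unitary household).
#' @param condition `"mp"` (moderate preferences and conformity for all) or
#'   `"cm"` (male conformity redrawn from the high distribution at the wage
#'   change; under `um` both members).
#' @param n_agents even agent count (default 200).
#' @param t_change last pre-change step (default 25); the new wage and, under
#'   `cm`, the high conformity apply from step `t_change + 1`.
#' @param t_end final step (default 150).
#' @param w_m male wage (default 0.6).
#' @param w_f_pre,w_f_post female wage before / after the change.
#' @param seed integer seed; the only source of randomness (parameter
#'   sampling). Dynamics are deterministic.
#' @param solver [solver_settings()].
#' @param um_pref_rule unitary preference construction, see
#'   [um_household_prefs()].
#' @return An object of class `hh_config`.
#' @export
model_config <- function(model = c("ihm", "im", "um"),
                         condition = c("mp", "cm"),
                         n_agents = 200L, t_change = 25L, t_end = 150L,
                         w_m = 0.6, w_f_pre = 0.1, w_f_post = 0.6,
                         seed = 1L, solver = solver_settings(),
                         um_pref_rule = c("mean", "head_male")) {
  model <- match.arg(model)
  condition <- match.arg(condition)
  um_pref_rule <- match.arg(um_pref_rule)
  n_agents <- as.integer(n_agents)
  if (n_agents < 2L || n_agents %% 2L != 0L)
    stop("`n_agents` must be even and >= 2", call. = FALSE)
  if (!(t_change > 0 && t_change < t_end))
    stop("need 0 < t_change < t_end", call. = FALSE)
  for (w in c(w_m, w_f_pre, w_f_post))
    .check_scalar(w, "wage", 0, Inf, strict_lo = TRUE)
  stopifnot(inherits(solver, "hh_settings"))
  structure(list(model = model, condition = condition, n_agents = n_agents,
                 t_change = as.integer(t_change), t_end = as.integer(t_end),
                 w_m = w_m, w_f_pre = w_f_pre, w_f_post = w_f_post,
                 seed = as.integer(seed), solver = solver,
                 um_pref_rule = um_pref_rule),
            class = "hh_config")
}

#' Sample an agent population
#'
#' Draws preference weights and conformity weights from `U(0.3, 0.7)` for
#' all agents, and in addition pre-samples replacement high-conformity
#' weights from `U(2.5, 3.0)` (applied at the change event under the `cm`
#' condition). The first half of the agents are female, the second half
#' male; female `i` is paired with male `i` into household `i`. Draws are a
#' pure function of the seed and identical across model types and
#' conditions, so `Agent 1` carries the same attributes in every model.
#'
#' @param condition `"mp"` or `"cm"` (draws are identical; kept for the
#'   record).
#' @param n_agents even agent count.
#' @param seed integer seed.
#' @param w_f,w_m initial wages by gender.
#' @return A data.frame with one row per agent: `agent_id`, `gender`,
#'   `household_id`, `p_alpha`, `c_alpha`, `c_gamma`, `c_theta`, the
#'   `*_high` replacement weights, and `wage`.
#' @export
sample_parameters <- function(condition = c("mp", "cm"), n_agents = 200L,
                              seed = 1L, w_f = 0.1, w_m = 0.6) {
  condition <- match.arg(condition)
  n_agents <- as.integer(n_agents)
  if (n_agents < 2L || n_agents %% 2L != 0L)
    stop("`n_agents` must be even and >= 2", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n <- n_agents
  p_alpha <- runif(n, 0.3, 0.7)
  conf <- matrix(runif(3L * n, 0.3, 0.7), n, 3L)
  conf_high <- matrix(runif(3L * n, 2.5, 3.0), n, 3L)
  nh <- n %/% 2L
  pop <- data.frame(
    agent_id = seq_len(n),
    gender = rep(c("female", "male"), each = nh),
    household_id = rep(seq_len(nh), 2L),
    p_alpha = p_alpha,
    c_alpha = conf[, 1L], c_gamma = conf[, 2L], c_theta = conf[, 3L],
    c_alpha_high = conf_high[, 1L], c_gamma_high = conf_high[, 2L],
    c_theta_high = conf_high[, 3L],
    wage = rep(c(w_f, w_m), each = nh),
    stringsAsFactors = FALSE)
  attr(pop, "condition") <- condition
  pop
}

.agent_from_row <- function(row) {
  agent_params(row$agent_id, row$gender, row$p_alpha,
               c(alpha = row$c_alpha, gamma = row$c_gamma,
                 theta = row$c_theta),
               row$wage)
}

.rebuild_agents <- function(state, config) {
  n <- nrow(state$pop)
  nh <- n %/% 2L
  state$agents <- lapply(seq_len(n), function(i) .agent_from_row(state$pop[i, ]))
  if (config$model == "um") {
    state$households <- lapply(seq_len(nh), function(h)
      household(state$agents[[h]], state$agents[[nh + h]]))
    state$um_prefs <- lapply(state$households, function(hh)
      um_household_prefs(hh$a, hh$b, config$um_pref_rule))
  }
  state
}

#' Initialise the simulation state
#'
#' All agents start at the gender-role allocations (male `alpha = 0.8`,
#' female `alpha = 0.2`), zero transfers, and norm means computed from those
#' allocations (`mu_theta = 0`). The household model's norms track
#' `alpha`, `gamma`, `theta`; the comparison models' track `alpha`, `gamma`.
#'
#' @param config [model_config()].
#' @return A state list (step 0) consumed by [sim_step()].
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "hh_config"))
  pop <- sample_parameters(config$condition, config$n_agents, config$seed,
                           config$w_f_pre, config$w_m)
  n <- nrow(pop)
  nh <- n %/% 2L
  alpha <- ifelse(pop$gender == "male", 0.8, 0.2)
  with_theta <- config$model == "ihm"
  mk_norm <- function(id, idx) {
    m <- c(alpha = mean(alpha[idx]), gamma = mean(1 - alpha[idx]))
    if (with_theta) m <- c(m, theta = 0)
    norm_state(id, m)
  }
  state <- list(step = 0L, pop = pop, alpha = alpha,
                theta = numeric(nh), dir = integer(nh),
                norms = list(female = mk_norm("female", seq_len(nh)),
                             male = mk_norm("male", nh + seq_len(nh))),
                records = vector("list", config$t_end),
                nonconv = integer(0), changed = FALSE)
  .rebuild_agents(state, config)
}

#' Apply the wage (and conformity) change event
#'
#' Sets the female wage to `w_f_post`; under the `cm` condition replaces
#' conformity weights with the pre-sampled high draws (males under `ihm`
#' and `im`; both members under `um`). Must be called when
#' `state$step == config$t_change`.
#'
#' @param state simulation state at step `t_change`.
#' @param config [model_config()].
#' @return The updated state.
#' @export
apply_change_event <- function(state, config) {
  if (state$step != config$t_change)
    stop("change event must be applied at step t_change = ", config$t_change,
         " (state is at step ", state$step, ")", call. = FALSE)
  fem <- state$pop$gender == "female"
  state$pop$wage[fem] <- config$w_f_post
  if (config$condition == "cm") {
    idx <- if (config$model == "um") rep(TRUE, nrow(state$pop)) else !fem
    state$pop$c_alpha[idx] <- state$pop$c_alpha_high[idx]
    state$pop$c_gamma[idx] <- state$pop$c_gamma_high[idx]
    state$pop$c_theta[idx] <- state$pop$c_theta_high[idx]
  }
  state$changed <- TRUE
  .rebuild_agents(state, config)
}

#' Advance the simulation by one step
#'
#' All households (or agents) decide against the norm means frozen at the
#' end of the previous step, so the processing order is irrelevant; the
#' gender-population means are then updated from the new behaviours.
#'
#' @param state simulation state.
#' @param config [model_config()].
#' @return The updated state; the per-agent record of the step is appended
#'   to `state$records`.
#' @export
sim_step <- function(state, config) {
  t <- state$step + 1L
  pop <- state$pop
  n <- nrow(pop)
  nh <- n %/% 2L
  fidx <- seq_len(nh)
  midx <- nh + fidx
  s <- config$solver
  mu_f <- state$norms$female$means
  mu_m <- state$norms$male$means
  new_alpha <- state$alpha
  util <- numeric(n)
  theta <- state$theta
  dir <- state$dir
  nonconv <- 0L

  if (config$model == "ihm") {
    res <- ihm_step_cpp(
      pop$p_alpha[fidx],
      as.matrix(pop[fidx, c("c_alpha", "c_gamma", "c_theta")]),
      pop$wage[fidx], unname(mu_f[c("alpha", "gamma", "theta")]),
      pop$p_alpha[midx],
      as.matrix(pop[midx, c("c_alpha", "c_gamma", "c_theta")]),
      pop$wage[midx], unname(mu_m[c("alpha", "gamma", "theta")]),
      state$alpha[fidx], state$alpha[midx], state$dir,
      s$alpha_grid_step, s$theta_grid_step, s$max_iterations,
      s$constraint_tol)
    new_alpha[fidx] <- res[, 1L]
    new_alpha[midx] <- res[, 2L]
    theta <- res[, 3L]
    dir <- as.integer(res[, 4L])
    util[fidx] <- res[, 5L]
    util[midx] <- res[, 6L]
    nonconv <- sum(res[, 8L])
  } else if (config$model == "im") {
    for (i in seq_len(n)) {
      prm <- state$agents[[i]]
      nrm <- state$norms[[prm$gender]]
      al <- im_solve(prm, nrm, s, prev_alpha = state$alpha[i])
      new_alpha[i] <- al$alpha
      mu <- .full_means(nrm)
      pen <- prm$conformity[["alpha"]] * (al$alpha - mu[["alpha"]])^2 +
             prm$conformity[["gamma"]] * (al$gamma - mu[["gamma"]])^2
      util[i] <- (prm$p_alpha * sqrt(prm$wage * al$alpha) +
                  prm$p_gamma * sqrt(al$gamma)) * exp(-pen)
    }
  } else { # um
    for (h in fidx) {
      res <- um_solve(state$households[[h]], state$um_prefs[[h]],
                      state$norms, s,
                      prev = c(state$alpha[h], state$alpha[nh + h]))
      new_alpha[h] <- res$alloc_a$alpha
      new_alpha[nh + h] <- res$alloc_b$alpha
      util[h] <- res$utility
      util[nh + h] <- res$utility
    }
  }

  mu_used_a <- ifelse(pop$gender == "female", mu_f[["alpha"]], mu_m[["alpha"]])
  mu_used_g <- ifelse(pop$gender == "female", mu_f[["gamma"]], mu_m[["gamma"]])
  mu_used_t <- if (config$model == "ihm")
    ifelse(pop$gender == "female", mu_f[["theta"]], mu_m[["theta"]]) else NA_real_
  theta_agent <- if (config$model == "ihm") theta[pop$household_id] else
    numeric(n)
  dir_agent <- if (config$model == "ihm") dir[pop$household_id] else integer(n)

  state$records[[t]] <- cbind(t = t, alpha = new_alpha, gamma = 1 - new_alpha,
                              theta = theta_agent, dir = dir_agent,
                              utility = util, norm_mu_alpha = mu_used_a,
                              norm_mu_gamma = mu_used_g,
                              norm_mu_theta = mu_used_t)

  with_theta <- config$model == "ihm"
  mk <- function(id, idx) {
    m <- c(alpha = mean(new_alpha[idx]), gamma = mean(1 - new_alpha[idx]))
    if (with_theta) m <- c(m, theta = mean(theta))
    norm_state(id, m)
  }
  state$norms <- list(female = mk("female", fidx), male = mk("male", midx))
  state$alpha <- new_alpha
  state$theta <- theta
  state$dir <- dir
  state$nonconv <- c(state$nonconv, nonconv)
  state$step <- t
  state
}

#' Run a full simulation
#'
#' Runs steps `1..t_end`, applying the change event after step `t_change`
#' so that step `t_change + 1` is the first decision under the new wage.
#' Deterministic given the config (the seed only drives parameter
#' sampling).
#'
#' @param config [model_config()].
#' @return A tidy data.frame (class `hh_series`) with one row per agent per
#'   step: `model`, `condition`, `seed`, `w_f_post`, `t`, `agent_id`,
#'   `household_id`, `gender`, `alpha`, `gamma`, `theta`,
#'   `theta_direction` (`"f_to_m"`, `"m_to_f"` or `"none"`), `utility`, and
#'   the norm means in force that step. Attributes: `nonconv` (count of
#'   non-converged bargain iterations per step) and `stabilization` (max
#'   allocation change over the five steps before the change).
#' @export
run_model <- function(config) {
  stopifnot(inherits(config, "hh_config"))
  state <- init_population(config)
  for (t in seq_len(config$t_end)) {
    state <- sim_step(state, config)
    if (t == config$t_change) state <- apply_change_event(state, config)
  }
  rec <- do.call(rbind, state$records)
  n <- config$n_agents
  out <- data.frame(
    model = config$model, condition = config$condition, seed = config$seed,
    w_f_post = config$w_f_post,
    t = as.integer(rec[, "t"]),
    agent_id = rep(state$pop$agent_id, config$t_end),
    household_id = rep(state$pop$household_id, config$t_end),
    gender = rep(state$pop$gender, config$t_end),
    alpha = rec[, "alpha"], gamma = rec[, "gamma"],
    theta = rec[, "theta"],
    theta_direction = c("m_to_f", "none", "f_to_m")[rec[, "dir"] + 2L],
    utility = rec[, "utility"],
    norm_mu_alpha = rec[, "norm_mu_alpha"],
    norm_mu_gamma = rec[, "norm_mu_gamma"],
    norm_mu_theta = rec[, "norm_mu_theta"],
    stringsAsFactors = FALSE)
  w0 <- max(2L, config$t_change - 4L)
  amat <- matrix(rec[, "alpha"], nrow = n)
  stab <- max(abs(amat[, w0:config$t_change, drop = FALSE] -
                  amat[, (w0 - 1L):(config$t_change - 1L), drop = FALSE]))
  attr(out, "nonconv") <- state$nonconv
  attr(out, "stabilization") <- stab
  class(out) <- c("hh_series", class(out))
  out
}
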