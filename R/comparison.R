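# Individual-based (im) and unitary-household (um) comparison models.
# Both share the activities and the norm mechanism of the household model
# but have no internal transfer; the norm components are alpha and gamma.

#' Individual-model time allocation
#'
#' A lone agent maximises
#' `[p_alpha * sqrt(wage * alpha) + p_gamma * sqrt(1 - alpha)] * exp(-N)`
#' over its own allocation grid; the public output uses own time only, and
#' `N` sums conformity-weighted squared distances for `alpha` and `gamma`.
#' With zero conformity the continuous maximiser has the closed form
#' `alpha* = p^2 w / ((1-p)^2 + p^2 w)`.
#'
#' @param params [agent_params()].
#' @param norm the agent's gender-population [norm_state()] (components
#'   `alpha`, `gamma`).
#' @param settings [solver_settings()].
#' @param prev_alpha previous allocation for tie-breaking, or `NULL`.
#' @return An [allocation()].
#' @export
im_solve <- function(params, norm, settings = solver_settings(),
                     prev_alpha = NULL) {
  stopifnot(inherits(params, "hh_agent"), inherits(norm, "hh_norm"))
  g <- .grid(settings$alpha_grid_step)
  mu <- .full_means(norm)
  pen <- params$conformity[["alpha"]] * (g - mu[["alpha"]])^2 +
         params$conformity[["gamma"]] * ((1 - g) - mu[["gamma"]])^2
  u <- (params$p_alpha * sqrt(params$wage * g) +
        params$p_gamma * sqrt(1 - g)) * exp(-pen)
  allocation(g[.argmax_tie(u, g, prev_alpha)])
}

#' Unitary household preferences
#'
#' Builds the single preference set of a unitary household from its members:
#' either the member mean (default) or the male head's preferences.
#'
#' @param params_a,params_b member [agent_params()].
#' @param rule `"mean"` or `"head_male"`.
#' @return A list with `p_alpha_h`, `p_gamma_h`.
#' @export
um_household_prefs <- function(params_a, params_b,
                               rule = c("mean", "head_male")) {
  rule <- match.arg(rule)
  p <- switch(rule,
    mean = (params_a$p_alpha + params_b$p_alpha) / 2,
    head_male = {
      if (params_a$gender == "male") params_a$p_alpha
      else if (params_b$gender == "male") params_b$p_alpha
      else stop("no male member for rule \"head_male\"", call. = FALSE)
    })
  list(p_alpha_h = p, p_gamma_h = 1 - p)
}

#' Unitary-household time allocation
#'
#' A single household utility pools the members' private outputs (separate
#' wages are retained, preserving gendered payoffs) and maximises
#' `p_alpha_h * sqrt(w_a a_a + w_b a_b) + p_gamma_h * sqrt(g_a + g_b)`
#' times `exp(-)` the household norm penalty: each member's
#' conformity-weighted distances to its own gender's `alpha`/`gamma` means,
#' summed over the two members. The search is the joint allocation grid;
#' ties break toward the previous step's allocations, then toward the
#' lexicographically smaller `(alpha_a, alpha_b)`.
#'
#' @param household a [household()].
#' @param prefs [um_household_prefs()]; defaults to the member mean.
#' @param norms list of [norm_state()] keyed by gender.
#' @param settings [solver_settings()].
#' @param prev optional numeric `c(alpha_a, alpha_b)` for tie-breaking.
#' @return A list with `alloc_a`, `alloc_b` ([allocation()]s) and `utility`
#'   (the household utility).
#' @export
um_solve <- function(household, prefs = NULL, norms,
                     settings = solver_settings(), prev = NULL) {
  stopifnot(inherits(household, "hh_household"))
  pa <- household$a; pb <- household$b
  if (is.null(prefs)) prefs <- um_household_prefs(pa, pb)
  mua <- .full_means(.norm_for(norms, pa))
  mub <- .full_means(.norm_for(norms, pb))
  g <- .grid(settings$alpha_grid_step)
  n <- length(g)
  pen_a <- pa$conformity[["alpha"]] * (g - mua[["alpha"]])^2 +
           pa$conformity[["gamma"]] * ((1 - g) - mua[["gamma"]])^2
  pen_b <- pb$conformity[["alpha"]] * (g - mub[["alpha"]])^2 +
           pb$conformity[["gamma"]] * ((1 - g) - mub[["gamma"]])^2
  priv <- sqrt(outer(pa$wage * g, pb$wage * g, "+"))
  pub <- sqrt(outer(1 - g, 1 - g, "+"))
  u <- (prefs$p_alpha_h * priv + prefs$p_gamma_h * pub) *
       outer(exp(-pen_a), exp(-pen_b))
  m <- max(u)
  cand <- which(u >= m - 1e-12 * max(1, m))
  if (length(cand) > 1L) {
    ia <- (cand - 1L) %% n + 1L
    ib <- (cand - 1L) %/% n + 1L
    if (!is.null(prev)) {
      d <- abs(g[ia] - prev[1L]) + abs(g[ib] - prev[2L])
      keep <- d <= min(d) + 1e-15
      cand <- cand[keep]; ia <- ia[keep]; ib <- ib[keep]
    }
    o <- order(g[ia], g[ib])
    cand <- cand[o[1L]]
  }
  ia <- (cand - 1L) %% n + 1L
  ib <- (cand - 1L) %/% n + 1L
  list(alloc_a = allocation(g[ia]), alloc_b = allocation(g[ib]),
       utility = u[cand])
}
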