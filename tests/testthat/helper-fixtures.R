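# Shared fixtures and independent oracles.

# An agent with all conformity weights zero (pure goods maximiser).
plain_agent <- function(id, gender, p_alpha, wage) {
  agent_params(id, gender, p_alpha,
               c(alpha = 0, gamma = 0, theta = 0), wage)
}

conf_agent <- function(id, gender, p_alpha, wage, c_all) {
  agent_params(id, gender, p_alpha,
               c(alpha = c_all, gamma = c_all, theta = c_all), wage)
}

# Norm pair (female/male) carrying all three components.
norm_pair <- function(mu_f = c(alpha = 0.2, gamma = 0.8, theta = 0),
                      mu_m = c(alpha = 0.8, gamma = 0.2, theta = 0)) {
  list(female = norm_state("female", mu_f),
       male = norm_state("male", mu_m))
}

# Independent continuous best-response oracle: direct maximisation of the
# member's utility in alpha via stats::optimize (penalty terms included).
continuous_best_response <- function(p_alpha, wage, conf, mu, alpha_partner,
                                     wage_partner, theta_signed, is_a) {
  th <- abs(theta_signed)
  gives <- th > 0 && (is_a == (theta_signed > 0))
  f <- function(a) {
    priv <- if (th == 0) wage * a
            else if (gives) wage * a * (1 - th)
            else wage * a + th * wage_partner * alpha_partner
    pub <- (1 - a) + (1 - alpha_partner)
    pen <- conf[["alpha"]] * (a - mu[["alpha"]])^2 +
           conf[["gamma"]] * ((1 - a) - mu[["gamma"]])^2 +
           conf[["theta"]] * (th - mu[["theta"]])^2
    (p_alpha * sqrt(priv) + (1 - p_alpha) * sqrt(pub)) * exp(-pen)
  }
  cand <- stats::optimize(f, c(0, 1), maximum = TRUE)
  # compare against the endpoints (optimize can miss corner maxima)
  vals <- c(f(0), cand$objective, f(1))
  c(0, cand$maximum, 1)[which.max(vals)]
}

# Closed-form individual optimum at zero conformity.
im_closed_form <- function(p, w) p^2 * w / ((1 - p)^2 + p^2 * w)

# Random household fixture with moderate parameters.
random_household <- function(id) {
  a <- agent_params(2 * id - 1, "female", runif(1, 0.3, 0.7),
                    c(alpha = runif(1, 0, 0.7), gamma = runif(1, 0, 0.7),
                      theta = runif(1, 0, 0.7)),
                    runif(1, 0.1, 1.1))
  b <- agent_params(2 * id, "male", runif(1, 0.3, 0.7),
                    c(alpha = runif(1, 0, 0.7), gamma = runif(1, 0, 0.7),
                      theta = runif(1, 0, 0.7)),
                    runif(1, 0.1, 1.1))
  household(a, b)
}

random_norms <- function() {
  norm_pair(c(alpha = runif(1), gamma = runif(1), theta = runif(1, 0, 0.5)),
            c(alpha = runif(1), gamma = runif(1), theta = runif(1, 0, 0.5)))
}
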