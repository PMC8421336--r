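# Wage-sweep harness and behaviour-change analytics.

#' Default female post-change wage grid
#'
#' Denser below 0.3 to resolve the low-wage regime, then 0.1 increments up
#' to 1.1 (well above the male wage of 0.6).
#' @export
default_wage_grid <- function() {
  c(0.15, 0.2, 0.25, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.1)
}

#' Per-agent behaviour change
#'
#' Change in time spent on the private activity between the step after the
#' wage change and the simulation end: `alpha(t_to) - alpha(t_from)`.
#'
#' @param series an `hh_series` from [run_model()].
#' @param t_from,t_to step indices (defaults 26 and 150).
#' @return A data.frame: `agent_id`, `household_id`, `gender`,
#'   `delta_alpha`.
#' @export
behavior_change <- function(series, t_from = 26L, t_to = 150L) {
  stopifnot(is.data.frame(series))
  a0 <- series[series$t == t_from, ]
  a1 <- series[series$t == t_to, ]
  if (nrow(a0) == 0L || nrow(a1) == 0L)
    stop("steps ", t_from, " and/or ", t_to, " not present in series",
         call. = FALSE)
  a1 <- a1[match(a0$agent_id, a1$agent_id), ]
  data.frame(agent_id = a0$agent_id, household_id = a0$household_id,
             gender = a0$gender, delta_alpha = a1$alpha - a0$alpha,
             stringsAsFactors = FALSE)
}

#' Run the female wage sweep
#'
#' Runs one simulation per post-change wage (shared seed, so the pre-change
#' segment is identical across wages) and assembles per-agent behaviour
#' changes.
#'
#' @param config base [model_config()]; `w_f_post` is overridden.
#' @param w_f_grid vector of post-change wages (default
#'   [default_wage_grid()]).
#' @param keep_series if `TRUE`, attach the full series list as an
#'   attribute.
#' @return A data.frame (class `hh_sweep`): `model`, `condition`, `gender`,
#'   `w_f_post`, `agent_id`, `delta_alpha`.
#' @export
wage_sweep <- function(config, w_f_grid = default_wage_grid(),
                       keep_series = FALSE) {
  stopifnot(inherits(config, "hh_config"))
  if (length(w_f_grid) == 0L || any(!is.finite(w_f_grid)) || any(w_f_grid <= 0))
    stop("`w_f_grid` must be non-empty positive wages", call. = FALSE)
  series_list <- list()
  rows <- lapply(w_f_grid, function(w) {
    cfg <- config
    cfg$w_f_post <- w
    ser <- run_model(cfg)
    if (keep_series) series_list[[as.character(w)]] <<- ser
    bc <- behavior_change(ser, config$t_change + 1L, config$t_end)
    data.frame(model = config$model, condition = config$condition,
               gender = bc$gender, w_f_post = w, agent_id = bc$agent_id,
               delta_alpha = bc$delta_alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  if (keep_series) attr(out, "series") <- series_list
  class(out) <- c("hh_sweep", class(out))
  out
}

#' Aggregate a sweep by gender and wage
#'
#' @param sweep an `hh_sweep`.
#' @return Mean and variance of `delta_alpha` per `(gender, w_f_post)`.
#' @export
summarize_sweep <- function(sweep) {
  stopifnot(is.data.frame(sweep))
  agg <- aggregate(delta_alpha ~ gender + w_f_post, data = sweep,
                   FUN = function(x) c(mean = mean(x), var = stats::var(x)))
  data.frame(gender = agg$gender, w_f_post = agg$w_f_post,
             mean_delta = agg$delta_alpha[, "mean"],
             var_delta = agg$delta_alpha[, "var"],
             stringsAsFactors = FALSE)
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (length >= 3, non-degenerate).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("`x` and `y` must be equal-length numerics", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in `x` or `y`", call. = FALSE)
  cor(x, y)
}

#' Workforce-transition threshold wage
#'
#' Operationalises "transitions suddenly at some wage": the largest grid
#' wage whose mean absolute behaviour change for the gender stays below
#' `rel_threshold` times the maximum mean absolute change over the grid.
#'
#' @param sweep an `hh_sweep` (or compatible data.frame).
#' @param gender `"female"` or `"male"`.
#' @param rel_threshold relative flatness threshold (default 0.05).
#' @return A list: `wage`; `no_transition` (`TRUE` when the response is
#'   flat everywhere, in which case `wage` is the largest grid value);
#'   `below_grid` (`TRUE` when even the smallest grid wage already responds,
#'   in which case `wage` is the smallest grid value); and `curve`, the
#'   mean |delta| per wage.
#' @export
transition_threshold <- function(sweep, gender, rel_threshold = 0.05) {
  stopifnot(is.data.frame(sweep))
  g <- sweep[sweep$gender == gender, ]
  if (nrow(g) == 0L) stop("no rows for gender \"", gender, "\"", call. = FALSE)
  # per-wage mean change, then its magnitude
  agg <- aggregate(delta_alpha ~ w_f_post, data = g, FUN = mean)
  curve <- data.frame(w_f_post = agg$w_f_post,
                      mean_abs_delta = abs(agg$delta_alpha))
  curve <- curve[order(curve$w_f_post), ]
  m_max <- max(curve$mean_abs_delta)
  if (m_max == 0)
    return(list(wage = max(curve$w_f_post), no_transition = TRUE,
                below_grid = FALSE, curve = curve))
  flat <- curve$w_f_post[curve$mean_abs_delta < rel_threshold * m_max]
  if (length(flat) == 0L)
    return(list(wage = min(curve$w_f_post), no_transition = FALSE,
                below_grid = TRUE, curve = curve))
  list(wage = max(flat), no_transition = FALSE, below_grid = FALSE,
       curve = curve)
}

#' Welch's two-sample comparison
#'
#' Unequal-variance t test between two groups of behaviour changes.
#'
#' @param deltas_low,deltas_high numeric vectors, each of length >= 2.
#' @return A list: `statistic`, `p_value`, `df`, `mean_low`, `mean_high`.
#' @export
compare_groups <- function(deltas_low, deltas_high) {
  if (length(deltas_low) < 2L || length(deltas_high) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (sd(deltas_low) == 0 && sd(deltas_high) == 0)
    stop("both groups are degenerate (zero variance)", call. = FALSE)
  tt <- t.test(deltas_low, deltas_high, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_low = mean(deltas_low),
       mean_high = mean(deltas_high))
}
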