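# Edge-strength distribution models and condition contrasts.

.edge_models <- c("power_law", "exponential", "truncated_power_law", "gamma")

edge_model_fun <- function(model) {
  switch(model,
    power_law = function(x, p) p["a"] * x^p["b"],
    exponential = function(x, p) p["a"] * exp(-p["c"] * x) + p["d"],
    truncated_power_law = function(x, p) p["a"] * x^p["b"] * exp(-p["c"] * x),
    gamma = function(x, p) (p["a"] / (gamma(p["b"]) * p["c"]^p["b"])) *
      x^(p["b"] - 1) * exp(-x / p["c"]))
}

edge_model_npar <- c(power_law = 2L, exponential = 3L,
                     truncated_power_law = 3L, gamma = 3L)

#' Fit closed-form models to a binned edge-strength distribution
#'
#' Bins the edge strengths (default: width 0.05 over \[0.35, 1\]) into a
#' histogram normalized to fractions of the total, then least-squares fits
#' four curves: a power law `a*x^b`, an exponential `a*exp(-c*x) + d`, a
#' truncated power law `a*x^b*exp(-c*x)` and a gamma curve
#' `(a/(Gamma(b)*c^b))*x^(b-1)*exp(-x/c)` (shape `b`, scale `c`). Model
#' quality is ranked by `AIC = n*log(RSS/n) + 2*k` (least-squares surrogate;
#' `k` = parameter count; small-sample AICc available via `aicc = TRUE`).
#' Models with more parameters than nonempty bins, or that fail to converge,
#' are excluded from the ranking (recorded as failed).
#'
#' @param strengths numeric vector of edge strengths (e.g. the `sttc` column
#'   of a graph's edges).
#' @param bin histogram bin width.
#' @param range two-element strength range.
#' @param aicc use the small-sample corrected criterion.
#' @return object of class `edge_fit_result`: per-model list with `params`,
#'   `rss`, `aic`, `converged`, plus `best` (model name), `bin_mids`,
#'   `fractions`, `bin_edges`.
#' @export
fit_edge_distributions <- function(strengths, bin = 0.05, range = c(0.35, 1.0),
                                   aicc = FALSE) {
  strengths <- strengths[is.finite(strengths) &
                           strengths >= range[1] & strengths <= range[2]]
  breaks <- seq(range[1], range[2], by = bin)
  if (breaks[length(breaks)] < range[2] - bin * 1e-9)
    breaks <- c(breaks, range[2])
  h <- graphics::hist(strengths, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  y <- if (sum(h$counts)) h$counts / sum(h$counts) else h$counts * 0
  x <- h$mids
  n_nonempty <- sum(y > 0)
  n_bins <- length(y)
  mu <- if (length(strengths)) mean(strengths) else NA_real_
  v <- if (length(strengths) > 1) stats::var(strengths) else NA_real_
  starts <- list(
    power_law = c(a = max(y, 1e-3), b = -1),
    exponential = c(a = max(y, 1e-3), c = 1 / max(mu, 1e-3), d = min(y)),
    truncated_power_law = c(a = max(y, 1e-3), b = 0.5, c = 1 / max(mu, 1e-3)),
    gamma = {
      b0 <- if (is.finite(v) && v > 0) max(mu^2 / v, 0.1) else 1
      c0 <- if (is.finite(v) && v > 0) max(v / mu, 1e-3) else max(mu, 1e-3)
      c(a = bin, b = b0, c = c0)
    })
  fits <- lapply(.edge_models, function(m) {
    k <- edge_model_npar[[m]]
    if (n_nonempty <= k)
      return(list(model = m, converged = FALSE,
                  reason = sprintf("%d nonempty bins for a %d-parameter model",
                                   n_nonempty, k)))
    fn <- edge_model_fun(m)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[m]],
                         fn = function(p) y - fn(x, p),
                         control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$par)))
      return(list(model = m, converged = FALSE, reason = "no convergence"))
    rss <- sum(fit$fvec^2)
    aic <- n_bins * log(max(rss, 1e-300) / n_bins) + 2 * k
    if (aicc) aic <- aic + 2 * k * (k + 1) / max(n_bins - k - 1, 1)
    list(model = m, converged = TRUE, params = fit$par, rss = rss, aic = aic)
  })
  names(fits) <- .edge_models
  aics <- vapply(fits, function(f) if (isTRUE(f$converged)) f$aic else Inf,
                 numeric(1))
  best <- if (any(is.finite(aics))) names(which.min(aics)) else NA_character_
  structure(list(fits = fits, best = best, bin_mids = x, fractions = y,
                 bin_edges = breaks, n_edges = length(strengths)),
            class = "edge_fit_result")
}

#' @export
print.edge_fit_result <- function(x, ...) {
  cat(sprintf("edge_fit_result: %d edges in %d bins; best model: %s\n",
              x$n_edges, length(x$bin_mids), x$best))
  for (m in names(x$fits)) {
    f <- x$fits[[m]]
    if (isTRUE(f$converged)) {
      cat(sprintf("  %-20s AIC %8.2f  params: %s\n", m, f$aic,
                  paste(sprintf("%s=%.3g", names(f$params), f$params),
                        collapse = ", ")))
    } else {
      cat(sprintf("  %-20s failed (%s)\n", m, f$reason))
    }
  }
  invisible(x)
}

#' Fractional difference curve between two fitted gamma models
#'
#' `(f_b - f_a) / (f_b + f_a)` evaluated on the bin grid, from the two
#' conditions' gamma-curve fits; positive values mean condition b holds a
#' larger fraction of edges at that strength.
#'
#' @param fit_a,fit_b [fit_edge_distributions] results (condition a =
#'   reference, e.g. control).
#' @param model which fitted model to compare (default `"gamma"`).
#' @return data.frame with `strength`, `f_a`, `f_b`, `fractional_difference`.
#' @export
edge_fit_fractional_difference <- function(fit_a, fit_b, model = "gamma") {
  fa <- fit_a$fits[[model]]
  fb <- fit_b$fits[[model]]
  if (!isTRUE(fa$converged) || !isTRUE(fb$converged))
    stopf("model '%s' did not converge in both conditions", model)
  x <- fit_a$bin_mids
  fn <- edge_model_fun(model)
  ya <- fn(x, fa$params)
  yb <- fn(x, fb$params)
  den <- ya + yb
  fd <- ifelse(den == 0, 0, (yb - ya) / den)
  data.frame(strength = x, f_a = ya, f_b = yb, fractional_difference = fd)
}

#' Shared, silenced and induced edge sets between two conditions
#'
#' Set operations on directed `(source, target)` pairs: `shared` edges are
#' present in both graphs, `silenced` only in the first (shut down in the
#' second condition), `induced` only in the second. Fractions are relative
#' to the union. Strength distributions per set use each graph's own STTC
#' values; the two conditions' overall edge-strength distributions are also
#' compared by a two-sample KS test (the stability analysis reuses this with
#' two time points of the same condition).
#'
#' @param graph_a,graph_b [build_graph] results over the same unit identity
#'   space.
#' @return list with `shared`, `silenced`, `induced` (data.frames with
#'   source, target, strength), `fractions`, `ks` (statistic + p), and
#'   `edge_density_change` (percent, b vs a).
#' @export
compare_edge_sets <- function(graph_a, graph_b) {
  key <- function(e) paste(e$source, e$target, sep = "->")
  ka <- key(graph_a$edges)
  kb <- key(graph_b$edges)
  pick <- function(graph, keys, from) {
    e <- graph$edges[key(graph$edges) %in% keys, c("source", "target", "sttc")]
    names(e)[3] <- "strength"
    rownames(e) <- NULL
    e
  }
  shared_keys <- intersect(ka, kb)
  out <- list(
    shared = pick(graph_a, shared_keys),
    silenced = pick(graph_a, setdiff(ka, kb)),
    induced = pick(graph_b, setdiff(kb, ka)))
  n_union <- length(union(ka, kb))
  out$fractions <- if (n_union) c(shared = length(shared_keys) / n_union,
                                  silenced = length(setdiff(ka, kb)) / n_union,
                                  induced = length(setdiff(kb, ka)) / n_union)
  else c(shared = NA_real_, silenced = NA_real_, induced = NA_real_)
  out$ks <- if (nrow(graph_a$edges) >= 2 && nrow(graph_b$edges) >= 2) {
    ks <- suppressWarnings(stats::ks.test(graph_a$edges$sttc, graph_b$edges$sttc))
    list(statistic = unname(ks$statistic), p_value = ks$p.value)
  } else list(statistic = NA_real_, p_value = NA_real_)
  out$edge_density_change <- if (graph_a$edge_density > 0)
    100 * (graph_b$edge_density - graph_a$edge_density) / graph_a$edge_density
  else NA_real_
  out
}
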