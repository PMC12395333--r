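# Resistance-cost records, the exponential+Gaussian mixture model, its
# maximum-likelihood fit, cost quantiles, and confidence intervals.

#' Construct or validate a table of resistance-cost records
#'
#' @param cost numeric vector of resistance costs (fractions; may be
#'   negative), or a data frame with at least a `cost` column.
#' @param localization `"plasmid"` or `"chromosome"` per record (recycled).
#' @param genus,antibiotic,source_doi optional metadata (recycled).
#' @return a data frame of class `cost_records`.
#' @export
cost_records <- function(cost, localization = "plasmid", genus = NA_character_,
                         antibiotic = NA_character_, source_doi = NA_character_) {
  if (is.data.frame(cost)) {
    df <- cost
    if (!"cost" %in% names(df)) stop_input("data frame needs a 'cost' column")
    if (!"localization" %in% names(df)) df$localization <- localization
  } else {
    n <- length(cost)
    df <- data.frame(cost = as.numeric(cost),
                     localization = rep_len(localization, n),
                     genus = rep_len(genus, n),
                     antibiotic = rep_len(antibiotic, n),
                     source_doi = rep_len(source_doi, n),
                     stringsAsFactors = FALSE)
  }
  if (any(!is.finite(df$cost))) stop_input("costs must be finite")
  bad <- setdiff(unique(df$localization), c("plasmid", "chromosome"))
  if (length(bad) > 0)
    stop_input("localization must be 'plasmid' or 'chromosome', got: ",
               paste(bad, collapse = ", "))
  class(df) <- c("cost_records", "data.frame")
  df
}

#' Remove outlying cost records
#'
#' Drops records with `|cost|` strictly above the threshold; a record at
#' exactly the threshold is retained.
#'
#' @param records a [cost_records()] table or data frame with a `cost`
#'   column.
#' @param threshold absolute-cost bound (default 0.25).
#' @return filtered records; the number removed is attached as attribute
#'   `n_removed`.
#' @examples
#' r <- cost_records(c(0.1, 0.3, -0.26))
#' nrow(filter_outliers(r))  # 1
#' @export
filter_outliers <- function(records, threshold = 0.25) {
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  keep <- abs(records$cost) <= threshold
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Exponential + Gaussian mixture model of resistance costs
#'
#' Density `w * Exp(rate)` on positive costs plus `(1 - w) * N(0, sigma)`:
#' the exponential component carries the actual, strictly positive cost of
#' resistance; the zero-centred Gaussian absorbs measurement noise and
#' fitness alterations not attributable to resistance (including the
#' negative costs seen in about 10% of reports). The Gaussian mean is
#' fixed at zero by construction.
#'
#' @param w weight of the exponential component, in (0, 1).
#' @param rate exponential rate (per unit cost, > 0).
#' @param sigma Gaussian standard deviation (> 0).
#' @param loglik,n,convergence optional fit metadata.
#' @return an object of class `cost_mixture_model`.
#' @export
cost_mixture_model <- function(w, rate, sigma, loglik = NA_real_,
                               n = NA_integer_, convergence = NULL) {
  check_number(w, "w", lower = 0, upper = 1, strict_lower = TRUE,
               strict_upper = TRUE)
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  structure(list(w = w, rate = rate, sigma = sigma, loglik = loglik,
                 n = n, convergence = convergence),
            class = "cost_mixture_model")
}

#' @export
print.cost_mixture_model <- function(x, ...) {
  cat(sprintf(
    "Cost mixture model: w = %.3f, rate = %.3f (exp. median %.3g), sigma = %.4f%s\n",
    x$w, x$rate, log(2) / x$rate, x$sigma,
    if (is.finite(x$loglik)) sprintf(", loglik = %.2f (n = %d)", x$loglik, x$n)
    else ""))
  invisible(x)
}

#' Mixture density
#'
#' @param model a [cost_mixture_model()].
#' @param x cost value(s).
#' @return density at `x`.
#' @export
mixture_density <- function(model, x) {
  stopifnot(inherits(model, "cost_mixture_model"))
  model$w * stats::dexp(x, rate = model$rate) * as.numeric(x >= 0) +
    (1 - model$w) * stats::dnorm(x, mean = 0, sd = model$sigma)
}

# Negative log-likelihood on the unconstrained scale
# theta = (qlogis(w), log(rate), log(sigma)).
#' @noRd
mixture_nll <- function(theta, x) {
  w <- stats::plogis(theta[1L])
  rate <- exp(theta[2L])
  sigma <- exp(theta[3L])
  if (!is.finite(rate) || !is.finite(sigma) || sigma == 0 || rate == 0)
    return(.Machine$double.xmax / 2)
  d <- w * stats::dexp(x, rate = rate) * as.numeric(x >= 0) +
    (1 - w) * stats::dnorm(x, mean = 0, sd = sigma)
  -sum(log(pmax(d, .Machine$double.xmin)))
}

# Deterministic start values derived from sample statistics.
#' @noRd
mixture_starts <- function(x, n_starts = 5L) {
  pos <- x[x > 0]
  rate0 <- if (length(pos) > 0) 1 / mean(pos) else 10
  sig_neg <- if (any(x < 0)) sqrt(mean(x[x < 0]^2)) else stats::sd(x) / 2
  sig0 <- max(sig_neg, 1e-4)
  w_grid <- c(0.7, 0.5, 0.9, 0.3, 0.8, 0.6)[seq_len(n_starts)]
  lapply(seq_len(n_starts), function(i) {
    c(stats::qlogis(w_grid[i]),
      log(rate0 * c(1, 0.5, 2, 1, 4)[((i - 1L) %% 5L) + 1L]),
      log(sig0 * c(1, 2, 0.5, 4, 1)[((i - 1L) %% 5L) + 1L]))
  })
}

#' Fit the cost mixture model by maximum likelihood
#'
#' Direct numerical maximization of the summed log mixture density over
#' `(w, rate, sigma)` on an unconstrained transformed scale, with several
#' deterministic starting points to guard against local optima.
#'
#' @param records a [cost_records()] table, data frame with a `cost`
#'   column, or numeric cost vector.
#' @param n_starts number of starting points (default 5).
#' @param min_records minimum sample size (default 30).
#' @return a [cost_mixture_model()] with `loglik`, `n` and per-start
#'   convergence diagnostics.
#' @export
fit_mixture <- function(records, n_starts = 5L, min_records = 30L) {
  x <- if (is.numeric(records)) records else records$cost
  x <- as.numeric(x)
  if (length(x) < min_records)
    stop(errorCondition(
      sprintf("insufficient records: %d < %d", length(x), min_records),
      class = c("pnecres_insufficient_records", "pnecres_input_error", "error")))
  if (all(x <= 0))
    stop_input("degenerate sample: no positive costs, exponential component unidentifiable")
  starts <- mixture_starts(x, n_starts)
  fits <- lapply(starts, function(s) {
    tryCatch(stats::optim(s, mixture_nll, x = x, method = "BFGS",
                          control = list(maxit = 500)),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop(errorCondition("mixture fit failed to converge from every start",
                        class = c("pnecres_fit_error", "error")))
  nlls <- vapply(fits, function(f) if (is.null(f)) Inf else f$value, numeric(1))
  best <- fits[[which.min(nlls)]]
  conv <- data.frame(start = seq_along(fits),
                     nll = nlls,
                     code = vapply(fits, function(f)
                       if (is.null(f)) NA_integer_ else f$convergence,
                       integer(1)))
  # clamp the weight away from the boundary: plogis saturates to exactly
  # 0/1 in double precision for extreme optima
  w_hat <- min(max(stats::plogis(best$par[1L]), 1e-12), 1 - 1e-12)
  cost_mixture_model(w = w_hat,
                     rate = exp(best$par[2L]),
                     sigma = exp(best$par[3L]),
                     loglik = -best$value,
                     n = length(x),
                     convergence = conv)
}

#' Cost quantile of the exponential mixture component
#'
#' Quantiles are taken from the exponential component alone because only it
#' reflects fitness loss strictly attributable to resistance:
#' `Q_p = -ln(1 - p)/rate`, so `p` is the tolerated share of resistance
#' determinants cheaper than `Q_p` (e.g. `p = 0.05`: 5% of determinants
#' would still be selected for below the resulting threshold).
#'
#' @param model a [cost_mixture_model()], or a bare exponential rate.
#' @param p probability in (0, 1); vectorized.
#' @return cost quantile(s) as fractions.
#' @examples
#' cost_quantile(log(2) / 0.054, c(0.05, 0.5))
#' @export
cost_quantile <- function(model, p) {
  rate <- if (inherits(model, "cost_mixture_model")) model$rate else model
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  if (any(p <= 0) || any(p >= 1)) stop_input("p must lie strictly in (0, 1)")
  -log(1 - p) / rate
}

#' Exponential rate from a known quantile
#'
#' Inverse calibration of [cost_quantile()]: the rate for which the
#' exponential component has quantile `q` at probability `p`.
#'
#' @param p probability in (0, 1).
#' @param q cost quantile (fraction, > 0).
#' @return exponential rate.
#' @examples
#' rate_from_quantile(0.5, 0.054)  # rate with median cost 5.4%
#' @export
rate_from_quantile <- function(p, q) {
  check_number(p, "p", lower = 0, upper = 1, strict_lower = TRUE,
               strict_upper = TRUE)
  check_number(q, "q", lower = 0, strict_lower = TRUE)
  -log(1 - p) / q
}

#' Bootstrap confidence interval for a cost quantile
#'
#' Ordinary bootstrap: records are resampled with replacement, the mixture
#' is refitted (warm-started at the full-data estimate), and the percentile
#' 2.5%/97.5% interval of the resampled `Q_p` is returned.
#'
#' @param records cost records (table or numeric vector).
#' @param p probability in (0, 1).
#' @param B bootstrap replicates (>= 200; default 1000).
#' @param seed integer seed for reproducibility.
#' @param conf confidence level (default 0.95).
#' @return list with `lower`, `upper`, `estimate` (full-data `Q_p`),
#'   `replicates` (the bootstrap `Q_p` draws) and `n_failed`.
#' @export
bootstrap_ci <- function(records, p, B = 1000L, seed = 1L, conf = 0.95) {
  if (!is.numeric(B) || length(B) != 1L || B < 200)
    stop_input("B must be at least 200")
  x <- if (is.numeric(records)) records else records$cost
  full <- fit_mixture(x)
  warm <- c(stats::qlogis(full$w), log(full$rate), log(full$sigma))
  rng <- local({
    set.seed(as.integer(seed))
    replicate(B, sample.int(length(x), replace = TRUE), simplify = FALSE)
  })
  qs <- vapply(rng, function(idx) {
    xb <- x[idx]
    if (all(xb <= 0)) return(NA_real_)
    fit <- tryCatch({
      cand <- list(
        stats::optim(warm, mixture_nll, x = xb, method = "BFGS",
                     control = list(maxit = 300)),
        stats::optim(mixture_starts(xb, 1L)[[1L]], mixture_nll, x = xb,
                     method = "BFGS", control = list(maxit = 300)))
      cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
    }, error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    -log(1 - p) / exp(fit$par[2L])
  }, numeric(1))
  n_failed <- sum(!is.finite(qs))
  if (n_failed > 0.2 * B)
    stop(errorCondition(
      sprintf("bootstrap unstable: %d of %d replicate fits failed", n_failed, B),
      class = c("pnecres_fit_error", "error")))
  qs <- qs[is.finite(qs)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(qs, c(alpha, 1 - alpha), names = FALSE)
  list(lower = ci[1L], upper = ci[2L],
       estimate = cost_quantile(full, p),
       replicates = qs, n_failed = n_failed)
}

#' Profile-likelihood confidence interval for the exponential rate
#'
#' Profiles the log-likelihood over the rate (re-optimizing weight and
#' Gaussian sd at each value) and cuts at `qchisq(0.95, 1)/2 = 1.92` below
#' the maximum. If the profile does not cross the cutoff within the search
#' bounds the interval is flagged one-sided.
#'
#' @param records cost records (table or numeric vector).
#' @param conf confidence level (default 0.95).
#' @param span multiplicative search range around the estimate (default 10).
#' @return list with `lower`, `upper`, `rate` (point estimate), and
#'   `one_sided` flag.
#' @export
profile_ci_rate <- function(records, conf = 0.95, span = 10) {
  x <- if (is.numeric(records)) records else records$cost
  full <- fit_mixture(x)
  cut <- stats::qchisq(conf, df = 1) / 2
  warm2 <- c(stats::qlogis(full$w), log(full$sigma))
  profile_nll <- function(log_rate) {
    nll2 <- function(th) mixture_nll(c(th[1L], log_rate, th[2L]), x)
    stats::optim(warm2, nll2, method = "Nelder-Mead",
                 control = list(maxit = 500))$value
  }
  nll_hat <- -full$loglik
  drop_fun <- function(log_rate) profile_nll(log_rate) - nll_hat - cut
  lhat <- log(full$rate)
  lims <- log(c(full$rate / span, full$rate * span))
  side <- function(bound) {
    if (drop_fun(bound) < 0) return(NA_real_)  # cutoff not reached: one-sided
    exp(stats::uniroot(drop_fun, sort(c(bound, lhat)), tol = 1e-8)$root)
  }
  lower <- side(lims[1L])
  upper <- side(lims[2L])
  list(lower = lower, upper = upper, rate = full$rate,
       one_sided = anyNA(c(lower, upper)))
}

#' Compare plasmid-borne and chromosomal resistance costs
#'
#' Two-sided Wilcoxon rank-sum test between the two localization groups,
#' with the direction of the shift reported. Plasmid-borne resistance
#' typically carries a lower cost than chromosomal resistance.
#'
#' @param records a [cost_records()] table with a `localization` column.
#' @return list with `statistic`, `p_value`, `direction` (sign of
#'   median(plasmid) - median(chromosome)), group sizes and medians.
#' @export
compare_localizations <- function(records) {
  pl <- records$cost[records$localization == "plasmid"]
  ch <- records$cost[records$localization == "chromosome"]
  if (length(pl) < 3 || length(ch) < 3)
    stop_input("need at least 3 records per localization group")
  ht <- stats::wilcox.test(pl, ch, alternative = "two.sided")
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       direction = sign(stats::median(pl) - stats::median(ch)),
       n_plasmid = length(pl), n_chromosome = length(ch),
       median_plasmid = stats::median(pl),
       median_chromosome = stats::median(ch))
}
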