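#' Parameters of the normal + exponential intensity model
#'
#' Net spot intensity is modelled as X = B + S with background
#' B ~ Normal(mu, sigma^2) and true signal S ~ Exponential(mean alpha).
#'
#' @param mu Background mean (intensity units).
#' @param sigma Background sd (> 0).
#' @param alpha Exponential signal mean (> 0).
#' @return An object of class `normexp_params`.
#' @export
normexp_params <- function(mu, sigma, alpha) {
  if (!is.finite(mu) || !is.finite(sigma) || !is.finite(alpha) ||
      sigma <= 0 || alpha <= 0)
    stopf("need finite mu, sigma > 0, alpha > 0")
  structure(list(mu = mu, sigma = sigma, alpha = alpha),
            class = "normexp_params")
}

#' @export
print.normexp_params <- function(x, ...) {
  cat(sprintf("normexp_params: mu = %.4g, sigma = %.4g, alpha = %.4g\n",
              x$mu, x$sigma, x$alpha))
  invisible(x)
}

#' Fit the normexp model to net intensities
#'
#' Maximum-likelihood estimation of (mu, sigma, alpha) for one channel of
#' one array, from net (foreground minus background) intensities of
#' non-flagged spots. Numerical optimization starts from method-of-moments
#' values (delegated to limma's normexp machinery, the implementation the
#' background-correction literature standardized on).
#'
#' @param net Numeric vector of net intensities (>= 50 values).
#' @return A [normexp_params].
#' @export
normexp_fit <- function(net) {
  net <- net[is.finite(net)]
  if (length(net) < 50L)
    stopf("normexp_fit needs >= 50 finite values, got %d", length(net))
  if (stats::sd(net) == 0)
    stopf("normexp_fit: degenerate input (all values identical)")
  fit <- limma::normexp.fit(net, method = "mle")
  normexp_params(fit$par[1], exp(fit$par[2]), exp(fit$par[3]))
}

#' Background-correct a net intensity
#'
#' Returns E[S | X = net] + offset, the posterior mean of the true signal
#' under the normexp convolution, evaluated in the log domain so it is
#' stable for extreme net values. The result is strictly positive and
#' strictly greater than `offset` for every finite input, so downstream
#' log-ratios are always defined.
#'
#' @param net Numeric vector of net intensities.
#' @param params A [normexp_params].
#' @param offset Intensity offset added after correction (default 50,
#'   damping log-ratio variance at low intensities).
#' @return Corrected intensities, same length as `net`.
#' @export
normexp_correct <- function(net, params, offset = 50) {
  stopifnot(inherits(params, "normexp_params"))
  par <- c(params$mu, log(params$sigma), log(params$alpha))
  # limma warns when it floors the posterior mean at a small positive value
  # for extreme inputs; that floor is exactly the documented behaviour here
  # (outputs stay in (offset, Inf)), so the warning is muffled
  withCallingHandlers(
    limma::normexp.signal(par, net) + offset,
    warning = function(w) {
      if (grepl("Limit of numerical accuracy", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' M/A transformation of corrected intensities
#'
#' @param corr_test,corr_ref Background-corrected intensities (> 0).
#' @param tip_group Print-tip group id per spot (typically the block).
#' @return Data frame of class `ma_values` with columns `M`
#'   (log2 test/ref), `A` (mean log2 intensity) and `tip_group`.
#' @export
ma_values <- function(corr_test, corr_ref, tip_group) {
  if (any(corr_test <= 0) || any(corr_ref <= 0))
    stopf("corrected intensities must be > 0")
  structure(data.frame(M = log2(corr_test) - log2(corr_ref),
                       A = 0.5 * (log2(corr_test) + log2(corr_ref)),
                       tip_group = tip_group),
            class = c("ma_values", "data.frame"))
}

#' Print-tip loess normalization
#'
#' Within each print-tip group, replaces M by M - c(A) where c is a robust
#' local linear regression of M on A (tricube weights, iteratively
#' reweighted). Groups with fewer than `min_spots` usable spots fall back
#' to the whole-array fit. A is never modified.
#'
#' @param ma An [ma_values] data frame.
#' @param span Loess span as a fraction of the data (default 0.3).
#' @param iterations Robustness iterations (default 4).
#' @param min_spots Minimum spots per tip group for a group-wise fit.
#' @return The normalized `ma_values`.
#' @export
printtip_loess <- function(ma, span = 0.3, iterations = 4L, min_spots = 10L) {
  stopifnot(inherits(ma, "ma_values"))
  if (nrow(ma) == 0L) stopf("printtip_loess: empty array")
  global_fit <- NULL
  for (g in unique(ma$tip_group)) {
    at <- which(ma$tip_group == g)
    if (length(at) >= min_spots) {
      fit <- limma::loessFit(ma$M[at], ma$A[at], span = span,
                             iterations = iterations)$fitted
    } else {
      if (is.null(global_fit))
        global_fit <- limma::loessFit(ma$M, ma$A, span = span,
                                      iterations = iterations)$fitted
      fit <- global_fit[at]
    }
    ma$M[at] <- ma$M[at] - fit
  }
  ma
}

#' Normalize a scan end to end
#'
#' Per channel: net = foreground - background, normexp parameters fitted on
#' non-flagged spots, all spots corrected with `offset`. The corrected
#' intensities are M/A-transformed and print-tip loess normalized, then
#' mapped back to a normalized test-channel intensity
#' (`2^(A + M/2) * sqrt(corr_ref/corr_test)`-free reconstruction:
#' `test_norm = 2^(A + M/2)` with the post-loess M and unchanged A).
#'
#' @param scan An [array_scan].
#' @param offset Normexp offset (default 50).
#' @param span,iterations Passed to [printtip_loess()].
#' @return A list of class `normalized_scan`: `strain_id`, `params_test`,
#'   `params_ref`, `offset`, and `table` with per-spot `probe_id`, `block`,
#'   `flagged`, `bg_test`, `corr_test`, `corr_ref`, `A`, `M`, `test_norm`.
#' @export
normalize_scan <- function(scan, offset = 50, span = 0.3, iterations = 4L) {
  stopifnot(inherits(scan, "array_scan"))
  sp <- scan$spots
  ok <- sp$flag >= 0
  net_test <- sp$fg_test - sp$bg_test
  net_ref <- sp$fg_ref - sp$bg_ref
  params_test <- normexp_fit(net_test[ok])
  params_ref <- normexp_fit(net_ref[ok])
  corr_test <- normexp_correct(net_test, params_test, offset)
  corr_ref <- normexp_correct(net_ref, params_ref, offset)
  ma <- ma_values(corr_test, corr_ref, sp$block)
  ma_ok <- printtip_loess(ma[ok, ], span = span, iterations = iterations)
  M <- ma$M
  M[ok] <- ma_ok$M
  tab <- data.frame(probe_id = sp$probe_id, block = sp$block,
                    flagged = !ok, bg_test = sp$bg_test,
                    corr_test = corr_test, corr_ref = corr_ref,
                    A = ma$A, M = M, test_norm = 2^(ma$A + M / 2),
                    stringsAsFactors = FALSE)
  structure(list(strain_id = scan$strain_id, params_test = params_test,
                 params_ref = params_ref, offset = offset, table = tab),
            class = "normalized_scan")
}
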