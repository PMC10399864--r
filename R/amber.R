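#' Poisson concentration from droplet counts
#'
#' With template molecules Poisson-partitioned into droplets, the mean
#' copies per droplet is \eqn{\lambda = -\ln(1 - \hat p)} where
#' \eqn{\hat p} is the positive-droplet fraction. The 95% CI is the exact
#' binomial (Clopper-Pearson) CI on \eqn{\hat p} transformed through the
#' same function, so it inherits the monotonicity of the transform.
#' A fully positive channel carries no concentration information and is
#' rejected as saturated.
#'
#' @param n_positive,n_total droplet counts (vectorized);
#'   `0 <= n_positive <= n_total`, `n_total >= 1`.
#' @param conf confidence level.
#' @return data.frame with columns `lambda`, `ci_low`, `ci_high`.
#' @examples
#' lambdaFromDroplets(10000, 20000)  # lambda = ln 2
#' @export
lambdaFromDroplets <- function(n_positive, n_total, conf = 0.95) {
  checkCounts(c(n_positive, n_total))
  if (any(n_total < 1)) stop("n_total must be >= 1", call. = FALSE)
  if (any(n_positive > n_total)) stop("need n_positive <= n_total", call. = FALSE)
  if (any(n_positive == n_total)) {
    stop("saturated channel: all droplets positive, lambda undefined",
         call. = FALSE)
  }
  p <- n_positive / n_total
  ci <- clopperPearson(n_positive, n_total, conf)
  if (is.null(dim(ci))) ci <- rbind(ci)
  data.frame(
    lambda = -log1p(-p),
    ci_low = -log1p(-ci[, "low"]),
    ci_high = -log1p(-pmin(ci[, "high"], 1 - .Machine$double.eps))
  )
}

#' Construct a DropletChannel
#'
#' @param locus locus label (P1 control, P2/P3/P4 targets, or the ACT1
#'   reference).
#' @param n_positive,n_total droplet counts.
#' @return a [DropletChannel-class] with Poisson-corrected concentration.
#' @export
dropletChannel <- function(locus, n_positive, n_total = 20000L) {
  lam <- lambdaFromDroplets(n_positive, n_total)
  new("DropletChannel", locus = as.character(locus),
      n_total = as.integer(n_total), n_positive = as.integer(n_positive),
      lambda = lam$lambda, lambda_ci_low = lam$ci_low,
      lambda_ci_high = lam$ci_high)
}

#' Target/reference concentration ratio with 95% CI
#'
#' `ratio = lambda_target / lambda_reference`. The default CI combines
#' the per-channel bounds conservatively
#' (`lower = t_low / r_high`, `upper = t_high / r_low`); a first-order
#' delta-method interval on `log(ratio)` is available via
#' `ci_method = "delta"`.
#'
#' @param target,reference [DropletChannel-class] objects; the reference
#'   concentration must be > 0.
#' @param ci_method `"conservative"` (default) or `"delta"`.
#' @param conf confidence level (delta method only).
#' @return list with `ratio`, `ci_low`, `ci_high`, `ci_method`.
#' @export
ratioWithCI <- function(target, reference,
                        ci_method = c("conservative", "delta"), conf = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(is(target, "DropletChannel"), is(reference, "DropletChannel"))
  if (reference@lambda <= 0) stop("reference lambda must be > 0", call. = FALSE)
  ratio <- target@lambda / reference@lambda
  if (ci_method == "conservative") {
    lo <- target@lambda_ci_low / reference@lambda_ci_high
    hi <- target@lambda_ci_high / reference@lambda_ci_low
  } else {
    # var(lambda-hat) = p / ((1-p) n) by the delta method on -log(1-p)
    relVar <- function(ch) {
      p <- ch@n_positive / ch@n_total
      p / ((1 - p) * ch@n_total) / ch@lambda^2
    }
    se <- sqrt(relVar(target) + relVar(reference))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    lo <- ratio * exp(-z * se)
    hi <- ratio * exp(z * se)
  }
  list(ratio = ratio, ci_low = lo, ci_high = hi, ci_method = ci_method)
}

#' Normalized copy-number time series from a droplet table
#'
#' For every timepoint and target locus, computes the Poisson-corrected
#' target/reference ratio and divides it by the same locus's 0-hr ratio,
#' so copy number is 1 at 0 hr by construction (1x before BIR, at most
#' 2x after complete replication of the donor). Values are not clamped:
#' sampling noise may carry estimates outside \[1, 2\].
#'
#' @param droplets data.frame in the droplet TSV schema (`strain`,
#'   `time_hr`, `locus`, `n_total`, `n_positive`) containing the
#'   reference locus at every timepoint and a 0-hr row per locus.
#' @param reference reference locus name (default `"ACT1"`).
#' @param ci_method passed to [ratioWithCI()].
#' @return data.frame with one row per (time_hr, locus): `ratio`,
#'   `copy_number`, `ci_low`, `ci_high` (the ratio CI scaled by the 0-hr
#'   point ratio), plus the raw droplet counts.
#' @export
copyNumberSeries <- function(droplets, reference = "ACT1",
                             ci_method = c("conservative", "delta")) {
  ci_method <- match.arg(ci_method)
  needed <- c("strain", "time_hr", "locus", "n_total", "n_positive")
  stopifnot(all(needed %in% names(droplets)))
  targets <- setdiff(unique(droplets$locus), reference)
  if (!length(targets)) stop("no target loci in table", call. = FALSE)
  out <- list()
  for (loc in targets) {
    tgt <- droplets[droplets$locus == loc, , drop = FALSE]
    ref <- droplets[droplets$locus == reference, , drop = FALSE]
    if (!any(tgt$time_hr == 0)) {
      stop(sprintf("missing 0-hr sample for locus %s", loc), call. = FALSE)
    }
    rows <- lapply(sort(unique(tgt$time_hr)), function(t) {
      tr <- tgt[tgt$time_hr == t, , drop = FALSE][1L, ]
      rr <- ref[ref$time_hr == t, , drop = FALSE]
      if (!nrow(rr)) {
        stop(sprintf("missing reference channel at %g hr", t), call. = FALSE)
      }
      rr <- rr[1L, ]
      rat <- ratioWithCI(
        dropletChannel(loc, tr$n_positive, tr$n_total),
        dropletChannel(reference, rr$n_positive, rr$n_total),
        ci_method = ci_method
      )
      data.frame(strain = tr$strain, time_hr = t, locus = loc,
                 n_positive = tr$n_positive, n_total = tr$n_total,
                 ratio = rat$ratio, ratio_ci_low = rat$ci_low,
                 ratio_ci_high = rat$ci_high, stringsAsFactors = FALSE)
    })
    ser <- do.call(rbind, rows)
    r0 <- ser$ratio[ser$time_hr == 0][1L]
    if (!is.finite(r0) || r0 <= 0) {
      stop(sprintf("0-hr ratio for locus %s is not positive", loc), call. = FALSE)
    }
    ser$copy_number <- ser$ratio / r0
    ser$ci_low <- ser$ratio_ci_low / r0
    ser$ci_high <- ser$ratio_ci_high / r0
    out[[loc]] <- ser
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call DNA synthesis from a copy-number estimate
#'
#' Evidence of BIR synthesis is an increase of the donor copy number to
#' at least 1.1x (inclusive). By default the call uses the point
#' estimate; with `require_ci = TRUE` synthesis is called only when the
#' whole 95% CI clears the threshold (`ci_low >= threshold`).
#'
#' @param copy_number point estimate(s), >= 0.
#' @param ci_low lower CI bound(s), needed when `require_ci = TRUE`.
#' @param threshold call threshold (default 1.1).
#' @param require_ci logical; CI-aware calling.
#' @return logical vector.
#' @examples
#' callSynthesis(c(1.09, 1.10, 1.7))  # FALSE TRUE TRUE
#' @export
callSynthesis <- function(copy_number, ci_low = NULL, threshold = 1.1,
                          require_ci = FALSE) {
  if (any(copy_number < 0)) stop("copy_number must be >= 0", call. = FALSE)
  if (require_ci) {
    if (is.null(ci_low)) stop("ci_low required when require_ci = TRUE", call. = FALSE)
    ci_low >= threshold
  } else {
    copy_number >= threshold
  }
}

#' Fit a Boltzmann sigmoid to a copy-number time course
#'
#' Least squares for
#' \eqn{y(t) = base + (top - base)/(1 + \exp((t_{1/2} - t)/\tau))},
#' the standard four-parameter sigmoid used to summarise replication
#' kinetics. Initialisation: `base = min(y)`, `top = max(y)`, `t_half` at
#' the mid-range crossing, `tau = 1` hr; `tau` is bounded to (0.01, 20].
#' Degenerate or non-converging fits return `converged = FALSE` with
#' best-effort parameters rather than erroring.
#'
#' @param times hours (>= 5 points spanning >= 4 hours).
#' @param values copy numbers.
#' @return a [KineticsFit-class] object.
#' @export
fitBoltzmann <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (length(times) < 5L) stop("need >= 5 points", call. = FALSE)
  if (diff(range(times)) < 4) stop("points must span >= 4 hours", call. = FALSE)
  yr <- range(values)
  mid <- mean(yr)
  tHalf0 <- if (diff(yr) > 0) {
    times[which.min(abs(values - mid))]
  } else {
    mean(range(times))
  }
  start <- list(base = yr[1L], top = yr[2L], t_half = tHalf0, tau = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      values ~ base + (top - base) / (1 + exp((t_half - times) / tau)),
      start = start,
      lower = c(base = -Inf, top = -Inf, t_half = -Inf, tau = 0.01),
      upper = c(base = Inf, top = Inf, t_half = Inf, tau = 20),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-15, ptol = 1e-15
      )
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new("KineticsFit", base = yr[1L], top = yr[2L], t_half = tHalf0,
               tau = 1, rss = sum((values - mean(values))^2), converged = FALSE))
  }
  cf <- stats::coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  new("KineticsFit", base = unname(cf["base"]), top = unname(cf["top"]),
      t_half = unname(cf["t_half"]), tau = unname(cf["tau"]),
      rss = sum(stats::residuals(fit)^2), converged = isTRUE(conv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict from a Boltzmann fit
#'
#' @param fit a [KineticsFit-class] object.
#' @param times hours.
#' @return predicted copy numbers.
#' @export
predictBoltzmann <- function(fit, times) {
  stopifnot(is(fit, "KineticsFit"))
  fit@base + (fit@top - fit@base) / (1 + exp((fit@t_half - times) / fit@tau))
}

#' Maximum copy number per locus over a time course
#'
#' The maximum observed copy number between 0 and 10 hr can exceed the
#' 10-hr value when BIR is interrupted and newly synthesised DNA is
#' degraded, so the maximum is reported with its timepoint.
#'
#' @param series output of [copyNumberSeries()] (needs `locus`,
#'   `time_hr`, `copy_number`).
#' @return data.frame with one row per locus: `max_copy_number`,
#'   `time_hr`.
#' @export
maxCopyNumber <- function(series) {
  stopifnot(all(c("locus", "time_hr", "copy_number") %in% names(series)))
  if (!nrow(series)) stop("empty series", call. = FALSE)
  out <- lapply(split(series, series$locus), function(s) {
    i <- which.max(s$copy_number)
    data.frame(locus = s$locus[i], max_copy_number = s$copy_number[i],
               time_hr = s$time_hr[i], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
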