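#' Estimate VAFs from ultra-deep amplicon read counts
#'
#' Point estimate alt/total with a Wilson 95% confidence interval.
#' Estimates below the detection floor (default 0.1% VAF) are censored:
#' at ~1e5-read redundancy with a realistic per-base miscall rate,
#' signal below that level cannot be distinguished from sequencing-error
#' background, so censored sites get no group assignment.
#'
#' @param obs Data frame with \code{total_reads}, \code{alt_reads} (e.g.
#'   from \code{\link{sample_reads}}).
#' @param vaf_floor Detection floor.
#' @param conf_level Confidence level for the Wilson interval.
#' @return Data frame: the input columns plus \code{vaf}, \code{ci_lower},
#'   \code{ci_upper}, \code{censored}.
#' @export
#' @examples
#' estimate_vaf(data.frame(total_reads = 1e5, alt_reads = 5e4))
estimate_vaf <- function(obs, vaf_floor = 0.001, conf_level = 0.95) {
  if (any(obs$total_reads == 0L)) stop("total_reads must be positive")
  n <- obs$total_reads
  x <- obs$alt_reads
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  out <- obs
  out$vaf <- p
  out$ci_lower <- pmax(0, centre - half)
  out$ci_upper <- pmin(1, centre + half)
  out$censored <- p < vaf_floor
  out
}

#' Classify SNVs into timing groups from their parent-clone VAF
#'
#' Group I collects the reprogramming-associated SNVs (higher VAF,
#' transversion-rich: acquired within the first few divisions so carried
#' by a substantial fraction of the colony); group II the spontaneous
#' culture mutations (VAF below about 1%, transition-rich). The default
#' is a contiguous split at 1%; \code{mode = "text"} uses the two-threshold
#' variant (group I >= 5%, group II < 1%) with an explicit
#' \code{intermediate} band. Censored estimates receive no group. The
#' origin generation is estimated by inverting the binary-tree carrier
#' model: a heterozygous mutation from generation k has VAF
#' \code{2^-(k+1)}, so \code{k_hat = round(log2(1 / (2 * vaf)))}, clamped
#' at 0. SNVs inside the 50%-VAF window are additionally flagged
#' clone-wide: they are present in every cell but cannot be demarcated as
#' de novo or pre-existing from VAF alone.
#'
#' @param est Data frame from \code{\link{estimate_vaf}} (columns
#'   \code{vaf}, \code{censored}), optionally with \code{ref}/\code{alt}
#'   for the substitution class.
#' @param mode \code{"contiguous"} (split at \code{group2_max}) or
#'   \code{"text"} (adds an intermediate band between \code{group2_max}
#'   and \code{group1_min}).
#' @param group1_min Lower VAF bound of group I (used in \code{"text"}
#'   mode; default 0.05).
#' @param group2_max Upper VAF bound of group II (default 0.01).
#' @param fifty_window VAF window flagged clone-wide.
#' @return Data frame: input columns plus \code{group} (\code{"I"},
#'   \code{"II"}, \code{"intermediate"}, \code{"censored"}),
#'   \code{k_hat}, \code{clone_wide}, and \code{substitution}
#'   (\code{"ts"}/\code{"tv"}) when ref/alt are available.
#' @export
classify_group <- function(est, mode = c("contiguous", "text"),
                           group1_min = 0.05, group2_max = 0.01,
                           fifty_window = c(0.35, 0.65)) {
  mode <- match.arg(mode)
  lo <- if (mode == "contiguous") group2_max else group1_min
  vaf <- est$vaf
  censored <- if (!is.null(est$censored)) est$censored else rep(FALSE, nrow(est))
  group <- ifelse(censored, "censored",
           ifelse(vaf >= lo, "I",
           ifelse(vaf < group2_max, "II", "intermediate")))
  k_hat <- ifelse(censored | vaf <= 0, NA_real_,
                  pmax(0, round(log2(1 / (2 * vaf)))))
  out <- est
  out$group <- group
  out$k_hat <- as.integer(k_hat)
  out$clone_wide <- !censored & vaf >= fifty_window[1] & vaf <= fifty_window[2]
  if (!is.null(est$ref) && !is.null(est$alt)) {
    ref <- toupper(est$ref)
    pyr_ref <- ifelse(ref %in% c("A", "G"), chartr("ACGT", "TGCA", ref), ref)
    pyr_alt <- ifelse(ref %in% c("A", "G"),
                      chartr("ACGT", "TGCA", toupper(est$alt)),
                      toupper(est$alt))
    out$substitution <- ifelse(paste0(pyr_ref, ">", pyr_alt) %in%
                                 TRANSITION_CLASSES, "ts", "tv")
  }
  out
}

#' Largest origin generation reliably observable above a detection floor
#'
#' A heterozygous mutation from generation k has true VAF
#' \code{2^-(k+1)}; it is reliably uncensored only while that VAF stays
#' at least a factor \code{margin} above the floor. Counts binned beyond
#' this generation are depressed by censoring rather than by a genuine
#' rate change and should not enter rate fits.
#'
#' @param vaf_floor Detection floor.
#' @param margin Safety factor above the floor (default 2).
#' @return Integer generation bound.
#' @export
detectable_k_max <- function(vaf_floor = 0.001, margin = 2) {
  as.integer(floor(log2(1 / (2 * margin * vaf_floor))))
}

poisson_loglik <- function(counts, means) {
  ok <- means > 0 | counts > 0
  # mean 0 with count 0 contributes log(1) = 0
  sum(stats::dpois(counts[ok], pmax(means[ok], .Machine$double.xmin),
                   log = TRUE))
}

#' Likelihood test of burst versus continuous mutation accumulation
#'
#' Bins SNVs by estimated origin generation and compares two Poisson
#' models of the per-generation counts \code{n_k}. Continuous: one rate
#' per division, \code{n_k ~ Poisson(mu * 2^k)} (the population doubles,
#' so a constant per-division rate yields exponentially growing counts).
#' Burst: a window rate inside a candidate interval \code{[a, b]} and a
#' background rate outside; every window of width \code{<= w_max} is
#' scanned and the maximum-likelihood window reported. Model support is
#' summarised as \code{delta_aic = AIC(continuous) - AIC(burst)}, with
#' the burst model charged four parameters (two rates plus the two
#' estimated window endpoints, as in changepoint-model AIC) against the
#' continuous model's one; the verdict is
#' \code{"burst"} when \code{delta_aic > 4}, the conventional cutoff for
#' considerable support, \code{"continuous"} otherwise, and
#' \code{"inconclusive"} with fewer than \code{min_calls} usable calls.
#'
#' @param k_hat Integer vector of estimated origin generations (censored
#'   calls excluded beforehand), or a data frame from
#'   \code{\link{classify_group}} (its non-censored \code{k_hat} used).
#' @param k_max Largest generation bin included in the fit. Near the
#'   detection floor censoring depresses the observed counts below the
#'   \code{2^k} expectation, which would mimic a rate change, so bins are
#'   only trusted while the true heterozygous VAF \code{2^-(k+1)} sits at
#'   least a factor \code{2} above the floor; the default is
#'   \code{detectable_k_max(vaf_floor)} and calls with larger
#'   \code{k_hat} are excluded from the fit.
#' @param vaf_floor Detection floor used for the default \code{k_max}.
#' @param w_max Maximum burst-window width scanned.
#' @param min_calls Minimum usable calls for a verdict.
#' @return A \code{burst_test} list: \code{counts}, \code{loglik_continuous},
#'   \code{loglik_burst}, \code{mu_continuous}, \code{mu_burst},
#'   \code{mu_outside}, \code{window}, \code{delta_aic}, \code{verdict}.
#' @export
burst_test <- function(k_hat, k_max = NULL, w_max = 4L, min_calls = 10L,
                       vaf_floor = 0.001) {
  if (is.data.frame(k_hat)) {
    k_hat <- k_hat$k_hat[!is.na(k_hat$k_hat)]
  }
  k_hat <- k_hat[!is.na(k_hat)]
  if (is.null(k_max)) k_max <- detectable_k_max(vaf_floor)
  k_hat <- k_hat[k_hat <= k_max]
  if (length(k_hat) < min_calls) {
    return(structure(list(counts = NULL, verdict = "inconclusive",
                          n = length(k_hat)),
                     class = "burst_test"))
  }
  ks <- 0:k_max
  counts <- tabulate(k_hat + 1L, nbins = k_max + 1L)
  w <- 2^ks

  mu_c <- sum(counts) / sum(w)
  ll_c <- poisson_loglik(counts, mu_c * w)

  best <- list(ll = -Inf)
  for (a in ks) for (b in a:min(k_max, a + w_max)) {
    inside <- ks >= a & ks <= b
    mu_b <- sum(counts[inside]) / sum(w[inside])
    mu_0 <- if (any(!inside)) sum(counts[!inside]) / sum(w[!inside]) else 0
    ll <- poisson_loglik(counts, ifelse(inside, mu_b, mu_0) * w)
    if (ll > best$ll) {
      best <- list(ll = ll, window = c(a, b), mu_b = mu_b, mu_0 = mu_0)
    }
  }
  # continuous: 1 parameter (mu); burst: 2 rates + 2 estimated window
  # endpoints, charged as parameters as in changepoint-model AIC
  aic_c <- 2 * 1 - 2 * ll_c
  aic_b <- 2 * 4 - 2 * best$ll
  delta <- aic_c - aic_b
  structure(list(
    counts = stats::setNames(counts, ks),
    loglik_continuous = ll_c, loglik_burst = best$ll,
    mu_continuous = mu_c, mu_burst = best$mu_b, mu_outside = best$mu_0,
    window = best$window, delta_aic = delta,
    verdict = if (delta > 4) "burst" else "continuous",
    n = length(k_hat)
  ), class = "burst_test")
}

#' @export
print.burst_test <- function(x, ...) {
  cat("<burst_test>", x$verdict)
  if (!is.null(x$window)) {
    cat(sprintf(" | window [%d, %d], dAIC = %.2f, n = %d",
                x$window[1], x$window[2], x$delta_aic, x$n))
  }
  cat("\n")
  invisible(x)
}

#' Build a per-SNV timeline report for a clone
#'
#' Convenience wrapper chaining VAF estimation, group classification and
#' the burst test over one clone's amplicon observations.
#'
#' @param amplicon_obs Read counts (\code{total_reads}, \code{alt_reads},
#'   plus any annotation columns carried through).
#' @param vaf_floor Detection floor.
#' @param mode Group mode, see \code{\link{classify_group}}.
#' @param w_max Maximum burst-window width scanned.
#' @return List with \code{calls} (per-SNV table) and \code{burst}
#'   (the \code{burst_test} result).
#' @export
timeline_report <- function(amplicon_obs, vaf_floor = 0.001,
                            mode = "contiguous", w_max = 4L) {
  est <- estimate_vaf(amplicon_obs, vaf_floor = vaf_floor)
  calls <- classify_group(est, mode = mode)
  list(calls = calls,
       burst = burst_test(calls, w_max = w_max, vaf_floor = vaf_floor))
}
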