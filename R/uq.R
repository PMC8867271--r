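# Forward uncertainty propagation through the surrogate: quasi-Monte Carlo
# sampling, per-day moments and coefficients of variation, central
# percentile bands, kernel densities, restenosis fractions and replication.

#' Propagate input uncertainty through a fitted surrogate
#'
#' Draws `N` scrambled-Sobol samples of the parameter space and evaluates
#' the surrogate at each.
#'
#' @param model a fitted `pod_gp`.
#' @param space parameter space (defaults to the training space).
#' @param N number of quasi-Monte Carlo samples.
#' @param seed scramble seed.
#' @return list with `inputs` (`N x d`) and one `N x Nt` matrix per QoI.
#' @export
run_uq <- function(model, space = model$space, N = 1e4, seed = 1L) {
  stopifnot(inherits(model, "pod_gp"))
  X <- sobol_samples(space, N, scramble_seed = seed)
  out <- list(inputs = X)
  pred <- predict(model, X)
  for (q in names(pred)) out[[q]] <- pred[[q]]$mean
  out
}

#' Column-wise moments and coefficient of variation
#'
#' @param samples `N x Nt` matrix (rows = samples, columns = days).
#' @return data frame with per-day `mean`, `sd` (unbiased) and `cv`
#'   (`sd/mean`, a fraction).
#' @export
moments_and_cv <- function(samples) {
  samples <- as.matrix(samples)
  check_that(nrow(samples) >= 2L, "need at least 2 samples")
  m <- colMeans(samples)
  s <- apply(samples, 2L, stats::sd)
  check_that(all(abs(m) > 0 | s == 0), "CV undefined: zero column mean")
  cv <- ifelse(s == 0, 0, s / m) # degenerate constant column: CV 0
  data.frame(day = seq_len(ncol(samples)) - 1L, mean = m, sd = s, cv = cv,
             row.names = NULL)
}

#' Central percentile bands of a sample matrix
#'
#' For central coverage c, the band `[quantile((1-c)/2), quantile((1+c)/2)]`
#' per day (linear interpolation between order statistics).
#'
#' @param samples `N x Nt` matrix.
#' @param coverages central coverage fractions.
#' @return named list of `2 x Nt` matrices (rows: lower, upper).
#' @export
percentile_bands <- function(samples, coverages = c(0.50, 0.75, 0.95)) {
  samples <- as.matrix(samples)
  check_that(nrow(samples) >= 20L, "need at least 20 samples for stable bands")
  out <- lapply(coverages, function(cc) {
    apply(samples, 2L, stats::quantile, probs = c((1 - cc) / 2, (1 + cc) / 2))
  })
  names(out) <- sprintf("band_%02d", round(100 * coverages))
  out
}

#' Fraction of samples past the restenosis threshold
#'
#' Restenosis is declared when the maximum relative area loss reaches the
#' threshold (clinically, 50% occlusion).
#'
#' @param mral_samples `N x Nt` matrix of MRAL series.
#' @param threshold area-loss threshold (default 0.5).
#' @param day day to evaluate (0-based; default the last day).
#' @return fraction of rows with `MRAL(day) >= threshold`.
#' @export
restenosis_fraction <- function(mral_samples, threshold = 0.5, day = NULL) {
  mral_samples <- as.matrix(mral_samples)
  nt <- ncol(mral_samples)
  if (is.null(day)) day <- nt - 1L
  check_that(day >= 0 && day <= nt - 1L, "day %d outside grid 0..%d", as.integer(day), nt - 1L)
  mean(mral_samples[, day + 1L] >= threshold)
}

#' Inputs of restenotic samples, with marginal histograms
#'
#' Filters the input rows whose MRAL at `day` reaches the threshold, the
#' sample subset behind restenosis scatter plots.
#'
#' @param inputs `N x d` input matrix.
#' @param mral_samples matching `N x Nt` MRAL matrix.
#' @inheritParams restenosis_fraction
#' @param breaks histogram bin count per parameter.
#' @return list with `inputs` (the filtered rows) and `histograms` (one
#'   `hist`-style density object per parameter); empty subset gives a
#'   zero-row matrix with a warning.
#' @export
restenosis_scatter <- function(inputs, mral_samples, day = NULL, threshold = 0.5,
                               breaks = 20L) {
  inputs <- as.matrix(inputs)
  mral_samples <- as.matrix(mral_samples)
  check_that(nrow(inputs) == nrow(mral_samples), "inputs and MRAL row counts disagree")
  nt <- ncol(mral_samples)
  if (is.null(day)) day <- nt - 1L
  sel <- mral_samples[, day + 1L] >= threshold
  sub <- inputs[sel, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning(sprintf("no samples reach MRAL >= %g at day %d", threshold, day))
    return(list(inputs = sub, histograms = NULL))
  }
  hists <- lapply(seq_len(ncol(sub)), function(j)
    graphics::hist(sub[, j], breaks = breaks, plot = FALSE))
  names(hists) <- colnames(inputs)
  list(inputs = sub, histograms = hists)
}

#' Replicated uncertainty quantification
#'
#' Runs [run_uq()] `reps` times with distinct scramble seeds and aggregates:
#' per-day mean/SD/CV (averaged over replicates) with across-replicate
#' spread, percentile bands, kernel densities and histograms at selected
#' days, and the restenosis fraction over time.
#'
#' @inheritParams run_uq
#' @param reps number of replicates.
#' @param master_seed master seed; replicate r is scrambled with
#'   `derive_seed(master_seed, 5000 + r)`.
#' @param days days at which densities/histograms are stored.
#' @param threshold restenosis threshold on MRAL.
#' @return an `isr_uq` object; see `print` and `plot` methods.
#' @export
replicate_uq <- function(model, space = model$space, N = 1e4, reps = 10L,
                         master_seed = 1L, days = c(5, 10, 15, 20, 30),
                         threshold = 0.5) {
  check_that(reps >= 2, "need reps >= 2")
  qnames <- names(model$qois)
  stats_reps <- list()
  last <- NULL
  for (r in seq_len(reps)) {
    res <- run_uq(model, space, N, seed = derive_seed(master_seed, 5000L + r))
    for (q in qnames) {
      mc <- moments_and_cv(res[[q]])
      stats_reps[[q]]$mean <- rbind(stats_reps[[q]]$mean, mc$mean)
      stats_reps[[q]]$sd <- rbind(stats_reps[[q]]$sd, mc$sd)
      stats_reps[[q]]$cv <- rbind(stats_reps[[q]]$cv, mc$cv)
    }
    rf <- vapply(seq_len(ncol(res$mral)) - 1L, function(dd)
      restenosis_fraction(res$mral, threshold, dd), numeric(1L))
    stats_reps$restenosis <- rbind(stats_reps$restenosis, rf)
    last <- res # densities/bands from the final replicate's samples
  }
  agg <- function(M) list(estimate = colMeans(M), rep_sd = apply(M, 2L, stats::sd))
  per_qoi <- list()
  for (q in qnames) {
    nt <- ncol(last[[q]])
    day_idx <- days[days <= nt - 1L] + 1L
    dens <- lapply(day_idx, function(i) stats::density(last[[q]][, i], bw = "nrd"))
    hists <- lapply(day_idx, function(i)
      graphics::hist(last[[q]][, i], breaks = 50L, plot = FALSE))
    names(dens) <- names(hists) <- paste0("day_", days[days <= nt - 1L])
    per_qoi[[q]] <- list(mean = agg(stats_reps[[q]]$mean),
                         sd = agg(stats_reps[[q]]$sd),
                         cv = agg(stats_reps[[q]]$cv),
                         bands = percentile_bands(last[[q]]),
                         densities = dens, histograms = hists)
  }
  structure(list(qois = per_qoi,
                 restenosis = agg(stats_reps$restenosis),
                 days = 0:(ncol(last$mral) - 1L), density_days = days,
                 N = as.integer(N), reps = as.integer(reps),
                 master_seed = as.integer(master_seed), threshold = threshold),
            class = "isr_uq")
}

#' @export
print.isr_uq <- function(x, ...) {
  cat(sprintf("Uncertainty quantification: %d qMC samples x %d replicates\n", x$N, x$reps))
  sel <- x$days %in% x$density_days
  for (q in names(x$qois)) {
    e <- x$qois[[q]]
    tab <- rbind(mean = e$mean$estimate[sel], sd = e$sd$estimate[sel],
                 `cv%` = 100 * e$cv$estimate[sel])
    colnames(tab) <- paste0("day_", x$days[sel])
    cat(sprintf("\n%s:\n", toupper(q)))
    print(round(tab, 3))
  }
  cat("\nrestenosis fraction (%):\n")
  rf <- 100 * x$restenosis$estimate[sel]
  names(rf) <- paste0("day_", x$days[sel])
  print(round(rf, 3))
  invisible(x)
}

#' @export
plot.isr_uq <- function(x, qoi = "acsa", ...) {
  e <- x$qois[[qoi]]
  m <- e$mean$estimate
  b <- e$bands
  ylim <- range(b$band_95)
  graphics::plot(x$days, m, type = "l", lwd = 2, ylim = ylim, xlab = "day",
                 ylab = toupper(qoi), main = sprintf("%s: mean and central bands", toupper(qoi)), ...)
  for (nm in rev(names(b))) {
    graphics::lines(x$days, b[[nm]][1L, ], lty = 2)
    graphics::lines(x$days, b[[nm]][2L, ], lty = 2)
  }
  invisible(x)
}
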