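# Plain-text artifact I/O: datasets, surrogate archives and result tables.
# All numeric payloads are written with 17 significant digits so that
# write -> read round-trips are bitwise exact for doubles.

.fmt17 <- function(x) sprintf("%.17g", x)

.write_num_csv <- function(M, path) {
  M <- as.matrix(M)
  df <- as.data.frame(apply(M, 2L, .fmt17), stringsAsFactors = FALSE)
  if (ncol(M) == 1L) { df <- data.frame(V1 = .fmt17(M[, 1L])) }
  colnames(df) <- colnames(M) %||% paste0("c", seq_len(ncol(M)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

.read_num_csv <- function(path) {
  check_that(file.exists(path), "missing file: %s", path)
  df <- tryCatch(utils::read.csv(path, colClasses = "character", check.names = FALSE),
                 error = function(e) stop(sprintf("failed to parse %s: %s", path,
                                                  conditionMessage(e)), call. = FALSE))
  M <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (!is.matrix(M)) M <- matrix(M, nrow = nrow(df), dimnames = list(NULL, names(df)))
  check_that(all(is.finite(M)), "non-numeric or non-finite entries in %s", path)
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an emulated dataset as CSV + JSON
#'
#' Writes `samples.csv` (physical units, one column per parameter),
#' `qoi_acsa.csv` and `qoi_mral.csv` (columns `day_00..day_30`) and
#' `provenance.json` (seeds and emulator constants) into `dir`.
#'
#' @param dataset an `isr_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "isr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_num_csv(dataset$samples, file.path(dir, "samples.csv"))
  .write_num_csv(dataset$acsa, file.path(dir, "qoi_acsa.csv"))
  .write_num_csv(dataset$mral, file.path(dir, "qoi_mral.csv"))
  prov <- list(provenance = dataset$provenance,
               config = unclass(dataset$config),
               space = unclass(dataset$space))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"), simplifyVector = TRUE)
  sp <- parameter_space(prov$space$names, prov$space$mins, prov$space$maxs, prov$space$units)
  cfg <- do.call(emulator_config, prov$config[names(formals(emulator_config))])
  structure(list(samples = .read_num_csv(file.path(dir, "samples.csv")),
                 acsa = .read_num_csv(file.path(dir, "qoi_acsa.csv")),
                 mral = .read_num_csv(file.path(dir, "qoi_mral.csv")),
                 space = sp, config = cfg,
                 provenance = prov$provenance),
            class = "isr_dataset")
}

#' Save / load a fitted surrogate as a text archive
#'
#' One directory per model: `meta.json` (ranks, seeds, scaling constants,
#' hyperparameters) plus full-precision CSV arrays for each POD basis and
#' each coefficient GP's training state.  Round-trips reproduce predictions
#' bitwise.
#'
#' @param model a fitted `pod_gp`.
#' @param dir archive directory.
#' @return `dir` (`save_surrogate`) or the restored `pod_gp`
#'   (`load_surrogate`).
#' @export
save_surrogate <- function(model, dir) {
  stopifnot(inherits(model, "pod_gp"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(space = unclass(model$space), n_train = model$n_train,
               n_snapshots = model$n_snapshots, energy = model$energy,
               restarts = model$restarts, seed = model$seed,
               qois = lapply(model$qois, function(e) {
                 list(k = e$basis$k,
                      singular_values = .fmt17(e$basis$singular_values),
                      snapshot_idx = e$basis$snapshot_idx,
                      snapshot_seed = e$snapshot_seed,
                      gps = lapply(e$gps, function(g)
                        list(sigma_f = .fmt17(g$sigma_f), sigma_n = .fmt17(g$sigma_n),
                             lengthscales = .fmt17(g$lengthscales),
                             y_mean = .fmt17(g$y_mean), y_sd = .fmt17(g$y_sd),
                             jitter = .fmt17(g$jitter),
                             log_marginal = .fmt17(g$log_marginal))))
               }))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (q in names(model$qois)) {
    e <- model$qois[[q]]
    .write_num_csv(e$basis$phi, file.path(dir, sprintf("%s_phi.csv", q)))
    first_gp <- e$gps[[1L]]
    .write_num_csv(first_gp$X, file.path(dir, sprintf("%s_X.csv", q)))
    Y <- vapply(e$gps, function(g) g$y, numeric(nrow(first_gp$X)))
    .write_num_csv(Y, file.path(dir, sprintf("%s_alpha.csv", q)))
  }
  invisible(dir)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  sp <- parameter_space(meta$space$names, meta$space$mins, meta$space$maxs, meta$space$units)
  qois <- list()
  for (q in names(meta$qois)) {
    mq <- meta$qois[[q]]
    phi <- .read_num_csv(file.path(dir, sprintf("%s_phi.csv", q)))
    X <- .read_num_csv(file.path(dir, sprintf("%s_X.csv", q)))
    A <- .read_num_csv(file.path(dir, sprintf("%s_alpha.csv", q)))
    basis <- structure(list(phi = phi,
                            singular_values = as.numeric(mq$singular_values),
                            v = NULL, k = mq$k, n_snapshots = ncol(phi),
                            snapshot_idx = mq$snapshot_idx),
                       class = "pod_basis")
    gps <- lapply(seq_len(mq$k), function(j) {
      g <- mq$gps[[j]]
      sigma_f <- as.numeric(g$sigma_f); sigma_n <- as.numeric(g$sigma_n)
      ell <- as.numeric(g$lengthscales)
      y <- A[, j]
      y_mean <- as.numeric(g$y_mean); y_sd <- as.numeric(g$y_sd)
      ys <- (y - y_mean) / y_sd
      K <- .gp_kernmat(X, X, sigma_f, ell)
      L <- chol(K + diag(sigma_n^2 + as.numeric(g$jitter), nrow(X)))
      structure(list(X = X, y = y, y_mean = y_mean, y_sd = y_sd,
                     sigma_f = sigma_f, sigma_n = sigma_n, lengthscales = ell,
                     L = L, alpha = backsolve(L, forwardsolve(t(L), ys)),
                     jitter = as.numeric(g$jitter),
                     log_marginal = as.numeric(g$log_marginal)),
                class = "ard_gp")
    })
    qois[[q]] <- list(basis = basis, gps = gps, snapshot_seed = mq$snapshot_seed)
  }
  structure(list(qois = qois, space = sp, n_train = meta$n_train,
                 n_snapshots = meta$n_snapshots, energy = meta$energy,
                 restarts = meta$restarts, seed = meta$seed),
            class = "pod_gp")
}

#' Write UQ summary tables
#'
#' `uq_summary.csv` (day x statistic for both QoIs), `restenosis.csv` and
#' `densities.json` (kernel-density curves at the selected days).
#'
#' @param uq an `isr_uq` from [replicate_uq()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_uq_results <- function(uq, dir) {
  stopifnot(inherits(uq, "isr_uq"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (q in names(uq$qois)) {
    e <- uq$qois[[q]]
    rows[[q]] <- data.frame(qoi = q, day = uq$days,
                            mean = e$mean$estimate, sd = e$sd$estimate,
                            cv = e$cv$estimate,
                            mean_rep_sd = e$mean$rep_sd, sd_rep_sd = e$sd$rep_sd,
                            cv_rep_sd = e$cv$rep_sd)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "uq_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(day = uq$days,
                              restenosis_fraction = uq$restenosis$estimate,
                              rep_sd = uq$restenosis$rep_sd),
                   file.path(dir, "restenosis.csv"), row.names = FALSE)
  dens <- lapply(uq$qois, function(e)
    lapply(e$densities, function(d) list(x = d$x, y = d$y, bw = d$bw)))
  jsonlite::write_json(dens, file.path(dir, "densities.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write Sobol sensitivity tables
#'
#' `sobol_first.csv` / `sobol_total.csv` (rows = days, columns = parameters)
#' plus matching `*_ci.csv` files with the across-replicate 95% intervals.
#'
#' @param sens a `sobol_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sensitivity_results <- function(sens, dir) {
  stopifnot(inherits(sens, "sobol_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dump <- function(M, path) {
    df <- as.data.frame(t(M))
    colnames(df) <- sens$parameters
    df <- cbind(day = sens$days, df)
    utils::write.csv(df, path, row.names = FALSE)
  }
  dump(sens$first, file.path(dir, sprintf("sobol_first_%s.csv", sens$qoi)))
  dump(sens$total, file.path(dir, sprintf("sobol_total_%s.csv", sens$qoi)))
  for (band in c("first", "total")) {
    ci <- sens[[paste0("ci_", band)]]
    lo <- ci[1L, , ]; hi <- ci[2L, , ]
    dump(lo, file.path(dir, sprintf("sobol_%s_%s_ci_lo.csv", band, sens$qoi)))
    dump(hi, file.path(dir, sprintf("sobol_%s_%s_ci_hi.csv", band, sens$qoi)))
  }
  invisible(dir)
}
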