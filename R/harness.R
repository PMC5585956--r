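#' Relative percentage bias of an estimator
#'
#' `100 * (mean(estimates) - truth) / truth`.  A bias below 5% for
#' parameters (and 2.5% for pooled correlations) is conventionally
#' treated as acceptable in simulation work.
#'
#' @param estimates Numeric vector of estimates across replications.
#' @param truth Population value (nonzero).
#' @return Percent bias; `NA` with a warning when `truth` is 0.
#' @export
rel_bias <- function(estimates, truth) {
  if (truth == 0) {
    warning("relative bias undefined for truth = 0")
    return(NA_real_)
  }
  100 * (mean(estimates) - truth) / truth
}

#' Relative percentage bias of a standard-error estimator
#'
#' `100 * (mean(ses) - sd(estimates)) / sd(estimates)`: the mean
#' estimated standard error against the empirical standard deviation of
#' the estimates across replications.  Below 10% is conventionally
#' acceptable.
#'
#' @param ses Numeric vector of estimated standard errors.
#' @param estimates Matching vector of parameter estimates (>= 2).
#' @return Percent bias; `NA` with a warning on zero empirical SD.
#' @export
se_rel_bias <- function(ses, estimates) {
  stopifnot(length(estimates) >= 2)
  s <- sd(estimates)
  if (s == 0) {
    warning("SE bias undefined for zero empirical SD")
    return(NA_real_)
  }
  100 * (mean(ses) - s) / s
}

#' 95% Monte Carlo acceptance band for an empirical rejection rate
#'
#' The normal-approximation band `100 * (alpha +- 1.96 *
#' sqrt(alpha (1 - alpha) / reps))` within which an empirical rejection
#' percentage is consistent with the nominal level.
#'
#' @param alpha Nominal level.
#' @param reps Number of Monte Carlo replications.
#' @return Numeric c(low, high) in percent, e.g. c(3.65, 6.35) for
#'   alpha = 0.05 and 1000 replications.
#' @export
acceptance_band <- function(alpha = 0.05, reps = 1000) {
  stopifnot(reps > 0, alpha > 0, alpha < 1)
  half <- 1.96 * sqrt(alpha * (1 - alpha) / reps)
  100 * c(low = alpha - half, high = alpha + half)
}

.methods_all <- c("unir", "uniz", "mgls", "tssem")

stage1_fun <- function(method) {
  switch(method,
         unir = pool_unir, uniz = pool_uniz,
         mgls = pool_mgls, tssem = pool_tssem)
}

# population parameter truths per stage-2 route
.truth_ml <- c(gamma11 = 0.4, gamma12 = 0.5, gamma21 = 0.3, beta21 = 0.5,
               phi11 = 1, phi22 = 1, phi12 = 0.2,
               psi11 = 0.51, psi22 = 0.51)
.truth_wls <- c(gamma11 = 0.4, gamma12 = 0.5, gamma21 = 0.3, beta21 = 0.5,
                phi12 = 0.2, psi11 = 0.51, psi22 = 0.51)

#' Run all replications of one simulation cell
#'
#' For each replicate: generate a [simulate_meta()] study set, pool it
#' with each requested stage-1 method, and (optionally) fit the path
#' model at stage 2 — by ML at total N for the univariate methods, by
#' WLS with the stage-1 asymptotic covariance for MGLS and TSSEM.
#' Summaries follow the usual Monte Carlo conventions: rejection rates
#' are percentages of converged replicates, relative biases compare
#' means across replications with the population values, SE biases
#' compare mean estimated SEs with empirical SDs, and nonconvergent
#' replicates are excluded from parameter summaries but counted.
#'
#' @param cfg A [sim_cell_config()].
#' @param methods Subset of `c("unir", "uniz", "mgls", "tssem")`.
#' @param stage2 Methods for which the stage-2 fit is run (`TRUE` for
#'   all requested methods, `FALSE` for none, or a character subset).
#' @param keep_records Keep the per-replicate records in the result
#'   (used by bookkeeping checks).
#' @return An object of class `cell_summary`: per-method rejection
#'   rate, pooled-correlation relative biases, parameter and SE
#'   relative biases, chi-square mean and SD, and nonconvergence
#'   counts.
#' @export
run_cell <- function(cfg, methods = .methods_all, stage2 = TRUE,
                     keep_records = FALSE) {
  stopifnot(inherits(cfg, "sim_cell_config"))
  methods <- match.arg(methods, .methods_all, several.ok = TRUE)
  s2_methods <- if (isTRUE(stage2)) methods
                else if (isFALSE(stage2)) character(0)
                else match.arg(stage2, .methods_all, several.ok = TRUE)
  reps <- cfg$replications
  N <- sum(cfg$sizes)

  rec <- lapply(methods, function(m) {
    npar <- if (m %in% c("unir", "uniz")) 9L else 7L
    list(reject = rep(NA, reps), conv1 = rep(NA, reps),
         pooled = matrix(NA_real_, reps, 6),
         est = matrix(NA_real_, reps, npar),
         se = matrix(NA_real_, reps, npar),
         chisq = rep(NA_real_, reps), conv2 = rep(NA, reps))
  })
  names(rec) <- methods

  for (r in seq_len(reps)) {
    ss <- simulate_meta(cfg, r)
    for (m in methods) {
      s1 <- tryCatch(stage1_fun(m)(ss, alpha = cfg$alpha),
                     error = function(e) NULL)
      if (is.null(s1) || !isTRUE(s1$converged)) {
        rec[[m]]$conv1[r] <- FALSE
        next
      }
      rec[[m]]$conv1[r] <- TRUE
      rec[[m]]$reject[r] <- s1$reject
      rec[[m]]$pooled[r, ] <- s1$pooled
      if (!(m %in% s2_methods)) next
      s2 <- tryCatch({
        if (m %in% c("unir", "uniz"))
          fit_ml(s1$pooled_matrix, N)
        else
          fit_wls(s1$pooled, s1$acov)
      }, error = function(e) NULL)
      if (is.null(s2) || !isTRUE(s2$converged)) {
        rec[[m]]$conv2[r] <- FALSE
        next
      }
      rec[[m]]$conv2[r] <- TRUE
      rec[[m]]$est[r, ] <- s2$estimates
      rec[[m]]$se[r, ] <- s2$ses
      rec[[m]]$chisq[r] <- s2$chisq
    }
  }

  corr_truth <- corr_vector(sigma_pop())
  per_method <- lapply(methods, function(m) {
    x <- rec[[m]]
    ok1 <- which(x$conv1 %in% TRUE)
    ok2 <- which(x$conv2 %in% TRUE)
    truth <- if (m %in% c("unir", "uniz")) .truth_ml else .truth_wls
    out <- list(
      method = toupper(m),
      rejection_rate = if (length(ok1)) 100 * mean(x$reject[ok1]) else NA_real_,
      corr_rel_bias = if (length(ok1))
        vapply(1:6, function(j)
          rel_bias(x$pooled[ok1, j], corr_truth[j]), numeric(1))
        else rep(NA_real_, 6),
      param_rel_bias = if (length(ok2) >= 2)
        vapply(seq_along(truth), function(j)
          rel_bias(x$est[ok2, j], truth[j]), numeric(1))
        else rep(NA_real_, length(truth)),
      se_rel_bias = if (length(ok2) >= 2)
        vapply(seq_along(truth), function(j)
          se_rel_bias(x$se[ok2, j], x$est[ok2, j]), numeric(1))
        else rep(NA_real_, length(truth)),
      chisq_mean = if (length(ok2)) mean(x$chisq[ok2]) else NA_real_,
      chisq_sd = if (length(ok2) >= 2) sd(x$chisq[ok2]) else NA_real_,
      n_nonconverged_stage1 = sum(x$conv1 %in% FALSE),
      n_nonconverged_stage2 = sum(x$conv2 %in% FALSE),
      replications_used = length(ok1))
    names(out$corr_rel_bias) <- .vec_names
    names(out$param_rel_bias) <- names(truth)
    names(out$se_rel_bias) <- names(truth)
    out
  })
  names(per_method) <- methods

  structure(list(cell = list(k = cfg$k, nbar = cfg$nbar,
                             design = cfg$design,
                             het_fraction = cfg$het_fraction,
                             alpha = cfg$alpha,
                             replications = reps, seed = cfg$seed),
                 methods = per_method,
                 records = if (keep_records) rec else NULL),
            class = "cell_summary")
}

#' @export
print.cell_summary <- function(x, ...) {
  c0 <- x$cell
  cat(sprintf("Cell k = %d, nbar = %g, design %s, heterogeneity %g%%, %d reps\n",
              c0$k, c0$nbar, c0$design, 100 * c0$het_fraction,
              c0$replications))
  for (m in names(x$methods)) {
    s <- x$methods[[m]]
    cat(sprintf("  %-5s reject %5.1f%%  max|corr bias| %5.2f%%  chisq %s\n",
                s$method,
                s$rejection_rate,
                max(abs(s$corr_rel_bias)),
                if (is.na(s$chisq_mean)) "-" else
                  sprintf("%.2f (%.2f)", s$chisq_mean, s$chisq_sd)))
  }
  invisible(x)
}

#' Run a grid of simulation cells and tabulate the results
#'
#' Executes [run_cell()] over every row of a cell grid and assembles
#' long-format tables of rejection rates, pooled-correlation biases,
#' chi-square moments, and parameter/SE biases.  When `out_dir` is
#' given the tables are written as CSV plus a JSON dump of all cell
#' summaries.
#'
#' @param grid Data frame with columns `k`, `nbar`, `design` and
#'   optionally `het_fraction` (default 0) and `replications`.
#' @param methods Stage-1 methods to run.
#' @param replications Default replication count for rows without their
#'   own `replications` column.
#' @param seed Base seed shared by every cell (cells are independent
#'   substreams).
#' @param stage2 Passed to [run_cell()].
#' @param out_dir Optional output directory for CSV/JSON files.
#' @param verbose Print one line per finished cell.
#' @return A list with `cells` (the `cell_summary` objects) and
#'   `tables` (data frames `rejection`, `corr_bias`, `chisq`,
#'   `param_bias`, `se_bias`).
#' @export
run_grid <- function(grid, methods = .methods_all, replications = 1000,
                     seed = 1, stage2 = TRUE, out_dir = NULL,
                     verbose = FALSE) {
  stopifnot(all(c("k", "nbar", "design") %in% names(grid)))
  if (is.null(grid$het_fraction)) grid$het_fraction <- 0
  if (is.null(grid$replications)) grid$replications <- replications
  cells <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_cell_config(grid$k[i], grid$nbar[i], grid$design[i],
                           het_fraction = grid$het_fraction[i],
                           replications = grid$replications[i],
                           seed = seed)
    cells[[i]] <- run_cell(cfg, methods = methods, stage2 = stage2)
    if (verbose) {
      cat(sprintf("[%d/%d] ", i, nrow(grid)))
      print(cells[[i]])
    }
  }
  tables <- summarize_grid(cells)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      utils::write.csv(tables[[nm]],
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(cells, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(cells = cells, tables = tables)
}

#' Assemble long-format tables from a list of cell summaries
#'
#' @param cells List of `cell_summary` objects from [run_cell()].
#' @return Named list of data frames: `rejection` (type I error or
#'   power per cell and method), `corr_bias`, `chisq`, `param_bias`,
#'   `se_bias`.
#' @export
summarize_grid <- function(cells) {
  row0 <- function(cs, m) {
    c0 <- cs$cell
    data.frame(k = c0$k, nbar = c0$nbar, design = c0$design,
               het = c0$het_fraction, method = toupper(m),
               stringsAsFactors = FALSE)
  }
  grab <- function(extract) {
    do.call(rbind, unlist(lapply(cells, function(cs)
      lapply(names(cs$methods), function(m)
        cbind(row0(cs, m), extract(cs$methods[[m]])))),
      recursive = FALSE))
  }
  list(
    rejection = grab(function(s)
      data.frame(rejection_pct = s$rejection_rate,
                 n_nonconverged = s$n_nonconverged_stage1,
                 replications_used = s$replications_used)),
    corr_bias = grab(function(s)
      as.data.frame(as.list(s$corr_rel_bias))),
    chisq = grab(function(s)
      data.frame(chisq_mean = s$chisq_mean, chisq_sd = s$chisq_sd,
                 n_nonconverged_stage2 = s$n_nonconverged_stage2)),
    param_bias = grab(function(s)
      as.data.frame(as.list(s$param_rel_bias))),
    se_bias = grab(function(s)
      as.data.frame(as.list(s$se_rel_bias))))
}
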