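#' Sample-size allocation designs
#'
#' Returns the tier structure of a sample-size design: fractions of the
#' k studies per tier and the multiplier applied to the average study
#' size n-bar.  The three designs share the same total sample size
#' k * n-bar:
#' * `"E"` (equal): one tier, every study of size n-bar.
#' * `"M"` (moderately unequal): 60% small studies at 0.6 n-bar, 40%
#'   large at 1.6 n-bar (large/small ratio 8/3, about 2.7).
#' * `"H"` (highly unequal): 40% small at 0.4 n-bar, 20% medium at
#'   n-bar, 40% large at 1.6 n-bar (large = 1.6x medium = 4x small).
#'
#' @param label One of `"E"`, `"M"`, `"H"`.
#' @return A list with `label`, `fractions` and `multipliers`.
#' @export
size_design <- function(label = c("E", "M", "H")) {
  label <- match.arg(label)
  tiers <- switch(label,
    E = list(fractions = 1,              multipliers = 1),
    M = list(fractions = c(0.6, 0.4),    multipliers = c(0.6, 1.6)),
    H = list(fractions = c(0.4, 0.2, 0.4), multipliers = c(0.4, 1.0, 1.6)))
  structure(c(list(label = label), tiers), class = "size_design")
}

#' Allocate per-study sample sizes under a design
#'
#' Splits the total sample size k * nbar over k studies according to the
#' tier fractions and multipliers of a [size_design()].  For example,
#' k = 5 studies at nbar = 50 give c(30, 30, 30, 80, 80) under `"M"` and
#' c(20, 20, 50, 80, 80) under `"H"`.
#'
#' @param k Number of studies.
#' @param nbar Average sample size per study.
#' @param design A design label (`"E"`, `"M"`, `"H"`) or [size_design()].
#' @return Integer vector of k sizes in ascending order, summing to
#'   k * nbar.  Errors when a tier's study count or size would be
#'   non-integral.
#' @export
allocate_sizes <- function(k, nbar, design = "E") {
  if (is.character(design)) design <- size_design(design)
  stopifnot(inherits(design, "size_design"), k >= 1, nbar >= 10)
  counts <- design$fractions * k
  sizes <- design$multipliers * nbar
  for (t in seq_along(counts)) {
    if (abs(counts[t] - round(counts[t])) > 1e-8)
      stop(sprintf("design %s tier %d: fraction %.2f of k = %d studies is not integral",
                   design$label, t, design$fractions[t], k))
    if (abs(sizes[t] - round(sizes[t])) > 1e-8)
      stop(sprintf("design %s tier %d: multiplier %.2f of nbar = %g is not integral",
                   design$label, t, design$multipliers[t], nbar))
  }
  out <- rep(as.integer(round(sizes)), times = as.integer(round(counts)))
  sort(out)
}

#' Assign population labels to studies under mixture heterogeneity
#'
#' Flags `round(het_fraction * k)` studies as drawn from the alternative
#' population matrix; the flagged studies are the smallest ones, with
#' ties broken by list position (so under the equal design the first
#' studies by index are flagged).  Rounding of half counts is half-up by
#' default (k = 5 with 50% heterogeneity flags 3 studies); set
#' `half = "down"` to flag 2 instead.
#'
#' @param sizes Integer vector of study sizes sorted ascending.
#' @param het_fraction Proportion of studies drawn from the alternative
#'   population, in `[0, 1)`.
#' @param half Tie rule for half-integer counts: `"up"` or `"down"`.
#' @return Character vector of per-study labels, `"sigma"` or
#'   `"sigma_prime"`.
#' @export
assign_populations <- function(sizes, het_fraction, half = c("up", "down")) {
  half <- match.arg(half)
  stopifnot(het_fraction >= 0, het_fraction < 1, !is.unsorted(sizes))
  k <- length(sizes)
  x <- het_fraction * k
  m <- if (half == "up") floor(x + 0.5) else ceiling(x - 0.5)
  labels <- rep("sigma", k)
  if (m > 0) labels[seq_len(m)] <- "sigma_prime"
  labels
}

#' Simulate one study's sample correlation matrix
#'
#' Draws `n` i.i.d. observations from a mean-zero multivariate normal
#' with covariance `pop` (via the Cholesky factor of `pop`) and returns
#' their Pearson correlation matrix.
#'
#' @param n Sample size (at least 5).
#' @param pop 4x4 positive definite population correlation matrix.
#' @param seed Optional integer seed applied before sampling; when
#'   `NULL` the current RNG stream is used.
#' @return 4x4 sample correlation matrix.
#' @export
simulate_study <- function(n, pop, seed = NULL) {
  pop <- as.matrix(pop)
  stopifnot(n >= 5)
  L <- tryCatch(chol(pop), error = function(e)
    stop("population matrix is not positive definite"))
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * ncol(pop)), n, ncol(pop)) %*% L
  stats::cor(X)
}

#' Configuration of one simulation cell
#'
#' A cell of the Monte Carlo grid: `k` studies of average size `nbar`
#' under one sample-size design, with a fraction of studies drawn from
#' the alternative population matrix.
#'
#' @param k Number of studies (5, 10 or 15 in the replication grid;
#'   other values are allowed if the design tiers remain integral).
#' @param nbar Average sample size per study (at least 10).
#' @param design `"E"`, `"M"` or `"H"` (see [size_design()]).
#' @param het_fraction Proportion of studies from [sigma_prime()]
#'   (0, 0.2 or 0.5 in the replication grid).
#' @param alpha Homogeneity test level.
#' @param replications Monte Carlo replication count.
#' @param seed Base seed of the cell; replicate streams are derived from
#'   it deterministically (see [simulate_meta()]).
#' @param het_half Tie rule for half-integer heterogeneous-study counts
#'   (see [assign_populations()]).
#' @return An object of class `sim_cell_config`.
#' @export
sim_cell_config <- function(k, nbar, design = "E", het_fraction = 0,
                            alpha = 0.05, replications = 1000, seed = 1,
                            het_half = "up") {
  stopifnot(nbar >= 10, het_fraction >= 0, het_fraction < 1,
            alpha > 0, alpha < 1, replications >= 0)
  sizes <- allocate_sizes(k, nbar, design)  # validates integrality
  structure(list(k = as.integer(k), nbar = nbar, design = design,
                 het_fraction = het_fraction, alpha = alpha,
                 replications = as.integer(replications),
                 seed = as.integer(seed), het_half = het_half,
                 sizes = sizes),
            class = "sim_cell_config")
}

# Deterministic hash of cell identity and replicate index into a seed in
# [1, 2^31 - 2], so any single replicate is reproducible in isolation.
cell_seed <- function(seed, k, nbar, design, het_fraction, replicate) {
  dcode <- match(design, c("E", "M", "H"))
  ints <- c(seed, k, nbar, dcode, round(1000 * het_fraction), replicate)
  h <- 104729
  for (v in ints) h <- (h * 69069 + v + 1) %% 2147483647
  as.integer(h) + 1L
}

#' Simulate one meta-analysis replicate
#'
#' Generates one `study_set`: per-study sample sizes from
#' [allocate_sizes()], population labels from [assign_populations()],
#' and a sample correlation matrix per study from [simulate_study()].
#' The RNG is seeded from a hash of (seed, cell identity, replicate), so
#' each replicate is reproducible in isolation and distinct replicates
#' use distinct streams.
#'
#' @param cfg A [sim_cell_config()].
#' @param replicate Replicate index (positive integer).
#' @return An object of class `study_set`: a list with `n` (sizes),
#'   `R` (list of correlation matrices), `labels` (population flags).
#' @export
simulate_meta <- function(cfg, replicate = 1L) {
  stopifnot(inherits(cfg, "sim_cell_config"), replicate >= 1)
  sizes <- cfg$sizes
  labels <- assign_populations(sizes, cfg$het_fraction, half = cfg$het_half)
  set.seed(cell_seed(cfg$seed, cfg$k, cfg$nbar, cfg$design,
                     cfg$het_fraction, replicate))
  pops <- list(sigma = sigma_pop(), sigma_prime = sigma_prime())
  R <- vector("list", length(sizes))
  for (i in seq_along(sizes))
    R[[i]] <- simulate_study(sizes[i], pops[[labels[i]]])
  study_set(sizes, R, labels)
}

#' Construct a study set
#'
#' A `study_set` holds the k (sample size, sample correlation matrix)
#' pairs forming one meta-analysis, plus per-study population labels.
#'
#' @param n Integer vector of study sizes (each at least 5).
#' @param R List of 4x4 sample correlation matrices.
#' @param labels Optional character vector of population flags.
#' @return An object of class `study_set`.
#' @export
study_set <- function(n, R, labels = NULL) {
  stopifnot(length(n) == length(R), all(n >= 5))
  for (Ri in R) {
    Ri <- as.matrix(Ri)
    if (max(abs(Ri - t(Ri))) > 1e-8 || max(abs(diag(Ri) - 1)) > 1e-8 ||
        max(abs(Ri)) > 1 + 1e-8)
      stop("each 'R' must be a symmetric correlation matrix with unit diagonal")
  }
  if (is.null(labels)) labels <- rep("sigma", length(n))
  structure(list(n = as.integer(n), R = lapply(R, as.matrix),
                 labels = labels),
            class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  cat(sprintf("study_set: %d studies, total N = %d\n",
              length(x$n), sum(x$n)))
  cat("  sizes:", paste(x$n, collapse = ", "), "\n")
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}
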