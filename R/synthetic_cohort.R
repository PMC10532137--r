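#' Metric names and display labels of the per-subject record
#'
#' Per-subject metric vector of the craniospinal flow study: CSF stroke
#' volumes at the aqueduct, foramen magnum, prepontine cistern and upper
#' cervical level, tonsil-motion stroke volume, syrinx stroke volume
#' (syrinx group only), mean cerebral arterial blood flow, vascular
#' (arteriovenous) stroke volume and the venous drainage repartition
#' factor.
#'
#' @return Named character vector mapping internal metric names to display
#'   labels with units.
#' @export
metric_labels <- function() {
  c(sv_csf_aqu  = "SV_CSF-aqu (µL/CC)",
    sv_csf_fm   = "SV_CSF-FM (µL/CC)",
    sv_tonsils  = "SV_tonsils (µL/CC)",
    sv_csf_ppc  = "SV_CSF-PPC (µL/CC)",
    sv_csf_cerv = "SV_CSF-cerv (µL/CC)",
    sv_syrinx   = "SV_syrinx (µL/CC)",
    cbfa        = "CBF (mL/min)",
    sv_blood    = "SV_blood (mL/CC)",
    alpha       = "α-factor")
}

#' Reference cohort statistics of the two Chiari groups
#'
#' Published group-level statistics used as the synthetic-cohort defaults:
#' per-metric means and SDs in each group (with or without a syrinx) and
#' the group-wise pairwise correlation targets between the vascular stroke
#' volume / alpha factor and the hydrodynamic metrics. Pairs without a
#' published value default to correlation 0 (an assumption, not a
#' measurement).
#'
#' @return A list with elements `means` (data.frame metric x group),
#'   `sds` (same shape) and `correlations` (data.frame with columns
#'   `metric_x`, `metric_y`, `group`, `r`).
#' @export
reference_cohort_stats <- function() {
  metrics <- names(metric_labels())
  means <- data.frame(
    metric = metrics,
    CS_with_syrinx    = c(47, 484, 181, 365, 587, 47, 728, 0.83, 1.46),
    CS_without_syrinx = c(39, 464, 181, 309, 584, NA, 685, 0.81, 1.49))
  sds <- data.frame(
    metric = metrics,
    CS_with_syrinx    = c(35, 193, 106, 169, 167, 7, 192, 0.19, 0.26),
    CS_without_syrinx = c(26, 208, 128, 212, 162, NA, 133, 0.27, 0.17))
  cor_pairs <- rbind(
    data.frame(metric_x = "sv_blood",
               metric_y = c("sv_csf_fm", "sv_csf_ppc", "sv_tonsils",
                            "sv_csf_cerv"),
               CS_with_syrinx    = c(0.32, 0.48, 0.17, 0.04),
               CS_without_syrinx = c(0.38, 0.15, -0.22, 0.67)),
    data.frame(metric_x = "alpha",
               metric_y = c("cbfa", "sv_csf_fm", "sv_tonsils",
                            "sv_csf_ppc", "sv_csf_cerv"),
               CS_with_syrinx    = c(0.46, -0.61, 0.47, -0.40, -0.80),
               CS_without_syrinx = c(0.36, -0.23, 0.30, -0.31, -0.05)))
  correlations <- rbind(
    data.frame(metric_x = cor_pairs$metric_x, metric_y = cor_pairs$metric_y,
               group = "CS_with_syrinx", r = cor_pairs$CS_with_syrinx),
    data.frame(metric_x = cor_pairs$metric_x, metric_y = cor_pairs$metric_y,
               group = "CS_without_syrinx", r = cor_pairs$CS_without_syrinx))
  list(means = means, sds = sds, correlations = correlations)
}

#' Two-group cohort specification
#'
#' @param n_with_syrinx,n_without_syrinx Group sizes; defaults 9 and 19,
#'   the study's group sizes.
#' @param means,sds Data frames as in [reference_cohort_stats()]; defaults
#'   are the published group statistics.
#' @param correlations Data frame of pairwise correlation targets
#'   (`metric_x`, `metric_y`, `group`, `r`); unlisted pairs default to 0.
#' @param repair_tol Maximum admissible absolute shift of any *specified*
#'   correlation target during positive-semidefinite completion; if the
#'   targets cannot be realised within this tolerance the generator stops
#'   and names the offending pairs.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_with_syrinx = 9L, n_without_syrinx = 19L,
                        means = NULL, sds = NULL, correlations = NULL,
                        repair_tol = 0.02, seed = 1L) {
  ref <- reference_cohort_stats()
  if (is.null(means)) means <- ref$means
  if (is.null(sds)) sds <- ref$sds
  if (is.null(correlations)) correlations <- ref$correlations
  for (g in c("CS_with_syrinx", "CS_without_syrinx")) {
    s <- sds[[g]]
    if (any(!is.na(s) & s <= 0)) stop("SDs must be positive (group ", g, ")")
  }
  if (any(abs(correlations$r) > 1)) stop("correlation targets must be in [-1, 1]")
  structure(list(n_with_syrinx = as.integer(n_with_syrinx),
                 n_without_syrinx = as.integer(n_without_syrinx),
                 means = means, sds = sds, correlations = correlations,
                 repair_tol = repair_tol, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Positive-semidefinite completion of a correlation matrix with fixed
# entries. `target` carries the wanted values; `fixed` marks entries
# (incl. the diagonal) that must be preserved exactly; free entries start
# at their defaults (0) and move as needed. Alternating projections
# between the PSD cone and the fixed-entry affine set.
.complete_correlation_psd <- function(target, fixed, tol = 0.02,
                                      max_iter = 5000L) {
  P <- target
  for (it in seq_len(max_iter)) {
    e <- eigen(P, symmetric = TRUE)
    Ppsd <- e$vectors %*% diag(pmax(e$values, 1e-7)) %*% t(e$vectors)
    Ppsd <- (Ppsd + t(Ppsd)) / 2
    d <- sqrt(diag(Ppsd))
    Ppsd <- Ppsd / outer(d, d)
    if (max(abs(Ppsd[fixed] - target[fixed])) < 1e-8) break
    P <- Ppsd
    P[fixed] <- target[fixed]
  }
  dimnames(Ppsd) <- dimnames(target)
  # Ppsd is a valid correlation matrix; check the specified targets held
  dev <- abs(Ppsd - target)
  dev[!fixed] <- 0
  if (max(dev) > tol) {
    bad <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    nm <- rownames(target)
    stop("correlation targets are infeasible: pair (",
         nm[bad[1]], ", ", nm[bad[2]], ") can only be realised ",
         signif(max(dev), 3), " away from its target")
  }
  Ppsd
}

# assemble the per-group correlation matrix (targets fixed, rest 0)
.group_correlation <- function(metrics, correlations, group, tol) {
  p <- length(metrics)
  R <- diag(p); dimnames(R) <- list(metrics, metrics)
  fixed <- diag(p) == 1; dimnames(fixed) <- dimnames(R)
  rows <- correlations[correlations$group == group, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    a <- rows$metric_x[i]; b <- rows$metric_y[i]
    if (!(a %in% metrics) || !(b %in% metrics)) next
    R[a, b] <- R[b, a] <- rows$r[i]
    fixed[a, b] <- fixed[b, a] <- TRUE
  }
  .complete_correlation_psd(R, fixed, tol = tol)
}

# draw one group, truncating at 0 by rejection (resampling whole subject
# rows preserves the correlation structure, unlike clipping)
.draw_group <- function(n, mu, sigma_diag, R, max_tries = 200L) {
  Sigma <- diag(sigma_diag) %*% R %*% diag(sigma_diag)
  out <- matrix(NA_real_, 0L, length(mu))
  need <- n
  for (i in seq_len(max_tries)) {
    X <- MASS::mvrnorm(max(2L * need, 16L), mu = mu, Sigma = Sigma,
                       tol = 1e-5)
    ok <- rowSums(X < 0) == 0L
    out <- rbind(out, X[ok, , drop = FALSE])
    if (nrow(out) >= n) break
    need <- n - nrow(out)
  }
  if (nrow(out) < n)
    stop("truncation rejection failed; means/SDs place too much mass ",
         "below zero")
  out[seq_len(n), , drop = FALSE]
}

#' Generate a two-group synthetic subject cohort
#'
#' Draws per-subject metric vectors from group-specific multivariate
#' normal distributions with the specified means, SDs and pairwise
#' correlation targets (completed to a valid correlation matrix while
#' holding the specified targets fixed), truncated at zero by resampling
#' so no volume or flow is negative. The syrinx stroke volume exists only
#' in the with-syrinx group and is `NA` elsewhere.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with columns `subject_id`, `group` and one column
#'   per metric of [metric_labels()].
#' @export
make_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("expected a cohort_spec")
  set.seed(spec$seed)
  metrics <- spec$means$metric
  groups <- list(CS_with_syrinx = spec$n_with_syrinx,
                 CS_without_syrinx = spec$n_without_syrinx)
  out <- list()
  for (g in names(groups)) {
    mu <- spec$means[[g]]; sd_ <- spec$sds[[g]]
    keep <- !is.na(mu) & !is.na(sd_)
    mg <- metrics[keep]
    R <- .group_correlation(mg, spec$correlations, g, spec$repair_tol)
    X <- .draw_group(groups[[g]], mu[keep], sd_[keep], R)
    colnames(X) <- mg
    df <- as.data.frame(X)
    for (m in setdiff(metrics, mg)) df[[m]] <- NA_real_
    df <- df[, metrics, drop = FALSE]
    df <- cbind(group = g, df)
    out[[g]] <- df
  }
  cohort <- do.call(rbind, out)
  cohort <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(cohort))),
                  cohort)
  rownames(cohort) <- NULL
  cohort
}
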