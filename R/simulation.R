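#' Study layouts for the operating-characteristics engine
#'
#' Three built-in layouts of two- and three-arm designs over four treatments
#' A, B, C, D:
#' \describe{
#'   \item{run1}{2 studies of each of the five designs ABC, ABD, AB, AC, AD
#'     (10 studies, 14 estimated treatment effects).}
#'   \item{run2}{10 studies of each of the same five designs (50 studies,
#'     70 effects).}
#'   \item{run3}{5 studies of each of all ten two- and three-arm designs
#'     ABC, ABD, ACD, BCD, AB, AC, AD, BC, BD, CD (50 studies, 70 effects).}
#' }
#'
#' @param layout `"run1"`, `"run2"` or `"run3"`.
#' @param n_per_design Optional override of the number of studies per design.
#'
#' @return A tibble with a list-column `treatments` and a column `n` (studies
#'   per design); the same shape can be hand-built for custom layouts.
#' @examples
#' sim_layout("run1")
#' @export
sim_layout <- function(layout = c("run1", "run2", "run3"),
                       n_per_design = NULL) {
  layout <- match.arg(layout)
  three <- list(c("A", "B", "C"), c("A", "B", "D"))
  two5 <- list(c("A", "B"), c("A", "C"), c("A", "D"))
  designs <- switch(layout,
    run1 = ,
    run2 = c(three, two5),
    run3 = c(
      three, list(c("A", "C", "D"), c("B", "C", "D")), two5,
      list(c("B", "C"), c("B", "D"), c("C", "D"))
    )
  )
  n <- if (!is.null(n_per_design)) {
    n_per_design
  } else {
    switch(layout, run1 = 2L, run2 = 10L, run3 = 5L)
  }
  tibble::tibble(treatments = designs, n = as.integer(n))
}

as_layout <- function(layout, n_per_design = NULL) {
  if (is.character(layout) && length(layout) == 1L) {
    return(sim_layout(layout, n_per_design))
  }
  layout <- tibble::as_tibble(layout)
  if (!all(c("treatments", "n") %in% names(layout)) ||
    !is.list(layout$treatments)) {
    stop("A custom layout must be a data frame with a list-column ",
      "`treatments` and a column `n`.",
      call. = FALSE
    )
  }
  layout
}

#' Draw truncated scaled chi-squared within-study variances
#'
#' Samples within-study variances as `scale` times chi-squared(1) deviates,
#' rejection-sampled until they fall inside `bounds` (inclusive). With the
#' defaults (scale 0.25, bounds 0.009 to 0.6) this is the classic generator
#' for the sampling variances of log odds ratios in meta-analysis simulation
#' studies.
#'
#' @param n Number of draws.
#' @param scale Multiplier of the chi-squared(1) deviate.
#' @param bounds Length-2 numeric, inclusive truncation interval.
#'
#' @return Numeric vector of length `n`, all values inside `bounds`.
#' @examples
#' set.seed(1)
#' range(sample_within_variance(1000))
#' @export
sample_within_variance <- function(n, scale = 0.25, bounds = c(0.009, 0.6)) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- scale * stats::rchisq(max(n, 32L), df = 1)
    out <- c(out, draw[draw >= bounds[1] & draw <= bounds[2]])
  }
  out[seq_len(n)]
}

# Skeleton: a full nma_network built once for a layout with placeholder data;
# simulated replicates substitute y and the within-study blocks.
layout_skeleton <- function(layout) {
  rows <- list()
  covs <- list()
  s <- 0L
  for (d in seq_len(nrow(layout))) {
    des <- canonicalize_design(layout$treatments[[d]])
    for (i in seq_len(layout$n[d])) {
      s <- s + 1L
      sid <- sprintf("s%03d", s)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        study = sid, base = des$baseline, treat = des$contrasts,
        y = 0, v = 1
      )
      if (des$c_d > 1L) {
        pr <- utils::combn(des$contrasts, 2L)
        covs[[length(covs) + 1L]] <- tibble::tibble(
          study = sid, treat_i = pr[1L, ], treat_j = pr[2L, ], cov = 0.5
        )
      }
    }
  }
  nma_network(
    dplyr::bind_rows(rows),
    cov = if (length(covs)) dplyr::bind_rows(covs) else NULL
  )
}

# One replicate: fresh within-study variances, S_di = sigma^2 P_cd, and Y
# drawn from the marginal model N(X delta, S + tau_beta^2 P1 + tau_omega^2 P2).
sim_draw <- function(skel, tau_beta_sq, tau_omega_sq, mu,
                     var_scale = 0.25, var_bounds = c(0.009, 0.6)) {
  ns <- length(skel$studies)
  sigma2 <- sample_within_variance(ns, var_scale, var_bounds)
  N <- skel$N
  S <- matrix(0, N, N)
  S_blocks <- vector("list", ns)
  for (j in seq_len(ns)) {
    idx <- skel$rows_by_study[[j]]
    P <- pcd_matrix(length(idx))
    S_blocks[[j]] <- sigma2[j] * P
    S[idx, idx] <- S_blocks[[j]]
  }
  Sigma <- S
  if (tau_beta_sq > 0) Sigma <- Sigma + tau_beta_sq * skel$P1
  if (tau_omega_sq > 0) Sigma <- Sigma + tau_omega_sq * skel$P2
  y <- mu + drop(crossprod(chol(Sigma), stats::rnorm(N)))
  list(y = y, S_blocks = S_blocks, S = S)
}

#' Simulate a network meta-analysis dataset
#'
#' Generates one synthetic contrast-level dataset: per-study within-study
#' variances are drawn from the truncated scaled chi-squared generator,
#' within-study covariance matrices are `sigma^2 * P_cd` (within-study
#' correlation 0.5, reflecting equal allocation across arms), and the vector
#' of estimated effects is drawn from the marginal model with the requested
#' heterogeneity and inconsistency variances.
#'
#' @param layout A layout name (`"run1"`, `"run2"`, `"run3"`) or a custom
#'   layout tibble as returned by [sim_layout()].
#' @param tau_beta_sq Between-study heterogeneity variance.
#' @param tau_omega_sq Inconsistency variance.
#' @param delta True basic parameters: a scalar (recycled) or a named vector;
#'   defaults to 0.
#' @param n_per_design Optional override of studies per design.
#' @param seed Optional integer seed.
#' @param var_scale,var_bounds Parameters of the within-study variance
#'   generator (see [sample_within_variance()]).
#'
#' @return An [nma_network()] with simulated `y` and within-study covariances.
#' @examples
#' net <- simulate_network("run1", tau_beta_sq = 0.024, tau_omega_sq = 0, seed = 1)
#' net
#' @export
simulate_network <- function(layout, tau_beta_sq, tau_omega_sq, delta = 0,
                             n_per_design = NULL, seed = NULL,
                             var_scale = 0.25, var_bounds = c(0.009, 0.6)) {
  if (!is.null(seed)) set.seed(seed)
  lay <- as_layout(layout, n_per_design)
  skel <- layout_skeleton(lay)
  mu <- layout_mean(skel, delta)
  dr <- sim_draw(skel, tau_beta_sq, tau_omega_sq, mu, var_scale, var_bounds)

  rows <- skel$data
  rows$y <- dr$y
  covs <- list()
  for (j in seq_along(skel$studies)) {
    idx <- skel$rows_by_study[[j]]
    rows$v[idx] <- diag(dr$S_blocks[[j]])
    if (length(idx) > 1L) {
      tr <- rows$treat[idx]
      pr <- utils::combn(seq_along(idx), 2L)
      covs[[length(covs) + 1L]] <- tibble::tibble(
        study = rows$study[idx[1L]],
        treat_i = tr[pr[1L, ]], treat_j = tr[pr[2L, ]],
        cov = dr$S_blocks[[j]][cbind(pr[1L, ], pr[2L, ])]
      )
    }
  }
  nma_network(rows, cov = if (length(covs)) dplyr::bind_rows(covs) else NULL)
}

layout_mean <- function(skel, delta) {
  cvec <- numeric(skel$c)
  names(cvec) <- skel$basic
  if (length(delta) == 1L && is.null(names(delta))) {
    cvec[] <- delta
  } else {
    if (is.null(names(delta)) || !all(names(delta) %in% skel$basic)) {
      stop("`delta` must be a scalar or a vector named by the basic parameters (",
        paste(skel$basic, collapse = ", "), ").",
        call. = FALSE
      )
    }
    cvec[names(delta)] <- delta
  }
  mu <- drop(skel$X %*% cvec)
  attr(mu, "delta") <- cvec
  mu
}

#' Excess kurtosis of a sample
#'
#' Raw moment-ratio estimator `m4 / m2^2 - 3` using central sample moments,
#' without small-sample bias correction. Zero for a normal distribution.
#'
#' @param x Numeric vector with at least 4 observations and positive variance.
#' @return A scalar.
#' @examples
#' excess_kurtosis(c(-1, 1, -1, 1)) # -2
#' @export
excess_kurtosis <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("Need at least 4 observations.", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("Zero variance: kurtosis undefined.", call. = FALSE)
  mean((x - m)^4) / m2^2 - 3
}

#' Operating-characteristics simulation study
#'
#' For every combination of heterogeneity and inconsistency variance in the
#' grid, repeatedly simulates datasets from the marginal model on the given
#' layout, fits the requested model, and summarises: empirical standard error
#' (SD of the point estimates), mean model-based standard error, coverage of
#' the nominal-level normal confidence interval, excess kurtosis of the point
#' estimates, and the mean and SD of the (truncated) variance-component
#' estimates together with the mean untruncated estimates.
#'
#' One master seed spawns an independent sub-seed per grid cell, so any cell
#' can be reproduced in isolation. Replicates in which the fit fails (e.g. an
#' identifiability error) are counted in `n_failed`, not silently dropped.
#'
#' @param layout Layout name or custom layout tibble (see [sim_layout()]).
#' @param tau_beta_sq,tau_omega_sq Numeric vectors of generating variance
#'   values; the study runs on their cross product.
#' @param n_reps Simulated datasets per grid cell.
#' @param seed Master seed.
#' @param model `"ri"` or `"rc"` -- the model fitted to each replicate.
#' @param level Nominal confidence level.
#' @param delta True basic parameters (scalar or named vector; default 0).
#' @param rc_estimator Heterogeneity estimator when `model = "rc"`.
#' @param n_per_design,var_scale,var_bounds Passed to the generator.
#'
#' @return A tibble of class `nma_sim` with one row per grid cell and basic
#'   parameter: columns `tau_beta_sq`, `tau_omega_sq`, `parameter`, `se_emp`,
#'   `se_model`, `coverage`, `excess_kurtosis`, plus cell-level
#'   variance-component summaries (`tau_beta_mean`, `tau_beta_sd`,
#'   `tau_omega_mean`, `tau_omega_sd`, untruncated means), `n_reps`,
#'   `n_failed` and the cell seed.
#' @examples
#' run_simulation_study("run1",
#'   tau_beta_sq = 0, tau_omega_sq = 0,
#'   n_reps = 50, seed = 1
#' )
#' @export
run_simulation_study <- function(layout = "run1",
                                 tau_beta_sq = c(0, 0.024, 0.168),
                                 tau_omega_sq = c(0, 0.024, 0.168),
                                 n_reps = 3000, seed = 1,
                                 model = c("ri", "rc"),
                                 level = 0.95, delta = 0,
                                 rc_estimator = "qnet",
                                 n_per_design = NULL,
                                 var_scale = 0.25, var_bounds = c(0.009, 0.6)) {
  model <- match.arg(model)
  if (n_reps < 2) stop("`n_reps` must be at least 2.", call. = FALSE)
  lay <- as_layout(layout, n_per_design)
  skel <- layout_skeleton(lay)
  mu <- layout_mean(skel, delta)
  true_delta <- attr(mu, "delta")
  grid <- expand.grid(
    tau_beta_sq = tau_beta_sq, tau_omega_sq = tau_omega_sq,
    KEEP.OUT.ATTRS = FALSE
  )
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  z <- stats::qnorm((1 + level) / 2)
  cpar <- skel$c

  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    tb <- grid$tau_beta_sq[g]
    tw <- grid$tau_omega_sq[g]
    set.seed(cell_seeds[g])
    est <- matrix(NA_real_, n_reps, cpar)
    sem <- matrix(NA_real_, n_reps, cpar)
    taus <- matrix(NA_real_, n_reps, 4L) # trunc b, trunc w, untrunc b, untrunc w
    n_failed <- 0L
    for (r in seq_len(n_reps)) {
      dr <- sim_draw(skel, tb, tw, mu, var_scale, var_bounds)
      ft <- tryCatch(
        fit_core(skel,
          y = dr$y, S_blocks = dr$S_blocks, S = dr$S,
          model = model, rc_estimator = rc_estimator
        ),
        error = function(e) NULL
      )
      if (is.null(ft)) {
        n_failed <- n_failed + 1L
        next
      }
      est[r, ] <- ft$delta
      sem[r, ] <- ft$se
      taus[r, ] <- c(
        ft$tau_beta_sq, ft$tau_omega_sq,
        ft$tau_beta_sq_untrunc, ft$tau_omega_sq_untrunc
      )
    }
    ok <- !is.na(est[, 1L])
    res <- purrr::map_dfr(seq_len(cpar), function(p) {
      e <- est[ok, p]
      s <- sem[ok, p]
      tibble::tibble(
        parameter = skel$basic[p],
        se_emp = stats::sd(e),
        se_model = mean(s),
        coverage = mean(abs(e - true_delta[p]) <= z * s),
        excess_kurtosis = excess_kurtosis(e)
      )
    })
    res$tau_beta_sq <- tb
    res$tau_omega_sq <- tw
    res$tau_beta_mean <- mean(taus[ok, 1L])
    res$tau_beta_sd <- stats::sd(taus[ok, 1L])
    res$tau_omega_mean <- mean(taus[ok, 2L])
    res$tau_omega_sd <- stats::sd(taus[ok, 2L])
    res$tau_beta_mean_untrunc <- mean(taus[ok, 3L])
    res$tau_omega_mean_untrunc <- mean(taus[ok, 4L])
    res$tau_beta_sd_untrunc <- stats::sd(taus[ok, 3L])
    res$tau_omega_sd_untrunc <- stats::sd(taus[ok, 4L])
    res$n_reps <- sum(ok)
    res$n_failed <- n_failed
    res$cell_seed <- cell_seeds[g]
    out[[g]] <- res
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::relocate(res, "tau_beta_sq", "tau_omega_sq", "parameter")
  attr(res, "model") <- toupper(model)
  attr(res, "level") <- level
  attr(res, "seed") <- seed
  class(res) <- c("nma_sim", class(res))
  res
}
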