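#' Linear combinations of basic parameters
#'
#' Estimates arbitrary treatment contrasts `L %*% delta` from a fitted model,
#' with covariance `L %*% Var(delta) %*% t(L)`. All relative effects in a
#' connected network are linear combinations of the basic parameters; for
#' example the B-versus-C effect is the difference between the C-versus-A and
#' B-versus-A rows.
#'
#' @param fit An [nma_fit()] object.
#' @param L Numeric matrix with one column per basic parameter (or a vector
#'   for a single combination). Row names, if present, label the output.
#' @param conf.level Confidence level for normal-quantile intervals.
#'
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`; the full covariance matrix of the combinations is attached
#'   as attribute `"cov"`.
#' @examples
#' net <- simulate_network("run1", tau_beta_sq = 0.1, tau_omega_sq = 0, seed = 3)
#' fit <- nma_fit(net)
#' # C vs B from the basic parameters B-vs-A and C-vs-A
#' nma_contrast(fit, rbind("C vs B" = c(-1, 1, 0)))
#' @export
nma_contrast <- function(fit, L, conf.level = fit$level) {
  stopifnot(inherits(fit, "nma_fit"))
  if (is.vector(L)) L <- matrix(L, nrow = 1)
  if (ncol(L) != length(fit$delta)) {
    stop("`L` must have ", length(fit$delta), " columns (one per basic parameter).",
      call. = FALSE
    )
  }
  est <- unname(drop(L %*% fit$delta))
  cv <- L %*% fit$cov %*% t(L)
  se <- unname(sqrt(diag(cv)))
  z <- stats::qnorm((1 + conf.level) / 2)
  out <- tibble::tibble(
    term = if (!is.null(rownames(L))) {
      rownames(L)
    } else {
      paste0("L", seq_len(nrow(L)))
    },
    estimate = est,
    std.error = se,
    conf.low = est - z * se,
    conf.high = est + z * se
  )
  attr(out, "cov") <- cv
  out
}

#' Probabilistic treatment ranking
#'
#' Simulates treatment-effect vectors from the approximate multivariate normal
#' sampling distribution of the estimated basic parameters (the reference
#' treatment's effect is fixed at exactly zero), ranks the treatments within
#' each draw, and tallies the proportion of draws in which each treatment
#' occupies each rank. The full rank distribution is reported, not just the
#' probability of being best, because the latter alone can mislead when the
#' network carries little information.
#'
#' @param fit An [nma_fit()] object.
#' @param n_draws Number of simulated effect vectors (default 10000).
#' @param seed Optional integer seed recorded in the result.
#' @param direction `"smaller_better"` or `"larger_better"`. No default:
#'   the sign convention of the effect scale must be stated explicitly.
#'
#' @return An object of class `nma_rank`: a tibble with columns `treatment`,
#'   `rank`, `prob` (rows and columns of the implied matrix each sum to one up
#'   to Monte Carlo error), with the draw count, seed and direction attached.
#' @examples
#' net <- simulate_network("run1", tau_beta_sq = 0.1, tau_omega_sq = 0, seed = 3)
#' fit <- nma_fit(net)
#' nma_rank(fit, n_draws = 2000, seed = 1, direction = "smaller_better")
#' @export
nma_rank <- function(fit, n_draws = 10000, seed = NULL,
                     direction = c("smaller_better", "larger_better")) {
  stopifnot(inherits(fit, "nma_fit"))
  if (missing(direction)) {
    stop("`direction` must be given explicitly (\"smaller_better\" or ",
      "\"larger_better\"): the sign convention depends on the outcome.",
      call. = FALSE
    )
  }
  direction <- match.arg(direction)
  if (!is.numeric(n_draws) || n_draws < 1) {
    stop("`n_draws` must be at least 1.", call. = FALSE)
  }
  n_draws <- as.integer(n_draws)
  if (!is.null(seed)) set.seed(seed)

  trts <- c(fit$network$reference, names(fit$delta))
  Tn <- length(trts)
  draws <- MASS::mvrnorm(n_draws, mu = fit$delta, Sigma = fit$cov)
  if (n_draws == 1L) draws <- matrix(draws, nrow = 1)
  draws <- cbind(0, draws) # reference effect fixed at exactly 0
  if (direction == "larger_better") draws <- -draws

  counts <- matrix(0L, Tn, Tn, dimnames = list(trts, paste0("rank", seq_len(Tn))))
  rk <- t(apply(draws, 1, rank, ties.method = "first"))
  for (r in seq_len(Tn)) counts[, r] <- colSums(rk == r)
  probs <- counts / n_draws

  out <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(probs), treatment = trts),
    -"treatment",
    names_to = "rank", names_prefix = "rank", names_transform = as.integer,
    values_to = "prob"
  )
  structure(out,
    class = c("nma_rank", class(out)),
    matrix = probs, n_draws = n_draws, seed = seed, direction = direction
  )
}

#' @export
print.nma_rank <- function(x, ...) {
  cat(sprintf(
    "Treatment ranking probabilities (%s draws, direction = %s%s)\n",
    format(attr(x, "n_draws"), big.mark = ","), attr(x, "direction"),
    if (!is.null(attr(x, "seed"))) paste0(", seed = ", attr(x, "seed")) else ""
  ))
  print(round(attr(x, "matrix"), 3))
  invisible(x)
}

#' R statistic comparing two nested model fits
#'
#' The R statistic is the c-th root of the ratio of the (generalised) volumes
#' of the confidence regions for the basic parameters under two nested models,
#' computed as \eqn{R = |C_{num} C_{den}^{-1}|^{1/(2c)}} from their covariance
#' matrices. The associated \eqn{I^2 = (R^2 - 1)/R^2 \times 100\%} expresses
#' the proportional impact of the additional variation in the numerator model.
#'
#' @param C_num Covariance matrix of the model with the additional source(s)
#'   of variation.
#' @param C_den Covariance matrix of the reduced model.
#'
#' @return A list with elements `R` and `I2` (a percentage).
#' @examples
#' r_statistic(diag(2) * 4, diag(2)) # R = 2, I2 = 75
#' @export
r_statistic <- function(C_num, C_den) {
  if (is.vector(C_num)) C_num <- matrix(C_num, 1, 1)
  if (is.vector(C_den)) C_den <- matrix(C_den, 1, 1)
  if (!all(dim(C_num) == dim(C_den))) {
    stop("Covariance matrices must have the same dimension.", call. = FALSE)
  }
  d <- nrow(C_num)
  ch <- tryCatch(chol(C_den), error = function(e) NULL)
  if (is.null(ch)) stop("Denominator covariance matrix is singular.", call. = FALSE)
  detratio <- det(C_num) / det(C_den)
  R <- detratio^(1 / (2 * d))
  list(R = R, I2 = (R^2 - 1) / R^2 * 100)
}

#' I-squared statistics for the impact of heterogeneity and inconsistency
#'
#' Fits the full (RI), consistency (RC) and common-effect (CC) models to the
#' network and reports the R and I-squared statistics for each nested
#' comparison: RI versus RC quantifies the impact of inconsistency, RC versus
#' CC the impact of between-study heterogeneity under consistency, and RI
#' versus CC their joint impact.
#'
#' @param network An [nma_network()].
#' @param subset Optional character vector of basic-parameter names (treatment
#'   labels) or integer indices: R and I-squared are then computed from the
#'   corresponding covariance submatrices with the reduced dimension.
#' @param rc_estimator Passed to [nma_fit()] for the RC model.
#'
#' @return A tibble with columns `comparison`, `R`, `I2` (percent).
#' @examples
#' net <- simulate_network("run1", tau_beta_sq = 0.1, tau_omega_sq = 0.05, seed = 5)
#' nma_i2(net)
#' @export
nma_i2 <- function(network, subset = NULL, rc_estimator = "qnet") {
  stopifnot(inherits(network, "nma_network"))
  fits <- list(
    RI = nma_fit(network, model = "ri"),
    RC = nma_fit(network, model = "rc", rc_estimator = rc_estimator),
    CC = nma_fit(network, model = "cc")
  )
  covs <- lapply(fits, function(f) {
    C <- f$cov
    if (!is.null(subset)) C <- C[subset, subset, drop = FALSE]
    C
  })
  pairs <- list(
    c("RI", "RC"),
    c("RI", "CC"),
    c("RC", "CC")
  )
  purrr::map_dfr(pairs, function(p) {
    rs <- r_statistic(covs[[p[1]]], covs[[p[2]]])
    tibble::tibble(
      comparison = paste(p[1], "vs", p[2]),
      R = rs$R, I2 = rs$I2
    )
  })
}
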