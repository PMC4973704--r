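# Fitting path shared by user data and the simulation engine. fit_core()
# operates on a network skeleton plus (possibly substituted) y and
# within-study blocks; nma_fit() is the user-facing wrapper.

fit_core <- function(net, y = net$data$y, S_blocks = net$S_blocks,
                     S = net$S, model = "ri", rc_estimator = "qnet",
                     p2_override = NULL) {
  P2 <- if (is.null(p2_override)) net$P2 else p2_override
  qc <- q_core(net, y = y, S_blocks = S_blocks, P2 = P2)

  notes <- character(0)
  sumK <- sum(qc$K_d)
  tol1 <- 1e-10 * max(1, sum(qc$W * net$P1))
  tol2 <- 1e-10 * max(1, sum(qc$W * P2))

  tau_b_un <- tau_w_un <- 0
  if (model == "ri") {
    if (sumK <= tol1) {
      stop("No within-design replication: every design has a single study, ",
        "so the heterogeneity variance is not identifiable.",
        call. = FALSE
      )
    }
    tau_b_un <- (sum(qc$Q_het) - qc$df_het) / sumK
    if (qc$trBP2 <= tol2) {
      notes <- c(notes, "omega_inestimable")
      tau_w_un <- 0
    } else {
      tau_w_un <- (qc$Q_net - qc$df_net - tau_b_un * qc$trBP1) / qc$trBP2
    }
  } else if (model == "rc") {
    if (rc_estimator == "qnet") {
      if (qc$trBP1 <= tol1) {
        stop("tr(BP1) is zero; the heterogeneity variance is not identifiable.",
          call. = FALSE
        )
      }
      tau_b_un <- (qc$Q_net - qc$df_net) / qc$trBP1
    } else {
      if (sumK <= tol1) {
        stop("No within-design replication: the design-level heterogeneity ",
          "estimator is not available.",
          call. = FALSE
        )
      }
      tau_b_un <- (sum(qc$Q_het) - qc$df_het) / sumK
    }
    tau_w_un <- 0
  } else if (model != "cc") {
    stop("Unknown model '", model, "'.", call. = FALSE)
  }

  tau_b <- max(0, tau_b_un)
  tau_w <- max(0, tau_w_un)
  if (model == "ri" && tau_b_un < 0) notes <- c(notes, "truncated_beta")
  if (model == "ri" && tau_w_un < 0) notes <- c(notes, "truncated_omega")
  if (model == "rc" && tau_b_un < 0) notes <- c(notes, "truncated_beta")

  V <- S
  if (tau_b > 0) V <- V + tau_b * net$P1
  if (tau_w > 0) V <- V + tau_w * P2
  Vchol <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(Vchol)) {
    stop("Total variance matrix V is not positive definite.", call. = FALSE)
  }
  Vi_X <- backsolve(Vchol, backsolve(Vchol, net$X, transpose = TRUE))
  A <- crossprod(net$X, Vi_X)
  Acho <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(Acho)) {
    stop("X'V^-1 X is singular; basic parameters are not estimable.",
      call. = FALSE
    )
  }
  cov <- chol2inv(Acho)
  delta <- drop(cov %*% crossprod(Vi_X, y))
  names(delta) <- colnames(net$X)
  dimnames(cov) <- list(colnames(net$X), colnames(net$X))

  list(
    model = toupper(model),
    tau_beta_sq_untrunc = tau_b_un,
    tau_omega_sq_untrunc = tau_w_un,
    tau_beta_sq = tau_b,
    tau_omega_sq = tau_w,
    notes = notes,
    qcore = qc,
    delta = delta,
    cov = cov,
    se = sqrt(diag(cov)),
    V = V
  )
}

#' Fit a network meta-analysis model by the method of moments
#'
#' Estimates the between-study heterogeneity variance and (for the full model)
#' the inconsistency variance from the decomposition of Cochran's Q, truncates
#' negative estimates to zero, and estimates the basic parameters by
#' generalized least squares treating the variance components as known.
#'
#' Three model families are available:
#' \describe{
#'   \item{`"ri"`}{random-effects, inconsistent: both variance components are
#'     estimated. The heterogeneity variance solves the within-design
#'     estimating equation; its untruncated value is then substituted into the
#'     network-level equation, which is solved for the inconsistency variance.}
#'   \item{`"rc"`}{random-effects, consistent: the inconsistency variance is
#'     constrained to zero. By default the heterogeneity variance solves the
#'     network-level equation so that the inconsistency sum of squares is
#'     attributed to heterogeneity (`rc_estimator = "qnet"`); set
#'     `rc_estimator = "qhet"` for the design-level ("het-only") estimator,
#'     which makes a full-model fit with a zero inconsistency estimate collapse
#'     exactly onto the consistency fit.}
#'   \item{`"cc"`}{common-effect, consistent: both variance components are
#'     fixed at zero and the total variance is the within-study covariance
#'     matrix.}
#' }
#'
#' Loop-inconsistency variants of the full model are obtained via
#' `p2_override`: a replacement inconsistency structure matrix with some
#' further entries set to zero, restricting which designs share inconsistency
#' random effects.
#'
#' @param network An [nma_network()].
#' @param model `"ri"`, `"rc"` or `"cc"` (see Details).
#' @param rc_estimator Heterogeneity estimator for `model = "rc"`:
#'   `"qnet"` (default) or `"qhet"`.
#' @param level Confidence level for intervals reported by [generics::tidy()];
#'   must be in (0, 1).
#' @param p2_override Optional replacement for the inconsistency structure
#'   matrix (full model only): symmetric, entries in \{0, 1/2, 1\}, and zero
#'   wherever the two rows belong to different designs.
#'
#' @return An object of class `nma_fit` with components `delta` (named vector
#'   of basic-parameter estimates), `cov`, `tau_beta_sq`, `tau_omega_sq`,
#'   their untruncated counterparts, `notes` (flags such as `truncated_beta`
#'   or `omega_inestimable`), and the Q decomposition.
#' @examples
#' net <- simulate_network("run1", tau_beta_sq = 0.1, tau_omega_sq = 0.05, seed = 7)
#' fit <- nma_fit(net, model = "ri")
#' fit
#' generics::tidy(fit)
#' @export
nma_fit <- function(network, model = c("ri", "rc", "cc"),
                    rc_estimator = c("qnet", "qhet"),
                    level = 0.95, p2_override = NULL) {
  stopifnot(inherits(network, "nma_network"))
  model <- match.arg(model)
  rc_estimator <- match.arg(rc_estimator)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be a single number in (0, 1).", call. = FALSE)
  }
  if (!is.null(p2_override)) {
    if (model != "ri") {
      stop("`p2_override` only applies to the full (ri) model.", call. = FALSE)
    }
    validate_p2_override(p2_override, network)
  }
  core <- fit_core(network,
    model = model, rc_estimator = rc_estimator,
    p2_override = p2_override
  )
  if ("omega_inestimable" %in% core$notes) {
    warning("Inconsistency variance is not estimable (tr(BP2) = 0, e.g. a ",
      "single-design network); it was set to 0.",
      call. = FALSE
    )
  }
  structure(
    c(core, list(
      network = network,
      level = level,
      rc_estimator = if (model == "rc") rc_estimator else NA_character_,
      loop = !is.null(p2_override),
      tau_ratio = if (core$tau_beta_sq > 0) {
        core$tau_omega_sq / core$tau_beta_sq
      } else {
        NA_real_
      }
    )),
    class = "nma_fit"
  )
}

validate_p2_override <- function(P2o, network) {
  N <- network$N
  if (!is.matrix(P2o) || !all(dim(P2o) == c(N, N))) {
    stop("`p2_override` must be a ", N, " x ", N, " matrix.", call. = FALSE)
  }
  if (max(abs(P2o - t(P2o))) > 1e-12) {
    stop("`p2_override` must be symmetric.", call. = FALSE)
  }
  vals <- unique(round(as.vector(P2o), 12))
  if (!all(vals %in% c(0, 0.5, 1))) {
    stop("`p2_override` entries must lie in {0, 1/2, 1}.", call. = FALSE)
  }
  if (any(P2o[network$P2 == 0] != 0)) {
    stop("`p2_override` must be zero wherever rows belong to different designs.",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' @export
print.nma_fit <- function(x, ...) {
  cat(sprintf(
    "Moment-based network meta-analysis fit (%s model%s)\n",
    x$model, if (isTRUE(x$loop)) ", loop-restricted inconsistency" else ""
  ))
  cat(sprintf(
    "  tau_beta^2  = %.4g (untruncated %.4g)\n",
    x$tau_beta_sq, x$tau_beta_sq_untrunc
  ))
  cat(sprintf(
    "  tau_omega^2 = %.4g (untruncated %.4g)\n",
    x$tau_omega_sq, x$tau_omega_sq_untrunc
  ))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = ", "), "\n")
  cat(sprintf(
    "  Q_net = %.4g on %d df; Q_inc = %.4g\n",
    x$qcore$Q_net, x$qcore$df_net, x$qcore$Q_inc
  ))
  cat("\nBasic parameters (vs reference", paste0(x$network$reference, "):\n"))
  print(as.data.frame(generics::tidy(x)), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.nma_fit <- function(object, ...) object$delta

#' @export
vcov.nma_fit <- function(object, ...) object$cov

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the basic-parameter estimates of a fitted network model
#'
#' @param x An [nma_fit()] object.
#' @param conf.level Confidence level; defaults to the level stored in the fit.
#' @param ... Unused.
#'
#' @return A tibble with one row per basic parameter: `term`, `treatment`,
#'   `reference`, `estimate`, `std.error`, `conf.low`, `conf.high` (normal
#'   quantiles).
#' @export
tidy.nma_fit <- function(x, conf.level = x$level, ...) {
  if (!is.numeric(conf.level) || length(conf.level) != 1L ||
    conf.level <= 0 || conf.level >= 1) {
    stop("`conf.level` must be a single number in (0, 1).", call. = FALSE)
  }
  z <- stats::qnorm((1 + conf.level) / 2)
  tibble::tibble(
    term = paste0(names(x$delta), " vs ", x$network$reference),
    treatment = names(x$delta),
    reference = x$network$reference,
    estimate = unname(x$delta),
    std.error = unname(x$se),
    conf.low = unname(x$delta - z * x$se),
    conf.high = unname(x$delta + z * x$se)
  )
}

#' One-row model summary of a fitted network model
#'
#' @param x An [nma_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble with the model tag, variance components
#'   (truncated and untruncated), Q statistics and network dimensions.
#' @export
glance.nma_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    tau_beta_sq = x$tau_beta_sq,
    tau_omega_sq = x$tau_omega_sq,
    tau_beta_sq_untrunc = x$tau_beta_sq_untrunc,
    tau_omega_sq_untrunc = x$tau_omega_sq_untrunc,
    tau_ratio = x$tau_ratio,
    Q_net = x$qcore$Q_net,
    Q_inc = x$qcore$Q_inc,
    df_net = x$qcore$df_net,
    df_het = x$qcore$df_het,
    n_studies = length(x$network$studies),
    n_designs = x$network$D,
    n_treatments = length(x$network$treatments)
  )
}
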