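# Core Q-statistic machinery. All fitting routes (user data and the
# simulation engine) go through q_core(), which works on the matrices of an
# nma_network skeleton with optionally substituted y / within-study blocks,
# so simulated replicates never pay the tibble-assembly cost.

# Per-study inverse covariance blocks via Cholesky; fails loudly on an
# indefinite block, naming the study.
invert_blocks <- function(S_blocks, study_names = names(S_blocks)) {
  lapply(seq_along(S_blocks), function(j) {
    ch <- tryCatch(chol(S_blocks[[j]]), error = function(e) NULL)
    if (is.null(ch)) {
      stop("Within-study covariance of study ",
        if (is.null(study_names)) j else study_names[j],
        " is singular or indefinite.",
        call. = FALSE
      )
    }
    chol2inv(ch)
  })
}

q_core <- function(net, y = net$data$y, S_blocks = net$S_blocks,
                   P2 = net$P2) {
  N <- net$N
  c_basic <- net$c
  X <- net$X
  P1 <- net$P1
  rows_by_study <- net$rows_by_study
  study_design <- vapply(net$studies, `[[`, "", "design")
  design_keys <- net$designs$design
  c_d <- net$designs$c_d
  n_d <- net$designs$n_d

  W_blocks <- invert_blocks(S_blocks, names(net$studies))
  W <- matrix(0, N, N)
  for (j in seq_along(W_blocks)) {
    idx <- rows_by_study[[j]]
    W[idx, idx] <- W_blocks[[j]]
  }

  # Per-design heterogeneity Q statistics and K constants. Within a design
  # the GLS mean of the stacked identity design matrix is the matrix-weighted
  # average of the study contrast vectors.
  D <- length(design_keys)
  Q_het <- numeric(D)
  K_d <- numeric(D)
  for (d in seq_len(D)) {
    js <- which(study_design == design_keys[d])
    if (length(js) == 1L) next # saturated: Q = 0, K = 0
    kd <- c_d[d]
    P <- pcd_matrix(kd)
    sumW <- matrix(0, kd, kd)
    sumWy <- numeric(kd)
    sumWPW <- matrix(0, kd, kd)
    trWP <- 0
    for (j in js) {
      Wi <- W_blocks[[j]]
      yi <- y[rows_by_study[[j]]]
      sumW <- sumW + Wi
      sumWy <- sumWy + Wi %*% yi
      WiP <- Wi %*% P
      trWP <- trWP + sum(diag(WiP))
      sumWPW <- sumWPW + WiP %*% Wi
    }
    beta_d <- solve(sumW, sumWy)
    q <- 0
    for (j in js) {
      r <- y[rows_by_study[[j]]] - beta_d
      q <- q + drop(crossprod(r, W_blocks[[j]] %*% r))
    }
    Q_het[d] <- q
    K_d[d] <- trWP - sum(diag(solve(sumW, sumWPW)))
  }

  # Network-level GLS under the consistency mean structure with weights S^-1.
  WX <- W %*% X
  A <- crossprod(X, WX)
  Achol <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(Achol)) {
    stop("X'WX is singular; the network cannot identify all basic parameters.",
      call. = FALSE
    )
  }
  delta0 <- backsolve(Achol, backsolve(Achol, crossprod(WX, y), transpose = TRUE))
  resid <- y - X %*% delta0
  Q_net <- drop(crossprod(resid, W %*% resid))

  # Trace constants tr(B P1), tr(B P2) with B = W - WX (X'WX)^-1 X'W,
  # computed as tr(W P) - tr((X'WX)^-1 (WX)' P (WX)).
  tr_pair <- function(P) {
    m <- crossprod(WX, P %*% WX)
    sum(W * P) - sum(diag(chol2inv(Achol) %*% m))
  }
  trBP1 <- tr_pair(P1)
  trBP2 <- tr_pair(P2)

  df_het_d <- (n_d - 1L) * c_d
  list(
    Q_net = Q_net,
    Q_het = Q_het,
    Q_inc = Q_net - sum(Q_het),
    K_d = K_d,
    df_het_d = df_het_d,
    df_het = sum(df_het_d),
    df_net = N - c_basic,
    trBP1 = trBP1,
    trBP2 = trBP2,
    W = W,
    W_blocks = W_blocks
  )
}

#' Decompose the network Q statistic
#'
#' Computes Cochran's Q statistic for the whole network under the consistency
#' mean structure (`Q_net`), its within-design heterogeneity components
#' (`Q_het`, one per design), and the inconsistency remainder
#' `Q_inc = Q_net - sum(Q_het)`, together with the constants that enter the
#' moment estimating equations: the per-design multipliers `K_d` and the trace
#' constants `tr(B P1)`, `tr(B P2)`.
#'
#' @param network An [nma_network()].
#'
#' @return An object of class `nma_qdecomp`: a list with a per-design tibble
#'   (`by_design`), scalars `Q_net`, `Q_inc`, `df_net`, `df_het`, `trBP1`,
#'   `trBP2`.
#' @examples
#' net <- simulate_network("run1", tau_beta_sq = 0.1, tau_omega_sq = 0, seed = 1)
#' q_decompose(net)
#' @export
q_decompose <- function(network) {
  stopifnot(inherits(network, "nma_network"))
  qc <- q_core(network)
  structure(
    list(
      by_design = tibble::tibble(
        design = gsub(":", "", network$designs$design),
        n_d = network$designs$n_d,
        c_d = network$designs$c_d,
        Q_het = qc$Q_het,
        df = qc$df_het_d,
        K_d = qc$K_d
      ),
      Q_net = qc$Q_net,
      Q_inc = qc$Q_inc,
      df_net = qc$df_net,
      df_het = qc$df_het,
      trBP1 = qc$trBP1,
      trBP2 = qc$trBP2
    ),
    class = "nma_qdecomp"
  )
}

#' @export
print.nma_qdecomp <- function(x, ...) {
  cat("Q decomposition\n")
  print(as.data.frame(x$by_design), row.names = FALSE, digits = 4)
  cat(sprintf(
    "  Q_net = %.4g on %d df;  sum Q_het = %.4g on %d df;  Q_inc = %.4g\n",
    x$Q_net, x$df_net, sum(x$by_design$Q_het), x$df_het, x$Q_inc
  ))
  cat(sprintf("  tr(BP1) = %.4g, tr(BP2) = %.4g\n", x$trBP1, x$trBP2))
  invisible(x)
}
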