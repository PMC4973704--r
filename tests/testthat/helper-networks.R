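# Small networks built in code for the unit tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

two_arm_network <- function(y, v, base = "A", treat = "B",
                            study = paste0("s", seq_along(y))) {
  nma_network(tibble::tibble(
    study = study, base = base, treat = treat, y = y, v = v
  ))
}

# n studies of a single three-arm ABC design, S_di = sigma2 * P_2.
abc_network <- function(y_ab, y_ac, sigma2 = rep(1, length(y_ab))) {
  n <- length(y_ab)
  ids <- paste0("s", seq_len(n))
  d <- tibble::tibble(
    study = rep(ids, each = 2),
    base = "A",
    treat = rep(c("B", "C"), n),
    y = as.vector(rbind(y_ab, y_ac)),
    v = rep(sigma2, each = 2)
  )
  cv <- tibble::tibble(
    study = ids, treat_i = "B", treat_j = "C", cov = sigma2 / 2
  )
  nma_network(d, cov = cv)
}

# Independently coded classical DerSimonian-Laird estimator for a set of
# two-arm studies: Q = sum w (y - ybar_w)^2, C = sum w - sum w^2 / sum w,
# tau2 = (Q - (k - 1)) / C.
dl_oracle <- function(y, v) {
  w <- 1 / v
  yb <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yb)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  list(
    tau2_untrunc = (Q - (length(y) - 1)) / C,
    tau2 = max(0, (Q - (length(y) - 1)) / C),
    Q = Q
  )
}

# Random small connected network with valid covariance structure, for
# property-style tests. Within-study blocks are sigma2 * P_cd, so they are
# always positive definite.
random_network <- function(seed) {
  set.seed(seed)
  n_trt <- sample(3:5, 1)
  trts <- LETTERS[seq_len(n_trt)]
  repeat {
    n_designs <- sample(2:4, 1)
    designs <- lapply(seq_len(n_designs), function(i) {
      sort(sample(trts, sample(2:3, 1)))
    })
    designs <- unique(designs)
    rows <- list()
    covs <- list()
    s <- 0L
    for (des in designs) {
      for (i in seq_len(sample(1:3, 1))) {
        s <- s + 1L
        sid <- sprintf("s%02d", s)
        k <- length(des) - 1L
        sigma2 <- runif(1, 0.05, 0.5)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          study = sid, base = des[1L], treat = des[-1L],
          y = rnorm(k), v = sigma2
        )
        if (k > 1L) {
          covs[[length(covs) + 1L]] <- tibble::tibble(
            study = sid, treat_i = des[2L], treat_j = des[3L],
            cov = sigma2 / 2
          )
        }
      }
    }
    net <- tryCatch(
      nma_network(
        dplyr::bind_rows(rows),
        cov = if (length(covs)) dplyr::bind_rows(covs) else NULL
      ),
      error = function(e) NULL
    )
    if (!is.null(net)) {
      return(net)
    }
  }
}
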