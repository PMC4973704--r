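test_that("pcd_matrix has unit diagonal, halves elsewhere, and is PD", {
  expect_equal(pcd_matrix(1), matrix(1, 1, 1))
  expect_equal(pcd_matrix(2), matrix(c(1, .5, .5, 1), 2))
  ev <- eigen(pcd_matrix(3), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), c(0.5, 0.5, 2))
  for (k in 1:6) {
    expect_gt(min(eigen(pcd_matrix(k), only.values = TRUE)$values), 0.5 - 1e-10)
  }
  expect_error(pcd_matrix(0), "positive integer")
  expect_error(pcd_matrix(-2), "positive integer")
})

test_that("designs are canonicalized on the lexicographically first baseline", {
  d <- canonicalize_design(c("A", "B", "E"))
  expect_equal(d$baseline, "A")
  expect_equal(d$contrasts, c("B", "E"))
  d2 <- canonicalize_design(c("G", "E", "C", "D"))
  expect_equal(d2$baseline, "C")
  expect_equal(d2$contrasts, c("D", "E", "G"))
  expect_equal(d2$c_d, 3L)
  expect_equal(
    canonicalize_design(c("B", "A"))$baseline,
    canonicalize_design(c("A", "B"))$baseline
  )
  expect_error(canonicalize_design("A"), "at least two")
})

test_that("design matrix X encodes contrasts of basic parameters", {
  # design {C,D,E,G} connected to A through an AC study
  d <- tibble::tibble(
    study = c("s1", rep("s2", 3)),
    base = c("A", rep("C", 3)),
    treat = c("C", "D", "E", "G"),
    y = 0, v = 1
  )
  cv <- tibble::tibble(
    study = "s2",
    treat_i = c("D", "D", "E"), treat_j = c("E", "G", "G"),
    cov = 0.5
  )
  net <- nma_network(d, cov = cv)
  i <- which(net$data$study == "s2" & net$data$treat == "D")
  expect_equal(unname(net$X[i, "C"]), -1)
  expect_equal(unname(net$X[i, "D"]), 1)
  expect_equal(sum(net$X[i, ] != 0), 2)
  # AB design row relative to the reference has a single +1
  j <- which(net$data$study == "s1")
  expect_equal(net$X[j, ], c(C = 1, D = 0, E = 0, G = 0))
})

test_that("X is a 0/1 incidence matrix for all-two-arm star networks", {
  d <- tibble::tibble(
    study = paste0("s", 1:6), base = "A",
    treat = rep(c("B", "C", "D"), 2), y = rnorm(6), v = 1
  )
  net <- nma_network(d)
  expect_true(all(net$X %in% c(0, 1)))
  expect_equal(rowSums(net$X), rep(1, 6))
})

test_that("P1 and P2 follow the study/design block rules", {
  # two 2-arm AB studies: P1 identity, P2 all ones
  net <- two_arm_network(c(0, 1), c(1, 1))
  expect_equal(net$P1, diag(2))
  expect_equal(net$P2, matrix(1, 2, 2))

  # two 3-arm ABC studies
  net3 <- abc_network(c(0, 0), c(0, 0))
  P2_exp <- matrix(
    c(
      1, .5, 1, .5,
      .5, 1, .5, 1,
      1, .5, 1, .5,
      .5, 1, .5, 1
    ),
    4, 4,
    byrow = TRUE
  )
  expect_equal(net3$P2, P2_exp)
  P1_exp <- P2_exp
  P1_exp[1:2, 3:4] <- 0
  P1_exp[3:4, 1:2] <- 0
  expect_equal(net3$P1, P1_exp)

  # single study: P1 = P2 = P_cd
  net1 <- abc_network(0, 0)
  expect_equal(net1$P1, pcd_matrix(2))
  expect_equal(net1$P2, pcd_matrix(2))
})

test_that("P1/P2 structural invariants hold on random networks", {
  for (seed in 1:25) {
    net <- random_network(seed)
    expect_true(all(net$P1 %in% c(0, 0.5, 1)))
    expect_true(all(net$P2 %in% c(0, 0.5, 1)))
    expect_true(all(diag(net$P1) == 1))
    expect_true(all(diag(net$P2) == 1))
    expect_true(all(net$P2 >= net$P1))
    # P1 zero across distinct studies, P2 zero across distinct designs
    diff_study <- outer(net$row_study, net$row_study, "!=")
    diff_design <- outer(net$row_design, net$row_design, "!=")
    expect_true(all(net$P1[diff_study] == 0))
    expect_true(all(net$P2[diff_design] == 0))
  }
})

test_that("fits are invariant to study input order and per-design baseline", {
  set.seed(5)
  d <- tibble::tibble(
    study = c("s1", "s1", "s2", "s2", "s3", "s4", "s5"),
    base = c("A", "A", "A", "A", "A", "A", "B"),
    treat = c("B", "C", "B", "C", "B", "C", "C"),
    y = rnorm(7), v = runif(7, .1, .4)
  )
  cv <- tibble::tibble(
    study = c("s1", "s2"), treat_i = "B", treat_j = "C",
    cov = c(0.05, 0.1)
  )
  net <- nma_network(d, cov = cv)
  perm <- c(7, 5, 3, 4, 1, 2, 6)
  net_p <- nma_network(d[perm, ], cov = cv[2:1, ])
  f <- nma_fit(net)
  f_p <- nma_fit(net_p)
  expect_equal(f$delta, f_p$delta)
  expect_equal(f$cov, f_p$cov)
  expect_equal(f$tau_beta_sq_untrunc, f_p$tau_beta_sq_untrunc)
  expect_equal(f$tau_omega_sq_untrunc, f_p$tau_omega_sq_untrunc)

  # re-express study s1 relative to baseline B: exact linear transform
  d2 <- d
  d2[d2$study == "s1", ] <- tibble::tibble(
    study = "s1", base = "B", treat = c("A", "C"),
    y = c(-d$y[1], d$y[2] - d$y[1]),
    v = c(d$v[1], d$v[1] + d$v[2] - 2 * 0.05)
  )
  cv2 <- cv
  cv2$treat_i[1] <- "A"
  cv2$treat_j[1] <- "C"
  cv2$cov[1] <- d$v[1] - 0.05
  f2 <- nma_fit(nma_network(d2, cov = cv2))
  expect_equal(f2$delta, f$delta, tolerance = 1e-12)
  expect_equal(f2$qcore$Q_net, f$qcore$Q_net, tolerance = 1e-12)
  expect_equal(f2$tau_beta_sq_untrunc, f$tau_beta_sq_untrunc, tolerance = 1e-12)
})

test_that("reference override re-expresses the basic parameters", {
  set.seed(8)
  d <- tibble::tibble(
    study = paste0("s", 1:6), base = "A",
    treat = rep(c("B", "C", "D"), 2), y = rnorm(6), v = runif(6, .1, .3)
  )
  fA <- nma_fit(nma_network(d), model = "cc")
  fB <- nma_fit(nma_network(d, reference = "B"), model = "cc")
  expect_equal(names(fB$delta), c("A", "C", "D"))
  expect_equal(unname(fB$delta["A"]), -unname(fA$delta["B"]), tolerance = 1e-12)
  expect_equal(unname(fB$delta["C"]),
    unname(fA$delta["C"] - fA$delta["B"]),
    tolerance = 1e-12
  )
})

test_that("invalid inputs produce specific errors", {
  d <- tibble::tibble(
    study = c("s1", "s2"), base = "A", treat = c("B", "B"),
    y = 0, v = 1
  )
  # disconnected network names the stranded component
  d2 <- tibble::tibble(
    study = c("s1", "s2"), base = c("A", "C"), treat = c("B", "D"),
    y = 0, v = 1
  )
  expect_error(nma_network(d2), "disconnected")
  # duplicate contrast rows
  expect_error(
    nma_network(dplyr::bind_rows(d, d[1, ])),
    "Duplicate"
  )
  # missing covariance for a 3-arm study
  d3 <- tibble::tibble(
    study = "s1", base = "A", treat = c("B", "C"), y = 0, v = 1
  )
  expect_error(nma_network(d3), "covariance")
  # unknown treatment in the covariance table
  expect_error(
    nma_network(d3, cov = tibble::tibble(
      study = "s1", treat_i = "B", treat_j = "Z", cov = .5
    )),
    "unknown treatment"
  )
  # non-positive-definite within-study covariance
  expect_error(
    nma_network(d3, cov = tibble::tibble(
      study = "s1", treat_i = "B", treat_j = "C", cov = 2
    )),
    "positive definite"
  )
  # self-comparison and negative variance
  expect_error(nma_network(tibble::tibble(
    study = "s1", base = "A", treat = "A", y = 0, v = 1
  )), "itself")
  expect_error(nma_network(tibble::tibble(
    study = "s1", base = "A", treat = "B", y = 0, v = -1
  )), "positive")
})

test_that("arm-level 2x2 counts convert to log odds ratio contrasts", {
  arms <- tibble::tibble(
    study = c("s1", "s1", "s2", "s2", "s2"),
    treat = c("A", "B", "A", "B", "C"),
    events = c(10, 5, 8, 4, 6),
    n = c(50, 50, 40, 40, 40)
  )
  out <- contrasts_from_counts(arms)
  lo <- function(e, n) log(e / (n - e))
  vo <- function(e, n) 1 / e + 1 / (n - e)
  expect_equal(
    out$contrasts$y[1], lo(5, 50) - lo(10, 50)
  )
  expect_equal(out$contrasts$v[1], vo(5, 50) + vo(10, 50))
  # multi-arm covariance is the baseline-arm log-odds variance
  expect_equal(out$cov$cov, vo(8, 40))
  net <- nma_network(out$contrasts, cov = out$cov)
  expect_s3_class(net, "nma_network")
})
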