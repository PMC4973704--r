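#' Contrast matrix with unit diagonal and off-diagonal halves
#'
#' Builds the \eqn{c_d \times c_d} matrix \eqn{P_{c_d} = I + (J - I)/2} (ones
#' on the diagonal, halves elsewhere) that gives the correlation structure of
#' a set of contrasts sharing a common baseline arm, under the standard
#' assumption of a common heterogeneity (or inconsistency) variance for every
#' pairwise comparison.
#'
#' @param c_d Number of contrasts (arms minus one) in the design; a positive
#'   integer.
#'
#' @return A `c_d` by `c_d` symmetric positive-definite matrix.
#' @examples
#' pcd_matrix(2)
#' @export
pcd_matrix <- function(c_d) {
  if (length(c_d) != 1L || is.na(c_d) || c_d < 1 || c_d != round(c_d)) {
    stop("`c_d` must be a single positive integer.", call. = FALSE)
  }
  c_d <- as.integer(c_d)
  m <- matrix(0.5, c_d, c_d)
  diag(m) <- 1
  m
}

#' Canonical form of a design
#'
#' A design is identified by its unordered set of treatments. The canonical
#' baseline is the lexicographically first treatment and the contrasts are the
#' remaining treatments in lexicographic order.
#'
#' @param treatments Character vector of at least two distinct treatment
#'   labels (case-sensitive).
#'
#' @return A list with elements `treatments` (sorted), `baseline`,
#'   `contrasts` (non-baseline treatments, sorted), `c_d` and `key` (a string
#'   identifying the design).
#' @examples
#' canonicalize_design(c("E", "A", "B"))
#' @export
canonicalize_design <- function(treatments) {
  treatments <- unique(as.character(treatments))
  if (length(treatments) < 2L) {
    stop("A design needs at least two distinct treatments.", call. = FALSE)
  }
  trts <- sort_labels(treatments)
  list(
    treatments = trts,
    baseline = trts[1L],
    contrasts = trts[-1L],
    c_d = length(trts) - 1L,
    key = paste(trts, collapse = ":")
  )
}

# Lexicographic byte order, independent of the session locale.
sort_labels <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x, method = "radix")
}

# Union-find connectivity over the design hypergraph: treatments are nodes,
# each design merges all of its members.
check_connected <- function(treatments, design_sets) {
  parent <- seq_along(treatments)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (set in design_sets) {
    idx <- match(set, treatments)
    r <- find(idx[1L])
    for (j in idx[-1L]) parent[find(j)] <- r
  }
  roots <- vapply(seq_along(treatments), find, integer(1))
  if (length(unique(roots)) > 1L) {
    comp <- split(treatments, roots)
    comp <- comp[order(lengths(comp), decreasing = TRUE)]
    stop(
      "Network is disconnected; treatments {",
      paste(comp[[2L]], collapse = ", "),
      "} are not linked to the rest of the network.",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

# Re-express a study's contrasts (y, S) from an arbitrary within-study
# baseline onto the canonical (lexicographically first) baseline. `treat`
# names the non-baseline arm of each row. Returns y/S/treat in canonical
# contrast order.
rebase_study <- function(base, treat, y, S, canonical) {
  stopifnot(length(unique(base)) == 1L)
  b <- base[1L]
  if (b == canonical) {
    ord <- order_labels(treat)
    return(list(treat = treat[ord], y = y[ord], S = S[ord, ord, drop = FALSE]))
  }
  if (!canonical %in% treat) {
    stop("Canonical baseline not among the study's arms.", call. = FALSE)
  }
  new_treat <- c(setdiff(treat, canonical), b)
  k <- length(y)
  # row for new contrast canonical -> t is (old contrast b -> t) minus
  # (old contrast b -> canonical); the b arm itself becomes its negation.
  Tm <- matrix(0, k, k)
  i_can <- match(canonical, treat)
  for (r in seq_len(k)) {
    t_new <- new_treat[r]
    if (t_new == b) {
      Tm[r, i_can] <- -1
    } else {
      Tm[r, match(t_new, treat)] <- 1
      Tm[r, i_can] <- -1
    }
  }
  y2 <- drop(Tm %*% y)
  S2 <- Tm %*% S %*% t(Tm)
  ord <- order_labels(new_treat)
  list(
    treat = new_treat[ord],
    y = y2[ord],
    S = S2[ord, ord, drop = FALSE]
  )
}

order_labels <- function(x) match(x, sort_labels(x))

#' Assemble a network meta-analysis dataset from a contrast table
#'
#' Validates a long-format contrast table and builds the design and
#' variance-structure matrices used throughout the package: the basic-parameter
#' design matrix `X`, the between-study structure `P1` (block diagonal by
#' study), the inconsistency structure `P2` (block diagonal by design) and the
#' block-diagonal within-study covariance matrix `S`.
#'
#' Studies whose contrasts are supplied relative to a non-canonical baseline
#' are re-expressed onto the lexicographically first treatment of their design;
#' this is an exact linear transformation of `y` and `S` and leaves all fits
#' unchanged.
#'
#' @param data A data frame with columns `study`, `base`, `treat`, `y`
#'   (estimated treatment effect of `treat` relative to `base`, e.g. a log
#'   odds ratio) and `v` (its within-study variance). One row per contrast;
#'   a study with `k` arms contributes `k - 1` rows sharing one `base`.
#' @param cov Optional data frame with columns `study`, `treat_i`, `treat_j`,
#'   `cov` giving within-study covariances between the contrasts of multi-arm
#'   studies (relative to the same `base` as in `data`). Required for every
#'   study with three or more arms.
#' @param reference Reference treatment for the basic parameters. Defaults to
#'   the lexicographically first treatment label.
#'
#' @return An object of class `nma_network`: a list with the canonical contrast
#'   table (`data`), per-study and per-design bookkeeping, and matrices `X`,
#'   `P1`, `P2`, `S`.
#' @examples
#' d <- tibble::tibble(
#'   study = c("s1", "s2", "s3"),
#'   base = "A", treat = c("B", "B", "C"),
#'   y = c(0.2, -0.1, 0.4), v = c(0.1, 0.2, 0.1)
#' )
#' net <- nma_network(d)
#' net
#' @export
nma_network <- function(data, cov = NULL, reference = NULL) {
  data <- tibble::as_tibble(data)
  req <- c("study", "base", "treat", "y", "v")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("Contrast table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  data <- dplyr::mutate(
    data,
    study = as.character(.data$study),
    base = as.character(.data$base),
    treat = as.character(.data$treat)
  )
  if (any(!is.finite(data$y)) || any(!is.finite(data$v)) || any(data$v <= 0)) {
    stop("`y` must be finite and `v` finite and positive.", call. = FALSE)
  }
  if (any(data$base == data$treat)) {
    stop("A contrast cannot compare a treatment with itself.", call. = FALSE)
  }
  dup <- duplicated(data[, c("study", "base", "treat")])
  if (any(dup)) {
    stop(
      "Duplicate (study, base, treat) rows: ",
      paste(unique(data$study[dup]), collapse = ", "),
      call. = FALSE
    )
  }

  if (!is.null(cov)) {
    cov <- tibble::as_tibble(cov)
    creq <- c("study", "treat_i", "treat_j", "cov")
    if (length(setdiff(creq, names(cov)))) {
      stop("Covariance table needs columns study, treat_i, treat_j, cov.",
        call. = FALSE
      )
    }
    cov <- dplyr::mutate(
      cov,
      study = as.character(.data$study),
      treat_i = as.character(.data$treat_i),
      treat_j = as.character(.data$treat_j)
    )
    known <- unique(c(data$treat, data$base))
    bad <- setdiff(unique(c(cov$treat_i, cov$treat_j)), known)
    if (length(bad)) {
      stop("Covariance table mentions unknown treatment(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }

  # Per-study canonicalization.
  study_ids <- unique(data$study)
  studies <- vector("list", length(study_ids))
  names(studies) <- study_ids
  for (sid in study_ids) {
    rows <- data[data$study == sid, ]
    if (length(unique(rows$base)) != 1L) {
      stop("Study ", sid, " uses more than one baseline treatment.",
        call. = FALSE
      )
    }
    arms <- c(rows$base[1L], rows$treat)
    if (anyDuplicated(arms)) {
      stop("Study ", sid, " lists a treatment more than once.", call. = FALSE)
    }
    des <- canonicalize_design(arms)
    k <- nrow(rows)
    S <- diag(rows$v, k, k)
    if (k > 1L) {
      if (is.null(cov)) {
        stop(
          "Study ", sid, " has ", k + 1L,
          " arms but no covariance table was supplied.",
          call. = FALSE
        )
      }
      crows <- cov[cov$study == sid, ]
      for (a in seq_len(k - 1L)) {
        for (b in seq(a + 1L, k)) {
          ti <- rows$treat[a]
          tj <- rows$treat[b]
          hit <- which((crows$treat_i == ti & crows$treat_j == tj) |
            (crows$treat_i == tj & crows$treat_j == ti))
          if (length(hit) != 1L) {
            stop(
              "Study ", sid, ": need exactly one covariance entry for the (",
              ti, ", ", tj, ") contrast pair.",
              call. = FALSE
            )
          }
          S[a, b] <- S[b, a] <- crows$cov[hit]
        }
      }
    }
    reb <- rebase_study(rows$base, rows$treat, rows$y, S, des$baseline)
    ok <- tryCatch(
      {
        chol(reb$S)
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) {
      stop("Within-study covariance matrix of study ", sid,
        " is not positive definite.",
        call. = FALSE
      )
    }
    studies[[sid]] <- list(
      study = sid, design = des$key, baseline = des$baseline,
      treat = reb$treat, y = reb$y, S = reb$S, c_d = des$c_d,
      trt_set = des$treatments
    )
  }

  treatments <- sort_labels(unique(unlist(lapply(studies, `[[`, "trt_set"))))
  check_connected(treatments, lapply(studies, `[[`, "trt_set"))

  if (is.null(reference)) {
    reference <- treatments[1L]
  } else {
    reference <- as.character(reference)
    if (!reference %in% treatments) {
      stop("Reference treatment '", reference, "' is not in the network.",
        call. = FALSE
      )
    }
  }

  # Stable ordering: designs sorted by key, studies in input order within
  # design, contrasts in lexicographic treatment order within study.
  design_keys <- sort_labels(unique(vapply(studies, `[[`, "", "design")))
  study_order <- unlist(lapply(design_keys, function(k) {
    study_ids[vapply(studies[study_ids], `[[`, "", "design") == k]
  }))
  studies <- studies[study_order]

  rows <- purrr::map_dfr(studies, function(st) {
    tibble::tibble(
      study = st$study, design = st$design, base = st$baseline,
      treat = st$treat, y = st$y, v = diag(st$S)
    )
  })
  N <- nrow(rows)
  c_basic <- length(treatments) - 1L
  basic <- setdiff(treatments, reference)

  X <- matrix(0, N, c_basic,
    dimnames = list(NULL, basic)
  )
  for (i in seq_len(N)) {
    b <- rows$base[i]
    t <- rows$treat[i]
    if (t != reference) X[i, t] <- 1
    if (b != reference) X[i, b] <- -1
  }
  if (qr(X)$rank < c_basic) {
    stop("Design matrix is rank deficient; the network cannot identify all basic parameters.",
      call. = FALSE
    )
  }

  row_study <- match(rows$study, names(studies))
  row_design <- match(rows$design, design_keys)
  contrast_id <- paste(rows$design, rows$treat, sep = "~")

  P1 <- matrix(0, N, N)
  P2 <- matrix(0, N, N)
  same_study <- outer(row_study, row_study, "==")
  same_design <- outer(row_design, row_design, "==")
  same_contrast <- outer(contrast_id, contrast_id, "==")
  P1[same_study] <- 0.5
  P1[same_study & same_contrast] <- 1
  P2[same_design] <- 0.5
  P2[same_design & same_contrast] <- 1

  S_blocks <- lapply(studies, `[[`, "S")
  S <- matrix(0, N, N)
  pos <- 1L
  rows_by_study <- vector("list", length(studies))
  for (j in seq_along(studies)) {
    k <- studies[[j]]$c_d
    idx <- seq.int(pos, pos + k - 1L)
    rows_by_study[[j]] <- idx
    S[idx, idx] <- S_blocks[[j]]
    pos <- pos + k
  }

  designs <- tibble::tibble(
    design = design_keys,
    treatments = lapply(strsplit(design_keys, ":", fixed = TRUE), identity),
    baseline = vapply(strsplit(design_keys, ":", fixed = TRUE), `[`, "", 1L),
    c_d = lengths(strsplit(design_keys, ":", fixed = TRUE)) - 1L,
    n_d = vapply(design_keys, function(k) {
      sum(vapply(studies, `[[`, "", "design") == k)
    }, integer(1), USE.NAMES = FALSE)
  )

  structure(
    list(
      data = rows,
      treatments = treatments,
      reference = reference,
      basic = basic,
      studies = studies,
      designs = designs,
      rows_by_study = rows_by_study,
      row_study = row_study,
      row_design = row_design,
      X = X, P1 = P1, P2 = P2, S = S,
      S_blocks = S_blocks,
      N = N, c = c_basic, D = length(design_keys)
    ),
    class = "nma_network"
  )
}

#' @export
print.nma_network <- function(x, ...) {
  cat("Network meta-analysis dataset\n")
  cat(
    "  ", length(x$treatments), "treatments:",
    paste(x$treatments, collapse = ", "), "\n"
  )
  cat(
    "  ", length(x$studies), "studies in", x$D, "designs;",
    x$N, "estimated treatment effects\n"
  )
  cat("   reference treatment:", x$reference, "\n")
  cat("   designs:\n")
  for (i in seq_len(nrow(x$designs))) {
    cat(sprintf(
      "     %-12s n_d = %d\n",
      gsub(":", "", x$designs$design[i]), x$designs$n_d[i]
    ))
  }
  invisible(x)
}

#' Contrast data and covariances from arm-level binary outcomes
#'
#' Converts arm-level 2x2 counts into the contrast representation used by
#' [nma_network()]: log odds ratios of each non-baseline arm against the
#' study's lexicographically first treatment, with Wald variances, and -- for
#' multi-arm studies -- within-study covariances equal to the variance of the
#' log odds in the shared baseline arm.
#'
#' @param arms Data frame with columns `study`, `treat`, `events`, `n`.
#' @param correction Continuity correction added to every cell of a study's
#'   table when any cell is zero (default 0.5).
#'
#' @return A list with elements `contrasts` and `cov`, ready to pass to
#'   [nma_network()] or [write_contrast_table()].
#' @export
contrasts_from_counts <- function(arms, correction = 0.5) {
  arms <- tibble::as_tibble(arms)
  req <- c("study", "treat", "events", "n")
  if (length(setdiff(req, names(arms)))) {
    stop("Arm table needs columns study, treat, events, n.", call. = FALSE)
  }
  arms <- dplyr::mutate(arms,
    study = as.character(.data$study),
    treat = as.character(.data$treat)
  )
  out_y <- list()
  out_c <- list()
  for (sid in unique(arms$study)) {
    a <- arms[arms$study == sid, ]
    if (nrow(a) < 2L) stop("Study ", sid, " has fewer than two arms.", call. = FALSE)
    a <- a[order_labels(a$treat), ]
    ev <- a$events
    nn <- a$n
    if (any(ev <= 0) || any(ev >= nn)) {
      ev <- ev + correction
      nn <- nn + 2 * correction
    }
    lodds <- log(ev / (nn - ev))
    vodds <- 1 / ev + 1 / (nn - ev)
    base <- a$treat[1L]
    k <- nrow(a) - 1L
    out_y[[sid]] <- tibble::tibble(
      study = sid, base = base, treat = a$treat[-1L],
      y = lodds[-1L] - lodds[1L], v = vodds[-1L] + vodds[1L]
    )
    if (k > 1L) {
      pr <- utils::combn(a$treat[-1L], 2L)
      out_c[[sid]] <- tibble::tibble(
        study = sid, treat_i = pr[1L, ], treat_j = pr[2L, ],
        cov = vodds[1L]
      )
    }
  }
  list(
    contrasts = dplyr::bind_rows(out_y),
    cov = if (length(out_c)) dplyr::bind_rows(out_c) else NULL
  )
}
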