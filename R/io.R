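#' Read a contrast table (and optional covariance table) from CSV
#'
#' The canonical on-disk format is a long CSV with columns `study`, `base`,
#' `treat`, `y`, `v` (one row per contrast) plus, for networks containing
#' multi-arm studies, a covariance CSV with columns `study`, `treat_i`,
#' `treat_j`, `cov`. Labels are case-sensitive strings.
#'
#' @param path Path to the contrast CSV.
#' @param cov_path Optional path to the covariance CSV; required when any
#'   study has three or more arms.
#' @param reference Optional reference treatment (defaults to the
#'   lexicographically first label).
#'
#' @return A validated [nma_network()].
#' @export
read_contrast_table <- function(path, cov_path = NULL, reference = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  cov <- if (!is.null(cov_path)) {
    readr::read_csv(cov_path, show_col_types = FALSE)
  } else {
    NULL
  }
  nma_network(data, cov = cov, reference = reference)
}

#' Write a network back to the canonical CSV format
#'
#' @param network An [nma_network()].
#' @param path Output path for the contrast CSV.
#' @param cov_path Output path for the covariance CSV; required when the
#'   network contains multi-arm studies.
#'
#' @return `network`, invisibly. Reading the files back reproduces the same
#'   fits to machine precision.
#' @export
write_contrast_table <- function(network, path, cov_path = NULL) {
  stopifnot(inherits(network, "nma_network"))
  readr::write_csv(
    network$data[, c("study", "base", "treat", "y", "v")], path
  )
  multi <- Filter(function(st) st$c_d > 1L, network$studies)
  if (length(multi)) {
    if (is.null(cov_path)) {
      stop("Network contains multi-arm studies: `cov_path` is required.",
        call. = FALSE
      )
    }
    covs <- purrr::map_dfr(multi, function(st) {
      pr <- utils::combn(seq_len(st$c_d), 2L)
      tibble::tibble(
        study = st$study,
        treat_i = st$treat[pr[1L, ]],
        treat_j = st$treat[pr[2L, ]],
        cov = st$S[cbind(pr[1L, ], pr[2L, ])]
      )
    })
    readr::write_csv(covs, cov_path)
  }
  invisible(network)
}
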