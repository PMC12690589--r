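#' Tidy an eRMSF result into a long tibble
#'
#' One row per (group, segment) cell of the fluctuation matrix, the natural
#' input for ggplot2 and dplyr post-processing.
#'
#' @param x an [run_ermsf()] result.
#' @param ... unused.
#' @return a tibble with columns `group` (factor, matrix row order), `chain`,
#'   `resid`, `resname`, `segment` (integer), `ermsf` (Angstrom).
#' @export
#' @examples
#' ref <- make_reference_peptide(6)
#' ens <- make_gaussian_ensemble(ref, sigma = 0.3, n_frames = 40, seed = 5)
#' res <- run_ermsf(ens, selection = "name CA", skip = 10, align = FALSE)
#' tidy(res)
tidy.ermsf_result <- function(x, ...) {
  m <- x$matrix
  out <- tibble::tibble(
    group = factor(rep(rownames(m), times = ncol(m)),
                   levels = rownames(m)),
    chain = rep(x$groups$chain, times = ncol(m)),
    resid = rep(x$groups$resid, times = ncol(m)),
    resname = rep(x$groups$resname, times = ncol(m)),
    segment = rep(seq_len(ncol(m)), each = nrow(m)),
    ermsf = as.vector(m)
  )
  out
}

#' One-row summary of an eRMSF result
#'
#' @param x an [run_ermsf()] result.
#' @param ... unused.
#' @return a one-row tibble: group/segment counts, skip, frame count,
#'   selection size, reference mode, alignment flag, and min/mean/max eRMSF.
#' @export
glance.ermsf_result <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$matrix),
    n_segments = ncol(x$matrix),
    skip = x$provenance$skip,
    n_frames = x$provenance$n_frames_analyzed,
    n_atoms_selected = x$provenance$n_atoms_selected,
    group_level = x$provenance$group_level,
    reference_mode = x$reference$mode,
    aligned = x$provenance$align,
    min_ermsf = min(x$matrix),
    mean_ermsf = mean(x$matrix),
    max_ermsf = max(x$matrix)
  )
}

#' Average per-group fluctuation profile as a tibble
#'
#' @param result an [run_ermsf()] result.
#' @return tibble with columns `group`, `chain`, `resid`, `resname`,
#'   `average_ermsf` (Angstrom).
#' @export
profile_table <- function(result) {
  tibble::tibble(
    group = factor(names(result$average_profile),
                   levels = names(result$average_profile)),
    chain = result$groups$chain,
    resid = result$groups$resid,
    resname = result$groups$resname,
    average_ermsf = as.numeric(result$average_profile)
  )
}
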