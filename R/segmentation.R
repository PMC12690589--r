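#' Partition frames into contiguous segments
#'
#' Splits the analyzed frame list into contiguous, non-overlapping segments of
#' `skip` frames each. With 100 frames and `skip = 10` this yields 10 segments
#' of 10 frames; with `skip = 1` every frame is its own segment. When
#' `n_frames` is not divisible by `skip`, the trailing remainder forms a final
#' shorter segment under `remainder_policy = "keep_partial"` (its own frame
#' count is used as the normalizer), or is discarded under `"drop_partial"`.
#'
#' @param n_frames number of frames to segment (after any slicing).
#' @param skip frames per segment (positive integer).
#' @param remainder_policy `"keep_partial"` (default) or `"drop_partial"`.
#' @return An object of class `segmentation`: list with `skip`,
#'   `remainder_policy`, and `boundaries`, a tibble with columns `segment`
#'   (1-based index), `first`, `last` (inclusive frame bounds) and `n_frames`.
#' @export
#' @examples
#' segment_frames(100, 10)
#' segment_frames(105, 10)$boundaries
segment_frames <- function(n_frames, skip,
                           remainder_policy = c("keep_partial",
                                                "drop_partial")) {
  remainder_policy <- match.arg(remainder_policy)
  n_frames <- as.integer(n_frames)
  skip <- as.integer(skip)
  if (is.na(n_frames) || n_frames < 1L) {
    stop("n_frames must be a positive integer (got ", n_frames, ")",
         call. = FALSE)
  }
  if (is.na(skip) || skip < 1L) {
    stop("skip must be a positive integer (got ", skip, ")", call. = FALSE)
  }
  n_seg <- if (remainder_policy == "keep_partial") {
    as.integer(ceiling(n_frames / skip))
  } else {
    n_frames %/% skip
  }
  if (n_seg < 1L) {
    stop("no complete segment: n_frames = ", n_frames, " < skip = ", skip,
         " under drop_partial", call. = FALSE)
  }
  first <- (seq_len(n_seg) - 1L) * skip + 1L
  last <- pmin(first + skip - 1L, n_frames)
  boundaries <- tibble::tibble(
    segment = seq_len(n_seg),
    first = first,
    last = last,
    n_frames = last - first + 1L
  )
  structure(list(skip = skip, remainder_policy = remainder_policy,
                 boundaries = boundaries),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  b <- x$boundaries
  cat("<segmentation> skip = ", x$skip, ", ", nrow(b), " segment(s) [",
      x$remainder_policy, "]\n", sep = "")
  lens <- unique(b$n_frames)
  cat("  lengths: ", paste(lens, collapse = ", "),
      if (length(lens) > 1) " (final partial)" else "", "\n", sep = "")
  invisible(x)
}

n_segments <- function(segmentation) nrow(segmentation$boundaries)

# list of frame-index vectors, one per segment
segment_frame_indices <- function(segmentation) {
  b <- segmentation$boundaries
  lapply(seq_len(nrow(b)), function(s) seq.int(b$first[s], b$last[s]))
}
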