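#' Align a read tag to a reference window by dynamic programming
#'
#' Desk-scale aligner using the scoring scheme of the read-filtering
#' pipeline: +5 per match, -4 per substitution and -4 per gapped position
#' on either sequence. `type = "fitting"` aligns the whole tag against the
#' best-scoring substring of the reference (free reference ends — the
#' usual read-to-window semantics); `type = "global"` aligns both
#' sequences end to end.
#'
#' @param tag,ref Non-empty ungapped DNA strings.
#' @param type `"fitting"` (default) or `"global"`.
#' @return List with `raw_score`, `normalized_score` (raw / tag length),
#'   `tag` and `ref` gapped display strings of the aligned block, and
#'   `ref_start`/`ref_end` (0-based half-open offsets of the aligned
#'   reference block within `ref`).
#' @export
align_read <- function(tag, ref, type = c("fitting", "global")) {
  type <- match.arg(type)
  if (!nzchar(tag) || !nzchar(ref)) stop("tag and ref must be nonempty", call. = FALSE)
  tc <- strsplit(tag, "", fixed = TRUE)[[1]]
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(tc)
  m <- length(rc)
  gap <- -4
  H <- matrix(0, n + 1L, m + 1L)
  H[, 1L] <- gap * (0:n)
  H[1L, ] <- if (type == "global") gap * (0:m) else 0
  for (i in 2L:(n + 1L)) {
    sub <- ifelse(rc == tc[i - 1L], 5, -4)
    for (j in 2L:(m + 1L)) {
      H[i, j] <- max(H[i - 1L, j - 1L] + sub[j - 1L],
                     H[i - 1L, j] + gap,
                     H[i, j - 1L] + gap)
    }
  }
  if (type == "global") {
    j_end <- m + 1L
    score <- H[n + 1L, m + 1L]
  } else {
    j_end <- which.max(H[n + 1L, ])
    score <- H[n + 1L, j_end]
  }

  # traceback from (n+1, j_end)
  i <- n + 1L
  j <- j_end
  tg <- character(0)
  rg <- character(0)
  while (i > 1L || (type == "global" && j > 1L)) {
    if (i > 1L && j > 1L &&
        H[i, j] == H[i - 1L, j - 1L] + (if (tc[i - 1L] == rc[j - 1L]) 5 else -4)) {
      tg <- c(tc[i - 1L], tg); rg <- c(rc[j - 1L], rg)
      i <- i - 1L; j <- j - 1L
    } else if (i > 1L && H[i, j] == H[i - 1L, j] + gap) {
      tg <- c(tc[i - 1L], tg); rg <- c("-", rg)
      i <- i - 1L
    } else {
      tg <- c("-", tg); rg <- c(rc[j - 1L], rg)
      j <- j - 1L
    }
    if (type == "fitting" && i == 1L) break
  }
  ref_start <- j - 1L
  list(raw_score = score,
       normalized_score = score / n,
       tag = paste(tg, collapse = ""),
       ref = paste(rg, collapse = ""),
       ref_start = if (type == "global") 0L else ref_start,
       ref_end = j_end - 1L)
}
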