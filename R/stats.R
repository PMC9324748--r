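# Rating-study statistics: one-tailed paired t-tests over cytogeneticist
# scores of original vs enhanced karyograms.

#' One-tailed paired t-test
#'
#' Computes `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = after - before` with `n - 1` degrees of freedom, and the one-tailed
#' p-value in the requested direction (`"greater"`: after exceeds before).
#'
#' @param before,after numeric vectors of equal length `n >= 2`.
#' @param direction `"greater"` or `"less"`.
#' @return `list(t, p, n)`.
#' @export
#' @examples
#' pairedOneTailedTTest(c(3, 2, 4, 3, 5), c(4, 3, 5, 5, 5), "greater")
pairedOneTailedTTest <- function(before, after,
                                 direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(before) != length(after))
    stop("validation error: before/after lengths differ")
  n <- length(before)
  if (n < 2) stop("degenerate input: need at least 2 pairs, got ", n)
  d <- after - before
  sdd <- sd(d)
  if (sdd == 0)
    stop("degenerate input: all paired differences are identical (sd = 0); ",
         "the t statistic is undefined")
  t <- mean(d) / (sdd / sqrt(n))
  p <- if (direction == "greater") pt(t, df = n - 1, lower.tail = FALSE)
       else pt(t, df = n - 1)
  list(t = t, p = p, n = n)
}

#' Validate and read a rating-record table
#'
#' Expected CSV columns: `karyogram_id`, `condition` (`"original"` or
#' `"enhanced"`), `rater_id`, `quality` (1-5), `sharpness` (1-5),
#' `analysis_time_s` (seconds, positive), `suspected_abnormality` (free
#' text, optional).
#'
#' @param path CSV file.
#' @return validated data.frame of rating records.
#' @export
readRatings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateRatings(df)
  df
}

#' @rdname readRatings
#' @param records a rating-record data.frame.
#' @export
validateRatings <- function(records) {
  need <- c("karyogram_id", "condition", "rater_id", "quality", "sharpness",
            "analysis_time_s")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing rating columns: ", paste(miss, collapse = ", "))
  if (!all(records$condition %in% c("original", "enhanced")))
    stop("condition must be 'original' or 'enhanced'")
  if (!all(records$quality %in% 1:5) || !all(records$sharpness %in% 1:5))
    stop("quality and sharpness must be integers 1-5")
  if (any(records$analysis_time_s <= 0))
    stop("analysis_time_s must be positive")
  key <- interaction(records$karyogram_id, records$condition, records$rater_id)
  if (anyDuplicated(key))
    stop("each karyogram must appear once per condition per rater")
  invisible(TRUE)
}

#' Rating-study analysis
#'
#' Per rater, three one-tailed paired t-tests pairing each karyogram's
#' original and enhanced conditions: hypothesis 1 — enhancement increases
#' overall quality; hypothesis 2 — enhancement increases band sharpness;
#' hypothesis 3 — enhancement increases analysis time. No multiple-testing
#' correction is applied by default.
#'
#' @param records rating-record data.frame (see [readRatings()]).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (`"none"` by default).
#' @return data.frame with columns `hypothesis_id`, `rater_id`,
#'   `t_statistic`, `p_value`, `n`.
#' @export
ratingAnalysis <- function(records, adjust = "none") {
  validateRatings(records)
  vars <- c("quality", "sharpness", "analysis_time_s")
  out <- list()
  for (rater in unique(records$rater_id)) {
    r <- records[records$rater_id == rater, ]
    orig <- r[r$condition == "original", ]
    enh <- r[r$condition == "enhanced", ]
    unpaired <- c(setdiff(orig$karyogram_id, enh$karyogram_id),
                  setdiff(enh$karyogram_id, orig$karyogram_id))
    if (length(unpaired))
      stop("pairing error for rater '", rater, "': unpaired karyogram ids ",
           paste(unique(unpaired), collapse = ", "))
    enh <- enh[match(orig$karyogram_id, enh$karyogram_id), ]
    for (h in 1:3) {
      tt <- pairedOneTailedTTest(orig[[vars[h]]], enh[[vars[h]]], "greater")
      out[[length(out) + 1L]] <- data.frame(
        hypothesis_id = h, rater_id = rater, t_statistic = tt$t,
        p_value = tt$p, n = tt$n, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$p_value <- stats::p.adjust(res$p_value, method = adjust)
  res
}
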