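# fragment_planner: overlapping fragment windows for sequences longer than a
# predictor's per-run limit.

round_half_up <- function(x) floor(x + 0.5)

new_fragment_plan <- function(intervals, L, target_len, min_overlap, max_len) {
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in% names(intervals)))
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  intervals$fragment <- seq_len(nrow(intervals))
  rownames(intervals) <- NULL
  structure(
    list(L = as.integer(L), target_len = as.integer(target_len),
         min_overlap = as.integer(min_overlap), max_len = as.integer(max_len),
         intervals = intervals[, c("fragment", "start", "end")]),
    class = "fragment_plan"
  )
}

#' @export
print.fragment_plan <- function(x, ...) {
  cat(sprintf("<fragment_plan> L=%d, %d fragment(s)\n", x$L, nrow(x$intervals)))
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Plan overlapping fragment windows for a long sequence
#'
#' Computes the smallest number of fragments of length `target_len` whose
#' consecutive overlaps are at least `min_overlap`, then spaces the fragment
#' starts evenly: `start_i = 1 + round((i-1) * (L - target_len) / (n-1))`
#' with round-half-up. Because `n` is minimal, actual overlaps can exceed
#' `min_overlap` (the overlap parameter is a floor, not a target). A sequence
#' of 4018 residues with the defaults yields four ~1500-residue fragments,
#' the scheme used for predictors capped at 2500 residues.
#'
#' @param L sequence length (residues)
#' @param target_len fragment length (residues)
#' @param min_overlap minimum residues shared by consecutive fragments
#' @param max_len predictor per-run residue limit (each fragment must fit)
#' @return `fragment_plan`: list with `L`, parameters and an `intervals`
#'   data.frame of 1-based inclusive `(start, end)` windows
#' @export
#' @examples
#' plan_fragments(4018)             # 4 fragments
#' plan_fragments(1000)$intervals   # fits in one
plan_fragments <- function(L, target_len = 1500, min_overlap = 500,
                           max_len = 2500) {
  L <- as.integer(L); target_len <- as.integer(target_len)
  min_overlap <- as.integer(min_overlap); max_len <- as.integer(max_len)
  if (L < 1) stop("parameter error: L must be >= 1")
  if (!(min_overlap > 0 && min_overlap < target_len && target_len <= max_len)) {
    stop("parameter error: need 0 < min_overlap < target_len <= max_len")
  }
  if (L <= target_len) {
    iv <- data.frame(start = 1L, end = L)
  } else {
    # minimal n with n*target_len - (n-1)*min_overlap >= L
    n <- ceiling((L - min_overlap) / (target_len - min_overlap))
    starts <- 1L + as.integer(round_half_up((seq_len(n) - 1) * (L - target_len) / (n - 1)))
    ends <- pmin(starts + target_len - 1L, L)
    iv <- data.frame(start = starts, end = ends)
  }
  plan <- new_fragment_plan(iv, L, target_len, min_overlap, max_len)
  rep <- validate_plan(plan)
  if (!rep$valid) {
    stop("internal planning failure: ", paste(rep$problems, collapse = "; "))
  }
  plan
}

#' Coverage report for a fragment plan
#'
#' Pure report: per-residue fragment multiplicity, consecutive overlaps and
#' any coverage gaps. Accepts hand-made plans, flagging violations rather
#' than erroring, so it can be used to audit externally supplied windows.
#'
#' @param plan `fragment_plan` (or a bare data.frame with `start`,`end` plus
#'   an `L` attribute-free length taken as `max(end)`)
#' @return list with `multiplicity` (integer per residue 1..L), `overlaps`
#'   (consecutive-pair overlap sizes), `min_overlap_observed`,
#'   `max_overlap_observed`, `uncovered` (residues with multiplicity 0),
#'   `valid` and `problems`
#' @export
validate_plan <- function(plan) {
  if (is.data.frame(plan)) {
    plan <- new_fragment_plan(plan, max(plan$end), max(plan$end - plan$start + 1),
                              1L, max(plan$end - plan$start + 1))
  }
  iv <- plan$intervals
  L <- plan$L
  mult <- integer(L)
  for (i in seq_len(nrow(iv))) {
    idx <- iv$start[i]:iv$end[i]
    mult[idx] <- mult[idx] + 1L
  }
  overlaps <- if (nrow(iv) > 1) {
    iv$end[-nrow(iv)] - iv$start[-1] + 1L
  } else integer(0)
  uncovered <- which(mult == 0L)
  problems <- character(0)
  if (length(uncovered) > 0) {
    problems <- c(problems, paste0(length(uncovered), " uncovered residue(s), first gap at ",
                                   uncovered[1]))
  }
  if (any(iv$end - iv$start + 1L > plan$max_len)) {
    problems <- c(problems, "fragment exceeds max_len")
  }
  if (nrow(iv) > 1 && any(overlaps < plan$min_overlap)) {
    problems <- c(problems, "consecutive overlap below min_overlap")
  }
  list(
    multiplicity = mult,
    overlaps = overlaps,
    min_overlap_observed = if (length(overlaps)) min(overlaps) else NA_integer_,
    max_overlap_observed = if (length(overlaps)) max(overlaps) else NA_integer_,
    uncovered = uncovered,
    valid = length(problems) == 0,
    problems = problems
  )
}

# overlap interval (start, end) between consecutive plan fragments i-1 and i
plan_overlap_interval <- function(plan, i) {
  iv <- plan$intervals
  stopifnot(i >= 2, i <= nrow(iv))
  c(start = iv$start[i], end = iv$end[i - 1])
}
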