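#' Construct an interval set
#'
#' Recurrence intervals of one unit type (a phrase type or a motif),
#' measured in whole phrases: by default the positional difference
#' between consecutive occurrences, so a strictly periodic ABCD... song
#' has phrase-type intervals of 4.
#'
#' @param unit_label label of the phrase type or motif.
#' @param level `"phrase"` or `"motif"`.
#' @param intervals positive numeric vector (empty if the unit occurred
#'   at most once).
#' @return an object of class `interval_set`.
#' @export
interval_set <- function(unit_label, level = c("phrase", "motif"),
                         intervals = numeric()) {
  level <- match.arg(level)
  intervals <- as.numeric(intervals)
  if (length(intervals) > 0 && any(intervals < 1)) {
    stop("intervals must be >= 1 phrase")
  }
  structure(list(unit_label = as.character(unit_label), level = level,
                 intervals = intervals),
            class = "interval_set")
}

#' Extract inter-phrase intervals (IPIs) per unit type
#'
#' For each phrase type (or motif) occurring at least twice, counts the
#' recurrence intervals along the performance. A motif occurs in a phrase
#' if it is present in that phrase's motif list; multiple renditions of a
#' motif within one phrase count once (intervals are measured in whole
#' phrases).
#'
#' @param perf a [performance()].
#' @param level `"phrase"` for phrase-type intervals or `"motif"` for
#'   shared-motif intervals.
#' @param interval_mode `"positional"` (default; difference between
#'   occurrence positions, 4 for an exact 4-cycle) or `"exclusive"`
#'   (number of phrases strictly in between, i.e. positional minus 1).
#' @return list of [interval_set()], one per unit occurring >= 2 times.
#' @export
extract_ipis <- function(perf, level = c("phrase", "motif"),
                         interval_mode = c("positional", "exclusive")) {
  validate_performance(perf)
  level <- match.arg(level)
  interval_mode <- match.arg(interval_mode)
  sub <- if (interval_mode == "exclusive") 1 else 0
  if (level == "phrase") {
    units <- unique(perf$phrase_type)
    positions <- lapply(units, function(u) which(perf$phrase_type == u))
  } else {
    units <- motif_alphabet(perf)
    if (length(units) == 0) {
      warning("performance has no motif annotations; no motif intervals")
      return(list())
    }
    positions <- lapply(units, function(u) {
      which(vapply(perf$motifs, function(m) u %in% m, logical(1)))
    })
  }
  keep <- vapply(positions, function(p) length(p) >= 2, logical(1))
  mapply(function(u, p) interval_set(u, level, diff(p) - sub),
         units[keep], positions[keep], SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Normalize an interval set by its mean
#'
#' Divides each interval by the mean of the set, so that every unit type
#' contributes values with mean exactly 1 regardless of how frequently it
#' occurs.
#'
#' @param s an [interval_set()] with at least one interval.
#' @return numeric vector of normalized intervals (mean 1).
#' @export
normalize_ipis <- function(s) {
  stopifnot(inherits(s, "interval_set"))
  if (length(s$intervals) == 0) {
    stop("cannot normalize an empty interval set (unit '", s$unit_label, "')")
  }
  s$intervals / mean(s$intervals)
}

#' Pooled CV* over normalized interval sets
#'
#' Pools the mean-normalized intervals of all unit types and returns
#' their coefficient of variation (s.d./mean). Because each unit's
#' normalized intervals have mean 1, the pooled mean is 1 and CV* equals
#' the pooled standard deviation. The population s.d. (divisor N) is the
#' default; units with a single interval contribute one normalized value
#' of 1.0 unless `include_singletons = FALSE`.
#'
#' @param sets list of [interval_set()] (at least one non-empty).
#' @param include_singletons keep unit types with exactly one interval?
#' @param sd_type `"population"` (divisor N, default) or `"sample"`
#'   (divisor N-1).
#' @param provenance provenance tag carried on the score.
#' @return an object of class `regularity_score` with fields `cv_star`,
#'   `level`, `provenance`, `n_units`, `n_intervals` and `pooled` (the
#'   pooled normalized values).
#' @export
pooled_cv <- function(sets, include_singletons = TRUE,
                      sd_type = c("population", "sample"),
                      provenance = "observed") {
  sd_type <- match.arg(sd_type)
  stopifnot(is.list(sets), length(sets) > 0)
  nonempty <- Filter(function(s) length(s$intervals) > 0, sets)
  if (!include_singletons) {
    nonempty <- Filter(function(s) length(s$intervals) > 1, nonempty)
  }
  if (length(nonempty) == 0) {
    stop("no unit type with enough intervals to pool")
  }
  pooled <- unlist(lapply(nonempty, normalize_ipis))
  m <- mean(pooled)
  n <- length(pooled)
  if (sd_type == "population") {
    s <- sqrt(sum((pooled - m)^2) / n)
  } else {
    s <- if (n > 1) stats::sd(pooled) else 0
  }
  level <- unique(vapply(nonempty, `[[`, character(1), "level"))
  structure(
    list(cv_star = s / m,
         level = if (length(level) == 1) level else "mixed",
         provenance = provenance,
         n_units = length(nonempty),
         n_intervals = n,
         pooled = pooled),
    class = "regularity_score")
}

#' @export
print.regularity_score <- function(x, ...) {
  cat(sprintf("<regularity_score> CV* = %.4f (%s level, %s; %d units, %d intervals)\n",
              x$cv_star, x$level, x$provenance, x$n_units, x$n_intervals))
  invisible(x)
}

#' Observed CV* of a performance
#'
#' Convenience wrapper: [extract_ipis()] then [pooled_cv()].
#'
#' @inheritParams extract_ipis
#' @inheritParams pooled_cv
#' @return a `regularity_score`.
#' @export
performance_cv <- function(perf, level = c("phrase", "motif"),
                           interval_mode = c("positional", "exclusive"),
                           include_singletons = TRUE,
                           sd_type = c("population", "sample")) {
  level <- match.arg(level)
  sets <- extract_ipis(perf, level, interval_mode)
  pooled_cv(sets, include_singletons, sd_type, provenance = "observed")
}

#' Shuffled null distribution of CV*
#'
#' Repeatedly permutes the phrase order uniformly at random (whole phrase
#' records move together; motif annotations ride along with their phrase)
#' and recomputes CV*. This is the chance level against which observed
#' regularity is judged.
#'
#' @inheritParams performance_cv
#' @param n_shuffles number of random permutations (default 100).
#' @param seed optional RNG seed (global RNG state is restored on exit).
#' @return an object of class `shuffled_null`: list with `scores`
#'   (numeric vector of replicate CV* values), `mean`, `sd`, `level` and
#'   `n_shuffles`.
#' @export
shuffled_null <- function(perf, level = c("phrase", "motif"),
                          n_shuffles = 100, seed = NULL,
                          interval_mode = c("positional", "exclusive"),
                          include_singletons = TRUE,
                          sd_type = c("population", "sample")) {
  validate_performance(perf)
  level <- match.arg(level)
  interval_mode <- match.arg(interval_mode)
  sd_type <- match.arg(sd_type)
  stopifnot(n_shuffles >= 1)
  local_seed(seed)
  n <- length(perf$phrase_type)
  scores <- vapply(seq_len(n_shuffles), function(i) {
    ord <- order(stats::runif(n))
    shuf <- performance(perf$phrase_type[ord], perf$motifs[ord],
                        bird_id = perf$bird_id)
    sets <- extract_ipis(shuf, level, interval_mode)
    pooled_cv(sets, include_singletons, sd_type,
              provenance = "shuffled")$cv_star
  }, numeric(1))
  structure(
    list(scores = scores, mean = mean(scores), sd = stats::sd(scores),
         level = level, n_shuffles = n_shuffles),
    class = "shuffled_null")
}

#' @export
print.shuffled_null <- function(x, ...) {
  cat(sprintf("<shuffled_null> %s level: mean CV* = %.4f (sd %.4f, %d shuffles)\n",
              x$level, x$mean, x$sd, x$n_shuffles))
  invisible(x)
}
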