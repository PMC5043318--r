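#' Paired t-test between observed and model scores
#'
#' Differences are model minus observed, one pair per bird; degrees of
#' freedom are n - 1. If every difference is exactly zero (identical
#' vectors) the test statistic is 0 with p = 1; constant non-zero
#' differences are a degenerate case and raise an error.
#'
#' @param observed,model equal-length numeric vectors (n >= 2).
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_test <- function(observed, model) {
  stopifnot(length(observed) == length(model), length(observed) >= 2)
  d <- model - observed
  n <- length(d)
  if (all(d == 0)) {
    return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
  }
  if (stats::sd(d) == 0) {
    stop("degenerate paired t-test: differences have zero variance")
  }
  tt <- stats::t.test(model, observed, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d))
}

#' One-sided sign test for ranks below the median
#'
#' Tests whether per-bird ranks fall below the 50th percentile of the
#' permutation scale more often than chance (binomial with p = 0.5,
#' alternative "greater"). Ranks exactly at the median are excluded.
#'
#' @param ranks vector of ranks in `[1, n_perm]`.
#' @param n_perm number of permutations defining the scale.
#' @return one-sided p-value.
#' @export
sign_test_below_median <- function(ranks, n_perm) {
  stopifnot(length(ranks) >= 1, all(ranks >= 1), all(ranks <= n_perm))
  med <- n_perm / 2
  below <- sum(ranks < med)
  above <- sum(ranks > med)
  n <- below + above
  if (n == 0) stop("no usable ranks (all exactly at the median)")
  stats::pbinom(below - 1, n, 0.5, lower.tail = FALSE)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length n >= 3 with non-zero
#'   variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Full per-bird analysis
#'
#' Observed CV* at both levels, shuffled-null means, and (when the
#' performance has shared motifs) the permuted-Markov rank, probability
#' and complexity.
#'
#' @param perf a [performance()] with motif annotations.
#' @param n_shuffles shuffled-null replicates.
#' @param n_perm,n_reps permuted-Markov parameters (see [rank_bird()]).
#' @param seed RNG seed for all stochastic stages.
#' @return one-row data.frame.
#' @export
analyze_performance <- function(perf, n_shuffles = 100, n_perm = 100,
                                n_reps = 100, seed = NULL) {
  validate_performance(perf)
  local_seed(seed)
  seeds <- draw_subseeds(3)
  cv_ph <- performance_cv(perf, "phrase")
  cv_m <- performance_cv(perf, "motif")
  sh_ph <- shuffled_null(perf, "phrase", n_shuffles, seed = seeds[1])
  sh_m <- shuffled_null(perf, "motif", n_shuffles, seed = seeds[2])
  rk <- tryCatch(rank_bird(perf, n_perm, n_reps, seed = seeds[3]),
                 error = function(e) NULL)
  data.frame(
    bird_id = perf$bird_id,
    n_phrases = length(perf$phrase_type),
    n_types = length(unique(perf$phrase_type)),
    cv_ph = cv_ph$cv_star,
    cv_ph_shuffled = sh_ph$mean,
    cv_m = cv_m$cv_star,
    cv_m_shuffled = sh_m$mean,
    cv_synth_bird = if (is.null(rk)) NA_real_ else rk$cv_synth_bird,
    rank = if (is.null(rk)) NA_integer_ else rk$rank,
    probability = if (is.null(rk)) NA_real_ else rk$probability,
    complexity = if (is.null(rk)) NA_integer_ else rk$complexity,
    stringsAsFactors = FALSE)
}

#' Default two-cohort pipeline configuration
#'
#' Mirrors the field design of an exploration cohort of 9 birds and a
#' confirmation cohort of 8 birds. Each cohort entry gives the number of
#' birds, its optimization mode and its transition density.
#'
#' @param cohorts list of cohort descriptions, each a list with
#'   `n_birds`, `optimization`, `density`.
#' @param n_types,n_motifs,sharing_degree,performance_length generator
#'   settings shared by all birds.
#' @param n_shuffles,n_perm,n_reps analysis Monte-Carlo sizes.
#' @param seed master seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohorts = list(
                              list(n_birds = 9, optimization = "optimized",
                                   density = 0.5),
                              list(n_birds = 8, optimization = "random",
                                   density = 0.15)),
                            n_types = 8, n_motifs = 8, sharing_degree = 2,
                            performance_length = 300, n_shuffles = 100,
                            n_perm = 100, n_reps = 100, seed = 1) {
  structure(list(cohorts = cohorts, n_types = n_types, n_motifs = n_motifs,
                 sharing_degree = sharing_degree,
                 performance_length = performance_length,
                 n_shuffles = n_shuffles, n_perm = n_perm, n_reps = n_reps,
                 seed = seed),
            class = "pipeline_config")
}

# Flat key = value config file -> pipeline_config. Cohorts are encoded as
# cohort<i>.n_birds / .optimization / .density keys.
pipeline_config_from_file <- function(path) {
  raw <- read_config(path)
  cohort_keys <- grep("^cohort[0-9]+\\.", names(raw), value = TRUE)
  cohorts <- list()
  for (key in cohort_keys) {
    i <- as.integer(sub("^cohort([0-9]+)\\..*$", "\\1", key))
    fld <- sub("^cohort[0-9]+\\.", "", key)
    while (length(cohorts) < i) cohorts[[length(cohorts) + 1]] <- list()
    cohorts[[i]][[fld]] <- raw[[key]]
  }
  args <- raw[setdiff(names(raw), cohort_keys)]
  args <- args[names(args) %in% names(formals(pipeline_config))]
  if (length(cohorts) > 0) args$cohorts <- cohorts
  do.call(pipeline_config, args)
}

#' Run the end-to-end synthetic-cohort pipeline
#'
#' Generates every bird from the configuration, runs the per-bird
#' analysis ([analyze_performance()]) and assembles cohort statistics:
#' paired t-tests of observed versus shuffled CV* at both levels, the
#' sign test of ranks below the median, and the correlations of rank
#' with synthetic CV* and of complexity with the effort score
#' (`n_perm + 1 - rank`). All randomness derives from `config$seed`, so
#' reruns are byte-identical.
#'
#' @param config a [pipeline_config()] or path to a key = value config
#'   file.
#' @param out_dir optional directory; if given, writes `birds.csv` and
#'   `summary.txt`.
#' @return a list of class `cohort_result` with `birds` (per-bird
#'   data.frame), `tests` (named list) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- pipeline_config_from_file(config)
  stopifnot(inherits(config, "pipeline_config"))
  local_seed(config$seed)
  rows <- list()
  bird_no <- 0L
  for (ci in seq_along(config$cohorts)) {
    co <- config$cohorts[[ci]]
    for (b in seq_len(co$n_birds)) {
      bird_no <- bird_no + 1L
      seeds <- draw_subseeds(2)
      cfg <- generator_config(
        n_types = config$n_types, n_motifs = config$n_motifs,
        sharing_degree = config$sharing_degree,
        density = co$density %||% 0.3,
        performance_length = config$performance_length,
        optimization = co$optimization %||% "random",
        seed = seeds[1])
      bird <- simulate_bird(cfg, bird_id = sprintf("cohort%d_bird%d", ci, b))
      row <- analyze_performance(bird$performance,
                                 n_shuffles = config$n_shuffles,
                                 n_perm = config$n_perm,
                                 n_reps = config$n_reps, seed = seeds[2])
      row$cohort <- ci
      row$optimization <- cfg$optimization
      rows[[bird_no]] <- row
    }
  }
  birds <- do.call(rbind, rows)
  ok <- !is.na(birds$rank)
  tests <- list(
    t_phrase = paired_t_test(birds$cv_ph, birds$cv_ph_shuffled),
    t_motif = paired_t_test(birds$cv_m, birds$cv_m_shuffled),
    sign_ranks = if (any(ok)) {
      sign_test_below_median(birds$rank[ok], config$n_perm)
    } else NA_real_,
    cor_rank_cv = if (sum(ok) >= 3) {
      tryCatch(pearson_correlation(birds$rank[ok], birds$cv_synth_bird[ok]),
               error = function(e) NULL)
    } else NULL,
    cor_complexity_effort = if (sum(ok) >= 3) {
      tryCatch(pearson_correlation(birds$complexity[ok],
                                   config$n_perm + 1 - birds$rank[ok]),
               error = function(e) NULL)
    } else NULL)
  res <- structure(list(birds = birds, tests = tests, config = config),
                   class = "cohort_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(birds, file.path(out_dir, "birds.csv"),
                     row.names = FALSE)
    writeLines(utils::capture.output(print(res)),
               file.path(out_dir, "summary.txt"))
  }
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  b <- x$birds
  cat("== cohort result:", nrow(b), "birds ==\n")
  cat(sprintf("mean CVph* = %.3f (shuffled %.3f), paired t%d = %.3f, p = %.4g\n",
              mean(b$cv_ph), mean(b$cv_ph_shuffled), x$tests$t_phrase$df,
              x$tests$t_phrase$t, x$tests$t_phrase$p))
  cat(sprintf("mean CVm*  = %.3f (shuffled %.3f), paired t%d = %.3f, p = %.4g\n",
              mean(b$cv_m), mean(b$cv_m_shuffled), x$tests$t_motif$df,
              x$tests$t_motif$t, x$tests$t_motif$p))
  ok <- !is.na(b$rank)
  if (any(ok)) {
    cat(sprintf("mean rank = %.2f of %d (sign test below median p = %.4g)\n",
                mean(b$rank[ok]), x$config$n_perm, x$tests$sign_ranks))
  }
  if (!is.null(x$tests$cor_rank_cv)) {
    cat(sprintf("cor(rank, CVm*[synth-bird]): r = %.3f, p = %.4g\n",
                x$tests$cor_rank_cv$r, x$tests$cor_rank_cv$p))
  }
  if (!is.null(x$tests$cor_complexity_effort)) {
    cat(sprintf("cor(complexity, effort): r = %.3f, p = %.4g\n",
                x$tests$cor_complexity_effort$r,
                x$tests$cor_complexity_effort$p))
  }
  invisible(x)
}

#' Raster plot of a performance
#'
#' One row per phrase, first-onset aligned. With pitch traces, segments
#' are coloured by pitch; otherwise each row is a bar coloured by phrase
#' type. `sort = "type"` groups rows by phrase type, as in a sorted
#' raster.
#'
#' @param perf a [performance()].
#' @param pitch_traces optional list (one per phrase) of data.frames
#'   with columns `time` and `pitch` (Hz), first-onset aligned.
#' @param sort `"performance"` (singing order) or `"type"`.
#' @param file optional path; if given, a PNG is written there.
#' @return invisibly, the plotted row order (integer vector), so callers
#'   can verify that sorted and unsorted rasters contain the same rows.
#' @export
plot_raster <- function(perf, pitch_traces = NULL,
                        sort = c("performance", "type"), file = NULL) {
  validate_performance(perf)
  sort <- match.arg(sort)
  n <- length(perf$phrase_type)
  ord <- if (sort == "type") order(perf$phrase_type, seq_len(n))
         else seq_len(n)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = max(200, 8 * n + 80))
    on.exit(grDevices::dev.off())
  }
  types <- unique(perf$phrase_type)
  pal <- grDevices::hcl.colors(max(3, length(types)), "Dark 3")
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(n + 0.5, 0.5),
                 xlab = "time (first-onset aligned)", ylab = "phrase",
                 main = paste0("raster: ", perf$bird_id,
                               if (sort == "type") " (sorted)" else ""))
  for (row in seq_len(n)) {
    i <- ord[row]
    if (!is.null(pitch_traces)) {
      tr <- pitch_traces[[i]]
      xmax <- max(tr$time) + 1e-9
      cols <- grDevices::hcl.colors(64, "Viridis")
      pit <- pmin(pmax(tr$pitch, 500), 3000)
      ci <- 1 + floor(63 * (pit - 500) / 2500)
      graphics::segments(tr$time / xmax, row,
                         c(tr$time[-1], xmax)[seq_along(tr$time)] / xmax,
                         row, col = cols[ci], lwd = 6)
    } else {
      graphics::rect(0, row - 0.4, 1, row + 0.4,
                     col = pal[match(perf$phrase_type[i], types)],
                     border = NA)
    }
  }
  invisible(ord)
}
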