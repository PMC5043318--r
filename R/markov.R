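#' Estimate the bigram (first-order Markov) model of a performance
#'
#' Counts how often each phrase type is immediately followed by each
#' other type in the natural singing order; the final phrase contributes
#' no outgoing transition. The initial/restart distribution is the
#' empirical phrase-token frequency.
#'
#' @param perf a [performance()] with at least 2 phrases.
#' @return a [transition_matrix()].
#' @export
estimate_bigram <- function(perf) {
  validate_performance(perf)
  n <- length(perf$phrase_type)
  if (n < 2) stop("need at least 2 phrases to estimate transitions")
  states <- unique(perf$phrase_type)
  from <- factor(perf$phrase_type[-n], levels = states)
  to <- factor(perf$phrase_type[-1], levels = states)
  counts <- unclass(table(from, to))
  init <- as.numeric(table(factor(perf$phrase_type, levels = states))) / n
  transition_matrix(counts, states = states, init = init)
}

#' Permute which phrase-type labels sit on which transition roles
#'
#' Returns the matrix with entries `T'[i, j] = T[p(i), p(j)]` for a
#' bijection `p` on the states. Phrase-level interval statistics of
#' sequences generated from `T'` are distributionally unchanged, but
#' motif-level statistics may change because the motif map stays
#' attached to the labels.
#'
#' @param tm a [transition_matrix()].
#' @param perm integer permutation of `seq_along(tm$states)`.
#' @return a [transition_matrix()] over the same state labels.
#' @export
permute_labels <- function(tm, perm) {
  stopifnot(inherits(tm, "transition_matrix"))
  n <- length(tm$states)
  perm <- as.integer(perm)
  if (length(perm) != n || !identical(sort(perm), seq_len(n))) {
    stop("perm must be a bijection on the states")
  }
  out <- tm
  out$counts <- tm$counts[perm, perm, drop = FALSE]
  out$probs <- tm$probs[perm, perm, drop = FALSE]
  dimnames(out$counts) <- dimnames(out$probs) <- list(tm$states, tm$states)
  out$init <- tm$init[perm]
  out$dead_ends <- tm$dead_ends[perm]
  out
}

# Unit membership matrix for the fast CV* path: states x units logical,
# TRUE where the state (phrase type) carries the unit.
unit_membership <- function(states, map, level = c("motif", "phrase")) {
  level <- match.arg(level)
  if (level == "phrase") {
    return(diag(TRUE, length(states)))
  }
  units <- sort(unique(unlist(map)))
  if (length(units) == 0) stop("motif map carries no motifs")
  mem <- matrix(FALSE, length(states), length(units),
                dimnames = list(states, units))
  for (ty in names(map)) {
    i <- match(ty, states)
    if (!is.na(i) && length(map[[ty]]) > 0) mem[i, map[[ty]]] <- TRUE
  }
  mem
}

#' Mean synthetic CV* under a Markov model
#'
#' Generates `n_reps` synthetic phrase sequences of the given length
#' from the model and computes the pooled normalized-interval CV* of
#' each (motif level by default), returning the replicate scores and
#' their mean. Uses a fast compiled path equivalent to
#' [generate_performance()] + [performance_cv()] (the equivalence is
#' exercised by the test suite).
#'
#' @param tm a [transition_matrix()].
#' @param map a [motif_map()] over `tm$states` (ignored at phrase level).
#' @param length sequence length (conventionally the source performance
#'   length).
#' @param n_reps number of synthetic sequences (default 100).
#' @param seed optional RNG seed.
#' @param level `"motif"` (default) or `"phrase"`.
#' @param include_singletons as in [pooled_cv()].
#' @return object of class `cv_synth`: list with `mean`, `scores`,
#'   `level`, `n_reps`.
#' @export
cv_synth <- function(tm, map = NULL, length = 300, n_reps = 100,
                     seed = NULL, level = c("motif", "phrase"),
                     include_singletons = TRUE) {
  level <- match.arg(level)
  stopifnot(inherits(tm, "transition_matrix"), n_reps >= 1, length >= 2)
  if (level == "motif") {
    if (is.null(map)) stop("motif-level cv_synth needs a motif map")
    extra <- setdiff(names(map), tm$states)
    if (length(extra) > 0) {
      stop("motif map names inconsistent with matrix states: ",
           paste(extra, collapse = ", "))
    }
  }
  mem <- unit_membership(tm$states, map, level)
  cum <- t(apply(tm$probs, 1, cumsum))
  init_cum <- cumsum(tm$init)
  local_seed(seed)
  scores <- vapply(seq_len(n_reps), function(i) {
    s <- simulate_chain_cpp(cum, init_cum, as.integer(length))
    pooled_cv_seq_cpp(s, mem, include_singletons, 0L)
  }, numeric(1))
  # a replicate can be NA when a (near-absorbing) chain never repeats
  # any unit; the mean is taken over the informative replicates
  if (all(is.na(scores))) {
    stop("no unit recurrence in any synthetic replicate; ",
         "cannot estimate CV*")
  }
  structure(list(mean = mean(scores, na.rm = TRUE), scores = scores,
                 level = level, n_reps = n_reps,
                 n_valid = sum(!is.na(scores))),
            class = "cv_synth")
}

#' @export
print.cv_synth <- function(x, ...) {
  cat(sprintf("<cv_synth> mean CV* = %.4f (%s level, %d replicates)\n",
              x$mean, x$level, x$n_reps))
  invisible(x)
}

#' Kolmogorov-complexity proxy of a transition matrix
#'
#' The number of non-zero entries of the bigram transition matrix: the
#' length of the shortest "programme" (list of admissible transitions
#' and their weights) that regenerates sequences like the bird's.
#'
#' @param tm a [transition_matrix()].
#' @return integer count of non-zero entries.
#' @export
kolmogorov_complexity <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  sum(tm$counts > 0)
}

# Rank of the bird's value among permuted-model values: 1 + number of
# permuted means strictly below, with exact ties counted as below
# (conservative, larger probability), capped at n_perm so that
# probability = rank / n_perm stays in (0, 1].
rank_from_values <- function(bird_value, permuted_values) {
  r <- 1L + sum(permuted_values <= bird_value)
  min(r, length(permuted_values))
}

# Sample n distinct non-identity permutations of 1..k uniformly.
sample_permutations <- function(k, n) {
  if (k <= 12) {  # factorial fits comfortably in double up to 12!
    if (n > factorial(k) - 1) {
      stop("cannot draw ", n, " distinct non-identity permutations of ",
           k, " states")
    }
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", n)
  got <- 0L
  id_key <- paste(seq_len(k), collapse = ",")
  while (got < n) {
    p <- sample(k)
    key <- paste(p, collapse = ",")
    if (key == id_key || !is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    got <- got + 1L
    out[[got]] <- p
  }
  out
}

#' Rank a bird's syntax among permuted Markov models
#'
#' The "effort" estimate: fit the bigram model and motif map to the
#' performance, compute the mean synthetic motif-level CV* under the
#' bird's own matrix, then under `n_perm` distinct random non-identity
#' label permutations of that matrix, and rank the bird's value among
#' the permuted ones (ascending). The rank divided by `n_perm` is a
#' direct empirical probability estimate: a low rank means the bird's
#' phrase transitions are near-optimal for motif temporal regularity.
#'
#' @param perf a [performance()] with >= 2 phrase types and at least one
#'   motif shared across phrase types.
#' @param n_perm number of permuted models (default 100, >= 2).
#' @param n_reps synthetic sequences per model (default 100).
#' @param length synthetic sequence length; default the performance
#'   length.
#' @param seed optional RNG seed; all nested Monte-Carlo seeds derive
#'   from it.
#' @param include_singletons as in [pooled_cv()].
#' @return object of class `rank_result`: list with `cv_synth_bird`,
#'   `cv_synth_permuted` (vector of permuted-model means), `rank`,
#'   `probability`, `complexity`, `n_perm`, `n_reps`, `bird_id`.
#' @export
rank_bird <- function(perf, n_perm = 100, n_reps = 100, length = NULL,
                      seed = NULL, include_singletons = TRUE) {
  validate_performance(perf)
  if (n_perm < 2) stop("n_perm must be >= 2")
  if (length(unique(perf$phrase_type)) < 2) {
    stop("need >= 2 phrase types to permute")
  }
  map <- derive_motif_map(perf)
  shared <- table(unlist(lapply(map, unique)))
  if (!any(shared >= 2)) {
    stop("rank undefined: no motif is shared across phrase types, ",
         "so permutations cannot change motif-level CV*")
  }
  tm <- estimate_bigram(perf)
  length <- as.integer(length %||% base::length(perf$phrase_type))
  local_seed(seed)
  seeds <- draw_subseeds(n_perm + 1L)
  bird <- cv_synth(tm, map, length = length, n_reps = n_reps,
                   seed = seeds[1], include_singletons = include_singletons)
  perms <- sample_permutations(base::length(tm$states), n_perm)
  permuted <- vapply(seq_len(n_perm), function(i) {
    cv_synth(permute_labels(tm, perms[[i]]), map, length = length,
             n_reps = n_reps, seed = seeds[i + 1L],
             include_singletons = include_singletons)$mean
  }, numeric(1))
  r <- rank_from_values(bird$mean, permuted)
  structure(
    list(cv_synth_bird = bird$mean, bird_scores = bird$scores,
         cv_synth_permuted = permuted, rank = r,
         probability = r / n_perm,
         complexity = kolmogorov_complexity(tm),
         n_perm = n_perm, n_reps = n_reps, bird_id = perf$bird_id),
    class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf(paste0("<rank_result> %s: CVm*[synth-bird] = %.4f, rank %d of %d",
                     " (p = %.3g), complexity %d\n"),
              x$bird_id, x$cv_synth_bird, x$rank, x$n_perm, x$probability,
              x$complexity))
  invisible(x)
}
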