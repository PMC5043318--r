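#' Generator configuration for synthetic singing performances
#'
#' Describes the stated world the generator emulates: a repertoire of
#' `n_types` phrase types composed from `n_motifs` motifs, with an
#' average of `sharing_degree` phrase types carrying each motif, phrase
#' syntax governed by a first-order Markov chain with a fraction
#' `density` of admissible transitions, and performances of
#' `performance_length` phrases. `optimization` controls whether the
#' label-to-transition assignment is tuned to minimize ("optimized"),
#' ignore ("random") or maximize ("anti-optimized") motif-level CV*.
#'
#' @param n_types number of phrase types (>= 1).
#' @param n_motifs number of motif labels (>= 1).
#' @param sharing_degree mean number of phrase types sharing each motif
#'   (>= 1, <= n_types).
#' @param density fraction of non-zero transition entries in (0, 1];
#'   must admit at least one outgoing edge per state.
#' @param performance_length number of phrases per performance (>= 2).
#' @param optimization one of `"optimized"`, `"random"`,
#'   `"anti-optimized"`.
#' @param jitter_sd s.d. of syllable-onset timing noise, seconds.
#' @param n_candidates candidate permutations evaluated by
#'   [assign_labels()] in optimized/anti-optimized mode.
#' @param concentration Dirichlet shape for transition-row weights;
#'   values below 1 produce dominant transitions (stereotyped syntax,
#'   like an 80/20 split), 1 gives flat Dirichlet rows.
#' @param seed RNG seed attached to the configuration.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_types = 10, n_motifs = 8, sharing_degree = 2,
                             density = 0.3, performance_length = 300,
                             optimization = c("random", "optimized",
                                              "anti-optimized"),
                             jitter_sd = 0.005, n_candidates = 100,
                             concentration = 1, seed = 1) {
  optimization <- match.arg(optimization)
  if (n_types < 1) stop("config error: n_types must be >= 1")
  if (n_motifs < 1) stop("config error: n_motifs must be >= 1")
  if (sharing_degree < 1 || sharing_degree > n_types) {
    stop("config error: sharing_degree must be in [1, n_types]")
  }
  if (performance_length < 2) {
    stop("config error: performance_length must be >= 2")
  }
  if (density <= 0 || density > 1) stop("config error: density must be in (0,1]")
  if (round(density * n_types^2) < 1) {
    stop("config error: density admits no transitions")
  }
  if (jitter_sd < 0) stop("config error: jitter_sd must be >= 0")
  if (n_candidates < 1) stop("config error: n_candidates must be >= 1")
  if (concentration <= 0) stop("config error: concentration must be > 0")
  structure(
    list(n_types = as.integer(n_types), n_motifs = as.integer(n_motifs),
         sharing_degree = sharing_degree, density = density,
         performance_length = as.integer(performance_length),
         optimization = optimization, jitter_sd = jitter_sd,
         n_candidates = as.integer(n_candidates),
         concentration = concentration, seed = seed),
    class = "generator_config")
}

#' Phrase template: the acoustic skeleton of one phrase type
#'
#' A phrase type is rendered as a fixed pattern of syllable onsets
#' (seconds from phrase start, first onset at 0) with a carrier
#' frequency per syllable in the species band (0.5-3 kHz).
#'
#' @param phrase_type label.
#' @param onset_times strictly increasing, `onset_times[1] == 0`, total
#'   duration <= 10 s.
#' @param motifs motif labels carried by this phrase type.
#' @param freqs per-syllable tone frequency in Hz (recycled if scalar);
#'   default 1500 Hz.
#' @return an object of class `phrase_template`.
#' @export
phrase_template <- function(phrase_type, onset_times, motifs = character(),
                            freqs = 1500) {
  onset_times <- as.numeric(onset_times)
  if (length(onset_times) < 1) stop("a phrase template needs >= 1 syllable")
  if (onset_times[1] != 0) stop("first syllable onset must be at time 0")
  if (any(diff(onset_times) <= 0)) stop("onset times must be strictly increasing")
  if (max(onset_times) > 10) stop("phrase duration must be <= 10 s")
  freqs <- rep_len(as.numeric(freqs), length(onset_times))
  if (any(freqs < 500 | freqs > 3000)) {
    stop("syllable frequencies must lie in the 0.5-3 kHz band")
  }
  structure(list(phrase_type = as.character(phrase_type),
                 onset_times = onset_times,
                 motifs = as.character(motifs), freqs = freqs),
            class = "phrase_template")
}

#' Generate a phrase-type inventory with motif sharing
#'
#' Creates one [phrase_template()] per phrase type (each with a distinct
#' syllable-onset pattern) and assigns each motif to on average
#' `sharing_degree` phrase types, every motif to at least one. With
#' `sharing_degree == 1` motifs are assigned round-robin so no motif is
#' shared across types (and when `n_motifs == n_types` each type carries
#' exactly one motif).
#'
#' @param cfg a [generator_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return list with `templates` (list of `phrase_template`) and `map`
#'   (a [motif_map()]).
#' @export
make_inventory <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  local_seed(seed %||% cfg$seed)
  types <- make_labels(cfg$n_types)
  motifs <- as.character(seq_len(cfg$n_motifs))
  assign <- vector("list", cfg$n_types)
  names(assign) <- types
  for (i in seq_len(cfg$n_types)) assign[[i]] <- character()
  if (cfg$sharing_degree == 1) {
    for (j in seq_len(cfg$n_motifs)) {
      ty <- types[((j - 1) %% cfg$n_types) + 1]
      assign[[ty]] <- c(assign[[ty]], motifs[j])
    }
  } else {
    for (j in seq_len(cfg$n_motifs)) {
      k <- 1 + stats::rpois(1, cfg$sharing_degree - 1)
      k <- min(k, cfg$n_types)
      for (ty in sample(types, k)) assign[[ty]] <- c(assign[[ty]], motifs[j])
    }
  }
  templates <- vector("list", cfg$n_types)
  for (i in seq_len(cfg$n_types)) {
    n_syl <- sample(4:9, 1)
    gaps <- stats::runif(n_syl - 1, 0.15, 0.45)
    onsets <- c(0, cumsum(gaps))
    freqs <- stats::runif(n_syl, 600, 2800)
    templates[[i]] <- phrase_template(types[i], onsets, assign[[types[i]]],
                                      freqs)
  }
  names(templates) <- types
  list(templates = templates, map = motif_map(assign))
}

# Phrase-type labels: A, B, ..., Z, T27, T28, ...
make_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else c(LETTERS, paste0("T", 27:n))
}

#' Generate a random irreducible transition matrix of given sparsity
#'
#' Builds a row-stochastic matrix whose number of non-zero entries is
#' within one of `round(density * n_types^2)`, subject to a floor of one
#' outgoing edge per state. Irreducibility (a single recurrent class
#' containing all states) is guaranteed by seeding the support with a
#' random Hamiltonian cycle before adding extra edges; probabilities are
#' drawn from a symmetric Dirichlet on each row's support. The `init`
#' slot is set to the stationary distribution.
#'
#' @param cfg a [generator_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return a [transition_matrix()] (counts hold the 0/1 support
#'   indicator).
#' @export
make_transition_matrix <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  local_seed(seed %||% cfg$seed)
  n <- cfg$n_types
  target <- max(n, round(cfg$density * n^2))
  if (target > n^2) stop("config error: infeasible density")
  states <- make_labels(n)
  support <- matrix(FALSE, n, n)
  cyc <- if (n > 1) sample(n) else 1L
  for (i in seq_len(n)) {
    support[cyc[i], cyc[if (i == n) 1 else i + 1]] <- TRUE
  }
  free <- which(!support)
  extra <- target - sum(support)
  if (extra > 0) support[sample(free, min(extra, length(free)))] <- TRUE
  probs <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- which(support[i, ])
    # concentrated Dirichlet: song syntax is stereotyped, with dominant
    # transitions (e.g. 80/20 splits) rather than uniform spreading
    w <- pmax(stats::rgamma(length(j), shape = cfg$concentration %||% 1),
              1e-9)
    probs[i, j] <- w / sum(w)
  }
  tm <- transition_matrix(1 * support, states = states)
  tm$probs <- probs
  dimnames(tm$probs) <- list(states, states)
  tm$init <- stationary_distribution(tm)
  tm
}

#' Choose a label-to-transition assignment (state permutation)
#'
#' The generator-side inverse of the rank analysis: among random
#' candidate permutations of the state labels, pick the one whose
#' permuted transition matrix yields the smallest (optimized) or largest
#' (anti-optimized) mean synthetic motif-level CV*, estimated with
#' [cv_synth()]. `mode = "random"` returns a uniform random permutation;
#' `n_candidates = 1` in optimized mode is equivalent to random.
#'
#' @param tm a [transition_matrix()].
#' @param map a [motif_map()] over the same states.
#' @param mode `"optimized"`, `"random"` or `"anti-optimized"`.
#' @param n_candidates number of candidate permutations (>= 1).
#' @param seed optional RNG seed.
#' @param eval_length,eval_reps size of the Monte-Carlo estimate used to
#'   score each candidate.
#' @return an integer state permutation `p` (to be applied with
#'   [permute_labels()], i.e. new transition `[i, j] = old[p[i], p[j]]`).
#' @export
assign_labels <- function(tm, map, mode = c("optimized", "random",
                                            "anti-optimized"),
                          n_candidates = 100, seed = NULL,
                          eval_length = 200, eval_reps = 20) {
  mode <- match.arg(mode)
  stopifnot(inherits(tm, "transition_matrix"), inherits(map, "motif_map"))
  if (n_candidates < 1) stop("n_candidates must be >= 1")
  if (length(tm$states) != length(map)) {
    stop("motif map must cover exactly the matrix states")
  }
  local_seed(seed)
  n <- length(tm$states)
  if (mode == "random" || n_candidates == 1 || n == 1) {
    return(if (n > 1) sample(n) else 1L)
  }
  cands <- replicate(n_candidates, sample(n), simplify = FALSE)
  seeds <- draw_subseeds(n_candidates)
  scores <- vapply(seq_len(n_candidates), function(i) {
    # a candidate labeling can make the chain near-absorbing in a
    # motif-free state; such candidates are simply not selectable
    tryCatch(
      cv_synth(permute_labels(tm, cands[[i]]), map, length = eval_length,
               n_reps = eval_reps, seed = seeds[i])$mean,
      error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(scores))) return(cands[[1L]])
  if (mode == "optimized") cands[[which.min(scores)]]
  else cands[[which.max(scores)]]
}

#' Generate a synthetic performance from a Markov model
#'
#' Draws the first phrase from the model's `init` distribution and each
#' subsequent phrase from the transition probabilities; dead-end states
#' restart from `init` so the sequence always reaches the requested
#' length. Motif lists are filled in from the motif map.
#'
#' @param tm a [transition_matrix()].
#' @param map a [motif_map()]; may be `NULL` for a motif-free sequence.
#' @param length number of phrases (>= 2).
#' @param seed optional RNG seed; fixed seed gives a bit-reproducible
#'   sequence.
#' @param bird_id identifier attached to the result.
#' @return a [performance()].
#' @export
generate_performance <- function(tm, map = NULL, length = 300, seed = NULL,
                                 bird_id = "synthetic") {
  stopifnot(inherits(tm, "transition_matrix"), length >= 2)
  if (!is.null(map) && !all(names(map) %in% tm$states)) {
    stop("motif map names must be a subset of the matrix states")
  }
  if (all(tm$dead_ends)) stop("generation error: all states are dead ends")
  local_seed(seed)
  idx <- simulate_chain_cpp(t(apply(tm$probs, 1, cumsum)),
                            cumsum(tm$init), as.integer(length))
  types <- tm$states[idx]
  motifs <- if (is.null(map)) NULL else {
    lapply(types, function(ty) map[[ty]] %||% character())
  }
  performance(types, motifs, bird_id = bird_id)
}

#' Render a performance as audio with ground-truth onsets
#'
#' Synthesizes each phrase as a train of constant-frequency tone bursts
#' (one per syllable, 5 ms cosine on/off ramps, frequencies in the
#' 0.5-3 kHz species band) at the template onsets plus Gaussian timing
#' jitter, with 2-3 s silent pauses between phrases. Optionally adds
#' white noise at a given SNR. Ground-truth onset times are returned for
#' scoring the acoustic front end.
#'
#' @param templates named list of [phrase_template()] covering every
#'   phrase type in `perf`.
#' @param perf a [performance()].
#' @param jitter_sd onset jitter s.d. in seconds.
#' @param sample_rate sampling rate in Hz (>= 8000).
#' @param seed optional RNG seed.
#' @param snr_db signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param syllable_dur tone-burst duration in seconds.
#' @param gap_range range of inter-phrase pause durations in seconds.
#' @return list with `wave` (numeric vector in \[-1, 1\]), `sample_rate`,
#'   `onsets` (data.frame `phrase_index`, `onset_seconds`, global times)
#'   and `phrases` (data.frame `phrase_index`, `start`, `end`).
#' @export
render_audio <- function(templates, perf, jitter_sd = 0.005,
                         sample_rate = 44100, seed = NULL, snr_db = Inf,
                         syllable_dur = 0.08, gap_range = c(2, 3)) {
  stopifnot(inherits(perf, "performance"))
  if (length(templates) == 0) stop("no phrase templates supplied")
  if (sample_rate < 8000) stop("sample_rate must be >= 8000 Hz")
  if (is.null(names(templates))) {
    names(templates) <- vapply(templates, `[[`, character(1), "phrase_type")
  }
  missing_t <- setdiff(unique(perf$phrase_type), names(templates))
  if (length(missing_t) > 0) {
    stop("no template for phrase type(s): ", paste(missing_t, collapse = ", "))
  }
  local_seed(seed)
  n_phr <- length(perf$phrase_type)
  gaps <- stats::runif(n_phr, gap_range[1], gap_range[2])
  onset_rows <- vector("list", n_phr)
  phrase_start <- numeric(n_phr)
  t0 <- 0.5  # lead-in silence
  for (i in seq_len(n_phr)) {
    tpl <- templates[[perf$phrase_type[i]]]
    on <- tpl$onset_times +
      if (jitter_sd > 0) stats::rnorm(length(tpl$onset_times), 0, jitter_sd)
      else 0
    if (any(diff(on) <= 0)) {
      stop("jitter too large: syllable onsets reordered in phrase ", i)
    }
    phrase_start[i] <- t0
    onset_rows[[i]] <- data.frame(phrase_index = i,
                                  onset_seconds = t0 + on - on[1])
    t0 <- t0 + (max(on) - on[1]) + syllable_dur + gaps[i]
  }
  onsets <- do.call(rbind, onset_rows)
  total <- t0 + 0.5
  wave <- numeric(ceiling(total * sample_rate))
  burst_n <- round(syllable_dur * sample_rate)
  ramp_n <- max(2L, round(0.005 * sample_rate))
  env <- c(0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n)),
           rep(1, max(0L, burst_n - 2L * ramp_n)),
           0.5 * (1 + cos(pi * seq_len(ramp_n) / ramp_n)))
  tt <- seq_len(length(env)) / sample_rate
  for (i in seq_len(n_phr)) {
    tpl <- templates[[perf$phrase_type[i]]]
    ph_on <- onsets$onset_seconds[onsets$phrase_index == i]
    for (s in seq_along(ph_on)) {
      start <- round(ph_on[s] * sample_rate) + 1L
      idx <- start:(start + length(env) - 1L)
      wave[idx] <- wave[idx] + env * sin(2 * pi * tpl$freqs[s] * tt)
    }
  }
  wave <- wave / max(abs(wave))
  if (is.finite(snr_db)) {
    p_sig <- mean(wave^2)
    wave <- wave + stats::rnorm(length(wave),
                                sd = sqrt(p_sig / 10^(snr_db / 10)))
    wave <- wave / max(abs(wave))
  }
  list(wave = wave, sample_rate = sample_rate, onsets = onsets,
       phrases = data.frame(
         phrase_index = seq_len(n_phr), start = phrase_start,
         end = phrase_start +
           vapply(seq_len(n_phr), function(i) {
             diff(range(onsets$onset_seconds[onsets$phrase_index == i]))
           }, numeric(1)) + syllable_dur))
}

#' Simulate a complete synthetic bird
#'
#' End-to-end generator: inventory, transition matrix, label assignment
#' per `cfg$optimization`, and one performance. The true (permuted)
#' matrix and assignment are returned as ground truth.
#'
#' @param cfg a [generator_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @param bird_id identifier for the generated bird.
#' @return list with `performance`, `tm` (label-permuted matrix actually
#'   used), `base_tm`, `permutation`, `map`, `templates`, `cfg`.
#' @export
simulate_bird <- function(cfg, seed = NULL, bird_id = "synthetic") {
  stopifnot(inherits(cfg, "generator_config"))
  local_seed(seed %||% cfg$seed)
  seeds <- draw_subseeds(4)
  inv <- make_inventory(cfg, seed = seeds[1])
  base_tm <- make_transition_matrix(cfg, seed = seeds[2])
  perm <- assign_labels(base_tm, inv$map, mode = cfg$optimization,
                        n_candidates = cfg$n_candidates, seed = seeds[3])
  tm <- permute_labels(base_tm, perm)
  perf <- generate_performance(tm, inv$map, cfg$performance_length,
                               seed = seeds[4], bird_id = bird_id)
  list(performance = perf, tm = tm, base_tm = base_tm, permutation = perm,
       map = inv$map, templates = inv$templates, cfg = cfg)
}
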