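# Shared fixtures, built in code.

# Strictly periodic ABCD... performance with one motif "i" shared by A
# and B (the canonical regular-phrase / irregular-motif toy).
abcd_performance <- function(n_cycles = 3) {
  types <- rep(c("A", "B", "C", "D"), n_cycles)
  motifs <- lapply(types, function(ty) {
    if (ty %in% c("A", "B")) "i" else character()
  })
  performance(types, motifs, bird_id = "abcd")
}

# The printed 12-phrase irregular sequence with a motif shared by every
# A and B phrase (regular at the motif level, irregular at the phrase
# level).
irregular_performance <- function() {
  types <- strsplit("ACADBDADBCBD", "")[[1]]
  motifs <- lapply(types, function(ty) {
    if (ty %in% c("A", "B")) "i" else character()
  })
  performance(types, motifs, bird_id = "irregular")
}

# A random performance over a small alphabet, each type carrying a fixed
# motif set (consistent annotation).
random_performance <- function(n = 50, n_types = 4, seed = 1) {
  withr::local_seed(seed)
  types <- make_type_labels(n_types)
  map <- lapply(types, function(ty) {
    sample(as.character(1:6), sample(0:3, 1))
  })
  names(map) <- types
  seqv <- sample(types, n, replace = TRUE)
  performance(seqv, lapply(seqv, function(ty) map[[ty]]), bird_id = "rand")
}

make_type_labels <- function(n) LETTERS[seq_len(n)]

# All permutations of 1..n (n small), for brute-force enumeration.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Deterministic k-cycle transition matrix over labels.
cycle_matrix <- function(labels) {
  n <- length(labels)
  cm <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) cm[i, (i %% n) + 1L] <- 1L
  transition_matrix(cm, states = labels)
}

# Jittered point-process phrases from K planted onset templates.
planted_point_processes <- function(templates, n_each = 10,
                                    jitter_sd = 0.005, seed = 1) {
  withr::local_seed(seed)
  truth <- integer()
  pps <- list()
  for (k in seq_along(templates)) {
    for (r in seq_len(n_each)) {
      on <- sort(templates[[k]] + rnorm(length(templates[[k]]), 0, jitter_sd))
      pps[[length(pps) + 1L]] <- to_point_process(on - on[1])
      truth <- c(truth, k)
    }
  }
  ord <- sample(length(pps))
  list(phrases = pps[ord], truth = truth[ord])
}
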