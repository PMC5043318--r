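test_that("generator_config validates its stated world", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_types = 0), "n_types")
  expect_error(generator_config(sharing_degree = 5, n_types = 3),
               "sharing_degree")
  expect_error(generator_config(performance_length = 1), "performance_length")
  expect_error(generator_config(density = 0), "density")
  expect_error(generator_config(n_candidates = 0), "n_candidates")
})

test_that("make_inventory assigns motifs with the requested sharing", {
  # the toy repertoire A:{1,2}, B:{1,3,4}, C:{5} is representable
  cfg <- generator_config(n_types = 3, n_motifs = 5, sharing_degree = 1.2,
                          seed = 1)
  found <- FALSE
  for (seed in 1:200) {
    inv <- make_inventory(cfg, seed = seed)
    sizes <- sort(vapply(inv$map, length, integer(1)))
    shared <- table(unlist(inv$map))
    if (identical(unname(sizes), c(1L, 2L, 3L)) && any(shared >= 2)) {
      found <- TRUE
      break
    }
  }
  expect_true(found)

  # sharing_degree = 1: no motif shared across types
  inv1 <- make_inventory(generator_config(n_types = 4, n_motifs = 4,
                                          sharing_degree = 1, seed = 2))
  shared <- table(unlist(inv1$map))
  expect_true(all(shared == 1))

  # every motif assigned to >= 1 type; mean sharing near the target
  cfg3 <- generator_config(n_types = 20, n_motifs = 40, sharing_degree = 3,
                           seed = 3)
  inv3 <- make_inventory(cfg3)
  counts <- table(factor(unlist(inv3$map), levels = as.character(1:40)))
  expect_true(all(counts >= 1))
  expect_lt(abs(mean(counts) - 3), 0.75)

  # determinism and distinct onset patterns
  inv_a <- make_inventory(cfg3, seed = 9)
  inv_b <- make_inventory(cfg3, seed = 9)
  expect_identical(inv_a, inv_b)
  pats <- lapply(inv_a$templates, `[[`, "onset_times")
  expect_equal(anyDuplicated(pats), 0)
})

test_that("make_transition_matrix yields irreducible row-stochastic chains", {
  for (seed in 1:5) {
    cfg <- generator_config(n_types = 7, density = 0.3, seed = seed)
    tm <- make_transition_matrix(cfg)
    live <- rowSums(tm$probs) > 0
    expect_true(all(live))
    expect_equal(unname(rowSums(tm$probs)), rep(1, 7), tolerance = 1e-12)
    expect_lte(abs(sum(tm$probs > 0) - round(0.3 * 49)), 1)
    g <- igraph::graph_from_adjacency_matrix(tm$probs > 0)
    expect_true(igraph::is_connected(g, mode = "strong"))
  }
  # density = 1/n with cyclic structure: one entry of 1 per row
  tm_c <- make_transition_matrix(generator_config(n_types = 5,
                                                  density = 0.2, seed = 1))
  expect_equal(unname(rowSums(tm_c$probs > 0)), rep(1, 5))
  expect_true(all(tm_c$probs %in% c(0, 1)))
  expect_error(make_transition_matrix(generator_config(n_types = 3,
                                                       density = 0.05)),
               "density")
})

test_that("generate_performance follows the chain law", {
  # deterministic 4-cycle: the sequence is periodic up to rotation
  tm <- cycle_matrix(LETTERS[1:4])
  perf <- generate_performance(tm, NULL, length = 12, seed = 1)
  start <- match(perf$phrase_type[1], LETTERS[1:4])
  expected <- LETTERS[1:4][((start - 1 + 0:11) %% 4) + 1]
  expect_equal(perf$phrase_type, expected)

  # determinism
  tm2 <- make_transition_matrix(generator_config(n_types = 5, density = 0.5,
                                                 seed = 3))
  p1 <- generate_performance(tm2, NULL, 500, seed = 42)
  p2 <- generate_performance(tm2, NULL, 500, seed = 42)
  expect_identical(p1$phrase_type, p2$phrase_type)

  # law of large numbers: empirical bigram within TV 0.05 per row
  long <- generate_performance(tm2, NULL, 10000, seed = 7)
  emp <- estimate_bigram(long)
  perm <- match(tm2$states, emp$states)
  for (i in seq_along(tm2$states)) {
    tv <- 0.5 * sum(abs(emp$probs[perm[i], perm] - tm2$probs[i, ]))
    expect_lt(tv, 0.05)
  }

  # motif lists are filled from the map
  map <- motif_map(list(A = "1", B = "1", C = "2", D = character(),
                        E = character()))
  withmot <- generate_performance(tm2, map, 50, seed = 9)
  i <- match("A", withmot$phrase_type)
  expect_equal(withmot$motifs[[i]], "1")
})

test_that("dead-end states restart from the initial distribution", {
  cm <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  cm[1, 2] <- 1  # B is a dead end; C unreachable except by restart
  cm[3, 1] <- 1
  tm <- transition_matrix(cm, init = c(0.5, 0, 0.5))
  perf <- generate_performance(tm, NULL, 200, seed = 11)
  expect_length(perf, 200)
  # after every B the chain restarts on A or C
  after_b <- perf$phrase_type[which(perf$phrase_type == "B") + 1]
  after_b <- after_b[!is.na(after_b)]
  expect_true(all(after_b %in% c("A", "C")))
})

test_that("phrase-type marginals approach the stationary law with length", {
  tm <- make_transition_matrix(generator_config(n_types = 6, density = 0.4,
                                                seed = 13))
  stat <- stationary_distribution(tm)
  kl <- vapply(c(100, 1000, 10000), function(n) {
    perf <- generate_performance(tm, NULL, n, seed = 17)
    emp <- as.numeric(table(factor(perf$phrase_type, levels = tm$states))) / n
    keep <- emp > 0
    sum(emp[keep] * log(emp[keep] / stat[keep]))
  }, numeric(1))
  expect_true(all(diff(kl) < 0))
})

test_that("assign_labels optimizes the synthetic motif CV*", {
  cfg <- generator_config(n_types = 6, n_motifs = 6, sharing_degree = 2,
                          density = 0.5, seed = 1)
  # degenerate: one candidate is just a random permutation
  inv <- make_inventory(cfg, seed = 2)
  tm <- make_transition_matrix(cfg, seed = 2)
  p1 <- assign_labels(tm, inv$map, "optimized", n_candidates = 1, seed = 3)
  withr::local_seed(3)
  expect_equal(p1, sample(6))

  # optimized beats random in expectation (Monte-Carlo over 100 draws)
  diffs <- vapply(1:100, function(i) {
    inv_i <- make_inventory(cfg, seed = 1000 + i)
    tm_i <- make_transition_matrix(cfg, seed = 2000 + i)
    po <- assign_labels(tm_i, inv_i$map, "optimized", n_candidates = 25,
                        seed = 10 + i, eval_reps = 5)
    pr <- assign_labels(tm_i, inv_i$map, "random", seed = 20 + i)
    cv_synth(permute_labels(tm_i, po), inv_i$map, 150, 5,
             seed = 30 + i)$mean -
      cv_synth(permute_labels(tm_i, pr), inv_i$map, 150, 5,
               seed = 40 + i)$mean
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_lt(mean(diffs) + 3 * sd(diffs) / 10, 0)

  # no shared motifs: permutations are CV*-equivalent, any is acceptable
  inv1 <- make_inventory(generator_config(n_types = 4, n_motifs = 4,
                                          sharing_degree = 1, seed = 5))
  tm1 <- make_transition_matrix(generator_config(n_types = 4, density = 0.5,
                                                 seed = 5))
  expect_length(assign_labels(tm1, inv1$map, "optimized", n_candidates = 5,
                              seed = 6, eval_reps = 2), 4)
  expect_error(assign_labels(tm1, inv1$map, "optimized", n_candidates = 0),
               "n_candidates")
})

test_that("generator outputs are pure functions of (cfg, seed)", {
  cfg <- generator_config(n_types = 5, n_motifs = 6, sharing_degree = 2,
                          density = 0.4, performance_length = 80,
                          optimization = "optimized", n_candidates = 10,
                          seed = 77)
  b1 <- simulate_bird(cfg)
  b2 <- simulate_bird(cfg)
  expect_identical(b1$performance$phrase_type, b2$performance$phrase_type)
  expect_identical(b1$permutation, b2$permutation)
  expect_identical(b1$tm$probs, b2$tm$probs)
})

test_that("render_audio produces ground truth consistent with templates", {
  tpl <- phrase_template("A", c(0, 0.2, 0.4, 0.6, 0.8), "m",
                         freqs = c(800, 1000, 1200, 1400, 1600))
  perf <- performance("A", list("m"))
  aud <- render_audio(list(A = tpl), perf, jitter_sd = 0, sample_rate = 8000,
                      seed = 1)
  expect_equal(nrow(aud$onsets), 5)
  expect_equal(diff(aud$onsets$onset_seconds), diff(tpl$onset_times),
               tolerance = 1e-9)
  expect_lte(max(abs(aud$wave)), 1)

  # silence-only template list errors
  expect_error(render_audio(list(), perf), "no phrase templates")
  expect_error(phrase_template("A", numeric()), ">= 1 syllable")
  # reordering jitter errors (20 phrases of a 1 ms gap template under
  # 50 ms jitter: reordering is near-certain in at least one phrase)
  tight <- phrase_template("B", c(0, 0.001), freqs = 1000)
  expect_error(render_audio(list(B = tight), performance(rep("B", 20)),
                            jitter_sd = 0.05, sample_rate = 8000, seed = 4),
               "reordered")
  expect_error(render_audio(list(A = tpl), perf, sample_rate = 4000),
               "8000")
})

test_that("phrase_template enforces its invariants", {
  expect_error(phrase_template("A", c(0.1, 0.2)), "time 0")
  expect_error(phrase_template("A", c(0, 0.2, 0.2)), "strictly increasing")
  expect_error(phrase_template("A", c(0, 11)), "<= 10")
  expect_error(phrase_template("A", c(0, 1), freqs = 100), "band")
})
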