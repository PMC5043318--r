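test_that("paired_t_test follows the paired-difference convention", {
  # identical vectors: t = 0, p = 1
  x <- c(0.5, 0.6, 0.7)
  res <- paired_t_test(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # df = n - 1
  withr::local_seed(1)
  a <- runif(9); b <- a + rnorm(9, 0.1, 0.05)
  expect_equal(paired_t_test(a, b)$df, 8)

  # hand-computed 3-pair example: differences {1,2,3} -> t = 2*sqrt(3)
  res3 <- paired_t_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(res3$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(res3$mean_diff, 2)

  # agreement with the closed form on random fixtures
  for (i in 1:10) {
    obs <- runif(8); mod <- obs + rnorm(8, 0.05, 0.1)
    d <- mod - obs
    t_ref <- mean(d) / (sd(d) / sqrt(8))
    p_ref <- 2 * pt(abs(t_ref), 7, lower.tail = FALSE)
    res_i <- paired_t_test(obs, mod)
    expect_equal(res_i$t, t_ref, tolerance = 1e-9)
    expect_equal(res_i$p, p_ref, tolerance = 1e-9)
  }

  # constant non-zero differences are degenerate
  expect_error(paired_t_test(c(1, 2, 3), c(2, 3, 4)), "degenerate")
})

test_that("sign_test_below_median uses the one-sided binomial", {
  # all 17 ranks below the median: p = 0.5^17
  expect_equal(sign_test_below_median(rep(10, 17), 100), 0.5^17,
               tolerance = 1e-12)
  # half below, half above: p > 0.5
  expect_gt(sign_test_below_median(c(10, 20, 80, 90), 100), 0.5)
  # median ties are dropped
  expect_equal(sign_test_below_median(c(50, 10, 10), 100), 0.25)
  expect_error(sign_test_below_median(50, 100), "no usable ranks")
  expect_error(sign_test_below_median(numeric(), 100), "length")
})

test_that("pearson_correlation matches closed forms and references", {
  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_correlation(1:5, -(1:5))$r, -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2))$r, 0.5,
               tolerance = 1e-12)
  # reference agreement on random fixtures
  withr::local_seed(2)
  for (i in 1:10) {
    x <- rnorm(12); y <- 0.5 * x + rnorm(12)
    ref <- cor(x, y)
    res <- pearson_correlation(x, y)
    expect_equal(res$r, ref, tolerance = 1e-9)
    expect_equal(res$n, 12)
  }
  expect_error(pearson_correlation(1:2, 1:2), "3 pairs")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("run_pipeline produces a complete, deterministic cohort result", {
  cfg <- pipeline_config(
    cohorts = list(list(n_birds = 3, optimization = "optimized",
                        density = 0.5),
                   list(n_birds = 2, optimization = "random",
                        density = 0.2)),
    n_types = 5, n_motifs = 5, sharing_degree = 2,
    performance_length = 120, n_shuffles = 20, n_perm = 20, n_reps = 10,
    seed = 42)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res <- run_pipeline(cfg, out_dir = out1)
  expect_s3_class(res, "cohort_result")
  expect_equal(nrow(res$birds), 5)
  expect_true(all(c("cv_ph", "cv_m", "rank", "complexity") %in%
                    names(res$birds)))
  expect_true(file.exists(file.path(out1, "birds.csv")))
  expect_true(file.exists(file.path(out1, "summary.txt")))

  # rerun: byte-identical outputs
  run_pipeline(cfg, out_dir = out2)
  expect_identical(readLines(file.path(out1, "birds.csv")),
                   readLines(file.path(out2, "birds.csv")))
  expect_identical(readLines(file.path(out1, "summary.txt")),
                   readLines(file.path(out2, "summary.txt")))
})

test_that("pipeline config round-trips through a key = value file", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("n_types = 5", "n_motifs = 4", "sharing_degree = 2",
               "performance_length = 100", "n_shuffles = 10",
               "n_perm = 10", "n_reps = 5", "seed = 7",
               "cohort1.n_birds = 2", "cohort1.optimization = optimized",
               "cohort1.density = 0.5",
               "cohort2.n_birds = 1", "cohort2.optimization = random",
               "cohort2.density = 0.25"), path)
  cfg <- motifcv:::pipeline_config_from_file(path)
  expect_equal(cfg$n_types, 5)
  expect_length(cfg$cohorts, 2)
  expect_equal(cfg$cohorts[[1]]$optimization, "optimized")
  expect_equal(cfg$cohorts[[2]]$n_birds, 1)
})

test_that("the audio route recovers planted phrase types end to end", {
  # render a short multi-type recording, run the front end, cluster, and
  # compare with the planted types
  cfg <- generator_config(n_types = 3, n_motifs = 3, sharing_degree = 1,
                          density = 0.35, performance_length = 15,
                          seed = 3)
  inv <- make_inventory(cfg, seed = 3)
  tm <- make_transition_matrix(cfg, seed = 3)
  perf <- generate_performance(tm, inv$map, 15, seed = 3)
  aud <- render_audio(inv$templates, perf, jitter_sd = 0.003,
                      sample_rate = 16000, seed = 4)
  fe <- extract_point_processes(aud$wave, aud$sample_rate)
  expect_equal(length(fe$point_processes), 15)
  S <- build_similarity_matrix(fe$point_processes, sigma = 0.01)
  as <- cluster_phrases(S, seed = 5)
  expect_gte(adjusted_rand_index(as$labels, perf$phrase_type), 0.9)
})

test_that("plot_raster writes an image and preserves row multisets", {
  perf <- performance(c("A", "B", "A", "C", "B"),
                      bird_id = "raster")
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  ord_perf <- plot_raster(perf, file = f1)
  ord_type <- plot_raster(perf, sort = "type", file = f2)
  expect_true(file.exists(f1) && file.size(f1) > 0)
  expect_true(file.exists(f2) && file.size(f2) > 0)
  expect_equal(ord_perf, 1:5)
  # sorted raster groups rows by type and is a permutation of the rows
  expect_equal(sort(ord_type), 1:5)
  expect_equal(perf$phrase_type[ord_type], sort(perf$phrase_type))
  # identical row multisets
  expect_equal(sort(perf$phrase_type[ord_perf]),
               sort(perf$phrase_type[ord_type]))
})

test_that("the CLI subcommands run end to end on temp files", {
  tmp <- withr::local_tempdir()
  gen_cfg <- file.path(tmp, "gen.cfg")
  writeLines(c("n_types = 4", "n_motifs = 4", "sharing_degree = 2",
               "density = 0.5", "performance_length = 60",
               "optimization = random", "seed = 9"), gen_cfg)
  perf_csv <- file.path(tmp, "perf.csv")
  bird <- motifcv_cli(c("simulate", gen_cfg, perf_csv, "3"))
  expect_true(file.exists(perf_csv))
  perf <- read_performance(perf_csv)
  expect_length(perf, 60)

  reg_csv <- file.path(tmp, "reg.csv")
  motifcv_cli(c("regularity", perf_csv, reg_csv, "4"))
  reg <- read.csv(reg_csv)
  expect_equal(reg$level, c("phrase", "motif"))
  expect_true(all(reg$cv_star >= 0))

  expect_error(motifcv_cli(c("nope", "a", "b")), "usage")
  expect_error(motifcv_cli(character()), "usage")
})
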