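test_that("simulated score tables are reproducible from the seed", {
  cfg <- synthetic_config(seed = 101, sequence_length = 30)
  a <- simulate_scores(cfg)
  b <- simulate_scores(cfg)
  expect_identical(a, b)
  # and byte-identical after serialisation
  pa <- tempfile(); pb <- tempfile()
  write_score_table(a$scores, pa); write_score_table(b$scores, pb)
  expect_identical(readLines(pa), readLines(pb))
  c <- simulate_scores(synthetic_config(seed = 102, sequence_length = 30))
  expect_false(identical(a$scores$score, c$scores$score))
})

test_that("empirical call rates at n = 5700 sit within 3 binomial SE of targets", {
  cfg <- synthetic_config(seed = 202) # defaults: 300 aa, published targets
  sim <- simulate_scores(cfg)
  expect_equal(nrow(sim$scores), 4L * 5700L)
  rates <- tabulate_categories(sim$scores)
  for (t in rates$tool) {
    target <- cfg$target_rates[[t]]
    se <- sqrt(target * (1 - target) / 5700)
    emp <- rates$n_pathogenic[rates$tool == t] / 5700
    expect_lt(abs(emp - target), 3 * se)
  }
})

test_that("degenerate configurations produce degenerate call rates", {
  cfg <- synthetic_config(seed = 7, sequence_length = 20,
                          p_pathogenic = 0,
                          target_rates = c(humdiv = 0, sift = 0),
                          benign_call_rate = 0)
  sim <- simulate_scores(cfg)
  rates <- tabulate_categories(sim$scores)
  expect_true(all(rates$n_pathogenic == 0L))
  expect_true(all(sim$scores$score[sim$scores$tool == "humdiv"] < 0.450))
  expect_true(all(sim$scores$score[sim$scores$tool == "sift"] >= 0.05))
})

test_that("a per-position latent profile shapes where damage lands", {
  # contrasted halves: latent pathogenic everywhere in 1-20, nowhere in 21-40
  p_lat <- rep(c(1, 0), each = 20)
  cfg <- synthetic_config(seed = 71, sequence_length = 40,
                          p_pathogenic = p_lat,
                          target_rates = c(humdiv = 0.5),
                          benign_call_rate = 0)
  sim <- simulate_scores(cfg)
  lat <- sim$substitutions
  expect_true(all(lat$latent[lat$position <= 20] == "pathogenic"))
  expect_true(all(lat$latent[lat$position > 20] == "benign"))
  # calibration against the mean latent rate: a = 0.5/0.5 = 1, so every
  # latent-pathogenic substitution is called pathogenic and none other
  rates <- tabulate_categories(sim$scores)
  expect_equal(rates$n_pathogenic, sum(lat$latent == "pathogenic"))
  expect_error(synthetic_config(seed = 1, sequence_length = 10,
                                p_pathogenic = rep(0.5, 7)),
               "per-position")
})

test_that("unachievable target rates raise a calibration error", {
  # latent pathogenic rate 0.5 cannot reach a 95.8% call rate with no
  # benign-side call-through
  expect_error(synthetic_config(seed = 1, p_pathogenic = 0.5,
                                target_rates = c(humdiv = 0.958),
                                benign_call_rate = 0),
               "unachievable")
})

test_that("simulated references realise requested confusion counts exactly", {
  seq <- random_protein(120, seed = 23)
  set.seed(24)
  for (rep in 1:5) {
    sens <- sample(c(100, 97.0, 90.9, 87.9), 4, replace = TRUE)
    spec <- sample(c(100, 66.7, 33.3, 0), 4, replace = TRUE)
    perf <- Map(c, sens, spec)
    names(perf) <- c("humdiv", "humvar", "provean", "sift")
    sim <- simulate_reference(seq, tool_performance = perf,
                              overlap = "random", seed = 300 + rep)
    for (t in names(perf)) {
      want <- derive_confusion(33, 3, perf[[t]][1], perf[[t]][2])
      calls <- sim$calls[sim$calls$tool == t, ]
      got <- confusion_counts(calls, sim$reference)
      expect_identical(unclass(got), unclass(want))
    }
  }
})

test_that("maximally overlapping panel errors give the consensus the shared confusion", {
  seq <- random_protein(200, seed = 25)
  perf <- list(humdiv = c(100, 66.7), humvar = c(100, 66.7),
               provean = c(100, 66.7))
  sim <- simulate_reference(seq, tool_performance = perf,
                            overlap = "maximal", seed = 5)
  sw <- sweep_combinations(sim$calls, sim$reference,
                           tools = c("humdiv", "humvar", "provean"))
  triple <- sw[sw$combination == "humdiv+humvar+provean", ]
  m <- round_metrics(performance_metrics(
    confusion(triple$tp, triple$tn, triple$fp, triple$fn)))
  expect_equal(c(triple$tp, triple$tn, triple$fp, triple$fn),
               c(33L, 2L, 1L, 0L))
  expect_equal(m$accuracy, 97.2)
  expect_equal(m$mcc, 0.804)
})

test_that("all-perfect tools make every sweep row perfect", {
  seq <- random_protein(100, seed = 26)
  perf <- list(humdiv = c(100, 100), humvar = c(100, 100),
               provean = c(100, 100), sift = c(100, 100))
  sim <- simulate_reference(seq, tool_performance = perf, seed = 8)
  sw <- sweep_combinations(sim$calls, sim$reference)
  expect_true(all(sw$mcc == 1))
  expect_true(all(sw$accuracy == 100))
})

test_that("disjoint overlap errors out when the error budget exceeds capacity", {
  seq <- random_protein(60, seed = 27)
  perf <- list(humdiv = c(100, 0), humvar = c(100, 0)) # 3 FP each, 3 benign
  expect_error(simulate_reference(seq, tool_performance = perf,
                                  overlap = "disjoint", seed = 9),
               "infeasible")
})
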