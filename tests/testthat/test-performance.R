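test_that("confusion counting matches degenerate and brute-force cases", {
  seq <- random_protein(100, seed = 21)
  ref <- toy_reference(seq, n_path = 33, n_ben = 3)

  all_path <- data.frame(position = ref$position, wt = ref$wt, mut = ref$mut,
                         call = "pathogenic")
  cc <- confusion_counts(all_path, ref)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 33L, tn = 0L, fp = 3L, fn = 0L))

  perfect <- all_path
  perfect$call <- ifelse(ref$label == "pathogenic", "pathogenic", "benign")
  cc2 <- confusion_counts(perfect, ref)
  expect_equal(unclass(cc2)[c("tp", "tn", "fp", "fn")],
               list(tp = 33L, tn = 3L, fp = 0L, fn = 0L))

  # random predictor vs independent recount
  set.seed(4)
  rand <- all_path
  rand$call <- sample(c("pathogenic", "benign"), nrow(ref), replace = TRUE)
  cc3 <- confusion_counts(rand, ref)
  expect_equal(cc3$tp, sum(ref$label == "pathogenic" & rand$call == "pathogenic"))
  expect_equal(cc3$fn, sum(ref$label == "pathogenic" & rand$call == "benign"))
  expect_equal(cc3$tn, sum(ref$label == "benign" & rand$call == "benign"))
  expect_equal(cc3$fp, sum(ref$label == "benign" & rand$call == "pathogenic"))
  expect_equal(cc3$tp + cc3$tn + cc3$fp + cc3$fn, nrow(ref))

  expect_error(confusion_counts(all_path[-1, ], ref), "no prediction")
})

test_that("metrics reproduce the reported benchmark values", {
  best <- round_metrics(performance_metrics(confusion(33, 2, 1, 0)))
  expect_equal(best$accuracy, 97.2)
  expect_equal(best$sensitivity, 100)
  expect_equal(best$specificity, 66.7)
  expect_equal(best$mcc, 0.804)

  expect_equal(round_metrics(performance_metrics(confusion(32, 0, 3, 1)))$mcc,
               -0.051)
  expect_equal(performance_metrics(confusion(75, 75, 25, 25))$mcc, 0.5)
  expect_equal(round_metrics(performance_metrics(confusion(33, 1, 2, 0)))$mcc,
               0.561)
})

test_that("undefined MCC stays NA and renders as a dash, never 0", {
  m <- performance_metrics(confusion(33, 0, 3, 0)) # tn+fn marginal is zero
  expect_true(is.na(m$mcc))
  expect_equal(format_mcc(m$mcc), "―")
  m2 <- performance_metrics(confusion(33, 0, 0, 3))
  expect_true(is.na(m2$mcc))
  # sensitivity/specificity undefined when their denominators vanish
  expect_true(is.na(performance_metrics(confusion(0, 3, 0, 0))$sensitivity))
  expect_true(is.na(performance_metrics(confusion(33, 0, 0, 0))$specificity))
  expect_error(performance_metrics(confusion(0, 0, 0, 0)), "empty")
})

test_that("MCC obeys class-swap symmetry and attains its bounds", {
  set.seed(10)
  for (i in 1:50) {
    cc <- as.list(rpois(4, 8)); names(cc) <- c("tp", "tn", "fp", "fn")
    m1 <- performance_metrics(do.call(confusion, cc))$mcc
    m2 <- performance_metrics(confusion(cc$tn, cc$tp, cc$fn, cc$fp))$mcc
    expect_equal(m1, m2)
    if (!is.na(m1)) expect_true(m1 >= -1 && m1 <= 1)
  }
  expect_equal(performance_metrics(confusion(5, 7, 0, 0))$mcc, 1)
  expect_equal(performance_metrics(confusion(0, 0, 7, 5))$mcc, -1)
})

test_that("accuracy identity links the three percentage metrics", {
  set.seed(11)
  for (i in 1:25) {
    cc <- confusion(rpois(1, 20) + 1, rpois(1, 5) + 1, rpois(1, 3), rpois(1, 3))
    m <- performance_metrics(cc)
    total <- cc$tp + cc$tn + cc$fp + cc$fn
    expect_equal(m$accuracy,
                 (m$sensitivity * (cc$tp + cc$fn) +
                    m$specificity * (cc$tn + cc$fp)) / total)
  }
})

test_that("derive_confusion inverts printed marginals and round-trips", {
  expect_equal(unclass(derive_confusion(33, 3, 100, 66.7))[c("tp","tn","fp","fn")],
               list(tp = 33L, tn = 2L, fp = 1L, fn = 0L))
  expect_equal(unclass(derive_confusion(33, 3, 97.0, 0.0))[c("tp","tn","fp","fn")],
               list(tp = 32L, tn = 0L, fp = 3L, fn = 1L))
  expect_equal(unclass(derive_confusion(33, 3, 100, 100))[c("tp","tn","fp","fn")],
               list(tp = 33L, tn = 3L, fp = 0L, fn = 0L))
  expect_equal(unclass(derive_confusion(33, 3, 100, 33.3))[c("tp","tn","fp","fn")],
               list(tp = 33L, tn = 1L, fp = 2L, fn = 0L))

  # round trip on every published benchmark row
  marg <- benchmark_marginals()
  for (i in seq_len(nrow(marg))) {
    cc <- derive_confusion(33, 3, marg$sensitivity[i], marg$specificity[i])
    m <- round_metrics(performance_metrics(cc))
    expect_equal(m$sensitivity, round_half_up(marg$sensitivity[i], 1))
    expect_equal(m$specificity, round_half_up(marg$specificity[i], 1))
  }
  expect_error(derive_confusion(33, 3, 50, 110))
})

test_that("sweep emits one row per non-empty subset with per-subset oracle agreement", {
  seq <- random_protein(80, seed = 33)
  sim <- simulate_reference(seq, seed = 6, overlap = "random")
  sw <- sweep_combinations(sim$calls, sim$reference)
  expect_equal(nrow(sw), 15L)
  expect_equal(as.vector(table(sw$n_tools)), c(4L, 6L, 4L, 1L))
  expect_equal(sw$n_tools, sort(sw$n_tools)) # singles, pairs, triples, quad

  # oracle: recompute each subset's consensus and metrics independently
  ref_key <- paste0(sim$reference$wt, sim$reference$position, sim$reference$mut)
  for (i in seq_len(nrow(sw))) {
    subset <- strsplit(sw$combination[i], "+", fixed = TRUE)[[1]]
    calls_mat <- sapply(subset, function(t) {
      sub <- sim$calls[sim$calls$tool == t, ]
      sub$call[match(ref_key, paste0(sub$wt, sub$position, sub$mut))]
    })
    calls_mat <- matrix(calls_mat, nrow = nrow(sim$reference))
    need <- if (length(subset) <= 2) 1 else 2
    cons <- ifelse(rowSums(calls_mat == "pathogenic") >=
                     (if (length(subset) == 1) 1 else need),
                   "pathogenic", "benign")
    tp <- sum(cons == "pathogenic" & sim$reference$label == "pathogenic")
    fp <- sum(cons == "pathogenic" & sim$reference$label == "benign")
    expect_equal(sw$tp[i], tp)
    expect_equal(sw$fp[i], fp)
    m <- performance_metrics(confusion(sw$tp[i], sw$tn[i], sw$fp[i], sw$fn[i]))
    expect_equal(sw$mcc[i], m$mcc)
  }

  # perfect tools -> every row perfect
  perfect_calls <- do.call(rbind, lapply(c("humdiv","humvar","provean","sift"),
    function(t) data.frame(position = sim$reference$position,
                           wt = sim$reference$wt, mut = sim$reference$mut,
                           tool = t,
                           call = ifelse(sim$reference$label == "pathogenic",
                                         "pathogenic", "benign"))))
  sw2 <- sweep_combinations(perfect_calls, sim$reference)
  expect_true(all(sw2$mcc == 1))

  expect_error(sweep_combinations(sim$calls[sim$calls$tool != "sift", ],
                                  sim$reference, tools = c("humdiv", "sift")),
               "sift")
})

test_that("sweep cardinality is 2^k - 1 in general", {
  seq <- random_protein(60, seed = 44)
  sim <- simulate_reference(seq, seed = 2)
  for (k in 2:4) {
    tools <- c("humdiv", "humvar", "provean", "sift")[1:k]
    sw <- sweep_combinations(sim$calls[sim$calls$tool %in% tools, ],
                             sim$reference, tools = tools)
    expect_equal(nrow(sw), 2L^k - 1L)
  }
})
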