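test_that("protein-level metrics reproduce hand-computed set overlaps", {
  # perfect predictions
  perfect <- list(a = "1.1.1.1", b = c("2.7.7.7", "2.7.7.8"))
  m <- protein_level_metrics(perfect, perfect)
  expect_equal(m$precision, c(1, 1))
  expect_equal(m$f1, c(1, 1))
  # pred {a}, truth {a, b}: P = 1, R = 0.5, F1 = 2/3
  m2 <- protein_level_metrics(list(x = "1.1.1.1"),
                              list(x = c("1.1.1.1", "1.1.1.2")), mode = "macro")
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 0.5)
  expect_equal(m2$f1, 2 / 3, tolerance = 1e-12)
  # three-protein mixed case, enumerated by hand:
  # p1: pred {A}, truth {A}          -> P 1,   R 1,   F1 1
  # p2: pred {A, B}, truth {B, C}    -> P 1/2, R 1/2, F1 1/2
  # p3: pred {D}, truth {C}          -> P 0,   R 0,   F1 0
  pred <- list(p1 = "1.1.1.1", p2 = c("1.1.1.1", "1.1.1.2"), p3 = "4.4.4.4")
  truth <- list(p1 = "1.1.1.1", p2 = c("1.1.1.2", "3.3.3.3"), p3 = "3.3.3.3")
  m3 <- protein_level_metrics(pred, truth, mode = "both")
  macro <- m3[m3$mode == "macro", ]
  expect_equal(macro$precision, (1 + 0.5 + 0) / 3)
  expect_equal(macro$recall, (1 + 0.5 + 0) / 3)
  expect_equal(macro$f1, (1 + 0.5 + 0) / 3)
  # micro: TP = 2, predicted = 4, true = 4 -> P = R = 0.5, F1 harmonic
  micro <- m3[m3$mode == "micro", ]
  expect_equal(micro$precision, 0.5)
  expect_equal(micro$recall, 0.5)
  expect_equal(micro$f1, 0.5)
  expect_error(protein_level_metrics(list(a = "1.1.1.1"), list(b = "1.1.1.1")),
               "different protein ids")
})

test_that("macro and micro agree when every protein has one prediction and one truth", {
  withr::local_seed(53)
  ecs <- c("1.1.1.1", "1.1.1.2", "2.7.7.7")
  for (rep in 1:10) {
    ids <- paste0("p", 1:6)
    pred <- as.list(sample(ecs, 6, TRUE)); names(pred) <- ids
    truth <- as.list(sample(ecs, 6, TRUE)); names(truth) <- ids
    m <- protein_level_metrics(pred, truth, mode = "both")
    expect_equal(m$precision[1], m$precision[2], tolerance = 1e-12)
    expect_equal(m$f1[1], m$f1[2], tolerance = 1e-12)
  }
})

test_that("per-digit metrics score prefix sets and weaken with depth", {
  # one wrong serial digit: levels 1-3 perfect, level 4 zero
  m <- per_digit_metrics(list(x = "2.7.7.6"), list(x = "2.7.7.7"))
  expect_equal(m$f1, c(1, 1, 1, 0))
  # level 4 equals the protein-level metrics
  pred <- list(p1 = "1.1.1.1", p2 = c("1.1.1.1", "1.1.1.2"))
  truth <- list(p1 = "1.1.1.1", p2 = c("1.1.1.2", "3.3.3.3"))
  m4 <- per_digit_metrics(pred, truth, mode = "macro")
  pl <- protein_level_metrics(pred, truth, mode = "macro")
  expect_equal(m4$f1[m4$level == 4], pl$f1)
  # a multi-EC truth sharing its class counts once at level 1: predicting one
  # of the five serial variants scores level-1 F1 = 1, not 1/5
  prdm9 <- c("2.1.1.359", "2.1.1.354", "2.1.1.355", "2.1.1.362", "2.1.1.361")
  m5 <- per_digit_metrics(list(x = "2.1.1.359"), list(x = prdm9))
  expect_equal(m5$f1[m5$level == 1], 1)
  expect_equal(m5$recall[m5$level == 4], 1 / 5)
})

test_that("per-digit F1 never increases with level on random prediction sets", {
  withr::local_seed(59)
  universe <- as.vector(outer(1:2, outer(1:2, outer(1:2, 1:2, paste, sep = "."),
                                         paste, sep = "."), paste, sep = "."))
  for (rep in 1:25) {
    ids <- paste0("p", 1:5)
    pred <- lapply(ids, function(i) sample(universe, sample(1:3, 1)))
    truth <- lapply(ids, function(i) sample(universe, sample(1:3, 1)))
    names(pred) <- ids; names(truth) <- ids
    for (mode in c("macro", "micro")) {
      m <- per_digit_metrics(pred, truth, mode = mode)
      expect_true(all(diff(m$f1) <= 1e-12))
      expect_true(all(m$f1 >= 0 & m$f1 <= 1))
    }
  }
})

test_that("frequency binning assigns half-open-left bins and aggregates per-EC F1", {
  pred <- list(a = "1.1.1.1", b = "1.1.1.1", c = "2.7.7.7")
  truth <- list(a = "1.1.1.1", b = "1.1.1.2", c = "2.7.7.7")
  freqs <- c("1.1.1.1" = 5L, "1.1.1.2" = 6L, "2.7.7.7" = 21L)
  rep <- bin_by_frequency(pred, truth, freqs)
  # frequency 5 falls in (0, 5]; 6 in (5, 10]; 21 beyond the last edge
  expect_identical(rep$bin, c("(0, 5]", "(5, 10]", "(20, Inf]"))
  # 1.1.1.1: TP 1 (a), FP 1 (b) -> F1 = 2/3; 1.1.1.2: FN only -> 0; 2.7.7.7: 1
  expect_equal(rep$f1, c(2 / 3, 0, 1), tolerance = 1e-12)
  expect_identical(rep$n_ecs, c(1L, 1L, 1L))
  # a single shared bin gives one row
  one <- bin_by_frequency(pred, truth,
                          c("1.1.1.1" = 2L, "1.1.1.2" = 3L, "2.7.7.7" = 4L))
  expect_identical(nrow(one), 1L)
  expect_error(bin_by_frequency(pred, truth, freqs[1:2]), "no training frequency")
  expect_identical(
    bin_by_frequency(pred, truth, freqs[1:2], missing_freq = "zero")$bin[1],
    "(0, 5]")
})

test_that("recovery rates count matches exactly and summarize correctly", {
  expect_equal(recovery_rate("ACDEFGHIKL", "ACDEFGHIKL"), 1)
  expect_equal(recovery_rate("AAAAAAAAAAAA", "AAACAACAACAA"), 0.75)  # 3 of 12 differ
  expect_error(recovery_rate("ACD", "AC"), "length mismatch")
  expect_error(recovery_rate("", ""), "empty")
  expect_equal(recovery_summary(1.0)$sd, 0)
  s <- recovery_summary(c(0.5, 1.0))
  expect_equal(s$mean, 0.75)
  expect_equal(s$median, 0.75)
  # seeded random rates against a direct two-pass computation
  withr::local_seed(61)
  rates <- rbeta(200, 8, 2)
  s2 <- recovery_summary(rates)
  expect_equal(s2$mean, sum(rates) / length(rates), tolerance = 1e-12)
  expect_equal(s2$sd, sqrt(sum((rates - mean(rates))^2) / (length(rates) - 1)),
               tolerance = 1e-12)
  expect_equal(s2$min, min(rates))
  expect_equal(s2$max, max(rates))
  expect_equal(recovery_summary(rates, sd_type = "population")$sd,
               sqrt(mean((rates - mean(rates))^2)), tolerance = 1e-12)
})

test_that("the ablation runner validates variants and mirrors the full pipeline", {
  synth <- generate_dataset(synth_config(branching = c(2L, 1L, 1L, 2L),
                                         proteins_per_leaf = 6L,
                                         length_range = c(8L, 10L), n_feat = 8L,
                                         separation = 4, noise = 1,
                                         multi_label_prob = 0, seed = 31L))
  sp <- split_dataset(synth$dataset, 0.25, seed = 31L)
  cfg <- model_config(n_feat = 8L, n_heads = 2L)
  tc <- train_config(phase1_epochs = 2L, phase1_batch = 20L, phase2_epochs = 30L,
                     phase2_batch = 64L, triplets_per_epoch = 16L, seed = 2L)
  expect_error(run_ablation(sp$train, sp$test, cfg, tc, variants = "bogus"),
               "unknown ablation variant")
  res <- run_ablation(sp$train, sp$test, cfg, tc,
                      variants = c("full", "-H"), seeds = 2L)
  expect_identical(res$variant, c("full", "-H"))
  expect_true(all(res$f1 >= 0 & res$f1 <= 1))
  # the "full" row equals an ordinary train/predict/evaluate run
  fit <- train_model(sp$train, cfg, tc)
  preds <- predict_dataset(sp$test, fit)
  m <- per_digit_metrics(preds, sp$test$labels, mode = "macro")
  expect_equal(res$f1[res$variant == "full"], m$f1[m$level == 4], tolerance = 1e-12)
})

test_that("the -H variant's later levels ignore earlier-level perturbations", {
  sp <- build_label_spaces(list(c("1.1.1.1", "1.1.1.2"), "2.7.7.7"))
  cfg <- model_config(n_feat = 8L, n_heads = 2L, autoregressive = FALSE)
  par <- init_model_params(cfg, sp, seed = 9L)
  x <- rnorm(fused_width(cfg))
  a <- autoregressive_forward(x, par, sp, cfg, prev_override = list(c(1, 0), NULL, NULL))
  b <- autoregressive_forward(x, par, sp, cfg, prev_override = list(c(0, 1), NULL, NULL))
  expect_identical(a$level2, b$level2)
})
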