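# Meta-classifier: training, prediction, cross-validation, sweep, regression.

# Tiny separable fixture: unanimous predictor agreement with the label.
separable_fixture <- function(n = 20, seed = 3) {
  set.seed(seed)
  rec <- make_records(sprintf("S%03d", seq_len(n)), 1, "K", "R",
                      ddg = rep(c(1, -1), length.out = n))
  rec$label <- assign_label(rec$ddg)
  repo <- dplyr::bind_rows(lapply(element_predictors(), function(p) {
    tibble::tibble(
      pdb_id = rec$pdb_id, chain = rec$chain, position = rec$position,
      wild_aa = rec$wild_aa, mutant_aa = rec$mutant_aa, predictor = p,
      call = ifelse(rec$label == "POSITIVE", "INCREASE", "DECREASE"),
      ddg_pred = NA_real_)
  }))
  list(records = rec, predictions = repo)
}

test_that("a separable toy set is fit perfectly and predictions are pure", {
  fx <- separable_fixture()
  feats <- encode_features(fx$records, fx$predictions, mode = "ws_only")
  model <- train_classifier(feats, fx$records$label)
  out <- predict(model, feats)
  expect_equal(out$.pred, fx$records$label)
  # decision sign matches the label
  expect_true(all((out$.decision > 0) == (out$.pred == "POSITIVE")))
  # purity: identical features give identical predictions
  out2 <- predict(model, feats)
  expect_equal(out, out2)
  # errors: single class / NA features
  expect_error(train_classifier(feats, rep("POSITIVE", nrow(feats$x))),
               "both classes")
  bad <- feats; bad$x[1, 1] <- NA
  expect_error(train_classifier(bad, fx$records$label), "NA")
})

test_that("duplicating every training row leaves the decision rule unchanged", {
  fx <- separable_fixture(n = 30)
  feats <- encode_features(fx$records, fx$predictions, mode = "ws_only")
  m1 <- train_classifier(feats, fx$records$label)
  dup <- feats
  dup$x <- rbind(feats$x, feats$x)
  m2 <- train_classifier(dup, rep(fx$records$label, 2))
  # probe grid: all unanimous and near-unanimous call patterns
  sim <- shared_sim()
  probe <- encode_features(sim$records[1:50, ], sim$predictions, mode = "ws_only")
  expect_equal(predict(m1, probe)$.pred, predict(m2, probe)$.pred)
})

test_that("prediction refuses a mismatched feature layout", {
  fx <- separable_fixture()
  model <- train_classifier(
    encode_features(fx$records, fx$predictions, mode = "ws_only"),
    fx$records$label)
  sim <- shared_sim()
  wrong <- encode_features(sim$records[1:5, ], sim$predictions, mode = "seq_ws")
  expect_error(predict(model, wrong), "layout")
})

test_that("flipping unanimous predictor calls flips the meta-prediction", {
  sim <- shared_sim()
  feats <- encode_features(sim$records, sim$predictions, mode = "ws_only")
  model <- train_classifier(feats, sim$records$label)
  mk <- function(call) {
    r <- sim$records[1, ]
    repo <- null_repo(r)
    repo$call <- call
    repo$ddg_pred <- NA_real_
    encode_features(r, repo, mode = "ws_only")
  }
  up <- predict(model, mk("INCREASE"))$.pred
  down <- predict(model, mk("DECREASE"))$.pred
  expect_equal(up, "POSITIVE")
  expect_equal(down, "NEGATIVE")
})

test_that("stratified folds partition the data and are seed-deterministic", {
  sim <- shared_sim()
  rec <- sim$records[1:10, ]
  cv <- cross_validate(rec, sim$predictions, mode = "ws_only", k = 5, seed = 2)
  expect_equal(sort(table(cv$folds)), sort(rep(2L, 5)), ignore_attr = TRUE)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(nrow(cv$predictions), 10)
  expect_false(anyNA(cv$predictions$.pred))

  cv2 <- cross_validate(rec, sim$predictions, mode = "ws_only", k = 5, seed = 2)
  expect_equal(cv$folds, cv2$folds)
  expect_equal(cv$metrics, cv2$metrics)

  # pooled counts cover every record exactly once
  m <- cv$metrics
  expect_equal(m$tp + m$fp + m$fn + m$tn, 10)
})

test_that("near-perfect element predictors give near-perfect cross-validated accuracy", {
  sim0 <- simulate_dataset(n = 400, seed = 13)
  cur <- compile_mutations(sim0$records, sim0$sequences)
  profiles <- predictor_profiles("M3131")
  profiles$sensitivity <- 0.99
  profiles$specificity <- 0.99
  profiles$null_rate <- 0
  preds <- simulate_predictions(cur, profiles, seed = 14)
  cv <- cross_validate(cur, preds, mode = "ws_only", seed = 15)
  expect_gte(cv$metrics$acc, 0.95)
})

test_that("the meta-classifier beats the median element predictor on simulated ensembles", {
  sim <- shared_sim()
  cv <- cross_validate(sim$records, sim$predictions, mode = "seq_ws", seed = 7)
  per_pred <- vapply(element_predictors(), function(p) {
    pr <- sim$predictions[sim$predictions$predictor == p &
                            sim$predictions$call != "NULL_PRED", ]
    truth <- sim$records$label[match(test_key(pr), test_key(sim$records))]
    m <- stability_metrics(truth, ifelse(pr$call == "INCREASE",
                                         "POSITIVE", "NEGATIVE"))
    c(sn = m$sn, sp = m$sp)
  }, numeric(2))
  expect_gt(cv$metrics$sn, stats::median(per_pred["sn", ]))
  expect_gt(cv$metrics$sp, stats::median(per_pred["sp", ]) - 0.02)
})

test_that("superfamily-restricted CV equals plain CV on a single-category dataset", {
  sim <- shared_sim()
  rec <- sim$records
  rec$superfamily <- "enzyme"
  a <- superfamily_cv(rec, sim$predictions, "enzyme", mode = "ws_only", seed = 4)
  b <- cross_validate(rec, sim$predictions, mode = "ws_only", seed = 4)
  expect_equal(a$metrics, b$metrics)
  expect_error(superfamily_cv(rec, sim$predictions, "nucleic_acid_binding"),
               "no records")
})

test_that("per-category difficulty ordering is recovered by superfamily CV", {
  set.seed(71)
  sims <- lapply(1:3, function(i) simulate_dataset(n = 260, seed = 70 + i))
  recs <- lapply(seq_along(sims), function(i) {
    cur <- compile_mutations(sims[[i]]$records, sims[[i]]$sequences)
    cur$pdb_id <- paste0(cur$pdb_id, i)  # keep keys disjoint across categories
    cur$superfamily <- c("easy", "medium", "hard")[i]
    cur
  })
  # planted difficulty: progressively weaker predictor ensembles
  prof <- function(sn, sp) {
    p <- predictor_profiles("M3131"); p$sensitivity <- sn; p$specificity <- sp; p
  }
  profs <- list(prof(0.95, 0.95), prof(0.75, 0.8), prof(0.55, 0.6))
  preds <- dplyr::bind_rows(lapply(1:3, function(i) {
    simulate_predictions(recs[[i]], profs[[i]], seed = 80 + i)
  }))
  all_rec <- dplyr::bind_rows(recs)
  mccs <- vapply(c("easy", "medium", "hard"), function(cat) {
    superfamily_cv(all_rec, preds, cat, mode = "ws_only", seed = 5)$metrics$mcc
  }, numeric(1))
  expect_true(mccs[["easy"]] > mccs[["medium"]])
  expect_true(mccs[["medium"]] > mccs[["hard"]])
})

test_that("a one-size sweep reproduces a direct cross-validation with shared folds", {
  sim <- shared_sim()
  rec <- sim$records[1:120, ]
  sw <- window_size_sweep(rec, sim$sequences, sim$predictions, sizes = 11,
                          mode = "seq_ws", seed = 9)
  direct <- cross_validate(rec, sim$predictions, mode = "seq_ws", seed = 9)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$mcc, direct$metrics$mcc)
  expect_equal(attr(sw, "folds"), direct$folds)
  expect_type(attr(sw, "fold_hash"), "character")
  expect_equal(attr(sw, "best_size"), 11)
})

test_that("a planted local signal favors small windows over large ones", {
  set.seed(91)
  n <- 150
  L <- 31; center <- 16
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(standard_aa(), L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("PL%02X", seq_len(n) - 1)
  label <- sample(label_levels(), n, replace = TRUE)
  # informative residue right next to the mutated site
  substr(seqs, center + 1, center + 1) <- ifelse(label == "POSITIVE", "W", "G")
  rec <- tibble::tibble(
    pdb_id = names(seqs), chain = "A", position = center,
    wild_aa = substr(seqs, center, center),
    mutant_aa = "Y", ph = 7, temperature = 25,
    ddg = ifelse(label == "POSITIVE", 1, -1), label = label
  )
  rec$mutant_aa <- ifelse(rec$wild_aa == "Y", "F", "Y")
  sw <- window_size_sweep(rec, seqs, null_repo(rec), sizes = c(7, 19),
                          mode = "seq_ws", seed = 10)
  expect_gte(sw$mcc[sw$window_size == 7], sw$mcc[sw$window_size == 19] - 0.1)
})

test_that("the ddG regressor recovers a recoverable signal on held-out folds", {
  sim0 <- simulate_dataset(n = 500, seed = 23)
  cur <- compile_mutations(sim0$records, sim0$sequences)
  # plant: I-Mutant_PDB reports the exact truth, the others pure noise
  set.seed(24)
  preds <- dplyr::bind_rows(lapply(svr_input_predictors(), function(p) {
    v <- if (p == "I-Mutant_PDB") cur$ddg else rnorm(nrow(cur), 0, 1.5)
    v[v == 0] <- 1e-6
    tibble::tibble(
      pdb_id = cur$pdb_id, chain = cur$chain, position = cur$position,
      wild_aa = cur$wild_aa, mutant_aa = cur$mutant_aa, predictor = p,
      call = ifelse(v > 0, "INCREASE", "DECREASE"), ddg_pred = v)
  }))
  res <- ddg_regression_cv(cur, preds, include_sequence = FALSE, seed = 25)
  expect_gt(res$r[res$set == "cv"], 0.95)
  expect_gt(res$r[res$set == "training"], res$r[res$set == "cv"] - 0.05)
})

test_that("the sequence-only ddG model passes the I-Mutant_SEQ value through bit-exactly", {
  sim <- shared_sim()
  m <- train_ddg_regressor(sim$records, sim$predictions, input = "sequence")
  got <- predict(m, sim$records, sim$predictions)
  pr <- sim$predictions[sim$predictions$predictor == "I-Mutant_SEQ", ]
  want <- pr$ddg_pred[match(test_key(sim$records), test_key(pr))]
  expect_identical(got, want)
})

test_that("constant ddG targets refuse to fit", {
  sim <- shared_sim()
  rec <- sim$records[1:20, ]
  rec$ddg <- 1.5
  expect_error(train_ddg_regressor(rec, sim$predictions), "constant")
})

test_that("tidiers and plots summarise fitted objects", {
  fx <- separable_fixture()
  feats <- encode_features(fx$records, fx$predictions, mode = "ws_only")
  model <- train_classifier(feats, fx$records$label)
  td <- tidy(model)
  expect_true(all(c("gamma", "cost") %in% td$term))
  gl <- glance(model)
  expect_equal(gl$n_train, 20)

  sim <- shared_sim()
  cv <- cross_validate(sim$records[1:60, ], sim$predictions,
                       mode = "ws_only", seed = 6)
  expect_equal(nrow(tidy(cv)), 60)
  expect_true(all(c("acc", "mcc", "k") %in% names(glance(cv))))
  expect_s3_class(autoplot(cv), "ggplot")
  sw <- window_size_sweep(sim$records[1:60, ], sim$sequences, sim$predictions,
                          sizes = c(7, 9), mode = "seq_ws", seed = 6)
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(plot_ddg_correlation(rnorm(20), rnorm(20)), "ggplot")
})
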