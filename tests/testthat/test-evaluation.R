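test_that("fold plans partition the known pairs into near-equal folds, reproducibly", {
  inst <- rand_instance(61, m = 8L, n = 6L, density = 0.5)
  P <- as.integer(sum(inst$net$Y))
  plan <- make_folds(inst$net, n_folds = 5L, repeats = 3L, seed = 99L)
  for (r in 1:3) {
    asg <- plan$assignments[plan$assignments$repeat_ == r, ]
    expect_identical(sort(asg$pair), seq_len(P))  # partition, no repeats
    sizes <- table(asg$fold)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_identical(sum(sizes), P)
  }
  plan2 <- make_folds(inst$net, n_folds = 5L, repeats = 3L, seed = 99L)
  expect_identical(plan$assignments, plan2$assignments)
  plan3 <- make_folds(inst$net, n_folds = 5L, repeats = 3L, seed = 100L)
  expect_false(identical(plan$assignments, plan3$assignments))
  # 23 pairs over 10 folds -> sizes in {2, 3}
  Y <- matrix(0, 5, 5); Y[1:23] <- 1
  net23 <- dd_network(Y, paste0("d", 1:5), paste0("s", 1:5))
  sizes <- table(make_folds(net23, 10L, 1L, 7L)$assignments$fold)
  expect_setequal(as.integer(sizes), 2:3)
  expect_error(make_folds(net23, n_folds = 30L), class = "cmaf_value_error")
})

test_that("ROC curves have the confusion-table semantics and canonical endpoints", {
  roc <- roc_curve(c(0.9, 0.8), c(0.2, 0.1))
  expect_identical(roc$tpr[1L], 0)
  expect_identical(roc$fpr[1L], 0)
  expect_identical(utils::tail(roc$tpr, 1L), 1)
  expect_identical(utils::tail(roc$fpr, 1L), 1)
  expect_true(all(diff(roc$tpr) >= 0) && all(diff(roc$fpr) >= 0))
  expect_true(any(roc$tpr == 1 & roc$fpr == 0))  # passes through (0, 1)
  expect_identical(auc(roc), 1)
  expect_identical(roc$tp + roc$fn, rep(2, nrow(roc)))
  expect_identical(roc$fp + roc$tn, rep(2, nrow(roc)))

  expect_equal(auc_scores(0.5, 0.5), 0.5, tolerance = 1e-15)
  expect_equal(auc_scores(0.8, c(0.9, 0.2, 0.1)), 2 / 3, tolerance = 1e-15)
  expect_identical(auc_scores(c(0.1, 0.2), c(0.8, 0.9)), 0)
  expect_error(roc_curve(numeric(), 1), class = "cmaf_value_error")
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney count with half ties", {
  for (seed in 1:20) {
    sc <- withr::with_seed(seed, {
      list(pos = round(runif(sample(2:15, 1L)), 1L),
           neg = round(runif(sample(2:20, 1L)), 1L))
    })
    expect_equal(auc_scores(sc$pos, sc$neg), mw_auc(sc$pos, sc$neg),
                 tolerance = 1e-12)
    # reversing all scores maps AUC to its complement
    expect_equal(auc_scores(-sc$pos, -sc$neg),
                 1 - auc_scores(sc$pos, sc$neg), tolerance = 1e-12)
  }
  big <- withr::with_seed(5, list(pos = runif(2000), neg = runif(3000)))
  expect_lt(abs(auc_scores(big$pos, big$neg) - 0.5), 0.03)
})

test_that("cross-validation is deterministic and grades an informative instance above chance", {
  sim <- simulate_network(synthetic_spec(m = 20L, n = 14L, r = 3L,
                                         density = 0.15,
                                         similarity_noise = 0.05, seed = 21))
  plan <- make_folds(sim$net, n_folds = 3L, repeats = 1L, seed = 2L)
  prm <- list(nmf = nmf_params(k = 5L, max_iter = 300L))
  cv1 <- cross_validate(sim$net, sim$S_r, sim$S_d, plan, params = prm)
  cv2 <- cross_validate(sim$net, sim$S_r, sim$S_d, plan, params = prm)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(sort(unique(cv1$folds$method)),
                   sort(c("LPRIA", "NMFRIA", "NCPRIA", "CMAF")))
  expect_true(all(cv1$folds$auc >= 0 & cv1$folds$auc <= 1))
  expect_gt(cv1$summary$auc[cv1$summary$method == "CMAF"], 0.6)
  expect_identical(nrow(cv1$folds), 12L)
})

test_that("de-novo hold-out reports per-drug and pooled AUCs deterministically", {
  sim <- simulate_network(synthetic_spec(m = 16L, n = 12L, r = 3L,
                                         density = 0.18,
                                         similarity_noise = 0.05, seed = 33))
  drugs <- sim$net$drug_ids[rowSums(sim$net$Y) > 0][1:3]
  prm <- list(nmf = nmf_params(k = 5L, max_iter = 300L))
  dn1 <- de_novo_drug_test(sim$net, sim$S_r, sim$S_d, params = prm,
                           drugs = drugs)
  dn2 <- de_novo_drug_test(sim$net, sim$S_r, sim$S_d, params = prm,
                           drugs = drugs)
  expect_identical(dn1$per_drug, dn2$per_drug)
  expect_identical(dn1$pooled, dn2$pooled)
  expect_identical(nrow(dn1$per_drug), 12L)  # 3 drugs x 4 methods
  expect_true(all(dn1$pooled$auc >= 0 & dn1$pooled$auc <= 1))
  expect_error(de_novo_drug_test(sim$net, sim$S_r, sim$S_d,
                                 drugs = "NOT_A_DRUG"),
               class = "cmaf_identifier_error")
})

test_that("candidate ranking excludes known pairs, breaks ties by id, truncates", {
  Y <- rbind(c(1, 0, 0, 1), c(0, 0, 0, 0))
  net <- dd_network(Y, c("dr1", "dr2"), c("diA", "diB", "diC", "diD"))
  R <- rbind(c(0.9, 0.7, 0.7, 0.8), c(0.1, 0.2, 0.3, 0.4))
  sc <- score_matrix(R, net$drug_ids, net$disease_ids)
  top <- top_candidates(sc, net, "dr1", n = 10L)
  expect_identical(top$disease_id, c("diB", "diC"))  # tie at 0.7 -> id order
  expect_identical(top$rank, 1:2)
  expect_identical(nrow(top_candidates(sc, net, "dr2", n = 2L)), 2L)
  expect_identical(top_candidates(sc, net, "dr2", n = 2L)$disease_id,
                   c("diD", "diC"))
  # all diseases known -> empty candidate list
  net_full <- dd_network(rbind(c(1, 1, 1, 1), Y[2L, , drop = FALSE]),
                         net$drug_ids, net$disease_ids)
  expect_identical(nrow(top_candidates(sc, net_full, "dr1")), 0L)
  expect_error(top_candidates(sc, net, "nope"),
               class = "cmaf_identifier_error")
})
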