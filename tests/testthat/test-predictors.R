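# ---- label propagation ------------------------------------------------------

test_that("label propagation reproduces the worked 2x2 stationary point", {
  S <- rbind(c(0, 1), c(1, 0))
  y <- label_propagation(S, cbind(c(1, 0)), lp_params(alpha = 0.5))
  expect_equal(drop(y), c(2, 1) / 3, tolerance = 1e-12)
  expect_identical(drop(label_propagation(S, cbind(c(0, 0)))), c(0, 0))
  # all-ones labels are a fixed point of the diffusion
  expect_equal(drop(label_propagation(S, cbind(c(1, 1)))), c(1, 1),
               tolerance = 1e-12)
})

test_that("closed-form propagation agrees with the iterative diffusion", {
  for (seed in 1:50) {
    p <- withr::with_seed(seed, sample(3:12, 1L))
    S <- rand_lns_sim(p)
    Y0 <- withr::with_seed(seed + 1000L, matrix(runif(p * 4), p, 4))
    cf <- label_propagation(S, Y0, lp_params(alpha = 0.5))
    it <- label_propagation(S, Y0, lp_params(alpha = 0.5, mode = "iterative",
                                             tol = 1e-12))
    expect_equal(cf, it, tolerance = 1e-8)
    expect_true(all(cf >= -1e-12 & cf <= 1 + 1e-12))
  }
})

test_that("two-sided propagation matches a naive oracle and is transpose-equivariant", {
  inst <- rand_instance(5, m = 3L, n = 2L)
  comp <- wknkn_complete(inst$net, inst$S_r, inst$S_d)
  Sr <- rand_lns_sim(3L, comp$drug_ids)
  Sd <- rand_lns_sim(2L, comp$disease_ids)
  got <- lpria_predict(comp, Sr, Sd)
  want <- naive_lpria(comp$Y, Sr$S, Sd$S, alpha = 0.5, iters = 2000L)
  expect_equal(unname(got$R), unname(want), tolerance = 1e-10)

  # swapping drugs and diseases transposes the scores
  compT <- dd_network(t(comp$Y), comp$disease_ids, comp$drug_ids,
                      completed = TRUE)
  gotT <- lpria_predict(compT, Sd, Sr)
  expect_equal(gotT$R, t(got$R), tolerance = 1e-10)
  expect_identical(got$source, "LPRIA")
  expect_error(lp_params(alpha = 1), class = "cmaf_value_error")
})

# ---- graph-regularized NMF --------------------------------------------------

scalar_sim <- function(id) sim_matrix(matrix(1, dimnames = list(id, id)))

test_that("the scalar hand iteration converges to an exact reconstruction", {
  net <- dd_network(matrix(1, dimnames = list("dr1", "di1")), completed = TRUE)
  net$Y[] <- 2  # direct scalar case Y = 2 (outside the [0,1] contract on purpose)
  fit <- nmfria_fit(net, scalar_sim("dr1"), scalar_sim("di1"),
                    nmf_params(k = 1L, lambda_l = 0, lambda_r = 0,
                               lambda_d = 0),
                    W0 = matrix(1), H0 = matrix(1))
  # first sweep: w <- 1 * (2*1)/(1*1*1) = 2, then h <- 1 * (2*2)/(1*2*2) = 1
  expect_equal(unname(fit$W), matrix(2), tolerance = 1e-12)
  expect_equal(unname(fit$H), matrix(1), tolerance = 1e-12)
  expect_equal(unname(nmfria_predict(fit)$R), matrix(2), tolerance = 1e-12)
})

test_that("an exact factorization with no regularization is a fixed point", {
  set.seed(13)
  W0 <- matrix(runif(8, 0.2, 1), 4, 2)
  H0 <- matrix(runif(6, 0.2, 1), 3, 2)
  scale <- sqrt(max(W0 %*% t(H0)))
  W0 <- W0 / scale
  H0 <- H0 / scale
  Y <- W0 %*% t(H0)  # entries in (0, 1] by construction
  net <- dd_network(Y, paste0("dr", 1:4), paste0("di", 1:3), completed = TRUE)
  fit <- nmfria_fit(net, sim_matrix(rand_input_sim(4), net$drug_ids),
                    sim_matrix(rand_input_sim(3), net$disease_ids),
                    nmf_params(k = 2L, lambda_l = 0, lambda_r = 0,
                               lambda_d = 0),
                    W0 = W0, H0 = H0)
  expect_equal(unname(fit$W), W0, tolerance = 1e-10)
  expect_equal(unname(fit$H), H0, tolerance = 1e-10)
  expect_lt(utils::tail(fit$objective_trace, 1L), 1e-18)
})

test_that("the regularized objective is non-increasing along the updates", {
  for (seed in 1:10) {
    inst <- rand_instance(seed + 200L, m = 8L, n = 6L, density = 0.3)
    comp <- wknkn_complete(inst$net, inst$S_r, inst$S_d)
    Sr <- rand_lns_sim(8L, comp$drug_ids)
    Sd <- rand_lns_sim(6L, comp$disease_ids)
    prm <- nmf_params(k = 3L, max_iter = 300L, seed = seed)
    fit <- nmfria_fit(comp, Sr, Sd, prm)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    expect_true(all(fit$W >= 0) && all(fit$H >= 0))
    # trace endpoints agree with direct evaluation of the objective
    direct <- nmf_obj_direct(comp$Y, fit$W, fit$H,
                             (Sr$S + t(Sr$S)) / 2, (Sd$S + t(Sd$S)) / 2,
                             prm$lambda_l, prm$lambda_r, prm$lambda_d)
    expect_equal(utils::tail(fit$objective_trace, 1L), direct,
                 tolerance = 1e-10)
    expect_true(all(nmfria_predict(fit)$R >= 0))
  }
})

# ---- network consistency projection -----------------------------------------

test_that("consistency projection reproduces the worked examples", {
  one <- dd_network(matrix(1, dimnames = list("dr1", "di1")), completed = TRUE)
  got <- ncpria_predict(one, scalar_sim("dr1"), scalar_sim("di1"))
  expect_equal(unname(got$R), matrix(1), tolerance = 1e-12)

  # 2x2 instance evaluated by hand from the projection formulas
  Y <- rbind(c(1, 0), c(0, 0))
  net <- dd_network(Y, c("dr1", "dr2"), c("di1", "di2"))
  comp <- dd_network(Y, net$drug_ids, net$disease_ids, completed = TRUE)
  Sr <- sim_matrix(rbind(c(1, 0.5), c(0.5, 1)), net$drug_ids)
  Sd <- sim_matrix(rbind(c(1, 0.2), c(0.2, 1)), net$disease_ids)
  got <- ncpria_predict(comp, Sr, Sd)
  eps <- 1e-30
  ncp_r <- (1 * 1 + 0.5 * eps) / sqrt(1 + eps^2)
  ncp_d <- (1 * 1 + eps * 0.2) / sqrt(1 + eps^2)
  expect_equal(got$R[1L, 1L], (ncp_r + ncp_d) / (sqrt(1.25) + sqrt(1.04)),
               tolerance = 1e-12)
  expect_equal(got$R[1L, 1L], 0.93552, tolerance = 1e-4)
})

test_that("vectorized projection equals the literal per-pair loop and stays in [0,1]", {
  for (seed in 1:15) {
    inst <- rand_instance(seed + 400L, m = 6L, n = 5L)
    comp <- wknkn_complete(inst$net, inst$S_r, inst$S_d)
    Sr <- rand_lns_sim(6L, comp$drug_ids)
    Sd <- rand_lns_sim(5L, comp$disease_ids)
    got <- ncpria_predict(comp, Sr, Sd)
    expect_equal(unname(got$R), naive_ncp(comp$Y, Sr$S, Sd$S),
                 tolerance = 1e-12)
    expect_true(all(got$R >= 0 & got$R <= 1))
    # transpose equivariance
    compT <- dd_network(t(comp$Y), comp$disease_ids, comp$drug_ids,
                        completed = TRUE)
    # raw transposed graphs (rows no longer stochastic, which the projection
    # does not require), bypassing the learned-graph constructor checks
    SdT <- structure(list(S = t(Sd$S), ids = Sd$ids,
                          kind = "linear_neighborhood"), class = "sim_matrix")
    SrT <- structure(list(S = t(Sr$S), ids = Sr$ids,
                          kind = "linear_neighborhood"), class = "sim_matrix")
    gotT <- ncpria_predict(compT, SdT, SrT)
    expect_equal(gotT$R, t(got$R), tolerance = 1e-12)
  }
})
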