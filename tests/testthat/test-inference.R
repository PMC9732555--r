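test_that("two-node toy model reproduces hand Bayes", {
  net <- build_network(toy_parameter_set(0.2), distress = FALSE)
  post <- posterior_marginals(net, c(S1 = "present"), "D1")
  expect_equal(post$posteriors$D1[["present"]], 2 / 3, tolerance = 1e-12)
  post2 <- posterior_marginals(net, c(S1 = "absent"), "D1")
  expect_equal(post2$posteriors$D1[["present"]], 1 / 19, tolerance = 1e-12)
})

test_that("empty evidence recovers the selected prevalence column exactly", {
  for (pop in c("clinical", "general")) {
    net <- build_network(builtin_ps, population = pop)
    post <- predict(net)
    expect_equal(unname(post),
                 setNames(builtin_ps$prevalence[[pop]],
                          builtin_ps$prevalence$disorder)[names(post)],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("configuration weights factor as prior times likelihood", {
  net <- builtin_net
  allabs <- setNames(rep("absent", 5), names(net$priors))
  expect_equal(joint_configuration_probability(net, allabs),
               prod(1 - c(0.124, 0.193, 0.119, 0.133, 0.091)),
               tolerance = 1e-12)
  some <- allabs; some["NAR"] <- "present"
  expect_equal(joint_configuration_probability(net, some),
               prod(1 - c(0.124, 0.193, 0.133, 0.091)) * 0.119,
               tolerance = 1e-12)
  onlyB <- allabs; onlyB["BDL"] <- "present"
  expect_equal(
    joint_configuration_probability(net, onlyB, c("DSM-BDL-03" = "present")),
    joint_configuration_probability(net, onlyB) * 0.886,
    tolerance = 1e-12)
  # normalizing the 32 weights reproduces the posterior marginals
  cfg <- parent_configurations(
    setNames(rep(list(c("absent", "present")), 5), names(net$priors)))
  ev <- c("DSM-BDL-03" = "present", "LPF-Identity" = "high")
  w <- apply(cfg, 1, function(row)
    joint_configuration_probability(net, setNames(row, names(net$priors)), ev))
  post <- posterior_marginals(net, ev)
  expect_equal(sum(w[cfg$BDL == "present"]) / sum(w),
               post$posteriors$BDL[["present"]], tolerance = 1e-9)
})

test_that("distress posteriors follow the zero-leak noisy-OR", {
  ps <- toy_parameter_set()
  ps$symptoms <- rbind(ps$symptoms, data.frame(id = "S2", framework = "DSM"))
  ps$arcs <- rbind(ps$arcs, data.frame(symptom = "S2", disorder = "D1",
                                       direction = "present", q = 0.7))
  ps$baselines <- rbind(ps$baselines, transform(ps$baselines, symptom = "S2"))
  ps$distress <- data.frame(source = c("S1", "S2"), pd = c(0.5, 0.5),
                            group = "PD-DSM")
  net <- build_network(ps)
  both <- distress_profile(net, c(S1 = "present", S2 = "present"))
  expect_equal(both$posteriors[["PD-DSM"]][["present"]], 0.75,
               tolerance = 1e-12)
  none <- distress_profile(net, c(S1 = "absent", S2 = "absent"))
  expect_equal(none$posteriors[["PD-DSM"]][["present"]], 0, tolerance = 1e-12)
})

test_that("a lone observed group member pins its distress node", {
  net <- builtin_net
  grp <- names(net$distress_links[["PD-DSM-BDL"]]$pd)
  ev <- setNames(rep("absent", length(grp)), grp)
  ev["DSM-BDL-03"] <- "present"
  prof <- distress_profile(net, ev)
  expect_equal(prof$posteriors[["PD-DSM-BDL"]][["present"]], 0.764,
               tolerance = 1e-12)
})

test_that("exact inference matches full-joint enumeration on random models", {
  worst <- 0
  for (seed in 1:12) {
    ps <- generate_fixture(seed, n_disorders = 2, n_symptoms = 4,
                           graded_fraction = 0.5)
    net <- build_network(ps, population = if (seed %% 2) "clinical" else "general")
    expect_lte(nrow(net$nodes), 12)
    set.seed(seed + 1000)
    # random evidence over symptoms and occasionally a distress node
    sym <- net$nodes$id[net$nodes$role == "symptom"]
    obs <- sample(sym, 2)
    ev <- setNames(vapply(obs, function(s)
      sample(net$states[[s]], 1), character(1)), obs)
    if (seed %% 3 == 0) {
      dn <- net$nodes$id[net$nodes$role == "distress"][1]
      ev[dn] <- "present"
    }
    targets <- c(names(net$priors), setdiff(net$nodes$id, c(names(ev), names(net$priors))))
    post <- tryCatch(posterior_marginals(net, ev, targets),
                     error = function(e) e)
    if (inherits(post, "error")) {
      expect_match(conditionMessage(post), "zero-probability")
      next
    }
    for (t in targets) {
      expected <- oracle_posterior(net, ev, t)
      worst <- max(worst, max(abs(post$posteriors[[t]] - expected)))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("observing a noisy-OR symptom present never lowers a parent's posterior", {
  net <- builtin_net
  base <- predict(net)
  for (id in c("DSM-ATS-03", "DSM-BDL-08", "MD-Denial", "DSM-NAR-07",
               "MD-Passive-aggression")) {
    post <- predict(net, setNames("present", id))
    for (d in net$parents[[id]]) {
      expect_gte(post[[d]] + 1e-12, base[[d]])
    }
  }
})

test_that("inference errors are signalled, not propagated as NaN", {
  net <- builtin_net
  expect_error(posterior_marginals(net, c(ATS = "present"), "ATS"),
               "target is observed")
  expect_error(posterior_marginals(net, c("DSM-BDL-03" = "maybe")),
               "not a state")
  expect_error(posterior_marginals(net, c(Nonexistent = "present")),
               "unknown node")
  # contradictory: distress present while every group parent is inactive
  grp <- names(builtin_net$distress_links[["PD-MD"]]$pd)
  ev <- setNames(rep("absent", length(grp)), grp)
  ev["PD-MD"] <- "present"
  expect_error(posterior_marginals(net, ev), "zero-probability evidence")
})

test_that("entering all seven antisocial criteria raises ATS and BDL together", {
  net <- builtin_net
  ev <- setNames(rep("present", 7), sprintf("DSM-ATS-%02d", 1:7))
  post <- predict(net, ev)
  expect_gt(post[["ATS"]], net$priors[["ATS"]])
  expect_gt(post[["BDL"]], net$priors[["BDL"]])
  # every reported posterior is a normalized distribution
  full <- posterior_marginals(net, ev,
                              setdiff(net$nodes$id, names(ev)))
  for (p in full$posteriors) {
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("evidence files round through the published spellings", {
  net <- builtin_net
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node\tstate", "DSM - BDL 03\tpresent", "LPF Empathy\thigh"), f)
  ev <- read_evidence(net, f)
  expect_equal(ev, c("DSM-BDL-03" = "present", "LPF-Empathy" = "high"))
})
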