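test_that("link calibration reproduces single-cause marginals", {
  expect_equal(calibrate_link(0.643, 0.364), (0.643 - 0.364) / (1 - 0.364))
  expect_equal(calibrate_link(0.5, 0.5), 0)    # no effect beyond the leak
  expect_equal(calibrate_link(1, 0.3), 1)      # deterministic cause
  expect_error(calibrate_link(0.2, 0.3), "arc weaker than leak")
  expect_error(calibrate_link(1, 1), "leak = 1")
})

test_that("leaky noisy-OR reproduces elicited probabilities and the leak", {
  # DSM-ATS-01: single parent
  cpt1 <- leaky_or_cpt("DSM-ATS-01", c(ATS = 0.764), leak = 0.114)
  expect_equal(cpt_distribution(cpt1, c(ATS = "present"))[["present"]], 0.764)
  expect_equal(cpt_distribution(cpt1, c(ATS = "absent"))[["present"]], 0.114)
  # DSM-ATS-03: two parents, both present (frozen from the product formula)
  cpt2 <- leaky_or_cpt("DSM-ATS-03", c(ATS = 0.643, BDL = 0.750), leak = 0.364)
  expect_equal(
    cpt_distribution(cpt2, c(ATS = "present", BDL = "present"))[["present"]],
    0.859669811320755, tolerance = 1e-12)
  expect_equal(
    cpt_distribution(cpt2, c(ATS = "absent", BDL = "absent"))[["present"]],
    0.364)
})

test_that("leaky noisy-OR matches brute-force inhibitor enumeration", {
  qs <- list(c(A = 0.6), c(A = 0.55, B = 0.9), c(A = 0.5, B = 0.7, C = 0.95))
  for (q in qs) {
    leak <- 0.2
    cpt <- leaky_or_cpt("S", q, leak)
    cfg <- parent_configurations(cpt$parent_states)
    for (r in seq_len(nrow(cfg))) {
      on <- names(q)[cfg[r, ] == "present"]
      expected <- unname(oracle_noisy_or(calibrate_link(q[on], leak), leak))
      expect_equal(unname(cpt$prob[r, "present"]), expected, tolerance = 1e-12)
    }
  }
})

test_that("leaky noisy-MAX calibrates single causes and the leak", {
  q <- c(ATS = 0.85, BDL = 0.757, NAR = 0.65, HST = 0.70, PAG = 0.786)
  cpt <- leaky_max_cpt("LPF-Empathy", q, leak = 0.15)
  only <- function(d) {
    cfg <- setNames(rep("absent", 5), names(q)); cfg[d] <- "present"; cfg
  }
  for (d in names(q)) {
    expect_equal(cpt_distribution(cpt, only(d))[["high"]], q[[d]],
                 tolerance = 1e-12)
  }
  allabs <- setNames(rep("absent", 5), names(q))
  expect_equal(cpt_distribution(cpt, allabs)[["high"]], 0.15)
  # MAX of two-point effects reduces to a noisy-OR on the top state
  two <- setNames(c("present", "present", "absent", "absent", "absent"), names(q))
  expect_equal(cpt_distribution(cpt, two)[["high"]],
               0.957117647058824, tolerance = 1e-12)
  # default split leaves nothing on the middle state
  expect_true(all(cpt$prob[, "medium"] == 0))
})

test_that("noisy-MAX medium split keeps calibration and normalization", {
  q <- c(A = 0.8, B = 0.6)
  cpt <- leaky_max_cpt("S", q, leak = 0.1, medium_split = 0.3)
  expect_equal(rowSums(cpt$prob), rep(1, 4), tolerance = 1e-12)
  expect_equal(cpt_distribution(cpt, c(A = "present", B = "absent"))[["high"]],
               0.8, tolerance = 1e-12)
  expect_true(all(cpt$prob[, "medium"] >= 0))
  expect_error(
    symptom_cpt(local({
      ps <- toy_parameter_set()
      ps$symptoms$framework <- "LPF"
      ps$arcs$direction <- "low"
      ps$baselines$b_present <- NA_real_
      ps$baselines$b_high <- 0.1
      ps
    }), "S1"), "evidence model")
})

test_that("evidence-weighting model calibrates single causes exactly", {
  # FFM Anxiety: ATS pushes low, BDL pushes high, both tails at 0.443
  cpt <- evidence_cpt("FFM-Anxiety", q_up = c(BDL = 0.779),
                      q_down = c(ATS = 0.579), b_high = 0.443, b_low = 0.443,
                      parents = c("ATS", "BDL"))
  expect_equal(
    cpt_distribution(cpt, c(ATS = "absent", BDL = "present"))[["high"]],
    0.779, tolerance = 1e-12)
  expect_equal(
    cpt_distribution(cpt, c(ATS = "present", BDL = "absent"))[["low"]],
    0.579, tolerance = 1e-12)
  # all causes absent: the baseline distribution
  expect_equal(
    unname(cpt_distribution(cpt, c(ATS = "absent", BDL = "absent"))),
    c(0.443, 1 - 2 * 0.443, 0.443), tolerance = 1e-12)
  # opposing evidence weighed against each other (frozen from the log-odds
  # formula evaluated by hand)
  both <- cpt_distribution(cpt, c(ATS = "present", BDL = "present"))
  expect_equal(unname(both),
               c(0.236823503607552, 0.0922931020287874, 0.670883394363661),
               tolerance = 1e-9)
  expect_error(evidence_cpt("X", q_up = c(A = 0.3), b_high = 0.4, b_low = 0.4),
               "weaker than its target-tail baseline")
  expect_error(evidence_cpt("X", q_up = c(A = 0.9), b_high = 0.6, b_low = 0.5),
               "b_high \\+ b_low")
})

test_that("tail overflow is rescaled and the middle floor preserved", {
  cpt <- evidence_cpt("S", q_up = c(A = 0.9, B = 0.9, C = 0.9),
                      q_down = numeric(), b_high = 0.45, b_low = 0.45,
                      epsilon = 0.01)
  expect_equal(rowSums(cpt$prob), rep(1, 8), tolerance = 1e-12)
  expect_true(all(cpt$prob[, "medium"] >= 0.01 - 1e-12))
  probit <- evidence_cpt("S", q_up = c(A = 0.8), b_high = 0.3, b_low = 0.2,
                         link = "probit")
  expect_equal(cpt_distribution(probit, c(A = "present"))[["high"]], 0.8,
               tolerance = 1e-12)
})

test_that("every built-in CPT row is a distribution", {
  for (cpt in builtin_net$cpts) {
    expect_true(all(abs(rowSums(cpt$prob) - 1) <= 1e-12))
    expect_true(all(cpt$prob >= 0))
  }
})

test_that("single-cause calibration holds across the whole knowledge base", {
  ps <- builtin_ps
  worst <- 0
  for (i in seq_len(nrow(ps$arcs))) {
    a <- ps$arcs[i, ]
    cpt <- builtin_net$cpts[[a$symptom]]
    cfg <- setNames(rep("absent", length(cpt$parents)), cpt$parents)
    cfg[a$disorder] <- "present"
    state <- ifelse(a$direction == "present", "present", a$direction)
    worst <- max(worst, abs(cpt_distribution(cpt, cfg)[[state]] - a$q))
  }
  expect_lt(worst, 1e-12)
})

test_that("all-absent rows reproduce the baselines exactly", {
  ps <- builtin_ps
  for (id in ps$symptoms$id) {
    cpt <- builtin_net$cpts[[id]]
    cfg <- setNames(rep("absent", length(cpt$parents)), cpt$parents)
    d <- cpt_distribution(cpt, cfg)
    fw <- ps$symptoms$framework[match(id, ps$symptoms$id)]
    if (fw %in% c("DSM", "DEFENSE")) {
      expect_equal(d[["present"]], baseline_of(ps, id, "present"))
    } else if (fw == "LPF") {
      expect_equal(d[["high"]], baseline_of(ps, id, "high"))
    } else {
      expect_equal(d[["high"]], baseline_of(ps, id, "high"))
      expect_equal(d[["low"]], baseline_of(ps, id, "low"))
    }
  }
})

test_that("OR/MAX models are monotone in added present parents", {
  for (id in c("DSM-ATS-03", "DSM-BDL-08", "MD-Denial", "LPF-Identity")) {
    cpt <- builtin_net$cpts[[id]]
    top <- if ("present" %in% cpt$states) "present" else "high"
    cfg <- parent_configurations(cpt$parent_states)
    for (r in seq_len(nrow(cfg))) {
      for (p in cpt$parents) {
        if (cfg[r, p] != "absent") next
        up <- as.character(cfg[r, ]); names(up) <- cpt$parents
        up[p] <- "present"
        expect_gte(cpt_distribution(cpt, up)[[top]] + 1e-12,
                   cpt$prob[r, top])
      }
    }
  }
})

test_that("causal influence is independent of parent order", {
  q <- c(A = 0.7, B = 0.9, C = 0.55)
  leak <- 0.2
  perms <- list(c("A", "B", "C"), c("C", "A", "B"), c("B", "C", "A"))
  ref <- leaky_or_cpt("S", q, leak)
  cfg <- c(A = "present", B = "absent", C = "present")
  for (pm in perms) {
    alt <- leaky_or_cpt("S", q[pm], leak)
    expect_equal(cpt_distribution(alt, cfg), cpt_distribution(ref, cfg)[colnames(alt$prob)],
                 tolerance = 1e-12)
    altm <- leaky_max_cpt("S", q[pm], leak)
    refm <- leaky_max_cpt("S", q, leak)
    expect_equal(cpt_distribution(altm, cfg), cpt_distribution(refm, cfg),
                 tolerance = 1e-12)
    alte <- evidence_cpt("S", q_up = q[pm][c(1, 2)], q_down = q[pm][3],
                         b_high = 0.3, b_low = 0.25)
    refe <- evidence_cpt("S", q_up = q[pm][c(1, 2)], q_down = q[pm][3],
                         b_high = 0.3, b_low = 0.25,
                         parents = rev(union(names(q[pm][c(1, 2)]), names(q[pm][3]))))
    expect_equal(cpt_distribution(alte, cfg), cpt_distribution(refe, cfg),
                 tolerance = 1e-12)
  }
})
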