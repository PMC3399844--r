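test_that("a single replicate maps identically to map_sample", {
  pool <- toy_step_pool()
  ref <- quiet_reference(pool, normalize = FALSE, min_side_fraction = 0.1)
  x <- stats::setNames(pool[, 2], rownames(pool))
  pp <- build_population_profile(x, ref, name = "solo")
  direct <- map_sample(x, ref, id = "solo")
  expect_equal(pp$activity$percentile, direct$percentile)
  expect_equal(pp$activity$call, direct$call)
  expect_equal(pp$n_replicates, 1L)
})

test_that("replicates are averaged before mapping", {
  pool <- toy_step_pool()
  ref <- quiet_reference(pool, normalize = FALSE, min_side_fraction = 0.1)
  reps <- cbind(r1 = rep(4, 4), r2 = rep(6, 4))
  rownames(reps) <- rownames(pool)
  pp <- build_population_profile(reps, ref, name = "avg")
  expect_equal(unname(pp$mean_intensity), rep(5, 4))
  expected <- vapply(seq_len(4), function(i)
    percentile_of(ref$profiles[[i]], 5), numeric(1))
  expect_equal(pp$activity$percentile, expected)
})

test_that("averaging is invariant to replicate order", {
  set.seed(420)
  pool <- generate_reference_pool(60, 20, seed = 8)$matrix
  ref <- quiet_reference(pool)
  reps <- matrix(rnorm(20 * 5, 7, 1), 20, 5,
                 dimnames = list(rownames(pool), paste0("r", 1:5)))
  p1 <- build_population_profile(reps, ref, name = "x")
  p2 <- build_population_profile(reps[, sample(5)], ref, name = "x")
  expect_equal(p1$activity$percentile, p2$activity$percentile)
})

test_that("models refuse mixed reference versions and duplicate names", {
  pool <- toy_step_pool()
  ref1 <- quiet_reference(pool, normalize = FALSE, min_side_fraction = 0.1)
  ref2 <- quiet_reference(pool + 0.01, normalize = FALSE,
                          min_side_fraction = 0.1)
  x <- stats::setNames(pool[, 1], rownames(pool))
  a <- build_population_profile(x, ref1, name = "a")
  b <- build_population_profile(x, ref2, name = "b")
  expect_error(expression_model("m", list(a, b), ref1),
               "different reference versions")
  a2 <- build_population_profile(x, ref1, name = "a")
  expect_error(expression_model("m", list(a, a2), ref1), "duplicate")
})

test_that("pattern search equals a brute-force filter over the call table", {
  toy <- make_toy_model()
  calls <- t(toy$want)  # probesets x populations
  patterns <- list(
    c(popA = "high", popB = "low", popC = "any"),
    c(popA = "any", popB = "any", popC = "any"),
    c(popA = "high", popB = "high", popC = "high"),
    c(popB = "low"),
    c(popA = "low", popB = "low", popC = "low")
  )
  dr <- reference_dynamic_ranges(toy$ref, trimmed = TRUE)
  for (pat in patterns) {
    hits <- pattern_search(toy$model, pat)
    keep <- rep(TRUE, nrow(calls))
    for (p in names(pat)) {
      if (toupper(pat[[p]]) == "ANY") next
      keep <- keep & calls[, p] == toupper(pat[[p]])
    }
    expected_ids <- rownames(calls)[keep]
    expected_ids <- expected_ids[order(-dr[expected_ids], expected_ids)]
    expect_identical(hits$probeset_id, expected_ids)
  }
  # hits come out sorted by trimmed dynamic range, greatest first
  all_hits <- pattern_search(toy$model, c(popA = "any"))
  expect_false(is.unsorted(rev(all_hits$trimmed_dynamic_range)))
  expect_error(pattern_search(toy$model, c(nope = "high")), "unknown")
  expect_error(pattern_search(toy$model, c(popA = "maybe")), "high, low or any")
})

test_that("activity summary tallies match brute force and partition", {
  toy <- make_toy_model()
  s <- activity_summary(toy$model)
  calls <- t(toy$want)
  all_high <- apply(calls == "HIGH", 1, all)
  all_low <- apply(calls == "LOW", 1, all)
  expect_equal(sum(s$counts), ncol(toy$want))
  expect_equal(unname(s$counts["dynamic"]), sum(!all_high & !all_low))
  expect_equal(unname(s$counts["always_very_high"] + s$counts["always_high"]),
               sum(all_high))
  expect_equal(unname(s$counts["always_very_low"] + s$counts["always_low"]),
               sum(all_low))
  # every all-HIGH probeset is returned by the all-high pattern and vice versa
  hits <- pattern_search(toy$model,
                         c(popA = "high", popB = "high", popC = "high"))
  expect_setequal(hits$probeset_id,
                  names(s$category)[s$category %in%
                                      c("always_high", "always_very_high")])
})

test_that("population-specific sets equal brute-force set comparison", {
  toy <- make_toy_model()
  calls <- t(toy$want)
  for (p in rownames(toy$want)) {
    ps <- population_specific(toy$model, p)
    others <- setdiff(rownames(toy$want), p)
    exp_high <- rownames(calls)[calls[, p] == "HIGH" &
                                  apply(calls[, others, drop = FALSE] == "LOW",
                                        1, all)]
    exp_low <- rownames(calls)[calls[, p] == "LOW" &
                                 apply(calls[, others, drop = FALSE] == "HIGH",
                                       1, all)]
    expect_setequal(ps$high_only, exp_high)
    expect_setequal(ps$low_only, exp_low)
  }
  # tp_01 is HIGH everywhere: specific to no population
  for (p in rownames(toy$want)) {
    ps <- population_specific(toy$model, p)
    expect_false("tp_01" %in% c(ps$high_only, ps$low_only))
  }
  expect_error(population_specific(toy$model, "nope"), "unknown population")
})

test_that("gene probesets rank by trimmed dynamic range, ties by id", {
  set.seed(421)
  pool <- generate_reference_pool(80, 30, seed = 12)$matrix
  ref <- quiet_reference(pool)
  mapping <- data.frame(gene = "Il16",
                        probeset_id = ref$probeset_ids[c(3, 9, 17, 25)])
  ranked <- rank_probesets_for_gene(mapping, ref, gene = "Il16")
  dr <- reference_dynamic_ranges(ref, trimmed = TRUE)[ranked]
  expect_false(is.unsorted(rev(dr)))
  expect_setequal(ranked, mapping$probeset_id)
  # singleton
  expect_identical(rank_probesets_for_gene(ref$probeset_ids[5], ref),
                   ref$probeset_ids[5])
  # exact ties fall back to id order
  pool2 <- toy_step_pool(n_probesets = 2)
  pool2[2, ] <- pool2[1, ]
  rownames(pool2) <- c("b_ps", "a_ps")
  ref2 <- quiet_reference(pool2, normalize = FALSE, min_side_fraction = 0.1)
  expect_identical(rank_probesets_for_gene(c("b_ps", "a_ps"), ref2),
                   c("a_ps", "b_ps"))
  expect_error(rank_probesets_for_gene("missing_ps", ref), "absent")
})

test_that("planted population-specific probesets are recovered end to end", {
  set.seed(422)
  # reference pool: bimodal archetypes only, so every probeset can go
  # either way across cell types
  pool <- generate_reference_pool(400, 40, mix = c(bimodal = 1),
                                  seed = 77)$matrix
  ref <- quiet_reference(pool)
  pops <- paste0("pop", 1:8)
  states <- matrix("LOW", 40, 8, dimnames = list(rownames(pool), pops))
  planted <- c("ps_0005", "ps_0019", "ps_0033")
  b_lineage <- c("pop2", "pop5", "pop6")
  states[planted, b_lineage] <- "HIGH"
  # background probesets vary across populations too
  others <- setdiff(rownames(pool), planted)
  for (i in seq_along(others))
    states[others[i], sample(8, 4)] <- "HIGH"
  sim <- generate_model_samples(states, n_replicates = 3, sigma_noise = 0.5,
                                seed = 5)
  profiles <- lapply(pops, function(p) {
    reps <- sim$matrix[, sim$populations[[p]]]
    norm <- vapply(colnames(reps),
                   function(s) frozen_normalize(reps[, s], ref),
                   numeric(nrow(reps)))
    rownames(norm) <- rownames(reps)
    build_population_profile(norm, ref, name = p)
  })
  model <- expression_model("hematopoiesis-like", profiles, ref)
  pat <- stats::setNames(ifelse(pops %in% b_lineage, "high", "low"), pops)
  hits <- pattern_search(model, pat)
  expect_setequal(hits$probeset_id, planted)
})
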