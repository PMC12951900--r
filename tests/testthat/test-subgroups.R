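test_that("subgroup sides apply the boundary rules exactly and partition", {
  co <- quick_sim(n = 500, p = 0, seed = 71)
  # force one row onto every boundary
  co$sex[1] <- "male"; co$age[1] <- 59; co$smoking[1] <- "previous"
  co$sbp[1] <- 139; co$total_chol[1] <- 5.4; co$hdl[1] <- 1.4
  co$non_hdl <- co$total_chol - co$hdl
  m <- assign_subgroups(co)
  expect_true(m$male[1]);        expect_false(m$female[1])
  expect_true(m$middle_aged[1]); expect_false(m$elderly[1])   # 59 < 60
  expect_true(m$smoking[1]);     expect_false(m$non_smoking[1])
  expect_true(m$sbp_low[1]);     expect_false(m$sbp_high[1])  # 139 < 140
  expect_true(m$non_hdl_high[1])                              # 4.0 >= 4

  # the two sides of each variable partition the cohort; 32 cells sum to n
  for (v in c("sex", "age", "smoking", "sbp", "non_hdl")) {
    sides <- switch(v, sex = c("female", "male"),
                    age = c("middle_aged", "elderly"),
                    smoking = c("non_smoking", "smoking"),
                    sbp = c("sbp_low", "sbp_high"),
                    non_hdl = c("non_hdl_low", "non_hdl_high"))
    expect_equal(sum(m[[sides[1]]]) + sum(m[[sides[2]]]), nrow(co))
    expect_false(any(m[[sides[1]]] & m[[sides[2]]]))
  }
  expect_equal(sum(table(m$cell)), nrow(co))
  expect_length(levels(m$cell), 32)
  expect_length(composite_sweep(), 32)
  expect_length(subgroup_roster(), 10)
})

test_that("composite subgroups conjoin sides and reject duplicates", {
  co <- quick_sim(n = 300, p = 0, seed = 72)
  hr <- composite_subgroup(subgroup_spec("sex", "male"),
                           subgroup_spec("smoking", "smoking"),
                           subgroup_spec("sbp", "sbp_high"),
                           subgroup_spec("non_hdl", "non_hdl_high"))
  mm <- composite_membership(co, hr)
  direct <- co$sex == "male" & co$smoking %in% c("previous", "current") &
    co$sbp >= 140 & co$non_hdl >= 4
  expect_identical(mm, direct)
  expect_equal(hr$name, "male&smoking&sbp_high&non_hdl_high")
  expect_error(composite_subgroup(subgroup_spec("sex", "male"),
                                  subgroup_spec("sex", "female")),
               "one side per variable")
})

test_that("panel intersections do exact set arithmetic", {
  out <- panel_intersections(list(a = c("A", "B"), b = "C"))
  expect_equal(nrow(out$membership), 3)
  expect_true(all(out$membership$n_subgroups == 1))
  expect_equal(sum(out$cells$n_proteins), 3)
  expect_equal(unname(out$panel_sizes), c(2L, 1L))

  shared <- panel_intersections(
    setNames(replicate(10, c("G", "X"), simplify = FALSE), letters[1:10]))
  expect_equal(shared$membership$n_subgroups[shared$membership$protein == "G"], 10)

  # intersection cells partition the union
  set.seed(4)
  rand <- lapply(1:6, function(i) sample(LETTERS, sample(3:8, 1)))
  names(rand) <- paste0("s", 1:6)
  pi2 <- panel_intersections(rand)
  expect_equal(sum(pi2$cells$n_proteins), nrow(pi2$membership))
  expect_equal(unname(pi2$panel_sizes), unname(vapply(rand, length, 0L)))
})

test_that("the subgroup pipeline recovers subgroup-specific panels", {
  # proteins 1-2 act only in females, protein 3 everywhere
  effs <- list(planted_effect(1, 0.8, subgroup_spec("sex", "female")),
               planted_effect(2, 0.8, subgroup_spec("sex", "female")),
               planted_effect(3, 0.6))
  co <- quick_prepared(n = 16000, p = 20, seed = 73, effects = effs)
  sc <- fast_selection(seed = 11)
  fem <- run_subgroup_pipeline(co, subgroup_spec("sex", "female"), sc,
                               min_events = 10, nri_boot = 50)
  mal <- run_subgroup_pipeline(co, subgroup_spec("sex", "male"), sc,
                               min_events = 10, nri_boot = 50)
  expect_false(fem$skipped)
  expect_true(all(c("prot_0001", "prot_0002") %in% fem$panel$selected_panel))
  expect_false(any(c("prot_0001", "prot_0002") %in% mal$panel$selected_panel))
  # evaluation rows identical across the subgroup's model cards
  expect_identical(fem$cards$clinical$valid_ids, fem$cards$specific$valid_ids)
  # comparison grid has the contract columns
  expect_true(all(c("auc_clinical", "auc_specific", "delta_auc", "delong_p",
                    "nri") %in% names(fem$comparison)))
})

test_that("the event floor and degenerate subgroups are reported, not fatal", {
  co <- quick_prepared(n = 600, p = 4, seed = 74)
  out <- run_subgroup_pipeline(co, subgroup_spec("sex", "female"),
                               fast_selection(), min_events = 1000)
  expect_true(out$skipped)
  expect_match(out$reason, "derivation events")
})

test_that("specific-vs-general comparison is null for identical panels", {
  effs <- list(planted_effect(1, 0.7), planted_effect(2, 0.5))
  co <- quick_prepared(n = 8000, p = 10, seed = 75, effects = effs)
  sc <- fast_selection(seed = 13)
  overall <- run_subgroup_pipeline(co, NULL, sc, min_events = 10,
                                   nri_boot = 50)
  fem <- run_subgroup_pipeline(co, subgroup_spec("sex", "female"), sc,
                               min_events = 10, nri_boot = 50)
  cmp <- compare_specific_vs_general(co, fem, overall$cards$specific,
                                     nri_boot = 50, seed = 1)
  expect_equal(cmp$subgroup, "female")
  expect_lte(cmp$n_specific, length(fem$panel$candidates))

  # same proteins, same training rows => identical scores, degenerate test
  self <- compare_specific_vs_general(co, fem, fem$cards$specific,
                                      nri_boot = 50, seed = 1)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$delong_p, 1)
  expect_equal(self$nri, 0)
})

test_that("high-risk evaluation uses the observed incidence and pools panels", {
  effs <- list(planted_effect(1, 0.8), planted_effect(2, 0.6))
  co <- quick_prepared(n = 12000, p = 10, seed = 76, effects = effs)
  sc <- fast_selection(seed = 17)
  roster <- subgroup_roster()
  sgs <- list(
    male = run_subgroup_pipeline(co, roster$male, sc, min_events = 10,
                                 nri_boot = 50),
    smoking = run_subgroup_pipeline(co, roster$smoking, sc, min_events = 10,
                                    nri_boot = 50))
  hr <- composite_subgroup(subgroup_spec("sex", "male"),
                           subgroup_spec("smoking", "smoking"))
  out <- evaluate_high_risk(co, hr, sgs, general_panel = c("prot_0001"),
                            sel_config = sc, min_events = 5, nri_boot = 50)
  expect_equal(out$threshold, round(out$observed_incidence, 2))
  expect_setequal(names(out$nri), c("specific", "specific_clinical",
                                    "general", "general_clinical"))
  expect_true(all(out$panel %in% names(co)))
  expect_equal(nrow(out$table), 4)

  # empty composite errors with the conjunction named
  impossible <- composite_subgroup(subgroup_spec("age", "middle_aged"),
                                   name = "nobody")
  co2 <- co; co2$age <- 65
  expect_error(evaluate_high_risk(co2, impossible, sgs, "prot_0001", sc),
               "nobody")

  # the 32-cell sweep reports every cell, skipping the underpowered ones
  sweep <- sweep_composites(co, sgs, "prot_0001", sc, min_events = 20,
                            nri_boot = 25)
  expect_equal(nrow(sweep), 32)
  expect_equal(sum(sweep$n), nrow(co))
  expect_true(any(sweep$skipped))
  expect_true(all(is.finite(sweep$nri[!sweep$skipped])))
})
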